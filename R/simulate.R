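#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults emulate the
#' study design the package is built around: an F1 mapping family of 2
#' parents and 318 offspring genotyped on 13 linkage groups, and an
#' independent cohort of 19 males and 19 females segregating an XY
#' sex-determining locus. Map lengths default to the observed per-LG averages
#' (female ~137 cM, male ~106 cM), yielding the ~1.29 female:male length
#' ratio typical of strong heterochiasmy.
#'
#' @param n_lgs number of linkage groups (chromosomes).
#' @param markers_per_lg markers simulated per LG.
#' @param female_lg_length_cM,male_lg_length_cM per-LG map lengths in cM
#'   (recycled to `n_lgs`). cM are Haldane: crossovers per meiosis per LG are
#'   Poisson with mean `length/100`.
#' @param sex_system `"XY"`, `"ZW"` or `"none"` (no sex-determining locus).
#' @param sd_lg linkage group carrying the sex-determining locus; `NULL`
#'   picks `min(6, n_lgs)`.
#' @param sd_position_cM locus position on the sex-averaged scale; `NULL`
#'   places it at the LG centre (where recombination is male-suppressed).
#' @param sd_region_markers number of markers (nearest the locus on `sd_lg`)
#'   whose Y (or W) haplotype carries the alternate allele.
#' @param linkage_decay_per_cM probability per cM of distance from the locus
#'   that a Y/W-linked allele reverts to a population draw in a given male
#'   (or female, under ZW) — a linear stand-in for recombination history.
#' @param n_offspring F1 family size.
#' @param n_males,n_females sexed-cohort sizes.
#' @param n_sex_specific_tags RADtags present only in the heterogametic sex
#'   (surface as monomorphic markers; detected by the presence/absence
#'   criterion).
#' @param allele_freq_distribution list; `type = "uniform"` with `min`/`max`
#'   bounds on the population alternate-allele frequency, `type = "beta"`
#'   with `shape1`/`shape2`, or `type = "fixed"` with `value`.
#' @param genotype_error_rate per-call probability of a genotype flip.
#' @param missing_rate per-call probability of a missing call.
#' @param depth_model list `(mean, dispersion)` of a negative-binomial
#'   per-call read depth; depth 0 forces a missing call. `NULL` disables
#'   depth simulation.
#' @param male_central_weight probability mass of male crossover positions
#'   falling in the central 50% of an LG (default 0.1: male recombination is
#'   pushed to the ends, mimicking terminal chiasmata; female crossovers are
#'   uniform).
#' @param seed integer seed; every generator call is fully deterministic
#'   given the config.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_lgs = 13L, markers_per_lg = 50L,
                       female_lg_length_cM = 137, male_lg_length_cM = 106,
                       sex_system = c("XY", "ZW", "none"),
                       sd_lg = NULL, sd_position_cM = NULL,
                       sd_region_markers = 20L, linkage_decay_per_cM = 0.005,
                       n_offspring = 318L, n_males = 19L, n_females = 19L,
                       n_sex_specific_tags = 5L,
                       allele_freq_distribution = list(type = "uniform",
                                                       min = 0.1, max = 0.9),
                       genotype_error_rate = 0.01, missing_rate = 0.05,
                       depth_model = list(mean = 13, dispersion = 5),
                       male_central_weight = 0.1, seed = NULL) {
  sex_system <- match.arg(sex_system)
  if (is.null(sd_lg)) sd_lg <- min(6L, n_lgs)
  cfg <- list(
    n_lgs = as.integer(n_lgs), markers_per_lg = as.integer(markers_per_lg),
    female_lg_length_cM = rep_len(female_lg_length_cM, n_lgs),
    male_lg_length_cM = rep_len(male_lg_length_cM, n_lgs),
    sex_system = sex_system, sd_lg = as.integer(sd_lg),
    sd_position_cM = sd_position_cM,
    sd_region_markers = as.integer(sd_region_markers),
    linkage_decay_per_cM = linkage_decay_per_cM,
    n_offspring = as.integer(n_offspring),
    n_males = as.integer(n_males), n_females = as.integer(n_females),
    n_sex_specific_tags = as.integer(n_sex_specific_tags),
    allele_freq_distribution = allele_freq_distribution,
    genotype_error_rate = genotype_error_rate, missing_rate = missing_rate,
    depth_model = depth_model, male_central_weight = male_central_weight,
    seed = seed
  )
  stopifnot(cfg$n_lgs >= 1L, cfg$markers_per_lg >= 0L,
            all(cfg$female_lg_length_cM > 0), all(cfg$male_lg_length_cM > 0),
            cfg$genotype_error_rate >= 0, cfg$genotype_error_rate <= 1,
            cfg$missing_rate >= 0, cfg$missing_rate <= 1,
            cfg$linkage_decay_per_cM >= 0)
  if (sex_system != "none") {
    stopifnot(cfg$sd_lg >= 1L, cfg$sd_lg <= cfg$n_lgs)
  }
  class(cfg) <- "sim_config"
  cfg
}

draw_allele_freqs <- function(dist, n) {
  switch(dist$type,
    uniform = stats::runif(n, dist$min, dist$max),
    beta = stats::rbeta(n, dist$shape1, dist$shape2),
    fixed = rep(dist$value, n),
    stop("unknown allele_freq_distribution type: ", dist$type)
  )
}

# Marker map shared by both generators: relative positions u in [0,1] per LG,
# scaled to sex-specific and sex-averaged cM.
build_marker_map <- function(config) {
  n <- config$n_lgs * config$markers_per_lg
  if (n == 0L) {
    return(data.frame(marker_id = character(), radtag_id = character(),
                      snp_offset = integer(), lg = character(), u = numeric(),
                      pos_female_cM = numeric(), pos_male_cM = numeric(),
                      pos_cM = numeric()))
  }
  lg_idx <- rep(seq_len(config$n_lgs), each = config$markers_per_lg)
  u <- as.vector(apply(matrix(stats::runif(n), nrow = config$markers_per_lg),
                       2L, sort))
  id <- sprintf("m%05d", seq_len(n))
  data.frame(
    marker_id = id, radtag_id = sub("^m", "t", id), snp_offset = 0L,
    lg = paste0("LG", lg_idx), u = u,
    pos_female_cM = u * config$female_lg_length_cM[lg_idx],
    pos_male_cM = u * config$male_lg_length_cM[lg_idx],
    pos_cM = u * (config$female_lg_length_cM[lg_idx] +
                    config$male_lg_length_cM[lg_idx]) / 2
  )
}

#' Simulate phased parental haplotypes for an F1 cross
#'
#' Places markers on `n_lgs` linkage groups at uniform positions and draws
#' the four parental haplotypes (two per parent) from the configured
#' population allele frequencies under Hardy-Weinberg, so that all seven
#' Mendelian segregation types arise at their HWE-expected rates.
#'
#' @param config a [sim_config].
#' @return list with `map` (marker table with per-sex cM positions),
#'   `haplotypes` (4 x markers 0/1 matrix, rows mother1, mother2, father1,
#'   father2), and `allele_freq` (per-marker population alt frequency).
#' @export
simulate_parent_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  map <- build_marker_map(config)
  n <- nrow(map)
  p <- draw_allele_freqs(config$allele_freq_distribution, n)
  hap <- matrix(stats::rbinom(4L * n, 1L, rep(p, each = 4L)), nrow = 4L,
                dimnames = list(c("mother1", "mother2", "father1", "father2"),
                                map$marker_id))
  list(map = map, haplotypes = hap, allele_freq = p)
}

# One gamete from a pair of haplotypes on one LG. u: marker relative
# positions; L: sex-specific LG length in cM; crossover positions drawn
# uniformly (female) or with mass `central_weight` on the central 50%
# (male). Haldane model: Poisson(L/100) crossovers, no interference.
draw_gamete <- function(h1, h2, u, L, central = NULL) {
  k <- stats::rpois(1L, L / 100)
  start <- stats::rbinom(1L, 1L, 0.5)
  n_before <- integer(length(u))
  if (k > 0L) {
    if (is.null(central)) {
      xo <- stats::runif(k)
    } else {
      in_centre <- stats::rbinom(k, 1L, central) == 1L
      xo <- numeric(k)
      xo[in_centre] <- stats::runif(sum(in_centre), 0.25, 0.75)
      lo <- stats::runif(sum(!in_centre), 0, 0.5)
      xo[!in_centre] <- ifelse(lo < 0.25, lo, lo + 0.5)
    }
    n_before <- findInterval(u, sort(xo))
  }
  phase <- (start + n_before) %% 2L
  list(allele = ifelse(phase == 0L, h1, h2), n_crossovers = k)
}

#' Simulate an F1 mapping family
#'
#' Each offspring receives one maternal and one paternal gamete per linkage
#' group. Crossover counts are Poisson(`length_cM/100`) without interference;
#' female crossover positions are uniform along the LG while male positions
#' avoid the central 50% (heterochiasmy, see [sim_config]). Genotype errors
#' and missingness are injected last via [inject_errors]; negative-binomial
#' depth is attached when configured, with depth 0 forcing a missing call.
#'
#' @param config a [sim_config].
#' @return list with `matrix` (a [genotype_matrix]: mother, father and
#'   `n_offspring` offspring) and `truth` (marker map, true segregation type
#'   per marker, parental genotypes, injected error/missing coordinates, and
#'   crossover counts per meiosis).
#' @export
simulate_f1_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ph <- simulate_parent_haplotypes(config)  # seeds the RNG when configured
  map <- ph$map; hap <- ph$haplotypes
  n_mark <- nrow(map); n_off <- config$n_offspring

  mother_gt <- hap["mother1", ] + hap["mother2", ]
  father_gt <- hap["father1", ] + hap["father2", ]
  seg_truth <- true_segregation_type(mother_gt, father_gt)

  geno <- matrix(NA_integer_, n_mark, n_off)
  xo_counts <- matrix(0L, 2L * n_off, config$n_lgs)
  lgs <- unique(map$lg)
  for (li in seq_along(lgs)) {
    idx <- which(map$lg == lgs[li])
    u <- map$u[idx]
    Lf <- config$female_lg_length_cM[li]; Lm <- config$male_lg_length_cM[li]
    for (o in seq_len(n_off)) {
      gm <- draw_gamete(hap["mother1", idx], hap["mother2", idx], u, Lf)
      gp <- draw_gamete(hap["father1", idx], hap["father2", idx], u, Lm,
                        central = config$male_central_weight)
      geno[idx, o] <- gm$allele + gp$allele
      xo_counts[2L * o - 1L, li] <- gm$n_crossovers
      xo_counts[2L * o, li] <- gp$n_crossovers
    }
  }

  samples <- data.frame(
    sample_id = c("mother", "father", sprintf("off%03d", seq_len(n_off))),
    role = c("mother", "father", rep("offspring", n_off)),
    sex = "unknown", replicate_group = NA_character_
  )
  markers <- data.frame(
    marker_id = map$marker_id, radtag_id = map$radtag_id,
    snp_offset = map$snp_offset,
    ref_allele = "A", alt_allele = "C",
    lg = map$lg, pos_cM = map$pos_cM
  )
  full <- cbind(mother_gt, father_gt, geno)
  x <- genotype_matrix(markers, samples, full)
  inj <- inject_errors(x, config$genotype_error_rate, config$missing_rate)
  x <- attach_depth(inj$matrix, config$depth_model)

  list(matrix = x,
       truth = list(map = map, seg_type = seg_truth,
                    mother_gt = mother_gt, father_gt = father_gt,
                    errors = inj$errors, missing = inj$missing,
                    crossovers = xo_counts, allele_freq = ph$allele_freq))
}

# Segregation-type name from true parental genotype codes (0/1/2).
true_segregation_type <- function(mother_gt, father_gt) {
  key <- paste(pmin(mother_gt, father_gt), pmax(mother_gt, father_gt))
  unname(c("0 0" = "AAxAA", "2 2" = "BBxBB", "0 2" = "AAxBB",
           "0 1" = "AAxAB", "1 2" = "BBxAB", "1 1" = "ABxAB")[key])
}

#' Simulate a sexed adult cohort carrying a sex-determining locus
#'
#' Homogametic individuals (females under XY, males under ZW) receive two
#' haplotypes drawn from the population allele frequencies; heterogametic
#' individuals receive one such haplotype plus a Y (or W) haplotype. Within
#' the sex-determining region (the `sd_region_markers` markers nearest the
#' locus on `sd_lg`), the population alternate-allele frequency is set to 0
#' — the alternate allele is Y/W-specific — and the Y/W haplotype carries the
#' alternate allele, except that in each individual each linked allele
#' independently reverts to a population draw with probability
#' `min(1, linkage_decay_per_cM * |distance to locus in cM|)`, producing the
#' imperfect sex linkage the detection criteria tolerate. `n_sex_specific_tags`
#' extra monomorphic markers are present only in the heterogametic sex.
#' Errors, missingness and depth are injected last.
#'
#' @param config a [sim_config] with `sex_system` `"XY"` or `"ZW"`; with
#'   `"none"` a null cohort (no sex-linked signal) is generated.
#' @return list with `matrix` (a [genotype_matrix] of `n_males + n_females`
#'   adults) and `truth` (true sexes, locus coordinates, sex-linked marker
#'   ids, sex-specific tag ids, injected error/missing coordinates).
#' @export
simulate_sexed_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  map <- build_marker_map(config)
  n_mark <- nrow(map)
  p <- draw_allele_freqs(config$allele_freq_distribution, n_mark)

  system <- config$sex_system
  sd_idx <- integer(0)
  sd_pos <- NA_real_
  if (system != "none" && n_mark > 0L) {
    on_lg <- which(map$lg == paste0("LG", config$sd_lg))
    sd_pos <- if (is.null(config$sd_position_cM)) {
      stats::median(map$pos_cM[on_lg])
    } else config$sd_position_cM
    dist <- abs(map$pos_cM[on_lg] - sd_pos)
    sd_idx <- on_lg[order(dist)][seq_len(min(config$sd_region_markers,
                                             length(on_lg)))]
    p[sd_idx] <- 0  # alternate allele exists only on the Y/W haplotype
  }

  n_m <- config$n_males; n_f <- config$n_females
  sexes <- c(rep("M", n_m), rep("F", n_f))
  het_sex <- if (system == "ZW") "F" else "M"
  n_tot <- n_m + n_f

  geno <- matrix(NA_integer_, max(n_mark, 0L), n_tot)
  for (s in seq_len(n_tot)) {
    h_pop1 <- stats::rbinom(n_mark, 1L, p)
    if (system != "none" && sexes[s] == het_sex) {
      h_sex <- stats::rbinom(n_mark, 1L, p)   # background draw
      if (length(sd_idx)) {
        d <- abs(map$pos_cM[sd_idx] - sd_pos)
        revert <- stats::runif(length(sd_idx)) <
          pmin(1, config$linkage_decay_per_cM * d)
        h_sex[sd_idx] <- ifelse(revert, h_sex[sd_idx], 1L)
      }
      geno[, s] <- h_pop1 + h_sex
    } else {
      h_pop2 <- stats::rbinom(n_mark, 1L, p)
      geno[, s] <- h_pop1 + h_pop2
    }
  }

  markers <- data.frame(
    marker_id = map$marker_id, radtag_id = map$radtag_id,
    snp_offset = map$snp_offset, ref_allele = "A", alt_allele = "C",
    lg = map$lg, pos_cM = map$pos_cM
  )
  tag_ids <- character(0)
  if (system != "none" && config$n_sex_specific_tags > 0L) {
    k <- config$n_sex_specific_tags
    tag_ids <- sprintf("sextag%02d", seq_len(k))
    extra <- data.frame(
      marker_id = tag_ids, radtag_id = tag_ids, snp_offset = 0L,
      ref_allele = "A", alt_allele = NA_character_,
      lg = paste0("LG", config$sd_lg),
      pos_cM = if (is.na(sd_pos)) 0 else sd_pos
    )
    markers <- rbind(markers, extra)
    tag_geno <- matrix(NA_integer_, k, n_tot)
    tag_geno[, sexes == het_sex] <- 0L
    geno <- rbind(geno, tag_geno)
  }

  samples <- data.frame(
    sample_id = sprintf("adult_%s%02d", sexes,
                        c(seq_len(n_m), seq_len(n_f))),
    role = "adult", sex = sexes, replicate_group = NA_character_
  )
  x <- genotype_matrix(markers, samples, geno)
  inj <- inject_errors(x, config$genotype_error_rate, config$missing_rate)
  x <- attach_depth(inj$matrix, config$depth_model)

  list(matrix = x,
       truth = list(map = map, true_sex = sexes, system = system,
                    sd_lg = if (system == "none") NA else paste0("LG", config$sd_lg),
                    sd_position_cM = sd_pos,
                    sd_marker_ids = map$marker_id[sd_idx],
                    sex_specific_tags = tag_ids,
                    allele_freq = p,
                    errors = inj$errors, missing = inj$missing))
}

#' Inject genotype errors and missingness
#'
#' Each called genotype is independently flipped to a uniformly chosen
#' different code with probability `genotype_error_rate` (monomorphic
#' markers are exempt — their only error mode is dropout), then set missing
#' with probability `missing_rate`. A cell hit by both is recorded as
#' missing only, so the reported error and missing coordinate sets are
#' disjoint. Depth, when present, is zeroed at newly missing cells.
#'
#' @param x a [genotype_matrix].
#' @param genotype_error_rate,missing_rate per-call probabilities in `[0,1]`.
#' @param seed optional seed for a self-contained deterministic call.
#' @return list with `matrix` and the coordinate data.frames `errors` and
#'   `missing` (`marker_id`, `sample_id`).
#' @export
inject_errors <- function(x, genotype_error_rate, missing_rate, seed = NULL) {
  stopifnot(genotype_error_rate >= 0, genotype_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- x$geno
  mono <- is.na(x$markers$alt_allele)
  called <- !is.na(g)
  flippable <- called & !mono
  flip <- flippable & (matrix(stats::runif(length(g)), nrow(g)) < genotype_error_rate)
  if (any(flip)) {
    # uniformly one of the two other codes
    shift <- matrix(sample(1:2, length(g), replace = TRUE), nrow(g))
    g[flip] <- (g[flip] + shift[flip]) %% 3L
  }
  miss <- called & (matrix(stats::runif(length(g)), nrow(g)) < missing_rate)
  g[miss] <- NA_integer_
  flip <- flip & !miss

  coords <- function(w) {
    ij <- which(w, arr.ind = TRUE)
    data.frame(marker_id = x$markers$marker_id[ij[, 1L]],
               sample_id = x$samples$sample_id[ij[, 2L]])
  }
  x$geno <- g
  if (!is.null(x$depth)) x$depth[miss] <- 0L
  list(matrix = x, errors = coords(flip), missing = coords(miss))
}

# Negative-binomial per-call depth; depth 0 forces a missing call and
# missing calls get depth 0, keeping the container invariant.
attach_depth <- function(x, depth_model) {
  if (is.null(depth_model)) return(x)
  g <- x$geno
  d <- matrix(stats::rnbinom(length(g), mu = depth_model$mean,
                             size = depth_model$dispersion), nrow(g))
  d[is.na(g)] <- 0L
  g[d == 0L] <- NA_integer_
  x$geno <- g
  x$depth <- d
  dimnames(x$depth) <- dimnames(x$geno)
  x
}
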