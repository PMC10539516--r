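#' Default thresholds for the five sex-linkage criteria
#'
#' Method 1: frequency of the X (or Z) allele above 0.95 in the homogametic
#' sex and within `[0.4, 0.6]` in the heterogametic sex. Method 2: every
#' called homogametic individual homozygous and at least 50% of the
#' heterogametic sex heterozygous. Method 3 (RADtag presence/absence): tag
#' absent in all homogametic individuals and present in at least 50% of the
#' heterogametic sex. Method 4: more than 75% of the heterogametic sex
#' heterozygous, more than 80% of the homogametic sex homozygous for the X
#' allele, fewer than 20% heterozygous and fewer than 10% homozygous for the
#' Y-linked allele. Method 5 relaxes the heterozygosity bound to 55% but
#' forbids any homogametic individual homozygous for the Y-linked allele.
#' Boundary semantics mirror the wording: "at least" inclusive, "more than"/
#' "higher than"/"fewer than" strict, "between 0.4 and 0.6" inclusive.
#'
#' @param min_sex_call_rate per-sex call-rate gate applied to the
#'   heterozygosity-based methods (1, 2, 4, 5); Method 3 is exempt.
#' @return named list of thresholds.
#' @export
sexlink_thresholds <- function(min_sex_call_rate = 0.6) {
  list(
    min_sex_call_rate = min_sex_call_rate,
    m1_homog_freq = 0.95, m1_het_lo = 0.4, m1_het_hi = 0.6,
    m2_het_min = 0.5,
    m3_present_min = 0.5,
    m4_het_min = 0.75, m4_homx_min = 0.8, m4_het_homog_max = 0.2,
    m4_homy_max = 0.1,
    m5_het_min = 0.55
  )
}

#' Per-sex genotype frequencies for every marker
#'
#' Frequencies are computed over called genotypes only. `pass_gate` marks
#' markers called in at least `min_sex_call_rate` of each sex — the filter
#' applied to the heterozygosity-based criteria.
#'
#' @param x a [genotype_matrix] of sexed adults (every sample sex M or F).
#' @param min_sex_call_rate per-sex call-rate gate (inclusive).
#' @return data.frame with per-sex call counts, genotype-class counts and
#'   frequencies, reference-allele frequencies, and `pass_gate`.
#' @export
compute_sex_genotype_freqs <- function(x, min_sex_call_rate = 0.6) {
  sexes <- x$samples$sex
  if (!all(sexes %in% c("M", "F"))) stop("every sample must be sexed M or F")
  if (!any(sexes == "M") || !any(sexes == "F")) {
    stop("both sexes must be present")
  }
  g <- x$geno
  out <- data.frame(marker_id = x$markers$marker_id)
  for (s in c("M", "F")) {
    gs <- g[, sexes == s, drop = FALSE]
    n <- ncol(gs)
    called <- rowSums(!is.na(gs))
    het <- rowSums(gs == 1L, na.rm = TRUE)
    href <- rowSums(gs == 0L, na.rm = TRUE)
    halt <- called - het - href
    out[[paste0("n_", s)]] <- n
    out[[paste0("n_called_", s)]] <- called
    out[[paste0("call_rate_", s)]] <- called / n
    out[[paste0("n_hom_ref_", s)]] <- href
    out[[paste0("n_het_", s)]] <- het
    out[[paste0("n_hom_alt_", s)]] <- halt
    out[[paste0("freq_hom_ref_", s)]] <- href / called
    out[[paste0("freq_het_", s)]] <- het / called
    out[[paste0("freq_hom_alt_", s)]] <- halt / called
    out[[paste0("ref_allele_freq_", s)]] <- (2 * href + het) / (2 * called)
  }
  out$pass_gate <- out$call_rate_M >= min_sex_call_rate &
    out$call_rate_F >= min_sex_call_rate
  out
}

# Core vectorised evaluation of the heterozygosity-based criteria
# (Methods 1, 2, 4, 5) on count matrices. Every argument is a markers x B
# matrix (B = 1 for an observed scan, B = n_perm for a permutation null) of
# genotype-class counts for the heterogametic (h) and homogametic (o) sex;
# n_h / n_o are the sex cohort sizes. Allele orientation: the X (or Z)
# allele is the major allele among called homogametic genotypes; an exact
# 0.5/0.5 tie is evaluated under both orientations (hit if either passes).
# All conditions are expressed as count comparisons (frequency f > t over n
# called becomes count > t * n), which keeps the hot permutation path free
# of divisions and NA handling. Returns a list of logical matrices.
sexlink_eval_counts <- function(cal_h, het_h, href_h, halt_h,
                                cal_o, het_o, href_o, halt_o,
                                n_h, n_o, th, methods = c(1L, 2L, 4L, 5L)) {
  gate <- cal_h > 0 & cal_o > 0 &
    (cal_h >= th$min_sex_call_rate * n_h) &
    (cal_o >= th$min_sex_call_rate * n_o)
  out <- list()
  if (any(c(4L, 5L) %in% methods)) {
    aref2_o <- 2 * href_o + het_o          # homogametic ref-allele count
    ref_major <- aref2_o > cal_o           # ref freq > 0.5
    tie <- aref2_o == cal_o
  }
  if (1L %in% methods) {
    # p_o > 0.95 already fixes the orientation: only one allele can exceed it
    aref2_o1 <- 2 * href_o + het_o
    aref2_h <- 2 * href_h + het_h
    hi_ref <- aref2_o1 > 2 * th$m1_homog_freq * cal_o
    hi_alt <- (2 * cal_o - aref2_o1) > 2 * th$m1_homog_freq * cal_o
    in_ref <- aref2_h >= 2 * th$m1_het_lo * cal_h &
      aref2_h <= 2 * th$m1_het_hi * cal_h
    in_alt <- (2 * cal_h - aref2_h) >= 2 * th$m1_het_lo * cal_h &
      (2 * cal_h - aref2_h) <= 2 * th$m1_het_hi * cal_h
    out$m1 <- gate & ((hi_ref & in_ref) | (hi_alt & in_alt))
  }
  if (2L %in% methods) {
    out$m2 <- gate & het_o == 0 & het_h >= th$m2_het_min * cal_h
  }
  if (4L %in% methods) {
    het_ok <- het_o < th$m4_het_homog_max * cal_o
    c4_ref <- href_o > th$m4_homx_min * cal_o & het_ok &
      halt_o < th$m4_homy_max * cal_o
    c4_alt <- halt_o > th$m4_homx_min * cal_o & het_ok &
      href_o < th$m4_homy_max * cal_o
    c4 <- (ref_major & c4_ref) | (!ref_major & !tie & c4_alt) |
      (tie & (c4_ref | c4_alt))
    out$m4 <- gate & het_h > th$m4_het_min * cal_h & c4
  }
  if (5L %in% methods) {
    het_ok <- het_o < th$m4_het_homog_max * cal_o
    c5_ref <- href_o > th$m4_homx_min * cal_o & het_ok & halt_o == 0
    c5_alt <- halt_o > th$m4_homx_min * cal_o & het_ok & href_o == 0
    c5 <- (ref_major & c5_ref) | (!ref_major & !tie & c5_alt) |
      (tie & (c5_ref | c5_alt))
    out$m5 <- gate & het_h > th$m5_het_min * cal_h & c5
  }
  out
}

# Count-matrix extraction for a freqs table, oriented by system.
freqs_to_counts <- function(freqs, system) {
  h <- if (system == "XY") "M" else "F"
  o <- if (system == "XY") "F" else "M"
  col <- function(pre, s) freqs[[paste0(pre, s)]]
  list(cal_h = col("n_called_", h), het_h = col("n_het_", h),
       href_h = col("n_hom_ref_", h), halt_h = col("n_hom_alt_", h),
       cal_o = col("n_called_", o), het_o = col("n_het_", o),
       href_o = col("n_hom_ref_", o), halt_o = col("n_hom_alt_", o),
       n_h = col("n_", h), n_o = col("n_", o))
}

sexlink_one_method <- function(freqs, system, method, thresholds) {
  ct <- freqs_to_counts(freqs, system)
  hits <- sexlink_eval_counts(ct$cal_h, ct$het_h, ct$href_h, ct$halt_h,
                              ct$cal_o, ct$het_o, ct$href_o, ct$halt_o,
                              ct$n_h, ct$n_o, thresholds, methods = method)
  out <- as.vector(hits[[paste0("m", method)]])
  names(out) <- freqs$marker_id
  out
}

#' Sex-linkage criteria 1, 2, 4 and 5
#'
#' Evaluate one genotype-frequency criterion per marker (see
#' [sexlink_thresholds] for the definitions) under an XY or ZW orientation.
#' Under XY the heterogametic sex is male; under ZW the expected genotype
#' proportions are inverted between the sexes. The X (or Z) allele at each
#' marker is the major allele among called homogametic-sex genotypes.
#'
#' @param freqs output of [compute_sex_genotype_freqs].
#' @param system `"XY"` or `"ZW"`.
#' @param thresholds see [sexlink_thresholds].
#' @return named logical vector over markers (FALSE for gated-out markers).
#' @export
sexlink_method1 <- function(freqs, system = c("XY", "ZW"),
                            thresholds = sexlink_thresholds()) {
  sexlink_one_method(freqs, match.arg(system), 1L, thresholds)
}

#' @rdname sexlink_method1
#' @export
sexlink_method2 <- function(freqs, system = c("XY", "ZW"),
                            thresholds = sexlink_thresholds()) {
  sexlink_one_method(freqs, match.arg(system), 2L, thresholds)
}

#' @rdname sexlink_method1
#' @export
sexlink_method4 <- function(freqs, system = c("XY", "ZW"),
                            thresholds = sexlink_thresholds()) {
  sexlink_one_method(freqs, match.arg(system), 4L, thresholds)
}

#' @rdname sexlink_method1
#' @export
sexlink_method5 <- function(freqs, system = c("XY", "ZW"),
                            thresholds = sexlink_thresholds()) {
  sexlink_one_method(freqs, match.arg(system), 5L, thresholds)
}

#' Sex-linkage criterion 3: RADtag presence/absence
#'
#' Flags RADtags absent in every homogametic individual and present in at
#' least 50% of heterogametic individuals (Y- or W-specific tags). Operates
#' at the tag level, including tags carrying only monomorphic markers, and
#' is exempt from the per-sex call-rate gate.
#'
#' @param tag_pres logical matrix RADtags x samples (see [tag_presence]).
#' @param sexes character vector of `"M"`/`"F"` per sample.
#' @param system `"XY"` or `"ZW"`.
#' @param thresholds see [sexlink_thresholds].
#' @return character vector of hit radtag ids.
#' @export
sexlink_method3 <- function(tag_pres, sexes, system = c("XY", "ZW"),
                            thresholds = sexlink_thresholds()) {
  system <- match.arg(system)
  het_sex <- if (system == "XY") "M" else "F"
  ph <- rowSums(tag_pres[, sexes == het_sex, drop = FALSE])
  po <- rowSums(tag_pres[, sexes != het_sex, drop = FALSE])
  n_h <- sum(sexes == het_sex)
  hit <- po == 0L & ph / n_h >= thresholds$m3_present_min
  rownames(tag_pres)[hit]
}

#' Scan a sexed cohort for sex-linked markers
#'
#' Evaluates all five criteria under both XY and ZW orientations and
#' aggregates per-marker calls. SNP-level criteria (1, 2, 4, 5) report
#' marker ids; the presence/absence criterion (3) reports RADtag ids.
#' `summary` counts hits per (method, system); `unique_markers` and
#' `unique_radtags` deduplicate across methods per system.
#'
#' @param x a [genotype_matrix] of sexed adults.
#' @param systems subset of `c("XY", "ZW")`.
#' @param methods subset of `1:5`.
#' @param thresholds see [sexlink_thresholds].
#' @return list of class `sexlink_scan` with elements `calls` (data.frame
#'   `id`, `id_type`, `system`, `method`), `freqs`, `summary`,
#'   `unique_markers`, `unique_radtags`.
#' @export
scan_sex_linkage <- function(x, systems = c("XY", "ZW"), methods = 1:5,
                             thresholds = sexlink_thresholds()) {
  systems <- match.arg(systems, several.ok = TRUE)
  stopifnot(all(methods %in% 1:5))
  freqs <- compute_sex_genotype_freqs(x, thresholds$min_sex_call_rate)
  tp <- tag_presence(x)
  sexes <- x$samples$sex

  calls <- list()
  for (system in systems) {
    for (m in methods) {
      if (m == 3L) {
        ids <- sexlink_method3(tp, sexes, system, thresholds)
        if (length(ids)) {
          calls[[length(calls) + 1L]] <- data.frame(
            id = ids, id_type = "radtag", system = system, method = 3L)
        }
      } else {
        hit <- sexlink_one_method(freqs, system, m, thresholds)
        if (any(hit)) {
          calls[[length(calls) + 1L]] <- data.frame(
            id = names(hit)[hit], id_type = "marker", system = system,
            method = m)
        }
      }
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(id = character(), id_type = character(),
               system = character(), method = integer())

  summary <- expand.grid(method = methods, system = systems,
                         stringsAsFactors = FALSE)
  summary$n_hits <- mapply(function(m, s) {
    sum(calls$method == m & calls$system == s)
  }, summary$method, summary$system)

  uniq <- function(s, type) {
    sub <- calls[calls$system == s, , drop = FALSE]
    if (type == "marker") {
      length(unique(sub$id[sub$id_type == "marker"]))
    } else {
      snp_tags <- x$markers$radtag_id[match(sub$id[sub$id_type == "marker"],
                                            x$markers$marker_id)]
      length(unique(c(snp_tags, sub$id[sub$id_type == "radtag"])))
    }
  }
  structure(
    list(calls = calls, freqs = freqs, summary = summary,
         unique_markers = vapply(stats::setNames(systems, systems), uniq,
                                 integer(1), type = "marker"),
         unique_radtags = vapply(stats::setNames(systems, systems), uniq,
                                 integer(1), type = "radtag")),
    class = "sexlink_scan"
  )
}

#' @export
print.sexlink_scan <- function(x, ...) {
  cat("sex-linkage scan\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  Method %d (%s): %d hit(s)\n", x$summary$method[i],
                x$summary$system[i], x$summary$n_hits[i]))
  }
  for (s in names(x$unique_markers)) {
    cat(sprintf("  %s: %d unique marker(s), %d unique RADtag(s)\n", s,
                x$unique_markers[[s]], x$unique_radtags[[s]]))
  }
  invisible(x)
}
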