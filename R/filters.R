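#' Filter markers by depth window, ploidy, call rate and MAF
#'
#' Applies the generic marker filters in a fixed order. Individual genotype
#' calls with depth outside `[depth_min, depth_max]` are first masked to
#' missing (so the depth window always precedes call-rate and MAF
#' evaluation); then markers are removed, each attributed to the first
#' criterion it fails: not bi-allelic/monomorphic, call rate, MAF.
#'
#' Threshold semantics follow the wording they implement: "at least" and
#' "minimum" thresholds are inclusive, "below"/"above" are strict, so a
#' marker at exactly `min_call_rate` or `min_maf` is retained and a call at
#' exactly `depth_min` or `depth_max` is kept.
#'
#' @param x a [genotype_matrix].
#' @param min_call_rate minimum fraction of samples with a call (inclusive).
#' @param min_maf minimum minor allele frequency over called genotypes
#'   (inclusive). MAF uses called genotypes only.
#' @param depth_min,depth_max per-call depth window; calls outside it are set
#'   missing before any marker-level evaluation. Use `depth_min = 0`,
#'   `depth_max = Inf` to disable. Ignored when the matrix has no depth.
#' @param biallelic_only drop markers that are neither bi-allelic nor
#'   monomorphic (the container admits only those, so this currently guards
#'   against future extensions; monomorphic handling is controlled below).
#' @param keep_monomorphic keep markers with no alternate allele and exempt
#'   them from the MAF filter (they may represent Y- or W-specific tags).
#'   When `FALSE`, monomorphic markers are removed as non-bi-allelic.
#' @return list with `matrix` (the filtered [genotype_matrix]) and `report`,
#'   a data.frame of removal counts per criterion (plus calls masked by
#'   depth).
#' @export
filter_markers <- function(x, min_call_rate = 0.6, min_maf = 0.02,
                           depth_min = 5L, depth_max = 50L,
                           biallelic_only = TRUE, keep_monomorphic = FALSE) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1, min_maf >= 0, min_maf <= 1,
            depth_min <= depth_max)
  n_masked <- 0L
  if (!is.null(x$depth)) {
    mask <- !is.na(x$geno) & (x$depth < depth_min | x$depth > depth_max)
    n_masked <- sum(mask)
    x$geno[mask] <- NA_integer_
    x$depth[mask] <- 0L
  }

  mono <- is.na(x$markers$alt_allele)
  keep <- rep(TRUE, nrow(x$geno))
  removed_by <- rep(NA_character_, nrow(x$geno))

  if (biallelic_only && !keep_monomorphic) {
    removed_by[mono] <- "not_biallelic"
    keep[mono] <- FALSE
  }

  cr <- rowMeans(!is.na(x$geno))
  bad_cr <- keep & cr < min_call_rate
  removed_by[bad_cr] <- "low_call_rate"
  keep[bad_cr] <- FALSE

  maf <- marker_maf(x)
  exempt <- keep_monomorphic & mono
  bad_maf <- keep & !exempt & (is.na(maf) | maf < min_maf)
  removed_by[bad_maf] <- "low_maf"
  keep[bad_maf] <- FALSE

  report <- data.frame(
    criterion = c("depth_masked_calls", "not_biallelic", "low_call_rate",
                  "low_maf", "retained"),
    n = c(n_masked,
          sum(removed_by == "not_biallelic", na.rm = TRUE),
          sum(removed_by == "low_call_rate", na.rm = TRUE),
          sum(removed_by == "low_maf", na.rm = TRUE),
          sum(keep))
  )
  if (!any(keep)) warning("all markers removed by filters")
  list(matrix = x[keep, ], report = report, removed_by = removed_by)
}

#' Drop samples with too much missing data
#'
#' Removes samples whose missing-call fraction strictly exceeds
#' `max_missing` ("more than" is strict: a sample at exactly the threshold
#' is retained). Parents are never auto-dropped; a warning names them
#' instead, since an F1 family is useless without its parents.
#'
#' @param x a [genotype_matrix].
#' @param max_missing maximum tolerated missing fraction (default 0.4).
#' @return the filtered [genotype_matrix].
#' @export
filter_samples <- function(x, max_missing = 0.4) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  miss <- sample_missing_rate(x)
  drop <- miss > max_missing
  is_parent <- x$samples$role %in% c("mother", "father")
  if (any(drop & is_parent)) {
    warning("parent sample(s) exceed the missing-data threshold but are kept: ",
            paste(x$samples$sample_id[drop & is_parent], collapse = ", "))
    drop[is_parent] <- FALSE
  }
  x[, !drop]
}

#' Keep one sample per technical-replicate group
#'
#' Within each `replicate_group`, keeps the sample with the least missing
#' data (i.e. removes the sample with the most missing data from each pair),
#' breaking ties by lexicographically smallest `sample_id`. Samples without
#' a replicate group pass through.
#'
#' @param x a [genotype_matrix].
#' @return the deduplicated [genotype_matrix].
#' @export
dedupe_replicates <- function(x) {
  grp <- x$samples$replicate_group
  miss <- sample_missing_rate(x)
  keep <- rep(TRUE, ncol(x$geno))
  for (g in unique(grp[!is.na(grp)])) {
    idx <- which(!is.na(grp) & grp == g)
    if (length(idx) < 2L) next
    ord <- order(miss[idx], x$samples$sample_id[idx])
    keep[idx[-ord[1L]]] <- FALSE
  }
  x[, keep]
}

#' Genotype mismatch rate between technical replicates, by depth
#'
#' For every replicate pair and every marker called in both members, a
#' mismatch is a genotype-code disagreement. Rates are binned by the minimum
#' of the two call depths and reported both over all comparisons and
#' restricted to comparisons where either call is heterozygous — the class
#' where low-depth allele dropout concentrates.
#'
#' @param x a [genotype_matrix] with depth and populated replicate groups.
#' @param depth_bins increasing integer break points; bins are
#'   `[b_i, b_{i+1})` with a final open bin.
#' @return data.frame with columns `depth_bin`, `genotype_class`
#'   (`"all"`/`"het"`), `n_comparisons`, `n_mismatch`, `rate`.
#' @export
replicate_mismatch_rate <- function(x, depth_bins = c(0L, 5L, 7L, 10L, 20L)) {
  if (is.null(x$depth)) stop("replicate_mismatch_rate requires depth")
  grp <- x$samples$replicate_group
  groups <- unique(grp[!is.na(grp)])
  groups <- groups[vapply(groups, function(g) sum(grp == g, na.rm = TRUE) >= 2L,
                          logical(1))]
  bin_labels <- c(paste0("[", utils::head(depth_bins, -1), ",",
                         utils::tail(depth_bins, -1), ")"),
                  paste0("[", utils::tail(depth_bins, 1), ",Inf)"))
  empty <- data.frame(depth_bin = character(), genotype_class = character(),
                      n_comparisons = integer(), n_mismatch = integer(),
                      rate = numeric())
  if (!length(groups)) {
    warning("no replicate pairs; empty mismatch table")
    return(empty)
  }
  rows <- list()
  for (g in groups) {
    idx <- which(!is.na(grp) & grp == g)
    prs <- utils::combn(idx, 2L)
    for (k in seq_len(ncol(prs))) {
      i <- prs[1L, k]; j <- prs[2L, k]
      both <- !is.na(x$geno[, i]) & !is.na(x$geno[, j])
      if (!any(both)) next
      mm <- x$geno[both, i] != x$geno[both, j]
      dmin <- pmin(x$depth[both, i], x$depth[both, j])
      het <- x$geno[both, i] == 1L | x$geno[both, j] == 1L
      rows[[length(rows) + 1L]] <- data.frame(dmin = dmin, mm = mm, het = het)
    }
  }
  if (!length(rows)) {
    warning("replicate pairs share no called markers; empty mismatch table")
    return(empty)
  }
  d <- do.call(rbind, rows)
  d$bin <- bin_labels[findInterval(d$dmin, depth_bins)]
  out <- lapply(c(all = FALSE, het = TRUE), function(het_only) {
    dd <- if (het_only) d[d$het, , drop = FALSE] else d
    if (!nrow(dd)) return(NULL)
    agg_n <- tapply(dd$mm, dd$bin, length)
    agg_m <- tapply(dd$mm, dd$bin, sum)
    data.frame(depth_bin = names(agg_n),
               n_comparisons = as.integer(agg_n),
               n_mismatch = as.integer(agg_m),
               rate = as.numeric(agg_m / agg_n))
  })
  res <- rbind(
    if (!is.null(out$all)) cbind(out$all[1], genotype_class = "all", out$all[-1]),
    if (!is.null(out$het)) cbind(out$het[1], genotype_class = "het", out$het[-1])
  )
  rownames(res) <- NULL
  res
}
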