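#' Relatedness/structure prefilter for association testing
#'
#' Association tests are confounded by fine-scale structure, so highly
#' related clusters are removed first. Pairwise relatedness is estimated as
#' the allele-sharing proportion over jointly called markers
#' (`1 - |g_i - g_j| / 2` averaged over markers; 1 for identical genotypes,
#' ~0.5-0.7 for unrelated individuals at intermediate allele frequencies).
#' Pairs above `relatedness_threshold` define edges of a graph whose
#' connected components are the related clusters; by default every member of
#' a cluster is flagged for removal (mirroring the conservative choice of
#' dropping all clustered individuals), or keep the least-missing member per
#' cluster with `prune = "keep_least_missing"`. A classical PCoA ordination
#' of `1 - relatedness` is returned for visual QC.
#'
#' @param x a [genotype_matrix].
#' @param relatedness_threshold edge threshold on allele sharing.
#' @param k_axes number of ordination axes to return.
#' @param prune `"all"` (flag whole clusters) or `"keep_least_missing"`.
#' @return list with `retained` (sample ids), `flagged` (sample ids),
#'   `relatedness` (symmetric matrix), `ordination` (samples x k_axes).
#' @export
prefilter_structure <- function(x, relatedness_threshold = 0.9, k_axes = 2L,
                                prune = c("all", "keep_least_missing")) {
  prune <- match.arg(prune)
  n <- ncol(x$geno)
  if (n < 2L) stop("need at least 2 samples")
  g <- x$geno
  rel <- matrix(1, n, n, dimnames = list(x$samples$sample_id,
                                         x$samples$sample_id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- !is.na(g[, i]) & !is.na(g[, j])
      rel[i, j] <- rel[j, i] <- if (any(both)) {
        mean(1 - abs(g[both, i] - g[both, j]) / 2)
      } else NA_real_
    }
  }
  adj <- !is.na(rel) & rel > relatedness_threshold
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)
  flagged <- character(0)
  miss <- sample_missing_rate(x)
  for (k in seq_len(comp$no)) {
    members <- which(comp$membership == k)
    if (length(members) < 2L) next
    ids <- x$samples$sample_id[members]
    if (prune == "all") {
      flagged <- c(flagged, ids)
    } else {
      ord <- order(miss[members], ids)
      flagged <- c(flagged, ids[-ord[1L]])
    }
  }
  d <- stats::as.dist(1 - rel)
  d[is.na(d)] <- max(d, na.rm = TRUE)
  k_axes <- min(k_axes, n - 1L)
  ordn <- suppressWarnings(stats::cmdscale(d, k = k_axes))
  rownames(ordn) <- x$samples$sample_id
  list(retained = setdiff(x$samples$sample_id, flagged), flagged = flagged,
       relatedness = rel, ordination = ordn)
}

#' Codominant genotype-sex association scan
#'
#' For each bi-allelic marker called in at least `min_call_rate` of the
#' individuals, tests the sex x genotype contingency table of called
#' genotypes with genotype as an unordered factor (the codominant model).
#' The default statistic is the likelihood-ratio chi-square
#' `2 * sum(O * log(O / E))` with `df = g - 1` where `g` is the number of
#' observed genotype classes (2 or 3); Pearson's chi-square is available as
#' an option. Markers with a single observed genotype class carry no
#' information and are skipped. P-values are Benjamini-Hochberg adjusted
#' over the tested markers; `significant` flags `q < alpha`.
#'
#' @param x a [genotype_matrix] of sexed adults.
#' @param min_call_rate minimum overall call-rate (inclusive; default 0.8).
#' @param alpha FDR significance level (default 0.05).
#' @param statistic `"lrt"` (default) or `"pearson"`.
#' @return data.frame with `marker_id`, `statistic`, `df`, `p`, `q`,
#'   `significant`, `skipped`, `skip_reason`.
#' @export
codominant_association <- function(x, min_call_rate = 0.8, alpha = 0.05,
                                   statistic = c("lrt", "pearson")) {
  statistic <- match.arg(statistic)
  sexes <- x$samples$sex
  if (!all(sexes %in% c("M", "F")) || length(unique(sexes)) < 2L) {
    stop("both sexes must be present and every sample sexed")
  }
  g <- x$geno
  res <- data.frame(
    marker_id = x$markers$marker_id,
    statistic = NA_real_, df = NA_integer_, p = NA_real_, q = NA_real_,
    significant = FALSE, skipped = FALSE, skip_reason = NA_character_
  )
  mono <- is.na(x$markers$alt_allele)
  cr <- rowMeans(!is.na(g))
  for (i in seq_len(nrow(g))) {
    if (mono[i]) {
      res$skipped[i] <- TRUE; res$skip_reason[i] <- "monomorphic"; next
    }
    if (cr[i] < min_call_rate) {
      res$skipped[i] <- TRUE; res$skip_reason[i] <- "low_call_rate"; next
    }
    called <- !is.na(g[i, ])
    tab <- table(sex = factor(sexes[called], levels = c("M", "F")),
                 geno = g[i, called])
    if (ncol(tab) < 2L) {
      res$skipped[i] <- TRUE; res$skip_reason[i] <- "single_genotype_class"
      next
    }
    expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (statistic == "lrt") {
      o <- as.numeric(tab); e <- as.numeric(expd)
      stat <- 2 * sum(ifelse(o > 0, o * log(o / e), 0))
    } else {
      stat <- sum((tab - expd)^2 / expd)
    }
    df <- ncol(tab) - 1L
    res$statistic[i] <- stat
    res$df[i] <- df
    res$p[i] <- stats::pchisq(stat, df, lower.tail = FALSE)
  }
  tested <- !res$skipped
  res$q[tested] <- fdr_adjust(res$p[tested])
  res$significant <- !is.na(res$q) & res$q < alpha
  if ("lg" %in% names(x$markers)) res$lg <- x$markers$lg
  if ("pos_cM" %in% names(x$markers)) res$pos_cM <- x$markers$pos_cM
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (q-values): monotone, order-preserving, in
#' `[0, 1]`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values of the same length.
#' @export
fdr_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  stopifnot(all(is.na(p_values) | (p_values >= 0 & p_values <= 1)))
  stats::p.adjust(p_values, method = "BH")
}

#' Observed vs expected quantiles of a p-value vector
#'
#' Returns the table behind a QQ plot of observed against uniform-expected
#' significance: expected quantiles at `(i - 0.5) / n` matched to the sorted
#' observed p-values, both on the `-log10` scale.
#'
#' @param p_values non-empty numeric vector of p-values.
#' @return data.frame with `expected_neglog10p`, `observed_neglog10p`
#'   (sorted, most significant first) and the sorted `p`.
#' @export
qq_observed_expected <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no non-missing p-values")
  n <- length(p)
  p_sorted <- sort(p)
  data.frame(
    expected_neglog10p = -log10((seq_len(n) - 0.5) / n),
    observed_neglog10p = -log10(p_sorted),
    p = p_sorted
  )
}
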