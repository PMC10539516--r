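#' Randomly permute sex labels
#'
#' Returns a uniform random permutation of the label multiset: sex counts
#' are preserved exactly, only the assignment to samples changes.
#'
#' @param sexes character vector of `"M"`/`"F"`.
#' @param seed optional seed for a self-contained deterministic call.
#' @return permuted character vector of the same length.
#' @export
permute_sexes <- function(sexes, seed = NULL) {
  stopifnot(all(sexes %in% c("M", "F")))
  if (!is.null(seed)) set.seed(seed)
  sample(sexes)
}

# Hit counts for each (method, system) under a set of label assignments.
# male_mat: samples x B 0/1 matrix flagging which samples are labelled male
# in each assignment. Recomputes the per-sex call-rate gate per assignment
# (the gate depends on the labels). Returns a matrix with rownames
# "m1".."m5" x B columns per system, as a named list.
sexlink_hit_counts <- function(x, male_mat, methods = 1:5,
                               systems = c("XY", "ZW"),
                               thresholds = sexlink_thresholds()) {
  g <- x$geno
  cal <- (!is.na(g)) + 0
  het <- (!is.na(g) & g == 1L) + 0
  href <- (!is.na(g) & g == 0L) + 0
  cal_t <- rowSums(cal); het_t <- rowSums(het); href_t <- rowSums(href)

  cal_m <- cal %*% male_mat
  het_m <- het %*% male_mat
  href_m <- href %*% male_mat
  halt_m <- cal_m - het_m - href_m
  cal_f <- cal_t - cal_m; het_f <- het_t - het_m; href_f <- href_t - href_m
  halt_f <- cal_f - het_f - href_f
  n_m <- sum(male_mat[, 1L]); n_f <- nrow(male_mat) - n_m

  tp_num <- NULL
  if (3L %in% methods) {
    tp <- tag_presence(x)
    tp_num <- tp + 0
    pres_t <- rowSums(tp_num)
    pres_m <- tp_num %*% male_mat
    pres_f <- pres_t - pres_m
  }

  out <- list()
  for (system in systems) {
    snp_methods <- setdiff(methods, 3L)
    if (system == "XY") {
      hits <- sexlink_eval_counts(cal_m, het_m, href_m, halt_m,
                                  cal_f, het_f, href_f, halt_f,
                                  n_m, n_f, thresholds, methods = snp_methods)
    } else {
      hits <- sexlink_eval_counts(cal_f, het_f, href_f, halt_f,
                                  cal_m, het_m, href_m, halt_m,
                                  n_f, n_m, thresholds, methods = snp_methods)
    }
    counts <- matrix(0L, 5L, ncol(male_mat),
                     dimnames = list(paste0("m", 1:5), NULL))
    for (m in setdiff(methods, 3L)) {
      counts[paste0("m", m), ] <- as.integer(colSums(hits[[paste0("m", m)]]))
    }
    if (3L %in% methods) {
      if (system == "XY") {
        hit3 <- pres_f == 0 & pres_m / n_m >= thresholds$m3_present_min
      } else {
        hit3 <- pres_m == 0 & pres_f / n_f >= thresholds$m3_present_min
      }
      counts["m3", ] <- as.integer(colSums(hit3))
    }
    out[[system]] <- counts
  }
  out
}

#' Permutation test for the number of sex-linked markers
#'
#' Builds the null distribution of hit counts for each detection method by
#' repeatedly shuffling the sex labels of the cohort (sex counts preserved)
#' and rerunning the scan. The per-sex call-rate gate is recomputed inside
#' every permutation, since which markers pass it depends on the labels.
#' Significance is assessed against the empirical upper 95% and 99%
#' quantiles of the null counts (order statistics at `ceil(0.95 n)` and
#' `ceil(0.99 n)` of the sorted counts — integer counts, no interpolation)
#' and via the add-one empirical p-value
#' `(1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param x a [genotype_matrix] of sexed adults.
#' @param methods subset of `1:5`.
#' @param systems subset of `c("XY", "ZW")`.
#' @param n_perm number of label permutations (default 10000).
#' @param seed seed for the permutation stream.
#' @param thresholds see [sexlink_thresholds].
#' @param block permutations evaluated per matrix-product block (memory
#'   knob; does not affect results).
#' @return data.frame of class `permutation_summary`, one row per
#'   (method, system): `observed_count`, `n_perm`, `null_mean`, `q95`,
#'   `q99`, `empirical_p`, `signif_95`, `signif_99`, `seed`. The null count
#'   vectors are attached as attribute `"null_counts"`.
#' @export
run_permutation_test <- function(x, methods = 1:5, systems = c("XY", "ZW"),
                                 n_perm = 10000L, seed = NULL,
                                 thresholds = sexlink_thresholds(),
                                 block = 500L) {
  stopifnot(all(methods %in% 1:5))
  systems <- match.arg(systems, several.ok = TRUE)
  if (n_perm < 100L) warning("n_perm < 100: null quantiles will be unstable")
  if (!is.null(seed)) set.seed(seed)
  sexes <- x$samples$sex
  if (!all(sexes %in% c("M", "F"))) stop("every sample must be sexed M or F")

  obs <- sexlink_hit_counts(x, matrix((sexes == "M") + 0, ncol = 1L),
                            methods, systems, thresholds)

  n <- length(sexes)
  null_counts <- lapply(systems, function(s)
    matrix(NA_integer_, 5L, n_perm, dimnames = list(paste0("m", 1:5), NULL)))
  names(null_counts) <- systems
  done <- 0L
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    perm <- matrix(0, n, b)
    for (j in seq_len(b)) perm[, j] <- (sample(sexes) == "M") + 0
    cts <- sexlink_hit_counts(x, perm, methods, systems, thresholds)
    for (s in systems) null_counts[[s]][, done + seq_len(b)] <- cts[[s]]
    done <- done + b
  }

  rows <- list()
  for (s in systems) {
    for (m in methods) {
      nc <- sort(null_counts[[s]][paste0("m", m), ])
      ob <- obs[[s]][paste0("m", m), 1L]
      q95 <- nc[ceiling(0.95 * n_perm)]
      q99 <- nc[ceiling(0.99 * n_perm)]
      p <- (1 + sum(nc >= ob)) / (n_perm + 1)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, system = s, observed_count = as.integer(ob),
        n_perm = as.integer(n_perm), null_mean = mean(nc),
        q95 = as.integer(q95), q99 = as.integer(q99),
        empirical_p = p, signif_95 = ob > q95, signif_99 = ob > q99,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("permutation_summary", class(res))
  attr(res, "null_counts") <- null_counts
  res
}
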