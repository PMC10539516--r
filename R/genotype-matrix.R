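#' Genotype codes
#'
#' Genotypes are stored as integers: `0` = homozygous reference (AA),
#' `1` = heterozygous (AB), `2` = homozygous alternate (BB), `NA` = missing.
#' The A/B alphabet refers to the two alleles of a bi-allelic RADseq marker;
#' monomorphic markers (no alternate allele) use code 0 / NA only.
#'
#' @format A named integer vector mapping code names to codes.
#' @export
GENO_CODES <- c(hom_ref = 0L, het = 1L, hom_alt = 2L, missing = NA_integer_)

#' Construct a genotype matrix
#'
#' The central data container of the package: a set of markers (rows) by a
#' set of samples (columns), with integer genotype codes (see [GENO_CODES])
#' and optional per-call read depth.
#'
#' @param markers data.frame with columns `marker_id`, `radtag_id`,
#'   `snp_offset` (integer >= 0), `ref_allele`, `alt_allele`
#'   (single nucleotide; `NA` alt marks a monomorphic marker). Optional
#'   columns `lg` and `pos_cM` carry map coordinates when known.
#' @param samples data.frame with columns `sample_id`, `role`
#'   (one of `"mother"`, `"father"`, `"offspring"`, `"adult"`), `sex`
#'   (`"M"`, `"F"` or `"unknown"`) and optional `replicate_group`.
#' @param geno integer matrix, markers x samples, codes in `{0, 1, 2, NA}`.
#' @param depth optional non-negative integer matrix of the same shape;
#'   depth 0 must coincide with a missing genotype.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(markers, samples, geno, depth = NULL) {
  markers <- as.data.frame(markers)
  samples <- as.data.frame(samples)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
  }
  if (!"replicate_group" %in% names(samples)) samples$replicate_group <- NA_character_
  rownames(geno) <- markers$marker_id
  colnames(geno) <- samples$sample_id
  if (!is.null(depth)) dimnames(depth) <- dimnames(geno)
  x <- structure(
    list(markers = markers, samples = samples, geno = geno, depth = depth),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(x)
  x
}

#' Validate a genotype matrix
#'
#' Checks the structural invariants: unique marker and sample ids, at most
#' one mother and one father, sexed adults with a known sex, genotype codes
#' in range, and (when depth is present) missing genotype iff depth 0.
#'
#' @param x a `genotype_matrix`.
#' @return `x` invisibly; stops on violation.
#' @export
validate_genotype_matrix <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  m <- x$markers; s <- x$samples; g <- x$geno
  req_m <- c("marker_id", "radtag_id", "snp_offset", "ref_allele", "alt_allele")
  if (!all(req_m %in% names(m))) {
    stop("markers table must have columns: ", paste(req_m, collapse = ", "))
  }
  if (anyDuplicated(m$marker_id)) stop("duplicated marker_id")
  if (anyDuplicated(s$sample_id)) stop("duplicated sample_id")
  if (!all(s$role %in% c("mother", "father", "offspring", "adult"))) {
    stop("invalid sample role")
  }
  if (sum(s$role == "mother") > 1L) stop("more than one mother")
  if (sum(s$role == "father") > 1L) stop("more than one father")
  if (!all(s$sex %in% c("M", "F", "unknown"))) stop("invalid sex code")
  if (any(s$role == "adult" & s$sex == "unknown")) {
    stop("sexed adults must have sex M or F")
  }
  if (nrow(g) != nrow(m) || ncol(g) != nrow(s)) stop("geno dimensions do not match")
  if (!all(g[!is.na(g)] %in% 0:2)) stop("genotype codes must be 0, 1, 2 or NA")
  if (!is.null(x$depth)) {
    d <- x$depth
    if (!all(dim(d) == dim(g))) stop("depth dimensions do not match")
    if (any(d[!is.na(d)] < 0L)) stop("negative depth")
    bad <- (is.na(g) & !is.na(d) & d > 0L) | (!is.na(g) & !is.na(d) & d == 0L)
    if (any(bad)) stop("depth 0 must coincide exactly with missing genotypes")
  }
  invisible(x)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d markers x %d samples (%d RADtags)\n",
    nrow(x$geno), ncol(x$geno), length(unique(x$markers$radtag_id))
  ))
  roles <- table(x$samples$role)
  cat("  samples:", paste(sprintf("%s=%d", names(roles), roles), collapse = ", "), "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotypes: %.1f%%; depth: %s\n",
              100 * miss, if (is.null(x$depth)) "absent" else "present"))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' `x[i, j]` subsets markers (`i`) and samples (`j`) keeping the marker and
#' sample tables, genotype and depth matrices in step.
#'
#' @param x a `genotype_matrix`.
#' @param i marker index (integer, logical or marker_id character).
#' @param j sample index (integer, logical or sample_id character).
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$geno))
  if (missing(j)) j <- seq_len(ncol(x$geno))
  if (is.character(i)) i <- match(i, x$markers$marker_id)
  if (is.character(j)) j <- match(j, x$samples$sample_id)
  structure(
    list(
      markers = x$markers[i, , drop = FALSE],
      samples = x$samples[j, , drop = FALSE],
      geno = x$geno[i, j, drop = FALSE],
      depth = if (is.null(x$depth)) NULL else x$depth[i, j, drop = FALSE]
    ),
    class = "genotype_matrix"
  )
}

#' Per-sample RADtag presence
#'
#' A RADtag is present in a sample if any of its markers has a non-missing
#' genotype call in that sample. Monomorphic markers count: a Y- or W-specific
#' tag typically surfaces as a monomorphic marker called only in the
#' heterogametic sex.
#'
#' @param x a `genotype_matrix`.
#' @return logical matrix, RADtags x samples, with radtag_id rownames.
#' @export
tag_presence <- function(x) {
  called <- !is.na(x$geno)
  tags <- unique(x$markers$radtag_id)
  f <- factor(x$markers$radtag_id, levels = tags)
  pres <- rowsum(called + 0L, f, reorder = FALSE) > 0L
  rownames(pres) <- tags
  pres
}

#' Per-sample fraction of missing genotype calls
#' @param x a `genotype_matrix`.
#' @return named numeric vector over samples.
#' @export
sample_missing_rate <- function(x) {
  r <- colMeans(is.na(x$geno))
  names(r) <- x$samples$sample_id
  r
}

#' Per-marker call rate
#' @param x a `genotype_matrix`.
#' @return named numeric vector over markers.
#' @export
marker_call_rate <- function(x) {
  r <- rowMeans(!is.na(x$geno))
  names(r) <- x$markers$marker_id
  r
}

#' Per-marker minor allele frequency over called genotypes
#'
#' Allele counts are taken over non-missing calls only. Markers with no calls
#' get `NA`; monomorphic markers get 0.
#'
#' @param x a `genotype_matrix`.
#' @return named numeric vector over markers.
#' @export
marker_maf <- function(x) {
  g <- x$geno
  n_called <- rowSums(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE)           # alt allele count = sum of codes
  p_alt <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  names(maf) <- x$markers$marker_id
  maf
}
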