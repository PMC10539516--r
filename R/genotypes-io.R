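#' Read a genotype matrix from VCF plus sample metadata
#'
#' Reads a bi-allelic SNP VCF (v4.2) together with a sample-metadata TSV and
#' assembles a [genotype_matrix]. Because the pipeline works without a
#' reference genome, coordinates are synthetic: the contig name is the linkage
#' group (or `"UN"`) and the position is a 1-based marker index. RADtag id and
#' SNP offset travel in the INFO fields `RT` and `SO`.
#'
#' @param vcf_path path to an (uncompressed or bgzipped) VCF.
#' @param meta_path path to a TSV with header
#'   `sample_id  role  sex  replicate_group` covering every VCF sample.
#' @param multiallelic `"error"` (default) to stop on records with more than
#'   one ALT allele, `"drop"` to discard them with a warning.
#' @return A [genotype_matrix] with depth when the VCF carries `DP`.
#' @export
read_genotypes <- function(vcf_path, meta_path, multiallelic = c("error", "drop")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  meta <- read_sample_meta(meta_path)
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "synthetic")

  n_alt <- lengths(VariantAnnotation::alt(vcf))
  if (any(n_alt > 1L)) {
    bad <- which(n_alt > 1L)
    coord <- paste0(as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(vcf)))[bad[1]],
                    ":", GenomicRanges::start(SummarizedExperiment::rowRanges(vcf))[bad[1]])
    if (multiallelic == "error") {
      stop("multi-allelic record at ", coord, " (", length(bad), " records); ",
           "split or drop them first")
    }
    warning("dropping ", length(bad), " multi-allelic records")
    vcf <- vcf[n_alt <= 1L, ]
    n_alt <- n_alt[n_alt <= 1L]
  }

  vcf_samples <- colnames(vcf)
  unknown <- setdiff(vcf_samples, meta$sample_id)
  if (length(unknown)) {
    stop("VCF sample(s) missing from metadata: ", paste(unknown, collapse = ", "))
  }
  meta <- meta[match(vcf_samples, meta$sample_id), , drop = FALSE]

  gt <- VariantAnnotation::geno(vcf)$GT
  codes <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
             "1|0" = 1L, "1/1" = 2L, "1|1" = 2L, "./." = NA_integer_,
             ".|." = NA_integer_, "." = NA_integer_)
  bad_gt <- !(gt %in% names(codes))
  if (any(bad_gt)) {
    idx <- which(bad_gt, arr.ind = TRUE)[1, ]
    rr <- SummarizedExperiment::rowRanges(vcf)
    stop(sprintf("malformed genotype '%s' at %s:%d",
                 gt[bad_gt][1],
                 as.character(GenomicRanges::seqnames(rr))[idx[1]],
                 GenomicRanges::start(rr)[idx[1]]))
  }
  g <- matrix(codes[gt], nrow = nrow(gt), dimnames = dimnames(gt))

  depth <- NULL
  if ("DP" %in% names(VariantAnnotation::geno(vcf))) {
    depth <- VariantAnnotation::geno(vcf)$DP
    depth[is.na(depth)] <- 0L
  }

  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_chr <- rep(NA_character_, length(vcf))
  has_alt <- n_alt == 1L
  alt_chr[has_alt] <- as.character(unlist(VariantAnnotation::alt(vcf)[has_alt]))
  alt_chr[!is.na(alt_chr) & alt_chr == ""] <- NA_character_
  info <- VariantAnnotation::info(vcf)
  markers <- data.frame(
    marker_id = rownames(gt),
    radtag_id = if ("RT" %in% names(info)) as.character(info$RT) else rownames(gt),
    snp_offset = if ("SO" %in% names(info)) as.integer(info$SO) else 0L,
    ref_allele = as.character(VariantAnnotation::ref(vcf)),
    alt_allele = alt_chr,
    lg = as.character(GenomicRanges::seqnames(rr)),
    stringsAsFactors = FALSE
  )
  if ("CM" %in% names(info)) markers$pos_cM <- as.numeric(info$CM)

  genotype_matrix(markers, meta, g, depth)
}

#' Write a genotype matrix to VCF plus sample metadata
#'
#' Emits VCFv4.2 with one unphased record per marker (`GT`, and `DP` when
#' depth is present) and a metadata sidecar TSV. Monomorphic markers get ALT
#' `"."`. Coordinates are synthetic (see [read_genotypes]); the optional
#' `pos_cM` marker column is preserved in INFO field `CM`.
#'
#' @param x a [genotype_matrix].
#' @param vcf_path output VCF path.
#' @param meta_path output metadata TSV path; defaults to
#'   `<vcf_path>.meta.tsv`.
#' @return Invisibly, the VCF path.
#' @export
write_genotypes <- function(x, vcf_path, meta_path = paste0(vcf_path, ".meta.tsv")) {
  validate_genotype_matrix(x)
  m <- x$markers
  lg <- if ("lg" %in% names(m)) as.character(m$lg) else rep("UN", nrow(m))
  lg[is.na(lg)] <- "UN"
  has_cm <- "pos_cM" %in% names(m)
  has_dp <- !is.null(x$depth)

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=radsexmap",
    "##INFO=<ID=RT,Number=1,Type=String,Description=\"RADtag id\">",
    "##INFO=<ID=SO,Number=1,Type=Integer,Description=\"SNP offset within RADtag\">",
    if (has_cm) "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Map position in cM\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_dp) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("##contig=<ID=", unique(lg), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples$sample_id), collapse = "\t")
  )

  con <- file(vcf_path, "w")
  on.exit(close(con))
  writeLines(header, con)

  if (nrow(m) > 0L) {
    gt_str <- matrix(c("0/0", "0/1", "1/1")[x$geno + 1L],
                     nrow = nrow(x$geno))
    gt_str[is.na(x$geno)] <- "./."
    if (has_dp) gt_str <- matrix(paste0(gt_str, ":", x$depth), nrow = nrow(gt_str))
    pos <- stats::ave(seq_len(nrow(m)), lg, FUN = seq_along)  # 1-based index per LG
    info <- paste0("RT=", m$radtag_id, ";SO=", m$snp_offset,
                   if (has_cm) paste0(";CM=", format(m$pos_cM, trim = TRUE)) else "")
    alt <- ifelse(is.na(m$alt_allele), ".", m$alt_allele)
    rec <- paste(lg, pos, m$marker_id, m$ref_allele, alt, ".", ".", info,
                 if (has_dp) "GT:DP" else "GT",
                 apply(gt_str, 1L, paste, collapse = "\t"),
                 sep = "\t")
    writeLines(rec, con)
  }
  write_sample_meta(x$samples, meta_path)
  invisible(vcf_path)
}

#' Read a sample-metadata TSV
#' @param path TSV with header `sample_id role sex replicate_group`
#'   (replicate_group optional).
#' @return data.frame with those columns.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character", na.strings = c("NA", ""))
  req <- c("sample_id", "role", "sex")
  if (!all(req %in% names(meta))) {
    stop("metadata must have columns: ", paste(req, collapse = ", "))
  }
  if (!"replicate_group" %in% names(meta)) meta$replicate_group <- NA_character_
  meta[, c(req, "replicate_group")]
}

#' Write a sample-metadata TSV
#' @param samples data.frame with sample metadata columns.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_sample_meta <- function(samples, path) {
  utils::write.table(
    samples[, c("sample_id", "role", "sex", "replicate_group")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
  )
  invisible(path)
}
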