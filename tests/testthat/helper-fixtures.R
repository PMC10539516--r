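# Small in-code fixtures shared across test files.

# Build a genotype_matrix from a bare genotype matrix with minimal metadata.
# sexes: recycled over samples; roles: recycled; depth optional.
make_gm <- function(geno, sexes = "unknown", roles = "adult",
                    radtag_id = NULL, alt = "C", depth = NULL,
                    replicate_group = NA_character_, lg = NULL) {
  geno <- as.matrix(geno)
  n_m <- nrow(geno); n_s <- ncol(geno)
  if (any(roles == "adult") && all(sexes == "unknown")) sexes <- "M"
  markers <- data.frame(
    marker_id = sprintf("m%03d", seq_len(n_m)),
    radtag_id = if (is.null(radtag_id)) sprintf("t%03d", seq_len(n_m)) else
      rep_len(radtag_id, n_m),
    snp_offset = rep(0L, n_m),
    ref_allele = rep("A", n_m),
    alt_allele = rep_len(alt, n_m)
  )
  if (!is.null(lg)) markers$lg <- rep_len(lg, n_m)
  samples <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n_s)),
    role = rep_len(roles, n_s),
    sex = rep_len(sexes, n_s),
    replicate_group = rep_len(replicate_group, n_s)
  )
  genotype_matrix(markers, samples, geno, depth)
}

# A sexed-adult matrix from per-sex genotype count vectors
# c(n_AA, n_AB, n_BB, n_missing). Used by the enumeration oracles.
gm_from_counts <- function(m_counts, f_counts) {
  expand <- function(ct) rep(c(0L, 1L, 2L, NA_integer_), times = ct)
  g <- matrix(c(expand(m_counts), expand(f_counts)), nrow = 1)
  make_gm(g, sexes = rep(c("M", "F"), c(sum(m_counts), sum(f_counts))),
          roles = "adult")
}

# Independent scalar re-implementation of the five sex-linkage criteria,
# written directly from the threshold definitions with plain frequency
# arithmetic. This is the oracle the vectorised implementation is checked
# against; keep it dumb and literal.
oracle_sexlink <- function(m_counts, f_counts, method, system) {
  if (system == "ZW") { tmp <- m_counts; m_counts <- f_counts; f_counts <- tmp }
  # after the swap: heterogametic counts = m_counts, homogametic = f_counts
  n_h <- sum(m_counts); n_f <- sum(f_counts)
  cal_h <- sum(m_counts[1:3]); cal_o <- sum(f_counts[1:3])
  if (cal_h == 0 || cal_o == 0) return(FALSE)
  if (cal_h / n_h < 0.6 || cal_o / n_f < 0.6) return(FALSE)
  fhet_h <- m_counts[2] / cal_h
  faa_o <- f_counts[1] / cal_o
  fhet_o <- f_counts[2] / cal_o
  fbb_o <- f_counts[3] / cal_o
  aref_o <- (2 * f_counts[1] + f_counts[2]) / (2 * cal_o)
  aref_h <- (2 * m_counts[1] + m_counts[2]) / (2 * cal_h)
  orientations <- if (aref_o > 0.5) "ref" else if (aref_o < 0.5) "alt" else
    c("ref", "alt")
  hit_under <- function(orient) {
    if (orient == "ref") {
      x_o <- aref_o; x_h <- aref_h
      hom_x_o <- faa_o; hom_y_o <- fbb_o; homy_count <- f_counts[3]
    } else {
      x_o <- 1 - aref_o; x_h <- 1 - aref_h
      hom_x_o <- fbb_o; hom_y_o <- faa_o; homy_count <- f_counts[1]
    }
    switch(as.character(method),
      "1" = x_o > 0.95 && x_h >= 0.4 && x_h <= 0.6,
      "2" = f_counts[2] == 0 && fhet_h >= 0.5,
      "4" = fhet_h > 0.75 && hom_x_o > 0.8 && fhet_o < 0.2 && hom_y_o < 0.1,
      "5" = fhet_h > 0.55 && hom_x_o > 0.8 && fhet_o < 0.2 && homy_count == 0
    )
  }
  any(vapply(orientations, hit_under, logical(1)))
}

# Deterministic random genotype matrix for tally oracles.
random_gm <- function(n_mark, n_samp, seed, miss = 0.1, sexes = "M") {
  set.seed(seed)
  g <- matrix(sample(c(0L, 1L, 2L, NA_integer_), n_mark * n_samp,
                     replace = TRUE, prob = c((1 - miss) / 3, (1 - miss) / 3,
                                              (1 - miss) / 3, miss)),
              n_mark, n_samp)
  make_gm(g, sexes = sexes, roles = "adult")
}
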