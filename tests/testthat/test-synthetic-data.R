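test_that("parent haplotype generation covers the degenerate corners", {
  cfg0 <- sim_config(markers_per_lg = 0L, seed = 1L)
  ph0 <- simulate_parent_haplotypes(cfg0)
  expect_equal(nrow(ph0$map), 0L)

  cfg1 <- sim_config(n_lgs = 2L, markers_per_lg = 40L,
                     allele_freq_distribution = list(type = "fixed", value = 0),
                     seed = 1L)
  ph1 <- simulate_parent_haplotypes(cfg1)
  expect_true(all(ph1$haplotypes == 0L))  # every marker AAxAA
})

test_that("segregation-type frequencies match the HWE expectation", {
  cfg <- sim_config(n_lgs = 4L, markers_per_lg = 2500L,
                    allele_freq_distribution = list(type = "uniform",
                                                    min = 0.1, max = 0.9),
                    seed = 3L)
  ph <- simulate_parent_haplotypes(cfg)
  seg <- radsexmap:::true_segregation_type(
    ph$haplotypes[1, ] + ph$haplotypes[2, ],
    ph$haplotypes[3, ] + ph$haplotypes[4, ])
  # analytic expectation: P(ABxAB) = E[(2p(1-p))^2] for p ~ U(0.1, 0.9)
  expected <- integrate(function(p) (2 * p * (1 - p))^2 / 0.8,
                        0.1, 0.9)$value
  obs <- mean(seg == "ABxAB")
  se <- sqrt(expected * (1 - expected) / length(seg))
  expect_lt(abs(obs - expected), 4 * se)
})

test_that("a zero-error F1 family is perfectly Mendelian", {
  cfg <- sim_config(n_lgs = 3L, markers_per_lg = 60L, n_offspring = 60L,
                    genotype_error_rate = 0, missing_rate = 0,
                    depth_model = NULL, seed = 7L)
  sim <- simulate_f1_family(cfg)
  res <- apply_segregation_filter(sim$matrix)
  expect_equal(nrow(res$silenced), 0L)
  expect_false(any(res$assessments$action == "remove_distorted"))
  # retained markers carry their true segregation type
  ok <- !is.na(res$assessments$assigned_type)
  expect_equal(res$assessments$assigned_type[ok],
               unname(sim$truth$seg_type[ok]))
})

test_that("crossover counts follow the Poisson map-length model", {
  cfg <- sim_config(n_lgs = 1L, markers_per_lg = 10L,
                    female_lg_length_cM = 150, male_lg_length_cM = 90,
                    n_offspring = 1000L, genotype_error_rate = 0,
                    missing_rate = 0, depth_model = NULL, seed = 9L)
  sim <- simulate_f1_family(cfg)
  xo <- sim$truth$crossovers
  maternal <- xo[seq(1, nrow(xo), 2), 1]
  paternal <- xo[seq(2, nrow(xo), 2), 1]
  for (pair in list(list(x = maternal, mu = 1.5), list(x = paternal, mu = 0.9))) {
    se <- sqrt(pair$mu / length(pair$x))
    expect_lt(abs(mean(pair$x) - pair$mu), 3 * se)
  }

  # (near-)zero male map length: paternal gametes are non-recombinant
  cfg0 <- sim_config(n_lgs = 1L, markers_per_lg = 10L,
                     male_lg_length_cM = 1e-9, n_offspring = 50L,
                     genotype_error_rate = 0, missing_rate = 0,
                     depth_model = NULL, seed = 10L)
  sim0 <- simulate_f1_family(cfg0)
  expect_true(all(sim0$truth$crossovers[seq(2, 100, 2), 1] == 0L))
})

test_that("sexed cohort has complete linkage at the locus when decay = 0", {
  cfg <- sim_config(n_lgs = 2L, markers_per_lg = 50L, sd_lg = 1L,
                    sex_system = "XY", linkage_decay_per_cM = 0,
                    genotype_error_rate = 0, missing_rate = 0,
                    depth_model = NULL, n_sex_specific_tags = 3L, seed = 21L)
  sim <- simulate_sexed_cohort(cfg)
  x <- sim$matrix
  males <- x$samples$sex == "M"
  sd_rows <- match(sim$truth$sd_marker_ids, x$markers$marker_id)
  expect_true(all(x$geno[sd_rows, males] == 1L))
  expect_true(all(x$geno[sd_rows, !males] == 0L))
  # sex-specific tags present only in males
  tp <- tag_presence(x)
  expect_true(all(tp[sim$truth$sex_specific_tags, males]))
  expect_false(any(tp[sim$truth$sex_specific_tags, !males]))
})

test_that("male heterozygosity decays with distance from the locus", {
  # two cohorts differing only in decay rate; higher decay -> fewer het males
  het_at_sd <- function(decay, seed) {
    cfg <- sim_config(n_lgs = 1L, markers_per_lg = 200L, sd_lg = 1L,
                      sd_region_markers = 100L, sex_system = "XY",
                      female_lg_length_cM = 200, male_lg_length_cM = 200,
                      linkage_decay_per_cM = decay, genotype_error_rate = 0,
                      missing_rate = 0, depth_model = NULL,
                      n_males = 50L, n_females = 5L,
                      n_sex_specific_tags = 0L, seed = seed)
    sim <- simulate_sexed_cohort(cfg)
    rows <- match(sim$truth$sd_marker_ids, sim$matrix$markers$marker_id)
    mean(sim$matrix$geno[rows, sim$matrix$samples$sex == "M"] == 1L)
  }
  h_none <- mean(vapply(1:3, function(s) het_at_sd(0, s), numeric(1)))
  h_weak <- mean(vapply(1:3, function(s) het_at_sd(0.005, s), numeric(1)))
  h_strong <- mean(vapply(1:3, function(s) het_at_sd(0.02, s), numeric(1)))
  expect_gt(h_none, h_weak)
  expect_gt(h_weak, h_strong)
})

test_that("inject_errors honours rates, disjointness and determinism", {
  x <- random_gm(60, 40, seed = 31, miss = 0.05)
  id0 <- inject_errors(x, 0, 0)
  expect_identical(id0$matrix$geno, x$geno)
  expect_equal(nrow(id0$errors) + nrow(id0$missing), 0L)

  all_miss <- inject_errors(x, 0, 1)
  expect_true(all(is.na(all_miss$matrix$geno)))

  set.seed(1); e1 <- inject_errors(x, 0.01, 0)
  n_calls <- sum(!is.na(x$geno))
  ci <- qbinom(c(0.005, 0.995), n_calls, 0.01)
  expect_gte(nrow(e1$errors), ci[1]); expect_lte(nrow(e1$errors), ci[2])

  both <- inject_errors(x, 0.3, 0.3, seed = 5)
  key <- function(df) paste(df$marker_id, df$sample_id)
  expect_length(intersect(key(both$errors), key(both$missing)), 0L)
  both2 <- inject_errors(x, 0.3, 0.3, seed = 5)
  expect_identical(both$matrix$geno, both2$matrix$geno)
})

test_that("the generator is fully deterministic given a seed", {
  cfg <- sim_config(n_lgs = 2L, markers_per_lg = 30L, n_offspring = 20L,
                    seed = 77L)
  a <- simulate_f1_family(cfg); b <- simulate_f1_family(cfg)
  expect_identical(a$matrix$geno, b$matrix$geno)
  expect_identical(a$matrix$depth, b$matrix$depth)
  cfg2 <- sim_config(n_lgs = 2L, markers_per_lg = 30L, seed = 78L)
  c1 <- simulate_sexed_cohort(cfg2); c2 <- simulate_sexed_cohort(cfg2)
  expect_identical(c1$matrix$geno, c2$matrix$geno)
})
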