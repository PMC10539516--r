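test_that("per-sex frequencies equal brute-force tallies", {
  x <- random_gm(50, 24, seed = 41, miss = 0.2,
                 sexes = rep(c("M", "F"), each = 12))
  fr <- compute_sex_genotype_freqs(x)
  g <- x$geno
  males <- x$samples$sex == "M"
  i <- sample(1:50, 1)
  expect_equal(fr$n_called_M[i], sum(!is.na(g[i, males])))
  expect_equal(fr$freq_het_F[i],
               sum(g[i, !males] == 1, na.rm = TRUE) /
                 sum(!is.na(g[i, !males])))
  expect_equal(fr$ref_allele_freq_M[i],
               (2 * sum(g[i, males] == 0, na.rm = TRUE) +
                  sum(g[i, males] == 1, na.rm = TRUE)) /
                 (2 * sum(!is.na(g[i, males]))))
  # frequencies over called genotypes sum to 1
  called <- fr$n_called_M > 0
  expect_equal(fr$freq_hom_ref_M[called] + fr$freq_het_M[called] +
                 fr$freq_hom_alt_M[called], rep(1, sum(called)))

  # the 60% per-sex gate: 11/19 females (57.9%) fails, 12/19 passes
  gx <- matrix(0L, 1, 38)
  gx[1, 20:27] <- NA_integer_  # 8 missing females -> 11/19 called
  xf <- make_gm(gx, sexes = rep(c("M", "F"), each = 19))
  expect_false(compute_sex_genotype_freqs(xf)$pass_gate)
  gx[1, 27] <- 0L
  xf2 <- make_gm(gx, sexes = rep(c("M", "F"), each = 19))
  expect_true(compute_sex_genotype_freqs(xf2)$pass_gate)
})

test_that("documented threshold examples behave as stated", {
  fr_of <- function(m, f) compute_sex_genotype_freqs(gm_from_counts(m, f))

  # Method 1: F x-freq 0.97, M 0.5 -> hit; M 0.39 -> miss
  # 19 females: 18 AA + 1 AB -> ref freq 37/38 = 0.974
  hit <- fr_of(c(0, 19, 0, 0), c(18, 1, 0, 0))
  expect_true(sexlink_method1(hit, "XY"))
  # males 4 AA, 6 AB, 9 BB -> ref freq 14/38 = 0.368 (< 0.4)
  miss <- fr_of(c(4, 6, 9, 0), c(18, 1, 0, 0))
  expect_false(sexlink_method1(miss, "XY"))

  # Method 2: all 19 F hom, 10/19 M het -> hit; 9/19 -> miss
  expect_true(sexlink_method2(fr_of(c(9, 10, 0, 0), c(19, 0, 0, 0)), "XY"))
  expect_false(sexlink_method2(fr_of(c(10, 9, 0, 0), c(19, 0, 0, 0)), "XY"))

  # Method 4: strict at exactly 75% male heterozygosity
  expect_true(sexlink_method4(
    fr_of(c(3, 16, 0, 0), c(17, 2, 0, 0)), "XY"))  # 84% het M
  expect_false(sexlink_method4(
    fr_of(c(4, 12, 0, 3), c(17, 2, 0, 0)), "XY"))  # 12/16 = 75% exactly

  # Method 5: one female hom for the Y allele kills the hit
  expect_true(sexlink_method5(fr_of(c(7, 12, 0, 0), c(16, 3, 0, 0)), "XY"))
  expect_false(sexlink_method5(fr_of(c(7, 12, 0, 0), c(15, 3, 1, 0)), "XY"))
})

test_that("method 3 flags tags absent in all females, present in >= 50% males", {
  tp <- rbind(t1 = rep(c(TRUE, FALSE), c(10, 28)),   # 10/19 M, 0/19 F
              t2 = c(rep(TRUE, 10), rep(FALSE, 9), TRUE, rep(FALSE, 18)),
              t3 = rep(c(TRUE, FALSE), c(9, 29)))    # 9/19 M only
  sexes <- rep(c("M", "F"), each = 19)
  expect_equal(sexlink_method3(tp, sexes, "XY"), "t1")
  expect_equal(sexlink_method3(tp, sexes, "ZW"), character(0))
})

test_that("methods agree with the scalar oracle on random configurations", {
  set.seed(53)
  fr_of <- function(m, f) compute_sex_genotype_freqs(gm_from_counts(m, f))
  for (rep in 1:300) {
    m <- as.vector(rmultinom(1, sample(2:8, 1), c(0.3, 0.3, 0.3, 0.1)))
    f <- as.vector(rmultinom(1, sample(2:8, 1), c(0.3, 0.3, 0.3, 0.1)))
    fr <- fr_of(m, f)
    for (method in c(1, 2, 4, 5)) {
      for (system in c("XY", "ZW")) {
        got <- switch(as.character(method),
                      "1" = sexlink_method1(fr, system),
                      "2" = sexlink_method2(fr, system),
                      "4" = sexlink_method4(fr, system),
                      "5" = sexlink_method5(fr, system))
        expect_identical(unname(got), oracle_sexlink(m, f, method, system),
                         label = sprintf("m=%s f=%s method %d %s",
                                         paste(m, collapse = ","),
                                         paste(f, collapse = ","),
                                         method, system))
      }
    }
  }
})

test_that("XY/ZW label symmetry is exact and scan hits the simulated locus", {
  cfg <- sim_config(n_lgs = 3L, markers_per_lg = 150L, sd_lg = 2L,
                    sex_system = "XY", genotype_error_rate = 0.02,
                    missing_rate = 0.05, depth_model = NULL, seed = 61L)
  sim <- simulate_sexed_cohort(cfg)
  x <- sim$matrix
  sc <- scan_sex_linkage(x)

  # swap all sexes: every XY call must become the identical ZW call
  y <- x
  y$samples$sex <- ifelse(x$samples$sex == "M", "F", "M")
  sc_sw <- scan_sex_linkage(y)
  flip <- function(calls) {
    calls$system <- ifelse(calls$system == "XY", "ZW", "XY")
    calls[order(calls$system, calls$method, calls$id), ]
  }
  expect_equal(flip(sc$calls)$id,
               sc_sw$calls[order(sc_sw$calls$system, sc_sw$calls$method,
                                 sc_sw$calls$id), ]$id)

  # hits concentrate in the simulated sex-determining region
  marker_hits <- unique(sc$calls$id[sc$calls$id_type == "marker" &
                                      sc$calls$system == "XY"])
  expect_gt(length(marker_hits), 0)
  expect_gte(mean(marker_hits %in% sim$truth$sd_marker_ids), 0.9)
  # and the Y-specific tags are found by method 3
  m3 <- sc$calls$id[sc$calls$method == 3 & sc$calls$system == "XY"]
  expect_true(all(sim$truth$sex_specific_tags %in% m3))
})

test_that("method 4 hits are method 5 hits when no female is hom for Y", {
  set.seed(71)
  for (rep in 1:200) {
    m <- as.vector(rmultinom(1, 8, c(0.25, 0.5, 0.15, 0.1)))
    f <- as.vector(rmultinom(1, 8, c(0.7, 0.2, 0, 0.1)))
    fr <- compute_sex_genotype_freqs(gm_from_counts(m, f))
    if (sexlink_method4(fr, "XY") && f[3] == 0) {
      expect_true(sexlink_method5(fr, "XY"))
    }
  }
})
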