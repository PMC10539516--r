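test_that("classify_offspring tallies classes and incompatibles", {
  res <- classify_offspring(rep(1L, 30), "AAxBB")
  expect_equal(unname(res$class_counts), 30L)
  expect_equal(res$incompatible_count, 0L)

  g <- c(rep(0L, 50), rep(1L, 52), rep(2L, 3), rep(NA_integer_, 4))
  res2 <- classify_offspring(g, "AAxAB")
  expect_equal(res2$class_counts, c(AA = 50L, AB = 52L))
  expect_equal(res2$incompatible_count, 3L)

  # random genotypes equal a brute-force tally
  set.seed(12)
  g3 <- sample(c(0:2, NA_integer_), 200, replace = TRUE)
  res3 <- classify_offspring(g3, "ABxAB")
  expect_equal(unname(res3$class_counts),
               c(sum(g3 == 0, na.rm = TRUE), sum(g3 == 1, na.rm = TRUE),
                 sum(g3 == 2, na.rm = TRUE)))
  expect_equal(res3$incompatible_count, 0L)

  res4 <- classify_offspring(g3, "ABxMissing")
  expect_equal(res4$incompatible_count, sum(g3 == 1, na.rm = TRUE))
})

test_that("test_segregation matches hand-computed chi-squares", {
  perfect <- test_segregation(c(AA = 25, AB = 50, BB = 25), 0, "ABxAB")
  expect_equal(perfect$chi2, 0)
  expect_equal(perfect$p, 1)
  expect_true(perfect$pass)

  r <- test_segregation(c(AA = 148, AB = 152), 3, "AAxAB")
  expect_equal(r$chi2, (148 - 150)^2 / 150 + (152 - 150)^2 / 150)
  expect_equal(r$error_fraction, 3 / 303)
  expect_equal(r$p, pchisq(r$chi2, 1, lower.tail = FALSE))
  expect_true(r$pass)

  bad <- test_segregation(c(AA = 100, AB = 0), 0, "AAxAB")
  expect_equal(bad$chi2, 100)
  expect_false(bad$pass)

  # error allowance is strict at > 2%
  e <- test_segregation(c(AA = 49, AB = 48), 3, "AAxAB")
  expect_gt(e$error_fraction, 0.02)
  expect_false(e$pass)

  none <- test_segregation(c(AA = 0, AB = 0), 0, "AAxAB")
  expect_false(none$pass)
  expect_equal(none$reason, "no called offspring")
})

test_that("chi-square agrees with stats::chisq.test on random tables", {
  set.seed(99)
  st <- segregation_types()
  multi <- st$name[lengths(st$expected) > 1]
  for (i in 1:250) {
    type <- sample(multi, 1)
    expected <- st$expected[[match(type, st$name)]]
    counts <- rpois(length(expected), lambda = sample(5:80, 1))
    names(counts) <- names(expected)
    if (sum(counts) == 0) next
    r <- test_segregation(counts, 0, type)
    oracle <- suppressWarnings(
      chisq.test(counts, p = expected / sum(expected)))
    expect_equal(r$chi2, unname(oracle$statistic), tolerance = 1e-12)
    expect_equal(r$p, unname(oracle$p.value), tolerance = 1e-12)
  }
})

test_that("assign_segregation resolves parents, corrections and ambiguity", {
  # uninformative cross
  a <- assign_segregation(0L, 2L, rep(1L, 80))
  expect_equal(a$assigned_type, "AAxBB")
  expect_equal(a$action, "remove_uninformative")

  # ABxMissing: mother AB, father missing, offspring ~1:1 AA:BB plus 1 AB
  g <- c(rep(0L, 100), rep(2L, 102), 1L)
  b <- assign_segregation(1L, NA_integer_, g)
  expect_equal(b$assigned_type, "ABxMissing")
  expect_equal(b$action, "retain")
  expect_null(b$corrected_parent)
  expect_equal(sum(b$incompatible), 1L)

  # missing mother imputed AB for an AAxAB cross
  set.seed(4)
  g2 <- sample(c(0L, 1L), 200, replace = TRUE)
  c1 <- assign_segregation(NA_integer_, 0L, g2)
  expect_equal(c1$assigned_type, "AAxAB")
  expect_equal(c1$corrected_parent$parent, "mother")
  expect_equal(c1$corrected_parent$genotype, 1L)

  # parent mismatch: offspring fit AAxAB but parents say BBxBB
  d <- assign_segregation(2L, 2L, g2)
  expect_equal(d$action, "remove_parent_mismatch")

  # highly distorted: no model passes
  e <- assign_segregation(1L, 1L, c(rep(0L, 100), rep(1L, 5), rep(2L, 100)))
  expect_equal(e$action, "remove_distorted")

  # enumeration oracle: for every informative type and every single-missing
  # parent configuration, the imputation recovers the true type
  st <- segregation_types()
  sim_offspring <- function(type, n = 400) {
    expected <- st$expected[[match(type, st$name)]]
    codes <- match(names(expected), c("AA", "AB", "BB")) - 1L
    sample(codes, n, replace = TRUE, prob = expected / sum(expected))
  }
  set.seed(8)
  for (type in c("AAxAB", "BBxAB", "ABxAB")) {
    cfg <- st$parents[[match(type, st$name)]]
    off <- sim_offspring(type)
    for (drop in 1:2) {
      m_gt <- if (drop == 1) NA_integer_ else cfg[1]
      f_gt <- if (drop == 1) cfg[2] else NA_integer_
      r <- assign_segregation(m_gt, f_gt, off)
      expect_equal(r$assigned_type, type)
      expect_equal(r$corrected_parent$parent,
                   if (drop == 1) "mother" else "father")
    }
  }
})

test_that("segregation filter silences only injected errors on simulations", {
  cfg <- sim_config(n_lgs = 3L, markers_per_lg = 80L, n_offspring = 300L,
                    genotype_error_rate = 0.01, missing_rate = 0.02,
                    depth_model = NULL, seed = 13L)
  sim <- simulate_f1_family(cfg)
  res <- apply_segregation_filter(sim$matrix)

  # actions partition the marker set
  expect_equal(sum(res$report$n), nrow(sim$matrix$geno))
  expect_false(any(is.na(res$assessments$action)))

  # silenced coordinates should essentially all be injected errors
  if (nrow(res$silenced)) {
    key <- function(df) paste(df$marker_id, df$sample_id)
    prec <- mean(key(res$silenced) %in% key(sim$truth$errors))
    expect_gte(prec, 0.95)
  }
})

test_that("assessments are invariant to offspring column order", {
  cfg <- sim_config(n_lgs = 1L, markers_per_lg = 40L, n_offspring = 80L,
                    genotype_error_rate = 0.02, missing_rate = 0.05,
                    depth_model = NULL, seed = 17L)
  sim <- simulate_f1_family(cfg)
  x <- sim$matrix
  res1 <- apply_segregation_filter(x)

  set.seed(1)
  off <- which(x$samples$role == "offspring")
  perm <- c(which(x$samples$role != "offspring"), sample(off))
  res2 <- apply_segregation_filter(x[, perm])
  expect_equal(res1$assessments$assigned_type, res2$assessments$assigned_type)
  expect_equal(res1$assessments$action, res2$assessments$action)
  expect_equal(res1$assessments$chi2, res2$assessments$chi2)
})
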