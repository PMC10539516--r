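test_that("filter_markers applies call-rate and MAF thresholds inclusively", {
  # marker 1: called 5/10; marker 2: called 10/10 with MAF exactly 0.02 is
  # impossible at n=10, so use 1 alt allele in 25 calls via a wider matrix
  g1 <- matrix(c(rep(0L, 5), rep(NA_integer_, 5)), 1)
  x1 <- make_gm(g1, sexes = "M")
  expect_equal(nrow(suppressWarnings(filter_markers(
    x1, min_call_rate = 0.6, min_maf = 0))$matrix$geno), 0L)
  expect_equal(nrow(filter_markers(x1, min_call_rate = 0.5,
                                   min_maf = 0)$matrix$geno), 1L)

  # MAF boundary: 1 het among 25 called -> maf = 1/50 = 0.02, retained at 0.02
  g2 <- matrix(c(1L, rep(0L, 24)), 1)
  x2 <- make_gm(g2, sexes = "M")
  expect_equal(nrow(filter_markers(x2, min_call_rate = 0,
                                   min_maf = 0.02)$matrix$geno), 1L)
  expect_equal(nrow(suppressWarnings(filter_markers(
    x2, min_call_rate = 0, min_maf = 0.021))$matrix$geno), 0L)
})

test_that("depth window masks calls before rate/MAF evaluation", {
  g <- matrix(c(0L, 1L, 2L, 0L), 1)
  d <- matrix(c(4L, 10L, 60L, 20L), 1)
  x <- make_gm(g, depth = d, sexes = "M")
  res <- suppressWarnings(filter_markers(x, min_call_rate = 0.6, min_maf = 0,
                                         depth_min = 5L, depth_max = 50L))
  # 2 of 4 calls masked -> call rate 0.5 < 0.6 -> removed
  expect_equal(res$report$n[res$report$criterion == "depth_masked_calls"], 2L)
  expect_equal(nrow(res$matrix$geno), 0L)

  # lowering depth_max can only decrease call rates
  x_all <- make_gm(matrix(c(0L, 1L, 2L, 0L), 1), depth = d, sexes = "M")
  loose <- filter_markers(x_all, 0, 0, depth_min = 0L, depth_max = 100L)
  tight <- filter_markers(x_all, 0, 0, depth_min = 0L, depth_max = 15L)
  expect_lte(sum(!is.na(tight$matrix$geno)), sum(!is.na(loose$matrix$geno)))
})

test_that("filter_markers matches a brute-force recount on random markers", {
  x <- random_gm(100, 20, seed = 5, miss = 0.3)
  set.seed(6)
  x$depth <- matrix(rpois(2000, 12), 100, 20)
  x$depth[is.na(x$geno)] <- 0L
  x$geno[x$depth == 0L] <- NA_integer_
  res <- filter_markers(x, min_call_rate = 0.6, min_maf = 0.05,
                        depth_min = 5L, depth_max = 20L)

  # independent recount: mask first, then attribute each marker to the
  # first failed criterion
  g <- x$geno; d <- x$depth
  g[!is.na(g) & (d < 5L | d > 20L)] <- NA_integer_
  cr <- rowMeans(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE); n_called <- rowSums(!is.na(g))
  maf <- pmin(alt / (2 * n_called), 1 - alt / (2 * n_called))
  fail_cr <- cr < 0.6
  fail_maf <- !fail_cr & (is.na(maf) | maf < 0.05)
  expect_equal(res$report$n[res$report$criterion == "low_call_rate"],
               sum(fail_cr))
  expect_equal(res$report$n[res$report$criterion == "low_maf"], sum(fail_maf))
  expect_equal(nrow(res$matrix$geno), sum(!fail_cr & !fail_maf))

  # idempotence
  res2 <- filter_markers(res$matrix, min_call_rate = 0.6, min_maf = 0.05,
                         depth_min = 5L, depth_max = 20L)
  expect_equal(res2$matrix$geno, res$matrix$geno)
})

test_that("filter_samples drops strictly above the threshold, keeps parents", {
  g <- matrix(0L, 100, 3)
  g[1:41, 1] <- NA_integer_  # 41% missing
  g[1:40, 2] <- NA_integer_  # exactly 40%
  x <- make_gm(g, roles = c("offspring", "offspring", "mother"),
               sexes = "unknown")
  y <- filter_samples(x, max_missing = 0.40)
  expect_equal(y$samples$sample_id, c("s002", "s003"))

  g2 <- matrix(NA_integer_, 100, 2); g2[, 2] <- 0L
  x2 <- make_gm(g2, roles = c("mother", "offspring"), sexes = "unknown")
  expect_warning(y2 <- filter_samples(x2, 0.4), "parent")
  expect_equal(ncol(y2$geno), 2L)
})

test_that("dedupe_replicates keeps the least-missing member", {
  g <- matrix(0L, 20, 4)
  g[1:2, 1] <- NA_integer_   # 10% missing
  g[1, 2] <- NA_integer_     # 5% missing -> kept
  x <- make_gm(g, sexes = "M",
               replicate_group = c("r1", "r1", "r2", NA))
  y <- dedupe_replicates(x)
  expect_setequal(y$samples$sample_id, c("s002", "s003", "s004"))

  # 3-way group: global minimum kept
  g3 <- matrix(0L, 20, 3)
  g3[1:3, 1] <- NA_integer_; g3[1, 2] <- NA_integer_; g3[1:2, 3] <- NA_integer_
  x3 <- make_gm(g3, sexes = "M", replicate_group = "r1")
  expect_equal(dedupe_replicates(x3)$samples$sample_id, "s002")
  expect_false(anyDuplicated(
    na.omit(dedupe_replicates(x3)$samples$replicate_group)) > 0)
})

test_that("replicate_mismatch_rate recovers injected error rates", {
  # identical replicates -> all rates zero
  g <- matrix(rep(c(0L, 1L, 2L), length.out = 20), 20, 2)
  d <- matrix(10L, 20, 2)
  x <- make_gm(g, sexes = "M", depth = d, replicate_group = "r1")
  tab <- replicate_mismatch_rate(x)
  expect_true(all(tab$rate == 0))

  # 1 mismatch in 10 shared markers -> overall rate 0.1
  g2 <- cbind(rep(0L, 10), c(1L, rep(0L, 9)))
  x2 <- make_gm(g2, sexes = "M", depth = matrix(10L, 10, 2),
                replicate_group = "r1")
  tab2 <- replicate_mismatch_rate(x2, depth_bins = c(0L))
  expect_equal(tab2$rate[tab2$genotype_class == "all"], 0.1)

  # simulation: flip rate 0.2 at low depth, 0 at high depth
  set.seed(42)
  n <- 4000
  base <- sample(0:2, n, replace = TRUE)
  dep <- sample(c(3L, 30L), n, replace = TRUE)
  flip <- dep == 3L & runif(n) < 0.2
  rep2 <- ifelse(flip, (base + 1L) %% 3L, base)
  x3 <- make_gm(cbind(base, as.integer(rep2)), sexes = "M",
                depth = cbind(dep, dep), replicate_group = "r1")
  tab3 <- replicate_mismatch_rate(x3, depth_bins = c(0L, 10L))
  lo <- tab3[tab3$genotype_class == "all" & tab3$depth_bin == "[0,10)", ]
  hi <- tab3[tab3$genotype_class == "all" & tab3$depth_bin == "[10,Inf)", ]
  ci <- binom.test(lo$n_mismatch, lo$n_comparisons)$conf.int
  expect_true(ci[1] <= 0.2 && 0.2 <= ci[2])
  expect_equal(hi$rate, 0)

  # no replicates -> warning + empty
  x4 <- make_gm(matrix(0L, 2, 2), sexes = "M", depth = matrix(5L, 2, 2))
  expect_warning(t4 <- replicate_mismatch_rate(x4), "no replicate")
  expect_equal(nrow(t4), 0L)
})
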