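test_that("collapse_umis counts distinct UMIs and skips malformed rows", {
  out <- collapse_umis(data.frame(
    sample = "s1", barcode = "bcA", umi = c("AAAA", "AAAA", "CCCC")))
  expect_equal(out$count, 2L)

  empty <- collapse_umis(data.frame(sample = character(0),
                                    barcode = character(0),
                                    umi = character(0)))
  expect_equal(nrow(empty), 0L)

  expect_message(
    bad <- collapse_umis(data.frame(sample = "s1", barcode = "b",
                                    umi = c("AAAA", "AA", "CCCC"))),
    "malformed")
  expect_equal(bad$count, 2L)
  expect_equal(nrow(attr(bad, "skipped")), 1L)
})

test_that("collapse_umis matches a set-based oracle on random input", {
  set.seed(11)
  reads <- data.frame(
    sample = sample(paste0("s", 1:4), 1e4, replace = TRUE),
    barcode = sample(paste0("bc", 1:6), 1e4, replace = TRUE),
    umi = sample(sprintf("%04d", 1:200), 1e4, replace = TRUE))
  out <- collapse_umis(reads)
  oracle <- tapply(reads$umi, paste(reads$sample, reads$barcode),
                   function(u) length(unique(u)))
  expect_equal(out$count,
               as.integer(oracle[paste(out$sample, out$barcode)]),
               ignore_attr = TRUE)
})

test_that("generations follow -log2 of the dilution factor", {
  expect_equal(round(generations_from_dilution(volume = 70, into = 16000), 1),
               7.8)
  expect_equal(generations_from_dilution(1 / 2), 1.0)
  expect_equal(generations_from_dilution(1 / 1024), 10.0)
  expect_error(generations_from_dilution(0), "0, 1")
  expect_error(generations_from_dilution(1.5), "0, 1")
})

test_that("Poisson counting error follows the 1/ln2 sqrt(1/N1+1/N2) law", {
  counts <- data.frame(timepoint = 1:2, generations = c(0, 7.8),
                       barcode = rep(c("a", "b"), each = 2),
                       count = c(100, 100, 400, 400))
  counts <- data.frame(timepoint = rep(1:2, 2), generations = rep(c(0, 7.8), 2),
                       barcode = rep(c("a", "b"), each = 2),
                       count = c(100, 400, 100, 400))
  tr <- ratio_trajectory(counts, "a", "b")
  expect_equal(tr$sigma_r, sqrt(1 / tr$n1 + 1 / tr$n2) / log(2))
  ## doubling both counts shrinks sigma_r by exactly sqrt(2)
  counts2 <- counts; counts2$count <- counts2$count * 2
  tr2 <- ratio_trajectory(counts2, "a", "b")
  expect_equal(tr$sigma_r / tr2$sigma_r, rep(sqrt(2), 2))
})

test_that("slope fit recovers exact trajectories and flags zero counts", {
  tr <- data.frame(tgen = c(0, 7.8, 15.6, 23.4, 31.2))
  tr$r <- 0.1 * tr$tgen
  f <- fit_relative_fitness(tr, n_boot = 50, seed = 1)
  expect_equal(f$s, 0.1, tolerance = 1e-12)
  expect_true(f$s_min <= f$s && f$s <= f$s_max)
  expect_true(f$ci[1] <= f$s && f$s <= f$ci[2])

  const <- data.frame(tgen = c(0, 10, 20), r = 1.5)
  fc <- fit_relative_fitness(const, n_boot = 20, seed = 1)
  expect_equal(fc$s, 0)
  expect_equal(fc$s_min, 0)
  expect_equal(fc$s_max, 0)

  withzero <- data.frame(timepoint = 1:4, tgen = c(0, 5, 10, 15),
                         r = c(0, 0.5, NA, 1.5))
  fz <- fit_relative_fitness(withzero, n_boot = 0)
  expect_equal(fz$n_used, 3L)
  expect_equal(fz$dropped, 3L)
  expect_error(fit_relative_fitness(data.frame(tgen = 1, r = 1)),
               "fewer than 2")
})

test_that("noiseless synthetic pools recover injected s to machine precision", {
  for (s in c(-0.5, -0.05, 0.02, 0.5)) {
    sim <- gen_competition_counts(sim_design(
      n_strains = 2, true_s = c(0, s), depth = Inf, sigma_log2r = 0,
      seed = 3))
    tr <- ratio_trajectory(sim$counts, "bc002", "bc001")
    f <- fit_relative_fitness(tr, n_boot = 0)
    expect_lt(abs(f$s - s), 1e-9)
  }
})

test_that("design precision formula matches the two-point closed form", {
  expect_equal(design_precision(0.2, 2, 10), 0.2 * sqrt(2) / 10)
  expect_equal(design_precision(0, 5, 30), 0)
  ## the experimental design claim: sub-1% precision at 5 points, ~30 gen
  expect_lt(design_precision(0.2, 5, 31.2), 0.01)
  expect_error(design_precision(0.2, 1, 10), "n_t")
})

test_that("t-based CI covers the true slope at the nominal rate", {
  set.seed(77)
  tgen <- seq(0, 31.2, length.out = 5)
  cover <- vapply(1:500, function(i) {
    r <- 0.03 * tgen + rnorm(5, 0, 0.2)
    f <- fit_relative_fitness(data.frame(tgen = tgen, r = r), n_boot = 0)
    f$ci[1] <= 0.03 && 0.03 <= f$ci[2]
  }, logical(1))
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.98)
})

test_that("isogenic precision audit summarizes same-genotype spread", {
  expect_error(isogenic_precision(0.1), "at least 2")
  p0 <- isogenic_precision(rep(0.02, 5))
  expect_equal(p0$sigma_s, 0)
  expect_equal(p0$median_abs_s, 0.02)

  ## simulated pool at sigma_log2r = 0.2: sd of isogenic s agrees with the
  ## closed-form design precision
  set.seed(5)
  s_iso <- replicate(300, {
    sim <- gen_competition_counts(sim_design(
      n_strains = 2, true_s = 0, depth = 1e5, sigma_log2r = 0.2,
      seed = sample.int(1e8, 1)))
    fit_relative_fitness(ratio_trajectory(sim$counts, "bc002", "bc001"),
                         n_boot = 0)$s
  })
  rep <- isogenic_precision(s_iso)
  expect_lt(abs(rep$sigma_s / design_precision(0.2, 5, 31.2) - 1), 0.2)
})

test_that("background subtraction is elementwise", {
  expect_equal(subtract_background(-0.030, -0.010), -0.020)
  expect_equal(subtract_background(0.5, 0), 0.5)
  s <- c(-0.03, 0.01, 0.2)
  expect_equal(subtract_background(s, -0.01),
               vapply(s, subtract_background, numeric(1),
                      control_mean = -0.01))
})

test_that("rescue resampling test behaves at its extremes", {
  set.seed(8)
  pool <- rnorm(96)
  r <- rescue_significance(pool[1:12], pool, n_resample = 4000, seed = 2)
  expect_gt(r$p_value, 0.3)
  expect_lt(r$p_value, 0.7)

  hi <- rescue_significance(rnorm(12, 10), rnorm(96, 0),
                            n_resample = 2000, seed = 3)
  expect_lte(hi$p_value, 1 / 2000)

  shifted <- rescue_significance(rnorm(12, 3), rnorm(96, 0),
                                 n_resample = 1e4, seed = 4)
  expect_lt(shifted$p_value, 1e-3)

  foc <- rnorm(12, 1); bg <- rnorm(96)
  a <- rescue_significance(foc, bg, n_resample = 500, seed = 9)
  b <- rescue_significance(foc, bg, n_resample = 500, seed = 9)
  expect_identical(a$p_value, b$p_value)  # same seed, same p
  expect_error(rescue_significance(numeric(0), 1:5), "non-empty")
})

test_that("cross-talk rates match a cell-by-cell tally", {
  m <- matrix(0, 4, 4); expected <- matrix(FALSE, 4, 4)
  diag(expected) <- TRUE
  diag(m) <- 250
  r <- crosstalk_rates(m, expected)
  expect_equal(r, list(intra = 0, inter = 0, correct = 1))

  m2 <- m; m2[2, 1] <- 1; m2[1, 1] <- 249
  r2 <- crosstalk_rates(m2, expected)
  expect_equal(r2$intra, 1 / 1000)

  set.seed(10)
  m3 <- matrix(rpois(100, 30), 10, 10)
  e3 <- matrix(FALSE, 10, 10); e3[cbind(1:5, 1:5)] <- TRUE
  r3 <- crosstalk_rates(m3, e3)
  in_cols <- m3[, colSums(e3) > 0]
  expect_equal(r3$inter, sum(m3[, colSums(e3) == 0]) / sum(m3))
  expect_equal(r3$intra, (sum(in_cols) - sum(m3[e3])) / sum(in_cols))
  expect_equal(r3$correct, sum(m3[e3]) / sum(m3))
})

test_that("pool-level fitting reports per-genotype medians and audit", {
  sim <- gen_competition_counts(sim_design(
    n_strains = 6, true_s = c(0, 0, 0, -0.05, -0.05, 0.1),
    genotype = c("WT", "WT", "WT", "mut1", "mut1", "mut2"),
    depth = Inf, sigma_log2r = 0, seed = 4))
  pf <- fit_pool(sim$counts, reference = "WT")
  g <- pf$genotypes
  expect_equal(g$median_s[g$genotype == "mut1"], -0.05, tolerance = 1e-9)
  expect_equal(g$median_s[g$genotype == "mut2"], 0.1, tolerance = 1e-9)
  expect_equal(pf$audit$sigma_s, 0, tolerance = 1e-12)
})
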