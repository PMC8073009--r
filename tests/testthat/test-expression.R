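test_that("edge-trimmed density and rpkm follow the worked arithmetic", {
  ## 1,000-nt gene at uniform 1 read/nt; pad the track to 1e6 total reads
  ann <- toy_annotation(100, 1000)
  trk <- uniform_track(ann, 1, chrom_len = 3000)
  v <- track_counts(trk, "chr", "+")
  v[2000] <- v[2000] + (1e6 - sum(v))
  track_counts(trk, "chr", "+") <- v
  expr <- gene_density(trk, ann)
  expect_equal(expr$reads, 960)
  expect_equal(expr$density, 1)
  expect_equal(expr$rpkm, 960 / 0.96 / 1.0)  # = 1000
})

test_that("reads within the trimmed edges contribute nothing", {
  ann <- toy_annotation(100, 300)
  trk <- pileup_track(c(chr = 1000L))
  v <- track_counts(trk, "chr", "+")
  v[101:120] <- 50  # first 20 nt of the gene only
  track_counts(trk, "chr", "+") <- v
  expr <- gene_density(trk, ann)
  expect_equal(expr$density, 0)
  ## edge-trim monotonicity on a uniform gene
  trku <- uniform_track(ann, 2)
  r <- vapply(c(0, 10, 20, 40), function(tr)
    gene_density(trku, ann, edge_trim = tr)$reads, numeric(1))
  expect_true(all(diff(r) <= 0))
})

test_that("gene density equals a position-by-position loop oracle", {
  set.seed(41)
  ann <- gen_annotation(sim_annotation_config(n_genes = 15, seed = 41))
  trk <- pileup_track(c(chr = max(ann$end) + 100L))
  for (st in c("+", "-"))
    track_counts(trk, "chr", st) <-
      rpois(max(ann$end) + 100L, 2)
  expr <- gene_density(trk, ann, edge_trim = 20)
  for (i in seq_len(nrow(ann))) {
    v <- track_counts(trk, "chr", ann$strand[i])
    idx <- (ann$start[i] + 21):(ann$end[i] - 20)
    expect_equal(expr$reads[i], sum(v[idx]))
  }
})

test_that("rpkm denominator excludes rRNA and tRNA reads", {
  ann <- toy_annotation(c(100, 2000), c(1000, 1000),
                        class = c("mRNA", "rRNA"))
  trk <- uniform_track(ann, c(1, 100), chrom_len = 4000)
  expr <- gene_density(trk, ann)
  total <- attr(expr, "total_reads")
  expect_equal(total, 1000)  # the rRNA gene's reads are excluded
  expect_equal(expr$rpkm[1], 960 / 0.96 / (1000 / 1e6))
})

test_that("short genes are excluded with a flag", {
  ann <- toy_annotation(c(100, 300), c(30, 300))
  trk <- uniform_track(ann, 1)
  expr <- suppressWarnings(gene_density(trk, ann))
  expect_true(expr$excluded[1])
  expect_false(expr$excluded[2])
})

test_that("synthesis fractions normalize and split by gene size", {
  ann1 <- toy_annotation(100, 900)
  expr1 <- gene_density(uniform_track(ann1, 3), ann1)
  expect_equal(unname(synthesis_fraction(expr1)), 1)

  ann2 <- toy_annotation(c(100, 600), c(300, 700))
  expr2 <- gene_density(uniform_track(ann2, 5), ann2)
  expect_equal(unname(synthesis_fraction(expr2)), c(0.3, 0.7))

  ## matches a total-read-count oracle on random data
  set.seed(3)
  ann3 <- gen_annotation(sim_annotation_config(n_genes = 20, seed = 3))
  sim <- gen_pileup(ann3, sim_profile_config(noise = "poisson", seed = 3))
  expr3 <- gene_density(sim$track, ann3, edge_trim = 0)
  f <- synthesis_fraction(expr3)
  expect_equal(sum(f, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_equal(unname(f), expr3$reads / sum(expr3$reads), tolerance = 1e-12)
})

test_that("regulon fractions sum member fractions and report absences", {
  ann <- toy_annotation(c(100, 600, 1200), c(300, 300, 300),
                        regulon = c("sigB", "sigB", NA))
  expr <- gene_density(uniform_track(ann, c(2, 2, 4)), ann)
  expect_equal(as.numeric(regulon_fraction(expr, expr$gene_id)), 1)
  expect_equal(as.numeric(regulon_fraction(expr, character(0))), 0)
  psi <- regulon_fraction(expr, "sigB")
  expect_equal(as.numeric(psi), 0.5)
  miss <- regulon_fraction(expr, c("g01", "nope"))
  expect_equal(attr(miss, "missing"), "nope")
})

test_that("sector calibration follows phi = alpha * dpsi + phi0", {
  m <- calibration_model()
  expect_equal(calibrate_sector(0.35, m, "translation"), 0.385)
  m2 <- calibration_model(psi0_sigb = 0.02, phi0_sigb = 0.02)
  expect_equal(calibrate_sector(0.12, m2, "sigB"),
               1.41 * 0.10 + 0.02)  # dpsi = 0.10 -> 0.161
  expect_equal(calibrate_sector(m2$psi0_sigb, m2, "sigB"), m2$phi0_sigb)
  ## round trip to machine precision
  for (sec in c("translation", "sigB")) {
    psi <- 0.137
    expect_equal(calibrate_sector(calibrate_sector(psi, m2, sec), m2, sec,
                                  inverse = TRUE), psi, tolerance = 1e-12)
  }
})

test_that("TE and corrected proteome fractions are multiplicative", {
  expect_equal(translation_efficiency(300, 100), 3)
  expect_warning(te <- translation_efficiency(c(300, 10), c(100, 0)),
                 "zero mRNA")
  expect_true(is.na(te[2]))
  expect_equal(corrected_proteome_fraction(1e-3, 2, 3), 6e-3)
  m <- calibration_model()
  expect_equal(unname(m$te_fc["RF2"]), 3.0)
  expect_equal(unname(m$te_fc["RF1"]), 0.66)
})

test_that("stop codon usage is flux-weighted and sums to one", {
  ann <- toy_annotation(c(100, 600), c(300, 300),
                        stop_codon = c("UAA", "UGA"))
  ann$stop_tetra <- c("UAAA", "UGAC")
  expr <- gene_density(uniform_track(ann, 5), ann)
  u <- stop_usage(expr)
  expect_equal(unname(u), c(0.5, 0, 0.5))
  expect_equal(sum(u), 1, tolerance = 1e-9)

  ann2 <- toy_annotation(c(100, 600), c(300, 300), stop_codon = "UAA")
  u2 <- stop_usage(gene_density(uniform_track(ann2, 2), ann2))
  expect_equal(unname(u2), c(1, 0, 0))

  ut <- stop_usage(expr, by = "stop_tetra")
  expect_equal(sum(ut), 1)
})

test_that("per-gene quantities are invariant under strand reflection", {
  ann <- gen_annotation(sim_annotation_config(n_genes = 12, seed = 13))
  sim <- gen_pileup(ann, sim_profile_config(noise = "poisson", seed = 13))
  L <- sim$track$chrom_lengths[["chr"]]
  ann_f <- flip_annotation(ann, L)
  trk_f <- flip_track(sim$track)
  e1 <- gene_density(sim$track, ann)
  e2 <- gene_density(trk_f, ann_f)
  expect_equal(e1$density, e2$density)
  expect_equal(e1$rpkm, e2$rpkm)
  expect_equal(e1$synth_frac, e2$synth_frac)
})

test_that("delta-Ct quantification applies the replicate and no-RT rules", {
  ct <- data.frame(
    sample = "s1",
    target = rep(c("gyrA", "tgt"), each = 3),
    ct = c(18, 18, 18, 20.0, 20.05, 20.5),
    rt = TRUE)
  out <- qpcr_relative_level(ct)
  tgt <- out[out$target == "tgt", ]
  expect_equal(tgt$n_dropped, 1L)          # the 20.5 outlier (> 0.2 Ct)
  expect_equal(tgt$mean_ct, 20.025)
  expect_equal(tgt$level, 2^(18 - 20.025))

  ## identical Ct gives level 1; +10 Ct gives 2^-10
  ct2 <- data.frame(sample = "s", target = c("gyrA", "a", "b"),
                    ct = c(20, 20, 30), rt = TRUE)
  out2 <- qpcr_relative_level(ct2)
  expect_equal(out2$level[out2$target == "a"], 1)
  expect_equal(out2$level[out2$target == "b"], 2^-10)

  ## no-RT control too close to the RT reaction gets flagged
  ct3 <- data.frame(sample = "s", target = rep(c("gyrA", "a"), each = 2),
                    ct = c(20, 33, 22, 25), rt = c(TRUE, FALSE, TRUE, FALSE))
  out3 <- qpcr_relative_level(ct3)
  expect_false(out3$flag_rt[out3$target == "gyrA"])  # delta 13 > 7
  expect_true(out3$flag_rt[out3$target == "a"])      # delta 3 <= 7
})
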