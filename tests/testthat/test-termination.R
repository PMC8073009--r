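test_that("uniform genes give a flat metagene trace at 1", {
  ann <- toy_annotation(c(100, 1200), c(900, 900),
                        stop_codon = c("UAA", "UGA"))
  trk <- uniform_track(ann, 2)
  mg <- suppressWarnings(metagene_stop_profile(trk, ann))
  ingene <- mg[mg$offset <= 0, ]
  expect_true(all(abs(ingene$value - 1) < 1e-9))
})

test_that("queues injected on UGA genes appear only in the UGA trace", {
  ann <- gen_annotation(sim_annotation_config(
    n_genes = 60, len_range = c(600, 1200), seed = 5))
  sim <- gen_pileup(ann, sim_profile_config(
    te = 0, slowdown = c(UAA = 1, UAG = 1, UGA = 4), noise = "none",
    seed = 5))
  mg <- metagene_stop_profile(sim$track, ann)

  uga <- mg[mg$stop_codon == "UGA", ]
  qm <- queue_metric(uga)
  expect_equal(qm$queue_length, 3)  # injected peak count
  ## peaks sit at offsets ~ 0, -25, -50 and troughs between them stay flat
  at <- function(o) uga$value[uga$offset == o]
  expect_true(all(c(at(0), at(-25), at(-50)) > 2 * median(uga$value)))
  expect_lt(max(at(-12), at(-37)), 1.2)

  for (sc in c("UAA", "UAG")) {
    tr <- mg[mg$stop_codon == sc & mg$offset <= 0, ]
    expect_equal(queue_metric(tr)$queue_length, 0)
    peak_height <- max(uga$value) - 1
    expect_lt(max(abs(tr$value - 1)), 0.1 * peak_height)
  }
})

test_that("the injected ~25 nt queue period is recovered by autocorrelation", {
  ann <- gen_annotation(sim_annotation_config(
    n_genes = 80, len_range = c(600, 1200), seed = 6))
  sim <- gen_pileup(ann, sim_profile_config(
    te = 0.3, slowdown = c(UAA = 1, UAG = 1, UGA = 4), noise = "poisson",
    depth = 20, seed = 6))
  mg <- metagene_stop_profile(sim$track, ann)
  uga <- mg[mg$stop_codon == "UGA" & mg$offset <= 0, ]
  v <- uga$value - mean(uga$value)
  ac <- vapply(10:40, function(lag) {
    n <- length(v)
    sum(v[1:(n - lag)] * v[(lag + 1):n])
  }, numeric(1))
  expect_lte(abs((10:40)[which.max(ac)] - 25), 1)
})

test_that("queue metric applies threshold and period-grid semantics", {
  flat <- data.frame(offset = -150:10, value = 1)
  expect_equal(queue_metric(flat)$queue_length, 0)

  tr <- data.frame(offset = -150:10, value = 1)
  tr$value[tr$offset %in% c(0, -25, -50)] <- 5
  expect_equal(queue_metric(tr)$queue_length, 3)

  low <- data.frame(offset = -150:10, value = 1)
  low$value[low$offset %in% c(0, -25, -50)] <- 1.5  # below 2x baseline
  expect_equal(queue_metric(low)$queue_length, 0)

  expect_error(queue_metric(data.frame(offset = -30:0, value = 1)),
               "2 periods")
  ## excess-density mode gives a comparable size for well-formed queues
  ex <- queue_metric(tr, mode = "excess")
  expect_gt(ex$queue_length, 0)
})

test_that("readthrough scores follow their defining ratio", {
  ann <- toy_annotation(500, 600)
  trk <- uniform_track(ann, 2)
  rt0 <- readthrough_score(trk, ann)
  expect_equal(rt0$score, 0)  # no downstream signal

  v <- track_counts(trk, "chr", "+")
  v[(ann$end + 1):(ann$end + 60)] <- 2  # downstream = body
  track_counts(trk, "chr", "+") <- v
  rt1 <- readthrough_score(trk, ann)
  expect_equal(rt1$score, 1)

  ## invariant under uniform scaling of the whole track
  trk2 <- trk
  track_counts(trk2, "chr", "+") <- v * 7.5
  expect_equal(readthrough_score(trk2, ann)$score, rt1$score)
})

test_that("non-isolated and weakly expressed genes are excluded", {
  ann <- toy_annotation(c(100, 760, 2000), c(600, 600, 600))
  ## gap g1-g2 is 60 (> 55, isolated); g2-g3 is 640
  trk <- uniform_track(ann, c(2, 2, 0.05))
  rt <- readthrough_score(trk, ann)
  excl <- attr(rt, "excluded")
  expect_true("g03" %in% excl$gene_id[excl$reason == "low_density"])
  expect_equal(sort(rt$gene_id), c("g01", "g02"))

  ann2 <- toy_annotation(c(100, 730), c(600, 600))  # gap 30 <= 55
  rt2 <- readthrough_score(uniform_track(ann2, 2), ann2)
  expect_equal(nrow(rt2), 0)
  expect_true(all(attr(rt2, "excluded")$reason == "not_isolated"))
})

test_that("stratification groups scores and pooling is consistent", {
  rec <- data.frame(gene_id = sprintf("g%d", 1:20),
                    stop_codon = rep(c("UAA", "UGA"), each = 10),
                    stop_tetra = rep(c("UAAA", "UGAC"), each = 10),
                    score = rep(0.02, 20))
  s <- stratify_readthrough(rec)
  expect_equal(s$median, rep(0.02, 2))

  rec$score[rec$stop_tetra == "UGAC"] <- rec$score[rec$stop_tetra == "UGAC"] * 2
  st <- stratify_readthrough(rec, by = "stop_tetra")
  ratio <- st$median[st$group == "UGAC"] / st$median[st$group == "UAAA"]
  expect_equal(ratio, 2, tolerance = 0.15)

  ## pooling the groups reproduces the ungrouped median
  expect_equal(median(rec$score),
               median(unlist(split(rec$score, rec$stop_codon))))
})

test_that("metagene traces are invariant under strand reflection", {
  ann <- gen_annotation(sim_annotation_config(
    n_genes = 40, len_range = c(600, 1000), seed = 8))
  sim <- gen_pileup(ann, sim_profile_config(
    te = 0.2, slowdown = c(UAA = 1, UAG = 1, UGA = 3), noise = "none",
    seed = 8))
  L <- sim$track$chrom_lengths[["chr"]]
  mg1 <- suppressWarnings(metagene_stop_profile(sim$track, ann))
  mg2 <- metagene_stop_profile(flip_track(sim$track),
                               flip_annotation(ann, L))
  expect_equal(mg1$value, mg2$value)
  expect_equal(mg1$n, mg2$n)
})

test_that("the median trace resists rescaling and minority corruption", {
  ann <- gen_annotation(sim_annotation_config(
    n_genes = 30, len_range = c(600, 1000), seed = 9,
    stop_freq = c(UAA = 1, UAG = 0, UGA = 0)))
  sim <- gen_pileup(ann, sim_profile_config(te = 0, noise = "none", seed = 9))
  mg1 <- suppressWarnings(metagene_stop_profile(sim$track, ann))

  ## rescaling one gene's whole trace leaves the median trace unchanged
  trk <- sim$track
  g <- ann[1, ]
  v <- track_counts(trk, "chr", g$strand)
  idx <- (g$start + 1):(g$end)
  v[idx] <- v[idx] * 50
  track_counts(trk, "chr", g$strand) <- v
  mg2 <- suppressWarnings(metagene_stop_profile(trk, ann))
  ingene <- mg1$offset <= 0
  expect_equal(mg1$value[ingene], mg2$value[ingene], tolerance = 1e-9)
})
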