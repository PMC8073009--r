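test_that("pair extraction assigns distances and overlap classes", {
  ## g1 [100, 700) UGA; g2 starts at 696: d = -4, A-UGA
  ann <- toy_annotation(c(100, 696), c(600, 600),
                        stop_codon = c("UGA", "UAA"))
  p <- extract_pairs(ann)
  expect_equal(p$d, -4L)
  expect_equal(p$class, "A_UGA")
  expect_equal(p$up_id, "g01")

  ann2 <- toy_annotation(c(100, 710), c(600, 600))
  p2 <- extract_pairs(ann2)
  expect_equal(p2$d, 10L)
  expect_equal(p2$class, "none")

  ## opposite strands are not pairs; nested genes are skipped
  ann3 <- toy_annotation(c(100, 710), c(600, 600), strand = c("+", "-"))
  expect_equal(nrow(extract_pairs(ann3)), 0L)
  ann4 <- toy_annotation(c(100, 150, 800), c(600, 90, 300))
  p4 <- extract_pairs(ann4)
  expect_equal(attr(p4, "skipped"), "g02")
  expect_equal(p4$up_id, "g01")
  expect_equal(p4$down_id, "g03")
})

test_that("pair list equals a brute-force adjacent scan", {
  ann <- gen_annotation(sim_annotation_config(n_genes = 300, seed = 17))
  p <- extract_pairs(ann, genome = NULL)
  ann_s <- ann[order(ann$start), ]
  brute <- list()
  for (i in seq_len(nrow(ann_s) - 1)) {
    if (ann_s$strand[i] != ann_s$strand[i + 1]) next
    if (ann_s$end[i + 1] <= ann_s$end[i]) next
    up <- if (ann_s$strand[i] == "+") i else i + 1L
    dn <- if (ann_s$strand[i] == "+") i + 1L else i
    brute[[length(brute) + 1L]] <- data.frame(
      up_id = ann_s$gene_id[up], down_id = ann_s$gene_id[dn],
      d = ann_s$start[i + 1] - ann_s$end[i])
  }
  brute <- do.call(rbind, brute)
  expect_equal(p[, c("up_id", "down_id", "d")], brute,
               ignore_attr = TRUE)
})

test_that("pair geometry is invariant under reverse complementation", {
  ann <- gen_annotation(sim_annotation_config(n_genes = 200, seed = 18))
  L <- max(ann$end) + 200
  p1 <- extract_pairs(ann, genome = NULL)
  p2 <- extract_pairs(flip_annotation(ann, L), genome = NULL)
  k1 <- p1[order(p1$up_id), c("up_id", "down_id", "d", "up_stop", "class")]
  k2 <- p2[order(p2$up_id), c("up_id", "down_id", "d", "up_stop", "class")]
  expect_equal(k1, k2, ignore_attr = TRUE)
})

test_that("stoichiometry fold-changes respect the read filter", {
  ann <- toy_annotation(c(100, 760, 1500, 2160), c(600, 600, 600, 600))
  pairs <- extract_pairs(ann)
  e_ref <- gene_density(uniform_track(ann, c(2, 2, 2, 0.01)), ann)
  e_pert <- gene_density(uniform_track(ann, c(2, 1, 2, 0.01)), ann)

  fc <- pair_fc(e_ref, e_pert, pairs)
  ## pair g3-g4 dropped: g4 has < 10 reads
  expect_false(any(fc$down_id == "g04"))
  expect_true("low_reads" %in% attr(fc, "excluded")$reason)
  expect_equal(fc$fc[fc$down_id == "g02"], 0.5)
  expect_equal(fc$fc[fc$down_id == "g03"], 2)  # upstream halved

  same <- pair_fc(e_ref, e_ref, pairs)
  expect_true(all(same$fc == 1))

  ## raising min_reads never adds pairs
  n_by_filter <- vapply(c(10, 100, 1000), function(m)
    nrow(pair_fc(e_ref, e_pert, pairs, min_reads = m)), numeric(1))
  expect_true(all(diff(n_by_filter) <= 0))
})

test_that("reshuffle test reports the add-one corrected extreme case", {
  eff <- data.frame(up_stop = rep(c("UGA", "UAA"), c(10, 30)),
                    fc = rep(c(0.5, 1.0), c(10, 30)))
  r <- reshuffle_test(eff, focal = "UGA", n_perm = 999, seed = 1)
  expect_equal(r$effect, 0.5)
  expect_equal(r$p_value, 1 / 1000)

  expect_error(reshuffle_test(eff, focal = "UAG"), "empty")
  expect_error(reshuffle_test(data.frame(up_stop = "UAA", fc = 1),
                              focal = "UAA"), "2 stop classes")
})

test_that("effect size and p are invariant to a global fold-change scale", {
  set.seed(19)
  eff <- data.frame(up_stop = sample(c("UAA", "UAG", "UGA"), 100, TRUE),
                    fc = exp(rnorm(100, 0, 0.2)))
  r1 <- reshuffle_test(eff, "UGA", n_perm = 500, seed = 7)
  eff2 <- eff; eff2$fc <- eff2$fc * 13
  r2 <- reshuffle_test(eff2, "UGA", n_perm = 500, seed = 7)
  expect_equal(r1$effect, r2$effect, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value)
  ## seed reproducibility
  r3 <- reshuffle_test(eff, "UGA", n_perm = 500, seed = 7)
  expect_identical(r1$p_value, r3$p_value)
})

test_that("an injected UGA stoichiometry effect is recovered end to end", {
  set.seed(23)
  n <- 300
  lab <- sample(c("UAA", "UAG", "UGA"), n, TRUE, prob = c(0.6, 0.16, 0.24))
  fc <- exp(rnorm(n, 0, 0.2)) * ifelse(lab == "UGA", 0.82, 1)
  r <- reshuffle_test(data.frame(up_stop = lab, fc = fc), "UGA",
                      n_perm = 2000, seed = 2)
  expect_equal(r$effect, 0.82, tolerance = 0.12)
  expect_lt(r$p_value, 0.01)
})

test_that("per-gene fold-changes are median-normalized by construction", {
  ann <- toy_annotation(c(100, 760, 1500), c(600, 600, 600),
                        stop_codon = c("UAA", "UAG", "UGA"))
  e_ref <- gene_density(uniform_track(ann, 2), ann)
  e2 <- gene_density(uniform_track(ann, 4), ann)  # uniform 2x scaling
  g <- gene_fc_by_stop(e_ref, e2)
  expect_equal(g$fc, rep(1, 3))
  gid <- gene_fc_by_stop(e_ref, e_ref)
  expect_equal(gid$fc, rep(1, 3))
})

test_that("hit clustering matches connected components and filters", {
  hits <- data.frame(species = "sp1", label = c("rsbV", "rsbW", "sigB"),
                     chrom = "c", start = c(0, 350, 700),
                     end = c(300, 650, 1000), strand = "+")
  call <- cluster_hits(hits, max_gap = 100,
                       required_labels = c("rsbV", "rsbW", "sigB"))
  expect_equal(nrow(call), 1L)
  expect_equal(call$n_hits, 3L)

  hits2 <- hits; hits2$start[3] <- 800; hits2$end[3] <- 1100  # gap 150
  expect_equal(nrow(cluster_hits(hits2, max_gap = 100,
                                 required_labels = hits$label)), 0L)

  ## random intervals: clusters equal brute-force connected components
  set.seed(24)
  st <- sort(sample.int(5000, 40))
  hp <- data.frame(species = "sp", label = "x", chrom = "c",
                   start = st, end = st + sample.int(80, 40, TRUE),
                   strand = "+")
  cl <- cluster_hits(hp, max_gap = 50, required_labels = "x")
  ## brute force: adjacency if gap <= 50 after sorting
  hp <- hp[order(hp$start), ]
  comp <- cumsum(c(1, (hp$start[-1] - head(hp$end, -1)) > 50))
  ## one call per species: the first complete cluster
  expect_equal(call$labels, "rsbV,rsbW,sigB")
  expect_equal(cl$n_hits, as.integer(table(comp)[1]))

  ## order and orientation filters
  hits3 <- hits; hits3$strand <- c("+", "+", "-")
  expect_equal(nrow(cluster_hits(hits3, 100, hits$label,
                                 require_cooriented = TRUE)), 0L)
  hits4 <- hits[c(2, 1, 3), ]; hits4$label <- c("rsbV", "rsbW", "sigB")
  expect_equal(nrow(cluster_hits(hits4, 100,
                                 c("rsbV", "rsbW", "sigB"),
                                 require_order = TRUE)), 0L)
})
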