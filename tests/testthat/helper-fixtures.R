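# shared fixture builders (all synthetic, generated in code)

# a hand-built annotation on one chromosome, plus strand unless stated
toy_annotation <- function(starts, lengths, strand = "+",
                           stop_codon = "UAA", class = "mRNA",
                           regulon = NA_character_) {
  n <- length(starts)
  ann <- data.frame(
    gene_id = sprintf("g%02d", seq_len(n)), chrom = "chr",
    strand = rep_len(strand, n), start = as.integer(starts),
    end = as.integer(starts + lengths), class = rep_len(class, n),
    stop_codon = rep_len(stop_codon, n),
    stop_tetra = paste0(rep_len(stop_codon, n), "A"),
    regulon = rep_len(regulon, n), stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  ann
}

# a track with given per-gene uniform density (transcription-strand aware)
uniform_track <- function(ann, density, chrom_len = max(ann$end) + 500,
                          mapping = "center") {
  trk <- pileup_track(c(chr = as.integer(chrom_len)), mapping = mapping)
  density <- rep_len(density, nrow(ann))
  for (i in seq_len(nrow(ann))) {
    v <- track_counts(trk, "chr", ann$strand[i])
    v[(ann$start[i] + 1):ann$end[i]] <-
      v[(ann$start[i] + 1):ann$end[i]] + density[i]
    track_counts(trk, "chr", ann$strand[i]) <- v
  }
  trk
}

# mirror an annotation + track through the chromosome midpoint
# (reverse-complement both): per-gene quantities must be invariant
flip_annotation <- function(ann, chrom_len) {
  out <- ann
  out$start <- chrom_len - ann$end
  out$end <- chrom_len - ann$start
  out$strand <- ifelse(ann$strand == "+", "-", "+")
  attr(out, "genome") <- NULL
  out
}

flip_track <- function(track) {
  out <- track
  for (ch in names(track$counts)) {
    out$counts[[ch]][["+"]] <- rev(track$counts[[ch]][["-"]])
    out$counts[[ch]][["-"]] <- rev(track$counts[[ch]][["+"]])
  }
  out
}

# lazily computed, shared across test files: p-values of the stop-codon
# reshuffling test under a label-neutral null (2,000 simulated pair sets)
.null_cache <- new.env(parent = emptyenv())
null_reshuffle_pvals <- function(n_sets = 2000, n_pairs = 120,
                                 n_perm = 999, seed = 20260101) {
  key <- paste(n_sets, n_pairs, n_perm, seed, sep = "_")
  if (!is.null(.null_cache[[key]])) return(.null_cache[[key]])
  set.seed(seed)
  p <- vapply(seq_len(n_sets), function(i) {
    eff <- data.frame(
      up_stop = sample(c("UAA", "UAG", "UGA"), n_pairs, replace = TRUE,
                       prob = c(0.6, 0.16, 0.24)),
      fc = exp(rnorm(n_pairs, 0, 0.2)))
    reshuffle_test(eff, focal = "UGA", n_perm = n_perm)$p_value
  }, numeric(1))
  .null_cache[[key]] <- p
  p
}
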