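#' Adjacent co-directional gene pairs with stop-codon context
#'
#' Pairs each gene with its nearest co-directional neighbour (adjacent in
#' genomic order), assigning the signed intergenic distance in the
#' transcription sense: \code{d} = (downstream start) - (end of upstream
#' stop), so the shared A-UGA start/stop punctuation yields \code{d = -4}.
#' Genes on opposite strands are not pairs, and nested genes are skipped with
#' a flag. The overlap class is \code{"A_UGA"} for a -4 nt overlap with
#' upstream stop UGA (verified against the genome sequence when available),
#' \code{"other_overlap"} for any other \code{d < 0}, else \code{"none"}.
#'
#' @param ann a \code{gene_annotation} (coordinate-sorted or not).
#' @param genome optional \code{Biostrings::DNAStringSet}; defaults to the
#'   genome attached to \code{ann}.
#' @return data.frame of class \code{gene_pairs}: \code{up_id},
#'   \code{down_id}, \code{strand}, \code{d}, \code{up_stop},
#'   \code{up_tetra}, \code{down_stop}, \code{class}. Skipped nested genes
#'   are in attribute \code{"skipped"}.
#' @export
extract_pairs <- function(ann, genome = genome_of(ann)) {
  g <- ann[order(ann$chrom, ann$start, ann$end), , drop = FALSE]
  res <- list(); skipped <- character(0)
  for (ch in unique(g$chrom)) {
    gc <- g[g$chrom == ch, , drop = FALSE]
    n <- nrow(gc)
    if (n < 2) next
    i <- 1L
    while (i < n) {
      j <- i + 1L
      ## nested gene: contained in the previous interval
      if (gc$end[j] <= gc$end[i]) {
        skipped <- c(skipped, gc$gene_id[j])
        gc <- gc[-j, , drop = FALSE]; n <- n - 1L
        next
      }
      if (gc$strand[i] == gc$strand[j]) {
        d <- gc$start[j] - gc$end[i]
        if (gc$strand[i] == "+") { up <- i; dn <- j } else { up <- j; dn <- i }
        cls <- if (d >= 0) "none"
          else if (d == -4 && gc$stop_codon[up] == "UGA" &&
                   .is_auga(gc, up, dn, genome)) "A_UGA"
          else "other_overlap"
        res[[length(res) + 1L]] <- data.frame(
          up_id = gc$gene_id[up], down_id = gc$gene_id[dn],
          strand = gc$strand[i], d = d,
          up_stop = gc$stop_codon[up],
          up_tetra = gc$stop_tetra[up] %||% NA_character_,
          down_stop = gc$stop_codon[dn], class = cls,
          stringsAsFactors = FALSE)
      }
      i <- i + 1L
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(up_id = character(0), down_id = character(0),
               strand = character(0), d = integer(0),
               up_stop = character(0), up_tetra = character(0),
               down_stop = character(0), class = character(0))
  rownames(out) <- NULL
  class(out) <- c("gene_pairs", "data.frame")
  attr(out, "skipped") <- skipped
  out
}

## verify the 4-nt A-UGA junction motif on the genome (ATGA in the
## transcription sense); without a genome, trust the -4/UGA geometry.
.is_auga <- function(gc, up, dn, genome) {
  if (is.null(genome)) return(TRUE)
  ch <- genome[[gc$chrom[up]]]
  if (gc$strand[up] == "+") {
    mot <- as.character(Biostrings::subseq(ch, gc$end[up] - 3L, gc$end[up]))
    identical(mot, "ATGA")
  } else {
    mot <- as.character(Biostrings::subseq(ch, gc$start[up] + 1L,
                                           gc$start[up] + 4L))
    identical(mot, "TCAT")
  }
}

#' Stoichiometry fold-changes for gene pairs between two conditions
#'
#' For each pair, the expression stoichiometry is the downstream-to-upstream
#' density ratio \code{r = density_down / density_up}; the reported effect is
#' the fold-change \code{FC = r_perturbed / r_reference}. Pairs are only
#' scored when both genes have more than \code{min_reads} reads in both
#' conditions; exclusions carry reason codes.
#'
#' @param expr_ref,expr_pert \code{expression_table}s for the reference and
#'   perturbed conditions.
#' @param pairs a \code{\link{extract_pairs}} result.
#' @param min_reads read filter, strictly greater-than (default 10).
#' @return data.frame of class \code{pair_effects}: pair columns plus
#'   \code{r_ref}, \code{r_pert}, \code{fc}. Attribute \code{"excluded"}
#'   lists (up_id, down_id, reason).
#' @export
pair_fc <- function(expr_ref, expr_pert, pairs, min_reads = 10) {
  look <- function(expr, id, what) {
    i <- match(id, expr$gene_id)
    if (is.na(i)) NA_real_ else expr[[what]][i]
  }
  res <- list(); excl <- list()
  for (k in seq_len(nrow(pairs))) {
    ids <- c(pairs$up_id[k], pairs$down_id[k])
    reads <- c(look(expr_ref, ids[1], "reads"), look(expr_ref, ids[2], "reads"),
               look(expr_pert, ids[1], "reads"), look(expr_pert, ids[2], "reads"))
    if (anyNA(reads)) {
      excl[[length(excl) + 1L]] <- c(ids, "missing_gene"); next
    }
    if (any(reads <= min_reads)) {
      excl[[length(excl) + 1L]] <- c(ids, "low_reads"); next
    }
    r_ref <- look(expr_ref, ids[2], "density") / look(expr_ref, ids[1], "density")
    r_pert <- look(expr_pert, ids[2], "density") / look(expr_pert, ids[1], "density")
    res[[length(res) + 1L]] <- cbind(pairs[k, , drop = FALSE],
      data.frame(r_ref = r_ref, r_pert = r_pert, fc = r_pert / r_ref))
  }
  out <- if (length(res)) do.call(rbind, res) else
    cbind(pairs[0, ], data.frame(r_ref = numeric(0), r_pert = numeric(0),
                                 fc = numeric(0)))
  rownames(out) <- NULL
  class(out) <- c("pair_effects", "data.frame")
  attr(out, "excluded") <- if (length(excl))
    data.frame(up_id = vapply(excl, `[`, "", 1),
               down_id = vapply(excl, `[`, "", 2),
               reason = vapply(excl, `[`, "", 3), stringsAsFactors = FALSE)
  else data.frame(up_id = character(0), down_id = character(0),
                  reason = character(0))
  out
}

#' Stop-codon reshuffling permutation test
#'
#' The observed effect size is the median fold-change of the focal stop
#' class divided by the median fold-change of the reference class (UAA, the
#' release-factor-agnostic stop). Stop-codon labels are randomly permuted
#' across pairs; the p-value is the add-one-corrected fraction of
#' reshufflings whose effect size is strictly more pronounced (smaller
#' ratio) than observed: \eqn{p = (1 + \#\{e^* < e\}) / (1 + n_{perm})}.
#'
#' @param effects data.frame with a fold-change column \code{fc} and a label
#'   column (default \code{up_stop}; use \code{stop} or any factor via
#'   \code{label_col}).
#' @param focal focal stop class (e.g. \code{"UGA"} for RF2 depletion).
#' @param reference reference class (default \code{"UAA"}).
#' @param n_perm number of reshufflings (default 1e4).
#' @param seed integer seed.
#' @param label_col name of the label column.
#' @return object of class \code{reshuffle_result}: \code{effect},
#'   \code{p_value}, \code{n_perm}, class medians and sizes.
#' @export
reshuffle_test <- function(effects, focal, reference = "UAA", n_perm = 1e4,
                           seed = NULL, label_col = "up_stop") {
  stopifnot("fc" %in% names(effects), label_col %in% names(effects))
  lab <- as.character(effects[[label_col]])
  fc <- effects$fc
  keep <- is.finite(fc) & !is.na(lab)
  lab <- lab[keep]; fc <- fc[keep]
  if (length(unique(lab)) < 2) stop("need at least 2 stop classes")
  nf <- sum(lab == focal); nr <- sum(lab == reference)
  if (nf == 0) stop("focal class '", focal, "' is empty")
  if (nr == 0) stop("reference class '", reference, "' is empty")

  obs <- median(fc[lab == focal]) / median(fc[lab == reference])
  .check_seed(seed)
  n <- length(fc)
  count <- 0L
  for (b in seq_len(n_perm)) {
    pl <- lab[sample.int(n)]
    e <- median(fc[pl == focal]) / median(fc[pl == reference])
    if (e < obs) count <- count + 1L  # strictly more pronounced (smaller)
  }
  structure(list(effect = obs, p_value = (1 + count) / (1 + n_perm),
                 n_perm = n_perm, focal = focal, reference = reference,
                 n_focal = nf, n_reference = nr,
                 median_focal = median(fc[lab == focal]),
                 median_reference = median(fc[lab == reference]),
                 seed = seed),
            class = "reshuffle_result")
}

#' @export
print.reshuffle_result <- function(x, ...) {
  cat(sprintf("Stop-codon reshuffling test: FC_%s = %.3f (vs %s), p = %.3g",
              x$focal, x$effect, x$reference, x$p_value))
  cat(sprintf("  [%d vs %d pairs, %d reshufflings]\n",
              x$n_focal, x$n_reference, x$n_perm))
  invisible(x)
}

#' Per-gene expression fold-changes stratified by the gene's own stop codon
#'
#' Computes per-gene fold-changes between a perturbed and a reference
#' condition (genes with more than \code{min_reads} reads in both),
#' normalizes by the global median fold-change, and attaches each gene's stop
#' codon; the same reshuffling test applies (with
#' \code{label_col = "stop"}).
#'
#' @param expr_ref,expr_pert \code{expression_table}s.
#' @param min_reads read filter, strictly greater-than (default 10).
#' @return data.frame: \code{gene_id}, \code{stop}, \code{fc} (normalized).
#' @export
gene_fc_by_stop <- function(expr_ref, expr_pert, min_reads = 10) {
  m <- merge(expr_ref[, c("gene_id", "stop_codon", "reads", "rpkm")],
             expr_pert[, c("gene_id", "reads", "rpkm")],
             by = "gene_id", suffixes = c("_ref", "_pert"))
  m <- m[!is.na(m$reads_ref) & !is.na(m$reads_pert) &
           m$reads_ref > min_reads & m$reads_pert > min_reads &
           !is.na(m$stop_codon), , drop = FALSE]
  fc <- m$rpkm_pert / m$rpkm_ref
  fc <- fc / median(fc)
  data.frame(gene_id = m$gene_id, stop = m$stop_codon, fc = fc,
             stringsAsFactors = FALSE)
}

#' Cluster homology hits into candidate operons
#'
#' Single-linkage clustering of hit intervals within a species: hits whose
#' start-to-end gap is at most \code{max_gap} are connected. Clusters are
#' retained only if they contain all \code{required_labels}; optional filters
#' demand co-orientation and a conserved label order along the cluster. At
#' most one call per species is returned (the cluster with the highest
#' \code{score} column if present, otherwise the first).
#'
#' @param hits data.frame with columns \code{species}, \code{label},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand} (optional
#'   \code{score}).
#' @param max_gap permissive spatial cutoff in bp (default 100).
#' @param required_labels labels a cluster must contain.
#' @param require_cooriented demand a single strand within the cluster.
#' @param require_order demand labels in the given order along the strand.
#' @return data.frame of calls: one row per retained species cluster with
#'   columns \code{species}, \code{chrom}, \code{start}, \code{end},
#'   \code{strand}, \code{n_hits}, \code{labels}.
#' @export
cluster_hits <- function(hits, max_gap = 100,
                         required_labels = unique(hits$label),
                         require_cooriented = FALSE, require_order = FALSE) {
  calls <- list()
  for (sp in unique(hits$species)) {
    h <- hits[hits$species == sp, , drop = FALSE]
    cand <- list()
    for (ch in unique(h$chrom)) {
      hc <- h[h$chrom == ch, , drop = FALSE]
      hc <- hc[order(hc$start), , drop = FALSE]
      cl <- cumsum(c(1, (hc$start[-1] - head(hc$end, -1)) > max_gap))
      for (k in unique(cl)) {
        sub <- hc[cl == k, , drop = FALSE]
        if (!all(required_labels %in% sub$label)) next
        if (require_cooriented && length(unique(sub$strand)) > 1) next
        if (require_order) {
          ord <- sub$label[order(sub$start)]
          if (all(sub$strand == "-")) ord <- rev(ord)
          if (!identical(ord[ord %in% required_labels], required_labels))
            next
        }
        cand[[length(cand) + 1L]] <- data.frame(
          species = sp, chrom = ch, start = min(sub$start),
          end = max(sub$end), strand = paste(unique(sub$strand),
                                             collapse = "/"),
          n_hits = nrow(sub),
          labels = paste(sub$label[order(sub$start)], collapse = ","),
          score = if ("score" %in% names(sub)) max(sub$score) else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      best <- if (all(is.na(cand$score))) 1 else which.max(cand$score)
      calls[[length(calls) + 1L]] <- cand[best, , drop = FALSE]
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(species = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               n_hits = integer(0), labels = character(0),
               score = numeric(0))
  rownames(out) <- NULL
  out
}
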