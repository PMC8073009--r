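#' Stop-codon-aligned metagene traces
#'
#' For each stop codon class, retains genes expressed to at least
#' \code{min_density} footprint reads/nt, normalizes each gene's density
#' trace by its mean density over the first half of the gene (transcription
#' sense), aligns traces at the stop codon, and takes the per-offset median
#' across genes. Offset 0 is the last nucleotide of the stop codon; negative
#' offsets are upstream (inside the gene), positive offsets downstream.
#'
#' Genes shorter than twice the upstream window are excluded so that the
#' normalization region (first half of the gene) cannot overlap the
#' stop-proximal window.
#'
#' @param track a center-mapped footprint \code{\link{pileup_track}}.
#' @param ann a \code{gene_annotation}.
#' @param min_density minimum mean footprint density (reads/nt), default 0.5.
#' @param window integer length-2, offsets spanned (default
#'   \code{c(-150, 60)}).
#' @return data.frame of class \code{metagene_trace}: \code{stop_codon},
#'   \code{offset}, \code{value} (median normalized density), \code{n}
#'   (genes contributing). Classes with no qualifying genes are absent, with
#'   a warning.
#' @export
metagene_stop_profile <- function(track, ann, min_density = 0.5,
                                  window = c(-150, 60)) {
  stopifnot(inherits(track, "pileup_track"), window[1] < 0, window[2] >= 0)
  up <- -window[1]
  genes <- ann[ann$class == "mRNA" & (ann$end - ann$start) >= 2 * up &
                 !is.na(ann$stop_codon), , drop = FALSE]
  offsets <- window[1]:window[2]
  res <- list()
  for (sc in STOP_CODONS) {
    sub <- genes[genes$stop_codon == sc, , drop = FALSE]
    mat <- NULL
    for (i in seq_len(nrow(sub))) {
      L <- sub$end[i] - sub$start[i]
      tr <- .gene_trace(track, sub$chrom[i], sub$strand[i],
                        sub$start[i], sub$end[i],
                        from = 0, to = L + window[2])
      if (mean(tr[1:L], na.rm = TRUE) < min_density) next
      norm <- mean(tr[1:(L %/% 2)], na.rm = TRUE)
      if (!is.finite(norm) || norm <= 0) next
      ## offset 0 = last nt of the stop codon = transcription position L - 1
      sel <- (L - 1) + offsets + 1L
      vals <- rep(NA_real_, length(offsets))
      ok <- sel >= 1 & sel <= length(tr)
      vals[ok] <- tr[sel[ok]] / norm
      mat <- rbind(mat, vals)
    }
    if (is.null(mat)) {
      warning("no qualifying genes for stop codon ", sc)
      next
    }
    res[[sc]] <- data.frame(
      stop_codon = sc, offset = offsets,
      value = apply(mat, 2, median, na.rm = TRUE),
      n = colSums(!is.na(mat)), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("metagene_trace", "data.frame")
  out
}

#' Ribosome queue size from a metagene trace
#'
#' Counts successive stop-proximal peaks at approximately one footprint
#' spacing, the signature of ribosomes queuing behind a slowly terminating
#' ribosome. Candidate peak positions are offsets \eqn{0, -p, -2p, \dots}
#' (period \eqn{p \approx 25} nt); the maximum within \code{tol} nt of each
#' grid position counts as a peak if it exceeds \code{threshold} times the
#' baseline (the median of the trace's upstream flank). Counting stops at the
#' first missing peak.
#'
#' @param trace a \code{metagene_trace} restricted to one stop class, or any
#'   data.frame with \code{offset} and \code{value}.
#' @param period queue spacing in nt (default 25).
#' @param threshold peak height multiple of baseline (default 2).
#' @param tol matching tolerance around the period grid (default 5 nt).
#' @param mode \code{"peaks"} (count of queued ribosomes, default) or
#'   \code{"excess"} (integrated excess density over baseline divided by one
#'   footprint's worth of density, an alternative queue-size estimate).
#' @return list: \code{queue_length}, \code{amplitudes}, \code{baseline},
#'   \code{mode}.
#' @export
queue_metric <- function(trace, period = 25, threshold = 2, tol = 5,
                         mode = c("peaks", "excess")) {
  mode <- match.arg(mode)
  if ("stop_codon" %in% names(trace) &&
      length(unique(trace$stop_codon)) > 1)
    stop("give a single stop class; subset the trace first")
  off <- trace$offset; val <- trace$value
  span <- -min(off)
  if (span < 2 * period) stop("trace shorter than 2 periods upstream")
  flank <- val[off < -(span / 2) & off < 0]
  baseline <- median(flank, na.rm = TRUE)
  if (!is.finite(baseline) || baseline <= 0) baseline <- 1
  if (mode == "excess") {
    excess <- pmax(val[off <= 0] - baseline, 0)
    return(list(queue_length = sum(excess, na.rm = TRUE) / (baseline * period),
                amplitudes = numeric(0), baseline = baseline, mode = mode))
  }
  amps <- numeric(0)
  k <- 0
  repeat {
    center <- -k * period
    if (center - tol < min(off)) break
    sel <- off >= center - tol & off <= center + tol
    pk <- suppressWarnings(max(val[sel], na.rm = TRUE))
    if (!is.finite(pk) || pk <= threshold * baseline) break
    amps <- c(amps, pk)
    k <- k + 1
  }
  list(queue_length = length(amps), amplitudes = amps, baseline = baseline,
       mode = mode)
}

#' Stop-codon readthrough scores
#'
#' The readthrough score of a gene is the ratio of mean footprint density in
#' a window downstream of the stop codon (+5 to +45 nt by default) to the
#' mean density inside the gene body. Only isolated genes - nearest
#' co-directional neighbours more than \code{isolation} nt away on both
#' sides - with body density above \code{min_density} are scored; excluded
#' genes are reported with reason codes. Scores above 1 (unannotated ORFs,
#' repeats) are retained but flagged.
#'
#' @param track footprint \code{\link{pileup_track}}.
#' @param ann a \code{gene_annotation}.
#' @param isolation minimum distance (nt) to the nearest co-directional
#'   neighbour (default 55).
#' @param window downstream window in nt after the stop (default
#'   \code{c(5, 45)}, inclusive).
#' @param min_density minimum body density (reads/nt), default 0.1.
#' @param edge_trim body trim in nt (default 20).
#' @return data.frame of class \code{readthrough_records}: \code{gene_id},
#'   \code{stop_codon}, \code{stop_tetra}, \code{body_density},
#'   \code{down_density}, \code{score}, \code{flag_gt1}. Excluded genes are
#'   in attribute \code{"excluded"} (gene_id, reason).
#' @export
readthrough_score <- function(track, ann, isolation = 55, window = c(5, 45),
                              min_density = 0.1, edge_trim = 20) {
  genes <- ann[ann$class == "mRNA", , drop = FALSE]
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  n <- nrow(genes)
  res <- list(); excl <- list()
  for (i in seq_len(n)) {
    L <- genes$end[i] - genes$start[i]
    ## nearest co-directional neighbour distance (gap between intervals;
    ## overlapping neighbours count as distance <= 0)
    same <- which(genes$chrom == genes$chrom[i] &
                    genes$strand == genes$strand[i])
    same <- setdiff(same, i)
    dmin <- Inf
    if (length(same)) {
      gap_r <- genes$start[same] - genes$end[i]
      gap_l <- genes$start[i] - genes$end[same]
      dmin <- min(pmax(gap_r, gap_l))  # overlap gives both negative
    }
    if (dmin <= isolation) {
      excl[[length(excl) + 1L]] <- c(genes$gene_id[i], "not_isolated"); next
    }
    if (L <= 2 * edge_trim) {
      excl[[length(excl) + 1L]] <- c(genes$gene_id[i], "too_short"); next
    }
    body <- .gene_trace(track, genes$chrom[i], genes$strand[i],
                        genes$start[i], genes$end[i],
                        from = edge_trim, to = L - edge_trim)
    bd <- mean(body, na.rm = TRUE)
    if (!is.finite(bd) || bd <= min_density) {
      excl[[length(excl) + 1L]] <- c(genes$gene_id[i], "low_density"); next
    }
    down <- .gene_trace(track, genes$chrom[i], genes$strand[i],
                        genes$start[i], genes$end[i],
                        from = L + window[1] - 1, to = L + window[2])
    dd <- mean(down, na.rm = TRUE)
    score <- dd / bd
    res[[length(res) + 1L]] <- data.frame(
      gene_id = genes$gene_id[i], stop_codon = genes$stop_codon[i],
      stop_tetra = genes$stop_tetra[i] %||% NA_character_,
      body_density = bd, down_density = dd, score = score,
      flag_gt1 = score > 1, stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(gene_id = character(0), stop_codon = character(0),
               stop_tetra = character(0), body_density = numeric(0),
               down_density = numeric(0), score = numeric(0),
               flag_gt1 = logical(0))
  rownames(out) <- NULL
  class(out) <- c("readthrough_records", "data.frame")
  attr(out, "excluded") <- if (length(excl))
    data.frame(gene_id = vapply(excl, `[`, "", 1),
               reason = vapply(excl, `[`, "", 2), stringsAsFactors = FALSE)
  else data.frame(gene_id = character(0), reason = character(0))
  out
}

#' Group readthrough scores by stop codon or tetranucleotide
#'
#' @param records a \code{\link{readthrough_score}} result.
#' @param by \code{"stop_codon"} or \code{"stop_tetra"}.
#' @param min_n groups smaller than this are flagged (default 5).
#' @return data.frame: group, \code{n}, \code{median}, \code{q25},
#'   \code{q75}, \code{small_group} flag.
#' @export
stratify_readthrough <- function(records, by = c("stop_codon", "stop_tetra"),
                                 min_n = 5) {
  by <- match.arg(by)
  grp <- split(records$score, records[[by]])
  out <- do.call(rbind, lapply(names(grp), function(g) {
    v <- grp[[g]]
    data.frame(group = g, n = length(v), median = median(v),
               q25 = quantile(v, 0.25, names = FALSE),
               q75 = quantile(v, 0.75, names = FALSE),
               small_group = length(v) < min_n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
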