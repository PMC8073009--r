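#' Strand-aware per-position read density track
#'
#' A \code{pileup_track} stores one numeric vector of per-position counts per
#' (chromosome, strand), with vector length equal to the chromosome length.
#' Positions are 0-based half-open internally; element \code{i} of a vector is
#' genomic position \code{i - 1}. Metadata records the mapping mode of the
#' underlying reads (3'-end counts for RNA-seq, center-mapped ribosome
#' footprints) and any footprint length filter applied upstream.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (nt).
#' @param mapping mapping mode, \code{"center"} (ribosome footprints) or
#'   \code{"3p"} (RNA-seq 3' ends).
#' @param footprint_range optional length-2 numeric, the footprint size filter
#'   (nt) used upstream (metadata only; default \code{c(14, 44)} for
#'   center-mapped data).
#' @return an object of class \code{pileup_track}.
#' @examples
#' trk <- pileup_track(c(chr = 1000L))
#' track_counts(trk, "chr", "+")[1:5]
#' @export
pileup_track <- function(chrom_lengths, mapping = c("center", "3p"),
                         footprint_range = NULL) {
  mapping <- match.arg(mapping)
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("'chrom_lengths' must be named")
  if (any(chrom_lengths < 1)) stop("chromosome lengths must be positive")
  if (is.null(footprint_range) && mapping == "center")
    footprint_range <- c(14, 44)
  counts <- lapply(chrom_lengths, function(L) {
    list("+" = numeric(L), "-" = numeric(L))
  })
  structure(
    list(counts = counts, chrom_lengths = chrom_lengths,
         mapping = mapping, footprint_range = footprint_range),
    class = "pileup_track")
}

#' @rdname pileup_track
#' @param track a \code{pileup_track}.
#' @param chrom chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @export
track_counts <- function(track, chrom, strand) {
  stopifnot(inherits(track, "pileup_track"))
  v <- track$counts[[chrom]][[strand]]
  if (is.null(v)) stop("no such chromosome/strand: ", chrom, strand)
  v
}

#' @rdname pileup_track
#' @param value replacement numeric vector (full chromosome length).
#' @export
`track_counts<-` <- function(track, chrom, strand, value) {
  stopifnot(inherits(track, "pileup_track"))
  if (length(value) != track$chrom_lengths[[chrom]])
    stop("replacement length must equal the chromosome length")
  if (any(value < 0)) stop("counts must be non-negative")
  track$counts[[chrom]][[strand]] <- value
  track
}

#' @export
print.pileup_track <- function(x, ...) {
  cat("pileup_track (", x$mapping, "-mapped)\n", sep = "")
  for (ch in names(x$counts)) {
    tp <- sum(x$counts[[ch]][["+"]]); tm <- sum(x$counts[[ch]][["-"]])
    cat(sprintf("  %s: %d nt, %.4g reads (+), %.4g reads (-)\n",
                ch, x$chrom_lengths[[ch]], tp, tm))
  }
  invisible(x)
}

## total mapped reads on the track
.track_total <- function(track) {
  sum(vapply(track$counts,
             function(ch) sum(ch[["+"]]) + sum(ch[["-"]]), numeric(1)))
}

## per-gene density vector in transcription sense (5' -> 3').
## ann_row: one row of a gene_annotation; from/to are offsets relative to the
## gene start in transcription coordinates (0-based), half-open [from, to).
.gene_trace <- function(track, chrom, strand, start, end, from = 0,
                        to = end - start) {
  v <- track$counts[[chrom]][[strand]]
  L <- length(v)
  if (strand == "+") {
    idx <- (start + from):(start + to - 1L) + 1L
  } else {
    ## transcription start at genomic end-1, moving leftwards
    idx <- (end - 1L - from):(end - to) + 1L
  }
  out <- rep(NA_real_, to - from)
  ok <- idx >= 1L & idx <= L
  out[ok] <- v[idx[ok]]
  out
}
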