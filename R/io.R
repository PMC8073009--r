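#' Read and write gene annotations as GFF3
#'
#' GFF3 files are 1-based closed-interval; internally coordinates are
#' 0-based half-open. Stop codon and stop tetranucleotide travel in the
#' \code{stop_codon} and \code{stop_tetranucleotide} attributes, the regulon
#' label in \code{regulon}.
#'
#' @param ann a \code{gene_annotation}.
#' @param path file path.
#' @return \code{write_annotation_gff3} returns \code{path} invisibly;
#'   \code{read_annotation_gff3} returns a \code{gene_annotation}.
#' @export
write_annotation_gff3 <- function(ann, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    type = "gene", ID = ann$gene_id, gene_class = ann$class,
    stop_codon = ann$stop_codon, stop_tetranucleotide = ann$stop_tetra,
    regulon = ann$regulon)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @param fasta optional genome FASTA to attach (enables sequence-dependent
#'   checks downstream).
#' @export
read_annotation_gff3 <- function(path, fasta = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  pick <- function(col) if (col %in% names(mc)) as.character(mc[[col]])
    else rep(NA_character_, length(gr))
  ann <- data.frame(
    gene_id = pick("ID"),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    class = pick("gene_class"),
    stop_codon = pick("stop_codon"),
    stop_tetra = pick("stop_tetranucleotide"),
    regulon = pick("regulon"),
    stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  if (!is.null(fasta))
    attr(ann, "genome") <- Biostrings::readDNAStringSet(fasta)
  ann
}

#' Write the genome attached to an annotation as FASTA
#'
#' @param ann a \code{gene_annotation} with an attached genome.
#' @param path file path.
#' @export
write_genome_fasta <- function(ann, path) {
  genome <- genome_of(ann)
  if (is.null(genome)) stop("no genome attached to this annotation")
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read and write pileup tracks as strand-paired bedGraph files
#'
#' One bedGraph per strand (0-based half-open intervals). Zero runs are
#' omitted on write and restored on read.
#'
#' @param track a \code{\link{pileup_track}}.
#' @param path_plus,path_minus file paths for the two strands.
#' @return the written paths / a \code{pileup_track}.
#' @export
write_pileup_bedgraph <- function(track, path_plus, path_minus) {
  wr <- function(strand, path) {
    grl <- list()
    for (ch in names(track$counts)) {
      v <- track$counts[[ch]][[strand]]
      r <- rle(v)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      keep <- r$values != 0
      if (any(keep)) {
        grl[[ch]] <- GenomicRanges::GRanges(
          seqnames = ch,
          ranges = IRanges::IRanges(start = starts[keep], end = ends[keep]),
          score = r$values[keep])
      }
    }
    gr <- if (length(grl)) do.call(c, unname(grl)) else
      GenomicRanges::GRanges(score = numeric(0))
    rtracklayer::export(gr, path, format = "bedGraph")
  }
  wr("+", path_plus); wr("-", path_minus)
  invisible(c(path_plus, path_minus))
}

#' @rdname write_pileup_bedgraph
#' @param chrom_lengths named chromosome lengths for the restored track.
#' @param mapping mapping mode metadata for the restored track.
#' @export
read_pileup_bedgraph <- function(path_plus, path_minus, chrom_lengths,
                                 mapping = "center") {
  track <- pileup_track(chrom_lengths, mapping = mapping)
  rd <- function(path, strand) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    for (i in seq_along(gr)) {
      ch <- as.character(GenomicRanges::seqnames(gr)[i])
      s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
      track$counts[[ch]][[strand]][s:e] <<-
        S4Vectors::mcols(gr)$score[i]
    }
  }
  rd(path_plus, "+"); rd(path_minus, "-")
  track
}

#' Read and write barcode count tables as TSV
#'
#' Columns: experiment, condition, timepoint, generations, barcode,
#' genotype, count.
#'
#' @param counts a count data.frame.
#' @param path file path.
#' @export
write_count_table <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
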