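#' Configuration for the synthetic gene-annotation generator
#'
#' Describes a bacterial-like chromosome: gene lengths, stop-codon usage,
#' intergenic spacing (including overlapping start/stop punctuation), strand
#' persistence, and optional rRNA/tRNA and regulon labelling. Defaults emulate
#' a \emph{B. subtilis}-like genome: stop codons sampled at roughly the
#' genomic gene-count frequencies, 7\% of co-directional gene pairs in the
#' 4-nt A-UGA start/stop overlap configuration and a further fraction in a
#' 1-nt overlap.
#'
#' @param n_genes number of genes to place.
#' @param len_range range (nt) from which gene lengths are drawn uniformly
#'   (rounded to codon multiples; minimum 60 nt).
#' @param stop_freq named simplex over \code{c("UAA","UAG","UGA")}.
#' @param frac_codir probability that a gene keeps the strand of its
#'   predecessor (strand persistence; sets the co-directional pair fraction).
#' @param frac_auga fraction of co-directional pairs placed at the -4 nt
#'   A-UGA overlap (forces the transcription-upstream stop to UGA).
#' @param frac_other_overlap fraction of co-directional pairs placed at a
#'   -1 nt overlap (upstream stop restricted to UAA/UGA for sequence
#'   consistency).
#' @param gap_mean,gap_max mean and cap (nt) of the exponential positive
#'   intergenic gap draw.
#' @param class_freq named simplex over gene classes
#'   \code{c("mRNA","rRNA","tRNA")}.
#' @param regulon_frac optional named numeric; for each name, that fraction of
#'   mRNA genes is labelled as a member of the regulon (disjoint assignment).
#' @param chrom_len optional declared chromosome length (nt); generation fails
#'   if the placed genes do not fit.
#' @param seed integer seed for reproducibility.
#' @return a list of class \code{sim_annotation_config}.
#' @export
sim_annotation_config <- function(n_genes = 200,
                                  len_range = c(300, 1500),
                                  stop_freq = c(UAA = 0.60, UAG = 0.16, UGA = 0.24),
                                  frac_codir = 0.75,
                                  frac_auga = 0.07,
                                  frac_other_overlap = 0.10,
                                  gap_mean = 60,
                                  gap_max = 300,
                                  class_freq = c(mRNA = 1, rRNA = 0, tRNA = 0),
                                  regulon_frac = NULL,
                                  chrom_len = NULL,
                                  seed = 1L) {
  stopifnot(n_genes >= 1, length(len_range) == 2, len_range[1] >= 60)
  stop_freq <- stop_freq[STOP_CODONS]
  if (any(is.na(stop_freq)) || abs(sum(stop_freq) - 1) > 1e-8)
    stop("'stop_freq' must be a simplex over UAA, UAG, UGA")
  .check_prob(frac_codir, "frac_codir", allow_one = TRUE)
  .check_prob(frac_auga, "frac_auga", allow_one = TRUE)
  .check_prob(frac_other_overlap, "frac_other_overlap", allow_one = TRUE)
  if (frac_auga + frac_other_overlap > 1)
    stop("overlap fractions exceed 1")
  if (abs(sum(class_freq) - 1) > 1e-8) stop("'class_freq' must sum to 1")
  structure(list(n_genes = as.integer(n_genes), len_range = len_range,
                 stop_freq = stop_freq, frac_codir = frac_codir,
                 frac_auga = frac_auga,
                 frac_other_overlap = frac_other_overlap,
                 gap_mean = gap_mean, gap_max = gap_max,
                 class_freq = class_freq, regulon_frac = regulon_frac,
                 chrom_len = chrom_len, seed = seed),
            class = "sim_annotation_config")
}

## the 61 sense codons (DNA alphabet)
.sense_codons <- local({
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

.revcomp_chr <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' Generate a synthetic gene annotation with genome sequence
#'
#' Places \code{n_genes} genes sequentially on one chromosome with
#' configurable strand persistence, intergenic gaps (including -4 nt A-UGA and
#' -1 nt start/stop overlaps between co-directional pairs) and stop-codon
#' usage, and writes a consistent genome sequence (ATG starts, sampled sense
#' codons, the annotated stop codon, and self-consistent overlap junctions).
#'
#' Coordinates are stored 0-based half-open. Each gene carries its stop codon
#' and stop tetranucleotide (stop + next transcribed base), both read back
#' from the generated genome.
#'
#' @param config a \code{\link{sim_annotation_config}}.
#' @return a \code{data.frame} of class \code{gene_annotation} with columns
#'   \code{gene_id}, \code{chrom}, \code{strand}, \code{start}, \code{end},
#'   \code{class}, \code{stop_codon}, \code{stop_tetra}, \code{regulon}. The
#'   genome is attached as attribute \code{"genome"}
#'   (\code{Biostrings::DNAStringSet}); retrieve it with
#'   \code{\link{genome_of}}.
#' @examples
#' ann <- gen_annotation(sim_annotation_config(n_genes = 20, seed = 42))
#' head(ann)
#' @export
gen_annotation <- function(config) {
  stopifnot(inherits(config, "sim_annotation_config"))
  set.seed(config$seed)
  n <- config$n_genes

  lens <- 3L * as.integer(round(runif(n, config$len_range[1],
                                      config$len_range[2]) / 3))
  lens <- pmax(lens, 60L)
  stops <- sample(STOP_CODONS, n, replace = TRUE, prob = config$stop_freq)
  strand <- character(n)
  strand[1] <- "+"
  if (n > 1) {
    keep <- runif(n - 1) < config$frac_codir
    for (i in 2:n) strand[i] <- if (keep[i - 1]) strand[i - 1] else
      setdiff(c("+", "-"), strand[i - 1])
  }

  ## gaps between gene i and i+1 (genomic: start[i+1] - end[i])
  gap <- integer(max(n - 1, 0))
  ovl_class <- character(max(n - 1, 0))  # "", "A_UGA", "minus1"
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      codir <- strand[i] == strand[i + 1]
      if (codir) {
        u <- runif(1)
        if (u < config$frac_auga) {
          gap[i] <- -4L; ovl_class[i] <- "A_UGA"
        } else if (u < config$frac_auga + config$frac_other_overlap) {
          gap[i] <- -1L; ovl_class[i] <- "minus1"
        } else {
          gap[i] <- 1L + min(as.integer(round(rexp(1, 1 / config$gap_mean))),
                             as.integer(config$gap_max))
        }
      } else {
        gap[i] <- 20L + min(as.integer(round(rexp(1, 1 / config$gap_mean))),
                            as.integer(config$gap_max))
      }
    }
  }

  ## force stop-codon constraints at overlap junctions
  ## (transcription-upstream member: left gene on "+", right gene on "-")
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (ovl_class[i] == "") next
      up <- if (strand[i] == "+") i else i + 1L
      if (ovl_class[i] == "A_UGA") stops[up] <- "UGA"
      else if (stops[up] == "UAG")
        stops[up] <- sample(c("UAA", "UGA"), 1, prob = c(0.7, 0.3))
    }
  }

  margin <- 200L
  start <- integer(n)
  start[1] <- margin
  if (n > 1) for (i in 2:n) start[i] <- start[i - 1] + lens[i - 1] + gap[i - 1]
  end <- start + lens
  total_len <- max(end) + margin
  if (!is.null(config$chrom_len)) {
    if (total_len > config$chrom_len)
      stop("infeasible packing: placed genes span ", total_len,
           " nt but declared chromosome length is ", config$chrom_len)
    total_len <- as.integer(config$chrom_len)
  }

  ## build the genome: random background, then gene sequences, then junctions
  genome <- sample(c("A", "C", "G", "T"), total_len, replace = TRUE)
  for (i in seq_len(n)) {
    ncod <- lens[i] %/% 3L
    body <- sample(.sense_codons, ncod - 2L, replace = TRUE)
    seq_i <- strsplit(paste0("ATG", paste(body, collapse = ""),
                             .stop_to_dna[stops[i]]), "")[[1]]
    if (strand[i] == "-") seq_i <- rev(chartr("ACGT", "TGCA", seq_i))
    genome[(start[i] + 1L):end[i]] <- seq_i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (ovl_class[i] == "") next
      if (strand[i] == "+") {
        e <- end[i]  # 0-based exclusive end of upstream gene
        if (ovl_class[i] == "A_UGA") {
          genome[(e - 3L):e] <- c("A", "T", "G", "A")
        } else {
          genome[(e - 2L):e] <- strsplit(.stop_to_dna[stops[i]], "")[[1]]
          genome[e:(e + 2L)] <- c("A", "T", "G")
        }
      } else {
        sR <- start[i + 1L]  # 0-based start of (transcription-upstream) gene
        if (ovl_class[i] == "A_UGA") {
          genome[(sR + 1L):(sR + 4L)] <- c("T", "C", "A", "T")
        } else {
          genome[(sR + 1L):(sR + 3L)] <-
            rev(chartr("ACGT", "TGCA",
                       strsplit(.stop_to_dna[stops[i + 1L]], "")[[1]]))
          genome[(sR - 1L):(sR + 1L)] <- c("C", "A", "T")
        }
      }
    }
  }

  ## stop tetranucleotide read back from the genome (stop + next base)
  tetra <- character(n)
  for (i in seq_len(n)) {
    if (strand[i] == "+") {
      tet <- paste(genome[(end[i] - 2L):(end[i] + 1L)], collapse = "")
    } else {
      tet <- paste(rev(chartr("ACGT", "TGCA",
                              genome[start[i]:(start[i] + 3L)])), collapse = "")
    }
    tetra[i] <- paste0(.dna_to_stop[substr(tet, 1, 3)], substr(tet, 4, 4))
  }

  cls <- sample(names(config$class_freq), n, replace = TRUE,
                prob = config$class_freq)
  regulon <- rep(NA_character_, n)
  if (!is.null(config$regulon_frac)) {
    idx_pool <- which(cls == "mRNA")
    for (lab in names(config$regulon_frac)) {
      k <- round(config$regulon_frac[[lab]] * length(which(cls == "mRNA")))
      pick <- sample(idx_pool, min(k, length(idx_pool)))
      regulon[pick] <- lab
      idx_pool <- setdiff(idx_pool, pick)
    }
  }

  ann <- data.frame(
    gene_id = sprintf("gene%05d", seq_len(n)),
    chrom = "chr", strand = strand, start = start, end = end,
    class = cls, stop_codon = stops, stop_tetra = tetra,
    regulon = regulon, stringsAsFactors = FALSE)
  class(ann) <- c("gene_annotation", "data.frame")
  attr(ann, "genome") <- Biostrings::DNAStringSet(
    setNames(paste(genome, collapse = ""), "chr"))
  attr(ann, "config") <- config
  ann
}

#' Retrieve the genome sequence attached to an annotation
#'
#' @param ann a \code{gene_annotation} produced by \code{\link{gen_annotation}}
#'   or \code{\link{read_annotation_gff3}} with a FASTA.
#' @return a \code{Biostrings::DNAStringSet} or \code{NULL}.
#' @export
genome_of <- function(ann) attr(ann, "genome")

#' Check stop-codon annotations against a genome sequence
#'
#' Reads the terminal codon of each gene from the genome (reverse-complemented
#' for minus-strand genes) and compares with the annotated stop codon.
#'
#' @param ann a \code{gene_annotation}.
#' @param genome a \code{Biostrings::DNAStringSet}; defaults to the genome
#'   attached to \code{ann}.
#' @return invisibly \code{TRUE}; stops with a message listing mismatches.
#' @export
validate_stop_codons <- function(ann, genome = genome_of(ann)) {
  if (is.null(genome)) stop("no genome sequence available")
  bad <- character(0)
  for (i in seq_len(nrow(ann))) {
    g <- genome[[ann$chrom[i]]]
    if (ann$strand[i] == "+") {
      cod <- as.character(Biostrings::subseq(g, ann$end[i] - 2L, ann$end[i]))
    } else {
      cod <- as.character(Biostrings::reverseComplement(
        Biostrings::subseq(g, ann$start[i] + 1L, ann$start[i] + 3L)))
    }
    if (is.na(.dna_to_stop[cod]) || .dna_to_stop[cod] != ann$stop_codon[i])
      bad <- c(bad, ann$gene_id[i])
  }
  if (length(bad))
    stop("stop codon inconsistent with genome for: ",
         paste(head(bad, 10), collapse = ", "))
  invisible(TRUE)
}
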