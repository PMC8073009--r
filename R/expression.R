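#' Per-gene expression from a pileup track
#'
#' Computes edge-trimmed mean read density, gene-body read counts, rpkm
#' (normalized by total reads not mapping to an exclusion class, by default
#' rRNA and tRNA), the transcriptome read fraction, and - for footprint
#' tracks - the proteome synthesis fraction and flags. Density is averaged
#' over \code{[start + edge_trim, end - edge_trim)} in the transcription
#' sense; genes shorter than \code{2 * edge_trim + 1} are excluded with a
#' flag.
#'
#' @param track a \code{\link{pileup_track}}.
#' @param ann a \code{gene_annotation} data.frame (0-based half-open
#'   coordinates; columns \code{gene_id}, \code{chrom}, \code{strand},
#'   \code{start}, \code{end}, \code{class}, and optionally
#'   \code{stop_codon}, \code{stop_tetra}, \code{regulon}).
#' @param edge_trim nt trimmed from each gene end (default 20).
#' @param exclude_classes classes excluded from the rpkm denominator
#'   (default rRNA and tRNA).
#' @return a data.frame of class \code{expression_table}: per gene
#'   \code{gene_id}, \code{class}, \code{stop_codon}, \code{stop_tetra},
#'   \code{regulon}, \code{length}, \code{body_length}, \code{reads}
#'   (body reads), \code{density} (reads/nt), \code{rpkm},
#'   \code{frac_reads} (share of the non-excluded total),
#'   \code{synth_frac} (synthesis fraction, mRNA genes; sums to 1),
#'   \code{excluded} flag. Attribute \code{"total_reads"} holds the rpkm
#'   denominator.
#' @export
gene_density <- function(track, ann, edge_trim = 20,
                         exclude_classes = c("rRNA", "tRNA")) {
  stopifnot(inherits(track, "pileup_track"), edge_trim >= 0)
  n <- nrow(ann)
  reads <- body_len <- dens <- rep(NA_real_, n)
  full_reads <- numeric(n)
  excluded <- logical(n)
  for (i in seq_len(n)) {
    L <- ann$end[i] - ann$start[i]
    tr_full <- .gene_trace(track, ann$chrom[i], ann$strand[i],
                           ann$start[i], ann$end[i])
    full_reads[i] <- sum(tr_full, na.rm = TRUE)
    if (L <= 2 * edge_trim) { excluded[i] <- TRUE; next }
    body <- tr_full[(edge_trim + 1):(L - edge_trim)]
    body_len[i] <- L - 2 * edge_trim
    reads[i] <- sum(body, na.rm = TRUE)
    dens[i] <- reads[i] / body_len[i]
  }
  total_excl <- sum(full_reads[ann$class %in% exclude_classes])
  total <- .track_total(track) - total_excl
  rpkm <- (reads / (body_len / 1000)) / (total / 1e6)
  ## transcriptome fraction: all reads mapping to the gene over the
  ## non-excluded total (untrimmed, per the regulon-fraction definition)
  frac_reads <- full_reads / total

  is_m <- ann$class == "mRNA" & !excluded
  sw <- ifelse(is_m, dens * (ann$end - ann$start), NA_real_)
  synth <- sw / sum(sw, na.rm = TRUE)

  out <- data.frame(
    gene_id = ann$gene_id, class = ann$class,
    stop_codon = ann$stop_codon %||% NA_character_,
    stop_tetra = ann$stop_tetra %||% NA_character_,
    regulon = ann$regulon %||% NA_character_,
    length = ann$end - ann$start, body_length = body_len,
    reads = reads, density = dens, rpkm = rpkm,
    frac_reads = frac_reads, synth_frac = synth,
    excluded = excluded, stringsAsFactors = FALSE)
  class(out) <- c("expression_table", "data.frame")
  attr(out, "total_reads") <- total
  attr(out, "mapping") <- track$mapping
  out
}

#' Proteome synthesis fractions from footprint expression
#'
#' The synthesis fraction of gene i is its synthesis rate (footprint density)
#' multiplied by gene length, divided by the sum of this quantity over all
#' (mRNA) genes - proportional to the gene's share of total footprint reads.
#' Under a stable proteome this equals the proteome mass fraction.
#'
#' @param expr an \code{expression_table} (footprint data) or data.frame with
#'   \code{density}, \code{length} and optionally \code{class},
#'   \code{excluded}.
#' @return named numeric vector of fractions (sums to 1 over included genes).
#' @export
synthesis_fraction <- function(expr) {
  keep <- (expr$class %||% "mRNA") == "mRNA" & !(expr$excluded %||% FALSE)
  w <- ifelse(keep, expr$density * expr$length, NA_real_)
  setNames(w / sum(w, na.rm = TRUE), expr$gene_id)
}

#' Summed expression fraction of a regulon
#'
#' The regulon transcriptome fraction (psi) is the sum of member genes'
#' transcriptome fractions; with footprint data and
#' \code{type = "synthesis"}, the proteome synthesis fraction (phi).
#' Members absent from the table are reported via attribute
#' \code{"missing"}.
#'
#' @param expr an \code{expression_table}.
#' @param members character vector of member gene ids (or a regulon label
#'   present in \code{expr$regulon}).
#' @param type \code{"transcript"} (read fraction) or \code{"synthesis"}.
#' @param exclude gene ids excluded from the member sum (e.g. the ectopic
#'   release-factor genes when quantifying the translation sector).
#' @return the summed fraction (scalar), with attribute \code{"missing"}.
#' @export
regulon_fraction <- function(expr, members,
                             type = c("transcript", "synthesis"),
                             exclude = character(0)) {
  type <- match.arg(type)
  if (length(members) == 1 && !is.na(members) &&
      members %in% expr$regulon %||% character(0))
    members <- expr$gene_id[!is.na(expr$regulon) & expr$regulon == members]
  members <- setdiff(members, exclude)
  missing <- setdiff(members, expr$gene_id)
  idx <- expr$gene_id %in% members
  val <- if (type == "transcript") expr$frac_reads else expr$synth_frac
  structure(sum(val[idx], na.rm = TRUE), missing = missing)
}

#' Calibration between transcriptome and proteome sector fractions
#'
#' Matched mRNA-level and protein-synthesis measurements give empirical
#' conversions from transcriptome fraction psi to proteome fraction phi:
#' for the translation sector \eqn{\phi_R = \alpha \psi_R} with
#' \eqn{\alpha \approx 1.1}; for the general-stress (sigma-B) regulon
#' \eqn{\phi = \alpha (\psi - \psi_0) + \phi_0} with
#' \eqn{\alpha \approx 1.41}, where \eqn{\psi_0, \phi_0} are the basal
#' fractions. Also records translation-efficiency fold-changes for ectopic
#' release-factor constructs (RF2 3.0, RF1 0.66, PrmC 1 as the parsimonious
#' default).
#'
#' @param alpha_translation,alpha_sigb conversion slopes.
#' @param psi0_sigb,phi0_sigb basal sigma-B transcriptome and proteome
#'   fractions.
#' @param te_fc named numeric of TE fold-changes for ectopic constructs.
#' @return list of class \code{calibration_model}.
#' @export
calibration_model <- function(alpha_translation = 1.1, alpha_sigb = 1.41,
                              psi0_sigb = 0.02, phi0_sigb = 0.02,
                              te_fc = c(RF2 = 3.0, RF1 = 0.66, PrmC = 1)) {
  stopifnot(alpha_translation > 0, alpha_sigb > 0)
  structure(list(alpha_translation = alpha_translation,
                 alpha_sigb = alpha_sigb, psi0_sigb = psi0_sigb,
                 phi0_sigb = phi0_sigb, te_fc = te_fc),
            class = "calibration_model")
}

#' Convert a transcriptome fraction to a calibrated proteome fraction
#'
#' @param psi transcriptome fraction(s).
#' @param model a \code{\link{calibration_model}}.
#' @param sector \code{"translation"} (\eqn{\phi = \alpha \psi}) or
#'   \code{"sigB"} (\eqn{\phi = \alpha(\psi - \psi_0) + \phi_0}).
#' @param inverse if TRUE, invert the map (proteome to transcriptome).
#' @return calibrated fraction(s).
#' @examples
#' calibrate_sector(0.35, calibration_model(), "translation")  # 0.385
#' @export
calibrate_sector <- function(psi, model = calibration_model(),
                             sector = c("translation", "sigB"),
                             inverse = FALSE) {
  sector <- match.arg(sector)
  if (sector == "translation") {
    if (inverse) psi / model$alpha_translation
    else model$alpha_translation * psi
  } else {
    if (inverse) (psi - model$phi0_sigb) / model$alpha_sigb + model$psi0_sigb
    else model$alpha_sigb * (psi - model$psi0_sigb) + model$phi0_sigb
  }
}

#' Translation efficiency and TE-corrected proteome fractions
#'
#' TE is the ribosome footprint rpkm divided by the mRNA rpkm (a proxy for
#' the per-mRNA initiation rate). \code{corrected_proteome_fraction} rescales
#' a wild-type proteome fraction by measured mRNA and TE fold-changes.
#'
#' @param footprint_rpkm,mrna_rpkm rpkm vectors (matched genes).
#' @return TE values; \code{NA} (flagged via warning) where mRNA rpkm is 0.
#' @export
translation_efficiency <- function(footprint_rpkm, mrna_rpkm) {
  te <- ifelse(mrna_rpkm > 0, footprint_rpkm / mrna_rpkm, NA_real_)
  if (anyNA(te)) warning(sum(is.na(te)), " gene(s) with zero mRNA rpkm: ",
                         "TE undefined")
  te
}

#' @rdname translation_efficiency
#' @param wt_fraction wild-type proteome fraction.
#' @param mrna_fc,te_fc fold-changes in mRNA level and TE.
#' @export
corrected_proteome_fraction <- function(wt_fraction, mrna_fc, te_fc = 1) {
  wt_fraction * mrna_fc * te_fc
}

#' Flux-weighted stop codon usage
#'
#' Usage of each stop codon (or stop tetranucleotide) is the summed synthesis
#' fraction of all genes terminating with it - the share of the termination
#' flux through that codon, as opposed to a gene count.
#'
#' @param expr an \code{expression_table} with \code{synth_frac} and
#'   \code{stop_codon} (and \code{stop_tetra}).
#' @param by \code{"stop_codon"} or \code{"stop_tetra"}.
#' @return named numeric of usages, summing to 1.
#' @export
stop_usage <- function(expr, by = c("stop_codon", "stop_tetra")) {
  by <- match.arg(by)
  keep <- !is.na(expr$synth_frac) & !is.na(expr[[by]])
  u <- tapply(expr$synth_frac[keep], expr[[by]][keep], sum)
  u <- u / sum(u)
  if (by == "stop_codon") {
    full <- setNames(numeric(3), STOP_CODONS)
    full[names(u)] <- u
    full
  } else as.numeric(u) |> setNames(names(u))
}

#' Relative mRNA levels from qPCR Ct values
#'
#' Applies the standard delta-Ct quantification with the protocol's quality
#' rules: technical replicates deviating by more than \code{outlier_ct} from
#' the replicate median are dropped; samples where the no-RT control Ct
#' exceeds the RT Ct by less than \code{min_rt_delta} are flagged for genomic
#' DNA contamination. The level of a target relative to the reference gene
#' (gyrA) is \eqn{2^{Ct_{ref} - Ct_{target}}} using replicate-mean Ct values.
#'
#' @param ct data.frame with columns \code{sample}, \code{target}, \code{ct},
#'   and logical \code{rt} (TRUE for +RT reactions, FALSE for no-RT
#'   controls; no-RT rows optional).
#' @param reference reference target name (default \code{"gyrA"}).
#' @param outlier_ct replicate outlier threshold in Ct units (default 0.2).
#' @param min_rt_delta minimum (no-RT Ct - RT Ct) difference (default 7).
#' @return data.frame: \code{sample}, \code{target}, \code{mean_ct},
#'   \code{n_used}, \code{n_dropped}, \code{rt_delta}, \code{flag_rt},
#'   \code{level}.
#' @export
qpcr_relative_level <- function(ct, reference = "gyrA", outlier_ct = 0.2,
                                min_rt_delta = 7) {
  stopifnot(all(c("sample", "target", "ct") %in% names(ct)))
  if (!"rt" %in% names(ct)) ct$rt <- TRUE
  grp <- split(ct, list(ct$sample, ct$target), drop = TRUE)
  rows <- lapply(grp, function(g) {
    v <- g$ct[g$rt]
    keep <- abs(v - median(v)) <= outlier_ct
    ## never drop everything: a lone replicate is its own median
    if (!any(keep)) keep <- rep(TRUE, length(v))
    nort <- g$ct[!g$rt]
    rt_delta <- if (length(nort)) mean(nort) - mean(v[keep]) else NA_real_
    data.frame(sample = g$sample[1], target = g$target[1],
               mean_ct = mean(v[keep]), n_used = sum(keep),
               n_dropped = sum(!keep), rt_delta = rt_delta,
               flag_rt = !is.na(rt_delta) && rt_delta <= min_rt_delta,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows); rownames(res) <- NULL
  ref <- res[res$target == reference, c("sample", "mean_ct")]
  names(ref)[2] <- "ref_ct"
  res <- merge(res, ref, by = "sample", all.x = TRUE)
  res$level <- 2^(res$ref_ct - res$mean_ct)
  res$ref_ct <- NULL
  res
}
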