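#' Simulate a regulon-induction condition series with proteome compression
#'
#' Starting from a basal expression state, generates one expression table per
#' requested regulon fraction: regulon members are scaled up so that the
#' regulon's expression fraction hits the target, while all other genes are
#' scaled down by the compression factor implied by the finite total
#' synthesis capacity (the non-regulon total becomes \code{1 - psi_target},
#' i.e. the classic compression by \eqn{1 - \phi_U} of every other sector).
#' The realized sector truths are recorded for round-trip validation of the
#' quantification stage.
#'
#' @param ann a \code{gene_annotation} whose \code{regulon} column labels the
#'   induced regulon (\code{regulon_label}) and, optionally, a monitored
#'   sector (e.g. \code{"translation"}).
#' @param psi_grid numeric vector of target regulon expression fractions,
#'   each in [0, 0.5] (the first value is taken as basal if
#'   \code{psi_basal} is NULL).
#' @param regulon_label label of the induced regulon in \code{ann$regulon}.
#' @param psi_basal basal regulon fraction; default the regulon's fraction
#'   in the basal state.
#' @param noise lognormal per-gene noise s.d. in log2 units (0 = noiseless).
#' @param depth mean expression level (arbitrary rpkm-like units).
#' @param seed integer seed.
#' @return list of class \code{condition_series}: \code{tables} (list of
#'   data.frames gene_id, class, stop_codon, regulon, length, level),
#'   \code{truth} (data.frame: condition, psi_target, psi_realized,
#'   phi_U (excess over basal), compression_factor, plus
#'   \code{sector_fraction} columns for every other regulon label present).
#' @export
gen_condition_series <- function(ann, psi_grid, regulon_label = "sigB",
                                 psi_basal = NULL, noise = 0, depth = 100,
                                 seed = 1L) {
  if (any(psi_grid < 0) || any(psi_grid > 0.5))
    stop("'psi_grid' values must lie in [0, 0.5]")
  set.seed(seed)
  n <- nrow(ann)
  is_reg <- !is.na(ann$regulon) & ann$regulon == regulon_label
  if (!any(is_reg)) stop("no genes labelled '", regulon_label, "'")

  ## basal per-gene levels (length-weighted expression)
  base_level <- depth * rlnorm(n, 0, 0.5)
  w0 <- base_level * (ann$end - ann$start)
  reg0 <- sum(w0[is_reg]); tot0 <- sum(w0)
  psi0 <- reg0 / tot0
  if (is.null(psi_basal)) psi_basal <- psi0

  other_labels <- setdiff(unique(ann$regulon[!is.na(ann$regulon)]),
                          regulon_label)
  tables <- list(); rows <- list()
  for (j in seq_along(psi_grid)) {
    psi_t <- psi_grid[j]
    a <- psi_t * tot0 / reg0               # regulon scale factor
    cfac <- (1 - psi_t) / (1 - psi0)       # compression of everything else
    lev <- base_level
    lev[is_reg] <- lev[is_reg] * a
    lev[!is_reg] <- lev[!is_reg] * cfac
    if (noise > 0) lev <- lev * 2^rnorm(n, 0, noise)
    tab <- data.frame(gene_id = ann$gene_id, class = ann$class,
                      stop_codon = ann$stop_codon, regulon = ann$regulon,
                      length = ann$end - ann$start, level = lev,
                      stringsAsFactors = FALSE)
    tables[[j]] <- tab
    w <- base_level * (ann$end - ann$start)
    w[is_reg] <- w[is_reg] * a; w[!is_reg] <- w[!is_reg] * cfac
    row <- data.frame(condition = sprintf("cond%02d", j),
                      psi_target = psi_t, psi_realized = sum(w[is_reg]) / sum(w),
                      phi_U = psi_t - psi_basal, compression_factor = cfac)
    for (lab in other_labels) {
      sel <- !is.na(ann$regulon) & ann$regulon == lab
      row[[paste0("fraction_", lab)]] <- sum(w[sel]) / sum(w)
    }
    rows[[j]] <- row
  }
  structure(list(tables = tables, truth = do.call(rbind, rows),
                 psi_basal = psi_basal, regulon_label = regulon_label),
            class = "condition_series")
}

#' Expression fractions from a simulated condition table
#'
#' Companion quantifier for \code{\link{gen_condition_series}} tables (which
#' carry levels rather than pileups): converts levels to expression
#' fractions compatible with \code{\link{regulon_fraction}}.
#'
#' @param tab one element of \code{condition_series$tables}.
#' @return an \code{expression_table}-compatible data.frame with
#'   \code{frac_reads} and \code{synth_frac} columns.
#' @export
expression_from_levels <- function(tab) {
  w <- tab$level * tab$length
  out <- data.frame(gene_id = tab$gene_id, class = tab$class,
                    stop_codon = tab$stop_codon, regulon = tab$regulon,
                    length = tab$length, reads = w,
                    density = tab$level, rpkm = tab$level,
                    frac_reads = w / sum(w), synth_frac = w / sum(w),
                    excluded = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("expression_table", "data.frame")
  out
}
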