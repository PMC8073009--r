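#' Configuration for the ribosome-traffic exclusion-process simulator
#'
#' Ribosome traffic on an mRNA is modelled as a continuous-time exclusion
#' process on a codon lattice with open boundaries: ribosomes of footprint
#' \code{footprint} codons (10 codons, about 30 nt, by default) initiate at
#' rate \code{alpha} when the first footprint of the ORF is free (the
#' initiation rate is the mechanistic proxy for translation efficiency),
#' hop forward at rate \code{k} when the site ahead is free, and terminate
#' at the stop site at rate \code{beta}. An optional competing readthrough
#' reaction (rate \code{gamma}) lets the ribosome elongate past the stop
#' instead. A second ORF downstream (gap in nt, possibly negative for
#' overlapping start/stop punctuation) can be configured to probe occlusion
#' of downstream initiation by terminating ribosomes. Time units are
#' arbitrary: only rate ratios matter.
#'
#' @param length ORF length in codons (> footprint).
#' @param footprint ribosome footprint in codons (default 10).
#' @param alpha initiation rate (events per time unit).
#' @param k elongation rate per unblocked ribosome (codons per time unit).
#' @param beta termination rate at the stop site.
#' @param gamma readthrough rate at the stop site (default 0).
#' @param orf2 optional list \code{list(length =, gap_nt =, alpha =)}
#'   describing a downstream ORF; \code{gap_nt} is the transcription-sense
#'   intergenic distance in nt (rounded to codons; -4 for the A-UGA
#'   overlap).
#' @param time,burnin total simulated time and burn-in discarded from
#'   statistics (\code{burnin < time}).
#' @param seed integer seed (reproducible event sequences).
#' @return list of class \code{traffic_config}.
#' @export
traffic_config <- function(length = 200, footprint = 10, alpha = 0.1,
                           k = 10, beta = 10, gamma = 0, orf2 = NULL,
                           time = 2000, burnin = 200, seed = 1L) {
  stopifnot(length > footprint, footprint >= 1, alpha >= 0, k >= 0,
            beta >= 0, gamma >= 0, time > 0)
  if (burnin >= time) stop("burn-in must be shorter than the total time")
  if (!is.null(orf2)) {
    stopifnot(is.list(orf2), all(c("length", "gap_nt", "alpha") %in%
                                   names(orf2)))
  }
  structure(list(length = as.integer(length),
                 footprint = as.integer(footprint), alpha = alpha, k = k,
                 beta = beta, gamma = gamma, orf2 = orf2, time = time,
                 burnin = burnin, seed = as.integer(seed)),
            class = "traffic_config")
}

#' Simulate ribosome traffic (exclusion process)
#'
#' Runs the continuous-time simulation described in
#' \code{\link{traffic_config}} and summarizes the steady state:
#' time-averaged per-site occupancy (fraction of time each codon is covered
#' by a ribosome), protein completion flux (terminations per time unit),
#' cross-section fluxes near the start and mid-ORF (for conservation
#' checks), mean queue length at the stop (time-averaged count of contiguous
#' blocked ribosomes ending at the stop site), readthrough flux, and - when
#' a second ORF is configured - its initiation and completion fluxes.
#'
#' @param config a \code{\link{traffic_config}}.
#' @return object of class \code{traffic_result}.
#' @examples
#' res <- simulate_traffic(traffic_config(length = 60, alpha = 0.05,
#'                                        time = 500, burnin = 50))
#' res$flux
#' @export
simulate_traffic <- function(config) {
  stopifnot(inherits(config, "traffic_config"))
  o2 <- config$orf2
  start2 <- 0L; len2 <- 0L; alpha2 <- 0
  if (!is.null(o2)) {
    gap_cod <- as.integer(round(o2$gap_nt / 3))
    start2 <- config$length + 1L + gap_cod
    if (start2 < 1L) stop("ORF2 would start before the lattice")
    len2 <- as.integer(o2$length)
    alpha2 <- o2$alpha
  }
  raw <- .tasep_run(config$length, config$footprint, config$alpha,
                    config$k, config$beta, config$gamma, start2, len2,
                    alpha2, config$time, config$burnin, config$seed)
  T <- raw$time
  structure(list(
    occupancy = raw$occupancy,
    flux = raw$completions1 / T,
    flux_readthrough = raw$readthroughs / T,
    flux_sections = c(initiation = raw$initiations1 / T,
                      first = raw$cross_first / T,
                      mid = raw$cross_mid / T,
                      termination = (raw$completions1 + raw$readthroughs) / T),
    counts = c(initiations = raw$initiations1,
               completions = raw$completions1,
               readthroughs = raw$readthroughs,
               initiations2 = raw$initiations2,
               completions2 = raw$completions2),
    flux_down = if (start2 > 0) raw$completions2 / T else NA_real_,
    queue_mean = raw$queue_mean,
    time = T, config = config), class = "traffic_result")
}

#' @export
print.traffic_result <- function(x, ...) {
  cat(sprintf("traffic_result: flux %.4g /t, mean queue %.2f ribosomes\n",
              x$flux, x$queue_mean))
  cat(sprintf("  section fluxes (init/first/mid/stop): %s\n",
              paste(signif(x$flux_sections, 3), collapse = " / ")))
  if (!is.na(x$flux_down))
    cat(sprintf("  downstream ORF flux %.4g /t\n", x$flux_down))
  invisible(x)
}

#' Queue length versus initiation rate (translation efficiency proxy)
#'
#' Sweeps the initiation rate at fixed elongation and termination rates:
#' genes with higher translation efficiency accumulate longer queues when
#' termination is slow.
#'
#' @param config a template \code{\link{traffic_config}}.
#' @param alpha_grid initiation rates to sweep.
#' @return data.frame: \code{alpha}, \code{queue_mean}, \code{flux}.
#' @export
queue_vs_te <- function(config, alpha_grid) {
  rows <- lapply(seq_along(alpha_grid), function(i) {
    cf <- config; cf$alpha <- alpha_grid[i]
    cf$seed <- config$seed + i - 1L
    r <- simulate_traffic(cf)
    data.frame(alpha = alpha_grid[i], queue_mean = r$queue_mean,
               flux = r$flux)
  })
  do.call(rbind, rows)
}

#' Occlusion of downstream initiation by terminating ribosomes
#'
#' For a closely spaced two-ORF configuration, compares the
#' downstream-to-upstream completion flux ratio under slowed termination
#' with the same ratio under the unperturbed (fast) termination rate:
#' \deqn{FC = \frac{(J_{down}/J_{up})_{slow}}{(J_{down}/J_{up})_{fast}}.}
#' When the footprint of a ribosome idling at the upstream stop overlaps the
#' downstream initiation region, FC falls below 1.
#'
#' @param config a \code{\link{traffic_config}} with \code{orf2} set.
#' @param beta_factor factor by which termination is slowed (default 60).
#' @return list: \code{fc}, \code{ratio_slow}, \code{ratio_fast}, the two
#'   \code{traffic_result}s.
#' @export
occlusion_effect <- function(config, beta_factor = 60) {
  stopifnot(!is.null(config$orf2), beta_factor >= 1)
  fast <- simulate_traffic(config)
  cfs <- config; cfs$beta <- config$beta / beta_factor
  cfs$seed <- config$seed + 1L
  slow <- simulate_traffic(cfs)
  ratio_fast <- fast$flux_down / fast$flux
  ratio_slow <- slow$flux_down / slow$flux
  list(fc = ratio_slow / ratio_fast, ratio_slow = ratio_slow,
       ratio_fast = ratio_fast, slow = slow, fast = fast)
}
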