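#' Design of a simulated pooled barcoded competition experiment
#'
#' Encodes the conditions of a pooled competition: strains with known relative
#' fitness grow exponentially, the pool is serially diluted (each transfer
#' contributing \code{generations_per_transfer} generations), and barcode
#' abundances are read out as UMI-collapsed counts with multinomial sampling,
#' optional extra log2-ratio noise and optional index cross-talk.
#'
#' The defaults mirror the standard competition protocol: 7.8 generations per
#' transfer (a 70 ul into 16 ml dilution), 5 harvest points spanning about 30
#' generations, and technical log2-ratio noise of s.d. 0.2.
#'
#' @param n_strains number of barcoded strains in the pool.
#' @param true_s per-strain relative fitness (dimensionless; length
#'   \code{n_strains}, recycled if length 1).
#' @param generations_per_transfer generations elapsing between harvests.
#' @param n_timepoints number of harvest points (>= 2), the first at 0
#'   generations.
#' @param depth expected UMI count per strain per timepoint; \code{Inf} for
#'   exact (noise-free) expected counts.
#' @param sigma_log2r extra technical noise: the standard deviation of the
#'   log2 ratio of a strain pair contributed by multiplicative noise (each
#'   strain receives independent lognormal noise of log2-s.d.
#'   \code{sigma_log2r / sqrt(2)}).
#' @param crosstalk_intra,crosstalk_inter probability that a read is
#'   reassigned to a uniformly chosen other strain within the same timepoint
#'   pool (intra) or to a strain in a different timepoint pool (inter).
#' @param init_jitter s.d. of lognormal jitter on the (nominally 1:1)
#'   inoculation ratios, in log2 units.
#' @param genotype optional per-strain genotype labels (default one genotype
#'   per strain, \code{"WT"} where \code{true_s == 0}).
#' @param seed integer seed.
#' @return a list of class \code{sim_design}.
#' @export
sim_design <- function(n_strains = 20,
                       true_s = 0,
                       generations_per_transfer = 7.8,
                       n_timepoints = 5,
                       depth = 1e5,
                       sigma_log2r = 0.2,
                       crosstalk_intra = 0,
                       crosstalk_inter = 0,
                       init_jitter = 0,
                       genotype = NULL,
                       seed = 1L) {
  n_strains <- as.integer(n_strains)
  stopifnot(n_strains >= 2, n_timepoints >= 2, depth > 0,
            generations_per_transfer > 0, sigma_log2r >= 0, init_jitter >= 0)
  .check_prob(crosstalk_intra, "crosstalk_intra")
  .check_prob(crosstalk_inter, "crosstalk_inter")
  true_s <- rep_len(true_s, n_strains)
  if (is.null(genotype)) {
    genotype <- ifelse(true_s == 0, "WT", sprintf("g%03d", seq_len(n_strains)))
  } else genotype <- rep_len(genotype, n_strains)
  structure(list(n_strains = n_strains, true_s = true_s,
                 generations_per_transfer = generations_per_transfer,
                 n_timepoints = as.integer(n_timepoints), depth = depth,
                 sigma_log2r = sigma_log2r,
                 crosstalk_intra = crosstalk_intra,
                 crosstalk_inter = crosstalk_inter,
                 init_jitter = init_jitter, genotype = genotype, seed = seed),
            class = "sim_design")
}

#' Simulate UMI-collapsed barcode counts for a pooled competition
#'
#' Strain frequencies follow exponential pooled growth,
#' \eqn{f_i(t) \propto f_i(0)\, 2^{s_i T_{gen}(t)}}, renormalized to the pool
#' at each harvest. Counts are drawn multinomially at total depth
#' \code{n_strains * depth} per timepoint (so per-timepoint totals are
#' conserved), after applying per-(strain, timepoint) lognormal noise that
#' realizes the configured pair log2-ratio s.d. With \code{depth = Inf} and
#' \code{sigma_log2r = 0} the exact (real-valued) expected counts are
#' returned, so downstream slope fits recover \code{true_s} to machine
#' precision. Cross-talk, when enabled, reassigns reads after sampling and
#' preserves the grand total.
#'
#' @param design a \code{\link{sim_design}}.
#' @return a list of class \code{competition_sim} with elements
#'   \code{counts} (data.frame: experiment, condition, timepoint,
#'   generations, barcode, genotype, count), \code{truth} (data.frame:
#'   barcode, genotype, s_true) and \code{design}.
#' @examples
#' sim <- gen_competition_counts(sim_design(n_strains = 2,
#'   true_s = c(0, -0.05), depth = Inf, sigma_log2r = 0, seed = 7))
#' head(sim$counts)
#' @export
gen_competition_counts <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  n <- design$n_strains
  nt <- design$n_timepoints
  tgen <- (seq_len(nt) - 1) * design$generations_per_transfer
  barcode <- sprintf("bc%03d", seq_len(n))

  f0 <- rep(1, n)
  if (design$init_jitter > 0)
    f0 <- f0 * 2^rnorm(n, 0, design$init_jitter)

  exact <- !is.finite(design$depth) && design$sigma_log2r == 0
  total <- if (is.finite(design$depth)) round(design$depth * n) else NA

  counts <- matrix(0, nrow = n, ncol = nt)
  for (t in seq_len(nt)) {
    w <- f0 * 2^(design$true_s * tgen[t])
    if (design$sigma_log2r > 0)
      w <- w * 2^rnorm(n, 0, design$sigma_log2r / sqrt(2))
    p <- w / sum(w)
    if (exact || !is.finite(design$depth)) {
      counts[, t] <- p * (if (is.finite(design$depth)) total else n * 1e6)
    } else {
      counts[, t] <- rmultinom(1, total, p)
    }
  }

  ## cross-talk: each read moves with the stated probability to a uniformly
  ## chosen other (strain, pool) cell; intra stays within the timepoint pool
  if (design$crosstalk_intra > 0 && is.finite(design$depth)) {
    for (t in seq_len(nt)) {
      moved <- rbinom(n, counts[, t], design$crosstalk_intra)
      counts[, t] <- counts[, t] - moved
      for (i in which(moved > 0)) {
        dest <- sample(setdiff(seq_len(n), i), moved[i], replace = TRUE)
        tab <- tabulate(dest, n)
        counts[, t] <- counts[, t] + tab
      }
    }
  }
  if (design$crosstalk_inter > 0 && is.finite(design$depth) && nt > 1) {
    for (t in seq_len(nt)) {
      moved <- rbinom(n, counts[, t], design$crosstalk_inter)
      counts[, t] <- counts[, t] - moved
      for (i in which(moved > 0)) {
        dt <- sample(setdiff(seq_len(nt), t), moved[i], replace = TRUE)
        di <- sample(seq_len(n), moved[i], replace = TRUE)
        for (k in seq_len(moved[i])) counts[di[k], dt[k]] <-
            counts[di[k], dt[k]] + 1
      }
    }
  }

  out <- data.frame(
    experiment = "sim", condition = "cond1",
    timepoint = rep(seq_len(nt), each = n),
    generations = rep(tgen, each = n),
    barcode = rep(barcode, nt),
    genotype = rep(design$genotype, nt),
    count = as.vector(counts),
    stringsAsFactors = FALSE)
  structure(list(counts = out,
                 truth = data.frame(barcode = barcode,
                                    genotype = design$genotype,
                                    s_true = design$true_s,
                                    stringsAsFactors = FALSE),
                 design = design),
            class = "competition_sim")
}
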