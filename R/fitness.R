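#' Collapse reads to UMI counts
#'
#' Collapses a read table to molecule counts: the count for each
#' (sample, barcode) is the number of distinct UMIs observed (exact string
#' collapse). UMIs whose length differs from the fixed expected length are
#' treated as malformed: the rows are skipped and reported.
#'
#' @param reads data.frame with columns \code{sample}, \code{barcode},
#'   \code{umi}.
#' @param umi_length expected UMI length; defaults to the most common length
#'   in the table.
#' @return data.frame with columns \code{sample}, \code{barcode},
#'   \code{count}; skipped malformed rows are attached as attribute
#'   \code{"skipped"}.
#' @examples
#' collapse_umis(data.frame(sample = "s1", barcode = "bcA",
#'                          umi = c("AAAA", "AAAA", "CCCC")))
#' @export
collapse_umis <- function(reads, umi_length = NULL) {
  stopifnot(all(c("sample", "barcode", "umi") %in% names(reads)))
  if (nrow(reads) == 0)
    return(structure(data.frame(sample = character(0), barcode = character(0),
                                count = integer(0)),
                     skipped = reads))
  len <- nchar(reads$umi)
  if (is.null(umi_length)) {
    tab <- table(len)
    umi_length <- as.integer(names(tab)[which.max(tab)])
  }
  bad <- len != umi_length
  skipped <- reads[bad, , drop = FALSE]
  if (any(bad)) {
    message(sum(bad), " row(s) with malformed UMI length skipped")
    reads <- reads[!bad, , drop = FALSE]
  }
  key <- paste(reads$sample, reads$barcode, sep = "\r")
  mol <- !duplicated(paste(key, reads$umi, sep = "\r"))
  agg <- aggregate(mol, by = list(key = key), FUN = sum)
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  out <- data.frame(sample = vapply(parts, `[`, "", 1),
                    barcode = vapply(parts, `[`, "", 2),
                    count = as.integer(agg$x), stringsAsFactors = FALSE)
  out <- out[order(out$sample, out$barcode), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, skipped = skipped)
}

#' Generations elapsed across a serial dilution
#'
#' Under balanced exponential growth between harvests at a fixed density, the
#' number of generations per transfer is \eqn{-\log_2} of the dilution
#' factor. The standard protocol of diluting 70 ul into 16 ml gives
#' \eqn{-\log_2(70/16000) \approx 7.8} generations.
#'
#' @param factor dilution factor(s) in (0, 1); alternatively give
#'   \code{volume} and \code{into}.
#' @param volume,into transferred volume and final volume (same units).
#' @return generations per transfer (vectorized).
#' @examples
#' generations_from_dilution(volume = 70, into = 16000)  # 7.8
#' generations_from_dilution(1 / 1024)                   # 10
#' @export
generations_from_dilution <- function(factor = NULL, volume = NULL,
                                      into = NULL) {
  if (is.null(factor)) {
    if (is.null(volume) || is.null(into))
      stop("give either 'factor' or both 'volume' and 'into'")
    factor <- volume / into
  }
  if (any(!is.finite(factor)) || any(factor <= 0) || any(factor >= 1))
    stop("dilution factor must lie in (0, 1)")
  -log2(factor)
}

#' Log2 barcode-ratio trajectory for a strain pair
#'
#' Builds the per-timepoint log2 ratio of UMI counts for a pair of barcodes,
#' together with the Poisson counting-noise error
#' \eqn{\sigma_r = \frac{1}{\ln 2}\sqrt{1/N_1 + 1/N_2}} at each point.
#' Timepoints where either count is zero get \code{NA} ratios and are later
#' dropped (and flagged) by the slope fit.
#'
#' @param counts a \code{BarcodeCountTable}-style data.frame with columns
#'   \code{timepoint}, \code{generations}, \code{barcode}, \code{count}
#'   (optionally \code{condition}; one condition at a time).
#' @param barcode1,barcode2 the focal (numerator) and reference (denominator)
#'   barcode ids.
#' @return data.frame of class \code{ratio_trajectory}: \code{timepoint},
#'   \code{tgen}, \code{n1}, \code{n2}, \code{r}, \code{sigma_r}.
#' @export
ratio_trajectory <- function(counts, barcode1, barcode2) {
  need <- c("timepoint", "generations", "barcode", "count")
  stopifnot(all(need %in% names(counts)))
  a <- counts[counts$barcode == barcode1, c("timepoint", "generations", "count")]
  b <- counts[counts$barcode == barcode2, c("timepoint", "count")]
  m <- merge(a, b, by = "timepoint", suffixes = c("1", "2"))
  m <- m[order(m$timepoint), ]
  if (is.unsorted(m$generations)) stop("generations must be non-decreasing")
  out <- data.frame(timepoint = m$timepoint, tgen = m$generations,
                    n1 = m$count1, n2 = m$count2)
  ok <- out$n1 > 0 & out$n2 > 0
  out$r <- ifelse(ok, log2(out$n1 / out$n2), NA_real_)
  out$sigma_r <- ifelse(ok, sqrt(1 / out$n1 + 1 / out$n2) / log(2), NA_real_)
  class(out) <- c("ratio_trajectory", "data.frame")
  attr(out, "pair") <- c(barcode1, barcode2)
  out
}

#' Fit relative fitness from a log2-ratio trajectory
#'
#' Relative fitness of a strain pair is \eqn{1 + s} where \eqn{s} is the
#' ordinary least-squares slope of the log2 barcode-count ratio against
#' generations. Timepoints with a zero count in either strain are dropped and
#' flagged. The reported range \code{(s_min, s_max)} comes from resampling
#' timepoints with replacement and refitting; the confidence interval is
#' t-based on the slope by default (set \code{ci = "bootstrap"} for the
#' bootstrap percentile interval).
#'
#' @param traj a \code{\link{ratio_trajectory}}, or any data.frame with
#'   columns \code{tgen} and \code{r} (optionally \code{sigma_r}).
#' @param n_boot number of bootstrap resamples (timepoints with replacement).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level.
#' @param ci \code{"t"} (default) or \code{"bootstrap"}.
#' @return an object of class \code{fitness_fit} with components \code{s},
#'   \code{intercept}, \code{ci}, \code{s_min}, \code{s_max}, \code{boot},
#'   \code{n_used}, \code{dropped} (flagged timepoints), \code{data}.
#' @examples
#' tr <- data.frame(tgen = c(0, 7.8, 15.6, 23.4, 31.2))
#' tr$r <- 0.1 * tr$tgen
#' coef(fit_relative_fitness(tr, seed = 1))
#' @export
fit_relative_fitness <- function(traj, n_boot = 200, seed = NULL,
                                 conf = 0.95, ci = c("t", "bootstrap")) {
  ci <- match.arg(ci)
  stopifnot(all(c("tgen", "r") %in% names(traj)))
  usable <- is.finite(traj$r)
  dropped <- traj$timepoint[!usable] %||% which(!usable)
  d <- traj[usable, , drop = FALSE]
  if (nrow(d) < 2) stop("fewer than 2 usable timepoints")
  fit <- lm(r ~ tgen, data = d)
  s <- unname(coef(fit)[2])
  if (all(d$r == d$r[1])) s <- 0  # constant ratios: slope exactly 0

  .check_seed(seed)
  boot <- rep(NA_real_, n_boot)
  n <- nrow(d)
  for (b in seq_len(n_boot)) {
    for (try in 1:50) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(d$tgen[idx])) >= 2) break
    }
    xb <- d$tgen[idx]; yb <- d$r[idx]
    boot[b] <- .ols_slope(xb, yb)
  }
  boot <- boot[is.finite(boot)]
  ci_int <- if (ci == "t") {
    unname(suppressWarnings(confint(fit, "tgen", level = conf)))
  } else {
    quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  }
  if (all(d$r == d$r[1])) { boot[] <- 0; ci_int <- c(0, 0) }

  structure(list(s = s, intercept = unname(coef(fit)[1]),
                 ci = as.numeric(ci_int), conf = conf, ci_type = ci,
                 s_min = min(boot, s), s_max = max(boot, s),
                 boot = boot, n_used = n, dropped = dropped,
                 data = d, lm = fit, call = match.call()),
            class = "fitness_fit")
}

.ols_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

#' @export
print.fitness_fit <- function(x, ...) {
  cat(sprintf("Relative fitness s = %.4f  (bootstrap range %.4f .. %.4f)\n",
              x$s, x$s_min, x$s_max))
  cat(sprintf("%d%% CI (%s): [%.4f, %.4f];  %d timepoints used",
              round(100 * x$conf), x$ci_type, x$ci[1], x$ci[2], x$n_used))
  if (length(x$dropped)) cat(";", length(x$dropped), "dropped (zero counts)")
  cat("\n")
  invisible(x)
}

#' @export
coef.fitness_fit <- function(object, ...) {
  c(intercept = object$intercept, s = object$s)
}

#' @export
summary.fitness_fit <- function(object, ...) {
  structure(list(fit = object, lm_summary = summary(object$lm)),
            class = "summary.fitness_fit")
}

#' @export
print.summary.fitness_fit <- function(x, ...) {
  print(x$fit)
  cat("\nUnderlying regression:\n")
  print(x$lm_summary$coefficients)
  invisible(x)
}

#' @export
predict.fitness_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data
  object$intercept + object$s * newdata$tgen
}

#' @export
residuals.fitness_fit <- function(object, ...) {
  object$data$r - predict(object)
}

#' @export
plot.fitness_fit <- function(x, ...) {
  d <- x$data
  plot(d$tgen, d$r, xlab = "generations", ylab = "log2 barcode ratio",
       pch = 19, ...)
  if (!is.null(d$sigma_r))
    arrows(d$tgen, d$r - d$sigma_r, d$tgen, d$r + d$sigma_r,
           angle = 90, code = 3, length = 0.03)
  abline(x$intercept, x$s)
  invisible(x)
}

#' Closed-form precision of the least-squares fitness slope
#'
#' For \code{n_t} evenly spaced sampling points spanning \code{tgen_tot}
#' generations with iid log2-ratio noise of standard deviation
#' \code{sigma_log2r}, the standard deviation of the least-squares slope is
#' \deqn{\sigma_{s,LS} = \frac{\sigma_{\log_2 r}}{T_{gen}^{tot}}
#'       \sqrt{\frac{12 (n_t - 1)}{n_t (n_t + 1)}}.}
#' With \eqn{\sigma = 0.2}, \eqn{n_t = 5} and 4 transfers of 7.8 generations
#' (31.2 total) this gives 0.0081, i.e. sub-1\% fitness precision.
#'
#' @param sigma_log2r iid log2-ratio noise s.d.
#' @param n_t number of sampling points (>= 2).
#' @param tgen_tot total generations spanned.
#' @return the slope standard deviation (dimensionless, same scale as s).
#' @examples
#' design_precision(0.2, 5, 4 * 7.8)
#' @export
design_precision <- function(sigma_log2r, n_t, tgen_tot) {
  if (n_t < 2) stop("'n_t' must be at least 2")
  if (tgen_tot <= 0) stop("'tgen_tot' must be positive")
  if (sigma_log2r < 0) stop("'sigma_log2r' must be non-negative")
  sigma_log2r * sqrt(12 * (n_t - 1) / (n_t * (n_t + 1))) / tgen_tot
}

#' Precision audit from isogenic strain pairs
#'
#' Isogenic strains differing only by barcode should have s = 0; the spread
#' of their measured fitness values is an empirical lower bound on the
#' precision of the readout. Reports the standard deviation across pairs, the
#' median absolute s, and the resolution defined as +/- 2 s.d.
#'
#' @param s numeric vector of fitness estimates for same-genotype pairs, or a
#'   list of \code{fitness_fit} objects.
#' @return list of class \code{precision_report}: \code{sigma_s},
#'   \code{median_abs_s}, \code{resolution}, \code{n}, \code{s}.
#' @export
isogenic_precision <- function(s) {
  if (is.list(s) && all(vapply(s, inherits, TRUE, "fitness_fit")))
    s <- vapply(s, `[[`, numeric(1), "s")
  s <- as.numeric(s)
  if (length(s) < 2) stop("need at least 2 isogenic pairs")
  structure(list(sigma_s = sd(s), median_abs_s = median(abs(s)),
                 resolution = 2 * sd(s), n = length(s), s = s),
            class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat(sprintf(paste0("Isogenic precision over %d pairs: sigma_s = %.4f ",
                     "(%.2f%%), median |s| = %.4f, resolution +/- %.4f\n"),
              x$n, x$sigma_s, 100 * x$sigma_s, x$median_abs_s, x$resolution))
  invisible(x)
}

#' Subtract a control-genotype background from fitness estimates
#'
#' For comparisons against a background carrying a marker deletion, the small
#' fitness effect of the deletion itself is removed by subtracting the mean
#' control fitness (averaged across all conditions of one experiment).
#'
#' @param s numeric vector of fitness estimates.
#' @param control_mean mean fitness of the control genotype.
#' @return adjusted s, elementwise \code{s - control_mean}.
#' @export
subtract_background <- function(s, control_mean) {
  stopifnot(is.numeric(s), length(control_mean) == 1)
  s - control_mean
}

#' Resampling test for a fitness rescue between two sets of pairwise
#' differences
#'
#' Repeatedly draws medians of \code{length(focal)} values sampled with
#' replacement from the background set and from the focal set; the p-value is
#' the fraction of draws in which the background median is at least as
#' extreme as the focal median (direction set by \code{alternative}:
#' \code{"greater"} tests whether focal differences exceed background).
#'
#' @param focal numeric vector of focal pairwise fitness differences.
#' @param background numeric vector of background pairwise differences.
#' @param n_resample number of resampling draws.
#' @param seed integer seed.
#' @param alternative \code{"greater"} (focal > background, default) or
#'   \code{"less"}.
#' @return list with \code{p_value}, \code{n_resample}, medians.
#' @export
rescue_significance <- function(focal, background, n_resample = 1e4,
                                seed = NULL,
                                alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(focal) == 0 || length(background) == 0)
    stop("'focal' and 'background' must be non-empty")
  .check_seed(seed)
  nf <- length(focal)
  mb <- apply(matrix(sample(background, nf * n_resample, replace = TRUE),
                     nrow = nf), 2, median)
  mf <- apply(matrix(sample(focal, nf * n_resample, replace = TRUE),
                     nrow = nf), 2, median)
  extreme <- if (alternative == "greater") mb >= mf else mb <= mf
  list(p_value = mean(extreme), n_resample = n_resample,
       median_focal = median(focal), median_background = median(background),
       alternative = alternative)
}

#' Index cross-talk rates from a spike-in count matrix
#'
#' Spiked-in barcodes placed at known (PCR1 index x PCR2 index) positions
#' measure read misassignment. Columns are PCR2 pools: inter-pool cross-talk
#' is the fraction of all spike-in reads found in columns with no expected
#' cell; intra-pool cross-talk is the fraction of reads at wrong rows within
#' expected columns, relative to the reads in those columns.
#'
#' @param mat numeric matrix of spike-in read counts
#'   (rows = PCR1 indices, columns = PCR2 indices).
#' @param expected logical matrix of the same shape, \code{TRUE} where the
#'   spike-in was actually added.
#' @return list with \code{intra}, \code{inter}, \code{correct} (fraction of
#'   reads at expected cells).
#' @export
crosstalk_rates <- function(mat, expected) {
  stopifnot(is.matrix(mat), identical(dim(mat), dim(expected)))
  expected <- expected & TRUE
  total <- sum(mat)
  if (total == 0) stop("empty count matrix")
  exp_col <- colSums(expected) > 0
  inter_reads <- sum(mat[, !exp_col, drop = FALSE])
  in_exp_cols <- sum(mat[, exp_col, drop = FALSE])
  wrong_rows <- in_exp_cols - sum(mat[expected])
  list(intra = if (in_exp_cols > 0) wrong_rows / in_exp_cols else 0,
       inter = inter_reads / total,
       correct = sum(mat[expected]) / total)
}

#' Fit relative fitness for every barcode in a pool against a reference
#' genotype
#'
#' Pairs every non-reference barcode with every reference-genotype barcode,
#' fits each pair's slope, and summarizes per genotype as the median s with
#' 25th-75th percentile bars. Same-genotype (isogenic) pairs among the
#' reference barcodes are also fitted and returned as a precision audit.
#'
#' @param counts count table as in \code{\link{ratio_trajectory}}, with a
#'   \code{genotype} column.
#' @param reference reference genotype id (e.g. \code{"WT"}).
#' @param n_boot,seed passed to \code{\link{fit_relative_fitness}}.
#' @param min_count timepoints where either count is below this value are
#'   treated as unusable (default 1, i.e. only zero counts dropped).
#' @return list of class \code{pool_fitness}: \code{estimates} (per-pair
#'   data.frame), \code{genotypes} (per-genotype median and quartiles),
#'   \code{audit} (\code{\link{isogenic_precision}} over reference pairs, or
#'   NULL if fewer than two reference barcodes).
#' @export
fit_pool <- function(counts, reference = "WT", n_boot = 0, seed = NULL,
                     min_count = 1) {
  stopifnot("genotype" %in% names(counts))
  .check_seed(seed)
  map <- unique(counts[, c("barcode", "genotype")])
  ref_bc <- map$barcode[map$genotype == reference]
  if (length(ref_bc) == 0) stop("no barcodes with reference genotype")
  other <- map[map$genotype != reference, , drop = FALSE]

  fit_one <- function(b1, b2) {
    tr <- ratio_trajectory(counts, b1, b2)
    tr$r[tr$n1 < min_count | tr$n2 < min_count] <- NA
    f <- fit_relative_fitness(tr, n_boot = n_boot)
    c(s = f$s, s_min = f$s_min, s_max = f$s_max)
  }

  res <- list()
  for (i in seq_len(nrow(other))) for (rb in ref_bc) {
    v <- fit_one(other$barcode[i], rb)
    res[[length(res) + 1L]] <- data.frame(
      barcode = other$barcode[i], genotype = other$genotype[i],
      reference_barcode = rb, s = v["s"], s_min = v["s_min"],
      s_max = v["s_max"], stringsAsFactors = FALSE)
  }
  estimates <- do.call(rbind, res)
  rownames(estimates) <- NULL

  gsum <- do.call(rbind, lapply(split(estimates$s, estimates$genotype),
    function(v) data.frame(median_s = median(v),
                           q25 = quantile(v, 0.25, names = FALSE),
                           q75 = quantile(v, 0.75, names = FALSE),
                           n_pairs = length(v))))
  gsum$genotype <- rownames(gsum); rownames(gsum) <- NULL

  audit <- NULL
  if (length(ref_bc) >= 3) {  # need >= 2 isogenic pairs for a spread
    iso <- utils::combn(ref_bc, 2)
    s_iso <- apply(iso, 2, function(p) fit_one(p[1], p[2])["s"])
    audit <- isogenic_precision(as.numeric(s_iso))
  }
  structure(list(estimates = estimates, genotypes = gsum, audit = audit,
                 reference = reference),
            class = "pool_fitness")
}

#' @export
print.pool_fitness <- function(x, ...) {
  cat("Pooled competition fitness vs reference '", x$reference, "'\n",
      sep = "")
  print(x$genotypes)
  if (!is.null(x$audit)) print(x$audit)
  invisible(x)
}
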