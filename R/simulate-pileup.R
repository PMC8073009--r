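#' Configuration for synthetic ribosome-footprint pileups
#'
#' Emulates center-mapped footprint density over an annotated genome:
#' each gene's body density is proportional to its translation efficiency;
#' genes whose stop codon has a termination slowdown > 1 receive
#' stop-proximal periodic peaks (one footprint apart, about 25 nt) whose
#' amplitude grows with expression; a readthrough plateau at the configured
#' fraction of the body density is placed downstream of the stop. Noise is
#' Poisson per position (or none).
#'
#' @param te per-gene translation efficiency: either a single lognormal
#'   log-sd (numeric scalar; TE drawn per gene with median 1), or a numeric
#'   vector of per-gene TE values matching the annotation.
#' @param slowdown named numeric over stop codons: termination slowdown
#'   (>= 1; 1 = unperturbed).
#' @param readthrough named numeric over stop codons: readthrough fraction
#'   in [0, 1].
#' @param queue_period queue spacing in nt (default 25).
#' @param queue_peaks number of queue peaks injected when slowed (default 3).
#' @param depth mean body density (reads/nt) for a TE = 1 gene (default 2).
#' @param noise \code{"poisson"} or \code{"none"}.
#' @param backend \code{"inject"} (phenomenological peak injection, default)
#'   or \code{"tasep"} (mechanistic profiles from
#'   \code{\link{simulate_traffic}}).
#' @param seed integer seed.
#' @return list of class \code{sim_profile_config}.
#' @export
sim_profile_config <- function(te = 0.75,
                               slowdown = c(UAA = 1, UAG = 1, UGA = 1),
                               readthrough = c(UAA = 0, UAG = 0, UGA = 0),
                               queue_period = 25, queue_peaks = 3,
                               depth = 2, noise = c("poisson", "none"),
                               backend = c("inject", "tasep"),
                               seed = 1L) {
  noise <- match.arg(noise); backend <- match.arg(backend)
  slowdown <- slowdown[STOP_CODONS]; readthrough <- readthrough[STOP_CODONS]
  if (any(is.na(slowdown)) || any(slowdown < 1))
    stop("'slowdown' must cover all stop codons with values >= 1")
  if (any(is.na(readthrough)) || any(readthrough < 0) ||
      any(readthrough > 1))
    stop("'readthrough' fractions must lie in [0, 1]")
  if (queue_period <= 0) stop("'queue_period' must be positive")
  structure(list(te = te, slowdown = slowdown, readthrough = readthrough,
                 queue_period = queue_period, queue_peaks = queue_peaks,
                 depth = depth, noise = noise, backend = backend,
                 seed = seed),
            class = "sim_profile_config")
}

#' Generate a synthetic footprint pileup with known ground truth
#'
#' @param ann a \code{gene_annotation}.
#' @param profile a \code{\link{sim_profile_config}}.
#' @return list of class \code{pileup_sim}: \code{track}
#'   (\code{\link{pileup_track}}, center-mapped) and \code{truth}
#'   (data.frame: gene_id, te, stop_codon, slowdown, readthrough,
#'   body_density).
#' @examples
#' ann <- gen_annotation(sim_annotation_config(n_genes = 10, seed = 3))
#' sim <- gen_pileup(ann, sim_profile_config(noise = "none", seed = 3))
#' @export
gen_pileup <- function(ann, profile) {
  stopifnot(inherits(profile, "sim_profile_config"))
  set.seed(profile$seed)
  n <- nrow(ann)
  te <- if (length(profile$te) == 1) rlnorm(n, 0, profile$te) else
    rep_len(profile$te, n)

  chrom_len <- max(ann$end) + 1000L
  lambda <- list()  # per (chrom, strand) expected-density vectors
  for (ch in unique(ann$chrom)) {
    lambda[[ch]] <- list("+" = numeric(chrom_len), "-" = numeric(chrom_len))
  }

  body_density <- numeric(n)
  for (i in seq_len(n)) {
    L <- ann$end[i] - ann$start[i]
    sc <- ann$stop_codon[i]
    dens <- profile$depth * te[i]
    body_density[i] <- dens
    if (profile$backend == "tasep") {
      prof <- .tasep_gene_profile(L, te[i], profile)
      gene_lambda <- dens * prof / mean(prof)
    } else {
      gene_lambda <- rep(dens, L)
      if (!is.na(sc) && profile$slowdown[sc] > 1) {
        ## periodic stop-proximal queue peaks, amplitude scaling with
        ## expression (higher-TE genes queue more)
        amp <- dens * (profile$slowdown[sc] - 1)
        for (p in seq_len(profile$queue_peaks) - 1) {
          center <- L - 1 - p * profile$queue_period
          if (center < L / 2) break  # keep the normalization half clean
          idx <- pmax(1, pmin(L, (center - 2):(center + 2) + 1))
          gene_lambda[idx] <- gene_lambda[idx] + amp
        }
      }
    }
    rt <- if (is.na(sc)) 0 else profile$readthrough[sc]
    down <- rep(dens * rt, 60)

    ## write expected densities (transcription sense) into genomic axis
    if (ann$strand[i] == "+") {
      gidx <- (ann$start[i] + 1L):(ann$end[i])
      didx <- (ann$end[i] + 1L):(ann$end[i] + 60L)
    } else {
      gidx <- (ann$end[i]):(ann$start[i] + 1L)
      didx <- (ann$start[i]):(ann$start[i] - 59L)
    }
    ok <- gidx >= 1 & gidx <= chrom_len
    v <- lambda[[ann$chrom[i]]][[ann$strand[i]]]
    v[gidx[ok]] <- v[gidx[ok]] + gene_lambda[ok]
    okd <- didx >= 1 & didx <= chrom_len
    v[didx[okd]] <- v[didx[okd]] + down[okd]
    lambda[[ann$chrom[i]]][[ann$strand[i]]] <- v
  }

  track <- pileup_track(setNames(rep(chrom_len, length(lambda)),
                                 names(lambda)), mapping = "center")
  for (ch in names(lambda)) for (st in c("+", "-")) {
    v <- lambda[[ch]][[st]]
    if (profile$noise == "poisson") v <- rpois(length(v), v)
    track$counts[[ch]][[st]] <- as.numeric(v)
  }

  truth <- data.frame(
    gene_id = ann$gene_id, te = te, stop_codon = ann$stop_codon,
    slowdown = profile$slowdown[ann$stop_codon],
    readthrough = profile$readthrough[ann$stop_codon],
    body_density = body_density, stringsAsFactors = FALSE)
  structure(list(track = track, truth = truth, profile = profile),
            class = "pileup_sim")
}

## mechanistic per-gene profile: occupancy of an l-TASEP with initiation
## rate proportional to TE and termination slowed per the profile config
.tasep_gene_profile <- function(L_nt, te, profile) {
  L_cod <- max(ceiling(L_nt / 3), 12)
  sc_slow <- max(profile$slowdown)
  cf <- traffic_config(length = L_cod, alpha = 0.05 * te, k = 10,
                       beta = 10 / sc_slow, time = 600, burnin = 100,
                       seed = sample.int(.Machine$integer.max / 2, 1))
  occ <- simulate_traffic(cf)$occupancy
  prof <- rep(occ, each = 3)[seq_len(L_nt)]
  prof[prof <= 0] <- min(prof[prof > 0], 1e-3)
  prof
}
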