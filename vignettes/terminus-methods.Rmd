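---
title: "Methods and design notes for terminus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for terminus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terminus)
```

`terminus` re-implements, as one tested pipeline, the quantitative analyses
that connect a molecular perturbation of bacterial translation termination to
its systemic physiological consequences: pooled-competition fitness, proteome
sector accounting with growth-law predictions, ribosome-profiling signatures
of termination stress, and operon-stoichiometry statistics. This vignette
explains each model, the tunable parameters and their defaults, the
synthetic-data generators used for validation, and the numerical choices
made where the design was genuinely open.

## Relative fitness from pooled barcoded competitions

Strains carrying chromosomal barcodes compete in one pool under serial
dilution. Under exponential growth with no strain interactions, the log2
ratio of a mutant's barcode count to a reference is linear in generations,

$$\log_2 \frac{R_{mut}(t)}{R_{ref}(t)} = \mathrm{const} + s\,T_{gen},$$

and the relative fitness is $1 + s$, with $s$ the ordinary least-squares
slope. Generations are counted as $-\log_2$ of the dilution factor per
transfer; the standard 70 ul into 16 ml protocol gives
`generations_from_dilution(volume = 70, into = 16000)` $\approx 7.8$
generations, and competitions run for 4 transfers (5 harvests, about 31
generations).

Error model. Each point carries a Poisson counting error
$\sigma_r = \frac{1}{\ln 2}\sqrt{1/N_1 + 1/N_2}$ on the log2 ratio
(`ratio_trajectory()`). Technical noise beyond counting is summarized as an
iid log2-ratio standard deviation $\sigma_{\log_2 r} \approx 0.2$, a value
measured by fixed-ratio mixing controls in the original protocol and adopted
here as the generator default. Under that model the least-squares slope for
$n_t$ evenly spaced samplings spanning $T_{gen}^{tot}$ generations has
standard deviation

$$\sigma_{s,LS} = \frac{\sigma_{\log_2 r}}{T_{gen}^{tot}}
  \sqrt{\frac{12\,(n_t - 1)}{n_t\,(n_t + 1)}},$$

which is the exact OLS result (`design_precision()`); at
$\sigma = 0.2,\ n_t = 5,\ T_{gen}^{tot} = 31.2$ it evaluates to 0.0081,
i.e. sub-1% fitness resolution. We use this exact form rather than the
large-$n_t$ approximation throughout.

Open choices resolved here:

* **Bootstrap range.** The reported $(s_{min}, s_{max})$ comes from
  resampling timepoints with replacement (200 resamples by default) and
  refitting; this respects the regression structure when the scheme is not
  otherwise pinned down.
* **Confidence interval.** Both a t-based interval on the slope (default)
  and a bootstrap percentile interval are available
  (`fit_relative_fitness(ci = )`). The t interval has exact nominal
  coverage under the iid-Gaussian noise model and is verified at
  95% $\pm$ 3% over 500 simulated pools in the test suite.
* **Zero counts.** A timepoint with a zero count in either strain is
  dropped from that pair's fit and flagged; no pseudocounts are fabricated.
* **Shared clock.** All strains share the reference generations axis, valid
  because most pool members grow at near-reference rates.

The isogenic audit (`isogenic_precision()`) treats same-genotype barcode
pairs as null comparisons: their spread $\sigma_s$ lower-bounds the
measurement precision and the resolution is quoted as $\pm 2\sigma_s$.
Background subtraction (`subtract_background()`) removes the mean control
fitness across all conditions of an experiment, and `rescue_significance()`
implements the with-replacement median-resampling test for fitness rescues
(drawing focal-sized samples from focal and background difference sets).

The competition generator (`gen_competition_counts()`) implements its noise
as independent lognormal factors per (strain, timepoint) with log2-s.d.
$\sigma_{\log_2 r}/\sqrt{2}$, so a pair's ratio realizes the full
$\sigma_{\log_2 r}$; multinomial sampling at fixed pool depth conserves
per-timepoint totals, and index cross-talk (intra- and inter-pool read
reassignment) is available but off by default. With `depth = Inf` and zero
noise the generator returns exact expectations, which the estimator must
recover to $10^{-9}$ - this separates estimator correctness from sampling
noise. What the generator does not emulate: lag phases between dilutions,
barcode-specific PCR efficiencies, and UMI saturation; conclusions about
those require the wet-lab controls, not this package.

## Expression quantification and proteome sectors

Per-gene quantities come from strand-aware per-position tracks
(`pileup_track`): 3'-end counts for RNA-seq, center-mapped footprints
(14-44 nt size range, recorded as metadata) for ribosome profiling. Mean
density excludes 20 nt at each gene edge; rpkm normalizes by total reads
not mapping to rRNA/tRNA. The transcriptome fraction of a gene uses its
full-gene read count over the same denominator. The proteome synthesis
fraction is density x gene length normalized over (mRNA) genes, which
equals the proteome mass fraction for a stable proteome. Stop-codon usage
is the synthesis-fraction-weighted (flux) share of each stop codon or stop
tetranucleotide.

Sector calibration: matched mRNA and footprint measurements give
$\phi_R = \alpha\,\psi_R$ with $\alpha \approx 1.1$ for the translation
sector (release factors RF1/RF2/PrmC excluded from the member sum to avoid
confounding by their own perturbation), and
$\phi = \alpha(\psi - \psi_0) + \phi_0$ with $\alpha \approx 1.41$ for the
general-stress (sigma-B) regulon, whose induced mRNA isoforms are better
translated than the basal ones. `calibrate_sector()` implements both maps
and their inverses; TE fold-changes for ectopic constructs default to 3.0
(RF2), 0.66 (RF1) and 1 (PrmC, the parsimonious assumption exposed as
configuration).

Coordinates are 0-based half-open internally, 1-based closed in GFF3, and
0-based half-open in bedGraph; minus-strand genes are processed on the
transcription-sense axis so "first half of gene" and "downstream of the
stop" mean the same thing on both strands, a property enforced by
strand-reflection invariance tests.

## Growth laws and proteome compression

Growth-law lines are fitted on relative growth rate ($\lambda = 1 + s$,
reference = 1): the translation line
$\lambda = \kappa_t(\phi_R - \phi_0)$ and the nutrition line
$\lambda = \kappa_n(\phi_R^{max} - \phi_R)$ (`fit_growth_line()`).
Gratuitous expression of a proteome fraction $\phi_U$ is predicted to
compress all other sectors. Two models are provided
(`predict_compression()`):

* **proportional**: every other fraction scales by $(1 - \phi_U)$ and
  $\Delta s = -\phi_U$, the empirical one-to-one compression;
* **growth_law (reconstructed)**: the steady state is the intersection of
  the two lines with $\phi_R^{max} \mapsto \phi_R^{max} - \phi_U$, giving
  $\Delta\lambda = -\kappa_t\kappa_n\,\phi_U/(\kappa_t+\kappa_n)$ and a
  relative defect $\phi_U/(\phi_R^{max} - \phi_0)$, always at least the
  proportional one. The underlying two-line derivation is reconstructed
  from the fitted parameters $(\kappa_t, \kappa_n, \phi_0, \phi_R^{max})$;
  outputs are labelled accordingly.

`trajectory_report()` fits the slopes of $\phi_R$ and $\Delta s$ against
$\phi_U$ and flags whether the one-to-one slope $-1$ lies in the CI.
`gen_condition_series()` builds induction series with exact sector
book-keeping: regulon genes are scaled to hit a target expression fraction,
everything else scales by $(1-\psi_t)/(1-\psi_0)$ so the total is
preserved; the recorded truths make the quantifier round-trip testable to
1%.

## Termination stress from ribosome profiling

Metagene traces (`metagene_stop_profile()`): genes expressed above 0.5
footprint reads/nt are normalized by their mean density over the first half
of the gene, aligned at the stop codon (offset 0 = last stop nucleotide),
and summarized by the per-offset median per stop-codon class. The window
defaults to [-150, +60] nt (not dictated by the protocol; configurable),
and genes shorter than twice the upstream window are excluded so
normalization cannot overlap the stop-proximal region. Queues appear as
periodic peaks about 25 nt apart (one footprint); `queue_metric()` counts
successive peaks on the period grid ($\pm$5 nt) exceeding 2x the upstream
flank median - peak counting is the default because it directly estimates
the number of stalled ribosomes, with an integrated excess-density variant
(`mode = "excess"`) available as a cross-check.

Readthrough (`readthrough_score()`): the ratio of mean density in +5..+45
nt after the stop to the gene-body mean, computed only for isolated genes
(nearest co-directional neighbours > 55 nt away, overlapping neighbours
count as distance $\le 0$) with body density > 0.1 reads/nt. Scores above
1 are retained but flagged (unannotated ORFs, repeats).

The pileup generator injects queues phenomenologically (5-nt-wide peaks at
0, -25, -50 nt with amplitude proportional to expression and slowdown) and
a downstream readthrough plateau; a mechanistic backend delegates per-gene
profiles to the traffic simulator. Tests use injection for speed and the
simulator for mechanism, so the analyzers are never validated against the
simulator's own assumptions only.

## Operon pair stoichiometry and the reshuffling null

Adjacent co-directional genes are paired with signed intergenic distance
$d$ = downstream start minus upstream stop end in transcription sense; the
shared A-UGA start/stop punctuation gives $d = -4$ and is verified against
the genome motif (ATGA) when sequence is available. Pair stoichiometry is
the downstream/upstream density ratio; effects are fold-changes of that
ratio between conditions, computed only when both genes exceed 10 reads
(strictly) in both conditions. Distance stratification treats "within 30
bp" as $d \le 30$ including overlaps.

The significance of a stop-codon-specific effect uses label reshuffling:
the effect size is median FC(focal stop) / median FC(UAA), labels are
permuted across the analyzed pairs (the natural exchangeable set), and the
p-value is the add-one-corrected fraction of reshufflings with a strictly
smaller (more pronounced) effect. The strict inequality matters only under
ties and keeps the degenerate all-ties case at $p = 1/(n_{perm}+1)$.
Permutations default to $10^4$ in tests (configurable; studies quoting
$P < 10^{-6}$ imply $10^6$ reshuffles). Calibration is verified by
simulation: under a stop-neutral null the rejection rate at $p < 0.05$ is
5% and the p-value distribution is uniform (KS-checked over 2,000
simulated pair sets).

`cluster_hits()` supports the comparative-genomics step: single-linkage
clustering of homology-hit intervals within 100 bp, retaining clusters
containing all required members, with optional co-orientation and
gene-order filters and one best call per species. It consumes a
precomputed hit table; running the homology search is out of scope.

## The ribosome-traffic simulator

`simulate_traffic()` is a continuous-time exclusion process (an
$\ell$-TASEP with open boundaries) on a codon lattice: footprint 10 codons
(about 30 nt, matching the observed queue spacing), initiation at rate
$\alpha$ into a free first footprint ($\alpha$ is the mechanistic proxy
for translation efficiency), elongation at rate $k$ per unblocked
ribosome, termination at rate $\beta$ at the stop, and optional
readthrough as a competing reaction at rate $\gamma$. Time units are
arbitrary; only ratios matter. The event loop is implemented in C++ (Rcpp)
with a seeded Mersenne-Twister so identical seeds give identical event
sequences. Reported statistics are time-averaged post burn-in: per-site
coverage occupancy, completion flux, cross-section fluxes (conservation
check), and the mean contiguous queue at the stop.

This simulator is a mechanistic stand-in for the stochastic queuing theory
behind the observed phenomenology; it reproduces the two qualitative laws
the data show (queues form at slow stops; queues grow with initiation
rate) and the steric occlusion of downstream initiation for closely spaced
pairs (`occlusion_effect()`), where slowing termination 60-fold suppresses
the downstream/upstream flux ratio only when the idle ribosome's footprint
overlaps the downstream start. Not modelled: ribosome drop-off,
collision-triggered mRNA cleavage, tRNA competition, and codon-specific
elongation rates.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: constant ratio trajectories give
$s = 0$ with a zero-width bootstrap range; all-equal $\phi_R$ states are a
fit error; empty focal stop classes are an error; genes failing filters are
excluded with reason codes rather than silently. Validation problem sizes
were chosen to keep each check's Monte-Carlo error well below its
tolerance: 500 simulated pools for slope-noise calibration, 10,000
trajectories for the design-precision estimate, 2,000 pair sets for null
calibration of the reshuffling test, 90-gene genomes for termination-stress
round trips, and simulator runs long enough that section-flux agreement is
tested at 3 counting standard errors.

## Limitations

The generators validate the estimators under the stated noise models; they
do not establish robustness to real-data pathologies (mapping artifacts,
rRNA contamination spikes, condition-dependent footprint size shifts,
unannotated ORFs beyond their effect on flagged readthrough scores).
Alignment, end-enrichment peak calling, and homology searching are upstream
of this package. The growth-law compression model is a reconstruction from
fitted line parameters, and the sigma-B calibration constants are
empirical conversions, not mechanistic predictions.
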