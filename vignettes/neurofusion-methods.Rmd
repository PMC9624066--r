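---
title: "Cross-modal decoding and representational fusion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal decoding and representational fusion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neurofusion)
```

`neurofusion` compares visual object representations across EEG, ECoG and
fMRI at the level of population codes: time-resolved multivariate
decoding, representational similarity analysis (RSA), cross-modal fusion,
and nonparametric inference, exercised end to end on a synthetic
multimodal generator with known ground truth. This vignette explains the
models behind each stage, the parameters that matter, the design choices
made where the design was genuinely open, and what the synthetic
validation studies do and do not establish.

## The experimental design

All analyses assume the 125-condition object-vision factorial: 5
categories × 5 identities × 5 viewing conditions (`v1` = 3° size/0°
rotation, `v2` = 3°/45°, `v3` = 3°/90°, `v4` = 1.5°/0°, `v5` = 6°/0°).
`make_design()` enumerates trials in a fixed canonical order (category,
then identity, then variation), and `condition_id` 1..125 indexes the
distinct triples. Under the full EEG design with 32 repetitions this
yields 4000 trials — 800 per category, of which 160 fall in the reference
condition `v1`; the fMRI design with 8 runs yields 125 beta estimates per
run, hence 175 training positives per leave-one-run-out fold and 40
reference-condition trials per category. These integers are asserted
exactly in the test suite.

## The synthetic generator

A trial of condition (category $c$, identity $i$, variation $v$) is

$$x(t) \;=\; a_c\, p_{civ}\, g(t) \;+\; \varepsilon(t),$$

where $p_{civ}$ is a unit-norm spatial pattern, $a_c$ a per-category
amplitude in units of the noise SD, $g(t)$ a temporal envelope, and
$\varepsilon$ Gaussian noise that is spatially correlated
(exponential decay over channel-index distance, scale
`channel_corr_scale`) and temporally AR(1)-smoothed
(`temporal_smoothing`). Choices worth spelling out:

* **Envelope.** $g$ is a Gaussian bump whose SD is derived from
  (`signal_onset`, `signal_peak`) by the rule that the envelope first
  exceeds 5% of its peak exactly at `signal_onset`; below the 5% floor the
  envelope is exactly zero. A smooth bump with an analytically known onset
  makes latency-recovery tests meaningful, and the hard floor guarantees
  pre-onset samples are pure noise, keeping null calibrations honest. The
  defaults (onset 80 ms, peak 150 ms) match the early visual response.
* **Invariance mixing.** $p_{civ} \propto \rho_\text{inv}\, s_c +
  (1-\rho_\text{inv})\, q_{cv} + j\, z_{ci}$, renormalized: a
  category-shared direction $s_c$, a variation-specific direction
  $q_{cv}$, and a variation-*independent* identity component $z_{ci}$
  (weight `identity_jitter`, default 0.3). At $\rho_\text{inv} = 1$
  patterns are identical across viewing conditions, so cross-decoding
  equals within-decoding; at 0 each viewing condition is unrelated. The
  identity component models the fact that individual objects evoke partly
  distinct patterns — it is what gives the 125-condition RDMs their
  within-category structure — and, being variation-independent, it leaves
  the $\rho_\text{inv} = 1$ contract intact.
* **Amplitudes.** The default `category_amplitudes` (face largest)
  reproduce the robust face advantage of visual decoding studies and put
  single-participant EEG peak accuracies in a realistic 0.75–1.0 band at
  the test problem sizes.
* **ECoG.** Electrodes are generated already pooled across pseudo-patients
  (a "super-subject", mirroring how sparse intracranial coverage is
  handled in practice), with region labels, per-region latency offsets
  (posterior regions first), a configurable fraction of non-selective
  (noise-only) electrodes, and noise correlated only within a region
  (electrodes from different patients share no noise source). Two
  modality-specific terms matter. First, the response rides on a rectified
  carrier, $g(t)\,\lvert\sin(2\pi f t)\rvert$ with `ecog_carrier_hz`
  defaulting to 60 Hz: intracranial category responses are broadband
  power modulations, and a slow bump alone would be invisible to the
  range features used to decode ECoG (a constant within a 25 ms bin has
  zero range). Second, `ecog_amplitude_scale` (default 4) reflects the
  far larger single-trial effect sizes of visually selective intracranial
  electrodes compared with scalp sensors; the default puts super-subject
  range-feature decoding in the 0.6–0.9 peak band typical of intracranial
  reports.
* **fMRI.** Per participant × ROI × run, each condition contributes one
  beta row: the (category, identity, variation) pattern over `n_voxels`,
  scaled by `roi_snr[roi]`, plus unit Gaussian voxel noise. The default
  SNR map grades from occipital-inferior (1.0) down to temporal-pole
  (0.15) cortex, emulating signal loss near the ear canals.
* **Reproducibility.** Participant $k$ draws from a stream seeded with
  $(1000\,\text{seed} + k) \bmod 2147483629$ — participants are
  independent yet individually reproducible, and identical parameters give
  bit-identical output.

The generator does **not** model volume conduction or forward head
models, hemodynamic convolution, eye/muscle artifacts, or trial-to-trial
amplitude variability. Passing tests therefore demonstrate that the
analysis code recovers known structure under realistic noise covariance
and SNR — not that it is robust to every artifact of real recordings.

## Preprocessing

The minimal EEG conditioning chain is: zero-phase FIR low-pass (Hamming
window, default order 396, cutoff 40 Hz, taps normalized to unit DC
gain), resampling to 1 kHz, re-referencing to a mastoid-like channel, and
epoching from −100 to +600 ms. Decisions:

* Filtering is applied causally after edge-replication padding and then
  shifted back by half the order, so the filter is effectively zero-phase
  and group delay cannot bias latency estimates.
* Resampling requires a rational rate ratio (grids stay commensurate),
  applies an internal zero-phase anti-alias low-pass at
  $0.45 \times$ the target rate when downsampling (a no-op after the
  40 Hz low-pass), and reconstructs the band-limited signal on the new
  grid by cubic splines, whose error is negligible far below Nyquist
  (verified against closed-form sinusoids at $10^{-3}$ amplitude
  tolerance).
* Epoch windows are closed at both ends on the sample grid; 0 ms is the
  event sample. No baseline correction is applied anywhere, and no
  high-pass filter is used (high-pass filtering is known to displace
  multivariate patterns into activity-silent periods).

## Decoding

One-vs-rest linear classification per category, with chance at 0.5:

1. **Balancing.** The four non-target categories are subsampled uniformly
   without replacement to the target count (800 vs 800 in the full EEG
   selectivity design; 160 vs 160 in the invariance schemes).
2. **Pseudo-trials** (category selectivity only). The balanced positives
   and negatives are each randomly partitioned into `n_pseudotrials` sets
   (sizes differing by at most one — 800 trials into 150 sets gives 100
   sets of 5 and 50 of 6) and averaged within sets.
3. **Multivariate noise normalization.** $W = \Sigma^{-1/2}$, with
   $\Sigma$ the per-class, per-timepoint covariance of training residuals
   averaged over timepoints and classes, shrunk toward
   $\bar{\sigma}^2 I$ (weight `shrinkage`, default 0.2). $\Sigma$ is
   estimated from the training fold only, so the test data never leak
   into the transform; with too few trials per class the estimate falls
   back to pooled residuals around the grand mean.
4. **Classifier.** Linear max-margin SVM with fixed `C = 1` (recorded in
   provenance). Decision values are computed from the support-vector
   expansion; exact ties go to the negative class, deterministically.
5. **Cross-validation.** Category selectivity uses leave-one-pseudo-trial-
   out; each fold holds out one pseudo-trial of *each* class, so training
   stays exactly balanced in every fold — holding out a single item
   leaves a 149-vs-150 imbalance whose majority-class pull biases the
   null visibly below chance at the small pseudo-trial counts used in
   testing. The invariance schemes train once on the balanced reference-
   condition pool and test every trial of each held-out viewing condition
   (balanced test sets), averaging the two test conditions. `max_folds`
   optionally evaluates a seeded random subset of folds (Monte-Carlo
   cross-validation) where full leave-one-out is wasteful.
6. **Aggregation.** Mean over folds → repeats → (per category) →
   participants. `n_repeats` defaults to 300 for selectivity and 150 for
   the invariance schemes.

Static patterns (fMRI betas, ECoG range features) run the same procedure
with leave-one-run-out (`cv = "run"`) or paired leave-one-trial-out
(`cv = "trial"`); test sets are balanced so chance stays at 0.5. ECoG
features are the per-electrode signal range (max − min) in 25 ms bins
tiling 50–300 ms half-open — a 250 ms window gives 10 bins per electrode,
and a pure ramp of slope $s$ yields exactly $24s$ per bin at 1 kHz.

## RSA and fusion

RDMs use $1 - \rho_\text{Spearman}$ (mid-ranks for ties) between
condition-mean feature patterns; matrices are symmetric with an undefined
(NaN) diagonal, and the upper triangle in row-major order is the
canonical vectorization. EEG RDMs are computed per timepoint per
participant and averaged elementwise (undefined entries propagate);
regional ECoG RDMs split the super-subject's electrodes by region — a
single all-electrode region reproduces the pooled stack bit-exactly. The
group-mean RDM averages dissimilarities directly without rank-transforming
first (simpler, and recorded in provenance). Constant patterns have no
rank variance; their entries are undefined, flagged with a warning, and
excluded pairwise downstream. By default ECoG RDM features are the raw
amplitude patterns at each sample; the 25 ms range-feature variant is
available through `ecog_feature_vector()`.

Fusion correlates upper-triangle vectors per timepoint (a static RDM is
broadcast across time), with a condition-label permutation test (rows and
columns of one RDM permuted jointly; $p = (1 + \#\{\rho^* \ge
\rho_\text{obs}\})/(1 + n_\text{perm})$, the +1 convention avoiding zero
p-values) and FDR correction over the curve; undefined correlations are
excluded from the FDR family. For EEG–ECoG accuracy-timecourse
comparisons on mismatched grids, the 1 ms curve is averaged within 25 ms
bins and compared at bin centers — resolution is never fabricated by
interpolation — and overall timecourse correlations use post-stimulus
samples by default. The upper-bound noise ceiling — the mean Spearman
correlation between each participant's RDM and the group mean including
that participant — serves as the regional fMRI SNR proxy; note its
self-inclusion bias scales like $1/\sqrt{N}$ and is shared across
regions, so regional *comparisons* remain meaningful.

## Inference

* Wilcoxon signed-rank, one-sided against chance, across participants per
  timepoint: exact null for $n \le 25$ untied samples, normal
  approximation otherwise; zero differences are dropped (their count is
  recorded) and an all-zero timepoint gets $p = 1$.
* Benjamini–Hochberg FDR at $q = 0.05$ over one curve (all timepoints of
  one scheme/category), matching per-curve significance lines; families
  are never pooled across curves.
* Onset latency: earliest time opening a run of at least `min_run`
  consecutive significant samples (15 samples at 1 kHz; scaled to the
  grid, e.g. 2 samples at 100 Hz), searched from stimulus onset only.
  "No onset" is a valid outcome, not an error.
* Peak latency: earliest global maximum in the search window.
* Participant bootstrap: resample with replacement, percentile 95% CI,
  two-sided $p = 2\min(P(s^* \le 0), P(s^* \ge 0))$ with +1 smoothing;
  aborts if the statistic is undefined on more than half the resamples.

## Validation studies and their configurations

Five `study_*()` functions freeze the synthetic validation designs used
by the acceptance tests and `scripts/acceptance.R`. Problem sizes are
scaled-down analysis choices (fewer channels, coarser grids) while the
generator's response structure keeps its defaults; each study finishes in
seconds to minutes on one core.

* `study_null_calibration()` — one participant, default amplitudes, trial
  labels randomly permuted, decoded on a 4-point grid; the pooled mean
  accuracy must sit inside the exact binomial 99% band around 0.5 given
  the evaluation count. The paired-holdout fold structure is what makes
  this band attainable.
* `study_latency_recovery()` — 21 participants, 12 channels, 10 ms grid
  from −100 to 250 ms, single-variation design with 32 repetitions (160
  trials/category, pseudo-trial sets of ~27 trials). Group onset must
  fall within ±20 ms of the 80 ms ground truth and peak within ±10 ms of
  150 ms, averaged over 10 meta-seeds. Detection necessarily lags the 5%
  envelope crossing slightly; the large per-category pools keep that lag
  inside one grid step.
* `study_invariance_ordering()` — $\rho_\text{inv} = 0.5$: category
  selectivity must beat the mean of the two cross-variation schemes
  (paired sign test over 20 seeds), mirroring the drop of decoding
  accuracy under identity-preserving variations.
* `study_whitening_benefit()` — strongly correlated channel noise
  (exponential scale 6 over 12 channels), moderate amplitudes; whitened
  decoding must beat unwhitened in at least 16 of 20 paired seeds.
* `study_snr_correspondence()` — fMRI with a steep occipital-to-temporal
  SNR gradient whose temporal tier sits at the noise floor, and ECoG with
  the same clearly separated category-amplitude profile ("matched
  category structure"). Per region, the Spearman correlation between the
  five-category accuracy profiles of the two modalities is paired with
  the region's noise-ceiling SNR; the summary Spearman across the six
  regions must be positive in at least 18 of 20 seeds. Two properties of
  this analysis deserve emphasis. The per-region correspondence is a
  rank correlation over only five points, so regions with no fMRI signal
  contribute pure rank noise — that is intrinsic to the statistic, not a
  code artifact. And a single pooled intracranial cohort carries
  substantial pattern-realization noise (which electrodes happen to load
  on which category); the study therefore averages accuracy profiles over
  four independently simulated cohorts, the generator-level analogue of
  recruiting more implanted patients. One-vs-rest range-feature
  decodability is additionally not strictly monotone in amplitude — a
  category far *below* the rest-mix mean is also distinctive — which is
  why the study's amplitude profile keeps its extremes well separated.

## Numerical choices and degenerate inputs

Covariance inverse square roots go through a symmetric eigendecomposition
with eigenvalues floored at $10^{-10}$ of the maximum; condition numbers
are reported. Spearman ties use mid-ranks. Classifier score ties go to
the negative class. Epoch grids must be uniform with step `1000/sfreq`;
RDMs are validated (symmetry within $10^{-12}$ in memory, $10^{-9}$ on
disk re-read) on every construction. Serialization is plain text (TSV
matrices + JSON metadata with a `schema_version`, CSV for RDMs with a NaN
diagonal), keeping artifacts diffable and the round trips lossless for
labels and metadata.

## Known limitations

* The generator's realism gaps listed above: no artifacts, no forward
  modeling, no hemodynamics, fixed trial amplitudes.
* The ECoG range feature responds to within-bin signal excursions only;
  its interaction with smooth low-frequency components is intentionally
  not modeled beyond the rectified carrier.
* The noise-ceiling SNR proxy includes the self-inclusion bias of the
  group mean; absolute values should not be compared across cohort sizes.
* The pipeline decodes categories one-vs-rest; five-way multiclass
  decoding, temporal generalization matrices, searchlights, and
  cluster-based permutation corrections are out of scope.
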