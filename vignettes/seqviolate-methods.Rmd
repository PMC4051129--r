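---
title: "Methods: stimulus generation, reproduction scoring, and spatiotemporal cluster statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulus generation, reproduction scoring, and spatiotemporal cluster statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqviolate)
```

## The experimental world this package models

`seqviolate` implements the analysis chain of a visuomotor
sequence-learning ERP experiment.  Observers watch a disk trace a path
of five connected 1 cm linear motion segments at 2 cm/s (0.50 s per
segment, with a 0.40 s pause at every corner), then reproduce the path
from memory with a stylus.  Each trajectory repeats four times.  Most
trials are *Congruent* (all four presentations identical); on *Flip*
trials the final segment of the fourth presentation is replaced by its
exact 180° opposite, violating the just-learned prediction.  Scalp EEG
recorded during viewing yields event-related potentials (ERPs) to
*new* (first-presentation), *familiar* (fourth-presentation congruent)
and *deviant* (flipped) segments; the scientific question is how the
late positive ERP complex (P3a/P3b) distinguishes these.

No recorded data ship with the package.  A synthetic-data module
generates behavior and EEG with the statistical structure the analysis
assumes, so every stage is testable end to end.

## Stimulus generation

Trajectories are drawn by rejection sampling.  The first direction is
uniform on [0°, 360°); each subsequent corner turn has magnitude
uniform in [30°, 150°] and random sign (clockwise/counter-clockwise
with equal probability).  A candidate segment is rejected when it

* leaves the display bounding box (default ±10 cm half-extents; any box
  that admits legal five-segment paths works — the original display
  dimensions are not critical, only the constraint structure),
* intersects a non-adjacent segment, or
* comes within half a segment length (`margin_fraction = 0.5`) of a
  non-adjacent segment.  Adjacent segments are exempt: they share a
  vertex by construction, and turns are bounded away from 0° and 180°,
  so they can neither overlap nor double back.

After 50 failed draws for one segment the whole path restarts; after
10,000 total draws `generate_sequence()` aborts with a diagnostic
(this only happens for degenerate parameters, e.g. a box too small).
`validate_sequence()` re-checks every constraint independently and
names each violated rule, and the test suite additionally checks
generated paths against a brute-force sampled-distance oracle.

Deviants are produced by `apply_flip()`: the chosen segment's direction
is rotated by exactly 180° and the downstream vertices are recomputed.
The flipped path is deliberately **not** re-validated against the
geometric constraints — whether the original experiment re-validated
flips is unstated, and exemption keeps the flip exact at 180°, which is
the property the analysis depends on.  The flip is recorded in the
sequence's `flipped_segment` field; flipping the same segment twice
restores the original.

Session schedules (`build_schedule()`) open with two Congruent warm-up
trials, then ten blocks of three trials each holding two Congruent and
one Flip in random order.  Four sessions of 32 trials give 128 trials,
88 Congruent and 40 Flip (≈31%).

## Reproduction scoring

Scoring is a two-step algorithm.  `segment_trace()` first divides the
stylus trace into motion segments using two cut criteria:

* **pauses** — instantaneous speed below 0.4 cm/s sustained for at
  least 0.15 s.  These thresholds are not published; they are set
  relative to the 2 cm/s nominal drawing speed and the 0.40 s
  inter-segment pause (a fifth of the nominal speed, held for a bit
  more than a third of a pause).
* **turns** — the heading, smoothed by a 5-sample circular moving
  average, departing from its running anchor by ≥ 35°.

Fragments whose endpoint chord is shorter than 0.2 cm (a fifth of a
stimulus segment) are merged into the temporally nearer neighbor.  A
segmentation is *valid* only when it yields exactly the exemplar's
segment count; invalid reproductions are excluded from analysis rather
than force-matched.

Each segment's direction is then fitted "from its beginning and end
points" — implemented literally as the vector from the first to the
last sample, respecting travel order.  A total-least-squares variant
(principal axis, oriented by the endpoint vector) is available behind
`method = "tls"` because the phrase is ambiguous, but the endpoint fit
is the default.  Accuracy is *directional error*: the unsigned angular
difference between reproduced and stimulus directions, wrapped to
[0°, 180°] (`angular_error()`).

Condition means are summarized with Morey bias-corrected within-subject
standard errors (`morey_within_subject_se()`): subject means removed,
grand mean restored, per-condition SE of the centered values inflated
by $\sqrt{M/(M-1)}$ for $M$ conditions.

## ERP pipeline

Epochs span $[-200, 600)$ ms around segment motion onset — 200 samples
at 250 Hz, 50 pre-onset — under a half-open window convention with
0-based sample arithmetic at the boundary.  The pipeline applies:

* **average reference** — subtract the across-channel mean at every
  sample (idempotent; exact by construction);
* **0.25–75 Hz bandpass** — a 4th-order Butterworth band applied with
  zero phase.  No IIR design routine is available in the dependency
  set, so the forward–backward filter is realized in the frequency
  domain: the data are reflection-padded and multiplied by the squared
  Butterworth magnitude response, which is exactly the transfer
  function of a filtfilt pass and introduces no phase shift (verified
  by a zero-lag cross-correlation test and FFT gain checks);
* **artifact rejection** — the original manual inspection and
  ICA-based blink removal are interactive and irreproducible, so they
  are replaced by a deterministic surrogate: epochs whose any-channel
  peak-to-peak amplitude exceeds a threshold are dropped, with a kept
  rejection log;
* **averaging** — `condition_average()` is the pointwise mean over an
  epoch cell; `grand_average()` weights subjects equally regardless of
  epoch counts.  No baseline correction is applied by default (none is
  part of the modeled analysis); `baseline = TRUE` subtracts the
  pre-onset mean when wanted.

## Spatiotemporal cluster-based permutation test

The core statistic guards against multiple comparisons across
(channel, time) cells without pre-selecting windows or sensors:

1. a paired Student *t* at every cell across subjects
   (`paired_tmap()`; zero-variance cells are undefined and treated as
   sub-threshold);
2. supra-threshold cells ($|t| > t_{crit}$) are grouped into maximal
   connected clusters.  Connectivity is same channel at consecutive
   samples, or spatially adjacent channels at the same sample; cells of
   opposite sign never join.  Spatial adjacency is a Euclidean distance
   threshold on montage positions, default radius 1.3× the median
   nearest-neighbor distance (the neighbor template of the original
   toolbox is unspecified; this default connects each sensor to its
   immediate ring and leaves the 129-channel cap connected);
3. each cluster is scored by its **mass**, the sum of member t-scores;
4. the null distribution is built by exchanging condition labels within
   subjects — sign-flipping each subject's difference, the standard
   paired scheme — and taking the largest cluster |mass| of each of
   `n_perm` permutations (default 1000), pooling both signs so
   family-wise error is controlled across positive and negative
   clusters jointly;
5. cluster p-values use the add-one convention
   $p = (1 + \#\{null \ge |mass|\})/(n_{perm}+1)$, ties counted as
   exceedances (conservative), so $p > 0$ always and the smallest
   attainable p is $1/(n_{perm}+1)$.  With `exhaustive = TRUE` all
   $2^n$ sign assignments (including the identity) are enumerated and
   $p = \#\{null \ge |mass|\}/2^n$; the test suite verifies the
   Monte-Carlo path against full enumeration at $n = 4$.

The cluster-forming threshold defaults to the two-tailed Student
quantile at the design's degrees of freedom (e.g. 3.106 at α = 0.01,
df = 11; 2.201 at α = 0.05).  It is exposed as configuration because
the threshold trades sensitivity against spatial/temporal specificity
and the original analysis chose it per comparison.

`find_clusters()` delegates connected-component labeling to *igraph*
after building the edge list vectorially; a hand-written flood-fill
oracle cross-checks it in the tests.

## Topography comparison

To ask whether two conditions differ in the *shape* of their scalp
distribution rather than overall strength, windowed per-electrode means
(`window_mean()`, half-open window) are divided by the root-mean-square
voltage across electrodes within each condition (`rms_normalize()`,
unit RMS to 1e−9, invariant to positive rescaling).  Normalization is
applied to the window-averaged topography per subject (sample-by-sample
normalization is not needed for a windowed analysis, and per-subject
normalization is what a within-subject ANOVA requires).  The normalized
amplitudes at three midline electrodes (Fz, Cz, Pz — resolved through
the montage alias table) enter a 2 × 3 repeated-measures ANOVA.

`rm_anova()` is a univariate two-way within-subject ANOVA on a
complete subjects × A × B table: each effect is tested against its own
subject-by-effect interaction term, with Greenhouse–Geisser sphericity
correction.  The GG ε is computed from the covariance of the effect's
orthonormal contrast scores, $\varepsilon = \mathrm{tr}(M)^2/((k-1)\,
\mathrm{tr}(M^2))$ with $M = C S C'$; for a 2-level factor ε = 1
exactly.  Corrected p-values evaluate F at (ε·df₁, ε·df₂); effect size
is partial η² = SS(effect)/(SS(effect)+SS(error)).  The implementation
matches an independently coded textbook oracle to 1e−10 in the tests
(and was cross-checked once against an external reference
implementation during development).  One caveat: the GG correction is
only guaranteed conservative away from the null bulk of the F
distribution — for F well below 1, shrinking both degrees of freedom
can *lower* the p-value, so the "corrected p ≥ uncorrected p" property
is asserted only where it actually holds.

`posthoc_paired_t()` wraps the standard two-tailed paired t.  Two
identical vectors degenerate to t = 0, p = 1 (the natural limit);
zero-variance non-zero differences are an error.

## The synthetic-data generator

The original study deposited no raw data, and it specifies no
generative model; every distributional choice here is this package's
own, chosen minimal:

* **Behavior** (`simulate_reproduction()`): reproduced segment
  directions are stimulus directions plus zero-mean Gaussian angular
  noise with per-presentation SD defaulting to (25°, 15°, 13°, 12°) —
  a large first-presentation error and most improvement after a single
  presentation, the qualitative learning profile of the task.  Speed
  jitter (10%) and pause jitter (0.03 s) at a 100 Hz tablet rate make
  the traces non-trivial for the segmentation algorithm while keeping
  its validity rate above 90%.
* **EEG** (`simulate_epochs()`): each epoch is a sum of separable
  components — spatial weight map × Gaussian temporal profile ×
  per-condition amplitude — scaled by a per-subject gain
  ($\mathcal{N}(1, 0.2)$, shared across conditions), plus spatially
  correlated Gaussian noise (squared-exponential covariance over sensor
  distance, SD 10 µV per sample, correlation length 0.3 head radii —
  neighboring sensors correlate ≈0.8, as high-density EEG does).
* **Default components** (`default_effect_spec()`): a broad
  centro-parietal positivity (latency 420 ms, width 40 ms) graded
  deviant (3.0 µV) > new (2.6) > familiar (2.0), and a sharper
  fronto-central positivity (latency 422 ms) strongly enhanced for
  deviants only (5.8 vs 0.3 µV).  The fronto-central width (σ = 39 ms)
  is set so that the component's full width at half maximum *is* its
  stated 376–468 ms window, making the half-max support definition and
  the window coincide; the deviant-vs-familiar centro-parietal gap is
  kept small (1 µV) so that comparison's injected difference is the
  compact fronto-central field, echoing the compact clusters such
  analyses report.  With these defaults the deviant-vs-familiar
  cluster test detects the injected effect essentially always at
  12 subjects × 32 epochs.
* **Montage**: `default_montage("hd129")` is a *synthetic* 129-channel
  high-density cap — a deterministic Fibonacci lattice on a spherical
  cap plus a vertex sensor — with Fz/Cz/Pz aliases resolved
  geometrically.  It has plausible coverage and spacing but is not a
  vendor coordinate file.  `"grid9"` is a 3×3 grid for exact tests.

### What a green test does and does not establish

The generator reproduces the *statistical structure* the analysis
assumes: separable signal templates, exchangeable within-subject
condition labels, spatially correlated stationary Gaussian noise, and
angular reproduction noise that shrinks with learning.  It does not
reproduce biophysical forward models, ocular or muscle artifacts,
non-stationarities, latency jitter across trials, or the actual
effect sizes of the original recordings.  Green recovery tests
therefore establish that the pipeline detects what it injects and
controls false positives under its own noise model — not that it would
reproduce the original study's empirical cluster windows or F values,
which are unattainable without the raw data.

### Known limitation: cluster extent vs. injected support

Recovery of the injected fronto-central effect is evaluated by the
Jaccard overlap between the winning cluster's member set and the
injected channels × window support (spatial weights ≥ half maximum ×
stated window).  Detection is universal at the default SNR, but the
mass-based cluster systematically overshoots the half-max support:
spatially correlated noise attaches a halo of low-weight channels for
a few samples each, holding the overlap near 0.49 ± 0.03 so that the
J ≥ 0.5 bar is met in only about half of the runs rather than
reliably.  This is a real property of cluster-mass statistics under
correlated noise — cluster extent is not an unbiased estimate of
effect extent — and the corresponding acceptance check is left failing
rather than weakened, with the behavior documented here.

## Numerical and convention choices

* Angles in degrees, counter-clockwise from +x, y up, origin at display
  center; `angular_error()` wraps to [0°, 180°].
* Half-open time windows everywhere (epochs, `window_mean()`), 0-based
  sample arithmetic at the epoch boundary.
* All randomness flows from integer seeds; sub-seeds derive via a fixed
  32-bit linear map (`derive_seed()`), so every artifact — sequence
  JSON, schedules, simulated cohorts, permutation draws — is
  byte-reproducible under a single master seed and all seeds stay below
  2³¹.
* Ties in the permutation null count as exceedances; zero-variance
  cells are sub-threshold; the identity assignment is included in
  exhaustive enumeration.
* The five-stage orchestrator `run_pipeline()` writes a manifest with
  an md5 hash per artifact; rerunning a config reproduces identical
  hashes.

```{r, eval = FALSE}
# a complete simulated analysis
cfg <- run_config(seed = 1, out_dir = "run1")
res <- run_pipeline(cfg)
res$permutation          # clusters with masses and permutation p-values
res$anova                # 2 x 3 condition-by-electrode ANOVA, GG-corrected
```
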