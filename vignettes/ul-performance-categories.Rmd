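---
title: "Methods: sensor-based categories of upper-limb performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor-based categories of upper-limb performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ulperf)
```

This vignette is the package's own account of its methods: the measurement
model behind the twelve upper-limb (UL) performance variables, the
cluster-analysis workflow that reduces them to five named categories, the
design of the synthetic-data generator, and the numerical choices made
where the underlying methodology leaves the details open.

## 1. From acceleration to activity counts

Wrist-worn tri-axial accelerometers record acceleration in units of g at
30 Hz, continuously over a day or more, on both wrists. Most performance
variables are defined on *activity counts*: each axis is band-pass
filtered, rectified, summed within 1-second epochs, and quantized at
1 count = 0.001664 g; the three axis counts are combined per second into a
vector magnitude, `round(sqrt(cx² + cy² + cz²))`.

The vendor's filter and quantizer are proprietary, so `ulperf` uses an
open emulation and documents it as such:

* **Band-pass 0.25–2.5 Hz** (`bandpass_filter()`): a 4th-order Butterworth
  band-pass applied forward–backward (`signal::filtfilt`), i.e. zero phase
  and squared magnitude response. The corners isolate volitional arm
  movement from postural drift (below 0.25 Hz) and tremor/impact artifact
  (above 2.5 Hz). Inputs shorter than the filter warm-up are
  reflection-padded; tests verify the realized sinusoidal gain against the
  designed transfer function evaluated analytically.
* **Quantization** (`to_activity_counts()`): `floor(sum(|a|)/0.001664)`
  per second per axis; a trailing partial second is dropped. Rectify-sum-
  floor is one plausible reading of the vendor's unpublished quantizer; if
  vendor-exported epoch counts are available they can be ingested directly
  (`read_epoch_csv()`), bypassing the emulation entirely.

Limb roles, not sides, are the analysis unit: for stroke subjects the
paretic limb takes the first role; for neurologically intact controls the
non-dominant limb does (`align_limbs()` maps left/right files using the
subject metadata).

## 2. The twelve performance variables

Nine variables are computed on the 1 Hz epoch series, three on the raw
30 Hz data. The central operational choice is the definition of "moving":

* **Movement threshold, 2 counts/s** (`active_mask()`, argument
  `threshold`). The methodology lineage these variables come from does not
  publish a single value; 2 counts/s is small enough to catch light
  activity and large enough to reject the 0–1-count noise floor of a still
  accelerometer. All package defaults and tests pin it at 2; it is
  configurable throughout.

Durations (`hours_p`, `hours_np`) are active seconds / 3600; isolated
hours count seconds where one limb moves while the other is still. The
magnitude (`med_accel_p`, median paretic counts over paretic-active
seconds; `bilateral_magnitude`, median of the summed counts over
either-active seconds) and variability (`accel_var_p`, sample SD over
paretic-active seconds) statistics are taken over *active seconds only*:
a 24-h recording is dominated by sleep and stillness, and including those
zeros would turn every magnitude statistic into a measure of wear time
rather than of movement intensity. With no qualifying second they are
defined as 0, and `use_ratio` (active-hours ratio) is undefined (`NA`)
when the non-paretic limb never moves. The `magnitude_ratio` is the median
over both-active seconds of `ln(vm_p/vm_np)`, with a second where exactly
one count is zero capped at ±7 (|ln| of any realizable count ratio stays
below 7 at these magnitudes) and both-zero seconds excluded — relevant
only when `threshold = 0`.

**Jerk asymmetry** compares mean jerk magnitudes (norm of the first
difference of the acceleration vector × sample rate, g/s):
`(J_p − J_np)/(J_p + J_np)`, 0 when both are 0. The sign convention is
paretic minus non-paretic — positive means the paretic limb moves less
smoothly — consistent with 0 denoting similar smoothness.

**SPARC** (spectral arc length) quantifies movement intermittency
independent of amplitude and duration. The recording is segmented into
bouts (maximal runs of active seconds from the same limb's mask; when raw
recordings enter through `compute_all_metrics()` their masks are derived
by running the counts pipeline on the raw signal itself). Per bout, the
acceleration-magnitude profile's magnitude spectrum is zero-padded to a
frequency step of at most 0.05 Hz and normalized by its DC value; the
adaptive cutoff is the highest frequency (capped at 10 Hz) where the
normalized spectrum still reaches 0.05; the arc length of the normalized
spectrum over [0, cutoff] is accumulated discretely and negated. The
10 Hz cap, 0.05 amplitude threshold and 0.05 Hz resolution are the
canonical parameterization of the spectral-arc-length smoothness measure.
Bout values are combined by a duration-weighted mean. Two properties are
guaranteed by construction and tested: amplitude invariance is exact
(doubling the signal cancels in the normalization bit-for-bit), and
SAL ≤ −1 with equality exactly in the DC-concentrated (constant-profile)
limit — when no frequency above DC reaches the 0.05 threshold the
implementation returns −1, the value the integrand's `1/ω_c` floor
integrates to. SPARC is computed on the acceleration magnitude rather
than a reconstructed velocity profile: numerical integration of wrist
acceleration drifts over daily-life recordings, and the acceleration
profile needs no integration constant. This is a deliberate deviation
risk to flag when comparing absolute SPARC values across studies.

## 3. Standardization, clustering tendency, PCA

Variables are z-scored (sample SD, n−1) because they live on incompatible
scales (hours, counts, ratios); the scaler is retained for later
classification of new subjects. The Hopkins statistic
(`hopkins_statistic()`) checks that clustering is worth pursuing: per
draw, m = ⌈0.1·n⌉ data points and m uniform points in the data bounding
box; H = Σu^d/(Σu^d + Σw^d) with u the uniform points' nearest-data
distances, w the sampled points' nearest-other-data distances, d the
dimensionality; averaged over 100 draws. This is the statistic's common
modern form: ≈0.5 for spatially random data (calibrated in the tests on
uniform samples), →1 for clustered data. It is computed on the 12-variable
matrix (tendency precedes variable reduction in the workflow); the
function accepts any variable subset.

PCA (`ul_pca()`) is an eigendecomposition of the correlation matrix
(the covariance of z-scores). Loading signs are made deterministic by
forcing the largest-magnitude loading of each component positive.

## 4. k-means and the model ladder

`kmeans_fit()` uses k-means++ seeding with 25 restarts and Lloyd
iterations (stats::kmeans, ≤300 iterations) in Euclidean standardized
space, keeping the lowest-WSS run; empty clusters trigger internal
re-seeding. Given a seed, results are bit-reproducible. Each solution
records WSS, BSS, TSS (the identity BSS + WSS = TSS is asserted to 1e-6
relative), percent total variance explained (100·BSS/TSS) and the mean
silhouette width.

The ladder (`run_model_ladder()`) crosses four nested variable sets with
k ∈ {3, 4, 5}. The sets are fixed: 12 (all); 9 (drop the three 30 Hz
movement-quality variables — harder to compute, less validated
clinically); 7 (additionally drop the two isolated-activity durations,
keeping at least one variable from each remaining aspect: duration,
magnitude, variability, symmetry); 5 (additionally drop bilateral
magnitude and magnitude ratio, whose information is largely carried by the
retained median acceleration and use ratio). Within a variable set, k = 4
and k = 5 are warm-started from the previous solution's centroids plus the
worst-fit point, which guarantees WSS non-increasing (and percent variance
non-decreasing) in k.

Cluster-count diagnostics (`choose_k_diagnostics()`): the elbow curve
(WSS per k, monotone by the same warm-start nesting), mean silhouette
width, and the gap statistic with B = 50 uniform reference sets drawn in
the principal-component-aligned bounding box
(`cluster::clusGap(spaceH0 = "scaledPCA")`), selected by the smallest k
with gap(k) ≥ gap(k+1) − SE(k+1).

Model fit across ladder cells is compared with a MANOVA-style refit
(`manova_refit_aic()`): a multivariate Gaussian with cluster-specific
means and one pooled full ML covariance; parameters k·q + q(q+1)/2;
AIC = −2·loglik + 2·params. The pooled covariance carries a 1e-6 ridge on
the diagonal so that degenerate (zero-variance) fixtures remain
well-defined; a still-singular covariance raises an error advising to
drop collinear variables. AIC magnitudes depend on this convention, so
only AIC *orderings* across cells are meaningful, and only orderings are
asserted anywhere in the package.

## 5. The frozen category model

`ul_category_model()` standardizes the five final variables, fits k = 5,
and freezes the result. Centroids are ordered by a composite score — the
mean of the five standardized centroid coordinates, ascending — and the
five category names are attached in that order. All five variables
increase essentially monotonically with overall performance, so the mean
is a faithful, tie-free ordering proxy; the ordering is content-derived,
hence invariant to any relabeling of the k-means output (tested).

New subjects are classified by nearest centroid through the stored scaler
(`predict()`), with ties broken toward the lower-ordered category.
Nearest-centroid rather than re-clustering is a deliberate design choice:
clinical use requires a frozen, auditable model whose assignments cannot
shift as new data arrive. The underlying methodology defines no
classification rule for new subjects; this one is the package's own and
is documented as such. The model serializes to JSON (scaler, centroids,
names, provenance) and round-trips exactly.

## 6. Reporting

`cluster_summary()` reports per-category means and min–max ranges in
original units, plus percent concordant (dominant = paretic; the
denominator excludes controls, who have no paretic limb) and ARAT
mean/range. `univariate_anova_tukey()` runs the per-variable one-way
ANOVA with Tukey HSD post-hoc comparisons (studentized range;
`stats::TukeyHSD` handles unbalanced groups). Coxcomb charts give each of
the five variables an equal-angle wedge whose radius is `sqrt(u)` of the
min–max-rescaled value `u`, so wedge *area* is proportional to the value;
the rescaling uses the sample-wide min–max of the plotted (standardized)
values, a choice the chart's definition leaves open. The scatterplot
matrix shows pairwise scatter by cluster, per-cluster densities on the
diagonal, and Spearman rank correlations above it.

## 7. The synthetic-data generator

The generator's defaults define the study conditions for every test: five
archetypes whose targets are the five category centroids (paretic hours
1.5→10.2, non-paretic hours 4.1→10.7, median paretic acceleration 0→61
counts, variability 27.3→80.3 counts, use ratio 0.38→0.96) with
29/41/43/57/41 subjects, 211 in total; 24-h recordings with a fixed 8-h
contiguous sleep block; 10% mean-preserving lognormal jitter on every
per-subject target.

Mechanics, per subject and limb: the non-paretic active/inactive state is
a two-state Markov chain over seconds with mean active bout 30 s and entry
probability solved so the stationary active fraction matches the jittered
hours target. The paretic stream is coupled to it: the paretic hours
target is derived as use-ratio × non-paretic hours (the archetype targets
are mutually consistent; inconsistent combinations raise an error), and
paretic-active seconds are drawn with higher probability inside
non-paretic-active seconds, calibrated so ~10% of paretic activity is
isolated — bimanual daily activity with a small unimanual remainder.
Active-second magnitudes are lognormal with the target median, clamped at
the movement threshold, with the spread solved from closed-form truncated
moments so the active-second SD matches its target; inactive seconds
carry {0, 1} noise counts. Raw 30 Hz data are generated separately as
minimum-jerk (quintic) bouts distributed over axes by a random unit
vector, with archetype-graded band-limited noise (a sparse sum of
3.5–7.5 Hz sinusoids along the movement direction) so smoothness degrades
toward the low-performance archetypes; each subject receives a short
representative bout pair (3 × 8 s per limb) rather than a full raw day,
which is what the three 30 Hz variables need.

One target is structurally unreachable: the lowest archetype's median
paretic acceleration is 0 counts, but the activity-mask definition
(counts ≥ 2) floors any recoverable active-second median at 2. The
generator therefore produces magnitudes hugging the threshold there, and
recovery checks for count-scale medians use |recovered − target| ≤
max(10%, 3 counts); the use-ratio checks use an absolute ±0.08 band.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real data: circadian structure beyond one sleep
block; non-wear periods; within-subject day-to-day variation; realistic
within-cluster covariance between variables (only marginal targets are
controlled; covariance arises implicitly from the coupling and jitter);
and biomechanically realistic kinematics. Synthetic cohorts are cleanly
separated by construction — Hopkins statistics near 1 and ~90% total
variance explained, versus 0.78 and 79% reported for the real pooled
cohort — so the tests establish correctness and recoverability of the
pipeline, not the effect sizes to expect clinically.

## 8. Problem sizes and numerical conventions

The test suite runs the metric-oracle equivalence on 1000 random
150-second streams; SPARC properties on 100 random 8-s bouts; Hopkins
calibration at n = 500, 100 draws; planted-cluster recovery at n = 300;
and the end-to-end recovery on the default 211-subject cohort with the
adjusted Rand index summarized as the median over ten cohort seeds (the
observed median is ≈0.92–0.94; individual seeds range ≈0.85–0.94, the
boundary between the two highest archetypes being genuinely fuzzy, as it
is in the published centroids). Degenerate inputs resolve as: no active
seconds → magnitude/variability 0 and use ratio `NA`; fewer than two
active seconds → variability 0; no bouts → SPARC `NA`; zero jerk in both
limbs → asymmetry 0; nearest-centroid ties → lower-ordered category;
k-means nearest-centroid ties → lowest cluster index (stats::kmeans
convention). All randomized functions take explicit seeds and restore the
caller's RNG state.
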