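---
title: "Co-activity and spatial coordination in striatal miniscope imaging: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-activity and spatial coordination in striatal miniscope imaging: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`minicoact` analyzes one-photon miniscope Ca²⁺ recordings of striatal
spiny-projection neurons (SPNs) made during open-field behavior.  It takes
extracted per-cell fluorescence traces (e.g. CNMF-E output), cell centroid
positions, and centroid tracking of the animal, and computes:

1. calcium events per cell (threshold-crossing on a normalized raster);
2. pairwise co-activity (Jaccard index) as a function of inter-cell
   distance, normalized to a circular-shift shuffle null, optionally split
   by behavioral state;
3. a per-frame **spatial coordination index** (SCI) quantifying whether
   co-active cells are closer together than chance, aligned to movement
   onsets;
4. rest/movement segmentation, bout statistics, and rule-based movement
   onset detection from the tracking stream;
5. a group-comparison layer (Mann-Whitney / Wilcoxon on per-animal means,
   and a linear mixed-effects condition contrast with per-animal
   grouping).

A synthetic-session generator with full ground-truth annotation stands in
for raw data, so every stage is testable end to end.

# Preprocessing

Each cell's trace is divided by its 99th percentile
(linear-interpolation quantile), z-scored over the whole session as
`(x - mean)/sd`, and downsampled to 5 Hz by taking the maximum within each
200 ms bin of the aligned grid.  Two conventions deserve note:

* Z-scoring is oriented so that **positive values are fluorescence above
  the session mean**; events are positive excursions.  (The operation is
  sometimes described as "subtracting each sample from the mean", which
  read literally flips the sign; with that orientation a positive event
  threshold would select troughs, so the conventional orientation is
  used.)
* The scale-then-z-score order makes the pipeline invariant to any
  positive gain applied to a raw trace, and whole-session moments are used
  (no sliding window).  Whether moments are taken before or after p99
  scaling is immaterial: scaling is linear.

Alignment uses half-open 200 ms bins `[t, t + 0.2)` anchored at the later
of the two stream starts, so bins partition the overlap and each frame
maps to exactly one bin.  Tracking gaps of at most 500 ms inherit the
nearest sample; longer gaps invalidate the affected bins, which are then
excluded from every statistic (the upstream literature is silent on
dropouts; exclusion is the conservative choice).

# Event detection

An event is a maximal run of 5 Hz bins with z ≥ 2.5 lasting at least 1 s
(5 bins).  The event time is the midpoint between the run's maximum and
the preceding local minimum (searching left from the run start; the first
sample serves as the minimum at the trace edge); amplitude is the run
maximum in z-units; duration is the time above threshold.  Runs separated
by a single sub-threshold bin are *not* merged.  The binary activity
raster used by the population statistics consists of exactly these
supra-threshold spans.

Because the threshold is 2.5 SD *of the cell's own full trace*, detection
is self-normalizing: very active cells have larger trace SDs and
correspondingly higher absolute thresholds.  This is a property of the
method itself, and it is why event recovery on synthetic data is
benchmarked at low-to-moderate event rates.

# Pairwise co-activity

The binary raster is forward-smoothed by 1 s (each active bin also
activates the following 5 bins), so near-coincident events with small
timing offsets count as co-active.  For each unordered cell pair the
Jaccard index is

$$J(a,b) = \frac{|\{t: a_t \wedge b_t\}|}{|\{t: a_t \vee b_t\}|},$$

optionally restricted to rest or movement frames (a frame is "rest" iff
its 5 Hz bin is labeled rest).  Pairs are assigned to half-open
inter-centroid distance bins `[kw, (k+1)w)` (w = 50 or 250 µm), and each
bin's mean observed J is divided by the mean over shuffle surrogates of
the same pairs.

The null: each surrogate independently rotates every cell's *unsmoothed*
binary trace by a uniform circular offset, re-applies the forward
smoothing, and recomputes J.  Circular rotation preserves each cell's
event count and run-length structure — which is exactly what a null that
"controls for activity level" must retain; a full permutation of bins
would destroy event durations.  Normalization is performed at the bin
level (ratio of bin means) rather than per pair, because per-pair shuffle
means can be zero for sparse cells.  Offsets are drawn once per shuffle
and reused across distance bins and states, so all conditions see the
identical surrogate ensemble.

Bin-level ratios computed from only a handful of pairs are dominated by
pair-sampling noise; analyses in this package interpret distance bins
with at least 10 pairs (`min_pairs`).

# Spatial coordination index

For each 5 Hz frame, the distances between all pairs of co-active cells
(on the same forward-smoothed raster as the co-activity analysis —
"active" means one thing) are compared against distance-shuffled
surrogates by a *pair* of one-sided two-sample Kolmogorov–Smirnov
comparisons: is the observed distance distribution left-shifted
(clustered) or right-shifted (dispersed)?  The index is −log₁₀ of the
smaller of the two p-values, signed positive when the clustered side
wins.  A frame with no active pair scores exactly 0.

Two details are deliberate design choices:

* **Sign and magnitude.**  The log₁₀ of a p-value is negative; an index
  defined that way would be most negative when clustering is strongest,
  yet the phenomenon of interest *peaks* at movement onset and its
  normalized peak is compared against 1.  The only orientation consistent
  with that usage is `sci = -log10(min p)` with a clustering sign, which
  is what this package implements.
* **Calibration of the null.**  The m = C(k,2) distances of a frame's k
  active cells are strongly dependent (they share cells).  If the
  surrogate draws are pooled into a single null sample and a single
  asymptotic KS p-value is computed (`sci_params(method = "pooled_ks")`),
  that dependence inflates the tail: under spatially uniform activity,
  frames with ≥ 6 active cells show |sci| > 2 at 6–10% instead of ≤ 2%.
  The default (`method = "permutation"`) therefore computes, per
  direction, the rank of the observed one-sided KS statistic (taken
  against the full pair-distance pool) among the statistics of 1000
  surrogates that each redraw k cell identities.  Under exchangeability
  of active-cell identity this permutation p-value is calibrated by
  construction — the measured false-positive rate for |sci| > 2 is
  ≈ 0.017–0.020 — at the cost of a magnitude ceiling of
  log₁₀(n_shuffles + 1) ≈ 3.  Both variants are exposed; the pooled
  variant is retained for comparability with the narrower reading of the
  original description.

The onset-aligned SCI averages the series across movement onsets,
normalizes by the mean SCI over the pre-onset baseline window, and
reports the peak of the normalized curve within 2.5 s after onset.  The
baseline window is not pinned down by the source description; the default
(4 s) matches the rest period the onset definition itself requires.
Frames with a single active cell have no pair and score 0.

# Behavior

Velocity is `cm_per_px · ‖Δposition‖ / Δt` at the tracking rate, median
filtered with a 1 s centered window (edge windows shrink), and
downsampled to 5 Hz by the within-bin mean (a max would inflate speeds).
Movement bins have v > 0.5 cm/s; the boundary value 0.5 is rest,
matching the strict inequality in the onset rule.  Contiguous movement
runs are bouts.

Onset detection works at the tracking rate in three steps: (1) a frame's
velocity is zeroed unless the centroid moves more than 1 cm from its
current position at some point in the next 1 s (suppressing in-place
dither); (2) the result is smoothed with a 167 ms moving average (5
frames at 30 fps); (3) onsets are the first frames of maximal runs with
v > 0.5 cm/s lasting ≥ 2 s whose preceding 4 s are entirely ≤ 0.5 cm/s.
The full 4 s pre-rest must exist, so movement in the first 4 s of a
recording can never be an onset.  The 5-frame centered smoothing can
advance a run start by up to 2 frames (~67 ms), which is why tests
locate onsets to within 0.2 s.

# Group statistics

Single-value-per-animal metrics are compared with the two-sided
Mann-Whitney U test (unpaired) or Wilcoxon signed-rank test (paired);
exact small-sample null distributions are used where available, and
all-zero paired differences are reported as degenerate rather than
tested.  Metrics measured repeatedly within animals across strata
(velocity bins, distance bins) are compared with a linear mixed-effects
model `value ~ condition + (1 | animal)` fit by lme4 on per-(animal,
stratum) means with equal stratum weight, reporting the Wald β, SE,
z = β/SE, normal two-sided p, and 95% CI — the reporting shape standard
for this design.  Singular random-effects fits are flagged, never
silently refit.  The mixed model is delegated to lme4; this package owns
only the design construction and reporting contract.

# The synthetic generator

The generator emulates the statistical structure the analyses assume; it
starts at extracted traces (no pixel-level video).

* **Behavior:** alternating rest/movement epochs with exponential lengths
  (defaults 12 s rest, 7 s bouts — a rest fraction of ~0.6, inside the
  range spanned by vehicle and drug conditions in the motivating
  experiments; the bout length matches typical vehicle values).  Moving
  speed is a lognormal AR(1) process (1 s correlation time) around
  4 cm/s; rest speed is half-normal jitter of scale 0.1 cm/s, keeping
  rest frames below the 0.5 cm/s threshold with margin.  The centroid
  performs a persistent random walk reflected at the walls of a 40 cm
  arena and is emitted at 30 frames/s in pixels (0.1 cm/px), so the
  calibration and two-rate alignment paths are exercised.
* **Events:** each cell is an inhomogeneous Poisson process with rate
  `base_rate + rate_velocity_slope · v(t)` (defaults 0.02 events/s and
  0.0025 (events/s)/(cm/s) — weak velocity coupling, consistent with the
  modest, often non-significant movement-rate increase seen in dSPNs).
  Spatial ensembles (cells within 100 µm of an ensemble center) receive
  shared events at a state-dependent rate (0.15/s at rest, 0.01/s during
  movement); at each shared event every member fires with probability
  `p_coactivate` at the identical time.  A homogeneous
  per-ensemble process with a state-dependent rate is the simplest
  mechanism that produces higher co-activity at rest with one knob.
* **Fluorescence:** each event contributes a difference-of-exponentials
  transient (rise 0.05 s, decay 1.2 s) with unit amplitude times
  lognormal jitter (σ = 0.25, strictly positive and heavy-tailed like
  real transients), plus Gaussian noise (SD 0.075).  The kernel models
  the **compound, multi-spike burst transient** that the 1 s duration
  rule targets, not a single-AP response: with a single-AP decay
  (~0.4 s) the supra-threshold span of any attainable transient is
  `0.4·ln(A/2.5σ) < 1 s`, so the detection rule that defines events
  would reject essentially everything, and a generator with such a
  kernel cannot emulate data on which the method operates.
* Emitted traces, positions, and timestamps are quantized (10⁻⁶ trace
  units / px; 10⁻³ ms) through their printed representation, mimicking
  finite-precision instrument export and making CSV round-trips
  bit-exact.

Fixed seeds give bit-identical sessions.  What the generator does *not*
emulate: sensor nonlinearity and saturation, neuropil contamination and
crosstalk between nearby ROIs, slow drift and bleaching, segmentation
errors, grooming/rearing postures that corrupt centroid tracking.
Passing tests therefore demonstrate correctness of the statistics on
data satisfying the model's assumptions, not robustness to those
artifacts.

# Numerical choices and problem sizes

* Quantiles use the linear-interpolation definition (R type 7); at
  session lengths (~10⁴–10⁵ frames) alternative definitions differ
  negligibly.
* One-sided two-sample KS statistics are computed exactly on the pooled
  order statistics (ties handled by evaluating at unique values); the
  asymptotic one-sided p is `exp(-2D²n₁n₂/(n₁+n₂))`, used only by the
  pooled SCI variant.  Permutation p-values use the add-one rank
  estimator `(1 + #{D_s ≥ D_obs})/(n + 1)`.
* Ties between the two directions of the SCI (identical p and identical
  D) yield an index of 0.
* The shuffle engine shares one drawn offset set per surrogate across
  states and bins; Jaccard matrices are computed by BLAS cross-products
  on the 0/1 raster.
* Validation simulations use 20–60 cells, 15–60 min sessions, and 1000
  surrogates — sizes at which every stochastic check in the test suite
  has comfortable expected margins while the suite stays quick; these
  are the same orders of magnitude as the motivating recordings.

# Known limitations

* Bin-level normalized co-activity is a ratio estimator; with very few
  pairs or nearly silent cells it is noisy, hence the `min_pairs`
  reporting convention.
* The permutation SCI magnitude saturates at log₁₀(n_shuffles+1).
* Forward smoothing leaks activity across state boundaries by up to 1 s,
  which dilutes rest/move contrasts when epochs are short relative to
  the smoothing window; with the default bout structure the rest > move
  direction is robust, but analyses of very rapidly alternating behavior
  should shorten the smoothing window deliberately.
* The onset detector's displacement rule uses a truncated lookahead in
  the final second of a recording.
* The mixed-model layer fits random intercepts only (matching the
  reporting contract it reproduces); random slopes by animal are out of
  scope.
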