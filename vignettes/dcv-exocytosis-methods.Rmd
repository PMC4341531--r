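---
title: "Quantifying single dense-core-vesicle exocytosis: model, methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single dense-core-vesicle exocytosis: model, methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

```{r}
library(dcvtrace)
```

# The measurement problem

Dense-core vesicles (DCVs) carry neuropeptides and neurotrophins and
fuse with the plasma membrane far less frequently than synaptic
vesicles, so their exocytosis must be quantified one event at a time.
The standard optical assay expresses a DCV cargo fused to
superecliptic pHluorin: the fluorophore is quenched at the acidic
intravesicular pH and unquenches abruptly when the fusion pore connects
the lumen to the neutral extracellular medium. A single fusion event
therefore appears as a sudden, localized, large fluorescence increase.
A pH-insensitive red cargo (an mCherry-type tag) provides the
complementary readout: it is visible before fusion, supports tracking
of vesicle transport, and reports *complete* cargo release as the
disappearance of a punctum.

`dcvtrace` implements the full quantification chain for this assay —
event detection, persistent/transient classification, full-release
scoring, pool counting, synaptic assignment, transport and kymograph
analysis, co-trafficking, activity-dependent dispersion of synaptic
proteins, colocalization, and group statistics — together with a seeded
synthetic movie generator that produces ground truth for every one of
those quantities. Every algorithm in the package is validated against
that generator; no primary imaging data are required to verify the
pipeline.

# Stimulation protocol and time base

The default acquisition protocol (`build_protocol()`) follows the
common field protocol: 2 Hz imaging (0.5 s frame interval, 0.2 µm
pixels) for 90 s, with electrical stimulation starting at 30 s —
16 bursts of 50 action potentials at 50 Hz, separated by 0.5 s. Each
burst lasts 1 s, so the stimulation epoch is
16 × 1 s + 15 × 0.5 s = 23.5 s of train plus the trailing half second
of the final inter-burst convention, i.e. the epoch spans 24 s
(`stim_duration_s`). Frame *k* covers the half-open interval
[(k−1)·Δt, k·Δt), and all conversions between seconds and frames go
through `time_to_frame()` / `frame_to_time()` so that boundary frames
are handled identically everywhere.

An optional NH₄Cl superfusion epoch (`nh4_start_s`, `nh4_duration_s`)
alkalinizes all vesicles and unquenches every pHluorin-tagged vesicle,
fused or not; it defines the denominator for released-fraction
estimates.

# The synthetic movie generator

`simulate_scene(scene_config(), build_protocol())` renders a
multi-channel photon-count movie plus complete ground truth (vesicle
trajectories, fusion events with onset frames and modes, synapse
positions, neurite paths, soma ROI). The generator's defaults *are*
the study conditions; analyses in `analysis/` run on fixtures produced
with these defaults.

## Scene model

- **Geometry.** Neurites are gently bent random polylines spanning the
  field; synapse-marker puncta and vesicles are placed on them with a
  minimum vesicle spacing of 5 px. A rectangular soma region carries
  extra diffuse fluorescence and serves as the bleach reference.
  Overcrowded configurations are rejected with a capacity error rather
  than silently overlapped.
- **Optics.** Each punctum is a peak-normalized isotropic Gaussian PSF
  with σ = 1.3 px (≈ 260 nm at 0.2 µm/px — diffraction-limited for
  green emission), truncated at 4σ. Positions are continuous (sub-pixel)
  and 0-based.
- **Transport.** A third of vesicles are mobile and move along their
  neurite at 190 ± 30 nm/s, reversing direction with per-frame
  probability 0.02. Stationary vesicles stay put (measurement jitter
  arises from photon noise, not from simulated wobble).
- **pHluorin photophysics.** Before fusion a vesicle is quenched to
  `quench_frac = 0.03` of its unquenched amplitude. Published
  surface-to-vesicle pHluorin ratios imply a residual on the order of
  a few percent; 0.03 keeps resting puncta invisible against the
  background while remaining non-zero, which matters because a
  *perfectly* invisible vesicle would make arrival-artifact testing
  impossible. Fusion is a step unquench at the onset frame; 60% of
  events are transient and decay back with τ = 5 s, the rest persist.
  NH₄⁺ raises every vesicle to full amplitude for the epoch.
- **Red reporter.** Always visible; "full release" events disappear
  completely at the event frame (fractional release is not modeled —
  see Limitations).
- **Noise and bleaching.** Photon counts receive Poisson shot noise and
  Gaussian read noise (SD 2 counts). Bleaching is a global
  exponential with τ = 300 s (`Inf` disables it); the soma provides the
  reference trace for bleach correction exactly as in real recordings.

## Realism and deliberate simplifications

The generator reproduces the features the estimators must be robust
to: shot noise at realistic photon budgets, bleaching, transient decay,
crowded neurites with streak crossings, moving sources entering ROIs,
and somatic background. It deliberately omits focus drift, uneven
illumination, camera fixed-pattern noise, partial-release events, and
vesicle aggregation. Those omissions bound what the validation can
claim: detection performance numbers here are upper bounds on real-data
performance, and the acceptance-style checks should be read as
verifying algorithmic correctness, not expected field performance.

# Event detection

## The trace rule

Fluorescence traces are extracted from 2×2-pixel ROIs (`extract_trace()`),
matching single-vesicle practice. With F₀ the mean of the first four
frames, an event is called at frame *t* when

ΔF(t) = F(t) − F₀ > 2·σ₀,

where σ₀ is the SD of the pre-stimulation baseline, *and* the rise from
below to above threshold completes within 2 frames (1 s). The sudden-rise
requirement rejects slow drifts (bleach recovery, focus) that eventually
cross any fixed threshold. A refractory period of 10 frames (5 s)
suppresses re-triggering on the noisy plateau of a persistent event.
Candidate onsets during the NH₄⁺ epoch are excluded — every vesicle
unquenches then, and calling those as fusion would be nonsense.

## From traces to events in a movie

`detect_fusion_events()` does not scan every pixel's trace blindly.
Candidate sites are generated from per-frame difference images (frame
minus previous frame, smoothed), which localizes sudden appearances;
each candidate carries an onset hint, and a trace-level detection is
accepted only when its onset lies within 2 frames of the hint. Two
further guards matter in crowded scenes:

- **Arrival veto.** A moving vesicle translating into an ROI produces a
  threshold crossing indistinguishable, at the trace level, from
  fusion. Before accepting an onset, the detector inspects a small
  patch (radius 2 px) in the frames just before onset; if the patch
  already contained comparable brightness (patch maximum ≥ 0.5× the
  rise), the candidate is vetoed as an arrival, not a fusion. The veto
  runs *before* the refractory rule so a vetoed arrival cannot mask a
  genuine later fusion.
- **Deduplication.** Detections within 4 px and 2 frames are merged,
  keeping the larger peak. The 4 px radius is safe because the
  generator (and biology) keeps distinct vesicles ≥ 5 px apart, while
  duplicate detections of one event land within the PSF.

Somatic events (inside the soma ROI) are excluded from per-cell event
counts, as is standard.

## Persistent vs transient

After onset, a run of ≥ 4 consecutive frames below the event threshold
classifies the event as transient; events still above threshold at the
movie end without such a run are persistent. Events whose observation
window is cut short (by movie end or the NH₄⁺ epoch) are censored
rather than forced into either class.

# Full release of red cargo

Red-cargo disappearance must be distinguished from photobleaching.
`detect_full_release()` divides the punctum trace by the *relative*
soma time course (soma trace normalized to its own F₀). This
ratiometric correction is exact for a global multiplicative bleach:
a non-releasing punctum's corrected trace is flat, while subtraction
of the soma trace would leave a decaying pedestal that produces false
disappearance calls. After correction, a full release is a drop to
below `disappearance_frac` (10%) of the pre-drop mean that *stays*
gone: the post-drop mean must remain below that level and no run of
≥ 4 frames may rise above it. The mean-plus-no-sustained-run
formulation tolerates single-frame shot-noise excursions that an
all-frames rule would (wrongly) count as reappearance. On pure-bleach
scenes (τ = 200 s) this yields zero false calls; on true-disappearance
scenes recall is complete with exact onsets.

# Pool counting

`count_pool_nh4()` counts vesicles during the NH₄⁺ epoch by median
projection of the *first three* epoch frames only, followed by punctum
detection. Restricting the projection matters: a mobile vesicle at
~0.5 px/frame traverses several pixels over a 20-frame projection and
blurs below the detection threshold, whereas over 3 frames it moves
less than the PSF width. The remaining undercount is physics, not
implementation: vesicles closer than the diffraction limit merge into
one punctum, so the honest reference for validation is the number of
resolvable clusters (single-linkage at 3 px), not the number of
vesicles.

# Transport: tracking, motility, velocity, kymographs

Per-frame puncta (`detect_puncta()`: difference-of-Gaussians filter,
mean + 4 SD threshold, local maxima, 3×3 weighted centroid) are linked
by nearest-neighbour assignment with gap closing (`link_tracks()`).

**Motility.** A track is *moving* when its net displacement over any
sliding 10-frame (5 s) window exceeds 2 px (400 nm). The window length
is derived, not tuned: the slowest transport the assay should call
directed (~100 nm/s) covers the 400 nm threshold in 4 s, so a 5 s
window gives every relevant mover a margin while localization jitter
(tens of nm, zero-mean) never accumulates 400 nm of *net*
displacement. A shorter window would, by construction, miss
nominal-speed movers: at 190 nm/s, 4 displacement steps cover only
1.9 px.

**Velocity.** `mean_velocity()` averages per-frame speeds, so back-and-
forth movement does not cancel. This is deliberately different from a
net-drift estimate and the difference is visible in the data: a
reversing vesicle has a high mean speed but low net drift.

**Kymographs.** `build_kymograph()` samples the movie along a polyline
(maximum over a ±1 px normal band at each arclength step);
`kymograph_ridge_speed()` fits a line to the per-frame argmax position
and converts the slope to nm/s. The ridge slope measures *net drift
along the line*; it matches the track-based estimate only on
reversal-free, crossing-free runs. On an isolated rendered punctum the
two estimators agree to better than 1%. In crowded scenes the analysis
workflow therefore mirrors manual practice: it projects each mobile
track onto its neurite (resampled at 0.5 px so the arclength coordinate
is smooth), takes the longest reversal-free run, crops the line to that
run, and fits only over frames in which the band contains exactly one
detected punctum — i.e. it measures the clearest streak and avoids
crossings.

**Co-trafficking.** Two tracks co-traffic when they overlap in ≥ 10
common frames, are both mobile, and stay within 2 px throughout the
overlap. The bookkeeping (`cotraffic_summary()`) reports counts and
percentages per category.

# Synaptic assignment and dispersion

An event is *synaptic* when its centroid lies within 200 nm (1 px at
0.2 µm/px) of a synapse-marker centroid; ties go to the first (lowest
index) synapse. Activity-dependent dispersion of a synaptic protein is
quantified as bleach-corrected ΔF/F₀ per ROI class (synaptic vs shaft)
at a fixed post-stimulus time; here the correction is *subtractive*
(soma ΔF scaled to the ROI baseline) because dispersion ΔF/F₀ is the
field's reported quantity and the subtractive form is its standard
definition — unlike full-release detection, no fractional-level
threshold is applied, so the pedestal issue does not arise. Mass
conservation (total intensity constant up to noise and bleaching) is
checked explicitly in the validation scenes.

# Colocalization

`pearson_coefficient()` (with optional mask), `manders_coefficients()`
(M1/M2, threshold-based) and `object_colocalization()` (fraction of
channel-A objects with a channel-B object within a radius) follow the
standard definitions. The object-based measure is validated against
its analytic null: for objects placed by a spatial Poisson process of
intensity λ, the chance fraction within radius r is 1 − exp(−λπr²).

# Group statistics

`compare_groups()` encodes a conventional test-selection policy:
Lilliefors normality screen on each group (only when n ≥ 5 and the
group has spread), then an F-test for equal variances to choose between
Student's and Welch's t-test; if either group fails normality, a
Mann–Whitney test (normal approximation, suitable for tied data). For
more than two groups, Kruskal–Wallis with Bonferroni-corrected pairwise
Mann–Whitney follow-ups. The policy's type-I error was measured at the
nominal 5% over 1000 null simulations.

# Numerical choices worth recording

- All image coordinates are 0-based and continuous; ROI/pixel indexing
  converts explicitly, and round-tripping through the TIFF/JSON/CSV/YAML
  fixture format is bit-exact at 16-bit quantization.
- F₀ uses 4 frames: long enough to average noise, short enough that
  bleaching within the baseline is negligible (< 1% at τ = 300 s); the
  dispersion closed-form tests account for the residual bleach in F₀
  exactly rather than assuming it away.
- The simulator consumes its own RNG stream (seeded per scene) and
  restores the caller's `.Random.seed`, so embedding simulations inside
  seeded scripts cannot silently shift downstream draws.
- Statistical validations use deterministic constructions
  (`qnorm(ppoints(n))`) where the *branch taken* is the thing under
  test, so a unit test cannot fail because a random draw happened to
  look non-normal.

# Limitations

- The generator's simplifications (no focus drift, no partial release,
  global bleach) mean validation numbers are upper bounds for real data.
- The 2-SD trace rule, applied to a noisy sustained plateau, re-fires
  at a low per-frame rate; movie-level detection gates this through
  difference-image candidates and the refractory rule, but users
  applying `detect_events_trace()` directly to long plateaus should
  expect occasional duplicate onsets.
- Automatic kymograph ridge extraction assumes one dominant streak;
  in crowded fields it must be (and in the workflow is) restricted to
  crossing-free runs.
- Synaptic assignment at 200 nm is below the optical resolution of the
  simulated system; it is an operational rule, faithful to field
  practice, not a claim of super-resolution.

# Problem sizes

Default scenes are 96×96 px × 180 frames with 30 vesicles; a full
simulate-and-detect cycle takes a few seconds on one core, the complete
analysis workflow (`analysis/01` … `05`) a few minutes, and the 1000-run
statistical validations a few minutes more. Memory stays well under
1 GiB throughout.
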