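---
title: "Fixation-related potential analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fixation-related potential analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the science inside `frptools`: what each stage
computes, the assumptions it makes, the parameters that matter, what the
synthetic generator does and does not emulate, and the choices made where
the design was genuinely open.

# The measurement problem

Co-registered EEG + eye tracking lets brain activity be segmented by the
viewer's own fixations instead of by system-generated stimulus triggers.
Three quantities are extracted per recording session of a two-panel
visual search task (targets shown left, searched for right, selection by
fixating a target and pressing space):

* time-independent gaze ratios per scene (difficulty),
* single-trial occipital P100 amplitudes per fixation (attentional
  effort toward the fixated content),
* relative band-power vectors per fixation-bound EEG segment
  (action vs. exploration).

Two practical obstacles shape the pipeline: the EEG (256 Hz) and eye
tracker (60 Hz per eye) run on separate computers whose clocks differ by
a static offset plus a linear drift, and raw EEG carries drift, line
noise, and ocular artifacts.

# Preprocessing

**Filtering.** A 0.1 Hz highpass removes drift and DC (channels are
demeaned first so the zero-DC-gain property holds exactly despite
forward–backward edge transients) and an 8th-order Butterworth 45–55 Hz
band-stop removes line noise. All filters are applied zero-phase
(`filtfilt`), since one-pass IIR group delay would bias FRP latencies;
the quoted order is the overall one-pass order, and the effective
attenuation is doubled by the two passes.

**Artifact removal.** EEG channels (EOG excluded) are decomposed with a
symmetric FastICA (tanh contrast, whitening by eigendecomposition).
Components are zeroed when (a) their absolute correlation with any EOG
channel exceeds 0.7, or (b) more than 80% of their spectral power lies
below 3 Hz. The second threshold is deliberately conservative: a
1/f-distributed neural background keeps its sub-3 Hz fraction near 0.5,
so only drift-like components trip it. A trained component classifier
can be substituted through the `flag_fun` argument. Reconstruction
leaves EOG channels untouched.

**Resynchronization.** Keypress events are logged on both clocks; the
affine relation `t_et = offset + drift * t_eeg` is fitted by least
squares and inverted to map gaze timestamps onto the session clock.
Matched-event timestamp quantization at the 60 Hz frame grid bounds the
recovery error: across injected offsets up to ±2 s and drifts within
±0.005 of unity, the fit recovers offsets within one eye-tracker frame
and drifts within 1e-4 (40 events over 300 s). Drift precision scales as
`residual_sd / (event_time_sd * sqrt(n))`, so short sessions with few
shared events will do worse; the `residual_rms` field flags poor fits.

**Fixation detection.** A dispersion criterion: a candidate run starts
at a sample, the acceptance circle (80 px diameter) is re-centered on
the running centroid after each accepted sample, and a fixation ends
when the gaze jumps more than 80 px from the previous sample. Runs
qualify with at least 6 frames and 100 ms. Since 6 intervals at 60 Hz
span 100 ms only when each frame is counted as lasting one period, a
fixation's offset is defined as its last sample time plus one frame
period, making duration = n_frames / 60 exactly. Dispersion criteria of
this family leave the circle's anchor unspecified; the running-centroid
choice is symmetric and makes the detector order-insensitive within a
run. The detector is verified sample-for-sample against a brute-force
oracle that re-evaluates every candidate window from scratch.

# Gaze-difficulty metrics

Within one scene with fixation centroids \(c_1 \dots c_n\) and durations
\(d_i\):

* \(M1 = \#\{d_i > 250\,\mathrm{ms}\}/n\),
* \(M2 = \#\{\lVert c_{i+1}-c_i\rVert > 80\,\mathrm{px}\}/(n-1)\),
* \(M3 = \#\{i : \exists j<i,\ \lVert c_i-c_j\rVert \le 80\,\mathrm{px}\}/n\),

with a fixation counting as one revisit however many earlier regions it
overlaps, and the first fixation never counting. The 80 px foveal
*radius* (screen geometry at 80 cm viewing distance) is deliberately
kept distinct from the 80 px dispersion *diameter* of the detector; the
two constants coincide numerically but answer different questions.
Scenes with fewer than two fixations are excluded rather than imputed.

Metric vectors are embedded in 2-D by exact t-SNE (perplexity 30,
clamped to (n−1)/3 for small n; quadratic exact gradient — adequate for
the ~138 scenes of one subject) for visual inspection, and classified
with multiclass FDA: discriminant directions are the leading generalized
eigenvectors of between-class scatter against within-class scatter
regularized by εI (ε = 1e-6), prediction is nearest class centroid in
the discriminant space, and at most classes−1 directions are used. In
the two-class case this reduces to the closed-form Fisher discriminant
w = S_w⁻¹(μ₁−μ₂), which the test suite uses as an independent oracle.

Cross-validation is stratified and balanced: each class is subsampled to
the largest multiple of k not exceeding the smallest class size, dealt
round-robin into k = 5 folds. Remainders are dropped (seed-controlled)
rather than unbalancing folds. Because the action/exploration problem
has a small minority class, a single fold assignment discards most
majority-class segments and is a high-variance estimate; `crossvalidate`
therefore supports repeated assignment (`repeats`, 10 in the pipeline)
and pools fold accuracies. Chance level is reported as 1/n_classes.

# Single-trial P100 estimation (MLRd)

Epochs run from 100 ms before to 900 ms after each fixation onset
(256 samples at 256 Hz), are baseline-corrected by the mean of the
pre-onset 100 ms (no canonical baseline rule exists for FRPs; the
pre-onset mean is standard ERP practice), and band-passed 1–10 Hz to
isolate the slow evoked deflections.

The reference template is the average of the epochs' first 250 ms on Oz
(the P100 is occipital-maximal). The fit window extends to +150 ms
post-onset rather than the nominal "first 200 ms of the epoch" because
the latter ends at +100 ms and would truncate the 50–150 ms peak-search
window and the ±20 ms latency variation the regressors are built to
absorb.

Regressors are built from a deterministic ensemble of template copies
over a grid of latency shifts (±20 ms) and width scalings (±30% about
the template peak), decomposed by uncentered PCA; the leading k = 3
orthonormal components span the template itself (first component), its
temporal derivative (latency direction), and a width/morphology
direction. Fitting is an orthogonal projection; the reconstruction's
maximum inside 50–150 ms post-onset gives the amplitude (µV, relative to
the epoch baseline — peak "amplitude" has no single operational
definition, so the signed reconstructed extremum was chosen) and
latency (ms). Estimates whose extremum sits on the search-window edge
are flagged low-confidence rather than dropped. Under injected truth at
SNR 2 with 200 epochs the estimator's amplitude bias stays under 10%
and latency RMSE under 8 ms, and recovered group means order correctly
with injected gains — the properties the test suite asserts.

Group comparisons use two-tailed Student t tests with the conventional
star code (ns / * / **) and no multiple-testing correction across the
four complementary pairs, mirroring how such panels are conventionally
reported; identical constant groups short-circuit to p = 1. Sequential,
overlapping fixations are kept — overlap correction is explicitly out of
scope.

# Fixation-bound relative band power

Segments cover exactly the fixation interval (half-open sample rule
`[ceil(onset·fs), ceil(offset·fs))`), are linearly detrended and Hann
tapered per channel, and the periodogram is integrated over delta
(0.5–4), theta (4–8), alpha1 (8–10), alpha2 (10–13) and beta
(13–30 Hz); the five powers are normalized to sum to one per channel and
averaged over the 16 EEG channels (no channel subset is canonical for
this analysis; a per-channel 16×5 feature mode would be the natural
extension). Normalization is over the five bands, not the full spectrum
— the alternative would shrink all fractions by the out-of-band share
without affecting their ordering.

Because most fixations are shorter than half a second, the native FFT
grid is coarser than the band structure (a 400 ms segment puts a single
2.5 Hz-spaced bin inside the delta band). Band power is therefore
integrated on a zero-padded grid (≥ 1024 points): padding adds no
information, but it interpolates the spectrum so the integral is taken
over the band rather than over one arbitrary bin. Segments still cannot
truly resolve the lowest edges; the residual bias depends only on
segment length, which has the same distribution in both classes under
the default generator, so it cancels in classification. The all-zero
segment is rejected as undefined rather than mapped to a uniform vector.

The five fractions feed the same FDA/CV machinery to separate keypress
(action) from exploratory fixations; duration distributions are compared
descriptively with normalized histograms, a Wilcoxon rank-sum test, and
the histogram overlap coefficient.

# The synthetic session generator

The generator emulates the study design so every stage is testable
against known truth.

**Scenes.** 1920×1080 screen, target panel left (3–5 non-overlapping
shapes; axis-aligned bounding boxes may not intersect), search panel
right. Distractor counts are drawn uniformly from 12–18 (few) or 30–45
(many) — no canonical counts exist for this design, so they are configurable
defaults. Shape centers keep ≥ 100 px (many) or ≥ 170 px (few)
spacing. One scene-level target color is drawn jointly with the
similarity class (a mid-gray target cannot reach the low-similarity
range, so the target color comes from an accepted in-class pair), and
every distractor color is kept in-class **relative to the target color**
— whether distractor–distractor pairs are also constrained is ambiguous
here, and this reading constrains only target–distractor
pairs. Similarity classes use half-open ranges [0,200), [200,475),
[475,765] of the weighted RGB distance; "different in color" in epoch
labeling means strictly D > 200. Schedules hold exactly
`n_per_condition` scenes per condition in a seeded random order, with
`round(missing_rate × N)` missing-target scenes drawn without
replacement (study values: 23 per condition, 8%).

**Gaze.** Piecewise-constant fixation centers with truncated Gaussian
within-fixation jitter (σ = 8 px, capped at 18 px so every sample stays
inside the dispersion circle with margin) and instantaneous saccades.
Durations are 100 ms + Gamma(shape 3, scale 75 ms): supported above
100 ms with mode near 250 ms, the canonical average fixation duration.
Fixation targets are shapes, hit with a truncated Gaussian landing error
(σ = 20 px, capped at 40 px) — without landing scatter every fovea would
contain exactly one shape and the object/color-count analyses would be
degenerate; with it, shapes spaced near the foveal diameter jointly
enter the fovea at a realistic (low) rate. Exploration alternates
between panels with a color-similarity-dependent target-panel revisit
probability (0.35/0.25/0.12 for high/medium/low), and the task's
completion rule is honored: every search-panel target receives selection
visits ending in a space press (geometric retries at `keypress_prob` =
0.8), with missing targets selected on the target panel. Mean
exploratory fixation counts are 16 (few) vs 40 (many): slightly more
fixations per shape on crowded displays, the inefficient-search behavior
that makes object count recoverable from time-independent revisit
ratios. `keypress_extra_ms` (default 0) optionally lengthens action
fixations to emulate the longer action fixations of real data; it is off
by default so that the null generator (keypress EEG component disabled)
leaves action and exploratory fixations statistically identical — the
clean calibration condition for the classifier.

**EEG.** 16 EEG + 4 EOG channels at 256 Hz in µV. Each fixation adds a
P100-like deflection: a Gaussian bump (σ = 15 ms; no analytic waveform
has a canonical form) at 95 ms post-onset, occipitally weighted
(Oz = 1), with amplitude `5 + 1.5·n_objects + 1.0·n_colors +
1.0·[target] + N(0,1)` µV. Keypresses add a centro-parietal (Cz-maximal)
slow transient: a Gaussian-windowed 3 Hz carrier (Gabor, envelope σ =
150 ms, 20 µV) — a unipolar bump of that envelope is near-constant
within a ~300 ms fixation and is erased by the band-power estimator's
detrending, i.e. it cannot express the in-segment delta elevation the
analysis targets, whereas keypress-locked averages in real data show
biphasic complexes with 2–5 Hz content, which the Gabor emulates.
Background is 1/f-shaped noise (10 µV rms) plus white sensor noise
(2 µV rms) per channel; EOG channels carry gaze-position potentials
(saccade-locked steps) and optional blinks that leak into frontal
channels for the artifact-removal tests. Eye-tracker clock error is
injected as `t_et = offset + drift·t_session` with ET-side event times
quantized to the frame grid.

**What the generator does not emulate** — and hence what passing tests
do not show about real recordings: overlap of sequential FRPs,
spatially correlated background EEG, real artifact morphologies beyond
steps and blinks, pupillometry and blinking in the gaze stream, subject
idiosyncrasies, photorealistic stimuli (geometry and color metadata
only), and the exact real-data classification accuracies, which depend
on all of the above. M2 is nearly constant at 1 in synthetic sessions:
consecutive generated fixations must be separated enough for the
dispersion detector to split them, so sub-foveal saccades essentially do
not occur — a structural limitation of pairing this gaze model with this
detector, not a property of real data.

# Numerical choices and degenerate inputs

* Filter edges must lie strictly inside (0, Nyquist); violations error.
* Fixation-duration comparisons carry a 1 ns tolerance because frame
  times of the form n/60 are not exactly representable.
* FDA regularizes within-class scatter by εI and refuses singular
  scatter at ε = 0 with an actionable message; eigenvectors are taken
  from the real part and unit-normalized.
* CV errors on any class smaller than k; balanced subsampling drops
  remainders.
* t-SNE clamps perplexity to (n−1)/3 and is deterministic given the
  global RNG state.
* `compare_groups` short-circuits identical constant groups to p = 1.
* All-zero band-power segments, epochs straddling record edges, and
  fixations outside the recording are rejected with counts in the
  report, never silently imputed.
* Simulation sizes in the test suite (12-scene sessions, 200-epoch
  recovery runs, 200-replicate calibrations) were chosen as the smallest
  sizes at which the asserted properties are stable.

# Known limitations

Latency inference is deliberately de-emphasized: residual
resynchronization error (2–4 samples, ~16 ms, for this pairing of sampling rates) makes
single-trial latency differences unreliable, and the MLRd search window
clips latencies to 50–150 ms. The MLRd realization (jitter grid, k = 3,
uncentered PCA) is one faithful reading of a method whose exact
hyperparameters live in prior work and supplementary material; the
structure is configurable. The ICA heuristics are a documented stand-in
for a trained artifact classifier, and err toward keeping components.
Real-data adapters (vendor formats) are out of scope; the plain-text
bundle format plus the `read_bundle`/`write_bundle` contract is the
supported interchange.
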