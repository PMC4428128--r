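---
title: "Gaze divergence, null thresholds and the iGDI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze divergence, null thresholds and the iGDI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igdi)
```

## The problem

Narrative video is designed to guide attention: at any instant, the frame
composition, editing and story should pull every viewer's gaze toward the
same region. The iGDI (eye-gaze Divergence Index) turns that idea into a
scalar per video: the fraction of time windows in which the cross-observer
scatter of gaze positions is larger than what a no-guidance null predicts.
It needs only raw gaze coordinates — no areas of interest, no
fixation/saccade event detection, no pupil measures — which is what makes
it applicable to arbitrary dynamic stimuli.

## Model and procedure

1. **Epoching.** Each subject's gaze stream is cut to the video's event
   markers with 1000 ms padding on both sides and re-referenced so the
   video onset is time 0. The padding is retained for inspection but the
   window grid is anchored at onset and spans video content only, so
   pre-roll samples never enter any score.
2. **Windowing.** A sliding grid of 250 ms windows stepped by 50 ms (80 %
   overlap). At 60 Hz each subject contributes ~15 samples per window; with
   S subjects a pooled rendition holds ~15·S columns. The grid is truncated
   to the shortest common stream duration so all renditions describe the
   same segment.
3. **Dispersion.** The between-viewings score is the mean over all column
   pairs of the squared coordinate distance between the two pooled
   renditions. The within-viewings score applies the same sum over ordered
   pairs n1 ≠ n2 of a single pooled rendition, normalized by N². Two
   details are deliberate:
   - The default metric keeps *squared* distances (squared-pixel units),
     matching the defining formula exactly; a `euclidean` mode (square root
     per pair before averaging, pixel units) is available. The downstream
     index thresholds each window against a null built from the same
     metric, so the choice does not change the index's meaning, only its
     intermediate units.
   - The within score's N² normalization is kept as defined rather than
     "corrected" to N(N−1); the constant factor is immaterial once scores
     are compared to a null built the same way.
   - When blink-dropping leaves the two renditions with different column
     counts, the prefactor generalizes to 1/(N_V·N_W), keeping the score a
     mean over all pairs.
4. **Null model.** For each video and mode, surrogate renditions are built
   by giving every contributing stream an independently uniform-random
   usable window start in the same video, and scoring the surrogate
   (default 1000 draws). Randomizing per stream (rather than moving whole
   renditions) maximally destroys cross-subject temporal alignment — the
   structure the null must lack — while preserving each stream's marginal
   gaze distribution. Draws come only from usable windows of the same
   viewing pool they replace, so viewing-specific statistics are
   preserved. A normal distribution is fitted by moments; since only its
   mean is consumed as the threshold, the fitting method cannot affect
   results.
5. **Classification and index.** A window is divergent when its dispersion
   is at or above the null mean, ties divergent. The default index is the
   *fraction* of usable windows labeled divergent, which lies in [0, 1];
   the divergence-weighted sum (1/T)·dᵀf is exposed as the `weighted`
   variant. The fraction is the definition all downstream analyses use:
   it is unit-free, bounded, and invariant to any strictly monotone
   rescoring applied to dispersions and threshold alike.
6. **Agreement.** The viewing-1 and viewing-2 within-viewings label vectors
   of the same video are compared as the proportion of jointly-usable
   windows on which the two classifications agree — over *all* such
   windows, not only divergent ones.

### Degenerate inputs and edge rules

- Windows whose pooled valid-sample fraction falls below
  `min_valid_fraction` (default 0.5) in either rendition are masked
  unusable: excluded from the series, from the null draws and from the
  index denominator. This avoids zero-filled artifacts inflating
  dispersion during blinks and track loss.
- A single-column rendition has within-dispersion 0 (no off-diagonal
  pairs); an empty rendition is an error.
- If the whole cohort fixates one constant point, every null sample is 0,
  the threshold is 0, and every usable window satisfies d ≥ 0: the index
  saturates at 1. This is the documented consequence of the "≥" tie rule
  under a degenerate null, not a bug; real recordings always carry noise.
- With fewer than 2 usable windows there is nothing to randomize over and
  the null sampler raises an error rather than fabricating a threshold.

## Prediction harness

Preference scores are regressed on iGDI by ordinary least squares
(`stats::lm`), reported with Pearson r, R², F on (1, n−2) degrees of
freedom and its two-tailed p. Generalizability uses leave-one-out
cross-validation: n refits, held-out predictions ŷ, RMSE, MAPE
(100·mean|y−ŷ|/|y|, undefined and reported absent when a score is 0),
cross-validated R² and shrinkage. Two R²_cv conventions exist in the
literature; the default here is 1 − SS_res(ŷ)/SS_tot(y) on held-out
predictions, which makes shrinkage the plain difference between fitted and
cross-validated R²; the squared-correlation alternative is exposed via
`r2_method = "cor"`. The expected negative slope (more divergence, lower
preference) is an empirical observation, so it is reported, never
enforced.

## Cardiac branch

RMSSD, √[(1/(I−1)) Σ (r(i)−r(i+1))²] over I consecutive inter-beat
intervals, indexes beat-to-beat parasympathetic variability. Each
subject-video-viewing RMSSD is normalized as percent change from the
subject's 5-min resting baseline, averaged across subjects per
video × viewing, and the group means are correlated (Pearson, two-tailed t
on n−2 df) with the between-viewings iGDI — one pair per video × viewing,
so 12 videos give 24 pairs and df = 22. Shapiro–Wilk normality checks on
both variables are reported but not enforced. First- and second-viewing
RMSSD are pooled; a paired t-test across videos is emitted alongside so
the pooling assumption is auditable.

Raw photoplethysmography traces are supported through `ppg_to_ibi`: a
zero-phase 4th-order Butterworth low-pass at 7 Hz (order chosen as common
physiological-signal practice; the cutoff preserves the pulse wave while
removing mains and movement noise), peak detection above an adaptive
mean + 0.5·SD threshold with a 300 ms refractory period, and a
deterministic artifact filter in place of manual editing: a configurable
plausibility band (300–2000 ms) plus a spike rule flagging intervals above
1.3× the running median, with dropped counts logged.

## The synthetic generator

The generator exists so that every stage has a ground truth. It emulates:

- a *shared attention path*: piecewise-constant fixation targets with
  exponentially distributed fixation durations (mean 300 ms, 80 ms floor),
  Gaussian target jumps (SD 120 px) mean-reverting toward screen center
  (pull 0.4 per fixation, stationary target SD 150 px), and 30 ms linear
  saccade ramps;
- *divergent segments*: inside configured intervals, each subject-viewing
  follows an independent path drawn from the same process;
- measurement realism: per-subject Gaussian noise (SD 20 px, roughly half
  a degree at desktop viewing distance), Poisson blink dropouts (0.15
  events/s, 200 ms, coordinates lost and validity cleared) and clipping to
  the 1024×758 px screen (clips counted).

Defaults mirror the acquisition conditions the method targets: 10
subjects, two viewings, 30-s videos at 60 Hz. The study-level generator
maps preference scores monotonically (decreasingly) onto divergent-segment
coverage in [0.05, 0.70] and generates matching inter-beat series whose
RMSSD targets decrease with coverage, so the gaze and cardiac branches
share one ground truth. The IBI generator is an AR(1) process whose
innovation SD is set analytically from the target RMSSD
(σ = target·√((1+φ)/2), φ = 0.5).

What the generator does *not* emulate: saliency-driven gaze on real video
frames, smooth pursuit, center-bias dynamics tied to cuts, head movement,
or tracker-specific noise spectra. Passing tests therefore demonstrate the
*method's* correctness and recoverability under controlled conditions, not
that any particular effect size will appear in real recordings.

### A ceiling worth knowing about

Because the null is built from the same video it thresholds, a *fully*
divergent video is its own null: actual windows and surrogate draws then
follow the same distribution, and the expected fraction of windows at or
above the null mean is roughly P(X ≥ E[X]) ≈ 0.45–0.5, not 1. The index
is therefore most sensitive in the low-to-moderate divergence range and
compresses near total divergence. The recovery tests accordingly assert
strict monotonicity of the index in designed coverage up to 0.75, and the
study generator caps coverage at 0.70.

## Numerical choices

- Squared-distance dispersions are computed from per-window sufficient
  statistics (counts and first/second coordinate moments) in a centered
  variance-decomposition form: rendition scatter plus squared mean
  separation. This is algebraically identical to the defining double sum
  but avoids the catastrophic cancellation the raw expansion suffers for
  far-from-origin coordinates (translation invariance holds to ~1e-12
  relative instead of ~1e-8), and it makes the Monte-Carlo null linear in
  per-stream window statistics — each surrogate draw is O(S), which is why
  1000 draws per video cost milliseconds.
- Euclidean-mode pairwise distances use direct coordinate differences
  rather than the sum-of-squares expansion, for the same reason.
- Dispersion is translation-invariant, so the screen-coordinate convention
  (origin top-left, y down) cannot affect any result; this is tested.
- All stochastic steps (generator, null draws) accept seeds; a rerun with
  the same seed is bit-identical.

## Test problem sizes

The suite validates closed forms against explicit loop oracles (200 random
matrices, N ≤ 30, relative tolerance 1e-9), metric axioms on randomized
inputs, null-threshold stability across seeds (two 1000-draw runs within 3
combined standard errors) and against exhaustive enumeration on a
two-window toy video. Index recovery uses cohorts of 8 subjects and 120-s
videos at divergence coverages {0, 0.25, 0.5, 0.75} × 10 seeds — the
duration chosen so that the ~0.02 Monte-Carlo standard error of a fraction
estimate sits well below the ~0.11 step between adjacent coverage levels.
The end-to-end check runs the full 12-video, 10-subject, 30-s study across
10 seeds and asserts the sign of the fitted slope, not its magnitude.

## Known limitations

- The index compresses near total divergence (see above); comparisons are
  most meaningful between videos of similar length and cohort size.
- The valid-fraction rule treats blinks as missing-at-random; systematic,
  stimulus-locked blinking would bias usable-window selection.
- MAPE is undefined for zero scores and reported absent there.
- The within-viewings rendition pools all subjects of one viewing; with
  very small cohorts the within scores are dominated by inter-subject
  spread rather than temporal structure.
- The PPG peak detector targets clean ear-lobe pulse trains; heavily
  motion-contaminated traces should be cleaned upstream.
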