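# igdi — eye-gaze Divergence Index for narrative video

When a narrative video does its job, it steers every viewer's eyes along
roughly the same path: attention converges on the storyline. When it fails,
gaze patterns scatter. **igdi** quantifies that failure. It implements the
eye-gaze Divergence Index (iGDI) — a single number per video measuring the
fraction of time the video loses control of its audience's attention — plus
the evaluation harness that links the index to audience preference scores
and to heart-rate-variability markers of attention allocation.

The package is aimed at researchers in psychophysiology, media/advertising
research and neurocinematics who have multi-subject eye-tracking recordings
of dynamic stimuli (and optionally cardiac data) and want a scalar,
AOI-free, saccade-free measure of attentional synchrony.

## The method

**Dispersion.** For a short time window, pool each viewing's gaze samples
across all S subjects into renditions V, W ∈ ℝ^(2×N) (columns are (x, y)
screen positions). The dispersion between renditions is the average
squared distance over all column pairs:

    D(V, W) = (1/(N_V·N_W)) Σ_{n1} Σ_{n2} Σ_{i=1,2} (v_i(n1) − w_i(n2))²

The *between-viewings* score compares viewing 1 against viewing 2 of the
same video; the *within-viewings* score applies the same sum to one pooled
rendition over all ordered pairs n1 ≠ n2, normalized by N². Scores are
computed over a sliding grid of 250 ms windows shifted by 50 ms (80 %
overlap). An optional `euclidean` metric mode takes the square root of the
per-pair coordinate sum before averaging.

**Null model and classification.** For each video, a Monte-Carlo null
destroys temporal alignment: every stream is assigned an independently
random usable window of the same video and the dispersion of the surrogate
renditions is recorded (1000 draws by default). A normal distribution is
fitted by moments; a window is *divergent* when its dispersion is at or
above the fitted mean D̄_null (ties divergent).

**The index.** iGDI is the fraction of usable windows labeled divergent —
a proportion in [0, 1]; high values mean the video repeatedly fails to
guide attention. (A `weighted` variant, (1/T)·dᵀf, is also available.)

**Evaluation harness.** A univariate least-squares model
`score = b0 + b1·iGDI` is fitted against audience preference ratings, with
leave-one-out cross-validation reporting RMSE, MAPE, cross-validated R² and
shrinkage. The cardiac branch computes RMSSD
(√[(1/(I−1)) Σ (r(i)−r(i+1))²]) from inter-beat intervals, its percent
change from a resting baseline, and the Pearson correlation between
group-level RMSSD change and iGDI.

Because no gaze/PPG recordings ship with the package, a first-class
synthetic generator produces cohorts with known ground truth — a shared
fixation/saccade attention path, per-subject noise, blink dropouts and
injected divergent segments — so every stage is testable end to end.

## Worked example

```r
library(igdi)

study <- generate_study(n_subjects = 6, duration_ms = 15000, seed = 42)
run   <- run_igdi(study$streams, study$markers, seed = 43)
head(run$summary[run$summary$mode == "between", ], 4)
#>            video    mode      igdi t_usable threshold
#> 1 between      1 between 0.1317568      296  84007.85
#> 10 between    10 between 0.3445946      296  90912.44
#> 11 between    11 between 0.2364865      296  70183.98
#> 12 between    12 between 0.2702703      296  80068.38

pred <- run_predict(run, study$scores)
pred$between$model
#> <igdi_lm> y = 7.948 -8.14 x  (n = 12)
#>   R = -0.743, R^2 = 0.5522, F(1, 10) = 12.333, p = 0.005615
pred$between$cv
#> <igdi_cv> leave-one-out over n = 12:
#>   RMSE = 0.9571, MAPE = 13.1%, R^2_cv = 0.2837, shrinkage = 0.2685
#>   sd(b1) = 1.005, sd(b0) = 0.2184 across refits

hrv <- run_hrv(study$ibi, run)
hrv$correlation
#> <igdi_hrv_cor> r_(22) = -0.570, p = 0.003624 (n = 24)
#>   Shapiro-Wilk: iGDI W = 0.918 (p = 0.0528); HRV W = 0.971 (p = 0.692)
```

Reading the output: video 10 (the lowest-rated spot in the reference score
table) spends ~34 % of its usable windows above the divergence threshold,
versus ~13 % for video 1. The fitted slope is negative — higher divergence,
lower preference rating — and explains 55 % of score variance on this small
synthetic cohort, with the leave-one-out report quantifying how much of
that fit survives held-out prediction. The cardiac branch recovers the
designed negative RMSSD–iGDI coupling over the 24 video × viewing pairs.

A thin command-line wrapper with `simulate` / `igdi` / `predict` / `hrv`
subcommands is shipped at `inst/cli/igdi.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","igdi.R",package="igdi"))')" \
  simulate --out simdir --seed 1
```

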