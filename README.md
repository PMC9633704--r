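# mmdfc — intrinsic dynamics of functional connectivity

`mmdfc` analyses the *intrinsic* dynamics of time-resolved (dynamic)
functional connectivity from parcellated BOLD timeseries. It is aimed at
researchers studying how brain network dynamics differ across states of
consciousness (anaesthesia, disorders of consciousness) or any ordered
clinical gradient, who want an individual-specific description of
connectivity dynamics instead of cohort-level state clustering.

## The approach

For each subject, tapered sliding-window correlation (window W = 24
timepoints, step 1, Gaussian taper) turns a T × R timeseries into N =
⌊(T − W)/step⌋ + 1 connectivity matrices. Correlating the vectorized upper
triangles of every pair of windows gives the **meta-matrix** (MM, a.k.a.
functional connectivity dynamics): an N × N landscape in which entry
(i, j) is the similarity of the brain's connectivity pattern at windows i
and j. The package quantifies this landscape with:

* **Temporal decay of similarity models (TDSM)** — null landscapes whose
  entries decay with lag |i − j| (linear, or exponential
  `exp(linspace(log 1e-4, 0, N)/c)` with c = 3 or 1.5). The Pearson
  correlation between the strict upper triangles of MM and model measures
  how *predictable* (never-revisiting) a subject's dynamics are.
* **Proximal transitions** — the MM sub-diagonals: the similarity series of
  connectivity patterns 1..L steps apart (~2 s per step), summarized by
  median, SD, Shannon entropy, sample entropy (SampEn = −ln(A/B),
  Chebyshev templates of lengths m+1 and m, r = 0.2·sd), and normalized
  effort-to-compress (ETC: NSRPS pair-substitution steps / (L − 1)).
* **Distal meta-matrix (dMM)** — the MM with the k nearest lags removed
  (k = 13 primary, 24 sensitivity) and the remaining triangle mirrored,
  `D[a,b] = MM[min(a,b), max(a,b)+k]`; per-column complexity measures how
  richly each state is defined by its temporally distant alternatives.
* **Structure–function series** — per window, the FC matrix is
  proportionally thresholded to the structural connectome's edge count and
  correlated with the structural weights; the complexity of that series
  measures how freely function departs from the anatomical backbone.
* **Proportional-odds ordinal regression** — per-subject measures as
  predictors of ordered condition labels,
  `P(Y ≤ j | x) = logistic(ζ_j − xβ)`, with odds ratios, Wald CIs, a
  likelihood-ratio proportional-odds check, Spearman inter-correlations and
  rank-sum group tests.

A synthetic-data module generates cohorts with piecewise-stationary
covariance regimes, geometric structural connectomes, and a planted
arousal gradient (dwell time, transition smoothness, structure–function
coupling, within-state drift), so the full pipeline is testable end to
end. See the vignette (`vignettes/intrinsic-dynamics.Rmd`) for the model
and every design decision.

## Worked example

```r
library(mmdfc)

cfg <- sim_config(seed = 7)                                  # 30 regions, 145 volumes, TR 2 s
sc  <- generate_structural_connectome(30, density = 0.2, seed = 8)
ts  <- generate_bold(cfg, sc)

cs <- sliding_window_connectivity(ts)
cs
#> Connectivity series (windowed): 122 matrices of 30 x 30, W = 24, step = 1

mm <- build_meta_matrix(cs)
round(tdsm_fit(mm, "exp_slow"), 3)
#> [1] 0.778  # how well a never-revisiting decay model explains this landscape

summarize_series(as.numeric(proximal_series(mm)))
#>                    mean                  median                      sd
#>                  0.9869                  0.9874                  0.0035
#>         shannon_entropy          sample_entropy effort_to_compress_norm
#>                  2.6020                  0.9704                  0.5583
#>     mean_abs_derivative
#>                  0.0010

dm <- distal_measures(mm, k = 13)
dm$effort_to_compress_norm   # 0.568 — complexity of distal state definitions
dm$mean_max_similarity       # 0.270 — average best distal match

struct_func_summary(struct_func_series(cs, sc))$sample_entropy
#> [1] 1.398  # irregularity of the function-structure similarity timecourse
```

Interpretation: consecutive windows are highly similar (median lag-1
similarity 0.987) because neighbouring windows share 23 of 24 timepoints;
the informative quantities are the *relative* differences across subjects
and conditions. A cohort-level analysis is one call:

```r
coh <- generate_cohort(cohort_spec(base_seed = 1))   # UWS < MCS < SED < CON, 59 subjects
res <- run_pipeline(coh)
res$analysis    # one proportional-odds odds ratio per measure
```

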