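---
title: "Intrinsic dynamics of functional connectivity: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrinsic dynamics of functional connectivity: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmdfc)
```

## The analysis in one paragraph

`mmdfc` characterises the *intrinsic* dynamics of a subject's functional
connectivity: instead of clustering connectivity states across subjects, it
describes each time-resolved connectivity pattern by its similarity to all
of the same subject's other patterns. Parcellated BOLD timeseries are turned
into a sequence of tapered sliding-window correlation matrices; correlating
the vectorized upper triangles of every pair of windows yields the
**meta-matrix** (MM, also known as functional connectivity dynamics) — an
N-window-by-N-window similarity landscape, windows ordered in time. The
package then asks, per subject: how predictable is that landscape (fit to a
temporal-decay null model), how fast and how regular are short-term
transitions (sub-diagonal series), how complex is each state's relation to
temporally distant states (distal meta-matrix), and how tightly do
functional patterns track the structural connectome (structure–function
series). Each question produces scalar per-subject measures which are
related to ordered condition labels (e.g. unresponsive wakefulness <
minimally conscious < sedated < awake) by proportional-odds ordinal
regression.

## Windowed connectivity

Window length W = 24 timepoints moved by 1 timepoint is the default (48 s
windows at TR = 2 s): long enough for stable correlation estimates in the
standard resting-state band, short enough to resolve state turnover, and
one-step advance maximises the number of windows (N = floor((T − W)/step)
+ 1; a 145-volume series gives 122 windows). A Gaussian taper de-weights
window extremities; its width is not dictated by common practice beyond
"exists", so we default to sigma = W/6 (≈ 4 for W = 24), which leaves the
central ~2/3 of the window dominant. Windows containing a zero-variance
region are flagged and rejected by downstream operations rather than
silently imputed.

An instantaneous phase-synchrony alternative is provided
(`phase_synchrony_series()`): a 0.03–0.07 Hz zero-phase second-order
Butterworth band-pass (narrow enough for meaningful analytic-signal
phases), per-timepoint synchrony `1 − |sin(Δθ/2)|`, and a default trim of
10 timepoints per edge against filter transients. The filter family and
trim are implementation decisions; only the band itself is standard.

## Meta-matrix, decay models, and their fit

The MM uses Pearson correlation between vectorized strict upper triangles
(column-major order, fixed throughout); Manhattan and cosine variants are
stored as distances with an `orientation` tag, and every directional
operation negates distances so that "higher = more similar" holds
uniformly.

The **temporal decay of similarity model** (TDSM) is the null landscape of
a trajectory that never revisits past states: entries depend only on lag,
through a profile `u` that is linear (`i/(n−1)`) or exponential
(`exp(l/c)` with `l` the arithmetic sequence from `log(0.0001)` to
`log(1)` and decay constant c = 3 for the slow, c = 1.5 for the fast
variant). `tdsm_fit()` is the Pearson correlation between the strict upper
triangles of MM and model. The diagonal (trivially 1 on both sides) is
excluded; whether to include it is genuinely open, and we record the
strict-upper choice as ours. Because Pearson is affine-invariant the
linear-kind fit does not depend on the profile's scale or offset.

The 2-D state-space picture (`embed_mm()`) is classical metric
multidimensional scaling on Euclidean distances between MM columns; it is
descriptive only and feeds no downstream statistic.

## Proximal and distal measures

The lag-1 sub-diagonal of the MM is the series of similarities between
consecutive connectivity patterns (~2 s apart). Multi-lag variants average
sub-diagonals 1..L aligned on their start index and truncated to common
length N − L (the literature's "averaging across sub-diagonals" is not
more specific; alignment on the start index is our choice). Each series is
summarized by mean, median, standard deviation, Shannon entropy (10
equal-width bins, log2), sample entropy, normalized effort-to-compress,
and the mean absolute first difference.

The **distal meta-matrix** removes the k nearest lags and mirrors the
remaining off-diagonal triangle: `D[a,b] = MM[min(a,b), max(a,b)+k]`,
diagonal undefined. k = 13 (just over half a window, 26 s) is the primary
choice and k = 24 (fully non-overlapping windows) the sensitivity one.
A dMM "column" under this literal mirror construction mixes one window's
distal past with the k-shifted window's distal future; the alternative
reading (one window's full distal profile) is computable from the same
cells, and we document rather than resolve the ambiguity. Column
sequences are ordered by ascending row index (temporal order of partner
windows), summarized per column and averaged; a vectorized mode treats
all defined cells as one sequence. `mean_max_similarity` — the average
best distal match — is reported alongside.

## Complexity kernels

*Sample entropy*: −ln(A/B) with template lengths m+1 and m (default
m = 1, i.e. lengths 2 and 1; the phrasing "lengths 2 and 1" also admits
m = 2, so m is exposed as a parameter), Chebyshev distance, tolerance
r = 0.2·sd(x). It is therefore invariant to affine rescaling of the
input. A constant series returns 0 (flagged degenerate); if no templates
match at either length the value is undefined and propagates as `NA`
with a warning, never as a silent 0 or infinity. Natural log for SampEn,
log2 for Shannon entropy — the conventional bases of their respective
sources.

*Effort-to-compress* (ETC) counts non-sequential recursive pair
substitution (NSRPS) steps until the sequence is constant or length 1,
normalized by L − 1. Pair frequencies are counted over all adjacent
(overlapping) positions; the most frequent pair's non-overlapping
occurrences are replaced left-to-right by a fresh symbol (the current
alphabet size); ties go to the pair whose first occurrence starts
earliest. This is the only counting/replacement combination consistent
with the canonical worked example (00101101 → 02212 → 3212 → 412 → 52 →
6, five steps), which the test suite pins symbol by symbol. Real-valued
series are symbolized into 10 equal-width bins (more bins stabilise ETC
on short sequences; the maximum maps into the top bin).

## Structure–function dynamics

Per window, the functional matrix is proportionally thresholded to
exactly the structural connectome's edge count — top-E cells by signed
value by default (most-positive correlations retained; absolute-value
ranking is available, since sign handling is not settled), ties broken
deterministically by (value, row, column) — and compared to the
structural weights by Pearson correlation (cosine and Manhattan
variants available). Structural weights enter raw; a `log1p` option
exists. The resulting per-window similarity series is summarized by
sample entropy, normalized ETC, and its maximum. Undefined windows are
dropped, not imputed.

## The synthetic cohort generator

No generative model is dictated by the analysis itself, so the generator
is a first-class design of this package, built to emulate the statistical
structure the analysis assumes while staying honest about what it is.

Each subject is a piecewise-stationary multivariate normal process:
a first-order Markov regime sequence (self-transition probability
1 − 1/mean_dwell, uniform switch targets) selects among `n_states`
correlation states; covariances blend linearly over `transition_width`
timepoints around switches; draws are AR(1)-smoothed and iid Gaussian
noise is added. Defaults emulate a five-minute resting-state scan:
R = 30 regions, T = 145 volumes at TR = 2 s, 5 states, noise at 10% of
signal amplitude.

Two design points deserve emphasis:

* **Amplitude-equalized state patterns.** Each state's correlation
  structure is a convex blend (weight `sc_coupling`) of a structural
  component — the correlation matrix of the positive-semidefinite part of
  SC/max(SC) — and a state-specific rank-3 factor component, both shrunk
  toward the identity to a common off-diagonal amplitude of 0.2. Without
  this equalization the structural term is much flatter than the factor
  term, so varying `sc_coupling` across conditions would change overall
  pattern strength relative to estimation noise — a confound that
  masquerades as (and in practice inverts) complexity differences. With
  it, `sc_coupling` moves pattern *content* only. The 0.2 amplitude sits
  just below the structural component's own positive-definiteness limit
  and yields distal-similarity maxima around 0.3–0.4, the range seen in
  real data. Any composed covariance that still loses definiteness is
  repaired by a logged diagonal eigenvalue shift.

* **Geometric connectomes.** Structural connectomes place regions at
  latent 2-D positions, keep exactly `round(density·R(R−1)/2)` shortest
  distances as edges, and let weights decay exponentially with distance.
  Distance dependence is the dominant organizing principle of real
  tractography connectomes, and it makes the weight matrix nearly
  positive semidefinite, so the structural correlation component is a
  faithful image of the connectome (at full coupling, windowed FC
  correlates with the SC pattern at r ≈ 0.55 despite window estimation
  noise).

**The arousal gradient.** `cohort_spec()` orders conditions from least to
most aware (defaults UWS < MCS < SED < CON with 12/11/18/18 subjects) and
interpolates four parameters linearly along that order:

| parameter          | least aware | most aware | planted story                              |
|--------------------|------------:|-----------:|--------------------------------------------|
| `mean_dwell`       | 60          | 6          | slower state turnover when unaware        |
| `transition_width` | 8           | 2          | more sluggish switches when unaware       |
| `sc_coupling`      | 0.35        | 0.15       | function pinned to structure when unaware |
| `ar_coefficient`   | 0.1         | 0.7        | richer within-state pattern drift when aware |

The first three directions are the conventional planted contrasts. The
fourth is this package's own addition, and it matters: with W = 24 and
step = 1 the lag-1 similarity series is dominated by the per-slide update
of the windowed estimator, and state switches — however frequent — produce
only *smooth* modulation at one-step resolution. Dwell, width and coupling
alone therefore cannot move proximal sample entropy or distal column
complexity in the directions observed in patients. The AR(1) coefficient
controls how far connectivity patterns drift within a state: large values
produce rich, weakly predictable short-term pattern exploration (the aware
phenotype: lower lag-1 median, higher proximal sample entropy, higher dMM
compressibility-resistance), small values produce shallow fluctuation
around a fixed pattern. Per-subject seeds are a deterministic hash of
(base seed, condition index, subject index), so cohorts are exactly
reproducible.

With these defaults, 4-condition cohorts recover all five planted
directions (TDSM fit and proximal median higher when less aware; proximal
sample entropy, dMM ETC and structure–function sample entropy higher when
more aware) in at least 90% of 20 base seeds — the recovery check the
test suite runs.

**What the generator does not emulate** (so what passing tests do not
show): hemodynamic convolution and its regional variability, scanner
drift and motion, physiological nuisance structure, spatial autocorrelation
of parcels, non-Gaussian BOLD marginals, and any real topography of brain
networks. Recovery of planted directions demonstrates that the pipeline
measures what it claims under its own assumptions — not that those
directions hold in any particular dataset. One planted sub-direction is
knowingly absent: in this generator the proximal standard deviation
co-moves with the AR-driven drift (higher when aware), so the patient
literature's "lower proximal SD when aware" is not recoverable here and is
excluded from the directional checks.

## Ordinal statistics

`fit_proportional_odds()` wraps the cumulative-logit model
`P(Y ≤ j | x) = logistic(ζ_j − xβ)` (fitted by `MASS::polr`; with two
outcome levels the model *is* ordinary logistic regression and is fitted
as such). Predictors are z-scored by default so odds ratios are per
standard deviation — the raw-vs-standardized scale of published ORs is
generally unknowable, so every result records the flag and OR magnitudes
are never compared across that divide. Wald CIs and z-based p-values are
the default; one-sided p-values halve the two-sided value when the sign
matches the declared direction. Reversing the condition order negates β
exactly (OR → 1/OR), which is how "decreasing" effects are reported on an
interpretable scale. Variance inflation factors are reported for joint
models (warning above 5). No multiple-testing correction is applied by
default, matching common reporting practice; Benjamini–Hochberg can be
applied to the results table by the user.

The proportional-odds assumption is checked by a likelihood-ratio test of
the parallel-slopes model against the unconstrained multinomial logit
(`nnet::multinom`), on (levels − 2) × predictors degrees of freedom. The
test suite verifies ~5% type-I error at n = 1000 over 200 null
simulations and >80% power against grossly non-parallel alternatives.
Brant's test proper is out of scope. The rank-sum comparison uses
mid-ranks with the tie-corrected normal approximation and is verified
against exact enumeration for small groups.

## Numerical choices and degenerate inputs

* Zero-variance vectors: weighted Pearson returns `NA` with a warning;
  windows containing them are flagged; flagged windows are rejected by
  the MM and dropped (with a message) by the structure–function summary.
* Constant series: entropies are defined as 0 and flagged `degenerate`.
* Sample entropy with no matching templates: `NA`, flagged, never silent.
* Cohorts with unequal scan lengths are truncated to the cohort-minimum
  window count from the start of the series before MM construction.
* Thresholding ties at the cutoff: deterministic (value, row, column)
  order.
* Non-positive-definite composed covariances: logged eigenvalue-shift
  repair, hard error only if repair fails.
* 1-based window indexing in code; lags are in window steps (1 step =
  1 TR = 2 s at defaults).

A known bookkeeping curiosity: published counts for a 300-volume
acquisition sometimes state 271 windows where N = T − W + 1 gives 272
after five dropped volumes; the package follows the formula and leaves
the discrepancy to the reader.

## Problem sizes used by the test suite

Unit tests run on small synthetic subjects (R = 10–20, T = 40–120).
The recovery check uses the full default cohort (59 subjects, R = 30,
T = 145) over 20 base seeds; calibration checks use 200 null simulations
at n = 1000 and slope recovery at n = 2000. These sizes were chosen as
the smallest at which the checked properties are stable.

## Worked example

```{r example, eval = FALSE}
library(mmdfc)

# one synthetic subject
cfg <- sim_config(seed = 7)
sc  <- generate_structural_connectome(30, density = 0.2, seed = 8)
ts  <- generate_bold(cfg, sc)

cs <- sliding_window_connectivity(ts)      # 122 windows of 30 x 30
mm <- build_meta_matrix(cs)                # 122 x 122 landscape
tdsm_fit(mm, "exp_slow")                   # predictability of the landscape
summarize_series(as.numeric(proximal_series(mm)))
distal_measures(mm, k = 13)
struct_func_summary(struct_func_series(cs, sc))

# a full cohort analysis
coh <- generate_cohort(cohort_spec(base_seed = 1))
res <- run_pipeline(coh)
res$analysis
```

## Limitations

The package analyses parcellated tables, not images; all MRI
preprocessing (denoising, nuisance regression, band-pass filtering,
tractography) is upstream and assumed done. The synthetic cohort is a
validation instrument, not a simulation of any clinical population, and
odds-ratio magnitudes from it have no quantitative relation to published
values — only directions are meaningful. The dMM column ambiguity and
the TDSM diagonal question are documented choices, not settled facts.
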