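---
title: "Decoding target odors in novel backgrounds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding target odors in novel backgrounds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glomix)
```

`glomix` simulates olfactory-bulb glomerular responses to odor mixtures and
benchmarks decoding algorithms on the go/no-go "target in novel background"
task. This vignette is the package's account of the underlying models, the
parameters that matter, the numerical choices, and what the synthetic data
do and do not establish.

## The response model

A glomerular response is a per-ROI z-score relative to a pre-odor baseline;
activation is **negative** z throughout (the intrinsic-imaging convention —
activated glomeruli reflect less light). The package never flips this sign.

### Atlases

An atlas is an odors × ROIs matrix of mean responses for one animal. The
generator (`generate_atlas()`) draws, for each odor, a Bernoulli activation
mask at the role's activation probability and a negative amplitude for each
active ROI. The default role statistics are the measured ones for awake
wild-type animals:

| role        | fraction active | mean amplitude (z) |
|-------------|-----------------|--------------------|
| target      | 0.295           | -0.32              |
| contextual  | 0.435           | -0.70              |
| fixed       | 0.37            | -0.41              |
| novel       | 0.461           | -0.63              |

with 155 ROIs per animal and a 20-odor panel (4 targets — 2 go, 2 no-go — 4
contextual backgrounds, 1 fixed background, 11 novel backgrounds).

Only the across-animal mean and s.d. of role amplitudes are known, not the
within-animal amplitude distribution. We draw active amplitudes from a
half-normal scaled so its mean equals the role mean (implied spread
|mean|·sqrt(pi/2 − 1)); a truncated-normal alternative with an explicit
`amplitude_dispersion` is available in `atlas_spec()`. ROIs are statistically
exchangeable: no spatial layout statistics are imposed, because none are
known.

### Trial-to-trial noise

A single trial is

s(t) = s̄ · (1 + CV_corr·g(t) + CV_uncorr·ε(t)) + σ_noise·η(t)

with `g` one standard Gaussian per odor presentation shared by all ROIs (the
population-wide gain), `ε` and `η` independent per entry. The shared-gain
s.d. is CV_corr = sqrt(CV² − CV_uncorr²), which makes the line-fit
decomposition below exact as a generative model. The per-entry variance is
then the mean–variance law

σ²(μ) = σ²_noise + CV²·μ².

The two measured regimes ship as constructors:

* `noise_model_wt()`: CV = 0.34, CV_uncorr = 0.25, σ_noise = 1.59,
  σ_uncorr_noise = 1.47, detection threshold −0.42;
* `noise_model_cntnap2()`: CV_uncorr = 0.44, σ_noise = 1.83,
  σ_uncorr_noise = 1.65, threshold −0.46. The total CV of this regime keeps
  the wild-type correlated-gain s.d., since only the uncorrelated component
  was reported to differ.

Imaging noise is additive, Gaussian and independent across ROIs, consistent
with the observation that σ_uncorr_noise ≈ σ_noise (imaging noise is mostly
uncorrelated across glomeruli).

## Estimators

### Variance–mean fit

`fit_variance_mean()` fits σ²(μ) by unweighted least squares over ROI–odor
pairs. The law is linear in (σ²_noise, CV²), so the minimizer is computed
exactly and clamped at the non-negativity boundary; this avoids the singular
Jacobian that a generic nonlinear solver hits when CV converges to exactly
zero. No weighting is applied.

Because μ is itself a trial mean, regressing on μ̂² attenuates CV²
(errors-in-variables). When the pair table carries trial counts, the fit
subtracts the estimated error variance from the regressor
(method-of-moments deattenuation: replace μ̂² by μ̂² − σ̂²/n and shrink the
denominator by the mean error variance of μ̂²). With 20 repeats this moves
CV by several percent — enough to matter against a 95% CI of ±0.035 — and
falls back to the uncorrected slope if the correction would remove more
than three quarters of the regressor variance. Confidence intervals are
percentile bootstrap over ROI–odor pairs (default 1000 resamples, seeded).

The strong-response preselection (keep ROIs with mean z < −2 for at least
one odor) is exposed as `strong_only` in `trial_stats()`, default on, since
weakly responding ROIs carry no information about CV.

### Correlated/uncorrelated decomposition

For every odor presentation, `decompose_uncorrelated()` regresses the
single-trial responses of **all** simultaneously recorded ROIs on their
trial-averaged responses (ordinary least squares, intercept included — the
intercept absorbs nothing under the generative model but stabilizes real
data). Deviations from the line are uncorrelated noise; their s.d. per
ROI–odor pair is fitted with the same law to give CV_uncorr and
σ_uncorr_noise.

Two numerical details matter:

* OLS residuals have variance (1 − hᵢ)σᵢ²; the high-leverage points are
  exactly the strongly responding ROIs that carry the CV signal, so
  residual s.d.s are studentized by 1/sqrt(1 − hᵢ) before the fit.
* The fit defaults to the squared law (σ² vs μ). Whether the s.d. or the
  variance is the better-conditioned target is genuinely ambiguous; both
  are implemented (`fit_on = "sd"`), variance is the default, and the two
  agree on clean data.

### Saturation

Mixture responses deviate from the linear sum R₀ of their components
following the odd sigmoid σ(R₀) = 2A/(1 + e^(R₀·s)) − A. `fit_saturation()`
estimates (A, s) by Levenberg–Marquardt least squares; the measured model
(A = −8.0934, s = 0.2091) ships as `saturation_model_measured()`.
Non-convergence raises an error rather than returning defaults.

## Virtual mixtures and designs

`compose_mixture()` follows the documented order: curtail each component at
the detection threshold (entries with z above it become 0), sum per ROI,
then apply the saturation. The order of thresholding vs saturation is only
implied by the order of description; we follow that order and the
saturation can be disabled (`saturation = NULL`), e.g. when decoding
measured mixture tables that already contain the nonlinearity. Trial noise
is added afterwards to the composed mean, uncorrelated only, matching how
virtual-mixture instantiations are evaluated.

`enumerate_design()` builds the stimulus sets: the full design is 4 targets
× 4 contexts with the fixed background (16 training mixtures) and the same
combinations with each of 11 novel backgrounds (176 test mixtures; 192
total). The reduced design pairs each context with one go and one no-go
target (8 training mixtures; the complementary 8 combinations × 11 novels
give 88 test mixtures). The specific go/no-go pairing within the reduced
design is not dictated by the counts; the package fixes one balanced
assignment so that every target appears twice and every context sees both
valences.

## Decoders

All decoders train on the mean training patterns and are evaluated on `n`
noisy instantiations of each test mixture (default 100),
`mean · (1 + CV·ε)`. Population decoders are evaluated at the uncorrelated
CV (0.25 wild-type regime): with access to the whole population a decoder
could in principle discount the shared gain, and the mixtures are composed
patterns rather than re-recorded trials. The single-glomerulus classifier
is evaluated at the total CV (0.34): one glomerulus has no reference by
which to remove the correlated fluctuation.

* **Single glomerulus** (`fit_best_glomerulus()`): picks the ROI maximizing
  training discriminability `abs(auROC − 0.5) + 0.5` (rank-based auROC,
  ties half-weighted) and thresholds at the ROC point tangent to the 45°
  line, i.e. the Youden maximum of TPR − FPR. Orientation (whether
  more-negative means go) is learned, not assumed. Ties in ROI selection go
  to the lowest index.
* **Linear families** (`train_linear()`): readout c = Σ wᵢsᵢ + w₀, labels
  ±1, decision by sign with exact zero mapped to no-go. The logistic family
  minimizes the L1-penalized logistic loss (glmnet); the SVM family
  minimizes L1-penalized squared hinge by FISTA proximal gradient with an
  unpenalized bias (no installed solver offers an L1 hinge). λ = 0 is the
  unpenalized fit. In the orchestration layer the default penalty is
  1/n_train, the customary default strength of linear-classifier libraries;
  exact solver internals of the reference implementations are not
  recoverable, so comparisons are behavioral (sweep shape, chance/ceiling
  properties), not weight-identical.
* **Nearest neighbor** (`nnc_fit()`): training mixtures are templates,
  centered per glomerulus by the training means; the test pattern
  (identically centered) is assigned the valence of the template with the
  largest dot product. ROIs below a training-discriminability selectivity
  threshold (grid 0.5–1; 0.5 keeps all) are excluded; dot-product ties go
  to the lowest template index.
* **Lasso deconvolution** (`lasso_solve()`): minimizes
  Σᵢ(sᵢ − Σⱼ cⱼ d_ij)² + λΣⱼ|cⱼ| over a dictionary of odor patterns,
  solved by glmnet coordinate descent. glmnet's objective is
  (1/2n)·RSS + λ_g·L1, so the user's λ (default 1e-4) maps to λ_g = λ/(2n);
  a short decreasing warm-start path makes the final solution accurate.
  Coefficients are unconstrained in sign as the cost is written
  (`nonneg = TRUE` is available, off by default). Observations are solved
  in raw (negative) z units; at λ = 1e-4 the penalty is nearly negligible
  against squared errors of order 1, so the solution is close to
  least-squares with a sparse tie-break, which is the intended operating
  point. The readout compares max(c) over the two go targets vs the two
  no-go targets; an exact tie is called no-go.

Dictionaries (`build_dictionary()`) hold the 9 trained odors (4 targets, 4
contexts, fixed background) plus synthetic elements drawn from a
multivariate Gaussian with the mean and ROI × ROI covariance of the full
20-odor panel. That 20-sample covariance in ~155 dimensions is
rank-deficient; draws use the eigendecomposition restricted to positive
eigenvalues, with no shrinkage, so the sampled ensemble reproduces the
stated mean/covariance exactly on its support. Every element is normalized
to unit variance of its entries across ROIs.

## Orchestrated experiments and their problem sizes

`run_comparison()`, `sweep_glomeruli()`, `cv_sensitivity()` and
`correlate_with_behavior()` chain the above per synthetic animal. Default
problem sizes are chosen so that a full comparison runs in tens of seconds
on one core: 3 animals × 155 ROIs, 100 instantiations per test mixture, 5
dictionaries of 100 elements for the Lasso; the test suite uses smaller
versions of the same settings (2 animals, 15–40 instantiations, dictionary
sizes 30–100). Estimates sharpen with more animals, instantiations and
dictionaries but the qualitative results are stable at these sizes.

`correlate_with_behavior()` needs a Monte-Carlo distribution of the
correlation between per-odor decoder performance and per-odor behavioral
performance. Rather than re-running the decoder 500 times, each repeat
resamples the stored instantiation-level outcomes with replacement per
mixture — a bootstrap over the same source of randomness that re-simulation
would redraw, at a fraction of the cost.

"Significance" inside sweeps (e.g. flagging the CV at which performance
first degrades) uses two-sided t-tests at α = 0.05 across animals or
mixtures; this mirrors the conventional reporting style and is a reporting
convention, not a scientific claim of the package.

## What the synthetic data do and do not show

The generator reproduces the first-order statistics of real atlases
(sparseness and amplitude per odor role, 155-ROI scale), the measured
noise structure (mean–variance law, correlated/uncorrelated split, additive
imaging noise) and the mixture nonlinearity. It deliberately does **not**
reproduce:

* correlations between the patterns of different odors (odor-odor pattern
  similarity structure) — odors are drawn independently;
* day-to-day and session-to-session variation of the measured patterns —
  training means are noise-free platonic patterns;
* spatial ROI layout, respiration/sniffing, and lick dynamics.

Consequences worth being explicit about: on these synthetic atlases the
max-margin-like linear SVM retains more reduced-training-set performance
than it does on recorded data, because noise-free, independently drawn
target patterns are easier to separate from 8 examples than real,
correlated, measurement-noisy ones. The robust qualitative findings — the
nearest-neighbor classifier collapsing to chance on the reduced design,
the Lasso staying on top of every other family, insensitivity of all
decoders to the measured variability increase (CV_uncorr 0.25 → 0.44) with
degradation only at roughly double that, and sparsity sweeps that trade
ROIs for performance — replicate here and are what the acceptance suite
asserts. Absolute percentages on real recordings are outside what synthetic
data can certify.

## Degenerate inputs and tie-breaks, collected

* Zero-variance baseline pixels in `zscore_movie()` get a
  machine-epsilon-scaled variance floor (noiseless fixtures must not emit
  non-finite z). Gaussian "radius σ" is read as the s.d. in µm, converted
  to pixels, with reflective boundary padding.
* `apply_detection_threshold()` is idempotent and never increases |z|.
* An all-zero pattern is rejected by `similarity()` (undefined cosine).
* CV is unidentifiable when all means are zero — error, not a guess.
* Exact-zero linear readout → no-go; NNC dot-product tie → lowest template
  index; ROI-selection tie → lowest ROI index.
* Seeds thread through every stochastic operation; results carry their
  seed, and identical seeds give bit-identical outputs.
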