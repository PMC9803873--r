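---
title: "Methods: diurnal rhythm detection, variability decomposition and internal-time prediction in two-layer skin transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diurnal rhythm detection, variability decomposition and internal-time prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

`skindiurnal` analyzes bulk transcriptome time series sampled from two skin
layers (dermis and epidermis) of a cohort of subjects over one day.  The
canonical design it targets is 11 subjects x 2 layers x 7 biopsies at 4-h
spacing (wall clock 8:00 through 32:00, stored unwrapped), with each
subject's chronotype measured as the sleep-corrected mid-sleep on free days
(MSF~sc~, hours).  All rhythm fitting is done against *internal time*

$$t_\mathrm{int} = t_\mathrm{wall} - \mathrm{MSF}_{sc},$$

so that hour 0 is each individual's mid-sleep and phases are comparable
across chronotypes.  Because MSF~sc~ differs between subjects, internal
times are unevenly spaced; every test in the package is therefore built on
harmonic regression, which needs no uniform sampling (rank-based detectors
such as JTK or RAIN do, and are out of scope).

Input is a genes x samples log2 expression matrix assumed already
normalized (e.g. by an RMA/limma microarray pipeline); probe-level matrices
are collapsed by `average_probes_to_genes()` (arithmetic mean on the log2
scale).  Missing values are rejected rather than imputed: the package
targets complete array data, and silent imputation would bias amplitude
estimates.  `flag_outlier_samples()` screens for aberrant samples by
centroid distance in PC1--PC2 using a z-score rule (`k = 4` SDs by
default); the threshold is configurable because outlier calls of this kind
are ultimately judgment calls, and the function only flags -- the caller
decides removal.  On data with strongly separated clusters (the two layers
typically split along PC1) the global centroid distance is nearly constant
for every sample, so the pipeline applies the rule within each layer.

# Population rhythms: the cosinor model

For one gene in one layer, pooling all subjects' samples (the *population
rhythm*, i.e. the cohort-average diurnal pattern), the model is

$$y(t) = m + a\cos\omega t + b\sin\omega t + \varepsilon,
  \qquad \omega = 2\pi/24\,\mathrm{h},$$

fit by ordinary least squares.  The period is fixed at 24 h (no period
scan); `period` is an argument everywhere for generality.  Derived
quantities follow the standard cosinor conventions:

* **MESOR** (magnitude) $m$ -- the rhythm-adjusted mean, log2 units.
* **Amplitude** $A = \sqrt{a^2+b^2}$ -- half the peak-to-trough swing in
  log2 units, so the peak-to-trough fold change is $2^{2A}$.  The fold
  change threshold 1.5 used for calling biologically relevant rhythms
  corresponds to $A > \log_2(1.5)/2 \approx 0.292$.
* **Acrophase** $\phi = (\mathrm{atan2}(b,a)/\omega) \bmod 24$ -- the peak
  time in hours after internal time 0, i.e. after MSF~sc~.

Rhythmicity is the F test of $H_0\!: a=b=0$ with $(2, n-3)$ degrees of
freedom, BH-corrected across genes within a scan.  `layerwise_rhythm_scan()`
optionally moderates residual variances across genes by empirical Bayes
(`limma::squeezeVar`); moderation is ON in the full pipeline (it stabilizes
per-gene variances in small designs) and OFF by default in the bare
function, where the exact F null is preferable for calibration work.

# Differential rhythmicity between layers

`fit_joint_model()` fits both layers jointly with six coefficients
(layer-specific intercept, cosine and sine).  The design is block-diagonal
by layer, so joint coefficients equal two independent per-layer fits -- the
joint form exists to share a single residual variance across the two
F tests:

* **any-rhythm**: $H_0\!: a_d=b_d=a_e=b_e=0$, $(4, n-6)$ df;
* **differential**: $H_0\!: (a_d,b_d)=(a_e,b_e)$, $(2, n-6)$ df.

`categorize()` applies a two-stage decision rule.  A gene passes the
*diurnal gate* when its any-rhythm BH q-value is below the FDR threshold
(0.05) **and** its larger layer fold change strictly exceeds 1.5.  The
differential q-values are then BH-corrected *within the gated set only*.
Gated genes that are statistically indistinguishable across layers count as
rhythmic in **both** layers even when one layer's fold change is below 1.5
(the sub-threshold inclusion rule); gated genes with a significant
difference are assigned `both_differential`, `dermis_only` or
`epidermis_only` by which layers' fold changes clear the threshold.  This
is the only assignment under which the per-layer totals decompose exactly
as

$$\mathrm{total}_L = \#\mathrm{indistinguishable}
  + \#L\mathrm{\_only}
  + \#\{\mathrm{differential\ with\ FC}_L > 1.5\},$$

a partition identity asserted on every run.  Ties at the threshold are
excluded (strict inequality).  Per-layer rhythmic gene lists reported to
users always come from the categorization, never from independent
per-layer scans, so the partition stays consistent.

Phase agreement between layers is summarized by `circular_phase_stats()`:
pairwise acrophase differences wrapped to $(-12, 12]$ h, their circular
mean, the mean resultant length $R$ and a Rayleigh test (series
approximation of the p-value, accurate for $n \gtrsim 10$).

# Variability decomposition: mixed models + error propagation

To quantify how much individual rhythms deviate from the population
rhythm, each gene (restricted to genes rhythmic in at least one layer) is
fit with a linear mixed model in which the full coefficient vector
receives crossed random deviations:

$$g(t) = (m + \Delta m_\mathrm{subj} + \Delta m_\mathrm{layer})
 + (a + \Delta a_\mathrm{subj} + \Delta a_\mathrm{layer})\cos\omega t
 + (b + \Delta b_\mathrm{subj} + \Delta b_\mathrm{layer})\sin\omega t
 + \varepsilon,$$

with $(\Delta m,\Delta a,\Delta b)_\mathrm{subj} \sim N(0,
\Sigma_\mathrm{subj})$ (full symmetric 3x3) and
$(\Delta m,\Delta a,\Delta b)_\mathrm{layer} \sim N(0,
\Sigma_\mathrm{layer})$ restricted to diagonal -- with only two layer
levels a full layer covariance is not estimable with any reliability, and
the diagonal restriction keeps the parameter count tractable.  Estimation
is maximum likelihood via `lme4::lmer(REML = FALSE)`; lme4's relative
Cholesky factorization guarantees positive semi-definite estimates, and
boundary (singular) fits are legitimate outcomes that are flagged, not
suppressed.  ML rather than REML keeps log-likelihoods comparable across
models with different fixed effects; with n = 154 observations and 3 fixed
effects the REML/ML distinction is immaterial next to the sampling noise
of variance components estimated from 11 subjects and especially from 2
layers -- layer variances should be read as order-of-magnitude statements.

Amplitude and phase are nonlinear in $(a, b)$, so their variability across
a source $x \in \{\mathrm{subj}, \mathrm{layer}\}$ is obtained by
delta-method error propagation:

$$\sigma^2_{A,x} = J_A \,\Sigma_x\, J_A^{\mathsf T}, \quad
  J_A = \left(0,\; a/A,\; b/A\right); \qquad
  \sigma^2_{\phi,x} = J_\phi \,\Sigma_x\, J_\phi^{\mathsf T}, \quad
  J_\phi = \left(0,\; -b/A^2,\; a/A^2\right),$$

with $\sigma_\phi$ converted from radians to hours by $24/2\pi$.  The
linearization assumes deviations are small relative to $A$; it is accurate
to a few percent when $\sigma_A/A < 0.2$ (verified against Monte-Carlo in
the test suite), and each gene carries a `phase_linearization_ok` flag
($\sigma_\phi < 2$ h for both sources).  Genes with $A = 0$ have undefined
Jacobians and are reported as `NA`.

The relative contribution of subjects is the variance fraction
$f = \sigma^2_\mathrm{subj} / (\sigma^2_\mathrm{subj} +
\sigma^2_\mathrm{layer})$ per parameter.  Relative amplitude variability
uses the coefficient of variation $\sigma_A/A$.  For phase, a CV is
ill-defined (the acrophase origin is arbitrary on the circle), so relative
phase variability is defined here as $\sigma_\phi/\mathrm{period}$; an
analysis preferring $\sigma_\phi/\phi$ can compute it from the returned
columns.

# Enrichment

**ORA.** `hypergeom_ora()` is the upper-tail hypergeometric test of a
query list against a caller-chosen background; there is deliberately no
default background because different questions use different universes
(all expressed genes vs all diurnal genes).  Sets are intersected with the
background first; sets contributing fewer than `min_set = 20` *query*
genes are excluded before BH correction (the exclusion counts query
members, the stricter of the two plausible readings of a min-set rule, and
the one that matches "pathways with fewer than 20 diurnal genes").

**PSEA.** `psea()` asks a different question: not whether a set contains
many diurnal genes, but whether its diurnal members are *phase
synchronized*.  Member acrophases are rounded to the full hour, and
non-uniformity on the circle is tested with the Kuiper statistic
$V = D^+ + D^-$, whose value -- unlike Kolmogorov--Smirnov -- is invariant
to rotating all phases by a constant (there is no privileged origin on a
clock).  It is also sensitive to multimodal departures, e.g. antiphase
clusters at 0 h and 12 h that a Rayleigh test cannot see because the
resultant vector cancels.  P-values use the asymptotic Kuiper series with
Stephens' small-sample factor $\sqrt n + 0.155 + 0.24/\sqrt n$; a
Monte-Carlo null is available behind `p_method = "montecarlo"` and agrees
with the series to well under 0.01 at n = 30 in the acceptance checks.
Sets with fewer than 5 diurnal members are excluded; BH across tested
sets; significance at q < 0.05.

# Internal-time prediction from a single sample

`train_predictor()` implements a sparse-principal-component time decoder
(periodic basis + penalized matrix decomposition + Gaussian maximum
likelihood).  The stages, per layer:

1. per-gene centering/scaling on the training samples;
2. per-gene periodic mean curves: least squares on a harmonic basis with
   orders 1..`n_knots - 1` (default `n_knots = 3`, i.e. two harmonics,
   5 coefficients).  A harmonic basis was chosen over periodic splines
   because with 7 distinct times per cycle a spline basis would be close
   to saturation, while two harmonics capture the waveforms a cosinor
   pipeline targets;
3. sparse PCA of the curve matrix evaluated on a 0.5-h grid:
   `sparse_pcs()` maximizes $u^{\mathsf T} X v$ under
   $\|v\|_2 \le 1, \|v\|_1 \le \texttt{sumabsv}$ by alternating
   soft-thresholded power iterations with rank-1 deflation, initialized
   deterministically from the leading singular vector; `sumabsv = 1`
   selects exactly one gene per component,
   `sumabsv \ge \sqrt{n_\mathrm{genes}}` reproduces dense PCA;
4. per-SPC periodic score curves plus a constant Gaussian residual
   variance (the simplest decodable likelihood; score noise is assumed
   time-homogeneous and independent across SPCs, a simplification flagged
   here);
5. `predict_time()` maximizes the score log-likelihood over a 0.1-h grid
   (ties to the earliest grid time).

Accuracy is evaluated by `loso_cv()`: leave one subject out, train on the
rest, predict each held-out sample, take the *median* circular absolute
error (MAE, in $[0, 12]$ h) over all held-out samples, one MAE per
`(sumabsv, nSPC)` grid point.  The default grid is sumabsv in {1, 1.5, 2,
3} and nSPC in {2, 3}, spanning single-gene to ~30-gene predictors.  On
synthetic clock cohorts at the canonical design (10 informative genes,
residual SD 0.15) the best grid point reaches an MAE well under 1.5 h.
Exact concordance with any external sparse-PC implementation is not a
goal; the behavioral properties (dense-PCA limit, single-gene limit,
support recovery, circular error bounds, closed-loop score geometry) are
what the tests pin down.

# The synthetic cohort generator

`simulate_cohort()` draws data from exactly the generative model the
variability analysis assumes, so every downstream stage can be validated
against known truth.  Defaults are the canonical study conditions: 11
subjects, 7 wall timepoints at 4-h spacing (8--32 h), both layers,
MSF~sc~ uniform on [2.5, 6] h (a 3.5-h chronotype spread typical of a
screened intermediate-chronotype cohort), 10% rhythmic genes, acrophases
from a two-component von Mises mixture centered 1 h and 13 h after
mid-sleep ($\kappa = 2$), lognormal log2 amplitudes (median 0.35 dermis,
0.5 epidermis, sdlog 0.4 -- fold changes mostly 1.5--3), MESOR
$N(8, 1.5^2)$ on the log2 intensity scale, subject covariance with SDs
(0.15, 0.10, 0.10) and correlation 0.3, diagonal layer covariance with
SDs (0.30, 0.05, 0.05) -- magnitude more layer-variable, rhythm
coefficients more subject-variable -- and residual SD 0.2.  Values not
fixed by the study design were chosen once as field-realistic microarray
magnitudes and are not tuned.

Two layer modes exist.  `"random"` (default) draws per-gene per-layer
deviations from the diagonal layer covariance, exactly matching the mixed
model.  `"fixed_contrast"` instead draws each layer's amplitude from its
layer-specific law, producing the epidermis-larger-amplitude regime
deterministically; this is the mode used when a run must contain genuine
layer-differential genes.  Randomness flows from a single mandatory seed
through one RNG stream, giving bit-identical cohorts per seed.

What the generator does **not** emulate: probe-level array artifacts
(background, dye, saturation), correlated residual noise within a biopsy,
non-sinusoidal waveforms, and count-like mean-variance coupling.  Passing
tests on synthetic cohorts therefore demonstrate correctness of the
statistical machinery under its own assumptions -- not robustness to
real-data violations of them.

# Numerical choices and degenerate inputs

* Cosinor scans solve one QR decomposition per layer and reuse it across
  genes; per-gene fits use `lm.fit`.  Rank-deficient time designs (all
  times equal modulo the period) are errors, not warnings.
* Times are stored unwrapped; all periodic computation reduces modulo the
  period internally.  Phase differences and prediction errors use the
  wrap to $(-12, 12]$ / $[0, 12]$ h.
* BH correction is `stats::p.adjust(method = "BH")`; the differential
  q-values are corrected within the gated set only.
* The sparse-PC L1 projection solves for the soft threshold by 60
  bisection steps; component signs are fixed by making the
  largest-magnitude loading positive, which makes training deterministic.
* Zero-variance genes get scale 1 (not dropped) in the predictor; an
  all-flat training matrix yields a predictor flagged `uninformative`.
* `variance_fraction(0, 0)` is NaN with a warning, never silently 0 or 1.
* Mixed-model convergence warnings from the optimizer mark the fit
  `converged = FALSE`; singular (boundary) fits are separately flagged.

# Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
cohorts at or near the canonical design: scans on 100--2000 genes, mixed
models on up to 200 genes (plus one 50-subject cohort for covariance
recovery), $10^6$-draw Monte-Carlo checks of the delta method, a
$10^5$-draw Kuiper null, and full LOSO-CV grids on 50-gene clock cohorts.
These sizes were chosen so a complete validation pass stays in the
low minutes on one core while keeping every statistical check
well-powered.

# Known limitations

* Layer variance components rest on two levels; their absolute values are
  noisy by construction (flagged, not shrunk).
* Delta-method phase SDs degrade for weakly rhythmic genes
  ($\sigma_A/A \gtrsim 0.2$ or $\sigma_\phi \gtrsim 2$ h).
* The population rhythm pools subjects without subject intercepts (by
  definition of a population rhythm); it is not a fixed-effects
  meta-analysis of individual fits.
* The predictor's Gaussian, time-homogeneous score likelihood is a
  simplification; heteroscedastic scores would warrant a richer decoder.
* Probe filtering by background intensity and array preprocessing are out
  of scope; the pipeline consumes a normalized log2 matrix.
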