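---
title: "Methods: strain dyssynchrony, activation mapping, prognosis and mediation in crtcmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain dyssynchrony, activation mapping, prognosis and mediation in crtcmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtcmr)
```

This vignette is the package's own account of the models it implements,
the free parameters and their defaults, what the synthetic generator
does and does not emulate, and the numerical and design choices made
where the methodology left them open.

## The clinical setting

Cardiac resynchronization therapy (CRT) paces the left ventricle to
correct dyssynchronous contraction in heart failure. Cohorts of
interest here mix three groups: (1) de novo CRT implants, (2) upgrades
in patients pacemaker-dependent on chronic right-ventricular pacing
(RVP-HF), and (3) upgrades without pacing dependence. CMR regional
circumferential strain (E~cc~; negative = shortening) measured on
basal, mid-ventricular and apical short-axis slices at a 17 ms frame
interval gives two mechanical quantities per patient: a global
dyssynchrony index and a per-segment mechanical activation time.

## CURE-SVD

`compute_cure_svd()` takes the sectors × frames E~cc~ matrix, extracts
the leading left singular vector $u_1$ (the dominant spatial
contraction pattern), orders its entries circumferentially within each
slice, and computes the spatial DFT powers at harmonic 0
($A_0 = |X_0|^2$, uniform contraction) and harmonic 1
($A_1 = |X_1|^2$, a single early-late cycle around the circumference).
The index is

$$\mathrm{CURE\text{-}SVD} \;=\; \sqrt{\frac{\sum_s A_0^{(s)}}
{\sum_s \left(A_0^{(s)} + A_1^{(s)}\right)}} \in [0,1],$$

with the sums over slices, so one index is reported per patient.
Because only squared Fourier magnitudes enter, the index is invariant
to the arbitrary sign of the singular vectors, to global rescaling of
strain, and to rotation of the sector labels; these invariances are
enforced as property tests. Uniform contraction gives exactly 1; a
zero-mean first-harmonic pattern gives exactly 0; an all-zero matrix is
an error (the index is undefined, not 1 or 0).

Implementation note: formulations of circumferential uniformity differ
in whether they weight slices or average frame-wise ratios. We sum the
two powers across slices *before* forming the ratio, and we compute
them on the rank-1 spatial vector; a frame-wise oracle on the rank-1
reconstruction gives the identical value (tested), because the temporal
factor cancels from the ratio.

## Mechanical activation (TOS) detection

The time to the onset of circumferential shortening is, per sector:
smooth the curve with a centred moving average (window 3 frames),
take forward differences, and report the first frame index $f$ at
which the difference drops below $-\delta$ ($\delta = 0.005$ strain
per frame) for $p = 3$ consecutive frames; $\mathrm{TOS} = f \cdot
\Delta t$. A curve that is still zero at its true onset time and
descends afterwards is detected exactly at that onset in the noiseless
case — the defaults were chosen so that these constructed cases are
exact, and $p = 3$ additionally rejects isolated noise-driven dips
(the differenced noise SD at the default generator noise of 0.01 is
close to $\delta$, so persistence is what provides robustness).
Sectors that never meet the criterion get the maximal time
$(n_f - 1)\Delta t$ plus a quality flag rather than a missing value,
so downstream cutoffs stay computable.

The sector field is then regularised with a circular median filter
(radius 1 sector) within each slice — a deliberate simplification of
contour-based activation-field extraction that preserves the defining
quantity (the first sustained negative slope) while keeping the field
spatially coherent — and aggregated to the AHA 17-segment model by the
*lower* median of member sectors, which keeps segment TOS on the frame
grid (an invariant: every reported TOS is a multiple of $\Delta t$).
The true apex (segment 17) has no short-axis sectors and is never
assigned. Angular convention: 0° at the anterior RV–LV insertion,
counterclockwise; 60° segments on the basal and mid rings, 90° on the
apical ring.

`classify_latest_activation()` reports the region/level of the segment
with maximal TOS (ties to the lowest AHA id, deterministic), and
`activation_at_segment()` dichotomises the TOS at the LV lead segment.
The favorable threshold is **inclusive** (TOS ≥ cutoff): source
descriptions of the 34 ms rule vary between "≥ 34" and "> 34", and
since detected TOS values are exact multiples of 17 ms the choice
matters; we adopt ≥ and state it rather than leaving it implicit.

## Response metrics and cutoff selection

`lvesvi_fractional_change()` is the exact ratio
$(\mathrm{post}-\mathrm{pre})/\mathrm{pre}$ of the LV end-systolic
volume index (negative = reverse remodeling) with the conventional
−0.15 responder threshold, inclusive (≤ −0.15; the strictness of the
boundary is not standardised, so we fix and document it).

`youden_optimal_cutoff()` scans cutoffs over multiples of a step (the
17 ms frame interval for activation times — the cutoff should be a
realisable measurement), classifies value ≥ cutoff as the favorable
test, computes $J = \text{sens} + \text{spec} - 1$ against 4-year
survival status, and returns the argmax with ties broken toward the
smallest cutoff (conservative and reproducible). The 4-year horizon
for the survival outcome follows the cohort's median follow-up scale.

## Prognostic models

`fit_l1_logistic_path()` is a from-scratch cyclic coordinate descent on
the IRLS quadratic approximation of the penalized logistic
log-likelihood, with glmnet's standardisation convention (mean 0, SD 1
with the $1/n$ variance), warm starts along a decreasing $\lambda$
grid, an unpenalized intercept, and coefficients reported back on the
original scale. At $\lambda \ge \lambda_{\max} =
\max_j |X^\top(y-\bar y)|/n$ all slopes are analytically zero; at
$\lambda = 0$ it reproduces the Newton/IRLS maximum-likelihood solution
to $10^{-6}$ (tested against an independent Newton oracle, and against
glmnet where available). Separation at $\lambda = 0$ is capped and
flagged, constant columns are dropped with a warning.

The selected model (pre-CRT BNP, pre-CRT creatinine, prior CABG, and
the TOS ≥ 34 ms flag at the lead site) is refit unpenalized
(`fit_logistic()`), evaluated on a 70/30 split at a probability
threshold of 0.5 (the threshold is a convention we fix explicitly),
and summarised by a rank-formulation AUC (half-credit ties, hence
invariance under monotone score transforms) with exact
beta-quantile (Clopper–Pearson) intervals at three operating points.
The "points of interest" are not standardised; we take the
Youden-optimal point and the points nearest sensitivity 0.8 and
specificity 0.8.

`build_nomogram()` maps each covariate's linear-predictor contribution
onto 0–100 points, reference at the favorable end:
$\mathrm{points}_j(x) = 100\,|\beta_j|\,|x - x_{\mathrm{fav},j}| /
\max_k |\beta_k|\,\mathrm{range}_k$, and total points map to
probability through the inverse logit of the reconstructed linear
predictor — an exact round trip (tested to $10^{-10}$; reading through
a table rounded to half points costs at most half a point of linear
predictor).

`fit_cox()` wraps `survival::coxph` with Efron tie handling (the
better approximation under tied event times; the choice is tagged in
the result), and `reverse_km_median_followup()` wraps
`survival::survfit` on the flipped indicator — censoring as the event
— whose median is the standard estimate of median follow-up. With no
censored observations that median is undefined and the maximum time is
returned flagged.

## Censored Gaussian mediation

The outcome model throughout the mediation module is a parametric
survival regression with a Gaussian distribution **on the
untransformed time scale**: latent time $T = X\beta + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2)$, with density contributions for
deaths and upper-tail survival contributions for censored patients
(`survival::survreg`, `dist = "gaussian"`; a log-time option exists
but is off by default, since the time-scale model is the one whose
coefficients are in years). With zero censoring the MLE reduces to
OLS (tested to $10^{-8}$); the small-sample fit is validated against
an iteratively refined grid search of the likelihood to $10^{-3}$.

`bootstrap_mediation()` computes path $a$ by OLS of the mediator on
the binary exposure (group 2 = RVP-HF upgrade vs group 1 = de novo;
group 3 is excluded from the mediation contrast), path $b$ and the
direct effect from the censored Gaussian model of time on exposure +
mediator, and the total effect $\tau$ from the model without the
mediator. ACME $= a \cdot b$; proportion mediated $=$ ACME$/\tau$,
reported verbatim with an *inconsistent mediation* flag when the paths
oppose in sign. No exposure–mediator interaction is modeled (the plain
product method). Inference is nonparametric patient-level resampling
with **percentile** intervals (the simplest interval consistent with a
bootstrap-only description; BCa would require jackknife influence
values and is not implemented), and a two-sided bootstrap p-value
taken as the smallest level at which the percentile interval excludes
zero (floored at $1/B$). Replicates drawing a single exposure class
are redrawn and counted; more than 10% redraws raises a warning. On
uncensored linear data the decomposition direct + ACME $= \tau$ is an
exact identity of nested fits and is tested to $10^{-6}$.

## Group comparison

`compare_groups()` uses the tie-corrected Kruskal–Wallis test with
Dunn's rank-based z post hoc contrasts for continuous variables (the
Dunn z is computed in-package from the joint ranks with the standard
tie correction; p-values unadjusted by default with an optional Holm
flag, since no adjustment convention is imposed), and chi-square for
categorical variables with a Fisher-exact fallback when any expected
cell is below 5 (the classical rule). Fisher p-values are validated
against complete hypergeometric enumeration.

## The synthetic generator

The generator's role is to define study-like conditions with known
ground truth, not to imitate images. Strain curves are a raised-cosine
shortening–reshortening waveform (flat zero before onset, cosine
descent to peak −0.15 over 150 ms, cosine recovery to 35% of peak over
200 ms) — the methodology constrains only "onset = start of sustained
negative slope", so the family is chosen smooth with a well-defined
onset. True onsets are snapped to the 17 ms frame grid and are
**piecewise constant over AHA segments**: mechanical activation
propagates as a wavefront, so neighbouring sectors activate together,
and a spatially white per-sector onset field would be unphysiological
(and would make any spatially regularised detector look biased). Each
patient's latest-activated segment is drawn from group-specific
region/level distributions that reproduce the anterior/basal shift of
late activation in the RVP-HF group (48.3% anterior vs 10% in de novo
patients), imposed at generation so the shift is a checkable property
rather than an emergent accident.

Clinical covariates follow the observed group distributions: skewed
labs (creatinine, BNP, LVESVI) lognormal parameterized by group
medians with log-SDs back-computed from interquartile ranges,
approximately symmetric measures (age, QRS, Q-LV) normal, binary
covariates by prevalence. Covariates are drawn independently within
group (within-group correlations among labs are not reported and
default to zero; the config exposes the marginal parameters, not a
copula). Group-2 creatinine is the group-1 lognormal baseline **plus
an additive shift** equal to the mediator path $a = 0.361$ mg/dL —
this prioritises the exact mediation structure over matching the
group-2 marginal median (the resulting median is ≈1.41 rather than the
observed 1.3 mg/dL), a trade we make deliberately since the mediation
paths are the quantity under test.

Survival inverts the analysis model: latent
$T = \beta_0 + c' \cdot 1[\text{g2}] + c_3 \cdot 1[\text{g3}] +
b \cdot \text{creatinine} + \varepsilon$, $\sigma = 1.5$ yr,
administrative censoring at 5 years (median follow-up in such cohorts
is just under 5 years; optional uniform early censoring is off by
default). Defaults: $b = -2.37$, $c' = -1.447$ (the total effect
−2.302 minus the mediated product −0.855 — an arithmetic identity of
linear mediation), $\beta_0 = 9$ and $c_3 = -0.8$ (neither is
reported; chosen once so group-1 5-year mortality is ≈20% and latent
times are almost surely positive — the rare negative latent time is
recorded as death on day one). Under these defaults the group-2 event
rate exceeds the observed cohort's: with effects expressed in years at
$\sigma = 1.5$, honoring the path coefficients forces stronger
survival separation than the real cohort shows. We keep the paths and
accept the rates. Optional prognostic paths for BNP, CABG and the TOS
flag exist for known-truth selection experiments but default to 0, so
the default latent model is exactly the stated mediation structure.
Short-term response measures (LVESVI fractional change, post BNP,
ΔpeakVO₂) are drawn around group medians with a configurable, weak
association to the latent time; they are descriptive plumbing, not
calibrated targets.

What passing tests on this generator do **not** show: robustness to
image-domain artifacts (off-resonance, phase unwrapping), scar beyond
a simple amplitude attenuation, correlated comorbidity structure, or
non-Gaussian survival noise. Recovery results on the generator are
statements about estimator correctness under the stated model, not
about clinical accuracy.

## Numerical choices and degenerate inputs

* Coordinate descent: convergence when the largest standardized
  coefficient change falls below $10^{-10}$; IRLS weights floored at
  $10^{-5}$; warm starts down the grid.
* `survreg` is run with `rel.tolerance` $10^{-10}$; non-convergence
  and all-censored inputs are explicit errors/flags, not silent.
* Youden and latest-activation ties break toward the smallest cutoff /
  lowest AHA id — deterministic and stated.
* Degenerate inputs fail loudly: all-zero strain (undefined CURE),
  single-class outcomes (undefined AUC/cutoff), constant covariates
  (dropped with warning in the L1 path, error in Cox), zero-range
  nomogram covariates (excluded with warning), no censored
  observations (flagged undefined median follow-up).
* Everything downstream of a config seed is a pure function of it:
  bundles are reproducible to the byte on the data components (model
  objects carry environments and are compared by value in tests).

## Problem sizes used in the shipped checks

Analytic-limit and oracle checks run at desk scale (6–300
observations). Recovery checks use: 40 patients × 36 sectors for TOS
(noise SD 0.01, ≥95% of segments within one frame), 2000 patients per
arm for the mediation paths and the censored-Gaussian consistency
checks (within 3 SEs of truth), 5000 per group for generator moment
recovery (within 3 Monte-Carlo SEs), 1000 random matrices for the
CURE-SVD range property, and 60 replicates × 120 bootstraps for the
90% bootstrap-coverage check — sizes chosen to make the statistical
assertions sharp at interactive runtimes.

## Known limitations

* The activation detector is a slope detector with median-filter
  regularisation, not a contour evolution guided by the strain
  gradient; on very gradual onsets the detected frame can lag the
  mathematical onset by design (the slope must clear $\delta$).
* The CURE-SVD definition here fixes one of several reasonable
  slice-combination conventions; comparisons across software should
  check the convention before comparing values.
* Percentile bootstrap intervals can undercover at small n with heavy
  censoring; the coverage test pins the uncensored behaviour.
* The three-group generator draws covariates independently within
  group; analyses that rely on lab–lab correlation (e.g. multivariable
  confounding structure) need the correlation injected by the user.
* The cohort-level fitted quantities of any real study (AUCs, hazard
  ratios, test accuracies) depend on the patient data and are not
  reproduction targets of the synthetic pipeline; the package
  reproduces the *methods*, the worked arithmetic, and the generator's
  known truth.
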