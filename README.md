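# crtcmr

Analysis toolkit for cardiac-resynchronization-therapy (CRT) cohorts
studied with cardiac magnetic resonance (CMR) regional strain. It is
aimed at biostatisticians and imaging researchers who want to analyse —
or prototype against realistic synthetic versions of — cohorts that mix
de novo CRT implants with device *upgrades* in patients with heart
failure from chronic right-ventricular pacing (RVP-HF), where the open
questions are: where is the left ventricle activated last, does pacing
near late-activated myocardium predict response and survival, and how
much of the upgrade group's excess mortality travels through comorbid
pathways such as renal dysfunction?

## What it computes

**Mechanical dyssynchrony (CURE-SVD).** From a sectors × frames matrix
of circumferential strain E<sub>cc</sub>, the matrix is reduced to its
dominant (rank-1) spatial singular vector *u*₁; within each short-axis
slice the spatial Fourier power at harmonic 0 (A₀) and harmonic 1 (A₁)
of the circumferentially ordered *u*₁ is computed, and

&nbsp;&nbsp;&nbsp;&nbsp;CURE-SVD = √( ΣA₀ / Σ(A₀+A₁) ) ∈ [0, 1],

with 1 = perfectly uniform (synchronous) contraction and 0 = pure
first-harmonic dyssynchrony. The index is invariant to strain
rescaling, sector-label rotation and sign flips.

**Mechanical activation mapping (TOS).** The time to onset of
circumferential shortening is detected per sector as the first frame at
which the smoothed strain curve acquires a sustained negative slope,
spatially regularised by a circular median filter, and aggregated to
the AHA 17-segment model. The segment-level TOS at the LV lead implant
site, dichotomised at a Youden-optimal multiple of the 17 ms frame
interval (≥ 34 ms = favorable), feeds the prognostic models.

**Prognosis.** L1-regularised logistic regression (coordinate descent,
glmnet-style standardisation) for covariate selection; an ordinary
logistic model of 4-year survival with 70/30 train/test evaluation, a
rank-based AUC with exact Clopper–Pearson intervals at three operating
points, and a 0–100-point nomogram; Cox proportional hazards (Efron
ties); reverse Kaplan–Meier median follow-up.

**Causal mediation.** The effect of the upgrade-with-RVP group (vs de
novo) on survival time is decomposed by the product-of-coefficients
method: the mediator (creatinine) is regressed on the group indicator
by OLS (path *a*), survival time on group + mediator by a **censored
Gaussian survival regression** (path *b*; `survival::survreg`,
`dist = "gaussian"`), ACME = *a·b*, with percentile confidence
intervals from 1000 patient-level bootstrap resamples and the
proportion mediated ACME/τ.

**Synthetic cohorts.** A generator emits strain matrices with known
per-sector onset fields (group 2 biased toward anterior/basal late
activation) and a three-group clinical cohort whose creatinine carries
the mediation path (*a* = 0.361 mg/dL, *b* = −2.37 yr/(mg/dL), direct
effect −1.447 yr, hence total −2.302 yr), so every downstream stage is
testable against known truth.

## Worked example

```r
library(crtcmr)
cfg <- pipeline_config(n_boot = 500, seed = 7)   # 50/29/23 patients
bundle <- run_pipeline(cfg)

bundle$cutoff$cutoff        # Youden-optimal TOS cutoff at the LV lead
print(bundle$mediation)
```

```
Causal mediation (product of coefficients, 500 bootstraps)
  a (exposure -> mediator)      : 0.357
  b (mediator -> survival time) : -2.66
  ACME = a*b : -0.951  [-1.83, -0.409]  p = 0.002
  total effect : -1.76  [-2.56, -0.948]  p = 0.002
  direct effect: -0.735
  proportion mediated: 0.54
```

At the study's size (102 patients, 79 in the two mediation arms) the
point estimates are noisy — the generating truth is ACME = −0.855 and
total = −2.302 — which is exactly why the estimators are validated at
n = 2000 per arm in the tests. `bundle$roc` prints the AUC with exact
binomial intervals at the three operating points, `bundle$nomogram`
the points scales, and `bundle$audit` re-derives every crude
percentage from the row-level data.

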