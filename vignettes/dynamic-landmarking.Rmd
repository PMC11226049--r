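---
title: "Dynamic risk prediction with stacked landmark supermodels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic risk prediction with stacked landmark supermodels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landstack)
```

## The problem

Electronic health records follow patients over years, accumulating repeated
lab values and clinical events. A prediction model fitted once at baseline
ignores everything learned after day one. *Landmarking* is the simplest
principled way to use the accumulating history: pick landmark times
$\ell_j$ (here $0, 0.5, \ldots, 5$ years), restrict attention at each
$\ell_j$ to subjects still event-free, read every covariate at its last
observed value, and predict the outcome over a fixed horizon $\tau$ (here 3
years) from that moment. `landstack` implements this workflow for overall
survival in a liver-cirrhosis setting: baseline age, sex and three etiology
indicators, plus time-varying MELD-Na, serum albumin, a cumulative count of
decompensating events, and a one-way HCC indicator.

Right-censoring makes the conditional outcome unobservable for some
subjects, so three model families are supported, differing in how the
outcome is summarised:

* **PM** — jackknife *pseudo-means* of the conditional restricted mean
  survival time (RMST), $\hat\mu_i(\tau) = n\hat\mu(\tau) -
  (n-1)\hat\mu^{-i}(\tau)$, regressed by GEE with identity link. The answer
  is in years of expected survival over the next $\tau$ years.
* **PP** — the same jackknife applied to the Kaplan–Meier survival
  probability at $\tau$; the answer is a probability.
* **Cox** — a stacked proportional-hazards model with delayed entry at each
  landmark, $P(T > \ell + \tau \mid T > \ell, X(\ell)) =
  \exp\{-[\Lambda_0(\ell+\tau) - \Lambda_0(\ell)]e^{\alpha'X(\ell)}\}$.

All three are fitted once on the *stacked* landmark datasets (a
"supermodel"), with each covariate effect allowed to vary smoothly across
landmarks through the quadratic basis

$$\beta_p(\ell) = \beta_{p0} + \beta_{p1}(\ell/s) + \beta_{p2}(\ell/s)^2,
\qquad s = 5 \text{ years.}$$

Because a subject contributes a row at every landmark it survives, all
stacked fits report subject-clustered sandwich standard errors. With an
independence working correlation and identity link the GEE point estimates
are exactly least squares on the expanded design; the clustering matters
only for the variance.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| landmark grid | $0,\,0.5,\ldots,5$ | years | half-yearly risk review over five years |
| horizon $\tau$ | 3 | years | a clinically meaningful window for transplant triage |
| basis scale $s$ | 5 | years | puts $\ell/s$ on $[0,1]$ over the grid, keeping the three basis coefficients comparable |
| basis degree | 2 | — | quadratic: lets an effect rise then fade; degree 1 forces a straight line, 0 a constant effect |
| train fraction | 0.75 | — | held-out quarter for honest discrimination/calibration |

The at-risk rule is strict ($T_i > \ell$): a subject whose observed time
ties the landmark has no positive residual time to model, so it is
excluded. A measurement at exactly $\ell$ is usable at $\ell$. Subjects at
risk but with no measurement at or before $\ell$ are excluded (and
counted) rather than imputed; inventing an imputation model would change
the estimand silently.

## Pseudo-observations: conventions and the estimable domain

Pseudo-values are computed *within each landmark dataset* on the residual
time scale, so the Kaplan–Meier curve involved is the conditional one given
survival to $\ell$. Ties are resolved with deaths before censorings. RMST
integrates the curve from 0, including the leading segment of height 1,
and carries the curve forward flat past the last observed time.

Two jackknife engines are provided. The naive one recomputes the KM curve
with each subject left out — correct by construction, $O(n^2)$. The fast
one updates the full-sample curve in closed form: removing subject $i$
rescales each KM factor at $t_j \le T_i$ by
$r_j = \frac{1 - d_j/(n_j-1)}{1 - d_j/n_j}$ (with a corrected factor at the
subject's own event time), so all $n$ leave-one-out integrals come from two
cumulative integrals of the full curve. The two engines agree to $10^{-10}$
on randomized tied and censored fixtures in the test suite; the fast one is
the default.

One boundary deserves care: the restricted mean at $\tau$ is identifiable
only when $\tau$ does not exceed the largest observed time. Inside that
range the pseudo-values average exactly to the full-sample estimate (a
property the tests verify to $10^{-10}$ across 200 random censored
fixtures). Beyond it the flat-tail convention takes over, the identity is
no longer owed — removing the last-observed subject changes the curve's
support — and the package warns rather than guesses.

## The Cox supermodel baseline

The printed form of the model leaves open how $\Lambda_0(\tau \mid \ell)$
depends on $\ell$. We use a single Breslow baseline on the study time axis
with delayed entry at each landmark and administrative censoring at
$\ell + \tau$; conditional survival then uses the increment
$\Lambda_0(\ell + \tau) - \Lambda_0(\ell)$. This keeps the baseline a
one-dimensional object shared across landmarks, mirroring how the dynamic
coefficient table carries no baseline-by-time interaction terms. Ties are
handled by Breslow's approximation. A per-landmark stratified baseline is a
natural alternative; it multiplies the number of baseline parameters by the
number of landmarks and was not needed for any validation target here.

## Static comparators

* **SM1** refits at every landmark but freezes covariates at their $t = 0$
  values — conditional on survival, blind to updates.
* **SM2** fits once at $\ell = 0$ and plugs updated covariates $X(\ell)$
  into that baseline model at prediction time.
* **SM3** refits at every landmark on $X(\ell)$.

For the pseudo-value families, SM1 is read as *per-landmark refits of the
conditional outcome on baseline covariates*: the description "a baseline
model used for prediction conditional on survival to $\ell$" is ambiguous,
and the alternative reading (a single $\ell = 0$ fit adjusted post hoc by a
conditional-survival factor) is only well-defined for the Cox family. The
per-landmark reading makes SM1's predictions genuinely conditional for all
three families and keeps the three comparators on the same footing.

## Evaluation

Discrimination is the pairwise concordance
$\mathrm{AUC} = \sum_{i,j} 1\{T_j < T_i\}\,1\{\eta_j > \eta_i\}\,\delta_j
\,/\, \sum_{i,j} 1\{T_j < T_i\}\,\delta_j$ with $\eta$ a *risk* score. The
models emit survival-type predictions (RMST, survival probability), which
are negated before scoring so that informative models sit above 0.5. As
printed, the strict inequality awards tied scores nothing; a
`ties = "half"` option gives the conventional half-credit, but the strict
form is the default. Calibration is the IPCW Brier score (probability
families) or its RMST analogue in years$^2$, with the censoring
distribution $\hat G$ estimated by KM on the same landmark risk set on the
residual scale and $\hat G(T^-)$ taken as a left limit; subjects censored
inside the window carry weight zero. With no censoring the IPCW form
reduces exactly to the plain Brier score. Metrics are computed per
landmark on that landmark's risk set, never pooled.

## The synthetic cohort generator

Because the motivating EHR cohort is private, the package ships a generator
whose *own hazard model is the ground truth*: death follows a proportional
hazards model in the current (LOCF) covariate values with a
piecewise-constant hazard between visits,
$\lambda_i(t) = \lambda_0 \exp\{\beta^T(X_i(t) - x_{\mathrm{ref}})\}$.
Exact conditional survival and conditional RMST under this model are
available by piecewise-exponential integration
(`true_conditional_survival()`, `true_conditional_rmst()`), which is what
makes parameter-recovery testing possible.

Default parameters were chosen once to match the shape of the motivating
cohort — roughly 19–20% deaths and a median follow-up near 1.1 years —
via baseline hazard 0.065/yr at the reference profile, exponential loss to
follow-up at 0.50/yr, and an 11-year administrative end. These are tuning
targets for realism, not assertions; no test asserts the event fraction.
Subjects enter with a Poisson(0.5) count of prior decompensating events
and 5% prevalent HCC: cohorts are assembled after diagnosis, so baseline
covariates must vary for the baseline-fitted comparators to be estimable
at all.
Visit spacing (quarterly with jitter, first visit pinned at $t = 0$ so
SM1/SM2 always have baseline values) is configurable and deliberately *not*
calibrated: visit density in the motivating data is unknown. Per-subject
random streams are split from the master seed, so growing `n_subjects`
extends a cohort without reshuffling earlier subjects.

What the generator does **not** emulate — and hence what passing tests do
not establish about real EHR data: informative visit schedules (sick
patients are seen more often in reality), covariate-dependent or
informative censoring (pseudo-value validity assumes covariate-independent
censoring), measurement-error structure beyond i.i.d. Gaussian noise, and
competing risks such as transplant.

## Validation problem sizes

The test suite checks parameter recovery at sizes chosen to balance
statistical resolution against a comfortably quick default run: cohorts of
$n = 2000$ with a single binary covariate (true log hazard ratio 0.6),
landmarks $0, 0.5, 1$ with $\tau = 3$, across 100 seeds; the Cox supermodel
must cover the true log hazard ratio and the PM-GEE the true
oracle-computed conditional-RMST difference within 3 robust standard
errors in at least 95% of seeds. Desk-scale identities (jackknife
closed forms, brute-force partial-likelihood maximization on 4-subject
fixtures, OLS equivalence, hand-computed metric values) are checked at
tolerances between $10^{-8}$ and $10^{-12}$.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  params = cohort_params(n_subjects = 1000, seed = 1),
  grid_start = 0, grid_end = 5, grid_step = 0.5, tau = 3,
  families = c("pm", "pp", "cox"),
  static_variants = c("sm1", "sm2", "sm3"),
  out_dir = "landstack-run")
res <- run_pipeline(cfg)
head(res$metrics)
```

The run directory contains the two cohort tables, the stacked training
table, the coefficient table (term, estimate, robust SE, p-value), the
per-landmark metric table, dynamic-coefficient figures, and a JSON manifest
recording seeds and per-stage row counts. Figures are views: every plotted
value is recomputable from `dynamic_coefficient()` or the emitted tables.

## Known limitations

* No model selection: every covariate keeps all three basis terms, chosen
  for comparability across families rather than parsimony.
* No spline time interactions; the quadratic basis cannot express effects
  with more than one turning point.
* No competing risks; censoring is assumed covariate-independent, which
  the IPCW weights and pseudo-values both rely on.
* Predictions outside the natural range ($[0, \tau]$ for RMST, $[0, 1]$
  for probabilities) are clipped and reported, a consequence of keeping
  the identity link.
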