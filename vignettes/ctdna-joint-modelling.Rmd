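---
title: "Joint modelling of longitudinal ctDNA and recurrence: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of longitudinal ctDNA and recurrence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate,
the numerical choices, and the known limitations. It states no empirical
result that the test suite does not itself compute.

## 1. The measurement pipeline

Ultradeep targeted sequencing of plasma cell-free DNA tags each original
molecule with a unique molecular identifier (UMI) pair. The MRD caller
reduces raw reads in three stages:

* **SSCS** — reads sharing a mapping position and UMI pair are a family;
  families with at least two reads emit one single-strand consensus read
  whose base is the within-family majority (ties are masked `N`, never
  guessed). Singletons are discarded: a lone read cannot distinguish a
  PCR/sequencing error from a real molecule.
* **DCS** — two SSCS with *transposed* UMI pairs at the same position are
  the two strands of one molecule; they merge into a duplex consensus,
  masking discordant positions. Unpartnered SSCS are retained but flagged,
  because true duplex confirmation is the strongest error suppressor.
* **Polishing** — every candidate (position, substitution) is tested
  against a background error database estimated from tumor-free plasma:
  a one-sided exact binomial test of (mutant consensus reads, consensus
  depth) against the database rate, retained at `alpha` (default 0.01)
  *and* a distinct-support minimum of one duplex-confirmed read or two
  SSCS reads. Published descriptions of such polishing pipelines usually
  require calls to stand significantly above background without fixing a
  statistic or a level; the exact binomial at 0.01 with the duplex/2-SSCS
  support floor is this package's reproducible, conservative rendering of
  that rule, and both knobs are exposed. Database cells never observed in error get a floor
  rate of 1e-6 so no test degenerates.

A plasma sample is **ctDNA-positive** when at least one mutation from the
patient's tumor-tissue profile is present with at least one unique
consensus mutant read passing polishing. The tissue profile itself keeps
variants at VAF >= 1% with >= 5 supporting reads (hotspots, >= 20 COSMIC
cases) or VAF >= 2% with >= 6 reads (all others), after subtracting
matched-normal variants. `mean_vaf` averages the VAF over the *tracked*
mutation set, counting undetected mutations as zero — this makes the
longitudinal marker continuous in detection; averaging over detected
mutations only is available (`mean_mode = "detected"`) because the study's
wording ("all mutations used for detection calling") is ambiguous.

The longitudinal response is the log ctDNA level
`ln(mean VAF + 1e-6) - ln(1e-6)`: zero VAF maps to exactly 0, and a VAF of
0.34% (a typical pretreatment maximum in resected NSCLC) maps to about
8.1, so the working scale runs over roughly 0-9.

## 2. The joint model

For subject $i$ with baseline covariates TP53 mutation and T4 stage:

$$y_{ij} = \eta_i(t_{ij}) + \varepsilon_{ij}, \qquad
  \eta_i(t) = \beta_0 + N(t)^\top(\beta + b_i), \quad
  b_i \sim N_2(0, D), \ \varepsilon \sim N(0, \sigma^2)$$

$$h_i(t) = h_0(t)\exp\{\gamma_1\,\mathrm{TP53}_i + \gamma_2\,\mathrm{T4}_i
  + \alpha_1 \eta_i(t) + \alpha_2 \eta_i'(t)
  + \alpha_3 \textstyle\int_0^t \eta_i(s)\,ds\}$$

* $N(t)$ is a natural cubic spline with two degrees of freedom (boundary
  knots at 0 and the 95th percentile of measurement days, interior knot at
  the median; columns rescaled to O(1) so coefficients are well
  conditioned with time in days). Natural constraints make extrapolation
  beyond the boundary exactly linear, and the truncated-power form gives
  closed-form derivatives and antiderivatives — the slope and
  cumulative-area associations are exact, not numeric.
* The random effects are a 2-vector on the two spline columns with a
  shared fixed intercept, so $D$ is 2x2. An alternative with a random
  intercept would make the integrals 3-dimensional; the 2-D structure is
  what the package's type contracts, oracles and quadrature assume.
* $h_0$ is piecewise-constant on five intervals cut at event-time
  quantiles. Within an interval the hazard is baseline-constant times a
  smooth exponential of spline terms, so Gauss-Legendre nodes per interval
  (7 for fitting, 15 in the simulator) integrate it to near machine
  precision.
* Association structures: current value ($\alpha_1$), value + slope
  ($\alpha_1,\alpha_2$), value + cumulative area ($\alpha_1,\alpha_3$; the
  default final model). `compare_association_structures()` ranks them by
  cross-validated AUROC/PE or AIC.

**Time units.** Days everywhere; month-denominated landmarks convert at
30.44 days/month (`months_to_days()`). The landmark is 8 months, horizons
12 and 15 months. $\alpha_3$ is per (log-level x day).

### Inference

The marginal likelihood integrates $b_i$ by **adaptive Gauss-Hermite
quadrature** (9 nodes per dimension; the C++ core also returns the
analytic gradient of the whole parameter vector). The quadrature centers
and scales come from the mode and curvature of each subject's *full*
integrand — longitudinal density x survival factor x prior — found by a
vectorised Newton ascent. Centering on the longitudinal posterior alone
(the classical pseudo-adaptive scheme) is not enough here: with a
cumulative association the survival factor can be a near-cliff in
$b$-space, and a misplaced grid can *overstate* the likelihood in
extreme-$\alpha$ regions, manufacturing spurious optima. Two safeguards
address the same geometry:

1. after optimisation the log-likelihood is recomputed at 9- and 25-node
   grids with re-adapted centers; a discrepancy above 2 units marks the
   optimum as numerically uncertifiable and triggers a damped restart;
2. the optimizer works inside a priori boxes $|\alpha_1|,|\alpha_2|,
   |\gamma| \le 4$ and $|\alpha_3| \le 0.05$/day that delimit the region
   where fixed-grid quadrature is reliable for data of this design; the
   boxes are several-fold wider than any plausible estimate and estimates
   sitting on a bound are flagged through the information-matrix warning.

`map_ml` (default) maximises with L-BFGS-B in two stages (association
parameters frozen at their two-stage starting values first, then
released), re-adapts the centers at the optimum and repeats; the
covariance is the inverse observed information (central differences of
the analytic gradient). Starting values come from the linear mixed model
(lme4, ML) plus a naive Cox fit on the empirical-Bayes trajectory
features at the observed times — the classical two-stage estimator, which
places the search in the right basin.

`engine = "mcmc"` runs random-walk Metropolis on the same marginal
likelihood (centers frozen at the MAP point) with weakly-informative
priors: normal(0, 10^2) on fixed effects, log hazard ratios, association
parameters, the Cholesky off-diagonal and log baseline rates; half-t(3,
2.5) on the residual and random-effect SDs. The proposal covariance is the
MAP covariance scaled by 2.38/sqrt(p) with Robbins-Monro adaptation during
burn-in toward 25% acceptance; split-Rhat above 1.1 warns. The priors and
sampler settings are this package's own choices; Bayesian joint-model
software rarely documents defaults fully, so they are stated here.

### Dynamic prediction

$\pi(u\,|\,t)$ is the probability of remaining recurrence-free to horizon
$u$ given survival to $t$ and the measurement history. The Monte-Carlo
estimator draws parameters from the fit's covariance (or posterior
draws), runs one Metropolis-Hastings chain per draw on
$p(b\,|\,\text{history}, T>t)$ (200 burn-in steps from the conditional
mode, proposals scaled by the conditional covariance), and reports the
median and 2.5/97.5 percentiles of $S(u|b)/S(t|b)$ — percentile bands,
matching a median-plus-pointwise-band presentation. $\pi(t|t)=1$ by
construction. The cross-validation harness instead uses a deterministic
plug-in (`predict_rfs_point()`): adaptive Gauss-Hermite evaluation of
$\int f(y|b)\phi(b)S(u|b)db \big/ \int f(y|b)\phi(b)S(t|b)db$ at the
point estimates, since metrics need point predictions, not bands.

### Comparators and evaluation

The landmark Cox model refits on the subjects still at risk at the
landmark using the *last observed* ctDNA status plus TP53 and T stage; the
static Cox model uses the fixed postsurgical status from time zero. Both
predict through the Breslow baseline. Discrimination is a pair-based
time-dependent AUROC in the window $(t, u]$; subjects censored inside the
window contribute fractionally with model-based conditional event
probabilities (an inverse-censoring-weighted variant is available).
Calibration is the prediction error with the event/survivor decomposition
at the censoring time, and leave-one-out Hosmer-Lemeshow with Kaplan-Meier
observed probabilities (5 groups by default — appropriate to cohort-scale
risk sets; groups whose KM is undefined at the horizon merge with a
neighbor and the degrees of freedom shrink accordingly). Cross-validation
is stratified by event status; fold splits with an event-free training
fold are redrawn. Paired model comparison uses the exact Wilcoxon
signed-rank test (dynamic-programming enumeration up to n = 25, valid
under ties; normal approximation with tie and continuity corrections
beyond).

## 3. The synthetic cohort: what it emulates and what it does not

`simulation_params()` defines the stated world once:

| parameter | default | why |
|---|---|---|
| visits | quarterly (91.3 d) + day-14 postsurgical draw, administrative censoring at 730 d | the study design: surveillance draws every 3 months for ~2 years, postsurgical sample within 30 days |
| dropout | 5% per visit, trajectory-independent (MAR) | no informative-missingness model is reported |
| $\beta_0,\beta$ | −1, (1.5, 1.8) | most subjects start below the detection offset; the population mean rises modestly. The magnitudes are set so that the recovery criterion (β to 10% median relative error at n = 300) is information-theoretically attainable — with much smaller β the sampling SE alone exceeds 10% for *any* estimator |
| $D$ | SDs 2.5 and 3.0, corr 0.2 | large subject spread: a minority of trajectories rise steeply (relapsing), most stay flat or fall. The curvature variance (second column) is deliberately generous because near-monotone trajectories make $\alpha_1$ and $\alpha_3$ nearly collinear ($\int\eta \propto t\,\eta$) and weakly identified |
| $\sigma$ | 0.4 | replicate noise of a deep-sequencing mean-VAF log level; also keeps the per-subject random-effect posterior tight enough for certifiable quadrature |
| $\gamma_1,\gamma_2$ | ln 3.3, ln 2.7 | the reported univariate TP53 and T-stage hazard-ratio magnitudes, used as realistic effect sizes |
| $\alpha_1,\alpha_3$ | 0.8, 0.02/day | the recovery study's pinned association strengths (current value + cumulative area) |
| baseline $h_0$ | 5 pieces, peak in the 4.5–9-month interval, scale 1e-4 | recurrence hazard peaking around nine months after surgery; the scale is calibrated once so the two-year event rate lands in the stated 30–40% band (≈38% at the defaults) |

Event times invert the subject's cumulative hazard by bisection to 1e-8
days, with 15-point Gauss-Legendre per baseline interval — exact against
the closed-form piecewise-exponential law when the associations are zero
(a tested equivalence). Measured levels are the Gaussian working scale;
values below zero are kept as-is in `log_ctdna` (they are what the model
sees), the materialised `mean_vaf` floors at zero, and `positive` means a
strictly positive measured level.

Two side effects of this world are worth naming. First, because the
random effects act only through the spline columns (zero at day 0),
subject-level variation needs time to accumulate: the day-14 postsurgical
draw is essentially noise around $\beta_0$ and, at $\sigma = 0.4$,
practically never positive. The static (postsurgical-status) comparator
therefore degenerates to a covariates-only model here — an acceptable
floor for the model-ordering comparison, but a place where the generator
is unfaithful to real cohorts (where roughly a fifth of patients are
postsurgically positive). Second, the ever-positive fraction (~60%) is
higher than in real surveillance (~34%), because positivity rides on a
continuous Gaussian level rather than discrete molecule counts.

What a green test on this generator does **not** establish: the generator
is the model's own inverse, so recovery and ordering results demonstrate
internal consistency and estimator correctness, not robustness to real
data. Real cohorts have assay positivity driven by discrete molecule
counts rather than a Gaussian level crossing zero; non-Gaussian, possibly
skewed measurement error; informative dropout; clonal hematopoiesis and
panel-coverage failures; and between-patient differences in tracked
mutation count. None of these are simulated.

## 4. Numerical choices in one place

* Spline basis: truncated-power natural form, columns scaled to O(1);
  evaluation, first/second derivative and running integral are closed
  form. Warning when evaluating further than half the knot span beyond a
  boundary.
* Quadrature: 9 GH nodes per dimension (fit), certified against 25;
  Gauss-Legendre 7 per baseline interval (fit) and 15 (simulator);
  log-hazard clamped at 100 before exponentiation so that excursions of
  the optimizer degrade gracefully instead of overflowing.
* Optimisation: L-BFGS-B with analytic gradients, staged release of the
  association parameters, up to 3 re-adaptation passes, and up to 2
  damped restarts when the optimum fails quadrature certification; a
  maxit exit at a point with max |gradient| < 0.1 is accepted with a
  warning.
* Cox partial likelihood: Newton-Raphson with step halving, Efron ties by
  default (Breslow available), score test at zero reported (it equals the
  log-rank statistic for a binary covariate without ties).
* Ties in the signed-rank test: average ranks, exact distribution by
  convolution over sign assignments (n <= 25), zeros dropped.
* Degenerate inputs: families of one read never emit consensus; empty
  tumor profiles mark samples unevaluable and exclude the patient;
  constant covariates are refused by `cox_fit` and silently dropped by
  the comparator predictors; H-L groups with undefined KM merge.

## 5. Known limitations

* The association-parameter boxes exclude |α₃| > 0.05/day; data truly
  generated with a stronger cumulative association would be clipped (and
  flagged), because the marginal likelihood there cannot be evaluated
  reliably by fixed-size quadrature for designs like this one.
* Wald intervals from the observed information can be optimistic when an
  estimate sits near a bound or the information matrix needs ridging —
  both conditions warn.
* The landmark/static comparators drop subjects with no sample before the
  landmark (status unavailable), so their risk sets can be slightly
  smaller than the joint model's.
* LOOCV Hosmer-Lemeshow with the joint model refits n times and is slow;
  it is practical with the Cox comparators and provided for completeness
  with the joint model.
* The pipeline writes text tables only; plotting is left to the user.
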