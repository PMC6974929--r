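---
title: "Population pharmacokinetics of artesunate and dihydroartemisinin in pregnancy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of artesunate and dihydroartemisinin in pregnancy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arsdhapk)
```

## The problem

Oral artesunate (ARS) is a first-line antimalarial that is hydrolyzed,
largely pre-systemically, into its active metabolite dihydroartemisinin
(DHA). Pregnancy alters the disposition of several antimalarials, and
under-exposure in pregnant patients risks treatment failure and resistance
selection. This package implements, as a reusable and tested workflow, a
simultaneous parent-metabolite population pharmacokinetic analysis of ARS
and DHA in pregnant and non-pregnant women with uncomplicated falciparum
malaria: structural modelling, censored-data maximum likelihood, covariate
analysis, bootstrap and visual-predictive-check diagnostics, and a paired
simulation quantifying the pregnancy effect on drug exposure.

The clinical dataset behind the original analysis is access-restricted, so
the package ships a synthetic-study generator that emulates the trial
design; every stage of the workflow runs end-to-end on that synthetic
cohort, and the parameter values of the published final model act as the
generating truth.

## Structural model

Absorption is a transit-compartment chain: the dose enters a depot and
passes through `nn = 3` hypothetical transit compartments, all with a
common rate constant

$$k_{TR} = \frac{nn + 1}{MTT},$$

which produces an Erlang-shaped absorption delay with mean transit time
$MTT$. ARS disposition is a single compartment with apparent clearance
$CL_{ARS}/F$ and volume $V_{ARS}/F$; elimination of ARS converts it
entirely into DHA (complete in-vivo conversion), which is itself a single
compartment with $CL_{DHA}/F$ and $V_{DHA}/F$ and first-order elimination.
All clearances and volumes are apparent (divided by the relative oral
bioavailability $F$, fixed to 1 for the typical subject). Amounts are in
mg, volumes in L, and predicted concentrations are converted to ng/mL
(×1000 from mg/L) before comparison with observations and quantification
limits, which keeps the printed clearances (L/h) and the LLOQs (ng/mL)
dimensionally consistent.

The system is linear with rate matrix lower-triangular in the state order
depot, transits, ARS, DHA, eliminated-mass sink. It is solved by the
matrix exponential of the rate matrix over each inter-event interval. The
transit chain gives the matrix a four-fold repeated eigenvalue $-k_{TR}$,
and near the frequent degeneracy $k_{TR} \approx CL_{ARS}/V_{ARS}$ an
eigendecomposition or partial-fraction solution is ill-conditioned; the
matrix exponential handles both without special-casing. Propagators for
interval lengths that are integer multiples of the smallest interval are
composed by binary powering of a single matrix exponential, which is exact
for this system and makes dense evaluation grids cheap. A sink row
accumulates eliminated mass so that mass balance
($\sum_i A_i(t) = F_1 \cdot \text{dose}$) is checkable directly; the test
suite enforces it to $10^{-9}$ relative and verifies the solver against an
independent adaptive ODE integration (deSolve::lsoda) to $10^{-6}$
relative over randomized parameter draws, including the forced degeneracy
$k_{TR} = k_{23}$.

No molecular-weight correction is applied in the ARS→DHA transfer: the
amount eliminated from the ARS compartment enters the DHA compartment
unchanged, so DHA clearances are interpreted in artesunate-mass
equivalents. This mirrors the published model code exactly.

## Individual parameters and covariates

Inter-individual variability is log-normal on ARS clearance, DHA
clearance, mean transit time and relative bioavailability
($\theta_i = \theta_{TV} e^{\eta_i}$, $\eta \sim N(0, \omega^2)$,
diagonal). Body weight enters allometrically on all clearances (power
0.75) and volumes (power 1), centered at the 52 kg cohort median. Other
covariates enter linearly and multiplicatively,
$1 + \theta_{cov}(x - x_{ref})$: pregnancy (0/1) on DHA clearance, and ALT
(centered at 20.75 IU) and log parasite count (centered at 5.88) on
relative bioavailability in the final model. The linear form can drive a
typical value negative under extreme covariates; the package treats that
as a domain error, and estimated covariate effects carry box bounds — the
published bounds for the ALT and biomass effects ((−0.024, 0.057) and
(−0.199, 0.334)), and data-driven bounds keeping the factor above 0.05
over the observed covariate range for other candidates in the stepwise
search, which codes no bounds for effects it never reports.

The final model's fixed effects are `final_model()`:
$CL_{ARS}/F = 3570$ L/h, $V_{ARS}/F = 1700$ L, $CL_{DHA}/F = 190$ L/h,
$V_{DHA}/F = 267$ L, $MTT = 0.832$ h, pregnancy effect $+21.4\%$ on
$CL_{DHA}/F$, ALT effect $+2.15\%$/IU and biomass effect $+13.8\%$/log
unit on $F$; IIV variances 0.0672, 0.00810, 0.320, 0.0887 and log-scale
residual variances 0.892 (ARS) and 0.660 (DHA).

## Likelihood: censored observations and the Laplacian approximation

Residual error is additive on the natural-log concentration scale
(equivalently exponential on the arithmetic scale), with separate
variances per analyte. Concentrations below the assay's lower limit of
quantification — 1.2 ng/mL for ARS, 2.0 ng/mL for DHA, which censors a
large fraction of ARS samples — are handled by one of three conventions:

* **M1** discards censored records;
* **M3** keeps them as censored data contributing
  $\log\{\Phi[(\log LLOQ - \hat y)/\sigma] + 10^{-6}\}$, the probability
  of falling below the limit;
* **M5** imputes them at half the LLOQ.

The $10^{-6}$ floor inside the censored probability is retained verbatim
from the published model code (it bounds the log away from $-\infty$); a
flag disables it. M3 requires the Laplacian method and the package
enforces that pairing.

The marginal likelihood integrates the joint density over each subject's
random effects. The package maximizes the joint log-density over $\eta$
per subject (a damped Newton iteration with finite-difference derivatives,
warm-started across outer iterations) and applies the second-order Laplace
formula with the observed Hessian at the mode:

$$\mathrm{OFV} = \sum_i \left[ 2 g_i(\hat\eta_i) - d \log 2\pi +
\log |H_i| \right],$$

with $g_i$ the negative joint log-density and $d = 4$. A
first-order-conditional-style variant (`estimation = "foce"`) replaces the
observed Hessian with a Gauss-Newton curvature built from the
$\eta$-Jacobian of the predictions; because the residual model is additive
on the log scale (prediction-independent variance), the two differ only in
this Hessian treatment. The OFV includes the full Gaussian constants, so
it is a proper $-2\log$ marginal likelihood and the zero-IIV limit reduces
exactly to $-2$ times the data log-likelihood; `ofv_nonmem` additionally
reports the convention that drops the $\log 2\pi$ data constants, in which
the published objective values are expressed. Likelihood-ratio tests and
all model comparisons are unaffected by the choice.

The approximation is validated against 64-node adaptive Gauss-Hermite
quadrature (nodes by Golub-Welsch) on single-free-eta subjects, agreeing
within 0.01 OFV units. The toys use rich sampling (8 time points), where
the conditional posterior is close enough to Gaussian for the comparison
to isolate implementation error; with very sparse data and large
$\omega^2$ ($\geq 0.3$) the residual difference is the Laplace
approximation itself (about 0.02 OFV units in our probes), not a defect of
either side.

## Estimation

`fit()` minimizes the OFV over 14 parameters: 5 positive structural
fixed effects and all variances on the log scale, and the signed covariate
effects on the raw scale under their bounds, with relative bioavailability
fixed at 1. The outer optimizer is L-BFGS-B (box bounds, limited-memory
inverse-Hessian with 25 pairs, convergence factor $10^{10} \cdot
\epsilon_{mach} \approx 2\times10^{-6}$ relative — about $4\times10^{-3}$
OFV units at this problem's scale; tighten `factr` for sharper optima).
During optimization the per-subject Laplace Hessian uses forward
differences for speed; reported OFVs are always recomputed with central
differences. Inner optimizations warm-start from the previous outer
iteration's modes. A fit is `converged` when L-BFGS-B reports success and
every inner problem converged, and `successful` (the condition counted in
bootstrap summaries) when additionally no parameter sits on a bound and no
variance has collapsed.

Covariate selection follows stepwise forward inclusion at $p < 0.05$
($\Delta\mathrm{OFV} \ge 3.84$, 1 df) and backward elimination at
$p < 0.01$ ($\Delta\mathrm{OFV} \ge 6.63$), with ties broken by fewest
added parameters then lexicographic candidate name (the selection rule
needs a deterministic order; nothing in the source analysis constrains
it). The full covariate approach adds the pregnancy effect simultaneously
on $F$, both clearances and $MTT$ and bootstraps the model to display the
effect distributions against a ±20% clinical-relevance band.

## Diagnostics

* **CV%**: IIV variances are reported as
  $100\sqrt{e^{\omega^2} - 1}$. (The source table's footnote prints the
  formula without the square root, but only the square-root form
  reproduces every printed CV% value; the footnote appears to be a
  typographical slip, and the package uses the standard log-normal form.)
* **CWRES**: conditional weighted residuals from a first-order
  linearization about the conditional modes,
  $V^{-1/2}\left[y - f(\hat\eta) + J\hat\eta\right]$ with
  $V = J\Omega J' + \Sigma$. Censored records never enter residuals.
* **Shrinkage**: $\eta$-shrinkage $1 - SD(EBE)/\omega$ per dimension and
  $\epsilon$-shrinkage $1 - SD(IWRES)$ per analyte.
* **pcVPC**: prediction-corrected visual predictive check; observations
  and simulated replicates are scaled per bin by
  $\mathrm{median}(PRED_{bin})/PRED_{ij}$ on the arithmetic concentration
  scale (the scale on which such checks are displayed), percentiles
  (5/50/95) compared with 95% simulation bands. Bins are the nominal
  sampling times, natural for this fixed-time design. Percentiles are
  computed over quantifiable values only, in both the observed and the
  simulated data, and a separate panel compares the per-bin BLQ fraction
  (uncorrected values against the analyte LLOQ) with its simulated band.
* **Bootstrap**: subjects resampled with replacement within pregnancy
  strata, preserving stratum sizes; refits warm-start from the original
  estimates; summaries (mean, SD, RSE% = 100·SD/mean, nonparametric
  2.5/97.5 percentiles) use successful fits only and report the success
  count.

## The synthetic-study generator

`study_design()` encodes the trial: 24 pregnant and 24 non-pregnant
subjects, a single oral dose at time zero of 1.5/2/2.5 × 100 mg artesunate
for <50 / 50-60 / >60 kg, and sampling at 0.25, 0.5, 1, 2, 3, 4, 5, 6, 8,
10, 12 h. (The trial dosed daily for three days but sampled only the first
dose; multiple doses are supported by the solver but unused here.)
Covariate distributions are truncated normals (weight, haemoglobin) and
truncated log-normals (parasite density, AST, ALT, bilirubin)
parameterized so that group medians sit at the reported cohort medians and
the truncation limits equal the reported ranges; spread parameters were
chosen once so that the in-range spread is plausible for cohorts of 24
(e.g. log-SD 1.2 for the pregnant parasite densities, whose reported range
spans three orders of magnitude). Gestational age is uniform over 4-8
months in the pregnant group and 0 otherwise. The published demographics
report only medians and ranges, so the distribution families are a
modelling choice of this package.

Simulation draws $\eta \sim N(0, \Omega)$, solves the profile, adds
log-scale residual noise, then censors observed values below the analyte
LLOQ — censoring after noise, as in the assay. Censored rows keep their
flag but have their `dv` masked (the latent values are retained in an
attribute for verification only). A pre-dose screening sample per analyte
is emitted with `mdv = 1`; the source analysis does not state how pre-dose
samples were handled, and this package excludes them from the likelihood
and from BLQ denominators. Under the final model this design yields about
58% ARS and 21% DHA samples below the LLOQ (the clinical data showed 62%
and 21%); whether the clinical figure includes pre-dose samples in its
denominator is unknown — including them would raise the ARS figure to
about 61% — and real assay/data features (repeated doses on later days,
sample handling) are not emulated.

What passing tests on this synthetic cohort do show: the estimator
recovers the generating parameters at the trial's size and censoring
level, the censored likelihood beats half-LLOQ imputation, and the
diagnostics are calibrated against their own generating model. What they
cannot show: anything about model misspecification on the real clinical
data, which only the restricted dataset could.

In the paired exposure simulation, each pregnant subject has a
non-pregnant twin with identical weight, covariates *and* random effects,
isolating the covariate effect; the source describes the groups as
identical except pregnancy without specifying the random-effect handling,
and sharing $\eta$ makes the DHA exposure ratio analytically
$1/(1+\theta_{preg})$ — a sharp correctness check — while an
independent-draws variant would only converge to it.

## Numerical choices and conventions

* Inner Newton: gradient by central differences (step $10^{-5}$),
  Hessian step $10^{-3}$, gradient tolerance $10^{-7}$, Levenberg damping
  with step halving; non-positive-definite curvature at the mode is
  ridged and flagged, and a subject whose inner problem stalls marks the
  OFV invalid rather than failing silently.
* $C_{max}$/$T_{max}$: profile evaluated on a 0.01 h grid over 0-12 h,
  then refined by golden-section maximization in the bracketing interval.
* AUC uses the closed form $F_1 \cdot \mathrm{dose}/CL$ for both analytes
  (exact for a linear system with complete conversion); the test suite
  checks it against trapezoidal integration of the solved profile.
* Dataset files: comma-separated with `#` comments and `.` for missing,
  in the 16-column layout `ID TIME DV WT EVID MDV AMT CMT BQL PREG LNPC
  HB AST ALT BIL EGA`; `DV` holds natural-log concentrations (a dialect
  flag logs raw-scale files on read). Numbers are written with 17
  significant digits so write-then-read is bit-exact.
* Every stochastic operation takes an explicit seed; there is no hidden
  global state.

## Problem sizes in the test suite

The simulate-and-refit experiments run at the trial design (48 subjects)
with 10 replicates, shared between the recovery check and the M3-vs-M5
comparison (whose M5 refits reuse the same simulated datasets). The
stepwise-search and bootstrap unit tests run on reduced cohorts (16-24
subjects) and small replicate counts — they exercise the machinery and its
decision rules, not Monte-Carlo precision — and the VPC calibration check
uses 200 simulated replicates. The analysis drivers under `analysis/`
default to 50 bootstrap replicates and 500 VPC simulations and accept
larger counts as arguments; the published analysis used 1,000 bootstrap
replicates, 500 for the full covariate model, and 2,000 VPC simulations.

## Known limitations

* The Laplace approximation (like any) carries $O(n^{-1})$ error relative
  to the exact marginal likelihood; with heavily censored, sparse subject
  data its absolute OFV can differ from quadrature by more than the 0.01
  seen on rich toys, though model comparisons subtract most of it.
* Off-diagonal $\Omega$ is not supported (the final model fixes it to
  zero), and only diagonal additive log-scale residual models are
  implemented.
* The rejected two-compartment DHA disposition exists only through the
  general solver for comparison purposes, not as a packaged model; no
  saturable elimination or enterohepatic recirculation.
* Standard errors come from the bootstrap; no asymptotic covariance
  matrix of the estimates is computed.
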