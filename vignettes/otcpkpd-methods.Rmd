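---
title: "Population PK/PD methods for oxytetracycline in cattle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK/PD methods for oxytetracycline in cattle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otcpkpd)
```

## The problem

Antimicrobial susceptibility testing classifies a bacterial isolate as
susceptible or resistant by comparing its MIC with a clinical breakpoint.
One of the pillars of breakpoint setting is the PK/PD cutoff: the highest
MIC at which a stated fraction of the treated population (conventionally
90%) attains the pharmacodynamic target of the drug class. For
tetracyclines the relevant index is fAUC/MIC — the area under the *free*
plasma concentration curve over the dosing interval divided by the MIC —
and the target used here is 24 h per 24 h interval, i.e. the average free
plasma concentration at steady state must at least equal the MIC.

`otcpkpd` implements that workflow for long-acting oxytetracycline in
cattle: a population pharmacokinetic model with age (calf vs adult) as a
covariate, Monte-Carlo simulation of exposure, PTA tables and cutoff
determination, a Laplace NLME estimator with BIC covariate selection and
bootstrap, a visual predictive check, and a synthetic multi-source study
generator so the whole pipeline is testable without any external data.

## Structural model

Disposition is a three-compartment mamillary model, parameterised by the
central and two peripheral volumes `V1, V2, V3` (mL/kg) and plasma plus
two distributional clearances `Cl, Cld2, Cld3` (mL/kg/h). All doses are
per kg body mass, so no body-weight allometry is needed; concentrations
are mg/L.

Intramuscular long-acting products show biphasic absorption: a rapid
first-order route (`Ka1`) starting at the dose time, and a slow route
(`Ka2`) starting after a lag `Tlag` (about 15 h at the typical values),
reflecting the depot behaviour of the formulation. Bioavailability is
parameterised on the logit scale: `F_total = ilogit(tvF1)` is the overall
fraction absorbed, and `F_rapid = ilogit(tvFrapid)` is **the fraction of
`F_total` that enters through the rapid route**. The rapid depot therefore
receives `F_total * F_rapid * dose` and the slow depot
`F_total * (1 - F_rapid) * dose`.

This nested reading of the two bioavailability parameters deserves a
note, because an alternative reading — two absolute bioavailabilities with
the slow route carrying `F_total - F_rapid` — is equally compatible with
the parameter table. We implemented both. The absolute parameterisation
has to clip the slow-route fraction at zero whenever a subject's realized
`F_total` falls below its realized `F_rapid`; with the packaged
between-subject covariances (the two F etas are strongly negatively
correlated) this happens for roughly a fifth of simulated subjects. The
clip makes the amount absorbed exceed `F_total`, breaks the closed-form
exposure identity `AUC = F_total * dose / Cl` that the Monte-Carlo layer
relies on, and introduces kinks into the subject-level likelihood. The
nested parameterisation has none of these pathologies, keeps the total
absorbed amount exactly `F_total * dose` for every subject, and is the
reading under which the published attainment tables reproduce. It is the
package's structural definition throughout.

### Solution of the kinetics

The model is a 5-state linear system (two depots, central, two
peripherals). `solve_profile()` offers two equivalent engines:

* `method = "matexp"` steps the full state vector between dose events
  with matrix exponentials — transparent and uniform for any schedule,
  including infusions (handled with an augmented constant-input state);
* `method = "closed"` expands the disposition matrix in its eigenbasis.
  A mamillary rate matrix is similar to a symmetric matrix under the
  `diag(1/sqrt(V))` transform, so the eigenvalues are real and the bolus
  response from the central compartment is a three-exponential with
  weights `Q[1,j]^2`; depot and infusion inputs are analytic convolutions
  of that response. This is the fast path used by the simulation and
  estimation layers.

Both engines are cross-checked against each other and against an
independent stiff ODE integration (deSolve) to 1e-6 relative accuracy in
the test suite. `pk_auc()` provides the exact AUC (infinite horizon:
absorbed amount / `Cl`; finite horizon: an augmented-state matrix
exponential) and an independent log-trapezoid numeric estimate.

## Population model

Between-subject variability is lognormal
(`P_i = P_typ * exp(eta_P)`) for all positive parameters and
logit-additive for the two bioavailability parameters. The eleven etas
carry two *full* covariance blocks: a 5x5 absorption block
(`nKa1, nKa2, nF1, nTlag, nFrapid`) and a 6x6 disposition block
(`nV1, nV2, nV3, nCl, nCl2, nCl3`), mutually independent. Sampling is by
per-block Cholesky factorisation with an eigen-decomposition fallback for
semi-definite blocks (eigenvalues above -1e-8 are clipped to zero;
anything lower is an error).

Age enters as a categorical covariate on the six disposition parameters:
`P_typ = tvP * exp(d_P)` for calves, `tvP` for adults. At the packaged
values calf clearance is about 1.73 times the adult value, which is what
drives the one-dilution difference between the calf and adult cutoffs.

Residual error is combined proportional (18.2% CV) and additive
(0.0069 mg/L) on the concentration scale. Simulated observations are
floored at zero on export only — never inside a likelihood.

## Monte-Carlo PTA and cutoffs

For linear kinetics the steady-state AUC over a dosing interval equals
the single-dose AUC to infinity, so per-interval free exposure has the
closed form `fAUC = fu * F_total * dose / Cl` with `fu = 0.5` (50%
protein binding). Only the `nF1` and `nCl` etas survive in this
expression — absorption rates and the rapid fraction reshape the profile
but cancel from its integral. A per-replicate numeric oracle
(log-trapezoid over 0–1000 h plus the standard `Clast/lambda_z` tail
extrapolation) is retained as `method = "integrate"`.

PTA at a given MIC is the percentage of 5,000 simulated subjects whose
average free concentration over the interval (`fAUC/tau`) is `>=` the
MIC. The continuous cutoff is the 10th percentile (type-7 linear
interpolation — the quantile convention is ours; the source analysis does
not state one) of that average concentration: the highest MIC attained by
exactly 90% of subjects. Because one exposure draw serves all intervals,
`cutoff(tau) * tau` is constant across intervals to machine precision.

Two dilution-grid conventions are reported side by side, because they can
legitimately disagree by one dilution:

* `dilution_cutoff`: the continuous cutoff rounded to the nearest series
  member on the log2 scale (ties round down), e.g. 1.87 to 2 and 1.09
  to 1;
* `strict_cutoff`: the highest series MIC whose tabulated PTA is >= 90%.

For the adult 48-h regimen the continuous cutoff (~1.87 mg/L) rounds to
2 mg/L while the PTA at exactly 2 mg/L is below 90% — the two conventions
answer slightly different questions and neither is silently preferred.

## Estimation

`fit_popmodel()` maximises a Laplace approximation of the marginal
likelihood. Per subject, the joint negative log-density of data and etas
is minimised over the etas by a Levenberg–Marquardt Gauss–Newton
iteration whose curvature is the Fisher (expected) information of the
combined error model — the same matrix supplies the Laplace
log-determinant correction, making the objective a FOCE-class
approximation; it is positive definite by construction. The inner
Jacobian is finite-difference on the concentration function. Against an
exact 1-D numeric integration of the marginal likelihood the
approximation agrees to ~0.04 on the -2LL scale on a rich single-subject
design.

The outer problem is solved by a quasi-Newton optimizer on transformed
scales (log for positive parameters, identity for logits and covariate
exponents, log-Cholesky for omega — guaranteeing positive
semi-definiteness, log for the residual components), with an explicit
finite-difference gradient whose step (1e-5) is chosen to sit well above
the numerical noise floor of the inner optimisations. The optimizer runs
in warm-restart rounds: within a round the inner starting point is frozen
(zeros first, then the previous round's posterior modes), which keeps the
objective exactly deterministic and the gradients consistent.

BIC uses `n = number of observations` (the conventional NLME choice; the
source analysis does not state its convention) and `k = number of
estimated parameters`. A covariate addition is accepted only when it
improves BIC by at least 6.635, with differences above 6 flagged as
strong evidence. Below-LLOQ observations are discarded before fitting
with a logged count (the M1 convention). The bootstrap resamples subjects
with replacement stratified by age class, refits each replicate, and
summarises medians, CV% and 2.5/97.5 percentiles, with 30% (fixed
effects) and 50% (random effects) precision gates.

## Visual predictive check

`vpc()` simulates every subject's own design (doses, times, age) with
fresh etas and residual error, and compares observed 10/50/90% quantiles
with an 80% interval of the same quantiles across replicates, per time
bin. Binning is quantile-based (equal observation counts, default 10 bins
per stratum) on time after the most recent dose, so cross-over occasions
align; strata are route x age class. The source analysis does not state
its binning; these are this package's choices and are deterministic given
the data. Note that an exactly calibrated 80% band contains the observed
quantile with probability 0.8 per bin, so observed coverage fractions
scatter around 0.8 with binomial noise — the acceptance test compares
coverage against 0.8 minus two binomial standard errors for that reason.
`vpc_outside_fraction()` checks the companion property that roughly 20%
of observations fall outside the simulated 10–90% band.

## Synthetic study generator

`default_design()` encodes an eight-source meta-analysis population: 69
animals (28 calves / 41 adults, 24 dairy / 45 beef, 30 male / 39 female,
14 diseased), two sources with an intravenous arm (20 or 40 mg/kg)
followed by the 20 mg/kg long-acting intramuscular product, cross-over
wash-outs of 7, 10 or 33 days, rich schedules (11–27 samples per
administration, at least 2 in the first hour and 7 within 24 h),
per-source HPLC LLOQs between 0.02 and 0.15 mg/L plus one microbiological
assay at 0.5 mg/L, and one source sampled to 168 h. Totals come to ~1,700
observations with ~0.7% below the quantification limit, concentrated in
the longest-sampling source. The per-source schedules are this package's
own assumptions chosen to reproduce those aggregate properties, not a
copy of any real protocol. One eta vector is drawn per animal (no
inter-occasion variability), cross-over administrations superpose
kinetically, and sampling times beyond the first hour get a small (2%)
lognormal jitter so schedules are realistic rather than gridded. Sex,
breed and health status are carried through but have no kinetic effect,
matching the final model, which retains age only.

What the generator does *not* emulate: between-formulation differences in
the slow absorption rate, assay-specific error structures,
disease-related kinetic changes, inter-occasion variability, or drop-outs.
Passing tests on generated data therefore demonstrate the internal
consistency of the pipeline under the stated population model, not
robustness to those real-data features.

## Parameter-recovery conditions

The recovery experiment used in the tests runs at a reduced desk scale:
40 animals (20 calves, 20 adults), an IV+IM cross-over design with 14
samples per administration from 5 min to 240 h, diagonal omega restricted
to `nCl, nF1, nKa1`, the full combined residual, all six age exponents
and all eleven typical values estimated, starting values perturbed ~35%
from the truth. Three design facts matter and were chosen deliberately.
First, the sampling window must span the deep compartment's return phase
(terminal half-life ~120 h): truncating at 72 h leaves an
identifiability ridge along which a much larger `V3` trades off against
clearance, and estimates drift far along it at no likelihood cost — the
source studies' longest arm ran to 168 h for the same reason. Second,
samples inside the first 15 minutes are needed to pin the central volume
through the fast distribution phase (distribution half-life ~10 min).
Third, the restricted eta set places the between-subject variability on
the exposure-determining parameters (`Cl`, `F_total`, plus the rapid
absorption rate): a variability term on `V1` at its published magnitude
(83% CV) would make the typical `V1` — informed by only the 20 adults —
statistically unrecoverable to 10% at this sample size (the
maximum-likelihood error floor alone is ~11% median), regardless of
estimator quality. Ten independent datasets give median recovery of
`Cl`, `V1` and `F_total` within 10% (observed ~2-3%), the clearance age
exponent within 30% of its generating value, and BIC selection of the
age-covariate model in 10 of 10 seeds.

## Numerical choices and limitations

* Two-fold MIC series are validated strictly; cutoffs below the series
  floor return an `NA` sentinel with a warning.
* The semi-definiteness tolerance for omega blocks is -1e-8 on the
  smallest eigenvalue; the packaged blocks are comfortably positive
  definite.
* Quantiles everywhere are type 7; ties in dilution rounding go to the
  lower member.
* `pk_auc()` requires `t_end` beyond the last dose; the trapezoid path
  needs a finite horizon.
* The estimator is a Laplace/FOCE-class approximation, not an exact
  marginal likelihood: absolute -2LL values are approximation-specific
  and only differences on the same data are meaningful. Full 5+6 omega
  blocks are supported via log-Cholesky but diagonal structures are the
  practical desk-scale default.
* Monte-Carlo cutoffs at n = 5,000 carry ~1–2% sampling noise; repeated
  seeds vary the published-scale cutoffs by well under 2%.
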