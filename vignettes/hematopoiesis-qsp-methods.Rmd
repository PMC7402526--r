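---
title: "Deconvolving drug effects on hematopoietic lineages: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving drug effects on hematopoietic lineages: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemaQSP)
```

## The problem

A six-day CD34+ multi-lineage differentiation assay measures how a compound
changes the abundance of 13 hematopoietic cell types (plus total dead cells)
across a dose panel. The observed suppression of any readout is *cumulative*:
a drop in neutrophils may reflect a direct effect on neutrophils, or the
propagated loss of granulocyte progenitors, GMPs, MPPs, or stem cells
upstream. `hemaQSP` implements a quantitative systems pharmacology model that
deconvolves these cumulative dose-response curves into per-cell-type
mechanisms: an anti-proliferation component and a cell-killing component with
a single potency per cell type.

## The differentiation model

The model is a system of ordinary differential equations over 15 internal
species: the 13 cell types, a quiescent neutrophil pool, and the accumulated
dead-cell pool. The lineage tree is rooted at hematopoietic stem cells
(HSC → MPP), with MPPs branching into the granulocyte/monocyte (via GMP),
erythroid, megakaryocyte, and lymphoid lineages.

Division of a renewing type consumes one parent and produces two daughters,
each of which independently renews (probability $\rho_C$) or differentiates
($1 - \rho_C$). This bookkeeping gives, for proliferation rate $\kappa_C$
and concentration $[C]$,

$$\frac{d[C]}{dt}\Big|_{\text{self}} = (2\rho_C - 1)\,\kappa_C [C],
\qquad \text{outflow} = 2(1 - \rho_C)\,\kappa_C [C],$$

the factor of two reflecting that one division yields two cells. Outflow from
a branch point is split by branching fractions $\beta$ that sum to one per
branch point. The reference configuration has 27 free system parameters:
13 $\kappa$, 7 $\rho$ (HSC, MPP, GMP, GranP, Gran, MonoP, ErythI), 6 $\beta$
(four MPP edges, two GMP edges), and one uniform terminal death rate
$\delta$. The breakdown is a package commitment: the free-parameter total is
fixed, and this enumeration reproduces it with the quiescent-pool transfer
rate held constant.

Three structural choices deserve comment:

* **Lymphoid progenitors** decline without measurable proliferation in this
  culture system, so LymP carries no renewal fraction and converts to B
  cells as a first-order flux $\kappa_{\mathrm{LymP}}[\mathrm{LymP}]$ without
  the division factor of two. The doubling alternative can be obtained by
  assigning LymP a renewal parameter in a custom topology, but is not the
  default.
* **The quiescent neutrophil pool** absorbs active neutrophils at a fixed
  rate `k_quiescence` (default 0.5/day). It neither divides nor
  differentiates, but is killed by drug with the neutrophil parameters, and
  it is folded into the reported neutrophil readout. Fixing the transfer
  rate keeps the free-parameter count at 27; the default value was chosen
  once as a plausible mid-range turnover and is configurable.
* **Terminal types** (ErythII, MK, Mono, Neut, B) proliferate at net rate
  $\kappa_C$ and die at the shared rate $\delta$ into the dead pool; no
  other type dies in the absence of drug.

## Drug effects

Drug effects use a total-Emax formulation with one pair
$(E_{\max,T,C}, \mathrm{EC50}_C)$ per cell type — 26 free parameters per
compound. The underlying assumption is that increasing concentrations first
block proliferation and only then kill: the anti-proliferation component is
$E_{\max,AP} = \min(1, E_{\max,T})$ and the cell-killing component is
$E_{\max,CK} = \max(0, E_{\max,T} - 1)$.

Anti-proliferation attenuates the basal division rate,

$$\kappa_C = \kappa_{C,0}\left(1 - \min(1, E_{\max,T,C})
\frac{[\mathrm{drug}]}{\mathrm{EC50}_C + [\mathrm{drug}]}\right),$$

and cell killing removes cells into the dead pool at

$$E_{\max,CK,C}\,\frac{[\mathrm{drug}]}{[\mathrm{drug}] +
\mathrm{EC50}_C}\,[C].$$

EC50s are stored and optimized as natural logarithms; the bounds
$\log \mathrm{EC50} \in [-2.3, 8.5]$ bracket roughly 0.1 nM to 5 µM around
the assay's 0.2–2500 nM panel. The published bound on $E_{\max,T}$ is
$[0, 2]$, yet reference fits report totals up to 2.762, which would be
infeasible under that bound; the package therefore defaults
`emax_upper_bound` to 3.0, keeps it configurable, and makes no attempt to
silently reconcile the discrepancy.

## Integration

With drug concentration held constant over the in vitro exposure, every
flux is linear in the state, so the full system is a linear time-invariant
ODE $\dot x = A x$. The default integrator exploits this: it propagates the
state exactly with per-interval matrix exponentials of the 15×15 rate
matrix (eigendecomposition with a scaling-and-squaring fallback). This is
both exact and fast, which matters because calibration evaluates the model
tens of thousands of times. A conventional stiff-capable integrator
(`deSolve::lsoda`, relative tolerance $10^{-8}$, with clipping of numerical
undershoot below zero) is retained as `method = "lsoda"`; the test suite
checks the two agree. States are non-negative analytically because all
fluxes are linear in their source compartment.

## Calibration to drug-free kinetics

The 27 system parameters plus 14 initial conditions are fitted to the
donor-mean kinetic table. Days 0 and 9 are excluded from the objective
(post-thaw recovery distorts the first interval; day 9 followed a
replating), so residuals run over days 2–6. The loss is a sum of squared
residuals with each readout scaled by its mean observed level — without
scaling, the most numerous lineage (neutrophils) would dominate; `raw` and
log-count variants are available. Initial conditions are bounded to 0.1–1
times the measured day-0 counts; the quiescent pool starts at zero and is
not fitted.

The optimizer is a hybrid of a bounded population search and local
refinement: a genetic algorithm (Latin-hypercube initialization, tournament
selection, blend crossover, Gaussian mutation, elitism) followed by
Levenberg–Marquardt refinement of the elite candidates on the residual
vector, plus basin-hopping restarts (perturb the incumbent at several
relative scales and re-refine). Reference budgets are 50 generations × 500
population for system calibration and 30 × 300 for drug calibration.
Branching fractions are optimized on the constrained simplex by projecting
each candidate's branch shares onto "sums to one with each share ≥ 0.001".
Every fit records its seed, bounds, optimizer trace, and evaluation count,
and is reproducible from (settings, seed).

### Identifiability

Two diagnostics are provided. `profile_likelihood()` fixes one parameter on
a grid and re-optimizes the rest; a profile whose relative range stays
below a configurable flatness threshold is flagged practically
non-identifiable. No formal confidence cutoff is published for this assay,
so the default threshold (5% relative) is a package-chosen stand-in and is
labeled as such in output. `assess_identifiability()` is the cheap
linearized version: it computes the scaled-residual Jacobian in a relative
parameterization and derives each parameter's asymptotic relative standard
error from the pseudo-inverse Fisher information under nominal 5% residual
noise; parameters above 20% relative SE are flagged. The linearized
diagnostic also defines, a priori, which parameters a recovery experiment
can be expected to pin down.

## Drug-effect estimation

For a compound, the observed table is the vehicle-normalized day-6 readout
matrix over the dose panel (each treated value divided by the vehicle
value, mirroring the assay's well-to-vehicle-mean normalization). The
objective is

$$\sum_C \left\| w_C \left( M_C^{\text{model}} - M_C^{\text{data}} \right)
\right\|^2 + \lambda \sum_C \left| E_{\max,T,C} \right|,$$

with $\lambda = 0.1$ and $w_C = 1$ except $w_{\text{totalDeadCells}} = 2$:
up-weighting the dead-cell readout is what makes cell killing separable
from anti-proliferation, and the L1 penalty drives near-zero effects to
exactly zero so each compound is explained by a parsimonious mechanism set.
Because $E_{\max,T} \ge 0$, the penalty is linear on the feasible box and
the whole objective stays smooth, so Levenberg–Marquardt refinement applies
after augmenting the residual vector with $\sqrt{\lambda E_{\max,T,C}}$
terms. The all-zero mechanism and a crude per-readout guess (suppression
depth at the top dose, crossing dose for the potency) are seeded into the
initial population, which guarantees the fitted objective never exceeds the
inert-drug objective and speeds convergence.

## Classical curve-level analysis

For comparison with the deconvolved mechanisms, `fit_ic50()` fits each
readout's cumulative curve with the one-parameter law
$\text{value} = 1 - c/(c + \mathrm{IC50})$ (Hill slope 1, asymptotes 0 and
1), and `percent_inhibition()` maps IC50s to percent-suppression matrices.
A readout that never falls below 0.5 of baseline within the tested range is
reported undetermined — the observed behavior of the megakaryocyte and
B-cell readouts — and shown as 0% suppression; curves rising above baseline
additionally trigger a monotonicity warning. No four-parameter logistic
variant is offered: the one-parameter form is the committed analysis.

## Cohort comparison

`assemble_parameter_matrix()` builds compounds × cell-types matrices of
total Emax, logEC50, or logIC50 (undetermined IC50s require an explicit
per-run policy: error, omit the compound, or impute a stated value), and
`run_pca()` performs column-mean-centered, unscaled PCA via singular value
decomposition — the parameter values share a scale, so no standardization
is applied by default (a standardized variant sits behind a flag). Signs
are fixed so each loading vector's largest-magnitude entry is positive, and
loadings are annotated with variable-score correlations (the convention for
labeling variables correlated above 0.1 with the top components).

## Synthetic data

The package generates both input kinds so the full pipeline is testable
without assay data. Kinetics: the model trajectory at days 0, 2–6 for six
virtual donors, each readout/day/donor perturbed by multiplicative
lognormal noise with mean 1 and CV 0.2. Dose-response: treated and vehicle
wells per donor (six virtual vehicle wells), per-donor normalization to the
vehicle-well mean, then pooling by averaging across donors (2–7 per
compound in the assay; 4 by default here). The lognormal noise law and its
CV are explicit surrogates — the assay publishes SEM bars, not a noise
model — and donor-level biological variation (true parameter heterogeneity
rather than measurement noise) is *not* emulated. Passing recovery tests on
these data therefore demonstrates correctness of the estimation machinery
under the stated noise model, not robustness to real donor biology.

Because the assay's fitted system parameters and day-0 counts are not
published in reusable form, the package ships a synthetic reference
parameter set and initial state (`default_system_parameters()`,
`default_initial_state()`), chosen once to give realistic six-day
multi-lineage expansion: growing stem/progenitor compartments, committed
compartments fed by differentiation, terminal turnover into the dead pool,
and a post-thaw dead-cell baseline. They are documented as synthetic
stand-ins, not fits.

## Numerical choices and problem sizes

* Matrix-exponential propagation is exact; the `lsoda` cross-check runs at
  relative tolerance $10^{-8}$, and halving tolerances moves day-6 readouts
  by less than $10^{-4}$ relative.
* Vehicle normalization defines 0/0 as 1: a compartment empty in the
  vehicle stays empty under treatment, and reporting "no change" keeps toy
  models and sparse seedings well-defined.
* Recovery demonstrations in the tests and the acceptance script use
  reduced optimizer budgets chosen as the package's standard small-problem
  settings: 10 generations × 100 population with local polish for drug
  fits, 12 × 120 with 30 basin hops for system fits. At these budgets,
  noiseless self-generated data are recovered to machine precision (system)
  and to a few hundredths in $E_{\max,T}$ (drug).
* Ties and degenerate inputs: zero-variance matrices yield a warning and
  zero components in PCA; fits of empty compartments are excluded by the
  0/0 convention; equal-bound box constraints implement profile fixing.

## Known limitations

* No cytokine feedback (G-CSF, EPO, TPO), no pharmacokinetics, no in vivo
  compartments: the model describes the in vitro assay only.
* One Emax/EC50 pair per cell type by design; systems where killing and
  anti-proliferation have distinct potencies need the rejected
  52-parameter alternative, which is out of scope.
* The kinetic model cannot explain an initial influx of dead cells from
  thawing; it is absorbed into the fitted initial dead-cell count.
* The noise model and reference parameter set are synthetic surrogates, as
  discussed above.
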