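---
title: "Methods: a mechanistic PBPK model of intravenous vincristine and its P-gp/CYP3A interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vincristine PBPK and DDI simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vincpbpk)
```

## Scope and model overview

`vincpbpk` simulates the whole-body disposition of intravenously infused
vincristine in virtual oncology subjects and the change in its plasma and
muscle exposure when P-gp/CYP3A inhibitors (ibrutinib, acalabrutinib,
itraconazole) are co-dosed orally at steady state.  The clinical question
behind the muscle read-out is vincristine-induced peripheral neuropathy
(VIPN): vincristine is a P-gp substrate, and inhibition of P-gp efflux in
muscle tissue is one hypothesis for the higher neuropathy rates seen when
vincristine-containing chemotherapy is combined with some BTK inhibitors.

The model is a conventional whole-body PBPK structure:

* perfusion-limited organs (adipose, bone, brain, gut, heart, skin,
  spleen, pancreas, muscle, rest-of-body, lung) with tissue-to-plasma
  partition coefficients,
* three-zone permeability-limited liver, kidney and muscle (vascular /
  extracellular water / intracellular water), with passive exchange driven
  by unbound concentrations (`fu_EW`, `fu_IW`),
* saturable CYP3A4 + CYP3A5 metabolism in the liver intracellular zone,
  with the CYP3A5 branch chosen by the subject's genotype,
* saturable P-gp efflux from the intracellular zone to bile (liver),
  urine (kidney) or extracellular water (muscle), scaled by RAF/REF 1.5,
* a first-order unassigned systemic clearance from venous blood
  (vincristine's mass balance in humans is incomplete; part of its
  elimination proceeds by routes that have never been assigned),
* dynamic competitive inhibition: each perpetrator scales the victim's
  P-gp (and, for itraconazole, CYP3A) Km at each site by
  `1 + Iu(t)/Ki`, with `Iu(t)` the unbound perpetrator concentration at
  that site.

The permeability-limited muscle organ *duplicates* the retained perfusion
muscle compartment rather than replacing it.  This mirrors the generic-organ
construction of the source analysis and is deliberately non-parsimonious:
muscle volume is counted twice.  Muscle exposure is always read from the
permeability-limited organ.  To preserve flow conservation (venous returns
sum to cardiac output) the muscle blood flow is split evenly between the two
muscle compartments.

## Tissue partitioning and Vss calibration

Partition coefficients come from the Rodgers & Rowland mechanistic
equations for a monoprotic acid (pKa 5.15, LogP 2.67, B/P 1.2, fu 0.51),
using a shipped standard tissue-composition table.  Vincristine is treated
as the declared monoprotic acid even though vinca alkaloids are often
modeled as bases; the compound file exposes `compound_class` if a user
wants the base parameterization.  A single global scalar on all tissue Kp
values is then solved in closed form so that

`Vss = Vplasma + Verythrocyte * E:P + sum(Vt * Kp * scalar)`

equals the observed 1.64 L/kg.  `calibrate_kp_scalar()` reproduces the
target to machine precision; the scalar itself is not an observable and is
reported for inspection only.

## Organ-level calibration constants

The source analysis was built in a commercial simulator whose organ-level
scalars (cell numbers per organ, activity scalings, intracellular binding)
are internal and unpublished.  The bundled vincristine file therefore
carries a set of calibration constants, fixed *once* against the reference
outputs and never revisited:

| constant | value | role |
|---|---|---|
| CYP3A abundance scalar | 1.9055 | overall hepatic CYP3A activity (ISEF-like) |
| liver P-gp scalar | 0.2672 | biliary efflux capacity |
| liver `ps_scalar` | 4053.5 | whole-liver membrane permeability (non-limiting) |
| liver `iw_binding` | 246.57 | intracellular sequestration (tubulin-class binding) |
| liver `vasc_ps_per_flow` | 51.81 | vascular-extracellular exchange (non-limiting) |
| `additional_systemic_cl` | 11.185 L/h | unassigned first-order clearance |
| kidney cells scalar | 1.1826e6 (million) | renal P-gp secretion = 3.3 L/h |
| muscle cells scalar | 2.2e6 (million) | muscle exchange timescale |
| muscle P-gp scalar | 0.023403 | muscle efflux tone (sets muscle:plasma exposure) |

The calibration targets were the published simulation outputs themselves:
pooled AUC ~52 ng·h/mL and CL ~666 mL/min, fraction metabolized ~32% with
a ~37% P-gp share of elimination, renal clearance 3.3 L/h derived from
transporter kinetics, terminal half-lives of ~79 h (poor CYP3A5
metabolizers) and ~18 h (extensive), and a baseline muscle AUC(0-24 h) of
~36 ng·h/mL.

Two of these constants deserve comment.  First, the printed passive
diffusion clearance (0.37 uL/min/million hepatocytes) would cap whole-liver
permeability at a few L/h, which cannot carry the hepatic share of a
~35 L/h total clearance; the large `ps_scalar` makes hepatic membrane
transport non-limiting, standing in for sinusoidal uptake processes the
declared parameter set does not describe.  Second, the liver
`iw_binding` factor creates a deeply bound hepatic intracellular pool.
This pool is what produces the long terminal phase: the apparent terminal
volume is several thousand litres, the tail is fed by slow release from
liver cells, and the tail slope is genotype-dependent because intracellular
vincristine is removed by CYP3A (fast in extensive metabolizers, slow in
poor metabolizers).  Deep intracellular binding is consistent with
vincristine's pharmacology (high-affinity tubulin binding; tissue:plasma
ratios of two orders of magnitude), and it reconciles a ~79 h terminal
half-life with a steady-state volume of only 1.64 L/kg - the two are
otherwise incompatible, since `Vz = CL * t1/2 / ln 2` is ~60 L/kg.

## Genotype branch

The enzyme-kinetics table carries both CYP3A5 branches (extensive
416/18.5; poor 114/89.8 pmol/min/mg over uM) plus CYP3A4 (0.90/19.5); a
subject's `cyp3a5_genotype` selects the branch.  The printed per-genotype
kinetics already encode the expression difference between expressors and
non-expressors (an intrinsic-clearance ratio of ~18), so no additional
expression multiplier is applied by default; `model_options()` exposes
`cyp3a5_expression_ratio` for users who want to impose a different ratio
(for example the flat fivefold assumption sometimes quoted for high vs low
CYP3A expression).  Using the printed branch kinetics directly is what
reproduces both the fraction metabolized and the observed half-life
separation; a stacked fivefold multiplier cannot do both.

## Renal model

Renal elimination is P-gp tubular secretion from the kidney intracellular
zone.  Glomerular filtration is off by default: fu x GFR alone (~3.7 L/h)
would exceed the transporter-derived renal clearance of 3.3 L/h, so the
filtered load is assumed to be reabsorbed; `model_options(renal_filtration
= TRUE)` adds fu x GFR if desired.  `derive_renal_clearance()` recomputes
renal clearance as cumulative urinary flux divided by plasma AUC from a
linear-regime run; the kidney cell scalar was solved so this equals
3.3 L/h, which is within 1.3-fold of the observed 4.18 L/h.

## Perpetrators

Perpetrators use simplified one-compartment oral disposition
(`cl_f`, `v_f`, `ka` from published clinical pharmacokinetics) with a
closed-form steady-state superposition profile - they are unaffected by
the victim, so no ODEs are co-integrated.  Inhibition is competitive,
with Ki = IC50 by default (probe concentrations at or below Km in the
underlying assays); the convention is switchable per inhibition entry.
When a perpetrator carries several IC50s for the same target (cell-based
and vesicle assays), the most potent is used, matching the convention of
dividing "the lowest of the original input values" in the sensitivity
analysis.

Site concentrations are unbound plasma times a site-enrichment factor.
For ibrutinib the liver factor (150) is a mechanistic hepatic-inlet
estimate (first-pass portal exposure plus intracellular accumulation); the
muscle factor (72.96) is a calibration constant fixed once so that the
30-fold-IC50 sensitivity run reproduces the reported muscle exposure
contrast (47 vs 36 ng·h/mL).  This mirrors the source methodology, where
the generic muscle organ was itself calibrated to "mimic the inhibiting
effect"; the muscle simulations are hypothesis-generating, not
mechanistic predictions.  The kidney site uses unbound plasma (no
proximal-tubule model).  Itraconazole ships with placeholder published
constants (its original supplemental parameter set, including the
hydroxy-itraconazole contribution, is not reproduced here) and is used
only for qualitative pathway attribution via `ddi_pathway_attribution()`.

## A structural limitation: plasma AUC(0-24) under inhibition

One reported output cannot be reproduced jointly with the others: the
simulated plasma AUC(0-24 h) ratio of 1.18 (with ibrutinib at steady
state).  With a deep distribution pool - forced by the 79 h half-life at
the printed AUC and clearance - the first 24 h of plasma exposure are
distribution-dominated, and even complete inhibition of biliary P-gp
changes AUC(0-24) by under 2%.  Conversely, a model whose 0-24 h exposure
is elimination-dominated cannot show a 79 h terminal slope at a
quantifiable level.  The reference values themselves are internally
inconsistent (Vd 8.05 L/kg with CL 666 mL/min implies a 9.8 h terminal
half-life, not 79 h), indicating that the original simulator realized
these read-outs from different internal quantities.  This package
prioritizes the half-life, elimination-split, renal and muscle outputs;
the plasma interaction ratio it produces (~1.0) is close to the *observed*
clinical ratio (0.89) but below the reported simulated one.  The
corresponding acceptance test is left failing by design and the behavior
is documented rather than patched.  The simulated Cmax ratio (1.08) is
equally unreachable for a 15-minute infusion, whose Cmax precedes any
elimination effect.

## Trial engine and NCA conventions

`run_scenario()` samples the virtual population (ages uniform 20-90, 47%
female, sex-conditional log-normal weights with medians 80/66 kg and 18%
CV, CYP3A5 non-expressor frequency 0.83, log-normal 30% CV multipliers on
CYP3A, P-gp and the unassigned clearance), simulates every subject with
and - for DDI scenarios - without the perpetrators, and pools
clinical-style NCA.  NCA uses linear-up/log-down trapezoids, a terminal
slope from the best-adjusted-r2 log-linear tail (at least three points
after Cmax), AUCinf = AUCt + Clast/lambda_z, CL = dose/AUCinf and
Vz = CL/lambda_z (the Vz convention is used and labeled as such).
Profiles are sampled on a rich oncology schedule (0.25-96 h) and censored
at an LLOQ of 0.05 ng/mL, a typical LC-MS/MS sensitivity for vincristine;
the half-life read-outs therefore reflect what a clinical NCA would see.
Muscle exposure is the dense 0-24 h AUC of total tissue concentration in
the permeability-limited muscle organ.

DDI summaries are paired (the same virtual subject with and without the
perpetrator) to isolate the interaction from inter-individual variability,
with geometric means and log-scale t-based 90% intervals.  The static
screen (`static_ddi_screen()`) uses current regulatory constants - gut
concentration dose/0.25 L with cut-off 10, unbound systemic Cmax with
cut-off 0.1 - all exposed as arguments.

## Numerical choices

The ODE system (30 states) is integrated with `deSolve::lsoda` at
rtol 1e-8 / atol 1e-10, with the infusion handled by exact segmentation at
the end-of-infusion time; mass balance holds to ~1e-12 relative at every
reported time and is checked on every run.  The reporting grid is 0.05 h.
Curve fits (IC50, Michaelis-Menten) use Levenberg-Marquardt least squares
(`minpack.lm::nls.lm`) with deterministic starts: top/bottom from the
response extremes, IC50 from the concentration bracketing the half
response, Hill = 1 with its sign chosen from the response direction.
Flat or non-bracketing designs are flagged unidentifiable rather than
fitted.  Negative ATP-minus-AMP transport is clipped to zero with a flag.

Problem sizes follow the declared trial design: 5 trials x 5 subjects per
scenario run; elimination decompositions use a single 600 h run per
genotype (>99% of the dose eliminated) combined with the 0.83/0.17
genotype weights, which is the deterministic expectation of the population
decomposition.

## What the synthetic data do and do not show

`generate_observed()` adds multiplicative log-normal residual error
(default CV 20%) to model-predicted concentrations and censors below an
LLOQ (default 0.1 ng/mL); `generate_assay_plate()` generates triplicate
in vitro plates from the same curve equations the fitters use.  Passing
the recovery tests demonstrates that the estimation chain is unbiased and
self-consistent under the assumed error model; it does not validate the
model against real patients, whose residual errors are neither log-normal
nor independent, and whose observed concentrations (shown only as figure
points in the source) are not redistributed here.

## Known limitations

* The muscle duplication double-counts muscle volume (accepted by design);
  absolute muscle concentrations are hypothesis-generating only.
* No mechanistic gut absorption, enterohepatic recirculation,
  time-dependent inhibition or induction; perpetrator models are
  one-compartment simplifications.
* The plasma DDI ratio limitation described above.
* Perpetrator input values for itraconazole (and the venetoclax/digoxin
  templates) are placeholders pending a published parameter set.
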