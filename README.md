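# vincpbpk

Whole-body physiologically based pharmacokinetic (PBPK) simulation of
intravenously infused vincristine, built to study its drug–drug
interactions (DDI) with orally dosed P-gp/CYP3A inhibitors — ibrutinib,
acalabrutinib, itraconazole — in plasma and in muscle tissue.

Vincristine (2 mg IV over 15 min, part of R-CHOP chemotherapy) is a
P-glycoprotein (P-gp, ABCB1) substrate metabolized predominantly by the
polymorphic CYP3A5. Its dose-limiting toxicity is peripheral neuropathy
(VIPN), and the incidence of VIPN rises when some BTK inhibitors are added
to R-CHOP. The package exists to ask, by simulation: does P-gp inhibition
by a co-dosed BTK inhibitor raise vincristine exposure — systemically, or
only inside muscle tissue — and how does CYP3A5 genotype (*3/*3
non-expressors vs expressors) shape the answer?

The model couples:

* perfusion-limited organs with Rodgers–Rowland tissue partitioning, the
  global Kp scalar solved so Vss = 1.64 L/kg;
* three-zone (vascular / extracellular / intracellular) liver, kidney and
  a *duplicated* permeability-limited muscle organ;
* Michaelis–Menten CYP3A4/CYP3A5 metabolism (genotype-branched: Vmax/Km
  416/18.5 for extensive, 114/89.8 for poor expressors, pmol/min/mg over
  µM) and saturable P-gp efflux (Jmax 77 pmol/min/10⁶ cells, Km 17.1 µM,
  RAF/REF 1.5) into bile, urine, or muscle extracellular water;
* dynamic competitive inhibition, `Km,app(t) = Km · (1 + Iu(t)/Ki)`, from
  closed-form steady-state perpetrator profiles;
* virtual oncology trials (5×5 subjects, ages 20–90, 47 % female, CYP3A5
  non-expressor frequency 0.83) with clinical-style NCA, paired
  geometric-mean DDI ratios, elimination-pathway decomposition, an
  EMA-style ÷30 IC50 sensitivity sweep and a static regulatory risk
  screen;
* in vitro analysis: efflux ratios, ATP-dependent vesicular transport,
  both IC50 parameterizations (linear and log-concentration 4PL) and
  Michaelis–Menten transport fits, plus a synthetic-data generator for
  assay plates and pseudo-observed concentration–time datasets.

See the methods vignette (`vignettes/vincristine-pbpk-methods.Rmd`) for
the model equations, calibration constants and their rationale, and known
limitations.

## Worked example

Simulate the worst-case subject — a CYP3A5 poor metabolizer given 2 mg
vincristine over 15 min — and summarize:

```r
library(vincpbpk)

vcr  <- load_compound(vincpbpk_file("compounds", "vincristine.yaml"))
subj <- reference_subject("non_expressor_star3_star3")
part <- calibrate_kp_scalar(predict_kp(vcr, subj$physiology),
                            vcr$vss_target, vcr, subj$physiology)
model <- pbpk_model(subj, vcr, partitions = part)

sim <- simulate_pbpk(model, horizon = 96)
sim
#> <pbpk_sim> vincristine, 2 mg, t 0-96 h (1921 points)
#>   Cmax plasma 36.88 ng/mL; eliminated 60.6% of dose; mass balance 5.5e-15

nca_from_sim(sim)
#> <nca>
#>   Cmax 36.88 ng/mL at 0.25 h; AUC0-t 38.39, AUC0-inf 59.95 ng.h/mL
#>   t1/2 81.28 h (lambda_z 0.008528 /h, 4 points, adj r2 1.0000); CL 556 mL/min; Vz 55.89

elimination_decomposition(simulate_pbpk(model, horizon = 600, dt = 0.25))
#> <elimination_decomposition>
#>   fm (CYP3A)            20.3%
#>   fe (total excretion)  79.7%
#>     P-gp (bile+urine)   43.1%
#>     renal filtration     0.0%
#>     unassigned route    36.5%
#>   (99.4% of dose eliminated)
```

Reading the output: the poor metabolizer clears vincristine slowly
(AUC0–∞ ≈ 60 ng·h/mL, terminal half-life ≈ 81 h — the long tail comes from
slow release of deeply bound hepatic drug, removed faster in CYP3A5
expressors, whose half-life is ≈ 17 h). For this genotype only ~20 % of
elimination is CYP3A metabolism; averaged over the 0.83/0.17 genotype mix
the model gives fm ≈ 29 %, a P-gp excretion share ≈ 38 % and renal
clearance 3.3 L/h. Population scenarios are one call each:

```r
run_scenario(named_scenario("baseline_population"), seed = 1)   # AUC/CL table
run_scenario(named_scenario("sensitivity_30x"), seed = 1)       # muscle DDI, IC50/30
sensitivity_sweep(named_scenario("ddi_ibrutinib_muscle"), c(1, 30))
static_ddi_screen(load_compound(vincpbpk_file("compounds", "ibrutinib.yaml")))
```

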