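Package: vincpbpk
Title: Whole-Body PBPK Simulation of Intravenous Vincristine and
    P-gp/CYP3A Drug-Drug Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic whole-body physiologically based pharmacokinetic
    (PBPK) simulation of intravenously dosed vincristine, including
    polymorphic CYP3A5 metabolism, saturable P-glycoprotein (P-gp) efflux in
    liver, kidney and a duplicated permeability-limited muscle organ, and
    dynamic competitive inhibition by orally dosed perpetrators (ibrutinib,
    acalabrutinib, itraconazole).  Provides Rodgers-Rowland tissue
    partitioning with Vss calibration, virtual oncology population sampling
    with CYP3A5 genotype, in vitro transport assay analysis (efflux ratios,
    ATP-dependent vesicular transport, IC50 and Michaelis-Menten fitting),
    non-compartmental analysis, drug-drug interaction ratio summaries,
    elimination-pathway decomposition, named trial scenarios including an
    EMA-style IC50 sensitivity sweep, and a synthetic-data generator for
    assay plates and pseudo-observed concentration-time datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
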