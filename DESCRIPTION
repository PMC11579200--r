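Package: qspvct
Title: Virtual Clinical Trials with a QSP Immuno-Oncology Model of
    Conditionally Activated Anti-PD-L1 Antibodies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A quantitative systems pharmacology (QSP) immuno-oncology
    pipeline for simulating virtual clinical trials of masked,
    protease-activated (conditionally activated) anti-PD-L1 antibodies.
    Provides a reduced four-compartment ODE model of tumor-immune
    dynamics with reversible antibody unmasking and irreversible linker
    cleavage, Latin-hypercube generation of proposed patients,
    plausibility filtering on pre-treatment tumor growth, omics-informed
    virtual-patient selection via density-ratio inclusion probabilities
    calibrated by simulated annealing, RECIST-based trial readouts
    (waterfall, spider, progression-free survival, compartmental drug
    exposure), partial-rank-correlation sensitivity analysis,
    responder/non-responder biomarker comparison, and T-cell-clone
    (tumor mutational burden proxy) stratified response analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    survival,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
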