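# qspvct

Virtual clinical trials of a **conditionally activated (masked,
protease-cleavable) anti-PD-L1 antibody** with a reduced
quantitative-systems-pharmacology immuno-oncology (QSP-IO) model.

Masked "probody"-style checkpoint inhibitors carry peptide masks over
their active sites, tethered by linkers that tumor-resident proteases
cleave, so the drug is preferentially activated inside the tumor
microenvironment. `qspvct` is for modelers who want to ask, *in
silico*: how does masking change efficacy and tumor localization of an
anti-PD-L1 antibody across a heterogeneous patient population, and
which patient characteristics drive response? It implements the full
virtual-trial workflow:

* a four-compartment ODE model (tumor, tumor-draining lymph node,
  central, peripheral) of the cancer-immunity cycle — CD8/CD4/Treg
  T-cell priming and trafficking, APC maturation, M1/M2 macrophages,
  out-of-synapse PD-L1 — coupled to masked-antibody kinetics with
  reversible unmasking (equilibrium constant *K*<sub>M</sub>) and
  irreversible tumor-restricted cleavage (rate *k*<sub>cvg</sub>);
* virtual-patient generation by Latin hypercube sampling and
  plausibility filtering on simulated pre-treatment tumor growth;
* omics-informed selection: patients are accepted with probability
  *p* = min{1, β·*f*<sub>ref</sub>(x)/*f*<sub>pla</sub>(x)} where
  *f*<sub>ref</sub>, *f*<sub>pla</sub> are kernel densities of the
  ε-clamped immune subset ratios
  x₁ = M1/(M1+M2), x₂ = Treg/(Treg+CD8), x₃ = CD4/(CD4+CD8)
  in a reference (omics) table and the plausible cohort, and β is
  calibrated by simulated annealing;
* RECIST 1.1 trial readouts (waterfall/spider percent change,
  Kaplan–Meier progression-free survival with Greenwood 95% CIs,
  per-compartment exposure AUC in %dose·day/g);
* analyses: partial-rank-correlation (PRCC) sensitivity,
  responder/non-responder biomarker rank-sum comparisons, median-split
  waterfall labels, and ORR stratified over percentile bands of the
  tumor-specific T-cell clone count (TCC, the model's tumor mutational
  burden proxy).

Everything runs from synthetic inputs: the package generates omics-like
immune-subset tables (beta marginals, Gaussian copula), ships a reduced
default NSCLC-like parameter-distribution table, and accepts full
external calibrations as plain CSV.

## Worked example

```r
library(qspvct)

## equilibrium binding-competent fraction of the masked antibody
unmasked_fraction(c(0.01, 1, 100))
#> [1] 0.01970395 0.75000000 0.99990197

## 50 proposed patients -> plausible cohort with pre-treatment states
coh <- generate_cohort(n = 50, seed = 42)
coh
#> <qsp_cohort> 50 plausible of 50 proposed patients (100%)

## masked-antibody monotherapy, 10 mg/kg every 2 weeks for 400 days
vt <- run_trial(coh, regimen(dose_mg_per_kg = 10, interval_days = 14,
                             duration_days = 400, arm = "masked"))
vt
#> <qsp_trial> 50 patients, arm = masked, ORR = 16%
#>
#> PD PR SD
#> 37  8  5

head(vt$outcomes[, c("patient", "percent_change", "class",
                     "progression_days", "censored", "auc_tumor",
                     "auc_central")], 4)
#>   patient percent_change class progression_days censored   auc_tumor
#> 1       1      171.22013    PD               66    FALSE 0.005588990
#> 2       2      -89.84165    PR              253    FALSE 0.014671265
#> 3       3      249.05918    PD               51    FALSE 0.007056351
#> 4       4      127.68020    PD              105    FALSE 0.155138241
#>   auc_central
#> 1 0.002255003
#> 2 0.001906978
#> 3 0.001794311
#> 4 0.003560978
```

Reading the output: 8 of 50 patients end the trial at or below −30%
tumor-size change (partial response), so the objective response rate is
16%; most others progress (≥ +20%). `progression_days` is the first day
the diameter exceeds 20% over its running nadir. The exposure columns
are the AUC of *active* antibody (at least one active site revealed, by
unmasking or cleavage) per gram of tissue as a percentage of the total
dose — here the tumor sees a few-fold more active drug per gram than
the blood, because cleaved antibody accumulates in the tumor while only
the ~2% open fraction is active elsewhere.

The full pipeline (generate → select → trial → analyses, with result
CSV/JSON files and a JSON-lines log) is one call:

```r
res <- run_pipeline(run_config(n_proposed = 200, seed = 1,
                               out_dir = "run1"))
```

or, from a shell, via the bundled thin CLI:

```sh
Rscript inst/cli/qspvct.R full-run --config inst/extdata/tiny_config.yaml --out run1
```

## Scope

The model is a structurally faithful *reduction*: same compartments,
cell types, ligand bookkeeping, mask states and dosing as the full
published QSP-IO framework, with every rate exposed as a named
parameter so a complete calibration table can be loaded verbatim
(`read_parameter_table()`). Cancer-associated fibroblasts, metastases,
toxicity/PBPK and masking of ligands other than PD-L1 are out of scope.
See the methods vignette (`vignettes/virtual-trials.Rmd`) for the model
equations' assumptions, parameter meanings and defaults, numerical
choices, and known limitations.
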