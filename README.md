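# iamdelta

Phospholipophilicity-excess descriptors and blood–brain-barrier QSPR in R.

## The problem

Whether a small molecule reaches the brain is routinely summarised by
log BB = log10(C_brain / C_blood), measured in vivo. Octanol–water
lipophilicity (log P) alone predicts log BB poorly. Retention on
immobilized-artificial-membrane (IAM) HPLC phases — phosphatidylcholine
analogues bonded to silica, available in two end-capping variants (MG and
DD2) — captures the *polar/electrostatic* component of drug–membrane
interaction that octanol misses. For structurally unrelated neutral
compounds, IAM retention extrapolated to fully aqueous eluent (log kw^IAM)
is linear in log P:

    E(log kw^IAM) = a · logP + b        (one line per IAM phase)

The **phospholipophilicity excess** of a compound is its distance above
that isolipophilic-neutral line:

    Δlog kw^IAM = log kw^IAM − (a · lip + b)

where `lip` is log P^N for neutrals, bases and ampholytes, and log D^7.4
(the pH 7.4 distribution coefficient) for acids — the primed convention
Δ′log kw^IAM. When the retention itself is calculated in silico rather than
measured, the descriptors are written cΔ/Δ′log kw^IAM. A large excess marks
strong polar interaction with membrane phospholipids and is *inversely*
related to brain uptake, most sharply in the low-permeation range
(log BB < −0.20).

The package is aimed at cheminformaticians and medicinal chemists who want
to use these descriptors as an early in-silico filter for compounds
unlikely to reach the CNS.

## What the package does

* **Data model** — validated compound tables (`compound_table`,
  `read_compound_table`, `write_compound_table`, `filter_subset`) and a
  packaged, fully published 56-compound reference dataset
  (`iam_dataset()`) with in-silico log kw on both phases, lipophilicity,
  log D^7.4 for acids, published delta values and experimental log BB.
* **Delta engine** — calibration lines as first-class objects
  (`phase_calibration`, shipped defaults `iam_calibrations()`: MG
  0.792/−0.732, DD2 0.934/−0.883), exact recovery of the lines from a
  table by least squares (`recover_calibration`), the
  ionization-dependent lipophilicity policy (`select_lipophilicity`) and
  descriptor computation (`compute_delta`, `compute_delta_table`).
* **Regression** — `fit_ols()` returns a classed model with the QSAR
  panel: r², leave-one-out q² (= 1 − PRESS/SST), SE of the estimate,
  F and p, and both variants of the Amemiya predictive criterion;
  `loo_q2()` is the brute-force reference implementation;
  `fit_logbb_simple()` runs the headline log BB regressions.
* **Automatic model search** — `univariate_screen()` (drop r² < 0.1),
  `vif_filter()` (iterative variance-inflation-factor filter, threshold
  5), `search_models()` (exhaustive subsets of 1–5 descriptors, LOO
  validation, optional single-compound exclusion), combined in
  `stepwise_qspr()`.
* **HLB calculators** — Griffin, Davies (group table shipped as editable
  config), surface-based, and their mean; plus a pluggable linear QSPR
  evaluator (`linear_qspr`, `predict_logkw`) for user-supplied
  phospholipophilicity models.
* **Synthetic generators** — seeded, configurable generators for compound
  tables and descriptor matrices with known truths
  (`synthetic_config`, `gen_compound_table`, `gen_descriptor_matrix`), so
  every stage is testable without external data.
* **Orchestration** — `run_deltas()`, `run_reproduce()`,
  `run_stepwise()`, `run_synth()` write CSV/JSON reports with a
  reproducibility manifest; `inst/scripts/iamdelta.R` exposes them as
  shell subcommands.

## Worked example

```r
library(iamdelta)
rep <- run_reproduce()   # packaged dataset, calibrations recovered from it
print(rep)
```

```
log BB vs phospholipophilicity-excess report
   variable  scope  n    r2    q2    se f_stat      excluded
1  delta_mg   full 56 0.375 0.325 0.414  32.34              
2 delta_dd2   full 56 0.378 0.322 0.413  32.82              
3  delta_mg subset  8 0.591 0.106 0.236   8.66 valproic acid
4 delta_dd2 subset  8 0.790 0.561 0.169  22.53 valproic acid
```

Reading the rows: over all 56 compounds the excess descriptors explain
~38 % of the log BB variance (r² 0.38 DD2 / 0.37 MG, both with negative
slope). Restricting to poorly permeating compounds (log BB < −0.20) and
excluding the flagged outlier valproic acid, the DD2-phase descriptor
explains 79 % of the variance and the MG-phase 59 % — the regime where the
descriptor is informative as a filter. Individual descriptors:

```r
tab <- iam_dataset()
cal <- recover_calibration(tab, phase = "DD2")
compute_delta(tab[tab$name == "valproic acid", ], cal)$delta
#> [1] 2.079446   # a primed delta (acid, from log D 7.4 = 0.37)
```

## Notes on the packaged data

The reference table ships exactly as published
(`inst/extdata/table1_table2_merged.csv`). One published cell is
internally inconsistent: isoflurane's experimental log P is printed as
missing, yet its published deltas on both phases back-solve to 2.06 — the
PubChem experimental value. A one-row errata file records this; it is
applied by default and can be disabled with
`iam_dataset(apply_errata = FALSE)`. See the methods vignette
(`vignettes/phospholipophilicity-excess.Rmd`) for the full account.
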