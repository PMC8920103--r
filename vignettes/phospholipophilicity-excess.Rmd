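---
title: "Phospholipophilicity excess and blood–brain-barrier QSPR: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phospholipophilicity excess and blood-brain-barrier QSPR: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iamdelta)
```

## The model

Retention on immobilized-artificial-membrane (IAM) HPLC phases, expressed
as the logarithm of the retention factor extrapolated to a fully aqueous
mobile phase (log kw), measures a compound's affinity for phospholipids.
For structurally unrelated *neutral* solutes this phospholipophilicity is,
to good approximation, an affine function of octanol–water lipophilicity.
The package represents that relationship as a `phase_calibration`, one per
IAM phase (MG and DD2 end-capping variants):

$$\widehat{\log k_w} = a \cdot \mathrm{lip} + b, \qquad a > 0.$$

The *phospholipophilicity excess* of a compound is the residual of its own
(here in-silico) retention from that line,

$$\Delta \log k_w = \log k_w - (a \cdot \mathrm{lip} + b),$$

interpreted as the polar/electrostatic component of membrane binding that
equal-lipophilicity neutrals do not show. The analysis then treats the
excess as a descriptor of blood–brain-barrier passage, regressing
experimental log BB values on it.

Assumptions worth keeping in mind:

* the calibration line is estimated on neutrals with log P roughly 1.0–4.8
  and is *extrapolated* outside that window. `DeltaResult` rows carry an
  `out_of_calibration_range` flag rather than refusing such compounds,
  since hydrophilic solutes (e.g. ethanol) are legitimately scored this
  way in practice;
* log BB is an equilibrium whole-tissue ratio from animal studies; it
  mixes passive and active transport, so a single descriptor is not
  expected to explain it fully;
* the retention inputs here are themselves model predictions
  ("clog kw"), so the excess is an entirely in-silico quantity (the
  "cΔ/Δ′" notation of the field).

## The lipophilicity-selection policy

The lipophilicity entering the line must describe the species actually
present at physiological pH. The default policy therefore is:

| class | lipophilicity used | convention |
|---|---|---|
| acid (A) | calculated log D at pH 7.4 | primed (Δ′), `is_prime = TRUE` |
| B / BB / N | experimental log P^N if recorded | Δ |
| B / BB / N without exp. value | calculated log P^N (MarvinSketch column) | Δ |

Acids use log D *even when an experimental log P is recorded*; the
packaged reference deltas for amobarbital, valproic acid and zidovudine
are only reproducible under that rule. The calculated fallback column is
the MarvinSketch one: back-solving the published deltas of every
no-experimental-log-P compound (n-heptane, n-hexane, n-pentane,
bretazenil, 1-hydroxymidazolam, ...) reproduces that column, not the
ALOGPS column. Alternative policies (`exp-only`, `calc-alogps`,
`calc-marvin`) are explicit; a policy that cannot be satisfied for a
compound raises an error naming the compound — it never falls back
silently, because a silent substitution would change the descriptor's
meaning.

## Recovering the calibration lines

The published calibration coefficients are not machine-readable in the
source material, but they are exactly recoverable from the reference
table: for each compound, `clog kw − published delta` *is* the expected
retention of its isolipophilic neutral, so an ordinary least-squares fit
of that quantity on the selected lipophilicity returns the line.
`recover_calibration()` implements this, flags fits with r² < 0.999 as
degenerate (the reconstruction should be essentially exact when the
printed data are self-consistent), and reports diagnostics. The
recovered defaults, shipped as `iam_calibrations()`, are MG
(0.792, −0.732) and DD2 (0.934, −0.883).

### The isoflurane erratum

One reference cell is internally inconsistent. The published table leaves
isoflurane's experimental log P empty, yet its published deltas back-solve
— on both phases independently — to a lipophilicity of 2.060 ± 0.001,
matching neither calculated column but equal to the PubChem experimental
log P for isoflurane (2.06), the stated source of the experimental values.
The packaged CSV stays exactly as published; a one-row errata file
(`table1_errata.csv`) records the back-solved value with its provenance
and is applied by default in `iam_dataset()`. With the erratum the affine
reconstruction holds to ±0.0006 across all 112 deltas; without it,
isoflurane is the single gross outlier, which `recover_calibration()`'s
iterative outlier exclusion (`outlier_resid`) isolates explicitly. Users
who prefer the letter of the published table can pass
`apply_errata = FALSE` and exclude isoflurane from calibration recovery.

### Tolerances

Published deltas are printed to 3 decimals and their inputs to 2–3
decimals. Reproduction is therefore asserted at ±0.005 — half of the last
printed digit of the inputs, propagated through a subtraction. Whether the
original computation rounded intermediates is unknowable from the printed
record; the tolerance absorbs that ambiguity.

## The regression panel

`fit_ols()` wraps an ordinary least-squares fit (via `stats::lm`) and
reports the panel conventional in QSPR work:

* r² = 1 − SSE/SST;
* **q² (leave-one-out)** = 1 − PRESS/SST with SST about the *full-sample*
  mean — the common QSAR convention. `loo_q2()` computes PRESS by
  explicitly refitting n times and is the reference implementation; the
  panel value uses the exact hat-matrix identity
  PRESS = Σ(eᵢ/(1−hᵢᵢ))², and the two are tested against each other;
* SE of the estimate = √(SSE/(n−k−1));
* F = (r²/k)/((1−r²)/(n−k−1)) with its upper-tail p-value. p-values are
  reported, never used as a selection criterion;
* **Amemiya predictive criterion**: the published reference statistics
  tabulate a "PC" column that numerically matches the raw SSE rather than
  any standard penalised form. Since the software that produced it is not
  inspectable, both variants are exposed (`amemiya_pc`): `standard`,
  (SSE/(n−k−1))·(1+(k+1)/n), and `sse_like`, the raw SSE. Neither is
  asserted as canonical; comparisons against the reference panel use
  `sse_like` because that is the scale the reference prints.

The subset analysis (`fit_logbb_simple`) uses a strict `<` threshold on
log BB (default −0.20) and an explicit, logged exclusion list defaulting
to valproic acid — an acid whose log D had to be calculated, flagged as an
outlier in the source analysis. Exclusions are user-visible parameters,
never silent behaviour, and subsets smaller than 4 points are refused.

## The automatic model search

The reference procedure screens a large descriptor pool, removes
collinearity, and searches models of 1–5 variables with leave-one-out
validation. The published account does not specify the stepping rule of
the original software, so the package makes a reproducible choice:

* **screen** (`univariate_screen`): drop descriptors with univariate
  r² < 0.1 (threshold exposed); constant columns are skipped with a
  warning;
* **collinearity** (`vif_filter`): VIFⱼ = 1/(1−R²ⱼ); the *highest*-VIF
  descriptor is removed and VIFs recomputed, iterating until all are
  below 5. Iterative worst-first removal is used because simultaneous
  thresholding is order-dependent. Exact duplicates (infinite VIF)
  tie-break by dropping the later-listed column — the one documented
  arbitrary choice;
* **search** (`search_models`): exhaustive enumeration of all subsets up
  to 5 variables when at most 20 candidates survive (at most 21 699
  fits), otherwise greedy forward selection; this is deterministic and at
  least as thorough as any stepwise variant. Ranking is by LOO q²
  (objective switchable to r²), ties broken by lower SE, then fewer
  variables;
* **exclusion** (`exclusion_search = TRUE`): mirroring the single "Exc"
  compound of the reference models, each top model is refit n more times
  leaving out one compound, and the exclusion that most improves the
  objective is reported next to the full-sample fit. Exactly one
  exclusion is allowed; multi-outlier search is out of scope.

The specific multi-descriptor models of the reference work are not
reproducible on published information (the underlying descriptor values
were never printed), so the search is validated by construction instead:
on generated matrices with a planted linear model among decoys, the
planted subset must rank first and its coefficients must land within three
standard errors of the truth (exactly, when generator noise is zero).

## The synthetic generators

`gen_compound_table()` emulates the *statistical* structure of the
reference table: retention = calibration line + class-dependent polar
excess + noise, acids with log D = log P − (positive ionization shift),
a log BB that is linear in the DD2 excess with negative slope, and
experimental log P present for only part of the table. Defaults follow
the reference conditions: 56 compounds, class proportions 5 A / 8 B /
2 BB / 41 N, lipophilicity uniform on −1.5 to 6, excess distributions
spanning roughly −1 to 2 (means 1.1 A, 0.1 B, 0.7 BB, 0.1 N; sds
0.3–0.6), retention noise sd 0.05, log BB = 0.3 − 0.55·Δ + ε with
ε sd 0.4 — values matched once to the observed ranges and slopes of the
packaged dataset. The retention backbone is built on the lipophilicity a
*consumer of the table will select* (log D for acids, experimental log P
when present, else the calculated column), so generated tables are
self-consistent under the default policy.

`gen_descriptor_matrix()` produces standard-normal descriptor columns, a
planted linear response over a named subset (defaults: 3 of 15 columns,
coefficients 1.5/−2.0/0.8, intercept 0.5, noise sd 0.1, n = 60), one
column correlated at 0.95 with the first planted descriptor, and
pure-noise decoys.

A single integer seed drives everything through a documented splitting
scheme (compound stream = seed, descriptor stream = seed + 10⁶), so
adding a generator never perturbs an existing stream and identical seeds
give bit-identical output.

What the generators deliberately do **not** emulate: chemical structure,
correlated real-descriptor blocks, heteroscedastic measurement error, or
class-dependent log BB mechanisms beyond the linear-in-excess model.
Passing the synthetic recovery tests therefore demonstrates correctness
of the *algorithms* under the stated data model, not predictive validity
on new chemistry.

## Numerical and design notes

* Missing values are `NA` end to end and serialize as empty cells; zero is
  always a legal value and never means missing.
* The packaged CSV stores values at the published precision (3 decimals
  for retention/deltas, 2 for log P/log BB); loading performs no
  re-rounding.
* Rank-deficient designs error naming the collinear columns; degenerate
  lipophilicity spreads (all equal) error rather than returning an
  unidentifiable slope.
* `filter_subset` uses strict `<`; with threshold +∞ it returns every
  record that has a log BB, verbatim.
* Test problem sizes were chosen to keep the full suite fast while leaving
  no algorithm untested at a non-trivial size: subset search on 15–16
  candidates (≈ 600 fits), LOO oracles on 10-point problems, calibration
  recovery replicates at n = 200, correlation checks at n = 500.

## Known limitations

* The package evaluates user-supplied phospholipophilicity models
  (`linear_qspr`) but ships no coefficients for predicting log kw from
  structure; the packaged clog kw columns are treated as authoritative
  precomputed inputs.
* The surface-based HLB variant is implemented as scale·PSA/Surface with
  the scale defaulting to 20 (Griffin-range); the exact normalisation
  used in the source work is not published, so the scale is exposed as a
  parameter.
* The Davies group-contribution table ships with the standard published
  group numbers as editable configuration; matching a specific vendor
  implementation may require editing it.
* With n = 56 and two highly correlated delta descriptors, multivariate
  models including both phases are rarely meaningful (their pairwise VIF
  far exceeds 5); the tooling will correctly refuse to keep both.
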