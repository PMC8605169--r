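# usigma

Six sigma evaluation of clinical laboratory assay performance — built for
urinary biochemistry — and risk-based statistical quality control (SQC)
design on top of it.

Laboratories measuring urinary potassium, sodium, chloride, calcium,
phosphorus, glucose, urea, creatinine, total protein and microalbumin need
to know (a) how good each assay actually is, (b) how much QC each assay
needs, and (c) what to fix first when performance falls short. `usigma`
answers all three from two routine data streams and a quality goal:

- **Imprecision**: the CV (%) of months of internal QC (IQC) series at two
  control levels.
- **Trueness**: the bias (%) of a 5-replicate panel of an external quality
  assessment (EQA) sample against its peer-group target.
- **Goal**: the total allowable error TEa (%), with builtin
  state-of-the-art goals for the ten urinary analytes.

The central statistic is the sigma metric

```
sigma = (TEa(%) − |bias(%)|) / CV(%)
```

the number of analytical standard deviations between current performance
and the goal. Six sigma corresponds to 3.4 defects per million under the
conventional 1.5-sigma shift (`sigma_to_dpm(6)`). From sigma the package
derives:

- the **Westgard sigma-rules SQC strategy** per assay (control rules such
  as 1_3s/2_2s/R_4s, number of control measurements N, and the run size —
  patient samples between QC events), using the minimum sigma across
  control levels;
- the **quality goal index** `QGI = bias / (1.5 · CV)` for assays below
  six sigma (QGI < 0.8 → fix imprecision first; > 1.2 → fix trueness;
  0.8–1.2 → both);
- **normalized method decision charts** (bias/TEa vs CV/TEa, six sigma
  zones cut by the lines y = 100 − s·x);
- a Westgard **multirule engine** (`evaluate_rules()`) to apply the
  selected rules to control data.

A synthetic-data generator produces IQC/EQA fixtures with known true CV,
bias and sigma (5 labs × 10 analytes × 2 levels by default), so the whole
chain is testable without access to any laboratory's raw data.

## Worked example

Strategy selection from a sigma pair (an assay at 5.94/5.97 sigma on its
two control levels):

```r
library(usigma)
select_strategy(c(level1 = 5.94, level2 = 5.97))
#> SQC strategy [6>sigma>=5, effective sigma 5.94]: 1_3s/2_2s/R_4s with N=2 and R=450
```

The effective (minimum) sigma 5.94 falls in the 5–6 sigma band, so the
assay needs the 1_3s/2_2s/R_4s multirule with N = 2 control measurements
per QC event and QC brackets every 450 patient samples. An assay above six
sigma would need only 1_3s with a run size of 1000.

End to end on a synthetic fixture with known truth:

```r
g <- default_scenario_grid()[1:10, ]          # 10 scenarios
paths <- build_study_fixture(g, seed = 42, dir = tempdir())
report <- run_pipeline(paths[["iqc"]], paths[["eqa"]])
report
#> usigma report
#>   assays evaluated : 10 lab/analyte/level records
#>   SQC strategies   : 5 lab/analyte pairs
#>   below six sigma  : 5 assays need improvement

report$metrics[1:4, c("lab","analyte","level","cv","bias","sigma","zone","improvement")]
#>     lab analyte  level   cv bias sigma       zone improvement
#> 1 Lab A      Ca level1 4.45 6.06  5.60 6>sigma>=5        both
#> 2 Lab A      Ca level2 3.84 9.80  5.52 6>sigma>=5    trueness
#> 3 Lab A      Cl level1 5.20 3.68  4.29 5>sigma>=4 imprecision
#> 4 Lab A      Cl level2 4.77 3.29  4.76 5>sigma>=4 imprecision
```

Each row is one assay at one control level: its estimated CV and bias, the
resulting sigma and chart zone, and — where sigma < 6 — which side of
performance the QGI says to improve first. `render_report(report, "out/")`
writes `metrics.csv`, `strategies.csv`, `improvement.csv`, the two
decision-chart SVGs, `report.md` and `provenance.json` (input SHA-256
digests, configuration, version); identical inputs give byte-identical
files.

Reference tables from a published five-laboratory multicenter evaluation
of these assays ship with the package (`fivelab_sigma()`,
`fivelab_strategies()`, `fivelab_qgi()`) and anchor the test suite: the
strategy selector reproduces all 50 published strategy cells and the QGI
classifier all 20 published improvement labels.

A thin CLI lives at `inst/exec/usigma`
(`usigma simulate | run | strategy | chart`).

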