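---
title: "Six sigma evaluation of urinary biochemical assays: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Six sigma evaluation of urinary biochemical assays: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usigma)
```

## The problem

Clinical laboratories run stabilized control materials (internal QC, IQC)
alongside patient samples and periodically measure external quality
assessment (EQA) samples whose target value is a peer-group consensus. The
six sigma framework condenses these two data streams and a quality goal
into a single number per assay:

$$\sigma = \frac{\mathrm{TEa}(\%) - |\mathrm{bias}(\%)|}{\mathrm{CV}(\%)}$$

- **TEa** (total allowable error, % of target) is the quality goal. For
  urinary biochemistry no biological-variation goals exist, so the
  builtin table (`load_tea_goals("china_eqa_2020")`) uses
  state-of-the-art goals derived from a national EQA program, calibrated
  so that more than 80% of participating laboratories pass.
- **CV** is the imprecision from months of IQC: sample SD (n − 1
  denominator) over the series mean, per control level. Two measurements
  per day over six months gives the default series length of 360.
- **bias** is the trueness error from a same-batch panel of 5 EQA
  replicates: each replicate's signed percent difference from the
  peer-group target, summarized as described below.

A sigma of 6 means six analytical SDs fit between current performance and
the goal; under the conventional 1.5-sigma long-run shift this is 3.4
defects per million (`sigma_to_dpm(6)`). Sigma drives two downstream
decisions:

1. **How much QC** — the Westgard sigma-rules flowchart
   (`select_strategy()`): high-sigma assays need only the 1~3s~ rule with
   N = 2 and a run size of 1000 patient samples between QC events;
   lower-sigma assays need progressively more rules (2~2s~, R~4s~, 4~1s~,
   8~x~), more control measurements, and shorter runs.
2. **What to fix** — for assays below six sigma, the quality goal index
   $\mathrm{QGI} = \mathrm{bias}/(1.5\,\mathrm{CV})$
   (`qgi()`, `classify_improvement()`): below 0.8 the problem is
   imprecision, above 1.2 trueness, between the two (inclusive) both.

## Conventions and why

**Bias summary.** Two readings of "average bias" coexist in practice: the
absolute value of the mean signed difference (`mean_then_abs`, the
default) and the mean of absolute differences (`abs_then_mean`). They
differ only when replicates straddle the target, which at realistic
analytical CVs (1–6%) and 5 replicates essentially happens only when the
true bias is near zero — exactly where the distinction does not change
any decision. Both are implemented (`compute_bias(convention = )`)
because published tables rarely say which was used.

**Band edges.** The six chart zones are closed on their lower edge:
sigma exactly 5 lies in `6>sigma>=5`, sigma 6 in `sigma>=6`. The same
convention drives strategy selection. `sigma_band()` snaps values within
1e-9 of an edge onto it so that points constructed exactly on a zone
boundary line classify deterministically despite floating-point rounding.

**Effective sigma across levels.** A strategy is chosen per
`(lab, analyte)` from the *minimum* sigma across the two control levels —
the conservative choice, and the only simple policy consistent with every
published five-laboratory strategy cell we reproduce in the tests (no
mixed-band pair occurs there, so min and mean are indistinguishable on
that reference; min is safer in general).

**Sub-four-sigma bands.** The worked flowchart anchors the bands at and
above four sigma. Below that we follow the published Westgard sigma-rules
convention — the full multirule with N = 4 and a run size of 45 for
3 ≤ σ < 4, and below three sigma the same rules with doubled QC events, a
run size of 23 and a "maximum QC / method improvement" flag. Because
these two bands are convention rather than a reproduced table, they are
overridable via `westgard_policy(overrides = )`.

**Rule engine semantics.** Observations are z-scored against each
material's established mean/SD. Counting rules (2~2s~, 4~1s~, 8~x~) run
over consecutive observations ordered within a run by material level and
then across runs; R~4s~ is within-run only (one control above +2 SD and
one below −2 SD). Limits are exceeded strictly (z > 2, not ≥ 2), the
classic reading; boundary hits have probability zero on continuous data.

**QGI reporting.** QGI is computed per level but only reported where
sigma < 6, matching how improvement tables are published. When the two
levels disagree on the improvement class, both labels are emitted
slash-joined rather than silently collapsed.

## The synthetic-data generator

The raw per-laboratory IQC/EQA data behind published multicenter
evaluations are typically not deposited, so validation rests on
synthetic data with known truth (`default_scenario_grid()`,
`build_study_fixture()`).

The generator emulates the study design: 5 laboratories × 10 urinary
analytes × 2 control levels, 360 IQC values per scenario (two per day for
six months), 5 EQA replicates. Measurement noise is i.i.d. Gaussian with
constant CV within a level — the minimal model consistent with mean/SD/CV
statistics. Bias enters as a multiplicative shift applied identically to
the IQC mean and the EQA replicates, emulating a single analytical state.
True sigma sweeps 4–18 across the grid (the range such evaluations
report) and the bias/CV ratio cycles through 0.5, 1, 2, 3 so that every
improvement class occurs. Nominal concentrations are typical urinary
values but cancel out of every statistic.

Per-scenario RNG streams are derived from the master seed plus a hash of
`(lab, analyte, level)`, so adding or removing scenarios never perturbs
the others and the whole fixture is byte-identical for a fixed seed.

What the generator does **not** model: drift, shifts, autocorrelation,
reagent-lot changes, heteroscedasticity beyond constant-CV, or outliers.
Passing recovery tests therefore demonstrates correctness of the
estimation chain under the idealized IQC noise model, not robustness to
real-world instability.

## What recovery can and cannot show

With 360 IQC values the CV estimate carries a relative sampling SD of
about $1/\sqrt{2(n-1)} \approx 3.7\%$. The bias estimate from 5
replicates carries an SD of $\mathrm{CV}/\sqrt{5}$, which propagates into
sigma as a relative error of $1/(\sigma\sqrt{5})$. The total relative SD
of an estimated sigma is therefore about

$$\sqrt{\tfrac{1}{2(n_\mathrm{IQC}-1)} + \tfrac{1}{n_\mathrm{EQA}\,\sigma^2}}$$

— about 6% at σ = 10 and 12% at σ = 4. Single-fixture sigma estimates for
mid-range assays are consequently only accurate to roughly ±10–25% at 95%
confidence, and band assignments near an edge flip readily. This is a
property of the study design itself (five EQA replicates), not of the
implementation; the test suite's recovery checks measure exactly these
rates, and any tighter claim would require more EQA replicates than the
protocol prescribes. Averaging over many seeds, the generator's recovered
bias and CV are unbiased, which the suite verifies with chi-square
interval and Monte-Carlo oracles.

## Numerical and degenerate-input choices

- A zero-variance IQC series yields CV 0 with a warning; sigma is then
  reported as `Inf` (with a warning), lands in `sigma>=6`, and no QGI is
  computed (QGI requires CV > 0 and is an error otherwise).
- Negative sigma (bias exceeding the goal) is never clamped; it bands as
  `sigma<2`.
- Table output rounds half-even to 2 decimals, standard reporting
  precision; JSON output keeps full precision.
- Chart points beyond the fixed 0–100% frame are clamped to the margin
  and drawn with a cross marker instead of silently dropped.
- Run identifiers are opaque sortable tokens; ties keep file order.
- Pipeline runs are deterministic: identical inputs give byte-identical
  CSV, JSON, markdown and SVG outputs (the SVG device embeds no
  timestamps).

## Problem sizes used in the test suite

Unit and property tests use series of 12–360 values; the end-to-end
recovery check runs the full 100-scenario grid at the default 360 IQC
values and 5 EQA replicates; the false-rejection sanity check uses 100
000 simulated control observations. These sizes make the sampling-error
bounds above tight enough to be meaningful while keeping the whole suite
fast on a single CPU.

## Known limitations

- Bias is EQA-replicate based only; method-comparison bias against a
  reference procedure is out of scope, as are uncertainty intervals on
  sigma (point values only, as published).
- The pipeline is cross-sectional: no longitudinal monitoring or
  post-improvement re-evaluation.
- Peer-group EQA targets are consensus means, not reference values; a
  laboratory matching a biased peer group will look truer than it is.
- Run-size recommendations assume the published flowchart's patient-risk
  derivation; no power curves or MaxE(Nuf) computations are performed.
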