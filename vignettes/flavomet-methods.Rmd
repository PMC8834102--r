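---
title: "Methods: MRM quantitation, validation statistics, and urinary mass balance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MRM quantitation, validation statistics, and urinary mass balance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavomet)
```

## The problem this package addresses

Naringin, a flavanone glycoside abundant in citrus, is hydrolyzed in the gut
to its aglycone naringenin, which is then conjugated and interconverted into
a family of flavonoid metabolites (glucuronides, a sulfate, and related
aglycones). Quantifying those metabolites in rat urine by targeted LC-MS/MS
(multiple reaction monitoring, MRM) requires three linked pieces of
statistics, all implemented here:

1. **Calibration** — a weighted (1/x) least-squares line relating the
   analyte/internal-standard (IS) peak-area ratio to concentration, with
   per-level back-calculation audits;
2. **Validation** — the ChP-style bioanalytical battery: selectivity,
   carry-over, precision/accuracy, IS-normalized matrix factor, dilution
   integrity, and stability, each with fixed acceptance thresholds;
3. **Mass balance** — conversion of per-interval urine concentrations into
   molar amounts and percent of the molar naringin dose recovered.

Because raw instrument data for such studies are rarely deposited, the
package ships a seeded synthetic-data generator with the statistical
structure the analysis assumes, so every stage is testable end to end.

## The panel registry

`build_default_panel()` returns the eleven-member panel: ten metabolites
plus isoquercitrin as IS. Each record carries the MRM transition (Q1/Q3),
declustering potential, collision energy, retention time, molecular
formula, and the analyte's base (LLOQ) concentration. Two kinds of mass are
computed from the formula: the **average molar mass** (IUPAC conventional
atomic weights), used for ng-to-nmol conversion, and the **monoisotopic
mass**, used only by `check_transition()` to verify that the tuned Q1 value
sits within 0.5 Da of the theoretical [M-H]⁻ m/z and that conjugate
transitions lose a glucuronide (176.032 Da) or SO₃ (79.957 Da) residue. The
0.5 Da tolerance reflects unit-resolution quadrupole settings, which are
tuned rather than theoretical. Isomeric glucuronide pairs share one
transition and are distinguished chromatographically; since peak
integration is upstream of this pipeline, synthetic data are keyed by
analyte identity directly.

The concentration design is multiplicative and shared panel-wide: standards
at 1, 2, 5, 15, 50, 150, 400, 500 × the base level, QCs at 3 (LQC), 30
(MQC), 375 (HQC) × the base level. Two structural consequences are used as
test invariants: the calibration range spans a 500-fold ratio for every
analyte, and the HQC always sits at 75 % of the top standard.

A per-analyte `correction_factor` (default 1) is carried for laboratories
that re-anchor nominal concentrations after assaying the actual reference
material; the design rules above always use the design values.

## The synthetic instrument model

`instrument_model()` draws the analyte area of an injection at true
concentration $x$ in lot $L$ as

$$A \;=\; (a + b x)\, A^{\mathrm{nom}}_{IS}\, f_L\, e^{\eta}\, e^{\varepsilon}
\;+\; c\,A_{\mathrm{prev}},$$

and the IS area as $A^{\mathrm{nom}}_{IS} g_L e^{\eta}$. Both lognormal
factors have mean 1 and coefficient of variation `noise_cv`
($\sigma^2 = \log(1+cv^2)$, mean $-\sigma^2/2$): $e^{\eta}$ is shared by
all channels of one injection (spray and injection-volume fluctuation — the
variability the IS exists to correct), $e^{\varepsilon}$ is specific to the
analyte channel. The area **ratio** therefore has CV exactly `noise_cv`,
which is the parameter every downstream RSD statement refers to.
Carry-over adds fraction $c$ of the previous injection's analyte area, on
the analyte channel only: the IS is added fresh to every processed sample
with the precipitation solvent, so a true blank shows no IS signal at all.
Lot factors $f_L, g_L$ model ionization matrix effects; configuring them
jointly ($f_L = g_L$) makes the IS-normalized matrix factor identically 1,
configuring them independently exercises the failure path.

Defaults, chosen once as realistic study conditions: slope
$b = 1/(500\,\mathrm{base})$ per analyte so the area ratio reaches 1 at the
top standard, intercept 0, nominal IS area $10^5$, `noise_cv` 0.05, no
carry-over, one unit lot. All are overridable; every simulator is seeded
and byte-reproducible.

## The excretion model

`excretion_model()` describes first-order urinary elimination: the amount
of metabolite $m$ excreted in the interval $[t_1, t_2]$ is
$F_m D\,(e^{-k t_1} - e^{-k t_2})$ nmol, with $D$ the molar dose
(`dose_to_nmol()`: $10^6\,\mathrm{bw_{kg}}\times\mathrm{dose_{mg/kg}} /
M_{\mathrm{naringin}}$) and $F_m$ the metabolite's molar fraction of dose
recovered at infinite time. Defaults: five rats of 0.32–0.38 kg dosed at
42 mg/kg; six collection intervals 0–4, 4–8, 8–12, 12–24, 24–36, 36–48 h;
fractions proportional to the observed ranking (the two naringenin
glucuronides dominate, then naringenin, then the minor metabolites)
totalling 4.27 % of dose; $k = 0.15\ \mathrm{h^{-1}}$, placing ≈97 % of
the excreted material within 24 h. Between-rat variability is a lognormal
spread (CV 0.25) on the fractions — a synthetic convention, since no
between-animal variance model is identifiable from summary data. Zero urine
volumes are legal (they occur in practice) and contribute zero amount while
keeping their interval in the cumulative series.

True concentration is amount × molar mass / volume; the measured value
multiplies in one lognormal noise factor. The generator returns the ground
truth alongside, so recovery of the configured fractions is a round-trip
test, exact in the noise-free limit.

## Calibration and its acceptance rules

`fit_weighted_line()` minimizes $\sum_i w_i (y_i - a - b x_i)^2$ with
$w = 1/x$ via the weighted normal equations (`stats::lm`). The reported
correlation coefficient is the **weighted** r (computed with the same
weights via `stats::cov.wt`); the unweighted Pearson r is carried alongside
because published linearity tables do not always say which convention they
use. Back-calculation is the algebraic inverse $(y-a)/b$; negative values
are preserved (flagged `below_zero`) so deviation audits remain faithful,
and `range_flag()` marks BQL and above-range values.

A batch is accepted when every standard's deviation,
$100(\mathrm{measured}-\mathrm{nominal})/\mathrm{nominal}$, is within
±20 % at the LLOQ and ±15 % elsewhere, and the weighted r ≥ 0.99. All
levels must pass; an optional drop-one-level relaxation exists but is off
by default, since the guideline text states no partial-acceptance rule.
Reported concentrations are conventionally printed to 4 significant
figures; internal arithmetic is full precision.

## The validation battery

All statistics use the sample standard deviation (n−1): RSD % =
100·sd/mean, RE % = 100·(mean − nominal)/nominal.

* **Selectivity** (`check_selectivity`): the guideline check is visual
  (no interference peaks); as a numeric surrogate the blank's analyte
  response must stay below 20 % of the LLOQ response and the blank IS
  response below 5 % of the working IS response. These percentages are
  borrowed from the carry-over criterion — a convention of this package,
  not a guideline number.
* **Carry-over** (`assess_carryover`): blank injected after the ULOQ;
  residual ≤ 20 % of the LLOQ response per analyte, ≤ 5 % for the IS.
* **Precision/accuracy** (`precision_accuracy`): 3 batches × 6 replicates
  at LLOQ/LQC/MQC/HQC, each replicate back-calculated against *its own
  batch's* curve. Intra-batch statistics are reported per batch;
  inter-batch statistics pool all 18 replicates per level (matching the
  "n = 6 × 3" convention) rather than averaging batch means. Thresholds:
  RSD and |RE| ≤ 20 % at the LLOQ, ≤ 15 % elsewhere.
* **Matrix effect** (`matrix_effect`): per lot, MF = mean post-extraction
  spiked area / mean neat area (means over the 3 replicates are taken
  before ratioing; a replicate-level option exists); IS-MF =
  MF\_analyte/MF\_IS; acceptance is RSD of the six per-lot IS-MF values
  ≤ 15 %. IS-MF is invariant to rescaling all areas of a lot — a test
  invariant.
* **Dilution integrity** (`dilution_integrity`): samples at 5× and 10× the
  HQC diluted back to HQC; back-calculated × dilution factor; |RE| ≤ 15 %
  against the pre-dilution nominal, RSD reported.
* **Stability** (`stability_evaluate`): five conditions (long-term 1 and
  3 months, 1 and 2 freeze–thaw cycles, autosampler 24 h) at LQC/HQC
  against a fresh curve; the ±15 % bound is applied to RE as a signed
  bound and to RSD as an upper bound, matching the guideline's joint
  phrasing.

`run_validation()` orchestrates all blocks over one role-labelled injection
table and reports per-block and overall pass flags.

## Numerical behaviour at the LLOQ — a known limitation

With eight single-replicate standards, a 1/x-weighted fit *with an
intercept*, and constant-CV multiplicative noise, the calibration curve's
prediction error at the LLOQ has standard deviation ≈ 6.8 % of the LLOQ
(about 2 % at the QC levels; this follows from the GLS covariance of the
design and is reproduced by simulation). QCs back-calculated against their
own batch's curve therefore inherit a per-batch bias of similar size at the
lowest level, inflating LLOQ relative errors and pooled inter-batch RSDs
beyond what replicate noise alone would give. Real assays show exactly this
signature — inter-batch LLOQ RSDs exceeding intra-batch ones by amounts
implying per-batch curve bias of several percent — so the generator
reproduces the structure of real data; but it also means that with
measurement CV around 4 %, the maximum RSD across a full
precision/accuracy suite fluctuates around 8–13 % between seeds, and
individual LLOQ RE values of 10–18 % occur regularly. Passing every cell of
a printed validation table at the LLOQ is partly a draw of the batch in
hand, not a guarantee of the method. This is stated here so that users do
not interpret an occasional LLOQ excursion in simulated suites as a
pipeline defect.

## What the generator does and does not emulate

Emulated: linear response over a 500-fold range, scale-proportional
(lognormal) ratio noise, per-lot ionization factors, additive carry-over
from the immediately preceding injection, first-order urinary elimination
with configurable per-metabolite fractions, zero-volume intervals, and
between-rat spread. Not emulated: chromatographic peak shape and
integration, retention-time drift, detector saturation or nonlinearity,
absorption/distribution pharmacokinetics beyond first-order elimination,
inter-day response drift within a batch sequence, and endogenous
interferences. Consequently, passing the synthetic suite demonstrates the
*statistical chain* is correct; it says nothing about chromatographic
selectivity on real matrices.

## Problem sizes and runtimes

The shipped tests and the acceptance script use the study-sized designs
throughout: 8-level curves, 3 × 6 × 4 precision/accuracy suites, 6 matrix
lots × 3 replicates, 3-replicate dilution and stability sets, five rats ×
six intervals; the heaviest property checks use 1 000 simulated batches
(slope recovery) and 500 replicate groups (RSD sampling distribution).
Everything runs in well under a minute on one CPU.

## Interval and unit conventions

Intervals are half-open $[t_1, t_2)$ hours from dose time, contiguous from
0. Concentrations are ng/mL, volumes mL, molar masses g/mol, amounts nmol,
doses mg/kg; `interval_amount()` relies on the exact identity
ng·mL⁻¹·mL / (g·mol⁻¹) = nmol. Sub-LLOQ concentrations contribute zero by
default (a conservative mass-balance choice); LLOQ/2 imputation is
available but off by default. Percent of dose is denominated in moles of
naringin — valid because each metabolite carries one flavonoid core per
molecule, so one mole of dose can yield at most one mole of any metabolite.
The cohort recovery is the unweighted mean of the per-rat percentages.
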