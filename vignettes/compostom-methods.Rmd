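---
title: "Methods: multi-technique assessment of organic-matter biodegradation during composting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-technique assessment of organic-matter biodegradation during composting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compostom)
```

## Scope and model of the data

`compostom` follows organic-matter (OM) transformation during composting of
agro-industrial wastes — the motivating system is the co-composting of
winery–distillery residues (grape marc, exhausted grape marc) with animal
manures — by combining six views of the same process:

1. **Classical chemical indices** from alkali-extractable carbon fractions
   and elemental measurements;
2. **First-order degradation kinetics** fitted to OM-loss time series;
3. **The exothermic index (EXI)** from pile/ambient temperature records;
4. **Thermal stability indices (R1/R2)** from TG/DTG/DTA thermograms;
5. **FT-IR relative-absorbance band profiles**;
6. **CPMAS ¹³C NMR chemical-shift-region integration**.

A seeded synthetic-data generator emulates all five instrument input kinds
with known ground truth, so every analysis stage is testable without
instrument exports.

## Chemical humification and maturity indices

With $C_T$ total organic carbon, $C_{ext}$ alkali-extractable carbon,
$C_{ha}$ and $C_{fa}$ the humic and fulvic acid-like fractions (all % dry
matter):

$$HR = 100\,\frac{C_{ext}}{C_T},\qquad HI = 100\,\frac{C_{ha}}{C_T},\qquad
P_{ha} = 100\,\frac{C_{ha}}{C_{ext}},\qquad \text{Cha/Cfa} = \frac{C_{ha}}{C_{fa}}$$

These satisfy the identity $P_{ha}\cdot HR / 100 = HI$, which the test
suite asserts to $10^{-9}$ relative on randomised fraction sets. OM loss
follows the ash balance from initial ($X_1$) and final ($X_2$) ash
contents:

$$\text{OM loss (\%)} = 100 - 100\,\frac{X_1 (100 - X_2)}{X_2 (100 - X_1)}$$

Design choices:

* When $C_{ext}$ is not measured it is defined as $C_{fa} + C_{ha}$; the
  reference table's rows are internally consistent with this definition.
* A negative OM loss (final ash below initial) is returned **with a
  warning**, not an error: early-phase field data are noisy and silently
  erroring would hide a diagnosable mass-balance anomaly.
* Maturity thresholds: TOC/TN strictly $< 20$; WSC $\le 1.7$ % (inclusive,
  since values "close to" the bound are conventionally accepted);
  germination index strictly $> 50$ %. Missing inputs yield an
  *undetermined* (`NA`) flag, never a silent `FALSE`.
* Rounding (2 d.p. ratios) happens only at report serialisation; full
  precision is kept internally.

One reference row deserves note: the pile C initial row of the bundled
chemical table carries derived columns (HR, Pha, Cha/Cfa) that duplicate
the pile B initial row and are inconsistent with its own Cfa/Cha inputs
(2.69/3.53 gives Cha/Cfa 0.76, not the printed 1.20). The table flags this
row via `roundtrip_ok = FALSE` and all consistency checks exclude it.
Three further rows differ by one unit in the last printed digit because
the printed inputs are themselves rounded; tests assert those at ±0.02.

## First-order degradation kinetics

OM loss over composting time $t$ (days) follows
$y(t) = A\,(1 - e^{-kt})$, with $A$ the maximum OM degradation (%) and
$k$ the rate constant (d⁻¹). `fit_first_order()` minimises the residual
sum of squares by Levenberg–Marquardt (via `minpack.lm::nlsLM`) with
physical bounds $A \in [0, 100]$, $k \in [0, 10]$.

* **Initialisation** (no published starting values exist): $A_0 = 1.1
  \max y$ and $k_0 = \ln 2 / t_{1/2}$, where $t_{1/2}$ is the first time
  the series exceeds half its maximum — scale-free and robust; a
  10-random-restart identifiability test agrees to $10^{-6}$ on clean
  data.
* **Statistics**: residual mean square $SS_{res}/(n-2)$, standard error of
  estimate $\sqrt{SS_{res}/(n-2)}$, $F = ((SS_{tot}-SS_{res})/2)\,/
  \,(SS_{res}/(n-2))$ against $F(2, n-2)$, $R^2$, and parameter standard
  errors from the Jacobian. The three published fits report an "RMS"
  column (0.878/0.769/0.880) that cannot equal SEE² under any df choice
  and numerically resembles an $R^2$-type statistic; the package therefore
  reports `residual_mean_square`, `see` and `r_squared` separately and
  takes no position on the published column's definition.
* The published $A$, $k$, $F$, SEE values cannot be re-fitted (the
  underlying OM-loss series was not tabulated); they serve as
  forward-evaluation constants and as generating parameters for recovery
  tests on synthetic data.
* The generator's default sampling design is 16 evenly spaced samplings
  across the 168-day composting trial (bio-oxidative phase plus
  maturation), with Gaussian noise of 1 percentage point as the reference
  noise level. Under these conditions parameter recovery (500 replicates
  per pile, pooled over the three published parameter sets) has a median
  relative error below 5 % for both parameters. The slowest pile
  (k = 0.0091 d⁻¹) reaches only ~78 % of its asymptote within the trial,
  so its *k*-only median sits near 6 % — an information limit of the
  design, not an optimiser artefact; the pooled criterion is the one
  asserted.

## Temperature processing and the exothermic index

Sub-daily records are averaged into half-open day bins $[d, d+1)$, day 0
being pile construction. The end of the bio-oxidative phase is the first
day from which $|T_{pile} - T_{amb}| < \delta$ (default 2 °C) holds for a
persistence window (default 7 days) — the conventional "close to ambient
without re-heating" rule. The EXI is

$$EXI = \sum_{d=0}^{d_{end}-1} (T_{pile,d} - T_{amb,d})\quad
[\text{cumulated °C}]$$

Negative daily terms are **included by default**; `clip_negative = TRUE`
exists because "exothermic" arguably implies clipping, and the clipped
value is provably $\ge$ the unclipped one. Days with missing readings are
skipped with a warning, never imputed. Which daily reducer (mean, max,
fixed hour) the original index used is unstated; the daily mean is the
default and the choice is configurable upstream of the index.

The published EXI values (1741/1344/1317 cumulated °C for piles B/A/C)
derive from figure-only temperature curves and are not reproducible from
tabulated data; the package instead checks the *ordering* B > A ≈ C on
pile-mimicking synthetic scenarios, across a 20-seed sweep.

## Thermogravimetry: DTG, peaks, and R1/R2

The DTG trace is $-dm/dT$ (%/°C, positive = mass loss), computed by
Savitzky–Golay filtering (`signal::sgolayfilt`; default 15 °C window,
order 2 — configurable because instrument noise varies). Peaks are local
maxima within configurable windows with a minimum height relative to the
trace maximum. Region mass loss is the interpolated mass difference
across region bounds (exactly additive over adjacent regions); DTA peak
areas are trapezoidal integrals above a baseline, by default the straight
line joining the signal at the region bounds, which makes areas exactly
invariant to constant or linear signal drift.

$$R1 = \frac{\text{P2 mass loss}}{\text{P1 mass loss}},\qquad
R2 = \frac{\text{P2 DTA area}}{\text{P1 DTA area}}$$

Default regions are P1 = 250–400 °C (carbohydrate/aliphatic combustion)
and P2 = 400–580 °C (recalcitrant aromatic structures), following the
DTA exotherm windows; the slightly different DTG peak ranges quoted in
the source prose (third peak 450–500 °C) are honoured via configurable
windows, and reports record the windows used. The moisture region
(< 150 °C) is excluded from all indices. Both ratios rise with compost
maturation, which the tests assert on the synthetic maturation sequence.

## FT-IR relative absorbance

Eight diagnostic bands are measured: 2927, 2854, 1640, 1548, 1420, 1384,
1037 and 875 cm⁻¹. (Source texts disagree between 1428 and 1420 cm⁻¹ for
the carboxylate band; the tabulated band set uses 1420, adopted here, and
the ±10 cm⁻¹ search window covers 1428.) A band height is the maximum
intensity within ±10 cm⁻¹ of the nominal position minus a local linear
baseline through two anchor points; the relative absorbance is
$rA_i = 100\,h_i / \sum_j h_j$, so profiles sum to 100 and are invariant
to global intensity scaling. The 1037/1384 ratio tracks the
polysaccharide-to-nitrate band balance.

Baseline anchors default to the **fixed positions** nominal ± 30 cm⁻¹,
with two exceptions: the 1420/1384 doublet shares its inner anchor at the
inter-band valley (1402 cm⁻¹), because a ±30 anchor would sit on the
neighbouring band's flank and over-subtract. Fixed anchors make heights
*exactly* invariant to adding any linear function of wavenumber — a
property the test suite asserts at machine precision. Valley snapping
(`snap_to_valley = TRUE`) is available but off by default, since a snapped
anchor can move when a sloped baseline is added, breaking that exactness.
The original study corrected heights against a baseline chosen in
acquisition software whose algorithm is undocumented; the linear-anchor
rule is this package's own documented choice.

## CPMAS ¹³C NMR region integration

Signal intensity is integrated over the seven standard chemical-shift
regions (carbonyl 210–165, O-aromatic 165–145, aromatic 145–110,
O₂-alkyl 110–95, O-alkyl 95–60, N-alkyl/methoxy 60–45, alkyl 45 to −10
ppm), normalised to 100 %. The Alkyl/O-Alkyl ratio (recalcitrant vs
labile carbon) rises with composting age. An optional constant baseline
offset is estimated as the median over a signal-free window (default
215–230 ppm); negative region integrals are floored at 0 with a warning
before normalisation (this affects only noisy tails). Cross-polarisation
is non-quantitative: spin counting against an external glycine standard
is implemented as the normalised per-mg-C-per-scan intensity ratio
(Cobs, %), reported separately — region percentages are *not*
Cobs-corrected, matching how such tables are conventionally built.
Relaxation-parameter experiments (T₁H, T₁ρH) are not modelled.

## Synthetic-data generators

All generators use Gaussian components — bands, DTG events, exotherms,
NMR region humps — because Gaussians have closed-form integrals, giving
every pipeline stage an exact oracle. Choices worth knowing:

* **Temperature**: double-exponential heating (rise 3 d, decay 30 d)
  scaled by `heating_amplitude × (0.5 + labile_fraction)`, plus
  re-heating spikes after each turning whose size decays as the labile
  pool empties; sinusoidal ambient. Pile B's larger labile fraction
  (grape marc's water-soluble compounds) makes it the most exothermic,
  reproducing the B > A ≈ C ordering. Exact per-day offsets are returned,
  so EXI has a closed-form expected value.
* **OM loss**: the first-order model itself plus Gaussian noise, clipped
  to [0, 100].
* **Thermograms**: mass = 100 − Σ cumulative-Gaussian losses; DTA = Σ
  Gaussian exotherms + optional linear drift. Component widths are chosen
  so ±5σ fits inside the target region, making region truths essentially
  exact. Pile-phase presets hit the published P1/P2 mass losses and DTA
  areas.
* **FT-IR**: Gaussian bands (σ = 6 cm⁻¹, ≈ 14 cm⁻¹ FWHM — typical of
  sharp mid-IR bands such as the 1384 cm⁻¹ nitrate band) on a 4000–400
  cm⁻¹ grid at 2 cm⁻¹.
* **NMR**: one Gaussian per region (σ = width/10) on a −20 to 220 ppm
  grid at 0.2 ppm, scaled to the target percentages.

What the generators deliberately do **not** emulate: Lorentzian/Voigt
band shapes, abscissa jitter, spinning sidebands, multi-step DTG
shoulders within one region, or mechanistic microbial heat balance.
Passing tests therefore demonstrate correctness of the numerical
pipeline under the stated statistical shape of the data, not robustness
to every instrument artefact.

## Pipeline and reproducibility

`run_pipeline()` drives all stages from one YAML config, writes one CSV
per technique table-analogue, a JSON bundle and a run log (package
version and config MD5; no timestamps, so **re-runs on identical inputs
are byte-identical** — asserted in the tests). Stages with missing
config sections are skipped; a failing stage is recorded per stage and
only aborts under `--strict`. All randomness in the generators is
governed by explicit seed arguments, and generator calls restore the
session RNG state.

Problem sizes used by the test-suite and the reproduction script:
thermogram grids of 501 points (150–650 °C at 1 °C), FT-IR grids of 1801
points, NMR grids of 1201 points, kinetic ensembles of 200–500 replicates
at n = 16, and 20-seed ordering sweeps — sizes at which every oracle
comparison is sharp while the whole suite runs in well under a minute.

## Known limitations

* Region/band defaults encode the source study's windows; other feedstocks
  may need different windows (all are configurable).
* The published EXI magnitudes and kinetic fit statistics are not
  reproducible from tabulated data (see above); the package checks
  orderings and recovery on synthetic data instead.
* JCAMP-DX reading covers AFFN (`XYDATA=(X++(Y..Y))`, `XYPOINTS`,
  `PEAK TABLE`) forms only; compressed SQZ/DIF/DUP files are rejected
  with a clear message rather than mis-parsed.
* The spin-count implementation is the normalised-intensity ratio only;
  it does not model relaxation corrections.
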