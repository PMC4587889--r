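# compostom

Multi-technique assessment of organic-matter (OM) biodegradation during
composting.

Compost maturity cannot be judged from any single measurement, and for
some feedstocks — notably winery–distillery wastes, whose polyphenols
co-extract with the humic fraction — the classical humification indices
are actively misleading. `compostom` implements, as one tested R
pipeline, the combination of methods used to follow OM transformation in
such systems:

* **Classical chemical indices** — humification ratio
  `HR = 100·Cext/CT`, humification index `HI = 100·Cha/CT`, percentage of
  humic acids `Pha = 100·Cha/Cext`, polymerisation rate `Cha/Cfa`,
  OM loss from the ash balance
  `100 − 100·[X1(100−X2)]/[X2(100−X1)]`, TOC/TN and WSC/TN ratios, and
  maturity flags (TOC/TN < 20, WSC ≤ 1.7 %, germination index > 50 %).
* **First-order degradation kinetics** — `OM loss(%) = A(1 − e^(−kt))`
  fitted by Levenberg–Marquardt, with F/SEE/R² statistics and parameter
  standard errors.
* **Exothermic index (EXI)** — cumulated daily pile-minus-ambient
  temperature difference over the bio-oxidative phase (cumulated °C),
  with automatic detection of the phase end.
* **Thermal stability indices** — DTG computation and peak detection
  from TG curves; R1 (P2/P1 region mass losses) and R2 (P2/P1 DTA peak
  areas) over the 250–400 °C and 400–580 °C exothermic regions.
* **FT-IR relative absorbance** — baseline-corrected heights of the
  2927, 2854, 1640, 1548, 1420, 1384, 1037 and 875 cm⁻¹ bands,
  normalised to `rA_i = 100·h_i/Σh_j`, and the 1037/1384 ratio.
* **CPMAS ¹³C NMR** — integration over the seven standard chemical-shift
  regions (carbonyl … alkyl), the Alkyl/O-Alkyl recalcitrance ratio, and
  glycine-referenced spin counting (Cobs).
* **Synthetic-data generators** for all five input kinds with exact
  ground truth, and a YAML-driven pipeline (`run_pipeline()`) emitting
  deterministic CSV/JSON reports.

Reference measurements from a three-pile co-composting study of grape
marc / exhausted grape marc with cattle and poultry manures are bundled
(`winery_compost_chemical()`, `_kinetics()`, `_thermal()`, `_ftir()`,
`_nmr()`) and serve as worked examples throughout the tests.

## Worked example

```r
library(compostom)

# Classical indices from the bundled reference table (pile A, day 0)
chem <- winery_compost_chemical()
r <- chem[chem$pile_id == "A" & chem$phase == "initial", ]
fr <- humic_fractions(r$cfa, r$cha)        # Cext = Cfa + Cha = 6.52
percentage_humic_acids(fr$cha, fr$cext)    # 45.71 (published: 45.72)
polymerisation_rate(r$cha, r$cfa)          # 0.84  (published: 0.84)

# First-order kinetics on a synthetic pile-B OM-loss series
sc  <- pile_scenario("B")
g   <- make_om_loss_series(sc, noise_sd = 1, seed = 42)
fit <- fit_first_order(g$times, g$losses)
fit
#> First-order OM-degradation fit (n = 16 )
#>   A (max degradation)  44.44 % (se 0.64)
#>   k (rate constant)    0.0221 per day (se 0.0010)
#>   SEE 1.037  RMS 1.075  F 1180.3  R2 0.994
fit_summary(fit)$significant               # TRUE (P < 0.001)

# Thermal stability indices across a synthetic maturation pair
ti <- thermal_indices(make_pile_thermogram(sc, "initial",  noise_sd = 0.02, seed = 1)$gram)
tm <- thermal_indices(make_pile_thermogram(sc, "maturity", noise_sd = 0.02, seed = 1)$gram)
round(c(ti$r1, tm$r1), 2)                  # 0.39 -> 0.70 (published: 0.39 -> 0.70)
round(c(ti$r2, tm$r2), 2)                  # 0.19 -> 1.61 (published: 0.18 -> 1.60)
```

The recovered kinetic parameters sit on pile B's generating values
(A = 44.2 %, k = 0.0215 d⁻¹), and both stability ratios rise from the
initial to the mature sample — the thermal signature of labile
carbohydrates burning away while recalcitrant aromatic structures
accumulate.

A thin command-line wrapper is installed at
`inst/scripts/compostom` (`compostom run --config cfg.yaml --out results/`;
`compostom generate --kind tg --pile B --seed 1 --out dir/`).

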