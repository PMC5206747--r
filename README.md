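# dropfreeze

Analysis and simulation of immersion-mode drop-freezing assays of
ice-nucleating particles (INPs).

Cold-stage drop-freezing assays are the workhorse for quantifying ice
nuclei (IN) in rainwater, cloud water, aerosol washes and microbial
suspensions: an array of small droplets (typically 5 plates × 47 droplets
of 10 µL) is cooled at a fixed rate and the freezing temperature of every
droplet is recorded. `dropfreeze` is for researchers who run such assays —
or simulate them — and need the standard derived quantities with honest
uncertainty:

* the **cumulative IN concentration spectrum** via the Vali equation,

  K(T) = (1/V) · ln( N₀ / N(T) ),

  where V is the droplet volume, N₀ the droplets tested and N(T) the
  number still unfrozen at temperature T, with exact (Clopper–Pearson)
  binomial confidence bounds transformed through K = −ln(p)/V;
* **onset** (warmest freezing) and **median freezing temperature (T50)**,
  pooled and per plate;
* **paired treatment comparisons** — heat (100 °C / 10 min) and
  filtration (0.22 µm) sensitivity: onset decrease, ΔT50, percent
  treatment-sensitive IN at reference temperatures (−6, −8, −10 °C by
  default), Welch tests and seeded bootstrap tests of ΔT50;
* a **singular-model simulator**: per droplet, each IN class contributes a
  Poisson(cV) number of nuclei with Gaussian characteristic temperatures,
  plus a droplet-intrinsic background for IN-free water; the droplet
  freezes at the warmest draw. Heat and filtration act as class-removal
  operators, and calibrated presets (`ps_control`, `pure_water`,
  `paper_like_rain`) cover the usual reference systems.

Everything is plain-text in and out: droplet CSVs, spectrum/comparison
TSVs, YAML scenario configs.

## Worked example

Simulate a rainwater-like sample and its heat-treated twin, fit the
spectrum, and compare:

```r
library(dropfreeze)

sc    <- in_preset("paper_like_rain")
crude <- simulate_assay(sc, seed = 101)
heat  <- simulate_assay(apply_heat(sc), seed = 102)

fit <- freeze_spectrum(crude)
fit
#> Drop-freezing spectrum fit
#>   sample 'paper_like_rain', treatment 'crude': 235 droplets (235 frozen), V = 0.01 mL
#>   onset -3.6 C, T50 -9.3 C
#>   K(-18.4 C) = 546.0 IN/mL at the coldest defined grid point

predict(fit, c(-6, -8, -10))
#>   temp_c n_unfrozen k_per_ml    ci_low  ci_high censored
#> 1     -6        207 12.68667  8.409096 18.34213    FALSE
#> 2     -8        152 43.57050 34.553265 54.12551    FALSE
#> 3    -10        103 82.48565 68.457786 98.38497    FALSE

compare_treatments(crude, heat, n_resamples = 2000, seed = 103)
#> Treatment comparison: sample 'paper_like_rain', crude vs heat
#>   onset: -3.6 -> -3.2 C (decrease -0.4 C)
#>   T50:   -9.3 -> -9.4 C (delta 0.0 C)
#>   at -6 C: K 12.7 -> 5.7 IN/mL, 55% sensitive
#>   at -8 C: K 43.6 -> 41.0 IN/mL, 6% sensitive
#>   at -10 C: K 82.5 -> 84.4 IN/mL, 0% sensitive
#>   delta-T50 = 0.01 C (control -9.34, treated -9.35)
#>   Welch t = 0.251, p = 0.8019; bootstrap p = 0.938 (2000 resamples, seed 103)
```

Reading the output: 12.7 IN mL⁻¹ of the crude sample are active at −6 °C
(95% CI 8.4–18.3); heating removes the warm biological mode, so 55% of the
−6 °C activity is heat-sensitive in this draw (the scenario programs 40%,
and at 235 droplets the share carries ~15–20 points of sampling noise),
while the dominant heat-resistant submicron mode leaves T50 essentially
unchanged (bootstrap p = 0.94). `plot(fit)` draws the frozen-fraction
curve and the log₁₀ spectrum with its confidence band;
`comparison_table()` + `write_comparison_tsv()` produce the table across
all samples and treatments of a CSV.

A thin command-line wrapper covers the same pipeline:

```sh
IN_ASSAY=$(Rscript -e 'cat(system.file("exec", "in-assay", package = "dropfreeze"))')
$IN_ASSAY simulate --scenario paper_like_rain --seed 7 -o drops.csv
$IN_ASSAY analyze  --input drops.csv -o out/
$IN_ASSAY compare  --input drops.csv --control crude --seed 7 -o table.tsv
```

## Package layout

* `R/` — assay containers and CSV I/O, curve/spectrum estimators,
  treatment comparison, simulator and presets, pipeline drivers.
* `inst/extdata/scenarios/` — preset scenario YAMLs.
* `inst/exec/in-assay` — command-line dispatcher.
* `vignettes/drop-freezing-assays.Rmd` — the model, conventions,
  uncertainty machinery, simulator calibration and known limitations.
* `tests/testthat/` — unit, property and end-to-end suites (all fixtures
  generated in code).
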