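---
title: "Drop-freezing assay analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drop-freezing assay analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropfreeze)
```

## The measurement and the model

A cold-stage drop-freezing assay distributes a suspension over many small
droplets (by default 5 plates × 47 droplets of 10 µL, i.e. 235 droplets),
cools them at a fixed rate (2 °C min⁻¹ by default), and records the
temperature at which each droplet freezes. `dropfreeze` analyses such data
under the *singular* (time-independent) description of immersion-mode
heterogeneous nucleation: every ice nucleus (IN) has a characteristic
freezing temperature, and a droplet freezes at the warmest characteristic
temperature among the nuclei it contains. Cooling rate is therefore carried
as metadata only; modelling time-dependent (stochastic, ABIFM-style)
nucleation rates is out of scope.

If nuclei are suspended homogeneously, the number per droplet active at or
above temperature $T$ is Poisson with mean $V\,\Lambda(T)$, where $V$ is the
droplet volume and $\Lambda(T)$ the cumulative concentration of IN active at
or above $T$ per unit liquid volume. The probability that a droplet is still
unfrozen at $T$ is then $e^{-V\Lambda(T)}$, which motivates the Vali
estimator implemented in `cumulative_spectrum()`:

$$K(T) \;=\; \frac{1}{V}\,\ln\frac{N_0}{N(T)},$$

with $N_0$ the number of droplets tested and $N(T)$ the number still
unfrozen at $T$. $K(T)$ is the empirical plug-in for $\Lambda(T)$, and the
frozen fraction $f(T) = 1 - N(T)/N_0$ satisfies the identity
$K = -\ln(1-f)/V$ wherever $N(T) \ge 1$.

## Conventions and degenerate inputs

Several small conventions matter for reproducibility; they are fixed
package-wide and tested:

* **Grid.** Curves and spectra are reported on a descending grid from 0 °C
  with step 0.2 °C by default (onsets and T50 values in this field are
  customarily printed at 0.1–0.2 °C resolution); the step is configurable.
  The grid extends to the coldest observed temperature.
* **Closed-above counting.** A droplet observed frozen exactly at a grid
  temperature counts as frozen at that temperature; $N(T)$ counts droplets
  with freezing temperatures strictly below $T$.
* **Censoring.** Droplets that never froze stay in $N(T)$ at every grid
  point. Where $N(T) = 0$ the estimator is *censored*, not infinite: the
  formula is undefined there, `k_per_ml` is `NA`, the spectrum records
  `censored_below`, and only the finite lower confidence bound is kept.
* **Pooling.** The headline spectrum pools droplets across plates
  ($N_0 = 235$ for the default layout); per-plate onsets and T50s are
  reported in `summary()`.
* **Onset** is the warmest grid temperature with at least one frozen
  droplet; undefined (`NA`) for fully censored assays.
* **T50** interpolates linearly in temperature between the grid points
  bracketing the $f = 0.5$ crossing (an exact crossing at a grid point is
  returned as-is); it is undefined when fewer than half the droplets froze.
  Whether published T50 values are interpolated or snapped to the grid is
  often unstated; interpolation was chosen because it is
  translation-equivariant for shifts that are multiples of the grid step
  and converges to the event-list median as the grid refines.
* **Temperatures** are signed °C throughout; there is no internal Kelvin
  conversion.

## Uncertainty

The raw random quantity behind $K$ is the binomial proportion of unfrozen
droplets, so pointwise uncertainty is computed as an exact Clopper–Pearson
interval on $p = N(T)/N_0$ and pushed through the monotone transform
$K = -\ln(p)/V$ (`k_confidence_interval()`). Exact bounds were preferred
over Wald/normal approximations because the interesting parts of a spectrum
are its tails, where $N(T)$ is small and approximations fail. Coverage is
checked by simulation in the test suite (500 assays at a known
concentration; nominal 95% must land in [0.92, 0.98] — exact coverage for
$n = 235$ at the chosen operating point is 0.958, slightly conservative as
is inherent to Clopper–Pearson).

For treatment effects on the median freezing temperature, `compare_t50()`
reports two complementary tests: a Welch two-sample $t$ on per-droplet
freezing temperatures (censored droplets excluded), and a seeded percentile
bootstrap of $\Delta T_{50}$ that resamples droplets with replacement
within each group (default 2000 resamples; a seed is required in the
pipeline drivers). The bootstrap p-value is
$\min(1, 2\min(\Pr^*(\Delta^* \le 0), \Pr^*(\Delta^* \ge 0)))$. Its null
calibration is verified in the tests (rejection rate at $\alpha = 0.05$
within [0.02, 0.09] over 400 same-scenario pairs). Letter-group displays
for multi-treatment figures are deliberately not reproduced — the grouping
procedures behind such figures are rarely specified; Holm-corrected
pairwise Welch tests (`pairwise_t50_tests()`) are provided instead.

Percent treatment-sensitive IN at a reference temperature is
$100\,(K_{ctrl}-K_{treat})/K_{ctrl}$, computed from *cumulative* spectra
(published tables report cumulative totals with the percentage in
parentheses, not differential spectra). Sampling noise can push the raw
value negative; tables clamp to [0, 100] but the raw value is always
retained (`attr(tbl, "pct_raw")`), and the value is undefined where the
control concentration is zero or censored.

## What the simulator emulates

`in_scenario()` draws, per droplet and per IN class, a Poisson($c_i V$)
number of nuclei with Gaussian characteristic temperatures (truncated at
0 °C; the two-parameter family is the simplest that reproduces narrow warm
biological modes, and the distribution is pluggable in principle), plus one
droplet-intrinsic *background* freezing temperature representing the
impurity/homogeneous pathway of IN-free water — by default
$N(-16, 0.8)$ °C truncated to ≤ −10 °C, anchored to the onset of ultra-pure
water near −15 °C. The droplet freezes at the warmest of all draws;
droplets below `min_temp_c` (default −25 °C) are censored. Treatment
operators act on scenarios: `apply_heat()` removes heat-sensitive classes
entirely (matching the complete elimination of warm activity seen when INA
bacteria are heated to 100 °C; no partial-attenuation knob in this
version), and `apply_filtration()` is a sharp size cutoff at the pore
diameter (default 220 nm; no retention-efficiency curve). Simulated
freezing temperatures are recorded to 0.001 °C — much finer than the
reporting grid — so that CSV round trips are exact without the recording
grain interacting with the closed-above counting convention.

The closed-form truth the estimator targets is
$\Lambda(T) = \sum_i c_i S_i(T)$ (`expected_spectrum()`), with $S_i$ the
upper-tail probability of class $i$'s temperature distribution; the
background is deliberately *not* part of $\Lambda$, since it is not a
suspended nucleus. The expected frozen fraction including background is
$f(T) = 1 - e^{-V\Lambda(T)}\Pr(T_{bg} < T)$
(`expected_frozen_fraction()`), which the simulator must match within
binomial error — a property tested at 10,000 droplets.

### Presets

Three calibrated presets ship with the package (also as YAML under
`inst/extdata/scenarios/`). Their concentrations are illustrative: real
rainwater compositions are unknown, so presets are tuned only to reproduce
reported onset/T50 ranges, and documented as such.

* `ps_control` — a dense INA-bacteria suspension: one narrow warm mode
  ($c = 600$ mL⁻¹, $\mu = -4.6$, $\sigma = 0.4$ °C, heat-sensitive,
  1000 nm). Calibrated so that a 235-droplet onset falls in
  $[-3.6, -2.8]$ °C in ≳99% of runs and freezing completes near −5.6 °C;
  after heat, all activity warmer than −10 °C vanishes (only background
  remains, which is truncated below −10 °C).
* `pure_water` — background only. Here the background is tightened to
  $N(-16.2, 0.5)$ °C rather than the generic default: with the default
  spread the warmest of 235 draws sits near −13.9 °C, which is warmer than
  ultra-pure water onsets reported for this droplet count; the tightened
  preset puts the onset near −15 °C and below −14 °C in ≳99% of runs. The
  generic scenario default is left untouched.
* `paper_like_rain` — a minor warm biological mode
  ($c = 7.4$ mL⁻¹, $\mu=-5.5$, $\sigma=1.2$, heat-sensitive, 1000 nm) over
  a dominant heat-resistant submicron mode
  ($c = 105$ mL⁻¹, $\mu=-8.8$, $\sigma=1.9$, 110 nm). By construction the
  heat-sensitive share of $\Lambda(-6\,°C)$ is 40.0%, crude T50 is
  −9.23 °C and filtrate T50 −9.58 °C in closed form. One known departure
  from field data: because the heat-resistant mode must simultaneously
  carry 60% of the −6 °C activity and keep the filtrate median below
  −9 °C, the filtration shift in T50 (~0.3 °C) is smaller than the
  1.5–4 °C shifts typical of real rain samples; the preset prioritises the
  calibrated shares and medians.

### What passing simulation tests does not show

The generator draws independent, identically distributed droplets from
smooth Gaussian mixtures. Real assays violate this in ways the tests
cannot probe: plate-to-plate temperature gradients, droplet-volume
variation, aerosol contamination during plating, non-Gaussian and
multi-modal site densities, partial (rather than all-or-none) heat
attenuation, and filter breakthrough. Passing the recovery and calibration
suites therefore validates the *estimators and their uncertainty
machinery under the stated model*, not the field accuracy of any
particular spectrum.

## Numerical choices

* Floating-point slack of $10^{-9}$ °C when mapping events onto grid
  temperatures (so an event recorded at −3.0 °C is frozen at the −3.0 °C
  grid point regardless of representation error).
* The spectrum identity $K = -\ln(1-f)/V$ is enforced to $10^{-9}$ in
  tests over randomized curves.
* Truncated-normal draws use inverse-CDF sampling, which keeps
  `simulate_assay()` deterministic given a seed with a single RNG stream;
  identical scenario + seed yields a byte-identical assay.
* Problem sizes in the test suite were chosen so statistical checks are
  decisively powered while the whole suite stays quick: 1000 random curves
  for the identity, 10,000-droplet assays for consistency/recovery checks
  (sampling sd of $\hat K$ ≤ 2% in the checked window), 200 runs for
  onset-range checks, 500 simulations for CI coverage, and 400 pairs ×
  500 resamples for bootstrap calibration.
* Degenerate inputs: empty assays error; fully censored assays give
  `NA` onset/T50 and an all-zero spectrum; constant-temperature groups in
  `compare_t50()` are handled without a division by zero in the Welch
  statistic.

## Scope and limitations

The package covers assay analysis, treatment comparison, simulation and
the thin command-line pipeline. It does not model time-dependent
nucleation, INAS surface-site densities, aerosol/cloud microphysics, or
any sequence-based identification of the organisms involved; spectra from
volumes other than the dispensed droplet volume (e.g. per-litre-of-air
normalisations) are left to the caller. Percent-sensitive values inherit
the large relative noise of $K$ at warm temperatures where few droplets
have frozen; at the standard 235-droplet size, shares at −6 °C carry a
sampling sd of roughly 15–20 percentage points, which is why recovery
checks are run at 10,000 droplets.
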