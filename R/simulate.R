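# Singular-model droplet-freezing simulator.
#
# Each droplet carries, for every IN class i, a Poisson(c_i * V) number of
# ice nuclei whose characteristic freezing temperatures are drawn from the
# class distribution (Gaussian truncated at 0 degC), plus one
# droplet-intrinsic "background" freezing temperature (impurity/homogeneous
# pathway of IN-free water). Under the singular hypothesis the droplet
# freezes at the warmest of all these temperatures; cooling rate is carried
# as metadata only.

# Draws from N(mean, sd) truncated above at `upper` (inverse-CDF method;
# sd = 0 gives the point mass at min(mean, upper)).
.rtnorm <- function(n, mean, sd, upper) {
  if (sd == 0) return(rep(min(mean, upper), n))
  p_up <- pnorm(upper, mean, sd)
  qnorm(runif(n) * p_up, mean, sd)
}

#' Define an ice-nucleus population for simulation
#'
#' One class of ice nuclei: a concentration in suspension, a Gaussian
#' distribution of characteristic freezing temperatures (truncated at
#' 0 degC), a heat-lability flag (destroyed by 100 degC / 10 min) and a
#' particle size governing retention on a filtration membrane.
#'
#' @param label Class label.
#' @param concentration_per_ml Number concentration of IN per mL (>= 0).
#' @param temp_mean_c Mean characteristic freezing temperature (degrees C).
#' @param temp_sd_c Spread of characteristic temperatures (degrees C, >= 0).
#' @param heat_sensitive Logical: removed entirely by [apply_heat()]
#'   (proteinaceous/biological nucleators). Default `FALSE`.
#' @param size_nm Particle size in nm (> 0); classes larger than the filter
#'   cutoff are removed by [apply_filtration()].
#' @return An object of class `"in_class"`.
#' @export
in_class <- function(label, concentration_per_ml, temp_mean_c, temp_sd_c,
                     heat_sensitive = FALSE, size_nm = 1000) {
  stopifnot(is.numeric(concentration_per_ml), concentration_per_ml >= 0,
            is.numeric(temp_sd_c), temp_sd_c >= 0,
            is.numeric(size_nm), size_nm > 0)
  structure(list(label = as.character(label),
                 concentration_per_ml = as.numeric(concentration_per_ml),
                 temp_mean_c = as.numeric(temp_mean_c),
                 temp_sd_c = as.numeric(temp_sd_c),
                 heat_sensitive = isTRUE(heat_sensitive),
                 size_nm = as.numeric(size_nm)),
            class = "in_class")
}

#' @export
print.in_class <- function(x, ...) {
  cat(sprintf(
    "IN class '%s': %g IN/mL, T ~ N(%g, %g) C, %s, %g nm\n",
    x$label, x$concentration_per_ml, x$temp_mean_c, x$temp_sd_c,
    if (x$heat_sensitive) "heat-sensitive" else "heat-resistant", x$size_nm))
  invisible(x)
}

#' Define a drop-freezing simulation scenario
#'
#' A full synthetic experiment: a mixture of IN populations ([in_class()]),
#' the assay geometry, and the droplet-intrinsic background freezing that
#' IN-free water exhibits on the cold stage.
#'
#' @param classes List of [in_class()] objects (possibly empty).
#' @param label Scenario label. Default `"scenario"`.
#' @param treatment Treatment label attached to simulated assays (one of
#'   `"crude"`, `"heat"`, `"filtrate"`, `"heat_filtrate"`, `"control"`).
#' @param droplet_volume_ml Droplet volume in mL. Default `0.01` (10 uL).
#' @param n_plates Number of plate replicates. Default `5`.
#' @param droplets_per_plate Droplets per plate. Default `47` (so the
#'   default experiment tests 235 droplets).
#' @param background `NULL` for no intrinsic freezing, or a list with
#'   `temp_mean_c`, `temp_sd_c` and `max_temp_c` (Gaussian truncated above
#'   at `max_temp_c`). Default `N(-16, 0.8)` truncated to <= -10 degC,
#'   anchored to the onset of ultra-pure water.
#' @param min_temp_c Temperature at which the run stops; droplets still
#'   unfrozen there are censored. Default `-25`.
#' @return An object of class `"in_scenario"`.
#' @seealso [simulate_assay()], [expected_spectrum()], [apply_heat()],
#'   [apply_filtration()], [in_preset()]
#' @export
in_scenario <- function(classes = list(), label = "scenario",
                        treatment = "crude",
                        droplet_volume_ml = 0.01,
                        n_plates = 5, droplets_per_plate = 47,
                        background = list(temp_mean_c = -16,
                                          temp_sd_c = 0.8,
                                          max_temp_c = -10),
                        min_temp_c = -25) {
  if (inherits(classes, "in_class")) classes <- list(classes)
  stopifnot(all(vapply(classes, inherits, logical(1), "in_class")),
            droplet_volume_ml > 0, n_plates >= 1, droplets_per_plate >= 1)
  treatment <- match.arg(treatment,
                         c("crude", "heat", "filtrate", "heat_filtrate", "control"))
  if (!is.null(background)) {
    stopifnot(is.list(background),
              all(c("temp_mean_c", "temp_sd_c") %in% names(background)))
    background <- list(temp_mean_c = as.numeric(background$temp_mean_c),
                       temp_sd_c = as.numeric(background$temp_sd_c),
                       max_temp_c = as.numeric(background$max_temp_c %||% -10))
    if (min_temp_c > background$temp_mean_c - 3 * background$temp_sd_c)
      warning("min_temp_c is above background mean - 3 sd; ",
              "many droplets may be censored")
  }
  structure(list(label = as.character(label), treatment = treatment,
                 classes = classes,
                 droplet_volume_ml = as.numeric(droplet_volume_ml),
                 n_plates = as.integer(n_plates),
                 droplets_per_plate = as.integer(droplets_per_plate),
                 background = background,
                 min_temp_c = as.numeric(min_temp_c)),
            class = "in_scenario")
}

#' @export
print.in_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s): %d x %d droplets of %g mL, censored below %g C\n",
              x$label, x$treatment, x$n_plates, x$droplets_per_plate,
              x$droplet_volume_ml, x$min_temp_c))
  if (is.null(x$background)) cat("  no background freezing\n")
  else cat(sprintf("  background N(%g, %g) C truncated <= %g C\n",
                   x$background$temp_mean_c, x$background$temp_sd_c,
                   x$background$max_temp_c))
  for (cl in x$classes) {
    cat("  "); print(cl)
  }
  invisible(x)
}

# Upper-tail probability of one class's characteristic-temperature
# distribution (Gaussian truncated at 0 degC), vectorized over temp_c.
.class_survival <- function(cl, temp_c) {
  if (cl$temp_sd_c == 0) {
    mu <- min(cl$temp_mean_c, 0)
    return(as.numeric(temp_c <= mu))
  }
  f0 <- pnorm(0, cl$temp_mean_c, cl$temp_sd_c)
  pmin(1, pmax(0, (f0 - pnorm(pmin(temp_c, 0), cl$temp_mean_c, cl$temp_sd_c)) / f0))
}

#' Expected cumulative IN spectrum of a scenario
#'
#' The closed-form cumulative active-IN concentration
#' \eqn{\Lambda(T) = \sum_i c_i S_i(T)}, where \eqn{S_i} is the upper-tail
#' probability of class \eqn{i}'s characteristic-temperature distribution.
#' This is the quantity that the Vali estimator \eqn{K(T)} targets;
#' droplet-intrinsic background freezing is not part of it (it is not a
#' suspended nucleus).
#'
#' @param scenario An [in_scenario()].
#' @param temp_c Temperatures (degrees C); vectorized.
#' @return Numeric vector of expected concentrations (IN per mL),
#'   non-negative and non-decreasing as temperature decreases.
#' @export
expected_spectrum <- function(scenario, temp_c) {
  stopifnot(inherits(scenario, "in_scenario"))
  out <- numeric(length(temp_c))
  for (cl in scenario$classes)
    out <- out + cl$concentration_per_ml * .class_survival(cl, temp_c)
  out
}

#' Expected frozen fraction of a scenario
#'
#' Closed-form frozen fraction at temperature `T`, combining Poisson IN
#' loading, \eqn{1 - e^{-V\Lambda(T)}}, with the droplet-intrinsic
#' background pathway:
#' \eqn{f(T) = 1 - e^{-V\Lambda(T)} P(T_{bg} < T)}.
#'
#' @inheritParams expected_spectrum
#' @return Numeric vector of frozen fractions in \[0, 1\].
#' @export
expected_frozen_fraction <- function(scenario, temp_c) {
  lam <- expected_spectrum(scenario, temp_c)
  p_unfrozen <- exp(-scenario$droplet_volume_ml * lam)
  bg <- scenario$background
  if (!is.null(bg)) {
    if (bg$temp_sd_c == 0) {
      s_bg <- as.numeric(temp_c <= min(bg$temp_mean_c, bg$max_temp_c))
    } else {
      f_up <- pnorm(bg$max_temp_c, bg$temp_mean_c, bg$temp_sd_c)
      s_bg <- (f_up - pnorm(pmin(temp_c, bg$max_temp_c),
                            bg$temp_mean_c, bg$temp_sd_c)) / f_up
    }
    p_unfrozen <- p_unfrozen * (1 - s_bg)
  }
  1 - p_unfrozen
}

#' Simulate a drop-freezing assay from a scenario
#'
#' For each droplet, draws a Poisson(\eqn{c_i V}) number of nuclei from
#' every class, a characteristic temperature for each nucleus, and one
#' background freezing temperature; under the singular model the droplet
#' freezes at the warmest of these. Droplets whose warmest temperature lies
#' below the scenario's `min_temp_c` (or that contain no nucleus and have no
#' background) are censored at `min_temp_c`. Simulated freezing
#' temperatures are recorded to 0.001 degC (finer than the reporting grid,
#' so discretization onto the grid is unaffected).
#'
#' @param scenario An [in_scenario()].
#' @param seed Integer seed; identical scenario + seed gives an identical
#'   assay. `NULL` uses (and advances) the current RNG state.
#' @return A [droplet_assay()] with the scenario's treatment label.
#' @examples
#' a <- simulate_assay(in_preset("ps_control"), seed = 1)
#' freeze_spectrum(a)
#' @export
simulate_assay <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "in_scenario"))
  with_seed(seed, {
    n <- scenario$n_plates * scenario$droplets_per_plate
    v <- scenario$droplet_volume_ml
    tmax <- rep(-Inf, n)
    for (cl in scenario$classes) {
      lam <- cl$concentration_per_ml * v
      if (lam <= 0) next
      cnt <- rpois(n, lam)
      m <- sum(cnt)
      if (m == 0) next
      draws <- .rtnorm(m, cl$temp_mean_c, cl$temp_sd_c, upper = 0)
      grp <- rep.int(seq_len(n), cnt)
      agg <- tapply(draws, grp, max)
      idx <- as.integer(names(agg))
      tmax[idx] <- pmax(tmax[idx], as.numeric(agg))
    }
    bg <- scenario$background
    if (!is.null(bg))
      tmax <- pmax(tmax, .rtnorm(n, bg$temp_mean_c, bg$temp_sd_c,
                                 upper = bg$max_temp_c))
    censored <- !is.finite(tmax) | tmax < scenario$min_temp_c
    temp <- ifelse(censored, scenario$min_temp_c, round(tmax, 3))
    droplet_assay(
      temp, censored = censored,
      sample_id = scenario$label, treatment = scenario$treatment,
      plate_id = sprintf("P%d", rep(seq_len(scenario$n_plates),
                                    each = scenario$droplets_per_plate)),
      droplet_id = sprintf("D%02d", rep(seq_len(scenario$droplets_per_plate),
                                        times = scenario$n_plates)),
      droplet_volume_ml = v)
  })
}

#' @rdname simulate_assay
#' @param object An [in_scenario()] (for the [simulate()] method).
#' @param nsim Number of assays to simulate.
#' @param ... Unused.
#' @return For `simulate()`: a [droplet_assay()] if `nsim = 1`, otherwise a
#'   list of them (seeds `seed`, `seed + 1`, ... when `seed` is given).
#' @export
simulate.in_scenario <- function(object, nsim = 1, seed = NULL, ...) {
  if (nsim == 1) return(simulate_assay(object, seed))
  lapply(seq_len(nsim), function(i)
    simulate_assay(object, if (is.null(seed)) NULL else seed + i - 1L))
}

#' Heat-treatment operator
#'
#' Models heating to 100 degC for 10 minutes: classes flagged
#' `heat_sensitive` (proteinaceous nucleators) are removed entirely; all
#' other classes and the background are unchanged.
#'
#' @param scenario An [in_scenario()].
#' @return The treated scenario, with its treatment label advanced
#'   (`crude -> heat`, `filtrate -> heat_filtrate`).
#' @export
apply_heat <- function(scenario) {
  stopifnot(inherits(scenario, "in_scenario"))
  scenario$classes <- Filter(function(cl) !cl$heat_sensitive,
                             scenario$classes)
  scenario$treatment <- switch(scenario$treatment,
                               crude = "heat", filtrate = "heat_filtrate",
                               scenario$treatment)
  scenario
}

#' Filtration-treatment operator
#'
#' Models passage through a membrane filter with the given pore size:
#' classes with `size_nm` larger than the cutoff are removed (sharp
#' cutoff); smaller classes and the background are retained.
#'
#' @param scenario An [in_scenario()].
#' @param cutoff_nm Pore diameter in nm. Default `220` (0.22 um membrane).
#' @return The treated scenario, with its treatment label advanced
#'   (`crude -> filtrate`, `heat -> heat_filtrate`).
#' @export
apply_filtration <- function(scenario, cutoff_nm = 220) {
  stopifnot(inherits(scenario, "in_scenario"), cutoff_nm > 0)
  scenario$classes <- Filter(function(cl) cl$size_nm <= cutoff_nm,
                             scenario$classes)
  scenario$treatment <- switch(scenario$treatment,
                               crude = "filtrate", heat = "heat_filtrate",
                               scenario$treatment)
  scenario
}
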