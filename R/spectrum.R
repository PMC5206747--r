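# Cumulative IN concentration spectra (Vali equation) with exact binomial
# confidence bounds.

# Clopper-Pearson bounds on the unfrozen proportion p = N(T)/N0, pushed
# through the monotone decreasing transform K = -ln(p)/V. Vectorized over
# n_unfrozen.
.k_ci <- function(n_unfrozen, n_total, volume_ml, level) {
  a <- (1 - level) / 2
  p_low <- ifelse(n_unfrozen == 0, 0,
                  qbeta(a, n_unfrozen, n_total - n_unfrozen + 1))
  p_high <- ifelse(n_unfrozen == n_total, 1,
                   qbeta(1 - a, n_unfrozen + 1, n_total - n_unfrozen))
  list(low = -log(p_high) / volume_ml,
       high = ifelse(p_low == 0, Inf, -log(p_low) / volume_ml))
}

#' Confidence interval for the cumulative IN concentration
#'
#' Exact (Clopper-Pearson) binomial confidence bounds on the unfrozen
#' proportion \eqn{p = N(T)/N_0}, transformed through the Vali equation
#' \eqn{K = -\ln(p)/V}. Because the transform is monotone, the binomial
#' bounds map directly onto bounds for \eqn{K}.
#'
#' @param n_unfrozen Number of unfrozen droplets (0..`n_total`); vectorized.
#' @param n_total Total number of droplets tested.
#' @param volume_ml Droplet volume in mL.
#' @param level Confidence level in (0, 1). Default `0.95`.
#' @return A data frame with columns `k_low` and `k_high` (IN per mL). When
#'   `n_unfrozen = 0` the point estimate is undefined and the upper bound is
#'   `Inf` (the spectrum is censored there); the lower bound stays finite.
#'   When `n_unfrozen = n_total` the lower bound is 0.
#' @examples
#' k_confidence_interval(50, 100, 0.01)  # brackets 100*log(2)
#' @export
k_confidence_interval <- function(n_unfrozen, n_total, volume_ml,
                                  level = 0.95) {
  stopifnot(length(n_total) == 1L, n_total >= 1,
            all(n_unfrozen >= 0), all(n_unfrozen <= n_total),
            volume_ml > 0, level > 0, level < 1)
  ci <- .k_ci(n_unfrozen, n_total, volume_ml, level)
  data.frame(k_low = ci$low, k_high = ci$high)
}

#' Cumulative IN concentration spectrum
#'
#' Applies the Vali equation \eqn{K(T) = \ln(N_0/N(T))/V} to a
#' frozen-fraction curve, giving the cumulative concentration of ice nuclei
#' active at or above each grid temperature, per mL of suspension, with
#' exact binomial confidence bounds.
#'
#' @param curve A [build_curve()] result.
#' @param volume_ml Droplet volume in mL (> 0).
#' @param conf_level Confidence level for the pointwise bounds. Default 0.95.
#' @return An object of class `"in_spectrum"`: a list with `temp_c`,
#'   `k_per_ml`, `ci_low`, `ci_high`, `n_unfrozen`, `n_total`, `censored`
#'   (logical, `TRUE` where \eqn{N(T)=0} so \eqn{K} is undefined),
#'   `censored_below` (the warmest grid temperature with \eqn{N(T)=0}, or
#'   `NA`), `volume_ml` and `conf_level`.
#' @details Where every droplet has frozen (\eqn{N(T) = 0}) the estimator is
#'   undefined rather than infinite: `k_per_ml` and the upper bound are `NA`
#'   there and the point is flagged in `censored`; the spectrum only bounds
#'   the IN concentration from below at such temperatures.
#' @examples
#' sp <- cumulative_spectrum(build_curve(droplet_assay(c(-3, -5))), 0.01)
#' sp$k_per_ml
#' @export
cumulative_spectrum <- function(curve, volume_ml, conf_level = 0.95) {
  stopifnot(inherits(curve, "freezing_curve"))
  if (!is.numeric(volume_ml) || length(volume_ml) != 1L || volume_ml <= 0)
    stop("volume_ml must be a single positive number")
  n0 <- curve$n_total
  if (n0 == 0L) stop("no droplets")
  n <- curve$n_unfrozen
  defined <- n >= 1L
  k <- rep(NA_real_, length(n))
  k[defined] <- log(n0 / n[defined]) / volume_ml
  ci <- .k_ci(n, n0, volume_ml, conf_level)
  ci$high[!defined] <- NA_real_
  j <- match(TRUE, !defined)
  structure(
    list(temp_c = curve$temp_c, k_per_ml = k,
         ci_low = ci$low, ci_high = ci$high,
         n_unfrozen = n, n_total = n0, censored = !defined,
         censored_below = if (is.na(j)) NA_real_ else curve$temp_c[j],
         volume_ml = volume_ml, conf_level = conf_level),
    class = "in_spectrum")
}

#' @export
print.in_spectrum <- function(x, ...) {
  ok <- !x$censored
  cat(sprintf("Cumulative IN spectrum: %d droplets, V = %g mL\n",
              x$n_total, x$volume_ml))
  if (any(ok))
    cat(sprintf("  K from %.3g to %.3g IN/mL over %g to %g C\n",
                min(x$k_per_ml[ok]), max(x$k_per_ml[ok]),
                max(x$temp_c[ok]), min(x$temp_c[ok])))
  if (!is.na(x$censored_below))
    cat(sprintf("  all droplets frozen at %g C and below (K undefined)\n",
                x$censored_below))
  invisible(x)
}

#' Fit the drop-freezing spectrum of an assay
#'
#' The central fitting function of the package: turns a [droplet_assay()]
#' into its frozen-fraction curve, cumulative IN spectrum (Vali equation
#' with exact binomial confidence bounds), onset freezing temperature and
#' median freezing temperature (T50), pooled across plates and per plate.
#'
#' @param assay A [droplet_assay()].
#' @param grid_step Reporting grid spacing in degrees C. Default `0.2`,
#'   matching the resolution at which onsets and T50 values are usually
#'   reported for 2 C/min cold-stage runs.
#' @param conf_level Confidence level for the spectrum bounds. Default 0.95.
#' @return An object of class `"freeze_spectrum"` with components
#'   `sample_id`, `treatment`, `volume_ml`, `curve` (a
#'   `"freezing_curve"`), `spectrum` (an `"in_spectrum"`), `onset_c`,
#'   `t50_c`, `n_total`, `n_frozen`, `plates` (per-plate data frame with
#'   onsets and T50s) and `records`.
#'   Methods: [print()], [summary()], [coef()] (onset and T50),
#'   [predict()] (K at arbitrary temperatures), [plot()] and
#'   [as.data.frame()] (the spectrum table).
#' @details The headline spectrum pools droplets across plates (for the
#'   standard 5 x 47 layout, \eqn{N_0 = 235}); per-plate curves are
#'   summarized in `$plates`. Onset or T50 are `NA` when undefined (no
#'   events, or fewer than half the droplets frozen).
#' @examples
#' a <- droplet_assay(runif(100, -9, -4), sample_id = "demo")
#' fit <- freeze_spectrum(a)
#' coef(fit)
#' predict(fit, temp_c = c(-6, -8))
#' @export
freeze_spectrum <- function(assay, grid_step = 0.2, conf_level = 0.95) {
  stopifnot(inherits(assay, "droplet_assay"))
  curve <- build_curve(assay, grid_step)
  spec <- cumulative_spectrum(curve, assay$droplet_volume_ml, conf_level)
  r <- assay$records
  plates <- lapply(split(seq_len(nrow(r)), r$plate_id), function(i) {
    sub <- droplet_assay(r$freeze_temp_c[i], censored = r$censored[i],
                         sample_id = assay$sample_id,
                         treatment = assay$treatment,
                         plate_id = r$plate_id[i], droplet_id = r$droplet_id[i],
                         droplet_volume_ml = assay$droplet_volume_ml,
                         cooling_rate_c_min = assay$cooling_rate_c_min)
    cu <- build_curve(sub, grid_step)
    data.frame(plate_id = r$plate_id[i[1L]], n = length(i),
               n_frozen = sum(!r$censored[i]),
               onset_c = onset_temperature(cu),
               t50_c = median_freezing_temperature(cu),
               stringsAsFactors = FALSE)
  })
  plates <- do.call(rbind, c(plates, list(make.row.names = FALSE)))
  structure(
    list(sample_id = assay$sample_id, treatment = assay$treatment,
         volume_ml = assay$droplet_volume_ml,
         curve = curve, spectrum = spec,
         onset_c = onset_temperature(curve),
         t50_c = median_freezing_temperature(curve),
         n_total = curve$n_total, n_frozen = sum(!r$censored),
         plates = plates, records = r,
         grid_step = grid_step, conf_level = conf_level),
    class = "freeze_spectrum")
}

#' @export
print.freeze_spectrum <- function(x, ...) {
  cat("Drop-freezing spectrum fit\n")
  cat(sprintf("  sample '%s', treatment '%s': %d droplets (%d frozen), V = %g mL\n",
              x$sample_id, x$treatment, x$n_total, x$n_frozen, x$volume_ml))
  cat(sprintf("  onset %s C, T50 %s C\n",
              if (is.na(x$onset_c)) "undefined" else sprintf("%.1f", x$onset_c),
              if (is.na(x$t50_c)) "undefined" else sprintf("%.1f", x$t50_c)))
  ok <- !x$spectrum$censored & x$spectrum$k_per_ml > 0
  if (any(ok))
    cat(sprintf("  K(%g C) = %.1f IN/mL at the coldest defined grid point\n",
                min(x$spectrum$temp_c[ok]),
                x$spectrum$k_per_ml[ok][sum(ok)]))
  invisible(x)
}

#' @export
coef.freeze_spectrum <- function(object, ...) {
  c(onset_c = object$onset_c, t50_c = object$t50_c)
}

#' @export
summary.freeze_spectrum <- function(object, ...) {
  structure(list(sample_id = object$sample_id, treatment = object$treatment,
                 n_total = object$n_total, n_frozen = object$n_frozen,
                 onset_c = object$onset_c, t50_c = object$t50_c,
                 plates = object$plates,
                 censored_below = object$spectrum$censored_below),
            class = "summary.freeze_spectrum")
}

#' @export
print.summary.freeze_spectrum <- function(x, ...) {
  cat(sprintf("Assay summary: sample '%s', treatment '%s'\n",
              x$sample_id, x$treatment))
  cat(sprintf("  droplets: %d tested, %d frozen\n", x$n_total, x$n_frozen))
  cat(sprintf("  pooled onset: %s C, pooled T50: %s C\n",
              if (is.na(x$onset_c)) "undefined" else sprintf("%.1f", x$onset_c),
              if (is.na(x$t50_c)) "undefined" else sprintf("%.1f", x$t50_c)))
  cat("  per plate:\n")
  print(x$plates, row.names = FALSE)
  invisible(x)
}

#' Evaluate the cumulative IN spectrum at arbitrary temperatures
#'
#' Computes \eqn{K(T)} (and confidence bounds) directly from the per-droplet
#' records, so `temp_c` need not lie on the reporting grid; at grid
#' temperatures the result agrees with the fitted spectrum.
#'
#' @param object A [freeze_spectrum()] fit.
#' @param temp_c Temperatures (degrees C) at which to evaluate; defaults to
#'   the reporting grid.
#' @param ... Unused.
#' @return A data frame with `temp_c`, `n_unfrozen`, `k_per_ml`, `ci_low`,
#'   `ci_high`, `censored`.
#' @export
predict.freeze_spectrum <- function(object, temp_c = NULL, ...) {
  if (is.null(temp_c)) temp_c <- object$curve$temp_c
  ev <- object$records$freeze_temp_c[!object$records$censored]
  n0 <- object$n_total
  n_unfrozen <- vapply(temp_c,
                       function(t) n0 - sum(ev >= t - .GRID_EPS), numeric(1))
  k <- ifelse(n_unfrozen >= 1, log(n0 / n_unfrozen) / object$volume_ml,
              NA_real_)
  ci <- .k_ci(n_unfrozen, n0, object$volume_ml, object$conf_level)
  ci$high[n_unfrozen == 0] <- NA_real_
  data.frame(temp_c = temp_c, n_unfrozen = n_unfrozen, k_per_ml = k,
             ci_low = ci$low, ci_high = ci$high,
             censored = n_unfrozen == 0)
}

#' @export
as.data.frame.freeze_spectrum <- function(x, ...) {
  s <- x$spectrum
  data.frame(temp_c = s$temp_c, k_per_ml = s$k_per_ml,
             ci_low = s$ci_low, ci_high = s$ci_high,
             n_unfrozen = s$n_unfrozen, n_total = s$n_total,
             censored = as.integer(s$censored))
}

#' Plot a drop-freezing spectrum fit
#'
#' Base-graphics display of the frozen-fraction curve and/or the cumulative
#' IN spectrum (log10 scale with pointwise confidence band).
#'
#' @param x A [freeze_spectrum()] fit.
#' @param what `"spectrum"`, `"curve"` or `"both"` (default).
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.freeze_spectrum <- function(x, what = c("both", "spectrum", "curve"),
                                 ...) {
  what <- match.arg(what)
  if (what == "both") {
    op <- par(mfrow = c(1, 2))
    on.exit(par(op))
  }
  if (what %in% c("both", "curve")) {
    plot(x$curve$temp_c, x$curve$frozen_fraction, type = "s",
         xlim = rev(range(x$curve$temp_c)),
         xlab = "Temperature (°C)", ylab = "Frozen fraction f(T)",
         main = sprintf("%s / %s", x$sample_id, x$treatment), ...)
    abline(h = 0.5, lty = 3)
    if (!is.na(x$t50_c)) abline(v = x$t50_c, lty = 2)
  }
  if (what %in% c("both", "spectrum")) {
    s <- x$spectrum
    ok <- !s$censored & s$k_per_ml > 0
    plot(s$temp_c[ok], log10(s$k_per_ml[ok]), type = "b", pch = 16,
         xlim = rev(range(s$temp_c)),
         xlab = "Temperature (°C)",
         ylab = expression(log[10] ~ "K(T) (IN mL"^-1 * ")"),
         main = "Cumulative IN spectrum", ...)
    lo <- s$ci_low[ok]
    segments(s$temp_c[ok], ifelse(lo > 0, log10(lo), par("usr")[3]),
             s$temp_c[ok], log10(s$ci_high[ok]), col = "grey50")
  }
  invisible(x)
}

#' Write a cumulative IN spectrum as TSV
#'
#' Writes the spectrum table with columns
#' `temp_c,k_per_ml,ci_low,ci_high,n_unfrozen,n_total,censored`.
#' Temperatures and concentrations are printed to 1 decimal place; grid
#' points where all droplets are frozen carry `censored = 1` with empty
#' `k_per_ml`/`ci_high`.
#'
#' @param x A [freeze_spectrum()] fit or an `"in_spectrum"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(x, path) {
  if (inherits(x, "freeze_spectrum")) x <- x$spectrum
  stopifnot(inherits(x, "in_spectrum"))
  fmt <- function(v) ifelse(is.na(v), "",
                            ifelse(is.infinite(v), "Inf", sprintf("%.1f", v)))
  d <- data.frame(temp_c = sprintf("%.1f", x$temp_c),
                  k_per_ml = fmt(x$k_per_ml),
                  ci_low = fmt(x$ci_low), ci_high = fmt(x$ci_high),
                  n_unfrozen = x$n_unfrozen, n_total = x$n_total,
                  censored = as.integer(x$censored))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
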