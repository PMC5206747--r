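# Frozen-fraction curves on the reporting temperature grid.
#
# Conventions (all shared with the spectrum code):
#  * the grid descends from 0 degC in steps of `grid_step` down to the
#    coldest observed temperature (event or censoring point);
#  * a droplet observed frozen exactly at a grid temperature counts as
#    frozen at that temperature (closed-above);
#  * censored droplets count as unfrozen at every grid point.

# Map temperatures onto grid indices: index k corresponds to grid
# temperature -k*step; a droplet with index k is frozen at grid point j
# iff k <= j.
.grid_index <- function(temp_c, step) {
  pmax(0L, as.integer(ceiling(-temp_c / step - .GRID_EPS)))
}

#' Build a frozen-fraction curve from an assay
#'
#' Discretizes the per-droplet freezing events of a [droplet_assay()] onto a
#' descending temperature grid and counts, at each grid temperature `T`, the
#' droplets still unfrozen (`n_unfrozen`, the \eqn{N(T)} of the Vali
#' equation) and the frozen fraction \eqn{f(T) = 1 - N(T)/N_0}.
#'
#' @param assay A [droplet_assay()].
#' @param grid_step Grid spacing in degrees C (> 0). Default `0.2`.
#' @return An object of class `"freezing_curve"`: a list with `temp_c`
#'   (descending grid), `n_total`, `n_unfrozen`, `frozen_fraction` and
#'   `grid_step`.
#' @details The grid spans from 0 degC down to the coldest observed
#'   temperature. `n_unfrozen` at a grid point counts droplets whose
#'   freezing temperature lies strictly below that temperature, plus all
#'   censored droplets; it is non-increasing as temperature decreases.
#' @seealso [cumulative_spectrum()], [onset_temperature()],
#'   [median_freezing_temperature()]
#' @examples
#' cu <- build_curve(droplet_assay(c(-3, -5)))
#' range(cu$frozen_fraction)
#' @export
build_curve <- function(assay, grid_step = 0.2) {
  stopifnot(inherits(assay, "droplet_assay"))
  if (!is.numeric(grid_step) || length(grid_step) != 1L || grid_step <= 0)
    stop("grid_step must be a single positive number")
  r <- assay$records
  n_total <- nrow(r)
  if (n_total < 1L) stop("no droplets")
  coldest <- min(r$freeze_temp_c)
  k_max <- .grid_index(coldest, grid_step)
  grid <- -(0:k_max) * grid_step
  kidx <- .grid_index(r$freeze_temp_c[!r$censored], grid_step)
  n_frozen <- cumsum(tabulate(kidx + 1L, nbins = k_max + 1L))
  structure(
    list(temp_c = grid,
         n_total = n_total,
         n_unfrozen = n_total - n_frozen,
         frozen_fraction = n_frozen / n_total,
         grid_step = grid_step),
    class = "freezing_curve")
}

#' @export
print.freezing_curve <- function(x, ...) {
  cat(sprintf(
    "Frozen-fraction curve: %d droplets, grid %g C from %g to %g C, f in [%g, %g]\n",
    x$n_total, x$grid_step, max(x$temp_c), min(x$temp_c),
    min(x$frozen_fraction), max(x$frozen_fraction)))
  invisible(x)
}

#' Onset freezing temperature
#'
#' The warmest grid temperature at which at least one droplet is frozen.
#'
#' @param curve A [build_curve()] result.
#' @return Onset temperature in degrees C, or `NA_real_` if no droplet froze
#'   (fully censored assay).
#' @export
onset_temperature <- function(curve) {
  stopifnot(inherits(curve, "freezing_curve"))
  j <- match(TRUE, curve$frozen_fraction > 0)
  if (is.na(j)) NA_real_ else curve$temp_c[j]
}

# Shared T50 kernel: cumulative frozen counts on the grid -> interpolated
# median freezing temperature (NA if f never reaches 0.5).
.t50_from_counts <- function(n_frozen, n_total, step) {
  f <- n_frozen / n_total
  j <- match(TRUE, f >= 0.5)
  if (is.na(j)) return(NA_real_)
  t_j <- -(j - 1L) * step
  if (j == 1L || abs(f[j] - 0.5) < 1e-12) return(t_j)
  f_prev <- f[j - 1L]
  t_prev <- t_j + step
  t_prev + (0.5 - f_prev) / (f[j] - f_prev) * (t_j - t_prev)
}

#' Median freezing temperature (T50)
#'
#' The temperature at which half of the droplets have frozen, obtained by
#' linear interpolation in temperature between the two grid points that
#' bracket the crossing of \eqn{f(T) = 0.5}; if the frozen fraction equals
#' 0.5 exactly at a grid point, that grid temperature is returned.
#'
#' @param curve A [build_curve()] result.
#' @return T50 in degrees C, or `NA_real_` if the frozen fraction never
#'   reaches 0.5 within the observed range (censored assay).
#' @export
median_freezing_temperature <- function(curve) {
  stopifnot(inherits(curve, "freezing_curve"))
  .t50_from_counts(curve$frozen_fraction * curve$n_total, curve$n_total,
                   curve$grid_step)
}

# T50 of one assay straight from its records (same grid conventions as
# build_curve, without materializing the curve) -- used by the bootstrap.
.t50_assay <- function(assay, grid_step) {
  median_freezing_temperature(build_curve(assay, grid_step))
}

# Bootstrap resamples of T50: droplets are resampled with replacement
# (censored droplets included); censored droplets carry an out-of-grid
# index so they are never counted as frozen.
.boot_t50 <- function(assay, grid_step, n_resamples) {
  r <- assay$records
  n <- nrow(r)
  coldest <- min(r$freeze_temp_c)
  nbins <- .grid_index(coldest, grid_step) + 1L
  kidx <- .grid_index(r$freeze_temp_c, grid_step)
  kidx[r$censored] <- nbins + 1L
  vapply(seq_len(n_resamples), function(b) {
    ks <- kidx[sample.int(n, n, replace = TRUE)]
    .t50_from_counts(cumsum(tabulate(ks + 1L, nbins = nbins)), n, grid_step)
  }, numeric(1))
}
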