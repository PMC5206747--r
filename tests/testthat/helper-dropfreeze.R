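# Shared fixtures: all assays are generated in code.

assay_from_events <- function(temps, censored = FALSE, ...) {
  droplet_assay(temps, censored = censored, ...)
}

# Brute-force recount of a frozen-fraction curve straight from the event
# list (independent of build_curve's tabulate/cumsum path): a droplet is
# frozen at grid temperature T iff its freezing temperature >= T.
recount_curve <- function(temps, censored, grid) {
  ev <- temps[!censored]
  n <- length(temps)
  vapply(grid, function(t) n - sum(ev >= t - 1e-9), numeric(1))
}

# Random assay with a mix of events and censored droplets.
random_assay <- function(n = 50, p_cens = 0.1, tmin = -20, tmax = -0.5) {
  cens <- runif(n) < p_cens
  temps <- round(runif(n, tmin, tmax), 2)
  temps[cens] <- tmin
  droplet_assay(temps, censored = cens)
}
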