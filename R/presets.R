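# Preset scenarios and YAML scenario configs.

.presets <- list(
  # Dense suspension of ice-nucleation-active bacteria (P. syringae-like,
  # 1e8 cells/mL of which a small fraction expresses an active site): a
  # single narrow, warm, heat-sensitive, cell-sized mode. Calibrated so the
  # simulated onset falls near -3 C and droplet freezing is essentially
  # complete by about -5.6 C.
  ps_control = function() in_scenario(
    classes = list(
      in_class("ina_bacteria", concentration_per_ml = 600,
               temp_mean_c = -4.6, temp_sd_c = 0.4,
               heat_sensitive = TRUE, size_nm = 1000)),
    label = "ps_control"),

  # Ultra-pure water: no suspended IN; only the droplet-intrinsic
  # background pathway, calibrated to an onset near -15 C for 235 droplets.
  pure_water = function() in_scenario(
    classes = list(),
    background = list(temp_mean_c = -16.2, temp_sd_c = 0.5,
                      max_temp_c = -10),
    label = "pure_water"),

  # Grassland-rainwater-like mixture: a minor warm biological mode
  # (heat-sensitive, cell-sized) over a dominant heat-resistant submicron
  # mode, plus the default background. Concentrations are illustrative and
  # calibrated so that the heat-sensitive share of the expected spectrum at
  # -6 C is 40%, crude T50 is near -9.2 C and filtrate T50 near -9.6 C.
  paper_like_rain = function() in_scenario(
    classes = list(
      in_class("biological_cells", concentration_per_ml = 7.4,
               temp_mean_c = -5.5, temp_sd_c = 1.2,
               heat_sensitive = TRUE, size_nm = 1000),
      in_class("submicron_resistant", concentration_per_ml = 105,
               temp_mean_c = -8.8, temp_sd_c = 1.9,
               heat_sensitive = FALSE, size_nm = 110)),
    label = "paper_like_rain")
)

#' Preset simulation scenarios
#'
#' Documented, calibrated scenarios for the three reference systems used
#' throughout the package:
#' \describe{
#'   \item{`ps_control`}{dense suspension of ice-nucleation-active bacteria
#'     (warm, narrow, heat-sensitive mode; simulated onset near -3 degC,
#'     freezing complete near -5.6 degC; heat removes all activity warmer
#'     than -10 degC).}
#'   \item{`pure_water`}{ultra-pure water: background freezing only, onset
#'     near -15 degC for 235 droplets.}
#'   \item{`paper_like_rain`}{rainwater-like mixture of a minor warm
#'     biological mode and a dominant heat-resistant submicron mode; 40% of
#'     the expected spectrum at -6 degC is heat-sensitive.}
#' }
#' Concentrations are illustrative calibrations, not measured compositions.
#' The same scenarios ship as YAML configs under
#' `system.file("extdata", "scenarios", package = "dropfreeze")`.
#'
#' @param name Preset name.
#' @return An [in_scenario()].
#' @examples
#' in_preset("paper_like_rain")
#' @export
in_preset <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% names(.presets))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; available presets: ", paste(names(.presets), collapse = ", "))
  .presets[[name]]()
}

#' Read or write a scenario config (YAML)
#'
#' Scenario configs are plain YAML with keys matching the [in_scenario()]
#' and [in_class()] fields (`label`, `treatment`, `droplet_volume_ml`,
#' `n_plates`, `droplets_per_plate`, `min_temp_c`, `background`, `classes`).
#' `background: ~` disables intrinsic freezing.
#'
#' @param path Path to the YAML file.
#' @return `read_scenario()`: an [in_scenario()]. `write_scenario()`:
#'   `path`, invisibly.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  y <- yaml::read_yaml(path)
  classes <- lapply(y$classes %||% list(), function(cl)
    in_class(label = cl$label %||% "class",
             concentration_per_ml = cl$concentration_per_ml,
             temp_mean_c = cl$temp_mean_c, temp_sd_c = cl$temp_sd_c,
             heat_sensitive = isTRUE(cl$heat_sensitive),
             size_nm = cl$size_nm %||% 1000))
  args <- list(classes = classes, label = y$label %||% "scenario")
  for (f in c("treatment", "droplet_volume_ml", "n_plates",
              "droplets_per_plate", "min_temp_c"))
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  if ("background" %in% names(y)) args["background"] <- list(y$background)
  do.call(in_scenario, args)
}

#' @rdname read_scenario
#' @param scenario An [in_scenario()] to write.
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "in_scenario"))
  y <- list(label = scenario$label, treatment = scenario$treatment,
            droplet_volume_ml = scenario$droplet_volume_ml,
            n_plates = scenario$n_plates,
            droplets_per_plate = scenario$droplets_per_plate,
            min_temp_c = scenario$min_temp_c,
            classes = lapply(scenario$classes, unclass))
  y["background"] <- list(scenario$background)
  yaml::write_yaml(y, path)
  invisible(path)
}
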