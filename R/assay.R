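#' Per-droplet freezing records from a cold-stage assay
#'
#' Container for one drop-freezing assay: the freezing temperature of every
#' droplet (or the last observed temperature for droplets that never froze),
#' together with plate/replicate structure and the assay geometry needed by
#' the Vali spectrum (droplet volume, cooling rate).
#'
#' @param freeze_temp_c Numeric vector of freezing temperatures in degrees
#'   Celsius (all non-censored values must be <= 0). For censored droplets
#'   this is the last temperature at which the droplet was observed unfrozen.
#' @param censored Logical (or 0/1) vector: `TRUE` for droplets that never
#'   froze within the observed range. Default all `FALSE`.
#' @param sample_id Sample identifier.
#' @param treatment One of `"crude"`, `"heat"`, `"filtrate"`,
#'   `"heat_filtrate"`, `"control"`.
#' @param plate_id Plate/replicate identifier per droplet (recycled if
#'   length 1). Default: single plate `"P1"`.
#' @param droplet_id Droplet identifier, unique within a plate. Default:
#'   `"D1"`, `"D2"`, ... within each plate.
#' @param droplet_volume_ml Droplet volume in mL. Default `0.01` (10 uL).
#' @param cooling_rate_c_min Cooling rate in degrees C per minute, carried as
#'   metadata only (the singular analysis is time-independent). Default `2`.
#'
#' @return An object of class `"droplet_assay"`: a list with elements
#'   `sample_id`, `treatment`, `droplet_volume_ml`, `cooling_rate_c_min`
#'   and `records` (a data frame with columns `plate_id`, `droplet_id`,
#'   `freeze_temp_c`, `censored`).
#' @seealso [freeze_spectrum()], [read_droplet_csv()]
#' @examples
#' a <- droplet_assay(c(-3.4, -5.1, -7.8), sample_id = "demo")
#' a
#' @export
droplet_assay <- function(freeze_temp_c, censored = FALSE,
                          sample_id = "sample", treatment = "crude",
                          plate_id = "P1", droplet_id = NULL,
                          droplet_volume_ml = 0.01,
                          cooling_rate_c_min = 2) {
  n <- length(freeze_temp_c)
  if (n < 1L) stop("no droplets")
  treatment <- match.arg(treatment,
                         c("crude", "heat", "filtrate", "heat_filtrate", "control"))
  if (!is.numeric(droplet_volume_ml) || length(droplet_volume_ml) != 1L ||
      is.na(droplet_volume_ml) || droplet_volume_ml <= 0)
    stop("droplet_volume_ml must be a single positive number")
  censored <- rep_len(as.logical(censored), n)
  freeze_temp_c <- as.numeric(freeze_temp_c)
  if (anyNA(freeze_temp_c) || anyNA(censored))
    stop("freeze_temp_c and censored must not contain NA")
  if (any(freeze_temp_c[!censored] > 0))
    stop("non-censored freezing temperatures must be <= 0 degrees C")
  plate_id <- rep_len(as.character(plate_id), n)
  if (is.null(droplet_id)) {
    droplet_id <- as.character(stats::ave(seq_len(n), plate_id, FUN = seq_along))
    droplet_id <- paste0("D", droplet_id)
  } else {
    droplet_id <- rep_len(as.character(droplet_id), n)
  }
  key <- paste(plate_id, droplet_id, sep = "\r")
  if (anyDuplicated(key))
    stop("droplet ids must be unique within a plate")
  structure(
    list(sample_id = as.character(sample_id)[1L],
         treatment = treatment,
         droplet_volume_ml = droplet_volume_ml,
         cooling_rate_c_min = cooling_rate_c_min,
         records = data.frame(plate_id = plate_id, droplet_id = droplet_id,
                              freeze_temp_c = freeze_temp_c,
                              censored = censored,
                              stringsAsFactors = FALSE)),
    class = "droplet_assay")
}

#' @export
print.droplet_assay <- function(x, ...) {
  r <- x$records
  cat("Drop-freezing assay: sample '", x$sample_id, "', treatment '",
      x$treatment, "'\n", sep = "")
  cat(sprintf("  %d droplets on %d plate(s); V = %g mL; cooling %g C/min\n",
              nrow(r), length(unique(r$plate_id)),
              x$droplet_volume_ml, x$cooling_rate_c_min))
  ev <- r$freeze_temp_c[!r$censored]
  if (length(ev))
    cat(sprintf("  %d froze between %.1f and %.1f C; %d censored\n",
                length(ev), max(ev), min(ev), sum(r$censored)))
  else
    cat(sprintf("  no freezing events; %d censored\n", sum(r$censored)))
  invisible(x)
}

.droplet_csv_cols <- c("sample_id", "treatment", "plate_id", "droplet_id",
                       "freeze_temp_c", "censored")

#' Read per-droplet freezing data from CSV
#'
#' Strict reader for the droplet CSV dialect: UTF-8, comma-separated, header
#' `sample_id,treatment,plate_id,droplet_id,freeze_temp_c,censored` with
#' `censored` in \{0, 1\} and temperatures as decimal degrees Celsius.
#' One [droplet_assay()] is built per `(sample_id, treatment)` pair.
#'
#' @param path Path to the CSV file.
#' @param droplet_volume_ml,cooling_rate_c_min Assay geometry applied to all
#'   assays in the file (the dialect carries per-droplet data only).
#' @return Named list of [droplet_assay()] objects; names are
#'   `"<sample_id>.<treatment>"`.
#' @details Malformed rows are reported with their line numbers and abort
#'   the read: missing columns, non-numeric temperatures, positive
#'   non-censored temperatures and `censored` values outside \{0, 1\} are
#'   all errors.
#' @seealso [write_droplet_csv()]
#' @export
read_droplet_csv <- function(path, droplet_volume_ml = 0.01,
                             cooling_rate_c_min = 2) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", check.names = FALSE)
  missing <- setdiff(.droplet_csv_cols, names(d))
  if (length(missing))
    stop("droplet CSV is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(d) == 0L) stop("no droplets")
  line <- seq_len(nrow(d)) + 1L  # header is line 1
  temp <- suppressWarnings(as.numeric(d$freeze_temp_c))
  if (anyNA(temp))
    stop("non-numeric freeze_temp_c at line(s): ",
         paste(line[is.na(temp)], collapse = ", "))
  if (!all(d$censored %in% c("0", "1")))
    stop("censored must be 0 or 1 at line(s): ",
         paste(line[!d$censored %in% c("0", "1")], collapse = ", "))
  cens <- d$censored == "1"
  bad <- !cens & temp > 0
  if (any(bad))
    stop("positive freeze_temp_c for non-censored droplet at line(s): ",
         paste(line[bad], collapse = ", "))
  key <- interaction(d$sample_id, d$treatment, drop = TRUE, lex.order = TRUE)
  out <- lapply(split(seq_len(nrow(d)), key), function(i) {
    droplet_assay(temp[i], censored = cens[i],
                  sample_id = d$sample_id[i[1L]],
                  treatment = d$treatment[i[1L]],
                  plate_id = d$plate_id[i], droplet_id = d$droplet_id[i],
                  droplet_volume_ml = droplet_volume_ml,
                  cooling_rate_c_min = cooling_rate_c_min)
  })
  out[order(names(out))]
}

#' Write per-droplet freezing data to CSV
#'
#' Inverse of [read_droplet_csv()]: writes one or more assays in the droplet
#' CSV dialect. Temperatures are written with full stored precision so a
#' write/read round trip reproduces the assay exactly.
#'
#' @param assays A [droplet_assay()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_droplet_csv <- function(assays, path) {
  if (inherits(assays, "droplet_assay")) assays <- list(assays)
  rows <- lapply(assays, function(a) {
    r <- a$records
    data.frame(sample_id = a$sample_id, treatment = a$treatment,
               plate_id = r$plate_id, droplet_id = r$droplet_id,
               freeze_temp_c = format(r$freeze_temp_c, trim = TRUE,
                                      digits = 10, scientific = FALSE),
               censored = as.integer(r$censored),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Freezing-event temperatures (non-censored) of an assay.
.events <- function(assay) {
  r <- assay$records
  r$freeze_temp_c[!r$censored]
}
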