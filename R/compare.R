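# Paired control/treatment comparison: onset decrease, delta-T50, percent
# treatment-sensitive IN at reference temperatures, Welch and bootstrap
# tests.

#' Decrease of the onset freezing temperature under a treatment
#'
#' @param onset_control,onset_treated Onset temperatures in degrees C
#'   (vectorized). `NA` inputs give `NA`.
#' @return `onset_control - onset_treated` in degrees C: positive when the
#'   treatment lowers (cools) the onset.
#' @examples
#' onset_decrease(-3.2, -5.8)  # 2.6
#' @export
onset_decrease <- function(onset_control, onset_treated) {
  onset_control - onset_treated
}

#' Percent treatment-sensitive IN
#'
#' The proportion of cumulative IN concentration removed by a treatment at
#' a reference temperature: \eqn{100 (K_{control} - K_{treated}) /
#' K_{control}}.
#'
#' @param k_control,k_treated Cumulative IN concentrations (IN per mL) at
#'   the same reference temperature (vectorized).
#' @param clamp Clamp the result into \[0, 100\]? Default `FALSE` (raw
#'   value; sampling noise can make it negative when the treated spectrum
#'   exceeds the control).
#' @return Percentage; `NA` where `k_control` is zero, negative or `NA`.
#' @examples
#' percent_sensitive(100, 25)  # 75
#' @export
percent_sensitive <- function(k_control, k_treated, clamp = FALSE) {
  pct <- ifelse(!is.na(k_control) & k_control > 0,
                100 * (k_control - k_treated) / k_control, NA_real_)
  if (clamp) pct <- pmin(100, pmax(0, pct))
  pct
}

#' Test the shift in median freezing temperature between two assays
#'
#' Two complementary tests of a treatment effect on freezing temperatures:
#' a Welch two-sample t-test on the per-droplet freezing temperatures
#' (censored droplets excluded), and a seeded percentile bootstrap of
#' \eqn{\Delta T_{50} = T_{50}^{control} - T_{50}^{treated}}, resampling
#' droplets with replacement within each group.
#'
#' @param assay_control,assay_treated [droplet_assay()] objects (>= 2
#'   droplets each, T50 defined for both).
#' @param grid_step Grid spacing for T50 computation. Default `0.2`.
#' @param n_resamples Bootstrap resamples. Default `2000`.
#' @param seed Integer seed for the bootstrap (recommended for
#'   reproducibility; `NULL` uses the current RNG state).
#' @return An object of class `"t50_test"`: a list with `delta_t50`,
#'   `statistic` and `p_welch` (Welch test), `p_boot` (two-sided percentile
#'   bootstrap p-value for \eqn{\Delta T_{50} = 0}), `n_resamples`, `seed`.
#' @details The bootstrap p-value is
#'   \eqn{\min(1,\; 2\min(\Pr^*(\Delta^* \le 0), \Pr^*(\Delta^* \ge 0)))},
#'   where \eqn{\Delta^*} are the resampled differences. Resamples in which
#'   a group's T50 is undefined are dropped.
#' @export
compare_t50 <- function(assay_control, assay_treated, grid_step = 0.2,
                        n_resamples = 2000, seed = NULL) {
  stopifnot(inherits(assay_control, "droplet_assay"),
            inherits(assay_treated, "droplet_assay"))
  if (nrow(assay_control$records) < 2L || nrow(assay_treated$records) < 2L)
    stop("compare_t50 needs at least 2 droplets in each group")
  t50_c <- .t50_assay(assay_control, grid_step)
  t50_t <- .t50_assay(assay_treated, grid_step)
  if (is.na(t50_c) || is.na(t50_t))
    stop("T50 is undefined for at least one assay (fewer than half froze)")
  ev_c <- .events(assay_control)
  ev_t <- .events(assay_treated)
  w <- if (stats::sd(ev_c) == 0 && stats::sd(ev_t) == 0) {
    # degenerate: constant temperatures in both groups
    list(statistic = c(t = if (isTRUE(all.equal(mean(ev_c), mean(ev_t)))) 0
                           else Inf),
         p.value = as.numeric(!isTRUE(all.equal(mean(ev_c), mean(ev_t)))))
  } else {
    stats::t.test(ev_c, ev_t)
  }
  boot <- with_seed(seed, {
    d <- .boot_t50(assay_control, grid_step, n_resamples) -
         .boot_t50(assay_treated, grid_step, n_resamples)
    d[!is.na(d)]
  })
  p_boot <- if (length(boot) == 0) NA_real_ else
    min(1, 2 * min(mean(boot <= 0), mean(boot >= 0)))
  structure(list(delta_t50 = t50_c - t50_t,
                 t50_control = t50_c, t50_treated = t50_t,
                 statistic = unname(w$statistic), p_welch = w$p.value,
                 p_boot = p_boot, n_resamples = n_resamples, seed = seed,
                 method = "Welch t + percentile bootstrap of delta-T50"),
            class = "t50_test")
}

#' @export
print.t50_test <- function(x, ...) {
  cat(sprintf("delta-T50 = %.2f C (control %.2f, treated %.2f)\n",
              x$delta_t50, x$t50_control, x$t50_treated))
  cat(sprintf("  Welch t = %.3g, p = %.4g; bootstrap p = %.4g (%d resamples%s)\n",
              x$statistic, x$p_welch, x$p_boot, x$n_resamples,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  invisible(x)
}

#' Paired control/treated comparison of two assays
#'
#' Compares a treated assay against its control: onset decrease,
#' \eqn{\Delta T_{50}}, cumulative IN concentrations and percent
#' treatment-sensitive IN at reference temperatures, plus Welch and
#' bootstrap significance tests.
#'
#' @param assay_control,assay_treated [droplet_assay()] objects.
#' @param ref_temps Reference temperatures (degrees C, negative) at which
#'   percent-sensitive IN is evaluated. Default `c(-6, -8, -10)`.
#' @param grid_step,conf_level Passed to [freeze_spectrum()].
#' @param n_resamples,seed Passed to [compare_t50()]; the test is skipped
#'   (fields `NA`) when either T50 is undefined.
#' @return An object of class `"treatment_comparison"`: a list with the two
#'   fits, `onset_decrease_c`, `delta_t50_c`, a `sensitivity` data frame
#'   (`ref_temp_c`, `k_control`, `k_treated`, `pct_sensitive` raw,
#'   `pct_clamped`, `clamped`, `treated_censored`) and `test` (a
#'   `"t50_test"` or `NULL`).
#' @details Percent-sensitive is computed from the cumulative spectra at
#'   the reference temperature and is undefined (`NA`) where the control
#'   concentration is zero or censored; where the treated spectrum is
#'   censored (all treated droplets frozen) the value is flagged. Raw
#'   negative values (treated above control by sampling noise) are kept
#'   alongside the \[0, 100\]-clamped copy.
#' @examples
#' sc <- in_preset("paper_like_rain")
#' cmp <- compare_treatments(simulate_assay(sc, seed = 1),
#'                           simulate_assay(apply_heat(sc), seed = 2),
#'                           n_resamples = 200, seed = 3)
#' cmp
#' @export
compare_treatments <- function(assay_control, assay_treated,
                               ref_temps = c(-6, -8, -10),
                               grid_step = 0.2, conf_level = 0.95,
                               n_resamples = 2000, seed = NULL) {
  stopifnot(all(ref_temps < 0))
  fit_c <- freeze_spectrum(assay_control, grid_step, conf_level)
  fit_t <- freeze_spectrum(assay_treated, grid_step, conf_level)
  pr_c <- predict(fit_c, ref_temps)
  pr_t <- predict(fit_t, ref_temps)
  raw <- percent_sensitive(pr_c$k_per_ml, pr_t$k_per_ml)
  raw[pr_c$censored | pr_t$censored] <- NA_real_
  sens <- data.frame(ref_temp_c = ref_temps,
                     k_control = pr_c$k_per_ml, k_treated = pr_t$k_per_ml,
                     pct_sensitive = raw,
                     pct_clamped = pmin(100, pmax(0, raw)),
                     clamped = !is.na(raw) & (raw < 0 | raw > 100),
                     treated_censored = pr_t$censored)
  test <- NULL
  if (!is.na(fit_c$t50_c) && !is.na(fit_t$t50_c) &&
      fit_c$n_total >= 2 && fit_t$n_total >= 2)
    test <- compare_t50(assay_control, assay_treated, grid_step,
                        n_resamples, seed)
  structure(list(sample_id = fit_c$sample_id,
                 control_label = fit_c$treatment,
                 treated_label = fit_t$treatment,
                 fit_control = fit_c, fit_treated = fit_t,
                 onset_decrease_c = onset_decrease(fit_c$onset_c,
                                                   fit_t$onset_c),
                 delta_t50_c = if (is.null(test)) NA_real_ else
                   test$delta_t50,
                 sensitivity = sens, test = test),
            class = "treatment_comparison")
}

#' @export
print.treatment_comparison <- function(x, ...) {
  cat(sprintf("Treatment comparison: sample '%s', %s vs %s\n",
              x$sample_id, x$control_label, x$treated_label))
  cat(sprintf("  onset: %.1f -> %.1f C (decrease %s C)\n",
              x$fit_control$onset_c, x$fit_treated$onset_c,
              if (is.na(x$onset_decrease_c)) "NA" else
                sprintf("%.1f", x$onset_decrease_c)))
  cat(sprintf("  T50:   %s -> %s C (delta %s C)\n",
              if (is.na(x$fit_control$t50_c)) "NA" else
                sprintf("%.1f", x$fit_control$t50_c),
              if (is.na(x$fit_treated$t50_c)) "NA" else
                sprintf("%.1f", x$fit_treated$t50_c),
              if (is.na(x$delta_t50_c)) "NA" else
                sprintf("%.1f", x$delta_t50_c)))
  s <- x$sensitivity
  for (i in seq_len(nrow(s)))
    cat(sprintf("  at %g C: K %s -> %s IN/mL, %s%% sensitive%s\n",
                s$ref_temp_c[i],
                ifelse(is.na(s$k_control[i]), "NA",
                       sprintf("%.1f", s$k_control[i])),
                ifelse(is.na(s$k_treated[i]), "NA",
                       sprintf("%.1f", s$k_treated[i])),
                ifelse(is.na(s$pct_clamped[i]), "NA",
                       sprintf("%.0f", s$pct_clamped[i])),
                ifelse(s$treated_censored[i], " (treated censored)", "")))
  if (!is.null(x$test)) {
    cat("  "); print(x$test)
  }
  invisible(x)
}

#' Comparison table for a set of assays
#'
#' Builds one row per sample x treatment, comparing every non-control
#' treatment against the sample's control: onset decrease, delta-T50,
#' cumulative IN concentration and percent treatment-sensitive IN at each
#' reference temperature, and the Welch/bootstrap p-values. The control's
#' own row carries its onset, T50 and concentrations with blank comparison
#' columns.
#'
#' @param assays List of [droplet_assay()] objects (e.g. from
#'   [read_droplet_csv()]); grouped by `sample_id`.
#' @param control Treatment label to use as control. Default `"crude"`.
#' @param ref_temps Reference temperatures. Default `c(-6, -8, -10)`.
#' @param grid_step,conf_level,n_resamples Passed through.
#' @param seed Base seed; row `i` of the table uses `seed + i` so rows are
#'   independent but the table is reproducible.
#' @param clamp Clamp percent-sensitive values into \[0, 100\] (default
#'   `TRUE`); raw values are attached as `attr(, "pct_raw")`.
#' @return A data frame with columns `sample_id`, `treatment`, `onset_c`,
#'   `onset_decrease_c`, `t50_c`, `delta_t50_c`, then `k_m<d>`, `pct_m<d>`
#'   per reference temperature (e.g. `k_m6`, `pct_m6`), `p_welch`,
#'   `p_boot`. Samples lacking a control are dropped with a warning.
#' @seealso [write_comparison_tsv()]
#' @export
comparison_table <- function(assays, control = "crude",
                             ref_temps = c(-6, -8, -10),
                             grid_step = 0.2, conf_level = 0.95,
                             n_resamples = 2000, seed = NULL,
                             clamp = TRUE) {
  if (inherits(assays, "droplet_assay")) assays <- list(assays)
  stopifnot(all(vapply(assays, inherits, logical(1), "droplet_assay")),
            all(ref_temps < 0))
  suffix <- function(t) vapply(abs(t), function(x)
    gsub("\\.", "p", format(x)), character(1))
  k_cols <- paste0("k_m", suffix(ref_temps))
  pct_cols <- paste0("pct_m", suffix(ref_temps))
  samples <- vapply(assays, `[[`, character(1), "sample_id")
  rows <- list(); raws <- list()
  ri <- 0L
  for (s in unique(samples)) {
    group <- assays[samples == s]
    labs <- vapply(group, `[[`, character(1), "treatment")
    ctrl_i <- which(labs == control)
    if (length(ctrl_i) == 0L) {
      warning("sample '", s, "' has no '", control,
              "' treatment; skipped")
      next
    }
    ctrl <- group[[ctrl_i[1L]]]
    fit_c <- freeze_spectrum(ctrl, grid_step, conf_level)
    pr_c <- predict(fit_c, ref_temps)
    row_c <- data.frame(sample_id = s, treatment = control,
                        onset_c = fit_c$onset_c,
                        onset_decrease_c = NA_real_,
                        t50_c = fit_c$t50_c, delta_t50_c = NA_real_,
                        stringsAsFactors = FALSE)
    for (j in seq_along(ref_temps)) {
      row_c[[k_cols[j]]] <- pr_c$k_per_ml[j]
      row_c[[pct_cols[j]]] <- NA_real_
    }
    row_c$p_welch <- NA_real_; row_c$p_boot <- NA_real_
    ri <- ri + 1L; rows[[ri]] <- row_c; raws[[ri]] <- rep(NA_real_, length(ref_temps))
    for (g in seq_along(group)) {
      if (labs[g] == control) next
      ri <- ri + 1L
      cmp <- compare_treatments(ctrl, group[[g]], ref_temps, grid_step,
                                conf_level, n_resamples,
                                seed = if (is.null(seed)) NULL else seed + ri)
      row <- data.frame(sample_id = s, treatment = labs[g],
                        onset_c = cmp$fit_treated$onset_c,
                        onset_decrease_c = cmp$onset_decrease_c,
                        t50_c = cmp$fit_treated$t50_c,
                        delta_t50_c = cmp$delta_t50_c,
                        stringsAsFactors = FALSE)
      for (j in seq_along(ref_temps)) {
        row[[k_cols[j]]] <- cmp$sensitivity$k_treated[j]
        row[[pct_cols[j]]] <- if (clamp) cmp$sensitivity$pct_clamped[j]
                              else cmp$sensitivity$pct_sensitive[j]
      }
      row$p_welch <- if (is.null(cmp$test)) NA_real_ else cmp$test$p_welch
      row$p_boot <- if (is.null(cmp$test)) NA_real_ else cmp$test$p_boot
      rows[[ri]] <- row; raws[[ri]] <- cmp$sensitivity$pct_sensitive
    }
  }
  out <- if (ri == 0L) {
    empty <- data.frame(sample_id = character(), treatment = character(),
                        onset_c = numeric(), onset_decrease_c = numeric(),
                        t50_c = numeric(), delta_t50_c = numeric(),
                        stringsAsFactors = FALSE)
    for (j in seq_along(ref_temps)) {
      empty[[k_cols[j]]] <- numeric(); empty[[pct_cols[j]]] <- numeric()
    }
    empty$p_welch <- numeric(); empty$p_boot <- numeric()
    empty
  } else do.call(rbind, c(rows, list(make.row.names = FALSE)))
  raw_mat <- do.call(rbind, raws)
  if (!is.null(raw_mat)) colnames(raw_mat) <- pct_cols
  attr(out, "pct_raw") <- raw_mat
  attr(out, "ref_temps") <- ref_temps
  out
}

#' Pairwise Welch tests of freezing temperatures with Holm correction
#'
#' All pairwise Welch two-sample t-tests on per-droplet freezing
#' temperatures among a set of assays (censored droplets excluded), with
#' p-values adjusted for multiple comparisons. A multiplicity-safe
#' alternative to letter-group displays.
#'
#' @param assays Named list of [droplet_assay()] objects; names default to
#'   treatment labels.
#' @param p_adjust_method Passed to [stats::p.adjust()]. Default `"holm"`.
#' @return A lower-triangular matrix of adjusted p-values.
#' @export
pairwise_t50_tests <- function(assays, p_adjust_method = "holm") {
  stopifnot(all(vapply(assays, inherits, logical(1), "droplet_assay")))
  if (is.null(names(assays)))
    names(assays) <- vapply(assays, `[[`, character(1), "treatment")
  k <- length(assays)
  if (k < 2L) stop("need at least two assays")
  pairs <- utils::combn(k, 2)
  p <- apply(pairs, 2, function(ij)
    stats::t.test(.events(assays[[ij[1]]]), .events(assays[[ij[2]]]))$p.value)
  p <- p.adjust(p, method = p_adjust_method)
  m <- matrix(NA_real_, k - 1, k - 1,
              dimnames = list(names(assays)[-1], names(assays)[-k]))
  for (c2 in seq_len(ncol(pairs)))
    m[pairs[2, c2] - 1L, pairs[1, c2]] <- p[c2]
  m
}

#' Write a comparison table as TSV
#'
#' Writes the [comparison_table()] output with the reporting precision used
#' throughout the package: temperatures to 1 decimal place, concentrations
#' to 1 decimal place, percentages as integers, p-values to 4 significant
#' digits. `NA` fields are left empty.
#'
#' @param tbl A [comparison_table()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_tsv <- function(tbl, path) {
  fmt <- function(v, f) ifelse(is.na(v), "", sprintf(f, v))
  out <- tbl
  for (nm in names(out)) {
    if (nm %in% c("sample_id", "treatment")) next
    out[[nm]] <- if (grepl("^pct_", nm)) fmt(tbl[[nm]], "%.0f")
    else if (grepl("^p_", nm)) ifelse(is.na(tbl[[nm]]), "",
                                      formatC(tbl[[nm]], digits = 4,
                                              format = "g"))
    else fmt(tbl[[nm]], "%.1f")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
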