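test_that("onset decrease and percent sensitive follow their definitions", {
  expect_equal(onset_decrease(-4.2, -4.2), 0)
  expect_equal(onset_decrease(c(-3.2, -5), c(-5.8, -5)), c(2.6, 0))
  expect_true(is.na(onset_decrease(NA, -5)))
  expect_equal(percent_sensitive(100, 100), 0)
  expect_equal(percent_sensitive(100, 25), 75)
  expect_true(is.na(percent_sensitive(0, 10)))
  expect_equal(percent_sensitive(100, 130), -30)          # raw retained
  expect_equal(percent_sensitive(100, 130, clamp = TRUE), 0)
  expect_equal(percent_sensitive(100, -5, clamp = TRUE), 100)
})

test_that("identical assays give a null T50 test", {
  a <- simulate_assay(in_preset("paper_like_rain"), seed = 3)
  cmp <- compare_t50(a, a, n_resamples = 400, seed = 1)
  expect_equal(cmp$delta_t50, 0)
  expect_gt(cmp$p_boot, 0.5)
  expect_equal(cmp$statistic, 0)
})

test_that("a pure temperature shift moves T50 and onset exactly", {
  a <- simulate_assay(in_preset("paper_like_rain"), seed = 4)
  shift <- -1.0  # multiple of the grid step, so grid quantities translate
  b <- a
  b$records$freeze_temp_c <- a$records$freeze_temp_c + shift
  cmp <- compare_t50(a, b, n_resamples = 400, seed = 2)
  expect_equal(cmp$delta_t50, 1.0)
  fa <- freeze_spectrum(a); fb <- freeze_spectrum(b)
  expect_equal(coef(fb), coef(fa) + shift, ignore_attr = TRUE)
  # percent-sensitive is invariant when reference temperatures shift along
  ref <- c(-6, -8, -10)
  ka <- predict(fa, ref)$k_per_ml
  kb <- predict(fb, ref + shift)$k_per_ml
  expect_equal(percent_sensitive(ka, kb), rep(0, 3))
})

test_that("a programmed 2 C shift in T50 is detected at n = 235", {
  base <- function(mu) in_scenario(
    list(in_class("m", 600, mu, 1)), background = NULL, min_temp_c = -20)
  hits <- 0L
  for (i in 1:10) {
    a <- simulate_assay(base(-8), seed = 100 + i)
    b <- simulate_assay(base(-10), seed = 200 + i)
    cmp <- compare_t50(a, b, n_resamples = 300, seed = i)
    hits <- hits + (cmp$p_welch < 0.05 && cmp$p_boot < 0.05)
    expect_equal(cmp$delta_t50, 2, tolerance = 0.25)
  }
  expect_gte(hits, 9L)
})

test_that("compare_t50 validates its inputs", {
  a <- assay_from_events(c(-3, -4, -5, -6))
  expect_error(compare_t50(assay_from_events(-3), a), "at least 2")
  half <- droplet_assay(c(-4, rep(-20, 3)), censored = c(FALSE, rep(TRUE, 3)))
  expect_error(compare_t50(a, half), "undefined")
})

test_that("heat removal of the warm mode shows ~100% sensitivity at -6 C", {
  sc <- in_scenario(
    list(in_class("warm", 30, -5, 0.8, heat_sensitive = TRUE),
         in_class("cold", 300, -12, 1, heat_sensitive = FALSE)),
    n_plates = 100, droplets_per_plate = 100,
    background = NULL, min_temp_c = -20)
  cmp <- compare_treatments(simulate_assay(sc, seed = 5),
                            simulate_assay(apply_heat(sc), seed = 6),
                            n_resamples = 200, seed = 7)
  s <- cmp$sensitivity
  pct6 <- s$pct_sensitive[s$ref_temp_c == -6]
  expect_gt(pct6, 95)
})

test_that("comparison tables have the documented shape and blanks", {
  sc <- in_preset("paper_like_rain")
  crude <- simulate_assay(sc, seed = 11)
  heat <- simulate_assay(apply_heat(sc), seed = 12)
  tbl <- comparison_table(list(crude, heat), n_resamples = 200, seed = 13)
  expect_named(tbl, c("sample_id", "treatment", "onset_c",
                      "onset_decrease_c", "t50_c", "delta_t50_c",
                      "k_m6", "pct_m6", "k_m8", "pct_m8", "k_m10", "pct_m10",
                      "p_welch", "p_boot"))
  expect_equal(tbl$treatment, c("crude", "heat"))
  expect_true(is.na(tbl$onset_decrease_c[1]))     # control row blanks
  expect_false(is.na(tbl$onset_decrease_c[2]))
  expect_true(all(tbl$pct_m6 >= 0 & tbl$pct_m6 <= 100, na.rm = TRUE))
  expect_true(!is.null(attr(tbl, "pct_raw")))
  # control-only input: the control row remains, comparison columns blank
  only <- comparison_table(list(crude), n_resamples = 200, seed = 13)
  expect_equal(nrow(only), 1L)
  expect_true(all(is.na(only[, c("onset_decrease_c", "delta_t50_c",
                                 "pct_m6", "p_welch")])))
  # a sample without control is skipped with a warning
  expect_warning(comparison_table(list(heat), n_resamples = 100, seed = 1),
                 "no 'crude'")
})

test_that("reference temperatures warmer than both onsets give NA sensitivity", {
  sc <- in_preset("paper_like_rain")
  cmp <- compare_treatments(simulate_assay(sc, seed = 21),
                            simulate_assay(apply_heat(sc), seed = 22),
                            ref_temps = c(-1, -8),
                            n_resamples = 100, seed = 23)
  s <- cmp$sensitivity
  expect_true(is.na(s$pct_sensitive[s$ref_temp_c == -1]))  # K_control = 0
  expect_false(is.na(s$pct_sensitive[s$ref_temp_c == -8]))
})

test_that("pairwise Welch tests return a Holm-adjusted matrix", {
  sc <- in_preset("paper_like_rain")
  assays <- list(crude = simulate_assay(sc, seed = 31),
                 heat = simulate_assay(apply_heat(sc), seed = 32),
                 filtrate = simulate_assay(apply_filtration(sc), seed = 33))
  m <- pairwise_t50_tests(assays)
  expect_equal(dim(m), c(2L, 2L))
  expect_true(all(m[!is.na(m)] >= 0 & m[!is.na(m)] <= 1))
  expect_true(is.na(m[1, 2]))  # lower triangle only
})
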