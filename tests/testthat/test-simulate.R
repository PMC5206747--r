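test_that("expected spectrum follows the class mixture closed form", {
  cl <- in_class("x", 100, -6, 1)
  sc1 <- in_scenario(list(cl), background = NULL, min_temp_c = -20)
  # Gaussian upper tail at its mean is 1/2 (0-truncation is negligible here)
  expect_equal(expected_spectrum(sc1, -6), 50, tolerance = 1e-6)
  expect_equal(expected_spectrum(in_scenario(list(), background = NULL,
                                             min_temp_c = -20),
                                 c(-2, -8, -15)),
               c(0, 0, 0))
  # additivity of classes
  cl2 <- in_class("y", 40, -9, 2)
  sc2 <- in_scenario(list(cl2), background = NULL, min_temp_c = -20)
  sc12 <- in_scenario(list(cl, cl2), background = NULL, min_temp_c = -20)
  tt <- c(-4, -6, -8, -10)
  expect_equal(expected_spectrum(sc12, tt),
               expected_spectrum(sc1, tt) + expected_spectrum(sc2, tt))
  # non-negative, non-decreasing as temperature decreases
  grid <- seq(0, -20, by = -0.2)
  lam <- expected_spectrum(sc12, grid)
  expect_true(all(lam >= 0))
  expect_true(all(diff(lam) >= 0))
})

test_that("simulation is deterministic given scenario and seed", {
  sc <- in_preset("paper_like_rain")
  a <- simulate_assay(sc, seed = 123)
  b <- simulate_assay(sc, seed = 123)
  expect_identical(a, b)
  expect_false(identical(a, simulate_assay(sc, seed = 124)))
  # simulate() generic dispatches and supports nsim
  many <- simulate(sc, nsim = 3, seed = 5)
  expect_length(many, 3L)
  expect_identical(many[[1]], simulate_assay(sc, seed = 5))
})

test_that("IN-free droplets freeze at the background distribution", {
  sc <- in_scenario(list(in_class("null", 0, -5, 1)),
                    n_plates = 20, droplets_per_plate = 47)
  a <- simulate_assay(sc, seed = 21)
  ev <- a$records$freeze_temp_c[!a$records$censored]
  expect_equal(length(ev), 940L)       # background always fires above -25
  expect_lt(abs(mean(ev) - -16), 0.15) # configured background mean
  expect_true(all(ev <= -10))          # truncation of the background
})

test_that("a dense narrow class freezes every droplet at its mode", {
  sc <- in_scenario(list(in_class("dense", 5000, -4, 0.01)),
                    background = NULL, min_temp_c = -20)
  # c*V = 50: Poisson(50) is positive with prob 1 - e^-50
  a <- simulate_assay(sc, seed = 33)
  ev <- a$records$freeze_temp_c[!a$records$censored]
  expect_gte(length(ev), 234)
  expect_gte(mean(abs(ev + 4) <= 0.1), 0.99)
})

test_that("empirical frozen fraction matches the closed form within 3 sigma", {
  sc <- in_preset("paper_like_rain")
  sc$n_plates <- 100L; sc$droplets_per_plate <- 100L
  a <- simulate_assay(sc, seed = 77)
  cu <- build_curve(a)
  f_true <- expected_frozen_fraction(sc, cu$temp_c)
  band <- 3 * sqrt(pmax(f_true * (1 - f_true), 1e-12) / cu$n_total)
  inside <- abs(cu$frozen_fraction - f_true) <= band + 3e-3
  # allow isolated boundary exceedances from the 0.01 C recording grain
  expect_gte(mean(inside), 0.97)
})

test_that("heat removes exactly the heat-sensitive classes", {
  sc <- in_preset("paper_like_rain")
  heated <- apply_heat(sc)
  expect_equal(vapply(heated$classes, `[[`, character(1), "label"),
               "submicron_resistant")
  expect_equal(heated$treatment, "heat")
  # idempotent on heat-resistant scenarios
  expect_equal(apply_heat(heated)$classes, heated$classes)
  # all classes heat-sensitive -> only background remains
  expect_length(apply_heat(in_preset("ps_control"))$classes, 0L)
})

test_that("post-heat PS-like suspensions lose all warm activity", {
  heated <- apply_heat(in_preset("ps_control"))
  for (seed in 1:5) {
    fit <- freeze_spectrum(simulate_assay(heated, seed = seed))
    expect_lt(fit$onset_c, -10)
  }
})

test_that("filtration is a sharp size cutoff", {
  sc <- in_preset("paper_like_rain")
  filt <- apply_filtration(sc)  # default 220 nm
  expect_equal(vapply(filt$classes, `[[`, character(1), "label"),
               "submicron_resistant")
  expect_equal(filt$treatment, "filtrate")
  expect_equal(length(apply_filtration(sc, cutoff_nm = 2000)$classes),
               length(sc$classes))  # cutoff above all sizes: identity
  # the submicron heat-resistant mode keeps the filtrate freezing above -7
  for (seed in 1:5) {
    fit <- freeze_spectrum(simulate_assay(filt, seed = seed))
    expect_gt(fit$onset_c, -7)
  }
})

test_that("removing a class never increases expected freezing activity", {
  set.seed(61)
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    classes <- lapply(seq_len(k), function(i)
      in_class(paste0("c", i), runif(1, 5, 300), runif(1, -12, -3),
               runif(1, 0.2, 2.5), size_nm = sample(c(50, 500, 1500), 1)))
    sc <- in_scenario(classes, background = NULL, min_temp_c = -20)
    drop_i <- sample(k, 1)
    sc_red <- sc; sc_red$classes <- sc$classes[-drop_i]
    grid <- seq(-1, -15, by = -0.5)
    expect_true(all(expected_spectrum(sc_red, grid) <=
                      expected_spectrum(sc, grid) + 1e-12))
  }
})

test_that("presets are documented, calibrated, and reject unknown names", {
  expect_error(in_preset("nope"), "available presets")
  expect_length(in_preset("pure_water")$classes, 0L)
  sc <- in_preset("paper_like_rain")
  # programmed heat-sensitive share of the expected spectrum at -6 C is 40%
  lam <- expected_spectrum(sc, -6)
  lam_heat <- expected_spectrum(apply_heat(sc), -6)
  expect_equal(100 * (lam - lam_heat) / lam, 40, tolerance = 0.01)
  # packaged YAML configs reproduce the presets exactly
  for (name in c("ps_control", "pure_water", "paper_like_rain")) {
    path <- system.file("extdata", "scenarios", paste0(name, ".yaml"),
                        package = "dropfreeze")
    expect_true(nzchar(path))
    expect_equal(read_scenario(path), in_preset(name))
  }
})

test_that("scenario YAML round trips", {
  sc <- in_scenario(list(in_class("a", 12, -7, 1.5, TRUE, 300)),
                    label = "rt", treatment = "crude",
                    n_plates = 2, droplets_per_plate = 10,
                    background = NULL, min_temp_c = -18)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(sc, path)
  expect_equal(read_scenario(path), sc)
})
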