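test_that("config validation rejects impossible designs", {
  expect_error(experiment_config(doses = c(-1, 10)), "non-negative")
  expect_error(experiment_config(true_ic50 = 0), "true_ic50")
  expect_error(experiment_config(noise_cv = -0.1), "noise_cv")
  expect_error(experiment_config(effect_signs = c(foo = 2)), "effect_signs")
})

test_that("noiseless growth hits the IC50 definition and grows exponentially", {
  cfg <- experiment_config(doses = c(0, 47.3), true_ic50 = 47.3,
                           noise_cv = 0, n_replicates = 1)
  g <- generate_growth(cfg)
  n_end <- function(d) g$density_cells_per_ml[g$dose_ug_per_l == d &
                                                g$time_h == 96]
  # dose == true IC50 -> exactly 50% density reduction at the endpoint
  expect_equal(as.numeric(relative_inhibition(n_end(47.3), n_end(0))), 50,
               tolerance = 1e-10)
  # control is purely exponential: equal log-increments every 24 h
  ctrl <- g[g$dose_ug_per_l == 0, ]
  incr <- diff(log(ctrl$density_cells_per_ml))
  expect_equal(max(incr) - min(incr), 0, tolerance = 1e-12)
  expect_equal(ctrl$density_cells_per_ml[1], 2.7e5)
})

test_that("default inhibition curve passes near the study's anchor points", {
  cfg <- experiment_config(noise_cv = 0)
  # independent closed-form evaluation of the log-logistic at 40 and 80 ug/L
  closed_form <- 100 / (1 + (cfg$true_ic50 / c(40, 80))^cfg$hill_slope)
  expect_equal(100 * loglogistic_inhibition(c(40, 80), cfg$true_ic50,
                                            cfg$hill_slope),
               closed_form, tolerance = 1e-12)
  expect_equal(closed_form, c(39, 83), tolerance = 0.03)
})

test_that("synthetic transients pass through the cardinal constraints", {
  tr <- generate_transient(list(f0 = 500, fm = 2500, vj = 0.5, vi = 0.85))
  at <- function(t) tr$fluorescence[tr$time_s == t]
  expect_equal(at(5e-5), 500, tolerance = 1e-9)
  expect_equal(at(2e-3), 1500, tolerance = 1e-9)   # F0 + VJ * FV
  expect_equal(at(3e-2), 2200, tolerance = 1e-9)   # F0 + VI * FV
  expect_equal(max(tr$fluorescence), 2500, tolerance = 1e-9)
  expect_true(all(diff(tr$fluorescence) >= -1e-12))
  expect_error(generate_transient(list(f0 = 500, fm = 2500, vj = 0.9,
                                       vi = 0.5)), "vj <= vi")
  expect_error(generate_transient(list(f0 = 2500, fm = 500, vj = 0.5,
                                       vi = 0.8)), "fm must exceed f0")
})

test_that("transient noise streams are reproducible under a fixed seed", {
  p <- list(f0 = 500, fm = 2500, vj = 0.5, vi = 0.85)
  a <- generate_transient(p, noise_sd = 25, seed = 42)
  b <- generate_transient(p, noise_sd = 25, seed = 42)
  c <- generate_transient(p, noise_sd = 25, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("spectrum generation is linear in concentrations", {
  lib <- gps_library()
  zero <- generate_spectrum(c(chl_a = 0, fucoxanthin = 0), lib)
  expect_equal(zero$absorbance, rep(0, 801))
  expect_equal(nrow(zero), 801)
  conc <- c(chl_a = 2, fucoxanthin = 1.2)
  one <- generate_spectrum(conc, lib)
  two <- generate_spectrum(2 * conc, lib)
  expect_equal(two$absorbance, 2 * one$absorbance, tolerance = 1e-12)
  expect_error(generate_spectrum(c(nonexistent = 1), lib), "absent")
  expect_error(generate_spectrum(c(chl_a = -1), lib), "non-negative")
})

test_that("bundles are byte-identical under a fixed seed", {
  cfg <- experiment_config(doses = c(0, 40, 80), n_replicates = 2, seed = 11)
  expect_identical(generate_bundle(cfg), generate_bundle(cfg))
})

test_that("noiseless endpoint trends match the configured signs exactly", {
  cfg <- experiment_config(noise_cv = 0, n_replicates = 1)
  b <- generate_bundle(cfg)
  doses <- cfg$doses
  gt <- b$ground_truth
  pull <- function(f) vapply(as.character(doses), function(d) f(gt[[d]]),
                             numeric(1))
  spearman_sign <- function(v) sign(stats::cor(v, doses, method = "spearman"))
  expect_equal(spearman_sign(pull(function(g) g$pigments[["chl_a"]])), -1)
  expect_equal(spearman_sign(pull(function(g) g$pigments[["chl_c"]])), 1)
  expect_equal(spearman_sign(pull(function(g) g$fa_pct[["c16_3"]])), 1)
  expect_equal(spearman_sign(pull(function(g) g$fa_pct[["c16_0"]])), -1)
  expect_equal(spearman_sign(pull(function(g) g$assays$mda_um)), 1)
  expect_equal(spearman_sign(pull(function(g) g$biochem$ets_rate)), 1)
  # untrended endpoints stay exactly flat, including after FA closure
  expect_equal(stats::sd(pull(function(g) g$assays$cat_rate)), 0)
  expect_equal(stats::sd(pull(function(g) g$fa_pct[["c14_0"]])), 0,
               tolerance = 1e-12)
})

test_that("all-zero effect signs produce identical treatments", {
  signs <- default_effect_signs(); signs[] <- 0
  cfg <- experiment_config(noise_cv = 0, n_replicates = 1,
                           effect_signs = signs, true_ic50 = 1e9)
  b <- generate_bundle(cfg)
  f_by_dose <- split(b$transients$fluorescence, b$transients$dose_ug_per_l)
  for (k in seq_along(f_by_dose)) {
    expect_equal(f_by_dose[[k]], f_by_dose[[1]])
  }
  pig_by_dose <- split(b$spectra$absorbance, b$spectra$dose_ug_per_l)
  expect_equal(pig_by_dose[[length(pig_by_dose)]], pig_by_dose[[1]])
})
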