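test_that("MDA conversion follows Beer-Lambert with turbidity correction", {
  k <- assay_constants()
  expect_equal(as.numeric(mda_concentration(0.3, 0.3, k)), 0)
  expect_equal(as.numeric(mda_concentration(0.205, 0.05, k)), 1)  # 0.155/155 mM
  expect_equal(as.numeric(mda_concentration(0.205, 0.05, k, dilution = 2)), 2)
  clipped <- mda_concentration(0.1, 0.2, k)
  expect_equal(as.numeric(clipped), 0)
  expect_true(attr(clipped, "clipped"))
})

test_that("kinetic rate is the least-squares slope per minute", {
  tr <- data.frame(time_s = 0:180, absorbance = 0.2 + 0.01 * (0:180))
  expect_equal(kinetic_rate(tr), 0.6)
  flat <- data.frame(time_s = 0:10, absorbance = 0.5)
  expect_equal(kinetic_rate(flat), 0)
  expect_error(kinetic_rate(tr, c(0, 1)), "fewer than 3")
})

test_that("noisy slopes land inside the regression confidence interval", {
  set.seed(8)
  for (k in 1:5) {
    slope_per_s <- runif(1, -0.002, -0.0002)
    tr <- data.frame(time_s = seq(0, 180, 5))
    tr$absorbance <- 1 + slope_per_s * tr$time_s + rnorm(nrow(tr), 0, 0.004)
    fit <- lm(absorbance ~ time_s, tr)
    ci <- confint(fit, "time_s", level = 0.999) * 60
    expect_gte(kinetic_rate(tr), ci[1])
    expect_lte(kinetic_rate(tr), ci[2])
  }
})

test_that("catalase and APX activities scale by their coefficients", {
  k <- assay_constants(reaction_vol_ml = 1, extract_vol_ml = 1)
  cat_a <- catalase_activity(-0.394, k, protein_mg = 1)
  # 0.394/39.4 = 0.01 mM/min turnover -> 10 nmol/min/mg at unit volumes
  expect_equal(cat_a$activity, 10, tolerance = 1e-12)
  expect_false(cat_a$increasing_flag)
  expect_equal(catalase_activity(0, k, 1)$activity, 0)
  expect_true(catalase_activity(0.1, k, 1)$increasing_flag)
  expect_equal(catalase_activity(-0.394, k, 0.5)$activity, 20)

  apx_a <- apx_activity(-0.28, k, protein_mg = 1)
  expect_equal(apx_a$activity, 100, tolerance = 1e-12)  # 0.28/2.8 = 0.1 mM/min
  k10 <- assay_constants(reaction_vol_ml = 2, extract_vol_ml = 0.2)
  expect_equal(apx_activity(-0.28, k10, 1)$activity, 1000, tolerance = 1e-12)
})

test_that("SOD units follow the 50%-inhibition convention", {
  s0 <- sod_activity(0.012, 0.012, protein_mg = 1)
  expect_equal(s0$inhibition_pct, 0)
  expect_equal(s0$activity, 0)
  s1 <- sod_activity(0.006, 0.012, protein_mg = 1)
  expect_equal(s1$inhibition_pct, 50)
  expect_equal(s1$activity, 1)
  expect_equal(sod_activity(0.006, 0.012, 0.5)$activity, 2)
  clip <- sod_activity(0.02, 0.012, 1)
  expect_true(clip$clipped)
  expect_equal(clip$inhibition_pct, 0)
  expect_error(sod_activity(0.01, 0, 1), "positive")
})

test_that("conversions agree with an independent Beer-Lambert oracle", {
  set.seed(12)
  for (k in 1:25) {
    eps <- runif(1, 1, 200); path <- runif(1, 0.5, 2)
    rate <- -runif(1, 0.01, 1); vr <- runif(1, 0.2, 2); ve <- runif(1, 0.05, 1)
    prot <- runif(1, 0.1, 2)
    kc <- assay_constants(eps_cat = eps, path_cm = path,
                          reaction_vol_ml = vr, extract_vol_ml = ve)
    got <- catalase_activity(rate, kc, prot)$activity
    # oracle: substrate umol/min in cuvette = (|dA|/eps/path mM) * vr mL,
    # referred back to the extract aliquot and protein load
    oracle_nmol <- (abs(rate) / (eps * path)) * vr * 1000 / (ve * prot)
    expect_equal(got, oracle_nmol, tolerance = 1e-12)

    a600 <- runif(1, 0, 0.2); da <- runif(1, 0, 0.5); dil <- sample(1:4, 1)
    km <- assay_constants(eps_mda = eps, path_cm = path)
    expect_equal(as.numeric(mda_concentration(a600 + da, a600, km, dil)),
                 da / (eps * path) * 1000 * dil, tolerance = 1e-9)
  }
})

test_that("the assay battery tabulates a bundle per replicate", {
  cfg <- experiment_config(doses = c(0, 80), n_replicates = 2, noise_cv = 0)
  b <- generate_bundle(cfg)
  out <- assay_analysis(b$assays$endpoint, b$assays$kinetic)
  expect_equal(nrow(out), 4)
  truth0 <- b$ground_truth[["0"]]$assays
  expect_equal(out$mda_um[out$dose_ug_per_l == 0], rep(truth0$mda_um, 2),
               tolerance = 1e-6)
  expect_equal(out$sod_inhibition_pct[out$dose_ug_per_l == 0],
               rep(truth0$sod_inhibition, 2), tolerance = 1e-6)
})
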