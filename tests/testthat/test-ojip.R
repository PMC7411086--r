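test_that("cardinal points are read off a constructed transient", {
  tr <- generate_transient(list(f0 = 500, fm = 2500, vj = 0.5, vi = 0.85))
  cp <- extract_cardinal_points(tr)
  expect_equal(cp$f0, 500, tolerance = 1e-9)
  expect_equal(cp$fj, 1500, tolerance = 1e-9)
  expect_equal(cp$fi, 2200, tolerance = 1e-9)
  expect_equal(cp$fm, 2500, tolerance = 1e-9)
  expect_false(cp$degenerate)
  short <- tr[tr$time_s > 1e-4, ]
  expect_error(extract_cardinal_points(short), "outside sampled range")
})

test_that("a flat transient is degenerate with all cardinals equal", {
  flat <- data.frame(time_s = ojip_time_grid(), fluorescence = 700)
  cp <- extract_cardinal_points(flat)
  expect_true(cp$degenerate)
  expect_equal(unlist(cp[c("f0", "f300", "fj", "fi", "fm")]),
               c(f0 = 700, f300 = 700, fj = 700, fi = 700, fm = 700))
  jp <- compute_jip(cp, flat)
  expect_true(jp$degenerate)
  expect_true(is.na(jp$phi_p0))
})

test_that("log-time interpolation matches a dense-grid nearest-sample oracle", {
  p <- list(f0 = 420, fm = 2100, vj = 0.45, vi = 0.8)
  dense_t <- 10^seq(-5, 0, length.out = 20000)
  dense <- generate_transient(p, times = sort(unique(c(dense_t, 5e-5, 1))))
  coarse <- generate_transient(p)
  cp <- extract_cardinal_points(coarse)
  for (target in c(3e-4, 2e-3, 3e-2)) {
    nearest <- dense$fluorescence[which.min(abs(dense$time_s - target))]
    got <- switch(as.character(target), "3e-04" = cp$f300, "0.002" = cp$fj,
                  "0.03" = cp$fi)
    expect_equal(got, nearest, tolerance = 1e-3)
  }
})

test_that("JIP yields follow Fv/Fm arithmetic", {
  tr <- generate_transient(list(f0 = 500, fm = 2500, vj = 0.5, vi = 0.85))
  jp <- compute_jip(extract_cardinal_points(tr), tr)
  expect_equal(jp$phi_p0, 0.8)
  expect_equal(jp$tr0_di0, 4, tolerance = 1e-9)
  expect_equal(jp$vj, 0.5, tolerance = 1e-9)
  expect_equal(jp$psi_e0, 0.5, tolerance = 1e-9)
  expect_equal(jp$psi_ratio, 1, tolerance = 1e-9)
  expect_equal(jp$delta_r0, 0.3, tolerance = 1e-8)
})

test_that("area above the curve matches a brute-force trapezoid oracle", {
  set.seed(5)
  for (k in 1:5) {
    p <- random_transient_params()
    tr <- generate_transient(p)
    jp <- compute_jip(extract_cardinal_points(tr), tr)
    # oracle: fine linear-time resampling, Riemann midpoint sum
    i_fm <- which.max(tr$fluorescence)
    tt <- seq(5e-5, tr$time_s[i_fm], length.out = 2e5)
    ff <- approx(tr$time_s, tr$fluorescence, xout = tt)$y
    oracle <- sum((max(tr$fluorescence) - (ff[-1] + ff[-length(ff)]) / 2) *
                    diff(tt))
    expect_equal(jp$area, oracle, tolerance = 5e-3)
  }
})

test_that("absorbed flux splits exactly into trapped plus dissipated", {
  set.seed(6)
  for (k in 1:25) {
    tr <- generate_transient(random_transient_params())
    jp <- compute_jip(extract_cardinal_points(tr), tr)
    expect_equal(jp$abs_cs, jp$tr_cs + jp$di_cs, tolerance = 1e-12)
    expect_true(jp$et_cs <= jp$tr_cs && jp$tr_cs <= jp$abs_cs)
    expect_true(all(c(jp$abs_cs, jp$tr_cs, jp$et_cs, jp$di_cs) >= 0))
  }
})

test_that("dimensionless parameters are invariant to fluorescence scaling", {
  p <- list(f0 = 500, fm = 2500, vj = 0.5, vi = 0.85)
  tr <- generate_transient(p)
  k <- 3.7
  tr_k <- transform(tr, fluorescence = fluorescence * k)
  a <- compute_jip(extract_cardinal_points(tr), tr)
  b <- compute_jip(extract_cardinal_points(tr_k), tr_k)
  for (f in c("vj", "vi", "phi_p0", "psi_e0", "delta_r0", "n", "tr0_di0",
              "sm", "m0", "rc_abs")) {
    expect_equal(b[[f]], a[[f]], tolerance = 1e-9, label = f)
  }
  for (f in c("abs_cs", "tr_cs", "et_cs", "di_cs", "rc_cs")) {
    expect_equal(b[[f]], k * a[[f]], tolerance = 1e-9, label = f)
  }
})

test_that("lowering FM at fixed F0 strictly lowers phi_P0 and TR0/DI0", {
  fms <- c(2500, 2200, 1900, 1600)
  phis <- numeric(0); ratios <- numeric(0)
  for (fm in fms) {
    tr <- generate_transient(list(f0 = 500, fm = fm, vj = 0.5, vi = 0.85))
    jp <- compute_jip(extract_cardinal_points(tr), tr)
    phis <- c(phis, jp$phi_p0); ratios <- c(ratios, jp$tr0_di0)
  }
  expect_true(all(diff(phis) < 0))
  expect_true(all(diff(ratios) < 0))
})

test_that("AOEC is 1 for self-reference and matches hand arithmetic", {
  ctrl <- list(vk = 0.3, vj = 0.5)
  expect_equal(aoec_fraction(ctrl, ctrl), 1)
  smp <- list(vk = 0.45, vj = 0.5)
  expect_equal(aoec_fraction(smp, ctrl), (1 - 0.45 / 0.5) / (1 - 0.3 / 0.5))
  # K step risen to the J level -> no active OECs
  expect_equal(aoec_fraction(list(vk = 0.5, vj = 0.5), ctrl), 0)
  expect_error(aoec_fraction(smp, list(vk = 0.6, vj = 0.5)), "positive")
})

test_that("jip_analysis tabulates replicates and control-referenced AOEC", {
  cfg <- experiment_config(doses = c(0, 80), n_replicates = 2, noise_cv = 0)
  b <- generate_bundle(cfg)
  tab <- jip_analysis(b$transients)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$aoec[tab$dose_ug_per_l == 0], c(1, 1), tolerance = 1e-9)
  expect_true(all(tab$abs_cs - tab$tr_cs - tab$di_cs < 1e-12))
})
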