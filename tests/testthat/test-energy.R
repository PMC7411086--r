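test_that("available energy sums the printed combustion equivalents", {
  expect_equal(available_energy(0, 0, 0, 1e6), 0)
  expect_equal(available_energy(1, 1, 1, 1e6), 81000)
  expect_equal(available_energy(1, 1, 1, 2e6), 40500)  # per-cell normalization
  expect_error(available_energy(-1, 0, 0, 1e6), "negative")
  expect_error(available_energy(1, 1, 1, 0), "positive")
})

test_that("Ea is linear in each component with the printed coefficients", {
  base <- available_energy(0.4, 0.2, 0.3, 1e6)
  h <- 1e-3
  expect_equal((available_energy(0.4 + h, 0.2, 0.3, 1e6) - base) / h, 17500,
               tolerance = 1e-6)
  expect_equal((available_energy(0.4, 0.2 + h, 0.3, 1e6) - base) / h, 24000,
               tolerance = 1e-6)
  expect_equal((available_energy(0.4, 0.2, 0.3 + h, 1e6) - base) / h, 39500,
               tolerance = 1e-6)
})

test_that("ETS conversion follows the formazan/oxygen stoichiometry", {
  expect_equal(ets_consumption(0, 1e6), 0)
  # per-M reading: dA 0.0159/min over eps 15,900 -> 1 uM formazan/min,
  # 0.5 uM O2/min; per-mM reading is 10^3 smaller
  k_mM <- energy_constants()
  k_M <- energy_constants(formazan_unit = "per_M")
  vr <- 0.2; cells <- 1e6
  o2_umol_h_M <- 1e-3 * vr * 60 / 2      # 1 uM/min * vr mL -> umol/min
  expect_equal(ets_consumption(0.0159, cells, k_M, vr), o2_umol_h_M * 480,
               tolerance = 1e-9)
  expect_equal(ets_consumption(0.0159, cells, k_mM, vr),
               ets_consumption(0.0159, cells, k_M, vr) / 1000,
               tolerance = 1e-9)
  # halving the reaction volume halves Ec
  expect_equal(ets_consumption(0.02, cells, k_mM, vr / 2),
               ets_consumption(0.02, cells, k_mM, vr) / 2)
  expect_error(ets_consumption(-0.01, cells), "negative")
})

test_that("Ec agrees with an independent stoichiometry oracle", {
  set.seed(9)
  for (i in 1:20) {
    rate <- runif(1, 0, 0.1); eps <- runif(1, 1000, 20000)
    path <- runif(1, 0.5, 2); vr <- runif(1, 0.05, 1)
    cells <- runif(1, 1e5, 1e7); oxy <- runif(1, 300, 600)
    k <- energy_constants(eps_formazan = eps, path_cm = path,
                          oxyenthalpic_kj_per_mol_o2 = oxy)
    # oracle in explicit unit steps
    formazan_mM_min <- rate / (eps * path)
    formazan_mol_h <- formazan_mM_min * 1e-3 * (vr * 1e-3) * 60
    o2_mol_h <- formazan_mol_h / 2
    mj_h <- o2_mol_h * oxy * 1000 * 1000   # kJ -> J -> mJ
    expect_equal(ets_consumption(rate, cells, k, vr),
                 mj_h / (cells / 1e6), tolerance = 1e-9)
  }
})

test_that("Ec is invariant to splitting a linear trace into sub-windows", {
  tr <- data.frame(time_s = seq(0, 180, 10))
  tr$absorbance <- 0.1 + 0.0003 * tr$time_s
  r_full <- kinetic_rate(tr)
  r_a <- kinetic_rate(tr, c(0, 90)); r_b <- kinetic_rate(tr, c(90, 180))
  expect_equal(r_a, r_full); expect_equal(r_b, r_full)
  expect_equal(ets_consumption(r_a, 1e6), ets_consumption(r_full, 1e6))
})

test_that("CEA is the exact ratio with a flagged undefined case", {
  expect_equal(as.numeric(cea(500, 500)), 1)
  expect_equal(as.numeric(cea(0, 50)), 0)
  undef <- cea(100, 0)
  expect_true(is.na(as.numeric(undef)))
  expect_true(attr(undef, "undefined"))
  # strictly decreasing in Ec at fixed Ea
  ecs <- c(10, 20, 40, 80)
  expect_true(all(diff(as.numeric(cea(1000, ecs))) < 0))
})

test_that("bundle energy budgets recover the generating values exactly", {
  cfg <- experiment_config(doses = c(0, 80), n_replicates = 1, noise_cv = 0)
  b <- generate_bundle(cfg)
  kin <- b$assays$kinetic
  ets <- do.call(rbind, lapply(split(kin[kin$assay == "ets", ],
                                     kin[kin$assay == "ets", "dose_ug_per_l"]),
    function(tr) data.frame(dose_ug_per_l = tr$dose_ug_per_l[1],
                            replicate = 1, da490_per_min = kinetic_rate(tr))))
  out <- energy_analysis(b$biochem, ets)
  for (d in c("0", "80")) {
    truth <- b$ground_truth[[d]]$biochem
    row <- out[out$dose_ug_per_l == as.numeric(d), ]
    expect_equal(row$ea, available_energy(truth$carb_mg, truth$protein_mg,
                                          truth$lipid_mg, row$cells),
                 tolerance = 1e-9)
    expect_equal(row$cea, row$ea / row$ec, tolerance = 1e-12)
  }
})
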