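#' Log-logistic growth-inhibition curve
#'
#' Fractional growth inhibition at a given dose for a two-parameter
#' log-logistic model, `I(d) = 1 / (1 + (ic50/d)^h)`, with `I(0) = 0`.
#'
#' @param dose Dose (same units as `ic50`), >= 0.
#' @param ic50 Concentration of half-maximal inhibition (> 0).
#' @param hill_slope Slope parameter h (> 0).
#' @return Inhibition fraction in [0, 1).
#' @export
loglogistic_inhibition <- function(dose, ic50, hill_slope) {
  ifelse(dose <= 0, 0, 1 / (1 + (ic50 / dose)^hill_slope))
}

#' Generate synthetic cell-density growth series
#'
#' Controls grow exponentially from the inoculation density; treated cultures
#' grow at the control rate during the 48 h acclimation phase and then at a
#' reduced rate during the 48 h exposure phase, chosen so that the relative
#' cell-density reduction versus control at the exposure endpoint equals the
#' log-logistic inhibition at that dose. Replicate noise is multiplicative
#' lognormal with the configured CV (cell counts are positive and CV-stable).
#'
#' @param config An [experiment_config()].
#' @param times_h Sampling times in hours since inoculation; must include the
#'   exposure start (48 h) and endpoint (96 h).
#' @param mu_control Control specific growth rate, per day.
#' @return `data.frame(time_h, density_cells_per_ml, dose_ug_per_l, replicate)`.
#' @export
generate_growth <- function(config, times_h = c(0, 24, 48, 72, 96),
                            mu_control = 0.8) {
  stopifnot(inherits(config, "experiment_config"))
  t_expose <- 48
  t_end <- max(times_h)
  if (!all(c(t_expose, t_end) %in% times_h) || t_end <= t_expose) {
    stop("times_h must include the exposure start (48 h) and a later endpoint")
  }
  exposure_days <- (t_end - t_expose) / 24
  out <- list()
  for (di in seq_along(config$doses)) {
    dose <- config$doses[di]
    inh <- min(loglogistic_inhibition(dose, config$true_ic50,
                                      config$hill_slope), 0.9999)
    # exposure-phase rate giving N_treated/N_control = 1 - inh at t_end
    mu_exposed <- mu_control + log(1 - inh) / exposure_days
    for (ri in seq_len(config$n_replicates)) {
      set.seed(replicate_seed(config$seed, di, ri))
      days_exposed <- pmax(times_h - t_expose, 0) / 24
      days_pre <- pmin(times_h, t_expose) / 24
      n_true <- config$initial_density *
        exp(mu_control * days_pre + mu_exposed * days_exposed)
      noise <- lognormal_noise(length(n_true), config$noise_cv)
      out[[length(out) + 1]] <- data.frame(
        time_h = times_h,
        density_cells_per_ml = n_true * noise,
        dose_ug_per_l = dose,
        replicate = ri
      )
    }
  }
  do.call(rbind, out)
}

# Lognormal multiplicative noise with unit mean and given CV.
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Generate a synthetic OJIP fluorescence transient
#'
#' Builds a monotone non-decreasing Kautsky rise as a weighted sum of three
#' sigmoidal phases in log10-time (the O-J, J-I and I-P rise phases). The
#' phase weights are solved from the requested relative variable fluorescence
#' at the J (2 ms) and I (30 ms) steps so the noiseless curve passes exactly
#' through (50 us, F0), (2 ms, F0 + VJ*FV), (30 ms, F0 + VI*FV) and reaches
#' FM at the plateau end of the record.
#'
#' @param target_params List with `f0`, `fm` (relative fluorescence, fm > f0),
#'   `vj`, `vi` (0 < vj <= vi <= 1), and optionally `phase_centers` /
#'   `phase_widths` (log10 seconds) of the three rise phases.
#' @param times Sampling times in seconds. The default log-spaced grid spans
#'   10 us - 1 s and contains the cardinal times exactly.
#' @param noise_sd Additive Gaussian noise SD (relative fluorescence units).
#' @param seed RNG seed for the noise.
#' @return `data.frame(time_s, fluorescence)`.
#' @export
generate_transient <- function(target_params, times = ojip_time_grid(),
                               noise_sd = 0, seed = 1L) {
  p <- target_params
  stopifnot(is.numeric(p$f0), is.numeric(p$fm), is.numeric(p$vj),
            is.numeric(p$vi))
  if (!(p$fm > p$f0)) stop("fm must exceed f0")
  if (!(p$vj > 0 && p$vj <= p$vi && p$vi <= 1)) {
    stop("require 0 < vj <= vi <= 1")
  }
  centers <- p$phase_centers %||% c(-3.35, -2.0, -0.9)
  widths <- p$phase_widths %||% c(0.22, 0.28, 0.18)
  t0 <- 5e-5; t_j <- 2e-3; t_i <- 3e-2; t_end <- max(times)
  sig <- function(t) {
    x <- log10(t)
    vapply(seq_len(3),
           function(k) 1 / (1 + exp(-(x - centers[k]) / widths[k])),
           numeric(1))
  }
  s0 <- sig(t0); sj <- sig(t_j); si <- sig(t_i); se <- sig(t_end)
  # Weights a (a3 = 1) from the two homogeneous step constraints
  # sum_k a_k [(sig_k(t_step) - sig_k(t0)) - V_step (sig_k(t_end) - sig_k(t0))] = 0
  m_row <- function(s_step, v) (s_step - s0) - v * (se - s0)
  r1 <- m_row(sj, p$vj); r2 <- m_row(si, p$vi)
  a12 <- solve(cbind(c(r1[1], r2[1]), c(r1[2], r2[2])), -c(r1[3], r2[3]))
  a <- c(a12, 1)
  if (any(a < -1e-9)) {
    stop("requested vj/vi not representable as a monotone three-phase rise")
  }
  a <- pmax(a, 0)
  rise <- function(t) {
    x <- log10(t)
    r <- 0
    for (k in 1:3) r <- r + a[k] / (1 + exp(-(x - centers[k]) / widths[k]))
    r
  }
  r0 <- rise(t0); re <- rise(t_end)
  f <- p$f0 + (p$fm - p$f0) * (rise(times) - r0) / (re - r0)
  if (noise_sd > 0) {
    set.seed(seed)
    f <- f + stats::rnorm(length(f), sd = noise_sd)
  }
  data.frame(time_s = times, fluorescence = f)
}

#' Standard log-spaced OJIP sampling grid
#'
#' 10 us to 1 s, log-spaced, with the cardinal times (50 us, 100/200/300 us,
#' 2 ms, 30 ms, 1 s) included exactly.
#' @param n Approximate number of log-spaced samples.
#' @return Numeric vector of times in seconds.
#' @export
ojip_time_grid <- function(n = 110) {
  grid <- 10^seq(-5, 0, length.out = n)
  sort(unique(c(grid, 5e-5, 1e-4, 2e-4, 3e-4, 2e-3, 3e-2, 1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic whole-cell absorbance spectrum
#'
#' Forward model of the GPS deconvolution: the spectrum is the sum of
#' concentration-scaled pigment Gaussian templates plus a smooth
#' (constant + linear) baseline, on the exact 350-750 nm / 0.5 nm grid,
#' with optional additive Gaussian noise.
#'
#' @param concentrations Named vector of pigment concentrations (template
#'   units, >= 0); names must exist in `library`.
#' @param library A GPS template library, see [gps_library()].
#' @param baseline Numeric length-2 `c(intercept, slope_per_nm)`; slope is per
#'   nm relative to 350 nm.
#' @param noise_sd Additive Gaussian noise SD (AU).
#' @param seed RNG seed for the noise.
#' @return `data.frame(wavelength_nm, absorbance)`.
#' @export
generate_spectrum <- function(concentrations, library = gps_library(),
                              baseline = c(0, 0), noise_sd = 0, seed = 1L) {
  if (any(concentrations < 0)) stop("concentrations must be non-negative")
  spec <- model_spectrum(concentrations, library, baseline)
  if (noise_sd > 0) {
    set.seed(seed)
    spec$absorbance <- spec$absorbance +
      stats::rnorm(nrow(spec), sd = noise_sd)
  }
  spec
}

# --- endpoint base levels used by generate_bundle -------------------------

pigment_base_conc <- function() {
  c(chl_a = 4, chl_c = 0.6, pheophytin_a = 0.3, beta_carotene = 0.35,
    fucoxanthin = 2.5, diadinoxanthin = 0.5, diatoxanthin = 0.15)
}

fa_base_pct <- function() {
  c(c14_0 = 6, c16_0 = 20, c16_1 = 25, c16_2 = 3.5, c16_3 = 7, c16_4 = 1.5,
    c18_3 = 1, c18_4 = 2, c20_4 = 1, c20_5 = 22)
}

fa_id_label <- function(key) {
  # c16_2 -> C16:2 ; internal keys use chain_bonds
  parts <- strsplit(sub("^c", "", key), "_")[[1]]
  paste0("C", parts[1], ":", parts[2])
}

#' Generate a complete synthetic experiment bundle
#'
#' Produces every input table the analysis stages consume - growth series,
#' OJIP transients, absorbance spectra, FAME peak tables, oxidative-stress
#' assay measurements, and energy-budget inputs - for the full dose-by-
#' replicate design, with all generating parameter values recorded as ground
#' truth. Endpoint dose trends are linear in dose with the configured signs
#' and fractional effect size at the top dose; fatty-acid trends are
#' mass-balanced so the total is dose-invariant and untrended FAs stay exactly
#' flat after closure to relative percentages.
#'
#' @param config An [experiment_config()].
#' @return List of class `synthetic_bundle` with elements `growth`,
#'   `transients`, `spectra`, `fa`, `assays` (endpoint + kinetic tables),
#'   `biochem`, and `ground_truth`.
#' @export
generate_bundle <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  signs <- config$effect_signs
  e <- config$effect_size
  doses <- config$doses
  lib <- gps_library()

  growth <- generate_growth(config)

  # dose-trend multiplier for one endpoint
  trend <- function(name, dose, size = e) {
    s <- if (name %in% names(signs)) signs[[name]] else 0
    1 + s * size * trend_fraction(dose, doses)
  }

  # mass-balanced FA effect sizes: scale the negative group so total area is
  # dose-invariant and relative % trends keep their signs exactly
  base_fa <- fa_base_pct()
  fa_signs <- signs[names(base_fa)]
  pos_mass <- sum(base_fa[fa_signs > 0]); neg_mass <- sum(base_fa[fa_signs < 0])
  e_pos <- e
  e_neg <- if (neg_mass > 0) e * pos_mass / neg_mass else 0

  transients <- list(); spectra <- list(); fa_rows <- list()
  endpoint_rows <- list(); kinetic_rows <- list(); biochem_rows <- list()
  gt <- list()

  base_tr <- list(f0 = 500, fm = 2500, vj = 0.5, vi = 0.85)
  tr_size <- c(f0 = 0.25, fm = 0.45, vj = 0.15, vi = 0.05)  # bounded shifts
  is_mass_ug <- 25  # C15:0 internal standard mass added per sample
  total_fa_area <- 5e5
  base_assay <- list(mda_um = 1.2, cat_rate = 0.04, apx_rate = 0.03,
                     sod_inhibition = 30, sod_control_rate = 0.012,
                     ets_rate = 0.02, protein_mg = 0.5)
  base_biochem <- list(carb_mg = 0.04, protein_mg = 0.06, lipid_mg = 0.05)

  for (di in seq_along(doses)) {
    dose <- doses[di]
    # --- per-dose noiseless truths ---
    tr_pars <- list(
      f0 = base_tr$f0 * (1 + signs[["f0"]] * tr_size[["f0"]] *
                           trend_fraction(dose, doses)),
      fm = base_tr$fm * (1 + signs[["fm"]] * tr_size[["fm"]] *
                           trend_fraction(dose, doses)),
      vj = base_tr$vj * (1 + signs[["vj"]] * tr_size[["vj"]] *
                           trend_fraction(dose, doses)),
      vi = base_tr$vi * (1 + signs[["vi"]] * tr_size[["vi"]] *
                           trend_fraction(dose, doses))
    )
    pig_conc <- pigment_base_conc()
    for (pp in names(pig_conc)) pig_conc[pp] <- pig_conc[pp] * trend(pp, dose)
    fa_pct <- base_fa
    for (ff in names(fa_pct)) {
      s <- fa_signs[[ff]]
      size <- if (s > 0) e_pos else if (s < 0) e_neg else 0
      fa_pct[ff] <- base_fa[ff] * (1 + s * size * trend_fraction(dose, doses))
    }
    assay_true <- list(
      mda_um = base_assay$mda_um * trend("tbars", dose),
      cat_rate = base_assay$cat_rate * trend("cat", dose),
      apx_rate = base_assay$apx_rate * trend("apx", dose),
      sod_inhibition = base_assay$sod_inhibition * trend("sod", dose)
    )
    biochem_true <- list(
      carb_mg = base_biochem$carb_mg * trend("carb", dose),
      protein_mg = base_biochem$protein_mg * trend("protein", dose),
      lipid_mg = base_biochem$lipid_mg * trend("lipid", dose),
      ets_rate = base_assay$ets_rate * trend("ets", dose)
    )
    inh <- loglogistic_inhibition(dose, config$true_ic50, config$hill_slope)
    gt[[as.character(dose)]] <- list(
      dose = dose, inhibition_pct = 100 * inh, transient = tr_pars,
      pigments = pig_conc, fa_pct = 100 * fa_pct / sum(fa_pct),
      assays = assay_true, biochem = biochem_true
    )

    for (ri in seq_len(config$n_replicates)) {
      seed_ij <- replicate_seed(config$seed, di, ri)
      set.seed(seed_ij)
      nz <- function(x) x * lognormal_noise(length(x), config$noise_cv)

      tr <- generate_transient(tr_pars,
                               noise_sd = config$noise_cv * base_tr$f0 * 0.2,
                               seed = seed_ij + 1L)
      tr$dose_ug_per_l <- dose; tr$replicate <- ri
      transients[[length(transients) + 1]] <- tr

      sp <- generate_spectrum(nz(pig_conc), lib,
                              noise_sd = config$noise_cv * 0.02,
                              seed = seed_ij + 2L)
      sp$dose_ug_per_l <- dose; sp$replicate <- ri
      spectra[[length(spectra) + 1]] <- sp

      areas <- nz(total_fa_area * fa_pct / sum(fa_pct))
      fa_rows[[length(fa_rows) + 1]] <- data.frame(
        fa_id = c(vapply(names(fa_pct), fa_id_label, character(1)), "C15:0"),
        peak_area = c(areas, total_fa_area * 0.05),
        is_standard = c(rep(FALSE, length(fa_pct)), TRUE),
        dose_ug_per_l = dose, replicate = ri, row.names = NULL
      )

      mda <- nz(assay_true$mda_um)
      a600 <- 0.05
      endpoint_rows[[length(endpoint_rows) + 1]] <- data.frame(
        a532 = a600 + mda * 155 / 1000, a600 = a600,
        sod_sample_rate = base_assay$sod_control_rate *
          (1 - nz(assay_true$sod_inhibition) / 100),
        sod_control_rate = base_assay$sod_control_rate,
        protein_mg = base_assay$protein_mg,
        dose_ug_per_l = dose, replicate = ri
      )

      tt <- seq(0, 180, by = 15)
      mk_trace <- function(assay, slope_per_min, a0) {
        noise <- if (config$noise_cv > 0)
          stats::rnorm(length(tt), sd = config$noise_cv * 0.002) else 0
        data.frame(time_s = tt, absorbance = a0 + slope_per_min * tt / 60 +
                     noise, assay = assay, dose_ug_per_l = dose,
                   replicate = ri)
      }
      kinetic_rows[[length(kinetic_rows) + 1]] <- rbind(
        mk_trace("cat", -nz(assay_true$cat_rate), 1.0),
        mk_trace("apx", -nz(assay_true$apx_rate), 0.8),
        mk_trace("ets", nz(biochem_true$ets_rate), 0.1)
      )

      harvest_density <- growth$density_cells_per_ml[
        growth$dose_ug_per_l == dose & growth$replicate == ri &
          growth$time_h == max(growth$time_h)]
      biochem_rows[[length(biochem_rows) + 1]] <- data.frame(
        carb_mg = nz(biochem_true$carb_mg),
        protein_mg = nz(biochem_true$protein_mg),
        lipid_mg = nz(biochem_true$lipid_mg),
        cells = harvest_density * 1.0,  # 1 mL aliquot
        dose_ug_per_l = dose, replicate = ri
      )
    }
  }

  structure(list(
    config = config,
    growth = growth,
    transients = do.call(rbind, transients),
    spectra = do.call(rbind, spectra),
    fa = do.call(rbind, fa_rows),
    assays = list(endpoint = do.call(rbind, endpoint_rows),
                  kinetic = do.call(rbind, kinetic_rows),
                  is_mass_ug = is_mass_ug),
    biochem = do.call(rbind, biochem_rows),
    ground_truth = gt
  ), class = "synthetic_bundle")
}
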