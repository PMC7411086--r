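#' Extract cardinal points from an OJIP transient
#'
#' Reads the fluorescence at the conventional cardinal times by linear
#' interpolation in log10-time between neighbouring samples: F0 at 50 us,
#' F300 at 300 us (K band region), FJ at 2 ms, FI at 30 ms; FM is the maximum
#' over the whole transient. A transient whose maximum does not exceed F0 is
#' flagged degenerate.
#'
#' @param transient `data.frame(time_s, fluorescence)`, strictly increasing
#'   times spanning at least 50 us to 30 ms.
#' @return List of class `cardinal_points`: `f0`, `f300`, `fj`, `fi`, `fm`,
#'   `t_fm` (time of the maximum, s), `degenerate`.
#' @export
extract_cardinal_points <- function(transient) {
  t <- transient$time_s; f <- transient$fluorescence
  stopifnot(length(t) >= 2, all(diff(t) > 0))
  at <- function(target) {
    if (target < min(t) || target > max(t)) {
      stop(sprintf("requested time %g s outside sampled range", target))
    }
    stats::approx(log10(t), f, xout = log10(target))$y
  }
  f0 <- at(5e-5); f300 <- at(3e-4); fj <- at(2e-3); fi <- at(3e-2)
  fm <- max(f)
  structure(list(f0 = f0, f300 = f300, fj = fj, fi = fi, fm = fm,
                 t_fm = t[which.max(f)], degenerate = !(fm > f0)),
            class = "cardinal_points")
}

#' JIP-test parameters from cardinal points
#'
#' Standard JIP-test (Strasser-school) definitions. Relative variable
#' fluorescence: `VJ = (FJ - F0)/(FM - F0)`, `VI = (FI - F0)/(FM - F0)`;
#' initial slope `M0 = 4 (F300 - F0)/(FM - F0)` per ms (the factor 4 is
#' 1/0.25 ms, the 50-300 us interval); `Area` is the area above the curve up
#' to FM (trapezoids on the raw time grid); normalized area `Sm = Area/FV`
#' (reported in ms), reaction-centre turnover `N = Sm * M0 / VJ`. Quantum
#' yields/efficiencies: `phi_P0 = 1 - F0/FM` (= FV/FM), `psi_E0 = 1 - VJ`,
#' `delta_R0 = (1 - VI)/(1 - VJ)`. Phenomenological fluxes per cross-section
#' use the F0 proxy for ABS/CS by default (`abs_cs_proxy = "f0"`; `"fm"`
#' selects the FM convention): `TR/CS = phi_P0 * ABS/CS`,
#' `ET/CS = phi_P0 * psi_E0 * ABS/CS`, `DI/CS = ABS/CS - TR/CS`,
#' `RC/ABS = phi_P0 * VJ / M0`, `RC/CS = RC/ABS * ABS/CS`. Derived ratios:
#' `TR0/DI0 = phi_P0/(1 - phi_P0)`, `psi_E0/(1 - psi_E0)`,
#' `delta_R0/(1 - delta_R0)`, `RE0/RC = (M0/VJ) * (1 - VI)`. The grouping
#' probability `P_G` is an experimental curvature index of the 100-300 us
#' relative variable fluorescence (see Details).
#'
#' @details `P_G` is computed as the mid-chord curvature of
#'   `W(t) = (F(t) - F0)/(FJ - F0)` over 100-300 us,
#'   `(W(200us) - (W(100us) + W(300us))/2) / (W(300us) - W(100us))`: positive
#'   curvature reflects the sigmoidicity attributed to energetic connectivity
#'   between PSII antenna units. The instrument's exact formula is not
#'   published, so this index is flagged experimental and should be compared
#'   only within an experiment.
#'
#' @param cardinals A `cardinal_points` object.
#' @param transient The transient the cardinals came from (needed for Area
#'   and `P_G`).
#' @param abs_cs_proxy `"f0"` (default) or `"fm"` cross-section convention;
#'   recorded in the output.
#' @return List of class `jip_parameters`. Degenerate transients (FM <= F0)
#'   return all derived fields as `NA` with `degenerate = TRUE`.
#' @export
compute_jip <- function(cardinals, transient, abs_cs_proxy = c("f0", "fm")) {
  abs_cs_proxy <- match.arg(abs_cs_proxy)
  cp <- cardinals
  if (cp$degenerate) {
    nas <- rep(NA_real_, 22)
    names(nas) <- c("vj", "vi", "m0", "area", "sm", "n", "phi_p0", "psi_e0",
                    "delta_r0", "abs_cs", "tr_cs", "et_cs", "di_cs", "rc_abs",
                    "rc_cs", "tr0_di0", "psi_ratio", "delta_ratio", "re0_rc",
                    "p_g", "vk", "fv")
    return(structure(c(as.list(nas), list(abs_cs_proxy = abs_cs_proxy,
                                          degenerate = TRUE)),
                     class = "jip_parameters"))
  }
  fv <- cp$fm - cp$f0
  vj <- (cp$fj - cp$f0) / fv
  vi <- (cp$fi - cp$f0) / fv
  vk <- (cp$f300 - cp$f0) / fv
  m0 <- 4 * vk                       # per ms
  t <- transient$time_s; f <- transient$fluorescence
  i_fm <- which.max(f)
  keep <- t >= 5e-5 & t <= t[i_fm]
  tt <- t[keep]; ff <- f[keep]
  area <- sum(diff(tt) * (2 * cp$fm - ff[-1] - ff[-length(ff)]) / 2)  # r.u.*s
  sm <- area / fv * 1000             # ms
  n <- sm * m0 / vj
  phi_p0 <- 1 - cp$f0 / cp$fm
  psi_e0 <- 1 - vj
  delta_r0 <- (1 - vi) / (1 - vj)
  abs_cs <- if (abs_cs_proxy == "f0") cp$f0 else cp$fm
  tr_cs <- phi_p0 * abs_cs
  et_cs <- phi_p0 * psi_e0 * abs_cs
  di_cs <- abs_cs - tr_cs
  rc_abs <- phi_p0 * vj / m0
  rc_cs <- rc_abs * abs_cs
  # experimental connectivity index from 100-300 us curvature of W(t)
  w <- function(target) {
    (stats::approx(log10(t), f, xout = log10(target))$y - cp$f0) /
      (cp$fj - cp$f0)
  }
  w1 <- w(1e-4); w2 <- w(2e-4); w3 <- w(3e-4)
  p_g <- if (abs(w3 - w1) > .Machine$double.eps^0.5) {
    (w2 - (w1 + w3) / 2) / (w3 - w1)
  } else NA_real_
  structure(list(
    vj = vj, vi = vi, vk = vk, m0 = m0, area = area, sm = sm, n = n,
    phi_p0 = phi_p0, psi_e0 = psi_e0, delta_r0 = delta_r0,
    abs_cs = abs_cs, tr_cs = tr_cs, et_cs = et_cs, di_cs = di_cs,
    rc_abs = rc_abs, rc_cs = rc_cs,
    tr0_di0 = phi_p0 / (1 - phi_p0),
    psi_ratio = psi_e0 / (1 - psi_e0),
    delta_ratio = delta_r0 / (1 - delta_r0),
    re0_rc = (m0 / vj) * (1 - vi),
    p_g = p_g, fv = fv,
    abs_cs_proxy = abs_cs_proxy, degenerate = FALSE
  ), class = "jip_parameters")
}

#' Fraction of active oxygen-evolving complexes relative to control
#'
#' `AOEC = [1 - VK/VJ]_sample / [1 - VK/VJ]_control`, where VK is the
#' relative variable fluorescence at 300 us (K band). A sample whose K step
#' rises to the J level (VK/VJ -> 1) has no active OECs (AOEC -> 0).
#'
#' @param sample_params,control_params `jip_parameters` objects.
#' @return Dimensionless fraction (1 when sample equals control).
#' @export
aoec_fraction <- function(sample_params, control_params) {
  denom <- 1 - control_params$vk / control_params$vj
  if (!is.finite(denom) || denom <= 0) {
    stop("control 1 - VK/VJ must be positive")
  }
  (1 - sample_params$vk / sample_params$vj) / denom
}

#' JIP analysis of a long-format transient table
#'
#' @param transients `data.frame(time_s, fluorescence, dose_ug_per_l,
#'   replicate)`.
#' @param abs_cs_proxy Cross-section convention, see [compute_jip()].
#' @return `data.frame` with one row per replicate carrying all JIP
#'   parameters plus `aoec` relative to the mean control VK/VJ.
#' @export
jip_analysis <- function(transients, abs_cs_proxy = "f0") {
  keys <- unique(transients[, c("dose_ug_per_l", "replicate")])
  pars <- lapply(seq_len(nrow(keys)), function(k) {
    tr <- transients[transients$dose_ug_per_l == keys$dose_ug_per_l[k] &
                       transients$replicate == keys$replicate[k], ]
    compute_jip(extract_cardinal_points(tr), tr, abs_cs_proxy)
  })
  num_fields <- c("vj", "vi", "vk", "m0", "area", "sm", "n", "phi_p0",
                  "psi_e0", "delta_r0", "abs_cs", "tr_cs", "et_cs", "di_cs",
                  "rc_abs", "rc_cs", "tr0_di0", "psi_ratio", "delta_ratio",
                  "re0_rc", "p_g")
  out <- cbind(keys, do.call(rbind, lapply(pars, function(p) {
    as.data.frame(p[num_fields])
  })))
  # AOEC against the control-group mean VK/VJ
  ctrl <- out[out$dose_ug_per_l == 0, ]
  if (nrow(ctrl) > 0) {
    denom <- 1 - mean(ctrl$vk / ctrl$vj)
    out$aoec <- if (denom > 0) (1 - out$vk / out$vj) / denom else NA_real_
  } else {
    out$aoec <- NA_real_
  }
  rownames(out) <- NULL
  out
}
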