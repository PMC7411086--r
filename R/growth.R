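#' Specific growth rate from a cell-density series
#'
#' Mean specific growth rate over a time window,
#' `mu = (ln N_final - ln N_initial) / dt`, with `dt` in days.
#'
#' @param series `data.frame` with columns `time_h` and
#'   `density_cells_per_ml` for a single replicate.
#' @param window Length-2 numeric, start and end times in hours; both must be
#'   sampled in `series`. Defaults to the full series range.
#' @return Growth rate, per day.
#' @export
specific_growth_rate <- function(series, window = range(series$time_h)) {
  stopifnot(all(c("time_h", "density_cells_per_ml") %in% names(series)))
  if (window[2] <= window[1]) stop("zero-length window")
  n0 <- series$density_cells_per_ml[series$time_h == window[1]]
  n1 <- series$density_cells_per_ml[series$time_h == window[2]]
  if (length(n0) != 1 || length(n1) != 1) {
    stop("window endpoints must each match exactly one sampled time")
  }
  if (n0 <= 0 || n1 <= 0) stop("densities must be positive")
  (log(n1) - log(n0)) / ((window[2] - window[1]) / 24)
}

#' Relative growth inhibition versus control
#'
#' Relative cell-density reduction of a treated culture toward its control at
#' a matched endpoint time: `(1 - N_treated / N_control) * 100`. Negative
#' values (growth stimulation) are retained and flagged via the
#' `"stimulated"` attribute.
#'
#' @param treated,control Endpoint cell densities (cells/mL), `control > 0`.
#' @return Inhibition percent (<= 100; negative when stimulated).
#' @export
relative_inhibition <- function(treated, control) {
  if (any(control <= 0)) stop("control density must be positive")
  out <- (1 - treated / control) * 100
  attr(out, "stimulated") <- any(out < 0)
  out
}

#' Fit an IC50 to per-dose growth inhibition
#'
#' Primary method: two-parameter log-logistic least squares of inhibition
#' percent against dose, `I(d) = 100 / (1 + (ic50/d)^h)`, with the control
#' (dose 0) anchoring the 0% asymptote (the model passes through 0 at dose 0
#' by construction, so the control point constrains nothing in log-dose
#' space). Fallback: log-linear interpolation of inhibition against
#' log10(dose) between the doses bracketing 50%. When 50% is not bracketed
#' and the fit does not converge inside the dose range, an explicit
#' "not reached" result is returned rather than an extrapolated number.
#'
#' @param doses Dose vector (>= 0).
#' @param inhibitions Matched inhibition percentages.
#' @param method `"loglogistic"` (default) or `"interpolation"`.
#' @return List of class `dose_response_fit`: `ic50`, `hill_slope`, `method`,
#'   `converged`, `residuals`, `inhibition` (per-dose table).
#' @export
fit_ic50 <- function(doses, inhibitions, method = c("loglogistic",
                                                    "interpolation")) {
  method <- match.arg(method)
  stopifnot(length(doses) == length(inhibitions))
  ord <- order(doses)
  doses <- doses[ord]; inhibitions <- inhibitions[ord]
  tab <- data.frame(dose_ug_per_l = doses, inhibition_pct = inhibitions)
  pos <- doses > 0
  bracketed <- any(inhibitions[pos] >= 50) && any(inhibitions <= 50)

  interp_ic50 <- function() {
    d <- doses[pos]; i <- inhibitions[pos]
    hi <- which(i >= 50)[1]
    if (is.na(hi)) return(NA_real_)
    if (i[hi] == 50) return(d[hi])
    if (hi == 1) return(NA_real_)  # 50% crossed below the lowest tested dose
    lo <- hi - 1
    10^(log10(d[lo]) + (50 - i[lo]) / (i[hi] - i[lo]) *
          (log10(d[hi]) - log10(d[lo])))
  }

  if (method == "interpolation") {
    ic <- interp_ic50()
    return(structure(list(
      ic50 = ic, hill_slope = NA_real_, method = "interpolation",
      converged = !is.na(ic), residuals = NULL, inhibition = tab,
      note = if (is.na(ic)) "IC50 not reached within tested doses" else NULL
    ), class = "dose_response_fit"))
  }

  d <- doses[pos]; i <- inhibitions[pos]
  if (length(d) < 2) stop("need at least two non-zero doses")
  obj <- function(par) {
    pred <- 100 * loglogistic_inhibition(d, exp(par[1]), exp(par[2]))
    sum((pred - i)^2)
  }
  start <- c(log(interp_ic50() %||% stats::median(d)), log(2))
  if (!is.finite(start[1])) start[1] <- log(stats::median(d))
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  ic <- exp(opt$par[1]); h <- exp(opt$par[2])
  resid <- i - 100 * loglogistic_inhibition(d, ic, h)
  converged <- opt$convergence == 0 && ic > 0
  in_range <- ic >= min(d) && ic <= max(d)
  if (!bracketed && !(converged && in_range)) {
    return(structure(list(
      ic50 = NA_real_, hill_slope = NA_real_, method = "loglogistic",
      converged = FALSE, residuals = resid, inhibition = tab,
      note = "IC50 not reached within tested doses"
    ), class = "dose_response_fit"))
  }
  structure(list(ic50 = ic, hill_slope = h, method = "loglogistic",
                 converged = converged, residuals = resid, inhibition = tab),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Dose-response fit (", x$method, ")\n", sep = "")
  if (is.na(x$ic50)) {
    cat("  IC50 not reached within tested doses\n")
  } else {
    cat(sprintf("  IC50 = %.2f ug/L", x$ic50))
    if (!is.na(x$hill_slope)) cat(sprintf(", hill slope = %.2f", x$hill_slope))
    cat("\n")
  }
  invisible(x)
}

#' Growth and inhibition summary for a full experiment
#'
#' Computes the per-replicate specific growth rate over the exposure window
#' and the relative cell-density reduction versus the mean control density at
#' the endpoint, then fits the IC50 on per-dose mean inhibition.
#'
#' @param growth Long growth table as produced by [generate_growth()].
#' @param exposure_window Length-2 hours, default `c(48, 96)`.
#' @param method IC50 method passed to [fit_ic50()].
#' @return List: `rates` (per replicate), `inhibition` (per dose), `fit`.
#' @export
growth_analysis <- function(growth, exposure_window = c(48, 96),
                            method = "loglogistic") {
  t_end <- exposure_window[2]
  keys <- unique(growth[, c("dose_ug_per_l", "replicate")])
  rates <- do.call(rbind, lapply(seq_len(nrow(keys)), function(k) {
    s <- growth[growth$dose_ug_per_l == keys$dose_ug_per_l[k] &
                  growth$replicate == keys$replicate[k], ]
    data.frame(dose_ug_per_l = keys$dose_ug_per_l[k],
               replicate = keys$replicate[k],
               mu_per_day = specific_growth_rate(s, exposure_window),
               endpoint_density = s$density_cells_per_ml[s$time_h == t_end])
  }))
  control_mean <- mean(rates$endpoint_density[rates$dose_ug_per_l == 0])
  if (!is.finite(control_mean) || control_mean <= 0) {
    stop("no valid control (dose 0) replicates at the endpoint")
  }
  per_dose <- stats::aggregate(endpoint_density ~ dose_ug_per_l, rates, mean)
  per_dose$inhibition_pct <- as.numeric(
    relative_inhibition(per_dose$endpoint_density, control_mean))
  fit <- fit_ic50(per_dose$dose_ug_per_l, per_dose$inhibition_pct,
                  method = method)
  list(rates = rates, inhibition = per_dose, fit = fit)
}
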