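#' Standard GPS wavelength grid
#'
#' 350-750 nm at 0.5 nm steps (801 points), the grid the spectrophotometer
#' protocol exports and on which all GPS fitting is performed.
#' @return Numeric vector of wavelengths, nm.
#' @export
gps_wavelengths <- function() seq(350, 750, by = 0.5)

#' Load a Gauss-peak-spectra pigment template library
#'
#' Each pigment is represented as a fixed sum of Gaussian peaks (center,
#' width, relative amplitude); a unit of concentration contributes the full
#' Gaussian sum to the spectrum. The shipped default covers the seven
#' pigments resolvable in diatom acetone extracts: chlorophyll a and c,
#' pheophytin a, beta-carotene, fucoxanthin, diadinoxanthin and diatoxanthin.
#' The shipped table is a synthetic parameterisation with literature-typical
#' acetone peak positions (see the file header for provenance notes); it can
#' be replaced by any CSV with the same columns.
#'
#' @param path CSV with columns `pigment, center_nm, sd_nm, amplitude`.
#'   Defaults to the library shipped with the package.
#' @return Object of class `gps_library`: list with `components`
#'   (the table) and `pigments` (names).
#' @export
gps_library <- function(path = system.file("extdata", "gps_library.csv",
                                           package = "phaeotox")) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("pigment", "center_nm", "sd_nm", "amplitude") %in%
                  names(tab)))
  if (any(tab$sd_nm <= 0) || any(tab$amplitude < 0)) {
    stop("library widths must be positive and amplitudes non-negative")
  }
  structure(list(components = tab, pigments = unique(tab$pigment)),
            class = "gps_library")
}

# unit-concentration template of one pigment on a wavelength grid
pigment_template <- function(library, pigment, wavelengths = gps_wavelengths()) {
  comp <- library$components[library$components$pigment == pigment, ]
  if (nrow(comp) == 0) stop(sprintf("pigment '%s' absent from library", pigment))
  out <- numeric(length(wavelengths))
  for (k in seq_len(nrow(comp))) {
    out <- out + comp$amplitude[k] *
      exp(-(wavelengths - comp$center_nm[k])^2 / (2 * comp$sd_nm[k]^2))
  }
  out
}

# template matrix (wavelengths x pigments)
template_matrix <- function(library, pigments = library$pigments,
                            wavelengths = gps_wavelengths()) {
  vapply(pigments, function(p) pigment_template(library, p, wavelengths),
         numeric(length(wavelengths)))
}

#' Forward GPS spectral model
#'
#' Pointwise sum of concentration-scaled pigment templates plus a smooth
#' baseline (constant + linear in wavelength, anchored at 350 nm).
#'
#' @param concentrations Named vector of pigment concentrations.
#' @param library A [gps_library()].
#' @param baseline_params `c(intercept_au, slope_au_per_nm)`.
#' @return `data.frame(wavelength_nm, absorbance)`.
#' @export
model_spectrum <- function(concentrations, library = gps_library(),
                           baseline_params = c(0, 0)) {
  wl <- gps_wavelengths()
  a <- numeric(length(wl))
  for (p in names(concentrations)) {
    a <- a + concentrations[[p]] * pigment_template(library, p, wl)
  }
  a <- a + baseline_params[1] + baseline_params[2] * (wl - 350)
  data.frame(wavelength_nm = wl, absorbance = a)
}

#' Deconvolute a spectrum into pigment concentrations (GPS fit)
#'
#' Linear GPS variant: the Gaussian shapes are fixed and only per-pigment
#' scales are fitted, by Lawson-Hanson non-negative least squares, together
#' with a sign-free constant + linear baseline (represented as +/- column
#' pairs so the problem stays pure NNLS). Spectra not on the standard grid
#' are linearly resampled to it.
#'
#' @param spectrum `data.frame(wavelength_nm, absorbance)`.
#' @param library A [gps_library()].
#' @return List of class `pigment_fit`: `concentrations` (named, template
#'   units), `baseline`, `residual_norm`, `relative_residual`, `converged`,
#'   and `gram_condition` (condition number of the normalized template Gram
#'   matrix, a collinearity diagnostic of the library itself).
#' @export
fit_pigments <- function(spectrum, library = gps_library()) {
  wl <- gps_wavelengths()
  b <- if (isTRUE(all.equal(spectrum$wavelength_nm, wl))) {
    spectrum$absorbance
  } else {
    stats::approx(spectrum$wavelength_nm, spectrum$absorbance, xout = wl,
                  rule = 2)$y
  }
  if (any(!is.finite(b))) stop("absorbance must be finite")
  tm <- template_matrix(library, wavelengths = wl)
  base1 <- rep(1, length(wl)); base2 <- (wl - 350) / 400
  a_mat <- cbind(tm, base1, -base1, base2, -base2)
  sol <- pracma::lsqnonneg(a_mat, b)
  x <- sol$x
  np <- length(library$pigments)
  conc <- stats::setNames(x[seq_len(np)], library$pigments)
  baseline <- c(intercept = x[np + 1] - x[np + 2],
                slope_per_nm = (x[np + 3] - x[np + 4]) / 400)
  fitted <- as.numeric(a_mat %*% x)
  rn <- sqrt(sum((b - fitted)^2))
  tm_n <- sweep(tm, 2, sqrt(colSums(tm^2)), "/")
  structure(list(
    concentrations = conc, baseline = baseline, residual_norm = rn,
    relative_residual = rn / max(sqrt(sum(b^2)), .Machine$double.eps),
    converged = TRUE,
    gram_condition = kappa(crossprod(tm_n), exact = TRUE)
  ), class = "pigment_fit")
}

#' Pigment deconvolution of a long-format spectra table
#'
#' @param spectra `data.frame(wavelength_nm, absorbance, dose_ug_per_l,
#'   replicate)`.
#' @param library A [gps_library()].
#' @return `data.frame` with one row per replicate: pigment concentrations,
#'   baseline terms and residual.
#' @export
pigment_analysis <- function(spectra, library = gps_library()) {
  keys <- unique(spectra[, c("dose_ug_per_l", "replicate")])
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    sp <- spectra[spectra$dose_ug_per_l == keys$dose_ug_per_l[k] &
                    spectra$replicate == keys$replicate[k], ]
    fit <- fit_pigments(sp, library)
    cbind(keys[k, ], as.data.frame(as.list(fit$concentrations)),
          residual_norm = fit$residual_norm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
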