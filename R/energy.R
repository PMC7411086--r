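#' Energy-budget constants
#'
#' Combustion energy equivalents (17,500 mJ/mg carbohydrate, 24,000 mJ/mg
#' protein, 39,500 mJ/mg lipid), the oxyenthalpic equivalent for an average
#' biomolecule mixture (480 kJ per mol O2), the INT-formazan extinction
#' coefficient at 490 nm, and the 2:1 formazan:O2 stoichiometry of the ETS
#' assay.
#'
#' The formazan coefficient is used as printed in the source protocol,
#' 15,900 in mM^-1 cm^-1. Literature for INT-formazan typically reports
#' about 15,900 M^-1 cm^-1; `formazan_unit = "per_M"` selects that reading.
#' The choice scales Ec (and hence CEA) by 10^3, so it is an explicit,
#' recorded switch rather than a guess.
#'
#' @param carb_mj_per_mg,protein_mj_per_mg,lipid_mj_per_mg Combustion
#'   equivalents, mJ/mg.
#' @param oxyenthalpic_kj_per_mol_o2 Energy per mol O2 consumed, kJ/mol.
#' @param eps_formazan INT-formazan extinction coefficient at 490 nm.
#' @param formazan_unit `"per_mM"` (as printed; default) or `"per_M"`.
#' @param formazan_per_o2 Stoichiometric ratio, umol formazan per umol O2.
#' @param path_cm Optical path length, cm.
#' @return List of class `energy_constants`.
#' @export
energy_constants <- function(carb_mj_per_mg = 17500,
                             protein_mj_per_mg = 24000,
                             lipid_mj_per_mg = 39500,
                             oxyenthalpic_kj_per_mol_o2 = 480,
                             eps_formazan = 15900,
                             formazan_unit = c("per_mM", "per_M"),
                             formazan_per_o2 = 2,
                             path_cm = 1) {
  formazan_unit <- match.arg(formazan_unit)
  vals <- c(carb_mj_per_mg, protein_mj_per_mg, lipid_mj_per_mg,
            oxyenthalpic_kj_per_mol_o2, eps_formazan, formazan_per_o2,
            path_cm)
  if (any(vals <= 0)) stop("all energy constants must be positive")
  structure(list(carb_mj_per_mg = carb_mj_per_mg,
                 protein_mj_per_mg = protein_mj_per_mg,
                 lipid_mj_per_mg = lipid_mj_per_mg,
                 oxyenthalpic_kj_per_mol_o2 = oxyenthalpic_kj_per_mol_o2,
                 eps_formazan = eps_formazan, formazan_unit = formazan_unit,
                 formazan_per_o2 = formazan_per_o2, path_cm = path_cm),
            class = "energy_constants")
}

#' Available energy (Ea) from biomolecule masses
#'
#' `Ea = 17,500 * carb + 24,000 * protein + 39,500 * lipid`, normalized to
#' 10^6 cells.
#'
#' @param carb_mg,protein_mg,lipid_mg Component masses in the sample, mg.
#' @param cells Cell count the masses came from (> 0).
#' @param constants An [energy_constants()] object.
#' @return Ea, mJ per 10^6 cells.
#' @export
available_energy <- function(carb_mg, protein_mg, lipid_mg, cells,
                             constants = energy_constants()) {
  if (any(c(carb_mg, protein_mg, lipid_mg) < 0)) stop("negative mass")
  if (any(cells <= 0)) stop("cells must be positive")
  (constants$carb_mj_per_mg * carb_mg +
     constants$protein_mj_per_mg * protein_mg +
     constants$lipid_mj_per_mg * lipid_mg) / (cells / 1e6)
}

#' Energy consumption (Ec) from ETS formazan kinetics
#'
#' The 490 nm absorbance rate is converted to a formazan production rate by
#' Beer-Lambert, halved to an O2 consumption rate via the 2:1
#' formazan:O2 stoichiometry, extrapolated to an hour, converted to energy
#' with the 480 kJ/mol O2 oxyenthalpic equivalent, and normalized to 10^6
#' cells.
#'
#' @param da490_per_min ETS absorbance rate, delta-A at 490 nm per minute
#'   (>= 0).
#' @param cells Cell count in the assayed aliquot (> 0).
#' @param constants An [energy_constants()] object.
#' @param reaction_vol_ml ETS reaction volume, mL.
#' @return Ec, mJ per 10^6 cells per hour.
#' @export
ets_consumption <- function(da490_per_min, cells,
                            constants = energy_constants(),
                            reaction_vol_ml = 0.2) {
  if (any(da490_per_min < 0)) stop("negative ETS rate")
  if (any(cells <= 0)) stop("cells must be positive")
  # formazan concentration rate in the well
  conc_mM_per_min <- if (constants$formazan_unit == "per_mM") {
    da490_per_min / (constants$eps_formazan * constants$path_cm)
  } else {
    1000 * da490_per_min / (constants$eps_formazan * constants$path_cm)
  }
  formazan_umol_per_h <- conc_mM_per_min * reaction_vol_ml * 60
  o2_umol_per_h <- formazan_umol_per_h / constants$formazan_per_o2
  # umol O2/h * (kJ/mol) = mJ/h
  mj_per_h <- o2_umol_per_h * constants$oxyenthalpic_kj_per_mol_o2
  mj_per_h / (cells / 1e6)
}

#' Cellular energy allocation
#'
#' `CEA = Ea / Ec`. Zero consumption yields an `NA` result with the
#' `"undefined"` attribute set instead of an infinity.
#'
#' @param ea Available energy, mJ per 10^6 cells.
#' @param ec Energy consumption, mJ per 10^6 cells per hour.
#' @return CEA (dimensionless x hours).
#' @export
cea <- function(ea, ec) {
  out <- ifelse(ec > 0, ea / ec, NA_real_)
  attr(out, "undefined") <- any(ec <= 0)
  out
}

#' Energy budget of a full experiment
#'
#' @param biochem `data.frame(carb_mg, protein_mg, lipid_mg, cells,
#'   dose_ug_per_l, replicate)`.
#' @param ets_rates `data.frame(dose_ug_per_l, replicate, da490_per_min)`.
#' @param constants An [energy_constants()] object.
#' @param reaction_vol_ml ETS reaction volume, mL.
#' @return Per-replicate `data.frame` with `ea`, `ec`, `cea`.
#' @export
energy_analysis <- function(biochem, ets_rates,
                            constants = energy_constants(),
                            reaction_vol_ml = 0.2) {
  m <- merge(biochem, ets_rates, by = c("dose_ug_per_l", "replicate"))
  m$ea <- available_energy(m$carb_mg, m$protein_mg, m$lipid_mg, m$cells,
                           constants)
  m$ec <- ets_consumption(m$da490_per_min, m$cells, constants,
                          reaction_vol_ml)
  m$cea <- as.numeric(cea(m$ea, m$ec))
  m[order(m$dose_ug_per_l, m$replicate), ]
}
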