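#' Spectrophotometric assay constants
#'
#' Molar extinction coefficients and cuvette geometry used by the
#' oxidative-stress conversions: MDA-TBA adduct 155 mM^-1 cm^-1 (A532 - A600),
#' H2O2 39.4 mM^-1 cm^-1 at 240 nm (catalase), ascorbate 2.8 mM^-1 cm^-1 at
#' 290 nm (ascorbate peroxidase); SOD uses pyrogallol autoxidation at 325 nm
#' and needs no coefficient. Reaction and extract volumes are explicit
#' because specific activities normalize by how much extract entered the
#' reaction.
#'
#' @param eps_mda,eps_cat,eps_apx Extinction coefficients, mM^-1 cm^-1.
#' @param path_cm Optical path length, cm.
#' @param reaction_vol_ml,extract_vol_ml Assay mixture and extract aliquot
#'   volumes, mL.
#' @return List of class `assay_constants`.
#' @export
assay_constants <- function(eps_mda = 155, eps_cat = 39.4, eps_apx = 2.8,
                            path_cm = 1, reaction_vol_ml = 1,
                            extract_vol_ml = 0.1) {
  stopifnot(eps_mda > 0, eps_cat > 0, eps_apx > 0, path_cm > 0,
            reaction_vol_ml > 0, extract_vol_ml > 0)
  structure(as.list(environment()), class = "assay_constants")
}

#' MDA concentration from TBARS endpoint absorbances
#'
#' Beer-Lambert conversion of the turbidity-corrected TBARS signal:
#' `C = (A532 - A600) / (eps_MDA * path) * dilution`, reported in uM.
#' A negative corrected absorbance is returned as 0 with the `"clipped"`
#' attribute set.
#'
#' @param a532,a600 Endpoint absorbances.
#' @param constants An [assay_constants()] object.
#' @param dilution Dilution factor of the extract.
#' @return MDA concentration, uM.
#' @export
mda_concentration <- function(a532, a600, constants = assay_constants(),
                              dilution = 1) {
  corrected <- a532 - a600
  clipped <- corrected < 0
  corrected[clipped] <- 0
  out <- corrected / (constants$eps_mda * constants$path_cm) * 1000 * dilution
  attr(out, "clipped") <- any(clipped)
  out
}

#' Absorbance change rate from a kinetic trace
#'
#' Least-squares slope of absorbance against time over a window, reported per
#' minute with the sign preserved (consumption assays give negative rates).
#'
#' @param trace `data.frame(time_s, absorbance)`.
#' @param window Length-2 seconds; defaults to the full trace.
#' @return Slope, delta-A per minute.
#' @export
kinetic_rate <- function(trace, window = range(trace$time_s)) {
  keep <- trace$time_s >= window[1] & trace$time_s <= window[2]
  if (sum(keep) < 3) stop("fewer than 3 points in window")
  fit <- stats::lm(absorbance ~ time_s, data = trace[keep, ])
  unname(stats::coef(fit)[2]) * 60
}

# shared Beer-Lambert specific-activity conversion for consumption assays:
# |dA/min| / (eps * path) [mM/min substrate turnover in the cuvette]
# * reaction volume / extract volume / protein -> nmol min^-1 mg^-1
consumption_activity <- function(rate_per_min, eps, constants, protein_mg,
                                 substrate) {
  if (protein_mg <= 0) stop("protein mass must be positive")
  flagged <- rate_per_min > 0
  # mM/min turnover in the cuvette, scaled to the extract aliquot:
  # umol/min = mM/min * reaction volume (mL); *1000 -> nmol/min
  structure(list(
    activity = abs(rate_per_min) / (eps * constants$path_cm) *
      constants$reaction_vol_ml * 1000 / constants$extract_vol_ml / protein_mg,
    unit = paste0("nmol ", substrate, " min^-1 mg protein^-1"),
    protein_mg = protein_mg, increasing_flag = flagged
  ), class = "enzyme_activity")
}

#' Catalase activity from the 240 nm H2O2 consumption rate
#'
#' `|dA240/min| / (eps_CAT * path)` gives the mM/min H2O2 turnover in the
#' cuvette; scaling by reaction volume over extract volume and normalizing by
#' protein yields nmol H2O2 min^-1 mg protein^-1. An increasing absorbance
#' (positive rate) is physically unexpected and sets `increasing_flag`.
#'
#' @param rate_per_min Kinetic rate from [kinetic_rate()] (expected <= 0).
#' @param constants An [assay_constants()] object.
#' @param protein_mg Protein content of the extract, mg/mL (the quantity a
#'   Bradford assay of the extract reports).
#' @return `enzyme_activity` list: `activity`, `unit`, `protein_mg`,
#'   `increasing_flag`.
#' @export
catalase_activity <- function(rate_per_min, constants = assay_constants(),
                              protein_mg) {
  consumption_activity(rate_per_min, constants$eps_cat, constants, protein_mg,
                       "H2O2")
}

#' Ascorbate peroxidase activity from the 290 nm ascorbate oxidation rate
#'
#' Same Beer-Lambert arithmetic as [catalase_activity()] with
#' eps = 2.8 mM^-1 cm^-1; units nmol ascorbate min^-1 mg protein^-1.
#'
#' @inheritParams catalase_activity
#' @return `enzyme_activity` list.
#' @export
apx_activity <- function(rate_per_min, constants = assay_constants(),
                         protein_mg) {
  consumption_activity(rate_per_min, constants$eps_apx, constants, protein_mg,
                       "ascorbate")
}

#' Superoxide dismutase activity from pyrogallol autoxidation inhibition
#'
#' `inhibition % = (1 - sample_rate / control_rate) * 100` where the control
#' is the substrate autoxidation rate without extract. Units follow the
#' Marklund convention: 1 U = 50% inhibition, normalized per mg protein.
#' Inhibition outside [0, 100] is clipped with a flag.
#'
#' @param sample_rate,autoxidation_control_rate Pyrogallol 325 nm rates,
#'   delta-A per minute; control must be positive.
#' @param protein_mg Protein content of the extract, mg/mL.
#' @return `enzyme_activity` list: `inhibition_pct`, `activity` (U/mg),
#'   `clipped`.
#' @export
sod_activity <- function(sample_rate, autoxidation_control_rate, protein_mg) {
  if (autoxidation_control_rate <= 0) {
    stop("autoxidation control rate must be positive")
  }
  if (protein_mg <= 0) stop("protein mass must be positive")
  inh <- (1 - sample_rate / autoxidation_control_rate) * 100
  clipped <- inh < 0 || inh > 100
  inh_c <- min(max(inh, 0), 100)
  structure(list(
    inhibition_pct = inh_c, activity = (inh_c / 50) / protein_mg,
    unit = "U mg protein^-1 (1 U = 50% inhibition)",
    protein_mg = protein_mg, clipped = clipped
  ), class = "enzyme_activity")
}

#' Oxidative-stress assay battery over an experiment
#'
#' Converts the endpoint and kinetic tables of a bundle into per-replicate
#' MDA concentration and CAT/APX/SOD specific activities.
#'
#' @param endpoint `data.frame(a532, a600, sod_sample_rate, sod_control_rate,
#'   protein_mg, dose_ug_per_l, replicate)`.
#' @param kinetic Long `data.frame(time_s, absorbance, assay, dose_ug_per_l,
#'   replicate)` with assays `"cat"` and `"apx"`.
#' @param constants An [assay_constants()] object.
#' @return `data.frame` per replicate: `mda_um`, `cat_activity`,
#'   `apx_activity`, `sod_u_per_mg`, `sod_inhibition_pct`.
#' @export
assay_analysis <- function(endpoint, kinetic, constants = assay_constants()) {
  rows <- lapply(seq_len(nrow(endpoint)), function(k) {
    e <- endpoint[k, ]
    tr <- function(a) kinetic[kinetic$assay == a &
                                kinetic$dose_ug_per_l == e$dose_ug_per_l &
                                kinetic$replicate == e$replicate, ]
    cat_act <- catalase_activity(kinetic_rate(tr("cat")), constants,
                                 e$protein_mg)
    apx_act <- apx_activity(kinetic_rate(tr("apx")), constants, e$protein_mg)
    sod <- sod_activity(e$sod_sample_rate, e$sod_control_rate, e$protein_mg)
    data.frame(dose_ug_per_l = e$dose_ug_per_l, replicate = e$replicate,
               mda_um = as.numeric(mda_concentration(e$a532, e$a600,
                                                     constants)),
               cat_activity = cat_act$activity,
               apx_activity = apx_act$activity,
               sod_u_per_mg = sod$activity,
               sod_inhibition_pct = sod$inhibition_pct)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
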