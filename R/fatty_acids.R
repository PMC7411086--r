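#' Parse a fatty-acid identifier
#'
#' Identifiers follow the `Cx:y` convention with an optional omega position
#' suffix (`C16:2n-7`, `C20:5n3`). The positional suffix is carried but does
#' not enter any computed statistic.
#'
#' @param fa_id Character vector of identifiers.
#' @return `data.frame(fa_id, chain_length, double_bonds)`.
#' @export
parse_fa_id <- function(fa_id) {
  m <- regmatches(fa_id, regexec("^C(\\d+):(\\d+)(n-?\\d+)?$", fa_id))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) {
    stop("unparseable fatty-acid identifier(s): ",
         paste(fa_id[bad], collapse = ", "))
  }
  data.frame(
    fa_id = fa_id,
    chain_length = vapply(m, function(x) as.integer(x[2]), integer(1)),
    double_bonds = vapply(m, function(x) as.integer(x[3]), integer(1))
  )
}

#' Quantify a FAME peak table against the internal standard
#'
#' Peak-surface quantification: `mass_i = area_i / area_IS * mass_IS` with
#' pentadecanoic acid (C15:0) as the internal standard, plus relative percent
#' of total identified fatty acids (internal standard excluded from the sum).
#'
#' @param peak_table `data.frame(fa_id, peak_area)` for one sample, with the
#'   internal standard either flagged by a logical `is_standard` column or
#'   identified by `is_id`.
#' @param is_mass Mass of internal standard added (any mass unit; output
#'   masses share it).
#' @param is_id Identifier of the internal standard row when no
#'   `is_standard` column is present.
#' @return `data.frame` of class `fatty_acid_profile`: `fa_id`,
#'   `chain_length`, `double_bonds`, `peak_area`, `mass`, `relative_pct`
#'   (sums to 100 over non-IS rows).
#' @export
quantify_fa <- function(peak_table, is_mass, is_id = "C15:0") {
  stopifnot(all(c("fa_id", "peak_area") %in% names(peak_table)))
  is_row <- if ("is_standard" %in% names(peak_table)) {
    peak_table$is_standard
  } else {
    peak_table$fa_id == is_id
  }
  if (sum(is_row) != 1) stop("exactly one internal standard row required")
  area_is <- peak_table$peak_area[is_row]
  if (area_is <= 0) stop("internal standard area must be positive")
  fa <- peak_table[!is_row, , drop = FALSE]
  parsed <- parse_fa_id(fa$fa_id)
  out <- data.frame(
    fa_id = fa$fa_id,
    chain_length = parsed$chain_length,
    double_bonds = parsed$double_bonds,
    peak_area = fa$peak_area,
    mass = fa$peak_area / area_is * is_mass,
    relative_pct = 100 * fa$peak_area / sum(fa$peak_area)
  )
  class(out) <- c("fatty_acid_profile", "data.frame")
  out
}

#' Saturation classes, ratios and the double bond index
#'
#' Classes by double-bond count: SFA (0), MUFA (1), PUFA (>= 2);
#' UFA = MUFA + PUFA. The double bond index is
#' `DBI = 2 * (%monoenes + 2*%dienes + 3*%trienes + 4*%tetraenes +
#' 5*%pentaenes) / 100`. Fatty acids with more than five double bonds extend
#' the same pattern (coefficient = bond count) with a warning, as the printed
#' formula stops at pentaenes.
#'
#' @param profile A [quantify_fa()] result (or any data.frame with
#'   `double_bonds` and `relative_pct`).
#' @return List of class `saturation_summary`: `sfa_pct`, `mufa_pct`,
#'   `pufa_pct`, `ufa_pct`, `sfa_ufa`, `pufa_sfa`, `dbi`.
#' @export
saturation_summary <- function(profile) {
  db <- profile$double_bonds; pct <- profile$relative_pct
  if (any(db > 5)) {
    warning("fatty acids with > 5 double bonds: DBI pattern extended ",
            "beyond pentaenes")
  }
  sfa <- sum(pct[db == 0]); mufa <- sum(pct[db == 1])
  pufa <- sum(pct[db >= 2]); ufa <- mufa + pufa
  dbi <- 2 * sum(db * pct) / 100
  structure(list(
    sfa_pct = sfa, mufa_pct = mufa, pufa_pct = pufa, ufa_pct = ufa,
    sfa_ufa = if (ufa > 0) sfa / ufa else NA_real_,
    pufa_sfa = if (sfa > 0) pufa / sfa else NA_real_,
    dbi = dbi
  ), class = "saturation_summary")
}

#' Fatty-acid analysis of a long-format peak table
#'
#' @param fa_table `data.frame(fa_id, peak_area, is_standard, dose_ug_per_l,
#'   replicate)`.
#' @param is_mass Internal standard mass per sample.
#' @return List: `profiles` (long per-replicate relative abundances),
#'   `summaries` (per-replicate saturation summary rows).
#' @export
fa_analysis <- function(fa_table, is_mass) {
  keys <- unique(fa_table[, c("dose_ug_per_l", "replicate")])
  profiles <- list(); summaries <- list()
  for (k in seq_len(nrow(keys))) {
    tab <- fa_table[fa_table$dose_ug_per_l == keys$dose_ug_per_l[k] &
                      fa_table$replicate == keys$replicate[k], ]
    prof <- quantify_fa(tab, is_mass)
    s <- saturation_summary(prof)
    prof$dose_ug_per_l <- keys$dose_ug_per_l[k]
    prof$replicate <- keys$replicate[k]
    profiles[[k]] <- prof
    summaries[[k]] <- cbind(keys[k, ], as.data.frame(unclass(s)))
  }
  out_p <- do.call(rbind, profiles); rownames(out_p) <- NULL
  out_s <- do.call(rbind, summaries); rownames(out_s) <- NULL
  list(profiles = out_p, summaries = out_s)
}
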