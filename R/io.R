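#' Read a typed CSV table with schema checking
#'
#' Comma-delimited UTF-8 CSV with a header; lines starting with `#`
#' (provenance comments) are ignored. Required columns are checked and
#' coerced to the schema's types; rows failing numeric coercion are reported
#' with their file line numbers. In strict mode (default) any bad row is an
#' error; in permissive mode bad rows are dropped and collected in the
#' `"row_errors"` attribute.
#'
#' @param path File path.
#' @param schema Named character vector mapping required column names to
#'   `"numeric"` or `"character"`.
#' @param permissive Drop bad rows instead of failing.
#' @param dec Decimal separator: `"."` (default) or `","` for European
#'   instrument exports (then the delimiter is `";"`).
#' @return `data.frame` with the schema's columns typed (extra columns kept).
#' @export
read_table <- function(path, schema, permissive = FALSE, dec = ".") {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dec == ",") ";" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(names(schema), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  # file line of each data row (header + any leading comment lines offset)
  first_lines <- readLines(path, n = 200L)
  n_comment <- which(!startsWith(first_lines, "#"))[1] - 1L
  line_no <- seq_len(nrow(raw)) + 1L + n_comment
  bad <- rep(FALSE, nrow(raw))
  for (col in names(schema)) {
    if (schema[[col]] == "numeric") {
      val <- raw[[col]]
      if (dec == ",") val <- gsub(",", ".", val, fixed = TRUE)
      coerced <- suppressWarnings(as.numeric(val))
      bad <- bad | is.na(coerced) & !is.na(raw[[col]]) | is.na(raw[[col]])
      raw[[col]] <- coerced
    }
  }
  if (any(bad)) {
    msg <- paste0("unparseable value(s) at line(s) ",
                  paste(line_no[bad], collapse = ", "))
    if (!permissive) stop(msg)
    errors <- data.frame(line = line_no[bad])
    raw <- raw[!bad, , drop = FALSE]
    attr(raw, "row_errors") <- errors
    warning(msg, " (rows dropped)")
  }
  rownames(raw) <- NULL
  raw
}

#' Write a CSV table with a provenance header
#'
#' Prepends a `#` comment line carrying the run seed, the config hash and the
#' content hash of the written values, so every output names where it came
#' from. [read_table()] skips the comment on the way back in.
#'
#' @param x `data.frame` to write.
#' @param path Output path.
#' @param seed,config_hash Run provenance to record.
#' @return Invisibly, the content hash.
#' @export
write_table <- function(x, path, seed = NA, config_hash = "") {
  ch <- content_hash(paste(utils::capture.output(
    utils::write.csv(x, row.names = FALSE)), collapse = "\n"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# provenance: seed=%s config_hash=%s content_hash=%s",
                     seed, config_hash, ch), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(ch)
}

# 31-bit polynomial rolling hash (hex); lightweight provenance fingerprint.
# (Multiplications stay below 2^53 so double arithmetic is exact.)
content_hash <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read a pipeline run configuration
#'
#' YAML file with optional sections `experiment` (arguments of
#' [experiment_config()]), `assay_constants`, `energy_constants`, and
#' `analysis` switches (`abs_cs_proxy`, `ic50_method`, `cap_m_rule`,
#' `n_perm`, `alpha`).
#'
#' @param path YAML file.
#' @return Nested list with all defaults filled in.
#' @export
read_run_config <- function(path) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  build_run_config(raw)
}

build_run_config <- function(raw = list()) {
  analysis_defaults <- list(abs_cs_proxy = "f0", ic50_method = "loglogistic",
                            cap_m_rule = "max_loo", n_perm = 999,
                            alpha = 0.05)
  analysis <- utils::modifyList(analysis_defaults, raw$analysis %||% list())
  list(
    experiment = do.call(experiment_config, raw$experiment %||% list()),
    assay_constants = do.call(assay_constants,
                              raw$assay_constants %||% list()),
    energy_constants = do.call(energy_constants,
                               raw$energy_constants %||% list()),
    analysis = analysis
  )
}

#' Run the full analysis pipeline on a synthetic experiment
#'
#' Generates the configured synthetic bundle, then runs every analysis stage
#' in order - growth/IC50, JIP-test, pigment deconvolution, fatty acids,
#' oxidative-stress assays, energy budget, and the statistics/CAP stage -
#' writing one CSV per stage plus a machine-readable JSON summary and a log
#' naming constants, switches and seeds. Any stage failure aborts with a
#' stage-scoped message; outputs of completed stages are kept.
#'
#' @param config Path to a YAML run config, a list as returned by
#'   [read_run_config()], or NULL for all defaults.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with every stage result and the summary.
#' @export
run_pipeline <- function(config = NULL, outdir = "phaeotox_results") {
  cfg <- if (is.character(config)) read_run_config(config)
         else if (is.null(config)) build_run_config()
         else config
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$experiment$seed
  config_hash <- content_hash(paste(deparse(cfg), collapse = ""))
  log_path <- file.path(outdir, "run_log.txt")
  log_lines <- c(sprintf("phaeotox %s", as.character(
                   utils::packageVersion("phaeotox"))),
                 sprintf("seed: %d", seed),
                 sprintf("config_hash: %s", config_hash),
                 sprintf("abs_cs_proxy: %s", cfg$analysis$abs_cs_proxy),
                 sprintf("ic50_method: %s", cfg$analysis$ic50_method),
                 sprintf("formazan_unit: %s",
                         cfg$energy_constants$formazan_unit),
                 sprintf("cap_m_rule: %s n_perm: %d",
                         as.character(cfg$analysis$cap_m_rule),
                         cfg$analysis$n_perm))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, sprintf("FAILED at stage '%s': %s", name,
                                      conditionMessage(e))), log_path)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  emit <- function(x, name) {
    write_table(x, file.path(outdir, paste0(name, ".csv")), seed, config_hash)
  }

  bundle <- stage("simulate", generate_bundle(cfg$experiment))
  emit(bundle$growth, "growth_series")

  growth <- stage("growth", growth_analysis(
    bundle$growth, method = cfg$analysis$ic50_method))
  emit(growth$rates, "growth_rates")
  emit(growth$inhibition, "growth_inhibition")

  jip <- stage("jip", jip_analysis(bundle$transients,
                                   cfg$analysis$abs_cs_proxy))
  emit(jip, "jip_parameters")

  pig <- stage("pigments", pigment_analysis(bundle$spectra))
  emit(pig, "pigments")

  fa <- stage("fatty_acids", fa_analysis(bundle$fa, bundle$assays$is_mass_ug))
  emit(fa$profiles, "fatty_acid_profiles")
  emit(fa$summaries, "fatty_acid_summaries")

  assays <- stage("assays", assay_analysis(bundle$assays$endpoint,
                                           bundle$assays$kinetic,
                                           cfg$assay_constants))
  emit(assays, "oxidative_stress")

  energy <- stage("energy", {
    kin <- bundle$assays$kinetic
    ets_keys <- unique(kin[kin$assay == "ets", c("dose_ug_per_l",
                                                 "replicate")])
    ets_rates <- do.call(rbind, lapply(seq_len(nrow(ets_keys)), function(k) {
      tr <- kin[kin$assay == "ets" &
                  kin$dose_ug_per_l == ets_keys$dose_ug_per_l[k] &
                  kin$replicate == ets_keys$replicate[k], ]
      data.frame(dose_ug_per_l = ets_keys$dose_ug_per_l[k],
                 replicate = ets_keys$replicate[k],
                 da490_per_min = kinetic_rate(tr))
    }))
    energy_analysis(bundle$biochem, ets_rates, cfg$energy_constants)
  })
  emit(energy, "energy_budget")

  stats_out <- stage("stats", {
    endpoints <- list(mu = growth$rates$mu_per_day,
                      phi_p0 = jip$phi_p0, abs_cs = jip$abs_cs,
                      dbi = fa$summaries$dbi, ea = energy$ea, ec = energy$ec,
                      cea = energy$cea)
    dose_of <- list(mu = growth$rates$dose_ug_per_l,
                    phi_p0 = jip$dose_ug_per_l, abs_cs = jip$dose_ug_per_l,
                    dbi = fa$summaries$dose_ug_per_l,
                    ea = energy$dose_ug_per_l, ec = energy$dose_ug_per_l,
                    cea = energy$dose_ug_per_l)
    do.call(rbind, lapply(names(endpoints), function(nm) {
      v <- endpoints[[nm]]; d <- dose_of[[nm]]
      kw <- kruskal_wallis_letters(v, d, cfg$analysis$alpha)
      sp <- spearman_dose(v, d)
      data.frame(endpoint = nm, kw_h = kw$h, kw_p = kw$p_value,
                 spearman_rho = sp$rho, signed_rho_sq = sp$signed_rho_sq,
                 spearman_p = sp$p_value)
    }))
  })
  emit(stats_out, "univariate_stats")

  cap_out <- stage("cap", {
    optical <- transient_feature_matrix(bundle$transients)
    fa_wide <- fa_feature_matrix(fa$profiles)
    list(optical = cap(optical$features, optical$groups,
                       m_rule = cfg$analysis$cap_m_rule,
                       n_perm = cfg$analysis$n_perm, seed = seed),
         fatty_acids = cap(fa_wide$features, fa_wide$groups,
                           m_rule = cfg$analysis$cap_m_rule,
                           n_perm = cfg$analysis$n_perm, seed = seed))
  })
  emit(as.data.frame(cap_out$optical$confusion), "cap_optical_confusion")
  emit(as.data.frame(cap_out$fatty_acids$confusion), "cap_fa_confusion")

  summary <- list(
    seed = seed, config_hash = config_hash,
    ic50_ug_per_l = growth$fit$ic50, ic50_method = growth$fit$method,
    hill_slope = growth$fit$hill_slope,
    inhibition_pct = stats::setNames(
      as.list(growth$inhibition$inhibition_pct),
      paste0("dose_", growth$inhibition$dose_ug_per_l)),
    cap_optical_accuracy_pct = cap_out$optical$accuracy_pct,
    cap_optical_p = cap_out$optical$p_permutation,
    cap_fa_accuracy_pct = cap_out$fatty_acids$accuracy_pct,
    cap_fa_p = cap_out$fatty_acids$p_permutation,
    mean_dbi = mean(fa$summaries$dbi),
    mean_cea_control = mean(energy$cea[energy$dose_ug_per_l == 0])
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(log_lines, "status: complete"), log_path)
  invisible(list(bundle = bundle, growth = growth, jip = jip,
                 pigments = pig, fatty_acids = fa, assays = assays,
                 energy = energy, stats = stats_out, cap = cap_out,
                 summary = summary))
}

#' Wide feature matrix from long transients (bio-optical CAP input)
#'
#' Each sample's features are the raw fluorescence values at every sampled
#' time of the Kautsky curve.
#'
#' @param transients Long transient table.
#' @return List: `features` (matrix), `groups` (dose labels).
#' @export
transient_feature_matrix <- function(transients) {
  keys <- unique(transients[, c("dose_ug_per_l", "replicate")])
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    tr <- transients[transients$dose_ug_per_l == keys$dose_ug_per_l[k] &
                       transients$replicate == keys$replicate[k], ]
    tr$fluorescence[order(tr$time_s)]
  })
  n_t <- unique(vapply(rows, length, integer(1)))
  if (length(n_t) != 1) stop("transients must share one time grid")
  list(features = do.call(rbind, rows), groups = keys$dose_ug_per_l)
}

#' Wide feature matrix from fatty-acid profiles (FA CAP input)
#'
#' @param profiles Long per-replicate profile table from [fa_analysis()].
#' @return List: `features` (relative abundance matrix, one column per FA),
#'   `groups` (dose labels).
#' @export
fa_feature_matrix <- function(profiles) {
  wide <- stats::reshape(
    profiles[, c("fa_id", "relative_pct", "dose_ug_per_l", "replicate")],
    idvar = c("dose_ug_per_l", "replicate"), timevar = "fa_id",
    direction = "wide")
  feat <- as.matrix(wide[, grep("^relative_pct", names(wide))])
  if (any(is.na(feat))) stop("missing fatty acids in some replicates")
  list(features = feat, groups = wide$dose_ug_per_l)
}
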