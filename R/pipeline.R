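# End-to-end pipeline: simulate -> features -> stats -> classify ---------

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Run the full synthetic mfVEP experiment
#'
#' One-command replication: calibrates the group presets (unless
#' pre-calibrated presets are supplied), simulates the cohort, builds the
#' normative database, extracts per-eye and per-patient features, runs the
#' group statistics and Kaplan-Meier analysis, and cross-validates the
#' RUSBoost classifier on (`SNR_min`, `b_max`).  All outputs are plain CSV
#' and JSON under `out_dir`, each run reproducible byte-for-byte from
#' `seed`.
#'
#' @param out_dir output directory (created if missing).
#' @param seed global seed; every stage derives its randomness from it.
#' @param n_conv,n_nonconv cohort composition (defaults replicate the
#'   5 / 10 study cohort).
#' @param config a [generator_config()].
#' @param presets calibrated presets, or `NULL` to calibrate now with
#'   `cal_n_*` batch sizes.
#' @param cal_n_snr,cal_n_noise,cal_n_bmax calibration batch sizes (see
#'   [calibrate_preset()]).
#' @param normdb a [normative_db()], a path to a normative-database CSV
#'   written by [write_normative_db()], or `NULL` to build one from
#'   `normdb_n` healthy eyes.
#' @param normdb_n healthy eyes for the normative database.
#' @param folds,n_rounds,tree_depth,ratio classifier settings.
#' @return (invisibly) list with `patients`, `eyes`, `group_stats`, `km`,
#'   `classifier`, `provenance`.
#' @export
run_pipeline <- function(out_dir, seed = 1, n_conv = 5, n_nonconv = 10,
                         config = generator_config(), presets = NULL,
                         cal_n_snr = 400, cal_n_noise = 100,
                         cal_n_bmax = 200, normdb = NULL, normdb_n = 8,
                         folds = NULL, n_rounds = 30, tree_depth = 2,
                         ratio = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  windows <- window_spec()
  scales <- cwt_default_scales()
  params <- list(seed = seed, n_conv = n_conv, n_nonconv = n_nonconv,
                 config = config[setdiff(names(config), "seed")],
                 cal_n_snr = cal_n_snr, cal_n_noise = cal_n_noise,
                 cal_n_bmax = cal_n_bmax, normdb_n = normdb_n,
                 folds = folds, n_rounds = n_rounds,
                 tree_depth = tree_depth, ratio = ratio)
  hash <- config_hash(params)

  if (is.null(presets))
    presets <- stage("calibrate", calibrate_presets(
      mfvep_presets(), config, seed = seed + 7L, n_snr = cal_n_snr,
      n_noise = cal_n_noise, n_bmax = cal_n_bmax))

  cohort <- stage("simulate", generate_cohort(
    n_conv, n_nonconv, config, presets, seed = seed))

  ndb <- stage("features", {
    if (is.character(normdb)) {
      if (!file.exists(normdb))
        stop("normative database file not found: ", normdb)
      read_normative_db(normdb)
    } else normdb %||%
      build_normative_db(normdb_n, config, presets$healthy,
                         seed = seed + 11L)
  })
  feats <- stage("features",
                 cohort_features(cohort, ndb, windows, scales))

  gs <- stage("stats", compare_groups(feats$patients))
  km <- stage("stats", km_estimate(cohort$events))

  cls <- stage("classify", {
    Xy <- feats$patients
    cross_validate(Xy[, c("snr_min", "bmax_ms")],
                   as.integer(Xy$group == "RIS_conv"),
                   folds = folds %||% nrow(Xy), seed = seed + 23L,
                   n_rounds = n_rounds, tree_depth = tree_depth,
                   ratio = ratio)
  })

  prov <- list(package = "mfvepris",
               version = as.character(utils::packageVersion("mfvepris")),
               seed = seed, config_hash = hash,
               presets = lapply(presets, function(p)
                 p[c("label", "target_eye_snr", "target_bmax",
                     "dispersion_factor", "amplitude_scale", "peak_time")]))

  wj <- function(x, file) jsonlite::write_json(
    x, file.path(out_dir, file), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, force = TRUE)
  utils::write.csv(feats$eyes, file.path(out_dir, "eye_features.csv"),
                   row.names = FALSE)
  write_patient_table(feats$patients, file.path(out_dir, "patients.csv"))
  utils::write.csv(cohort$events, file.path(out_dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(time = km$time, n_risk = km$n_risk,
                              n_event = km$n_event, n_censor = km$n_censor,
                              surv = km$surv),
                   file.path(out_dir, "km_curve.csv"), row.names = FALSE)
  wj(gs, "group_stats.json")
  wj(list(sensitivity = cls$sensitivity, specificity = cls$specificity,
          auc = cls$auc,
          confusion = as.data.frame(cls$confusion),
          training = cls$training, folds = cls$folds),
     "classifier_report.json")
  wj(prov, "provenance.json")

  invisible(list(patients = feats$patients, eyes = feats$eyes,
                 group_stats = gs, km = km, classifier = cls,
                 presets = presets, provenance = prov))
}

#' Write / read a normative database as CSV
#'
#' Plain-text persistence of the 60 x 600 template matrix.
#'
#' @param ndb a [normative_db()].
#' @param path file path.
#' @return `read_normative_db` returns the database; the writer its path,
#'   invisibly.
#' @export
write_normative_db <- function(ndb, path) {
  utils::write.table(format(ndb$templates, digits = 17, trim = TRUE,
                            scientific = TRUE),
                     path, row.names = FALSE, col.names = FALSE, sep = ",",
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_normative_db
#' @export
read_normative_db <- function(path) {
  m <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(m) <- NULL
  normative_db(m)
}
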