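#' Run the full pipeline: simulate, featurize, train, evaluate
#'
#' Drives every stage end-to-end from a single configuration: generates the
#' synthetic paired study, computes window power spectra and paired RMS
#' targets, trains and evaluates the state classifier (and, when requested,
#' the RMS regressor) under the configured protocols, and optionally writes
#' every intermediate artifact plus a JSON report under `out_dir`. A run is
#' reproducible from its configuration alone: one global seed fans out
#' deterministically to every stochastic stage.
#'
#' @param config A `run_config` from [read_run_config()] / [as_run_config()],
#'   or a plain list of overrides.
#' @param out_dir Optional output directory; when given, the study, the
#'   feature matrix and a `report.json` are written there.
#' @param tasks Which models to run: subset of `c("classify", "regress")`.
#'   Regression trains a CNN per evaluated fold and dominates runtime.
#' @return A named list of `eval_report` objects (invisibly when writing).
#' @export
run_pipeline <- function(config = as_run_config(), out_dir = NULL,
                         tasks = c("classify", "regress")) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  tasks <- match.arg(tasks, several.ok = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  profiles <- stage("profiles", default_profiles(
    config$study$n_subjects, seed = config$seed,
    base_amp = config$study$base_amp))
  channels <- if ("regress" %in% tasks) c("ppg", "emg") else "ppg"
  study <- stage("simulate", generate_study(
    profiles, config$study$reps_per_state, config$study$duration_s,
    channels = channels, seed = config$seed))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stage("write-study", write_study(study, file.path(out_dir, "study")))
    feats <- stage("featurize", featurize_study(
      study, config$windowing$window_s, config$windowing$overlap_frac,
      config$windowing$drop_dc))
    stage("write-features",
          write_features(feats, file.path(out_dir, "features.tsv")))
  }

  reports <- list()
  subjects <- unique(study$subject_id)
  reg_cfg <- do.call(cnn_config, c(config$regressor, list(seed = config$seed)))

  if ("dependent" %in% config$protocol) {
    if ("classify" %in% tasks) {
      reports$classify_dependent <- stage("cv-classify", purrr::map(
        rlang::set_names(subjects), function(s) {
          cv_user_dependent(dplyr::filter(study, .data$subject_id == s),
                            k = config$k, task = "classify",
                            seed = config$seed, merge = config$classifier$merge)
        }))
    }
    if ("regress" %in% tasks) {
      reports$regress_dependent <- stage("cv-regress", purrr::map(
        rlang::set_names(subjects), function(s) {
          cv_user_dependent(dplyr::filter(study, .data$subject_id == s),
                            k = config$k, task = "regress",
                            seed = config$seed, config = reg_cfg,
                            folds = config$regression_folds)
        }))
    }
  }
  if ("independent" %in% config$protocol && "classify" %in% tasks) {
    reports$classify_independent <- stage("loso-classify", purrr::map(
      rlang::set_names(subjects), function(s) {
        eval_user_independent(study, s, task = "classify",
                              seed = config$seed,
                              merge = config$classifier$merge)
      }))
  }

  if (!is.null(out_dir)) {
    digest <- purrr::map(reports, function(group) {
      purrr::map(group, function(rep) as.list(tidy(rep)))
    })
    jsonlite::write_json(digest, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(reports))
  }
  reports
}
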