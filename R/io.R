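#' Write a study to disk as plain-text segment files plus a manifest
#'
#' Each segment becomes one two-column tab-delimited file (`time_s`,
#' `value`); a `manifest.tsv` records subject, state, repetition, channel,
#' sampling rate, seed and relative path for every segment, and is the single
#' source of truth for PPG/EMG pairing.
#'
#' @param study Segment tibble from [generate_study()].
#' @param dir Output directory (created if absent).
#' @return The manifest tibble, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(is.data.frame(study), nrow(study) > 0)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- purrr::map_dfr(seq_len(nrow(study)), function(i) {
    seg <- study[i, ]
    path <- sprintf("%s_%s.tsv", seg$segment_id, seg$channel)
    x <- seg$values[[1]]
    utils::write.table(
      data.frame(time_s = (seq_along(x) - 1) / seg$fs_hz, value = x),
      file.path(dir, path),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    tibble::tibble(
      subject_id = seg$subject_id, state = as.character(seg$state),
      rep = seg$rep, segment_id = seg$segment_id, channel = seg$channel,
      fs_hz = seg$fs_hz, duration_s = seg$duration_s, seed = seg$seed,
      path = path
    )
  })
  utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a study written by [write_study()]
#'
#' @param dir Directory containing `manifest.tsv` and the segment files.
#' @return A segment tibble equivalent to the one that was written.
#' @export
read_study <- function(dir) {
  mpath <- file.path(dir, "manifest.tsv")
  if (!file.exists(mpath)) stop("no manifest.tsv under ", dir, call. = FALSE)
  manifest <- tibble::as_tibble(
    utils::read.table(mpath, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  )
  purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    vals <- utils::read.table(file.path(dir, m$path), header = TRUE,
                              sep = "\t")$value
    seg <- signal_segment(m$subject_id, m$state, m$channel, m$fs_hz,
                          m$duration_s, m$seed, vals)
    seg$rep <- m$rep
    seg$segment_id <- m$segment_id
    dplyr::relocate(seg, "rep", "segment_id", .after = "state")
  })
}

#' Write a window feature matrix as delimited text
#'
#' One row per window: identifying metadata followed by the `p<k>` power
#' bins.
#'
#' @param features Feature tibble from [power_spectrum()].
#' @param path Output file path (tab-delimited).
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  keep <- intersect(c("subject_id", "segment_id", "state", "window_id",
                      "end_time_s", feature_bins(features)),
                    names(features))
  utils::write.table(features[keep], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a pipeline run configuration
#'
#' A YAML file with optional blocks `study` (n_subjects, reps_per_state,
#' duration_s, base_amp), `windowing` (window_s, overlap_frac, drop_dc),
#' `classifier` (merge, num_trees), `regressor` (any [cnn_config()] field),
#' `protocol` (`"dependent"` and/or `"independent"`), `k` and `seed`.
#' Missing fields fall back to the package defaults, so an empty file is a
#' valid configuration.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  as_run_config(cfg)
}

as_run_config <- function(cfg = list()) {
  defaults <- list(
    study = list(n_subjects = 5, reps_per_state = 30, duration_s = 10,
                 base_amp = NULL),
    windowing = list(window_s = 2, overlap_frac = 0.5, drop_dc = TRUE),
    classifier = list(merge = TRUE, num_trees = 100),
    regressor = list(),
    protocol = "dependent",
    k = 10,
    regression_folds = 1,
    seed = 1L
  )
  out <- utils::modifyList(defaults, cfg)
  out$seed <- as.integer(out$seed)
  structure(out, class = "run_config")
}

#' Persist a fitted model with a JSON sidecar
#'
#' Writes the model object to `path` (RDS) and a human-readable
#' `<path>.json` sidecar describing what the artifact is (type, classes or
#' architecture, seed, training size), so runs can be audited without
#' loading the binary.
#'
#' @param model A `state_classifier` or `rms_regressor`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  meta <- if (inherits(model, "state_classifier")) {
    list(type = "state_classifier", classes = model$classes,
         n_features = length(model$bins), num_trees = model$num_trees,
         seed = model$seed, n_train = model$n_train,
         subjects = model$subjects)
  } else if (inherits(model, "rms_regressor")) {
    list(type = "rms_regressor", n_params = model$n_params,
         conv_filters = model$config$conv_filters,
         seed = model$config$seed, trained = model$trained,
         target_scale = model$target_scale)
  } else {
    stop("unsupported model class", call. = FALSE)
  }
  saveRDS(model, path)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a model written by [write_model()]
#'
#' @param path File path given to [write_model()].
#' @return The model object.
#' @export
read_model <- function(path) readRDS(path)
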