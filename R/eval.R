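#' Per-class confusion counts
#'
#' @param truth,prediction Equal-length factors (or vectors coercible to the
#'   same label set).
#' @return Tibble with one row per class: `class`, `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' confusion_counts(factor(c("a", "a", "b")), factor(c("a", "b", "b")))
confusion_counts <- function(truth, prediction) {
  stopifnot(length(truth) == length(prediction), length(truth) > 0)
  lv <- union(levels(factor(truth)), levels(factor(prediction)))
  truth <- factor(truth, levels = lv)
  prediction <- factor(prediction, levels = lv)
  purrr::map_dfr(lv, function(cl) {
    tp <- sum(truth == cl & prediction == cl)
    fp <- sum(truth != cl & prediction == cl)
    fn <- sum(truth == cl & prediction != cl)
    tibble::tibble(class = cl, tp = tp, fp = fp, fn = fn,
                   tn = length(truth) - tp - fp - fn)
  })
}

#' Precision, recall and F-value from confusion counts
#'
#' Precision is `TP / (TP + FP)`, recall is `TP / (TP + FN)` and the F-value
#' is their harmonic mean, equal to `2 TP / (2 TP + FP + FN)`; it reaches 1
#' for perfect per-class recognition and 0 when no window of the class is
#' recovered. A class with all-zero counts gets F-value 0 with a warning.
#'
#' @param counts Tibble from [confusion_counts()].
#' @return The counts tibble with `precision`, `recall` and `f_value` columns
#'   appended.
#' @export
#' @examples
#' f_value(tibble::tibble(class = "a", tp = 8, fp = 2, fn = 4, tn = 0))
f_value <- function(counts) {
  stopifnot(is.data.frame(counts), all(c("tp", "fp", "fn") %in% names(counts)))
  if (any(counts$tp + counts$fp + counts$fn == 0)) {
    warning("class with no positives anywhere; its F-value is defined as 0")
  }
  dplyr::mutate(
    tibble::as_tibble(counts),
    precision = ifelse(.data$tp + .data$fp > 0, .data$tp / (.data$tp + .data$fp), 0),
    recall = ifelse(.data$tp + .data$fn > 0, .data$tp / (.data$tp + .data$fn), 0),
    f_value = ifelse(2 * .data$tp + .data$fp + .data$fn > 0,
                     2 * .data$tp / (2 * .data$tp + .data$fp + .data$fn), 0)
  )
}

#' Relative L1 error rate of RMS predictions
#'
#' The regression metric: mean absolute error divided by the mean true RMS,
#' `mean(|y - r|) / mean(r)`. A predictor stuck at zero scores exactly 1
#' (100%); the metric is invariant to rescaling predictions and targets by a
#' common positive gain.
#'
#' @param predictions,targets Equal-length numeric vectors; `mean(targets)`
#'   must be positive.
#' @return A single non-negative number (1 = 100%).
#' @export
#' @examples
#' error_rate(c(90, 110), c(100, 100))  # 0.1
error_rate <- function(predictions, targets) {
  if (length(predictions) != length(targets) || length(targets) == 0) {
    stop("predictions and targets must have equal, nonzero length", call. = FALSE)
  }
  if (mean(targets) <= 0) {
    stop("error rate is undefined for non-positive mean target", call. = FALSE)
  }
  mean(abs(predictions - targets)) / mean(targets)
}

# Stratified fold assignment over SEGMENTS (never windows): all windows cut
# from one 10-s segment land in the same fold, so overlapping windows can
# never leak between training and test.
assign_folds <- function(segments, k, seed) {
  ids <- dplyr::distinct(segments, .data$state, .data$segment_id)
  per_state <- dplyr::count(ids, .data$state)
  if (k < 2) stop("k-fold cross-validation needs k >= 2", call. = FALSE)
  if (any(per_state$n < k)) {
    stop("fewer segments per state (", min(per_state$n),
         ") than folds (", k, ")", call. = FALSE)
  }
  withr::with_seed(seed, {
    ids |>
      dplyr::group_by(.data$state) |>
      dplyr::mutate(fold = sample(rep_len(seq_len(k), dplyr::n()))) |>
      dplyr::ungroup()
  })
}

new_eval_report <- function(task, protocol, metrics, pooled, folds = NULL,
                            held_out = NULL) {
  structure(
    list(task = task, protocol = protocol, metrics = metrics, pooled = pooled,
         folds = folds, held_out = held_out),
    class = "eval_report"
  )
}

#' User-dependent segment-level k-fold cross-validation
#'
#' Evaluates one subject's data under the within-subject protocol: the
#' subject's 10-s segments are partitioned into `k` folds, stratified by
#' state, so that every window of a test segment is unseen at training time.
#' With 30 segments per state and `k = 10`, each fold trains on 27 and tests
#' on 3 segments per state -- the canonical 27/3 regression split is the
#' one-fold specialization of this scheme.
#'
#' For `task = "classify"` each fold fits a random forest on window power
#' spectra and the report pools test predictions over folds into per-class
#' precision/recall/F-value. For `task = "regress"` each evaluated fold
#' trains the CNN regressor and reports the per-state relative L1 error rate;
#' since CNN training dominates runtime, `folds` may name a subset of folds
#' to evaluate (e.g. `folds = 1` for the single 27/3 split).
#'
#' @param study Segment tibble for a single subject (both channels needed for
#'   regression; PPG only suffices for classification).
#' @param k Number of folds.
#' @param task `"classify"` or `"regress"`.
#' @param seed Integer seed driving fold assignment and model fits.
#' @param merge Use the merged 3-class label set (classification)?
#' @param config [cnn_config()] for the regressor.
#' @param folds Optional integer vector of fold ids to evaluate (regression).
#' @return An `eval_report`: per-fold `metrics`, `pooled` summary and the
#'   segment-to-fold map.
#' @export
cv_user_dependent <- function(study, k = 10, task = c("classify", "regress"),
                              seed = 1L, merge = TRUE, config = cnn_config(),
                              folds = NULL) {
  task <- match.arg(task)
  subjects <- unique(study$subject_id)
  if (length(subjects) != 1) {
    stop("user-dependent CV expects segments from a single subject; got ",
         length(subjects), call. = FALSE)
  }
  fold_map <- assign_folds(dplyr::filter(study, .data$channel == "ppg"), k, seed)
  eval_folds <- if (is.null(folds)) seq_len(k) else intersect(folds, seq_len(k))

  if (task == "classify") {
    features <- featurize_study(study)
    features <- dplyr::left_join(features, fold_map[c("segment_id", "fold")],
                                 by = "segment_id")
    per_fold <- purrr::map_dfr(eval_folds, function(f) {
      train <- dplyr::filter(features, .data$fold != f)
      test <- dplyr::filter(features, .data$fold == f)
      model <- train_state_classifier(train, merge = merge,
                                      seed = derive_seed(seed, f))
      truth <- if (merge) merge_states(test$state) else as_activity_state(test$state)
      pred <- predict_state(model, test)
      dplyr::mutate(f_value(confusion_counts(truth, pred)), fold = f,
                    .before = 1)
    })
    pooled <- per_fold |>
      dplyr::group_by(.data$class) |>
      dplyr::summarise(dplyr::across(c("tp", "fp", "fn", "tn"), sum),
                       .groups = "drop") |>
      f_value()
    return(new_eval_report("classify", "user_dependent", per_fold, pooled,
                           fold_map))
  }

  pairs <- pair_study(study)
  pairs <- dplyr::left_join(pairs, fold_map[c("segment_id", "fold")],
                            by = "segment_id")
  per_fold <- purrr::map_dfr(eval_folds, function(f) {
    train <- dplyr::filter(pairs, .data$fold != f)
    test <- dplyr::filter(pairs, .data$fold == f)
    cfg <- config
    cfg$seed <- derive_seed(seed, f)
    model <- train_rms_regressor(train, cfg)
    test$pred <- predict_rms(model, test)
    test |>
      dplyr::group_by(.data$state) |>
      dplyr::summarise(error_rate = error_rate(.data$pred, .data$r),
                       n_windows = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(fold = f, .before = 1)
  })
  pooled <- per_fold |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(error_rate = stats::weighted.mean(.data$error_rate,
                                                       .data$n_windows),
                     n_windows = sum(.data$n_windows), .groups = "drop")
  new_eval_report("regress", "user_dependent", per_fold, pooled, fold_map)
}

#' Leave-one-subject-out (user-independent) evaluation
#'
#' Trains on every window of all other subjects and evaluates on every window
#' of the held-out subject. Cross-subject transfer of this method is known to
#' degrade sharply when subjects' pulse amplitudes differ, because the
#' classifier keys on absolute spectral power.
#'
#' @param study Multi-subject segment tibble.
#' @param held_out_subject Subject id to hold out.
#' @param task `"classify"` (classification is the documented protocol).
#' @param seed,merge,config As in [cv_user_dependent()].
#' @return An `eval_report` with per-class metrics for the held-out subject.
#' @export
eval_user_independent <- function(study, held_out_subject,
                                  task = c("classify", "regress"),
                                  seed = 1L, merge = TRUE,
                                  config = cnn_config()) {
  task <- match.arg(task)
  subjects <- unique(study$subject_id)
  if (length(subjects) < 2) {
    stop("user-independent evaluation needs at least two subjects", call. = FALSE)
  }
  if (!held_out_subject %in% subjects) {
    stop("held-out subject ", held_out_subject, " not present in the study",
         call. = FALSE)
  }
  train_study <- dplyr::filter(study, .data$subject_id != held_out_subject)
  test_study <- dplyr::filter(study, .data$subject_id == held_out_subject)

  if (task == "classify") {
    train <- featurize_study(train_study)
    test <- featurize_study(test_study)
    stopifnot(!held_out_subject %in% train$subject_id)
    model <- train_state_classifier(train, merge = merge, seed = seed)
    truth <- if (merge) merge_states(test$state) else as_activity_state(test$state)
    metrics <- f_value(confusion_counts(truth, predict_state(model, test)))
    return(new_eval_report("classify", "user_independent", metrics, metrics,
                           held_out = held_out_subject))
  }

  train <- pair_study(train_study)
  test <- pair_study(test_study)
  cfg <- config
  cfg$seed <- as.integer(seed)
  model <- train_rms_regressor(train, cfg)
  test$pred <- predict_rms(model, test)
  metrics <- test |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(error_rate = error_rate(.data$pred, .data$r),
                     n_windows = dplyr::n(), .groups = "drop")
  new_eval_report("regress", "user_independent", metrics, metrics,
                  held_out = held_out_subject)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation report:", x$task, "/", x$protocol, "\n")
  if (!is.null(x$held_out)) cat("  held-out subject:", x$held_out, "\n")
  print(x$pooled)
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param pooled Return fold-pooled metrics (default) or per-fold rows?
#' @param ... Unused.
#' @return A tibble of per-class F-values or per-state error rates.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, pooled = TRUE, ...) {
  tibble::as_tibble(if (pooled) x$pooled else x$metrics)
}

#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  if (x$task == "classify") {
    tibble::tibble(task = x$task, protocol = x$protocol,
                   n_classes = nrow(x$pooled),
                   macro_f_value = mean(x$pooled$f_value))
  } else {
    tibble::tibble(task = x$task, protocol = x$protocol,
                   n_states = nrow(x$pooled),
                   mean_error_rate = mean(x$pooled$error_rate))
  }
}
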