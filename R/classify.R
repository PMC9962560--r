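#' Train the muscle-activity state classifier
#'
#' Fits a random forest (100 trees by default) on the one-sided FFT power
#' spectra of 2-s PPG windows. By default the four recorded states are merged
#' to the 3-class problem (`strength` and `dumbbell` relabelled `strain`)
#' before fitting, since those two states are nearly indistinguishable in the
#' pulse wave; pass `merge = FALSE` to fit the 4-class variant.
#'
#' @param features Feature tibble from [power_spectrum()] / [featurize_study()]
#'   with a `state` column and `p<k>` bin columns.
#' @param merge Merge to the 3-class label set before fitting?
#' @param num_trees Number of trees in the forest.
#' @param seed Integer seed; fits are reproducible (single-threaded).
#' @return A `state_classifier` object wrapping the fitted forest.
#' @export
train_state_classifier <- function(features, merge = TRUE, num_trees = 100,
                                   seed = 1L) {
  stopifnot(is.data.frame(features), "state" %in% names(features))
  bins <- feature_bins(features)
  if (length(bins) == 0) stop("no power-spectrum bin columns found", call. = FALSE)
  y <- if (merge) merge_states(features$state) else as_activity_state(features$state)
  y <- droplevels(y)
  if (nlevels(y) < 2) {
    stop("training data must contain at least two classes", call. = FALSE)
  }
  dat <- features[bins]
  dat$.state <- y
  fit <- ranger::ranger(
    dependent.variable.name = ".state",
    data = dat,
    num.trees = num_trees,
    importance = "impurity",
    seed = as.integer(seed),
    num.threads = 1
  )
  structure(
    list(fit = fit, bins = bins, merge = merge, classes = levels(y),
         seed = as.integer(seed), num_trees = num_trees,
         subjects = unique(as.character(features$subject_id)),
         n_train = nrow(features)),
    class = "state_classifier"
  )
}

#' Predict muscle-activity states for new PPG windows
#'
#' @param model A `state_classifier` from [train_state_classifier()].
#' @param features Feature tibble with the same power-bin columns the model
#'   was trained on.
#' @return Factor of predicted states (merged labels if the model merged),
#'   one per row of `features`; empty input gives an empty factor.
#' @export
predict_state <- function(model, features) {
  stopifnot(inherits(model, "state_classifier"), is.data.frame(features))
  if (nrow(features) == 0) {
    return(factor(character(0), levels = model$classes))
  }
  bins <- feature_bins(features)
  if (!identical(bins, model$bins)) {
    stop("feature columns do not match the ", length(model$bins),
         " bins the model was trained on", call. = FALSE)
  }
  # fixed seed: ranger breaks prediction vote ties randomly otherwise
  pred <- stats::predict(model$fit, data = features[bins], num.threads = 1,
                         seed = model$seed)
  factor(as.character(pred$predictions), levels = model$classes)
}

#' @export
print.state_classifier <- function(x, ...) {
  cat("Random-forest muscle-activity classifier\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  trees:", x$num_trees, " features:", length(x$bins), "bins\n")
  cat("  OOB error:", signif(x$fit$prediction.error, 3), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the state classifier: per-bin variable importance
#'
#' @param x A `state_classifier`.
#' @param ... Unused.
#' @return Tibble with `bin` (DFT bin index), `frequency_hz` (at the 100 Hz /
#'   200-sample default grid) and impurity `importance`, sorted by importance.
#' @method tidy state_classifier
#' @export
tidy.state_classifier <- function(x, ...) {
  imp <- x$fit$variable.importance
  k <- as.integer(sub("^p", "", names(imp)))
  tibble::tibble(
    bin = k,
    frequency_hz = k * 100 / 200,
    importance = unname(imp)
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @method glance state_classifier
#' @export
glance.state_classifier <- function(x, ...) {
  tibble::tibble(
    num_trees = x$num_trees,
    n_features = length(x$bins),
    n_classes = length(x$classes),
    n_train = x$n_train,
    oob_error = x$fit$prediction.error
  )
}
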