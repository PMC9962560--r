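#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot raw signal segments
#'
#' Line plot of one or more segments against time, faceted by state, useful
#' for eyeballing the simulated pulse shapes: tall sharp-decay pulses when
#' the arm hangs down, attenuated gentle-decay pulses under load.
#'
#' @param segments Segment tibble (one channel at a time reads best).
#' @param max_seconds Clip the time axis, seconds.
#' @return A ggplot object.
#' @export
plot_segments <- function(segments, max_seconds = 4) {
  df <- segments |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$.row) |>
    dplyr::reframe(
      subject_id = .data$subject_id, state = .data$state,
      channel = .data$channel,
      time_s = (seq_along(.data$values[[1]]) - 1) / .data$fs_hz,
      value = .data$values[[1]]
    ) |>
    dplyr::filter(.data$time_s <= max_seconds)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$value,
                                   group = .data$.row)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~state, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = "signal",
                  title = "Simulated segments by activity state")
}

#' Plot state-averaged power spectra
#'
#' Mean one-sided FFT power per bin for each activity state -- the feature
#' view the classifier sees. Spectral power shrinks monotonically as muscle
#' load compresses the brachial artery.
#'
#' @param features Feature tibble from [power_spectrum()].
#' @param max_hz Clip the frequency axis, Hz.
#' @return A ggplot object.
#' @export
plot_mean_spectra <- function(features, max_hz = 10) {
  fs <- if ("fs_hz" %in% names(features)) features$fs_hz[1] else 100
  n <- if ("n" %in% names(features)) features$n[1] else 200
  df <- features |>
    tidyr::pivot_longer(dplyr::all_of(feature_bins(features)),
                        names_to = "bin", values_to = "power") |>
    dplyr::mutate(frequency_hz = as.integer(sub("^p", "", .data$bin)) * fs / n) |>
    dplyr::group_by(.data$state, .data$frequency_hz) |>
    dplyr::summarise(power = mean(.data$power), .groups = "drop") |>
    dplyr::filter(.data$frequency_hz <= max_hz)
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency_hz, .data$power,
                                   colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency [Hz]", y = "mean power",
                  title = "Average FFT power spectrum by state")
}

#' Autoplot an evaluation report
#'
#' Classification reports become per-class F-value bars; regression reports
#' become per-state error-rate bars.
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidy(object)
  if (object$task == "classify") {
    ggplot2::ggplot(df, ggplot2::aes(.data$class, .data$f_value)) +
      ggplot2::geom_col() +
      ggplot2::coord_cartesian(ylim = c(0, 1)) +
      ggplot2::labs(y = "F-value",
                    title = paste("Muscle-activity recognition,",
                                  object$protocol))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$state, .data$error_rate)) +
      ggplot2::geom_col() +
      ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
      ggplot2::labs(y = "error rate",
                    title = paste("EMG RMS estimation,", object$protocol))
  }
}

#' Autoplot a trained RMS regressor: training curve
#'
#' @param object A trained `rms_regressor`.
#' @param ... Unused.
#' @return A ggplot object of train/validation L1 loss per epoch.
#' @method autoplot rms_regressor
#' @export
autoplot.rms_regressor <- function(object, ...) {
  if (is.null(object$loss_trace)) stop("model has no loss trace (untrained)")
  df <- tidyr::pivot_longer(object$loss_trace, -"epoch",
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(stats::na.omit(df),
                  ggplot2::aes(.data$epoch, .data$loss,
                               colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "L1 loss (scaled targets)", title = "CNN training curve")
}

#' Tidy a trained RMS regressor: its loss trace
#'
#' @param x A trained `rms_regressor`.
#' @param ... Unused.
#' @return The per-epoch loss-trace tibble.
#' @method tidy rms_regressor
#' @export
tidy.rms_regressor <- function(x, ...) {
  if (is.null(x$loss_trace)) {
    return(tibble::tibble(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0)))
  }
  x$loss_trace
}

#' @method glance rms_regressor
#' @export
glance.rms_regressor <- function(x, ...) {
  tibble::tibble(
    n_params = x$n_params,
    trained = x$trained,
    epochs_run = if (is.null(x$loss_trace)) 0L else nrow(x$loss_trace),
    best_epoch = if (is.null(x$best_epoch)) NA_integer_ else x$best_epoch,
    target_scale = x$target_scale
  )
}
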