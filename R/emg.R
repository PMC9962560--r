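#' Trailing-window RMS of an EMG segment
#'
#' The regression target: the root-mean-square of the sEMG over the 2-s span
#' ending at time `T`, i.e. `r(T) = sqrt(mean(s(t)^2))` over the trailing
#' `span_samples` samples (2000 at the default 1000 Hz rate). RMS amplitude is
#' the standard scalar summary of muscle-activation level.
#'
#' @param emg One-row EMG segment tibble.
#' @param end_time_s Wall-clock end time(s) `T` of the span, seconds.
#' @param span_samples Span length in samples (default `10 * 200 = 2000`,
#'   i.e. 2 s at 1000 Hz).
#' @return A tibble with one row per end time: `r`, `end_time_s`,
#'   `span_samples`, `state`.
#' @export
#' @examples
#' seg <- generate_emg_segment(subject_profile(), "bend", 10, seed = 1)
#' emg_rms(seg, end_time_s = 2)
emg_rms <- function(emg, end_time_s, span_samples = 2000) {
  emg <- profile_check_segment(emg, "emg")
  x <- emg$values[[1]]
  fs <- emg$fs_hz
  stopifnot(span_samples >= 1)
  purrr::map_dfr(end_time_s, function(tt) {
    end_idx <- round(tt * fs)
    start_idx <- end_idx - span_samples + 1
    if (start_idx < 1 || end_idx > length(x)) {
      stop("RMS span [", start_idx, ", ", end_idx,
           "] falls outside the segment", call. = FALSE)
    }
    tibble::tibble(
      r = sqrt(mean(x[start_idx:end_idx]^2)),
      end_time_s = tt,
      span_samples = as.integer(span_samples),
      state = emg$state
    )
  })
}

profile_check_segment <- function(seg, channel) {
  if (!is.data.frame(seg) || nrow(seg) != 1) {
    stop("expected a single-row segment tibble", call. = FALSE)
  }
  if (!is.null(seg$channel) && seg$channel != channel) {
    stop("expected a ", toupper(channel), " segment, got ", seg$channel,
         call. = FALSE)
  }
  seg
}

#' Pair PPG windows with their EMG RMS targets
#'
#' Each PPG window ending at wall-clock time `T` is annotated with the EMG
#' RMS over the span of the same duration ending at the same `T`. The two
#' channels run on different clocks (100 Hz vs 1000 Hz); `T` is shared and
#' sample indices are derived by rounding `T * fs`. Windows whose EMG span
#' would underflow the start of the recording are dropped and counted in the
#' `dropped` attribute (none are dropped on the default 10-s grid, where the
#' first window ends at `T = 2` s).
#'
#' @param ppg_windows Window tibble from [slide_windows()] for one PPG
#'   segment.
#' @param emg Matching one-row EMG segment tibble (same subject and state).
#' @return The window tibble with an added `r` column (the RMS target) and a
#'   `dropped` attribute giving the number of discarded windows.
#' @export
pair_windows <- function(ppg_windows, emg) {
  emg <- profile_check_segment(emg, "emg")
  stopifnot(is.data.frame(ppg_windows), nrow(ppg_windows) >= 1)
  if (!identical(unique(ppg_windows$subject_id), emg$subject_id) ||
      !identical(as.character(unique(ppg_windows$state)),
                 as.character(emg$state))) {
    stop("PPG windows and EMG segment disagree on subject or state",
         call. = FALSE)
  }
  span <- round(unique(ppg_windows$n) / unique(ppg_windows$fs_hz) * emg$fs_hz)
  ok <- round(ppg_windows$end_time_s * emg$fs_hz) - span + 1 >= 1
  kept <- ppg_windows[ok, ]
  targets <- emg_rms(emg, kept$end_time_s, span_samples = span)
  kept$r <- targets$r
  attr(kept, "dropped") <- sum(!ok)
  kept
}

#' Build the paired CNN training set for a whole study
#'
#' Slides windows over every PPG segment and pairs each window with the RMS
#' of its time-aligned EMG partner.
#'
#' @param study Paired study tibble from [generate_study()] (both channels).
#' @inheritParams slide_windows
#' @return A tibble with one row per (window, target) pair: window metadata,
#'   `samples` (200 PPG samples) and `r` (EMG RMS over the matching span).
#' @export
#' @examples
#' study <- generate_study(default_profiles(1), reps_per_state = 1)
#' nrow(pair_study(study))  # 4 states x 9 windows
pair_study <- function(study, window_s = 2, overlap_frac = 0.5) {
  ppg <- dplyr::filter(study, .data$channel == "ppg")
  emg <- dplyr::filter(study, .data$channel == "emg")
  if (nrow(ppg) == 0 || nrow(emg) == 0) {
    stop("study must contain both PPG and EMG segments", call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(ppg)), function(i) {
    seg <- ppg[i, ]
    partner <- dplyr::filter(emg, .data$segment_id == seg$segment_id)
    if (nrow(partner) != 1) {
      stop("no unique EMG partner for segment ", seg$segment_id, call. = FALSE)
    }
    pair_windows(slide_windows(seg, window_s, overlap_frac), partner)
  })
}
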