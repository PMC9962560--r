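#' Sliding-window segmentation of a signal segment
#'
#' Cuts a segment into fixed-length windows, left-aligned from the first
#' sample, with a configurable overlap. At the defaults (2-s window, 50%
#' overlap) a 10-s PPG segment at 100 Hz yields exactly 9 windows of 200
#' samples. A trailing partial window is discarded, so no window ever crosses
#' the segment boundary.
#'
#' @param segments Segment tibble (one or more rows) as produced by
#'   [generate_study()] or [generate_ppg_segment()].
#' @param window_s Window length in seconds.
#' @param overlap_frac Fractional overlap between consecutive windows, in
#'   `[0, 1)`.
#' @return A tibble with one row per window: segment metadata plus
#'   `window_id`, `end_time_s`, `n` (samples per window) and a `samples`
#'   list-column.
#' @export
#' @examples
#' seg <- generate_ppg_segment(subject_profile(), "normal", 10, seed = 1)
#' nrow(slide_windows(seg))  # 9
slide_windows <- function(segments, window_s = 2, overlap_frac = 0.5) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1)
  if (overlap_frac < 0 || overlap_frac >= 1) {
    stop("overlap_frac must lie in [0, 1)", call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    x <- seg$values[[1]]
    fs <- seg$fs_hz
    n <- round(window_s * fs)
    if (length(x) < n) {
      stop("segment shorter than one window (", length(x), " < ", n, " samples)",
           call. = FALSE)
    }
    hop <- round(n * (1 - overlap_frac))
    starts <- seq(1L, length(x) - n + 1L, by = hop)
    meta <- seg[setdiff(names(seg), "values")]
    purrr::map_dfr(seq_along(starts), function(w) {
      s0 <- starts[w]
      dplyr::bind_cols(
        meta,
        tibble::tibble(
          window_id = w,
          end_time_s = (s0 + n - 1) / fs,
          n = n,
          samples = list(x[s0:(s0 + n - 1)])
        )
      )
    })
  })
}

#' Unnormalized discrete Fourier transform of a window
#'
#' Computes `X(k) = sum_t p(t) exp(-j 2 pi k t / N)` over the window's `N`
#' samples -- the raw forward DFT with no 1/N factor, no taper and no
#' detrending.
#'
#' @param samples Numeric vector, the window's samples.
#' @return Complex vector of length `N`, indices `k = 0 .. N-1`.
#' @export
#' @examples
#' dft_window(rep(1, 8))[1]  # N * mean = 8
dft_window <- function(samples) {
  stopifnot(is.numeric(samples), length(samples) >= 1)
  stats::fft(samples)
}

#' One-sided FFT power spectrum of PPG windows
#'
#' The classifier's feature vector: `P(k) = |X(k)|^2` over the one-sided bins
#' `k = 1 .. N/2` (the DC bin `k = 0` is dropped by default, since it mostly
#' encodes sensor offset; set `drop_dc = FALSE` to keep it). At the default
#' 200-sample window this yields 100 power bins per window.
#'
#' @param windows Window tibble from [slide_windows()].
#' @param drop_dc Drop the DC bin? Default `TRUE`.
#' @return The input tibble without `samples`, with one `p<k>` column per
#'   retained bin (e.g. `p1` .. `p100`).
#' @export
#' @examples
#' seg <- generate_ppg_segment(subject_profile(), "normal", 10, seed = 1)
#' feats <- power_spectrum(slide_windows(seg))
#' ncol(dplyr::select(feats, dplyr::starts_with("p")))  # 100
power_spectrum <- function(windows, drop_dc = TRUE) {
  stopifnot(is.data.frame(windows), nrow(windows) >= 1,
            "samples" %in% names(windows))
  n <- length(windows$samples[[1]])
  k <- seq(if (drop_dc) 1L else 0L, floor(n / 2))
  pw <- purrr::map(windows$samples, function(x) {
    stopifnot(length(x) == n)
    Mod(stats::fft(x))[k + 1]^2
  })
  mat <- do.call(rbind, pw)
  colnames(mat) <- paste0("p", k)
  out <- dplyr::bind_cols(
    windows[setdiff(names(windows), "samples")],
    tibble::as_tibble(mat)
  )
  attr(out, "bin_indices") <- k
  out
}

feature_bins <- function(features) {
  grep("^p[0-9]+$", names(features), value = TRUE)
}

feature_matrix <- function(features) {
  as.matrix(features[feature_bins(features)])
}

#' Featurize a study: windows plus power spectra in one step
#'
#' Convenience wrapper: takes the PPG rows of a study, slides windows and
#' computes their power spectra.
#'
#' @inheritParams slide_windows
#' @inheritParams power_spectrum
#' @return Feature tibble, one row per window (see [power_spectrum()]).
#' @export
featurize_study <- function(segments, window_s = 2, overlap_frac = 0.5,
                            drop_dc = TRUE) {
  ppg <- dplyr::filter(segments, .data$channel == "ppg")
  if (nrow(ppg) == 0) stop("no PPG segments to featurize", call. = FALSE)
  power_spectrum(slide_windows(ppg, window_s, overlap_frac), drop_dc = drop_dc)
}
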