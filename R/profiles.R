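#' Virtual-subject profile for the paired PPG/sEMG simulator
#'
#' A profile holds everything the simulator needs to emit signals for one
#' virtual subject: cardiac beat period, baseline pulse amplitude, per-state
#' pulse attenuation (muscle contraction under the upper-arm band compresses
#' the brachial artery, weakening the distal pulse), per-state diastolic decay
#' rate (the arm-down pulse falls off fast after the systolic peak; bent-arm
#' pulses decay gently), per-state sEMG RMS scale, and noise levels.
#'
#' Default amplitude attenuations are 1 : 0.759 : 0.701 : 0.677 across
#' normal/bend/strength/dumbbell, so that spectral *power* maxima fall in the
#' ratios 1 : 0.58 : 0.49 : 0.46 observed in real tourniquet-compressed
#' recordings; default sEMG scales are 422 / 848 / 1261 / 2351
#' (microvolt-scale). Attenuation never increases and EMG amplitude never
#' decreases as the muscle load grows. The heavily compressed states
#' (`strength`, `dumbbell`) get a very gentle diastolic decay: their pulse is
#' low and flattened, with the peak hard to pick out.
#'
#' @param subject_id Subject label, e.g. `"S01"`.
#' @param beat_period_s Cardiac beat period in seconds (typical 0.7--1.1).
#' @param base_amp Baseline (unattenuated) pulse amplitude, arbitrary units.
#' @param attenuation Named numeric, amplitude multiplier in (0, 1] per state;
#'   must be non-increasing along normal, bend, strength, dumbbell.
#' @param decay_shape Named numeric, post-peak exponential decay rate (1/s)
#'   per state; `normal` must be the fastest.
#' @param emg_sigma Named numeric, target full-segment sEMG RMS per state
#'   (microvolts); must be non-decreasing along the state order.
#' @param amp_jitter_sd Standard deviation (log scale) of the multiplicative
#'   per-beat pulse-amplitude jitter; real pulse waves vary beat to beat by
#'   roughly 5--10% even at rest.
#' @param force_jitter_sd Standard deviation (log scale) of the
#'   per-repetition exerted-force factor used by [generate_study()]: a
#'   repetition held with more force compresses the artery harder (scaling
#'   the pulse amplitude down) and recruits more muscle (scaling the sEMG RMS
#'   up). This trial-to-trial variation is what blurs neighbouring states
#'   into one another, as seen in real recordings.
#' @param ppg_noise_sd Standard deviation of additive Gaussian PPG noise.
#' @param emg_band_hz Length-2 numeric, sEMG pass-band in Hz (inside the
#'   1000 Hz Nyquist range).
#' @param seed Integer seed associated with the subject.
#' @return A one-row tibble with list-columns for the per-state maps.
#' @export
#' @examples
#' subject_profile("S01")
subject_profile <- function(subject_id = "S01",
                            beat_period_s = 0.9,
                            base_amp = 1,
                            attenuation = c(normal = 1, bend = 0.759,
                                            strength = 0.701, dumbbell = 0.677),
                            decay_shape = c(normal = 8, bend = 4.5,
                                            strength = 1.5, dumbbell = 1.5),
                            emg_sigma = c(normal = 422, bend = 848,
                                          strength = 1261, dumbbell = 2351),
                            amp_jitter_sd = 0.1,
                            force_jitter_sd = 0.06,
                            ppg_noise_sd = 0.03,
                            emg_band_hz = c(20, 450),
                            seed = 1L) {
  attenuation <- check_state_map(attenuation, "attenuation")
  decay_shape <- check_state_map(decay_shape, "decay_shape")
  emg_sigma <- check_state_map(emg_sigma, "emg_sigma")
  stopifnot(beat_period_s > 0, base_amp > 0, ppg_noise_sd >= 0,
            amp_jitter_sd >= 0, force_jitter_sd >= 0)
  if (any(attenuation < 0) || any(attenuation > 1)) {
    stop("attenuation values must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(attenuation) > 1e-12)) {
    stop("attenuation must be non-increasing along normal, bend, strength, dumbbell",
         call. = FALSE)
  }
  if (any(diff(emg_sigma) < -1e-12)) {
    stop("emg_sigma must be non-decreasing along normal, bend, strength, dumbbell",
         call. = FALSE)
  }
  if (any(emg_sigma < 0)) stop("emg_sigma must be non-negative", call. = FALSE)
  if (decay_shape[["normal"]] <= max(decay_shape[-1])) {
    stop("decay_shape must be fastest (largest) for the normal state", call. = FALSE)
  }
  if (length(emg_band_hz) != 2 || emg_band_hz[1] <= 0 ||
      emg_band_hz[2] <= emg_band_hz[1] || emg_band_hz[2] >= 500) {
    stop("emg_band_hz must satisfy 0 < low < high < 500 (Nyquist of 1000 Hz)",
         call. = FALSE)
  }
  tibble::tibble(
    subject_id = as.character(subject_id),
    beat_period_s = beat_period_s,
    base_amp = base_amp,
    attenuation = list(attenuation),
    decay_shape = list(decay_shape),
    emg_sigma = list(emg_sigma),
    amp_jitter_sd = amp_jitter_sd,
    force_jitter_sd = force_jitter_sd,
    ppg_noise_sd = ppg_noise_sd,
    emg_band_hz = list(as.numeric(emg_band_hz)),
    seed = as.integer(seed)
  )
}

check_state_map <- function(x, what) {
  lv <- state_levels()
  if (is.null(names(x)) || !all(lv %in% names(x))) {
    stop(what, " must be a named vector with entries for ",
         paste(lv, collapse = ", "), call. = FALSE)
  }
  stats::setNames(as.numeric(x[lv]), lv)
}

#' A cohort of default virtual subjects
#'
#' Draws `n_subjects` profiles whose beat periods are spread over the typical
#' resting range (0.7--1.1 s) and whose baseline amplitudes vary mildly around
#' 1, emulating between-subject physiological variation while keeping every
#' subject's within-state structure identical to [subject_profile()] defaults.
#' Set `base_amp` explicitly (one value per subject) to emulate cohorts with
#' disjoint pulse amplitudes, the regime where cross-subject transfer fails.
#'
#' @param n_subjects Number of virtual subjects.
#' @param seed Integer seed for the profile draws.
#' @param base_amp Optional numeric vector of length `n_subjects` overriding
#'   the drawn baseline amplitudes.
#' @return A tibble with one profile row per subject.
#' @export
#' @examples
#' default_profiles(5, seed = 1)
default_profiles <- function(n_subjects = 5, seed = 1L, base_amp = NULL) {
  stopifnot(n_subjects >= 1)
  draws <- withr::with_seed(seed, {
    list(period = stats::runif(n_subjects, 0.7, 1.1),
         amp = stats::runif(n_subjects, 0.85, 1.15))
  })
  if (!is.null(base_amp)) {
    stopifnot(length(base_amp) == n_subjects)
    draws$amp <- as.numeric(base_amp)
  }
  purrr::map_dfr(seq_len(n_subjects), function(i) {
    subject_profile(
      subject_id = sprintf("S%02d", i),
      beat_period_s = draws$period[i],
      base_amp = draws$amp[i],
      seed = derive_seed(seed, i)
    )
  })
}
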