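PPG_FS <- 100
EMG_FS <- 1000

# Deterministic seed fan-out: maps a study seed and a small index to a
# distinct 31-bit seed. 48271 is a classic minimal-standard LCG multiplier;
# the map index -> (index * 48271) mod (2^31 - 1) is injective for the index
# ranges a study can produce, so derived seeds never collide.
derive_seed <- function(seed, index) {
  p <- 2147483647
  as.integer((as.numeric(seed) %% p + (as.numeric(index) * 48271) %% p) %% p)
}

profile_row <- function(profile) {
  if (!is.data.frame(profile) || nrow(profile) != 1) {
    stop("expected a single-row subject profile; see subject_profile()",
         call. = FALSE)
  }
  profile
}

#' Simulate one wrist-PPG segment
#'
#' Emits a beat-periodic pulse waveform for a held arm state. Each beat is an
#' asymmetric pulse: a Gaussian systolic upstroke followed by an exponential
#' diastolic decay whose rate depends on the state (fast when the arm hangs
#' down, gentle when bent). The pulse is scaled by the subject's baseline
#' amplitude times the state's attenuation factor -- muscle contraction under
#' the upper-arm band weakens the distal pulse -- and white Gaussian sensor
#' noise is added. Sampling rate is fixed at 100 Hz.
#'
#' @param profile One-row profile tibble from [subject_profile()].
#' @param state Activity state (name or code 1--4).
#' @param duration_s Segment duration in seconds; must cover at least one
#'   beat period.
#' @param seed Integer seed; the output is bit-identical for identical inputs.
#' @param amp_scale Extra multiplicative amplitude factor (default 1);
#'   [generate_study()] uses it to apply the per-repetition force factor.
#' @return A one-row tibble: `subject_id`, `state`, `channel`, `fs_hz`,
#'   `duration_s`, `seed` and a `values` list-column holding the samples.
#' @export
#' @examples
#' seg <- generate_ppg_segment(subject_profile(), "normal", 10, seed = 7)
#' length(seg$values[[1]])
generate_ppg_segment <- function(profile, state, duration_s = 10, seed = 1L,
                                 amp_scale = 1) {
  profile <- profile_row(profile)
  state <- as_activity_state(state)
  if (length(state) != 1 || is.na(state)) {
    stop("state must be a single known activity state", call. = FALSE)
  }
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive", call. = FALSE)
  }
  if (duration_s < profile$beat_period_s) {
    stop("duration_s must cover at least one beat period", call. = FALSE)
  }
  n <- round(PPG_FS * duration_s)
  period <- profile$beat_period_s
  atten <- profile$attenuation[[1]][[as.character(state)]]
  decay <- profile$decay_shape[[1]][[as.character(state)]]
  amp <- profile$base_amp * atten * amp_scale

  values <- withr::with_seed(as.integer(seed), {
    phase <- stats::runif(1, 0, period)
    t <- (seq_len(n) - 1) / PPG_FS
    tau <- (t + phase) %% period      # time since current beat onset
    beat <- floor((t + phase) / period) + 1L
    t_peak <- 0.18 * period
    sigma_up <- 0.06 * period
    shape <- ifelse(
      tau < t_peak,
      exp(-(tau - t_peak)^2 / (2 * sigma_up^2)),
      exp(-decay * (tau - t_peak))
    )
    # beat-to-beat amplitude jitter (multiplicative, log-normal)
    jitter <- exp(stats::rnorm(max(beat), 0, profile$amp_jitter_sd))
    amp * jitter[beat] * shape + stats::rnorm(n, 0, profile$ppg_noise_sd)
  })

  signal_segment(profile$subject_id, state, "ppg", PPG_FS, duration_s,
                 as.integer(seed), values)
}

#' Simulate one surface-EMG segment
#'
#' Emits zero-mean Gaussian noise band-pass filtered to the subject's sEMG
#' pass-band (default 20--450 Hz, the conventional surface-EMG bandwidth) and
#' rescaled so the full-segment RMS equals the state's `emg_sigma` exactly.
#' Sampling rate is fixed at 1000 Hz.
#'
#' @inheritParams generate_ppg_segment
#' @param rms_scale Extra multiplicative factor on the target RMS (default 1);
#'   [generate_study()] uses it to apply the per-repetition force factor.
#' @return A one-row segment tibble (see [generate_ppg_segment()]).
#' @export
#' @examples
#' seg <- generate_emg_segment(subject_profile(), "strength", 10, seed = 7)
#' sqrt(mean(seg$values[[1]]^2))  # == emg_sigma["strength"]
generate_emg_segment <- function(profile, state, duration_s = 10, seed = 1L,
                                 rms_scale = 1) {
  profile <- profile_row(profile)
  state <- as_activity_state(state)
  if (length(state) != 1 || is.na(state)) {
    stop("state must be a single known activity state", call. = FALSE)
  }
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be positive", call. = FALSE)
  }
  band <- profile$emg_band_hz[[1]]
  if (band[1] <= 0 || band[2] >= EMG_FS / 2) {
    stop("emg_band_hz must lie strictly inside (0, ", EMG_FS / 2, ") Hz",
         call. = FALSE)
  }
  n <- round(EMG_FS * duration_s)
  sigma <- profile$emg_sigma[[1]][[as.character(state)]] * rms_scale

  values <- withr::with_seed(as.integer(seed), {
    white <- stats::rnorm(n)
    bf <- signal::butter(4, band / (EMG_FS / 2), type = "pass")
    x <- signal::filtfilt(bf, white)
    rms0 <- sqrt(mean(x^2))
    if (sigma == 0 || rms0 == 0) rep(0, n) else x * (sigma / rms0)
  })

  signal_segment(profile$subject_id, state, "emg", EMG_FS, duration_s,
                 as.integer(seed), values)
}

signal_segment <- function(subject_id, state, channel, fs_hz, duration_s,
                           seed, values) {
  tibble::tibble(
    subject_id = subject_id,
    state = as_activity_state(state),
    channel = channel,
    fs_hz = fs_hz,
    duration_s = duration_s,
    seed = seed,
    values = list(as.numeric(values))
  )
}

#' Simulate a full paired PPG/sEMG study
#'
#' For every subject, state and repetition, generates one time-aligned
#' PPG/sEMG segment pair (the default protocol: each state held for 10 s,
#' 30 repetitions per state). Each repetition draws a force factor
#' (log-normal, sd `force_jitter_sd` from the profile) shared by both
#' channels: more force means a more compressed artery (weaker pulse) and
#' more recruited muscle (larger sEMG RMS). Each segment gets a unique seed
#' derived deterministically from the study seed, so the whole study is
#' reproducible from its arguments alone. Rest periods between repetitions
#' are not generated; only the held states enter any analysis.
#'
#' @param profiles Tibble of subject profiles ([default_profiles()]).
#' @param reps_per_state Repetitions of each state per subject.
#' @param duration_s Held duration of each repetition, seconds.
#' @param channels Channels to generate, subset of `c("ppg", "emg")`.
#' @param seed Study-level integer seed fanning out to every segment.
#' @return A tibble with one row per segment: `subject_id`, `state`, `rep`,
#'   `segment_id` (shared between the members of a PPG/EMG pair), `channel`,
#'   `fs_hz`, `duration_s`, `seed`, `values`.
#' @export
#' @examples
#' study <- generate_study(default_profiles(1), reps_per_state = 2)
#' dplyr::count(study, channel)
generate_study <- function(profiles, reps_per_state = 30, duration_s = 10,
                           channels = c("ppg", "emg"), seed = 1L) {
  if (!is.data.frame(profiles) || nrow(profiles) == 0) {
    stop("profiles must be a non-empty profile tibble", call. = FALSE)
  }
  stopifnot(reps_per_state >= 1)
  channels <- match.arg(channels, several.ok = TRUE)
  grid <- tidyr::expand_grid(
    subject_idx = seq_len(nrow(profiles)),
    state = as_activity_state(1:4),
    rep = seq_len(reps_per_state),
    channel = channels
  )
  purrr::pmap_dfr(grid, function(subject_idx, state, rep, channel) {
    prof <- profiles[subject_idx, ]
    pair_idx <- ((subject_idx - 1) * 4 + (as.integer(state) - 1)) *
      reps_per_state + (rep - 1)
    idx <- pair_idx * 3 + (channel == "emg")
    seg_seed <- derive_seed(seed, idx + 1)
    # per-repetition force factor, shared by both channels of the pair
    force <- withr::with_seed(derive_seed(seed, pair_idx * 3 + 3),
                              stats::rnorm(1))
    fj <- prof$force_jitter_sd
    seg <- if (channel == "ppg") {
      generate_ppg_segment(prof, state, duration_s, seg_seed,
                           amp_scale = exp(-fj * force))
    } else {
      generate_emg_segment(prof, state, duration_s, seg_seed,
                           rms_scale = exp(0.8 * fj * force))
    }
    seg$rep <- rep
    seg$segment_id <- sprintf("%s_%s_r%02d", prof$subject_id, state, rep)
    dplyr::relocate(seg, "rep", "segment_id", .after = "state")
  })
}
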