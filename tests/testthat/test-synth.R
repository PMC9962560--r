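test_that("PPG generation is deterministic and validates its inputs", {
  p <- quick_profile()
  a <- generate_ppg_segment(p, "bend", 10, seed = 9)
  b <- generate_ppg_segment(p, "bend", 10, seed = 9)
  expect_identical(a$values, b$values)
  expect_length(a$values[[1]], 1000)  # round(fs * duration)
  expect_false(identical(
    a$values, generate_ppg_segment(p, "bend", 10, seed = 10)$values))
  expect_error(generate_ppg_segment(p, "jump", 10, 1), "unknown")
  expect_error(generate_ppg_segment(p, "bend", -1, 1), "positive")
  expect_error(generate_ppg_segment(p, "bend", 0.5, 1), "beat period")
})

test_that("degenerate zero-amplitude noiseless profile yields constant zero", {
  p <- quick_profile(
    attenuation = c(normal = 0, bend = 0, strength = 0, dumbbell = 0),
    ppg_noise_sd = 0)
  seg <- generate_ppg_segment(p, "normal", 5, seed = 1)
  expect_equal(seg$values[[1]], rep(0, 500))
})

test_that("EMG segments hit their target RMS exactly and are zero-mean", {
  p <- quick_profile()
  for (st in c("normal", "dumbbell")) {
    seg <- generate_emg_segment(p, st, 10, seed = 3)
    x <- seg$values[[1]]
    sigma <- p$emg_sigma[[1]][[st]]
    expect_equal(sqrt(mean(x^2)), sigma, tolerance = 1e-9)
    # CLT bound: |mean| < 3 sigma / sqrt(n)
    expect_lt(abs(mean(x)), 3 * sigma / sqrt(length(x)))
  }
  p0 <- quick_profile(emg_sigma = c(normal = 0, bend = 0, strength = 0,
                                    dumbbell = 0))
  expect_equal(generate_emg_segment(p0, "bend", 2, 1)$values[[1]], rep(0, 2000))
  expect_error(
    generate_emg_segment(quick_profile(emg_band_hz = c(20, 600)), "bend", 2, 1),
    "Nyquist|500")
})

test_that("study generation produces the full protocol with distinct seeds", {
  st <- tiny_study()
  expect_equal(nrow(st), 1 * 4 * 3 * 2)
  expect_equal(sum(st$channel == "ppg"), 12)
  # every PPG segment has exactly one time-aligned EMG partner
  pairing <- table(st$segment_id)
  expect_true(all(pairing == 2))
  expect_false(any(duplicated(st$seed)))
  expect_error(generate_study(quick_profile()[0, ]), "non-empty")
})

test_that("derived seeds are distinct across a 5-subject 30-rep study", {
  n_sub <- 5; reps <- 30
  idx <- 0:(n_sub * 4 * reps * 3 - 1)
  seeds <- vapply(idx + 1, function(i) ppgmuscle:::derive_seed(123, i), 1L)
  expect_false(any(duplicated(seeds)))
  expect_true(all(seeds >= 0 & seeds < 2^31))
})

test_that("expected pulse amplitude falls and EMG RMS rises with muscle load", {
  p <- quick_profile()
  states <- c("normal", "bend", "strength", "dumbbell")
  max_power <- sapply(states, function(s) {
    mean(sapply(1:50, function(seed) {
      seg <- generate_ppg_segment(p, s, 2, seed = seed)
      f <- power_spectrum(slide_windows(seg))
      max(as.matrix(f[grep("^p[0-9]+$", names(f))]))
    }))
  })
  expect_true(max_power[["normal"]] > max_power[["bend"]])
  expect_true(max_power[["bend"]] > max_power[["strength"]])
  expect_true(max_power[["strength"]] >= max_power[["dumbbell"]])
  sig <- p$emg_sigma[[1]]
  expect_true(all(diff(sig[states]) >= 0))
})

test_that("simulated spectral maxima fall off like the reference ratios", {
  # reference power maxima fall as roughly 1 : 0.58 : 0.49 : 0.46; amplitude
  # attenuation reproduces the bend ratio directly, and the flattened pulse
  # shape of the strained states pushes them further down, below bend
  p <- quick_profile(amp_jitter_sd = 0, ppg_noise_sd = 0)
  states <- c("normal", "bend", "strength", "dumbbell")
  mx <- sapply(states, function(s) {
    seg <- generate_ppg_segment(p, s, 10, seed = 5)
    f <- power_spectrum(slide_windows(seg))
    mean(apply(as.matrix(f[grep("^p[0-9]+$", names(f))]), 1, max))
  })
  ratios <- mx / mx[["normal"]]
  expect_equal(ratios[["bend"]], 0.58, tolerance = 0.1)
  expect_true(all(diff(unname(ratios)) <= 0))
  expect_true(ratios[["strength"]] < ratios[["bend"]])
  expect_gt(ratios[["dumbbell"]], 0.15)
})

test_that("diastolic decay is steeper for the arm-down state than bent", {
  fit_decay <- function(state) {
    p <- quick_profile(amp_jitter_sd = 0, ppg_noise_sd = 0)
    seg <- generate_ppg_segment(p, state, 10, seed = 2)
    x <- seg$values[[1]]
    # isolate one beat: global max in the second second
    i0 <- 100 + which.max(x[101:300])
    span <- i0:(i0 + round(0.25 * p$beat_period_s * 100))
    stats::coef(stats::lm(log(x[span]) ~ I(span / 100)))[[2]]
  }
  expect_lt(fit_decay("normal"), fit_decay("bend"))  # more negative slope
  expect_equal(-fit_decay("normal"), 8, tolerance = 0.05)
})
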