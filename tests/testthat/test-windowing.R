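naive_dft <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k) {
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
  }, complex(1))
}

test_that("window counts match the protocol arithmetic and a formula check", {
  seg <- generate_ppg_segment(quick_profile(), "normal", 10, seed = 1)
  expect_equal(nrow(slide_windows(seg)), 9)
  expect_equal(nrow(slide_windows(seg, overlap_frac = 0)), 5)
  # exact-length segment: one window equal to the segment
  short <- seg
  short$values <- list(seg$values[[1]][1:200])
  w1 <- slide_windows(short)
  expect_equal(nrow(w1), 1)
  expect_equal(w1$samples[[1]], short$values[[1]])
  expect_error(slide_windows(dplyr::mutate(short, values = list(1:100))),
               "shorter")
  # count formula floor((L - N)/hop) + 1 against enumeration
  for (L in seq(200, 3000, by = 217)) {
    seg$values <- list(seq_len(L) * 0.01)
    expect_equal(nrow(slide_windows(seg)), floor((L - 200) / 100) + 1)
  }
})

test_that("the DFT matches closed forms and a naive O(N^2) oracle", {
  # DC-only: constant c -> X(0) = N c, rest 0
  X <- dft_window(rep(3, 16))
  expect_equal(X[1], 48 + 0i)
  expect_equal(max(Mod(X[-1])), 0, tolerance = 1e-10)
  # cosine at bin k0: |X(k0)| = |X(N - k0)| = N/2
  n <- 64; k0 <- 5
  x <- cos(2 * pi * k0 * (0:(n - 1)) / n)
  Xc <- dft_window(x)
  expect_equal(Mod(Xc[k0 + 1]), n / 2, tolerance = 1e-9)
  expect_equal(Mod(Xc[n - k0 + 1]), n / 2, tolerance = 1e-9)
  expect_lt(max(Mod(Xc[-c(k0 + 1, n - k0 + 1)])), 1e-9)
  # brute-force oracle on random windows
  withr::with_seed(7, {
    for (i in 1:10) {
      x <- stats::rnorm(120)
      expect_equal(dft_window(x), naive_dft(x),
                   tolerance = 1e-9)
    }
  })
})

test_that("power spectrum satisfies Parseval and locates pure tones", {
  withr::with_seed(8, x <- stats::rnorm(200))
  X <- dft_window(x)
  expect_equal(sum(x^2), sum(Mod(X)^2) / 200, tolerance = 1e-9)

  seg <- tibble::tibble(
    subject_id = "S", state = as_activity_state("normal"), channel = "ppg",
    fs_hz = 100, duration_s = 2, seed = 1L,
    values = list(cos(2 * pi * 7 * (0:199) / 200))
  )
  f <- power_spectrum(slide_windows(seg))
  bins <- as.matrix(f[grep("^p[0-9]+$", names(f))])
  expect_equal(colnames(bins)[which.max(bins[1, ])], "p7")
  # zero signal -> all-zero feature
  seg$values <- list(rep(0, 200))
  f0 <- power_spectrum(slide_windows(seg))
  expect_true(all(as.matrix(f0[grep("^p", names(f0))]) == 0))
})

test_that("dropping DC makes the feature invariant to constant offsets", {
  seg <- generate_ppg_segment(quick_profile(), "bend", 2, seed = 3)
  f1 <- power_spectrum(slide_windows(seg))
  seg$values <- list(seg$values[[1]] + 5)
  f2 <- power_spectrum(slide_windows(seg))
  expect_equal(as.matrix(f1[grep("^p", names(f1))]),
               as.matrix(f2[grep("^p", names(f2))]), tolerance = 1e-8)
  # with DC kept they differ
  f3 <- power_spectrum(slide_windows(seg), drop_dc = FALSE)
  expect_true("p0" %in% names(f3))
})

test_that("feature dimension is 100 bins at the default 200-sample window", {
  f <- tiny_features()
  expect_length(grep("^p[0-9]+$", names(f)), 100)
  expect_equal(nrow(f), 12 * 9)
})
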