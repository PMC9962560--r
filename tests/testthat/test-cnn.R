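test_that("L1 loss matches hand arithmetic and is symmetric", {
  expect_equal(l1_loss(c(1, 3), c(2, 1)), 1.5)
  expect_equal(l1_loss(c(4, 4), c(4, 4)), 0)
  withr::with_seed(1, { a <- stats::rnorm(20); b <- stats::rnorm(20) })
  expect_equal(l1_loss(a, b), l1_loss(b, a))
  expect_error(l1_loss(1:3, 1:2), "equal length")
  expect_error(l1_loss(numeric(0), numeric(0)), "at least one")
})

test_that("network shape, parameter count and init determinism", {
  cfg <- cnn_config()
  m <- build_rms_regressor(cfg)
  # closed-form parameter count for kernel 3, blocks (16, 32), input 200:
  # conv1 3*1*16+16; conv2 3*16*32+32; dense (50*32)*128+128; out 128+1
  expect_equal(m$n_params,
               (3 * 1 * 16 + 16) + (3 * 16 * 32 + 32) +
                 (50 * 32) * 128 + 128 + (128 + 1))
  m2 <- build_rms_regressor(cfg)
  expect_identical(m$weights, m2$weights)
  # one scalar output per window
  w <- tiny_pairs()[1:3, ]
  fwd <- ppgmuscle:::cnn_forward(m$weights,
                                 ppgmuscle:::pairs_to_tensor(w, 200), cfg)
  expect_length(fwd$y, 3)
  expect_error(cnn_config(input_len = 50, conv_filters = c(4, 4, 4, 4, 4, 4)),
               "survive")
})

test_that("analytic gradients agree with finite differences on a tiny net", {
  cfg <- cnn_config(input_len = 8, conv_filters = c(2, 2), hidden_units = 4,
                    dropout_rate = 0, batch_size = 4, seed = 3)
  w <- ppgmuscle:::cnn_init_weights(cfg)
  withr::with_seed(4, {
    X <- array(stats::rnorm(4 * 8), c(4, 8, 1))
    r <- stats::runif(4, 0.5, 2)
  })
  loss_at <- function(w) {
    f <- ppgmuscle:::cnn_forward(w, X, cfg, training = FALSE)
    l1_loss(f$y, r)
  }
  fwd <- ppgmuscle:::cnn_forward(w, X, cfg, training = FALSE)
  g <- ppgmuscle:::cnn_backward(w, X, fwd$y, r, fwd$cache, cfg)
  eps <- 1e-6
  check <- function(get, set, gval) {
    w1 <- set(w, get(w) + eps); w2 <- set(w, get(w) - eps)
    expect_equal((loss_at(w1) - loss_at(w2)) / (2 * eps), gval,
                 tolerance = 1e-4)
  }
  # probe one coordinate in every parameter tensor
  check(function(w) w$conv[[1]]$W[2, 1],
        function(w, v) { w$conv[[1]]$W[2, 1] <- v; w }, g$conv[[1]]$W[2, 1])
  check(function(w) w$conv[[1]]$b[2],
        function(w, v) { w$conv[[1]]$b[2] <- v; w }, g$conv[[1]]$b[2])
  check(function(w) w$conv[[2]]$W[5, 2],
        function(w, v) { w$conv[[2]]$W[5, 2] <- v; w }, g$conv[[2]]$W[5, 2])
  check(function(w) w$dense$W[3, 2],
        function(w, v) { w$dense$W[3, 2] <- v; w }, g$dense$W[3, 2])
  check(function(w) w$dense$b[1],
        function(w, v) { w$dense$b[1] <- v; w }, g$dense$b[1])
  check(function(w) w$out$W[4, 1],
        function(w, v) { w$out$W[4, 1] <- v; w }, g$out$W[4, 1])
  check(function(w) w$out$b,
        function(w, v) { w$out$b <- v; w }, g$out$b)
})

test_that("constant targets are recovered to within 5%", {
  pr <- dplyr::filter(tiny_pairs(), state == "bend")
  pr$r <- rep(7, nrow(pr))
  cfg <- cnn_config(epochs = 600, batch_size = 16, lr_decay = 0.996,
                    validation_frac = 0, patience = 600, seed = 2)
  m <- train_rms_regressor(pr, cfg)
  preds <- predict_rms(m, pr)
  expect_true(all(abs(preds - 7) / 7 < 0.05))
})

test_that("inference is deterministic, clamped and shape-safe", {
  pr <- tiny_pairs()[1:20, ]
  m <- train_rms_regressor(pr, cnn_config(epochs = 2, seed = 5))
  p1 <- predict_rms(m, pr)
  p2 <- predict_rms(m, pr)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0))
  expect_length(predict_rms(m, pr[0, ]), 0)
  short <- pr[1, ]; short$samples <- list(short$samples[[1]][1:100])
  expect_error(predict_rms(m, short), "input_len")
  expect_error(train_rms_regressor(pr[0, ]), "empty")
})

test_that("doubling targets doubles the optimal constant-predictor loss", {
  withr::with_seed(6, r <- stats::runif(50, 1, 5))
  best_const_loss <- function(r) min(sapply(r, function(c) mean(abs(c - r))))
  expect_equal(best_const_loss(2 * r), 2 * best_const_loss(r),
               tolerance = 1e-12)
})

test_that("training loss decreases on learnable synthetic data", {
  pr <- tiny_pairs()
  m <- train_rms_regressor(pr, cnn_config(epochs = 15, validation_frac = 0,
                                          patience = 15, seed = 8))
  tr <- tidy(m)$train_loss
  expect_lt(mean(utils::tail(tr, 3)), mean(utils::head(tr, 3)))
})

test_that("noiseless deterministic RMS is recovered below 10% held-out error", {
  # true RMS is a deterministic function of the (well-separated) pulse
  # attenuation: the regressor should recover it almost exactly
  p <- quick_profile(
    attenuation = c(normal = 1, bend = 0.7, strength = 0.45, dumbbell = 0.25),
    amp_jitter_sd = 0, force_jitter_sd = 0, ppg_noise_sd = 0)
  st <- generate_study(p, reps_per_state = 6, seed = 77)
  pr <- pair_study(st)
  fm <- ppgmuscle:::assign_folds(dplyr::filter(st, channel == "ppg"),
                                 k = 6, seed = 77)
  pr <- dplyr::left_join(pr, fm[c("segment_id", "fold")], by = "segment_id")
  m <- train_rms_regressor(dplyr::filter(pr, fold != 1),
                           cnn_config(epochs = 80, lr_decay = 0.99, seed = 77))
  held <- dplyr::filter(pr, fold == 1)
  expect_lt(error_rate(predict_rms(m, held), held$r), 0.10)
})
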