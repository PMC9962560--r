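test_that("confusion counts and F-values match direct arithmetic", {
  counts <- tibble::tibble(class = "x", tp = 8, fp = 2, fn = 4, tn = 0)
  expect_equal(f_value(counts)$f_value, 2 * 8 / (16 + 2 + 4))
  expect_equal(f_value(tibble::tibble(class = "x", tp = 10, fp = 0, fn = 0,
                                      tn = 0))$f_value, 1)
  expect_equal(f_value(tibble::tibble(class = "x", tp = 0, fp = 3, fn = 2,
                                      tn = 0))$f_value, 0)
  expect_warning(
    out <- f_value(tibble::tibble(class = "x", tp = 0, fp = 0, fn = 0, tn = 5)),
    "defined as 0")
  expect_equal(out$f_value, 0)
  cc <- confusion_counts(factor(c("a", "a", "b")), factor(c("a", "b", "b")))
  expect_equal(cc$tp, c(1, 1))
  expect_equal(cc$fp, c(0, 1))
  expect_equal(cc$fn, c(1, 0))
})

test_that("the F-value is symmetric in the two component ratios", {
  # harmonic mean is invariant to swapping precision and recall, so the
  # reported metric is unaffected by which ratio carries which name
  tp <- 8; fp <- 2; fn <- 4
  prec <- tp / (tp + fp); rec <- tp / (tp + fn)
  expect_equal(2 * prec * rec / (prec + rec), 2 * rec * prec / (rec + prec))
  expect_equal(2 * prec * rec / (prec + rec), 2 * tp / (2 * tp + fp + fn))
})

test_that("error rate has the right anchors and scale invariance", {
  expect_equal(error_rate(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(error_rate(c(0, 0), c(5, 15)), 1)     # zero predictor = 100%
  withr::with_seed(2, { y <- stats::runif(30, 1, 3); r <- stats::runif(30, 1, 3) })
  expect_equal(error_rate(3.7 * y, 3.7 * r), error_rate(y, r),
               tolerance = 1e-12)
  expect_error(error_rate(1, numeric(0)), "length")
  expect_error(error_rate(c(1, 1), c(0, 0)), "undefined")
})

test_that("fold assignment partitions segments, stratified by state", {
  st <- generate_study(quick_profile(), reps_per_state = 10,
                       channels = "ppg", seed = 3)
  fm <- ppgmuscle:::assign_folds(st, k = 5, seed = 1)
  # union of test folds covers every segment exactly once
  expect_equal(sort(fm$segment_id), sort(unique(st$segment_id)))
  per <- dplyr::count(fm, state, fold)
  expect_true(all(per$n == 2))
  expect_error(ppgmuscle:::assign_folds(st, k = 1, seed = 1), "k >= 2")
  expect_error(ppgmuscle:::assign_folds(st, k = 11, seed = 1), "fewer")
})

test_that("no test window shares a segment with any training window", {
  st <- generate_study(quick_profile(), reps_per_state = 4,
                       channels = "ppg", seed = 4)
  fm <- ppgmuscle:::assign_folds(st, k = 2, seed = 9)
  feats <- featurize_study(st)
  feats <- dplyr::left_join(feats, fm[c("segment_id", "fold")],
                            by = "segment_id")
  for (f in 1:2) {
    tr <- dplyr::filter(feats, fold != f)
    te <- dplyr::filter(feats, fold == f)
    expect_length(intersect(tr$segment_id, te$segment_id), 0)
  }
})

test_that("user-dependent CV reports are reproducible and well-formed", {
  st <- generate_study(quick_profile(), reps_per_state = 4,
                       channels = "ppg", seed = 6)
  r1 <- cv_user_dependent(st, k = 2, task = "classify", seed = 5)
  r2 <- cv_user_dependent(st, k = 2, task = "classify", seed = 5)
  expect_identical(tidy(r1), tidy(r2))
  expect_true(all(tidy(r1)$f_value >= 0 & tidy(r1)$f_value <= 1))
  expect_setequal(tidy(r1)$class, c("normal", "bend", "strain"))
  expect_error(cv_user_dependent(st, k = 5, task = "classify"), "fewer")
  multi <- generate_study(default_profiles(2), reps_per_state = 2,
                          channels = "ppg", seed = 1)
  expect_error(cv_user_dependent(multi, k = 2), "single subject")
})

test_that("leave-one-subject-out transfer tracks amplitude overlap", {
  # shared amplitude profile: transfer succeeds
  shared <- default_profiles(3, seed = 10, base_amp = c(1, 1, 1))
  st_shared <- generate_study(shared, reps_per_state = 4, channels = "ppg",
                              seed = 10)
  rep_shared <- eval_user_independent(st_shared, "S01", seed = 1)
  expect_gte(mean(tidy(rep_shared)$f_value), 0.7)
  expect_false("S01" %in% unique(
    dplyr::filter(st_shared, subject_id != "S01")$subject_id))
  # disjoint amplitudes: transfer degrades markedly
  disjoint <- default_profiles(3, seed = 10, base_amp = c(0.4, 1.0, 1.8))
  st_dis <- generate_study(disjoint, reps_per_state = 4, channels = "ppg",
                           seed = 10)
  rep_dis <- eval_user_independent(st_dis, "S01", seed = 1)
  expect_lt(mean(tidy(rep_dis)$f_value), mean(tidy(rep_shared)$f_value) - 0.2)
  expect_error(eval_user_independent(st_dis, "S99"), "not present")
  single <- dplyr::filter(st_dis, subject_id == "S01")
  expect_error(eval_user_independent(single, "S01"), "two subjects")
})

test_that("regression CV evaluates a named subset of folds", {
  st <- tiny_study()
  rep <- cv_user_dependent(st, k = 3, task = "regress", seed = 2,
                           config = cnn_config(epochs = 3, seed = 2),
                           folds = 1)
  td <- tidy(rep)
  expect_equal(nrow(td), 4)
  expect_true(all(td$error_rate >= 0))
  expect_equal(unique(tidy(rep, pooled = FALSE)$fold), 1)
})
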