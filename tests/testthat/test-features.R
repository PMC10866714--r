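test_that("feature extraction matches hand-computed values", {
  tt <- seq(0, 10, by = 0.5)
  const <- structure(list(cell_id = "c", times = tt, shr = rep(2, length(tt)),
                          norm_size = seq(0, 1, length.out = length(tt))),
                     class = "cell_cycle_segment")
  f <- extract_features(const)
  expect_equal(f$shr_max_level, 2)
  expect_equal(f$shr_mean_level, 2)
  expect_equal(f$shr_auc, 20)          # 10 h x level 2, trapezoid
  expect_equal(f$shr_max_rate, 0)
  expect_equal(f$duration, 10)

  # linear ramp 0 -> 1 over 4 h sampled every 0.25 h
  tt2 <- seq(0, 4, by = 0.25)
  ramp <- structure(list(cell_id = "c", times = tt2,
                         shr = seq(0, 1, length.out = length(tt2))),
                    class = "cell_cycle_segment")
  f2 <- extract_features(ramp)
  expect_equal(f2$shr_auc, 2)
  expect_equal(f2$shr_max_rate, 0.25)  # slope of a 0 -> 1 rise over 4 h
  expect_equal(f2$shr_time_to_half_max, 2)

  # a quarter the unit never visits is flagged missing, not zero
  stuck <- structure(list(cell_id = "c", times = tt2,
                          shr = seq(0, 1, length.out = length(tt2)),
                          norm_size = rep(0.1, length(tt2))),
                     class = "cell_cycle_segment")
  f3 <- extract_features(stuck)
  expect_true(is.na(f3$shr_max_in_q3))
  expect_false(is.na(f3$shr_max_in_q1))
  expect_error(extract_features(list(times = numeric(0), shr = numeric(0))),
               class = "shrscr_argument_error")
})

test_that("feature extraction is stable under 2x grid refinement", {
  tt <- seq(0, 12, by = 0.5)
  v <- plogis((tt - 5)) + 0.1
  unit <- structure(list(cell_id = "c", times = tt, shr = v),
                    class = "cell_cycle_segment")
  tt_fine <- seq(0, 12, by = 0.25)
  fine <- structure(list(cell_id = "c", times = tt_fine,
                         shr = approx(tt, v, tt_fine)$y),
                    class = "cell_cycle_segment")
  a <- extract_features(unit); b <- extract_features(fine)
  expect_lt(abs(b$shr_auc / a$shr_auc - 1), 0.01)
  expect_lt(abs(b$shr_mean_level / a$shr_mean_level - 1), 0.01)
  expect_equal(b$shr_max_level, a$shr_max_level, tolerance = 1e-9)
})

test_that("the cross-validated classifier separates separable data and is seed-stable", {
  set.seed(1)
  n <- 120
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  feats <- data.frame(a = ifelse(lab, 1, 0) + rnorm(n, 0, 0.01),
                      b = rnorm(n), label = lab)
  rep1 <- train_classifier(feats, folds = 5, seed = 3)
  expect_equal(rep1$cv_accuracy, 1)
  expect_equal(rep1$cv_accuracy, mean(rep1$per_fold))
  # identical seed and data -> identical folds and accuracies
  rep2 <- train_classifier(feats, folds = 5, seed = 3)
  expect_identical(rep1$per_fold, rep2$per_fold)
  # permuting row order leaves the cross-validated accuracy unchanged
  perm <- sample(n)
  rep3 <- train_classifier(feats[perm, ], folds = 5, seed = 3)
  expect_equal(rep3$cv_accuracy, rep1$cv_accuracy)
  # missing values are imputed, not fatal
  feats$a[c(3, 50)] <- NA
  expect_s3_class(train_classifier(feats, folds = 5, seed = 3),
                  "classifier_report")
  expect_error(train_classifier(feats[1:6, ], folds = 5, seed = 1))
})

test_that("label-shuffled features classify near chance", {
  set.seed(21)
  n <- 200
  feats <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n),
                      label = rep(c(TRUE, FALSE), each = n / 2))
  accs <- vapply(1:10, function(s) {
    shuffled <- feats
    shuffled$label <- sample(shuffled$label)
    train_classifier(shuffled, folds = 5, seed = s)$cv_accuracy
  }, numeric(1))
  expect_true(mean(accs >= 0.4 & accs <= 0.6) >= 0.8)
})

test_that("single-feature discrimination ranks informative features first", {
  set.seed(5)
  n <- 300
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  feats <- data.frame(oracle = as.numeric(lab),
                      noise = rnorm(n),
                      constant = rep(1, n),
                      label = lab)
  rank <- single_feature_discrimination(feats)
  expect_equal(rank$feature[1], "oracle")
  expect_equal(rank$accuracy[rank$feature == "oracle"], 1)
  expect_true(rank$uninformative[rank$feature == "constant"])
  expect_equal(rank$accuracy[rank$feature == "constant"], 0.5)
  noise_acc <- rank$accuracy[rank$feature == "noise"]
  expect_lt(noise_acc, 0.6)
  # the trivial classifier is always available
  expect_true(all(rank$accuracy >= max(mean(lab), 1 - mean(lab)) - 1 / n))
})
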