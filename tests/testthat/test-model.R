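test_that("trapezoidal AUC equals pair counting on random inputs including ties", {
  set.seed(33)
  for (rep in 1:50) {
    n <- sample(6:30, 1)
    scores <- sample(round(rnorm(n), sample(0:2, 1)))  # forces ties sometimes
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    mw <- auc_mann_whitney(scores, labels)
    tz <- auc_trapezoid(scores, labels)
    expect_equal(mw, tz, tolerance = 1e-12)
    expect_equal(mw, naive_pair_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC worked example and conventions", {
  # positives 0.9, 0.8; negatives 0.7, 0.85 -> 3 wins of 4 pairs
  expect_equal(auc_mann_whitney(c(0.9, 0.8, 0.7, 0.85),
                                c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(auc_trapezoid(c(0.9, 0.8, 0.7, 0.85),
                             c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  # all scores equal -> 0.5 by the tie convention
  expect_equal(auc_mann_whitney(rep(1, 8), rep(c(TRUE, FALSE), 4)), 0.5)
  # single class -> undefined
  expect_true(is.na(auc_mann_whitney(1:4, rep(TRUE, 4))))
})

test_that("AUC is invariant under strictly monotone transforms and agrees with pROC", {
  set.seed(14)
  scores <- rnorm(40)
  labels <- runif(40) < 0.35
  a <- auc_mann_whitney(scores, labels)
  expect_equal(auc_mann_whitney(exp(scores), labels), a)
  expect_equal(auc_mann_whitney(scores^3 + 5 * scores, labels), a)
  skip_if_not_installed("pROC")
  expect_equal(a, as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                 quiet = TRUE,
                                                 direction = "<"))))
})

test_that("outcome-stratified folds satisfy the one-positive-per-group invariant", {
  mk <- function(npos, nneg) data.frame(
    patient_id = sprintf("p%03d", seq_len(npos + nneg)),
    refractory = c(rep(TRUE, npos), rep(FALSE, nneg)))
  # 24 patients, 12 positive -> 12 groups of 2
  f <- make_refractory_folds(mk(12, 12), seed = 1)
  tab <- table(f$group)
  expect_equal(length(tab), 12L)
  expect_true(all(tab == 2))
  # 167 patients, 12 positive -> sizes 13 or 14
  o <- mk(12, 155)
  f <- make_refractory_folds(o, seed = 2)
  tab <- table(f$group)
  expect_true(all(tab %in% c(13, 14)))
  pos_per_group <- tapply(o$refractory, f$group, sum)
  expect_true(all(pos_per_group == 1))
  # fewer than 2 positives is an error
  expect_error(make_refractory_folds(mk(1, 10), seed = 1), "at least 2")
})

test_that("boosting reaches zero training error on a separable toy set", {
  set.seed(4)
  x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 4), 20, 2))
  y <- rep(c(FALSE, TRUE), each = 20)
  fit <- train_boosted_svm(x, y, n_stages = 10)
  expect_gte(length(fit$stages), 1L)
  expect_equal(predict(fit, x) > 0, y)
})

test_that("training is deterministic under seed; duplication keeps standardization", {
  set.seed(5)
  x <- matrix(rnorm(60), 30, 2)
  y <- x[, 1] + 0.5 * rnorm(30) > 0
  set.seed(99); f1 <- train_boosted_svm(x, y, n_stages = 5)
  set.seed(99); f2 <- train_boosted_svm(x, y, n_stages = 5)
  expect_equal(predict(f1, x), predict(f2, x))
  fd <- train_boosted_svm(rbind(x, x), c(y, y), n_stages = 5)
  expect_equal(fd$center, f1$center)
  # scale differs only by the n-1 denominator on 2n rows
  expect_equal(fd$scale, apply(rbind(x, x), 2, sd))
  expect_error(train_boosted_svm(x, rep(TRUE, 30)), "single class")
})

test_that("leave-2-groups-out evaluation: separable signal scores AUC 1, error 0", {
  set.seed(6)
  n <- 24
  feats <- data.frame(f1 = c(rnorm(6, 50), rnorm(18, 0)),
                      f2 = rnorm(n))
  outc <- data.frame(patient_id = sprintf("p%02d", 1:n),
                     refractory = rep(c(TRUE, FALSE), c(6, 18)))
  folds <- make_refractory_folds(outc, seed = 3)
  ev <- evaluate_leave_2_groups_out(feats, outc, folds, c("f1", "f2"),
                                    n_stages = 10, cost = 100,
                                    n_boot = 200, seed = 3)
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$total_error_rate, 0)
  expect_true(ev$ci_low <= ev$auc && ev$auc <= ev$ci_high)
  # determinism end to end
  ev2 <- evaluate_leave_2_groups_out(feats, outc, folds, c("f1", "f2"),
                                     n_stages = 10, cost = 100,
                                     n_boot = 200, seed = 3)
  expect_identical(ev$scores, ev2$scores)
  expect_identical(c(ev$auc, ev$ci_low, ev$ci_high),
                   c(ev2$auc, ev2$ci_low, ev2$ci_high))
})

test_that("single-feature baseline conventions", {
  y <- rep(c(TRUE, FALSE), c(5, 15))
  # feature equal to the label separates perfectly
  ev <- single_feature_auc(as.numeric(y), y, n_boot = 100, seed = 1)
  expect_equal(ev$auc, 1.0)
  expect_true(is.na(ev$total_error_rate))
  # anti-predictive feature reported as-is
  ev <- single_feature_auc(-as.numeric(y), y, n_boot = 100, seed = 1)
  expect_equal(ev$auc, 0.0)
  # constant feature -> 0.5
  ev <- single_feature_auc(rep(2, 20), y, n_boot = 100, seed = 1)
  expect_equal(ev$auc, 0.5)
  # independent feature -> near 0.5
  set.seed(10)
  reps <- vapply(1:30, function(i)
    auc_mann_whitney(rnorm(200), runif(200) < 0.3), numeric(1))
  expect_lt(abs(mean(reps) - 0.5), 3 * sd(reps) / sqrt(length(reps)) + 0.02)
})
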