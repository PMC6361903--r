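#' Area under the ROC curve
#'
#' Two independent routes to the same quantity: `auc_mann_whitney()` counts
#' positive-negative score pairs (ties count 1/2, via midranks);
#' `auc_trapezoid()` integrates the ROC curve with the trapezoidal rule,
#' grouping tied scores at a single cut-point. Both return the probability
#' that a random positive scores above a random negative. Orientation is
#' taken as-is: an anti-predictive score yields an AUC below 0.5.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical (TRUE = positive) aligned with `scores`.
#' @return AUC in \eqn{[0,1]}; `NA` when either class is absent.
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname auc_mann_whitney
#' @export
auc_trapezoid <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # cumulative counts at each distinct score cut (ties grouped)
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[last_of_group] / n1
  fp <- cumsum(!y)[last_of_group] / n0
  tp <- c(0, tp); fp <- c(0, fp)
  sum(diff(fp) * (tp[-1] + tp[-length(tp)]) / 2)
}

# Bootstrap percentile CI for the AUC; resamples (score,label) pairs.
.auc_boot_ci <- function(scores, labels, n_boot = 2000, conf = 0.95) {
  n <- length(scores)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    auc_mann_whitney(scores[idx], labels[idx])
  }, numeric(1))
  reps <- reps[!is.na(reps)]
  a <- (1 - conf) / 2
  stats::quantile(reps, c(a, 1 - a), names = FALSE, type = 7)
}

#' Outcome-stratified group assignment
#'
#' Splits the cohort into `G` groups, where `G` is the number of refractory
#' cases, with exactly one refractory case per group and the remaining
#' patients dealt so that group sizes differ by at most 1. This mirrors the
#' protocol of training on `G - 2` groups and testing on the held-out 2.
#'
#' @param outcomes data.frame with `patient_id` and logical `refractory`.
#' @param seed integer seed for the random permutation.
#' @return data.frame `patient_id`, `group` (1..G) of class
#'   `fold_assignment`.
#' @export
make_refractory_folds <- function(outcomes, seed = 1L) {
  stopifnot(all(c("patient_id", "refractory") %in% names(outcomes)))
  pos <- outcomes$patient_id[outcomes$refractory]
  neg <- outcomes$patient_id[!outcomes$refractory]
  G <- length(pos)
  if (G < 2) stop("need at least 2 refractory cases to form groups; got ", G)
  n <- nrow(outcomes)
  set.seed(seed)
  pos <- sample(pos)
  neg <- sample(neg)
  sizes <- rep(n %/% G, G)
  extra <- n %% G
  if (extra > 0) sizes[sample.int(G, extra)] <- sizes[1] + 1L
  grp_neg <- rep(seq_len(G), times = sizes - 1L)
  out <- data.frame(
    patient_id = c(pos, neg),
    group = c(seq_len(G), grp_neg),
    stringsAsFactors = FALSE
  )
  out <- out[match(outcomes$patient_id, out$patient_id), ]
  rownames(out) <- NULL
  class(out) <- c("fold_assignment", "data.frame")
  out
}

#' AdaBoost over linear SVM weak learners
#'
#' Discrete AdaBoost in which each weak learner is a linear-kernel support
#' vector machine fitted on a weighted bootstrap resample of the training
#' rows (resampling with probability proportional to the boosting weights).
#' Stage weights are \eqn{\alpha_t = \tfrac12 \ln((1-\epsilon_t)/\epsilon_t)}
#' on the weighted training error \eqn{\epsilon_t}; boosting stops early
#' when \eqn{\epsilon_t = 0} (the stage gets a large capped weight) or
#' \eqn{\epsilon_t \ge 0.5}. Features are z-scored with training-set mean
#' and sd (stored in the model and re-applied at prediction).
#'
#' @param x numeric matrix (rows = training cases, columns = features).
#' @param y logical (TRUE = refractory) or -1/+1 vector.
#' @param n_stages maximum boosting stages (default 50).
#' @param cost SVM cost parameter.
#' @return An object of class `boosted_svm` with elements `stages` (list of
#'   `list(fit, alpha)`), `center`, `scale`, `feature_names`.
#' @export
train_boosted_svm <- function(x, y, n_stages = 50L, cost = 1) {
  x <- as.matrix(x)
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  y <- as.numeric(y)
  stopifnot(all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2) stop("training set contains a single class")
  n <- nrow(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = ctr, scale = scl)

  w <- rep(1 / n, n)
  stages <- list()
  for (t in seq_len(n_stages)) {
    fit <- NULL
    for (try in 1:10) {
      idx <- sample.int(n, n, replace = TRUE, prob = w)
      if (length(unique(y[idx])) == 2) {
        fit <- e1071::svm(xs[idx, , drop = FALSE],
                          factor(y[idx], levels = c(-1, 1)),
                          kernel = "linear", cost = cost, scale = FALSE)
        break
      }
    }
    if (is.null(fit)) break  # weights degenerate on one class
    h <- as.numeric(as.character(predict(fit, xs)))
    eps <- sum(w * (h != y))
    if (eps >= 0.5) {
      if (length(stages) > 0) break
      # first stage no better than chance: keep it with near-zero weight
      stages[[1]] <- list(fit = fit, alpha = 1e-8)
      break
    }
    alpha <- if (eps == 0) 0.5 * log((1 - 1e-10) / 1e-10) else
      0.5 * log((1 - eps) / eps)
    stages[[length(stages) + 1L]] <- list(fit = fit, alpha = alpha)
    if (eps == 0) break
    w <- w * exp(-alpha * y * h)
    w <- w / sum(w)
  }
  structure(list(stages = stages, center = ctr, scale = scl,
                 feature_names = colnames(x)),
            class = "boosted_svm")
}

#' Ensemble score and predicted label
#'
#' The score is the alpha-weighted sum of stage votes
#' \eqn{\sum_t \alpha_t h_t(x)}; the predicted label is positive when the
#' score is strictly greater than 0.
#'
#' @param object a [train_boosted_svm()] model.
#' @param newdata feature matrix.
#' @param ... unused.
#' @return Numeric score vector (attribute-free); use `> 0` for labels.
#' @export
predict.boosted_svm <- function(object, newdata, ...) {
  xs <- scale(as.matrix(newdata), center = object$center, scale = object$scale)
  score <- rep(0, nrow(xs))
  for (st in object$stages) {
    h <- as.numeric(as.character(predict(st$fit, xs)))
    score <- score + st$alpha * h
  }
  score
}

.new_eval_result <- function(auc, ci, err, scores_df) {
  structure(list(auc = auc, ci_low = ci[1], ci_high = ci[2],
                 total_error_rate = err, scores = scores_df),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result> AUC %.3f (95%% CI %.3f-%.3f), total error rate %s, %d scored cases\n",
              x$auc, x$ci_low, x$ci_high,
              if (is.na(x$total_error_rate)) "NA" else
                sprintf("%.3f", x$total_error_rate),
              nrow(x$scores)))
  invisible(x)
}

#' Leave-2-groups-out evaluation of the boosted model
#'
#' For each evaluation round, 2 of the `G` outcome-stratified groups are
#' held out, the boosted SVM is trained on the remaining `G - 2` groups and
#' the held-out patients are scored out-of-sample. `mode = "rotate"`
#' (default) cycles over all unordered group pairs (optionally capped at
#' `max_rounds` randomly chosen pairs); `mode = "single"` reproduces a
#' single random 2-group holdout. Out-of-sample scores are pooled across
#' rounds; the pooled AUC is computed by pair counting with a bootstrap
#' percentile confidence interval, and the total error rate is the pooled
#' misclassification fraction at score threshold 0.
#'
#' @param features data.frame/matrix of per-patient features (rows aligned
#'   with `outcomes`).
#' @param outcomes data.frame with `patient_id` and `refractory`.
#' @param folds a [make_refractory_folds()] assignment.
#' @param feature_names columns of `features` used by the model.
#' @param mode `"rotate"` or `"single"`.
#' @param n_stages,cost passed to [train_boosted_svm()].
#' @param max_rounds cap on rotation rounds (default all `C(G,2)` pairs).
#' @param n_boot bootstrap resamples for the CI.
#' @param seed integer seed governing resampling, round order and bootstrap.
#' @return An `eval_result`: `auc`, `ci_low`, `ci_high`,
#'   `total_error_rate`, and `scores` (pooled per-case data.frame).
#' @export
evaluate_leave_2_groups_out <- function(features, outcomes, folds,
                                        feature_names,
                                        mode = c("rotate", "single"),
                                        n_stages = 50L, cost = 1,
                                        max_rounds = Inf, n_boot = 2000L,
                                        seed = 1L) {
  mode <- match.arg(mode)
  x <- as.matrix(as.data.frame(features)[, feature_names, drop = FALSE])
  y <- outcomes$refractory
  grp <- folds$group[match(outcomes$patient_id, folds$patient_id)]
  stopifnot(!anyNA(grp))
  G <- max(grp)
  if (G < 3)
    stop("leave-2-groups-out needs at least 3 groups (3 refractory cases); got ", G)

  set.seed(seed)
  pairs <- utils::combn(G, 2)
  if (mode == "single") {
    pairs <- pairs[, sample.int(ncol(pairs), 1), drop = FALSE]
  } else if (is.finite(max_rounds) && max_rounds < ncol(pairs)) {
    pairs <- pairs[, sample.int(ncol(pairs), max_rounds), drop = FALSE]
  }

  pooled <- list()
  for (r in seq_len(ncol(pairs))) {
    test <- grp %in% pairs[, r]
    fit <- train_boosted_svm(x[!test, , drop = FALSE], y[!test],
                             n_stages = n_stages, cost = cost)
    sc <- predict(fit, x[test, , drop = FALSE])
    pooled[[r]] <- data.frame(patient_id = outcomes$patient_id[test],
                              round = r, score = sc, refractory = y[test],
                              stringsAsFactors = FALSE)
  }
  pooled <- do.call(rbind, pooled)
  auc <- auc_mann_whitney(pooled$score, pooled$refractory)
  ci <- .auc_boot_ci(pooled$score, pooled$refractory, n_boot = n_boot)
  err <- mean((pooled$score > 0) != pooled$refractory)
  .new_eval_result(auc, ci, err, pooled)
}

#' Single-feature ROC baseline
#'
#' Uses one raw feature value as the score (no model), e.g. Volume (MTV),
#' TLG or GlobalMax (SUVmax), and reports AUC with a bootstrap percentile
#' CI. The orientation is not flipped: a feature that scores negatives
#' higher yields an AUC below 0.5. A constant feature gives AUC 0.5 by the
#' tie convention. No score threshold is defined for a raw feature, so the
#' error rate is `NA`.
#'
#' @param values numeric feature values per patient.
#' @param refractory logical labels.
#' @param n_boot,seed bootstrap controls.
#' @return An `eval_result` (with `total_error_rate = NA`).
#' @export
single_feature_auc <- function(values, refractory, n_boot = 2000L, seed = 1L) {
  set.seed(seed)
  auc <- auc_mann_whitney(values, refractory)
  ci <- .auc_boot_ci(values, refractory, n_boot = n_boot)
  .new_eval_result(auc, ci, NA_real_,
                   data.frame(score = values, refractory = refractory))
}
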