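# Random-forest case/control classification protocol: abundance filtering
# with probiotic-species exclusion, stratified cross-validation with
# in-fold standardisation and Gini-based feature elimination, and signed
# permutation attribution.

#' Prepare the classifier feature matrix
#'
#' Keeps features with mean relative abundance above `min_mean_abundance`,
#' drops named excluded features (typically therapeutically administered
#' probiotic species, whose abundance reflects exposure rather than
#' endogenous community state), and returns the samples x features matrix
#' with case/control labels. Standardisation is deliberately *not* applied
#' here: scaling parameters are computed inside training folds by
#' [train_evaluate()] to avoid information leakage.
#'
#' @param table A relative `feature_table`.
#' @param cohort A [cohort_table()] covering the table's samples.
#' @param min_mean_abundance Mean-abundance threshold (default 1%).
#' @param exclude Character vector of feature names to drop.
#' @param age_range Optional `c(lo, hi]` collection-age window (months);
#'   samples outside are dropped.
#' @return List: `x` (samples x features), `y` (factor control/case),
#'   `sample_ids`.
#' @export
prepare_features <- function(table, cohort, min_mean_abundance = 0.01,
                             exclude = character(), age_range = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(cohort, "cohort"))
  v <- table$values
  ids <- colnames(v)
  s <- cohort$samples[match(ids, cohort$samples$sample_id), ]
  if (any(is.na(s$sample_id))) stop("table contains samples absent from cohort")
  if (!is.null(age_range)) {
    keep <- s$age_months > age_range[1] & s$age_months <= age_range[2]
    v <- v[, keep, drop = FALSE]
    s <- s[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  keep_f <- rowMeans(v) > min_mean_abundance
  keep_f[rownames(v) %in% exclude] <- FALSE
  if (!any(keep_f)) stop("no features survive the abundance filter")
  grp <- cohort$infants$group[match(s$infant_id, cohort$infants$infant_id)]
  list(x = t(v[keep_f, , drop = FALSE]),
       y = factor(grp, levels = c("control", "case")),
       sample_ids = ids)
}

scale_train_test <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sd_ <- apply(x_train, 2, stats::sd)
  flat <- sd_ == 0
  sd_[flat] <- 1  # zero-variance features pass through centred only
  list(train = sweep(sweep(x_train, 2, mu), 2, sd_, "/"),
       test = sweep(sweep(x_test, 2, mu), 2, sd_, "/"),
       zero_variance = names(sd_)[flat])
}

fit_weighted_forest <- function(x, y, ntree) {
  cw <- as.numeric(1 / table(y)[levels(y)])
  cw <- cw / sum(cw)
  randomForest::randomForest(x = x, y = y, ntree = ntree,
                             classwt = stats::setNames(cw, levels(y)),
                             importance = TRUE)
}

# drop the lowest-Gini decile per iteration until <= n_keep features remain
eliminate_features <- function(x, y, n_keep, ntree) {
  feats <- colnames(x)
  while (length(feats) > n_keep) {
    fit <- fit_weighted_forest(x[, feats, drop = FALSE], y, ntree)
    gini <- randomForest::importance(fit, type = 2)[, 1]
    n_drop <- min(ceiling(0.10 * length(feats)), length(feats) - n_keep)
    drop <- names(sort(gini))[seq_len(n_drop)]
    feats <- setdiff(feats, drop)
  }
  feats
}

#' Cross-validated random-forest evaluation
#'
#' Stratified k-fold cross-validation. Inside each training fold only:
#' features are standardised, a class-weighted forest is grown, the
#' lowest-Gini decile of features is iteratively removed until at most
#' `n_keep` remain, and the reduced forest predicts the held-out fold.
#' Per-class correct-classification rates are aggregated over folds. A
#' final model (features selected on the full data with the same schedule)
#' and its signed permutation attribution are included for interpretation.
#'
#' @param x Samples x features numeric matrix (e.g. from
#'   [prepare_features()]).
#' @param y Factor with levels `control`, `case`.
#' @param n_keep Features retained after elimination.
#' @param folds Number of CV folds.
#' @param seed Integer seed; the full run is deterministic given it.
#' @param ntree Trees per forest.
#' @return List of class `classifier_report`: `confusion` (true x
#'   predicted), `class_rates` (per-class correct fraction), `accuracy`,
#'   `selected_features`, `attribution` (data frame), `final_model`,
#'   `folds`, `seed`.
#' @export
train_evaluate <- function(x, y, n_keep = 120, folds = 5, seed = 1,
                           ntree = 500) {
  stopifnot(is.matrix(x), nrow(x) == length(y), is.factor(y))
  if (any(table(y) < folds)) stop("need at least `folds` samples per class")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_id <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  pred <- factor(rep(NA, length(y)), levels = levels(y))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    sc <- scale_train_test(x[tr, , drop = FALSE], x[!tr, , drop = FALSE])
    feats <- if (n_keep >= ncol(x)) colnames(x) else
      eliminate_features(sc$train, y[tr], n_keep, ntree)
    fit <- fit_weighted_forest(sc$train[, feats, drop = FALSE], y[tr], ntree)
    pred[!tr] <- stats::predict(fit, sc$test[, feats, drop = FALSE])
  }
  confusion <- table(true = y, predicted = pred)
  class_rates <- diag(confusion) / rowSums(confusion)
  # final interpretive model on the full data
  sc_all <- scale_train_test(x, x)
  feats_all <- if (n_keep >= ncol(x)) colnames(x) else
    eliminate_features(sc_all$train, y, n_keep, ntree)
  final <- fit_weighted_forest(sc_all$train[, feats_all, drop = FALSE], y,
                               ntree)
  attrib <- attribution(final, sc_all$train[, feats_all, drop = FALSE], y)
  structure(list(confusion = confusion,
                 class_rates = class_rates,
                 accuracy = mean(pred == y),
                 selected_features = feats_all,
                 attribution = attrib,
                 final_model = final,
                 folds = folds, seed = seed),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report>\n")
  print(x$confusion)
  cat(sprintf("per-class rates: control %.3f, case %.3f; overall %.3f\n",
              x$class_rates["control"], x$class_rates["case"], x$accuracy))
  invisible(x)
}

#' Signed permutation attribution
#'
#' Per-feature importance is the mean decrease, over `n_perm` permutations
#' of that feature, in the model's mean predicted probability of the true
#' class; the sign is the correlation between the feature value and the
#' predicted case probability (positive = higher values push towards
#' case). This plays the interpretive role of Shapley-value summaries
#' (ranking plus direction) without additional dependencies; an exact
#' Shapley implementation can be slotted in where available.
#'
#' @param model A fitted [randomForest::randomForest] classifier.
#' @param x The feature matrix the model was fitted on (samples x
#'   features).
#' @param y True labels (factor with levels matching the model).
#' @param n_perm Permutations per feature.
#' @param seed Seed for the permutations.
#' @return Data frame sorted by `abs(importance)` descending: feature,
#'   importance (signed), mean_abs (unsigned magnitude), direction
#'   (case-associated / control-associated / none).
#' @export
attribution <- function(model, x, y, n_perm = 10, seed = 1) {
  stopifnot(inherits(model, "randomForest"), is.matrix(x),
            nrow(x) == length(y))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  prob <- stats::predict(model, x, type = "prob")
  base_q <- mean(prob[cbind(seq_along(y), as.integer(y))])
  case_prob <- prob[, "case"]
  n <- nrow(x)
  rows <- lapply(colnames(x), function(f) {
    drops <- numeric(n_perm)
    for (r in seq_len(n_perm)) {
      xp <- x
      xp[, f] <- xp[sample(n), f]
      pp <- stats::predict(model, xp, type = "prob")
      drops[r] <- base_q - mean(pp[cbind(seq_len(n), as.integer(y))])
    }
    mag <- mean(drops)
    sgn <- if (stats::sd(x[, f]) == 0) 0 else
      sign(stats::cor(x[, f], case_prob))
    if (is.na(sgn)) sgn <- 0
    data.frame(feature = f, importance = sgn * abs(mag), mean_abs = abs(mag),
               direction = if (sgn > 0) "case-associated"
                           else if (sgn < 0) "control-associated" else "none")
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_abs, out$feature), ]
  rownames(out) <- NULL
  out
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's
# random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
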