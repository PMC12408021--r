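# Multivariable per-feature association model for compositional tables:
# arcsine-square-root transform, abundance/prevalence filtering, per-feature
# ordinary least squares with Wald tests, Benjamini-Hochberg correction.

#' Arcsine square-root transform
#'
#' Variance-stabilising transform `asin(sqrt(x))` for proportions.
#'
#' @param x Numeric in `[0, 1]`.
#' @return Transformed values in `[0, pi/2]`.
#' @examples
#' ast_transform(0.25)  # pi/6
#' @export
ast_transform <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE)) stop("proportions must lie in [0, 1]")
  asin(sqrt(x))
}

#' Filter features by abundance and prevalence
#'
#' Keeps features whose relative abundance is at least `min_abundance` in at
#' least a `min_prevalence` fraction of samples. Defaults complete the
#' common "at least 0.1% abundance" rule with a 10% prevalence floor.
#'
#' @param table A relative `feature_table`.
#' @param min_abundance Abundance threshold in `[0, 1]`.
#' @param min_prevalence Prevalence fraction in `[0, 1]`.
#' @return Filtered `feature_table`.
#' @export
filter_features <- function(table, min_abundance = 0.001,
                            min_prevalence = 0.10) {
  stopifnot(inherits(table, "feature_table"))
  if (min_abundance < 0 || min_abundance > 1 ||
      min_prevalence < 0 || min_prevalence > 1) {
    stop("thresholds must lie in [0, 1]")
  }
  prev <- rowMeans(table$values >= min_abundance)
  keep <- if (min_prevalence == 0) {
    prev > 0  # reduces to: attains the abundance somewhere
  } else {
    prev >= min_prevalence
  }
  if (!any(keep)) stop("no features pass the filter")
  feature_table(table$values[keep, , drop = FALSE], type = table$type,
                level = table$level, taxonomy = table$taxonomy[keep],
                check_sums = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, clipped to 1 and monotone in
#' rank.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-feature multivariable association model
#'
#' For each feature that survives [filter_features()], fits ordinary least
#' squares of the arcsine-square-root transformed abundance on the encoded
#' fixed effects, and reports the Wald t-test p-value per covariate with
#' Benjamini-Hochberg q-values computed across features within each
#' covariate. Default fixed effects are symptom group, delivery mode, age
#' at collection, and first-year probiotic use, with treatment coding
#' referenced at control / vaginal / no-probiotic.
#'
#' Longitudinal handling: supplying `subset` (e.g. a disease-state subset
#' from [select_state_subsets()] plus its matched controls) restricts the
#' fit to one sample per infant by construction. Without a subset,
#' `aggregate_window` (an age window in months) reduces the data to one
#' sample per infant — the sample closest to the window midpoint — before
#' fitting, so infants with many samples do not dominate.
#'
#' @param table A relative `feature_table`.
#' @param cohort A [cohort_table()].
#' @param fixed_effects Covariates to include; any of `"group"`,
#'   `"delivery"`, `"age"`, `"probiotics"`.
#' @param subset Optional character vector of sample ids to restrict to.
#' @param aggregate_window Optional `c(lo, hi)` age window (months); samples
#'   outside are dropped and one sample per infant (closest to the window
#'   midpoint, ties by sample id) is kept.
#' @param min_abundance,min_prevalence Passed to [filter_features()].
#' @param alpha,q_threshold Significance thresholds for the `significant`
#'   flag (both must hold).
#' @return Data frame of class `differential_result`: feature, covariate,
#'   coefficient, p_value, q_value, n, direction, significant.
#' @export
fit_associations <- function(table, cohort,
                             fixed_effects = c("group", "delivery", "age",
                                               "probiotics"),
                             subset = NULL, aggregate_window = NULL,
                             min_abundance = 0.001, min_prevalence = 0.10,
                             alpha = 0.05, q_threshold = 0.25) {
  stopifnot(inherits(table, "feature_table"), inherits(cohort, "cohort"))
  fixed_effects <- match.arg(fixed_effects, several.ok = TRUE)
  ids <- colnames(table$values)
  if (!is.null(subset)) {
    missing <- setdiff(subset, ids)
    if (length(missing)) stop("subset samples absent from table: ",
                              paste(utils::head(missing, 3), collapse = ", "))
    ids <- intersect(ids, subset)
  }
  s <- cohort$samples[match(ids, cohort$samples$sample_id), ]
  if (any(is.na(s$sample_id))) stop("table contains samples absent from cohort")
  if (!is.null(aggregate_window)) {
    stopifnot(length(aggregate_window) == 2)
    mid_ <- mean(aggregate_window)
    inw <- s$age_months >= aggregate_window[1] &
      s$age_months < aggregate_window[2]
    s <- s[inw, , drop = FALSE]
    s$dev <- abs(s$age_months - mid_)
    s <- s[order(s$infant_id, s$dev, s$sample_id), ]
    s <- s[!duplicated(s$infant_id), ]
    ids <- s$sample_id
  }
  if (length(ids) < 4) stop("too few samples after subsetting")
  inf <- cohort$infants[match(s$infant_id, cohort$infants$infant_id), ]
  design <- data.frame(row.names = ids)
  if ("group" %in% fixed_effects) {
    design$group <- stats::relevel(factor(inf$group), ref = "control")
  }
  if ("delivery" %in% fixed_effects) {
    dl <- factor(inf$delivery_mode)
    if ("vaginal" %in% levels(dl)) dl <- stats::relevel(dl, ref = "vaginal")
    design$delivery <- dl
  }
  if ("age" %in% fixed_effects) design$age <- s$age_months
  if ("probiotics" %in% fixed_effects) {
    design$probiotics <- factor(inf$probiotic_first_year,
                                levels = c(FALSE, TRUE))
  }
  # drop covariates that are constant on this subset (rank deficiency)
  nlev <- vapply(design, function(v) length(unique(v)), 1L)
  if (any(nlev < 2)) {
    design <- design[, nlev >= 2, drop = FALSE]
  }
  if (ncol(design) == 0) stop("no varying covariates in this subset")
  if ("group" %in% fixed_effects && !"group" %in% names(design)) {
    stop("covariate 'group' is constant in this subset (rank deficient)")
  }
  grp <- table$values[, ids, drop = FALSE]
  sub_tab <- feature_table(grp, type = table$type, level = table$level,
                           taxonomy = table$taxonomy, check_sums = FALSE)
  filt <- filter_features(sub_tab, min_abundance, min_prevalence)
  mm <- stats::model.matrix(~ ., data = design)
  if (qr(mm)$rank < ncol(mm)) stop("design matrix is rank deficient")
  rows <- list()
  for (f in rownames(filt$values)) {
    y <- ast_transform(filt$values[f, ])
    if (stats::sd(y) == 0) {
      message("feature constant in all samples, skipped: ", f)
      next
    }
    fit <- stats::lm.fit(mm, y)
    rss <- sum(fit$residuals^2)
    df <- length(y) - fit$rank
    sigma2 <- rss / df
    xtxi <- chol2inv(chol(crossprod(mm)))
    se <- sqrt(diag(xtxi) * sigma2)
    tval <- fit$coefficients / se
    pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
    for (j in setdiff(colnames(mm), "(Intercept)")) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, covariate = j,
        coefficient = unname(fit$coefficients[j]),
        p_value = unname(pval[j]), n = length(y))
    }
  }
  if (!length(rows)) stop("no testable features")
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  for (j in unique(out$covariate)) {
    sel <- out$covariate == j
    out$q_value[sel] <- bh_adjust(out$p_value[sel])
  }
  out$direction <- ifelse(out$coefficient >= 0, "case-enriched",
                          "control-enriched")
  is_grp <- grepl("^group", out$covariate)
  out$direction[!is_grp] <- ifelse(out$coefficient[!is_grp] >= 0,
                                   "positive", "negative")
  out$significant <- out$p_value < alpha & out$q_value < q_threshold
  rownames(out) <- NULL
  class(out) <- c("differential_result", "data.frame")
  out
}
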