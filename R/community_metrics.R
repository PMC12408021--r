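# Community-level metrics: alpha/beta diversity, ordination, top-taxa
# summaries, prevalence curves, and longitudinal stability.

#' Construct a feature table
#'
#' Features (taxa or pathways) x samples matrix of non-negative values with
#' a counts-vs-relative flag and a taxonomy level tag. Relative tables must
#' sum to 1 per sample (within tolerance); use `normalise = TRUE` to rescale
#' columns.
#'
#' @param values Numeric matrix, features in rows, samples in columns; both
#'   dimnames required.
#' @param type `"counts"` or `"relative"`.
#' @param level Free-text level tag, e.g. `"species"`, `"genus"`,
#'   `"pathway"`.
#' @param taxonomy Optional character vector of full clade strings, parallel
#'   to rows.
#' @param normalise Rescale each sample to sum to 1 (only for
#'   `type = "relative"`).
#' @param check_sums Validate per-sample closure of relative tables. Set
#'   `FALSE` for deliberate subsets of a composition (e.g. after feature
#'   filtering), whose columns no longer sum to 1.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(values, type = c("relative", "counts"),
                          level = "species", taxonomy = NULL,
                          normalise = FALSE, check_sums = TRUE) {
  type <- match.arg(type)
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  if (any(values < 0)) stop("feature table must be non-negative")
  if (!is.null(taxonomy)) stopifnot(length(taxonomy) == nrow(values))
  if (type == "relative") {
    if (normalise) {
      cs <- colSums(values)
      if (any(cs == 0)) stop("cannot normalise all-zero sample")
      values <- sweep(values, 2, cs, "/")
    } else if (check_sums) {
      cs <- colSums(values)
      if (any(abs(cs - 1) > 1e-6)) {
        stop("relative table columns must sum to 1 (max deviation ",
             format(max(abs(cs - 1))), ")")
      }
    }
  }
  structure(list(values = values, type = type, level = level,
                 taxonomy = taxonomy),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples (%s, %s)\n",
              nrow(x$values), ncol(x$values), x$type, x$level))
  invisible(x)
}

#' Convert a count table to relative abundances
#' @param table A `feature_table` of counts.
#' @return A relative `feature_table`.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  cs <- colSums(v)
  if (any(cs == 0)) stop("all-zero sample; cannot form relative abundances")
  feature_table(sweep(v, 2, cs, "/"), type = "relative",
                level = table$level, taxonomy = table$taxonomy)
}

#' Chao1 richness estimate
#'
#' Nonparametric richness estimator from singleton/doubleton counts:
#' `S_obs + f1^2 / (2 f2)`, with the bias-corrected form
#' `S_obs + f1 (f1 - 1) / 2` when there are no doubletons. Requires integer
#' counts; a relative-abundance input degrades to observed richness with a
#' warning, since singletons are undefined without counts.
#'
#' @param counts Numeric vector of per-feature counts for one sample, or a
#'   counts `feature_table` (returns a per-sample vector).
#' @return Richness estimate(s).
#' @examples
#' chao1(c(5, 1, 1, 2))  # S_obs=4, f1=2, f2=1 -> 4 + 4/2 = 6
#' @export
chao1 <- function(counts) {
  if (inherits(counts, "feature_table")) {
    if (counts$type != "counts") {
      warning("Chao1 on a relative table degrades to observed richness")
      return(colSums(counts$values > 0))
    }
    return(apply(counts$values, 2, chao1))
  }
  if (any(counts < 0)) stop("negative counts")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    warning("non-integer counts; Chao1 degrades to observed richness")
    return(sum(counts > 0))
  }
  s_obs <- sum(counts > 0)
  if (s_obs == 0) return(0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

#' Shannon diversity (natural log)
#'
#' `-sum(p log p)` over positive proportions; input is renormalised
#' internally so counts or unnormalised abundances are accepted.
#'
#' @param x Numeric vector of non-negative abundances for one sample, or a
#'   `feature_table` (per-sample vector returned).
#' @return Shannon index (nats).
#' @export
shannon <- function(x) {
  if (inherits(x, "feature_table")) return(apply(x$values, 2, shannon))
  if (any(x < 0)) stop("negative abundances")
  tot <- sum(x)
  if (tot == 0) stop("all-zero sample has undefined Shannon diversity")
  p <- x[x > 0] / tot
  -sum(p * log(p))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `sum |u - v| / sum (u + v)` per sample pair, computed with
#' [vegan::vegdist()].
#'
#' @param table A relative `feature_table` (counts accepted; the metric is
#'   scale-dependent so relative input is the intended use).
#' @return Object of class `dist_matrix`: list with `matrix` (symmetric,
#'   zero diagonal), `metric`.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  d <- as.matrix(vegan::vegdist(t(table$values), method = "bray"))
  new_dist_matrix(d, "bray_curtis")
}

#' Aitchison distance matrix
#'
#' Euclidean distance between centred log-ratio (clr) transformed
#' compositions after zero replacement by a pseudocount. The default
#' pseudocount is half the minimum non-zero value in the table.
#'
#' @param table A relative `feature_table`.
#' @param pseudocount Positive replacement added to all entries before
#'   renormalisation and clr.
#' @return A `dist_matrix`.
#' @export
aitchison <- function(table, pseudocount = NULL) {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  if (is.null(pseudocount)) pseudocount <- min(v[v > 0]) / 2
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  v <- v + pseudocount
  v <- sweep(v, 2, colSums(v), "/")
  clr <- log(v) - matrix(colMeans(log(v)), nrow(v), ncol(v), byrow = TRUE)
  d <- as.matrix(stats::dist(t(clr)))
  new_dist_matrix(d, "aitchison")
}

new_dist_matrix <- function(m, metric) {
  stopifnot(is.matrix(m), isTRUE(all.equal(m, t(m), tolerance = 1e-10)))
  diag(m) <- 0
  structure(list(matrix = m, metric = metric, sample_ids = colnames(m)),
            class = "dist_matrix")
}

#' Principal coordinates analysis with axis-1 group test
#'
#' Classical metric MDS: double-centre the squared-distance Gram matrix,
#' eigendecompose, keep axes with positive eigenvalues. Explained-variance
#' fractions use only the positive eigenvalues in the denominator. Axis
#' signs follow a deterministic convention: the largest-magnitude score on
#' each axis is positive. When `groups` is supplied, a one-way ANOVA of
#' axis-1 scores on group is reported.
#'
#' @param dm A `dist_matrix`.
#' @param n_axes Number of coordinate axes to return.
#' @param groups Optional factor-like vector, parallel to the samples, for
#'   the axis-1 ANOVA.
#' @return List: `coordinates` (samples x axes), `explained` (variance
#'   fractions), `eigenvalues`, and `anova_axis1` (data frame with F and p)
#'   when `groups` is given.
#' @export
pcoa_ordination <- function(dm, n_axes = 2, groups = NULL) {
  stopifnot(inherits(dm, "dist_matrix"))
  d <- dm$matrix
  n <- nrow(d)
  a <- -0.5 * d^2
  centre <- diag(n) - matrix(1 / n, n, n)
  g <- centre %*% a %*% centre
  g <- (g + t(g)) / 2
  eig <- eigen(g, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-12
  if (n_axes > sum(pos)) stop("n_axes exceeds the rank of the configuration")
  vals <- eig$values[pos][seq_len(n_axes)]
  vecs <- eig$vectors[, pos, drop = FALSE][, seq_len(n_axes), drop = FALSE]
  coords <- sweep(vecs, 2, sqrt(vals), "*")
  for (j in seq_len(ncol(coords))) {
    if (coords[which.max(abs(coords[, j])), j] < 0) {
      coords[, j] <- -coords[, j]
    }
  }
  rownames(coords) <- dm$sample_ids
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  out <- list(coordinates = coords,
              explained = eig$values[pos][seq_len(n_axes)] /
                sum(eig$values[pos]),
              eigenvalues = eig$values)
  if (!is.null(groups)) {
    stopifnot(length(groups) == n)
    fit <- stats::aov(coords[, 1] ~ factor(groups))
    tab <- summary(fit)[[1]]
    out$anova_axis1 <- data.frame(F = tab[1, "F value"],
                                  p_value = tab[1, "Pr(>F)"])
  }
  out
}

#' Correlate alpha diversity with age
#'
#' Pearson correlation of each per-sample diversity index (Chao1 and
#' Shannon) against infant age at collection.
#'
#' @param table A `feature_table` (counts preferred, see [chao1()]).
#' @param cohort A [cohort_table()] whose samples cover the table columns.
#' @return Data frame: index, r, p_value, n.
#' @export
age_diversity_correlation <- function(table, cohort) {
  stopifnot(inherits(table, "feature_table"), inherits(cohort, "cohort"))
  ids <- colnames(table$values)
  age <- cohort$samples$age_months[match(ids, cohort$samples$sample_id)]
  if (any(is.na(age))) stop("table contains samples absent from cohort")
  if (length(ids) < 3) stop("need at least 3 samples")
  idx <- list(chao1 = suppressWarnings(chao1(table)), shannon = shannon(table))
  out <- lapply(names(idx), function(nm) {
    v <- idx[[nm]]
    if (stats::sd(v) == 0 || stats::sd(age) == 0) stop("zero variance in ", nm)
    ct <- stats::cor.test(v, age, method = "pearson")
    data.frame(index = nm, r = unname(ct$estimate), p_value = ct$p.value,
               n = length(v))
  })
  do.call(rbind, out)
}

#' Longitudinal stability across visit transitions
#'
#' For each consecutive pair of age bins, compares within-infant to
#' between-infant Bray-Curtis distances, and within-infant distances of
#' cases to controls. When an infant has several samples in a bin, the one
#' closest to the bin's target visit age (the bin midpoint) is used. A
#' transition with no eligible within-infant pair is skipped with a
#' message.
#'
#' @param table A relative `feature_table`.
#' @param cohort A [cohort_table()].
#' @param binning An [age_binning()].
#' @param between_max_pairs Cap on the number of between-infant pairs
#'   sampled per transition (deterministic subset by index stride) to keep
#'   large cohorts tractable.
#' @return Data frame, one row per transition: counts, mean within / between
#'   distance, Welch t p-value within-vs-between, and mean within-infant
#'   distance and Welch p for cases vs controls.
#' @export
stability_analysis <- function(table, cohort, binning = age_binning(),
                               between_max_pairs = 2000L) {
  stopifnot(inherits(table, "feature_table"), inherits(cohort, "cohort"))
  s <- cohort$samples
  s <- s[s$sample_id %in% colnames(table$values), ]
  s$bin <- assign_age_bin(s$age_months, binning)
  th <- binning$thresholds
  mid <- (th[-length(th)] + th[-1]) / 2
  names(mid) <- binning$labels
  dm <- bray_curtis(table)$matrix
  grp <- cohort$infants$group[match(s$infant_id, cohort$infants$infant_id)]
  s$group <- grp
  res <- list()
  for (i in seq_len(length(binning$labels) - 1L)) {
    b1 <- binning$labels[i]; b2 <- binning$labels[i + 1L]
    pick_bin <- function(b) {
      sub <- s[s$bin == b, ]
      if (nrow(sub) == 0) return(sub)
      sub$dev <- abs(sub$age_months - mid[b])
      sub <- sub[order(sub$infant_id, sub$dev, sub$sample_id), ]
      sub[!duplicated(sub$infant_id), ]
    }
    s1 <- pick_bin(b1); s2 <- pick_bin(b2)
    common <- intersect(s1$infant_id, s2$infant_id)
    if (length(common) == 0) {
      message("stability: no within-infant pair for transition ",
              b1, " -> ", b2, "; skipped")
      next
    }
    w1 <- s1$sample_id[match(common, s1$infant_id)]
    w2 <- s2$sample_id[match(common, s2$infant_id)]
    within <- dm[cbind(w1, w2)]
    wgrp <- s1$group[match(common, s1$infant_id)]
    # between: all cross-infant pairs across the two bins
    bet_idx <- expand.grid(a = seq_len(nrow(s1)), b = seq_len(nrow(s2)))
    bet_idx <- bet_idx[s1$infant_id[bet_idx$a] != s2$infant_id[bet_idx$b], ]
    if (nrow(bet_idx) > between_max_pairs) {
      keep <- round(seq(1, nrow(bet_idx), length.out = between_max_pairs))
      bet_idx <- bet_idx[keep, ]
    }
    between <- dm[cbind(s1$sample_id[bet_idx$a], s2$sample_id[bet_idx$b])]
    p_wb <- if (length(within) >= 2 && length(between) >= 2) {
      stats::t.test(within, between)$p.value
    } else NA_real_
    wc <- within[wgrp == "case"]; wn <- within[wgrp == "control"]
    p_cc <- if (length(wc) >= 2 && length(wn) >= 2) {
      stats::t.test(wc, wn)$p.value
    } else NA_real_
    res[[length(res) + 1L]] <- data.frame(
      transition = paste(b1, "->", b2),
      n_within = length(within), n_between = length(between),
      mean_within = mean(within), mean_between = mean(between),
      p_within_vs_between = p_wb,
      mean_within_case = if (length(wc)) mean(wc) else NA_real_,
      mean_within_control = if (length(wn)) mean(wn) else NA_real_,
      p_case_vs_control = p_cc)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Collapse to the top-k taxa plus "Others"
#'
#' Keeps the `k` features with the highest overall mean relative abundance
#' and sums the remainder into an `"Others"` row, so column sums are
#' preserved. Optionally also returns group x age-bin stratified means.
#'
#' @param table A relative `feature_table`.
#' @param k Number of taxa to keep.
#' @param cohort,binning Optional; when both given, `$stratified` holds mean
#'   abundances per group x bin.
#' @return List: `table` (collapsed `feature_table`), `top` (kept feature
#'   ids), and optionally `stratified`.
#' @export
top_taxa_summary <- function(table, k = 15, cohort = NULL, binning = NULL) {
  stopifnot(inherits(table, "feature_table"))
  v <- table$values
  if (k > nrow(v)) stop("k exceeds the number of features")
  top <- names(sort(rowMeans(v), decreasing = TRUE))[seq_len(k)]
  rest <- setdiff(rownames(v), top)
  others <- if (length(rest)) colSums(v[rest, , drop = FALSE]) else
    stats::setNames(rep(0, ncol(v)), colnames(v))
  collapsed <- rbind(v[top, , drop = FALSE], Others = others)
  out_tab <- feature_table(collapsed, type = table$type, level = table$level)
  out <- list(table = out_tab, top = top)
  if (!is.null(cohort) && !is.null(binning)) {
    s <- cohort$samples[match(colnames(v), cohort$samples$sample_id), ]
    bin <- assign_age_bin(s$age_months, binning)
    grp <- cohort$infants$group[match(s$infant_id, cohort$infants$infant_id)]
    strata <- interaction(grp, bin, sep = "|", drop = TRUE)
    mean_by <- sapply(levels(strata), function(lv) {
      rowMeans(collapsed[, strata == lv, drop = FALSE])
    })
    out$stratified <- mean_by
  }
  out
}

#' Detection prevalence of a feature across age bins
#'
#' Fraction of samples with abundance above a detection threshold, per age
#' bin, stratified by feeding mode or case/control group. Strata with no
#' samples in a bin are reported `NA`, not zero.
#'
#' @param table A relative `feature_table`.
#' @param cohort A [cohort_table()].
#' @param feature Feature id (row name).
#' @param by `"feeding"` (infant `initial_feeding`) or `"group"`.
#' @param detection_threshold Abundance strictly above which a feature
#'   counts as detected.
#' @param binning An [age_binning()].
#' @return Data frame: stratum, bin, n, prevalence.
#' @export
prevalence_curve <- function(table, cohort, feature,
                             by = c("feeding", "group"),
                             detection_threshold = 0,
                             binning = age_binning()) {
  by <- match.arg(by)
  stopifnot(inherits(table, "feature_table"), inherits(cohort, "cohort"))
  if (!feature %in% rownames(table$values)) stop("unknown feature: ", feature)
  ids <- colnames(table$values)
  s <- cohort$samples[match(ids, cohort$samples$sample_id), ]
  bin <- assign_age_bin(s$age_months, binning)
  inf <- cohort$infants[match(s$infant_id, cohort$infants$infant_id), ]
  stratum <- if (by == "feeding") inf$initial_feeding else inf$group
  detected <- table$values[feature, ] > detection_threshold
  grid <- expand.grid(stratum = sort(unique(stratum)),
                      bin = binning$labels, stringsAsFactors = FALSE)
  grid$n <- mapply(function(st, b) sum(stratum == st & bin == b),
                   grid$stratum, grid$bin)
  grid$prevalence <- mapply(function(st, b) {
    sel <- stratum == st & bin == b
    if (!any(sel)) NA_real_ else mean(detected[sel])
  }, grid$stratum, grid$bin)
  grid
}
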