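test_that("Chao1 matches its closed form and degrades gracefully", {
  expect_equal(chao1(c(5, 1, 1, 2)), 6.0)            # 4 + 2^2/(2*1)
  expect_equal(chao1(c(5, 5, 3)), 3)                 # no f1/f2 -> S_obs
  expect_equal(chao1(c(3, 1, 1, 1)), 3 + 1 + 3 * 2 / 2)  # f2=0 corrected form
  expect_equal(chao1(numeric(4)), 0)
  expect_error(chao1(c(-1, 2)), "negative")
  expect_warning(r <- chao1(c(0.5, 0.25, 0.25)), "observed richness")
  expect_equal(r, 3)
  # Chao1 >= observed richness, always
  set.seed(1)
  for (i in 1:20) {
    x <- rpois(30, 2)
    expect_gte(chao1(x), sum(x > 0))
  }
})

test_that("Shannon matches hand values and is maximal at uniformity", {
  expect_equal(shannon(rep(1, 4)), log(4))
  expect_equal(shannon(c(7, 0, 0)), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25)), 1.0397, tolerance = 1e-4)
  expect_error(shannon(c(0, 0)), "all-zero")
  set.seed(2)
  for (i in 1:10) {
    p <- rgamma(6, 1); p <- p / sum(p)
    expect_lte(shannon(p), shannon(rep(1 / 6, 6)) + 1e-12)
  }
})

test_that("Bray-Curtis and Aitchison behave as metrics on compositions", {
  m <- cbind(s1 = c(0.5, 0.5, 0), s2 = c(0, 0.5, 0.5), s3 = c(0.5, 0.5, 0),
             s4 = c(1, 0, 0), s5 = c(0, 0, 1))
  rownames(m) <- paste0("t", 1:3)
  ft <- feature_table(m, type = "relative")
  bc <- bray_curtis(ft)$matrix
  expect_equal(bc["s1", "s2"], 0.5)
  expect_equal(bc["s1", "s3"], 0)        # identical samples
  expect_equal(bc["s4", "s5"], 1)        # disjoint supports
  expect_true(all(bc >= 0 & bc <= 1))
  expect_equal(bc, t(bc))
  ait <- aitchison(ft)$matrix
  expect_equal(ait["s1", "s3"], 0)
  expect_equal(ait, t(ait))
  expect_true(all(diag(ait) == 0))
  expect_error(aitchison(ft, pseudocount = 0), "pseudocount")
})

test_that("PCoA recovers planar geometry and flags separation", {
  # three points of a right triangle: distances reproduce exactly
  pts <- rbind(a = c(0, 0), b = c(1, 0), c = c(0, 1))
  d <- as.matrix(dist(pts))
  dm <- structure(list(matrix = d, metric = "euclidean",
                       sample_ids = rownames(d)), class = "dist_matrix")
  p <- pcoa_ordination(dm, n_axes = 2)
  expect_equal(as.matrix(dist(p$coordinates)), d, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(p$explained >= 0) && sum(p$explained) <= 1 + 1e-9)
  # collinear points: one axis carries all variance
  line <- as.matrix(dist(cbind(c(0, 1, 3))))
  dimnames(line) <- list(letters[1:3], letters[1:3])
  dml <- structure(list(matrix = line, metric = "euclidean",
                        sample_ids = letters[1:3]), class = "dist_matrix")
  pl <- pcoa_ordination(dml, n_axes = 1)
  expect_equal(pl$explained[1], 1, tolerance = 1e-9)
  expect_error(pcoa_ordination(dml, n_axes = 3), "rank")
  # agreement with the classical-scaling reference implementation
  set.seed(3)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("s", 1:10), NULL))
  dr <- as.matrix(dist(x))
  dmr <- structure(list(matrix = dr, metric = "euclidean",
                        sample_ids = rownames(dr)), class = "dist_matrix")
  ours <- pcoa_ordination(dmr, n_axes = 3)$coordinates
  ref <- cmdscale(dr, k = 3)
  for (j in 1:3) {
    expect_equal(abs(ours[, j]), abs(ref[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
  # two separated clusters: axis-1 ANOVA detects the groups
  y <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 6), 10))
  rownames(y) <- paste0("s", 1:20)
  dy <- as.matrix(dist(y))
  dmy <- structure(list(matrix = dy, metric = "euclidean",
                        sample_ids = rownames(dy)), class = "dist_matrix")
  py <- pcoa_ordination(dmy, n_axes = 2, groups = rep(c("a", "b"), each = 10))
  expect_lt(py$anova_axis1$p_value, 0.05)
})

test_that("diversity-age correlation has the right sign structure", {
  fx <- default_fixture()
  res <- age_diversity_correlation(fx$counts, fx$cohort)
  expect_true(all(res$r > 0))
  expect_true(all(res$p_value < 1e-10))
  # antisymmetry: reversing ages negates r
  co2 <- fx$cohort
  co2$samples$age_months <- max(co2$samples$age_months) -
    co2$samples$age_months
  res2 <- age_diversity_correlation(fx$counts, co2)
  expect_equal(res2$r, -res$r, tolerance = 1e-12)
})

test_that("within-infant stability exceeds between-infant similarity", {
  fx <- default_fixture()
  st <- stability_analysis(fx$relative, fx$cohort)
  expect_true(all(st$mean_within < st$mean_between))
  expect_true(all(st$p_within_vs_between < 1e-5))
})

test_that("stability uses the closest-to-target sample and zero for identical profiles", {
  co <- toy_cohort()
  m <- matrix(1 / 3, 3, 9, dimnames = list(paste0("t", 1:3),
                                           co$samples$sample_id))
  # infant A has A1 (0.5mo) and A2 (1.2mo): A1 in "0.5 months" bin, A2 in
  # "1 month" bin; identical profiles -> within-distance 0
  ft <- feature_table(m, type = "relative")
  st <- stability_analysis(ft, co)
  expect_true(all(st$mean_within == 0, na.rm = TRUE))
})

test_that("top-taxa collapse preserves column sums and ranking", {
  fx <- default_fixture()
  res <- top_taxa_summary(fx$relative, k = 15)
  expect_equal(colSums(res$table$values), colSums(fx$relative$values),
               tolerance = 1e-12)
  expect_equal(nrow(res$table$values), 16)
  # membership equals the overall-mean ranking
  expect_setequal(res$top,
                  names(sort(rowMeans(fx$relative$values),
                             decreasing = TRUE))[1:15])
  # k = n_features: Others row is all zero
  all_k <- top_taxa_summary(fx$relative, k = nrow(fx$relative$values))
  expect_true(all(all_k$table$values["Others", ] == 0))
  expect_error(top_taxa_summary(fx$relative, k = 1e5), "exceeds")
})

test_that("prevalence curves are monotone in the detection threshold", {
  fx <- default_fixture()
  p0 <- prevalence_curve(fx$relative, fx$cohort, "Escherichia_coli",
                         by = "group", detection_threshold = 0)
  p1 <- prevalence_curve(fx$relative, fx$cohort, "Escherichia_coli",
                         by = "group", detection_threshold = 0.001)
  ok <- !is.na(p0$prevalence)
  expect_true(all(p1$prevalence[ok] <= p0$prevalence[ok] + 1e-12))
  # absent feature: zero everywhere it is defined
  m <- fx$relative$values
  m["Species_001", ] <- 0
  m <- sweep(m, 2, colSums(m), "/")
  ft <- feature_table(m, type = "relative")
  pz <- prevalence_curve(ft, fx$cohort, "Species_001", by = "group")
  expect_true(all(pz$prevalence[!is.na(pz$prevalence)] == 0))
  expect_error(prevalence_curve(fx$relative, fx$cohort, "nope"), "unknown")
})
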