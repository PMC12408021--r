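test_that("age bins are half-open, lower-edge inclusive, and partition [0,14)", {
  b <- age_binning()
  expect_equal(assign_age_bin(3.9, b), "4 months")
  expect_equal(assign_age_bin(0.35, b), "0.5 months")
  expect_equal(assign_age_bin(13.9, b), "12 months")
  expect_error(assign_age_bin(14.0, b), "out of binning range")
  expect_error(assign_age_bin(-0.1, b), "out of binning range")
  # partition property: every age maps to exactly one label
  ages <- seq(0, 13.999, by = 0.05)
  labs <- assign_age_bin(ages, b)
  expect_false(any(is.na(labs)))
  expect_true(all(labs %in% b$labels))
  # each bin's two half-open ends behave consistently
  for (i in seq_along(b$labels)) {
    expect_equal(assign_age_bin(b$thresholds[i], b), b$labels[i])
  }
})

test_that("cohort validation enforces state ordering and referential integrity", {
  co <- toy_cohort()
  expect_s3_class(co, "cohort")
  bad <- toy_cohort()
  bad$samples$symptom_state[bad$samples$sample_id == "A1"] <- "resolved"
  expect_error(cohort_table(bad$infants, bad$samples), "out of order")
  orphan <- toy_cohort()$samples
  orphan$infant_id[1] <- "ZZZ"
  expect_error(cohort_table(toy_cohort()$infants, orphan), "unknown infant")
  wrong <- toy_cohort()$samples
  wrong$symptom_state[wrong$sample_id == "C1"] <- "symptomatic"
  expect_error(cohort_table(toy_cohort()$infants, wrong), "only state")
})

test_that("disease-state subsets pick last-pre/first-sym/first-res per infant", {
  subsets <- select_state_subsets(toy_cohort())
  # infant A: pre at 0.5, 1.2; sym at 2.5; res at 8.0
  expect_equal(subsets$last_pre_symptomatic$sample_id[
    subsets$last_pre_symptomatic$infant_id == "A"], "A2")
  expect_equal(subsets$first_symptomatic$sample_id[
    subsets$first_symptomatic$infant_id == "A"], "A3")
  expect_equal(subsets$first_resolved$sample_id[
    subsets$first_resolved$infant_id == "A"], "A4")
  # infant B has only symptomatic samples: first one selected, absent elsewhere
  expect_equal(subsets$first_symptomatic$sample_id[
    subsets$first_symptomatic$infant_id == "B"], "B1")
  expect_false("B" %in% subsets$last_pre_symptomatic$infant_id)
  expect_false("B" %in% subsets$first_resolved$infant_id)
  # subset sizes bounded by the number of AP infants
  expect_lte(nrow(subsets$first_symptomatic), 2)
})

test_that("age ties in subset selection break by lexicographic sample id", {
  infants <- data.frame(infant_id = "X", group = "case", sex = "female",
                        delivery_mode = "vaginal",
                        initial_feeding = "exclusive",
                        probiotic_first_year = FALSE)
  samples <- data.frame(sample_id = c("X_b", "X_a"), infant_id = "X",
                        age_months = c(2, 2),
                        symptom_state = c("symptomatic", "symptomatic"))
  co <- cohort_table(infants, samples)
  expect_equal(select_state_subsets(co)$first_symptomatic$sample_id, "X_a")
})

test_that("age matching reproduces the hand-enumerated optimum", {
  m <- match_by_age(c(0.5, 2.0), c(0.4, 1.0, 2.2))
  expect_equal(m$total_cost, 0.3, tolerance = 1e-12)
  expect_setequal(paste(m$pairs$case_age, m$pairs$control_age),
                  c("0.5 0.4", "2 2.2"))
  expect_equal(length(m$unmatched_controls), 1L)
  expect_equal(match_by_age(c(1, 5, 9), c(1, 5, 9))$total_cost, 0)
  expect_equal(match_by_age(1, 3)$total_cost, 2)
  expect_error(match_by_age(numeric(), 1), "non-empty")
})

test_that("age matching equals brute-force optimum on random instances", {
  set.seed(7)
  for (rep in 1:25) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    a <- round(runif(n1, 0, 14), 2)
    b <- round(runif(n2, 0, 14), 2)
    m <- match_by_age(a, b)
    expect_equal(m$total_cost, brute_match_cost(a, b), tolerance = 1e-9)
    # one-to-one invariant
    expect_false(anyDuplicated(m$pairs$case_id) > 0)
    expect_false(anyDuplicated(m$pairs$control_id) > 0)
  }
})

test_that("surplus cases are reported unmatched when cases outnumber controls", {
  m <- match_by_age(c(1, 2, 3, 4), c(1.1, 3.9))
  expect_equal(nrow(m$pairs), 2)
  expect_equal(length(m$unmatched_cases), 2)
})

test_that("demographic Fisher tests match exact hypergeometric values", {
  # [[10,10],[10,10]]: no association
  infants <- data.frame(
    infant_id = sprintf("I%02d", 1:40),
    group = rep(c("case", "control"), each = 20),
    sex = rep(c("female", "male"), 20),
    delivery_mode = "vaginal",
    initial_feeding = rep(c("exclusive", "partial"), 20),
    probiotic_first_year = rep(c(TRUE, FALSE), 20))
  samples <- data.frame(sample_id = sprintf("S%02d", 1:40),
                        infant_id = infants$infant_id, age_months = 1,
                        symptom_state = ifelse(infants$group == "case",
                                               "symptomatic", "control"))
  co <- cohort_table(infants, samples)
  res <- demographic_tests(co, covariates = c("sex", "probiotic_first_year"))
  expect_true(all(abs(res$p_value - 1) < 1e-12))
  # [[5,0],[0,5]]: p = 2 / choose(10, 5)
  inf2 <- infants[1:10, ]
  inf2$group <- rep(c("case", "control"), each = 5)
  inf2$probiotic_first_year <- rep(c(TRUE, FALSE), each = 5)
  smp2 <- samples[1:10, ]
  smp2$infant_id <- inf2$infant_id
  smp2$symptom_state <- ifelse(inf2$group == "case", "symptomatic", "control")
  co2 <- cohort_table(inf2, smp2)
  res2 <- demographic_tests(co2, covariates = "probiotic_first_year")
  expect_equal(res2$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_error(demographic_tests(co2, covariates = "delivery_mode"),
               "single level")
})
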