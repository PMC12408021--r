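# Shared fixtures and independent oracles for the suite.

# one default synthetic cohort, generated once per test run
.fixture <- new.env()
default_fixture <- function() {
  if (is.null(.fixture$data)) {
    cfg <- sim_config(seed = 101)
    cohort <- generate_cohort(cfg)
    ab <- generate_abundances(cohort, cfg)
    .fixture$data <- list(cfg = cfg, cohort = cohort,
                          counts = ab$counts, relative = ab$relative)
  }
  .fixture$data
}

# tiny hand-built cohort for deterministic clinical-logic tests
toy_cohort <- function() {
  infants <- data.frame(
    infant_id = c("A", "B", "C", "D"),
    group = c("case", "case", "control", "control"),
    sex = c("female", "male", "female", "male"),
    delivery_mode = c("vaginal", "cesarean", "vaginal", "vaginal"),
    initial_feeding = c("exclusive", "formula", "exclusive", "partial"),
    probiotic_first_year = c(TRUE, TRUE, FALSE, TRUE))
  samples <- data.frame(
    sample_id = c("A1", "A2", "A3", "A4", "B1", "B2", "C1", "C2", "D1"),
    infant_id = c("A", "A", "A", "A", "B", "B", "C", "C", "D"),
    age_months = c(0.5, 1.2, 2.5, 8.0, 2.0, 4.0, 0.6, 9.0, 3.0),
    symptom_state = c("pre_symptomatic", "pre_symptomatic", "symptomatic",
                      "resolved", "symptomatic", "symptomatic",
                      "control", "control", "control"))
  cohort_table(infants, samples)
}

# brute-force minimum-cost injective assignment (oracle for match_by_age)
brute_match_cost <- function(case_ages, control_ages) {
  if (length(case_ages) > length(control_ages)) {
    return(brute_match_cost(control_ages, case_ages))
  }
  n <- length(case_ages); m <- length(control_ages)
  best <- Inf
  perms <- utils::combn(m, n, simplify = FALSE)
  for (subset in perms) {
    for (p in perm_all(length(subset))) {
      cost <- sum(abs(case_ages - control_ages[subset[p]]))
      if (cost < best) best <- cost
    }
  }
  best
}

perm_all <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in perm_all(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, (seq_len(n)[-i])[rest])
    }
  }
  out
}

# step-up FDR from its definition (oracle for bh_adjust)
bh_stepup_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  running <- 1
  for (i in rev(seq_len(n))) {
    running <- min(running, p[ord[i]] * n / i)
    q[ord[i]] <- running
  }
  q
}

# random DNA string
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

reverse_complement <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}
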