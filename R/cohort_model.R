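# Clinical cohort model: age bins, symptom-state sample subsets,
# optimal age matching, demographic contingency tests.

#' Construct a cohort table
#'
#' Bundles infant-level and sample-level clinical metadata and validates the
#' invariants the downstream analyses rely on: every sample's infant exists,
#' control infants carry only the `"control"` state, and within an AP infant
#' symptom states are ordered pre_symptomatic -> symptomatic -> resolved
#' along age.
#'
#' @param infants Data frame with columns `infant_id`, `group` ("case" or
#'   "control"), `sex`, `delivery_mode`, `initial_feeding`,
#'   `probiotic_first_year` (logical).
#' @param samples Data frame with columns `sample_id`, `infant_id`,
#'   `age_months` (non-negative), `symptom_state` (one of "control",
#'   "pre_symptomatic", "symptomatic", "resolved").
#' @return An object of class `cohort` (list with `$infants`, `$samples`).
#' @export
cohort_table <- function(infants, samples) {
  req_i <- c("infant_id", "group", "sex", "delivery_mode", "initial_feeding",
             "probiotic_first_year")
  req_s <- c("sample_id", "infant_id", "age_months", "symptom_state")
  stopifnot(all(req_i %in% names(infants)), all(req_s %in% names(samples)))
  infants$infant_id <- as.character(infants$infant_id)
  samples$infant_id <- as.character(samples$infant_id)
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(infants$infant_id)) stop("duplicate infant_id")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id")
  if (!all(samples$infant_id %in% infants$infant_id)) {
    stop("sample references unknown infant_id")
  }
  if (!all(infants$group %in% c("case", "control"))) {
    stop("group must be 'case' or 'control'")
  }
  if (any(samples$age_months < 0)) stop("negative age_months")
  states <- c("control", "pre_symptomatic", "symptomatic", "resolved")
  if (!all(samples$symptom_state %in% states)) stop("unknown symptom_state")
  grp <- infants$group[match(samples$infant_id, infants$infant_id)]
  if (any(grp == "control" & samples$symptom_state != "control")) {
    stop("control infants must carry only state 'control'")
  }
  if (any(grp == "case" & samples$symptom_state == "control")) {
    stop("case samples must carry a disease-phase state")
  }
  ord <- c(pre_symptomatic = 1L, symptomatic = 2L, resolved = 3L)
  for (id in unique(samples$infant_id[grp == "case"])) {
    s <- samples[samples$infant_id == id, ]
    s <- s[order(s$age_months, s$sample_id), ]
    if (is.unsorted(ord[s$symptom_state])) {
      stop("symptom states out of order along age for infant ", id)
    }
  }
  structure(list(infants = infants, samples = samples), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n_case <- sum(x$infants$group == "case")
  cat(sprintf("<cohort> %d infants (%d case / %d control), %d samples\n",
              nrow(x$infants), n_case, nrow(x$infants) - n_case,
              nrow(x$samples)))
  invisible(x)
}

#' Age binning scheme for scheduled clinic visits
#'
#' Half-open intervals `[lo, hi)` over collection age, labelled by the
#' scheduled visit each bin surrounds. The default thresholds 0, 0.35, 0.75,
#' 1.5, 3, 5, 8, 10.5, 14 months bracket the usual pediatric visit schedule
#' (birth, 2 weeks, 1, 2, 4, 6, 9, 12 months).
#'
#' @param thresholds Strictly increasing numeric vector of bin edges (months).
#' @param labels Character vector of visit names, one fewer than thresholds.
#' @return An object of class `age_binning`.
#' @export
age_binning <- function(thresholds = c(0, 0.35, 0.75, 1.5, 3, 5, 8, 10.5, 14),
                        labels = c("birth", "0.5 months", "1 month",
                                   "2 months", "4 months", "6 months",
                                   "9 months", "12 months")) {
  stopifnot(is.numeric(thresholds), length(thresholds) >= 2,
            all(diff(thresholds) > 0),
            length(labels) == length(thresholds) - 1L)
  structure(list(thresholds = thresholds, labels = as.character(labels)),
            class = "age_binning")
}

#' Assign ages to visit bins
#'
#' Maps each age to the label of the half-open interval `[lo, hi)` that
#' contains it (lower edge inclusive). Ages below the first threshold or at
#' or above the last are an error.
#'
#' @param age_months Numeric vector of ages.
#' @param binning An [age_binning()] scheme.
#' @return Character vector of bin labels (a factor-ordering-safe character;
#'   use `factor(x, levels = binning$labels)` for plotting order).
#' @examples
#' b <- age_binning()
#' assign_age_bin(3.9, b)   # "4 months"
#' assign_age_bin(0.35, b)  # "0.5 months" (lower edge inclusive)
#' @export
assign_age_bin <- function(age_months, binning = age_binning()) {
  stopifnot(inherits(binning, "age_binning"), is.numeric(age_months))
  th <- binning$thresholds
  if (any(is.na(age_months))) stop("NA age")
  if (any(age_months < th[1] | age_months >= th[length(th)])) {
    stop(sprintf("age out of binning range [%g, %g)", th[1], th[length(th)]))
  }
  idx <- findInterval(age_months, th, rightmost.closed = FALSE)
  binning$labels[idx]
}

#' Select one sample per disease phase per AP infant
#'
#' For each case infant picks at most one sample per phase: the *last*
#' pre-symptomatic sample (maximum age before onset), the *first*
#' symptomatic sample, and the *first* resolved sample. Infants lacking a
#' phase are simply absent from that subset. Age ties are broken by
#' lexicographic `sample_id`.
#'
#' @param cohort A [cohort_table()].
#' @return Named list with data frames `last_pre_symptomatic`,
#'   `first_symptomatic`, `first_resolved` (columns `infant_id`, `sample_id`,
#'   `age_months`).
#' @export
select_state_subsets <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  s <- cohort$samples
  grp <- cohort$infants$group[match(s$infant_id, cohort$infants$infant_id)]
  s <- s[grp == "case", , drop = FALSE]
  pick <- function(state, which_end) {
    sub <- s[s$symptom_state == state, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(data.frame(infant_id = character(), sample_id = character(),
                        age_months = numeric()))
    }
    # deterministic: sort by age then sample_id, take first/last per infant
    sub <- sub[order(sub$infant_id, sub$age_months, sub$sample_id), ]
    idx <- if (which_end == "first") {
      !duplicated(sub$infant_id)
    } else {
      !duplicated(sub$infant_id, fromLast = TRUE)
    }
    out <- sub[idx, c("infant_id", "sample_id", "age_months")]
    rownames(out) <- NULL
    out
  }
  list(last_pre_symptomatic = pick("pre_symptomatic", "last"),
       first_symptomatic = pick("symptomatic", "first"),
       first_resolved = pick("resolved", "first"))
}

#' Optimal one-to-one age matching of case and control samples
#'
#' Solves the linear sum assignment problem on the cost matrix of absolute
#' age differences (Hungarian method, via [clue::solve_LSAP()]), pairing
#' each sample on the smaller side with a distinct sample on the larger
#' side so that the total absolute age difference is minimal. Surplus
#' samples on the larger side are reported unmatched.
#'
#' @param case_ages Numeric vector of case sample ages (months). Names, if
#'   present, are carried through as identifiers; otherwise indices are used.
#' @param control_ages Numeric vector of control sample ages.
#' @return List of class `match_result`: `pairs` (data frame `case_id`,
#'   `control_id`, `case_age`, `control_age`, `cost`), `total_cost`,
#'   `unmatched_cases`, `unmatched_controls`.
#' @export
match_by_age <- function(case_ages, control_ages) {
  if (length(case_ages) == 0 || length(control_ages) == 0) {
    stop("both age lists must be non-empty")
  }
  case_ids <- names(case_ages) %||% as.character(seq_along(case_ages))
  ctrl_ids <- names(control_ages) %||% as.character(seq_along(control_ages))
  cost <- abs(outer(unname(case_ages), unname(control_ages), "-"))
  # solve_LSAP needs nrow <= ncol; transpose when cases outnumber controls
  flipped <- nrow(cost) > ncol(cost)
  m <- if (flipped) t(cost) else cost
  sol <- as.integer(clue::solve_LSAP(m))
  if (flipped) {
    ctrl_idx <- seq_along(ctrl_ids)
    case_idx <- sol
  } else {
    case_idx <- seq_along(case_ids)
    ctrl_idx <- sol
  }
  pairs <- data.frame(case_id = case_ids[case_idx],
                      control_id = ctrl_ids[ctrl_idx],
                      case_age = unname(case_ages)[case_idx],
                      control_age = unname(control_ages)[ctrl_idx])
  pairs$cost <- abs(pairs$case_age - pairs$control_age)
  structure(list(pairs = pairs,
                 total_cost = sum(pairs$cost),
                 unmatched_cases = setdiff(case_ids, pairs$case_id),
                 unmatched_controls = setdiff(ctrl_ids, pairs$control_id)),
            class = "match_result")
}

#' Demographic 2x2 contingency tests
#'
#' For each binary infant-level covariate, tabulates case/control counts and
#' runs a two-sided Fisher's exact test. The odds ratio reported is the
#' sample odds ratio with the Haldane-Anscombe 0.5 correction applied when
#' any cell is zero (the test itself is exact and uncorrected).
#'
#' @param cohort A [cohort_table()].
#' @param covariates Character vector of infant columns to test; each must
#'   have exactly two levels after coercion. `initial_feeding` (three
#'   levels) is expanded into one-vs-rest binary indicators.
#' @return Data frame: covariate, level tested, the 2x2 counts
#'   (`case_yes`, `case_no`, `control_yes`, `control_no`), `odds_ratio`,
#'   `p_value`.
#' @export
demographic_tests <- function(cohort,
                              covariates = c("sex", "delivery_mode",
                                             "initial_feeding",
                                             "probiotic_first_year")) {
  stopifnot(inherits(cohort, "cohort"))
  inf <- cohort$infants
  rows <- list()
  for (cv in covariates) {
    if (!cv %in% names(inf)) stop("unknown covariate: ", cv)
    v <- inf[[cv]]
    levs <- sort(unique(as.character(v)))
    if (length(levs) < 2) stop("covariate with a single level: ", cv)
    # binary: test the first level; multi-level: one-vs-rest per level
    test_levels <- if (length(levs) == 2) levs[1] else levs
    for (lv in test_levels) {
      yes <- as.character(v) == lv
      tab <- matrix(c(sum(yes & inf$group == "case"),
                      sum(!yes & inf$group == "case"),
                      sum(yes & inf$group == "control"),
                      sum(!yes & inf$group == "control")),
                    nrow = 2, byrow = TRUE)
      ft <- stats::fisher.test(tab, alternative = "two.sided")
      or <- if (any(tab == 0)) {
        ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) /
          ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
      } else {
        (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = cv, level = lv,
        case_yes = tab[1, 1], case_no = tab[1, 2],
        control_yes = tab[2, 1], control_no = tab[2, 2],
        odds_ratio = or, p_value = ft$p.value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
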