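# MAG (metagenome-assembled genome) quality tiering.

#' Assign a quality tier to a MAG
#'
#' Tiers a genome bin by its completeness and contamination estimates:
#' `"high"` if completeness >= 85 and contamination < 5, `"medium"` if
#' 50 <= completeness < 85 and contamination < 5, otherwise `"low"`.
#' Boundary semantics are literal: completeness 85 is high-eligible,
#' contamination 5 is not.
#'
#' @param completeness Numeric vector of completeness percentages in `[0, 100]`.
#' @param contamination Numeric vector of contamination percentages (>= 0).
#' @return Character vector of tiers (`"high"`, `"medium"`, `"low"`).
#' @examples
#' assign_tier(90, 3)   # "high"
#' assign_tier(85, 5)   # "low": contamination boundary fails
#' assign_tier(60, 2)   # "medium"
#' @export
assign_tier <- function(completeness, contamination) {
  stopifnot(length(completeness) == length(contamination))
  if (any(is.na(completeness)) || any(is.na(contamination))) {
    stop("completeness/contamination must not contain NA")
  }
  if (any(completeness < 0 | completeness > 100)) {
    stop("completeness must be within [0, 100]")
  }
  if (any(contamination < 0)) stop("contamination must be >= 0")
  tier <- rep("low", length(completeness))
  clean <- contamination < 5
  tier[clean & completeness >= 85] <- "high"
  tier[clean & completeness >= 50 & completeness < 85] <- "medium"
  tier
}

#' Summarise MAG quality tiers
#'
#' Counts and percentages per tier (one-decimal rounding), plus the fraction
#' of samples that yielded at least one MAG when the total sample count is
#' supplied.
#'
#' @param records Data frame with at least a `tier` column; a `sample_id`
#'   column is used for the per-sample yield statistic.
#' @param n_samples_total Optional total number of samples processed (the
#'   denominator for the yield percentage). Defaults to the number of
#'   distinct `sample_id`s in `records`.
#' @return List with `counts`, `percent` (named by tier, high/medium/low
#'   order), `n_total`, and, when computable, `samples_with_mag` and
#'   `percent_samples_with_mag`.
#' @export
tier_summary <- function(records, n_samples_total = NULL) {
  stopifnot(is.data.frame(records), nrow(records) > 0, "tier" %in% names(records))
  lev <- c("high", "medium", "low")
  counts <- table(factor(records$tier, levels = lev))
  counts <- stats::setNames(as.integer(counts), lev)
  total <- sum(counts)
  pct <- round(100 * counts / total, 1)
  out <- list(counts = counts, percent = pct, n_total = total)
  if ("sample_id" %in% names(records)) {
    n_with <- length(unique(records$sample_id))
    if (is.null(n_samples_total)) n_samples_total <- n_with
    out$samples_with_mag <- n_with
    out$percent_samples_with_mag <- round(100 * n_with / n_samples_total, 1)
  }
  out
}
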