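#' Relative risk from a 2x2 contingency table
#'
#' Computes the risk ratio of an outcome between exposed and unexposed
#' groups, with the Katz log-scale normal 95\% confidence interval and a
#' two-sided Wald p-value on the log scale:
#' `rr = (a/(a+b)) / (c/(c+d))`,
#' `CI = exp(log(rr) +/- z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`.
#'
#' When any cell is zero, 0.5 is added to all four cells
#' (Haldane-Anscombe) and the estimate is flagged as corrected. A zero
#' margin (no exposed or no unexposed subjects, or no outcome variation
#' interpretable) makes the estimate undefined; it is reported with
#' `defined = FALSE` rather than an error so covariate screens can
#' proceed.
#'
#' @param a Exposed with outcome.
#' @param b Exposed without outcome.
#' @param c_ Unexposed with outcome.
#' @param d Unexposed without outcome.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row data frame: `a`, `b`, `c`, `d`, `rr`, `ci_lo`,
#'   `ci_hi`, `p_value`, `corrected`, `defined`.
#' @examples
#' relative_risk(10, 90, 20, 80)   # rr = 0.5
#' @export
relative_risk <- function(a, b, c_, d, conf_level = 0.95) {
  stopifnot(a >= 0, b >= 0, c_ >= 0, d >= 0)
  out <- data.frame(a = a, b = b, c = c_, d = d,
                    rr = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                    p_value = NA_real_, corrected = FALSE, defined = FALSE)
  if ((a + b) == 0 || (c_ + d) == 0) {
    return(out)
  }
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  rr <- (a / (a + b)) / (c_ / (c_ + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c_ - 1 / (c_ + d))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out$rr <- rr
  out$ci_lo <- exp(log(rr) - z * se)
  out$ci_hi <- exp(log(rr) + z * se)
  out$p_value <- 2 * stats::pnorm(-abs(log(rr) / se))
  out$corrected <- corrected
  out$defined <- TRUE
  out
}

#' End-of-study outcome indicators for every attending infant
#'
#' @param classification An `adherence_classification`.
#' @return Data frame with `infant_id` and logical columns
#'   `unvaccinated` (zero doses), `at_least_one_dose`, `full_series`
#'   (all scheduled doses).
#' @export
outcome_indicators <- function(classification) {
  k <- n_doses(classification$schedule)
  inf <- classification$infants
  data.frame(
    infant_id = inf$infant_id,
    unvaccinated = inf$total_doses == 0,
    at_least_one_dose = inf$total_doses >= 1,
    full_series = inf$total_doses >= k
  )
}

#' Screen binary covariates against end-of-study vaccination outcomes
#'
#' Builds the full covariate-by-outcome grid of unadjusted relative
#' risks among attending infants. Logical covariates are used as-is;
#' numeric covariates are dichotomised at (strictly above) their median
#' across attending infants, with the split recorded in the output. No
#' multiplicity correction is applied: the grid is a screen, and
#' apparent associations must be judged against the number of
#' comparisons made.
#'
#' @param cohort A `cohort_tables`.
#' @param classification An `adherence_classification` for that cohort.
#' @param covariates Character vector of roster column names; defaults
#'   to every non-identifier, non-date roster column.
#' @param outcomes Character subset of
#'   `c("unvaccinated", "at_least_one_dose", "full_series")`.
#' @return Data frame: one row per covariate-outcome pair with the
#'   columns of [relative_risk()] plus `covariate`, `outcome`, `coding`.
#' @export
covariate_screen <- function(cohort, classification,
                             covariates = NULL,
                             outcomes = c("unvaccinated",
                                          "at_least_one_dose",
                                          "full_series")) {
  stopifnot(inherits(cohort, "cohort_tables"))
  roster <- cohort$roster
  if (is.null(covariates)) {
    covariates <- setdiff(names(roster),
                          c("infant_id", "birth_date", "enrolment_date"))
  }
  oi <- outcome_indicators(classification)
  roster <- roster[match(oi$infant_id, roster$infant_id), , drop = FALSE]
  rows <- list()
  for (cv in covariates) {
    x <- roster[[cv]]
    if (is.null(x)) stop("covariate not in roster: ", cv, call. = FALSE)
    if (is.logical(x)) {
      exposed <- x
      coding <- "TRUE vs FALSE"
    } else if (is.numeric(x)) {
      med <- stats::median(x, na.rm = TRUE)
      exposed <- x > med
      coding <- sprintf("> median (%g)", med)
    } else {
      stop("covariate ", cv, " is neither logical nor numeric; ",
           "recode it before screening", call. = FALSE)
    }
    for (oc in outcomes) {
      y <- oi[[oc]]
      ok <- !is.na(exposed) & !is.na(y)
      est <- relative_risk(
        a = sum(exposed & y & ok), b = sum(exposed & !y & ok),
        c_ = sum(!exposed & y & ok), d = sum(!exposed & !y & ok)
      )
      rows[[length(rows) + 1L]] <-
        cbind(covariate = cv, outcome = oc, coding = coding, est)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Demographics summary stratified by study attendance
#'
#' Summarises roster covariates in three nested strata: all enrolled
#' infants, attending infants (at least one scheduled visit), and
#' infants who completed the study (attended all scheduled visits).
#' Logical covariates are reported as percentages, numeric covariates as
#' median with interquartile range.
#'
#' @param cohort A `cohort_tables`.
#' @param covariates Roster columns to summarise; default as in
#'   [covariate_screen()].
#' @param n_scheduled_total Number of protocol visits that defines
#'   completion (default 6).
#' @return A list with `n` (named stratum sizes) and `table` (one row
#'   per covariate: `covariate`, `type`, and formatted `enrolled`,
#'   `attending`, `completed` columns).
#' @export
demographics_table <- function(cohort, covariates = NULL,
                               n_scheduled_total = 6L) {
  stopifnot(inherits(cohort, "cohort_tables"))
  roster <- cohort$roster
  if (is.null(covariates)) {
    covariates <- setdiff(names(roster),
                          c("infant_id", "birth_date", "enrolment_date"))
  }
  att <- attending_set(cohort)
  strata <- list(
    enrolled = rep(TRUE, nrow(roster)),
    attending = att$attending[match(roster$infant_id, att$infant_id)],
    completed = att$n_scheduled[match(roster$infant_id, att$infant_id)] >=
      n_scheduled_total
  )
  summarise_one <- function(x, keep) {
    x <- x[keep]
    if (length(x) == 0 || all(is.na(x))) return("-")
    if (is.logical(x)) {
      sprintf("%.1f%%", 100 * mean(x, na.rm = TRUE))
    } else {
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
      sprintf("%g (%g-%g)", q[2], q[1], q[3])
    }
  }
  tab <- do.call(rbind, lapply(covariates, function(cv) {
    x <- roster[[cv]]
    data.frame(
      covariate = cv,
      type = if (is.logical(x)) "percent" else "median_iqr",
      enrolled = summarise_one(x, strata$enrolled),
      attending = summarise_one(x, strata$attending),
      completed = summarise_one(x, strata$completed)
    )
  }))
  list(
    n = vapply(strata, sum, integer(1)),
    table = tab
  )
}
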