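#' Cumulative dose-administration probability curve
#'
#' Estimates the probability that an attending infant has received a
#' given dose by each age, under one of two censoring assumptions:
#'
#' \describe{
#'   \item{`"standard"`}{The product-limit (Kaplan-Meier) estimator.
#'     Infants without the dose are right-censored at their last
#'     scheduled visit age, and are assumed to go on receiving doses at
#'     the same rate as infants still under observation. Computed with
#'     [survival::survfit()]; the cumulative administration probability
#'     is `1 - S(age)`.}
#'   \item{`"worst_case"`}{Infants lost to follow-up are assumed to
#'     receive no further doses: the curve is simply the number of
#'     infants with the dose by each age divided by the full attending
#'     count, so censored infants stay in the denominator forever. This
#'     curve can never exceed the standard one and may plateau below any
#'     quantile of interest.}
#' }
#'
#' Ties between an administration and a censoring at the same age are
#' resolved with events first, the usual product-limit convention.
#'
#' @param cohort A `cohort_tables` object.
#' @param dose_number Which dose of the schedule to analyse.
#' @param assumption `"standard"` or `"worst_case"`.
#' @param schedule A `schedule_spec` (default [zambia_epi_schedule()]);
#'   used to validate `dose_number` and to anchor delay quantiles.
#' @return An object of class `delay_curve`: a list with `steps` (data
#'   frame `age`, `cum_prob`, `n_risk`, `n_event`), `assumption`,
#'   `dose_number`, `target_age`, `n_attending`, `n_events`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_infants = 200, seed = 7))
#' curve <- km_curve(cohort, 1, "worst_case")
#' delay_quantiles(curve)
#' @export
km_curve <- function(cohort, dose_number,
                     assumption = c("standard", "worst_case"),
                     schedule = zambia_epi_schedule()) {
  stopifnot(inherits(cohort, "cohort_tables"))
  assumption <- match.arg(assumption)
  dose_number <- as.integer(dose_number)
  if (!dose_number %in% schedule$doses$dose_number) {
    stop("dose_number ", dose_number, " is not in the schedule",
         call. = FALSE)
  }
  att <- attending_set(cohort)
  att <- att[att$attending, , drop = FALSE]
  dd <- cohort$doses[cohort$doses$dose_number == dose_number, , drop = FALSE]
  birth <- cohort$roster$birth_date[match(dd$infant_id,
                                          cohort$roster$infant_id)]
  dose_age <- stats::setNames(as.integer(dd$admin_date - birth),
                              dd$infant_id)
  has_dose <- att$infant_id %in% names(dose_age)
  time <- ifelse(has_dose,
                 dose_age[att$infant_id],
                 att$last_visit_age)
  status <- as.integer(has_dose)
  n <- nrow(att)

  if (assumption == "standard") {
    fit <- survival::survfit(survival::Surv(time, status) ~ 1)
    steps <- data.frame(
      age = fit$time,
      cum_prob = 1 - fit$surv,
      n_risk = fit$n.risk,
      n_event = fit$n.event
    )
  } else {
    ev <- sort(unique(time[status == 1L]))
    cum <- vapply(ev, function(a) sum(time <= a & status == 1L),
                  integer(1))
    steps <- data.frame(
      age = ev,
      cum_prob = cum / n,
      n_risk = rep.int(n, length(ev)),
      n_event = vapply(ev, function(a) sum(time == a & status == 1L),
                       integer(1))
    )
  }
  structure(
    list(
      steps = steps,
      assumption = assumption,
      dose_number = dose_number,
      target_age =
        schedule$doses$target_age[schedule$doses$dose_number == dose_number],
      n_attending = n,
      n_events = sum(status)
    ),
    class = "delay_curve"
  )
}

#' @export
print.delay_curve <- function(x, ...) {
  cat(sprintf("<delay_curve> dose %d, %s censoring\n", x$dose_number,
              x$assumption))
  cat(sprintf("  %d/%d infants with dose; final cumulative probability %.3f\n",
              x$n_events, x$n_attending,
              if (nrow(x$steps)) max(x$steps$cum_prob) else 0))
  invisible(x)
}

#' Evaluate a delay curve at given ages
#'
#' @param curve A `delay_curve`.
#' @param age Integer vector of ages (days).
#' @return Cumulative administration probability at each age (0 before
#'   the first step).
#' @export
curve_at <- function(curve, age) {
  stopifnot(inherits(curve, "delay_curve"))
  s <- curve$steps
  vapply(as.numeric(age), function(a) {
    i <- which(s$age <= a)
    if (length(i) == 0) 0 else s$cum_prob[max(i)]
  }, numeric(1))
}

#' Delay quantiles of a dose-administration curve
#'
#' The delay at quantile `q` is the smallest age at which the cumulative
#' administration probability reaches `q` (left-continuous generalised
#' inverse), minus the dose's target age. Infants vaccinated before the
#' target age pull quantiles negative; raw values are preserved. Under
#' worst-case censoring a curve may plateau below a requested quantile,
#' in which case that quantile is reported as not attained.
#'
#' @param curve A `delay_curve`.
#' @param probs Quantiles to extract; defaults to the median, upper
#'   quartile (slowest 25\%) and upper decile (slowest 10\%).
#' @return Data frame with `prob`, `attained`, `age_at_quantile`,
#'   `delay` (days; `NA` when not attained).
#' @export
delay_quantiles <- function(curve, probs = c(0.5, 0.75, 0.9)) {
  stopifnot(inherits(curve, "delay_curve"))
  s <- curve$steps
  do.call(rbind, lapply(probs, function(q) {
    hit <- which(s$cum_prob >= q - 1e-12)
    if (length(hit) == 0) {
      data.frame(prob = q, attained = FALSE,
                 age_at_quantile = NA_integer_, delay = NA_integer_)
    } else {
      a <- s$age[min(hit)]
      data.frame(prob = q, attained = TRUE,
                 age_at_quantile = as.integer(a),
                 delay = as.integer(a - curve$target_age))
    }
  }))
}

#' Delay-quantile summary for every dose under one assumption
#'
#' @param cohort A `cohort_tables`.
#' @param schedule A `schedule_spec`.
#' @param assumption Censoring assumption, see [km_curve()].
#' @param probs Quantiles, see [delay_quantiles()].
#' @return Data frame of per-dose quantile rows with a `dose_number`
#'   column prepended.
#' @export
delay_summary <- function(cohort, schedule = zambia_epi_schedule(),
                          assumption = "worst_case",
                          probs = c(0.5, 0.75, 0.9)) {
  do.call(rbind, lapply(schedule$doses$dose_number, function(k) {
    q <- delay_quantiles(
      km_curve(cohort, k, assumption, schedule = schedule),
      probs = probs
    )
    cbind(dose_number = k, q)
  }))
}
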