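#' Classify one infant's dose trajectory against a schedule
#'
#' The per-infant state machine at the heart of the pipeline. Each dose
#' event is assessed for window membership, earliness and compression;
#' each schedule window receives a status block (visited, received,
#' up-to-date, unvaccinated).
#'
#' Status definitions, for window `k` with targeted dose `k`:
#' \itemize{
#'   \item \emph{visited}: at least one scheduled visit at an age inside
#'     the window (boundaries inclusive).
#'   \item \emph{received}: at least one dose event (any dose number) at
#'     an age inside the window.
#'   \item \emph{up-to-date}: the infant possesses at least `k` doses by
#'     the window's last day \emph{and} was up-to-date at window `k - 1`.
#'     Possession-based: an early dose counts towards being up-to-date.
#'     Once a window is missed, up-to-date status is never regained.
#'   \item \emph{unvaccinated}: zero cumulative doses by the window's
#'     last day.
#' }
#'
#' A dose is \emph{early} when its administration age is at or below the
#' schedule's early cutoff, and \emph{compressed} when it falls less than
#' `min_interval` days after the preceding dose (never applicable to
#' dose 1). Ages are whole-day differences from the birth date, with the
#' day of birth as age 0.
#'
#' @param schedule A `schedule_spec`.
#' @param birth_date Infant's birth `Date`.
#' @param visit_dates `Date` vector of scheduled visit dates (unscheduled
#'   visits must be excluded by the caller; [classify_cohort()] does so).
#' @param dose_events Data frame with `dose_number` and `admin_date` for
#'   this infant.
#' @param compression_threshold Spacing in days below which a dose is
#'   compressed; defaults to the schedule's `min_interval`.
#' @return A list with elements `doses` (one row per dose event:
#'   `dose_number`, `admin_age`, `window`, `early`, `spacing`,
#'   `compressed`), `windows` (one row per schedule window: `window`,
#'   `visited`, `received`, `up_to_date`, `unvaccinated`,
#'   `cum_doses_by_end`) and `total_doses`.
#' @export
classify_infant <- function(schedule, birth_date, visit_dates, dose_events,
                            compression_threshold = NULL) {
  stopifnot(inherits(schedule, "schedule_spec"))
  if (is.null(compression_threshold)) {
    compression_threshold <- schedule$min_interval
  }
  birth_date <- as.Date(birth_date)
  visit_ages <- as.integer(as.Date(visit_dates) - birth_date)
  if (nrow(dose_events) > 0) {
    dose_events <- dose_events[order(dose_events$dose_number), , drop = FALSE]
    dose_ages <- as.integer(as.Date(dose_events$admin_date) - birth_date)
  } else {
    dose_ages <- integer(0)
  }
  spacing <- c(NA_integer_, diff(dose_ages))
  doses <- data.frame(
    dose_number = if (nrow(dose_events) > 0) {
      as.integer(dose_events$dose_number)
    } else integer(0),
    admin_age = dose_ages,
    window = assign_window(schedule, dose_ages),
    early = dose_ages <= schedule$early_cutoff,
    spacing = spacing[seq_along(dose_ages)],
    compressed = !is.na(spacing[seq_along(dose_ages)]) &
      spacing[seq_along(dose_ages)] < compression_threshold
  )
  d <- schedule$doses
  k <- nrow(d)
  cum <- vapply(d$window_end, function(e) sum(dose_ages <= e), integer(1))
  utd <- cum >= seq_len(k)
  utd <- cumprod(utd) > 0  # monotone decay: lost once, lost forever
  windows <- data.frame(
    window = seq_len(k),
    visited = vapply(seq_len(k), function(i) {
      any(visit_ages >= d$window_start[i] & visit_ages <= d$window_end[i])
    }, logical(1)),
    received = vapply(seq_len(k), function(i) {
      any(dose_ages >= d$window_start[i] & dose_ages <= d$window_end[i])
    }, logical(1)),
    up_to_date = utd,
    unvaccinated = cum == 0L,
    cum_doses_by_end = cum
  )
  list(doses = doses, windows = windows, total_doses = length(dose_ages))
}

#' Classify every attending infant in a cohort
#'
#' Applies [classify_infant()] across the attending roster (infants with
#' at least one scheduled visit; never-attenders are excluded). Only
#' scheduled visits enter the window `visited` flags.
#'
#' @param cohort A `cohort_tables` object.
#' @param schedule A `schedule_spec` (default [zambia_epi_schedule()]).
#' @param compression_threshold See [classify_infant()].
#' @return An object of class `adherence_classification`: a list with
#'   \describe{
#'     \item{doses}{data frame of per-dose assessments (with `infant_id`)}
#'     \item{windows}{data frame of per-infant-per-window statuses}
#'     \item{infants}{data frame with `infant_id`, `total_doses`,
#'       `last_visit_age`, `n_scheduled`}
#'     \item{schedule}{the schedule used}
#'     \item{n_attending}{number of attending infants}
#'   }
#' @export
classify_cohort <- function(cohort, schedule = zambia_epi_schedule(),
                            compression_threshold = NULL) {
  stopifnot(inherits(cohort, "cohort_tables"))
  att <- attending_set(cohort)
  keep <- att$infant_id[att$attending]
  roster <- cohort$roster[match(keep, cohort$roster$infant_id), ,
                          drop = FALSE]
  sv <- cohort$visits[cohort$visits$scheduled &
                        cohort$visits$infant_id %in% keep, , drop = FALSE]
  dv <- cohort$doses[cohort$doses$infant_id %in% keep, , drop = FALSE]
  visits_by <- split(sv$visit_date, factor(sv$infant_id, levels = keep))
  doses_by <- split(seq_len(nrow(dv)), factor(dv$infant_id, levels = keep))

  dose_rows <- vector("list", length(keep))
  win_rows <- vector("list", length(keep))
  totals <- integer(length(keep))
  for (i in seq_along(keep)) {
    id <- keep[i]
    cl <- classify_infant(
      schedule,
      birth_date = roster$birth_date[i],
      visit_dates = visits_by[[i]],
      dose_events = dv[doses_by[[i]], , drop = FALSE],
      compression_threshold = compression_threshold
    )
    if (nrow(cl$doses) > 0) {
      cl$doses <- cbind(infant_id = id, cl$doses)
      dose_rows[[i]] <- cl$doses
    }
    win_rows[[i]] <- cbind(infant_id = id, cl$windows)
    totals[i] <- cl$total_doses
  }
  doses_df <- do.call(rbind, dose_rows)
  if (is.null(doses_df)) {
    doses_df <- data.frame(
      infant_id = character(), dose_number = integer(),
      admin_age = integer(), window = character(), early = logical(),
      spacing = integer(), compressed = logical()
    )
  }
  structure(
    list(
      doses = doses_df,
      windows = do.call(rbind, win_rows),
      infants = data.frame(
        infant_id = keep,
        total_doses = totals,
        last_visit_age = att$last_visit_age[att$attending],
        n_scheduled = att$n_scheduled[att$attending],
        row.names = NULL
      ),
      schedule = schedule,
      n_attending = length(keep)
    ),
    class = "adherence_classification"
  )
}

#' @export
print.adherence_classification <- function(x, ...) {
  cat("<adherence_classification>\n")
  cat(sprintf("  %d attending infants, %d dose events, schedule: %s\n",
              x$n_attending, nrow(x$doses), x$schedule$name))
  invisible(x)
}

#' Estimate the hesitant fraction of a cohort
#'
#' Operationalises vaccine hesitancy as attending care while declining
#' vaccination: the estimator is the fraction of infants still attending
#' when the last dose window opens (and who therefore had the
#' opportunity to receive every scheduled dose) that nonetheless have
#' zero dose events.
#'
#' @param classification An `adherence_classification`.
#' @return A list with `estimate`, `n_zero_dose`, `n_at_risk`.
#' @export
hesitancy_estimate <- function(classification) {
  stopifnot(inherits(classification, "adherence_classification"))
  d <- classification$schedule$doses
  last_start <- d$window_start[nrow(d)]
  inf <- classification$infants
  at_risk <- inf$last_visit_age >= last_start
  n_zero <- sum(at_risk & inf$total_doses == 0)
  list(
    estimate = n_zero / sum(at_risk),
    n_zero_dose = n_zero,
    n_at_risk = sum(at_risk)
  )
}

#' Distribution of total doses received by study completion
#'
#' Counts infants by exact number of doses received (0 up to the number
#' of scheduled doses) together with the complementary at-least counts
#' (suffix sums), and percentages of the attending cohort rounded to one
#' decimal, half away from zero.
#'
#' @param classification An `adherence_classification`.
#' @return Data frame with columns `n_doses`, `exact`, `exact_pct`,
#'   `at_least`, `at_least_pct`.
#' @export
end_of_study_doses <- function(classification) {
  stopifnot(inherits(classification, "adherence_classification"))
  k <- n_doses(classification$schedule)
  n <- classification$n_attending
  exact <- vapply(0:k, function(j) {
    sum(classification$infants$total_doses == j)
  }, integer(1))
  at_least <- rev(cumsum(rev(exact)))
  data.frame(
    n_doses = 0:k,
    exact = exact,
    exact_pct = round_half_away(100 * exact / n, 1),
    at_least = at_least,
    at_least_pct = round_half_away(100 * at_least / n, 1)
  )
}
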