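#' Build a vaccination schedule specification
#'
#' A schedule specification is the declarative object every downstream stage
#' of the pipeline consults: per-dose target ages, admissible age windows,
#' the minimum age for the first dose, and the minimum interval between
#' consecutive doses.
#'
#' @param doses A data frame with one row per dose and columns
#'   `dose_number` (integer, 1-based, consecutive), `target_age` (days),
#'   `window_start` (days, inclusive), `window_end` (days, inclusive) and
#'   optionally `label`.
#' @param min_first_age Minimum administration age in days for dose 1.
#' @param min_interval Minimum admissible interval in days between
#'   consecutive doses; doses spaced closer are flagged as compressed.
#' @param early_cutoff Ages less than or equal to this value (days) are
#'   classified as early, i.e. before the first admissible window.
#' @param name Optional schedule name carried through to printed output.
#'
#' @return An object of class `schedule_spec`: a list with elements
#'   `doses`, `min_first_age`, `min_interval`, `early_cutoff`, `name`.
#'
#' @details Windows of consecutive doses must be ordered and non-overlapping,
#'   and each window must contain its dose's target age. `early_cutoff`
#'   defaults to one day before the first window opens.
#'
#' @examples
#' sched <- schedule_spec(
#'   doses = data.frame(
#'     dose_number = 1:2, target_age = c(60, 120),
#'     window_start = c(55, 110), window_end = c(90, 150)
#'   ),
#'   min_first_age = 60, min_interval = 28
#' )
#' sched
#' @seealso [zambia_epi_schedule()] for the built-in 6-10-14 week schedule.
#' @export
schedule_spec <- function(doses, min_first_age, min_interval,
                          early_cutoff = NULL, name = "custom") {
  stopifnot(is.data.frame(doses), nrow(doses) >= 1)
  required <- c("dose_number", "target_age", "window_start", "window_end")
  missing_cols <- setdiff(required, names(doses))
  if (length(missing_cols) > 0) {
    stop("schedule doses table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  doses <- doses[order(doses$dose_number), , drop = FALSE]
  if (!identical(as.integer(doses$dose_number), seq_len(nrow(doses)))) {
    stop("dose_number must be consecutive integers starting at 1",
         call. = FALSE)
  }
  if (is.null(doses$label)) {
    doses$label <- paste0("dose ", doses$dose_number)
  }
  with(doses, {
    if (any(window_start > target_age | target_age > window_end)) {
      stop("each target_age must lie inside its window", call. = FALSE)
    }
    if (nrow(doses) > 1 &&
        any(window_start[-1] <= window_end[-nrow(doses)])) {
      stop("dose windows must be ordered and non-overlapping", call. = FALSE)
    }
  })
  if (is.null(early_cutoff)) early_cutoff <- doses$window_start[1] - 1L
  if (min_interval <= 0) stop("min_interval must be positive", call. = FALSE)
  structure(
    list(
      doses = doses,
      min_first_age = as.integer(min_first_age),
      min_interval = as.integer(min_interval),
      early_cutoff = as.integer(early_cutoff),
      name = name
    ),
    class = "schedule_spec"
  )
}

#' @export
print.schedule_spec <- function(x, ...) {
  cat("<schedule_spec> ", x$name, "\n", sep = "")
  cat(sprintf("  %d dose(s); min first age %d d; min interval %d d; early cutoff %d d\n",
              nrow(x$doses), x$min_first_age, x$min_interval, x$early_cutoff))
  for (i in seq_len(nrow(x$doses))) {
    d <- x$doses[i, ]
    cat(sprintf("  dose %d: target %d d, window [%d, %d]\n",
                d$dose_number, d$target_age, d$window_start, d$window_end))
  }
  invisible(x)
}

#' Number of doses in a schedule
#' @param schedule A `schedule_spec`.
#' @return Integer count of scheduled doses.
#' @export
n_doses <- function(schedule) {
  stopifnot(inherits(schedule, "schedule_spec"))
  nrow(schedule$doses)
}

#' The Zambian 6-10-14 week EPI schedule for the primary DTP series
#'
#' Three pentavalent DTP doses targeted at 42, 70 and 98 days of age
#' (6, 10 and 14 weeks), with admissible windows of 41-69, 70-97 and
#' 98-127 days, a minimum first-dose age of 42 days and a minimum
#' inter-dose interval of 28 days. Window 1 opens one day before the
#' 6-week target to absorb uncertainty in the exact timing of birth and
#' vaccination; doses at 40 days of age or less are "early".
#'
#' @param window3_end End of the third window in days (inclusive).
#'   Defaults to 127; 126 is the other convention seen for this schedule
#'   and is accepted here for sensitivity analyses.
#' @return A `schedule_spec` for the 3-dose series.
#' @examples
#' sched <- zambia_epi_schedule()
#' assign_window(sched, c(40, 41, 69, 70, 98, 128))
#' @export
zambia_epi_schedule <- function(window3_end = 127L) {
  window3_end <- as.integer(window3_end)
  if (!window3_end %in% c(126L, 127L)) {
    stop("window3_end must be 126 or 127", call. = FALSE)
  }
  schedule_spec(
    doses = data.frame(
      dose_number = 1:3,
      target_age = c(42L, 70L, 98L),
      window_start = c(41L, 70L, 98L),
      window_end = c(69L, 97L, window3_end),
      label = paste0("DTP", 1:3)
    ),
    min_first_age = 42L,
    min_interval = 28L,
    early_cutoff = 40L,
    name = "Zambia EPI 6-10-14 weeks (DTP)"
  )
}

#' Assign ages to schedule windows
#'
#' Maps each age in days to exactly one category: `"early"` (at or below
#' the early cutoff), `"window k"` for the k-th dose window, `"gap"` for
#' an age falling between the early cutoff and window 1 or between two
#' consecutive windows (empty for schedules with contiguous windows), or
#' `"after"` for ages past the last window. Window boundaries are
#' inclusive on both ends.
#'
#' @param schedule A `schedule_spec`.
#' @param age Integer vector of ages in days; must be non-negative.
#' @return A character vector, same length as `age`.
#' @examples
#' assign_window(zambia_epi_schedule(), c(0, 40, 41, 69, 70, 127, 128))
#' @export
assign_window <- function(schedule, age) {
  stopifnot(inherits(schedule, "schedule_spec"))
  age <- as.integer(age)
  if (anyNA(age)) stop("age must not contain NA", call. = FALSE)
  if (any(age < 0)) stop("age must be non-negative", call. = FALSE)
  out <- rep("gap", length(age))
  out[age <= schedule$early_cutoff] <- "early"
  d <- schedule$doses
  for (k in seq_len(nrow(d))) {
    out[age >= d$window_start[k] & age <= d$window_end[k]] <-
      paste0("window ", k)
  }
  out[age > d$window_end[nrow(d)]] <- "after"
  out
}

#' Integer index of the window containing each age
#'
#' Vectorised companion to [assign_window()]: returns the 1-based window
#' index, or `NA` for ages outside every dose window.
#'
#' @inheritParams assign_window
#' @return Integer vector of window indices with `NA` for early/gap/after.
#' @export
window_index <- function(schedule, age) {
  lab <- assign_window(schedule, age)
  idx <- rep(NA_integer_, length(lab))
  hit <- startsWith(lab, "window ")
  idx[hit] <- as.integer(sub("^window ", "", lab[hit]))
  idx
}

#' Read a schedule specification from a YAML file
#'
#' The file must contain `min_first_age`, `min_interval`, optionally
#' `early_cutoff` and `name`, and a `doses` list whose entries provide
#' `dose_number`, `target_age`, `window_start`, `window_end` and
#' optionally `label`. This allows non-Zambian schedules (e.g. a
#' 2-4-6 month series) to be analysed with the same pipeline.
#'
#' @param path Path to the YAML schedule file.
#' @return A `schedule_spec`.
#' @export
read_schedule <- function(path) {
  cfg <- yaml::read_yaml(path)
  doses <- do.call(rbind, lapply(cfg$doses, function(d) {
    data.frame(
      dose_number = as.integer(d$dose_number),
      target_age = as.integer(d$target_age),
      window_start = as.integer(d$window_start),
      window_end = as.integer(d$window_end),
      label = if (is.null(d$label)) NA_character_ else d$label
    )
  }))
  if (all(is.na(doses$label))) doses$label <- NULL
  schedule_spec(
    doses = doses,
    min_first_age = cfg$min_first_age,
    min_interval = cfg$min_interval,
    early_cutoff = cfg$early_cutoff,
    name = if (is.null(cfg$name)) basename(path) else cfg$name
  )
}
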