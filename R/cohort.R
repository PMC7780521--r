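#' Bundle roster, visit and dose tables into a cohort object
#'
#' @param roster Data frame with columns `infant_id`, `birth_date`,
#'   `enrolment_date` (ISO-8601 dates or `Date`) and any number of
#'   covariate columns.
#' @param visits Data frame with columns `infant_id`, `visit_date`,
#'   `scheduled` (logical; `TRUE` for protocol-scheduled visits).
#' @param doses Data frame with columns `infant_id`, `dose_number`,
#'   `admin_date`.
#' @param validate If `TRUE` (default), run [validate_cohort()] and stop
#'   on any issue.
#' @return An object of class `cohort_tables`.
#' @export
cohort_tables <- function(roster, visits, doses, validate = TRUE) {
  roster$birth_date <- as.Date(roster$birth_date)
  roster$enrolment_date <- as.Date(roster$enrolment_date)
  visits$visit_date <- as.Date(visits$visit_date)
  visits$scheduled <- as.logical(visits$scheduled)
  doses$admin_date <- as.Date(doses$admin_date)
  doses$dose_number <- as.integer(doses$dose_number)
  x <- structure(
    list(roster = roster, visits = visits, doses = doses),
    class = "cohort_tables"
  )
  if (validate) {
    issues <- validate_cohort(x)
    if (nrow(issues) > 0) {
      stop("cohort validation failed:\n",
           paste(utils::capture.output(print(issues)), collapse = "\n"),
           call. = FALSE)
    }
  }
  x
}

#' @export
print.cohort_tables <- function(x, ...) {
  cat("<cohort_tables>\n")
  cat(sprintf("  roster: %d infants (%d covariate column(s))\n",
              nrow(x$roster),
              ncol(x$roster) - 3L))
  cat(sprintf("  visits: %d events (%d scheduled)\n",
              nrow(x$visits), sum(x$visits$scheduled)))
  cat(sprintf("  doses:  %d events\n", nrow(x$doses)))
  invisible(x)
}

#' Validate the referential and ordering invariants of a cohort
#'
#' Checks performed: required columns present; dates parseable;
#' `enrolment_date >= birth_date`; unique `infant_id` in the roster;
#' every visit and dose references a rostered infant; visits and doses
#' not before birth; per infant, no duplicate `dose_number` and
#' administration dates strictly increasing with dose number.
#'
#' @param cohort A `cohort_tables` object (or plain list with the same
#'   elements).
#' @return A data frame of issues with columns `table`, `row`,
#'   `infant_id`, `problem`; zero rows when the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  issues <- list()
  add <- function(table, row, infant_id, problem) {
    issues[[length(issues) + 1L]] <<- data.frame(
      table = table, row = as.integer(row),
      infant_id = as.character(infant_id), problem = problem
    )
  }
  roster <- cohort$roster
  visits <- cohort$visits
  doses <- cohort$doses

  for (spec in list(
    list("roster", roster, c("infant_id", "birth_date", "enrolment_date")),
    list("visits", visits, c("infant_id", "visit_date", "scheduled")),
    list("doses", doses, c("infant_id", "dose_number", "admin_date"))
  )) {
    missing_cols <- setdiff(spec[[3]], names(spec[[2]]))
    if (length(missing_cols) > 0) {
      add(spec[[1]], NA, NA, paste0(
        "missing column(s): ", paste(missing_cols, collapse = ", ")
      ))
    }
  }
  if (length(issues) > 0) return(do.call(rbind, issues))

  for (i in which(is.na(roster$birth_date) | is.na(roster$enrolment_date))) {
    add("roster", i, roster$infant_id[i], "unparseable or missing date")
  }
  for (i in which(is.na(visits$visit_date))) {
    add("visits", i, visits$infant_id[i], "unparseable or missing date")
  }
  for (i in which(is.na(doses$admin_date))) {
    add("doses", i, doses$infant_id[i], "unparseable or missing date")
  }
  dup <- duplicated(roster$infant_id)
  for (i in which(dup)) {
    add("roster", i, roster$infant_id[i], "duplicate infant_id")
  }
  bad <- which(!is.na(roster$enrolment_date) & !is.na(roster$birth_date) &
                 roster$enrolment_date < roster$birth_date)
  for (i in bad) {
    add("roster", i, roster$infant_id[i], "enrolment_date before birth_date")
  }

  birth <- roster$birth_date[match(visits$infant_id, roster$infant_id)]
  orphan <- is.na(match(visits$infant_id, roster$infant_id))
  for (i in which(orphan)) {
    add("visits", i, visits$infant_id[i], "infant_id not in roster")
  }
  early_v <- which(!orphan & !is.na(visits$visit_date) &
                     visits$visit_date < birth)
  for (i in early_v) {
    add("visits", i, visits$infant_id[i], "visit_date before birth_date")
  }

  birth_d <- roster$birth_date[match(doses$infant_id, roster$infant_id)]
  orphan_d <- is.na(match(doses$infant_id, roster$infant_id))
  for (i in which(orphan_d)) {
    add("doses", i, doses$infant_id[i], "infant_id not in roster")
  }
  early_d <- which(!orphan_d & !is.na(doses$admin_date) &
                     doses$admin_date < birth_d)
  for (i in early_d) {
    add("doses", i, doses$infant_id[i], "admin_date before birth_date")
  }
  if (nrow(doses) > 0) {
    for (id in unique(doses$infant_id)) {
      rows <- which(doses$infant_id == id)
      sub <- doses[rows, ]
      if (anyDuplicated(sub$dose_number)) {
        add("doses", rows[which(duplicated(sub$dose_number))[1]], id,
            "duplicate dose_number for infant")
      }
      o <- order(sub$dose_number)
      if (any(diff(as.numeric(sub$admin_date[o])) <= 0)) {
        add("doses", rows[1], id,
            "admin dates not strictly increasing with dose_number")
      }
    }
  }
  if (length(issues) == 0) {
    return(data.frame(table = character(), row = integer(),
                      infant_id = character(), problem = character()))
  }
  do.call(rbind, issues)
}

#' Load a cohort from three delimited text files
#'
#' Reads comma-separated roster, visit and dose tables (headers as
#' documented in [cohort_tables()]), parses dates as ISO-8601, and
#' validates referential integrity before returning.
#'
#' @param roster_file,visits_file,doses_file Paths to CSV files.
#' @return A validated `cohort_tables` object.
#' @export
load_cohort <- function(roster_file, visits_file, doses_file) {
  roster <- utils::read.csv(roster_file, stringsAsFactors = FALSE)
  visits <- utils::read.csv(visits_file, stringsAsFactors = FALSE)
  doses <- utils::read.csv(doses_file, stringsAsFactors = FALSE)
  cohort_tables(roster, visits, doses)
}

#' Write a cohort to three delimited text files
#'
#' @param cohort A `cohort_tables` object.
#' @param dir Output directory (created if absent).
#' @param prefix Optional file-name prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_cohort <- function(cohort, dir, prefix = "") {
  stopifnot(inherits(cohort, "cohort_tables"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("roster.csv", "visits.csv",
                                           "doses.csv")))
  utils::write.csv(cohort$roster, paths[1], row.names = FALSE)
  utils::write.csv(cohort$visits, paths[2], row.names = FALSE)
  utils::write.csv(cohort$doses, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Attendance intervals and the attending roster
#'
#' An enrolled infant is *attending* if it has at least one scheduled
#' clinic visit; attending infants are on-study from enrolment until
#' their last recorded clinic visit. Infants with no scheduled visits
#' are excluded from all downstream analyses.
#'
#' @param cohort A `cohort_tables` object.
#' @return A data frame with one row per rostered infant and columns
#'   `infant_id`, `attending` (logical), `enrol_age`, `first_visit_age`,
#'   `last_visit_age` (days; `NA` for never-attenders), `n_scheduled`
#'   (count of scheduled visits attended).
#' @export
attending_set <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_tables"))
  roster <- cohort$roster
  sv <- cohort$visits[cohort$visits$scheduled, , drop = FALSE]
  birth <- roster$birth_date[match(sv$infant_id, roster$infant_id)]
  age <- as.integer(sv$visit_date - birth)
  first_age <- tapply(age, factor(sv$infant_id, levels = roster$infant_id),
                      min)
  last_age <- tapply(age, factor(sv$infant_id, levels = roster$infant_id),
                     max)
  n_sched <- tapply(age, factor(sv$infant_id, levels = roster$infant_id),
                    length)
  n_sched[is.na(n_sched)] <- 0L
  data.frame(
    infant_id = roster$infant_id,
    attending = !is.na(first_age),
    enrol_age = as.integer(roster$enrolment_date - roster$birth_date),
    first_visit_age = as.integer(first_age),
    last_visit_age = as.integer(last_age),
    n_scheduled = as.integer(n_sched),
    row.names = NULL
  )
}

#' Count infants still attending at a given age
#'
#' An attending infant counts at age `a` when its on-study interval
#' `[enrolment age, last scheduled visit age]` covers `a`. This is the
#' participation-by-age profile underlying attendance figures such as
#' the number of infants still attending when each dose window opens.
#'
#' @param cohort A `cohort_tables` object.
#' @param age Integer vector of ages (days).
#' @return Integer vector of counts, one per requested age.
#' @export
attending_at_age <- function(cohort, age) {
  att <- attending_set(cohort)
  att <- att[att$attending, , drop = FALSE]
  vapply(
    as.integer(age),
    function(a) sum(att$enrol_age <= a & a <= att$last_visit_age),
    integer(1)
  )
}

#' Apply a per-infant random date offset for deidentification
#'
#' Draws one integer offset per infant, uniformly from
#' `[-max_offset, +max_offset]`, and shifts all of that infant's study
#' dates (birth, enrolment, visits, doses) by it. Within-infant ages are
#' invariant under this transform, so every analytic output of the
#' pipeline is unchanged; only calendar positions move.
#'
#' @param cohort A `cohort_tables` object.
#' @param max_offset Maximum absolute offset in days (default 3).
#' @param seed Integer seed making the draw reproducible.
#' @return A new `cohort_tables` with shifted dates.
#' @export
deidentify <- function(cohort, max_offset = 3L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_tables"), max_offset >= 0)
  ids <- cohort$roster$infant_id
  offsets <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    vals <- seq.int(-max_offset, max_offset)
    if (length(vals) == 1L) rep(vals, length(ids))
    else sample(vals, length(ids), replace = TRUE)
  })
  names(offsets) <- ids
  out <- cohort
  out$roster$birth_date <- out$roster$birth_date + offsets[ids]
  out$roster$enrolment_date <- out$roster$enrolment_date + offsets[ids]
  out$visits$visit_date <-
    out$visits$visit_date + offsets[out$visits$infant_id]
  out$doses$admin_date <-
    out$doses$admin_date + offsets[out$doses$infant_id]
  out
}
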