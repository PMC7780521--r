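#' Configuration for the stochastic cohort simulator
#'
#' Collects every parameter of [simulate_cohort()] into a validated
#' object. Defaults describe a well-behaved cohort (full attendance, no
#' dropout, no hesitancy, modest right-skewed delays); see
#' [sim_config_realworld()] for a preset emulating a low-resource urban
#' cohort with substantial attrition.
#'
#' @param n_infants Number of infants enrolled.
#' @param enrolment_start Calendar date the intake period opens.
#' @param enrolment_span Days of staggered calendar intake (births are
#'   uniform over this span).
#' @param enrolment_age_mean Mean age at enrolment in days; per-infant
#'   enrolment ages are Poisson with this mean, shifted by 1 so the
#'   enrolment visit never falls on the day of birth.
#' @param visit_offsets Scheduled visit ages in days, strictly
#'   increasing. The default places six routine visits at 2-week
#'   intervals from 4 through 14 weeks, matching a 6-10-14-week dosing
#'   series with interleaved well-child visits.
#' @param visit_ceiling Latest possible realised visit age in days; a
#'   delayed visit that would land beyond it is not made up.
#' @param per_visit_attendance_prob Probability an on-study infant
#'   attends any given scheduled visit (missed visits are skipped, not
#'   rescheduled).
#' @param never_attend_prob Probability an enrolled infant never attends
#'   any scheduled visit (enrols but drops out immediately).
#' @param dropout_hazard Per-visit probability of permanent loss to
#'   follow-up, applied before each scheduled visit after the first.
#' @param hesitancy_fraction Probability an infant attends visits as
#'   usual but declines every vaccination.
#' @param delay_shape,delay_scale Gamma parameters of the non-negative
#'   per-visit timing delay (days, rounded to integers) added to each
#'   scheduled visit age. The default gives a median delay near 2 days
#'   with a long right tail.
#' @param violation_prob Probability, per dose opportunity, that clinic
#'   staff disregard the minimum-age / minimum-interval rules, allowing
#'   early or compressed administration by up to `violation_max_days`.
#' @param violation_max_days Maximum schedule violation in days.
#' @param schedule The `schedule_spec` doses are given against.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_infants = 1000,
                       enrolment_start = as.Date("2015-03-01"),
                       enrolment_span = 300,
                       enrolment_age_mean = 7,
                       visit_offsets = c(28L, 42L, 56L, 70L, 84L, 98L),
                       visit_ceiling = 126L,
                       per_visit_attendance_prob = 1,
                       never_attend_prob = 0,
                       dropout_hazard = 0,
                       hesitancy_fraction = 0,
                       delay_shape = 1.5,
                       delay_scale = 1.69,
                       violation_prob = 0,
                       violation_max_days = 7L,
                       schedule = zambia_epi_schedule(),
                       seed = 1L) {
  probs <- c(per_visit_attendance_prob, never_attend_prob, dropout_hazard,
             hesitancy_fraction, violation_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  visit_offsets <- as.integer(visit_offsets)
  if (length(visit_offsets) == 0) {
    stop("visit_offsets must contain at least one visit", call. = FALSE)
  }
  if (any(diff(visit_offsets) <= 0)) {
    stop("visit_offsets must be strictly increasing", call. = FALSE)
  }
  if (delay_shape <= 0 || delay_scale < 0) {
    stop("delay distribution parameters must be positive", call. = FALSE)
  }
  structure(
    list(
      n_infants = as.integer(n_infants),
      enrolment_start = as.Date(enrolment_start),
      enrolment_span = as.integer(enrolment_span),
      enrolment_age_mean = enrolment_age_mean,
      visit_offsets = visit_offsets,
      visit_ceiling = as.integer(visit_ceiling),
      per_visit_attendance_prob = per_visit_attendance_prob,
      never_attend_prob = never_attend_prob,
      dropout_hazard = dropout_hazard,
      hesitancy_fraction = hesitancy_fraction,
      delay_shape = delay_shape,
      delay_scale = delay_scale,
      violation_prob = violation_prob,
      violation_max_days = as.integer(violation_max_days),
      schedule = schedule,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Real-world preset for the cohort simulator
#'
#' Overrides the defaults of [sim_config()] with values chosen to
#' reproduce, qualitatively, the shape of a low-resource urban birth
#' cohort: roughly a quarter of enrollees never attend, attrition that
#' leaves roughly three quarters of attenders on-study when the third
#' dose window opens, a persistent hesitant subgroup, right-skewed
#' visit delays that compound across doses, and occasional early or
#' compressed administration.
#'
#' @param ... Named overrides passed through to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_realworld <- function(...) {
  defaults <- list(
    n_infants = 2000L,
    per_visit_attendance_prob = 0.93,
    never_attend_prob = 0.24,
    dropout_hazard = 0.07,
    hesitancy_fraction = 0.06,
    delay_shape = 1.5,
    delay_scale = 1.69,
    violation_prob = 0.04,
    violation_max_days = 7L
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(sim_config, defaults)
}

#' Simulate a longitudinal vaccination cohort
#'
#' Generates roster, visit and dose tables with the structure the
#' adherence pipeline assumes, together with per-infant ground-truth
#' labels for parameter-recovery testing.
#'
#' The generative process, per infant: a birth date uniform over the
#' intake span; enrolment at roughly one week of age; a hesitancy flag;
#' then, for each scheduled visit, a permanent-dropout draw followed by
#' an attendance draw, the realised visit age being the scheduled offset
#' plus an integer gamma delay (visits beyond the ceiling are dropped).
#' At each attended visit, every not-yet-given dose whose minimum age
#' and minimum inter-dose interval are satisfied at that age is
#' administered (one dose per visit), unless the infant is hesitant.
#' With small probability the minimum-age/interval check is relaxed by a
#' few days, generating early and compressed doses. Dropout truncates
#' all later visits and doses. Covariates (sex, birth location,
#' birth-dose vaccines, maternal attributes) are drawn independently of
#' the vaccination process.
#'
#' @param config A `sim_config`.
#' @return A `cohort_tables` object carrying an attribute `truth`
#'   (retrievable with [sim_truth()]): a data frame with
#'   `infant_id`, `hesitant`, `dropout_visit` (index of first visit lost
#'   to dropout, `NA` if never), `true_dose1_delay` (realised dose-1 age
#'   minus target, `NA` if no dose 1).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_infants
  sched <- config$schedule
  nd <- n_doses(sched)
  ids <- sprintf("SIM%05d", seq_len(n))

  birth <- config$enrolment_start +
    sample.int(config$enrolment_span, n, replace = TRUE) - 1L
  enrol_age <- 1L + stats::rpois(n, max(config$enrolment_age_mean - 1, 0))
  hesitant <- stats::runif(n) < config$hesitancy_fraction
  never <- stats::runif(n) < config$never_attend_prob

  nv <- length(config$visit_offsets)
  roster_rows <- vector("list", n)
  visit_rows <- vector("list", n)
  dose_rows <- vector("list", n)
  dropout_visit <- rep(NA_integer_, n)
  dose_ages_mat <- matrix(NA_integer_, nrow = n, ncol = nd)

  for (i in seq_len(n)) {
    attended_ages <- integer(0)
    dose_ages <- integer(0)
    if (!never[i]) {
      last_age <- -1L
      for (j in seq_len(nv)) {
        if (j > 1 && stats::runif(1) < config$dropout_hazard) {
          dropout_visit[i] <- j
          break
        }
        if (stats::runif(1) >= config$per_visit_attendance_prob) next
        k <- length(dose_ages) + 1L
        pending <- !hesitant[i] && k <= nd
        # the clinic reschedules a pending dosing visit so the minimum
        # inter-dose interval has elapsed by the appointment date
        sched_age <- config$visit_offsets[j]
        if (pending && k > 1L) {
          sched_age <- max(sched_age,
                           dose_ages[k - 1L] + sched$min_interval)
        }
        lax <- stats::runif(1) < config$violation_prob
        shift <- if (lax) sample.int(config$violation_max_days, 1) else 0L
        age <- sched_age - shift +
          as.integer(round(stats::rgamma(1, shape = config$delay_shape,
                                         scale = config$delay_scale)))
        # consecutive appointments never share a day
        age <- max(age, last_age + 1L)
        if (age > config$visit_ceiling) next
        last_age <- age
        attended_ages <- c(attended_ages, age)
        if (pending) {
          min_age <- if (k == 1L) {
            sched$min_first_age
          } else {
            max(sched$min_first_age,
                dose_ages[k - 1L] + sched$min_interval)
          }
          # a lax visit relaxes the minimum-age/interval check by the
          # same few days it was moved forward
          if (age >= min_age - shift &&
              (k == 1L || age > dose_ages[k - 1L])) {
            dose_ages <- c(dose_ages, age)
            dose_ages_mat[i, k] <- age
          }
        }
      }
    }
    attended_ages <- sort(unique(attended_ages))
    roster_rows[[i]] <- data.frame(
      infant_id = ids[i],
      birth_date = birth[i],
      enrolment_date = birth[i] + enrol_age[i]
    )
    if (length(attended_ages) > 0) {
      visit_rows[[i]] <- data.frame(
        infant_id = ids[i],
        visit_date = birth[i] + attended_ages,
        scheduled = TRUE
      )
    }
    if (length(dose_ages) > 0) {
      dose_rows[[i]] <- data.frame(
        infant_id = ids[i],
        dose_number = seq_along(dose_ages),
        admin_date = birth[i] + dose_ages
      )
    }
  }

  roster <- do.call(rbind, roster_rows)
  # covariates drawn independently of the vaccination process
  roster$sex_female <- stats::runif(n) < 0.47
  roster$born_at_clinic <- stats::runif(n) < 0.57
  roster$bcg_at_birth <- stats::runif(n) < 0.46
  roster$opv_at_birth <- stats::runif(n) < 0.33
  roster$maternal_hiv <- stats::runif(n) < 0.18
  roster$married <- stats::runif(n) < 0.90
  roster$maternal_age <- pmin(pmax(round(stats::rnorm(n, 25, 5)), 18), 45)
  roster$infants_in_house <- 1L + stats::rpois(n, 0.15)
  roster$children_under5 <- roster$infants_in_house + stats::rpois(n, 0.9)

  visits <- do.call(rbind, visit_rows)
  if (is.null(visits)) {
    visits <- data.frame(infant_id = character(),
                         visit_date = as.Date(character()),
                         scheduled = logical())
  }
  doses <- do.call(rbind, dose_rows)
  if (is.null(doses)) {
    doses <- data.frame(infant_id = character(),
                        dose_number = integer(),
                        admin_date = as.Date(character()))
  }
  cohort <- cohort_tables(roster, visits, doses)
  attr(cohort, "truth") <- data.frame(
    infant_id = ids,
    hesitant = hesitant,
    never_attend = never,
    dropout_visit = dropout_visit,
    true_dose1_delay = dose_ages_mat[, 1] -
      sched$doses$target_age[1]
  )
  cohort
}

#' Ground-truth labels of a simulated cohort
#'
#' @param cohort A cohort produced by [simulate_cohort()].
#' @return The per-infant truth table stored at generation time.
#' @export
sim_truth <- function(cohort) {
  tr <- attr(cohort, "truth")
  if (is.null(tr)) {
    stop("cohort carries no ground-truth labels (not simulated?)",
         call. = FALSE)
  }
  tr
}
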