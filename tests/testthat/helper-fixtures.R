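# Shared fixtures and independent oracles.
#
# The oracles below re-derive expected results from first principles with
# plain loops, deliberately independent of the package's implementation
# paths, so agreement is a genuine cross-check.

# Build a cohort_tables object from compact per-infant specs:
# each element of `infants` is list(id=, visit_ages=, dose_ages=,
# enrol_age=, birth_offset=). Visit ages are scheduled visits.
make_cohort <- function(infants, birth0 = as.Date("2015-06-01"),
                        validate = TRUE) {
  roster <- list(); visits <- list(); doses <- list()
  for (i in seq_along(infants)) {
    inf <- infants[[i]]
    id <- if (is.null(inf$id)) sprintf("I%03d", i) else inf$id
    birth <- birth0 + (if (is.null(inf$birth_offset)) i else inf$birth_offset)
    enrol_age <- if (is.null(inf$enrol_age)) 7L else inf$enrol_age
    roster[[i]] <- data.frame(infant_id = id, birth_date = birth,
                              enrolment_date = birth + enrol_age)
    if (length(inf$visit_ages) > 0) {
      visits[[i]] <- data.frame(infant_id = id,
                                visit_date = birth + inf$visit_ages,
                                scheduled = TRUE)
    }
    if (length(inf$dose_ages) > 0) {
      doses[[i]] <- data.frame(infant_id = id,
                               dose_number = seq_along(inf$dose_ages),
                               admin_date = birth + inf$dose_ages)
    }
  }
  empty_v <- data.frame(infant_id = character(),
                        visit_date = as.Date(character()),
                        scheduled = logical())
  empty_d <- data.frame(infant_id = character(),
                        dose_number = integer(),
                        admin_date = as.Date(character()))
  cohort_tables(
    do.call(rbind, roster),
    if (length(visits)) do.call(rbind, visits) else empty_v,
    if (length(doses)) do.call(rbind, doses) else empty_d,
    validate = validate
  )
}

# Independent classifier oracle for the 6-10-14 week schedule.
# Windows, cutoffs and the minimum interval are restated here as plain
# constants rather than taken from the schedule object.
oracle_classify <- function(visit_ages, dose_ages) {
  ws <- c(41, 70, 98); we <- c(69, 97, 127)
  early_cutoff <- 40; min_interval <- 28
  k <- 3
  cum <- integer(k); visited <- logical(k); received <- logical(k)
  utd <- logical(k); unvax <- logical(k)
  for (w in 1:k) {
    for (v in visit_ages) {
      if (v >= ws[w] && v <= we[w]) visited[w] <- TRUE
    }
    for (d in dose_ages) {
      if (d >= ws[w] && d <= we[w]) received[w] <- TRUE
      if (d <= we[w]) cum[w] <- cum[w] + 1L
    }
    unvax[w] <- cum[w] == 0
    ok <- TRUE
    for (j in 1:w) if (cum[j] < j) ok <- FALSE
    utd[w] <- ok
  }
  early <- logical(length(dose_ages))
  compressed <- logical(length(dose_ages))
  for (i in seq_along(dose_ages)) {
    early[i] <- dose_ages[i] <= early_cutoff
    if (i > 1) {
      compressed[i] <- (dose_ages[i] - dose_ages[i - 1]) < min_interval
    }
  }
  list(visited = visited, received = received, cum = cum,
       up_to_date = utd, unvaccinated = unvax,
       early = early, compressed = compressed)
}

# Independent product-limit oracle: direct risk-set enumeration,
# events before censorings at tied times.
oracle_km <- function(time, status) {
  ev <- sort(unique(time[status == 1]))
  surv <- numeric(length(ev))
  s <- 1
  for (i in seq_along(ev)) {
    t <- ev[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & status == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(age = ev, cum_prob = 1 - surv)
}

# Random single-dose survival fixture as a cohort: each infant either
# has dose 1 at its event age or is censored at its last visit age.
random_km_cohort <- function(n, seed) {
  set.seed(seed)
  time <- sample(30:130, n, replace = TRUE)
  status <- stats::rbinom(n, 1, 0.6)
  infants <- lapply(seq_len(n), function(i) {
    if (status[i] == 1) {
      list(visit_ages = time[i], dose_ages = time[i])
    } else {
      list(visit_ages = time[i], dose_ages = integer(0))
    }
  })
  list(cohort = make_cohort(infants), time = time, status = status)
}
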