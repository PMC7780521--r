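#' Window-stratified adherence table
#'
#' One row per schedule window, with denominators equal to the number of
#' unique infants attending at least one scheduled visit inside that
#' window. Columns count, among those visitors: infants who received (or
#' missed) a dose in the window, infants whose in-window dose was
#' compressed, infants up-to-date at the window, and infants still
#' unvaccinated by the window's end. Percentages are out of visits,
#' rounded to one decimal, half away from zero.
#'
#' Because an up-to-date infant may owe its status to a dose received
#' before the window (an early first dose), the up-to-date count can
#' exceed the received-in-window count.
#'
#' @param classification An `adherence_classification`.
#' @return Data frame with columns `window`, `age_range`, `target_dose`,
#'   `visits`, `received`, `received_pct`, `missed`, `missed_pct`,
#'   `compressed`, `compressed_pct`, `up_to_date`, `up_to_date_pct`,
#'   `unvaccinated`, `unvaccinated_pct`.
#' @export
window_table <- function(classification) {
  stopifnot(inherits(classification, "adherence_classification"))
  sched <- classification$schedule
  d <- sched$doses
  w <- classification$windows
  doses <- classification$doses
  rows <- lapply(seq_len(nrow(d)), function(k) {
    wk <- w[w$window == k, , drop = FALSE]
    visitors <- wk$infant_id[wk$visited]
    nv <- length(visitors)
    received_ids <- wk$infant_id[wk$visited & wk$received]
    in_window <- doses$infant_id %in% visitors &
      doses$admin_age >= d$window_start[k] &
      doses$admin_age <= d$window_end[k]
    compressed_ids <- unique(doses$infant_id[in_window & doses$compressed])
    utd <- sum(wk$visited & wk$up_to_date)
    unvax <- sum(wk$visited & wk$unvaccinated)
    data.frame(
      window = k,
      age_range = paste0(d$window_start[k], "-", d$window_end[k]),
      target_dose = d$dose_number[k],
      visits = nv,
      received = length(received_ids),
      received_pct = pct(length(received_ids), nv),
      missed = nv - length(received_ids),
      missed_pct = pct(nv - length(received_ids), nv),
      compressed = length(compressed_ids),
      compressed_pct = pct(length(compressed_ids), nv),
      up_to_date = utd,
      up_to_date_pct = pct(utd, nv),
      unvaccinated = unvax,
      unvaccinated_pct = pct(unvax, nv)
    )
  })
  do.call(rbind, rows)
}

#' Unvaccinated fraction of the attending cohort, by window end
#'
#' A companion statistic to the `unvaccinated` column of
#' [window_table()]: the same zero-dose-by-window-end numerator concept,
#' but counted over \emph{all} attending infants (not only the window's
#' visitors) and expressed as a percentage of the attending cohort.
#'
#' @param classification An `adherence_classification`.
#' @return Data frame with `window`, `window_end_age`, `unvaccinated`,
#'   `unvaccinated_pct` (of attending).
#' @export
unvaccinated_of_attending <- function(classification) {
  stopifnot(inherits(classification, "adherence_classification"))
  d <- classification$schedule$doses
  w <- classification$windows
  n <- classification$n_attending
  do.call(rbind, lapply(seq_len(nrow(d)), function(k) {
    n0 <- sum(w$unvaccinated[w$window == k])
    data.frame(
      window = k,
      window_end_age = d$window_end[k],
      unvaccinated = n0,
      unvaccinated_pct = pct(n0, n)
    )
  }))
}

#' Cumulative doses received across the study
#'
#' For each scheduled dose, counts the unique infants whose
#' administration of that dose fell in the early range or in each
#' window, plus the running total by each window's end. The bottom
#' margin counts all dose events administered within each column's age
#' range (an infant can contribute more than one event per window).
#' Dose events after the last window are excluded (reported via
#' `n_after`).
#'
#' @param classification An `adherence_classification`.
#' @return A list with `by_window` (dose x column incremental counts),
#'   `cumulative` (dose x column running totals), `total_administered`
#'   (bottom margin) and `n_after` (events past the last window).
#' @export
cumulative_table <- function(classification) {
  stopifnot(inherits(classification, "adherence_classification"))
  sched <- classification$schedule
  d <- sched$doses
  doses <- classification$doses
  k <- nrow(d)
  breaks_lo <- c(0L, d$window_start)
  breaks_hi <- c(sched$early_cutoff, d$window_end)
  col_names <- c(paste0("early_0_", sched$early_cutoff),
                 paste0("window_", seq_len(k)))
  m <- matrix(0L, nrow = k, ncol = k + 1,
              dimnames = list(d$label, col_names))
  total <- integer(k + 1)
  for (j in seq_len(k + 1)) {
    in_col <- doses$admin_age >= breaks_lo[j] &
      doses$admin_age <= breaks_hi[j]
    total[j] <- sum(in_col)
    for (i in seq_len(k)) {
      m[i, j] <- sum(in_col & doses$dose_number == i)
    }
  }
  list(
    by_window = m,
    cumulative = t(apply(m, 1, cumsum)),
    total_administered = stats::setNames(total, col_names),
    n_after = sum(doses$admin_age > d$window_end[k])
  )
}

#' Dose-timing histograms
#'
#' Three binned series for plotting: weekly dose counts per dose number
#' (week bin = `floor(age / 7)`), the age histogram of early doses, and
#' the inter-dose spacing histogram split into compressed versus
#' appropriately spaced doses.
#'
#' @param classification An `adherence_classification`.
#' @return A list of data frames `weekly` (`dose_number`, `week`, `n`),
#'   `early_ages` (`admin_age`, `n`) and `spacing` (`dose_number`,
#'   `spacing`, `compressed`, `n`).
#' @export
timing_histograms <- function(classification) {
  stopifnot(inherits(classification, "adherence_classification"))
  doses <- classification$doses
  weekly <- as.data.frame(table(
    dose_number = doses$dose_number,
    week = floor(doses$admin_age / 7)
  ), responseName = "n", stringsAsFactors = FALSE)
  weekly$dose_number <- as.integer(weekly$dose_number)
  weekly$week <- as.integer(weekly$week)
  weekly <- weekly[weekly$n > 0, , drop = FALSE]
  weekly <- weekly[order(weekly$dose_number, weekly$week), , drop = FALSE]
  rownames(weekly) <- NULL

  early <- doses[doses$early, , drop = FALSE]
  early_ages <- as.data.frame(table(admin_age = early$admin_age),
                              responseName = "n",
                              stringsAsFactors = FALSE)
  if (nrow(early_ages) > 0) {
    early_ages$admin_age <- as.integer(early_ages$admin_age)
  }

  sp <- doses[!is.na(doses$spacing), , drop = FALSE]
  spacing <- as.data.frame(table(
    dose_number = sp$dose_number,
    spacing = sp$spacing,
    compressed = sp$compressed
  ), responseName = "n", stringsAsFactors = FALSE)
  spacing <- spacing[spacing$n > 0, , drop = FALSE]
  if (nrow(spacing) > 0) {
    spacing$dose_number <- as.integer(spacing$dose_number)
    spacing$spacing <- as.integer(spacing$spacing)
    spacing$compressed <- as.logical(spacing$compressed)
    spacing <- spacing[order(spacing$dose_number, spacing$spacing), ,
                       drop = FALSE]
    rownames(spacing) <- NULL
  }
  list(weekly = weekly, early_ages = early_ages, spacing = spacing)
}

#' Count infants with compressed dose spacing at a set of thresholds
#'
#' Reports, at each spacing threshold, the number of unique infants with
#' at least one inter-dose interval strictly below it and the number of
#' such dose events. Useful for sensitivity analyses of the compression
#' definition (e.g. 28, 25 and 20 days).
#'
#' @param classification An `adherence_classification`.
#' @param thresholds Integer vector of spacing thresholds in days.
#' @return Data frame with `threshold`, `infants`, `events`.
#' @export
compression_summary <- function(classification,
                                thresholds = c(28L, 25L, 20L)) {
  sp <- classification$doses
  sp <- sp[!is.na(sp$spacing), , drop = FALSE]
  do.call(rbind, lapply(as.integer(thresholds), function(th) {
    hit <- sp$spacing < th
    data.frame(
      threshold = th,
      infants = length(unique(sp$infant_id[hit])),
      events = sum(hit)
    )
  }))
}
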