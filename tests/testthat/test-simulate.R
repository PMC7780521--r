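test_that("degenerate configurations are rejected", {
  expect_error(sim_config(per_visit_attendance_prob = 1.2), "probabilities")
  expect_error(sim_config(visit_offsets = integer(0)), "at least one")
  expect_error(sim_config(visit_offsets = c(42, 42)), "increasing")
  expect_error(sim_config(delay_shape = 0), "positive")
})

test_that("perfect adherence limit: every infant completes the series on time", {
  co <- simulate_cohort(sim_config(n_infants = 120, seed = 6,
                                   delay_scale = 0.01))
  cl <- classify_cohort(co)
  expect_equal(cl$n_attending, 120L)
  expect_true(all(cl$infants$total_doses == 3))
  expect_true(all(cl$windows$up_to_date))
  expect_false(any(cl$doses$early))
  expect_false(any(cl$doses$compressed))
})

test_that("simulated cohorts always pass validation and are seed-reproducible", {
  cfg <- sim_config_realworld(n_infants = 250, seed = 13)
  co1 <- simulate_cohort(cfg)
  expect_equal(nrow(validate_cohort(co1)), 0)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$roster, co2$roster)
  expect_identical(co1$visits, co2$visits)
  expect_identical(co1$doses, co2$doses)
  co3 <- simulate_cohort(sim_config_realworld(n_infants = 250, seed = 14))
  expect_false(identical(co1$visits, co3$visits))
})

test_that("hesitant infants attend but never vaccinate; labels are consistent", {
  co <- simulate_cohort(sim_config(n_infants = 800, seed = 21,
                                   hesitancy_fraction = 0.10))
  truth <- sim_truth(co)
  dosed <- unique(co$doses$infant_id)
  expect_false(any(dosed %in% truth$infant_id[truth$hesitant]))
  # full attendance, no dropout: hesitant fraction within 3 binomial SE
  frac <- mean(truth$hesitant)
  expect_lt(abs(frac - 0.10), 3 * sqrt(0.1 * 0.9 / 800))
  # and every non-hesitant infant completes
  cl <- classify_cohort(co)
  inf <- merge(cl$infants, truth, by = "infant_id")
  expect_true(all(inf$total_doses[!inf$hesitant] == 3))
  expect_true(all(inf$total_doses[inf$hesitant] == 0))
})

test_that("unvaccinated-at-end fraction matches the hesitancy parameter", {
  co <- simulate_cohort(sim_config(n_infants = 5000, seed = 88,
                                   hesitancy_fraction = 0.10))
  cl <- classify_cohort(co)
  eos <- end_of_study_doses(cl)
  frac0 <- eos$exact[eos$n_doses == 0] / cl$n_attending
  expect_lt(abs(frac0 - 0.10), 3 * sqrt(0.1 * 0.9 / 5000))
})

test_that("dropout produces monotone attrition in the attendance profile", {
  co <- simulate_cohort(sim_config(n_infants = 600, seed = 17,
                                   dropout_hazard = 0.15,
                                   per_visit_attendance_prob = 0.9))
  profile <- attending_at_age(co, 28:126)
  expect_true(all(diff(profile) <= 0))
  expect_lt(profile[length(profile)], profile[1])
})

test_that("minimum interval binds dose spacing unless violations are enabled", {
  co <- simulate_cohort(sim_config(n_infants = 400, seed = 19,
                                   per_visit_attendance_prob = 0.85))
  cl <- classify_cohort(co)
  expect_true(all(cl$doses$spacing >= 28, na.rm = TRUE))
  expect_true(all(cl$doses$admin_age >= 42))

  lax <- simulate_cohort(sim_config(n_infants = 600, seed = 20,
                                    violation_prob = 0.2))
  cll <- classify_cohort(lax)
  expect_true(any(cll$doses$compressed) || any(cll$doses$early))
  # violations are bounded: spacing never shrinks below 28 - 7
  expect_true(all(cll$doses$spacing >= 21, na.rm = TRUE))
  expect_true(all(cll$doses$admin_age >= 35))
})

test_that("delay propagation: a late first dose delays the second at least as much, minus slack", {
  co <- simulate_cohort(sim_config(n_infants = 500, seed = 25))
  cl <- classify_cohort(co)
  d1 <- cl$doses[cl$doses$dose_number == 1, c("infant_id", "admin_age")]
  d2 <- cl$doses[cl$doses$dose_number == 2, c("infant_id", "admin_age")]
  both <- merge(d1, d2, by = "infant_id", suffixes = c("_1", "_2"))
  delay1 <- both$admin_age_1 - 42
  delay2 <- both$admin_age_2 - 70
  # scheduling slack between windows: target gap (28) equals the
  # minimum interval, so a dose-1 delay must propagate fully
  expect_true(all(delay2 >= delay1))
})

test_that("the real-world preset reproduces the intended cohort shape", {
  co <- simulate_cohort(sim_config_realworld(n_infants = 1500, seed = 33))
  att <- attending_set(co)
  # roughly a quarter never attend
  expect_gt(mean(!att$attending), 0.18)
  expect_lt(mean(!att$attending), 0.32)
  # roughly three quarters of attenders reach the third window
  w3 <- attending_at_age(co, 98) / sum(att$attending)
  expect_gt(w3, 0.65)
  expect_lt(w3, 0.88)
  # first-dose coverage in the intended envelope
  cl <- classify_cohort(co)
  eos <- end_of_study_doses(cl)
  expect_gt(eos$at_least_pct[2], 85)
  expect_lt(eos$at_least_pct[2], 97)
  # median delays grow with dose number
  med <- subset(delay_summary(co, assumption = "worst_case"), prob == 0.5)
  expect_true(all(med$attained))
  expect_true(all(diff(med$delay) >= 0))
})
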