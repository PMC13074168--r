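WINDOW <- as.Date(c("2014-05-15", "2023-03-13"))
END <- WINDOW[2]

test_that("eligibility keeps 18-89 year olds with at least two in-window visits", {
  h <- function(id, age, enc) make_history(id, age, encounter_dates = enc)
  res <- filter_eligible(
    list(
      h("A", 90, c("2018-01-01", "2018-06-01", "2019-01-01", "2019-06-01", "2020-01-01")),
      h("B", 50, "2018-01-01"),
      h("C", 50, c("2018-01-01", "2019-01-01", "2020-01-01")),
      h("D", NA, c("2018-01-01", "2019-01-01")),
      h("E", 45, c("2010-01-01", "2012-01-01", "2018-06-01"))  # only 1 in window
    ),
    window = WINDOW
  )
  expect_equal(vapply(res$eligible, `[[`, "", "patient_id"), "C")
  expect_equal(res$exclusions$reason[match(c("A", "B", "D", "E"), res$exclusions$patient_id)],
               c("age_out_of_range", "fewer_than_two_visits", "missing_age",
                 "fewer_than_two_visits"))
})

test_that("a single-record history has identical baseline and final regimens", {
  h <- make_history(events = list(met_ev("2022-06-01")),
                    encounter_dates = c("2022-06-01", "2022-12-01"))
  traj <- build_trajectory(h, extraction_end = END)
  expect_equal(traj$baseline$members, traj$final$members)
  expect_equal(traj$baseline$members$daily_total, 1000)
})

test_that("first/last 12-month agreement yields equal snapshots despite interim changes", {
  # 1000 -> 2000 -> 1000 mg/day within 24 months: endpoint windows agree
  h <- make_history(events = list(
    met_ev("2021-01-01", 500, 2),   # 1000, ends the baseline window on this dose
    met_ev("2022-02-01", 1000, 2),  # interim 2000, between the two windows
    met_ev("2022-09-01", 500, 2)    # 1000 in final window
  ), encounter_dates = c("2021-01-01", "2022-09-01"))
  traj <- build_trajectory(h, extraction_end = END)
  expect_equal(traj$baseline$members$daily_total, 1000)
  expect_equal(traj$final$members$daily_total, 1000)
  cl <- classify_patient(traj)
  expect_equal(cl$top_level, "NOT_DEPRESCRIBED")
  expect_equal(cl$subtype, "NO_CHANGE")
})

test_that("trajectories are invariant to input row order and to rigid date shifts", {
  events <- list(met_ev("2016-02-01", 1000, 2), sita_ev("2016-02-01"),
                 sita_ev("2019-05-01", 50), met_ev("2022-06-15", 500, 2),
                 sita_ev("2022-08-01", 50))
  encs <- c("2016-02-01", "2019-05-01", "2022-08-01")
  h1 <- make_history(events = events, encounter_dates = encs)
  h2 <- make_history(events = rev(events), encounter_dates = rev(encs))
  t1 <- build_trajectory(h1, END)
  t2 <- build_trajectory(h2, END)
  expect_identical(t1, t2)

  shift <- 37L
  shifted <- lapply(events, function(e) { e$date <- as.Date(e$date) + shift; e })
  h3 <- make_history(events = shifted, encounter_dates = as.Date(encs) + shift)
  t3 <- build_trajectory(h3, END + shift)
  expect_equal(t3$baseline$members, t1$baseline$members)
  expect_equal(t3$final$members, t1$final$members)
  expect_equal(t3$n_interim_transitions, t1$n_interim_transitions)
  expect_equal(t3$inferred_discontinuation, t1$inferred_discontinuation)
})

test_that("same-date duplicate records resolve to the higher daily dose", {
  h <- make_history(events = list(met_ev("2022-06-01", 500, 2),
                                  met_ev("2022-06-01", 500, 1)),
                    encounter_dates = c("2022-06-01", "2022-07-01"))
  traj <- build_trajectory(h, END)
  expect_equal(traj$final$members$daily_total, 1000)
})

test_that("interim add/stop events are counted between the two windows", {
  # metformin refilled continuously (annual refills, no >1y gap);
  # sitagliptin appears and disappears wholly between baseline and final
  met_refills <- lapply(as.character(seq(as.Date("2015-01-01"),
                                         as.Date("2022-12-01"), by = 300)),
                        met_ev)
  h <- make_history(events = c(met_refills, list(sita_ev("2018-06-01"),
                                                 sita_ev("2018-09-01"))),
                    encounter_dates = c("2015-01-01", "2022-09-01"))
  expect_error(build_trajectory(h, END), NA)
  traj <- build_trajectory(h, END)
  expect_equal(traj$n_interim_transitions, 2L)  # sitagliptin start + stop
  expect_equal(traj$n_interim_oral_transitions, 2L)
})

test_that("inferred discontinuation requires a >1 year gap AND a later encounter", {
  mk <- function(last_rx, encs) make_history(
    events = list(met_ev("2016-01-01"), met_ev(last_rx)),
    encounter_dates = encs
  )
  # gap > 1 year with an active-patient encounter afterwards
  expect_true(detect_inferred_discontinuation(
    mk("2021-06-01", c("2016-01-01", "2022-09-01")), END))
  # last prescription within the final 12 months
  expect_false(detect_inferred_discontinuation(
    mk("2022-12-01", c("2016-01-01", "2022-09-01")), END))
  # no encounter after the last prescription
  expect_false(detect_inferred_discontinuation(
    mk("2021-06-01", c("2016-01-01", "2021-01-01")), END))
  # no records at all
  expect_false(detect_inferred_discontinuation(
    make_history(encounter_dates = c("2016-01-01", "2022-01-01")), END))
})

test_that("discontinuation flag matches its defining property on random configurations", {
  set.seed(11)
  for (i in 1:300) {
    last_rx <- END - sample(0:1500, 1)
    enc <- END - sample(0:1500, 2)
    h <- make_history(events = list(met_ev("2015-06-01"), met_ev(last_rx)),
                      encounter_dates = enc)
    expected <- (max(as.Date("2015-06-01"), last_rx) < END - 365) &&
      any(enc > max(as.Date("2015-06-01"), last_rx))
    expect_identical(detect_inferred_discontinuation(h, END), expected)
  }
})

test_that("adding a later prescription can only clear the discontinuation flag", {
  set.seed(12)
  for (i in 1:100) {
    last_rx <- END - sample(200:1500, 1)
    enc <- END - sample(0:1400, 3)
    h <- make_history(events = list(met_ev(last_rx)), encounter_dates = enc)
    before <- detect_inferred_discontinuation(h, END)
    extra <- last_rx + sample(1:600, 1)
    h2 <- make_history(events = list(met_ev(last_rx), met_ev(extra)),
                       encounter_dates = enc)
    after <- detect_inferred_discontinuation(h2, END)
    expect_false(!before && after)  # never flips FALSE -> TRUE
  }
})
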