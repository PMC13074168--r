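test_that("rule evaluation matches the published tier definitions", {
  # fewer total insulin units
  expect_setequal(evaluate_rules(make_traj(snap(ins = 40), snap(ins = 20))),
                  "INSULIN_DOSE_REDUCED")
  # insulin stopped, metformin started: switch, with discontinuation implied
  m <- evaluate_rules(make_traj(snap(ins = 30), snap(met = 1000)))
  expect_true(all(c("INSULIN_TO_NONINSULIN", "INSULIN_DISCONTINUED") %in% m))
  # moving up from metformin to insulin on top
  expect_true(any(grepl("^ESCALATION",
                        evaluate_rules(make_traj(snap(met = 1000),
                                                 snap(met = 1000, ins = 20))))))
  # swap between two non-insulin agents is lateral, not a stop
  b <- regimen_snapshot("glipizide", "NON_INSULIN_OTHER", 10, "mg")
  f <- regimen_snapshot("empagliflozin", "NON_INSULIN_OTHER", 10, "mg")
  m2 <- evaluate_rules(make_traj(b, f))
  expect_true("LATERAL_SWITCH" %in% m2)
  expect_false("NONINSULIN_STOPPED" %in% m2)
  # empty on both sides matches nothing
  expect_length(evaluate_rules(make_traj(snap(), snap())), 0)
})

test_that("classification resolves subtypes in the framework's printed order", {
  cl <- function(b, f, ...) classify_patient(make_traj(b, f, ...))

  same <- cl(snap(met = 1000), snap(met = 1000))
  expect_equal(c(same$top_level, same$subtype), c("NOT_DEPRESCRIBED", "NO_CHANGE"))

  less_met <- cl(snap(met = 2000), snap(met = 1000))
  expect_equal(c(less_met$top_level, less_met$subtype),
               c("DEPRESCRIBED", "METFORMIN_DOSE_REDUCED"))

  # multiple meds + metformin -> metformin only is the to-metformin subtype,
  # not the generic stop
  b <- regimen_snapshot(c("sitagliptin", "metformin", "glipizide"),
                        c("NON_INSULIN_OTHER", "METFORMIN", "NON_INSULIN_OTHER"),
                        c(100, 1000, 10), c("mg", "mg", "mg"))
  consol <- cl(b, snap(met = 1000))
  expect_equal(c(consol$top_level, consol$subtype),
               c("DEPRESCRIBED", "NONINSULIN_TO_METFORMIN"))

  # insulin change outranks metformin change when both are deprescribing
  both <- cl(snap(ins = 40, met = 2000), snap(ins = 20, met = 1000))
  expect_equal(both$subtype, "INSULIN_DOSE_REDUCED")
  expect_true(all(c("INSULIN_DOSE_REDUCED", "METFORMIN_DOSE_REDUCED") %in%
                    both$all_matched_rules))
})

test_that("mixed de-escalation and escalation routes to review, never a net calculus", {
  mixed <- classify_patient(make_traj(snap(ins = 40, met = 1000),
                                      snap(ins = 20, met = 2000)))
  expect_equal(mixed$top_level, "UNCLEAR")
  expect_equal(mixed$subtype, "NEEDS_REVIEW")
  expect_false(any(mixed$subtype %in% c("INSULIN_DOSE_REDUCED")))
})

test_that("metformin stopped requires no restart at any point", {
  END <- as.Date("2023-03-13")
  # continuous course then stopped (other agent continues): matches
  stopped <- make_history(events = list(
    met_ev("2016-01-01"), met_ev("2016-06-01"), met_ev("2017-01-01"),
    sita_ev("2016-01-01"), sita_ev("2022-12-01")
  ), encounter_dates = c("2016-01-01", "2022-12-01"))
  cl1 <- classify_patient(build_trajectory(stopped, END))
  expect_equal(c(cl1$top_level, cl1$subtype), c("DEPRESCRIBED", "METFORMIN_STOPPED"))

  # stopped, restarted after a >1 year gap, stopped again: must NOT match
  restarted <- make_history(events = list(
    met_ev("2016-01-01"), met_ev("2016-06-01"),
    met_ev("2019-01-01"), met_ev("2019-06-01"),  # restart
    sita_ev("2016-01-01"), sita_ev("2022-12-01")
  ), encounter_dates = c("2016-01-01", "2022-12-01"))
  traj <- build_trajectory(restarted, END)
  expect_false("METFORMIN_STOPPED" %in% evaluate_rules(traj))
  expect_false(classify_patient(traj)$subtype == "METFORMIN_STOPPED")
})

test_that("an empty final regimen is deprescribing only with an active-patient encounter", {
  flagged <- classify_patient(make_traj(snap(met = 1000), snap(), inferred = TRUE))
  expect_equal(c(flagged$top_level, flagged$subtype),
               c("DEPRESCRIBED", "METFORMIN_STOPPED"))
  # highest tier discontinued names the subtype
  flagged_ins <- classify_patient(make_traj(snap(ins = 20, met = 1000), snap(),
                                            inferred = TRUE))
  expect_equal(flagged_ins$subtype, "INSULIN_DISCONTINUED")
  # lost to follow-up: no inference possible
  lost <- classify_patient(make_traj(snap(met = 1000), snap(), inferred = FALSE))
  expect_equal(c(lost$top_level, lost$subtype), c("UNCLEAR", "NEEDS_REVIEW"))
})

test_that("dose-change rules are suppressed when a category is not dose-comparable", {
  b <- regimen_snapshot(c("metformin", "semaglutide"),
                        c("METFORMIN", "NON_INSULIN_OTHER"),
                        c(2000, 1), c("mg", "mg/week"))
  f <- regimen_snapshot(c("metformin", "semaglutide"),
                        c("METFORMIN", "NON_INSULIN_OTHER"),
                        c(1000, 0.5), c("mg", "mg"))  # unit changed mid-course
  m <- evaluate_rules(make_traj(b, f))
  # metformin (mg on both sides) still compares; semaglutide does not
  expect_true("METFORMIN_DOSE_REDUCED" %in% m)
  expect_false("NONINSULIN_DOSE_REDUCED" %in% m)
})

test_that("insulin product switches at equal total units are no change", {
  b <- regimen_snapshot("insulin glargine", "INSULIN", 20, "units")
  f <- regimen_snapshot("insulin nph", "INSULIN", 20, "units")
  cl <- classify_patient(make_traj(b, f))
  expect_equal(c(cl$top_level, cl$subtype), c("NOT_DEPRESCRIBED", "NO_CHANGE"))
  # ... but fewer total units across the switch is still a dose reduction
  f2 <- regimen_snapshot("insulin nph", "INSULIN", 10, "units")
  expect_equal(classify_patient(make_traj(b, f2))$subtype, "INSULIN_DOSE_REDUCED")
})

test_that("every trajectory gets exactly one classification (totality)", {
  set.seed(99)
  levels <- list(ins = c(0, 10, 20, 40), met = c(0, 500, 1000, 2000),
                 nio = c(0, 25, 50, 100))
  for (i in 1:200) {
    traj <- make_traj(
      snap(sample(levels$ins, 1), sample(levels$met, 1), sample(levels$nio, 1)),
      snap(sample(levels$ins, 1), sample(levels$met, 1), sample(levels$nio, 1)),
      inferred = sample(c(TRUE, FALSE), 1)
    )
    cl <- classify_patient(traj)
    expect_length(cl$top_level, 1)
    expect_length(cl$subtype, 1)
    expect_true(cl$top_level %in% c("DEPRESCRIBED", "NOT_DEPRESCRIBED", "UNCLEAR"))
    if (cl$top_level == "DEPRESCRIBED") {
      expect_true(cl$subtype %in% deprescribr:::DEPRESCRIBING_SUBTYPES)
      expect_true(length(intersect(cl$all_matched_rules,
                                   deprescribr:::DEPRESCRIBING_SUBTYPES)) > 0 ||
                    traj$inferred_discontinuation)
    }
  }
})

test_that("uniformly scaling final doses up never yields deprescribing", {
  set.seed(123)
  for (i in 1:150) {
    b <- snap(sample(c(0, 10, 20, 40), 1), sample(c(0, 500, 1000), 1),
              sample(c(0, 25, 50), 1))
    if (!nrow(b$members)) next
    factor <- sample(c(1, 1.5, 2, 3), 1)
    f <- regimen_snapshot(b$members$canonical_name, b$members$category,
                          b$members$daily_total * factor, b$members$dose_unit)
    cl <- classify_patient(make_traj(b, f))
    expect_false(cl$top_level == "DEPRESCRIBED")
  }
})
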