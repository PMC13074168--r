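# Fixed dose menus per tier keep scenarios enumerable: insulin glargine
# {10,20,40} units/day, metformin {500,1000,2000} mg/day (as 1-2 daily
# administrations), sitagliptin {25,50,100} mg/day, glipizide/empagliflozin
# at their common strengths.
.rx <- function(drug, written, amount, unit, freq) {
  data.frame(canonical = drug, written = written, amount = amount,
             unit = unit, freq = freq, stringsAsFactors = FALSE)
}

.RX <- list(
  glargine_40 = .rx("insulin glargine", "Lantus", 40, "units", 1),
  glargine_30 = .rx("insulin glargine", "Lantus", 30, "units", 1),
  glargine_20 = .rx("insulin glargine", "insulin glargine", 20, "units", 1),
  glargine_10 = .rx("insulin glargine", "Lantus SoloStar", 10, "units", 1),
  met_2000 = .rx("metformin", "Metformin HCL 1000 MG tab", 1000, "mg", 2),
  met_1000 = .rx("metformin", "METFORMIN 500 MG TAB", 500, "mg", 2),
  met_500  = .rx("metformin", "Glucophage", 500, "mg", 1),
  sita_100 = .rx("sitagliptin", "Januvia 100 MG tablet", 100, "mg", 1),
  sita_50  = .rx("sitagliptin", "sitagliptin 50 mg", 50, "mg", 1),
  sita_25  = .rx("sitagliptin", "Januvia", 25, "mg", 1),
  glip_10  = .rx("glipizide", "Glucotrol", 10, "mg", 1),
  empa_10  = .rx("empagliflozin", "Jardiance 10 MG tablet", 10, "mg", 1),
  empa_25  = .rx("empagliflozin", "Jardiance", 25, "mg", 1)
)

.SUBTYPE_BY_TIER <- c(INSULIN = "INSULIN_DISCONTINUED",
                      NON_INSULIN_OTHER = "NONINSULIN_STOPPED",
                      METFORMIN = "METFORMIN_STOPPED")

# Each scenario: phase regimens (phase A holds from the first record to the
# change point, phase B from the change point to near the extraction end)
# and the planted truth label. NULL phase B = prescriptions simply stop at
# the change point.
.scenario_catalog <- function() {
  R <- .RX
  list(
    insulin_dose_reduced = function() list(
      A = rbind(R$glargine_40), B = rbind(R[[sample(c("glargine_10", "glargine_20"), 1)]]),
      truth = c("DEPRESCRIBED", "INSULIN_DOSE_REDUCED")),
    insulin_to_noninsulin = function() list(
      A = rbind(R$glargine_30), B = rbind(R$met_1000),
      truth = c("DEPRESCRIBED", "INSULIN_TO_NONINSULIN")),
    insulin_discontinued = function() list(
      A = rbind(R$glargine_20, R$met_1000), B = rbind(R$met_1000),
      truth = c("DEPRESCRIBED", "INSULIN_DISCONTINUED")),
    noninsulin_stopped = function() list(
      A = rbind(R$sita_100, R$empa_10), B = rbind(R$sita_100),
      truth = c("DEPRESCRIBED", "NONINSULIN_STOPPED")),
    noninsulin_dose_reduced = function() list(
      A = rbind(R$sita_100), B = rbind(R[[sample(c("sita_25", "sita_50"), 1)]]),
      truth = c("DEPRESCRIBED", "NONINSULIN_DOSE_REDUCED")),
    noninsulin_to_metformin = function() list(
      A = rbind(R$glip_10), B = rbind(R$met_1000),
      truth = c("DEPRESCRIBED", "NONINSULIN_TO_METFORMIN")),
    metformin_stopped = function() list(
      A = rbind(R$met_1000, R$sita_100), B = rbind(R$sita_100),
      truth = c("DEPRESCRIBED", "METFORMIN_STOPPED")),
    metformin_dose_reduced = function() list(
      A = rbind(R$met_2000), B = rbind(R[[sample(c("met_500", "met_1000"), 1)]]),
      truth = c("DEPRESCRIBED", "METFORMIN_DOSE_REDUCED")),
    lateral_switch = function() list(
      A = rbind(R$glip_10), M = rbind(R$sita_100),
      B = rbind(R[[sample(c("empa_10", "empa_25"), 1)]]),
      truth = c("NOT_DEPRESCRIBED", "LATERAL_CHANGE")),
    dose_escalation = function() list(
      A = rbind(R$met_1000), B = rbind(R$met_1000, R$glargine_10),
      truth = c("NOT_DEPRESCRIBED", "MEDICATION_INCREASE")),
    stable_regimen = function() list(
      A = rbind(R$met_1000), B = rbind(R$met_1000),
      truth = c("NOT_DEPRESCRIBED", "NO_CHANGE")),
    inferred_discontinuation = function() list(
      A = rbind(R$met_1000), B = NULL, keep_encounters = TRUE,
      truth = c("DEPRESCRIBED", "METFORMIN_STOPPED")),
    lost_to_follow_up = function() list(
      A = rbind(R$met_1000), B = NULL, keep_encounters = FALSE,
      truth = c("UNCLEAR", "NEEDS_REVIEW")),
    mixed_signal = function() list(
      A = rbind(R$glargine_40, R$met_1000), B = rbind(R$glargine_20, R$met_2000),
      truth = c("UNCLEAR", "NEEDS_REVIEW")),
    ineligible_age = function() list(
      A = rbind(R$met_1000), B = rbind(R$met_1000), age = sample(90:95, 1),
      truth = c("EXCLUDED", "age_out_of_range")),
    ineligible_visits = function() list(
      A = rbind(R$met_1000), B = rbind(R$met_1000), single_visit = TRUE,
      truth = c("EXCLUDED", "fewer_than_two_visits"))
  )
}

#' Scenario names available to the generator
#'
#' The 14 core scenarios (the 8 deprescribing subtypes, a lateral switch
#' chain, dose escalation, a stable regimen, inferred discontinuation, lost
#' to follow-up, and a mixed de-escalation + escalation signal) plus two
#' planted-ineligible scenarios used to exercise the eligibility filter.
#'
#' @param include_ineligible Include the planted-ineligible scenarios.
#' @return Character vector of scenario names.
#' @export
synthetic_scenarios <- function(include_ineligible = FALSE) {
  nm <- names(.scenario_catalog())
  if (!include_ineligible) nm <- setdiff(nm, c("ineligible_age", "ineligible_visits"))
  nm
}

.refill_dates <- function(from, to, interval = c(90, 120)) {
  if (from > to) return(as.Date(character()))
  d <- from
  out <- d
  repeat {
    d <- d + sample(seq(interval[1], interval[2]), 1)
    if (d > to) break
    out <- c(out, d)
  }
  out
}

#' Generate a synthetic cohort with planted trajectory labels
#'
#' Emulates the shape of a primary-care EHR dashboard export (prescription
#' records, encounter dates, demographics) for patients whose medication
#' trajectories follow known scenarios, so the full pipeline can be tested
#' with no patient data. Each patient starts therapy within the first year of
#' the analysis window, changes regimen once (at least 90 days from window
#' edges and, for lateral chains, between successive switches), and — except
#' in the discontinuation and ineligibility scenarios — keeps refilling into
#' the final 12 months. Encounters recur every 4-6 months, satisfying the
#' two-visit eligibility rule except in the planted-ineligible scenario.
#' Medication names are written in mixed brand/generic/suffixed forms so the
#' generated tables also exercise name normalization.
#'
#' Output is reproducible: the same seed yields byte-identical tables.
#'
#' @param n Number of patients (> 0).
#' @param mix Named numeric vector of scenario proportions (must sum to 1);
#'   `NULL` = uniform over the 14 core scenarios.
#' @param seed Integer random seed.
#' @param window Length-2 analysis window (Dates or `"YYYY-MM-DD"`); the
#'   default mirrors the documented analysis period 2014-05-15 to 2023-03-13.
#' @param extraction_end End of data extraction (default: window end).
#' @return An object of class `synthetic_cohort`: list with `records`,
#'   `encounters`, `patients`, `truth` data frames (the exact table dialects
#'   consumed by the classification pipeline) plus `window`,
#'   `extraction_end`, `seed`.
#' @export
generate_cohort <- function(n, mix = NULL, seed = 1L,
                            window = c("2014-05-15", "2023-03-13"),
                            extraction_end = NULL) {
  stopifnot(n > 0)
  window <- as.Date(window)
  extraction_end <- if (is.null(extraction_end)) window[2] else as.Date(extraction_end)
  catalog <- .scenario_catalog()
  if (is.null(mix)) {
    core <- synthetic_scenarios()
    mix <- stats::setNames(rep(1 / length(core), length(core)), core)
  }
  unknown <- setdiff(names(mix), names(catalog))
  if (length(unknown)) {
    stop("unknown scenario name(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(mix)) || any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
    stop("mix must be a named vector of non-negative proportions summing to 1",
         call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  scenarios <- sample(names(mix), n, replace = TRUE, prob = mix)
  rec_rows <- vector("list", n)
  enc_rows <- vector("list", n)
  pat_rows <- vector("list", n)
  truth_rows <- vector("list", n)

  for (i in seq_len(n)) {
    pid <- sprintf("P%05d", i)
    sc <- catalog[[scenarios[i]]]()
    age <- if (!is.null(sc$age)) sc$age else sample(25:85, 1)
    discontinued <- is.null(sc$B)

    t0 <- window[1] + sample(0:300, 1)
    tc <- if (discontinued) {
      # last prescription must predate the extraction end by well over a year
      t0 + sample(550:as.integer(extraction_end - 450 - t0), 1)
    } else {
      t0 + sample(550:as.integer(extraction_end - 550 - t0), 1)
    }
    last_rx_day <- extraction_end - sample(10:40, 1)

    phase_records <- function(regimen, from, to) {
      if (is.null(regimen) || from > to) return(NULL)
      do.call(rbind, lapply(seq_len(nrow(regimen)), function(j) {
        dates <- .refill_dates(from, to)
        data.frame(patient_id = pid, date = as.character(dates),
                   medication_name = regimen$written[j],
                   strength_amount = regimen$amount[j],
                   strength_unit = regimen$unit[j],
                   frequency_per_day = regimen$freq[j],
                   stringsAsFactors = FALSE)
      }))
    }
    recs <- if (!is.null(sc$M)) {
      # three-phase lateral chain: A -> M -> B with >= 90-day phase spans
      tm <- t0 + floor(as.numeric(tc - t0) / 2)
      rbind(phase_records(sc$A, t0, tm - 1), phase_records(sc$M, tm, tc - 1),
            phase_records(sc$B, tc, last_rx_day))
    } else if (discontinued) {
      phase_records(sc$A, t0, tc)
    } else {
      rbind(phase_records(sc$A, t0, tc - 1), phase_records(sc$B, tc, last_rx_day))
    }

    # lost-to-follow-up: encounters must all predate the last refill, which
    # falls within 120 days of the change point
    enc_to <- if (discontinued && !isTRUE(sc$keep_encounters)) tc - 150 else extraction_end - 20
    enc_dates <- .refill_dates(window[1] + sample(10:60, 1), enc_to, interval = c(120, 180))
    if (isTRUE(sc$single_visit)) enc_dates <- enc_dates[1]

    rec_rows[[i]] <- recs
    enc_rows[[i]] <- data.frame(patient_id = pid, date = as.character(enc_dates),
                                stringsAsFactors = FALSE)
    pat_rows[[i]] <- data.frame(patient_id = pid, age = age, stringsAsFactors = FALSE)
    truth_rows[[i]] <- data.frame(patient_id = pid, top_level = sc$truth[1],
                                  subtype = sc$truth[2], scenario = scenarios[i],
                                  stringsAsFactors = FALSE)
  }

  structure(
    list(records = do.call(rbind, rec_rows),
         encounters = do.call(rbind, enc_rows),
         patients = do.call(rbind, pat_rows),
         truth = do.call(rbind, truth_rows),
         window = window, extraction_end = extraction_end, seed = as.integer(seed)),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$truth), "patients,",
      nrow(x$records), "prescription records,",
      nrow(x$encounters), "encounters\n")
  print(table(x$truth$scenario))
  invisible(x)
}

#' Write a synthetic cohort as CSV tables
#'
#' Emits `records.csv`, `encounters.csv`, `patients.csv` (the input dialects
#' of the classification pipeline) and `truth.csv`
#' (`patient_id,top_level,subtype,scenario`).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(records = file.path(dir, "records.csv"),
             encounters = file.path(dir, "encounters.csv"),
             patients = file.path(dir, "patients.csv"),
             truth = file.path(dir, "truth.csv"))
  utils::write.csv(cohort$records, paths[["records"]], row.names = FALSE)
  utils::write.csv(cohort$encounters, paths[["encounters"]], row.names = FALSE)
  utils::write.csv(cohort$patients, paths[["patients"]], row.names = FALSE)
  utils::write.csv(cohort$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
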