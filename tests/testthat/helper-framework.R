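# Shared builders for snapshot/trajectory fixtures, built in code.

# one-drug-per-tier snapshot: 0 = absent
snap <- function(ins = 0, met = 0, nio = 0) {
  name <- character(); cat <- character(); tot <- numeric(); unit <- character()
  if (ins > 0) { name <- c(name, "insulin glargine"); cat <- c(cat, "INSULIN")
                 tot <- c(tot, ins); unit <- c(unit, "units") }
  if (met > 0) { name <- c(name, "metformin"); cat <- c(cat, "METFORMIN")
                 tot <- c(tot, met); unit <- c(unit, "mg") }
  if (nio > 0) { name <- c(name, "sitagliptin"); cat <- c(cat, "NON_INSULIN_OTHER")
                 tot <- c(tot, nio); unit <- c(unit, "mg") }
  regimen_snapshot(name, cat, tot, unit)
}

make_traj <- function(baseline, final, inferred = FALSE, med_runs = NULL,
                      n_oral_transitions = 0L) {
  if (is.null(med_runs)) {
    med_runs <- stats::setNames(rep(1L, nrow(baseline$members)),
                                baseline$members$canonical_name)
  }
  new_trajectory_summary(
    patient_id = "T1", baseline = baseline, final = final,
    n_interim_transitions = n_oral_transitions,
    n_interim_oral_transitions = n_oral_transitions,
    inferred_discontinuation = inferred, med_runs = med_runs
  )
}

# prescription history builder: events = list(list(drug, category, date,
# amount, unit, freq), ...)
make_history <- function(patient_id = "H1", age = 60, events = list(),
                         encounter_dates = character()) {
  rows <- lapply(events, function(e) {
    data.frame(
      date = as.Date(e$date), raw_name = e$drug, canonical_name = e$drug,
      category = e$category, strength_amount = e$amount,
      strength_unit = e$unit, frequency_per_day = e$freq,
      daily_total = e$amount * e$freq, dose_unit = e$unit,
      stringsAsFactors = FALSE
    )
  })
  records <- if (length(rows)) do.call(rbind, rows) else NULL
  encounters <- if (length(encounter_dates)) {
    data.frame(date = as.Date(encounter_dates), stringsAsFactors = FALSE)
  } else NULL
  patient_history(patient_id, age, records, encounters)
}

ev <- function(drug, category, date, amount, unit = "mg", freq = 1) {
  list(drug = drug, category = category, date = date, amount = amount,
       unit = unit, freq = freq)
}

met_ev <- function(date, amount = 500, freq = 2)
  ev("metformin", "METFORMIN", date, amount, "mg", freq)
ins_ev <- function(date, amount = 20, freq = 1)
  ev("insulin glargine", "INSULIN", date, amount, "units", freq)
sita_ev <- function(date, amount = 100, freq = 1)
  ev("sitagliptin", "NON_INSULIN_OTHER", date, amount, "mg", freq)
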