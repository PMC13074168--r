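#' Construct a patient history
#'
#' Bundles one patient's normalized prescription records and clinic
#' encounters. Records and encounters are sorted by date on construction, so
#' every downstream result is invariant to input row order.
#'
#' @param patient_id Scalar identifier.
#' @param age Age in years (may be `NA`; eligibility filtering will exclude).
#' @param records Data frame with columns `date` (Date), `raw_name`,
#'   `canonical_name`, `category`, `strength_amount`, `strength_unit`,
#'   `frequency_per_day`, `daily_total`, `dose_unit`.
#' @param encounters Data frame with column `date` (Date).
#' @return An object of class `patient_history`.
#' @export
patient_history <- function(patient_id, age = NA_real_,
                            records = NULL, encounters = NULL) {
  if (is.null(records)) {
    records <- data.frame(date = as.Date(character()), raw_name = character(),
                          canonical_name = character(), category = character(),
                          strength_amount = numeric(), strength_unit = character(),
                          frequency_per_day = numeric(), daily_total = numeric(),
                          dose_unit = character(), stringsAsFactors = FALSE)
  }
  if (is.null(encounters)) {
    encounters <- data.frame(date = as.Date(character()), stringsAsFactors = FALSE)
  }
  records$date <- as.Date(records$date)
  encounters$date <- as.Date(encounters$date)
  records <- records[order(records$date, records$canonical_name), , drop = FALSE]
  encounters <- encounters[order(encounters$date), , drop = FALSE]
  rownames(records) <- NULL
  rownames(encounters) <- NULL
  structure(
    list(patient_id = patient_id, age = as.numeric(age),
         records = records, encounters = encounters),
    class = "patient_history"
  )
}

#' Apply cohort eligibility criteria
#'
#' Retains patients aged 18 to 89 (inclusive) with at least two clinic
#' encounters dated inside the analysis window. Every exclusion is counted by
#' reason; a missing age excludes (reason `missing_age`) rather than erroring.
#'
#' @param histories List of `patient_history` objects.
#' @param window Length-2 Date vector `c(start, end)` of the analysis period.
#' @return List with `eligible` (the retained histories) and `exclusions`
#'   (data frame `patient_id`, `reason`).
#' @export
filter_eligible <- function(histories, window) {
  window <- as.Date(window)
  stopifnot(length(window) == 2L, !anyNA(window))
  reasons <- character(0)
  ids <- character(0)
  keep <- logical(length(histories))
  for (i in seq_along(histories)) {
    h <- histories[[i]]
    n_visits <- sum(h$encounters$date >= window[1] & h$encounters$date <= window[2])
    reason <- if (is.na(h$age)) "missing_age"
      else if (h$age < 18 || h$age > 89) "age_out_of_range"
      else if (n_visits < 2) "fewer_than_two_visits"
      else NA_character_
    if (is.na(reason)) {
      keep[i] <- TRUE
    } else {
      ids <- c(ids, as.character(h$patient_id))
      reasons <- c(reasons, reason)
    }
  }
  list(
    eligible = histories[keep],
    exclusions = data.frame(patient_id = ids, reason = reasons,
                            stringsAsFactors = FALSE)
  )
}

# One row per canonical medication active in [start, end) (or [start, end]
# when closed_end): the most recent record of that medication in the window
# defines its dose; a same-date duplicate resolves to the higher daily total
# (conservative against over-calling a dose reduction).
.regimen_snapshot <- function(records, start, end, closed_end = FALSE) {
  inside <- records$date >= start & (if (closed_end) records$date <= end
                                     else records$date < end)
  rows <- records[inside, , drop = FALSE]
  n_ties <- 0L
  if (nrow(rows)) {
    rows <- rows[order(rows$canonical_name, rows$date, rows$daily_total), , drop = FALSE]
    n_ties <- sum(duplicated(rows[, c("canonical_name", "date")]))
    rows <- rows[!duplicated(rows$canonical_name, fromLast = TRUE), , drop = FALSE]
    rownames(rows) <- NULL
  }
  structure(
    list(window = c(start = start, end = end),
         members = rows[, intersect(c("canonical_name", "category", "daily_total",
                                      "dose_unit"), names(rows)), drop = FALSE],
         n_same_day_ties = n_ties),
    class = "regimen_snapshot"
  )
}

#' Build a regimen snapshot directly
#'
#' Convenience constructor for tests, examples and grid enumeration: a
#' snapshot is the set of medications (one per canonical name) with their
#' total daily doses attributed to a reference window.
#'
#' @param canonical_name,category,daily_total,dose_unit Parallel vectors
#'   describing the members (zero-length for an empty regimen).
#' @return A `regimen_snapshot`.
#' @export
regimen_snapshot <- function(canonical_name = character(),
                             category = character(),
                             daily_total = numeric(),
                             dose_unit = character()) {
  stopifnot(!anyDuplicated(canonical_name),
            all(category %in% MED_CATEGORIES) || length(category) == 0)
  structure(
    list(window = NULL,
         members = data.frame(canonical_name = as.character(canonical_name),
                              category = as.character(category),
                              daily_total = as.numeric(daily_total),
                              dose_unit = as.character(dose_unit),
                              stringsAsFactors = FALSE),
         n_same_day_ties = 0L),
    class = "regimen_snapshot"
  )
}

#' @export
print.regimen_snapshot <- function(x, ...) {
  cat("<regimen_snapshot>", nrow(x$members), "medication(s)\n")
  if (nrow(x$members)) {
    with(x$members, cat(sprintf("  %s [%s]: %g %s/day\n",
                                canonical_name, category, daily_total, dose_unit)))
  }
  invisible(x)
}

# split one medication's record dates into prescribing runs: a gap longer
# than gap_days (annual-refill convention) ends a run; a later record starts
# a new one (a "restart")
.med_runs <- function(dates, gap_days) {
  if (!length(dates)) return(list())
  dates <- sort(unique(dates))
  breaks <- c(0L, which(diff(as.numeric(dates)) > gap_days), length(dates))
  lapply(seq_len(length(breaks) - 1L), function(k) {
    d <- dates[(breaks[k] + 1L):breaks[k + 1L]]
    c(start = d[1], end = d[length(d)])
  })
}

#' Infer discontinuation under the annual-refill policy
#'
#' In practices that require at least one visit per year for refills, a
#' patient with no prescription in the final 12 months of the data period who
#' nonetheless kept attending is taken to have had their medications
#' discontinued. The flag is `TRUE` iff the last medication record predates
#' `extraction_end` by more than `window_days` days AND at least one
#' encounter is dated after that last record (evidence the patient remained
#' active). Adding a later prescription can only clear the flag, never set it.
#'
#' @param history A `patient_history`.
#' @param extraction_end Date the data export ends.
#' @param window_days Length of the "final" period in days (default 365).
#' @return Logical scalar.
#' @export
detect_inferred_discontinuation <- function(history, extraction_end,
                                            window_days = 365) {
  stopifnot(inherits(history, "patient_history"))
  extraction_end <- as.Date(extraction_end)
  if (!nrow(history$records)) return(FALSE)
  last_rx <- max(history$records$date)
  last_rx < (extraction_end - window_days) &&
    any(history$encounters$date > last_rx)
}

#' Summarize a patient's medication trajectory
#'
#' Reduces a dated record history to the comparison the framework is built
#' on: the regimen in the first 12 months after the first diabetes-medication
#' record (baseline) versus the regimen in the last 12 months ending at the
#' extraction date (final), plus the interim transition count, per-drug
#' prescribing runs (for restart detection), and the inferred-discontinuation
#' flag. Within each window the most recent record of each medication defines
#' its dose, so a patient who "ended up on the same dosage" compares equal
#' even if doses moved in between.
#'
#' Intervals are half-open `[start, end)` except the final window, which is
#' closed at `extraction_end`.
#'
#' @param history A `patient_history`.
#' @param extraction_end Date the data export ends (anchors the final window).
#' @param window_days Window length in days (default 365, i.e. 12 months).
#' @return An object of class `trajectory_summary`.
#' @export
build_trajectory <- function(history, extraction_end, window_days = 365) {
  stopifnot(inherits(history, "patient_history"))
  extraction_end <- as.Date(extraction_end)
  recs <- history$records
  if (!nrow(recs)) {
    empty <- regimen_snapshot()
    return(new_trajectory_summary(
      patient_id = history$patient_id, baseline = empty, final = empty,
      n_interim_transitions = 0L, n_interim_oral_transitions = 0L,
      inferred_discontinuation = FALSE, med_runs = integer(0)
    ))
  }
  first_rx <- min(recs$date)
  baseline_end <- first_rx + window_days
  final_start <- extraction_end - window_days
  baseline <- .regimen_snapshot(recs, first_rx, baseline_end, closed_end = FALSE)
  final <- .regimen_snapshot(recs, final_start, extraction_end, closed_end = TRUE)

  drugs <- unique(recs$canonical_name)
  runs_per_drug <- stats::setNames(integer(length(drugs)), drugs)
  n_interim <- 0L
  n_interim_oral <- 0L
  for (d in drugs) {
    sub <- recs[recs$canonical_name == d, , drop = FALSE]
    runs <- .med_runs(sub$date, gap_days = window_days)
    runs_per_drug[[d]] <- length(runs)
    oral <- sub$category[1] != "INSULIN"
    for (r in runs) {
      # a start strictly after the baseline window, or a stop strictly before
      # the final window, is an interim add/stop event
      if (r[["start"]] >= baseline_end && r[["start"]] < final_start) {
        n_interim <- n_interim + 1L
        if (oral) n_interim_oral <- n_interim_oral + 1L
      }
      if (r[["end"]] >= baseline_end && r[["end"]] < final_start) {
        n_interim <- n_interim + 1L
        if (oral) n_interim_oral <- n_interim_oral + 1L
      }
    }
  }

  new_trajectory_summary(
    patient_id = history$patient_id,
    baseline = baseline, final = final,
    n_interim_transitions = n_interim,
    n_interim_oral_transitions = n_interim_oral,
    inferred_discontinuation =
      detect_inferred_discontinuation(history, extraction_end, window_days),
    med_runs = runs_per_drug
  )
}

#' Construct a trajectory summary from its parts
#'
#' Low-level constructor used by [build_trajectory()] and by tests that
#' enumerate baseline/final regimen pairs directly.
#'
#' @param patient_id Identifier.
#' @param baseline,final `regimen_snapshot` objects.
#' @param n_interim_transitions,n_interim_oral_transitions Counts of
#'   medication add/stop events between the two windows (all drugs / oral
#'   drugs only).
#' @param inferred_discontinuation Logical flag from the annual-refill rule.
#' @param med_runs Named integer vector: prescribing runs per canonical
#'   medication over the whole history (>1 means the drug was restarted after
#'   a gap longer than the window).
#' @return A `trajectory_summary`.
#' @export
new_trajectory_summary <- function(patient_id = NA_character_,
                                   baseline = regimen_snapshot(),
                                   final = regimen_snapshot(),
                                   n_interim_transitions = 0L,
                                   n_interim_oral_transitions = 0L,
                                   inferred_discontinuation = FALSE,
                                   med_runs = integer(0)) {
  stopifnot(inherits(baseline, "regimen_snapshot"),
            inherits(final, "regimen_snapshot"),
            n_interim_transitions >= 0)
  structure(
    list(patient_id = patient_id, baseline = baseline, final = final,
         n_interim_transitions = as.integer(n_interim_transitions),
         n_interim_oral_transitions = as.integer(n_interim_oral_transitions),
         inferred_discontinuation = isTRUE(inferred_discontinuation),
         med_runs = med_runs),
    class = "trajectory_summary"
  )
}

#' @export
print.trajectory_summary <- function(x, ...) {
  cat("<trajectory_summary> patient", as.character(x$patient_id), "\n")
  cat(" baseline:\n"); print(x$baseline)
  cat(" final:\n"); print(x$final)
  cat(" interim transitions:", x$n_interim_transitions,
      "| inferred discontinuation:", x$inferred_discontinuation, "\n")
  invisible(x)
}
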