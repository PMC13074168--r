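#' Run configuration for the classification pipeline
#'
#' @param records_path Prescription-records CSV
#'   (`patient_id,date,medication_name,strength_amount,strength_unit,frequency_per_day`).
#' @param encounters_path Encounters CSV (`patient_id,date`).
#' @param patients_path Optional demographics CSV (`patient_id,age`); patients
#'   absent from it are excluded with reason `missing_age`.
#' @param lexicon_path Optional lexicon CSV; `NULL` uses the bundled lexicon.
#' @param window Length-2 analysis window (defaults mirror the documented
#'   analysis period 2014-05-15 to 2023-03-13).
#' @param extraction_end End of data extraction (default: window end).
#' @param window_days Snapshot window length in days (default 365).
#' @param max_transitions Complexity threshold routed to review (default 4).
#' @param output_dir Where `cmd_classify()`/`run_classify()` writes its tables;
#'   `NULL` = return results without writing.
#' @param seed Seed (simulation only).
#' @return A list of class `run_config`.
#' @export
run_config <- function(records_path = NULL, encounters_path = NULL,
                       patients_path = NULL, lexicon_path = NULL,
                       window = c("2014-05-15", "2023-03-13"),
                       extraction_end = NULL, window_days = 365L,
                       max_transitions = 4L, output_dir = NULL, seed = 1L) {
  window <- as.Date(window)
  if (anyNA(window) || length(window) != 2L) {
    stop("window must be two parseable dates", call. = FALSE)
  }
  extraction_end <- if (is.null(extraction_end)) window[2] else as.Date(extraction_end)
  if (is.na(extraction_end)) stop("extraction_end is not a valid date", call. = FALSE)
  if (window_days <= 0) stop("window_days must be positive", call. = FALSE)
  structure(
    list(records_path = records_path, encounters_path = encounters_path,
         patients_path = patients_path, lexicon_path = lexicon_path,
         window = window, extraction_end = extraction_end,
         window_days = as.integer(window_days),
         max_transitions = as.integer(max_transitions),
         output_dir = output_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

.read_table <- function(path, required, date_cols = character(),
                        numeric_cols = character()) {
  if (is.null(path) || !file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("file ", path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in date_cols) {
    parsed <- as.Date(as.character(df[[col]]), format = "%Y-%m-%d")
    bad <- which(is.na(parsed) & !is.na(df[[col]]))
    if (length(bad)) {
      stop("file ", path, ", line ", bad[1] + 1L, ", column '", col,
           "': unparseable date '", df[[col]][bad[1]], "' (expected YYYY-MM-DD)",
           call. = FALSE)
    }
    df[[col]] <- parsed
  }
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(parsed) & !is.na(df[[col]]) & nzchar(trimws(df[[col]])))
    if (length(bad)) {
      stop("file ", path, ", line ", bad[1] + 1L, ", column '", col,
           "': not a number '", df[[col]][bad[1]], "'", call. = FALSE)
    }
    df[[col]] <- parsed
  }
  df
}

#' Read and normalize a prescription-records table
#'
#' Parses the records CSV, normalizes medication names against the lexicon,
#' splits fixed-dose combinations into components, computes daily doses, and
#' drops (with counts) unrecognized medications and records dated outside
#' the analysis window.
#'
#' @param path Records CSV path.
#' @param lexicon A `med_lexicon`.
#' @param window Length-2 Date analysis window.
#' @return List with `records` (normalized rows), `unrecognized` (data frame
#'   `raw,n` of dropped names), `n_out_of_window`, `n_unclear_split`.
#' @export
read_records <- function(path, lexicon, window) {
  df <- .read_table(
    path,
    required = c("patient_id", "date", "medication_name", "strength_amount",
                 "strength_unit", "frequency_per_day"),
    date_cols = "date",
    numeric_cols = c("strength_amount", "frequency_per_day")
  )
  window <- as.Date(window)
  out_of_window <- df$date < window[1] | df$date > window[2]
  n_out <- sum(out_of_window)
  df <- df[!out_of_window, , drop = FALSE]

  norm <- normalize_name(df$medication_name, lexicon)
  unrecognized <- norm$category == "UNRECOGNIZED"
  unrec_tab <- if (any(unrecognized)) {
    t <- sort(table(norm$raw[unrecognized]), decreasing = TRUE)
    data.frame(raw = names(t), n = as.integer(t), stringsAsFactors = FALSE)
  } else {
    data.frame(raw = character(), n = integer(), stringsAsFactors = FALSE)
  }

  df$raw_name <- df$medication_name
  df$canonical_name <- norm$canonical_name
  df$category <- norm$category
  df <- df[!unrecognized, , drop = FALSE]
  df <- expand_combination(df, lexicon)
  n_unclear_split <- sum(df$unclear_split)
  df$daily_total <- compute_daily_dose(df$strength_amount, df$frequency_per_day)
  df$dose_unit <- df$strength_unit
  rownames(df) <- NULL
  list(records = df, unrecognized = unrec_tab,
       n_out_of_window = n_out, n_unclear_split = n_unclear_split)
}

#' Assemble per-patient histories from normalized tables
#'
#' @param records Normalized records (from [read_records()]`$records`).
#' @param encounters Data frame `patient_id,date` (Date).
#' @param patients Optional data frame `patient_id,age`.
#' @return Named list of `patient_history` objects (every patient appearing
#'   in any table).
#' @export
assemble_histories <- function(records, encounters, patients = NULL) {
  ids <- unique(c(as.character(records$patient_id),
                  as.character(encounters$patient_id)))
  ids <- sort(ids)
  ages <- if (!is.null(patients)) {
    stats::setNames(as.numeric(patients$age), as.character(patients$patient_id))
  } else {
    stats::setNames(numeric(0), character(0))
  }
  out <- lapply(ids, function(id) {
    patient_history(
      patient_id = id,
      age = if (id %in% names(ages)) ages[[id]] else NA_real_,
      records = records[as.character(records$patient_id) == id, , drop = FALSE],
      encounters = encounters[as.character(encounters$patient_id) == id, , drop = FALSE]
    )
  })
  stats::setNames(out, ids)
}

#' Run the full classification pipeline
#'
#' Reads the input tables, normalizes and filters, classifies every eligible
#' patient, and (optionally) writes `classifications.csv`, `summary.csv`,
#' `exclusions.csv` and `unrecognized.csv` to `config$output_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `classifications`, `summary`, `exclusions`,
#'   `unrecognized`, `n_out_of_window`, `n_unclear_split`.
#' @export
run_classify <- function(config) {
  stopifnot(inherits(config, "run_config"))
  lexicon <- load_lexicon(config$lexicon_path)
  rec <- read_records(config$records_path, lexicon, config$window)
  enc <- .read_table(config$encounters_path, required = c("patient_id", "date"),
                     date_cols = "date")
  pat <- if (!is.null(config$patients_path)) {
    .read_table(config$patients_path, required = c("patient_id", "age"),
                numeric_cols = "age")
  } else NULL

  histories <- assemble_histories(rec$records, enc, pat)
  elig <- filter_eligible(histories, config$window)
  classifications <- classify_cohort(
    elig$eligible, extraction_end = config$extraction_end,
    window_days = config$window_days,
    policy = classifier_policy(config$max_transitions)
  )
  summary_tab <- summarize_classifications(classifications)

  result <- list(classifications = classifications, summary = summary_tab,
                 exclusions = elig$exclusions, unrecognized = rec$unrecognized,
                 n_out_of_window = rec$n_out_of_window,
                 n_unclear_split = rec$n_unclear_split)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(classifications,
                     file.path(config$output_dir, "classifications.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_tab, file.path(config$output_dir, "summary.csv"),
                     row.names = FALSE)
    utils::write.csv(elig$exclusions,
                     file.path(config$output_dir, "exclusions.csv"),
                     row.names = FALSE)
    utils::write.csv(rec$unrecognized,
                     file.path(config$output_dir, "unrecognized.csv"),
                     row.names = FALSE)
  }
  invisible(result)
}

#' Generate a synthetic cohort from a run configuration
#'
#' Thin wrapper over [generate_cohort()] + [write_cohort()] used by the
#' `simulate` CLI subcommand.
#'
#' @param config A [run_config()] (`seed`, `window`, `output_dir` are used).
#' @param n Number of patients.
#' @param mix Optional named scenario proportions (see [generate_cohort()]).
#' @return Invisibly, the `synthetic_cohort`.
#' @export
run_simulate <- function(config, n, mix = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(n = n, mix = mix, seed = config$seed,
                            window = config$window,
                            extraction_end = config$extraction_end)
  if (!is.null(config$output_dir)) write_cohort(cohort, config$output_dir)
  invisible(cohort)
}
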