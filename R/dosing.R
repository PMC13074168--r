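#' Daily dose of one prescription
#'
#' The standardization used throughout the framework: daily dose equals the
#' dose per administration multiplied by the number of administrations per
#' day. The product is exact, with no rounding; weekly-dosed injectables are
#' represented by a fractional frequency (e.g. 1/7 per day).
#'
#' @param amount Dose per administration (>= 0), in the medication's own unit
#'   (mg/mcg for oral and injectable non-insulin agents, units for insulin).
#' @param frequency_per_day Administrations per day (> 0); may be fractional.
#' @return `amount * frequency_per_day`, vectorized.
#' @examples
#' compute_daily_dose(500, 2) # 1000 mg/day
#' @export
compute_daily_dose <- function(amount, frequency_per_day) {
  amount <- as.numeric(amount)
  frequency_per_day <- as.numeric(frequency_per_day)
  if (any(is.na(amount)) || any(amount < 0)) {
    stop("dose amount must be a non-negative number", call. = FALSE)
  }
  if (any(is.na(frequency_per_day)) || any(frequency_per_day <= 0)) {
    stop("frequency_per_day must be a positive number", call. = FALSE)
  }
  amount * frequency_per_day
}

# unify mass units on mg; insulin units on "units"; NA when unknown
.normalize_unit <- function(unit) {
  u <- tolower(trimws(as.character(unit)))
  out <- rep(NA_character_, length(u))
  out[u %in% c("mg", "milligram", "milligrams")] <- "mg"
  out[u %in% c("mcg", "ug", "microgram", "micrograms")] <- "mcg"
  out[u %in% c("unit", "units", "u", "iu")] <- "units"
  out
}

.to_comparable <- function(amount, unit) {
  # mcg expressed as mg so mg/mcg doses of one drug are on a single scale
  ifelse(.normalize_unit(unit) == "mcg", amount / 1000, amount)
}

.comparable_unit <- function(unit) {
  u <- .normalize_unit(unit)
  ifelse(u == "mcg", "mg", u)
}

#' Total daily dose in a medication category
#'
#' Sums daily totals over the members of a regimen snapshot that belong to
#' one category. Insulin is summed in units (basal and bolus together, as a
#' total-units comparison); metformin in mg; mcg is converted to mg. If the
#' members of the category carry incomparable units the total cannot be
#' interpreted and the result is flagged not dose-comparable — dose-change
#' rules are then suppressed for that category while presence/absence rules
#' still apply.
#'
#' @param snapshot A `regimen_snapshot` (or its member data frame) with
#'   columns `canonical_name`, `category`, `daily_total`, `dose_unit`.
#' @param category One of `"INSULIN"`, `"METFORMIN"`, `"NON_INSULIN_OTHER"`.
#' @return List with `total` (numeric; 0 for an empty category) and
#'   `dose_comparable` (logical).
#' @export
category_daily_total <- function(snapshot, category) {
  members <- if (inherits(snapshot, "regimen_snapshot")) snapshot$members else snapshot
  category <- match.arg(category, MED_CATEGORIES)
  rows <- members[members$category == category, , drop = FALSE]
  if (!nrow(rows)) return(list(total = 0, dose_comparable = TRUE))
  units <- .comparable_unit(rows$dose_unit)
  comparable <- !anyNA(units) && length(unique(units)) == 1L
  if (category == "INSULIN") comparable <- comparable && all(units == "units")
  if (category == "METFORMIN") comparable <- comparable && all(units == "mg")
  total <- sum(.to_comparable(rows$daily_total, rows$dose_unit))
  list(total = if (comparable) total else NA_real_, dose_comparable = comparable)
}
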