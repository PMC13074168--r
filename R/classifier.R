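#' Deprescribing subtypes, in the framework's printed precedence order
#' @keywords internal
DEPRESCRIBING_SUBTYPES <- c(
  "INSULIN_DOSE_REDUCED",     # (1) total units of insulin decreased
  "INSULIN_TO_NONINSULIN",    # (2) insulin stopped, non-insulin/metformin started
  "INSULIN_DISCONTINUED",     # (3) all insulin discontinued
  "NONINSULIN_STOPPED",       # (4) a non-insulin, non-metformin agent stopped
  "NONINSULIN_DOSE_REDUCED",  # (5) same non-insulin agent, dose decreased
  "NONINSULIN_TO_METFORMIN",  # (6) switch/consolidation to metformin (only)
  "METFORMIN_STOPPED",        # (7) metformin stopped, not restarted
  "METFORMIN_DOSE_REDUCED"    # (8) total metformin dose decreased
)

ESCALATION_RULES <- c(
  "ESCALATION_INSULIN_DOSE_INCREASED",
  "ESCALATION_NONINSULIN_DOSE_INCREASED",
  "ESCALATION_METFORMIN_DOSE_INCREASED",
  "ESCALATION_TO_INSULIN",
  "ESCALATION_FROM_METFORMIN",
  "ESCALATION_AGENT_ADDED",
  "ESCALATION_THERAPY_INITIATED"
)

#' Classifier policy settings
#'
#' @param max_transitions Interim add/stop events among oral agents above
#'   which a trajectory with no net category change is routed to review
#'   (default 4).
#' @return A list of class `classifier_policy`.
#' @export
classifier_policy <- function(max_transitions = 4L) {
  stopifnot(max_transitions >= 0)
  structure(list(max_transitions = as.integer(max_transitions)),
            class = "classifier_policy")
}

# per-category view of a snapshot pair used by every rule predicate
.rule_context <- function(traj) {
  b <- traj$baseline$members
  f <- traj$final$members
  pick <- function(m, cat) m[m$category == cat, , drop = FALSE]
  b_ins <- pick(b, "INSULIN");  f_ins <- pick(f, "INSULIN")
  b_nio <- pick(b, "NON_INSULIN_OTHER"); f_nio <- pick(f, "NON_INSULIN_OTHER")

  ins_b_tot <- category_daily_total(traj$baseline, "INSULIN")
  ins_f_tot <- category_daily_total(traj$final, "INSULIN")
  met_b_tot <- category_daily_total(traj$baseline, "METFORMIN")
  met_f_tot <- category_daily_total(traj$final, "METFORMIN")

  list(
    b = b, f = f,
    has_ins_b = nrow(b_ins) > 0, has_ins_f = nrow(f_ins) > 0,
    has_met_b = "METFORMIN" %in% b$category, has_met_f = "METFORMIN" %in% f$category,
    b_nio = b_nio, f_nio = f_nio,
    stopped_nio = setdiff(b_nio$canonical_name, f_nio$canonical_name),
    new_nio = setdiff(f_nio$canonical_name, b_nio$canonical_name),
    ins_comparable = ins_b_tot$dose_comparable && ins_f_tot$dose_comparable,
    met_comparable = met_b_tot$dose_comparable && met_f_tot$dose_comparable,
    ins_b = ins_b_tot$total, ins_f = ins_f_tot$total,
    met_b = met_b_tot$total, met_f = met_f_tot$total
  )
}

# per-drug dose comparison within the non-insulin tier: each agent in its own
# units, never summed across agents
.nio_dose_changes <- function(ctx) {
  shared <- intersect(ctx$b_nio$canonical_name, ctx$f_nio$canonical_name)
  reduced <- increased <- FALSE
  for (d in shared) {
    bi <- ctx$b_nio[ctx$b_nio$canonical_name == d, ]
    fi <- ctx$f_nio[ctx$f_nio$canonical_name == d, ]
    ub <- .comparable_unit(bi$dose_unit); uf <- .comparable_unit(fi$dose_unit)
    if (is.na(ub) || is.na(uf) || ub != uf) next  # not dose-comparable: suppress
    db <- .to_comparable(bi$daily_total, bi$dose_unit)
    df <- .to_comparable(fi$daily_total, fi$dose_unit)
    if (df < db) reduced <- TRUE
    if (df > db) increased <- TRUE
  }
  list(reduced = reduced, increased = increased)
}

#' Evaluate the framework's rules on a trajectory
#'
#' Applies every deprescribing, escalation and lateral-change predicate to
#' the baseline/final snapshot pair and returns all that match. Rules are
#' pure predicates on the pair (plus the restart runs and the
#' inferred-discontinuation flag); dose-change rules are suppressed for a
#' category flagged not dose-comparable. The generic stop rule
#' (`NONINSULIN_STOPPED`) matches only a *pure* stop: a stop that is part of
#' a replacement by another non-insulin agent is a lateral switch, and a stop
#' that is part of a switch or consolidation to metformin belongs to
#' `NONINSULIN_TO_METFORMIN`.
#'
#' @param traj A `trajectory_summary`.
#' @return Character vector of matched rule labels (possibly empty).
#' @export
evaluate_rules <- function(traj) {
  stopifnot(inherits(traj, "trajectory_summary"))
  ctx <- .rule_context(traj)
  if (!nrow(ctx$b) && !nrow(ctx$f)) return(character(0))
  nio <- .nio_dose_changes(ctx)

  met_newly_started <- ctx$has_met_f && !ctx$has_met_b
  # "multiple meds + metformin changed to only metformin"
  consolidation <- ctx$has_met_b && ctx$has_met_f &&
    nrow(ctx$b_nio) > 0 && nrow(ctx$f_nio) == 0 && !ctx$has_ins_f
  met_drugs <- ctx$b$canonical_name[ctx$b$category == "METFORMIN"]
  met_runs <- if (any(met_drugs %in% names(traj$med_runs)))
    max(traj$med_runs[intersect(met_drugs, names(traj$med_runs))]) else 1L

  matched <- character(0)
  add <- function(m, lab) if (m) c(matched, lab) else matched

  ## -- deprescribing -------------------------------------------------------
  matched <- add(ctx$has_ins_b && ctx$has_ins_f && ctx$ins_comparable &&
                   ctx$ins_f < ctx$ins_b, "INSULIN_DOSE_REDUCED")
  matched <- add(ctx$has_ins_b && !ctx$has_ins_f &&
                   (length(ctx$new_nio) > 0 || met_newly_started),
                 "INSULIN_TO_NONINSULIN")
  matched <- add(ctx$has_ins_b && !ctx$has_ins_f, "INSULIN_DISCONTINUED")
  matched <- add(length(ctx$stopped_nio) > 0 && length(ctx$new_nio) == 0 &&
                   !met_newly_started && !consolidation, "NONINSULIN_STOPPED")
  matched <- add(nio$reduced, "NONINSULIN_DOSE_REDUCED")
  matched <- add((length(ctx$stopped_nio) > 0 && met_newly_started) || consolidation,
                 "NONINSULIN_TO_METFORMIN")
  matched <- add(ctx$has_met_b && !ctx$has_met_f && met_runs <= 1L,
                 "METFORMIN_STOPPED")
  matched <- add(ctx$has_met_b && ctx$has_met_f && ctx$met_comparable &&
                   ctx$met_f < ctx$met_b, "METFORMIN_DOSE_REDUCED")

  ## -- escalation (medication increase) ------------------------------------
  matched <- add(ctx$has_ins_b && ctx$has_ins_f && ctx$ins_comparable &&
                   ctx$ins_f > ctx$ins_b, "ESCALATION_INSULIN_DOSE_INCREASED")
  matched <- add(nio$increased, "ESCALATION_NONINSULIN_DOSE_INCREASED")
  matched <- add(ctx$has_met_b && ctx$has_met_f && ctx$met_comparable &&
                   ctx$met_f > ctx$met_b, "ESCALATION_METFORMIN_DOSE_INCREASED")
  matched <- add(ctx$has_ins_f && !ctx$has_ins_b && nrow(ctx$b) > 0,
                 "ESCALATION_TO_INSULIN")
  matched <- add(ctx$has_met_b && !ctx$has_ins_b && nrow(ctx$b_nio) == 0 &&
                   length(ctx$new_nio) > 0, "ESCALATION_FROM_METFORMIN")
  matched <- add(nrow(ctx$b) > 0 &&
                   length(setdiff(ctx$f$canonical_name, ctx$b$canonical_name)) > 0 &&
                   length(setdiff(ctx$b$canonical_name, ctx$f$canonical_name)) == 0,
                 "ESCALATION_AGENT_ADDED")
  matched <- add(nrow(ctx$b) == 0 && nrow(ctx$f) > 0,
                 "ESCALATION_THERAPY_INITIATED")

  ## -- lateral -------------------------------------------------------------
  matched <- add(length(ctx$stopped_nio) > 0 && length(ctx$new_nio) > 0,
                 "LATERAL_SWITCH")

  matched
}

.same_members <- function(b, f) {
  if (nrow(b) != nrow(f)) return(FALSE)
  if (!setequal(b$canonical_name, f$canonical_name)) return(FALSE)
  i <- match(b$canonical_name, f$canonical_name)
  ub <- .comparable_unit(b$dose_unit); uf <- .comparable_unit(f$dose_unit)[i]
  if (anyNA(ub) || anyNA(uf) || any(ub != uf)) return(FALSE)
  all(.to_comparable(b$daily_total, b$dose_unit) ==
        .to_comparable(f$daily_total, f$dose_unit)[i])
}

# Insulin and metformin compare at category level (total units / total mg),
# so a product switch at equal totals — glargine to NPH at the same units —
# is no change; other non-insulin agents compare per drug.
.regimens_equal <- function(bsnap, fsnap) {
  b <- bsnap$members; f <- fsnap$members
  for (cat in c("INSULIN", "METFORMIN")) {
    bt <- category_daily_total(bsnap, cat)
    ft <- category_daily_total(fsnap, cat)
    bi <- b[b$category == cat, , drop = FALSE]
    fi <- f[f$category == cat, , drop = FALSE]
    if (bt$dose_comparable && ft$dose_comparable) {
      if ((nrow(bi) > 0) != (nrow(fi) > 0)) return(FALSE)
      if (bt$total != ft$total) return(FALSE)
    } else if (!.same_members(bi, fi)) {
      return(FALSE)
    }
  }
  .same_members(b[b$category == "NON_INSULIN_OTHER", , drop = FALSE],
                f[f$category == "NON_INSULIN_OTHER", , drop = FALSE])
}

#' Classify one patient trajectory
#'
#' Resolves the matched rules into a single top-level label and subtype.
#' Resolution order: (a) inferred discontinuation with an empty final regimen
#' is deprescribing, subtyped by the highest tier discontinued (insulin >
#' non-insulin > metformin); (a2) an empty final regimen *without* evidence
#' the patient remained active (no encounter after the last prescription) is
#' unclear — nothing can be said about a patient lost to follow-up; (b)
#' deprescribing rules with no escalation → deprescribed, subtype = first
#' matched rule in the framework's printed order (1)-(8); (c) escalation only
#' → medication increase; (d) deprescribing and escalation both matched
#' (mixed signal) → unclear; (e) lateral switches only → lateral change; (f)
#' identical baseline and final regimens → no change (even if doses moved in
#' between); (g) more interim oral-agent transitions than
#' `policy$max_transitions` without a net category change → unclear; (h) any
#' remaining pattern → unclear. Every trajectory receives exactly one
#' classification.
#'
#' @param traj A `trajectory_summary`.
#' @param policy A [classifier_policy()].
#' @return An object of class `deprescribing_classification`: list with
#'   `patient_id`, `top_level` (`DEPRESCRIBED`, `NOT_DEPRESCRIBED`,
#'   `UNCLEAR`), `subtype`, `all_matched_rules`, `evidence` (character lines).
#' @export
classify_patient <- function(traj, policy = classifier_policy()) {
  stopifnot(inherits(traj, "trajectory_summary"))
  matched <- evaluate_rules(traj)
  depr <- intersect(DEPRESCRIBING_SUBTYPES, matched)
  esc <- intersect(ESCALATION_RULES, matched)
  lateral <- "LATERAL_SWITCH" %in% matched
  b <- traj$baseline$members
  f <- traj$final$members
  evidence <- c(
    sprintf("baseline regimen: %s", .describe_members(b)),
    sprintf("final regimen: %s", .describe_members(f)),
    sprintf("matched rules: %s",
            if (length(matched)) paste(matched, collapse = ", ") else "none")
  )
  out <- function(top, sub, why) {
    structure(list(patient_id = traj$patient_id, top_level = top, subtype = sub,
                   all_matched_rules = matched,
                   evidence = c(evidence, why)),
              class = "deprescribing_classification")
  }

  if (nrow(f) == 0 && nrow(b) > 0) {
    if (traj$inferred_discontinuation) {                                 # (a)
      sub <- if ("INSULIN" %in% b$category) "INSULIN_DISCONTINUED"
        else if ("NON_INSULIN_OTHER" %in% b$category) "NONINSULIN_STOPPED"
        else "METFORMIN_STOPPED"
      return(out("DEPRESCRIBED", sub,
                 "no prescription in final 12 months with a later encounter: discontinuation inferred under annual-refill policy"))
    }
    return(out("UNCLEAR", "NEEDS_REVIEW",                                # (a2)
               "no prescription in final 12 months and no encounter after last prescription: lost to follow-up, insufficient evidence"))
  }
  if (length(depr) && !length(esc)) {                                    # (b)
    sub <- DEPRESCRIBING_SUBTYPES[match(TRUE, DEPRESCRIBING_SUBTYPES %in% depr)]
    return(out("DEPRESCRIBED", sub,
               sprintf("deprescribing rule(s) matched without escalation; subtype by framework order: %s", sub)))
  }
  if (length(esc) && !length(depr)) {                                    # (c)
    return(out("NOT_DEPRESCRIBED", "MEDICATION_INCREASE",
               "escalation matched without any deprescribing rule"))
  }
  if (length(esc) && length(depr)) {                                     # (d)
    return(out("UNCLEAR", "NEEDS_REVIEW",
               "mixed signal: deprescribing and escalation both matched; no cross-category netting is defined"))
  }
  if (lateral) {                                                         # (e)
    return(out("NOT_DEPRESCRIBED", "LATERAL_CHANGE",
               "transition(s) between non-insulin, non-metformin agents; treated as equivalent in intensity"))
  }
  if (.regimens_equal(traj$baseline, traj$final)) {                      # (f)
    return(out("NOT_DEPRESCRIBED", "NO_CHANGE",
               "same medications and doses in first and last 12 months (interim changes, if any, disregarded)"))
  }
  if (traj$n_interim_oral_transitions > policy$max_transitions) {        # (g)
    return(out("UNCLEAR", "NEEDS_REVIEW",
               sprintf("complex trajectory: %d interim oral-agent transitions exceed policy maximum %d",
                       traj$n_interim_oral_transitions, policy$max_transitions)))
  }
  out("UNCLEAR", "NEEDS_REVIEW",                                         # (h)
      "regimens differ but no framework rule applies; flagged for comprehensive record review")
}

.describe_members <- function(m) {
  if (!nrow(m)) return("(none)")
  paste(sprintf("%s %g %s/day", m$canonical_name, m$daily_total, m$dose_unit),
        collapse = "; ")
}

#' @export
print.deprescribing_classification <- function(x, ...) {
  cat("<classification> patient", as.character(x$patient_id), "\n")
  cat("  ", x$top_level, "/", x$subtype, "\n")
  for (e in x$evidence) cat("   -", e, "\n")
  invisible(x)
}

#' Classify a cohort of patient histories
#'
#' Builds a trajectory and a classification for each history and returns one
#' row per patient.
#'
#' @param histories List of `patient_history` objects.
#' @param extraction_end Date the data export ends.
#' @param window_days Snapshot window length in days (default 365).
#' @param policy A [classifier_policy()].
#' @return Data frame `patient_id, top_level, subtype, matched_rules,
#'   evidence` (rules and evidence collapsed with `"; "`).
#' @export
classify_cohort <- function(histories, extraction_end, window_days = 365,
                            policy = classifier_policy()) {
  rows <- lapply(histories, function(h) {
    traj <- build_trajectory(h, extraction_end, window_days)
    cl <- classify_patient(traj, policy)
    data.frame(patient_id = as.character(cl$patient_id),
               top_level = cl$top_level, subtype = cl$subtype,
               matched_rules = paste(cl$all_matched_rules, collapse = "; "),
               evidence = paste(cl$evidence, collapse = " | "),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(res)) {
    res <- data.frame(patient_id = character(), top_level = character(),
                      subtype = character(), matched_rules = character(),
                      evidence = character(), stringsAsFactors = FALSE)
  }
  res
}

#' Tabulate classification counts
#'
#' @param classifications Data frame from [classify_cohort()].
#' @return Data frame `top_level, subtype, n`, ordered with deprescribing
#'   subtypes first in framework order.
#' @export
summarize_classifications <- function(classifications) {
  lev <- c(DEPRESCRIBING_SUBTYPES, "LATERAL_CHANGE", "MEDICATION_INCREASE",
           "NO_CHANGE", "NEEDS_REVIEW")
  tab <- table(factor(classifications$subtype, levels = lev))
  top <- c(rep("DEPRESCRIBED", length(DEPRESCRIBING_SUBTYPES)),
           rep("NOT_DEPRESCRIBED", 3L), "UNCLEAR")
  data.frame(top_level = top, subtype = lev, n = as.integer(tab),
             stringsAsFactors = FALSE)
}
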