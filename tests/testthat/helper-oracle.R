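# Independent transcription of the published category definitions, used as
# the brute-force oracle for grid enumeration. Deliberately written as a flat
# decision procedure over one-drug-per-tier regimen pairs (insulin units/day,
# metformin mg/day, one non-insulin agent mg/day; 0 = absent), separate from
# the engine's rule/resolution machinery. With a single non-insulin agent a
# lateral switch cannot occur on this grid; lateral behaviour is covered by
# dedicated spot tests.
oracle_classify <- function(b_ins, f_ins, b_met, f_met, b_nio, f_nio,
                            inferred_disc = FALSE) {
  b_empty <- b_ins == 0 && b_met == 0 && b_nio == 0
  f_empty <- f_ins == 0 && f_met == 0 && f_nio == 0

  if (f_empty && !b_empty) {
    if (inferred_disc) {
      sub <- if (b_ins > 0) "INSULIN_DISCONTINUED"
        else if (b_nio > 0) "NONINSULIN_STOPPED"
        else "METFORMIN_STOPPED"
      return(c("DEPRESCRIBED", sub))
    }
    return(c("UNCLEAR", "NEEDS_REVIEW"))
  }

  depr <- character(0)
  # insulin tier: total units decreased / switched away / discontinued
  if (b_ins > 0 && f_ins > 0 && f_ins < b_ins) depr <- c(depr, "INSULIN_DOSE_REDUCED")
  if (b_ins > 0 && f_ins == 0 &&
      ((f_nio > 0 && b_nio == 0) || (f_met > 0 && b_met == 0)))
    depr <- c(depr, "INSULIN_TO_NONINSULIN")
  if (b_ins > 0 && f_ins == 0) depr <- c(depr, "INSULIN_DISCONTINUED")
  # non-insulin tier: a stop that is a switch to metformin, or a
  # multiple-meds-plus-metformin consolidation to metformin only, is the
  # to-metformin category, not a plain stop
  switch_to_met <- b_nio > 0 && f_nio == 0 && f_met > 0 && b_met == 0
  consolidation <- b_nio > 0 && f_nio == 0 && b_met > 0 && f_met > 0 && f_ins == 0
  if (b_nio > 0 && f_nio == 0 && !switch_to_met && !consolidation)
    depr <- c(depr, "NONINSULIN_STOPPED")
  if (b_nio > 0 && f_nio > 0 && f_nio < b_nio) depr <- c(depr, "NONINSULIN_DOSE_REDUCED")
  if (switch_to_met || consolidation) depr <- c(depr, "NONINSULIN_TO_METFORMIN")
  # metformin tier (grid has no restarts)
  if (b_met > 0 && f_met == 0) depr <- c(depr, "METFORMIN_STOPPED")
  if (b_met > 0 && f_met > 0 && f_met < b_met) depr <- c(depr, "METFORMIN_DOSE_REDUCED")

  esc <- FALSE
  if (b_ins > 0 && f_ins > b_ins) esc <- TRUE                 # more insulin units
  if (b_nio > 0 && f_nio > b_nio) esc <- TRUE                 # same agent, higher dose
  if (b_met > 0 && f_met > b_met) esc <- TRUE                 # more metformin
  if (b_ins == 0 && f_ins > 0 && !b_empty) esc <- TRUE        # moved up to insulin
  if (b_ins == 0 && b_nio == 0 && b_met > 0 && f_nio > 0) esc <- TRUE # up from metformin
  added <- (b_ins == 0 || f_ins > 0) && (b_met == 0 || f_met > 0) &&
    (b_nio == 0 || f_nio > 0) &&
    ((b_ins == 0 && f_ins > 0) || (b_met == 0 && f_met > 0) ||
       (b_nio == 0 && f_nio > 0))
  if (!b_empty && added) esc <- TRUE                          # agent added on top
  if (b_empty && !f_empty) esc <- TRUE                        # therapy initiated

  if (length(depr) && !esc) {
    order8 <- c("INSULIN_DOSE_REDUCED", "INSULIN_TO_NONINSULIN",
                "INSULIN_DISCONTINUED", "NONINSULIN_STOPPED",
                "NONINSULIN_DOSE_REDUCED", "NONINSULIN_TO_METFORMIN",
                "METFORMIN_STOPPED", "METFORMIN_DOSE_REDUCED")
    return(c("DEPRESCRIBED", order8[order8 %in% depr][1]))
  }
  if (esc && !length(depr)) return(c("NOT_DEPRESCRIBED", "MEDICATION_INCREASE"))
  if (esc && length(depr)) return(c("UNCLEAR", "NEEDS_REVIEW"))
  if (b_ins == f_ins && b_met == f_met && b_nio == f_nio)
    return(c("NOT_DEPRESCRIBED", "NO_CHANGE"))
  c("UNCLEAR", "NEEDS_REVIEW")
}

# all (baseline, final) pairs over the 3-medication, 3-dose-level grid
# (plus absence): 64 x 64 = 4096 pairs
grid_levels <- list(ins = c(0, 10, 20, 40), met = c(0, 500, 1000, 2000),
                    nio = c(0, 25, 50, 100))

enumerate_grid_pairs <- function() {
  one <- expand.grid(ins = grid_levels$ins, met = grid_levels$met,
                     nio = grid_levels$nio)
  b <- one[rep(seq_len(nrow(one)), each = nrow(one)), ]
  f <- one[rep(seq_len(nrow(one)), times = nrow(one)), ]
  names(b) <- paste0("b_", names(b)); names(f) <- paste0("f_", names(f))
  cbind(b, f)
}
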