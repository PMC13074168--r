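#' @keywords internal
MED_CATEGORIES <- c("INSULIN", "METFORMIN", "NON_INSULIN_OTHER")

# tokens that may trail a written medication name without changing its identity
.SUFFIX_TOKEN_RE <- paste0(
  "^(",
  "[0-9]+([./-][0-9]+)*",                                  # 500, 50-500, 0.5, 70/30
  "|[0-9]+([./-][0-9]+)*(mg|mcg|g|ml|unit|units|iu|u)",    # 500mg, 10u
  "|mg|mcg|g|ml|unit|units|iu|u|u/ml|units/ml",
  "|tab|tabs|tablet|tablets|cap|caps|capsule|capsules",
  "|pen|pens|vial|vials|cartridge|kwikpen|flexpen|flextouch|solostar",
  "|soln|solution|susp|suspension|inj|injection|injectable|subcutaneous|sc|oral",
  "|xr|er|sr|xl|hcl|hydrochloride|daily|weekly",
  ")$"
)

#' Load a diabetes-medication lexicon
#'
#' Reads a delimited lexicon table mapping free-text medication names (brand
#' names, abbreviations, spelling variants) to canonical generic names, each
#' assigned to exactly one of the three intensity tiers used by the
#' classification framework: `INSULIN`, `METFORMIN`, or `NON_INSULIN_OTHER`.
#' Fixed-dose combination products list their `components` (pipe-separated
#' canonical names) and per-administration `component_strengths` so they can be
#' split into per-component exposure records.
#'
#' The lexicon is deliberately data, not code: sites can extend the bundled
#' table (a stand-in compiled from public US brand/generic names, not a
#' reproduction of any study drug list) with local abbreviations.
#'
#' @param path Path to a CSV with header
#'   `canonical_name,category,synonyms,components,component_strengths`
#'   (synonyms/components/strengths pipe-separated within the cell). `NULL`
#'   loads the lexicon bundled with the package.
#' @return An object of class `med_lexicon`: a list with `entries`
#'   (data frame, one row per canonical medication) and `lookup` (named
#'   character vector mapping every normalized synonym to a canonical name).
#' @examples
#' lex <- load_lexicon()
#' normalize_name("METFORMIN 500 MG TAB", lex)
#' @export
load_lexicon <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "diabetes_lexicon.csv", package = "deprescribr")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("lexicon file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("canonical_name", "category", "synonyms", "components", "component_strengths")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("lexicon table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  raw$canonical_name <- tolower(trimws(raw$canonical_name))
  raw$category <- trimws(raw$category)
  if (any(!nzchar(raw$canonical_name))) {
    stop("lexicon row without canonical_name", call. = FALSE)
  }
  bad_cat <- !(raw$category %in% MED_CATEGORIES)
  if (any(bad_cat)) {
    stop("unknown category token(s) ",
         paste(sQuote(unique(raw$category[bad_cat])), collapse = ", "),
         " in lexicon; allowed: ", paste(MED_CATEGORIES, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(raw$canonical_name)) {
    dup <- unique(raw$canonical_name[duplicated(raw$canonical_name)])
    stop("duplicate canonical_name in lexicon: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }

  split_pipe <- function(x) {
    out <- strsplit(x, "|", fixed = TRUE)
    lapply(out, function(v) {
      v <- tolower(trimws(v))
      v[nzchar(v)]
    })
  }
  syn_list <- split_pipe(raw$synonyms)
  comp_list <- split_pipe(raw$components)
  strength_list <- split_pipe(raw$component_strengths)

  # every canonical name is also a lookup key for itself
  keys <- mapply(function(canon, syns) unique(c(canon, syns)),
                 raw$canonical_name, syn_list, SIMPLIFY = FALSE)
  lookup <- stats::setNames(
    rep(raw$canonical_name, lengths(keys)),
    unlist(keys, use.names = FALSE)
  )
  if (anyDuplicated(names(lookup))) {
    dup_syn <- unique(names(lookup)[duplicated(names(lookup))])
    owners <- vapply(dup_syn, function(s) {
      paste(unique(lookup[names(lookup) == s]), collapse = " and ")
    }, character(1))
    stop("synonym(s) mapped to more than one lexicon entry: ",
         paste(sprintf("'%s' (%s)", dup_syn, owners), collapse = "; "),
         call. = FALSE)
  }

  # combination components must resolve to non-combination entries
  is_combo <- lengths(comp_list) > 0
  for (i in which(is_combo)) {
    comps <- comp_list[[i]]
    unknown <- setdiff(comps, raw$canonical_name)
    if (length(unknown)) {
      stop("combination '", raw$canonical_name[i],
           "' has unresolvable component(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    nested <- comps[lengths(comp_list[match(comps, raw$canonical_name)]) > 0]
    if (length(nested)) {
      stop("combination '", raw$canonical_name[i],
           "' has combination component(s): ", paste(nested, collapse = ", "),
           call. = FALSE)
    }
    ns <- length(strength_list[[i]])
    if (ns > 0 && ns != length(comps)) {
      stop("combination '", raw$canonical_name[i],
           "' lists ", length(comps), " components but ", ns, " strengths",
           call. = FALSE)
    }
  }

  entries <- data.frame(
    canonical_name = raw$canonical_name,
    category = raw$category,
    is_combination = is_combo,
    stringsAsFactors = FALSE
  )
  entries$synonyms <- syn_list
  entries$components <- comp_list
  entries$component_strengths <- lapply(strength_list, as.numeric)

  structure(
    list(entries = entries, lookup = lookup),
    class = "med_lexicon"
  )
}

#' @export
print.med_lexicon <- function(x, ...) {
  tab <- table(x$entries$category)
  cat("<med_lexicon> ", nrow(x$entries), " medications, ",
      length(x$lookup), " recognized names\n", sep = "")
  for (cat_name in MED_CATEGORIES) {
    cat("  ", cat_name, ": ", if (cat_name %in% names(tab)) tab[[cat_name]] else 0L,
        "\n", sep = "")
  }
  invisible(x)
}

.clean_med_string <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

.match_one_name <- function(clean, lookup) {
  if (!is.na(clean) && clean %in% names(lookup)) return(lookup[[clean]])
  tokens <- strsplit(clean, " ", fixed = TRUE)[[1]]
  # peel dose/form suffix tokens from the right until the remainder matches
  while (length(tokens) > 1 && grepl(.SUFFIX_TOKEN_RE, tokens[length(tokens)])) {
    tokens <- tokens[-length(tokens)]
    cand <- paste(tokens, collapse = " ")
    if (cand %in% names(lookup)) return(lookup[[cand]])
  }
  NA_character_
}

#' Normalize free-text medication names
#'
#' Matches written medication names against a lexicon, case-insensitively,
#' ignoring surrounding whitespace and any trailing strength/form suffix
#' (e.g. `"METFORMIN 500 MG TAB"` resolves to `"metformin"`). Names that do
#' not match any lexicon entry are returned as unrecognized (category
#' `"UNRECOGNIZED"`, canonical name `NA`) rather than raising, so that
#' non-diabetes drugs in a real export can be counted and set aside.
#'
#' @param raw Character vector of medication names as written.
#' @param lexicon A `med_lexicon` from [load_lexicon()].
#' @return Data frame with columns `raw`, `canonical_name`, `category`
#'   (one row per input name).
#' @export
normalize_name <- function(raw, lexicon) {
  stopifnot(inherits(lexicon, "med_lexicon"))
  if (length(raw) == 0) {
    return(data.frame(raw = character(), canonical_name = character(),
                      category = character(), stringsAsFactors = FALSE))
  }
  raw <- as.character(raw)
  if (any(is.na(raw)) || any(!nzchar(trimws(raw)))) {
    stop("medication name must be a non-empty string", call. = FALSE)
  }
  clean <- .clean_med_string(raw)
  canonical <- vapply(clean, .match_one_name, character(1),
                      lookup = lexicon$lookup, USE.NAMES = FALSE)
  category <- ifelse(
    is.na(canonical), "UNRECOGNIZED",
    lexicon$entries$category[match(canonical, lexicon$entries$canonical_name)]
  )
  data.frame(raw = raw, canonical_name = canonical, category = category,
             stringsAsFactors = FALSE)
}

#' Split fixed-dose combination records into component records
#'
#' The classification rules operate on the three intensity tiers, so a
#' metformin-containing combination must contribute to both the metformin and
#' the non-insulin regimen. Combination records are split into one record per
#' component; per-component strengths are taken from a `X-Y` pattern in the
#' written name when present (e.g. `"sitagliptin-metformin 50-500"`),
#' otherwise from the lexicon's encoded `component_strengths`. A combination
#' whose split cannot be determined is passed through unchanged with
#' `unclear_split = TRUE` rather than silently dropped. Non-combination
#' records pass through as-is.
#'
#' @param records Data frame of normalized prescription records with columns
#'   `canonical_name`, `category`, `raw_name`, `strength_amount`,
#'   `strength_unit`, `frequency_per_day` (plus any others, preserved).
#' @param lexicon A `med_lexicon`.
#' @return The records data frame with combinations expanded and a logical
#'   `unclear_split` column.
#' @export
expand_combination <- function(records, lexicon) {
  stopifnot(inherits(lexicon, "med_lexicon"))
  if (!nrow(records)) {
    records$unclear_split <- logical(0)
    return(records)
  }
  if (!"unclear_split" %in% names(records)) records$unclear_split <- FALSE
  ent <- lexicon$entries
  idx <- match(records$canonical_name, ent$canonical_name)
  combo_rows <- which(!is.na(idx) & ent$is_combination[idx])
  if (!length(combo_rows)) return(records)

  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    if (!(i %in% combo_rows)) {
      out[[i]] <- records[i, , drop = FALSE]
      next
    }
    e <- idx[i]
    comps <- ent$components[[e]]
    # strengths written into the name ("50-500") win over lexicon defaults
    m <- regmatches(records$raw_name[i],
                    regexpr("[0-9]+(\\.[0-9]+)?(-[0-9]+(\\.[0-9]+)?)+",
                            records$raw_name[i]))
    strengths <- if (length(m)) as.numeric(strsplit(m, "-", fixed = TRUE)[[1]]) else
      ent$component_strengths[[e]]
    if (length(strengths) != length(comps) || any(is.na(strengths))) {
      row <- records[i, , drop = FALSE]
      row$unclear_split <- TRUE
      out[[i]] <- row
      next
    }
    reps <- records[rep(i, length(comps)), , drop = FALSE]
    reps$canonical_name <- comps
    reps$category <- ent$category[match(comps, ent$canonical_name)]
    reps$strength_amount <- strengths
    out[[i]] <- reps
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
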