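# Domain types for discordant-review cases. All containers are validated S3
# lists; enum fields reject out-of-vocabulary values and "unknown" is always an
# explicit level, never an empty string.

yn_unknown_levels <- c("yes", "no", "unknown")
language_levels <- c("none", "restricted", "unknown")
pubstatus_levels <- c("published_only", "includes_unpublished", "unknown")
robis_levels <- c("low_risk", "high_risk", "unknown")
benefit_levels <- c("lower_better", "higher_better")
measure_levels <- c("RR", "OR", "MD", "SMD")
tool_levels <- c("AMSTAR", "AMSTAR2", "OXMAN_GUYATT", "ROBIS")
step_levels <- c("A", "B", "C", "D", "E", "F", "G", "H", "I")
terminal_steps <- c("B", "E", "F", "H", "I")
extraction_levels <- c("duplicate", "single", "unknown")

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_field <- function(field, msg) {
  stop(sprintf("invalid field `%s`: %s", field, msg), call. = FALSE)
}

check_enum <- function(value, levels, field) {
  value <- as.character(value)
  if (length(value) != 1L || is.na(value) || !value %in% levels) {
    abort_field(field, sprintf(
      "must be one of %s, got %s",
      paste(sQuote(levels), collapse = ", "),
      sQuote(paste(value, collapse = "/"))
    ))
  }
  value
}

check_flag <- function(value, field) {
  if (length(value) != 1L || !is.logical(value) || is.na(value)) {
    abort_field(field, "must be TRUE or FALSE")
  }
  value
}

check_scalar_number <- function(value, field, allow_na = FALSE) {
  if (allow_na && (is.null(value) || (length(value) == 1L && is.na(value)))) {
    return(NA_real_)
  }
  if (length(value) != 1L || !is.numeric(value) || is.na(value)) {
    abort_field(field, "must be a single number")
  }
  as.numeric(value)
}

check_terms <- function(terms, field) {
  if (is.null(terms)) return(character())
  terms <- as.character(terms)
  terms <- terms[!is.na(terms) & nzchar(terms)]
  unique(tolower(trimws(terms)))
}

#' PICO frame
#'
#' A population / intervention / comparator / outcome description of a review
#' question. Each element carries free text plus an optional normalized term
#' list used for computed eligibility-criteria comparison (Step G).
#'
#' @param population,intervention,comparator,outcome Free-text descriptions.
#' @param population_terms,intervention_terms,comparator_terms,outcome_terms
#'   Optional character vectors of normalized terms.
#' @return An object of class `pico_frame`.
#' @export
pico_frame <- function(population = "", intervention, comparator = "",
                       outcome,
                       population_terms = NULL, intervention_terms = NULL,
                       comparator_terms = NULL, outcome_terms = NULL) {
  intervention <- as.character(intervention)
  outcome <- as.character(outcome)
  if (!nzchar(intervention)) abort_field("intervention", "must be non-empty")
  if (!nzchar(outcome)) abort_field("outcome", "must be non-empty")
  structure(list(
    population = as.character(population),
    intervention = intervention,
    comparator = as.character(comparator),
    outcome = outcome,
    population_terms = check_terms(population_terms, "population_terms"),
    intervention_terms = check_terms(intervention_terms, "intervention_terms"),
    comparator_terms = check_terms(comparator_terms, "comparator_terms"),
    outcome_terms = check_terms(outcome_terms, "outcome_terms")
  ), class = "pico_frame")
}

#' Normalize a trial or review label to a stable identifier
#'
#' Lowercases, strips punctuation, drops "et al." tokens, and joins the
#' remaining tokens with hyphens, yielding `firstauthor-year` style
#' identifiers. The transformation is idempotent.
#'
#' @param raw_label Character vector of labels such as `"Feng 2015"`.
#' @return Character vector of normalized identifiers.
#' @examples
#' normalize_trial_id("FENG, 2015")
#' @export
normalize_trial_id <- function(raw_label) {
  if (length(raw_label) == 0L) return(character())
  raw_label <- as.character(raw_label)
  if (any(is.na(raw_label)) || any(!nzchar(trimws(raw_label)))) {
    stop("labels must be non-empty strings", call. = FALSE)
  }
  vapply(raw_label, function(x) {
    x <- tolower(x)
    x <- gsub("[^a-z0-9]+", " ", x)
    tokens <- strsplit(trimws(x), " +")[[1]]
    tokens <- tokens[!tokens %in% c("et", "al")]
    if (length(tokens) == 0L) {
      stop("label reduces to nothing after normalization", call. = FALSE)
    }
    paste(tokens, collapse = "-")
  }, character(1), USE.NAMES = FALSE)
}

#' Trial roster
#'
#' The set of randomized trials included in a review, held as normalized
#' unique identifiers. Labels that normalize to the same identifier are
#' rejected (flagged) rather than merged silently.
#'
#' @param trial_ids Character vector of trial labels or identifiers.
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(trial_ids = character()) {
  ids <- normalize_trial_id(trial_ids)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf("trial identifier collision after normalization: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  structure(list(trial_ids = sort(ids)), class = "trial_set")
}

#' Search profile of a systematic review
#'
#' Records the search-comprehensiveness metadata the Jadad algorithm consults
#' at Steps H and I. All categorical fields use explicit `"unknown"` values.
#'
#' @param databases Character vector of database names searched.
#' @param grey_literature,duplicate_independent_screening yes/no/unknown.
#' @param last_search_date ISO-8601 date string or `"unknown"`.
#' @param language_restriction none/restricted/unknown.
#' @param publication_status_scope published_only/includes_unpublished/unknown.
#' @param ipd_analysis yes/no — whether an individual-patient-data
#'   meta-analysis was performed.
#' @return An object of class `search_profile`.
#' @export
search_profile <- function(databases = character(),
                           grey_literature = "unknown",
                           last_search_date = "unknown",
                           duplicate_independent_screening = "unknown",
                           language_restriction = "unknown",
                           publication_status_scope = "unknown",
                           ipd_analysis = "no") {
  databases <- unique(as.character(databases))
  databases <- databases[nzchar(databases)]
  last_search_date <- as.character(last_search_date)
  if (!identical(last_search_date, "unknown")) {
    parsed <- tryCatch(as.Date(last_search_date),
                       error = function(e) as.Date(NA))
    if (is.na(parsed)) {
      abort_field("last_search_date", "must be an ISO-8601 date or 'unknown'")
    }
    last_search_date <- format(parsed)
  }
  structure(list(
    databases = databases,
    n_databases = length(databases),
    grey_literature = check_enum(grey_literature, yn_unknown_levels,
                                 "grey_literature"),
    last_search_date = last_search_date,
    duplicate_independent_screening =
      check_enum(duplicate_independent_screening, yn_unknown_levels,
                 "duplicate_independent_screening"),
    language_restriction = check_enum(language_restriction, language_levels,
                                      "language_restriction"),
    publication_status_scope = check_enum(publication_status_scope,
                                          pubstatus_levels,
                                          "publication_status_scope"),
    ipd_analysis = check_enum(ipd_analysis, c("yes", "no"), "ipd_analysis")
  ), class = "search_profile")
}

# Tool-specific ordinal scales (higher rank = better).
quality_scales <- list(
  AMSTAR = c(critically_low = 1, low = 2, moderate = 3, high = 4, highest = 5),
  AMSTAR2 = c(critically_low = 1, low = 2, moderate = 3, high = 4, highest = 5),
  OXMAN_GUYATT = stats::setNames(1:7, as.character(1:7)),
  ROBIS = c(high_risk = 1, low_risk = 2)
)

#' Quality or risk-of-bias rating of a review
#'
#' One appraisal of a systematic review on a specific instrument's ordinal
#' scale. Ratings from different instruments are never compared directly.
#'
#' @param tool One of `"AMSTAR"`, `"AMSTAR2"`, `"OXMAN_GUYATT"`, `"ROBIS"`.
#' @param raw_level Tool-specific label (e.g. `"high"`, `"low_risk"`, `"5"`).
#' @param ordinal_rank Integer rank on the tool's scale (higher = better);
#'   derived from `raw_level` when omitted.
#' @param rct_quality_assessed yes/no/unknown — did the review itself appraise
#'   its included trials (used as Step I2).
#' @return An object of class `quality_rating`.
#' @export
quality_rating <- function(tool, raw_level, ordinal_rank = NULL,
                           rct_quality_assessed = "unknown") {
  tool <- check_enum(tool, tool_levels, "tool")
  scale <- quality_scales[[tool]]
  raw_level <- tolower(gsub("[ -]+", "_", trimws(as.character(raw_level))))
  if (is.null(ordinal_rank)) {
    if (!raw_level %in% names(scale)) {
      abort_field("raw_level", sprintf(
        "unknown %s level %s (expected one of %s)",
        tool, sQuote(raw_level), paste(sQuote(names(scale)), collapse = ", ")))
    }
    ordinal_rank <- as.integer(unname(scale[[raw_level]]))
  } else {
    ordinal_rank <- as.integer(ordinal_rank)
    if (raw_level %in% names(scale) &&
        ordinal_rank != unname(scale[[raw_level]])) {
      abort_field("ordinal_rank",
                  sprintf("inconsistent with %s level %s", tool,
                          sQuote(raw_level)))
    }
    if (ordinal_rank < min(scale) || ordinal_rank > max(scale)) {
      abort_field("ordinal_rank", sprintf("outside the %s scale", tool))
    }
  }
  structure(list(
    tool = tool,
    raw_level = raw_level,
    ordinal_rank = ordinal_rank,
    rct_quality_assessed = check_enum(rct_quality_assessed, yn_unknown_levels,
                                      "rct_quality_assessed")
  ), class = "quality_rating")
}

#' Pooled effect estimate of a review's primary outcome
#'
#' @param measure `"RR"`, `"OR"`, `"MD"`, or `"SMD"`. The null value is 1 for
#'   ratio measures and 0 for difference measures and is derived, never set.
#' @param point Point estimate.
#' @param ci_low,ci_high 95% confidence bounds (may be `NA`).
#' @param p_value P-value in \[0, 1\] or `NA` when not reported.
#' @param benefit_direction `"lower_better"` or `"higher_better"` for the
#'   outcome the estimate addresses.
#' @return An object of class `effect_estimate`.
#' @export
effect_estimate <- function(measure, point, ci_low = NA, ci_high = NA,
                            p_value = NA,
                            benefit_direction) {
  measure <- check_enum(measure, measure_levels, "measure")
  point <- check_scalar_number(point, "point")
  ci_low <- check_scalar_number(ci_low, "ci_low", allow_na = TRUE)
  ci_high <- check_scalar_number(ci_high, "ci_high", allow_na = TRUE)
  p_value <- check_scalar_number(p_value, "p_value", allow_na = TRUE)
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    abort_field("p_value", "must lie in [0, 1]")
  }
  if (!is.na(ci_low) && !is.na(ci_high)) {
    if (!(ci_low <= point && point <= ci_high)) {
      abort_field("ci_low/ci_high", "must bracket the point estimate")
    }
  }
  structure(list(
    measure = measure,
    point = point,
    ci_low = ci_low,
    ci_high = ci_high,
    p_value = p_value,
    benefit_direction = check_enum(benefit_direction, benefit_levels,
                                   "benefit_direction"),
    null_value = if (measure %in% c("RR", "OR")) 1 else 0
  ), class = "effect_estimate")
}

#' Synthesis sub-judgments used at Step E
#'
#' Three ordinal sub-fields compared lexicographically when reviews share both
#' trials and quality: data-extraction rigour, whether clinical heterogeneity
#' was assessed, and whether the synthesis method was appropriate. Unknown is
#' always the worst tier.
#'
#' @param data_extraction duplicate/single/unknown.
#' @param heterogeneity_assessed,synthesis_appropriate yes/no/unknown.
#' @return An object of class `synthesis_profile`.
#' @export
synthesis_profile <- function(data_extraction = "unknown",
                              heterogeneity_assessed = "unknown",
                              synthesis_appropriate = "unknown") {
  structure(list(
    data_extraction = check_enum(data_extraction, extraction_levels,
                                 "data_extraction"),
    heterogeneity_assessed = check_enum(heterogeneity_assessed,
                                        yn_unknown_levels,
                                        "heterogeneity_assessed"),
    synthesis_appropriate = check_enum(synthesis_appropriate,
                                       yn_unknown_levels,
                                       "synthesis_appropriate")
  ), class = "synthesis_profile")
}

#' One systematic review's machine-readable record
#'
#' @param sr_id Identifier, unique within a case; defaults to the normalized
#'   label.
#' @param label Display label, conventionally first author + year.
#' @param is_cochrane Logical.
#' @param pico A [pico_frame()].
#' @param trials A [trial_set()].
#' @param search A [search_profile()].
#' @param quality List of [quality_rating()] objects (possibly several tools).
#' @param effect An [effect_estimate()] or `NULL` when no pooled estimate is
#'   recorded.
#' @param robis_verdict low_risk/high_risk/unknown.
#' @param synthesis A [synthesis_profile()].
#' @return An object of class `sr_record`.
#' @export
sr_record <- function(label, sr_id = normalize_trial_id(label),
                      is_cochrane = FALSE,
                      pico, trials = trial_set(), search = search_profile(),
                      quality = list(), effect = NULL,
                      robis_verdict = "unknown",
                      synthesis = synthesis_profile()) {
  if (!inherits(pico, "pico_frame")) abort_field("pico", "must be a pico_frame")
  if (!inherits(trials, "trial_set")) {
    abort_field("trials", "must be a trial_set")
  }
  if (!inherits(search, "search_profile")) {
    abort_field("search", "must be a search_profile")
  }
  if (inherits(quality, "quality_rating")) quality <- list(quality)
  if (!all(vapply(quality, inherits, logical(1), "quality_rating"))) {
    abort_field("quality", "must be a list of quality_rating objects")
  }
  if (!is.null(effect) && !inherits(effect, "effect_estimate")) {
    abort_field("effect", "must be an effect_estimate or NULL")
  }
  if (!inherits(synthesis, "synthesis_profile")) {
    abort_field("synthesis", "must be a synthesis_profile")
  }
  structure(list(
    sr_id = as.character(sr_id),
    label = as.character(label),
    is_cochrane = check_flag(is_cochrane, "is_cochrane"),
    pico = pico,
    trials = trials,
    search = search,
    quality = quality,
    effect = effect,
    robis_verdict = check_enum(robis_verdict, robis_levels, "robis_verdict"),
    synthesis = synthesis
  ), class = "sr_record")
}

#' A discordant-review case
#'
#' A clinical question plus at least two competing systematic reviews with
#' meta-analysis, together with the recorded human judgments the algorithm
#' consumes (question match per review; Step G same-criteria judgment).
#'
#' @param case_id Identifier.
#' @param question A [pico_frame()] for the case's question.
#' @param primary_outcome,primary_intervention Labels.
#' @param reviews List of [sr_record()]s, length >= 2, unique `sr_id`s.
#' @param judged_same_question Named logical vector over `sr_id`s (missing
#'   names default to `TRUE`).
#' @param judged_same_criteria `TRUE`/`FALSE` human Step G judgment, or `NA`
#'   to force the computed PICO-term comparison.
#' @return An object of class `discordant_case`.
#' @export
discordant_case <- function(case_id, question, primary_outcome,
                            primary_intervention, reviews,
                            judged_same_question = NULL,
                            judged_same_criteria = NA) {
  if (!inherits(question, "pico_frame")) {
    abort_field("question", "must be a pico_frame")
  }
  if (!is.list(reviews) ||
      !all(vapply(reviews, inherits, logical(1), "sr_record"))) {
    abort_field("reviews", "must be a list of sr_record objects")
  }
  if (length(reviews) < 2L) {
    stop("a discordant case requires at least two systematic reviews",
         call. = FALSE)
  }
  ids <- vapply(reviews, `[[`, character(1), "sr_id")
  if (anyDuplicated(ids)) {
    abort_field("reviews", sprintf("duplicate sr_id: %s",
                                   paste(unique(ids[duplicated(ids)]),
                                         collapse = ", ")))
  }
  jsq <- stats::setNames(rep(TRUE, length(ids)), ids)
  if (!is.null(judged_same_question)) {
    if (is.null(names(judged_same_question)) ||
        !all(names(judged_same_question) %in% ids)) {
      abort_field("judged_same_question",
                  "must be a named logical over existing sr_ids")
    }
    jsq[names(judged_same_question)] <- as.logical(judged_same_question)
  }
  if (length(judged_same_criteria) != 1L ||
      !is.logical(as.logical(judged_same_criteria))) {
    abort_field("judged_same_criteria", "must be TRUE, FALSE, or NA")
  }
  structure(list(
    case_id = as.character(case_id),
    question = question,
    primary_outcome = as.character(primary_outcome),
    primary_intervention = as.character(primary_intervention),
    reviews = stats::setNames(reviews, ids),
    judged_same_question = jsq,
    judged_same_criteria = as.logical(judged_same_criteria)
  ), class = "discordant_case")
}

#' The three-colour ease-of-use rubric
#'
#' @return A data.frame with the rubric's three levels (`green` = easy,
#'   `yellow` = moderate, `red` = hard) and their criterion texts.
#' @export
ease_rubric <- function() {
  data.frame(
    colour = c("green", "yellow", "red"),
    meaning = c("easy", "moderate", "hard"),
    criterion = c(
      paste("The step can be accomplished easily by the reviewer, due to low",
            "cognitive load or because it is a recognised method."),
      paste("The step requires a notable degree of cognitive load but can",
            "generally be accomplished with some effort."),
      paste("The step is difficult, due to significant cognitive load or",
            "confusion; some reviewers would likely fail or abandon the",
            "task.")
    ),
    stringsAsFactors = FALSE
  )
}

#' A paired assessment of one case by two assessor groups
#'
#' @param case_id Case identifier.
#' @param original_choice,replication_choice Non-empty character vectors of
#'   chosen `sr_id`s; the first element is the flagged primary review.
#' @param original_final_step,replication_final_step A step letter or
#'   `"not_reported"`.
#' @param ease_rating green/yellow/red or `NA`.
#' @param minutes Assessment duration in minutes or `NA`.
#' @param pilot Logical; pilot assessments are excluded from timing summaries.
#' @return An object of class `assessment_pair`.
#' @export
assessment_pair <- function(case_id, original_choice, original_final_step,
                            replication_choice, replication_final_step,
                            ease_rating = NA, minutes = NA, pilot = FALSE) {
  original_choice <- unique(as.character(original_choice))
  replication_choice <- unique(as.character(replication_choice))
  if (length(original_choice) == 0L || any(!nzchar(original_choice))) {
    abort_field("original_choice", "must be a non-empty set of sr_ids")
  }
  if (length(replication_choice) == 0L || any(!nzchar(replication_choice))) {
    abort_field("replication_choice", "must be a non-empty set of sr_ids")
  }
  step_vocab <- c(step_levels, "not_reported")
  if (!is.na(ease_rating)) {
    ease_rating <- check_enum(ease_rating, ease_rubric()$colour, "ease_rating")
  } else {
    ease_rating <- NA_character_
  }
  structure(list(
    case_id = as.character(case_id),
    original_choice = original_choice,
    original_final_step = check_enum(original_final_step, step_vocab,
                                     "original_final_step"),
    replication_choice = replication_choice,
    replication_final_step = check_enum(replication_final_step, step_vocab,
                                        "replication_final_step"),
    ease_rating = ease_rating,
    minutes = check_scalar_number(minutes, "minutes", allow_na = TRUE),
    pilot = check_flag(pilot, "pilot")
  ), class = "assessment_pair")
}

#' @export
print.discordant_case <- function(x, ...) {
  cat(sprintf("<discordant_case> %s: %s vs %s\n", x$case_id,
              x$primary_intervention, x$primary_outcome))
  cat(sprintf("  %d systematic reviews: %s\n", length(x$reviews),
              paste(vapply(x$reviews, `[[`, character(1), "label"),
                    collapse = ", ")))
  crit <- if (is.na(x$judged_same_criteria)) "not judged" else
    if (x$judged_same_criteria) "same" else "different"
  cat(sprintf("  eligibility criteria judged: %s\n", crit))
  invisible(x)
}

#' @export
print.effect_estimate <- function(x, ...) {
  ci <- if (is.na(x$ci_low)) "" else sprintf(" (%g, %g)", x$ci_low, x$ci_high)
  p <- if (is.na(x$p_value)) "p not reported" else sprintf("p = %g", x$p_value)
  cat(sprintf("<effect_estimate> %s %g%s, %s [null at %g, %s]\n",
              x$measure, x$point, ci, p, x$null_value, x$benefit_direction))
  invisible(x)
}
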