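# The hierarchical decision engine (Steps A-I). Routing: A filters reviews to
# those matching the question (terminal B when fewer than two remain); C asks
# whether all rosters coincide; if so D compares quality (equal -> terminal E
# synthesis comparison, unequal -> terminal F highest quality); if not G asks
# whether eligibility criteria are the same (yes -> terminal H search rigour,
# no -> terminal I publication hierarchy). Comparative terminals maximize
# lexicographically and keep ALL maximal reviews: ties select several.

step_error <- function(step, msg) {
  stop(sprintf("[Step %s] %s", step, msg), call. = FALSE)
}

#' Step A/B: filter reviews to those matching the case question
#'
#' @param case A [discordant_case()].
#' @return A list with `candidates` (sr_ids still in play) and `terminal`
#'   (`NULL`, or a Step B result list when fewer than two candidates remain).
#' @export
step_question_match <- function(case) {
  stopifnot(inherits(case, "discordant_case"))
  ids <- names(case$reviews)
  keep <- ids[case$judged_same_question[ids]]
  if (length(keep) == 0L) {
    step_error("A", "no review matches the case question")
  }
  if (length(keep) < 2L) {
    return(list(candidates = keep,
                terminal = list(step = "B", chosen = keep)))
  }
  list(candidates = keep, terminal = NULL)
}

#' Step C: do all candidate reviews include the same trials?
#'
#' @param candidates List of [sr_record()]s (length >= 2).
#' @return `TRUE` iff every trial roster is set-equal to the first.
#' @export
step_same_trials <- function(candidates) {
  rosters <- lapply(candidates, function(r) r$trials$trial_ids)
  if (any(vapply(rosters, length, integer(1)) == 0L)) {
    step_error("C", "every review needs a non-empty trial roster")
  }
  all(vapply(rosters[-1], setequal, logical(1), rosters[[1]]))
}

# Pick the instrument shared by every candidate, preferring the more recent
# review-appraisal tools; comparisons never cross instruments.
shared_quality_tool <- function(candidates) {
  tool_sets <- lapply(candidates, function(r) {
    vapply(r$quality, `[[`, character(1), "tool")
  })
  shared <- Reduce(intersect, tool_sets)
  preference <- c("AMSTAR2", "AMSTAR", "ROBIS", "OXMAN_GUYATT")
  shared <- preference[preference %in% shared]
  if (length(shared) == 0L) {
    step_error("D", paste(
      "no quality instrument is shared by all candidate reviews;",
      "ratings on different tools are incomparable - supply a common",
      "assessment (e.g. ROBIS verdicts for every review)"))
  }
  shared[[1]]
}

quality_rank <- function(record, tool) {
  tools <- vapply(record$quality, `[[`, character(1), "tool")
  record$quality[[which(tools == tool)[1]]]$ordinal_rank
}

#' Step D: are the candidates of the same quality / risk of bias?
#'
#' @param candidates List of [sr_record()]s carrying ratings on a shared tool.
#' @return `TRUE` iff all ordinal ranks on the shared instrument are equal.
#' @export
step_same_quality <- function(candidates) {
  tool <- shared_quality_tool(candidates)
  ranks <- vapply(candidates, quality_rank, numeric(1), tool)
  length(unique(ranks)) == 1L
}

#' Step F (terminal): choose the highest-quality review(s)
#'
#' @param candidates List of [sr_record()]s.
#' @return Character vector of chosen `sr_id`s (ties keep all maximal).
#' @export
step_choose_highest_quality <- function(candidates) {
  tool <- shared_quality_tool(candidates)
  ranks <- vapply(candidates, quality_rank, numeric(1), tool)
  ids <- vapply(candidates, `[[`, character(1), "sr_id")
  sort(unname(ids[ranks == max(ranks)]))
}

# Ordinal encodings: larger is better, unknown strictly worst.
rank_level <- function(values, levels_ascending) {
  match(values, levels_ascending)
}

synthesis_rank_matrix <- function(candidates) {
  cbind(
    rank_level(vapply(candidates, function(r) r$synthesis$data_extraction,
                      character(1)), c("unknown", "single", "duplicate")),
    rank_level(vapply(candidates,
                      function(r) r$synthesis$heterogeneity_assessed,
                      character(1)), c("unknown", "no", "yes")),
    rank_level(vapply(candidates,
                      function(r) r$synthesis$synthesis_appropriate,
                      character(1)), c("unknown", "no", "yes"))
  )
}

# Lexicographic maximization: survivors are narrowed tier by tier; reviews
# tied on every tier are all kept.
lexicographic_max <- function(ids, rank_matrix) {
  survivors <- seq_along(ids)
  for (j in seq_len(ncol(rank_matrix))) {
    col <- rank_matrix[survivors, j]
    survivors <- survivors[col == max(col)]
    if (length(survivors) == 1L) break
  }
  sort(unname(ids[survivors]))
}

#' Step E (terminal): compare extraction, heterogeneity, and synthesis
#'
#' Reached only when candidates share both trials and quality. Preference is
#' lexicographic over the three [synthesis_profile()] sub-judgments; a full
#' tie keeps all candidates.
#'
#' @param candidates List of [sr_record()]s.
#' @return Character vector of chosen `sr_id`s.
#' @export
step_compare_synthesis <- function(candidates) {
  ids <- vapply(candidates, `[[`, character(1), "sr_id")
  lexicographic_max(ids, synthesis_rank_matrix(candidates))
}

jaccard <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) return(1)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

pico_similarity <- function(pico_a, pico_b) {
  mean(c(
    jaccard(pico_a$population_terms, pico_b$population_terms),
    jaccard(pico_a$intervention_terms, pico_b$intervention_terms),
    jaccard(pico_a$comparator_terms, pico_b$comparator_terms),
    jaccard(pico_a$outcome_terms, pico_b$outcome_terms)
  ))
}

#' Step G: do the candidates apply the same eligibility criteria?
#'
#' A recorded human judgment takes precedence; otherwise every pair of
#' candidates must reach an average per-element PICO-term Jaccard similarity
#' of at least the ruleset threshold.
#'
#' @param candidates List of [sr_record()]s.
#' @param ruleset A [jadad_ruleset()].
#' @param judged Optional logical human judgment (`NA` = compute).
#' @return `TRUE` or `FALSE`.
#' @export
step_same_criteria <- function(candidates, ruleset = jadad_ruleset(),
                               judged = NA) {
  if (!is.na(judged)) return(isTRUE(as.logical(judged)))
  has_terms <- vapply(candidates, function(r) {
    length(c(r$pico$population_terms, r$pico$intervention_terms,
             r$pico$comparator_terms, r$pico$outcome_terms)) > 0L
  }, logical(1))
  if (!all(has_terms)) {
    step_error("G", paste(
      "neither a same-criteria judgment nor PICO term lists are available",
      "for every review"))
  }
  n <- length(candidates)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      sim <- pico_similarity(candidates[[i]]$pico, candidates[[j]]$pico)
      if (sim < ruleset$criteria_similarity_threshold) return(FALSE)
    }
  }
  TRUE
}

date_rank <- function(dates) {
  num <- rep(-Inf, length(dates))
  known <- dates != "unknown"
  num[known] <- as.numeric(as.Date(dates[known]))
  num[is.na(num)] <- -Inf
  num
}

search_criterion_rank <- function(candidates, criterion) {
  value_of <- function(r, field) r$search[[field]]
  switch(criterion,
    n_databases = vapply(candidates, value_of, numeric(1), "n_databases"),
    grey_literature = rank_level(
      vapply(candidates, value_of, character(1), "grey_literature"),
      c("unknown", "no", "yes")),
    duplicate_independent_screening = rank_level(
      vapply(candidates, value_of, character(1),
             "duplicate_independent_screening"),
      c("unknown", "no", "yes")),
    last_search_date = date_rank(
      vapply(candidates, value_of, character(1), "last_search_date")),
    publication_status_scope = rank_level(
      vapply(candidates, value_of, character(1), "publication_status_scope"),
      c("unknown", "published_only", "includes_unpublished")),
    language_restriction = rank_level(
      vapply(candidates, value_of, character(1), "language_restriction"),
      c("unknown", "restricted", "none")),
    ipd_analysis = rank_level(
      vapply(candidates, value_of, character(1), "ipd_analysis"),
      c("no", "yes")),
    rct_quality_assessed = rank_level(
      vapply(candidates, function(r) {
        vals <- vapply(r$quality, `[[`, character(1), "rct_quality_assessed")
        if (any(vals == "yes")) "yes"
        else if (any(vals == "no")) "no"
        else "unknown"
      }, character(1)),
      c("unknown", "no", "yes")),
    stop(sprintf("unknown criterion %s", sQuote(criterion)), call. = FALSE)
  )
}

criterion_rank_matrix <- function(candidates, order) {
  do.call(cbind, lapply(order, function(cr) {
    search_criterion_rank(candidates, cr)
  }))
}

#' Step H (terminal): choose by search rigour
#'
#' Lexicographic maximization over the ruleset's `step_h_order`: more
#' databases, grey-literature searching, duplicate independent screening, and
#' a later last-search date are better; unknown always ranks worst.
#'
#' @param candidates List of [sr_record()]s.
#' @param ruleset A [jadad_ruleset()].
#' @return Character vector of chosen `sr_id`s (ties keep all maximal).
#' @export
step_search_rigour <- function(candidates, ruleset = jadad_ruleset()) {
  ids <- vapply(candidates, `[[`, character(1), "sr_id")
  lexicographic_max(ids, criterion_rank_matrix(candidates,
                                               ruleset$step_h_order))
}

#' Step I (terminal): choose by publication hierarchy
#'
#' Lexicographic maximization over the ruleset's `step_i_order`: including
#' unpublished work beats published-only, appraising trial quality beats not,
#' no language restriction beats a restriction, and an individual-patient-data
#' analysis beats none.
#'
#' @inheritParams step_search_rigour
#' @return Character vector of chosen `sr_id`s.
#' @export
step_publication_hierarchy <- function(candidates,
                                       ruleset = jadad_ruleset()) {
  ids <- vapply(candidates, `[[`, character(1), "sr_id")
  lexicographic_max(ids, criterion_rank_matrix(candidates,
                                               ruleset$step_i_order))
}

new_trace <- function(case, ruleset, steps, terminal, chosen) {
  structure(list(
    case_id = case$case_id,
    ruleset_id = ruleset$ruleset_id,
    steps = data.frame(step_id = vapply(steps, `[[`, character(1), "step"),
                       verdict = vapply(steps, `[[`, character(1), "verdict"),
                       stringsAsFactors = FALSE),
    terminal_step = terminal,
    chosen = sort(chosen)
  ), class = "jadad_trace")
}

#' Run the full decision algorithm on a case
#'
#' Produces an ordered decision trace ending at one of the terminal steps
#' (B, E, F, H, I) with a non-empty chosen review set. Deterministic for a
#' fixed `(case, ruleset)` pair, and invariant to the order in which the
#' case's reviews are listed.
#'
#' @param case A [discordant_case()].
#' @param ruleset A [jadad_ruleset()].
#' @return An object of class `jadad_trace` with elements `case_id`,
#'   `ruleset_id`, `steps` (step/verdict data.frame), `terminal_step`, and
#'   `chosen` (sorted sr_ids).
#' @export
run_jadad <- function(case, ruleset = jadad_ruleset()) {
  stopifnot(inherits(case, "discordant_case"),
            inherits(ruleset, "jadad_ruleset"))
  steps <- list()
  note <- function(step, verdict) {
    steps[[length(steps) + 1L]] <<- list(step = step, verdict = verdict)
  }

  a <- step_question_match(case)
  n_all <- length(case$reviews)
  note("A", sprintf("%d of %d reviews address the case question",
                    length(a$candidates), n_all))
  if (!is.null(a$terminal)) {
    note("B", sprintf("fewer than two on-question reviews; chose closest: %s",
                      paste(a$terminal$chosen, collapse = ", ")))
    return(new_trace(case, ruleset, steps, "B", a$terminal$chosen))
  }
  candidates <- case$reviews[a$candidates]

  same_trials <- step_same_trials(candidates)
  note("C", if (same_trials) "same trials included across reviews"
       else "different trials included across reviews")

  if (same_trials) {
    same_quality <- step_same_quality(candidates)
    note("D", if (same_quality) "same methodological quality"
         else "quality differs across reviews")
    if (same_quality) {
      chosen <- step_compare_synthesis(candidates)
      note("E", sprintf("compared extraction/heterogeneity/synthesis; chose %s",
                        paste(chosen, collapse = ", ")))
      return(new_trace(case, ruleset, steps, "E", chosen))
    }
    chosen <- step_choose_highest_quality(candidates)
    note("F", sprintf("chose highest quality: %s",
                      paste(chosen, collapse = ", ")))
    return(new_trace(case, ruleset, steps, "F", chosen))
  }

  same_criteria <- step_same_criteria(candidates, ruleset,
                                      judged = case$judged_same_criteria)
  note("G", if (same_criteria) "same eligibility criteria"
       else "different eligibility criteria")
  if (same_criteria) {
    chosen <- step_search_rigour(candidates, ruleset)
    note("H", sprintf("compared search rigour; chose %s",
                      paste(chosen, collapse = ", ")))
    return(new_trace(case, ruleset, steps, "H", chosen))
  }
  chosen <- step_publication_hierarchy(candidates, ruleset)
  note("I", sprintf("compared publication hierarchy; chose %s",
                    paste(chosen, collapse = ", ")))
  new_trace(case, ruleset, steps, "I", chosen)
}

#' @export
print.jadad_trace <- function(x, ...) {
  cat(sprintf("<jadad_trace> case %s (ruleset %s)\n", x$case_id,
              x$ruleset_id))
  for (i in seq_len(nrow(x$steps))) {
    cat(sprintf("  Step %s: %s\n", x$steps$step_id[i], x$steps$verdict[i]))
  }
  cat(sprintf("  terminal: Step %s -> chosen {%s}\n", x$terminal_step,
              paste(x$chosen, collapse = ", ")))
  invisible(x)
}

#' Serialize a decision trace to JSON
#'
#' @param trace A `jadad_trace`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
trace_to_json <- function(trace, path = NULL) {
  stopifnot(inherits(trace, "jadad_trace"))
  payload <- list(
    case_id = trace$case_id,
    ruleset_id = trace$ruleset_id,
    steps = trace$steps,
    terminal_step = trace$terminal_step,
    chosen = as.list(trace$chosen)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
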