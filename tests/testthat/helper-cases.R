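# Builders for small in-code cases plus an independent brute-force comparator
# used to cross-check every lexicographic selection in the engine.

minimal_pico <- function(int_terms = c("drug"), out_terms = c("pain")) {
  pico_frame(intervention = "intervention", outcome = "outcome",
             intervention_terms = int_terms, outcome_terms = out_terms)
}

make_review <- function(id, trials = paste0("trial-", id),
                        amstar = "high", search = search_profile(),
                        synthesis = synthesis_profile(),
                        pico = minimal_pico(), effect = NULL,
                        rct_quality_assessed = "unknown") {
  sr_record(
    label = id, sr_id = id, pico = pico, trials = trial_set(trials),
    search = search,
    quality = if (is.null(amstar)) list() else
      list(quality_rating("AMSTAR", amstar,
                          rct_quality_assessed = rct_quality_assessed)),
    effect = effect, synthesis = synthesis
  )
}

make_case <- function(reviews, case_id = "case-1",
                      judged_same_question = NULL,
                      judged_same_criteria = NA) {
  discordant_case(
    case_id = case_id, question = minimal_pico(),
    primary_outcome = "outcome", primary_intervention = "intervention",
    reviews = reviews, judged_same_question = judged_same_question,
    judged_same_criteria = judged_same_criteria
  )
}

rand_search_profile <- function() {
  pool <- c("db1", "db2", "db3", "db4", "db5", "db6")
  n_db <- sample(0:6, 1)
  search_profile(
    databases = if (n_db) sample(pool, n_db) else character(),
    grey_literature = sample(c("yes", "no", "unknown"), 1),
    last_search_date = sample(c("unknown", "2012-05-01", "2015-10-01",
                                "2019-01-01"), 1),
    duplicate_independent_screening = sample(c("yes", "no", "unknown"), 1),
    language_restriction = sample(c("none", "restricted", "unknown"), 1),
    publication_status_scope = sample(c("published_only",
                                        "includes_unpublished", "unknown"),
                                      1),
    ipd_analysis = sample(c("yes", "no"), 1)
  )
}

rand_synthesis <- function() {
  synthesis_profile(
    data_extraction = sample(c("duplicate", "single", "unknown"), 1),
    heterogeneity_assessed = sample(c("yes", "no", "unknown"), 1),
    synthesis_appropriate = sample(c("yes", "no", "unknown"), 1)
  )
}

rand_candidates <- function(n = sample(2:5, 1)) {
  lapply(seq_len(n), function(i) {
    make_review(sprintf("rev-%d", i), search = rand_search_profile(),
                synthesis = rand_synthesis(),
                amstar = sample(c("low", "moderate", "high", "highest"), 1),
                rct_quality_assessed = sample(c("yes", "no", "unknown"), 1))
  })
}

# ---- independent brute-force comparator -----------------------------------
# Encodes each criterion on its own, then declares review i "beaten" if some
# other review outranks it at the first criterion on which they differ; the
# selection is every unbeaten review. This is a pairwise-tournament statement
# of lexicographic preference, deliberately different from the engine's
# tier-by-tier survivor filtering.

oracle_criterion_value <- function(record, criterion) {
  s <- record$search
  enum_rank <- function(value, worst_to_best) {
    which(worst_to_best == value)
  }
  if (criterion == "n_databases") return(s$n_databases)
  if (criterion == "grey_literature") {
    return(enum_rank(s$grey_literature, c("unknown", "no", "yes")))
  }
  if (criterion == "duplicate_independent_screening") {
    return(enum_rank(s$duplicate_independent_screening,
                     c("unknown", "no", "yes")))
  }
  if (criterion == "last_search_date") {
    if (s$last_search_date == "unknown") return(-Inf)
    return(as.numeric(as.Date(s$last_search_date)))
  }
  if (criterion == "publication_status_scope") {
    return(enum_rank(s$publication_status_scope,
                     c("unknown", "published_only", "includes_unpublished")))
  }
  if (criterion == "language_restriction") {
    return(enum_rank(s$language_restriction,
                     c("unknown", "restricted", "none")))
  }
  if (criterion == "ipd_analysis") {
    return(enum_rank(s$ipd_analysis, c("no", "yes")))
  }
  if (criterion == "rct_quality_assessed") {
    vals <- vapply(record$quality, `[[`, character(1),
                   "rct_quality_assessed")
    agg <- if ("yes" %in% vals) "yes" else if ("no" %in% vals) "no"
    else "unknown"
    return(enum_rank(agg, c("unknown", "no", "yes")))
  }
  if (criterion == "data_extraction") {
    return(enum_rank(record$synthesis$data_extraction,
                     c("unknown", "single", "duplicate")))
  }
  if (criterion == "heterogeneity_assessed") {
    return(enum_rank(record$synthesis$heterogeneity_assessed,
                     c("unknown", "no", "yes")))
  }
  if (criterion == "synthesis_appropriate") {
    return(enum_rank(record$synthesis$synthesis_appropriate,
                     c("unknown", "no", "yes")))
  }
  stop("unknown criterion in oracle: ", criterion)
}

oracle_lex_select <- function(candidates, criteria) {
  vals <- lapply(candidates, function(r) {
    vapply(criteria, function(cr) oracle_criterion_value(r, cr), numeric(1))
  })
  beats <- function(i, j) {
    for (k in seq_along(criteria)) {
      if (vals[[i]][k] != vals[[j]][k]) return(vals[[i]][k] > vals[[j]][k])
    }
    FALSE
  }
  n <- length(candidates)
  unbeaten <- vapply(seq_len(n), function(i) {
    !any(vapply(seq_len(n), function(j) j != i && beats(j, i), logical(1)))
  }, logical(1))
  sort(vapply(candidates[unbeaten], `[[`, character(1), "sr_id"))
}

step_h_criteria_for_test <- function() {
  c("n_databases", "grey_literature", "duplicate_independent_screening",
    "last_search_date")
}

step_i_criteria_for_test <- function() {
  c("publication_status_scope", "rct_quality_assessed",
    "language_restriction", "ipd_analysis")
}

# Raw-list view of a case, edited by tests to construct invalid files.
case_to_list_for_test <- function(case) {
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_case(case, path)
  jsonlite::read_json(path, simplifyVector = FALSE)
}

fixture_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_fixture_tables()
    cache
  }
})
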