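# JSON case files and the bundled CSV corpus. Case files carry one
# discordant-review case per file with field names matching the constructors;
# the corpus CSVs transcribe the characteristics, paired choices, and pooled
# effect estimates of the 21-case replication corpus shipped under
# inst/extdata/fixtures.

pico_to_list <- function(p) {
  list(population = p$population, intervention = p$intervention,
       comparator = p$comparator, outcome = p$outcome,
       population_terms = as.list(p$population_terms),
       intervention_terms = as.list(p$intervention_terms),
       comparator_terms = as.list(p$comparator_terms),
       outcome_terms = as.list(p$outcome_terms))
}

pico_from_list <- function(x) {
  pico_frame(
    population = x$population %||% "",
    intervention = x$intervention %||% "",
    comparator = x$comparator %||% "",
    outcome = x$outcome %||% "",
    population_terms = unlist(x$population_terms),
    intervention_terms = unlist(x$intervention_terms),
    comparator_terms = unlist(x$comparator_terms),
    outcome_terms = unlist(x$outcome_terms)
  )
}

review_to_list <- function(r) {
  list(
    sr_id = r$sr_id,
    label = r$label,
    is_cochrane = r$is_cochrane,
    pico = pico_to_list(r$pico),
    trials = as.list(r$trials$trial_ids),
    search = list(
      databases = as.list(r$search$databases),
      grey_literature = r$search$grey_literature,
      last_search_date = r$search$last_search_date,
      duplicate_independent_screening =
        r$search$duplicate_independent_screening,
      language_restriction = r$search$language_restriction,
      publication_status_scope = r$search$publication_status_scope,
      ipd_analysis = r$search$ipd_analysis
    ),
    quality = lapply(r$quality, function(q) {
      list(tool = q$tool, raw_level = q$raw_level,
           ordinal_rank = q$ordinal_rank,
           rct_quality_assessed = q$rct_quality_assessed)
    }),
    effect = if (is.null(r$effect)) NULL else list(
      measure = r$effect$measure, point = r$effect$point,
      ci_low = r$effect$ci_low, ci_high = r$effect$ci_high,
      p_value = r$effect$p_value,
      benefit_direction = r$effect$benefit_direction
    ),
    robis_verdict = r$robis_verdict,
    synthesis = list(
      data_extraction = r$synthesis$data_extraction,
      heterogeneity_assessed = r$synthesis$heterogeneity_assessed,
      synthesis_appropriate = r$synthesis$synthesis_appropriate
    )
  )
}

review_from_list <- function(x) {
  search <- x$search %||% list()
  sr_record(
    label = x$label %||% abort_field("label", "missing"),
    sr_id = x$sr_id %||% normalize_trial_id(x$label),
    is_cochrane = isTRUE(x$is_cochrane),
    pico = pico_from_list(x$pico %||% abort_field("pico", "missing")),
    trials = trial_set(unlist(x$trials)),
    search = search_profile(
      databases = unlist(search$databases),
      grey_literature = search$grey_literature %||% "unknown",
      last_search_date = search$last_search_date %||% "unknown",
      duplicate_independent_screening =
        search$duplicate_independent_screening %||% "unknown",
      language_restriction = search$language_restriction %||% "unknown",
      publication_status_scope = search$publication_status_scope %||%
        "unknown",
      ipd_analysis = search$ipd_analysis %||% "no"
    ),
    quality = lapply(x$quality %||% list(), function(q) {
      quality_rating(tool = q$tool, raw_level = q$raw_level,
                     ordinal_rank = q$ordinal_rank,
                     rct_quality_assessed = q$rct_quality_assessed %||%
                       "unknown")
    }),
    effect = if (is.null(x$effect)) NULL else effect_estimate(
      measure = x$effect$measure, point = x$effect$point,
      ci_low = x$effect$ci_low %||% NA, ci_high = x$effect$ci_high %||% NA,
      p_value = x$effect$p_value %||% NA,
      benefit_direction = x$effect$benefit_direction
    ),
    robis_verdict = x$robis_verdict %||% "unknown",
    synthesis = do.call(synthesis_profile, x$synthesis %||% list())
  )
}

case_to_list <- function(case) {
  list(
    case_id = case$case_id,
    question = pico_to_list(case$question),
    primary_outcome = case$primary_outcome,
    primary_intervention = case$primary_intervention,
    reviews = lapply(unname(case$reviews), review_to_list),
    judged_same_question = as.list(case$judged_same_question),
    judged_same_criteria = if (is.na(case$judged_same_criteria)) NULL
    else case$judged_same_criteria
  )
}

case_from_list <- function(x) {
  jsq <- x$judged_same_question
  discordant_case(
    case_id = x$case_id %||% abort_field("case_id", "missing"),
    question = pico_from_list(x$question %||%
                                abort_field("question", "missing")),
    primary_outcome = x$primary_outcome %||% "",
    primary_intervention = x$primary_intervention %||% "",
    reviews = lapply(x$reviews %||% list(), review_from_list),
    judged_same_question = if (is.null(jsq)) NULL else
      stats::setNames(vapply(jsq, isTRUE, logical(1)), names(jsq)),
    judged_same_criteria = x$judged_same_criteria %||% NA
  )
}

#' Read / write a discordant-review case file
#'
#' Case files are JSON, one case per file, with field names matching the
#' constructor arguments (see `inst/extdata/schema/case-schema.json`). All
#' type invariants are re-validated on load; a file describing fewer than two
#' reviews is rejected.
#'
#' @param path File path.
#' @return `load_case` returns a validated [discordant_case()]; `write_case`
#'   returns `path` invisibly.
#' @export
load_case <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("case file not found: %s", path), call. = FALSE)
  }
  case_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' @rdname load_case
#' @param case A [discordant_case()].
#' @export
write_case <- function(case, path) {
  stopifnot(inherits(case, "discordant_case"))
  jsonlite::write_json(case_to_list(case), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Path to the bundled replication corpus
#' @return Directory containing the corpus CSVs.
#' @export
fixture_dir <- function() {
  system.file("extdata", "fixtures", package = "jadadr", mustWork = TRUE)
}

split_multi <- function(x, n = NULL) {
  out <- if (is.na(x) || !nzchar(x)) character() else
    trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  if (!is.null(n) && length(out) == 1L && n > 1L) out <- rep(out, n)
  out
}

parse_p <- function(x) {
  x <- trimws(as.character(x))
  if (!nzchar(x) || x == "NR") return(NA_real_)
  if (startsWith(x, "<")) return(as.numeric(substring(x, 2)))
  as.numeric(x)
}

tokenize_terms <- function(x) {
  toks <- strsplit(tolower(gsub("[^a-z0-9 ]", " ", tolower(x))), " +")[[1]]
  unique(toks[nzchar(toks)])
}

map_ease <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NA_character_)
  switch(x, easy = "green", moderate = "yellow",
         moderate_hard = "red", hard = "red",
         stop(sprintf("unknown ease label %s", sQuote(x)), call. = FALSE))
}

fixture_integrity_error <- function(msg) {
  stop(sprintf("fixture integrity: %s", msg), call. = FALSE)
}

build_fixture_case <- function(case_row, choice_rows, effect_rows) {
  question <- pico_frame(
    population = case_row$label,
    intervention = case_row$primary_intervention,
    comparator = "comparator arm",
    outcome = case_row$primary_outcome,
    intervention_terms = tokenize_terms(case_row$primary_intervention),
    outcome_terms = tokenize_terms(case_row$primary_outcome)
  )

  labels <- character()
  for (i in seq_len(nrow(choice_rows))) {
    labels <- c(labels, split_multi(choice_rows$chosen[i]))
  }
  labels <- unique(c(labels, effect_rows$sr_label))
  ids <- normalize_trial_id(labels)

  meta <- stats::setNames(vector("list", length(labels)), ids)
  for (i in seq_len(nrow(choice_rows))) {
    ch <- split_multi(choice_rows$chosen[i])
    n <- length(ch)
    coch <- split_multi(choice_rows$cochrane[i], n)
    rob <- split_multi(choice_rows$robis[i], n)
    judg <- split_multi(choice_rows$tool_judgment[i], n)
    tool <- choice_rows$tool[i]
    for (k in seq_len(n)) {
      id <- normalize_trial_id(ch[k])
      m <- meta[[id]] %||% list()
      if (length(coch) >= k && nzchar(coch[k])) m$cochrane <- coch[k]
      if (length(rob) >= k && nzchar(rob[k])) m$robis <- rob[k]
      if (!is.na(tool) && nzchar(tool) && length(judg) >= k &&
          nzchar(judg[k])) {
        m$tool <- tool
        m$judgment <- judg[k]
      }
      meta[[id]] <- m
    }
  }
  for (i in seq_len(nrow(effect_rows))) {
    id <- normalize_trial_id(effect_rows$sr_label[i])
    if (!id %in% ids) next
    m <- meta[[id]] %||% list()
    m$cochrane <- m$cochrane %||% effect_rows$cochrane[i]
    m$robis <- m$robis %||% effect_rows$robis[i]
    m$effect_row <- effect_rows[i, , drop = FALSE]
    meta[[id]] <- m
  }

  make_review <- function(label, id, roster_tag, m) {
    quality <- list()
    if (!is.null(m$tool)) {
      quality <- list(quality_rating(m$tool, m$judgment,
                                     rct_quality_assessed = "unknown"))
    }
    effect <- NULL
    if (!is.null(m$effect_row)) {
      er <- m$effect_row
      effect <- effect_estimate(
        measure = er$measure, point = er$point, ci_low = er$ci_low,
        ci_high = er$ci_high, p_value = parse_p(er$p_value),
        benefit_direction = case_row$benefit_direction
      )
    }
    sr_record(
      label = label, sr_id = id,
      is_cochrane = identical(m$cochrane, "yes"),
      pico = question,
      # Rosters are not part of the corpus tables; distinct one-element
      # placeholder rosters encode the recorded fact that no two reviews
      # shared the same trial set.
      trials = trial_set(paste0("unrecorded roster ", roster_tag)),
      search = search_profile(),
      quality = quality,
      effect = effect,
      robis_verdict = m$robis %||% "unknown"
    )
  }

  reviews <- vector("list", case_row$n_reviews)
  for (k in seq_along(labels)) {
    reviews[[k]] <- make_review(labels[k], ids[k], ids[k],
                                meta[[ids[k]]] %||% list())
  }
  if (length(labels) > case_row$n_reviews) {
    fixture_integrity_error(sprintf(
      "case %s names more reviews (%d) than its recorded count (%d)",
      case_row$case_id, length(labels), case_row$n_reviews))
  }
  for (k in seq_len(case_row$n_reviews - length(labels))) {
    idx <- length(labels) + k
    reviews[[idx]] <- make_review(sprintf("Unnamed review %d", k),
                                  sprintf("unnamed-%d", k),
                                  sprintf("unnamed-%d", k), list())
  }
  discordant_case(
    case_id = case_row$case_id,
    question = question,
    primary_outcome = case_row$primary_outcome,
    primary_intervention = case_row$primary_intervention,
    reviews = reviews,
    judged_same_criteria = identical(case_row$judged_same_criteria, "yes")
  )
}

#' Load the bundled replication corpus
#'
#' Reads the three corpus CSVs (case characteristics, paired review choices,
#' pooled effect estimates), validates their integrity (21 cases, one
#' authors + one replication row per case, 27 effect rows, every chosen label
#' resolving to a review of its case), and assembles the package's domain
#' objects.
#'
#' @param dir Fixture directory; defaults to the corpus shipped with the
#'   package.
#' @return A list with `cases` (named list of [discordant_case()]),
#'   `pairs` (list of [assessment_pair()]), and `effects` (data.frame of
#'   pooled effect rows keyed by case, assessor, and review).
#' @export
load_fixture_tables <- function(dir = fixture_dir()) {
  read <- function(name) {
    path <- file.path(dir, name)
    if (!file.exists(path)) {
      fixture_integrity_error(sprintf("missing %s", name))
    }
    utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA"))
  }
  cases_tab <- read("table1_cases.csv")
  choices_tab <- read("table2_choices.csv")
  effects_tab <- read("table3_effects.csv")

  if (nrow(cases_tab) != 21L) {
    fixture_integrity_error(sprintf("expected 21 cases, found %d",
                                    nrow(cases_tab)))
  }
  if (nrow(effects_tab) != 27L) {
    fixture_integrity_error(sprintf("expected 27 effect rows, found %d",
                                    nrow(effects_tab)))
  }
  if (anyDuplicated(cases_tab$case_id)) {
    fixture_integrity_error("duplicate case_id in case table")
  }
  bad_case <- setdiff(unique(c(choices_tab$case_id, effects_tab$case_id)),
                      cases_tab$case_id)
  if (length(bad_case)) {
    fixture_integrity_error(sprintf("unknown case_id: %s",
                                    paste(bad_case, collapse = ", ")))
  }

  cases <- list()
  pairs <- list()
  for (i in seq_len(nrow(cases_tab))) {
    row <- cases_tab[i, , drop = FALSE]
    ch <- choices_tab[choices_tab$case_id == row$case_id, , drop = FALSE]
    ef <- effects_tab[effects_tab$case_id == row$case_id, , drop = FALSE]
    if (!setequal(ch$assessor, c("authors", "replication")) ||
        nrow(ch[ch$assessor == "replication", ]) != 1L) {
      fixture_integrity_error(sprintf(
        "case %s needs exactly one authors and one replication choice row",
        row$case_id))
    }
    case <- build_fixture_case(row, ch, ef)
    cases[[row$case_id]] <- case

    arow <- ch[ch$assessor == "authors", , drop = FALSE]
    rrow <- ch[ch$assessor == "replication", , drop = FALSE]
    orig <- normalize_trial_id(split_multi(arow$chosen))
    repl <- normalize_trial_id(split_multi(rrow$chosen))
    missing_ids <- setdiff(c(orig, repl), names(case$reviews))
    if (length(missing_ids)) {
      fixture_integrity_error(sprintf(
        "case %s: chosen label(s) %s do not resolve to a review",
        row$case_id, paste(missing_ids, collapse = ", ")))
    }
    pairs[[row$case_id]] <- assessment_pair(
      case_id = row$case_id,
      original_choice = orig,
      original_final_step = arow$final_step,
      replication_choice = repl,
      replication_final_step = rrow$final_step,
      ease_rating = map_ease(rrow$ease),
      minutes = if (is.na(rrow$minutes)) NA else as.numeric(rrow$minutes),
      pilot = identical(row$pilot, "yes")
    )
  }

  effects <- effects_tab
  effects$sr_id <- normalize_trial_id(effects$sr_label)
  effects$p_raw <- as.character(effects$p_value)
  effects$p_value <- vapply(effects$p_raw, parse_p, numeric(1),
                            USE.NAMES = FALSE)
  effects$benefit_direction <- cases_tab$benefit_direction[
    match(effects$case_id, cases_tab$case_id)]

  list(cases = cases, pairs = unname(pairs), effects = effects)
}

#' Classify every corpus effect row and export the verdict table
#'
#' Runs [classify_effect()] on each pooled effect row and returns the rows
#' with a `verdict` column appended (the printed verdict is retained in
#' `printed_verdict` for cross-checking).
#'
#' @param effects Effect-row data.frame from [load_fixture_tables()].
#' @param alpha Significance level.
#' @return The data.frame with a computed `verdict` column.
#' @export
classify_effect_table <- function(effects, alpha = 0.05) {
  effects$verdict <- vapply(seq_len(nrow(effects)), function(i) {
    classify_effect(effect_from_row(effects[i, , drop = FALSE]),
                    alpha = alpha)$verdict
  }, character(1))
  effects
}
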