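# Synthetic discordant-review cases with controlled statistical structure.
# Each case has a latent true effect; every review reports a pooled estimate
# drawn around it with its own standard error (log scale for ratio measures),
# a 95% Wald interval, and a Wald p-value. Rosters are Bernoulli samples from
# a per-case trial universe, so roster overlap - and hence the Step C verdict
# - is controlled by one inclusion probability. Assessor disagreement is
# modeled purely as ruleset perturbation.

db_pool <- c("MEDLINE", "Embase", "CENTRAL", "Web of Science", "Scopus",
             "CINAHL", "PsycINFO", "CNKI", "Wanfang", "VIP", "SinoMed",
             "ClinicalTrials.gov")

#' Simulation configuration
#'
#' Defaults emulate the bundled corpus: 21 cases whose review counts span 2
#' to 10, partially overlapping trial rosters that essentially never
#' coincide, review quality centred on moderate-to-high AMSTAR levels, and
#' individual-patient-data analyses almost never performed.
#'
#' @param n_cases Number of cases to generate.
#' @param reviews_per_case Integer range (length 2) of reviews per case.
#' @param trial_universe_size Trials available to each case.
#' @param trial_inclusion_prob Probability a review includes each trial.
#' @param quality_probs Named probabilities over the AMSTAR levels.
#' @param db_range Range of the number of databases searched per review.
#' @param grey_prob Probability a review searched grey literature.
#' @param screening_prob Probability of duplicate independent screening.
#' @param search_years Calendar-year window for last-search dates.
#' @param pico_jitter Probability a review drops or adds an eligibility term,
#'   controlling how often Step G's computed comparison fires.
#' @param true_effect_sd Standard deviation of the per-case latent effect
#'   (log scale for ratio measures); 0 gives a global null.
#' @param se_range Range of per-review standard errors.
#' @param measure_probs Named probabilities over effect measures.
#' @param benefit_direction Benefit direction shared by all generated
#'   outcomes.
#' @param ipd_prob Probability a review performed an IPD analysis.
#' @param seed Mandatory integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 21,
                       reviews_per_case = c(2, 10),
                       trial_universe_size = 30,
                       trial_inclusion_prob = 0.5,
                       quality_probs = c(critically_low = 0.05, low = 0.15,
                                         moderate = 0.30, high = 0.35,
                                         highest = 0.15),
                       db_range = c(2, 10),
                       grey_prob = 0.5,
                       screening_prob = 0.6,
                       search_years = c(2008, 2020),
                       pico_jitter = 0.15,
                       true_effect_sd = 0.2,
                       se_range = c(0.05, 0.4),
                       measure_probs = c(RR = 0.4, OR = 0.2, MD = 0.4),
                       benefit_direction = "lower_better",
                       ipd_prob = 0.02,
                       seed) {
  if (missing(seed) || length(seed) != 1L || is.na(seed)) {
    stop("a seed is mandatory for simulation configs", call. = FALSE)
  }
  if (length(reviews_per_case) != 2L ||
      reviews_per_case[1] < 2L ||
      reviews_per_case[1] > reviews_per_case[2]) {
    abort_field("reviews_per_case",
                "must be an increasing range with minimum >= 2")
  }
  if (trial_universe_size < 1L) {
    abort_field("trial_universe_size", "must be at least 1")
  }
  for (p in c(trial_inclusion_prob, grey_prob, screening_prob, pico_jitter,
              ipd_prob)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]",
                             call. = FALSE)
  }
  if (any(quality_probs < 0) || sum(quality_probs) <= 0) {
    abort_field("quality_probs", "must be non-negative with positive sum")
  }
  if (!setequal(names(measure_probs), c("RR", "OR", "MD"))) {
    abort_field("measure_probs", "must be named over RR, OR, MD")
  }
  if (se_range[1] <= 0 || se_range[1] > se_range[2]) {
    abort_field("se_range", "must be a positive increasing range")
  }
  check_enum(benefit_direction, benefit_levels, "benefit_direction")
  structure(list(
    n_cases = as.integer(n_cases),
    reviews_per_case = as.integer(reviews_per_case),
    trial_universe_size = as.integer(trial_universe_size),
    trial_inclusion_prob = trial_inclusion_prob,
    quality_probs = quality_probs / sum(quality_probs),
    db_range = as.integer(db_range),
    grey_prob = grey_prob,
    screening_prob = screening_prob,
    search_years = as.integer(search_years),
    pico_jitter = pico_jitter,
    true_effect_sd = true_effect_sd,
    se_range = se_range,
    measure_probs = measure_probs / sum(measure_probs),
    benefit_direction = benefit_direction,
    ipd_prob = ipd_prob,
    seed = as.integer(seed)
  ), class = "sim_config")
}

sample_one <- function(x, size = 1, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size = size, replace = replace, prob = prob)]
}

term_pool <- function(prefix, n = 12) sprintf("%s%02d", prefix, seq_len(n))

generate_review <- function(case_idx, rev_idx, theta, universe, config) {
  measure <- sample_one(names(config$measure_probs),
                        prob = config$measure_probs)
  se <- stats::runif(1, config$se_range[1], config$se_range[2])
  est <- stats::rnorm(1, theta, se)
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  lo <- est - 1.96 * se
  hi <- est + 1.96 * se
  if (measure %in% c("RR", "OR")) {
    point <- exp(est); lo <- exp(lo); hi <- exp(hi)
  } else {
    point <- est
  }
  roster <- universe[stats::runif(length(universe)) <
                       config$trial_inclusion_prob]
  if (length(roster) == 0L) roster <- sample_one(universe)
  year <- sample_one(seq(config$search_years[1], config$search_years[2]))
  label <- sprintf("Review%02d %d", rev_idx, year)
  sr_record(
    label = label,
    sr_id = sprintf("case%03d-%s", case_idx, normalize_trial_id(label)),
    is_cochrane = stats::runif(1) < 0.15,
    pico = jitter_pico(case_idx, config),
    trials = trial_set(roster),
    search = search_profile(
      databases = sample_one(db_pool,
                             size = sample_one(seq(config$db_range[1],
                                                   config$db_range[2]))),
      grey_literature = if (stats::runif(1) < config$grey_prob) "yes"
      else "no",
      last_search_date = sprintf("%d-%02d-01", year, sample_one(1:12)),
      duplicate_independent_screening =
        if (stats::runif(1) < config$screening_prob) "yes" else "no",
      language_restriction = sample_one(c("none", "restricted"),
                                        prob = c(0.7, 0.3)),
      publication_status_scope = if (stats::runif(1) < config$grey_prob) {
        "includes_unpublished"
      } else {
        "published_only"
      },
      ipd_analysis = if (stats::runif(1) < config$ipd_prob) "yes" else "no"
    ),
    quality = list(quality_rating(
      "AMSTAR", sample_one(names(config$quality_probs),
                           prob = config$quality_probs),
      rct_quality_assessed = sample_one(c("yes", "no"), prob = c(0.6, 0.4))
    )),
    effect = effect_estimate(measure, point, lo, hi, p,
                             benefit_direction = config$benefit_direction),
    robis_verdict = sample_one(c("low_risk", "high_risk")),
    synthesis = synthesis_profile(
      data_extraction = sample_one(c("duplicate", "single", "unknown"),
                                   prob = c(0.5, 0.3, 0.2)),
      heterogeneity_assessed = sample_one(c("yes", "no")),
      synthesis_appropriate = sample_one(c("yes", "no"), prob = c(0.8, 0.2))
    )
  )
}

jitter_pico <- function(case_idx, config) {
  base <- list(
    population = term_pool(sprintf("pop%03d-", case_idx), 4),
    intervention = term_pool(sprintf("int%03d-", case_idx), 3),
    comparator = term_pool(sprintf("cmp%03d-", case_idx), 2),
    outcome = term_pool(sprintf("out%03d-", case_idx), 3)
  )
  jitter <- function(terms, tag) {
    keep <- terms[stats::runif(length(terms)) >= config$pico_jitter]
    if (length(keep) == 0L) keep <- terms[1]
    if (stats::runif(1) < config$pico_jitter) {
      keep <- c(keep, sprintf("%s-extra%02d", tag, sample_one(1:99)))
    }
    keep
  }
  pico_frame(
    population = "simulated population",
    intervention = "simulated intervention",
    comparator = "simulated comparator",
    outcome = "simulated outcome",
    population_terms = jitter(base$population, "pop"),
    intervention_terms = jitter(base$intervention, "int"),
    comparator_terms = jitter(base$comparator, "cmp"),
    outcome_terms = jitter(base$outcome, "out")
  )
}

#' Generate synthetic discordant-review cases
#'
#' Reproducible for a fixed config (the config's seed is set internally).
#'
#' @param config A [sim_config()].
#' @return Named list of [discordant_case()]s.
#' @export
generate_cases <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lapply(stats::setNames(seq_len(config$n_cases),
                         sprintf("sim-case-%03d", seq_len(config$n_cases))),
         function(i) {
    n_rev <- sample_one(seq(config$reviews_per_case[1],
                            config$reviews_per_case[2]))
    theta <- stats::rnorm(1, 0, config$true_effect_sd)
    universe <- sprintf("trial%03d %d", seq_len(config$trial_universe_size),
                        sample_one(1995:2019, config$trial_universe_size,
                                   replace = TRUE))
    reviews <- lapply(seq_len(n_rev), function(j) {
      generate_review(i, j, theta, universe, config)
    })
    discordant_case(
      case_id = sprintf("sim-case-%03d", i),
      question = pico_frame(
        population = "simulated population",
        intervention = "simulated intervention",
        comparator = "simulated comparator",
        outcome = "simulated outcome"
      ),
      primary_outcome = "simulated outcome",
      primary_intervention = "simulated intervention",
      reviews = reviews,
      judged_same_criteria = NA
    )
  })
}

#' Run two rulesets over the same cases and pair the assessments
#'
#' The deterministic engine is run once per case under each ruleset; the two
#' chosen sets and terminal steps form one [assessment_pair()] per case
#' (ruleset A plays the "original" assessor, B the "replication").
#'
#' @param cases List of [discordant_case()]s.
#' @param ruleset_a,ruleset_b [jadad_ruleset()]s.
#' @return List of [assessment_pair()]s; the traces are attached as
#'   attributes `traces_a` and `traces_b`.
#' @export
simulate_assessor_pair <- function(cases, ruleset_a, ruleset_b) {
  traces_a <- lapply(cases, run_jadad, ruleset = ruleset_a)
  traces_b <- lapply(cases, run_jadad, ruleset = ruleset_b)
  pairs <- Map(function(ta, tb) {
    assessment_pair(
      case_id = ta$case_id,
      original_choice = ta$chosen,
      original_final_step = ta$terminal_step,
      replication_choice = tb$chosen,
      replication_final_step = tb$terminal_step
    )
  }, traces_a, traces_b)
  structure(unname(pairs), traces_a = traces_a, traces_b = traces_b)
}

# Effect rows for simulated cases in the same layout the classifier expects:
# both assessors see the same underlying estimates.
sim_effect_rows <- function(cases) {
  rows <- list()
  for (case in cases) {
    for (r in case$reviews) {
      e <- r$effect
      for (assessor in c("authors", "replication")) {
        rows[[length(rows) + 1L]] <- data.frame(
          case_id = case$case_id, assessor = assessor, sr_id = r$sr_id,
          measure = e$measure, point = e$point, ci_low = e$ci_low,
          ci_high = e$ci_high, p_value = e$p_value,
          benefit_direction = e$benefit_direction, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Agreement as a function of ruleset perturbation
#'
#' For each cell of a perturbation grid, generates fresh case sets, runs the
#' engine under the baseline ruleset and under the perturbed one, and records
#' Monte-Carlo mean choice-agreement and direction-agreement rates.
#'
#' @param config A [sim_config()]; each replicate uses a seed derived from
#'   `config$seed`.
#' @param perturbations Named list; each element is a list of ruleset field
#'   overrides (see [perturb_ruleset()]), with `list()` meaning no
#'   perturbation.
#' @param n_rep Replicates per cell.
#' @return A data.frame with one row per cell: `perturbation`,
#'   `choice_agreement`, `direction_agreement`, `n_rep`, `n_cases`, `seed`.
#' @export
agreement_curve <- function(config, perturbations, n_rep = 3) {
  stopifnot(inherits(config, "sim_config"))
  if (length(perturbations) == 0L) {
    stop("perturbation grid must be non-empty", call. = FALSE)
  }
  if (is.null(names(perturbations)) || any(!nzchar(names(perturbations)))) {
    stop("perturbations must be a named list", call. = FALSE)
  }
  base <- jadad_ruleset("baseline")
  out <- lapply(seq_along(perturbations), function(ci) {
    overrides <- perturbations[[ci]]
    perturbed <- if (length(overrides)) {
      do.call(perturb_ruleset,
              c(list(base), overrides,
                list(ruleset_id = names(perturbations)[ci])))
    } else {
      base
    }
    choice_rates <- numeric(n_rep)
    dir_rates <- numeric(n_rep)
    for (rep in seq_len(n_rep)) {
      rep_seed <- (config$seed + 7919L * ci + 104729L * rep) %% .Machine$integer.max
      rep_config <- config
      rep_config$seed <- rep_seed
      cases <- generate_cases(rep_config)
      pairs <- simulate_assessor_pair(cases, base, perturbed)
      effects <- sim_effect_rows(cases)
      choice_rates[rep] <- choice_agreement(pairs)$frac_agree
      dir_rates[rep] <-
        direction_concordance(pairs, effects)$frac_direction_agree_overall
    }
    data.frame(
      perturbation = names(perturbations)[ci],
      choice_agreement = mean(choice_rates),
      direction_agreement = mean(dir_rates),
      n_rep = n_rep,
      n_cases = config$n_cases,
      seed = config$seed,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
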