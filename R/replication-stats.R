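# Descriptive agreement statistics over paired assessments. Everything here
# is counting: choice agreement is strict set equality of the chosen review
# sets, final-step agreement compares reported terminal steps, and direction
# concordance delegates to the effect classifier. Percentages are displayed
# rounded to whole numbers; exact fractions are kept alongside.

pct <- function(k, n) if (n == 0) NA_real_ else round(100 * k / n)

pair_agrees <- function(pair) {
  setequal(pair$original_choice, pair$replication_choice)
}

check_pairs <- function(pairs) {
  if (inherits(pairs, "assessment_pair")) pairs <- list(pairs)
  if (!all(vapply(pairs, inherits, logical(1), "assessment_pair"))) {
    stop("expected a list of assessment_pair objects", call. = FALSE)
  }
  pairs
}

#' Choice agreement between original and replication assessments
#'
#' Agreement is strict set equality of the two chosen review sets: choosing
#' the original review plus one more counts as disagreement.
#'
#' @param pairs List of [assessment_pair()]s.
#' @return List with `n_pairs`, `n_agree`, `n_disagree`, `pct_agree`,
#'   `pct_disagree` (display-rounded), and `frac_agree` (exact).
#' @export
choice_agreement <- function(pairs) {
  pairs <- check_pairs(pairs)
  agree <- vapply(pairs, pair_agrees, logical(1))
  n <- length(pairs)
  list(n_pairs = n, n_agree = sum(agree), n_disagree = sum(!agree),
       pct_agree = pct(sum(agree), n), pct_disagree = pct(sum(!agree), n),
       frac_agree = if (n == 0) NA_real_ else sum(agree) / n)
}

#' Final-decision-step agreement
#'
#' @param pairs List of [assessment_pair()]s.
#' @param restrict_to_disagree If `TRUE`, only pairs whose choice sets differ
#'   are tallied.
#' @return List with `n_same_step`, `n_diff_step`, `n_not_reported` (pairs
#'   where either side's step is unreported), and `n_subset`.
#' @export
step_agreement <- function(pairs, restrict_to_disagree = FALSE) {
  pairs <- check_pairs(pairs)
  if (restrict_to_disagree) {
    pairs <- Filter(function(p) !pair_agrees(p), pairs)
  }
  if (length(pairs) == 0L) {
    return(list(n_same_step = 0L, n_diff_step = 0L, n_not_reported = 0L,
                n_subset = 0L))
  }
  orig <- vapply(pairs, `[[`, character(1), "original_final_step")
  repl <- vapply(pairs, `[[`, character(1), "replication_final_step")
  nr <- orig == "not_reported" | repl == "not_reported"
  list(n_same_step = sum(!nr & orig == repl),
       n_diff_step = sum(!nr & orig != repl),
       n_not_reported = sum(nr),
       n_subset = length(pairs))
}

#' Tally terminal steps
#'
#' @param traces A list of `jadad_trace` objects, or a character vector of
#'   step letters / `"not_reported"`.
#' @return A data.frame with `step`, `n`, and display-rounded `pct`.
#' @export
routing_tally <- function(traces) {
  steps <- if (is.character(traces)) traces
  else vapply(traces, function(t) {
    stopifnot(inherits(t, "jadad_trace"))
    t$terminal_step
  }, character(1))
  levels <- c(terminal_steps, "not_reported")
  counts <- table(factor(steps, levels = levels))
  out <- data.frame(step = levels, n = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$pct <- vapply(out$n, pct, numeric(1), n = length(steps))
  out[out$n > 0L, , drop = FALSE]
}

#' Direction-of-effect concordance across paired assessments
#'
#' Pairs with identical choice sets concord by construction (the same primary
#' review yields the same verdict); the rest are classified via
#' [direction_agreement()].
#'
#' @param pairs List of [assessment_pair()]s.
#' @param effects Effect-row data.frame (see [direction_agreement()]).
#' @param alpha Significance level.
#' @return List with overall and among-disagreeing-choice counts, exact
#'   fractions, and display-rounded percentages.
#' @export
direction_concordance <- function(pairs, effects, alpha = 0.05) {
  pairs <- check_pairs(pairs)
  agree_choice <- vapply(pairs, pair_agrees, logical(1))
  disagreeing <- pairs[!agree_choice]
  dir <- vapply(disagreeing, direction_agreement, character(1),
                effects = effects, alpha = alpha)
  n <- length(pairs)
  n_dis <- length(disagreeing)
  n_dir_agree_dis <- sum(dir == "agree")
  n_overall <- sum(agree_choice) + n_dir_agree_dis
  list(
    n_pairs = n,
    n_direction_agree_overall = n_overall,
    pct_direction_agree_overall = pct(n_overall, n),
    frac_direction_agree_overall = if (n == 0) NA_real_ else n_overall / n,
    n_choice_disagree = n_dis,
    n_direction_agree_among_disagree = n_dir_agree_dis,
    pct_direction_agree_among_disagree = pct(n_dir_agree_dis, n_dis),
    n_direction_disagree = n_dis - n_dir_agree_dis
  )
}

#' Ease-of-use distribution and timing summary
#'
#' Pilot pairs and pairs without recorded ratings are excluded from the
#' distribution (and counted); the minutes summary is the median and
#' interquartile range over non-pilot pairs with recorded timings.
#'
#' @param pairs List of [assessment_pair()]s.
#' @return List with `n_rated`, `n_unrated`, `ease_counts` (green / yellow /
#'   red), `minutes_median`, `minutes_iqr` (length-2 vector, `NA` when fewer
#'   than two timings), and `n_timed`.
#' @export
ease_time_summary <- function(pairs) {
  pairs <- check_pairs(pairs)
  usable <- Filter(function(p) !p$pilot, pairs)
  ratings <- vapply(usable, `[[`, character(1), "ease_rating")
  rated <- ratings[!is.na(ratings)]
  minutes <- vapply(usable, `[[`, numeric(1), "minutes")
  minutes <- minutes[!is.na(minutes)]
  counts <- table(factor(rated, levels = ease_rubric()$colour))
  list(
    n_rated = length(rated),
    n_unrated = length(pairs) - length(rated),
    ease_counts = stats::setNames(as.integer(counts), names(counts)),
    pct_ease = stats::setNames(
      vapply(as.integer(counts), pct, numeric(1), n = length(rated)),
      names(counts)),
    n_timed = length(minutes),
    minutes_median = if (length(minutes)) stats::median(minutes) else NA_real_,
    minutes_iqr = if (length(minutes) >= 2L) {
      unname(stats::quantile(minutes, c(0.25, 0.75)))
    } else {
      c(NA_real_, NA_real_)
    }
  )
}

#' Full agreement report over a set of paired assessments
#'
#' Aggregates choice agreement, final-step agreement (overall and among
#' choice disagreements), terminal-step tallies for both assessor groups,
#' direction-of-effect concordance, and the ease/timing summary.
#'
#' @param pairs List of [assessment_pair()]s.
#' @param effects Effect-row data.frame (see [direction_agreement()]).
#' @param alpha Significance level for the classifier.
#' @return An object of class `agreement_report`.
#' @export
agreement_report <- function(pairs, effects, alpha = 0.05) {
  pairs <- check_pairs(pairs)
  choice <- choice_agreement(pairs)
  structure(list(
    n_pairs = choice$n_pairs,
    choice = choice,
    steps_all = step_agreement(pairs, restrict_to_disagree = FALSE),
    steps_among_disagree = step_agreement(pairs, restrict_to_disagree = TRUE),
    step_tally_original = routing_tally(
      vapply(pairs, `[[`, character(1), "original_final_step")),
    step_tally_replication = routing_tally(
      vapply(pairs, `[[`, character(1), "replication_final_step")),
    direction = direction_concordance(pairs, effects, alpha = alpha),
    ease_time = ease_time_summary(pairs)
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d paired assessments\n", x$n_pairs))
  cat(sprintf("  choice of review(s): %d agreed (%d%%), %d disagreed (%d%%)\n",
              x$choice$n_agree, x$choice$pct_agree,
              x$choice$n_disagree, x$choice$pct_disagree))
  cat(sprintf(
    "  among the %d disagreements: %d same final step, %d different\n",
    x$steps_among_disagree$n_subset, x$steps_among_disagree$n_same_step,
    x$steps_among_disagree$n_diff_step))
  cat(sprintf(
    "  direction of effect: %d/%d agree overall (%d%%); %d/%d (%d%%) among\n",
    x$direction$n_direction_agree_overall, x$n_pairs,
    x$direction$pct_direction_agree_overall,
    x$direction$n_direction_agree_among_disagree,
    x$direction$n_choice_disagree,
    x$direction$pct_direction_agree_among_disagree))
  cat("    assessments that chose a different review\n")
  et <- x$ease_time
  cat(sprintf(
    "  ease (n=%d rated): %d green / %d yellow / %d red; median %.1f min\n",
    et$n_rated, et$ease_counts[["green"]], et$ease_counts[["yellow"]],
    et$ease_counts[["red"]], et$minutes_median))
  invisible(x)
}

#' Export an agreement report as JSON
#'
#' @param report An `agreement_report`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "agreement_report"))
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, dataframe = "rows")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
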