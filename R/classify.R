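# Direction-of-effect classification. A pooled estimate is "significant" by
# the reported p-value when one is available (p takes precedence over the CI:
# printed intervals are rounded and can touch the null while p < alpha), else
# by strict exclusion of the null value from the 95% CI. Non-significant
# estimates are "null"; significant ones are "favourable" when the point lies
# on the outcome's benefit side of the null and "unfavourable" otherwise.

#' Classify a pooled effect as favourable, null, or unfavourable
#'
#' @param effect An [effect_estimate()].
#' @param alpha Significance level (default 0.05).
#' @return An object of class `effect_verdict`: list with `verdict`
#'   (favourable/null/unfavourable) and `significance_source`
#'   (p_value/ci/none).
#' @examples
#' classify_effect(effect_estimate("RR", 0.39, 0.26, 0.59, 0.005,
#'                                 benefit_direction = "lower_better"))
#' @export
classify_effect <- function(effect, alpha = 0.05) {
  stopifnot(inherits(effect, "effect_estimate"))
  has_p <- !is.na(effect$p_value)
  has_ci <- !is.na(effect$ci_low) && !is.na(effect$ci_high)
  if (!has_p && !has_ci) {
    stop("cannot classify: neither a p-value nor both CI bounds are present",
         call. = FALSE)
  }
  if (has_p) {
    significant <- effect$p_value < alpha
    source <- "p_value"
  } else {
    significant <- effect$ci_low > effect$null_value ||
      effect$ci_high < effect$null_value
    source <- "ci"
  }
  if (!significant) {
    return(structure(list(verdict = "null", significance_source = "none"),
                     class = "effect_verdict"))
  }
  if (effect$point == effect$null_value) {
    stop(paste("inconsistent estimate: point sits exactly at the null value",
               "yet the decision rule reports significance"), call. = FALSE)
  }
  below <- effect$point < effect$null_value
  favourable <- if (effect$benefit_direction == "lower_better") below
  else !below
  structure(list(
    verdict = if (favourable) "favourable" else "unfavourable",
    significance_source = source
  ), class = "effect_verdict")
}

#' @export
print.effect_verdict <- function(x, ...) {
  cat(sprintf("<effect_verdict> %s (significance via %s)\n", x$verdict,
              x$significance_source))
  invisible(x)
}

# Look up the effect row for one assessment's flagged primary review.
find_effect_row <- function(effects, case_id, assessor, sr_id) {
  hit <- effects$case_id == case_id & effects$assessor == assessor &
    effects$sr_id == sr_id
  which(hit)
}

effect_from_row <- function(row) {
  effect_estimate(
    measure = row$measure,
    point = row$point,
    ci_low = row$ci_low,
    ci_high = row$ci_high,
    p_value = row$p_value,
    benefit_direction = row$benefit_direction
  )
}

#' Do two assessments of a case agree in direction of effect?
#'
#' Classifies the pooled estimate of each assessment's flagged primary review
#' (the first element of its choice set) and compares verdicts. Symmetric in
#' the two assessments.
#'
#' @param pair An [assessment_pair()].
#' @param effects Effect-row data.frame as returned by
#'   [load_fixture_tables()]: columns `case_id`, `assessor`
#'   (`original`/`replication` or `authors`/`replication`), `sr_id`,
#'   `measure`, `point`, `ci_low`, `ci_high`, `p_value`, `benefit_direction`.
#' @param alpha Significance level passed to [classify_effect()].
#' @return `"agree"` or `"disagree"`.
#' @export
direction_agreement <- function(pair, effects, alpha = 0.05) {
  stopifnot(inherits(pair, "assessment_pair"))
  verdicts <- lapply(c(original = "authors", replication = "replication"),
                     function(assessor) {
    side <- if (assessor == "authors") "original" else "replication"
    primary <- pair[[paste0(side, "_choice")]][1]
    idx <- find_effect_row(effects, pair$case_id, assessor, primary)
    if (length(idx) == 0L) {
      stop(sprintf(
        "no effect row for the %s assessment of case %s (primary review %s)",
        side, pair$case_id, primary), call. = FALSE)
    }
    classify_effect(effect_from_row(effects[idx[1], , drop = FALSE]),
                    alpha = alpha)$verdict
  })
  if (identical(verdicts$original, verdicts$replication)) "agree"
  else "disagree"
}
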