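# Operationalization of the algorithm's tie-breaking tiers. The original
# decision procedure names the criteria consulted at Steps G-I but not their
# order or thresholds, so both tier orders and the Step G similarity threshold
# are explicit, serializable parameters: alternative operationalizations are
# first-class objects, which is what the simulator perturbs.

step_h_criteria <- c("n_databases", "grey_literature",
                     "duplicate_independent_screening", "last_search_date")
step_i_criteria <- c("publication_status_scope", "rct_quality_assessed",
                     "language_restriction", "ipd_analysis")

#' Ruleset: one operationalization of the algorithm's comparative steps
#'
#' @param ruleset_id Identifier recorded in every trace.
#' @param step_h_order Permutation of the four Step H search-rigour criteria,
#'   consulted lexicographically.
#' @param step_i_order Permutation of the four Step I publication-hierarchy
#'   criteria.
#' @param criteria_similarity_threshold Fraction in \[0, 1\]: minimum average
#'   PICO-term Jaccard similarity for Step G to declare criteria "the same"
#'   when no human judgment is recorded.
#' @param quality_comparison_mode Fixed at `"within_tool_only"`: quality is
#'   only ever compared on a single instrument's ordinal scale.
#' @return An object of class `jadad_ruleset`.
#' @export
jadad_ruleset <- function(ruleset_id = "default",
                          step_h_order = step_h_criteria,
                          step_i_order = step_i_criteria,
                          criteria_similarity_threshold = 0.8,
                          quality_comparison_mode = "within_tool_only") {
  if (!setequal(step_h_order, step_h_criteria) ||
      length(step_h_order) != length(step_h_criteria)) {
    abort_field("step_h_order",
                "must be a permutation of the Step H criterion set")
  }
  if (!setequal(step_i_order, step_i_criteria) ||
      length(step_i_order) != length(step_i_criteria)) {
    abort_field("step_i_order",
                "must be a permutation of the Step I criterion set")
  }
  thr <- check_scalar_number(criteria_similarity_threshold,
                             "criteria_similarity_threshold")
  if (thr < 0 || thr > 1) {
    abort_field("criteria_similarity_threshold", "must lie in [0, 1]")
  }
  quality_comparison_mode <- check_enum(quality_comparison_mode,
                                        "within_tool_only",
                                        "quality_comparison_mode")
  structure(list(
    ruleset_id = as.character(ruleset_id),
    step_h_order = as.character(step_h_order),
    step_i_order = as.character(step_i_order),
    criteria_similarity_threshold = thr,
    quality_comparison_mode = quality_comparison_mode
  ), class = "jadad_ruleset")
}

#' Perturb a ruleset
#'
#' Returns a copy of `ruleset` with the supplied fields replaced; the
#' simulator uses this to model a second assessor who interprets the
#' algorithm's under-specified tiers differently.
#'
#' @param ruleset A [jadad_ruleset()].
#' @param ... Fields to override (`step_h_order`, `step_i_order`,
#'   `criteria_similarity_threshold`, `ruleset_id`).
#' @return A new `jadad_ruleset`.
#' @export
perturb_ruleset <- function(ruleset, ...) {
  stopifnot(inherits(ruleset, "jadad_ruleset"))
  override <- list(...)
  args <- ruleset[c("ruleset_id", "step_h_order", "step_i_order",
                    "criteria_similarity_threshold",
                    "quality_comparison_mode")]
  bad <- setdiff(names(override), names(args))
  if (length(bad)) {
    stop(sprintf("unknown ruleset field(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  args[names(override)] <- override
  do.call(jadad_ruleset, args)
}

#' Write / read a ruleset as JSON
#' @param ruleset A [jadad_ruleset()].
#' @param path File path.
#' @return `write_ruleset` returns `path` invisibly; `read_ruleset` returns a
#'   validated `jadad_ruleset`.
#' @export
write_ruleset <- function(ruleset, path) {
  stopifnot(inherits(ruleset, "jadad_ruleset"))
  jsonlite::write_json(unclass(ruleset), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ruleset
#' @export
read_ruleset <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  jadad_ruleset(
    ruleset_id = raw$ruleset_id %||% "default",
    step_h_order = raw$step_h_order %||% step_h_criteria,
    step_i_order = raw$step_i_order %||% step_i_criteria,
    criteria_similarity_threshold = raw$criteria_similarity_threshold %||% 0.8,
    quality_comparison_mode = raw$quality_comparison_mode %||%
      "within_tool_only"
  )
}
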