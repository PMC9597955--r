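test_that("trial-id normalization collapses case and punctuation and is idempotent", {
  expect_equal(normalize_trial_id("Feng 2015"), "feng-2015")
  expect_equal(normalize_trial_id("FENG, 2015"), "feng-2015")
  expect_equal(normalize_trial_id("Dai et al. 2017"), "dai-2017")
  expect_equal(normalize_trial_id("van Eck   2012"), "van-eck-2012")
  expect_error(normalize_trial_id(""), "non-empty")

  set.seed(11)
  for (i in 1:50) {
    raw <- paste(sample(c(LETTERS, letters, 0:9, ",", ".", "-", " "),
                        sample(3:15, 1), replace = TRUE), collapse = "")
    norm <- tryCatch(normalize_trial_id(raw), error = function(e) NULL)
    if (!is.null(norm)) expect_identical(normalize_trial_id(norm), norm)
  }
})

test_that("domain types enforce their invariants", {
  expect_error(pico_frame(intervention = "", outcome = "pain"), "intervention")
  expect_error(trial_set(c("Feng 2015", "feng-2015")), "collision")
  expect_error(search_profile(grey_literature = "maybe"), "grey_literature")
  expect_error(search_profile(last_search_date = "soon"), "last_search_date")
  expect_error(quality_rating("AMSTAR", "stellar"), "unknown AMSTAR level")
  expect_error(quality_rating("AMSTAR", "high", ordinal_rank = 2),
               "inconsistent")
  expect_error(quality_rating("NIH", "high"), "tool")
  expect_error(effect_estimate("RR", 2, ci_low = 0.5, ci_high = 1.5,
                               benefit_direction = "lower_better"),
               "bracket")
  expect_error(effect_estimate("RR", 1, p_value = 2,
                               benefit_direction = "lower_better"),
               "p_value")
  # null value is derived from the measure alone
  expect_equal(effect_estimate("OR", 2, benefit_direction = "higher_better")$null_value, 1)
  expect_equal(effect_estimate("MD", 2, benefit_direction = "higher_better")$null_value, 0)

  r <- list(make_review("a"), make_review("b"))
  expect_error(make_case(r[1]), "at least two")
  expect_error(make_case(list(make_review("a"), make_review("a", "trial-x"))),
               "duplicate sr_id")
  expect_error(make_case(r, judged_same_question = c(zz = FALSE)),
               "judged_same_question")
  expect_error(assessment_pair("c", character(), "H", "a", "H"),
               "original_choice")
  expect_error(assessment_pair("c", "a", "H", "b", "H",
                               ease_rating = "blue"), "ease_rating")
  expect_error(assessment_pair("c", "a", "Z", "b", "H"),
               "original_final_step")
})

test_that("the ease rubric has exactly three colour levels", {
  rubric <- ease_rubric()
  expect_equal(rubric$colour, c("green", "yellow", "red"))
  expect_equal(nrow(rubric), 3L)
})

test_that("case files round-trip through JSON and reject invalid input", {
  case <- make_case(list(
    make_review("alpha-2010", amstar = "high",
                search = search_profile(databases = c("MEDLINE", "Embase"),
                                        grey_literature = "yes",
                                        last_search_date = "2018-03-01"),
                effect = effect_estimate("RR", 0.8, 0.6, 1.1, 0.2,
                                         benefit_direction = "lower_better")),
    make_review("beta-2012", amstar = "moderate")
  ), judged_same_criteria = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_case(case, path)
  expect_identical(load_case(path), case)

  # one-review file violates the two-review minimum
  bad <- case_to_list_for_test(case)
  bad$reviews <- bad$reviews[1]
  bad_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, bad_path, auto_unbox = TRUE, null = "null")
  expect_error(load_case(bad_path), "at least two")

  # out-of-vocabulary enum named in the error
  bad2 <- case_to_list_for_test(case)
  bad2$reviews[[1]]$robis_verdict <- "medium_risk"
  bad2_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad2, bad2_path, auto_unbox = TRUE, null = "null")
  expect_error(load_case(bad2_path), "robis_verdict")

  expect_error(load_case("no-such-file.json"), "not found")
})

test_that("synthetic round-trip holds across generated cases", {
  cfg <- sim_config(n_cases = 3, seed = 202)
  for (case in generate_cases(cfg)) {
    path <- withr::local_tempfile(fileext = ".json")
    write_case(case, path)
    # equality up to JSON float serialization (last-bit differences)
    expect_equal(load_case(path), case, tolerance = 1e-12)
  }
})

test_that("the bundled corpus loads with full integrity", {
  fx <- fixture_bundle()
  expect_length(fx$cases, 21L)
  expect_length(fx$pairs, 21L)
  expect_equal(nrow(fx$effects), 27L)

  expect_length(fx$cases[["song-2016"]]$reviews, 6L)
  expect_length(fx$cases[["xing-2016"]]$reviews, 10L)

  # every chosen review resolves to a review of its case
  for (pair in fx$pairs) {
    ids <- names(fx$cases[[pair$case_id]]$reviews)
    expect_true(all(pair$original_choice %in% ids))
    expect_true(all(pair$replication_choice %in% ids))
  }
  # every effect row resolves too
  for (i in seq_len(nrow(fx$effects))) {
    expect_true(fx$effects$sr_id[i] %in%
                  names(fx$cases[[fx$effects$case_id[i]]]$reviews))
  }
})

test_that("a truncated corpus fails the integrity check", {
  src <- fixture_dir()
  tmp <- withr::local_tempdir()
  file.copy(file.path(src, list.files(src, pattern = "csv$")), tmp)
  tab <- utils::read.csv(file.path(tmp, "table1_cases.csv"))
  utils::write.csv(tab[-1, ], file.path(tmp, "table1_cases.csv"),
                   row.names = FALSE)
  expect_error(load_fixture_tables(tmp), "fixture integrity")
})

test_that("the shipped example case file matches the corpus-built case", {
  path <- system.file("extdata", "cases", "song-2016.json",
                      package = "jadadr")
  expect_identical(load_case(path), fixture_bundle()$cases[["song-2016"]])
})
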