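test_that("Step A filters off-question reviews and Step B picks the closest", {
  r3 <- list(make_review("a"), make_review("b"), make_review("c"))
  case <- make_case(r3)

  all_on <- step_question_match(case)
  expect_null(all_on$terminal)
  expect_setequal(all_on$candidates, c("a", "b", "c"))

  one_off <- step_question_match(
    make_case(r3, judged_same_question = c(b = FALSE)))
  expect_null(one_off$terminal)
  expect_setequal(one_off$candidates, c("a", "c"))

  two_rev <- make_case(r3[1:2], judged_same_question = c(a = FALSE))
  res <- step_question_match(two_rev)
  expect_equal(res$terminal$step, "B")
  expect_equal(res$terminal$chosen, "b")
  trace <- run_jadad(two_rev)
  expect_equal(trace$terminal_step, "B")
  expect_equal(trace$chosen, "b")

  expect_error(
    step_question_match(make_case(r3[1:2],
                                  judged_same_question = c(a = FALSE,
                                                           b = FALSE))),
    "Step A")
})

test_that("Step C compares trial rosters as sets", {
  same <- list(make_review("a", trials = c("x 2001", "y 2002")),
               make_review("b", trials = c("Y, 2002", "X 2001")))
  expect_true(step_same_trials(same))
  diff <- list(make_review("a", trials = c("x 2001", "y 2002")),
               make_review("b", trials = c("x 2001", "z 2003")))
  expect_false(step_same_trials(diff))
  expect_error(step_same_trials(list(make_review("a", trials = character()),
                                     make_review("b"))),
               "Step C")
})

test_that("quality comparison stays within one instrument", {
  hh <- list(make_review("a", amstar = "high"),
             make_review("b", amstar = "high"))
  expect_true(step_same_quality(hh))
  hm <- list(make_review("a", amstar = "high"),
             make_review("b", amstar = "moderate"))
  expect_false(step_same_quality(hm))

  mixed <- list(
    make_review("a", amstar = "high"),
    sr_record(label = "b", sr_id = "b", pico = minimal_pico(),
              trials = trial_set("trial-b"),
              quality = list(quality_rating("ROBIS", "low_risk")))
  )
  expect_error(step_same_quality(mixed), "incomparable")
  expect_error(step_choose_highest_quality(mixed), "incomparable")
})

test_that("Step F keeps every review attaining the maximal rank", {
  cands <- list(make_review("a", amstar = "highest"),
                make_review("b", amstar = "high"),
                make_review("c", amstar = "high"))
  expect_equal(step_choose_highest_quality(cands), "a")
  tie <- list(make_review("a", amstar = "high"),
              make_review("b", amstar = "high"))
  expect_equal(step_choose_highest_quality(tie), c("a", "b"))

  set.seed(21)
  for (i in 1:200) {
    cands <- rand_candidates()
    ranks <- vapply(cands, function(r) r$quality[[1]]$ordinal_rank,
                    numeric(1))
    ids <- vapply(cands, `[[`, character(1), "sr_id")
    expect_equal(step_choose_highest_quality(cands),
                 sort(ids[ranks == max(ranks)]))
  }
})

test_that("Step E prefers duplicate extraction lexicographically and ties keep all", {
  dup <- make_review("a", synthesis = synthesis_profile("duplicate", "no",
                                                        "no"))
  single <- make_review("b", synthesis = synthesis_profile("single", "yes",
                                                           "yes"))
  expect_equal(step_compare_synthesis(list(dup, single)), "a")
  same <- list(make_review("a", synthesis = synthesis_profile("single",
                                                              "yes", "yes")),
               make_review("b", synthesis = synthesis_profile("single",
                                                              "yes", "yes")))
  expect_equal(step_compare_synthesis(same), c("a", "b"))
})

test_that("Step G honours the recorded judgment and otherwise averages Jaccard overlap", {
  cands <- list(make_review("a"), make_review("b"))
  expect_true(step_same_criteria(cands, judged = TRUE))
  expect_false(step_same_criteria(cands, judged = FALSE))

  # identical term lists: similarity 1 >= 0.8
  expect_true(step_same_criteria(cands, jadad_ruleset()))

  # disjoint outcome terms, everything else equal: mean Jaccard over
  # P/I/C/O = (1 + 1 + 1 + 0) / 4 = 0.75 < 0.8
  a <- make_review("a", pico = minimal_pico(out_terms = c("pain")))
  b <- make_review("b", pico = minimal_pico(out_terms = c("function")))
  expect_false(step_same_criteria(list(a, b), jadad_ruleset()))
  expect_true(step_same_criteria(
    list(a, b), jadad_ruleset(criteria_similarity_threshold = 0.75)))

  no_terms <- list(
    sr_record(label = "a", sr_id = "a", trials = trial_set("t-a"),
              pico = pico_frame(intervention = "i", outcome = "o")),
    sr_record(label = "b", sr_id = "b", trials = trial_set("t-b"),
              pico = pico_frame(intervention = "i", outcome = "o"))
  )
  expect_error(step_same_criteria(no_terms), "Step G")
})

test_that("Step H tiers decide in the configured order", {
  big <- make_review("a", search = search_profile(
    databases = paste0("db", 1:8)))
  small <- make_review("b", search = search_profile(
    databases = paste0("db", 1:4), grey_literature = "yes"))
  expect_equal(step_search_rigour(list(big, small)), "a")

  grey <- make_review("a", search = search_profile(
    databases = paste0("db", 1:4), grey_literature = "yes"))
  nogrey <- make_review("b", search = search_profile(
    databases = paste0("db", 1:4), grey_literature = "no"))
  expect_equal(step_search_rigour(list(grey, nogrey)), "a")

  # a reordered ruleset consults grey literature first
  flipped <- jadad_ruleset("flip", step_h_order = c(
    "grey_literature", "n_databases", "duplicate_independent_screening",
    "last_search_date"))
  expect_equal(step_search_rigour(list(big, small), flipped), "b")
})

test_that("Step I ranks unpublished-inclusive scope first and IPD cannot discriminate when absent", {
  unpub <- make_review("a", search = search_profile(
    publication_status_scope = "includes_unpublished"))
  pub <- make_review("b", search = search_profile(
    publication_status_scope = "published_only"))
  expect_equal(step_publication_hierarchy(list(unpub, pub)), "a")

  tied <- list(make_review("a"), make_review("b"))
  expect_equal(step_publication_hierarchy(tied), c("a", "b"))

  # with every earlier tier tied and no review doing IPD, I4 never splits
  no_ipd <- list(make_review("a"), make_review("b"))
  ipd_first <- jadad_ruleset("ipd-first", step_i_order = c(
    "ipd_analysis", "publication_status_scope", "rct_quality_assessed",
    "language_restriction"))
  expect_equal(step_publication_hierarchy(no_ipd, ipd_first), c("a", "b"))
})

test_that("routing follows the decision graph to a valid terminal", {
  roster <- c("x 2001", "y 2002")
  # same trials + same quality -> E
  e_case <- make_case(list(make_review("a", trials = roster),
                           make_review("b", trials = roster)))
  expect_equal(run_jadad(e_case)$terminal_step, "E")
  expect_equal(run_jadad(e_case)$chosen, c("a", "b"))

  # same trials + different quality -> F
  f_case <- make_case(list(make_review("a", trials = roster,
                                       amstar = "highest"),
                           make_review("b", trials = roster,
                                       amstar = "high")))
  f_trace <- run_jadad(f_case)
  expect_equal(f_trace$terminal_step, "F")
  expect_equal(f_trace$chosen, "a")

  # different trials, same criteria judged -> H
  h_case <- make_case(list(make_review("a"), make_review("b")),
                      judged_same_criteria = TRUE)
  expect_equal(run_jadad(h_case)$terminal_step, "H")

  # different trials, criteria judged different -> I
  i_case <- make_case(list(make_review("a"), make_review("b")),
                      judged_same_criteria = FALSE)
  expect_equal(run_jadad(i_case)$terminal_step, "I")

  # steps C, D, G appear as routing verdicts only
  for (tr in list(run_jadad(e_case), f_trace, run_jadad(h_case),
                  run_jadad(i_case))) {
    expect_true(tr$terminal_step %in% c("B", "E", "F", "H", "I"))
    expect_equal(tr$steps$step_id[nrow(tr$steps)], tr$terminal_step)
    expect_gt(length(tr$chosen), 0)
  }
})

test_that("identical inputs give byte-identical traces", {
  case <- make_case(list(make_review("a", search = rand_search_profile()),
                         make_review("b", search = rand_search_profile())),
                    judged_same_criteria = TRUE)
  j1 <- trace_to_json(run_jadad(case))
  j2 <- trace_to_json(run_jadad(case))
  expect_identical(as.character(j1), as.character(j2))
})

test_that("tie selection is invariant to review order", {
  set.seed(33)
  for (i in 1:100) {
    cands <- rand_candidates(4)
    case <- make_case(cands, judged_same_criteria = sample(c(TRUE, FALSE), 1))
    fwd <- run_jadad(case)
    bwd <- run_jadad(make_case(rev(cands),
                               judged_same_criteria =
                                 case$judged_same_criteria))
    expect_identical(fwd$chosen, bwd$chosen)
    expect_identical(fwd$terminal_step, bwd$terminal_step)
  }
})

test_that("every lexicographic selection matches the brute-force comparator", {
  set.seed(77)
  rs <- jadad_ruleset()
  for (i in 1:300) {
    cands <- rand_candidates()
    expect_equal(step_search_rigour(cands, rs),
                 oracle_lex_select(cands, rs$step_h_order))
    expect_equal(step_publication_hierarchy(cands, rs),
                 oracle_lex_select(cands, rs$step_i_order))
    expect_equal(step_compare_synthesis(cands),
                 oracle_lex_select(cands, c("data_extraction",
                                            "heterogeneity_assessed",
                                            "synthesis_appropriate")))
  }
})

test_that("rulesets validate their permutations and round-trip as JSON", {
  expect_error(jadad_ruleset(step_h_order = c("n_databases")), "permutation")
  expect_error(jadad_ruleset(criteria_similarity_threshold = 1.2), "0, 1")
  expect_error(perturb_ruleset(jadad_ruleset(), nope = 1), "unknown ruleset")

  rs <- perturb_ruleset(jadad_ruleset(), ruleset_id = "alt",
                        criteria_similarity_threshold = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_ruleset(rs, path)
  expect_equal(read_ruleset(path), rs)
})
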