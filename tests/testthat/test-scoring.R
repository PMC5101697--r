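test_that("proportional score is actual over maximum possible score", {
  r <- score_case_proportional(c(1, 1), c(1, 2))
  expect_equal(r$score, 2 / 3)
  expect_true(r$complete)
  expect_equal(score_case_proportional(c(1, 2, 3), c(1, 2, 3))$score, 1)

  miss <- score_case_proportional(c(1, NA), c(1, 2))
  expect_true(is.na(miss$score))
  expect_false(miss$complete)
  avail <- score_case_proportional(c(1, NA, 2), c(1, 2, 3),
                                   missing_policy = "available_items")
  expect_equal(avail$score, 3 / 4)   # hand sum over non-missing items
  expect_false(avail$complete)
  expect_error(score_case_proportional(3, 2), "outside")
})

test_that("dichotomous recoding maps any performance to 1, exhaustively", {
  expect_identical(recode_dichotomous(c(0L, 1L, 2L, NA)),
                   c(0L, 1L, 1L, NA))
  for (mx in 1:5) {
    v <- 0:mx
    expect_identical(recode_dichotomous(v), as.integer(v > 0L))
  }
})

test_that("dichotomous case score is 1 iff all steps followed", {
  expect_equal(score_case_dichotomous(c(1, 1), c(1, 2))$score, 1)
  expect_equal(score_case_dichotomous(c(1, 0), c(1, 2))$score, 0)
  # zero is decisive by default even with another item missing
  expect_equal(score_case_dichotomous(c(0, NA), c(1, 2))$score, 0)
  expect_true(is.na(score_case_dichotomous(c(0, NA), c(1, 2),
                                           zero_decisive = FALSE)$score))
  expect_true(is.na(score_case_dichotomous(c(1, NA), c(1, 2))$score))
})

test_that("dichotomous equals proportional-over-recoded-items = 1", {
  set.seed(42)
  for (i in 1:200) {
    k <- sample(1:8, 1)
    mx <- sample(1:3, k, replace = TRUE)
    v <- vapply(mx, function(m) sample(0:m, 1), 0L)
    dich <- score_case_dichotomous(v, mx)$score
    prop_rec <- score_case_proportional(recode_dichotomous(v),
                                        rep(1L, k))$score
    expect_identical(dich == 1, prop_rec == 1)
  }
})

test_that("raising one item never lowers the proportional score", {
  set.seed(7)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    mx <- sample(1:3, k, replace = TRUE)
    v <- vapply(mx, function(m) sample(0:m, 1), 0L)
    idx <- which(v < mx)
    if (!length(idx)) next
    j <- idx[sample.int(length(idx), 1)]
    v2 <- v; v2[j] <- v2[j] + 1L
    expect_gte(score_case_proportional(v2, mx)$score,
               score_case_proportional(v, mx)$score)
  }
})

test_that("harmonization recodes to binary items and is idempotent", {
  df <- wide_cases(case_id = "c1", referral = "direct_access",
                   qi1_item1 = 1L, qi1_item2 = 1L, qi1_item3 = 0L,
                   qi1_item4 = 2L, qi1_item5 = NA)
  cases <- load_cases(df)
  h <- harmonize_survey_to_ehr(cases)
  expect_true(all(h$max_value == 1L))
  expect_identical(h$value, c(1L, 1L, 0L, 1L, NA))
  h2 <- harmonize_survey_to_ehr(h)
  expect_equal(as.data.frame(h2), as.data.frame(h))

  ehr_like <- validate_ehr_copy(cases)
  expect_warning(harmonize_survey_to_ehr(ehr_like), "already dichotomous")
})

test_that("score_cases agrees with the per-case scorers", {
  coh <- generate_cohort(solo_config(3L, cases = 6L, indicators = c(2, 3, 8)),
                         seed = 5)
  cases <- coh$survey
  for (mode in c("proportional", "dichotomous")) {
    scored <- score_cases(cases, mode = mode)
    for (i in sample(nrow(scored), 20)) {
      row <- scored[i]
      sub <- cases[cases$case_id == row$case_id &
                     cases$indicator_id == row$indicator_id]
      # fixed-item indicators: unrecorded items are missing
      d <- qi_registry()[[as.character(row$indicator_id)]]
      v <- rep(NA_integer_, d$max_items)
      m <- d$item_max
      v[sub$item_index] <- sub$value
      oracle <- if (mode == "proportional") {
        score_case_proportional(v, m)
      } else {
        score_case_dichotomous(v, m)
      }
      expect_equal(row$score, oracle$score)
      expect_equal(row$complete, oracle$complete)
    }
  }
})

test_that("combined outcome indicator derives from QI5 and QI6", {
  df <- wide_cases(case_id = c("c1", "c2", "c3"),
                   qi5_item1 = c(1L, 0L, 1L),
                   qi6_ngoals = c(2L, 1L, 1L),
                   qi6_goal1 = c(3L, NA, NA),
                   qi6_goal2 = c(2L, NA, NA))
  cases <- derive_combined_outcome(load_cases(df))
  reg <- qi_registry(combine_qi5_qi6 = TRUE)
  sc <- score_cases(cases, registry = reg, mode = "dichotomous",
                    indicators = 56L)
  # c1: administrated + a recorded perceived result -> 1
  expect_equal(sc$score[sc$case_id == "c1"], 1)
  # c2: not administrated -> 0 (zero decisive)
  expect_equal(sc$score[sc$case_id == "c2"], 0)
  # c3: administrated but goal recorded without an answer -> 0
  expect_equal(sc$score[sc$case_id == "c3"], 0)
})

test_that("every case feeds exactly one of QI1/QI2 and all universal QIs", {
  coh <- generate_cohort(solo_config(4L, cases = 8L, indicators = 1:8),
                         seed = 9)
  scored <- score_cases(coh$survey, mode = "dichotomous")
  tab <- table(scored$case_id, scored$indicator_id)
  expect_true(all(tab[, "1"] + tab[, "2"] == 1L))
  for (id in c("3", "5", "6", "8")) expect_true(all(tab[, id] == 1L))
})

test_that("therapist aggregation reproduces the 8-of-10 example", {
  scores <- data.table::data.table(
    case_id = sprintf("c%02d", 1:10), therapist_id = "t1",
    practice_id = "p1", source = "survey", cohort_year = 2010L,
    indicator_id = 1L, scoring_mode = "dichotomous",
    score = c(rep(1, 8), 0, 0), complete = TRUE, n_items = 2L,
    n_missing = 0L)
  data.table::setattr(scores, "class", c("qi_case_scores", class(scores)))
  res <- therapist_scores(scores)
  expect_equal(res$mean_score, 0.8)
  expect_equal(res$completeness, 1)

  # undefined case scores are excluded from the mean but not the denominator
  scores$score[1:5] <- NA_real_
  scores$complete[1:5] <- FALSE
  scores$n_missing[1:5] <- 1L
  res <- therapist_scores(scores)
  expect_equal(res$n_cases_applicable, 10L)
  expect_equal(res$n_cases_complete, 5L)
  expect_equal(res$mean_score, mean(c(1, 1, 1, 0, 0)))

  one <- therapist_scores(scores[1])
  expect_true(is.na(one$mean_score))
  mixed <- data.table::copy(scores)[1, scoring_mode := "proportional"]
  expect_error(therapist_scores(mixed), "mix")
})
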