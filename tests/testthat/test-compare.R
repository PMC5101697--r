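test_that("relative change reproduces table arithmetic and guards zero", {
  expect_equal(relative_change(10, 10), 0)
  expect_equal(relative_change(0.5, 0.6), 20)
  expect_error(relative_change(0, 1), "survey-side value is 0")
  expect_error(relative_change(NA, 1), "NA")
  # sign always follows the mean difference
  set.seed(3)
  s <- runif(50, 0.1, 1); e <- runif(50, 0.1, 1)
  expect_equal(sign(relative_change(s, e)), sign(e - s))
})

make_results <- function(ids, source, values, year = NULL,
                         indicator_id = 1L) {
  year <- year %||% if (source == "survey") 2010L else 2011L
  res <- data.table::data.table(
    therapist_id = ids, indicator_id = indicator_id, source = source,
    cohort_year = year, scoring_mode = "dichotomous",
    n_cases_applicable = 10L, n_cases_complete = 9L,
    completeness = values, n_cases_scored = 9L, mean_score = values)
  data.table::setattr(res, "class",
                      c("qi_therapist_results", class(res)))
  res
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("matching joins the shared therapists only", {
  s <- make_results(c("A", "B", "C"), "survey", c(0.9, 0.8, 0.7))
  e <- make_results(c("B", "C", "D"), "ehr", c(0.85, 0.75, 0.6))
  pairs <- match_therapists(s, e)
  expect_setequal(pairs$therapist_id, c("B", "C"))
  expect_equal(attr(pairs, "n_unmatched_survey"), 1L)
  expect_equal(attr(pairs, "n_unmatched_ehr"), 1L)

  expect_warning(
    none <- match_therapists(make_results("A", "survey", 1),
                             make_results("Z", "ehr", 1)),
    "nothing to compare")
  expect_equal(nrow(none), 0L)
})

test_that("survey cohort-year precedence selects one record", {
  s <- rbind(make_results("A", "survey", 0.5, year = 2009L),
             make_results("A", "survey", 0.9, year = 2010L))
  data.table::setattr(s, "class", c("qi_therapist_results", class(s)))
  e <- make_results("A", "ehr", 0.7)
  most_recent <- match_therapists(s, e)
  expect_equal(most_recent$value_survey, 0.9)
  earliest <- match_therapists(s, e, precedence = "earliest")
  expect_equal(earliest$value_survey, 0.5)

  dup <- rbind(s[2], s[2])
  data.table::setattr(dup, "class", c("qi_therapist_results", class(dup)))
  expect_error(match_therapists(dup, e), "duplicate therapist")
})

test_that("pairs with an undefined side are dropped and counted", {
  s <- make_results(c("A", "B"), "survey", c(0.9, NA))
  e <- make_results(c("A", "B"), "ehr", c(0.8, 0.7))
  pairs <- match_therapists(s, e, metric = "correctness")
  expect_equal(nrow(pairs), 1L)
  expect_equal(attr(pairs, "n_dropped_undefined"), 1L)
})

test_that("identical sources compare as null; pair order is irrelevant", {
  set.seed(21)
  v <- runif(40, 0.5, 1)
  s <- make_results(sprintf("t%02d", 1:40), "survey", v)
  e <- make_results(sprintf("t%02d", 1:40), "ehr", v)
  pairs <- match_therapists(s, e)
  res <- compare_indicator(pairs)
  expect_false(res$significant)
  expect_false(res$relevant)
  expect_equal(res$relative_change_pct, 0)

  # a shuffled copy of nontrivial pairs yields the identical result
  e2 <- make_results(sprintf("t%02d", 1:40), "ehr",
                     pmin(1, v + runif(40, -0.1, 0.2)))
  pairs2 <- match_therapists(s, e2)
  perm <- pairs2[sample(nrow(pairs2))]
  expect_equal(as.data.frame(compare_indicator(pairs2)),
               as.data.frame(compare_indicator(perm)))
})

test_that("a shifted alternative at n = 500 is significant and relevant", {
  set.seed(77)
  n <- 500
  v <- runif(n, 0.6, 0.95)
  s <- make_results(sprintf("t%03d", 1:n), "survey", v)
  e <- make_results(sprintf("t%03d", 1:n), "ehr",
                    pmin(1, v * 1.10 + rnorm(n, 0, 0.02)))
  res <- compare_indicator(match_therapists(s, e))
  expect_true(res$significant)
  expect_true(res$relevant)
  expect_gt(res$relative_change_pct, 5)
})

test_that("validity filter drops indicators with too few valid scores", {
  make_scores <- function(frac_valid, n = 500L) {
    sc <- data.table::data.table(
      case_id = sprintf("c%04d", 1:n), therapist_id = "t1",
      practice_id = "p1", source = "ehr", cohort_year = 2011L,
      indicator_id = 5L, scoring_mode = "dichotomous",
      score = ifelse(seq_len(n) <= round(frac_valid * n), 1, NA_real_),
      complete = TRUE, n_items = 1L, n_missing = 0L)
    data.table::setattr(sc, "class", c("qi_case_scores", class(sc)))
    sc
  }
  res <- validity_filter(make_scores(0.116))
  expect_false(res$keep)
  expect_equal(res$valid_fraction, 0.116)
  expect_match(res$reason, "below_threshold")

  expect_true(validity_filter(make_scores(1))$keep)
  # >= semantics at the boundary
  expect_true(validity_filter(make_scores(0.5))$keep)
  expect_false(validity_filter(make_scores(0.499, n = 1000L))$keep)
})

test_that("sample characteristics summarize per source with reduced Ns", {
  df <- wide_cases(case_id = c("c1", "c2", "c3", "c4"),
                   referral = c("direct_access", "referred", "referred",
                                "referred"),
                   chronic = NA, qi5_item1 = 1L)
  df$sex <- c("male", "male", "female", "female")
  df$age <- c(14L, 15L, 44L, 65L)
  tab <- sample_characteristics(load_cases(df))
  g <- function(ch) tab[tab$characteristic == ch & tab$source == "survey"]
  expect_equal(g("male")$pct, 50)
  expect_equal(g("direct_access")$pct, 25)
  # closed band bounds: 14 -> 0-14, 15 -> 15-24
  expect_equal(g("age_0_14")$pct, 25)
  expect_equal(g("age_15_24")$pct, 25)
  expect_equal(g("age_45_64")$pct, 0)
  expect_equal(g("age_65_plus")$pct, 25)
  # all chronic flags missing: reported over zero cases
  expect_equal(g("chronic")$n, 0L)
  expect_equal(g("male")$n, 4L)
  expect_equal(g("therapists_1")$pct, 100)
})
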