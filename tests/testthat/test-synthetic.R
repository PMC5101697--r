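test_that("config validation rejects bad probabilities", {
  expect_error(cohort_config(p_direct_access = c(survey = 1.4, ehr = 0.4)),
               "config error")
  expect_error(cohort_config(n_practices = 0), "config error")
})

test_that("missingness defaults derive from completeness targets", {
  cfg <- cohort_config()
  # 5-item indicator at target 0.922: m = 1 - 0.922^(1/5)
  expect_equal(cfg$missingness$survey[["1"]], 1 - 0.922^(1 / 5))
  expect_equal(cfg$missingness$ehr[["2"]], 1 - 0.919^(1 / 4))
  expect_equal((1 - cfg$missingness$survey[["8"]])^7, 0.314)
})

test_that("no missingness gives completeness 1 everywhere", {
  cfg <- solo_config(5L, cases = 6L, indicators = c(1, 2, 3, 8),
                     completeness_targets = list(
                       survey = c(`1` = 1, `2` = 1, `3` = 1, `8` = 1),
                       ehr = c(`1` = 1, `2` = 1, `3` = 1, `8` = 1)))
  coh <- generate_cohort(cfg, seed = 2)
  for (src in c("survey", "ehr")) {
    res <- therapist_scores(score_cases(coh[[src]], mode = "dichotomous"))
    expect_true(all(res$completeness == 1))
  }
})

test_that("theta = 1 with no missingness puts every score at ceiling", {
  cfg <- solo_config(5L, cases = 6L, indicators = c(3, 8),
                     ceiling_mass = 1, ceiling_theta = 1,
                     completeness_targets = list(survey = c(`3` = 1, `8` = 1),
                                                 ehr = c(`3` = 1, `8` = 1)))
  coh <- generate_cohort(cfg, seed = 4)
  res <- therapist_scores(score_cases(coh$ehr, mode = "dichotomous"))
  expect_true(all(res$mean_score == 1))
  prop <- therapist_scores(score_cases(coh$survey, mode = "proportional"))
  expect_true(all(prop$mean_score == 1))
})

test_that("generation is seed-deterministic and streams are splittable", {
  cfg <- solo_config(4L, cases = 5L, indicators = c(1, 3, 6))
  a <- generate_cohort(cfg, seed = 42)
  b <- generate_cohort(cfg, seed = 42)
  expect_equal(as.data.frame(a$survey), as.data.frame(b$survey))
  expect_equal(as.data.frame(a$ehr), as.data.frame(b$ehr))
  expect_equal(a$truth$theta, b$truth$theta)
  c_ <- generate_cohort(cfg, seed = 43)
  expect_false(isTRUE(all.equal(as.data.frame(a$survey),
                                as.data.frame(c_$survey))))

  # enlarging the cohort leaves the existing therapists' draws untouched
  big <- generate_cohort(solo_config(6L, cases = 5L,
                                     indicators = c(1, 3, 6)), seed = 42)
  small_t <- unique(a$survey$therapist_id)
  expect_equal(
    as.data.frame(big$survey[big$survey$therapist_id %in% small_t]),
    as.data.frame(a$survey))
})

test_that("ground truth records theta per therapist and indicator", {
  coh <- generate_cohort(solo_config(3L, indicators = c(2, 5)), seed = 6)
  expect_setequal(names(coh$truth$theta),
                  c("therapist_id", "indicator_id", "theta"))
  expect_equal(nrow(coh$truth$theta), 3L * 2L)
  expect_true(all(coh$truth$theta$theta >= 0 & coh$truth$theta$theta <= 1))
  expect_equal(coh$truth$seed, 6)
})

test_that("EHR source omits non-extractable indicators and binary items", {
  coh <- generate_cohort(solo_config(3L, indicators = 1:8), seed = 8)
  expect_setequal(unique(coh$ehr$indicator_id), c(1, 2, 3, 5, 6, 8))
  expect_setequal(unique(coh$survey$indicator_id), 1:8)
  expect_true(all(coh$ehr$max_value == 1L))
  expect_true(all(coh$ehr$value %in% c(0L, 1L, NA)))
})

test_that("supplier deviation invalidates the arithmetic share of cases", {
  cfg <- solo_config(40L, cases = 10L, indicators = 5L,
                     completeness_targets = list(survey = c(`5` = 1),
                                                 ehr = c(`5` = 1)),
                     supplier_shares = c(S1 = 0.5, S2 = 0.3, S3 = 0.2))
  coh <- generate_cohort(cfg, seed = 10)
  expect_identical(
    as.data.frame(inject_supplier_deviation(coh$ehr, "S1",
                                            invalid_fraction = 0)),
    as.data.frame(coh$ehr))
  expect_error(inject_supplier_deviation(coh$ehr, "nope"), "unknown supplier")

  flagged <- unique(coh$ehr$supplier_id)[1:2]
  dev <- inject_supplier_deviation(coh$ehr, flagged, indicator = 5L,
                                   invalid_fraction = 0.8, seed = 10)
  sc <- score_cases(dev, mode = "dichotomous")
  n_flagged <- length(unique(coh$ehr$case_id[coh$ehr$supplier_id %in%
                                               flagged]))
  expected_invalid <- round(0.8 * n_flagged)
  expect_equal(sum(is.na(sc$score)), expected_invalid)
  vf <- validity_filter(sc)
  expect_equal(vf$valid_fraction,
               1 - expected_invalid / length(unique(coh$ehr$case_id)))
})

test_that("an unmatched-therapist fraction thins one source", {
  cfg <- solo_config(10L, cases = 3L, indicators = 5L,
                     unmatched_fraction = 0.4)
  coh <- generate_cohort(cfg, seed = 12)
  s_t <- unique(coh$survey$therapist_id)
  e_t <- unique(coh$ehr$therapist_id)
  expect_equal(length(union(s_t, e_t)), 10L)
  expect_equal(length(intersect(s_t, e_t)), 6L)
})

test_that("chronic cases are rarer in the EHR source at scale", {
  cfg <- solo_config(60L, cases = 20L, indicators = 5L)
  coh <- generate_cohort(cfg, seed = 14)
  chronic_rate <- function(x) {
    u <- unique(as.data.frame(x)[c("case_id", "chronic")])
    mean(u$chronic)
  }
  expect_gt(chronic_rate(coh$survey), chronic_rate(coh$ehr))
})
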