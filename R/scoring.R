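#' Recode a polytomous item response to the dichotomous framework
#'
#' Survey items may be polytomous (e.g. no = 0, somewhat = 1, completely =
#' 2); the EHR extraction can only assess \emph{whether} a step was
#' performed, not the degree. Recoding maps 'no' to 0 and any partial or
#' full performance to 1; a missing response stays missing.
#'
#' @param value integer vector of item responses; `NA` = missing.
#' @return integer vector in \{0, 1, `NA`\}.
#' @examples
#' recode_dichotomous(c(0, 1, 2, NA))  # 0 1 1 NA
#' @export
recode_dichotomous <- function(value) {
  as.integer(pmin(as.integer(value), 1L))
}

#' Proportional case score: actual score over maximum possible score
#'
#' The survey framework scores a patient case on an indicator as the sum of
#' its item values divided by the sum of the item maxima — the degree to
#' which the steps of the clinical reasoning process were followed. A case
#' with item values 1 (of max 1) and 1 (of max 2) scores 2/3 = 0.67.
#'
#' @param values integer vector of item responses for one case on one
#'   indicator; `NA` = missing.
#' @param max_values integer vector of the per-item maxima.
#' @param missing_policy `"exclude_incomplete"` (default): a case with any
#'   missing item has an undefined score. `"available_items"`: both sums run
#'   over the non-missing items only.
#' @return list with `score` (proportion in \[0, 1\], or `NA` when
#'   undefined) and `complete` (logical: no item missing).
#' @examples
#' score_case_proportional(c(1, 1), c(1, 2))$score  # 0.6667
#' @export
score_case_proportional <- function(values, max_values,
                                    missing_policy = c("exclude_incomplete",
                                                       "available_items")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(length(values) == length(max_values), all(max_values >= 1))
  ok <- !is.na(values)
  if (any(values[ok] < 0 | values[ok] > max_values[ok])) {
    stop("item value outside 0..max_value")
  }
  complete <- all(ok)
  score <- if (missing_policy == "exclude_incomplete") {
    if (complete) sum(values) / sum(max_values) else NA_real_
  } else {
    if (any(ok)) sum(values[ok]) / sum(max_values[ok]) else NA_real_
  }
  list(score = score, complete = complete)
}

#' Dichotomous case score: all steps followed, or not
#'
#' The EHR framework scores a case 1 on an indicator only when every item
#' recodes to 1 (every step of the clinical reasoning process was followed),
#' and 0 otherwise. The same worked example that scores 2/3 proportionally
#' scores 1 dichotomously, because 'somewhat' recodes to 1.
#'
#' @inheritParams score_case_proportional
#' @param zero_decisive logical; when `TRUE` (default) a single item recoded
#'   to 0 decides the case score (0) even if other items are missing —
#'   failing one step already means not all steps were followed. When
#'   `FALSE` (strict), any missing item makes the score undefined.
#' @return list with `score` (0, 1 or `NA`) and `complete`.
#' @examples
#' score_case_dichotomous(c(1, 1), c(1, 2))$score  # 1
#' score_case_dichotomous(c(1, 0), c(1, 2))$score  # 0
#' @export
score_case_dichotomous <- function(values, max_values = NULL,
                                   zero_decisive = TRUE) {
  if (!is.null(max_values)) {
    stopifnot(length(values) == length(max_values))
    ok <- !is.na(values)
    if (any(values[ok] < 0 | values[ok] > max_values[ok])) {
      stop("item value outside 0..max_value")
    }
  }
  rec <- recode_dichotomous(values)
  complete <- !anyNA(rec)
  any0 <- any(!is.na(rec) & rec == 0L)
  score <- if (any0 && (zero_decisive || complete)) {
    0
  } else if (!complete) {
    NA_real_
  } else {
    1
  }
  list(score = score, complete = complete)
}

#' Recode a survey dataset into the dichotomous (EHR) framework
#'
#' The proportional survey scores and the dichotomous EHR scores cannot be
#' compared as-is; the survey items must be recoded to 0/1 and the scores
#' recalculated the EHR way. This applies [recode_dichotomous()] to every
#' response and sets every item maximum to 1. The operation is idempotent.
#'
#' @param cases a `qi_cases` object with `source == "survey"`.
#' @return The harmonized `qi_cases`.
#' @export
harmonize_survey_to_ehr <- function(cases) {
  stopifnot(inherits(cases, "qi_cases"))
  if (any(cases$source == "ehr")) {
    warning("harmonizing data with source 'ehr': already dichotomous")
  }
  out <- copy(cases)
  out[, `:=`(value = recode_dichotomous(value), max_value = 1L)]
  out
}

#' Derive the combined outcome indicator (results administrated AND
#' perceived results recorded)
#'
#' The EHR extraction scheme merged the administration of intervention
#' results (indicator 5) with the recording of perceived results per goal
#' (indicator 6) into one outcome indicator. This derives its two binary
#' items per case: item 1 is the recoded indicator-5 response; item 2 is 1
#' when the case has at least one recorded goal with a non-missing
#' perceived-result response, 0 when goals were recorded but none answered,
#' and missing when indicator 6 was not recorded at all for the case.
#' The derived responses are appended as indicator 56; score them with a
#' registry built via `qi_registry(combine_qi5_qi6 = TRUE)`. It was never
#' successfully compared in practice, hence it is off by default
#' everywhere.
#'
#' @param cases a `qi_cases` dataset containing indicators 5 and 6.
#' @return The dataset with indicator-56 responses appended.
#' @export
derive_combined_outcome <- function(cases) {
  stopifnot(inherits(cases, "qi_cases"))
  dt <- as.data.table(cases)
  base_cols <- setdiff(names(dt), c("indicator_id", "item_index", "value",
                                    "max_value"))
  q5 <- dt[dt$indicator_id == 5L]
  item1 <- q5[, c(base_cols, "value"), with = FALSE]
  item1[, `:=`(indicator_id = 56L, item_index = 1L,
               value = recode_dichotomous(value), max_value = 1L)]
  q6 <- dt[dt$indicator_id == 6L]
  item2 <- q6[, list(value = as.integer(any(!is.na(value)))),
              by = base_cols]
  item2[, `:=`(indicator_id = 56L, item_index = 2L, max_value = 1L)]
  out <- rbind(dt, item1, item2, use.names = TRUE)
  setorderv(out, c("source", "therapist_id", "case_id", "indicator_id",
                   "item_index"))
  validate_cases(out)
}

#' Score every applicable (case, indicator) in a dataset
#'
#' The workhorse scorer. For each indicator scored, the applicable cases are
#' determined by referral status (QI1 direct-access only, QI2 referred only,
#' others all). Fixed-item indicators expect every item: a case lacking a
#' recorded response on an expected item is incomplete. Per-goal indicators
#' (6 and 7) are scored over the goals actually recorded for the case; a
#' case with no recorded goals is incomplete with an undefined score.
#'
#' @param cases a `qi_cases` object ([load_cases()] / [generate_cohort()]).
#' @param registry a [qi_registry()].
#' @param mode `"proportional"` (survey framework) or `"dichotomous"` (EHR
#'   framework; polytomous values are recoded on the fly).
#' @param missing_policy see [score_case_proportional()].
#' @param zero_decisive see [score_case_dichotomous()].
#' @param indicators integer vector of indicator ids to score; default all
#'   registry indicators present in the data.
#' @return A `qi_case_scores` data.table: one row per applicable (case,
#'   indicator) with `case_id`, `therapist_id`, `practice_id`, `source`,
#'   `indicator_id`, `scoring_mode`, `score` (`NA` = undefined), `complete`,
#'   `n_items`, `n_missing`.
#' @export
score_cases <- function(cases, registry = qi_registry(),
                        mode = c("proportional", "dichotomous"),
                        missing_policy = c("exclude_incomplete",
                                           "available_items"),
                        zero_decisive = TRUE,
                        indicators = NULL) {
  stopifnot(inherits(cases, "qi_cases"))
  mode <- match.arg(mode)
  missing_policy <- match.arg(missing_policy)
  dt <- as.data.table(cases)
  if (is.null(indicators)) {
    indicators <- intersect(as.integer(names(registry)),
                            unique(dt$indicator_id))
  }

  case_cols <- c("case_id", "therapist_id", "practice_id", "source",
                 "cohort_year")
  universe_base <- unique(dt[, c(case_cols, "referral"), with = FALSE],
                          by = c("case_id", "source"))
  out <- vector("list", length(indicators))
  for (i in seq_along(indicators)) {
    id <- indicators[i]
    d <- registry[[as.character(id)]]
    app <- universe_base[indicator_applicable(d, universe_base$referral)]
    sub <- dt[dt$indicator_id == id & indicator_applicable(d, dt$referral)]
    if (mode == "dichotomous") {
      sub <- copy(sub)[, value := recode_dichotomous(value)]
      sub[, max_value := 1L]
    }
    agg <- sub[, list(
      n_resp = .N,
      n_miss_rec = sum(is.na(value)),
      sum_v = sum(value, na.rm = TRUE),
      sum_m = sum(max_value),
      sum_v_avail = sum(value[!is.na(value)]),
      sum_m_avail = sum(max_value[!is.na(value)]),
      any_zero = any(!is.na(value) & value == 0L)
    ), by = case_cols]
    res <- merge(app[, case_cols, with = FALSE], agg, by = case_cols,
                 all.x = TRUE)
    res[is.na(n_resp), `:=`(n_resp = 0L, n_miss_rec = 0L, sum_v = 0,
                            sum_m = 0L, sum_v_avail = 0, sum_m_avail = 0L,
                            any_zero = FALSE)]
    n_expected <- if (d$variable_items) {
      pmax(res$n_resp, 1L)          # zero recorded goals still expects one
    } else {
      rep(d$max_items, nrow(res))
    }
    n_missing <- res$n_miss_rec + (n_expected - res$n_resp)
    complete <- n_missing == 0L
    score <- if (mode == "proportional") {
      if (missing_policy == "exclude_incomplete") {
        ifelse(complete, res$sum_v / res$sum_m, NA_real_)
      } else {
        ifelse(res$sum_m_avail > 0, res$sum_v_avail / res$sum_m_avail,
               NA_real_)
      }
    } else {
      ifelse(res$any_zero & (zero_decisive | complete), 0,
             ifelse(complete, 1, NA_real_))
    }
    res[, `:=`(indicator_id = id, scoring_mode = mode, score = score,
               complete = complete, n_items = n_expected,
               n_missing = n_missing)]
    out[[i]] <- res[, c(case_cols, "indicator_id", "scoring_mode", "score",
                        "complete", "n_items", "n_missing"), with = FALSE]
  }
  scores <- rbindlist(out)
  setorderv(scores, c("source", "indicator_id", "therapist_id", "case_id"))
  data.table::setattr(scores, "class", c("qi_case_scores", class(scores)))
  scores
}

#' Aggregate case scores to therapist-level indicator results
#'
#' Per (therapist, indicator, source): completeness is the proportion of
#' applicable cases without any missing item value; the mean indicator score
#' is the mean of the defined case scores (under the dichotomous framework,
#' the proportion of cases in which the therapist followed all the steps).
#' A therapist whose 10 cases include 8 with all steps followed scores 0.8.
#'
#' @param case_scores a `qi_case_scores` object from [score_cases()].
#' @return A `qi_therapist_results` data.table: `therapist_id`,
#'   `indicator_id`, `source`, `scoring_mode`, `n_cases_applicable`,
#'   `n_cases_complete`, `completeness`, `n_cases_scored`, `mean_score`
#'   (`NA` when no case has a defined score).
#' @export
therapist_scores <- function(case_scores) {
  stopifnot(inherits(case_scores, "qi_case_scores"))
  if (length(unique(case_scores$scoring_mode)) > 1L) {
    stop("case scores mix scoring modes; aggregate one mode at a time")
  }
  res <- as.data.table(case_scores)[, list(
    scoring_mode = scoring_mode[1L],
    n_cases_applicable = .N,
    n_cases_complete = sum(complete),
    completeness = mean(complete),
    n_cases_scored = sum(!is.na(score)),
    mean_score = {
      s <- score[!is.na(score)]
      if (length(s)) mean(s) else NA_real_
    }
  ), by = c("therapist_id", "indicator_id", "source", "cohort_year")]
  setorderv(res, c("source", "indicator_id", "therapist_id", "cohort_year"))
  data.table::setattr(res, "class", c("qi_therapist_results", class(res)))
  res
}
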