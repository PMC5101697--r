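#' Relative change between survey and EHR values
#'
#' Measured as (EHR - Survey) / Survey * 100 %. A relative change of at
#' least 5 % in magnitude is conventionally considered a relevant
#' difference between the two data sources.
#'
#' @param mean_survey numeric vector of survey-side values (> 0).
#' @param mean_ehr numeric vector of EHR-side values.
#' @return Signed percentages.
#' @examples
#' relative_change(31.4, 99.7)   # +217.5 at 1-decimal display
#' relative_change(0.97, 0.90)   # -7.2
#' @export
relative_change <- function(mean_survey, mean_ehr) {
  if (any(is.na(mean_survey)) || any(is.na(mean_ehr))) {
    stop("relative change undefined: NA input")
  }
  if (any(mean_survey == 0)) {
    stop("relative change undefined: survey-side value is 0")
  }
  (mean_ehr - mean_survey) / mean_survey * 100
}

#' Match therapist-level results across the two data sources
#'
#' Only therapists present in both the survey cohort and the EHR cohort can
#' be compared; this performs the inner join on therapist id, per indicator,
#' for the requested metric. When a therapist has survey results from more
#' than one cohort year, the precedence rule selects one (default: the most
#' recent year). Pairs in which either side's value is undefined are
#' excluded and counted — for correctness this explains why the matched N
#' is smaller than for completeness.
#'
#' @param survey,ehr `qi_therapist_results` objects from
#'   [therapist_scores()].
#' @param metric `"completeness"` (proportion of cases without missing item
#'   values) or `"correctness"` (mean indicator score).
#' @param precedence `"most_recent"` (default) or `"earliest"` survey cohort
#'   year for therapists present in several.
#' @return A `qi_matched_pairs` data.table with `therapist_id`,
#'   `indicator_id`, `metric`, `value_survey`, `value_ehr`; attributes
#'   `n_unmatched_survey`, `n_unmatched_ehr`, `n_dropped_undefined`.
#'   Warns (and returns zero rows) when the sources share no therapists.
#' @export
match_therapists <- function(survey, ehr,
                             metric = c("completeness", "correctness"),
                             precedence = c("most_recent", "earliest")) {
  metric <- match.arg(metric)
  precedence <- match.arg(precedence)
  value_col <- if (metric == "completeness") "completeness" else "mean_score"
  s <- as.data.table(survey)
  e <- as.data.table(ehr)
  if (any(s$source != "survey") || any(e$source != "ehr")) {
    stop("match_therapists expects survey-source and ehr-source results")
  }
  for (side in list(s, e)) {
    if (anyDuplicated(side[, c("therapist_id", "indicator_id",
                               "cohort_year"), with = FALSE])) {
      stop("duplicate therapist within one source-year")
    }
  }
  pick_year <- if (precedence == "most_recent") max else min
  s <- s[, .SD[cohort_year == pick_year(cohort_year)],
         by = c("therapist_id", "indicator_id")]
  e <- e[, .SD[cohort_year == pick_year(cohort_year)],
         by = c("therapist_id", "indicator_id")]

  sv <- s[, c("therapist_id", "indicator_id", value_col), with = FALSE]
  ev <- e[, c("therapist_id", "indicator_id", value_col), with = FALSE]
  setnames(sv, value_col, "value_survey")
  setnames(ev, value_col, "value_ehr")
  pairs <- merge(sv, ev, by = c("therapist_id", "indicator_id"))
  n_unmatched_survey <- length(setdiff(unique(s$therapist_id),
                                       unique(e$therapist_id)))
  n_unmatched_ehr <- length(setdiff(unique(e$therapist_id),
                                    unique(s$therapist_id)))
  defined <- !is.na(pairs$value_survey) & !is.na(pairs$value_ehr)
  n_dropped <- sum(!defined)
  pairs <- pairs[defined]
  pairs[, metric := metric]
  setcolorder(pairs, c("therapist_id", "indicator_id", "metric",
                       "value_survey", "value_ehr"))
  setorderv(pairs, c("indicator_id", "therapist_id"))
  if (!nrow(pairs)) {
    warning("no therapists shared between survey and EHR sources; ",
            "nothing to compare")
  }
  data.table::setattr(pairs, "n_unmatched_survey", n_unmatched_survey)
  data.table::setattr(pairs, "n_unmatched_ehr", n_unmatched_ehr)
  data.table::setattr(pairs, "n_dropped_undefined", n_dropped)
  data.table::setattr(pairs, "class", c("qi_matched_pairs", class(pairs)))
  pairs
}

#' Compare one indicator between sources on matched therapist pairs
#'
#' Runs the matched-pairs Wilcoxon signed-rank test on the therapist pairs,
#' computes the relative change of the group means, and applies the
#' significance (p < alpha) and relevance (|relative change| >= threshold)
#' rules.
#'
#' @param pairs a `qi_matched_pairs` table for a single indicator and
#'   metric (columns `value_survey`, `value_ehr`).
#' @param alpha significance level; default 0.001.
#' @param relevance_pct relevance threshold on |relative change| in percent;
#'   default 5.
#' @param exact_threshold passed to [wilcoxon_signed_rank()].
#' @param scale multiply group means by this before reporting (100 to
#'   report completeness as a percentage, 1 for mean scores). The relative
#'   change is scale-invariant.
#' @return A one-row data.table (`indicator_id`, `metric`, `mean_survey`,
#'   `mean_ehr`, `relative_change_pct`, `z_score`, `p_value`, `n_pairs`,
#'   `n_zero_diff`, `significant`, `relevant`) with the full `qi_wilcoxon`
#'   object in attribute `"wilcoxon"`.
#' @export
compare_indicator <- function(pairs, alpha = 0.001, relevance_pct = 5,
                              exact_threshold = 12L, scale = 1) {
  pairs <- as.data.table(pairs)
  if (!nrow(pairs)) stop("no matched pairs to compare")
  if (length(unique(pairs$indicator_id)) > 1L) {
    stop("compare_indicator expects pairs for a single indicator")
  }
  w <- wilcoxon_signed_rank(pairs$value_ehr, pairs$value_survey,
                            exact_threshold = exact_threshold)
  mean_s <- mean(pairs$value_survey) * scale
  mean_e <- mean(pairs$value_ehr) * scale
  rc <- relative_change(mean_s, mean_e)
  res <- data.table(
    indicator_id = pairs$indicator_id[1L],
    metric = if ("metric" %in% names(pairs)) pairs$metric[1L] else NA,
    mean_survey = mean_s,
    mean_ehr = mean_e,
    relative_change_pct = rc,
    z_score = w$z_score,
    p_value = w$p_value,
    n_pairs = nrow(pairs),
    n_zero_diff = w$n_zero,
    significant = w$p_value < alpha,
    relevant = abs(rc) >= relevance_pct)
  data.table::setattr(res, "wilcoxon", w)
  res
}

#' Validity filter: can an indicator be compared at all?
#'
#' An indicator is excluded from the source comparison when too few of the
#' applicable cases yield a valid (defined) score — as happens when EHR
#' suppliers deviate from the extraction algorithm and emit unusable values.
#' The fraction of applicable cases with a defined score is computed per
#' indicator and compared against `min_valid_fraction` (kept when greater
#' than or equal to the threshold).
#'
#' @param case_scores a `qi_case_scores` table (typically EHR-side,
#'   dichotomous).
#' @param min_valid_fraction minimum fraction of applicable cases with a
#'   defined score; default 0.5.
#' @return A data.table per indicator: `indicator_id`, `n_applicable`,
#'   `n_valid`, `valid_fraction`, `keep`, `reason` (`""` when kept).
#' @export
validity_filter <- function(case_scores, min_valid_fraction = 0.5) {
  stopifnot(inherits(case_scores, "qi_case_scores"))
  res <- as.data.table(case_scores)[, list(
    n_applicable = .N,
    n_valid = sum(!is.na(score))
  ), by = "indicator_id"]
  res[, valid_fraction := n_valid / n_applicable]
  res[, keep := valid_fraction >= min_valid_fraction]
  res[, reason := ifelse(keep, "", sprintf(
    "valid_fraction_below_threshold (%.3f < %.2f)", valid_fraction,
    min_valid_fraction))]
  setorderv(res, "indicator_id")
  res[]
}

#' Descriptive sample characteristics per data source
#'
#' Summarizes the patient, therapist and practice mix of a dataset, per
#' source: gender, direct access, age bands (0-14, 15-24, 25-44, 45-64,
#' 65+, closed bounds), chronic cases (treatment episodes of 3 months or
#' more), therapists per practice (1, 2, 3-4, 5+) and mono- vs
#' multidisciplinary practices. Categories with missing values (e.g. an
#' unextracted chronic flag) are summarized over the non-missing cases, so
#' their N is smaller than the total.
#'
#' @param cases a `qi_cases` object; the optional case columns `sex`
#'   (`"male"`/`"female"`), `age` (years) and `multidisciplinary` (logical)
#'   are used when present.
#' @return A data.table with `section`, `characteristic`, `source`, `pct`
#'   (percentage, 1-decimal scale), `n` (denominator).
#' @export
sample_characteristics <- function(cases) {
  stopifnot(inherits(cases, "qi_cases"))
  dt <- as.data.table(cases)
  keep <- c("case_id", "therapist_id", "practice_id", "source", "referral",
            "chronic", intersect(OPTIONAL_CASE_COLUMNS, names(dt)))
  u <- unique(dt[, keep, with = FALSE], by = c("case_id", "source"))

  rows <- list()
  add <- function(section, characteristic, flag, by_source) {
    # flag: logical (NA allowed); by_source: source of each element
    for (src in unique(by_source)) {
      f <- flag[by_source == src]
      n <- sum(!is.na(f))
      rows[[length(rows) + 1L]] <<- data.table(
        section = section, characteristic = characteristic, source = src,
        pct = if (n) 100 * mean(f, na.rm = TRUE) else NA_real_, n = n)
    }
  }

  if ("sex" %in% names(u)) {
    add("patient", "male", u$sex == "male", u$source)
  }
  add("patient", "direct_access", u$referral == "direct_access", u$source)
  if ("age" %in% names(u)) {
    bands <- list(`age_0_14` = c(0, 14), `age_15_24` = c(15, 24),
                  `age_25_44` = c(25, 44), `age_45_64` = c(45, 64),
                  `age_65_plus` = c(65, Inf))
    for (b in names(bands)) {
      add("patient", b, u$age >= bands[[b]][1] & u$age <= bands[[b]][2],
          u$source)
    }
  }
  add("patient", "chronic", u$chronic, u$source)

  pr <- u[, list(n_therapists = length(unique(therapist_id)),
                 multidisciplinary = if ("multidisciplinary" %in% names(u))
                   multidisciplinary[1L] else NA),
          by = c("practice_id", "source")]
  size_band <- cut(pr$n_therapists, c(0, 1, 2, 4, Inf),
                   labels = c("1", "2", "3-4", "5+"))
  for (b in levels(size_band)) {
    add("practice", paste0("therapists_", b), size_band == b, pr$source)
  }
  if ("multidisciplinary" %in% names(u)) {
    add("practice", "multidisciplinary", pr$multidisciplinary, pr$source)
  }
  res <- rbindlist(rows)
  setorderv(res, c("section", "characteristic", "source"))
  res[]
}
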