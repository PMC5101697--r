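# Fixture builders used across the suite. All data is constructed in code.

# Wide-format case table with sensible defaults; item columns passed as ...
wide_cases <- function(..., case_id, therapist_id = "t1",
                       practice_id = "p1", source = "survey",
                       cohort_year = 2010L, referral = "referred",
                       chronic = FALSE) {
  data.frame(case_id = case_id, therapist_id = therapist_id,
             practice_id = practice_id, source = source,
             cohort_year = cohort_year, referral = referral,
             chronic = chronic, ..., stringsAsFactors = FALSE)
}

# A two-item indicator matching the canonical worked example: item 1 binary,
# item 2 three-level (no/somewhat/completely). Registry via YAML override.
worked_example_registry <- function() {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  yaml::write_yaml(list(indicators = list(
    list(indicator_id = 1L, short_name = "worked example",
         applicability = "all", item_max = c(1L, 2L)))), path)
  registry_from_yaml(path)
}

# Independent oracle: exact two-sided signed-rank p by brute-force
# enumeration over all 2^n sign vectors (expand.grid; no shared code with
# the implementation).
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- signs %*% r
  eps <- 1e-9
  min(1, 2 * min(mean(w_all <= w_obs + eps), mean(w_all >= w_obs - eps)))
}

# Relabel a survey dataset as its own EHR extraction (identical content):
# the null comparison in which both sources measure the same thing.
validate_ehr_copy <- function(cases, cohort_year = 2011L) {
  out <- data.table::copy(cases)
  out[, `:=`(source = "ehr", cohort_year = cohort_year)]
  out
}

# Small generator config: one therapist per practice.
solo_config <- function(n_therapists, cases = 10L, indicators = 3L, ...) {
  cohort_config(
    n_practices = n_therapists,
    therapists_per_practice_weights = c(`1` = 1, `2` = 0, `3-4` = 0,
                                        `5+` = 0),
    cases_per_therapist = c(survey = cases, ehr = cases),
    indicators = indicators, ...)
}
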