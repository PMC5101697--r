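#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: a hierarchy of
#' practices, therapists and patient cases, observed through two sources —
#' a provider survey (at least 30 scored cases per therapist, polytomous
#' items) and an EHR extraction (fewer cases per therapist, binary items,
#' chronic patients underrepresented). Defaults reproduce the published
#' cohort structure: ~2,400 practices with the printed practice-size mix,
#' therapists present in both sources, source-specific direct-access,
#' chronic, gender and age-band rates, strong ceiling effects in the
#' per-therapist step-following probabilities, and per-item missingness
#' calibrated so that expected completeness matches the printed per-source
#' marginals via (1 - m)^k.
#'
#' @param n_practices number of practices (default 2400).
#' @param therapists_per_practice_weights named weights over practice-size
#'   bands `1`, `2`, `3-4`, `5+` (normalized internally).
#' @param cases_per_therapist named integer vector `c(survey=, ehr=)`.
#' @param p_direct_access,p_chronic,p_male named per-source probabilities.
#' @param age_band_probs list with per-source probabilities over the age
#'   bands 0-14, 15-24, 25-44, 45-64, 65+.
#' @param p_multidisciplinary probability a practice is multidisciplinary.
#' @param ceiling_mass,ceiling_theta,theta_beta the per-(therapist,
#'   indicator) step-following probability theta is drawn from a
#'   ceiling-heavy mixture: with probability `ceiling_mass`, theta =
#'   `ceiling_theta`; otherwise theta ~ Beta(`theta_beta[1]`,
#'   `theta_beta[2]`).
#' @param theta_shift_ehr additive shift applied to theta for the EHR
#'   source (clamped to \[0, 1\]); 0 generates the null of identical
#'   process quality in both sources.
#' @param completeness_targets list with per-source named vectors of target
#'   expected completeness per indicator; per-item missingness is derived
#'   as m = 1 - target^(1/k) for a k-item indicator. Indicators without a
#'   published marginal default to 0.98.
#' @param missingness optional list with per-source named vectors of
#'   per-item missingness per indicator, overriding the derivation from
#'   `completeness_targets`.
#' @param goal_count_probs probabilities over 1, 2, ... recorded goals per
#'   case for the per-goal indicators.
#' @param p_full_given_success given a step was performed, probability the
#'   polytomous survey response is the maximum level (vs. a partial level).
#' @param supplier_shares named shares of practices per EHR supplier; the
#'   default has 15 suppliers, the two largest covering 68.4 % and the five
#'   largest 92.5 % of practices.
#' @param indicators indicator ids to generate (default 1:8; EHR rows are
#'   only emitted for EHR-extractable indicators).
#' @param unmatched_fraction fraction of therapists present in only one
#'   source (alternating), to exercise the matching join; default 0.
#' @return A validated list of class `qi_cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(
    n_practices = 2400L,
    therapists_per_practice_weights = c(`1` = 0.032, `2` = 0.188,
                                        `3-4` = 0.336, `5+` = 0.445),
    cases_per_therapist = c(survey = 30L, ehr = 15L),
    p_direct_access = c(survey = 0.383, ehr = 0.440),
    p_chronic = c(survey = 0.160, ehr = 0.089),
    p_male = c(survey = 0.422, ehr = 0.443),
    age_band_probs = list(
      survey = c(0.064, 0.087, 0.278, 0.357, 0.213),
      ehr = c(0.034, 0.096, 0.266, 0.371, 0.233)),
    p_multidisciplinary = 0.286,
    ceiling_mass = 0.7,
    ceiling_theta = 0.995,
    theta_beta = c(12, 1.5),
    theta_shift_ehr = 0,
    completeness_targets = list(
      survey = c(`1` = 0.922, `2` = 0.999, `3` = 0.924, `8` = 0.314),
      ehr = c(`1` = 0.999, `2` = 0.919, `3` = 0.962, `8` = 0.997)),
    missingness = NULL,
    goal_count_probs = c(0.50, 0.35, 0.15),
    p_full_given_success = 0.7,
    supplier_shares = NULL,
    indicators = 1:8,
    unmatched_fraction = 0) {
  if (is.null(supplier_shares)) {
    supplier_shares <- c(S01 = 0.40, S02 = 0.284,
                         S03 = 0.0803, S04 = 0.0803, S05 = 0.0804,
                         stats::setNames(rep(0.0075, 10),
                                         sprintf("S%02d", 6:15)))
  }
  cfg <- list(
    n_practices = as.integer(n_practices),
    therapists_per_practice_weights =
      therapists_per_practice_weights / sum(therapists_per_practice_weights),
    cases_per_therapist = cases_per_therapist,
    p_direct_access = p_direct_access, p_chronic = p_chronic,
    p_male = p_male, age_band_probs = age_band_probs,
    p_multidisciplinary = p_multidisciplinary,
    ceiling_mass = ceiling_mass, ceiling_theta = ceiling_theta,
    theta_beta = theta_beta, theta_shift_ehr = theta_shift_ehr,
    completeness_targets = completeness_targets,
    goal_count_probs = goal_count_probs / sum(goal_count_probs),
    p_full_given_success = p_full_given_success,
    supplier_shares = supplier_shares / sum(supplier_shares),
    indicators = as.integer(indicators),
    unmatched_fraction = unmatched_fraction)

  probs <- c(cfg$therapists_per_practice_weights, cfg$p_direct_access,
             cfg$p_chronic, cfg$p_male, unlist(cfg$age_band_probs),
             cfg$p_multidisciplinary, cfg$ceiling_mass, cfg$ceiling_theta,
             cfg$goal_count_probs, cfg$p_full_given_success,
             cfg$supplier_shares, cfg$unmatched_fraction)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("config error: all probabilities must lie in [0, 1]")
  }
  if (abs(cfg$theta_shift_ehr) > 1) {
    stop("config error: |theta_shift_ehr| must be <= 1")
  }
  if (cfg$n_practices < 1L || any(cfg$cases_per_therapist < 1L)) {
    stop("config error: need at least one practice and one case per source")
  }
  cfg$missingness <- if (is.null(missingness)) {
    derive_missingness(cfg)
  } else {
    missingness
  }
  structure(cfg, class = "qi_cohort_config")
}

# m = 1 - completeness^(1/k): per-item missingness giving the target
# expected completeness for a k-item indicator. Per-goal indicators use the
# expected recorded goal count as k.
derive_missingness <- function(cfg, registry = qi_registry()) {
  k_goal <- sum(seq_along(cfg$goal_count_probs) * cfg$goal_count_probs)
  lapply(stats::setNames(nm = c("survey", "ehr")), function(src) {
    targets <- cfg$completeness_targets[[src]]
    vapply(stats::setNames(nm = as.character(cfg$indicators)), function(id) {
      d <- registry[[id]]
      k <- if (d$variable_items) k_goal else d$max_items
      tgt <- if (id %in% names(targets)) targets[[id]] else 0.98
      1 - tgt^(1 / k)
    }, 0)
  })
}

# Derive a per-unit RNG seed from the master seed so that each therapist
# (or practice) has its own stream: adding units never perturbs the draws
# of earlier ones. Kept below 2^31.
unit_seed <- function(seed, unit_index, salt = 0L) {
  (as.double(seed) * 48271 + unit_index * 7919 + salt * 104729) %% 2147483629
}

#' Generate a matched survey + EHR synthetic cohort
#'
#' Draws the practice/therapist hierarchy, per-(therapist, indicator)
#' step-following probabilities theta from a ceiling-heavy mixture, and
#' item-level case data for both sources: each item succeeds independently
#' with probability theta (survey responses polytomous over 0..max with the
#' success mass split between partial and full levels; EHR responses
#' binary), then is masked missing with the configured per-item rate. Each
#' therapist appears in both sources (minus any configured unmatched
#' fraction); chronic patients are underrepresented in the EHR source;
#' per-goal indicators record a data-driven number of goals per case; each
#' practice is assigned to an EHR supplier by the configured market shares.
#'
#' All randomness flows from `seed` through per-practice and per-therapist
#' streams, so enlarging the cohort does not perturb the draws of existing
#' therapists.
#'
#' @param config a [cohort_config()].
#' @param seed integer master seed.
#' @return A list of class `qi_cohort`:
#'   \describe{
#'     \item{survey, ehr}{`qi_cases` datasets (survey cases in cohort year
#'       2010, EHR cases in 2011).}
#'     \item{truth}{ground truth for recovery tests: `theta` (per
#'       therapist and indicator), `missingness` (per source and
#'       indicator), `suppliers` (practice-to-supplier map), `seed` and the
#'       config.}
#'   }
#' @examples
#' coh <- generate_cohort(cohort_config(n_practices = 3,
#'                                      cases_per_therapist = c(survey = 5,
#'                                                              ehr = 5),
#'                                      indicators = c(1, 2, 3)), seed = 7)
#' nrow(unique(coh$survey[, c("case_id", "source")]))
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "qi_cohort_config"))
  registry <- qi_registry()
  band_sizes <- list(`1` = 1L, `2` = 2L, `3-4` = 3:4, `5+` = 5:8)

  # --- structure: practices, sizes, suppliers, therapists ----------------
  n_p <- config$n_practices
  practice_id <- sprintf("p%05d", seq_len(n_p))
  sizes <- integer(n_p)
  supplier <- character(n_p)
  multi <- logical(n_p)
  for (i in seq_len(n_p)) {
    set.seed(unit_seed(seed, i, salt = 1L))
    band <- sample(names(band_sizes), 1L,
                   prob = config$therapists_per_practice_weights)
    sizes[i] <- if (length(band_sizes[[band]]) == 1L) band_sizes[[band]] else
      sample(band_sizes[[band]], 1L)
    supplier[i] <- sample(names(config$supplier_shares), 1L,
                          prob = config$supplier_shares)
    multi[i] <- stats::runif(1) < config$p_multidisciplinary
  }
  therapists <- data.table(
    practice_id = rep(practice_id, sizes),
    supplier_id = rep(supplier, sizes),
    multidisciplinary = rep(multi, sizes))
  therapists[, therapist_id := sprintf("t%06d", .I)]
  therapists[, therapist_index := .I]
  n_t <- nrow(therapists)

  # unmatched therapists alternate between survey-only and ehr-only
  in_both <- rep(TRUE, n_t)
  n_unmatched <- floor(config$unmatched_fraction * n_t)
  skip_src <- rep(c("ehr", "survey"), length.out = n_unmatched)

  m_rates <- config$missingness
  ind_ids <- config$indicators
  pieces <- vector("list", n_t * 2L)
  theta_list <- vector("list", n_t)

  for (ti in seq_len(n_t)) {
    th <- therapists[ti]
    set.seed(unit_seed(seed, ti, salt = 2L))
    at_ceiling <- stats::runif(length(ind_ids)) < config$ceiling_mass
    theta <- ifelse(at_ceiling, config$ceiling_theta,
                    stats::rbeta(length(ind_ids), config$theta_beta[1],
                                 config$theta_beta[2]))
    names(theta) <- as.character(ind_ids)
    theta_list[[ti]] <- data.table(therapist_id = th$therapist_id,
                                   indicator_id = ind_ids, theta = theta)
    for (src in c("survey", "ehr")) {
      if (ti <= n_unmatched && skip_src[ti] == src) next
      pieces[[(ti - 1L) * 2L + (src == "ehr") + 1L]] <-
        gen_therapist_source(th, src, theta, config, m_rates[[src]],
                             registry, ind_ids)
    }
  }
  truth <- list(
    theta = rbindlist(theta_list),
    missingness = m_rates,
    suppliers = data.table(practice_id = practice_id,
                           supplier_id = supplier),
    seed = seed,
    config = config)
  all_rows <- rbindlist(pieces[!vapply(pieces, is.null, TRUE)])
  out <- list(
    survey = validate_cases(all_rows[all_rows$source == "survey"]),
    ehr = validate_cases(all_rows[all_rows$source == "ehr"]),
    truth = truth)
  structure(out, class = "qi_cohort")
}

# Item-level rows for one therapist in one source. Called inside the
# therapist's RNG stream.
gen_therapist_source <- function(th, src, theta, config, m_ind, registry,
                                 ind_ids) {
  n_cases <- as.integer(config$cases_per_therapist[[src]])
  year <- if (src == "survey") 2010L else 2011L
  referral <- ifelse(stats::runif(n_cases) < config$p_direct_access[[src]],
                     "direct_access", "referred")
  chronic <- stats::runif(n_cases) < config$p_chronic[[src]]
  sex <- ifelse(stats::runif(n_cases) < config$p_male[[src]],
                "male", "female")
  band_lo <- c(0L, 15L, 25L, 45L, 65L)
  band_hi <- c(14L, 24L, 44L, 64L, 89L)
  band <- sample.int(5L, n_cases, replace = TRUE,
                     prob = config$age_band_probs[[src]])
  age <- band_lo[band] +
    floor(stats::runif(n_cases) * (band_hi[band] - band_lo[band] + 1L))
  case_id <- sprintf("%s_%s_c%03d", th$therapist_id, src, seq_len(n_cases))

  shift <- if (src == "ehr") config$theta_shift_ehr else 0
  pieces <- vector("list", length(ind_ids))
  for (j in seq_along(ind_ids)) {
    id <- ind_ids[j]
    d <- registry[[as.character(id)]]
    if (src == "ehr" && !d$extractable_from_ehr) next
    app <- indicator_applicable(d, referral)
    if (!any(app)) next
    idx <- which(app)
    if (d$variable_items) {
      ngoals <- sample.int(length(config$goal_count_probs), length(idx),
                           replace = TRUE, prob = config$goal_count_probs)
      row_case <- rep(idx, ngoals)
      item_index <- unlist(lapply(ngoals, seq_len), use.names = FALSE)
    } else {
      row_case <- rep(idx, each = d$max_items)
      item_index <- rep(seq_len(d$max_items), length(idx))
    }
    n_rows <- length(row_case)
    max_value <- d$item_max[item_index]
    th_eff <- min(1, max(0, theta[[as.character(id)]] + shift))
    success <- stats::runif(n_rows) < th_eff
    value <- integer(n_rows)
    if (src == "survey") {
      full <- stats::runif(n_rows) < config$p_full_given_success
      partial <- pmax(1L, ceiling(stats::runif(n_rows) * (max_value - 1L)))
      value[success] <- ifelse(full | max_value == 1L, max_value,
                               partial)[success]
    } else {
      value[success] <- 1L
      max_value <- rep(1L, n_rows)
    }
    value[stats::runif(n_rows) < m_ind[[as.character(id)]]] <- NA_integer_
    pieces[[j]] <- data.table(
      case_id = case_id[row_case], indicator_id = id,
      item_index = item_index, value = value, max_value = max_value,
      referral = referral[row_case], chronic = chronic[row_case],
      sex = sex[row_case], age = age[row_case])
  }
  rows <- rbindlist(pieces[!vapply(pieces, is.null, TRUE)])
  if (!nrow(rows)) return(NULL)
  rows[, `:=`(therapist_id = th$therapist_id, practice_id = th$practice_id,
              supplier_id = th$supplier_id,
              multidisciplinary = th$multidisciplinary,
              source = src, cohort_year = year)]
  setcolorder(rows, c(CASE_COLUMNS,
                      c("supplier_id", "sex", "age", "multidisciplinary"),
                      c("indicator_id", "item_index", "value", "max_value")))
  rows
}

#' Inject a supplier-level extraction deviation
#'
#' Emulates EHR suppliers deviating from the uniform extraction algorithm:
#' a configured fraction of the flagged suppliers' cases lose their valid
#' score on the designated indicator (all of the indicator's item values
#' become missing for those cases). Deterministic under `seed`.
#'
#' @param cases an EHR-source `qi_cases` dataset with a `supplier_id`
#'   column.
#' @param suppliers character vector of supplier ids to flag.
#' @param indicator indicator id affected (default 5, administration of
#'   intervention results).
#' @param invalid_fraction fraction of each flagged supplier's cases whose
#'   scores are invalidated (default 1).
#' @param seed integer seed for selecting the affected cases.
#' @return The modified `qi_cases`.
#' @export
inject_supplier_deviation <- function(cases, suppliers, indicator = 5L,
                                      invalid_fraction = 1, seed = 1L) {
  stopifnot(inherits(cases, "qi_cases"))
  if (!"supplier_id" %in% names(cases)) {
    stop("dataset has no supplier_id column")
  }
  unknown <- setdiff(suppliers, unique(cases$supplier_id))
  if (length(unknown)) {
    stop("unknown supplier(s): ", paste(unknown, collapse = ", "))
  }
  if (invalid_fraction < 0 || invalid_fraction > 1) {
    stop("invalid_fraction must lie in [0, 1]")
  }
  if (invalid_fraction == 0) return(cases)
  out <- copy(as.data.table(cases))
  affected <- out$supplier_id %in% suppliers & out$indicator_id == indicator
  target_cases <- sort(unique(out$case_id[affected]))
  set.seed(unit_seed(seed, 0L, salt = 3L))
  n_hit <- round(invalid_fraction * length(target_cases))
  hit <- sample(target_cases, n_hit)
  out[affected & out$case_id %in% hit, value := NA_integer_]
  data.table::setattr(out, "class", class(cases))
  out
}
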