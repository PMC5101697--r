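#' Compare survey-based and EHR-based quality measurement end to end
#'
#' Runs the full comparability analysis on two item-level datasets:
#' \enumerate{
#'   \item score the survey cases under the original proportional framework
#'     (actual score over maximum possible score);
#'   \item harmonize the survey into the dichotomous framework
#'     ([harmonize_survey_to_ehr()]) and rescore;
#'   \item score the EHR cases dichotomously;
#'   \item aggregate to therapist level (completeness and mean score);
#'   \item drop indicators that cannot be compared: not extractable from
#'     EHRs, absent from the EHR data, or failing the validity filter
#'     (too few cases with a valid extracted score);
#'   \item match therapists across sources and compare each remaining
#'     indicator on completeness and correctness with the matched-pairs
#'     Wilcoxon signed-rank test and the relative-change relevance rule;
#'   \item render a per-indicator comparability overview.
#' }
#'
#' @param survey,ehr `qi_cases` datasets (from [load_cases()] or
#'   [generate_cohort()]) with sources `"survey"` and `"ehr"`.
#' @param registry a [qi_registry()].
#' @param alpha significance level for the Wilcoxon tests (default 0.001).
#' @param relevance_pct relevance threshold on |relative change| (default
#'   5 %). A change of exactly 5 % counts as relevant (not "the same"),
#'   following the strict `< 5 %` convention for sameness.
#' @param exact_threshold see [wilcoxon_signed_rank()].
#' @param min_valid_fraction see [validity_filter()].
#' @param missing_policy,zero_decisive see [score_cases()].
#' @param precedence survey cohort-year precedence, see
#'   [match_therapists()].
#' @return A `qi_comparison` object: list with `completeness` and
#'   `correctness` comparison tables (one row per compared indicator),
#'   `overview` (per-indicator comparability ledger), `validity` (validity
#'   filter table), `dropped` (indicator, reason code, detail),
#'   `therapist_results` (the three therapist-level result sets), `log`
#'   (character), and `params`.
#' @seealso [run_pipeline()] for the file-driven version.
#' @export
qi_compare <- function(survey, ehr, registry = qi_registry(),
                       alpha = 0.001, relevance_pct = 5,
                       exact_threshold = 12L, min_valid_fraction = 0.5,
                       missing_policy = "exclude_incomplete",
                       zero_decisive = TRUE,
                       precedence = "most_recent") {
  stopifnot(inherits(survey, "qi_cases"), inherits(ehr, "qi_cases"))
  if (any(survey$source != "survey")) stop("survey dataset has non-survey rows")
  if (any(ehr$source != "ehr")) stop("ehr dataset has non-ehr rows")
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  note("scoring survey data under the proportional framework")
  sv_prop <- therapist_scores(score_cases(survey, registry, "proportional",
                                          missing_policy = missing_policy))
  note("harmonizing survey data and rescoring dichotomously")
  sv_harm <- harmonize_survey_to_ehr(survey)
  sv_dich <- therapist_scores(score_cases(sv_harm, registry, "dichotomous",
                                          zero_decisive = zero_decisive))
  note("scoring EHR data under the dichotomous framework")
  ehr_case_scores <- score_cases(ehr, registry, "dichotomous",
                                 zero_decisive = zero_decisive)
  ehr_res <- therapist_scores(ehr_case_scores)

  validity <- validity_filter(ehr_case_scores, min_valid_fraction)

  dropped <- list()
  drop <- function(id, code, detail) {
    dropped[[length(dropped) + 1L]] <<- data.table(
      indicator_id = id, reason_code = code, detail = detail)
    note("QI%d not compared [%s]: %s", id, code, detail)
  }
  compared <- integer()
  for (id in as.integer(names(registry))) {
    d <- registry[[as.character(id)]]
    if (!d$extractable_from_ehr) {
      drop(id, "not_extractable_from_ehr",
           "indicator cannot be extracted from the EHRs")
    } else if (!id %in% ehr_res$indicator_id) {
      drop(id, "not_in_ehr_data", "no EHR cases for this indicator")
    } else if (!id %in% sv_dich$indicator_id) {
      drop(id, "not_in_survey_data", "no survey cases for this indicator")
    } else if (!validity$keep[validity$indicator_id == id]) {
      drop(id, "extraction_deviation", sprintf(
        "only %.1f%% of EHR cases have a valid score (threshold %.0f%%)",
        100 * validity$valid_fraction[validity$indicator_id == id],
        100 * min_valid_fraction))
    } else {
      compared <- c(compared, id)
    }
  }

  cmp_one <- function(metric, scale) {
    rows <- lapply(compared, function(id) {
      pairs <- match_therapists(
        sv_dich[sv_dich$indicator_id == id],
        ehr_res[ehr_res$indicator_id == id],
        metric = metric, precedence = precedence)
      if (!nrow(pairs)) {
        drop(id, "no_matched_pairs",
             sprintf("no therapist present in both sources (%s)", metric))
        return(NULL)
      }
      res <- compare_indicator(pairs, alpha = alpha,
                               relevance_pct = relevance_pct,
                               exact_threshold = exact_threshold,
                               scale = scale)
      res[, short_name := registry[[as.character(id)]]$short_name]
      res
    })
    rbindlist(rows[!vapply(rows, is.null, TRUE)])
  }
  note("comparing completeness on matched therapist pairs")
  completeness <- cmp_one("completeness", scale = 100)
  note("comparing correctness (mean indicator scores) on matched pairs")
  correctness <- cmp_one("correctness", scale = 1)

  out <- structure(list(
    completeness = completeness,
    correctness = correctness,
    validity = validity,
    dropped = if (length(dropped)) rbindlist(dropped) else
      data.table(indicator_id = integer(), reason_code = character(),
                 detail = character()),
    therapist_results = list(survey_proportional = sv_prop,
                             survey_dichotomous = sv_dich,
                             ehr = ehr_res),
    log = log,
    params = list(alpha = alpha, relevance_pct = relevance_pct,
                  exact_threshold = exact_threshold,
                  min_valid_fraction = min_valid_fraction,
                  missing_policy = missing_policy,
                  zero_decisive = zero_decisive,
                  precedence = precedence)),
    class = "qi_comparison")
  out$overview <- render_overview(out, registry)
  out
}

#' Per-indicator comparability overview
#'
#' One row per indicator summarizing the transition from survey-based to
#' EHR-based measurement: whether the indicator was extracted and compared,
#' whether its definition was changed (dichotomized), whether survey items
#' had to be recoded (any polytomous item), the original (proportional)
#' survey score, the recalculated (dichotomous) survey score, the EHR
#' score, and the completeness and correctness verdicts. Verdicts:
#' completeness `+` when EHR data is more complete (positive relative
#' change), `-` otherwise; correctness `+` when the scores are the same
#' (|relative change| below the relevance threshold), `-` otherwise.
#' Cells that do not apply are `"n.a."`.
#'
#' @param comparison a `qi_comparison` from [qi_compare()].
#' @param registry the registry used in the comparison.
#' @return A data.table with one row per registry indicator.
#' @export
render_overview <- function(comparison, registry = qi_registry()) {
  stopifnot(inherits(comparison, "qi_comparison"))
  tr <- comparison$therapist_results
  mean_of <- function(res, id) {
    v <- res$mean_score[res$indicator_id == id]
    v <- v[!is.na(v)]
    if (length(v)) sprintf("%.2f", mean(v)) else "n.a."
  }
  rows <- lapply(registry, function(d) {
    id <- d$indicator_id
    cmp_c <- comparison$completeness[comparison$completeness$indicator_id == id]
    cmp_s <- comparison$correctness[comparison$correctness$indicator_id == id]
    compared <- nrow(cmp_c) > 0L || nrow(cmp_s) > 0L
    extracted <- d$extractable_from_ehr &&
      !id %in% comparison$dropped$indicator_id
    recoded <- any(d$item_max > 1L)
    data.table(
      indicator_id = id,
      short_name = d$short_name,
      extracted_from_ehr = if (extracted) "yes" else "no",
      definition_changed = if (d$extractable_from_ehr) "yes" else "n.a.",
      items_recoded = if (extracted) (if (recoded) "yes" else "no") else
        "n.a.",
      original_survey_score = mean_of(tr$survey_proportional, id),
      recalculated_survey_score = if (extracted)
        mean_of(tr$survey_dichotomous, id) else "n.a.",
      ehr_score = if (extracted) mean_of(tr$ehr, id) else "n.a.",
      completeness_verdict = if (nrow(cmp_c)) {
        if (cmp_c$relative_change_pct > 0) "+"
        else if (cmp_c$relative_change_pct < 0) "-"
        else "="
      } else "n.a.",
      correctness_verdict = if (nrow(cmp_s))
        (if (abs(cmp_s$relative_change_pct) <
               comparison$params$relevance_pct) "+" else "-") else "n.a.")
  })
  rbindlist(rows)
}

#' @export
print.qi_comparison <- function(x, ...) {
  cat("Quality-indicator comparability: survey vs EHR data\n\n")
  fmt_cmp <- function(tab, label, digits) {
    if (!nrow(tab)) {
      cat(label, ": no indicator compared\n", sep = "")
      return(invisible())
    }
    cat(label, ":\n", sep = "")
    disp <- data.frame(
      QI = tab$indicator_id,
      survey = sprintf(paste0("%.", digits, "f"), tab$mean_survey),
      EHR = sprintf(paste0("%.", digits, "f"), tab$mean_ehr),
      rel_change = format_signed(tab$relative_change_pct, 1L),
      Z = sprintf("%.2f", tab$z_score),
      p = format.pval(tab$p_value, digits = 3),
      N = tab$n_pairs,
      sig = ifelse(tab$significant, "*", ""),
      rel = ifelse(tab$relevant, "R", ""))
    print(disp, row.names = FALSE)
    cat("\n")
  }
  fmt_cmp(x$completeness, "Completeness (% cases without missing values)", 1)
  fmt_cmp(x$correctness, "Correctness (mean indicator score, 0-1)", 2)
  if (nrow(x$dropped)) {
    cat("Not compared:\n")
    for (i in seq_len(nrow(x$dropped))) {
      cat(sprintf("  QI%d: %s\n", x$dropped$indicator_id[i],
                  x$dropped$detail[i]))
    }
    cat("\n")
  }
  cat(sprintf("alpha = %g, relevance threshold = %g%% (* p < alpha, ",
              x$params$alpha, x$params$relevance_pct))
  cat("R |relative change| >= threshold)\n")
  invisible(x)
}

#' @export
summary.qi_comparison <- function(object, ...) {
  print(object)
  cat("\nOverview:\n")
  print(as.data.frame(object$overview), row.names = FALSE)
  invisible(object)
}

#' Plot relative changes per indicator
#'
#' Barplot of the relative change (EHR vs survey, %) per compared
#' indicator, for completeness and correctness, with the relevance band
#' marked.
#'
#' @param x a `qi_comparison`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.qi_comparison <- function(x, ...) {
  tabs <- list(completeness = x$completeness, correctness = x$correctness)
  tabs <- tabs[vapply(tabs, nrow, 0L) > 0]
  if (!length(tabs)) {
    warning("nothing to plot: no indicator compared")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = c(1, length(tabs)))
  on.exit(graphics::par(old))
  for (nm in names(tabs)) {
    tab <- tabs[[nm]]
    graphics::barplot(tab$relative_change_pct,
                      names.arg = paste0("QI", tab$indicator_id),
                      main = nm, ylab = "relative change (%)", ...)
    graphics::abline(h = c(-1, 1) * x$params$relevance_pct, lty = 2,
                     col = "grey40")
    graphics::abline(h = 0)
  }
  invisible(x)
}

PIPELINE_KEYS <- c("survey", "ehr", "format", "registry", "alpha",
                   "relevance_pct", "exact_threshold", "min_valid_fraction",
                   "missing_policy", "zero_decisive", "precedence",
                   "generator", "seed")

#' File-driven pipeline: load or generate, compare, write the bundle
#'
#' Thin driver over [load_cases()], [generate_cohort()] and [qi_compare()]
#' for scripted use. The configuration (YAML file or list) either names the
#' two input CSVs (`survey:`, `ehr:`, optional `format:` and `registry:`
#' YAML override) or requests synthetic data (`generator:` holding
#' [cohort_config()] arguments, plus `seed:`); the remaining keys are the
#' [qi_compare()] options. Unknown keys are rejected.
#'
#' Writes `completeness.csv`, `correctness.csv`, `overview.csv`,
#' `results.json` and `log.txt` into `out_dir`; reruns with identical
#' inputs, config and seed produce byte-identical files. If any stage
#' fails, partial outputs are removed and the stage is named in the error.
#'
#' @param config path to a YAML file, or a named list.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return The `qi_comparison`, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown)) {
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  }
  registry <- if (!is.null(config$registry)) {
    registry_from_yaml(config$registry)
  } else {
    qi_registry()
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (!is.null(config$generator) || is.null(config$survey)) {
    coh <- stage("generate", {
      gen_args <- config$generator %||% list()
      generate_cohort(do.call(cohort_config, gen_args),
                      seed = config$seed %||% 1L)
    })
    survey <- coh$survey
    ehr <- coh$ehr
  } else {
    fmt <- config$format %||% "wide"
    survey <- stage("load_survey",
                    load_cases(config$survey, format = fmt,
                               registry = registry))
    ehr <- stage("load_ehr",
                 load_cases(config$ehr, format = fmt, registry = registry))
  }
  cmp <- stage("compare", qi_compare(
    survey, ehr, registry = registry,
    alpha = config$alpha %||% 0.001,
    relevance_pct = config$relevance_pct %||% 5,
    exact_threshold = config$exact_threshold %||% 12L,
    min_valid_fraction = config$min_valid_fraction %||% 0.5,
    missing_policy = config$missing_policy %||% "exclude_incomplete",
    zero_decisive = config$zero_decisive %||% TRUE,
    precedence = config$precedence %||% "most_recent"))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    written <- character()
    tryCatch({
      for (nm in c("completeness", "correctness")) {
        if (nrow(cmp[[nm]])) {
          f <- file.path(out_dir, paste0(nm, ".csv"))
          write_results(cmp[[nm]], f)
          written <- c(written, f)
        }
      }
      f <- file.path(out_dir, "overview.csv")
      fwrite(cmp$overview, f)
      written <- c(written, f)
      f <- file.path(out_dir, "results.json")
      jsonlite::write_json(list(
        completeness = cmp$completeness, correctness = cmp$correctness,
        dropped = cmp$dropped, params = cmp$params),
        f, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
      written <- c(written, f)
      writeLines(cmp$log, file.path(out_dir, "log.txt"))
    }, error = function(e) {
      unlink(written)
      stop(sprintf("pipeline stage 'write' failed: %s",
                   conditionMessage(e)), call. = FALSE)
    })
  }
  invisible(cmp)
}
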