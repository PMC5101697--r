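#' @importFrom data.table := .N .I .SD data.table as.data.table setcolorder
#'   setorderv fread fwrite rbindlist setnames copy
NULL

# Case-level (non-item) columns of the canonical long representation.
CASE_COLUMNS <- c("case_id", "therapist_id", "practice_id", "source",
                  "cohort_year", "referral", "chronic")
OPTIONAL_CASE_COLUMNS <- c("supplier_id", "sex", "age", "multidisciplinary")

#' Load item-level patient-case records from CSV
#'
#' Reads a case-level table in either of two dialects and returns the
#' canonical long representation used by the scoring functions: one row per
#' (case, indicator, item) response, carrying the case covariates and the
#' item maximum from the registry.
#'
#' \strong{Wide dialect} (default; how a survey export looks): one row per
#' case, item responses in columns `qi<k>_item<j>` for fixed-item indicators
#' and `qi<k>_ngoals`, `qi<k>_goal1` .. `qi<k>_goal15` for the per-goal
#' indicators (6 and 7). \strong{Long dialect} (how an EHR extraction dump
#' looks): one row per case-item with columns `indicator_id`, `item_index`,
#' `value` in addition to the case columns.
#'
#' A blank cell (or any string in `na_strings`) is a \emph{missing} response:
#' the item belongs to the case but no value was recorded. This is distinct
#' from the value 0, which means the care step was assessed and not
#' performed. For the per-goal indicators, goal slots beyond the recorded
#' goal count (`qi<k>_ngoals`) are absent by design, not missing: they are
#' dropped and never enter completeness denominators. For a fixed-item
#' indicator whose columns are present in the file, every item of every case
#' is materialized (blank cells become missing responses); an indicator with
#' no columns at all in the file is treated as not collected and yields no
#' rows.
#'
#' @param path CSV file path, or a data.frame already in the given dialect.
#' @param format `"wide"` (default) or `"long"`.
#' @param registry a [qi_registry()]; supplies item maxima and item counts.
#' @param na_strings strings read as missing; default empty cell and `"NA"`.
#' @return A `qi_cases` object: a `data.table` with the case columns
#'   (`case_id`, `therapist_id`, `practice_id`, `source`, `cohort_year`,
#'   `referral`, `chronic`, plus any of `supplier_id`, `sex`, `age`,
#'   `multidisciplinary` present) and the response columns `indicator_id`,
#'   `item_index`, `value` (integer, `NA` = missing), `max_value`.
#' @section Validation errors:
#'   A malformed header (missing required case columns, or no recognizable
#'   item columns) is a schema error. A value outside `0..max_value` or a
#'   duplicate (case, source, indicator, item) response is a validation
#'   error naming the offending rows.
#' @examples
#' csv <- data.frame(case_id = c("c1", "c2"), therapist_id = "t1",
#'                   practice_id = "p1", source = "survey",
#'                   cohort_year = 2010, referral = "referred",
#'                   chronic = FALSE,
#'                   qi3_item1 = 1, qi3_item2 = 1, qi3_item3 = c(1, 0),
#'                   qi3_item4 = 1)
#' cases <- load_cases(csv)
#' nrow(cases)  # 8 responses: 2 cases x 4 items
#' @export
load_cases <- function(path, format = c("wide", "long"),
                       registry = qi_registry(),
                       na_strings = c("", "NA")) {
  format <- match.arg(format)
  raw <- if (is.data.frame(path)) {
    as.data.table(path)
  } else {
    if (!file.exists(path)) stop("file not found: ", path)
    fread(path, na.strings = na_strings, colClasses = list(
      character = intersect(c("case_id", "therapist_id", "practice_id",
                              "supplier_id"), names(fread(path, nrows = 0L)))))
  }
  missing_cols <- setdiff(CASE_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  long <- switch(format,
                 wide = wide_to_long(raw, registry),
                 long = long_to_long(raw, registry))
  # responses on indicators not applicable to the case's referral status
  # (QI1 for referred patients, QI2 for direct access) do not exist as data
  app_of <- vapply(registry, function(d) d$applicability, "")
  app <- app_of[as.character(long$indicator_id)]
  long <- long[app == "all" |
                 (app == "direct_access" & long$referral == "direct_access") |
                 (app == "referred" & long$referral == "referred")]
  validate_cases(long)
}

wide_to_long <- function(raw, registry) {
  keep <- c(CASE_COLUMNS, intersect(OPTIONAL_CASE_COLUMNS, names(raw)))
  item_cols <- grep("^qi[0-9]+_(item|goal)[0-9]+$", names(raw), value = TRUE)
  if (!length(item_cols)) {
    stop("schema error: no item columns (qi<k>_item<j> / qi<k>_goal<j>) found")
  }
  parsed <- regmatches(item_cols,
                       regexec("^qi([0-9]+)_(item|goal)([0-9]+)$", item_cols))
  col_ind <- as.integer(vapply(parsed, `[`, "", 2L))
  col_item <- as.integer(vapply(parsed, `[`, "", 4L))
  unknown <- setdiff(unique(col_ind), as.integer(names(registry)))
  if (length(unknown)) {
    stop("schema error: item columns for indicator(s) not in registry: ",
         paste(unknown, collapse = ", "))
  }

  base <- raw[, keep, with = FALSE]
  base[, `__row` := .I]
  pieces <- vector("list", length(item_cols))
  for (i in seq_along(item_cols)) {
    d <- registry[[as.character(col_ind[i])]]
    if (col_item[i] > d$max_items) {
      stop("schema error: column ", item_cols[i], " exceeds the ",
           d$max_items, "-item maximum of indicator ", col_ind[i])
    }
    pieces[[i]] <- data.table(
      `__row` = base$`__row`,
      indicator_id = col_ind[i],
      item_index = col_item[i],
      value = suppressWarnings(as.integer(raw[[item_cols[i]]])),
      max_value = d$item_max[col_item[i]])
  }
  long <- rbindlist(pieces)

  # Per-goal indicators: slots past the recorded goal count are absent by
  # design, not missing. ngoals columns give the recorded count; when absent
  # it is inferred from the last non-blank goal slot.
  for (id in unique(col_ind[vapply(parsed, `[`, "", 3L) == "goal"])) {
    ncol_name <- paste0("qi", id, "_ngoals")
    sub <- long[long$indicator_id == id]
    if (ncol_name %in% names(raw)) {
      ngoals <- suppressWarnings(as.integer(raw[[ncol_name]]))
    } else {
      last_rec <- sub[!is.na(sub$value),
                      list(n = max(item_index)), by = "__row"]
      ngoals <- rep(0L, nrow(raw))
      ngoals[last_rec$`__row`] <- last_rec$n
    }
    ngoals[is.na(ngoals)] <- 0L
    long <- long[long$indicator_id != id |
                   long$item_index <= ngoals[long$`__row`]]
  }

  out <- merge(base, long, by = "__row", allow.cartesian = TRUE)
  out[, `__row` := NULL]
  out
}

long_to_long <- function(raw, registry) {
  need <- c("indicator_id", "item_index", "value")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("schema error: long format requires column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  keep <- c(CASE_COLUMNS, intersect(OPTIONAL_CASE_COLUMNS, names(raw)), need)
  out <- raw[, keep, with = FALSE]
  out[, `:=`(indicator_id = as.integer(indicator_id),
             item_index = as.integer(item_index),
             value = suppressWarnings(as.integer(value)))]
  items <- registry_items(registry)[, c("indicator_id", "item_index",
                                        "max_value"), with = FALSE]
  out <- merge(out, items, by = c("indicator_id", "item_index"),
               all.x = TRUE, sort = FALSE)
  if (anyNA(out$max_value)) {
    bad <- unique(out[is.na(out$max_value),
                      c("indicator_id", "item_index"), with = FALSE])
    stop("schema error: (indicator, item) not in registry: ",
         paste(sprintf("(%d,%d)", bad$indicator_id, bad$item_index),
               collapse = ", "))
  }
  setcolorder(out, c(setdiff(names(out),
                             c("indicator_id", "item_index", "value",
                               "max_value")),
                     c("indicator_id", "item_index", "value", "max_value")))
  out
}

validate_cases <- function(long) {
  long <- as.data.table(long)
  bad_source <- !long$source %in% c("survey", "ehr")
  if (any(bad_source)) {
    stop("validation error: source must be 'survey' or 'ehr'; offending ",
         "case(s): ", paste(unique(long$case_id[bad_source])[1:5],
                            collapse = ", "))
  }
  bad_ref <- !long$referral %in% c("direct_access", "referred")
  if (any(bad_ref)) {
    stop("validation error: referral must be 'direct_access' or 'referred';",
         " offending case(s): ",
         paste(unique(long$case_id[bad_ref])[1:5], collapse = ", "))
  }
  long[, chronic := as.logical(chronic)]
  oob <- !is.na(long$value) & (long$value < 0L | long$value > long$max_value)
  if (any(oob)) {
    bad <- long[oob][1:min(5L, sum(oob))]
    stop("validation error: item value outside 0..max_value in row(s): ",
         paste(sprintf("case %s QI%d item %d: value %d > max %d",
                       bad$case_id, bad$indicator_id, bad$item_index,
                       bad$value, bad$max_value), collapse = "; "))
  }
  dup <- duplicated(long[, c("case_id", "source", "indicator_id",
                             "item_index"), with = FALSE])
  if (any(dup)) {
    bad <- long[dup][1:min(5L, sum(dup))]
    stop("validation error: duplicate response for (case, indicator, item): ",
         paste(sprintf("case %s QI%d item %d", bad$case_id,
                       bad$indicator_id, bad$item_index), collapse = "; "))
  }
  data.table::setattr(long, "class", c("qi_cases", class(long)))
  long
}

#' Write patient cases back to a wide CSV
#'
#' Inverse of [load_cases()] for the wide dialect: one row per case,
#' `qi<k>_item<j>` / `qi<k>_ngoals` + `qi<k>_goal<j>` columns, blank cells
#' for missing responses. Loading the written file reproduces the cases
#' (round-trip property).
#'
#' @param cases a `qi_cases` object.
#' @param path output CSV path.
#' @param registry the registry used to lay out columns.
#' @return `path`, invisibly.
#' @export
write_cases <- function(cases, path, registry = qi_registry()) {
  stopifnot(inherits(cases, "qi_cases"))
  dt <- as.data.table(cases)
  keep <- c(CASE_COLUMNS, intersect(OPTIONAL_CASE_COLUMNS, names(dt)))
  base <- unique(dt[, keep, with = FALSE], by = c("case_id", "source"))
  present <- sort(unique(dt$indicator_id))
  wide <- copy(base)
  for (id in present) {
    d <- registry[[as.character(id)]]
    sub <- dt[dt$indicator_id == id]
    tag <- if (d$variable_items) "goal" else "item"
    if (d$variable_items) {
      ngoals <- sub[, .N, by = c("case_id", "source")]
      wide <- merge(wide, setnames(ngoals, "N", paste0("qi", id, "_ngoals")),
                    by = c("case_id", "source"), all.x = TRUE)
      n_slots <- max(sub$item_index)
    } else {
      n_slots <- d$max_items
    }
    for (j in seq_len(n_slots)) {
      cell <- sub[sub$item_index == j,
                  c("case_id", "source", "value"), with = FALSE]
      setnames(cell, "value", paste0("qi", id, "_", tag, j))
      wide <- merge(wide, cell, by = c("case_id", "source"), all.x = TRUE)
    }
  }
  setorderv(wide, c("source", "therapist_id", "case_id"))
  fwrite(wide, path, na = "")
  invisible(path)
}

#' Write therapist-level or comparison results to CSV
#'
#' Writes results with a deterministic column order. Every proportion or
#' percentage column is written unrounded, and a rounded display column
#' (suffix `_disp`) is appended alongside it: one decimal for percentages
#' (completeness and relative change, as printed in comparison tables) and
#' two decimals for mean scores.
#'
#' @param results a data.frame of therapist-level results
#'   (from [therapist_scores()]) or comparison results (from
#'   [compare_indicators()] / a `qi_comparison` element).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (is.null(results) || !nrow(as.data.frame(results))) {
    stop("no results to write: refusing to create an empty file")
  }
  dt <- as.data.table(as.data.frame(results))
  pct_cols <- intersect(c("relative_change_pct", "completeness_survey_pct",
                          "completeness_ehr_pct"), names(dt))
  score_cols <- intersect(c("mean_score", "completeness", "mean_survey",
                            "mean_ehr", "value_survey", "value_ehr"),
                          names(dt))
  for (col in pct_cols) {
    dt[[paste0(col, "_disp")]] <- format_signed(dt[[col]], 1L)
  }
  for (col in score_cols) {
    dt[[paste0(col, "_disp")]] <- ifelse(is.na(dt[[col]]), "",
                                         sprintf("%.2f", dt[[col]]))
  }
  setcolorder(dt, sort(names(dt)))
  lead <- intersect(c("indicator_id", "short_name", "metric", "therapist_id",
                      "source"), names(dt))
  setcolorder(dt, c(lead, setdiff(names(dt), lead)))
  fwrite(dt, path, na = "")
  invisible(path)
}

# Signed fixed-decimal display used in the comparison tables: "+8.4",
# "-8.0", "+217.5". Rounds half away from zero so that printed values match
# hand-rounded tables regardless of binary representation.
format_signed <- function(x, digits = 1L) {
  out <- ifelse(is.na(x), "",
                sprintf("%+.*f", digits,
                        sign(x) * round_half_up(abs(x), digits)))
  sub("^[+-]0\\.0$", "0.0", out)
}

round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}
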