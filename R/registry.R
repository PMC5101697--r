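#' Indicator registry for the physical-therapy care process
#'
#' The quality-indicator set contains eight process indicators, one per step
#' of the clinical reasoning process (screening/diagnostics, goal setting,
#' intervention, evaluation, patient communication). Each indicator is scored
#' from a small number of documentation items per patient case.
#'
#' `qi_registry()` returns the shipped definitions:
#'
#' \describe{
#'   \item{QI1}{Direct access: screening and diagnostic process (5 items).
#'     Applicable only to direct-access patients.}
#'   \item{QI2}{Referred patients: diagnostic process (4 items). Applicable
#'     only to referred patients.}
#'   \item{QI3}{Intervention goals determined methodically (4 items).}
#'   \item{QI4}{Intervention process (5 items). Not extractable from EHRs
#'     (narrative registration of interventions).}
#'   \item{QI5}{Administration of intervention results (1 item).}
#'   \item{QI6}{Perceived intervention results, per goal (up to 15 goals).}
#'   \item{QI7}{Measured intervention results, per goal (up to 15 goals).
#'     Not extractable from EHRs.}
#'   \item{QI8}{Information shared with and agreed upon by the patient
#'     (7 items).}
#' }
#'
#' Per-item maxima are not standardized across publications of the item set;
#' the shipped defaults assume administrative yes/no items are binary
#' (maximum 1), one "determined systematically" item in QI1 and QI2 is
#' three-level (0/1/2, as in the canonical worked example no/somewhat/
#' completely), and per-goal result items in QI6/QI7 are four-level (0..3:
#' not at all/somewhat/largely/completely). The maxima are configurable via
#' `registry_from_yaml()`.
#'
#' @param combine_qi5_qi6 logical; if `TRUE`, add a derived indicator 56
#'   ("result administrated AND perceived result recorded") used by some EHR
#'   extraction schemes. Default `FALSE` (the combined indicator was never
#'   successfully compared).
#' @return An object of class `qi_registry`: a list of indicator definitions,
#'   each a list with elements `indicator_id`, `short_name`, `applicability`
#'   (`"direct_access"`, `"referred"` or `"all"`), `item_max` (integer vector
#'   of per-item maxima, indexed by item), `variable_items` (logical; items
#'   are per-goal, with a data-driven count up to `max_items`), `max_items`,
#'   and `extractable_from_ehr`.
#' @seealso [registry_from_yaml()], [load_cases()], [score_cases()]
#' @examples
#' reg <- qi_registry()
#' length(reg[["1"]]$item_max)  # 5 items
#' reg[["2"]]$applicability     # "referred"
#' @export
qi_registry <- function(combine_qi5_qi6 = FALSE) {
  def <- function(id, short_name, applicability, item_max,
                  variable_items = FALSE, max_items = length(item_max),
                  extractable_from_ehr = TRUE) {
    list(indicator_id = as.integer(id), short_name = short_name,
         applicability = applicability, item_max = as.integer(item_max),
         variable_items = variable_items, max_items = as.integer(max_items),
         extractable_from_ehr = extractable_from_ehr)
  }
  reg <- list(
    def(1L, "Screening and diagnostics direct access patient",
        "direct_access", c(1L, 1L, 1L, 2L, 1L)),
    def(2L, "Screening and diagnostics referred patient",
        "referred", c(1L, 1L, 2L, 1L)),
    def(3L, "Intervention goals determined methodically",
        "all", c(1L, 1L, 1L, 1L)),
    def(4L, "Intervention process",
        "all", c(1L, 1L, 1L, 1L, 1L), extractable_from_ehr = FALSE),
    def(5L, "Administration intervention results",
        "all", 1L),
    def(6L, "Perceived intervention results",
        "all", rep(3L, 15L), variable_items = TRUE, max_items = 15L),
    def(7L, "Measured intervention results",
        "all", rep(3L, 15L), variable_items = TRUE, max_items = 15L,
        extractable_from_ehr = FALSE),
    def(8L, "Information shared with patient",
        "all", rep(1L, 7L))
  )
  names(reg) <- vapply(reg, function(d) as.character(d$indicator_id), "")
  if (isTRUE(combine_qi5_qi6)) {
    reg[["56"]] <- def(56L, "Intervention result administrated and perceived",
                       "all", c(1L, 1L))
  }
  structure(reg, class = "qi_registry")
}

#' @export
print.qi_registry <- function(x, ...) {
  cat("Quality-indicator registry (", length(x), " indicators)\n", sep = "")
  for (d in x) {
    cat(sprintf("  QI%-2d %-50s %s, %s%d item%s%s\n",
                d$indicator_id, d$short_name,
                switch(d$applicability,
                       direct_access = "direct-access only",
                       referred = "referred only",
                       "all cases"),
                if (d$variable_items) "up to " else "",
                d$max_items, if (d$max_items > 1L) "s" else "",
                if (d$extractable_from_ehr) "" else " [not EHR-extractable]"))
  }
  invisible(x)
}

#' Load an indicator registry from a YAML configuration
#'
#' Allows the per-item maxima, applicability and extractability assumptions
#' of the shipped registry to be overridden. The YAML file holds a list of
#' indicator entries, e.g.
#'
#' ```yaml
#' indicators:
#'   - indicator_id: 1
#'     short_name: Screening and diagnostics direct access patient
#'     applicability: direct_access    # direct_access | referred | all
#'     item_max: [1, 1, 1, 2, 1]
#'   - indicator_id: 6
#'     short_name: Perceived intervention results
#'     applicability: all
#'     item_max: 3        # scalar: recycled over max_items
#'     variable_items: true
#'     max_items: 15
#'     extractable_from_ehr: true
#' ```
#'
#' @param path path to a YAML file.
#' @return A `qi_registry` object.
#' @export
registry_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$indicators)) {
    stop("registry YAML must contain a top-level 'indicators' list")
  }
  allowed <- c("indicator_id", "short_name", "applicability", "item_max",
               "variable_items", "max_items", "extractable_from_ehr")
  reg <- lapply(cfg$indicators, function(e) {
    unknown <- setdiff(names(e), allowed)
    if (length(unknown)) {
      stop("unknown registry keys: ", paste(unknown, collapse = ", "))
    }
    if (is.null(e$indicator_id) || is.null(e$item_max)) {
      stop("each indicator entry needs 'indicator_id' and 'item_max'")
    }
    variable <- isTRUE(e$variable_items)
    max_items <- as.integer(e$max_items %||%
                              (if (variable) 15L else length(e$item_max)))
    item_max <- as.integer(e$item_max)
    if (length(item_max) == 1L && max_items > 1L) {
      item_max <- rep(item_max, max_items)
    }
    if (length(item_max) != max_items) {
      stop("indicator ", e$indicator_id, ": item_max length (",
           length(item_max), ") != max_items (", max_items, ")")
    }
    if (any(item_max < 1L)) {
      stop("indicator ", e$indicator_id, ": item maxima must be >= 1")
    }
    applicability <- match.arg(e$applicability %||% "all",
                               c("all", "direct_access", "referred"))
    list(indicator_id = as.integer(e$indicator_id),
         short_name = e$short_name %||% paste0("QI", e$indicator_id),
         applicability = applicability,
         item_max = item_max,
         variable_items = variable,
         max_items = max_items,
         extractable_from_ehr = e$extractable_from_ehr %||% TRUE)
  })
  names(reg) <- vapply(reg, function(d) as.character(d$indicator_id), "")
  if (anyDuplicated(names(reg))) stop("duplicate indicator_id in registry")
  structure(reg, class = "qi_registry")
}

#' Registry as a long item table
#'
#' Expands a registry into one row per (indicator, item) with the item
#' maximum — the join table used by the loader, scorer and generator.
#'
#' @param registry a `qi_registry`.
#' @return A `data.table` with columns `indicator_id`, `item_index`,
#'   `max_value`, `applicability`, `variable_items`.
#' @keywords internal
registry_items <- function(registry) {
  stopifnot(inherits(registry, "qi_registry"))
  data.table::rbindlist(lapply(registry, function(d) {
    data.table::data.table(
      indicator_id = d$indicator_id,
      item_index = seq_along(d$item_max),
      max_value = d$item_max,
      applicability = d$applicability,
      variable_items = d$variable_items)
  }))
}

#' Which indicators apply to a case
#'
#' QI1 applies only to direct-access patients and QI2 only to referred
#' patients; every other indicator applies to all cases.
#'
#' @param referral character vector with values `"direct_access"` or
#'   `"referred"`.
#' @param definition a single indicator definition from a `qi_registry`.
#' @return logical vector: is the indicator applicable to each case?
#' @export
indicator_applicable <- function(definition, referral) {
  switch(definition$applicability,
         all = rep(TRUE, length(referral)),
         direct_access = referral == "direct_access",
         referred = referral == "referred")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
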