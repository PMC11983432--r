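# The report_set container: a screened (or raw) collection of individual
# case safety reports with provenance of the filters applied to it.

#' Construct a set of case safety reports
#'
#' A `report_set` holds one row per spontaneous report together with an
#' ordered log of the screening filters that produced it. The reports table
#' uses list-columns for the multi-valued fields:
#'
#' * `report_id` — opaque identifier, unique within a set,
#' * `drugs` — named character vector per report; names are drug names,
#'   values are roles (`primary_suspect`, `secondary_suspect`,
#'   `concomitant`, `interacting`),
#' * `reactions` — non-empty character vector of MedDRA preferred terms,
#' * `sex`, `age_group`, `continent` — controlled vocabularies with an
#'   explicit `"unknown"` level,
#' * `year` — integer calendar year, `NA` for unknown,
#' * `seriousness` — character vector drawn from `death`,
#'   `hospitalization`, `disability`, `none_reported`.
#'
#' @param reports A data frame with the columns above (list-columns for
#'   `drugs`, `reactions`, `seriousness`).
#' @param source Free-text provenance string.
#' @param filters A data frame logging applied filters (`step`, `removed`,
#'   `detail`); usually left at its default and grown by screening
#'   functions.
#' @return An object of class `report_set`.
#' @seealso [read_reports()], [screen_primary_suspect()],
#'   [simulate_reports()]
#' @export
report_set <- function(reports, source = "in-memory", filters = empty_filter_log()) {
  reports <- tibble::as_tibble(reports)
  validate_reports_tbl(reports)
  if (anyDuplicated(reports$report_id) > 0) {
    rlang::warn("report_set contains duplicated report_id values; screen_primary_suspect() removes duplicates")
  }
  structure(
    list(reports = reports, filters = tibble::as_tibble(filters), source = source),
    class = "report_set"
  )
}

empty_filter_log <- function() {
  tibble::tibble(step = character(), removed = integer(), detail = character())
}

empty_reports_tbl <- function() {
  tibble::tibble(
    report_id = character(),
    drugs = list(),
    reactions = list(),
    sex = character(),
    age_group = character(),
    continent = character(),
    year = integer(),
    seriousness = list()
  )
}

report_cols <- c(
  "report_id", "drugs", "reactions", "sex", "age_group",
  "continent", "year", "seriousness"
)

validate_reports_tbl <- function(tbl) {
  missing <- setdiff(report_cols, names(tbl))
  if (length(missing) > 0) {
    rlang::abort(paste0("reports table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(tbl) == 0) {
    return(invisible(tbl))
  }
  if (any(lengths(tbl$reactions) == 0)) {
    rlang::abort("every report must list at least one reaction preferred term")
  }
  bad_role <- vapply(
    tbl$drugs,
    function(d) length(d) > 0 && (!all(d %in% role_levels) || anyDuplicated(names(d)) > 0),
    logical(1)
  )
  if (any(bad_role)) {
    rlang::abort("drugs entries must map each drug name to one role from the role vocabulary")
  }
  check_levels <- function(x, levels, field) {
    if (!all(x %in% levels)) {
      rlang::abort(paste0("field '", field, "' contains values outside its vocabulary"))
    }
  }
  check_levels(tbl$sex, sex_levels, "sex")
  check_levels(tbl$age_group, age_levels, "age_group")
  check_levels(tbl$continent, continent_levels, "continent")
  bad_serious <- vapply(
    tbl$seriousness,
    function(s) length(s) == 0 || !all(s %in% seriousness_levels),
    logical(1)
  )
  if (any(bad_serious)) {
    rlang::abort("seriousness entries must be non-empty subsets of the seriousness vocabulary")
  }
  invisible(tbl)
}

#' Number of reports in a report_set
#' @param rs A `report_set`.
#' @return Integer count of reports.
#' @export
n_reports <- function(rs) nrow(rs$reports)

# total PT occurrences: a report with k reactions contributes k
n_reactions <- function(rs) sum(lengths(rs$reports$reactions))

add_filter <- function(rs, step, removed, detail = "") {
  rs$filters <- dplyr::bind_rows(
    rs$filters,
    tibble::tibble(step = step, removed = as.integer(removed), detail = detail)
  )
  rs
}

#' @export
print.report_set <- function(x, ...) {
  cat(sprintf(
    "<report_set> %d report(s), %d reaction term(s), source: %s\n",
    n_reports(x), n_reactions(x), x$source
  ))
  if (nrow(x$filters) > 0) {
    cat("filters applied:\n")
    for (i in seq_len(nrow(x$filters))) {
      cat(sprintf(
        "  %d. %s (removed %d) %s\n",
        i, x$filters$step[i], x$filters$removed[i], x$filters$detail[i]
      ))
    }
  }
  invisible(x)
}

#' @export
format.report_set <- function(x, ...) {
  sprintf("<report_set: %d reports>", n_reports(x))
}

# logical vector: does each report carry `drug` with role primary_suspect?
has_primary <- function(rs, drug) {
  vapply(
    rs$reports$drugs,
    function(d) any(names(d) == drug & d == "primary_suspect"),
    logical(1)
  )
}
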