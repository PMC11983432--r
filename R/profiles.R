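# Descriptive ADR profiling of a screened report set: demographic strata,
# SOC-level reaction rates, top-N preferred-term tables, serious-outcome
# rates.
#
# Two denominator conventions coexist and are distinct code paths:
# * report-level: percentages of the number of reports (demographics),
# * reaction-level: percentages of the total number of PT occurrences
#   (SOC profiles; default for top-PT tables and serious-AE rates).
# On data where every report carries exactly one reaction they coincide.

new_stratified_counts <- function(stratum, count, denominator, axis) {
  out <- tibble::tibble(
    stratum = stratum,
    count = as.integer(count),
    denominator = as.integer(denominator),
    percent = .pct(count, denominator)
  )
  class(out) <- c("stratified_counts", class(out))
  attr(out, "axis") <- axis
  attr(out, "degenerate") <- denominator == 0
  out
}

#' @export
print.stratified_counts <- function(x, ...) {
  cat(sprintf("<stratified_counts> axis: %s, denominator: %d\n",
              attr(x, "axis"), x$denominator[1] %||% 0L))
  if (isTRUE(attr(x, "degenerate"))) {
    cat("  (empty report set: percentages undefined)\n")
  }
  NextMethod()
}

year_strata <- function(years) {
  known <- sort(unique(years[!is.na(years)]))
  upper <- if (length(known) > 0) max(max(known), 2024L) else 2024L
  c("Before 2017", as.character(2017:upper), "Unknown")
}

#' Demographic distribution of a screened report set
#'
#' Tabulates reports along one demographic axis with the number of reports
#' as denominator. Every vocabulary level, including `unknown`, gets a
#' stratum; the year axis bins all years before 2017 into `"Before 2017"`.
#' Percentages are `count / denominator * 100` rounded half-up to two
#' decimals; on an empty report set the denominator is 0 and percentages
#' are reported as missing.
#'
#' @param rs A [report_set()], typically already screened to one drug.
#' @param axis One of `"sex"`, `"age_group"`, `"continent"`, `"year"`.
#' @return A `stratified_counts` tibble (`stratum`, `count`,
#'   `denominator`, `percent`).
#' @export
demographic_table <- function(rs, axis = c("sex", "age_group", "continent", "year")) {
  axis <- match.arg(axis)
  stopifnot(inherits(rs, "report_set"))
  tbl <- rs$reports
  denom <- nrow(tbl)
  values_and_levels <- switch(axis,
    sex = list(
      v = tbl$sex,
      lev = c("Female", "Male", "Unknown"),
      map = c(female = "Female", male = "Male", unknown = "Unknown")
    ),
    age_group = list(
      v = tbl$age_group, lev = unname(age_labels), map = age_labels
    ),
    continent = list(
      v = tbl$continent,
      lev = c("Africa", "Americas", "Asia", "Europe", "Oceania", "Unknown"),
      map = stats::setNames(
        c("Africa", "Americas", "Asia", "Europe", "Oceania", "Unknown"),
        continent_levels
      )
    ),
    year = {
      lev <- year_strata(tbl$year)
      v <- dplyr::case_when(
        is.na(tbl$year) ~ "Unknown",
        tbl$year < 2017 ~ "Before 2017",
        TRUE ~ as.character(tbl$year)
      )
      list(v = v, lev = lev, map = NULL)
    }
  )
  lev <- values_and_levels$lev
  v <- values_and_levels$v
  if (!is.null(values_and_levels$map)) v <- unname(values_and_levels$map[v])
  counts <- table(factor(v, levels = lev))
  new_stratified_counts(lev, as.integer(counts), denom, axis)
}

#' SOC-level reaction profile
#'
#' Resolves every reaction PT occurrence through the PT-to-SOC map and
#' partitions them by system organ class. The denominator is the total
#' number of PT occurrences across all reports (a report with k reactions
#' contributes k), not the report count. Reactions whose PT is absent from
#' the map are excluded from the per-SOC counts, tallied in an unmapped
#' bucket, and flagged with a warning.
#'
#' @param rs A screened [report_set()].
#' @param map A [meddra_map()].
#' @param drug Optional drug label carried into the result.
#' @return A `soc_profile` object: `drug`, `total_reactions`, `table`
#'   (tibble `soc`, `count`, `percent` over the map's full SOC list),
#'   `unmapped` (tibble `pt`, `count`).
#' @export
soc_profile <- function(rs, map, drug = NULL) {
  stopifnot(inherits(rs, "report_set"), inherits(map, "meddra_map"))
  pts <- normalize_pt(unlist(rs$reports$reactions, use.names = FALSE))
  total <- length(pts)
  socs <- pt_soc(map, pts)
  unmapped_pts <- pts[is.na(socs)]
  if (length(unmapped_pts) > 0) {
    rlang::warn(sprintf(
      "soc_profile: %d reaction occurrence(s) over %d distinct PT(s) not in the SOC map",
      length(unmapped_pts), length(unique(unmapped_pts))
    ))
  }
  counts <- table(factor(socs[!is.na(socs)], levels = map$soc_levels))
  unmapped <- if (length(unmapped_pts) > 0) {
    tab <- table(unmapped_pts)
    tibble::tibble(pt = names(tab), count = as.integer(tab))
  } else {
    tibble::tibble(pt = character(), count = integer())
  }
  structure(
    list(
      drug = drug,
      total_reactions = total,
      table = tibble::tibble(
        soc = map$soc_levels,
        count = as.integer(counts),
        percent = .pct(as.integer(counts), total)
      ),
      unmapped = unmapped
    ),
    class = "soc_profile"
  )
}

#' @export
print.soc_profile <- function(x, ...) {
  cat(sprintf(
    "<soc_profile>%s N = %d reaction occurrence(s), %d unmapped\n",
    if (is.null(x$drug)) "" else paste0(" ", x$drug, ":"),
    x$total_reactions, sum(x$unmapped$count)
  ))
  print(dplyr::arrange(x$table, dplyr::desc(.data$count)))
  invisible(x)
}

#' Top-N preferred-term rate table
#'
#' Counts PT occurrences and reports the `n` most frequent as rates. The
#' default denominator is the reaction-level total (consistent with the
#' SOC profile); `denominator = "report"` switches to the report count.
#' Rows are sorted by rate descending with ties broken lexicographically
#' by PT. If fewer than `n` distinct PTs are observed, all are returned.
#'
#' @param rs A screened [report_set()].
#' @param n Maximum number of rows (default 20).
#' @param denominator `"reaction"` (default) or `"report"`.
#' @return A `pt_rate_table` tibble (`pt`, `count`, `rate`) with the
#'   denominator stored as an attribute.
#' @export
top_pt_table <- function(rs, n = 20, denominator = c("reaction", "report")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(rs, "report_set"), n >= 1)
  pts <- normalize_pt(unlist(rs$reports$reactions, use.names = FALSE))
  denom <- if (denominator == "reaction") length(pts) else n_reports(rs)
  tab <- table(pts)
  out <- tibble::tibble(pt = names(tab), count = as.integer(tab)) |>
    dplyr::mutate(rate = .pct(.data$count, denom)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$pt) |>
    utils::head(n)
  class(out) <- c("pt_rate_table", class(out))
  attr(out, "denominator") <- denom
  attr(out, "denominator_kind") <- denominator
  out
}

#' Serious adverse-event rates
#'
#' Counts reports whose seriousness set contains each severe outcome
#' (death, hospitalization, disability); a report may count toward several
#' outcomes. The default denominator is the reaction-level total, matching
#' the convention of pairing the reaction N with the serious-AE rate;
#' `denominator = "report"` gives per-report rates instead.
#'
#' @param rs A screened [report_set()].
#' @param denominator `"reaction"` (default) or `"report"`.
#' @return A `stratified_counts` tibble with one stratum per severe
#'   outcome.
#' @export
serious_ae_rates <- function(rs, denominator = c("reaction", "report")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(rs, "report_set"))
  outcomes <- c("death", "hospitalization", "disability")
  counts <- vapply(outcomes, function(o) {
    sum(vapply(rs$reports$seriousness, function(s) o %in% s, logical(1)))
  }, integer(1))
  denom <- if (denominator == "reaction") n_reactions(rs) else n_reports(rs)
  new_stratified_counts(
    c("Death", "Hospitalization", "Disability"), counts, denom,
    axis = paste0("seriousness/", denominator)
  )
}
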