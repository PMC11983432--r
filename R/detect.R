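# Building 2x2 tables from a report universe and running the four
# algorithms over every event observed with a target drug.

#' Build the 2x2 table for one drug-event pair
#'
#' Counts reports in the full multi-drug universe. Cell `a` counts reports
#' where `drug` is a primary suspect and any reaction matches the
#' selector; `b`, `c`, `d` complete the partition of the universe. The
#' selector names a single PT (`level = "pt"`) or a whole system organ
#' class (`level = "soc"`, matching every PT the map places under it).
#'
#' @param rs A [report_set()] holding the full universe (not pre-screened
#'   to one drug).
#' @param drug Target drug name.
#' @param event PT or SOC name, depending on `level`.
#' @param map A [meddra_map()] used to resolve the selector.
#' @param level `"pt"` or `"soc"`.
#' @return A [contingency_table()].
#' @export
build_contingency <- function(rs, drug, event, map, level = c("pt", "soc")) {
  level <- match.arg(level)
  stopifnot(inherits(rs, "report_set"), inherits(map, "meddra_map"))
  event <- normalize_pt(event)
  if (level == "pt") {
    if (!event %in% map$table$pt) {
      rlang::abort(paste0("unknown preferred term: ", event))
    }
    targets <- event
  } else {
    if (!event %in% map$soc_levels) {
      rlang::abort(paste0("unknown system organ class: ", event))
    }
    targets <- map$table$pt[map$table$soc == event]
  }
  has_drug <- has_primary(rs, drug)
  has_event <- vapply(
    rs$reports$reactions,
    function(r) any(normalize_pt(r) %in% targets),
    logical(1)
  )
  a <- sum(has_drug & has_event)
  b <- sum(has_drug & !has_event)
  c <- sum(!has_drug & has_event)
  d <- sum(!has_drug & !has_event)
  contingency_table(a, b, c, d)
}

#' Detect disproportionality signals for one drug
#'
#' Runs all four algorithms over every event observed at least once with
#' the target drug as primary suspect, against the background of all other
#' reports in the universe. The per-algorithm criteria are: ROR CI lower
#' bound > 1; PRR >= 2 with CI lower bound > 1; IC025 > 0; EBGM05 > 2. An
#' event is marked a `signal` when at least one flag fires
#' (`rule = "any"`, the default) or when all four do (`rule = "all"`).
#'
#' @param rs A [report_set()] holding the full multi-drug universe.
#' @param drug Target drug name; an absent drug yields an empty result.
#' @param map A [meddra_map()]; at PT level it supplies the SOC column (PTs
#'   outside the map get `NA`), at SOC level it defines the events.
#' @param level Analyze events at `"pt"` (default) or `"soc"` level.
#' @param prior A [bcpnn_prior()].
#' @param correction,conf_level,min_count Passed to [disprop_stats()].
#' @param rule Signal consensus rule, `"any"` (default) or `"all"`.
#' @return A tibble with one row per event: `event`, `soc`, the 2x2
#'   cells, all estimates and bounds, the four flags and `signal`.
#' @export
detect_signals <- function(rs, drug, map, level = c("pt", "soc"),
                           prior = bcpnn_prior(), correction = TRUE,
                           conf_level = 0.95, min_count = 0,
                           rule = c("any", "all")) {
  level <- match.arg(level)
  rule <- match.arg(rule)
  stopifnot(inherits(rs, "report_set"), inherits(map, "meddra_map"))

  empty <- tibble::tibble(event = character(), soc = character())
  if (n_reports(rs) == 0) return(empty)

  has_drug <- has_primary(rs, drug)
  if (!any(has_drug)) return(empty)

  reactions <- rs$reports$reactions
  lens <- lengths(reactions)
  long <- tibble::tibble(
    idx = rep.int(seq_along(reactions), lens),
    pt = normalize_pt(unlist(reactions, use.names = FALSE))
  )
  if (level == "soc") {
    long$event <- pt_soc(map, long$pt)
    n_unmapped <- sum(is.na(long$event))
    if (n_unmapped > 0) {
      rlang::warn(sprintf(
        "detect_signals: dropping %d reaction occurrence(s) with PT outside the SOC map",
        n_unmapped
      ))
      long <- long[!is.na(long$event), , drop = FALSE]
    }
  } else {
    long$event <- long$pt
  }
  long <- dplyr::distinct(long, .data$idx, .data$event)
  long$with_drug <- has_drug[long$idx]

  counts <- long |>
    dplyr::group_by(.data$event) |>
    dplyr::summarise(
      a = sum(.data$with_drug),
      n_event = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$a > 0)
  if (nrow(counts) == 0) return(empty)

  n_total <- n_reports(rs)
  n_drug <- sum(has_drug)
  a <- counts$a
  b <- n_drug - a
  c <- counts$n_event - a
  d <- n_total - n_drug - c

  stats <- disprop_stats(a, b, c, d, prior = prior, conf_level = conf_level,
                         correction = correction, min_count = min_count)
  soc <- if (level == "pt") pt_soc(map, counts$event) else counts$event

  out <- dplyr::bind_cols(
    tibble::tibble(event = counts$event, soc = soc),
    stats
  )
  out$signal <- if (rule == "any") {
    out$flag_ror | out$flag_prr | out$flag_bcpnn | out$flag_ebgm
  } else {
    out$flag_ror & out$flag_prr & out$flag_bcpnn & out$flag_ebgm
  }
  dplyr::arrange(out, dplyr::desc(.data$a), .data$event)
}

#' Write a signal-detection table to CSV
#'
#' @param detections Output of [detect_signals()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signals <- function(detections, path) {
  readr::write_csv(detections, path)
  invisible(path)
}
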