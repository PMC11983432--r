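# Cross-drug comparison of signal sets: PTs signalled for every drug
# (grouped by SOC) versus drug-exclusive PTs.

#' A drug's set of signalled events
#'
#' @param drug Drug name.
#' @param events Tibble (or data frame) with columns `pt` and `soc`; each
#'   PT may appear at most once.
#' @return A `signal_set`.
#' @export
signal_set <- function(drug, events) {
  events <- tibble::as_tibble(events)[, c("pt", "soc")]
  events$pt <- normalize_pt(events$pt)
  events$soc <- normalize_pt(events$soc)
  if (anyDuplicated(events$pt) > 0) {
    rlang::abort("a signal_set lists each PT at most once")
  }
  structure(list(drug = drug, events = events), class = "signal_set")
}

#' Extract a signal_set from a detection table
#'
#' Keeps the rows of a [detect_signals()] result marked `signal`.
#'
#' @param detections Output of [detect_signals()] at PT level.
#' @param drug Drug name to attach.
#' @return A [signal_set()].
#' @export
as_signal_set <- function(detections, drug) {
  sig <- detections[isTRUE_vec(detections$signal), c("event", "soc")]
  signal_set(drug, tibble::tibble(pt = sig$event, soc = sig$soc))
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.signal_set <- function(x, ...) {
  cat(sprintf("<signal_set> %s: %d signalled PT(s)\n", x$drug, nrow(x$events)))
  invisible(x)
}

#' Shared and drug-exclusive signals across drugs
#'
#' Partitions the signalled PTs of two or more drugs into: `shared` (PTs
#' signalled for every input drug, grouped by SOC with per-SOC counts),
#' `unique_per_drug` (PTs signalled for exactly one drug), and `partial`
#' (PTs signalled for more than one but not all drugs, which belong to
#' neither of the first two groups). SOCs are ranked by shared-signal
#' count descending, ties broken lexicographically.
#'
#' @param sets A list of two or more [signal_set()] objects with mutually
#'   consistent PT-to-SOC assignments.
#' @return A `comparison_result`: `shared` (tibble `soc`, `pts`
#'   list-column, `n`), `unique_per_drug` (named list of tibbles),
#'   `partial` (tibble `pt`, `soc`, `drugs`), `soc_ranking`, `drugs`.
#' @export
intersect_signals <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 ||
      !all(vapply(sets, inherits, logical(1), "signal_set"))) {
    rlang::abort("supply a list of at least two signal_set objects")
  }
  drugs <- vapply(sets, function(s) s$drug, character(1))
  if (anyDuplicated(drugs) > 0) {
    rlang::abort("signal sets must come from distinct drugs")
  }
  all_events <- dplyr::bind_rows(lapply(sets, function(s) {
    dplyr::mutate(s$events, drug = s$drug)
  }))
  soc_of <- all_events |>
    dplyr::distinct(.data$pt, .data$soc)
  if (anyDuplicated(soc_of$pt) > 0) {
    bad <- soc_of$pt[duplicated(soc_of$pt)]
    rlang::abort(paste0(
      "inconsistent SOC assignment across sets for PT(s): ",
      paste(unique(bad), collapse = ", ")
    ))
  }
  membership <- all_events |>
    dplyr::group_by(.data$pt, .data$soc) |>
    dplyr::summarise(
      n_drugs = dplyr::n_distinct(.data$drug),
      drugs = list(sort(unique(.data$drug))),
      .groups = "drop"
    )
  k <- length(sets)

  shared <- membership |>
    dplyr::filter(.data$n_drugs == k) |>
    dplyr::group_by(.data$soc) |>
    dplyr::summarise(pts = list(sort(.data$pt)), n = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$soc)

  uniq <- membership |> dplyr::filter(.data$n_drugs == 1)
  unique_per_drug <- lapply(stats::setNames(drugs, drugs), function(d) {
    uniq |>
      dplyr::filter(vapply(.data$drugs, function(x) identical(x, d), logical(1))) |>
      dplyr::group_by(.data$soc) |>
      dplyr::summarise(pts = list(sort(.data$pt)), n = dplyr::n(), .groups = "drop") |>
      dplyr::arrange(dplyr::desc(.data$n), .data$soc)
  })

  partial <- membership |>
    dplyr::filter(.data$n_drugs > 1, .data$n_drugs < k) |>
    dplyr::select("pt", "soc", "drugs") |>
    dplyr::arrange(.data$soc, .data$pt)

  structure(
    list(
      shared = shared,
      unique_per_drug = unique_per_drug,
      partial = partial,
      soc_ranking = shared$soc,
      drugs = drugs
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> %s: %d shared PT(s) in %d SOC(s); unique: %s; %d partially shared\n",
    paste(x$drugs, collapse = " vs "),
    sum(x$shared$n), nrow(x$shared),
    paste(sprintf("%s=%d", x$drugs,
                  vapply(x$unique_per_drug, function(u) sum(u$n), numeric(1))),
          collapse = ", "),
    nrow(x$partial)
  ))
  invisible(x)
}

#' Render a comparison as shared/distinct tables
#'
#' Produces the two table layouts used to report cross-drug ADR overlap:
#' a shared table (`soc`, comma-joined ADR list, `signal_n`) ordered by
#' per-SOC count, and a distinct table with one ADR-list column per drug.
#'
#' @param cr A `comparison_result` from [intersect_signals()].
#' @return A `comparison_report`: list of tibbles `shared` and
#'   `distinct`, plus `note` when the shared set is empty.
#' @export
comparison_report <- function(cr) {
  stopifnot(inherits(cr, "comparison_result"))
  shared <- tibble::tibble(
    soc = cr$shared$soc,
    adrs = vapply(cr$shared$pts, paste, character(1), collapse = ", "),
    signal_n = cr$shared$n
  )
  socs <- sort(unique(unlist(lapply(cr$unique_per_drug, function(u) u$soc))))
  distinct <- tibble::tibble(soc = socs)
  for (d in cr$drugs) {
    u <- cr$unique_per_drug[[d]]
    joined <- stats::setNames(
      vapply(u$pts, paste, character(1), collapse = ", "), u$soc
    )
    distinct[[d]] <- ifelse(socs %in% names(joined), joined[socs], "")
  }
  note <- if (nrow(shared) == 0) "no PT is signalled for every drug" else NULL
  structure(
    list(shared = shared, distinct = distinct, note = note),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Shared signals by SOC:\n")
  if (!is.null(x$note)) cat("  ", x$note, "\n", sep = "")
  print(x$shared)
  cat("\nDrug-exclusive signals by SOC:\n")
  print(x$distinct)
  invisible(x)
}

#' Write a comparison report to CSV files
#'
#' @param report A [comparison_report()].
#' @param dir Output directory (created if absent).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_comparison <- function(report, dir) {
  stopifnot(inherits(report, "comparison_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  shared_path <- file.path(dir, "comparison_shared.csv")
  distinct_path <- file.path(dir, "comparison_distinct.csv")
  readr::write_csv(report$shared, shared_path)
  readr::write_csv(report$distinct, distinct_path)
  invisible(c(shared_path, distinct_path))
}
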