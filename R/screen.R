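# Report screening: restrict a database to reports naming one target drug
# as the primary suspect, then drop duplicates and structurally invalid
# records.

#' Screen a report set for one primary-suspect drug
#'
#' Keeps exactly the reports in which `drug` appears with role
#' `primary_suspect` (without requiring exclusivity when several suspects
#' are listed), then removes duplicate reports (identical `report_id`,
#' first occurrence kept) and invalid reports (empty reaction list or no
#' drug entry). All three steps are logged with removal counts in the
#' filter provenance of the result.
#'
#' The operation is idempotent and never alters the fields of surviving
#' reports.
#'
#' @param rs A [report_set()] (typically the raw multi-drug universe).
#' @param drug Non-empty drug name, matched exactly.
#' @return A screened `report_set`; empty if the drug never appears as
#'   primary suspect.
#' @export
screen_primary_suspect <- function(rs, drug) {
  stopifnot(inherits(rs, "report_set"))
  if (!is.character(drug) || length(drug) != 1 || !nzchar(trimws(drug))) {
    rlang::abort("drug must be a single non-empty string")
  }
  drug <- trimws(drug)
  tbl <- rs$reports

  n0 <- nrow(tbl)
  tbl <- tbl[has_primary(rs, drug), , drop = FALSE]
  n1 <- nrow(tbl)

  tbl <- tbl[!duplicated(tbl$report_id), , drop = FALSE]
  n2 <- nrow(tbl)

  valid <- lengths(tbl$reactions) > 0 & lengths(tbl$drugs) > 0
  tbl <- tbl[valid, , drop = FALSE]
  n3 <- nrow(tbl)

  out <- structure(
    list(reports = tbl, filters = rs$filters, source = rs$source),
    class = "report_set"
  )
  out <- add_filter(out, "primary_suspect", n0 - n1, paste0("drug=", drug))
  out <- add_filter(out, "deduplicate", n1 - n2, "identical report_id, first kept")
  out <- add_filter(out, "drop_invalid", n2 - n3, "empty reactions or no drug entry")
  out
}
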