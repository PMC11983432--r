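# Reading and writing report databases.
#
# CSV dialect: UTF-8, comma-separated, one row per report. Multi-valued
# fields (drug, role, reactions, seriousness) are pipe-delimited within one
# column; `drug` and `role` are parallel lists. One-row-per-report keeps
# report-level denominators trivial.
#
# JSON: an array of objects with the same keys; `drugs` is an array of
# {drug, role} objects, `reactions` and `seriousness` are arrays.

report_csv_cols <- c(
  "report_id", "drug", "role", "reactions", "sex",
  "age_group", "continent", "year", "seriousness"
)

.split_pipe <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character())
  trimws(strsplit(x, "|", fixed = TRUE)[[1]])
}

.row_abort <- function(i, field, value) {
  rlang::abort(sprintf("row %d: invalid %s value '%s'", i, field, value))
}

.norm_or_abort <- function(x, fn, i, field) {
  out <- fn(x)
  bad <- which(is.na(out))
  if (length(bad) > 0) .row_abort(i, field, x[bad[1]])
  out
}

# Turn one raw record (all character / lists) into a one-row reports tibble,
# or NULL when the record has no reactions (rejected upstream).
.parse_record <- function(rec, i) {
  reactions <- normalize_pt(rec$reactions)
  reactions <- reactions[nzchar(reactions)]
  if (length(reactions) == 0) {
    return(NULL)
  }
  drug_names <- trimws(rec$drug)
  drug_names <- drug_names[nzchar(drug_names)]
  roles <- .norm_or_abort(rec$role, normalize_role, i, "role")
  if (length(drug_names) != length(roles)) {
    .row_abort(i, "role", paste(rec$role, collapse = "|"))
  }
  if (anyDuplicated(drug_names) > 0) {
    .row_abort(i, "drug", paste(drug_names, collapse = "|"))
  }
  year_raw <- .norm_key(rec$year)
  if (year_raw %in% .unknown_keys) {
    year <- NA_integer_
  } else {
    year <- suppressWarnings(as.integer(rec$year))
    if (is.na(year)) .row_abort(i, "year", rec$year)
  }
  serious <- rec$seriousness
  if (length(serious) == 0) serious <- "none_reported"
  serious <- unique(.norm_or_abort(serious, normalize_seriousness, i, "seriousness"))
  if (length(serious) > 1) serious <- setdiff(serious, "none_reported")
  tibble::tibble(
    report_id = as.character(rec$report_id),
    drugs = list(stats::setNames(roles, drug_names)),
    reactions = list(reactions),
    sex = .norm_or_abort(rec$sex, normalize_sex, i, "sex"),
    age_group = .norm_or_abort(rec$age_group, normalize_age_group, i, "age_group"),
    continent = .norm_or_abort(rec$continent, normalize_continent, i, "continent"),
    year = year,
    seriousness = list(serious)
  )
}

#' Read case safety reports from CSV or JSON
#'
#' Parses one report per record, normalizing demographic fields through the
#' package's frozen synonym tables (for example `"M "` becomes `male`).
#' Unknown or missing demographic values map to the explicit `"unknown"`
#' level and are never dropped; unrecognized non-missing tokens raise an
#' error naming the row and field. Records with an empty reaction list are
#' rejected, with the rejection count logged in the returned filter log.
#'
#' @param path Path to the input file.
#' @param format `"csv"` (default, pipe-delimited list columns) or
#'   `"json"`.
#' @return A [report_set()].
#' @examples
#' f <- system.file("extdata", "example_reports.csv", package = "pvsignal")
#' rs <- read_reports(f)
#' rs
#' @export
read_reports <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path))
  }
  records <- if (format == "csv") .read_records_csv(path) else .read_records_json(path)
  rows <- vector("list", length(records))
  rejected <- 0L
  for (i in seq_along(records)) {
    row <- .parse_record(records[[i]], i)
    if (is.null(row)) {
      rejected <- rejected + 1L
    } else {
      rows[[i]] <- row
    }
  }
  reports <- dplyr::bind_rows(rows)
  if (nrow(reports) == 0) reports <- empty_reports_tbl()
  if (rejected > 0) {
    rlang::inform(sprintf("read_reports: rejected %d record(s) with no reactions", rejected))
  }
  rs <- report_set(reports, source = path)
  add_filter(rs, "ingest_reject_invalid", rejected, "records with empty reaction list")
}

.read_records_csv <- function(path) {
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE
  )
  missing <- setdiff(report_csv_cols, names(tbl))
  if (length(missing) > 0) {
    rlang::abort(paste0("reports CSV lacks column(s): ", paste(missing, collapse = ", ")))
  }
  lapply(seq_len(nrow(tbl)), function(i) {
    list(
      report_id = tbl$report_id[i],
      drug = .split_pipe(tbl$drug[i]),
      role = .split_pipe(tbl$role[i]),
      reactions = .split_pipe(tbl$reactions[i]),
      sex = tbl$sex[i],
      age_group = tbl$age_group[i],
      continent = tbl$continent[i],
      year = tbl$year[i],
      seriousness = .split_pipe(tbl$seriousness[i])
    )
  })
}

.read_records_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(rec) {
    drugs <- rec$drugs %||% list()
    list(
      report_id = rec$report_id %||% "",
      drug = vapply(drugs, function(d) as.character(d$drug), character(1)),
      role = vapply(drugs, function(d) as.character(d$role), character(1)),
      reactions = as.character(unlist(rec$reactions)),
      sex = rec$sex %||% "",
      age_group = rec$age_group %||% "",
      continent = rec$continent %||% "",
      year = as.character(rec$year %||% ""),
      seriousness = as.character(unlist(rec$seriousness))
    )
  })
}

#' Write case safety reports to CSV or JSON
#'
#' Inverse of [read_reports()]: `read_reports(write_reports(rs, f), ...)`
#' reproduces `rs` field for field. Age groups are written with their
#' display labels (`"<18"`, `"18-44"`, ...) which the reader maps back.
#'
#' @param rs A [report_set()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_reports <- function(rs, path, format = c("csv", "json")) {
  format <- match.arg(format)
  tbl <- rs$reports
  if (format == "csv") {
    out <- tibble::tibble(
      report_id = tbl$report_id,
      drug = vapply(tbl$drugs, function(d) paste(names(d), collapse = "|"), character(1)),
      role = vapply(tbl$drugs, function(d) paste(unname(d), collapse = "|"), character(1)),
      reactions = vapply(tbl$reactions, paste, character(1), collapse = "|"),
      sex = tbl$sex,
      age_group = unname(age_labels[tbl$age_group]),
      continent = tbl$continent,
      year = ifelse(is.na(tbl$year), "", as.character(tbl$year)),
      seriousness = vapply(tbl$seriousness, paste, character(1), collapse = "|")
    )
    readr::write_csv(out, path)
  } else {
    recs <- lapply(seq_len(nrow(tbl)), function(i) {
      drugs <- tbl$drugs[[i]]
      list(
        report_id = tbl$report_id[i],
        drugs = lapply(seq_along(drugs), function(j) {
          list(drug = names(drugs)[j], role = unname(drugs[j]))
        }),
        reactions = as.list(tbl$reactions[[i]]),
        sex = tbl$sex[i],
        age_group = unname(age_labels[tbl$age_group[i]]),
        continent = tbl$continent[i],
        year = if (is.na(tbl$year[i])) "" else tbl$year[i],
        seriousness = as.list(tbl$seriousness[[i]])
      )
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}
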