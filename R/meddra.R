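# PT -> SOC dictionary. A toy two-level MedDRA-like hierarchy: every
# preferred term maps to exactly one system organ class.

#' Build a PT to SOC map
#'
#' @param pt Character vector of preferred terms (unique after
#'   [normalize_pt()] normalization).
#' @param soc Character vector of the system organ class of each PT.
#' @param soc_levels Optional ordered character vector of the closed SOC
#'   set; defaults to the SOCs in order of first appearance. SOC values in
#'   `soc` must all be drawn from it.
#' @return An object of class `meddra_map` with elements `table` (a tibble
#'   `pt`, `soc`), `pt_to_soc` (named lookup vector) and `soc_levels`.
#' @seealso [read_meddra_map()], [meddra_fixture_map()]
#' @export
meddra_map <- function(pt, soc, soc_levels = NULL) {
  pt <- normalize_pt(pt)
  soc <- normalize_pt(soc)
  if (length(pt) != length(soc)) {
    rlang::abort("pt and soc must have equal length")
  }
  dup <- pt[duplicated(pt)]
  if (length(dup) > 0) {
    conflicting <- unique(dup[vapply(
      dup, function(p) length(unique(soc[pt == p])) > 1, logical(1)
    )])
    if (length(conflicting) > 0) {
      rlang::abort(paste0(
        "PT(s) mapped to more than one SOC: ",
        paste(conflicting, collapse = ", ")
      ))
    }
    keep <- !duplicated(pt)
    pt <- pt[keep]
    soc <- soc[keep]
  }
  if (is.null(soc_levels)) {
    soc_levels <- unique(soc)
  } else if (!all(soc %in% soc_levels)) {
    rlang::abort(paste0(
      "SOC value(s) outside the declared SOC list: ",
      paste(setdiff(unique(soc), soc_levels), collapse = ", ")
    ))
  }
  structure(
    list(
      table = tibble::tibble(pt = pt, soc = soc),
      pt_to_soc = stats::setNames(soc, pt),
      soc_levels = soc_levels
    ),
    class = "meddra_map"
  )
}

#' Read a PT to SOC map from a two-column CSV
#'
#' Expects columns `pt` and `soc`.
#'
#' @param path Path to the CSV file.
#' @param soc_levels Optional ordered SOC list; see [meddra_map()].
#' @return A `meddra_map`.
#' @export
read_meddra_map <- function(path, soc_levels = NULL) {
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("pt", "soc") %in% names(tbl))) {
    rlang::abort("PT map CSV must have columns 'pt' and 'soc'")
  }
  meddra_map(tbl$pt, tbl$soc, soc_levels = soc_levels)
}

#' Write a PT to SOC map to CSV
#' @param map A `meddra_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meddra_map <- function(map, path) {
  readr::write_csv(map$table, path)
  invisible(path)
}

# SOC of each PT; NA for PTs outside the map
pt_soc <- function(map, pts) {
  unname(map$pt_to_soc[normalize_pt(pts)])
}

#' @export
print.meddra_map <- function(x, ...) {
  cat(sprintf(
    "<meddra_map> %d preferred terms across %d system organ classes\n",
    nrow(x$table), length(x$soc_levels)
  ))
  invisible(x)
}
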