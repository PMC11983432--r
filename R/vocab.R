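# Controlled vocabularies for case-safety-report fields, plus the frozen
# normalization tables used when ingesting free-text CSV/JSON columns.

sex_levels <- c("male", "female", "unknown")

age_levels <- c("lt18", "a18_44", "a45_64", "a65_74", "ge75", "unknown")

# display labels mirror the age bands used in VigiAccess summaries
age_labels <- c(
  lt18 = "<18", a18_44 = "18-44", a45_64 = "45-64",
  a65_74 = "65-74", ge75 = ">=75", unknown = "Unknown"
)

continent_levels <- c("Africa", "Americas", "Asia", "Europe", "Oceania", "unknown")

role_levels <- c("primary_suspect", "secondary_suspect", "concomitant", "interacting")

seriousness_levels <- c("death", "hospitalization", "disability", "none_reported")

.norm_key <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  stringr::str_squish(tolower(x))
}

.unknown_keys <- c("", "unknown", "u", "na", "n/a", "not reported", "missing")

.sex_table <- c(
  male = "male", m = "male",
  female = "female", f = "female",
  stats::setNames(rep("unknown", length(.unknown_keys)), .unknown_keys)
)

.age_table <- c(
  "lt18" = "lt18", "<18" = "lt18", "0-17" = "lt18", "under 18" = "lt18",
  "a18_44" = "a18_44", "18-44" = "a18_44", "18–44" = "a18_44",
  "a45_64" = "a45_64", "45-64" = "a45_64", "45–64" = "a45_64",
  "a65_74" = "a65_74", "65-74" = "a65_74", "65–74" = "a65_74",
  "ge75" = "ge75", ">=75" = "ge75", "≥75" = "ge75", "75+" = "ge75",
  stats::setNames(rep("unknown", length(.unknown_keys)), .unknown_keys)
)

.continent_table <- c(
  africa = "Africa", americas = "Americas", america = "Americas",
  asia = "Asia", europe = "Europe", oceania = "Oceania",
  stats::setNames(rep("unknown", length(.unknown_keys)), .unknown_keys)
)

.role_table <- c(
  "primary_suspect" = "primary_suspect", "primary suspect" = "primary_suspect",
  "primary" = "primary_suspect", "suspect" = "primary_suspect",
  "secondary_suspect" = "secondary_suspect",
  "secondary suspect" = "secondary_suspect", "secondary" = "secondary_suspect",
  "concomitant" = "concomitant", "companion" = "concomitant",
  "interacting" = "interacting", "interaction" = "interacting"
)

.seriousness_table <- c(
  death = "death", died = "death", fatal = "death",
  hospitalization = "hospitalization", hospitalisation = "hospitalization",
  hospitalized = "hospitalization", hospitalised = "hospitalization",
  disability = "disability", disabling = "disability",
  none_reported = "none_reported", none = "none_reported",
  "not serious" = "none_reported",
  stats::setNames("none_reported", "")
)

# Returns the canonical level, or NA for tokens outside the frozen table.
# match() rather than name-indexing so the empty-string key is honored.
.lookup <- function(x, table) {
  unname(table[match(.norm_key(x), names(table))])
}

normalize_sex <- function(x) .lookup(x, .sex_table)
normalize_age_group <- function(x) .lookup(x, .age_table)
normalize_continent <- function(x) .lookup(x, .continent_table)
normalize_role <- function(x) .lookup(x, .role_table)
normalize_seriousness <- function(x) .lookup(x, .seriousness_table)

#' Normalize a MedDRA preferred-term string
#'
#' Trims leading/trailing whitespace and collapses internal runs of
#' whitespace. PT matching everywhere in the package is exact after this
#' normalization; no case folding or synonym resolution is applied.
#'
#' @param x Character vector of PT strings.
#' @return Character vector of normalized PT strings.
#' @export
normalize_pt <- function(x) stringr::str_squish(as.character(x))

#' Round half away from zero
#'
#' Fixed-point rounding with ties going up (away from zero), the convention
#' used for all printed percentages in this package. `base::round()` rounds
#' half to even, which does not reproduce tabulated rates.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(100 * 10751 / 11452) # 93.88
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # epsilon guards values that are exact halves in decimal but sit just
  # below .5 in binary floating point
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# percentage on 0-100 scale rounded to 2 decimals; NA when denominator is 0
.pct <- function(count, denom, digits = 2) {
  out <- round_half_up(100 * count / denom, digits)
  out[rep_len(denom == 0, length(out))] <- NA_real_
  out
}
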