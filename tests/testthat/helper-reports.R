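# Small in-code builders for hand-crafted report fixtures.

toy_report <- function(id, drug, reactions,
                       role = "primary_suspect",
                       sex = "male", age_group = "ge75",
                       continent = "Americas", year = 2023L,
                       seriousness = "none_reported") {
  if (length(role) == 1) role <- rep(role, length(drug))
  tibble::tibble(
    report_id = id,
    drugs = list(stats::setNames(role, drug)),
    reactions = list(reactions),
    sex = sex, age_group = age_group, continent = continent,
    year = as.integer(year),
    seriousness = list(seriousness)
  )
}

toy_set <- function(..., source = "toy") {
  report_set(dplyr::bind_rows(...), source = source)
}

# the four-report two-drug universe used in the contingency examples
toy_universe4 <- function() {
  toy_set(
    toy_report("U1", "drugA", "rash"),
    toy_report("U2", "drugA", "nausea"),
    toy_report("U3", "drugB", "rash"),
    toy_report("U4", "drugB", "nausea")
  )
}

toy_map2 <- function() {
  meddra_map(c("rash", "nausea"), c("Skin", "Gastro"))
}
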