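# Report ingestion: schema parsing, field normalization, rejection of
# structurally invalid records, and write/read round-trips.

test_that("CSV ingestion parses well-formed rows and normalizes fields", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "report_id,drug,role,reactions,sex,age_group,continent,year,seriousness",
    'A1,drugA,primary suspect,Rash|Fatigue,M ,>=75,americas,2023,none',
    'A2,drugA|drugB,primary suspect|concomitant,Nausea,f,65-74,Europe,2022,hospitalisation|death',
    'A3,drugB,primary,Dizziness,,,,,'
  ), f)
  rs <- read_reports(f)

  expect_s3_class(rs, "report_set")
  expect_equal(n_reports(rs), 3)
  # "M " with trailing space folds to male; "f" to female; empty to unknown
  expect_equal(rs$reports$sex, c("male", "female", "unknown"))
  expect_equal(rs$reports$age_group, c("ge75", "a65_74", "unknown"))
  expect_equal(rs$reports$continent, c("Americas", "Europe", "unknown"))
  expect_equal(rs$reports$year, c(2023L, 2022L, NA))
  expect_equal(rs$reports$drugs[[2]],
               c(drugA = "primary_suspect", drugB = "concomitant"))
  expect_setequal(rs$reports$seriousness[[2]], c("hospitalization", "death"))
  expect_equal(rs$reports$seriousness[[3]], "none_reported")
})

test_that("records without reactions are rejected and counted, not kept", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "report_id,drug,role,reactions,sex,age_group,continent,year,seriousness",
    "B1,drugA,primary,Rash,M,45-64,Asia,2020,none",
    "B2,drugA,primary,,M,45-64,Asia,2020,none"
  ), f)
  expect_message(rs <- read_reports(f), "rejected 1 record")
  expect_equal(n_reports(rs), 1)
  rej <- rs$filters[rs$filters$step == "ingest_reject_invalid", ]
  expect_equal(rej$removed, 1L)
})

test_that("malformed fields raise errors naming the row and field", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "report_id,drug,role,reactions,sex,age_group,continent,year,seriousness",
    "C1,drugA,primary,Rash,banana,45-64,Asia,2020,none"
  ), f)
  expect_error(read_reports(f), "row 1.*sex.*banana")

  writeLines(c(
    "report_id,drug,role,reactions,sex,age_group,continent,year,seriousness",
    "C1,drugA,primary,Rash,M,45-64,Asia,twenty,none"
  ), f)
  expect_error(read_reports(f), "row 1.*year")
})

test_that("write/read round-trips CSV and JSON field for field", {
  rs <- toy_set(
    toy_report("R1", c("drugA", "drugB"), c("Rash", "Fatigue", "Hot flush"),
               role = c("primary_suspect", "interacting"),
               seriousness = c("death", "hospitalization")),
    toy_report("R2", "drugB", "Nausea", sex = "unknown", age_group = "unknown",
               continent = "unknown", year = NA),
    toy_report("R3", "drugA", "Dizziness", sex = "female", age_group = "lt18",
               continent = "Oceania", year = 2017L)
  )
  for (fmt in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_reports(rs, path, fmt)
    back <- read_reports(path, fmt)
    expect_equal(back$reports, rs$reports, ignore_attr = TRUE)
  }
})

test_that("multi-reaction lists keep their order through serialization", {
  pts <- c("Zoster", "Alopecia", "Nausea", "Back pain")
  rs <- toy_set(toy_report("M1", "drugA", pts))
  path <- tempfile(fileext = ".csv")
  write_reports(rs, path)
  expect_equal(read_reports(path)$reports$reactions[[1]], pts)
})

test_that("an empty report set writes a header-only file that reads back empty", {
  rs <- report_set(pvsignal:::empty_reports_tbl())
  path <- tempfile(fileext = ".csv")
  write_reports(rs, path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(n_reports(read_reports(path)), 0)
})
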