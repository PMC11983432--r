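# Descriptive profiling: demographic strata, SOC partitions, top-PT
# ordering, serious-AE rates, and the two denominator conventions.

test_that("demographic percentages follow count/denominator at 2 decimals", {
  rs <- toy_set(
    toy_report("P1", "drugA", "Rash", sex = "male"),
    toy_report("P2", "drugA", "Rash", sex = "male"),
    toy_report("P3", "drugA", "Rash", sex = "female"),
    toy_report("P4", "drugA", "Rash", sex = "unknown")
  )
  tab <- demographic_table(rs, "sex")
  expect_equal(tab$stratum, c("Female", "Male", "Unknown"))
  expect_equal(tab$count, c(1L, 2L, 1L))
  expect_equal(tab$percent, c(25, 50, 25))
  expect_equal(sum(tab$count), tab$denominator[1])
})

test_that("the year axis bins pre-2017 years and labels unknowns", {
  rs <- toy_set(
    toy_report("Y1", "drugA", "Rash", year = 2012L),
    toy_report("Y2", "drugA", "Rash", year = 2016L),
    toy_report("Y3", "drugA", "Rash", year = 2019L),
    toy_report("Y4", "drugA", "Rash", year = NA)
  )
  tab <- demographic_table(rs, "year")
  expect_equal(tab$count[tab$stratum == "Before 2017"], 2L)
  expect_equal(tab$count[tab$stratum == "2019"], 1L)
  expect_equal(tab$count[tab$stratum == "Unknown"], 1L)
})

test_that("an empty report set yields zero counts with undefined percentages", {
  rs <- report_set(pvsignal:::empty_reports_tbl())
  tab <- demographic_table(rs, "sex")
  expect_equal(tab$count, c(0L, 0L, 0L))
  expect_true(all(is.na(tab$percent)))
  expect_true(attr(tab, "degenerate"))
})

test_that("SOC counts plus the unmapped bucket partition the reactions", {
  map <- toy_map2()
  rs <- toy_set(
    toy_report("Q1", "drugA", c("rash", "nausea", "mystery pt")),
    toy_report("Q2", "drugA", c("rash", "rash extra"))
  )
  expect_warning(prof <- soc_profile(rs, map), "not in the SOC map")
  expect_equal(prof$total_reactions, 5L)
  expect_equal(sum(prof$table$count) + sum(prof$unmapped$count), 5L)
  expect_equal(prof$table$count[prof$table$soc == "Skin"], 2L)
  expect_equal(prof$table$percent[prof$table$soc == "Skin"], 40)
})

test_that("a single-SOC fixture concentrates 100% in that SOC", {
  map <- toy_map2()
  rs <- toy_set(
    toy_report("R1", "drugA", "rash"),
    toy_report("R2", "drugA", "rash")
  )
  prof <- soc_profile(rs, map)
  expect_equal(prof$table$percent[prof$table$soc == "Skin"], 100)
  expect_equal(sum(prof$table$count), prof$total_reactions)
})

test_that("top-PT tables sort by rate with lexicographic tie-breaks", {
  rs <- toy_set(
    toy_report("T1", "drugA", c("rash", "nausea")),
    toy_report("T2", "drugA", "rash"),
    toy_report("T3", "drugA", "rash")
  )
  tab <- top_pt_table(rs, 10)
  expect_equal(tab$pt[1], "rash")
  expect_equal(tab$rate[1], 75)   # 3 of 4 reaction occurrences
  # ties: equal counts ordered lexicographically
  rs2 <- toy_set(toy_report("T4", "drugA", c("zoster", "alopecia")))
  tab2 <- top_pt_table(rs2, 5)
  expect_equal(tab2$pt, c("alopecia", "zoster"))
  # n larger than the distinct PT count returns everything, unpadded
  expect_equal(nrow(top_pt_table(rs, 99)), 2)
})

test_that("report- and reaction-level denominators coincide on single-reaction data", {
  rs <- toy_set(
    toy_report("U1", "drugA", "rash"),
    toy_report("U2", "drugA", "nausea"),
    toy_report("U3", "drugA", "rash", seriousness = "death")
  )
  by_reaction <- top_pt_table(rs, 5, denominator = "reaction")
  by_report <- top_pt_table(rs, 5, denominator = "report")
  expect_equal(by_reaction$rate, by_report$rate)
  expect_equal(serious_ae_rates(rs, "reaction")$percent,
               serious_ae_rates(rs, "report")$percent)
})

test_that("serious outcomes count reports per outcome, multiply when combined", {
  rs <- toy_set(
    toy_report("V1", "drugA", c("rash", "nausea"),
               seriousness = c("death", "hospitalization")),
    toy_report("V2", "drugA", "rash", seriousness = "death"),
    toy_report("V3", "drugA", "rash")
  )
  tab <- serious_ae_rates(rs)  # reaction-level denominator: 4 occurrences
  expect_equal(tab$count[tab$stratum == "Death"], 2L)
  expect_equal(tab$count[tab$stratum == "Hospitalization"], 1L)
  expect_equal(tab$denominator[1], 4L)
  expect_equal(tab$percent[tab$stratum == "Death"], 50)
  # no serious outcomes at all
  calm <- toy_set(toy_report("V4", "drugA", "rash"))
  expect_equal(sum(serious_ae_rates(calm)$count), 0L)
})

test_that("published demographic cells reproduce through the package rounding rule", {
  demo <- vigiaccess_demographics()
  totals <- vigiaccess_report_counts()
  demo <- dplyr::left_join(demo, totals, by = "drug")
  recomputed <- round_half_up(100 * demo$count / demo$n_reports)
  expect_equal(recomputed, demo$percent)
  # the named examples: apalutamide males, darolutamide 2024 reports
  expect_equal(round_half_up(100 * 10751 / 11452), 93.88)
  expect_equal(round_half_up(100 * 999 / 2269), 44.03)
})

test_that("published SOC cells reproduce except four known mis-rounded ones", {
  soc <- dplyr::left_join(vigiaccess_soc_rates(), vigiaccess_reaction_totals(),
                          by = "drug")
  recomputed <- round_half_up(100 * soc$count / soc$n_reactions)
  off <- which(recomputed != soc$percent)
  # the four source cells whose printed percent exceeds its own
  # count/denominator by exactly one cent
  expect_equal(length(off), 4)
  expect_equal(soc$percent[off] - recomputed[off], rep(0.01, 4))
  expect_setequal(
    paste(soc$drug[off], soc$soc[off]),
    c("apalutamide Renal and urinary disorders",
      "darolutamide Respiratory, thoracic and mediastinal disorders",
      "darolutamide Social circumstances",
      "enzalutamide Immune system disorders")
  )
  # the named examples verify exactly
  expect_equal(round_half_up(100 * 4078 / 20965), 19.45)
  expect_equal(round_half_up(100 * 15569 / 145819), 10.68)
})
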