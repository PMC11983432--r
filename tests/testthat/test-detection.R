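# Contingency construction from a report universe and whole-drug signal
# detection.

test_that("the four-report universe yields the enumerated 2x2 cells", {
  rs <- toy_universe4()
  map <- toy_map2()
  t <- build_contingency(rs, "drugA", "rash", map, level = "pt")
  expect_equal(unlist(t[c("a", "b", "c", "d")]), c(a = 1, b = 1, c = 1, d = 1))
  # SOC-level selector spanning both PTs of a two-PT universe
  map2 <- meddra_map(c("rash", "nausea"), c("Skin", "Skin"))
  t2 <- build_contingency(rs, "drugA", "Skin", map2, level = "soc")
  expect_equal(unlist(t2[c("a", "b", "c", "d")]), c(a = 2, b = 0, c = 2, d = 0))
})

test_that("cells always partition the universe", {
  sim <- simulate_reports(generator_config(n_reports = 1000, seed = 21))
  map <- meddra_fixture_map()
  t <- build_contingency(sim$reports, "enzalutamide", "Fatigue", map)
  expect_equal(t$a + t$b + t$c + t$d, 1000)
  t2 <- build_contingency(sim$reports, "apalutamide",
                          "General disorders and administration site conditions",
                          map, level = "soc")
  expect_equal(t2$n, 1000)
})

test_that("unknown selectors raise errors naming them", {
  rs <- toy_universe4()
  expect_error(build_contingency(rs, "drugA", "made-up pt", toy_map2()),
               "made-up pt")
  expect_error(build_contingency(rs, "drugA", "Not a SOC", toy_map2(), level = "soc"),
               "Not a SOC")
})

test_that("a strongly planted association is flagged by all four algorithms", {
  cfg <- generator_config(
    n_reports = 5000, seed = 31,
    planted = tibble::tibble(drug = "darolutamide", pt = "Malaise", rr = 10)
  )
  sim <- simulate_reports(cfg)
  det <- detect_signals(sim$reports, "darolutamide", meddra_fixture_map())
  hit <- det[det$event == "Malaise", ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$flag_ror && hit$flag_prr && hit$flag_bcpnn && hit$flag_ebgm)
  expect_true(hit$signal)
})

test_that("detection output is empty for absent drugs and sane for single-drug universes", {
  sim <- simulate_reports(generator_config(n_reports = 200, seed = 32))
  map <- meddra_fixture_map()
  expect_equal(nrow(detect_signals(sim$reports, "nosuchdrug", map)), 0)

  solo <- generator_config(
    n_reports = 200, seed = 33,
    drugs = tibble::tibble(drug = "onlydrug", weight = 1)
  )
  det <- detect_signals(simulate_reports(solo)$reports, "onlydrug", map)
  expect_gt(nrow(det), 0)
  # c = d = 0 for every event: all tables degenerate, nothing crashes
  expect_true(all(det$c == 0 & det$d == 0))
  expect_true(all(det$degenerate))
})

test_that("the all-flag consensus rule is at least as strict as any-flag", {
  cfg <- generator_config(
    n_reports = 3000, seed = 34,
    planted = tibble::tibble(drug = "apalutamide", pt = "Nausea", rr = 4)
  )
  sim <- simulate_reports(cfg)
  map <- meddra_fixture_map()
  any_rule <- detect_signals(sim$reports, "apalutamide", map, rule = "any")
  all_rule <- detect_signals(sim$reports, "apalutamide", map, rule = "all")
  merged <- dplyr::left_join(
    any_rule[, c("event", "signal")], all_rule[, c("event", "signal")],
    by = "event", suffix = c("_any", "_all")
  )
  expect_true(all(!merged$signal_all | merged$signal_any))
})

test_that("SOC-level detection aggregates events by organ class", {
  sim <- simulate_reports(generator_config(n_reports = 1000, seed = 35))
  map <- meddra_fixture_map()
  det <- detect_signals(sim$reports, "enzalutamide", map, level = "soc")
  expect_true(all(det$event %in% map$soc_levels))
  expect_equal(det$event, det$soc)
})
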