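# Cross-drug signal comparison: set algebra, invariants, and the
# published-table regression.

sset <- function(drug, pts, soc = "SOC1") {
  signal_set(drug, tibble::tibble(pt = pts, soc = soc))
}

test_that("two sets {x,y} and {y,z} split into shared {y} and uniques {x},{z}", {
  cr <- intersect_signals(list(sset("A", c("x", "y")), sset("B", c("y", "z"))))
  expect_equal(unlist(cr$shared$pts), "y")
  expect_equal(unlist(cr$unique_per_drug$A$pts), "x")
  expect_equal(unlist(cr$unique_per_drug$B$pts), "z")
  expect_equal(nrow(cr$partial), 0)
})

test_that("a PT signalled for two of three drugs is neither shared nor unique", {
  cr <- intersect_signals(list(
    sset("A", c("p", "q")), sset("B", c("p", "q")), sset("C", "q")
  ))
  expect_equal(unlist(cr$shared$pts), "q")
  expect_equal(sum(vapply(cr$unique_per_drug, function(u) sum(u$n), numeric(1))), 0)
  expect_equal(cr$partial$pt, "p")
})

test_that("fewer than two sets is an error", {
  expect_error(intersect_signals(list(sset("A", "x"))), "at least two")
})

test_that("the comparison is invariant to input order", {
  sets <- list(sset("A", c("x", "y", "w")), sset("B", c("y", "z")),
               sset("C", c("y", "w")))
  cr1 <- intersect_signals(sets)
  cr2 <- intersect_signals(rev(sets))
  expect_equal(cr1$shared, cr2$shared)
  expect_equal(cr1$unique_per_drug[sort(names(cr1$unique_per_drug))],
               cr2$unique_per_drug[sort(names(cr2$unique_per_drug))])
  expect_equal(cr1$partial, cr2$partial)
})

test_that("shared, unique and partial conserve each drug's signal count", {
  sets <- list(
    sset("A", c("x", "y", "w", "v")), sset("B", c("y", "z", "w")),
    sset("C", c("y", "u"))
  )
  cr <- intersect_signals(sets)
  for (s in sets) {
    n_shared <- sum(cr$shared$n)
    n_unique <- sum(cr$unique_per_drug[[s$drug]]$n)
    n_partial <- sum(vapply(cr$partial$drugs, function(d) s$drug %in% d, logical(1)))
    expect_equal(n_shared + n_unique + n_partial, nrow(s$events))
  }
})

test_that("SOC ranking orders by shared count with lexicographic ties", {
  sets <- list(
    signal_set("A", tibble::tibble(
      pt = c("p1", "p2", "p3", "q1", "r1"),
      soc = c("SocB", "SocB", "SocB", "SocC", "SocA")
    )),
    signal_set("B", tibble::tibble(
      pt = c("p1", "p2", "p3", "q1", "r1"),
      soc = c("SocB", "SocB", "SocB", "SocC", "SocA")
    ))
  )
  cr <- intersect_signals(sets)
  expect_equal(cr$soc_ranking, c("SocB", "SocA", "SocC"))
})

test_that("inconsistent PT-to-SOC assignments across sets are rejected", {
  bad <- list(sset("A", "x", soc = "SocA"), sset("B", "x", soc = "SocB"))
  expect_error(intersect_signals(bad), "inconsistent SOC")
})

test_that("comparison_report renders shared and distinct layouts", {
  cr <- intersect_signals(list(
    sset("A", c("x", "y")), sset("B", c("y", "z"))
  ))
  rep <- comparison_report(cr)
  expect_equal(rep$shared$signal_n, 1L)
  expect_equal(sort(names(rep$distinct)), sort(c("soc", "A", "B")))
  # empty shared set gets an explanatory note
  rep2 <- comparison_report(intersect_signals(list(sset("A", "x"), sset("B", "z"))))
  expect_equal(nrow(rep2$shared), 0)
  expect_match(rep2$note, "no PT")
})

test_that("21 of 22 published shared-signal rows match their printed counts", {
  sh <- vigiaccess_shared_adrs()
  listed <- lengths(sh$pts)
  mismatch <- which(listed != sh$signal_n)
  # the source's General-disorders row lists 26 PTs against a printed 25
  expect_equal(sh$soc[mismatch],
               "General disorders and administration site conditions")
  expect_equal(listed[mismatch] - sh$signal_n[mismatch], 1L)
  expect_equal(sum(sh$signal_n), 162L)
})

test_that("intersecting the transcribed per-drug sets recovers the published partition", {
  cr <- intersect_signals(unname(vigiaccess_signal_sets()))
  sh <- vigiaccess_shared_adrs()
  # shared PTs grouped by SOC match the shared table transcription
  expect_setequal(unlist(cr$shared$pts), unlist(sh$pts))
  for (i in seq_len(nrow(sh))) {
    expect_setequal(cr$shared$pts[[match(sh$soc[i], cr$shared$soc)]], sh$pts[[i]])
  }
  # exclusive PTs per drug match the distinct table transcription
  di <- vigiaccess_distinct_adrs()
  for (d in unique(di$drug)) {
    expect_setequal(
      unlist(cr$unique_per_drug[[d]]$pts),
      unlist(di$pts[di$drug == d])
    )
  }
  expect_equal(nrow(cr$partial), 0)
})
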