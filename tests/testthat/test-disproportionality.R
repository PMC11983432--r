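# The four 2x2 algorithms: worked closed-form examples, interval oracles,
# algebraic identities, limits, and zero-cell behavior.

test_that("worked example a=20,b=80,c=100,d=900 matches the closed forms", {
  t <- contingency_table(20, 80, 100, 900)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 100 + 1 / 900)

  r <- ror(t)
  expect_equal(r$estimate, 2.25)
  expect_equal(r$ci_low, exp(log(2.25) - 1.96 * se), tolerance = 1e-4)
  expect_equal(r$ci_high, exp(log(2.25) + 1.96 * se), tolerance = 1e-4)

  p <- prr(t)
  expect_equal(p$estimate, 2)
  expect_equal(p$ci_low, exp(log(2) - 1.96 * se), tolerance = 1e-4)

  b <- bcpnn_ic(t)
  expect_equal(b$ic, log2(11 / 6))

  e <- ebgm(t)
  expect_equal(e$estimate, 11 / 6)
  expect_equal(e$ebgm05, exp(log(11 / 6) - 1.96 * se), tolerance = 1e-4)
})

test_that("symmetric and homogeneous tables give unit estimates", {
  t <- contingency_table(10, 10, 10, 10)
  expect_equal(ror(t)$estimate, 1)
  expect_equal(prr(t)$estimate, 1)
  expect_equal(ebgm(t)$estimate, 1)
  # a/(a+b) == c/(c+d) by construction
  t2 <- contingency_table(30, 70, 60, 140)
  expect_equal(prr(t2)$estimate, 1)
})

test_that("EBGM equals 2^IC on arbitrary tables", {
  set.seed(11)
  for (i in 1:50) {
    cells <- sample(1:500, 4, replace = TRUE)
    s <- disprop_stats(cells[1], cells[2], cells[3], cells[4])
    expect_equal(s$ebgm, 2^s$ic, tolerance = 1e-12)
  }
})

test_that("all four point estimates increase strictly in a", {
  a <- 1:40
  s <- disprop_stats(a, 50, 60, 700)
  expect_true(all(diff(s$ror) > 0))
  expect_true(all(diff(s$prr) > 0))
  expect_true(all(diff(s$ic) > 0))
  expect_true(all(diff(s$ebgm) > 0))
})

test_that("intervals bracket the estimate whenever all cells are positive", {
  set.seed(12)
  for (i in 1:50) {
    cells <- sample(1:200, 4, replace = TRUE)
    s <- disprop_stats(cells[1], cells[2], cells[3], cells[4])
    expect_lt(s$ror_l, s$ror); expect_gt(s$ror_u, s$ror)
    expect_lt(s$prr_l, s$prr); expect_gt(s$prr_u, s$prr)
    expect_lt(s$ebgm_l, s$ebgm); expect_gt(s$ebgm_u, s$ebgm)
  }
})

test_that("the shrunk E(IC) converges to the observed IC as counts scale", {
  base <- c(20, 80, 100, 900)
  small <- disprop_stats(base[1], base[2], base[3], base[4])
  k <- 1000
  big <- disprop_stats(k * base[1], k * base[2], k * base[3], k * base[4])
  expect_equal(big$e_ic, big$ic, tolerance = 1e-3)
  expect_gt(abs(small$e_ic - small$ic), abs(big$e_ic - big$ic))
})

test_that("zero cells are handled without crashing and flagged degenerate", {
  # a = 0, correction disabled: zero estimate, degenerate interval
  s0 <- disprop_stats(0, 80, 100, 900, correction = FALSE)
  expect_equal(s0$ror, 0)
  expect_true(s0$degenerate)
  expect_false(s0$flag_ror)
  # a = 0 with correction: BCPNN stays finite through the prior
  s1 <- disprop_stats(0, 80, 100, 900)
  expect_true(is.infinite(s1$ic) && s1$ic < 0)
  expect_true(is.finite(s1$e_ic) && is.finite(s1$ic025))
  # c = 0: infinite PRR sentinel, finite corrected interval
  s2 <- disprop_stats(20, 80, 0, 900)
  expect_true(is.infinite(s2$prr))
  expect_true(is.finite(s2$prr_l))
  expect_true(s2$degenerate)
})

test_that("contingency tables reject negative or empty cell configurations", {
  expect_error(contingency_table(-1, 2, 3, 4), "non-negative")
  expect_error(contingency_table(0, 0, 0, 0), "positive")
  expect_error(contingency_table(1.5, 2, 3, 4), "non-negative integers")
})

test_that("signal flags recompute deterministically from the estimates", {
  set.seed(13)
  for (i in 1:30) {
    cells <- sample(1:300, 4, replace = TRUE)
    s <- disprop_stats(cells[1], cells[2], cells[3], cells[4])
    expect_equal(s$flag_ror, s$ror_l > 1)
    expect_equal(s$flag_prr, s$prr >= 2 & s$prr_l > 1)
    expect_equal(s$flag_bcpnn, s$ic025 > 0)
    expect_equal(s$flag_ebgm, s$ebgm05 > 2)
  }
  # the minimum-report floor is off by default but available
  s <- disprop_stats(2, 8, 10, 90, min_count = 3)
  expect_false(any(s$flag_ror, s$flag_prr, s$flag_bcpnn, s$flag_ebgm))
})
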