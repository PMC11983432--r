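# The four disproportionality algorithms on a 2x2 report-count table
#
#                 event      not event
#   target drug     a            b
#   other drugs     c            d        N = a + b + c + d
#
# ROR  = ad/bc,            95% CI = exp(ln ROR +- z sqrt(1/a+1/b+1/c+1/d))
# PRR  = [a/(a+b)]/[c/(c+d)], CI on the same log scale
# IC   = log2( a N / ((a+b)(a+c)) )  (observed information component)
# E(IC), V(IC): Bayesian shrinkage of IC under the Bate et al. (1998)
#   Dirichlet prior; IC025 = E(IC) - z sqrt(V(IC))
# EBGM = a N / ((a+b)(a+c))  -- the observed/expected ratio, identical to
#   2^IC; its log-normal CI uses the same variance term as ROR/PRR, and
#   EBGM05 is the lower CI bound used one-sidedly.
#
# Zero cells: the point estimates are computed on raw counts whenever
# defined; when any cell is zero a Haldane-Anscombe +0.5 correction on all
# four cells is used for the ROR/PRR/EBGM confidence intervals (and for the
# point estimate only when the raw one is 0/0-undefined). The BCPNN prior
# needs no correction.

#' 2x2 contingency table for one drug-event pair
#'
#' @param a Reports with the target drug and the target event.
#' @param b Reports with the drug, without the event.
#' @param c Reports with the event, without the drug.
#' @param d Reports with neither.
#' @return A `contingency_table` (list with `a`, `b`, `c`, `d`, `n`).
#' @examples
#' contingency_table(20, 80, 100, 900)
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells))) {
    rlang::abort("cells a, b, c, d must be non-negative integers")
  }
  if (sum(cells) <= 0) {
    rlang::abort("the table total N must be positive")
  }
  structure(
    list(a = a, b = b, c = c, d = d, n = a + b + c + d),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> a=%g b=%g c=%g d=%g (N=%g)\n",
              x$a, x$b, x$c, x$d, x$n))
  invisible(x)
}

#' BCPNN prior hyperparameters
#'
#' Marginal pseudo-counts `alpha1`, `beta1` with normalizers `alpha`,
#' `beta`, and joint pseudo-count `gamma11`. The joint normalizer `gamma`
#' is derived per table as
#' `gamma11 * (N+alpha)(N+beta) / ((a+b+alpha1)(a+c+beta1))`, the Bate
#' et al. (1998) construction under which E(IC) shrinks the observed IC
#' toward 0 (exactly 0 only in the large-margin limit).
#'
#' @param alpha1,beta1 Marginal prior pseudo-counts (default 1).
#' @param alpha,beta Marginal normalizers (default 2).
#' @param gamma11 Joint prior pseudo-count (default 1).
#' @return A `bcpnn_prior` object.
#' @export
bcpnn_prior <- function(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2, gamma11 = 1) {
  vals <- c(alpha1 = alpha1, beta1 = beta1, alpha = alpha, beta = beta, gamma11 = gamma11)
  if (any(vals <= 0)) rlang::abort("all prior hyperparameters must be strictly positive")
  structure(as.list(vals), class = "bcpnn_prior")
}

# Vectorized core used by detect_signals(); scalar accessors wrap it.
#' Disproportionality statistics for vectors of 2x2 cells
#'
#' Vectorized computation of all four algorithms with confidence bounds
#' and the per-algorithm signal criteria flags (ROR CI lower > 1; PRR >= 2
#' with CI lower > 1; IC025 > 0; EBGM05 > 2).
#'
#' @param a,b,c,d Numeric vectors of cell counts (recycled to a common
#'   length).
#' @param prior A [bcpnn_prior()].
#' @param conf_level Confidence level for all intervals (default 0.95).
#' @param correction Apply the +0.5 continuity correction to zero-cell
#'   tables when computing ROR/PRR/EBGM intervals (default `TRUE`).
#' @param min_count Minimum `a` for a pair to be flag-eligible (default 0,
#'   i.e. no floor).
#' @return A tibble with one row per table: estimates, interval bounds,
#'   flags and a `degenerate` marker for zero-cell tables.
#' @export
disprop_stats <- function(a, b, c, d, prior = bcpnn_prior(),
                          conf_level = 0.95, correction = TRUE,
                          min_count = 0) {
  stopifnot(inherits(prior, "bcpnn_prior"))
  len <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), len); b <- rep_len(as.numeric(b), len)
  c <- rep_len(as.numeric(c), len); d <- rep_len(as.numeric(d), len)
  n <- a + b + c + d
  # the conventional 1.96 at the default level, as the formulas are
  # usually printed; exact normal quantile otherwise
  z <- if (isTRUE(all.equal(conf_level, 0.95))) 1.96 else {
    stats::qnorm(1 - (1 - conf_level) / 2)
  }

  degenerate <- a == 0 | b == 0 | c == 0 | d == 0
  corr <- ifelse(correction & degenerate, 0.5, 0)
  ac <- a + corr; bc_ <- b + corr; cc <- c + corr; dc <- d + corr

  # log-scale standard error shared by ROR / PRR / EBGM intervals
  se <- sqrt(1 / ac + 1 / bc_ + 1 / cc + 1 / dc)

  ror_raw <- (a * d) / (b * c)
  ror_corr <- (ac * dc) / (bc_ * cc)
  ror_est <- ifelse(is.nan(ror_raw), ror_corr, ror_raw)
  ror_ci_mid <- ifelse(degenerate, ror_corr, ror_est)
  ror_l <- exp(log(ror_ci_mid) - z * se)
  ror_u <- exp(log(ror_ci_mid) + z * se)

  prr_raw <- (a / (a + b)) / (c / (c + d))
  prr_corr <- (ac / (ac + bc_)) / (cc / (cc + dc))
  prr_est <- ifelse(is.nan(prr_raw), prr_corr, prr_raw)
  prr_ci_mid <- ifelse(degenerate, prr_corr, prr_est)
  prr_l <- exp(log(prr_ci_mid) - z * se)
  prr_u <- exp(log(prr_ci_mid) + z * se)

  # observed/expected ratio; identical for IC (log2 scale) and EBGM
  oe <- (a * n) / ((a + b) * (a + c))
  ic <- log2(oe)

  p <- prior
  gamma <- p$gamma11 * (n + p$alpha) * (n + p$beta) /
    ((a + b + p$alpha1) * (a + c + p$beta1))
  e_ic <- log2(
    (a + p$gamma11) * (n + p$alpha) * (n + p$beta) /
      ((n + gamma) * (a + b + p$alpha1) * (a + c + p$beta1))
  )
  v_ic <- (1 / log(2)^2) * (
    (n - a + gamma - p$gamma11) / ((a + p$gamma11) * (1 + n + gamma)) +
      (n - a - b + p$alpha - p$alpha1) / ((a + b + p$alpha1) * (1 + n + p$alpha)) +
      (n - a - c + p$beta - p$beta1) / ((a + c + p$beta1) * (1 + n + p$beta))
  )
  ic025 <- e_ic - z * sqrt(v_ic)

  ebgm_est <- oe
  ebgm_ci_mid <- ifelse(
    degenerate, (ac * (ac + bc_ + cc + dc)) / ((ac + bc_) * (ac + cc)), oe
  )
  ebgm_l <- exp(log(ebgm_ci_mid) - z * se)
  ebgm_u <- exp(log(ebgm_ci_mid) + z * se)

  eligible <- a >= min_count & a > 0
  tibble::tibble(
    a = a, b = b, c = c, d = d, n = n,
    ror = ror_est, ror_l = ror_l, ror_u = ror_u,
    prr = prr_est, prr_l = prr_l, prr_u = prr_u,
    ic = ic, e_ic = e_ic, v_ic = v_ic, ic025 = ic025,
    ebgm = ebgm_est, ebgm05 = ebgm_l, ebgm_l = ebgm_l, ebgm_u = ebgm_u,
    degenerate = degenerate,
    flag_ror = eligible & is.finite(ror_l) & ror_l > 1,
    flag_prr = eligible & prr_est >= 2 & is.finite(prr_l) & prr_l > 1,
    flag_bcpnn = eligible & is.finite(ic025) & ic025 > 0,
    flag_ebgm = eligible & is.finite(ebgm_l) & ebgm_l > 2
  )
}

.as_cells <- function(t) {
  stopifnot(inherits(t, "contingency_table"))
  t
}

#' Reporting odds ratio
#'
#' `ROR = ad/bc` with the log-normal confidence interval
#' `exp(ln ROR +- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param t A [contingency_table()].
#' @param conf_level Confidence level (default 0.95).
#' @param correction Continuity correction for zero cells; see
#'   [disprop_stats()].
#' @return List with `estimate`, `ci_low`, `ci_high`, `degenerate`.
#' @examples
#' ror(contingency_table(20, 80, 100, 900)) # estimate 2.25
#' @export
ror <- function(t, conf_level = 0.95, correction = TRUE) {
  t <- .as_cells(t)
  s <- disprop_stats(t$a, t$b, t$c, t$d, conf_level = conf_level, correction = correction)
  list(estimate = s$ror, ci_low = s$ror_l, ci_high = s$ror_u, degenerate = s$degenerate)
}

#' Proportional reporting ratio
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` with the log-normal interval on the same
#' variance term as the ROR. A zero `c` cell gives an infinite raw
#' estimate, reported as `Inf` with `degenerate = TRUE`.
#'
#' @inheritParams ror
#' @return List with `estimate`, `ci_low`, `ci_high`, `degenerate`.
#' @export
prr <- function(t, conf_level = 0.95, correction = TRUE) {
  t <- .as_cells(t)
  s <- disprop_stats(t$a, t$b, t$c, t$d, conf_level = conf_level, correction = correction)
  list(estimate = s$prr, ci_low = s$prr_l, ci_high = s$prr_u, degenerate = s$degenerate)
}

#' BCPNN information component
#'
#' Observed `IC = log2(aN / ((a+b)(a+c)))`, its prior-shrunk expectation
#' `E(IC)` and the lower credibility bound `IC025 = E(IC) - z sqrt(V(IC))`
#' with the delta-method variance of Bate et al. (1998). With `a = 0` the
#' observed IC is `-Inf` but `E(IC)` and `IC025` remain finite through the
#' prior.
#'
#' @param t A [contingency_table()].
#' @param prior A [bcpnn_prior()].
#' @param conf_level Credibility level for the one-sided bound (default
#'   0.95, i.e. z = 1.96 on the two-sided scale).
#' @return List with `ic`, `e_ic`, `ic025`, `v_ic`.
#' @export
bcpnn_ic <- function(t, prior = bcpnn_prior(), conf_level = 0.95) {
  t <- .as_cells(t)
  s <- disprop_stats(t$a, t$b, t$c, t$d, prior = prior, conf_level = conf_level)
  list(ic = s$ic, e_ic = s$e_ic, ic025 = s$ic025, v_ic = s$v_ic)
}

#' Observed/expected EBGM-style ratio
#'
#' `EBGM = aN / ((a+b)(a+c))`, the unshrunk observed-to-expected report
#' ratio (algebraically `2^IC`), with a log-normal interval on the ROR/PRR
#' variance term. `EBGM05` is that interval's lower bound used one-sidedly.
#' This is deliberately not the DuMouchel Gamma-Poisson shrinker: no
#' mixture prior is fitted, matching the plain O/E formulation used with
#' the `EBGM05 > 2` screening criterion here.
#'
#' @inheritParams ror
#' @return List with `estimate`, `ebgm05`, `ci_low`, `ci_high`,
#'   `degenerate`.
#' @export
ebgm <- function(t, conf_level = 0.95, correction = TRUE) {
  t <- .as_cells(t)
  s <- disprop_stats(t$a, t$b, t$c, t$d, conf_level = conf_level, correction = correction)
  list(estimate = s$ebgm, ebgm05 = s$ebgm05, ci_low = s$ebgm_l,
       ci_high = s$ebgm_u, degenerate = s$degenerate)
}
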