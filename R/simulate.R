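# Synthetic spontaneous-report databases with known structure: background
# reporting rates, demographic strata, multi-reaction reports, and planted
# drug-event associations whose strength is controlled by a relative
# reporting-rate multiplier.

#' Configuration for the synthetic report generator
#'
#' Defaults emulate the structure of the three-drug androgen-antagonist
#' report database: drug market shares proportional to the published
#' report totals, demographic margins from the apalutamide column of the
#' published demographic table (illustrative, not inferential), a 20-PT
#' catalog with background weights from the published enzalutamide top-20
#' rates, and a truncated-geometric reactions-per-report distribution
#' whose mean (2.578) matches the published reaction-to-report ratio.
#'
#' @param n_reports Number of reports to draw.
#' @param drugs Tibble `drug`, `weight` (market-share weights, any
#'   positive scale).
#' @param pt_catalog Tibble `pt`, `soc`, `weight` (background reporting
#'   weights, any positive scale).
#' @param planted Tibble `drug`, `pt`, `rr` of planted associations: for
#'   reports of that drug, the PT's per-draw selection probability is
#'   exactly `rr` (>= 1) times its background value, with the non-planted
#'   PTs rescaled to absorb the complement.
#' @param mean_reactions Mean of the truncated geometric distribution of
#'   reactions per report (support 1, 2, ..., capped at the catalog
#'   size).
#' @param sex_probs,age_probs,continent_probs,year_probs Named
#'   non-negative weights over the respective vocabulary (years as
#'   integer names).
#' @param seriousness_probs Named per-outcome probabilities for `death`,
#'   `hospitalization`, `disability`, drawn independently per report.
#' @param seed Integer seed; identical seed and config give identical
#'   output.
#' @return A `generator_config`.
#' @export
generator_config <- function(
    n_reports = 5000,
    drugs = default_drug_weights(),
    pt_catalog = default_pt_catalog(),
    planted = tibble::tibble(drug = character(), pt = character(), rr = numeric()),
    mean_reactions = 172020 / 66728,
    sex_probs = c(male = 10751, female = 35, unknown = 666),
    age_probs = c(lt18 = 3, a18_44 = 10, a45_64 = 722, a65_74 = 2217,
                  ge75 = 3624, unknown = 4876),
    continent_probs = c(Africa = 141, Americas = 5932, Asia = 1639,
                        Europe = 3724, Oceania = 16),
    year_probs = c("2016" = 3, "2017" = 4, "2018" = 75, "2019" = 844,
                   "2020" = 1091, "2021" = 1317, "2022" = 2191,
                   "2023" = 2385, "2024" = 3542),
    seriousness_probs = c(death = 0.030, hospitalization = 0.020,
                          disability = 0.003),
    seed = NULL) {
  drugs <- tibble::as_tibble(drugs)
  pt_catalog <- tibble::as_tibble(pt_catalog)
  planted <- tibble::as_tibble(planted)
  stopifnot(
    all(c("drug", "weight") %in% names(drugs)),
    all(c("pt", "soc", "weight") %in% names(pt_catalog)),
    all(c("drug", "pt", "rr") %in% names(planted))
  )
  if (n_reports < 1) rlang::abort("n_reports must be positive")
  if (any(drugs$weight <= 0) || any(pt_catalog$weight <= 0)) {
    rlang::abort("drug and PT weights must be strictly positive")
  }
  if (anyDuplicated(pt_catalog$pt) > 0) rlang::abort("pt_catalog PTs must be unique")
  if (mean_reactions < 1) rlang::abort("mean_reactions must be >= 1")
  if (nrow(planted) > 0) {
    if (any(planted$rr < 1)) rlang::abort("planted rr multipliers must be >= 1")
    for (d in unique(planted$drug)) {
      hits <- planted[planted$drug == d, ]
      idx <- match(hits$pt, pt_catalog$pt)
      mass <- sum(pt_catalog$weight[idx] * hits$rr, na.rm = TRUE) /
        sum(pt_catalog$weight)
      if (is.finite(mass) && mass >= 1) {
        rlang::abort(paste0(
          "planted probability mass for drug '", d,
          "' reaches or exceeds 1; lower rr or background weights"
        ))
      }
    }
    bad_drug <- setdiff(planted$drug, drugs$drug)
    bad_pt <- setdiff(planted$pt, pt_catalog$pt)
    if (length(bad_drug) > 0 || length(bad_pt) > 0) {
      rlang::abort(paste0(
        "planted pair references unknown ",
        paste(c(
          if (length(bad_drug) > 0) paste0("drug(s): ", paste(bad_drug, collapse = ", ")),
          if (length(bad_pt) > 0) paste0("PT(s): ", paste(bad_pt, collapse = ", "))
        ), collapse = "; ")
      ))
    }
  }
  check_probs <- function(p, name) {
    if (any(p < 0) || sum(p) <= 0 || is.null(names(p))) {
      rlang::abort(paste0(name, " must be named non-negative weights with positive sum"))
    }
  }
  check_probs(sex_probs, "sex_probs"); check_probs(age_probs, "age_probs")
  check_probs(continent_probs, "continent_probs"); check_probs(year_probs, "year_probs")
  if (any(seriousness_probs < 0) || any(seriousness_probs > 1)) {
    rlang::abort("seriousness_probs must lie in [0, 1]")
  }
  structure(
    list(
      n_reports = as.integer(n_reports), drugs = drugs,
      pt_catalog = pt_catalog, planted = planted,
      mean_reactions = mean_reactions,
      sex_probs = sex_probs, age_probs = age_probs,
      continent_probs = continent_probs, year_probs = year_probs,
      seriousness_probs = seriousness_probs, seed = seed
    ),
    class = "generator_config"
  )
}

#' Default market-share weights of the three-drug universe
#' @return Tibble `drug`, `weight` (published report totals).
#' @export
default_drug_weights <- function() {
  tibble::tibble(
    drug = c("apalutamide", "darolutamide", "enzalutamide"),
    weight = c(11452, 2269, 53007)
  )
}

#' Default 20-PT background catalog
#'
#' The published enzalutamide top-20 PTs with their report rates as
#' background weights and SOCs from the bundled map.
#'
#' @return Tibble `pt`, `soc`, `weight`.
#' @export
default_pt_catalog <- function() {
  top <- vigiaccess_top_pt()
  top <- top[top$drug == "enzalutamide", ]
  map <- meddra_fixture_map()
  tibble::tibble(pt = top$pt, soc = pt_soc(map, top$pt), weight = top$rate)
}

#' Generate a synthetic report database
#'
#' Reports are drawn independently: the suspect drug from the
#' market-share weights (always with role `primary_suspect`), the
#' reaction count from a truncated geometric distribution, reactions from
#' the PT catalog without replacement within a report (background weight
#' times the planted multiplier when the report's drug carries a planted
#' association for that PT), and demographics and seriousness
#' independently of the reactions.
#'
#' @param config A [generator_config()].
#' @return List with `reports` (a [report_set()]) and `truth` (tibble of
#'   planted pairs with `rr` and an approximate `expected_count` of
#'   drug-and-event reports, computed from the realized drug assignments
#'   and reaction counts under a with-replacement approximation).
#' @examples
#' sim <- simulate_reports(generator_config(n_reports = 200, seed = 1))
#' sim$reports
#' @export
simulate_reports <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_reports
  n_pt <- nrow(config$pt_catalog)

  drug <- sample(config$drugs$drug, n, replace = TRUE,
                 prob = config$drugs$weight / sum(config$drugs$weight))
  k <- 1L + stats::rgeom(n, prob = 1 / config$mean_reactions)
  k <- pmin(k, n_pt)

  # Per-drug per-draw selection probabilities. A planted (drug, pt, rr)
  # sets that PT's probability to exactly rr times its background value;
  # the non-planted PTs are rescaled to absorb the complement, so the
  # per-draw relative reporting rate of a planted pair is rr by
  # construction.
  weights_for <- function(d) {
    w <- config$pt_catalog$weight / sum(config$pt_catalog$weight)
    hits <- config$planted[config$planted$drug == d, ]
    if (nrow(hits) > 0) {
      idx <- match(hits$pt, config$pt_catalog$pt)
      planted_mass <- sum(w[idx] * hits$rr)
      w[-idx] <- w[-idx] * (1 - planted_mass) / sum(w[-idx])
      w[idx] <- w[idx] * hits$rr
    }
    w
  }
  wtab <- lapply(stats::setNames(config$drugs$drug, config$drugs$drug), weights_for)

  pts <- config$pt_catalog$pt
  reactions <- vector("list", n)
  for (i in seq_len(n)) {
    reactions[[i]] <- sample(pts, k[i], replace = FALSE, prob = wtab[[drug[i]]])
  }

  draw_cat <- function(p) sample(names(p), n, replace = TRUE, prob = p / sum(p))
  sex <- draw_cat(config$sex_probs)
  age <- draw_cat(config$age_probs)
  continent <- draw_cat(config$continent_probs)
  year <- as.integer(draw_cat(config$year_probs))

  sp <- config$seriousness_probs
  death <- stats::runif(n) < (sp[["death"]] %||% 0)
  hosp <- stats::runif(n) < (sp[["hospitalization"]] %||% 0)
  disab <- stats::runif(n) < (sp[["disability"]] %||% 0)
  seriousness <- Map(function(de, ho, di) {
    s <- c("death", "hospitalization", "disability")[c(de, ho, di)]
    if (length(s) == 0) "none_reported" else s
  }, death, hosp, disab)

  reports <- tibble::tibble(
    report_id = sprintf("S%06d", seq_len(n)),
    drugs = lapply(drug, function(d) stats::setNames("primary_suspect", d)),
    reactions = reactions,
    sex = sex,
    age_group = age,
    continent = continent,
    year = year,
    seriousness = seriousness
  )

  truth <- config$planted
  if (nrow(truth) > 0) {
    truth$expected_count <- vapply(seq_len(nrow(truth)), function(j) {
      d <- truth$drug[j]
      w <- wtab[[d]]
      q <- w[match(truth$pt[j], pts)] / sum(w)
      sum(1 - (1 - q)^k[drug == d])
    }, numeric(1))
  } else {
    truth$expected_count <- numeric(0)
  }

  list(
    reports = report_set(reports, source = "synthetic"),
    truth = truth
  )
}
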