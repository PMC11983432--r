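---
title: "Disproportionality signal detection for spontaneous reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection for spontaneous reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous-report databases such as WHO VigiBase (publicly summarized
through VigiAccess) collect individual case safety reports (ICSRs): one
report links one or more suspect drugs to one or more reaction terms,
coded as MedDRA preferred terms (PTs) that roll up into system organ
classes (SOCs), together with patient demographics and seriousness
outcomes. Because there is no denominator of drug exposure, safety
screening relies on *disproportionality*: comparing how often a
drug–event pair is reported against the background of all other
drug–event pairs in the same database.

`pvsignal` implements that workflow end to end for comparative drug
safety profiling — the motivating application is the three oral
androgen-receptor antagonists used in prostate cancer (apalutamide,
darolutamide, enzalutamide), whose published VigiAccess summary counts
are bundled as regression fixtures — but every stage operates on generic
report sets.

## Data model and screening

A `report_set` holds one row per report: an opaque `report_id`, a set of
(drug, role) pairs, a non-empty PT list, demographics with explicit
`unknown` levels, an integer year (`NA` for unknown), and a seriousness
set over death / hospitalization / disability / none-reported. Ingestion
(`read_reports()`) normalizes free-text fields through a frozen synonym
table (`"M "` → `male`, `"hospitalisation"` → `hospitalization`, …);
unrecognized tokens are errors naming the row and field, while missing
values map to `unknown` and are never dropped. PT strings are only
whitespace-normalized; matching is exact, with no synonym resolution.

`screen_primary_suspect()` mirrors the screening used with VigiAccess
extracts: keep the reports naming the target drug as *primary suspect*
(without demanding exclusivity when several suspects are listed — the
portal does not document how ties are handled, so eligibility is the
inclusive reading), then drop duplicate `report_id`s (first occurrence
kept; record-linkage beyond exact id match is out of scope, as the
upstream database deduplicates case-level records) and structurally
invalid reports (no reactions, or no drug entry). Every step is logged
with its removal count in the set's filter provenance.

## Two denominators

Published summary tables of this kind mix two conventions, and the
package keeps them as distinct code paths:

* **report-level** — demographic tables divide by the number of
  *reports* (`demographic_table()`);
* **reaction-level** — SOC profiles divide by the total number of PT
  *occurrences*, a report with $k$ reactions contributing $k$
  (`soc_profile()`).

Top-PT tables (`top_pt_table()`) and serious-AE rates
(`serious_ae_rates()`) default to the reaction-level denominator, which
is the convention consistent with the bundled summary tables (e.g. a
9.93% rash rate against a reaction total, and serious-AE rates printed
next to the reaction N); both expose `denominator = "report"` as the
alternative. On data where every report carries exactly one reaction the
two conventions coincide, which the test suite uses as a consistency
check.

Percentages are rounded **half away from zero at two decimals**
(`round_half_up()`), the rule that reproduces 143 of the 147 printed
demographic/SOC percentages from their own printed numerators and
denominators. The remaining four printed cells exceed their own
count/denominator ratio by exactly one cent and are inconsistent with
*any* single rounding rule that also reproduces the demographic table
(they match an intermediate three-decimal rounding, which in turn breaks
four demographic cells); the regression tests pin this state rather than
paper over it.

## The four algorithms

All four statistics are computed from the 2×2 report-count table for a
drug–event pair ($N = a+b+c+d$):

|            | event | no event |
|------------|-------|----------|
| target drug | $a$  | $b$      |
| other drugs | $c$  | $d$      |

* **ROR** $= ad/bc$, with the log-normal interval
  $\exp(\ln\mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$.
  Criterion: lower 95% bound $> 1$.
* **PRR** $= \frac{a/(a+b)}{c/(c+d)}$ with the interval on the same
  variance term. Criterion: PRR $\ge 2$ *and* lower bound $> 1$.
* **BCPNN information component** IC
  $= \log_2 \frac{aN}{(a+b)(a+c)}$, shrunk to
  $E(\mathrm{IC}) = \log_2 \frac{(a+\gamma_{11})(N+\alpha)(N+\beta)}
  {(N+\gamma)(a+b+\alpha_1)(a+c+\beta_1)}$ under the Bate et al. (1998)
  prior, with
  $\gamma = \gamma_{11}(N+\alpha)(N+\beta) / ((a+b+\alpha_1)(a+c+\beta_1))$
  and the companion delta-method variance $V(\mathrm{IC})$;
  $\mathrm{IC}_{025} = E(\mathrm{IC}) - 1.96\sqrt{V(\mathrm{IC})}$.
  Criterion: $\mathrm{IC}_{025} > 0$.
* **EBGM-style ratio** $= aN/((a+b)(a+c))$, the *unshrunk*
  observed/expected ratio (identically $2^{\mathrm{IC}}$), with the
  log-normal interval on the ROR/PRR variance term; EBGM05 is that
  interval's lower bound used one-sidedly. Criterion: EBGM05 $> 2$.

Design notes, in decreasing order of consequence:

* **EBGM is deliberately not the DuMouchel Gamma–Poisson shrinker.** The
  formulation implemented here — and screened with EBGM05 > 2 — is the
  plain O/E ratio as commonly tabulated alongside ROR/PRR/IC in
  comparative ADR studies. No mixture prior is fitted; users wanting the
  shrunk estimator should treat this column as the O/E ratio it is.
* **BCPNN prior defaults** are $\alpha_1=\beta_1=\gamma_{11}=1$,
  $\alpha=\beta=2$. Under this construction $E(\mathrm{IC})$ shrinks the
  observed IC toward zero; at exact independence it is *near* zero but
  not exactly zero at finite margins (for $a{=}100, b{=}900, c{=}9900,
  d{=}89100$ it is $-0.0015$), vanishing as the margins grow. This is a
  property of the prior, not an implementation error, and the tests
  assert the closed-form value rather than an idealized zero.
* **Zero cells.** Point estimates are computed on raw counts whenever
  defined ($a=0$ gives ROR 0, $c=0$ gives an infinite PRR sentinel); when
  any cell is zero, the Haldane–Anscombe +0.5 correction on all four
  cells is used for the ROR/PRR/EBGM intervals, and the table is flagged
  `degenerate`. The BCPNN expectation and bound stay finite through the
  prior without correction.
* **$z$ multiplier.** At the default 95% level the conventional literal
  1.96 is used, matching how these formulas are universally printed; any
  other `conf_level` uses the exact normal quantile.
* **No minimum-count floor** is imposed by default ($a \ge 1$ suffices);
  `min_count` reinstates the common $a \ge 3$ floor if wanted.
* **Signal rule.** An event is a signal when *any* criterion fires
  (default) or with `rule = "all"`, the four-way consensus.

`detect_signals()` computes all events observed with the drug in one
vectorized pass; `build_contingency()` exposes single pairs, at PT level
or aggregating a whole SOC.

## Cross-drug comparison

`intersect_signals()` partitions the drugs' PT-level signal sets into
*shared* (signalled for every drug, grouped by SOC and ranked by per-SOC
count), *drug-exclusive* (signalled for exactly one drug), and
*partially shared* (more than one but not all drugs — reported
separately because two-way overlaps belong to neither of the published
table layouts). The per-drug identity
$|\mathrm{signals}| = |\mathrm{shared}| + |\mathrm{exclusive}| +
|\mathrm{partial}|$ is a tested invariant, as is permutation invariance
in the input order.

One structural fact matters when validating this on simulated data: in a
*closed* universe containing only the compared drugs, an association
planted with the same strength in all of them can never be flagged for
any — each drug is contrasted against the equally elevated remainder. A
shared signal is only recoverable against background reports that do not
carry the elevation, so the end-to-end tests simulate a fourth,
unplanted background drug. The same logic explains why a published
shared-signal list cannot be reproduced from the compared drugs' reports
alone: it presupposes the full database background.

## The synthetic report generator

`simulate_reports()` draws reports independently: drug from market-share
weights (role always primary suspect), reaction count from a truncated
geometric distribution on $\{1, 2, \dots\}$ capped at the catalog size,
reactions without replacement from the PT catalog (so PT lists contain
no duplicates, matching how PTs are counted per report), demographics
and seriousness independent of the reactions. With a fixed seed the
output is byte-identical across runs.

Defaults are the study conditions of the bundled three-drug dataset,
chosen once from its published margins: market shares proportional to
the report totals (11,452 / 2,269 / 53,007), demographic margins from
the apalutamide column of the demographic table (illustrative, not
inferential — the source gives no joint distribution, so demographics
are independent of drug and reactions), a 20-PT catalog weighted by the
published enzalutamide top-20 report rates, and mean reactions per
report 172,020 / 66,728 ≈ 2.578, the dataset's reaction-to-report ratio.

A planted association `(drug, pt, rr)` sets that PT's per-draw selection
probability to exactly `rr` times its background value, with the
non-planted PTs rescaled to absorb the complement — so the per-draw
relative reporting rate *is* the nominal multiplier. Report-level
containment rates are nevertheless compressed toward 1 by multi-reaction
saturation, and the observed/expected statistics are further diluted by
the drug's own share of the event background; both effects are intrinsic
to report-level disproportionality, not generator artifacts. The ground
truth returned with each simulation carries an expected
drug-and-event report count computed from the realized drug assignments
and reaction counts.

The calibration and recovery experiments in the test suite use 5,000
reports per null universe (200 replicates) and 20,000 reports per
planted replicate (100 replicates per multiplier). The latter size was
fixed by a power calculation before any experiment was run: at rr = 5 on
a low-share drug and a mid-weight PT it yields an expected $a \approx
150$ and places the EBGM05 criterion several standard errors above its
threshold, so the ≥95% all-four-criteria recovery requirement tests the
method rather than Monte-Carlo luck.

## What the synthetic data does and does not show

The generator reproduces the *structure* that the pipeline consumes —
multi-reaction reports, skewed market shares, demographic margins,
controlled association strengths — so passing tests demonstrate correct
arithmetic, calibrated false-positive behavior, and recovery of known
signals. It does not emulate reporting delays or secular trends, the
Weber effect, drug–demographic or reaction–reaction dependence, country
mixes below continent level, masking by competing signals, or duplicate
and incomplete submissions. Conclusions about real databases therefore
rest on the screening and statistics being correct, not on the simulator
being a faithful model of pharmacovigilance reporting behavior.

Dataset-level published figures that depend on record-level data (the
162 shared-signal total and the 4.94 / 2.85 / 5.06% serious-AE rates)
are carried as transcriptions and exercised only through internal
consistency checks; record-level VigiAccess data cannot be downloaded,
so these are not recomputable here. Two internal inconsistencies in the
published tables — four SOC percentages off by one cent from their own
counts, and one shared-signal row listing 26 PTs against a printed count
of 25 — are documented by the regression tests exactly as found.

## Worked example

```{r example}
cfg <- generator_config(
  n_reports = 2000, seed = 8,
  planted = tibble::tibble(drug = "darolutamide", pt = "Malaise", rr = 6)
)
sim <- simulate_reports(cfg)
map <- meddra_fixture_map()

det <- detect_signals(sim$reports, "darolutamide", map)
det[det$signal, c("event", "soc", "a", "ror", "ror_l", "prr",
                  "ic025", "ebgm05")]
```

The planted pair surfaces with all four criteria; unplanted events
hover near their null expectations. The same objects feed
`soc_profile()`, `top_pt_table()` and, across drugs,
`intersect_signals()` — or `run_pipeline()` drives all stages from one
configuration list and writes a results directory with a manifest.
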