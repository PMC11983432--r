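# pvsignal

Disproportionality signal detection and adverse-drug-reaction (ADR)
profiling for spontaneous-report databases.

Pharmacovigilance databases of individual case safety reports — one
report linking suspect drug(s) to one or more MedDRA preferred terms
(PTs), with demographics and seriousness outcomes — have no exposure
denominator, so safety screening works by *disproportionality*: each
drug–event pair is contrasted with the background of all other pairs via
its 2×2 report-count table (a, b, c, d; N = a+b+c+d). `pvsignal` is for
analysts who screen such databases and compare ADR profiles across
drugs. It implements:

* **Ingestion and screening** of report sets (CSV/JSON), with frozen
  field normalization, primary-suspect filtering, deduplication, and a
  logged filter provenance.
* **Descriptive profiles**: demographic tables (report-level
  denominator), SOC-level and top-N PT reaction rates and serious-AE
  rates (reaction-level denominator), with half-up rounding at two
  decimals.
* **Four disproportionality algorithms** with their standard criteria:
  * ROR = ad/bc, 95% CI = exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)); signal
    if the lower bound > 1;
  * PRR = [a/(a+b)]/[c/(c+d)], same interval form; signal if PRR ≥ 2 and
    lower bound > 1;
  * BCPNN information component IC = log2(aN/((a+b)(a+c))) with the Bate
    (1998) Bayesian shrinkage E(IC) and credibility bound IC025; signal
    if IC025 > 0;
  * an EBGM-style observed/expected ratio aN/((a+b)(a+c)) (= 2^IC) with
    a log-normal interval; signal if its lower bound EBGM05 > 2.
* **Cross-drug comparison**: PT signals shared by all drugs (grouped and
  ranked by SOC) versus drug-exclusive signals.
* **A seeded synthetic report generator** with planted drug–event
  associations of controlled strength, used to calibrate false-positive
  rates and verify signal recovery end to end.
* Bundled transcriptions of the published VigiAccess summary tables for
  apalutamide, darolutamide and enzalutamide (report/reaction totals,
  demographics, SOC rates, top-20 PTs, shared/distinct signal lists) and
  a toy PT→SOC map built from them, used as regression fixtures.

## Worked example

```r
library(pvsignal)

# screen a small bundled report file for one drug
f <- system.file("extdata", "example_reports.csv", package = "pvsignal")
rs <- read_reports(f)
screen_primary_suspect(rs, "apalutamide")
#> <report_set> 3 report(s), 5 reaction term(s), source: .../example_reports.csv
#> filters applied:
#>   1. ingest_reject_invalid (removed 0) records with empty reaction list
#>   2. primary_suspect (removed 9) drug=apalutamide
#>   3. deduplicate (removed 0) identical report_id, first kept
#>   4. drop_invalid (removed 0) empty reactions or no drug entry

# a worked 2x2 table: a=20, b=80, c=100, d=900
t <- contingency_table(20, 80, 100, 900)
ror(t)        # estimate 2.25, 95% CI 1.32-3.83
bcpnn_ic(t)   # IC 0.874, E(IC) 0.799, IC025 0.089

# plant a 6x association and recover it
cfg <- generator_config(
  n_reports = 2000, seed = 8,
  planted = tibble::tibble(drug = "darolutamide", pt = "Malaise", rr = 6)
)
sim <- simulate_reports(cfg)
det <- detect_signals(sim$reports, "darolutamide", meddra_fixture_map())
det[det$signal, c("event", "soc", "a", "ror", "ror_l", "prr", "ic025", "ebgm05")]
#>     event                                                  soc  a  ror ror_l  prr ic025 ebgm05
#> 1 Malaise General disorders and administration site conditions 21 6.31  3.64 4.57   1.1   2.37
```

The planted pair — and only it — is flagged: its reporting odds are 6.3
times the background (CI excluding 1), the proportional reporting ratio
exceeds 2, the shrunk information component's lower bound is above 0,
and the O/E lower bound is above 2. `intersect_signals()` then compares
such signal sets across drugs, and `run_pipeline()` drives
simulate/ingest → screen → profile → detect → compare from a single
configuration list (or YAML file, see
`inst/scripts/pvsignal-pipeline.R`), writing CSV outputs and a run
manifest.

The methods vignette (`vignettes/pvsignal-methods.Rmd`) documents the
model, the two denominator conventions, the prior and zero-cell
handling, the generator's design, and known limitations.

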