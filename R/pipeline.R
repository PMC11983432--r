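# One-call pipeline: simulate or ingest a report universe, screen it per
# drug, write descriptive profiles, run signal detection, and compare the
# drugs' signal sets. A manifest recording the configuration hash, seed
# and package version is always written, even on failure.

#' Run the full analysis pipeline
#'
#' Stages: (1) obtain the report universe, either by simulation
#' (`config$simulate`, passed to [generator_config()]) or from a file
#' (`config$input$path` / `config$input$format`); (2) for each drug in
#' `config$drugs`, screen to primary-suspect reports and write the four
#' demographic tables, the SOC profile, the top-PT table and the
#' serious-AE table; (3) run [detect_signals()] per drug against the full
#' universe; (4) intersect the signal sets and write the shared/distinct
#' comparison tables.
#'
#' @param config A named list, or the path to a YAML file holding one.
#'   Recognized fields: `out_dir` (required), `drugs` (default: all drugs
#'   appearing as primary suspects), `level` (`"pt"`/`"soc"`), `top_n`
#'   (default 20), `min_count`, `rule`, `seed`, `map` (path to a PT-SOC
#'   CSV; default the bundled map), and `simulate` or `input` as above.
#' @return Invisibly, a list with `status` (0 on success), `out_dir`,
#'   `files` and the `universe` report_set. On stage failure the partial
#'   outputs are retained next to a `FAILED` marker file and `status` is
#'   1.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  status <- 0L
  err_msg <- NULL
  universe <- NULL

  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(x, path)
    files <<- c(files, path)
    path
  }

  result <- tryCatch({
    map <- if (!is.null(config$map)) read_meddra_map(config$map) else meddra_fixture_map()

    if (!is.null(config$input)) {
      universe <- read_reports(config$input$path, config$input$format %||% "csv")
    } else {
      sim_args <- config$simulate %||% list()
      if (!is.null(config$seed)) sim_args$seed <- config$seed
      if (!is.null(sim_args$planted)) {
        sim_args$planted <- tibble::as_tibble(sim_args$planted)
      }
      gen <- do.call(generator_config, sim_args)
      sim <- simulate_reports(gen)
      universe <- sim$reports
      if (nrow(sim$truth) > 0) {
        jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                             dataframe = "rows", auto_unbox = TRUE, digits = NA)
        files <- c(files, file.path(out_dir, "truth.json"))
      }
      files <- c(files, write_reports(universe, file.path(out_dir, "universe.csv")))
    }

    drugs <- config$drugs %||% sort(unique(unlist(
      lapply(universe$reports$drugs, function(d) names(d)[d == "primary_suspect"])
    )))
    if (length(drugs) == 0) rlang::abort("no drugs to analyze")
    level <- config$level %||% "pt"

    detections <- list()
    for (d in drugs) {
      rs_d <- screen_primary_suspect(universe, d)
      for (axis in c("sex", "age_group", "continent", "year")) {
        emit(demographic_table(rs_d, axis),
             sprintf("demographics_%s_%s.csv", d, axis))
      }
      prof <- soc_profile(rs_d, map, drug = d)
      emit(prof$table, sprintf("soc_profile_%s.csv", d))
      emit(top_pt_table(rs_d, n = config$top_n %||% 20),
           sprintf("top_pt_%s.csv", d))
      emit(serious_ae_rates(rs_d), sprintf("serious_%s.csv", d))
      det <- detect_signals(
        universe, d, map, level = level,
        min_count = config$min_count %||% 0,
        rule = config$rule %||% "any"
      )
      emit(det, sprintf("signals_%s.csv", d))
      detections[[d]] <- det
    }

    if (length(drugs) >= 2 && level == "pt") {
      sets <- lapply(drugs, function(d) as_signal_set(detections[[d]], d))
      cr <- intersect_signals(sets)
      files <- c(files, write_comparison(comparison_report(cr), out_dir))
    }
    TRUE
  }, error = function(e) {
    status <<- 1L
    err_msg <<- conditionMessage(e)
    writeLines(err_msg, file.path(out_dir, "FAILED"))
    FALSE
  })

  manifest <- list(
    package = "pvsignal",
    version = as.character(utils::packageVersion("pvsignal")),
    config_hash = rlang::hash(config),
    seed = config$seed %||% NA,
    status = status,
    error = err_msg,
    files = basename(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(status = status, out_dir = out_dir, files = files,
                 universe = universe))
}
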