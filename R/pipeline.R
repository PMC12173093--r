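#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run. `data_dir` must contain a
#' cohort laid out as written by [generate_cohort()]: a `manifest.json`
#' listing per-patient survey/GPS/relapse files and a schema file.
#'
#' @param data_dir Input cohort directory.
#' @param out_dir Output directory.
#' @param imputation An [imputation_config()].
#' @param ensemble List of [build_ensemble()] arguments
#'   (`strategies`, `k_list`, `methods`, `k_max`, `restarts`).
#' @param passive List of [find_significant_locations()] arguments
#'   (`max_locations`, `radius_m`, `min_dwell_frac`, `max_gap_min`).
#' @param window_days Analysis window length in days.
#' @param ratio_threshold SD-ratio threshold for anomaly flags.
#' @param report_features Character vector of length 2: the features of the
#'   left and right report panels.
#' @param seed Master seed; per-(stage, patient) seeds are derived from it.
#' @param tz Timezone for local-day bucketing of GPS pings.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir, out_dir,
                            imputation = imputation_config("locf"),
                            ensemble = list(),
                            passive = list(),
                            window_days = 30L,
                            ratio_threshold = 2,
                            report_features = c("mca_trend", "home_time"),
                            seed = 0L,
                            tz = "UTC") {
  ensemble_defaults <- list(strategies = c("predefined", "natural"),
                            k_list = c(2L, 3L, 4L),
                            methods = c("kmeans", "agglomerative"),
                            k_max = 6L, restarts = 5L)
  passive_defaults <- list(max_locations = 6L, radius_m = 200,
                           min_dwell_frac = 0.01, max_gap_min = 60)
  structure(
    list(data_dir = data_dir, out_dir = out_dir,
         imputation = imputation,
         ensemble = utils::modifyList(ensemble_defaults, ensemble),
         passive = utils::modifyList(passive_defaults, passive),
         window_days = as.integer(window_days),
         ratio_threshold = ratio_threshold,
         report_features = report_features,
         seed = as.integer(seed),
         tz = tz),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the
#' `imputation` block maps to [imputation_config()] fields.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  imp <- do.call(imputation_config, raw$imputation %||% list())
  args <- raw[setdiff(names(raw), "imputation")]
  do.call(pipeline_config, c(args, list(imputation = imp)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_seed <- function(master, patient_index, stage) {
  offset <- match(stage, c("impute", "ensemble", "passive"))
  (as.integer(master) %% 65536L) * 26003L + patient_index * 29L + offset * 7L
}

process_patient <- function(entry, index, schema, config) {
  pid <- entry$patient_id
  pdir <- file.path(config$out_dir, pid)
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  survey <- read_survey(file.path(config$data_dir, entry$survey), schema)
  gps <- read_gps(file.path(config$data_dir, entry$gps), tz = config$tz)
  relapse <- read_relapse(file.path(config$data_dir, entry$relapse))[[pid]] %||%
    as.Date(character())

  imp_cfg <- config$imputation
  imp_cfg$seed <- stage_seed(config$seed, index, "impute")
  complete <- impute_survey(survey, schema, imp_cfg)
  write_survey(complete, file.path(pdir, "survey_complete.csv"))

  mcas <- fit_section_mcas(complete, schema)
  trends <- lapply(mcas, mca_trend)
  trend_mat <- do.call(cbind, lapply(trends, function(t) t$score))
  rownames(trend_mat) <- format(trends[[1]]$date, "%Y-%m-%d")
  write_matrix(trend_mat, file.path(pdir, "mca_trends.csv"))
  gap_tab <- dplyr::bind_rows(lapply(names(mcas), function(sec) {
    g <- eigengaps(mcas[[sec]])
    tibble::tibble(section = sec, first = g$first, second = g$second,
                   degenerate = mcas[[sec]]$degenerate)
  }))
  readr::write_csv(gap_tab, file.path(pdir, "eigengaps.csv"))

  vectors <- list(AV = make_av(complete, schema), CV = make_cv(complete, schema))
  coassoc <- list()
  for (kind in c("AV", "CV")) {
    ens <- do.call(build_ensemble, c(
      list(vectors = vectors, kinds = kind,
           seed = stage_seed(config$seed, index, "ensemble")),
      config$ensemble))
    co <- coassociation(ens)
    write_matrix(unclass(co), file.path(pdir, paste0("coassociation_",
                                                     tolower(kind), ".csv")))
    coassoc[[kind]] <- co
  }

  locs <- do.call(find_significant_locations, c(
    list(gps = gps, seed = stage_seed(config$seed, index, "passive")),
    config$passive))
  daily <- daily_summaries(gps, locs, tz = config$tz)
  readr::write_csv(daily, file.path(pdir, "daily_locations.csv"), na = "")

  span <- range(survey$date)
  windows <- define_windows(relapse, span, config$window_days)
  summary <- summarize_windows(trends, windows)
  flags <- flag_anomalous_windows(summary, config$ratio_threshold)
  readr::write_csv(summary, file.path(pdir, "window_summary.csv"), na = "")
  readr::write_csv(flags, file.path(pdir, "window_flags.csv"), na = "")

  results_by_feature <- list(
    mca_trend = trends,
    eigengap = gap_tab[, c("section", "first", "second")],
    coassociation = coassoc$AV,
    home_time = daily,
    location_pies = daily
  )
  specs <- lapply(config$report_features, function(f) {
    panel_spec(f, pid, results_by_feature[[f]],
               params = list(impute = config$imputation$method,
                             seed = config$seed),
               relapse_dates = relapse)
  })
  render_report(specs[[1]], specs[[2]], file.path(pdir, "report.html"),
                title = paste("patient", pid))
  list(patient_id = pid, flags = flags, n_dates = nrow(trend_mat),
       report = file.path(pid, "report.html"))
}

#' Run the full pipeline over a cohort
#'
#' For every patient in the cohort manifest: read and validate inputs,
#' impute, fit per-section MCAs and trends, build AV/CV clustering
#' ensembles and coassociation matrices, summarize GPS into daily
#' home-time/dwell tables, compute window summaries and anomaly flags, and
#' render a two-panel report. All intermediate tables are written as CSV
#' under `out_dir/<patient>/`, a cohort `index.html` links the reports, and
#' `run_manifest.json` records package version, seeds and parameters. A
#' failing patient is logged and skipped; the run fails only if every
#' patient fails. Numerically reproducible (bit-identical CSVs) for a fixed
#' configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with per-patient results and the paths
#'   written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- jsonlite::fromJSON(file.path(config$data_dir, "manifest.json"),
                                 simplifyDataFrame = FALSE)
  schema <- read_schema(file.path(config$data_dir, manifest$schema_file))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  failures <- character()
  entries <- manifest$patients
  for (i in seq_along(entries)) {
    entry <- entries[[i]]
    res <- tryCatch(
      process_patient(entry, i, schema, config),
      error = function(e) {
        message("patient ", entry$patient_id, " failed: ", conditionMessage(e))
        NULL
      }
    )
    if (is.null(res)) {
      failures <- c(failures, entry$patient_id)
    } else {
      results[[entry$patient_id]] <- res
    }
  }
  if (length(entries) > 0 && length(results) == 0) {
    stop("all patients failed", call. = FALSE)
  }
  index <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>cohort index</title></head><body><h2>cohort index</h2><ul>",
    vapply(results, function(r) {
      paste0("<li><a href='", r$report, "'>", r$patient_id, "</a> (",
             r$n_dates, " dates)</li>")
    }, character(1)),
    "</ul></body></html>"
  )
  writeLines(index, file.path(config$out_dir, "index.html"))
  run_manifest <- list(
    package = "phenovis",
    version = as.character(utils::packageVersion("phenovis")),
    seed = config$seed,
    imputation = unclass(config$imputation),
    ensemble = config$ensemble,
    passive = config$passive,
    window_days = config$window_days,
    ratio_threshold = config$ratio_threshold,
    data_dir = config$data_dir,
    patients_ok = names(results),
    patients_failed = failures
  )
  jsonlite::write_json(run_manifest,
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = results, failures = failures,
                 out_dir = config$out_dir))
}
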