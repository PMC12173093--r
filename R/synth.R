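#' Synthetic digital-phenotyping cohort configuration
#'
#' Defines the generative model for offline testing of the whole pipeline:
#' ordinal survey responses arise from a latent Gaussian per (section, day)
#' shared across the section's questions plus per-question noise, rounded
#' to the nearest legal level; inside the 30 days before each relapse the
#' day-level SD is multiplied by `relapse_sd_inflation` and the mean
#' shifted by `relapse_mean_shift` (erratic responding before relapse).
#' Responses are deleted completely at random with probability
#' `missing_rate`. GPS pings are emitted at a fixed daily rate, each at the
#' home location with probability `home_ping_prob_control`
#' (`home_ping_prob_prerelapse` inside pre-relapse windows, elevated home
#' time) else uniformly at one of several other locations, with small
#' coordinate jitter.
#'
#' The baseline day-level SD (0.6 on the 0-3 level scale) makes responses
#' fluctuate between adjacent levels day to day, so control-window trend
#' SDs are positive and stable while a 3x pre-relapse SD inflation still
#' dominates them — the regime in which relapse shows up as an SD ratio.
#'
#' @param n_patients Number of patients in a cohort.
#' @param span_days Study length in days.
#' @param schema A [survey_schema()] (default [default_schema()]).
#' @param relapse_spec List (one element per patient, recycled) of integer
#'   day offsets (1-based) of relapse dates; `NULL` draws one relapse per
#'   patient uniformly in the middle of the study.
#' @param baseline_response_mean Named numeric (per section, recycled) of
#'   latent means on the level scale.
#' @param baseline_response_sd Day-level latent SD (shared across sections).
#' @param question_noise_sd Per-question latent noise SD.
#' @param relapse_sd_inflation Multiplier (>= 1) on the day-level SD inside
#'   pre-relapse windows.
#' @param relapse_mean_shift Additive latent mean shift inside pre-relapse
#'   windows.
#' @param missing_rate MCAR deletion probability in `[0, 1)`.
#' @param window_days Length of the pre-relapse window.
#' @param start_date First study date.
#' @param gps List of GPS parameters: `home_lat`, `home_lon`,
#'   `n_other_locations`, `home_ping_prob_control`,
#'   `home_ping_prob_prerelapse`, `pings_per_day`, `jitter_sd_m`.
#' @param seed Master seed; all draws are deterministic given
#'   (seed, patient_index).
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_patients = 24L,
                         span_days = 180L,
                         schema = default_schema(),
                         relapse_spec = NULL,
                         baseline_response_mean = c(mood = 1.2, sleep = 1.0,
                                                    social = 1.4, anxiety = 1.1,
                                                    psychosis = 0.8),
                         baseline_response_sd = 0.6,
                         question_noise_sd = 0.5,
                         relapse_sd_inflation = 3,
                         relapse_mean_shift = 0.3,
                         missing_rate = 0.15,
                         window_days = 30L,
                         start_date = as.Date("2021-10-01"),
                         gps = list(),
                         seed = 0L) {
  stopifnot(inherits(schema, "survey_schema"),
            relapse_sd_inflation >= 1,
            missing_rate >= 0, missing_rate < 1,
            span_days >= 2)
  gps_defaults <- list(home_lat = 12.9716, home_lon = 77.5946,
                       n_other_locations = 3L,
                       home_ping_prob_control = 0.6,
                       home_ping_prob_prerelapse = 0.85,
                       pings_per_day = 24L,
                       jitter_sd_m = 20)
  gps <- utils::modifyList(gps_defaults, gps)
  stopifnot(gps$home_ping_prob_control >= 0, gps$home_ping_prob_control <= 1,
            gps$home_ping_prob_prerelapse >= 0,
            gps$home_ping_prob_prerelapse <= 1)
  mu <- baseline_response_mean
  if (is.null(names(mu))) {
    mu <- stats::setNames(rep_len(mu, length(schema$sections)), schema$sections)
  }
  missing_sec <- setdiff(schema$sections, names(mu))
  if (length(missing_sec)) {
    mu[missing_sec] <- mean(mu)
  }
  structure(
    list(n_patients = as.integer(n_patients),
         span_days = as.integer(span_days),
         schema = schema,
         relapse_spec = relapse_spec,
         baseline_response_mean = mu[schema$sections],
         baseline_response_sd = baseline_response_sd,
         question_noise_sd = question_noise_sd,
         relapse_sd_inflation = relapse_sd_inflation,
         relapse_mean_shift = relapse_mean_shift,
         missing_rate = missing_rate,
         window_days = as.integer(window_days),
         start_date = as.Date(start_date),
         gps = gps,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

synth_seed <- function(config, patient_index, stream) {
  offset <- match(stream, c("relapse", "survey", "gps"))
  (as.integer(config$seed) %% 65536L) * 30011L +
    as.integer(patient_index) * 17L + offset * 5L
}

patient_relapses <- function(config, patient_index) {
  if (!is.null(config$relapse_spec)) {
    spec <- config$relapse_spec
    days <- spec[[(patient_index - 1L) %% length(spec) + 1L]]
  } else {
    lo <- min(90L, max(2L, config$span_days %/% 2L))
    hi <- max(lo, config$span_days - 14L)
    days <- withr::with_seed(synth_seed(config, patient_index, "relapse"),
                             sample(lo:hi, 1))
  }
  days <- sort(unique(as.integer(days)))
  if (length(days) && (min(days) < 1 || max(days) > config$span_days)) {
    stop("relapse day offset outside study span", call. = FALSE)
  }
  config$start_date + days - 1L
}

#' Generate one synthetic patient
#'
#' @param config A [synth_config()].
#' @param patient_index 1-based patient index; the patient id is
#'   `P<index>`.
#' @return List with `survey` (long tibble with MCAR-deleted rows dropped),
#'   `gps` (ping tibble), `relapse_dates` (Date vector), `patient_id`.
#' @export
generate_patient <- function(config, patient_index) {
  stopifnot(inherits(config, "synth_config"))
  pid <- sprintf("P%02d", patient_index)
  schema <- config$schema
  days <- config$start_date + seq_len(config$span_days) - 1L
  relapse_dates <- patient_relapses(config, patient_index)
  in_window <- rep(FALSE, length(days))
  for (r in relapse_dates) {
    in_window <- in_window | (days >= r - config$window_days & days < r)
  }

  survey <- withr::with_seed(synth_seed(config, patient_index, "survey"), {
    secs <- lapply(schema$sections, function(sec) {
      qs <- schema$questions[[sec]]
      sd_day <- ifelse(in_window,
                       config$baseline_response_sd * config$relapse_sd_inflation,
                       config$baseline_response_sd)
      mu_day <- config$baseline_response_mean[[sec]] +
        ifelse(in_window, config$relapse_mean_shift, 0)
      a <- stats::rnorm(length(days), 0, 1) * sd_day
      latent <- outer(mu_day + a, rep(1, length(qs))) +
        matrix(stats::rnorm(length(days) * length(qs), 0,
                            config$question_noise_sd),
               nrow = length(days))
      resp <- matrix(NA_integer_, nrow = length(days), ncol = length(qs))
      for (j in seq_along(qs)) {
        resp[, j] <- round_to_levels(latent[, j], schema$levels[[qs[j]]])
      }
      tibble::tibble(
        patient_id = pid,
        date = rep(days, times = length(qs)),
        section = sec,
        question_id = rep(qs, each = length(days)),
        response = as.integer(resp)
      )
    })
    tab <- dplyr::bind_rows(secs)
    if (config$missing_rate > 0) {
      keep <- stats::runif(nrow(tab)) >= config$missing_rate
      tab <- tab[keep, , drop = FALSE]
    }
    dplyr::arrange(tab, .data$date, .data$section, .data$question_id)
  })

  gps <- withr::with_seed(synth_seed(config, patient_index, "gps"), {
    g <- config$gps
    # other locations on a fixed ring ~2-4 km from home
    angle <- 2 * pi * seq_len(g$n_other_locations) / max(1, g$n_other_locations)
    dist_m <- 2000 + 600 * seq_len(g$n_other_locations)
    deg_lat <- dist_m * cos(angle) / 111320
    deg_lon <- dist_m * sin(angle) /
      (111320 * cos(g$home_lat * pi / 180))
    other <- cbind(lat = g$home_lat + deg_lat, lon = g$home_lon + deg_lon)
    n_day <- g$pings_per_day
    step <- 24 * 3600 / n_day
    rows <- vector("list", length(days))
    for (i in seq_along(days)) {
      p_home <- if (in_window[i]) g$home_ping_prob_prerelapse else
        g$home_ping_prob_control
      at_home <- stats::runif(n_day) < p_home
      which_other <- if (g$n_other_locations > 0) {
        sample.int(g$n_other_locations, n_day, replace = TRUE)
      } else rep(1L, n_day)
      lat <- ifelse(at_home, g$home_lat, other[which_other, "lat"])
      lon <- ifelse(at_home, g$home_lon, other[which_other, "lon"])
      jit_lat <- stats::rnorm(n_day, 0, g$jitter_sd_m / 111320)
      jit_lon <- stats::rnorm(n_day, 0, g$jitter_sd_m /
                                (111320 * cos(g$home_lat * pi / 180)))
      ts <- as.POSIXct(paste(days[i], "00:00:00"), tz = "UTC") +
        (seq_len(n_day) - 1) * step + stats::runif(n_day, 0, step / 4)
      rows[[i]] <- tibble::tibble(
        patient_id = pid, timestamp = ts,
        latitude = lat + jit_lat, longitude = lon + jit_lon
      )
    }
    dplyr::arrange(dplyr::bind_rows(rows), .data$timestamp)
  })

  list(patient_id = pid, survey = survey, gps = gps,
       relapse_dates = relapse_dates)
}

#' Generate and write a synthetic cohort to disk
#'
#' Writes, per patient, `survey_<id>.csv`, `gps_<id>.csv` and
#' `relapse_<id>.json`, plus `schema.json` and a `manifest.json` recording
#' the generator parameters, seed and file listing. Byte-identical for a
#' given configuration and seed.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if absent).
#' @return The manifest as a list, invisibly.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (config$n_patients == 0) {
    warning("generating an empty cohort (n_patients = 0)", call. = FALSE)
  }
  patients <- list()
  for (i in seq_len(config$n_patients)) {
    p <- generate_patient(config, i)
    write_survey(p$survey, file.path(out_dir, paste0("survey_", p$patient_id, ".csv")))
    write_gps(p$gps, file.path(out_dir, paste0("gps_", p$patient_id, ".csv")))
    write_relapse(stats::setNames(list(p$relapse_dates), p$patient_id),
                  file.path(out_dir, paste0("relapse_", p$patient_id, ".json")))
    patients[[i]] <- list(
      patient_id = p$patient_id,
      survey = paste0("survey_", p$patient_id, ".csv"),
      gps = paste0("gps_", p$patient_id, ".csv"),
      relapse = paste0("relapse_", p$patient_id, ".json"),
      n_relapses = length(p$relapse_dates)
    )
  }
  write_schema(config$schema, file.path(out_dir, "schema.json"))
  manifest <- list(
    generator = "phenovis::generate_cohort",
    seed = config$seed,
    n_patients = config$n_patients,
    span_days = config$span_days,
    start_date = format(config$start_date, "%Y-%m-%d"),
    missing_rate = config$missing_rate,
    relapse_sd_inflation = config$relapse_sd_inflation,
    relapse_mean_shift = config$relapse_mean_shift,
    window_days = config$window_days,
    gps = config$gps,
    schema_file = "schema.json",
    patients = patients
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
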