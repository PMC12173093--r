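#' Imputation configuration
#'
#' @param method `"locf"` (last observation carried forward) or `"mice"`
#'   (chained-equations imputation).
#' @param mice_iterations Number of chained-equation sweeps over the
#'   variables (>= 1).
#' @param mice_chains Number of independent chains; when > 1 the completed
#'   chains are averaged cell-wise and re-rounded to legal levels.
#' @param seed Integer seed making the stochastic draws reproducible.
#' @param leading_missing_policy For LOCF, how to treat dates before the
#'   first observation of a question: `"backfill_first"` copies the first
#'   observed value backwards; `"drop_date"` drops grid dates that precede
#'   the first observation of any question in the section.
#' @return A list of class `imputation_config`.
#' @export
imputation_config <- function(method = c("locf", "mice"),
                              mice_iterations = 5L,
                              mice_chains = 1L,
                              seed = 0L,
                              leading_missing_policy = c("backfill_first", "drop_date")) {
  method <- match.arg(method)
  leading_missing_policy <- match.arg(leading_missing_policy)
  stopifnot(mice_iterations >= 1, mice_chains >= 1)
  structure(
    list(method = method,
         mice_iterations = as.integer(mice_iterations),
         mice_chains = as.integer(mice_chains),
         seed = as.integer(seed),
         leading_missing_policy = leading_missing_policy),
    class = "imputation_config"
  )
}

# Daily date grid spanning a patient's observed survey dates.
patient_date_grid <- function(dates) {
  dates <- dates[!is.na(dates)]
  if (!length(dates)) return(as.Date(character()))
  seq(min(dates), max(dates), by = "day")
}

# Wide dates x questions matrix for one patient-section, expanded to the
# daily grid (unobserved days become all-NA rows).
section_wide <- function(table, schema, section, grid = NULL) {
  qs <- schema$questions[[section]]
  sub <- table[table$section == section, , drop = FALSE]
  if (is.null(grid)) grid <- patient_date_grid(table$date)
  m <- matrix(NA_integer_, nrow = length(grid), ncol = length(qs),
              dimnames = list(format(grid, "%Y-%m-%d"), qs))
  if (nrow(sub)) {
    i <- match(sub$date, grid)
    j <- match(sub$question_id, qs)
    ok <- !is.na(i) & !is.na(j)
    m[cbind(i[ok], j[ok])] <- sub$response[ok]
  }
  m
}

section_long <- function(m, patient_id, section) {
  grid <- as.Date(rownames(m))
  tibble::tibble(
    patient_id = patient_id,
    date = rep(grid, times = ncol(m)),
    section = section,
    question_id = rep(colnames(m), each = nrow(m)),
    response = as.integer(m)
  ) |>
    dplyr::arrange(.data$date, .data$question_id)
}

locf_fill <- function(x, backfill_first = TRUE) {
  obs <- which(!is.na(x))
  if (!length(obs)) return(x)
  idx <- cumsum(!is.na(x))
  out <- x
  pos <- idx > 0
  out[pos] <- x[obs][idx[pos]]
  if (backfill_first) out[!pos] <- x[obs[1]]
  out
}

#' Impute a survey table by last observation carried forward
#'
#' Per (patient, section, question), responses are laid on the daily grid
#' from the patient's first to last observed survey date and each missing
#' day takes the most recent earlier observation. Leading missing days are
#' handled per `config$leading_missing_policy`. Observed values are never
#' altered.
#'
#' @param table Survey tibble (see [read_survey()]); may contain `NA`
#'   responses and absent day rows.
#' @param schema A [survey_schema()].
#' @param config An [imputation_config()].
#' @return A complete survey tibble on the daily grid.
#' @export
impute_locf <- function(table, schema, config = imputation_config("locf")) {
  out <- lapply(split(table, table$patient_id), function(pt) {
    grid <- patient_date_grid(pt$date)
    secs <- lapply(schema$sections, function(sec) {
      m <- section_wide(pt, schema, sec, grid)
      n_obs <- colSums(!is.na(m))
      if (any(n_obs == 0)) {
        stop("no observations to carry forward for question(s) ",
             paste(colnames(m)[n_obs == 0], collapse = ", "),
             " of patient ", pt$patient_id[1], call. = FALSE)
      }
      if (config$leading_missing_policy == "drop_date") {
        first_obs <- max(apply(m, 2, function(x) which(!is.na(x))[1]))
        m <- m[seq(first_obs, nrow(m)), , drop = FALSE]
      }
      filled <- apply(m, 2, locf_fill,
                      backfill_first = config$leading_missing_policy == "backfill_first")
      filled <- matrix(filled, ncol = ncol(m), dimnames = dimnames(m))
      section_long(filled, pt$patient_id[1], sec)
    })
    dplyr::bind_rows(secs)
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$patient_id, .data$date, .data$section, .data$question_id)
}

col_mode <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_integer_)
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])  # ties -> smallest level
}

round_to_levels <- function(x, levels) {
  levels[pmax(1L, pmin(length(levels), vapply(
    x, function(v) which.min(abs(levels - v)), integer(1))))]
}

# One chained-equations chain on a dates x questions integer matrix.
mice_chain <- function(m, levels_by_q, iterations) {
  miss <- is.na(m)
  work <- m * 1.0
  for (j in seq_len(ncol(m))) {
    if (any(miss[, j])) work[miss[, j], j] <- col_mode(m[, j])
  }
  fallback <- colSums(!miss) < 2
  for (it in seq_len(iterations)) {
    for (j in seq_len(ncol(m))) {
      if (!any(miss[, j]) || fallback[j]) next
      obs <- !miss[, j]
      x_other <- work[, -j, drop = FALSE]
      keep <- apply(x_other[obs, , drop = FALSE], 2,
                    function(v) stats::var(v) > 0)
      if (!any(keep)) next
      fit <- stats::lm.fit(cbind(1, x_other[obs, keep, drop = FALSE]),
                           work[obs, j])
      sigma <- sqrt(max(0, sum(fit$residuals^2) /
                          max(1, sum(obs) - length(fit$coefficients))))
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      pred <- drop(cbind(1, x_other[!obs, keep, drop = FALSE]) %*% beta)
      work[miss[, j], j] <- pred + stats::rnorm(sum(miss[, j]), 0, sigma)
    }
  }
  work
}

#' Impute a survey table by chained equations
#'
#' Per patient and section, the dates x questions matrix of ordinal
#' responses is completed by a chained-equations cycle: missing cells are
#' initialized with the column mode, then each variable in turn is regressed
#' (ordinary least squares on the integer level codes) on all other
#' questions in the section over the observed rows, and its missing cells
#' are redrawn as prediction plus a Gaussian residual draw. After
#' `mice_iterations` sweeps the imputed values are rounded to the nearest
#' legal level and clipped to the level range. Columns with fewer than 2
#' observed values fall back to mode fill with a warning. Observed cells are
#' never altered, and the whole procedure is deterministic given
#' `config$seed`.
#'
#' @inheritParams impute_locf
#' @return A complete survey tibble on the daily grid.
#' @export
impute_mice <- function(table, schema, config = imputation_config("mice")) {
  out <- lapply(split(table, table$patient_id), function(pt) {
    grid <- patient_date_grid(pt$date)
    secs <- lapply(schema$sections, function(sec) {
      m <- section_wide(pt, schema, sec, grid)
      n_obs <- colSums(!is.na(m))
      if (any(n_obs == 0)) {
        stop("no observed values for question(s) ",
             paste(colnames(m)[n_obs == 0], collapse = ", "),
             " of patient ", pt$patient_id[1], call. = FALSE)
      }
      if (any(n_obs < 2)) {
        warning("question(s) ", paste(colnames(m)[n_obs < 2], collapse = ", "),
                " have < 2 observed values; falling back to mode fill",
                call. = FALSE)
      }
      if (!anyNA(m)) return(section_long(m, pt$patient_id[1], sec))
      seed <- section_seed(config$seed, pt$patient_id[1], sec)
      completed <- withr::with_seed(seed, {
        chains <- lapply(seq_len(config$mice_chains), function(chain) {
          mice_chain(m, schema$levels[colnames(m)], config$mice_iterations)
        })
        Reduce(`+`, chains) / length(chains)
      })
      final <- m
      for (j in seq_len(ncol(m))) {
        fill <- is.na(m[, j])
        final[fill, j] <- round_to_levels(completed[fill, j],
                                          schema$levels[[colnames(m)[j]]])
      }
      section_long(final, pt$patient_id[1], sec)
    })
    dplyr::bind_rows(secs)
  })
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$patient_id, .data$date, .data$section, .data$question_id)
}

# Stable small-integer seed for a (seed, patient, section) stream.
section_seed <- function(seed, patient_id, section) {
  h <- sum(utf8ToInt(paste(patient_id, section, sep = "/")) *
             seq_along(utf8ToInt(paste(patient_id, section, sep = "/"))))
  (as.integer(seed) %% 100000L) * 19777L + (h %% 19763L)
}

#' Impute a survey table with the configured method
#'
#' Thin dispatcher over [impute_locf()] and [impute_mice()].
#'
#' @inheritParams impute_locf
#' @return A complete survey tibble.
#' @export
impute_survey <- function(table, schema, config = imputation_config()) {
  switch(config$method,
         locf = impute_locf(table, schema, config),
         mice = impute_mice(table, schema, config))
}
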