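#' Define control and pre-relapse analysis windows
#'
#' For each relapse date r the relapse window is the 30 days leading to it,
#' `[r - window_days, r)`. The control window is the earliest
#' `window_days`-day span of the study that does not overlap any relapse
#' window (overridable via `control_start`). Windows are truncated at the
#' study span edges, with a warning when a relapse falls within
#' `window_days` of the study start.
#'
#' @param relapse_dates Date vector (possibly empty) of relapse dates.
#' @param span Date vector of length 2: study start and end (inclusive).
#' @param window_days Window length in days (default 30: a fixed-length
#'   "month", chosen for determinism over calendar months).
#' @param control_start Optional Date forcing the control window start.
#' @return Tibble with `label` ("control", "relapse-1", ...), `start`
#'   (inclusive), `end` (exclusive).
#' @export
define_windows <- function(relapse_dates, span, window_days = 30L,
                           control_start = NULL) {
  span <- as.Date(span)
  stopifnot(length(span) == 2, span[1] <= span[2])
  relapse_dates <- sort(as.Date(relapse_dates))
  if (length(relapse_dates) &&
      (min(relapse_dates) < span[1] || max(relapse_dates) > span[2])) {
    stop("relapse date outside study span", call. = FALSE)
  }
  rel <- NULL
  if (length(relapse_dates)) {
    starts <- pmax(relapse_dates - window_days, span[1])
    if (any(relapse_dates - window_days < span[1])) {
      warning("relapse window truncated at study start", call. = FALSE)
    }
    rel <- tibble::tibble(
      label = paste0("relapse-", seq_along(relapse_dates)),
      start = starts,
      end = relapse_dates
    )
  }
  overlaps <- function(s, e) {
    !is.null(rel) && any(s < rel$end & rel$start < e)
  }
  if (is.null(control_start)) {
    control_start <- span[1]
    while (overlaps(control_start, control_start + window_days) &&
           control_start <= span[2]) {
      control_start <- control_start + 1
    }
  } else {
    control_start <- as.Date(control_start)
  }
  ctrl <- tibble::tibble(
    label = "control",
    start = control_start,
    end = min(control_start + window_days, span[2] + 1)
  )
  dplyr::bind_rows(ctrl, rel)
}

#' Summarize MCA trends within analysis windows
#'
#' Per (section, window): the number of trend dates inside the window, the
#' arithmetic mean and the sample standard deviation (ddof = 1; reported as
#' 0 when n = 1, missing when n = 0) of the first-component trend values.
#' This is the per-window quantitative summary backing the relapse
#' comparison tables.
#'
#' @param trends Named list section -> tibble(`date`, `score`) from
#'   [mca_trend()].
#' @param windows Window tibble from [define_windows()].
#' @return Tidy tibble `section`, `window`, `n`, `mean`, `sd`.
#' @export
summarize_windows <- function(trends, windows) {
  rows <- list()
  for (sec in names(trends)) {
    tr <- trends[[sec]]
    for (i in seq_len(nrow(windows))) {
      inside <- tr$date >= windows$start[i] & tr$date < windows$end[i]
      v <- tr$score[inside]
      n <- length(v)
      rows[[length(rows) + 1]] <- tibble::tibble(
        section = sec,
        window = windows$label[i],
        n = n,
        mean = if (n > 0) mean(v) else NA_real_,
        sd = if (n > 1) stats::sd(v) else if (n == 1) 0 else NA_real_
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Flag relapse windows with anomalously variable trends
#'
#' A section is flagged for a relapse window when the ratio of its trend SD
#' in that window to the control-window SD reaches `ratio_threshold`. The
#' control SD is floored at `eps` so that a flat control trend (SD 0) with
#' any relapse-window variability flags. Missing summaries propagate as
#' unflagged with a reason.
#'
#' @param summary Tibble from [summarize_windows()].
#' @param ratio_threshold SD ratio at or above which a window flags
#'   (default 2).
#' @param eps Floor for the control SD.
#' @return Tibble `section`, `window`, `sd_ratio`, `flagged`, `reason`.
#' @export
flag_anomalous_windows <- function(summary, ratio_threshold = 2, eps = 1e-6) {
  ctrl <- summary[summary$window == "control", c("section", "sd")]
  names(ctrl)[2] <- "control_sd"
  rel <- summary[summary$window != "control", , drop = FALSE]
  out <- dplyr::left_join(rel, ctrl, by = "section")
  ratio <- out$sd / pmax(out$control_sd, eps)
  flagged <- !is.na(ratio) & ratio >= ratio_threshold
  reason <- rep(NA_character_, nrow(out))
  reason[is.na(out$sd)] <- "relapse-window summary missing"
  reason[is.na(out$control_sd)] <- "control summary missing"
  tibble::tibble(
    section = out$section,
    window = out$window,
    sd_ratio = ratio,
    flagged = flagged,
    reason = reason
  )
}
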