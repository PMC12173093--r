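#' Panel specification for the comparative report
#'
#' Bundles one renderable feature with its precomputed analysis results and
#' the parameters that produced them. Rendering is pure presentation: no
#' analysis numbers are computed at render time, and every report records
#' the parameters needed to regenerate it.
#'
#' @param feature One of `"mca_trend"`, `"eigengap"`, `"coassociation"`,
#'   `"home_time"`, `"location_pies"`.
#' @param patient_id Patient identifier shown in captions.
#' @param results Feature-specific precomputed data: a trend tibble or
#'   named list of trend tibbles (`mca_trend`); a tibble
#'   `section,first,second` or named list of `mca_result`s (`eigengap`); a
#'   dates x dates matrix (`coassociation`); a [daily_summaries()] tibble
#'   (`home_time`, `location_pies`). `NULL` renders a placeholder panel.
#' @param params Named list of provenance parameters (imputation method,
#'   vector kind, seeds, ...), recorded verbatim in the report.
#' @param relapse_dates Date vector marked on date-indexed charts.
#' @return List of class `panel_spec`.
#' @export
panel_spec <- function(feature = c("mca_trend", "eigengap", "coassociation",
                                   "home_time", "location_pies"),
                       patient_id, results = NULL, params = list(),
                       relapse_dates = as.Date(character())) {
  feature <- match.arg(feature)
  structure(list(feature = feature, patient_id = patient_id,
                 results = results, params = params,
                 relapse_dates = as.Date(relapse_dates)),
            class = "panel_spec")
}

placeholder_panel <- function(caption) {
  ggplot2::ggplot() +
    ggplot2::annotate("text", x = 0, y = 0, label = caption, size = 4) +
    ggplot2::theme_void()
}

#' Render one panel to a ggplot object
#'
#' Dispatches on the panel's feature: per-section trend lines with relapse
#' markers; per-section first/second eigengap bars; a date x date
#' coassociation heatmap with a marker at 30 days before each relapse; a
#' calendar grid colored by daily home-time percentage; or a calendar of
#' pie glyphs of daily dwell fractions. Blank calendar cells correspond to
#' days without data. Empty results yield an explanatory placeholder.
#'
#' @param spec A [panel_spec()].
#' @return A ggplot object.
#' @export
render_chart <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  if (is.null(spec$results) ||
      (is.data.frame(spec$results) && nrow(spec$results) == 0) ||
      (is.list(spec$results) && !is.data.frame(spec$results) &&
       length(spec$results) == 0)) {
    return(placeholder_panel(paste0("no data for ", spec$feature,
                                    " (patient ", spec$patient_id, ")")))
  }
  switch(spec$feature,
    mca_trend = plot_mca_trend(spec$results, spec$relapse_dates),
    eigengap = plot_eigengaps(spec$results),
    coassociation = plot_coassociation(spec$results, spec$relapse_dates),
    home_time = plot_home_calendar(spec$results),
    location_pies = plot_location_pies(spec$results)
  )
}

#' Trend line chart of first MCA components
#' @param trends Tibble `date,score` or a named list of such tibbles (one
#'   facet per section).
#' @param relapse_dates Dates marked with vertical dashed lines.
#' @return ggplot object.
#' @export
plot_mca_trend <- function(trends, relapse_dates = as.Date(character())) {
  if (is.data.frame(trends)) trends <- list(section = trends)
  df <- dplyr::bind_rows(trends, .id = "section")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$score)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::facet_wrap(~section, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "MCA component 1") +
    ggplot2::theme_minimal()
  if (length(relapse_dates)) {
    p <- p + ggplot2::geom_vline(xintercept = as.numeric(relapse_dates),
                                 linetype = "dashed", color = "#b2182b")
  }
  p
}

#' Bar chart of first/second eigengaps per section
#' @param results Named list of `mca_result`s or tibble
#'   `section,first,second`.
#' @return ggplot object.
#' @export
plot_eigengaps <- function(results) {
  if (!is.data.frame(results)) {
    results <- dplyr::bind_rows(lapply(names(results), function(sec) {
      g <- eigengaps(results[[sec]])
      tibble::tibble(section = sec, first = g$first, second = g$second)
    }))
  }
  df <- tidyr::pivot_longer(results, c("first", "second"),
                            names_to = "gap", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$section, y = .data$value,
                                   fill = .data$gap)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(first = "#2166ac", second = "#92c5de")) +
    ggplot2::labs(x = NULL, y = "eigengap (inertia proportion)") +
    ggplot2::theme_minimal()
}

#' Heatmap of a coassociation matrix
#' @param matrix Dates x dates matrix in `[0, 1]`.
#' @param relapse_dates For each relapse, a dotted marker is drawn at 30
#'   days before it.
#' @return ggplot object.
#' @export
plot_coassociation <- function(matrix, relapse_dates = as.Date(character())) {
  dates <- as.Date(rownames(matrix))
  df <- expand.grid(i = dates, j = dates)
  df$value <- as.vector(matrix[])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac",
                                 limits = c(0, 1), name = "coassoc.") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (length(relapse_dates)) {
    marks <- as.numeric(relapse_dates - 30)
    p <- p +
      ggplot2::geom_vline(xintercept = marks, linetype = "dotted") +
      ggplot2::geom_hline(yintercept = marks, linetype = "dotted")
  }
  p
}

calendar_frame <- function(dates, week_start = c("monday", "sunday")) {
  week_start <- match.arg(week_start)
  wd <- as.integer(format(dates, "%u"))  # 1 = Monday
  if (week_start == "sunday") wd <- wd %% 7L + 1L
  first <- min(dates)
  week <- as.integer((as.numeric(dates - first) + as.integer(format(first, "%u")) - 1) %/% 7)
  tibble::tibble(date = dates, weekday = wd, week = week,
                 month = format(dates, "%Y-%m"))
}

#' Calendar heatmap of daily home time
#'
#' One tile per day, colored on a single-hue sequential gradient from 0 to
#' 100 percent home time; days without pings are blank (grey) cells.
#'
#' @param summaries Tibble from [daily_summaries()].
#' @param week_start First day of the calendar week.
#' @return ggplot object.
#' @export
plot_home_calendar <- function(summaries, week_start = "monday") {
  cal <- calendar_frame(summaries$date, week_start)
  df <- dplyr::bind_cols(cal, summaries["home_time_pct"])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$weekday, y = -.data$week,
                                   fill = .data$home_time_pct)) +
    ggplot2::geom_tile(color = "white", linewidth = 0.4) +
    ggplot2::scale_fill_gradient(low = "#f7fbff", high = "#08306b",
                                 limits = c(0, 100), na.value = "grey85",
                                 name = "home time %") +
    ggplot2::facet_wrap(~month, scales = "free_y") +
    ggplot2::scale_x_continuous(breaks = 1:7) +
    ggplot2::labs(x = "weekday", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

pie_wedges <- function(fracs, cx, cy, r = 0.42, n_arc = 24) {
  start <- pi / 2  # 12 o'clock, clockwise
  out <- list()
  for (nm in names(fracs)) {
    f <- fracs[[nm]]
    if (is.na(f) || f <= 0) next
    end <- start - 2 * pi * f
    theta <- seq(start, end, length.out = max(2, ceiling(n_arc * f)))
    out[[nm]] <- tibble::tibble(
      x = c(cx, cx + r * cos(theta)),
      y = c(cy, cy + r * sin(theta)),
      slice = nm
    )
    start <- end
  }
  dplyr::bind_rows(out, .id = "id")
}

#' Calendar of pie glyphs of daily dwell fractions
#'
#' One pie per day whose sectors are the dwell fractions over significant
#' locations (plus "other"); a fraction f spans 360 x f degrees. Days
#' without pings are blank.
#'
#' @inheritParams plot_home_calendar
#' @return ggplot object.
#' @export
plot_location_pies <- function(summaries, week_start = "monday") {
  cal <- calendar_frame(summaries$date, week_start)
  frac_cols <- grep("^frac_", names(summaries), value = TRUE)
  wedges <- list()
  for (i in seq_len(nrow(summaries))) {
    f <- unlist(summaries[i, frac_cols])
    names(f) <- sub("^frac_", "", frac_cols)
    if (all(is.na(f))) next
    w <- pie_wedges(as.list(f), cx = cal$weekday[i], cy = -cal$week[i])
    w$day <- format(summaries$date[i], "%Y-%m-%d")
    w$month <- cal$month[i]
    wedges[[length(wedges) + 1]] <- w
  }
  if (!length(wedges)) {
    return(placeholder_panel("no days with location data"))
  }
  df <- dplyr::bind_rows(wedges)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = interaction(.data$day, .data$slice),
                                   fill = .data$slice)) +
    ggplot2::geom_polygon(color = "white", linewidth = 0.1) +
    ggplot2::facet_wrap(~month, scales = "free_y") +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "location") +
    ggplot2::labs(x = "weekday", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

panel_data_json <- function(spec) {
  res <- spec$results
  payload <- if (is.null(res)) {
    NULL
  } else if (is.matrix(res)) {
    list(labels = rownames(res), values = apply(unclass(res), 1, as.numeric,
                                                simplify = FALSE))
  } else if (is.data.frame(res)) {
    res
  } else {
    lapply(res, function(x) if (is.data.frame(x)) x else NULL)
  }
  jsonlite::toJSON(list(feature = spec$feature, patient_id = spec$patient_id,
                        params = spec$params,
                        relapse_dates = format(spec$relapse_dates, "%Y-%m-%d"),
                        data = payload),
                   dataframe = "columns", auto_unbox = TRUE, digits = NA,
                   null = "null")
}

png_base64 <- function(plot, width = 640, height = 480) {
  tmp <- tempfile(fileext = ".png")
  on.exit(unlink(tmp), add = TRUE)
  grDevices::png(tmp, width = width, height = height, res = 96)
  print(plot)
  grDevices::dev.off()
  jsonlite::base64_enc(readBin(tmp, "raw", file.info(tmp)$size))
}

#' Render a two-panel comparative report to self-contained HTML
#'
#' The side-by-side layout supports the comparative reading the portal is
#' designed around: the same patient under two parameterizations (e.g. MCA
#' trend with LOCF vs chained-equations imputation) or two patients under
#' the same feature. Each panel embeds its chart as an inline PNG, a
#' caption with the full parameter provenance, and its source data as a
#' JSON block, so any report can be audited and regenerated.
#'
#' @param left,right [panel_spec()] objects.
#' @param out_path Output .html path.
#' @param title Report title.
#' @return `out_path`, invisibly.
#' @export
render_report <- function(left, right, out_path, title = "comparative report") {
  panels <- lapply(list(left = left, right = right), function(spec) {
    plot <- render_chart(spec)
    caption <- paste0(
      "patient ", spec$patient_id, " | feature ", spec$feature,
      if (length(spec$params)) paste0(" | ", paste(names(spec$params),
                                                   unlist(spec$params),
                                                   sep = "=", collapse = " ")),
      if (length(spec$relapse_dates))
        paste0(" | relapse: ", paste(format(spec$relapse_dates, "%Y-%m-%d"),
                                     collapse = ", "))
    )
    list(img = png_base64(plot), caption = caption, data = panel_data_json(spec))
  })
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset='utf-8'>",
    paste0("<title>", title, "</title>"),
    "<style>body{font-family:sans-serif} .row{display:flex}",
    ".panel{flex:1;margin:8px;border:1px solid #ccc;padding:8px}",
    ".caption{font-size:12px;color:#333}</style></head><body>",
    paste0("<h2>", title, "</h2>"),
    "<div class='row'>",
    unlist(lapply(names(panels), function(side) {
      p <- panels[[side]]
      c(paste0("<div class='panel' id='panel-", side, "'>"),
        paste0("<img alt='", side, " panel' src='data:image/png;base64,",
               p$img, "'/>"),
        paste0("<div class='caption'>", p$caption, "</div>"),
        paste0("<script type='application/json' id='panel-", side, "-data'>",
               p$data, "</script>"),
        "</div>")
    })),
    "</div></body></html>"
  )
  writeLines(html, out_path)
  invisible(out_path)
}
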