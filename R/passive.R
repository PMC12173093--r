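#' Derive significant locations from GPS pings
#'
#' Pings are projected onto a local planar frame (equirectangular about the
#' patient's median coordinate — adequate at city scale), clustered by
#' k-means, and each ping is weighted by its dwell time (gap to the next
#' ping, capped). Clusters contributing less than `min_dwell_frac` of total
#' dwell are merged into an implicit "other" bucket. Locations are ranked
#' by total dwell; rank 1 is "home". Dwell ties are broken by the earliest
#' first visit. Deterministic given `seed`.
#'
#' @param gps GPS tibble for one patient (see [read_gps()]).
#' @param max_locations Upper bound on the number of significant locations.
#' @param radius_m Assignment radius in meters: pings farther than this from
#'   every centroid count as "other" in daily summaries.
#' @param min_dwell_frac Minimum share of total dwell for a cluster to be
#'   kept as a significant location.
#' @param max_gap_min Cap (minutes) on the per-ping dwell weight.
#' @param seed Integer seed for k-means.
#' @return Object of class `significant_locations`: tibble `locations`
#'   (id, latitude, longitude, dwell_minutes, rank, first_visit), `home_id`,
#'   and the projection reference used.
#' @export
find_significant_locations <- function(gps, max_locations = 6L, radius_m = 200,
                                       min_dwell_frac = 0.01,
                                       max_gap_min = 60, seed = 0L) {
  if (nrow(gps) == 0) stop("empty GPS table", call. = FALSE)
  stopifnot(length(unique(gps$patient_id)) == 1)
  gps <- dplyr::arrange(gps, .data$timestamp)
  ref <- c(lat = stats::median(gps$latitude), lon = stats::median(gps$longitude))
  xy <- project_xy(gps$latitude, gps$longitude, ref)
  w <- dwell_weights(gps$timestamp, max_gap_min)
  # heuristic for distinct places: grid cells of ~radius size with any ping
  cell <- paste(round(xy[, 1] / radius_m), round(xy[, 2] / radius_m))
  k <- min(max_locations, length(unique(cell)))
  if (k == 1) {
    assign <- rep(1L, nrow(gps))
  } else {
    assign <- withr::with_seed(seed, {
      uniq <- unique(xy)
      if (nrow(uniq) <= k) {
        key <- paste(xy[, 1], xy[, 2])
        key_u <- paste(uniq[, 1], uniq[, 2])
        match(key, key_u)
      } else {
        stats::kmeans(xy, centers = k, nstart = 5, iter.max = 50)$cluster
      }
    })
  }
  # k-means can split one dwell cloud across clusters; merge clusters whose
  # centroids sit within the assignment radius of each other
  cent <- vapply(sort(unique(assign)), function(cl) {
    c(sum(xy[assign == cl, 1] * w[assign == cl]),
      sum(xy[assign == cl, 2] * w[assign == cl])) / sum(w[assign == cl])
  }, numeric(2))
  if (ncol(cent) > 1) {
    merge_lab <- stats::cutree(
      stats::hclust(stats::dist(t(cent)), method = "single"), h = radius_m)
    assign <- merge_lab[match(assign, sort(unique(assign)))]
  }
  total_dwell <- sum(w)
  info <- tibble::tibble(cluster = assign, w = w,
                         lat = gps$latitude, lon = gps$longitude,
                         ts = gps$timestamp) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      latitude = sum(.data$lat * .data$w) / sum(.data$w),
      longitude = sum(.data$lon * .data$w) / sum(.data$w),
      dwell_minutes = sum(.data$w),
      first_visit = min(.data$ts),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$dwell_minutes >= min_dwell_frac * total_dwell)
  info <- info |>
    dplyr::arrange(dplyr::desc(.data$dwell_minutes), .data$first_visit) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  id = paste0("loc", .data$rank)) |>
    dplyr::select("id", "latitude", "longitude", "dwell_minutes", "rank",
                  "first_visit")
  structure(
    list(locations = info, home_id = info$id[1], projection_ref = ref,
         radius_m = radius_m, max_gap_min = max_gap_min),
    class = "significant_locations"
  )
}

#' @export
print.significant_locations <- function(x, ...) {
  cat("<significant_locations> ", nrow(x$locations), " location(s); home = ",
      x$home_id, "\n", sep = "")
  print(x$locations)
  invisible(x)
}

# Equirectangular local projection (meters) about a reference coordinate.
project_xy <- function(lat, lon, ref) {
  R <- 6371000
  cbind(
    x = (lon - ref[["lon"]]) * pi / 180 * R * cos(ref[["lat"]] * pi / 180),
    y = (lat - ref[["lat"]]) * pi / 180 * R
  )
}

# Per-ping dwell weight in minutes: gap to next ping, capped. The final
# ping's dwell is right-censored; it takes its preceding gap (capped),
# which keeps fractions invariant under uniform ping-rate changes.
dwell_weights <- function(timestamps, max_gap_min) {
  n <- length(timestamps)
  if (n == 1) return(max_gap_min)
  gaps <- as.numeric(diff(timestamps), units = "mins")
  pmin(c(gaps, gaps[n - 1]), max_gap_min)
}

#' Daily home-time and dwell-fraction summaries
#'
#' Each ping is assigned to its nearest significant location if within the
#' assignment radius, else to "other"; dwell is the capped gap to the next
#' ping. Pings are bucketed into local calendar days and per-day dwell
#' fractions are computed; `home_time_pct` is 100 x the home fraction. Days
#' in the span without pings are emitted with `ping_count` 0 and missing
#' fractions (rendered as blank calendar cells).
#'
#' @param gps GPS tibble for one patient.
#' @param locations A `significant_locations` fit on the same patient.
#' @param tz Timezone for local-day bucketing.
#' @param span Optional Date vector of length 2 delimiting the emitted days;
#'   defaults to the observed ping date range.
#' @return Tibble with `date`, `ping_count`, `home_time_pct`, and one
#'   `frac_<id>` column per significant location plus `frac_other`.
#' @export
daily_summaries <- function(gps, locations, tz = "UTC", span = NULL) {
  stopifnot(inherits(locations, "significant_locations"))
  loc <- locations$locations
  if (nrow(gps) > 0) {
    gps <- dplyr::arrange(gps, .data$timestamp)
    xy <- project_xy(gps$latitude, gps$longitude, locations$projection_ref)
    cxy <- project_xy(loc$latitude, loc$longitude, locations$projection_ref)
    d2 <- outer(xy[, 1], cxy[, 1], "-")^2 + outer(xy[, 2], cxy[, 2], "-")^2
    nearest <- max.col(-d2, ties.method = "first")
    within <- sqrt(d2[cbind(seq_len(nrow(gps)), nearest)]) <= locations$radius_m
    assigned <- ifelse(within, loc$id[nearest], "other")
    w <- dwell_weights(gps$timestamp, locations$max_gap_min)
    day <- as.Date(format(gps$timestamp, "%Y-%m-%d", tz = tz))
  } else {
    assigned <- character(0); w <- numeric(0); day <- as.Date(character(0))
  }
  if (is.null(span)) {
    if (!length(day)) stop("empty GPS table and no span given", call. = FALSE)
    span <- range(day)
  }
  all_days <- seq(span[1], span[2], by = "day")
  ids <- c(loc$id, "other")
  out <- tibble::tibble(date = all_days,
                        ping_count = 0L,
                        home_time_pct = NA_real_)
  fracs <- matrix(NA_real_, nrow = length(all_days), ncol = length(ids),
                  dimnames = list(NULL, paste0("frac_", ids)))
  if (length(day)) {
    for (i in seq_along(all_days)) {
      sel <- day == all_days[i]
      if (!any(sel)) next
      out$ping_count[i] <- sum(sel)
      tot <- sum(w[sel])
      f <- vapply(ids, function(id) sum(w[sel][assigned[sel] == id]) / tot,
                  numeric(1))
      fracs[i, ] <- f
      out$home_time_pct[i] <- 100 * f[[locations$home_id]]
    }
  }
  dplyr::bind_cols(out, tibble::as_tibble(fracs))
}
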