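#' Per-date aggregate vectors (AV)
#'
#' One row per date; component s is the mean of that date's responses in
#' section s, sections in schema order. The AV is a coarse per-date summary
#' of mental state whose length equals the number of sections.
#'
#' @param complete_table Complete (imputed) survey tibble for one patient.
#' @param schema A [survey_schema()].
#' @param standardize Z-score each component across dates (constant
#'   components are left at 0). Off by default: components already share
#'   the ordinal scale.
#' @return Numeric matrix dates x sections, dates as rownames.
#' @export
make_av <- function(complete_table, schema, standardize = FALSE) {
  stopifnot(!anyNA(complete_table$response))
  dates <- sort(unique(complete_table$date))
  m <- matrix(NA_real_, nrow = length(dates), ncol = length(schema$sections),
              dimnames = list(format(dates, "%Y-%m-%d"), schema$sections))
  agg <- complete_table |>
    dplyr::group_by(.data$date, .data$section) |>
    dplyr::summarise(v = mean(.data$response), .groups = "drop")
  m[cbind(match(agg$date, dates), match(agg$section, schema$sections))] <- agg$v
  if (anyNA(m)) stop("some dates lack responses for some sections", call. = FALSE)
  if (standardize) m <- zscore_cols(m)
  m
}

zscore_cols <- function(m) {
  apply(m, 2, function(x) {
    s <- stats::sd(x)
    if (s > 0) (x - mean(x)) / s else rep(0, length(x))
  }) |> `dimnames<-`(dimnames(m))
}

#' Per-date complete vectors (CV)
#'
#' One row per date; the schema-ordered concatenation of all question
#' responses, so the length equals the total question count across sections.
#'
#' @inheritParams make_av
#' @return Numeric matrix dates x questions, dates as rownames.
#' @export
make_cv <- function(complete_table, schema, standardize = FALSE) {
  stopifnot(!anyNA(complete_table$response))
  dates <- sort(unique(complete_table$date))
  qs <- schema_questions(schema)
  m <- matrix(NA_real_, nrow = length(dates), ncol = length(qs),
              dimnames = list(format(dates, "%Y-%m-%d"), qs))
  m[cbind(match(complete_table$date, dates),
          match(complete_table$question_id, qs))] <- complete_table$response
  if (anyNA(m)) stop("some dates lack responses for some questions", call. = FALSE)
  if (standardize) m <- zscore_cols(m)
  m
}

new_partition <- function(labels, method, seed = NA_integer_, degenerate = FALSE) {
  structure(list(labels = labels, method = method, seed = seed,
                 degenerate = degenerate),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("<partition> ", length(unique(x$labels)), " cluster(s) over ",
      length(x$labels), " dates [", x$method, "]\n", sep = "")
  invisible(x)
}

#' Cluster dates with a user-supplied cluster count
#'
#' Predefined clustering: k is chosen from prior knowledge (e.g. "baseline
#' vs relapse month"). Euclidean distance on the raw date vectors.
#'
#' @param vectors Dates x features matrix ([make_av()] or [make_cv()]).
#' @param k Number of clusters, `2 <= k <= nrow(vectors)`.
#' @param method `"kmeans"` or `"agglomerative"` (Ward linkage).
#' @param seed Integer seed (k-means initialization).
#' @return A `partition`: named integer labels per date plus method/seed tags.
#' @export
cluster_predefined <- function(vectors, k, method = c("kmeans", "agglomerative"),
                               seed = 0L) {
  method <- match.arg(method)
  stopifnot(k >= 2)
  if (k > nrow(vectors)) {
    stop("k = ", k, " exceeds the number of dates (", nrow(vectors), ")",
         call. = FALSE)
  }
  labels <- if (method == "kmeans") {
    km_labels(vectors, k, seed)
  } else {
    stats::cutree(stats::hclust(stats::dist(vectors), method = "ward.D2"), k = k)
  }
  names(labels) <- rownames(vectors)
  new_partition(labels, paste0(method, "_k", k), seed)
}

# k-means robust to duplicate points: fall back to jittered-free restart on
# the distinct rows, then map back.
km_labels <- function(vectors, k, seed) {
  withr::with_seed(seed, {
    uniq <- unique(vectors)
    if (nrow(uniq) <= k) {
      lab_u <- seq_len(nrow(uniq))
    } else {
      lab_u <- stats::kmeans(uniq, centers = k, nstart = 5,
                             iter.max = 50)$cluster
    }
    key <- apply(vectors, 1, paste, collapse = "\r")
    key_u <- apply(uniq, 1, paste, collapse = "\r")
    unname(lab_u[match(key, key_u)])
  })
}

mean_silhouette <- function(vectors, labels) {
  if (length(unique(labels)) < 2) return(-1)
  sil <- cluster::silhouette(labels, stats::dist(vectors))
  mean(sil[, "sil_width"])
}

#' Cluster dates with a data-determined cluster count
#'
#' Natural clustering: k-means is run for every k in `2:k_max` and the k
#' maximizing the mean silhouette width is kept (ties broken toward the
#' smallest k, favouring parsimony). Identical vectors yield a degenerate
#' single-cluster partition.
#'
#' @inheritParams cluster_predefined
#' @param k_max Largest candidate k (capped at `nrow(vectors) - 1`).
#' @return A `partition` with attribute fields `method = "natural_k<k>"`.
#' @export
cluster_natural <- function(vectors, k_max = 6L, seed = 0L) {
  stopifnot(k_max >= 2)
  if (nrow(unique(vectors)) == 1) {
    labels <- stats::setNames(rep(1L, nrow(vectors)), rownames(vectors))
    return(new_partition(labels, "natural_degenerate", seed, degenerate = TRUE))
  }
  ks <- 2:min(k_max, nrow(vectors) - 1)
  fits <- lapply(seq_along(ks), function(i) {
    labels <- km_labels(vectors, ks[i], seed + i)
    list(k = ks[i], labels = labels,
         sil = mean_silhouette(vectors, labels))
  })
  sils <- vapply(fits, `[[`, numeric(1), "sil")
  best <- fits[[which.max(sils)]]  # which.max takes the first (smallest k) tie
  labels <- stats::setNames(best$labels, rownames(vectors))
  new_partition(labels, paste0("natural_k", best$k), seed)
}

#' Build an ensemble of date partitions
#'
#' Runs the configured clustering strategies over AV and/or CV date vectors
#' with several seeded restarts, yielding the list of partitions condensed
#' by [coassociation()]. Member seeds are derived deterministically from the
#' master seed, so the same configuration always reproduces the same
#' ensemble.
#'
#' @param vectors Named list with elements `AV` and/or `CV` (matrices).
#' @param kinds Subset of `c("AV", "CV")` to use.
#' @param strategies Subset of `c("predefined", "natural")`.
#' @param k_list Cluster counts for the predefined strategy.
#' @param methods Base algorithms for the predefined strategy.
#' @param k_max `k_max` for the natural strategy.
#' @param restarts Seeded restarts per method.
#' @param seed Master seed.
#' @return List of `partition` objects (length = methods x restarts).
#' @export
build_ensemble <- function(vectors,
                           kinds = c("AV", "CV"),
                           strategies = c("predefined", "natural"),
                           k_list = c(2L, 3L, 4L),
                           methods = c("kmeans", "agglomerative"),
                           k_max = 6L,
                           restarts = 5L,
                           seed = 0L) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  strategies <- match.arg(strategies, several.ok = TRUE)
  stopifnot(length(kinds) >= 1, length(strategies) >= 1, restarts >= 1)
  jobs <- list()
  for (kind in kinds) {
    v <- vectors[[kind]]
    if (is.null(v)) stop("vectors[['", kind, "']] missing", call. = FALSE)
    if ("predefined" %in% strategies) {
      for (m in methods) {
        for (k in k_list) {
          if (k <= nrow(v)) {
            jobs[[length(jobs) + 1]] <- list(kind = kind, fn = "predefined",
                                             method = m, k = k)
          }
        }
      }
    }
    if ("natural" %in% strategies) {
      jobs[[length(jobs) + 1]] <- list(kind = kind, fn = "natural")
    }
  }
  out <- list()
  idx <- 0L
  for (job in jobs) {
    for (r in seq_len(restarts)) {
      idx <- idx + 1L
      member_seed <- (as.integer(seed) %% 1000000L) * 1009L + idx
      p <- if (job$fn == "predefined") {
        cluster_predefined(vectors[[job$kind]], job$k, job$method, member_seed)
      } else {
        cluster_natural(vectors[[job$kind]], k_max, member_seed)
      }
      p$method <- paste0(job$kind, ":", p$method, ":r", r)
      out[[idx]] <- p
    }
  }
  out
}

#' Coassociation (consensus) matrix of a partition ensemble
#'
#' Entry (i, j) is the fraction of ensemble partitions placing dates i and j
#' in the same cluster: 1 means the pair always co-clusters, 0 never. The
#' matrix is symmetric with unit diagonal and entries that are multiples of
#' 1/E for an ensemble of E partitions; it is invariant to relabeling
#' clusters within any member partition.
#'
#' @param partitions List of `partition` objects over the same date set.
#' @return Dates x dates numeric matrix of class `coassociation`.
#' @export
coassociation <- function(partitions) {
  stopifnot(length(partitions) >= 1)
  n <- length(partitions[[1]]$labels)
  ref <- names(partitions[[1]]$labels)
  acc <- matrix(0, n, n, dimnames = list(ref, ref))
  for (p in partitions) {
    lab <- if (is.null(ref)) p$labels else p$labels[ref]
    if (length(lab) != n || anyNA(lab)) {
      stop("partitions cover different date sets", call. = FALSE)
    }
    acc <- acc + outer(lab, lab, "==")
  }
  m <- acc / length(partitions)
  class(m) <- c("coassociation", class(m))
  m
}

#' @export
print.coassociation <- function(x, ...) {
  cat("<coassociation> ", nrow(x), " dates; mean off-diagonal ",
      signif(mean(x[row(x) != col(x)]), 4), "\n", sep = "")
  invisible(x)
}
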