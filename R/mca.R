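#' Build the indicator matrix for one survey section
#'
#' Each date becomes a row; each (question, level) pair a 0/1 column in
#' schema order. Every question contributes exactly one indicated level per
#' date, so each row sums to the number of questions in the section. Levels
#' never used by any date are retained as all-zero columns so the column
#' layout depends only on the schema.
#'
#' @param section_table Complete (post-imputation) survey tibble restricted
#'   to one patient and one section.
#' @param schema A [survey_schema()].
#' @param section Section name; defaults to the single section present.
#' @return 0/1 matrix with dates as rownames and `question:level` colnames.
#'   The per-date mean raw response is attached as attribute
#'   `mean_response` (used downstream to fix component signs).
#' @export
build_indicator <- function(section_table, schema, section = NULL) {
  stopifnot(inherits(schema, "survey_schema"))
  if (is.null(section)) {
    section <- unique(section_table$section)
    stopifnot(length(section) == 1)
  }
  qs <- schema$questions[[section]]
  if (is.null(qs)) stop("unknown section: ", section, call. = FALSE)
  sub <- section_table[section_table$section == section, , drop = FALSE]
  if (anyNA(sub$response)) {
    stop("indicator matrix requires a complete table; run imputation first",
         call. = FALSE)
  }
  dates <- sort(unique(sub$date))
  cols <- unlist(lapply(qs, function(q) {
    paste0(q, ":", schema$levels[[q]])
  }), use.names = FALSE)
  Z <- matrix(0L, nrow = length(dates), ncol = length(cols),
              dimnames = list(format(dates, "%Y-%m-%d"), cols))
  i <- match(sub$date, dates)
  j <- match(paste0(sub$question_id, ":", sub$response), cols)
  if (anyNA(j)) {
    stop("response outside declared levels in section ", section, call. = FALSE)
  }
  Z[cbind(i, j)] <- 1L
  bad <- rowSums(Z) != length(qs)
  if (any(bad)) {
    stop(sum(bad), " date(s) with incomplete responses in section ", section,
         call. = FALSE)
  }
  attr(Z, "mean_response") <- vapply(split(sub$response, sub$date), mean,
                                     numeric(1))[format(dates, "%Y-%m-%d")]
  attr(Z, "n_questions") <- length(qs)
  Z
}

#' Fit multiple correspondence analysis on an indicator matrix
#'
#' Correspondence analysis of the 0/1 indicator matrix: with grand total N,
#' correspondence matrix P = Z/N, row and column masses r and c, the
#' standardized residual matrix S = Dr^(-1/2) (P - r c') Dc^(-1/2) is
#' decomposed by SVD; the principal inertias (eigenvalues) are the squared
#' singular values and the row principal coordinates are Dr^(-1/2) U Sigma.
#' Components are ordered by decreasing eigenvalue. The sign of each
#' component is fixed so that its correlation with the dates' mean raw
#' response is non-negative (ties resolved by making the leading loading
#' positive), removing the SVD sign indeterminacy.
#'
#' Zero-mass columns (levels never used) carry no inertia and are excluded
#' from the residual decomposition. If all rows are identical the section
#' has zero total inertia: all eigenvalues and scores are 0 and the result
#' is flagged `degenerate`.
#'
#' @param indicator Matrix from [build_indicator()] (or any non-negative
#'   matrix with constant row sums).
#' @param section Section label stored in the result.
#' @param benzecri Apply the Benzecri eigenvalue correction
#'   (`(Q/(Q-1))^2 (lambda - 1/Q)^2` for eigenvalues above `1/Q`, others
#'   dropped) before computing inertia proportions and eigengaps. Off by
#'   default; raw indicator-matrix inertias are reported.
#' @return An object of class `mca_result`: `section`, `dates`,
#'   `eigenvalues`, `inertia_proportions`, `row_scores` (dates x
#'   components), `first_eigengap`, `second_eigengap`, `degenerate`.
#' @export
fit_mca <- function(indicator, section = "section", benzecri = FALSE) {
  Z <- as.matrix(indicator)
  stopifnot(nrow(Z) >= 2)
  q <- unique(round(rowSums(Z), 10))
  if (length(q) != 1) stop("indicator row sums must be constant", call. = FALSE)
  dates <- rownames(Z)
  if (is.null(dates)) dates <- as.character(seq_len(nrow(Z)))
  n <- nrow(Z)
  N <- sum(Z)
  P <- Z / N
  r <- rowSums(P)
  cc <- colSums(P)
  keep <- cc > 0
  S <- (P[, keep, drop = FALSE] - tcrossprod(r, cc[keep])) /
    sqrt(tcrossprod(r, cc[keep]))
  max_comp <- max(1L, min(n, sum(keep)) - 1L)
  sv <- svd(S)
  lambda <- sv$d^2
  # numerical floor: components below machine-level inertia are noise
  lambda[lambda < 1e-12] <- 0
  ord <- order(lambda, decreasing = TRUE)
  lambda <- lambda[ord]
  U <- sv$u[, ord, drop = FALSE]
  d_ord <- sv$d[ord]
  ncomp <- min(max_comp, length(lambda))
  lambda <- lambda[seq_len(ncomp)]
  scores <- (U[, seq_len(ncomp), drop = FALSE] *
               rep(d_ord[seq_len(ncomp)], each = n)) / sqrt(r)
  scores[, lambda == 0] <- 0
  degenerate <- all(lambda == 0)
  plambda <- lambda
  if (benzecri && q > 1) {
    adj <- (q / (q - 1))^2 * pmax(lambda - 1 / q, 0)^2
    if (any(adj > 0)) plambda <- adj
  }
  total <- sum(plambda)
  props <- if (total > 0) plambda / total else rep(0, length(plambda))
  mean_resp <- attr(indicator, "mean_response")
  for (k in seq_len(ncol(scores))) {
    if (lambda[k] == 0) next
    flip <- 0
    if (!is.null(mean_resp) && stats::sd(mean_resp) > 0 &&
        stats::sd(scores[, k]) > 0) {
      flip <- sign(stats::cor(scores[, k], mean_resp))
    }
    if (flip == 0) flip <- sign(scores[which.max(abs(scores[, k])), k])
    if (flip < 0) scores[, k] <- -scores[, k]
  }
  dimnames(scores) <- list(dates, paste0("comp", seq_len(ncol(scores))))
  gaps <- eigengaps_from_proportions(props)
  structure(
    list(section = section,
         dates = as.Date(dates),
         eigenvalues = lambda,
         inertia_proportions = props,
         row_scores = scores,
         first_eigengap = gaps[[1]],
         second_eigengap = gaps[[2]],
         degenerate = degenerate),
    class = "mca_result"
  )
}

#' @export
print.mca_result <- function(x, ...) {
  cat("<mca_result> section '", x$section, "': ", length(x$dates), " dates, ",
      length(x$eigenvalues), " components",
      if (x$degenerate) " (degenerate: zero inertia)", "\n", sep = "")
  cat("  first eigengap ", signif(x$first_eigengap, 4),
      ", second eigengap ", signif(x$second_eigengap, 4), "\n", sep = "")
  invisible(x)
}

eigengaps_from_proportions <- function(props) {
  p <- c(props, 0, 0, 0)[1:3]
  list(first = p[1] - p[2], second = p[2] - p[3])
}

#' First and second eigengaps of an MCA fit
#'
#' Computed on inertia proportions (scale-free across sections with
#' different question counts): first = p1 - p2, second = p2 - p3, padding
#' with zero proportions when fewer than 3 components exist. A large first
#' eigengap indicates responses dominated by one consistent dimension; a
#' degenerate (zero-inertia) fit yields (0, 0).
#'
#' @param result An `mca_result`.
#' @return Named list `first`, `second`.
#' @export
eigengaps <- function(result) {
  stopifnot(inherits(result, "mca_result"))
  if (result$degenerate) return(list(first = 0, second = 0))
  eigengaps_from_proportions(result$inertia_proportions)
}

#' Date-indexed trend of the first MCA component
#'
#' The per-date score on the leading component under the fixed sign
#' convention; the daily series plotted in the survey-trend view.
#'
#' @param result An `mca_result`.
#' @return Tibble `date`, `score`.
#' @export
mca_trend <- function(result) {
  stopifnot(inherits(result, "mca_result"))
  tibble::tibble(date = result$dates, score = unname(result$row_scores[, 1]))
}

#' Fit per-section MCA trends for one patient
#'
#' Convenience wrapper: builds the indicator and fits the MCA for every
#' section of the schema on a complete (imputed) table.
#'
#' @param complete_table Complete survey tibble for one patient.
#' @param schema A [survey_schema()].
#' @return Named list section -> `mca_result`.
#' @export
fit_section_mcas <- function(complete_table, schema) {
  stopifnot(length(unique(complete_table$patient_id)) == 1)
  res <- lapply(schema$sections, function(sec) {
    fit_mca(build_indicator(complete_table, schema, sec), section = sec)
  })
  names(res) <- schema$sections
  res
}
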