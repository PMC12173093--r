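#' Read and validate a long-format survey table
#'
#' Expects a CSV with header columns `patient_id,date,section,question_id,
#' response` and ISO-8601 dates. Rows are validated against the schema:
#' unknown sections or question ids are rejected, as are responses outside a
#' question's declared levels. Duplicate (patient, date, section, question)
#' rows are collapsed keeping the last occurrence (mobile resubmission
#' semantics) with a warning. Missing responses (empty cells) are kept as
#' `NA` and filled later by [impute_survey()].
#'
#' @param path CSV file path.
#' @param schema A [survey_schema()].
#' @return A tibble with columns `patient_id` (character), `date` (Date),
#'   `section` (character), `question_id` (character), `response` (integer,
#'   `NA` allowed), sorted by (patient_id, date, section, question_id).
#' @export
read_survey <- function(path, schema) {
  stopifnot(inherits(schema, "survey_schema"))
  tab <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      date = readr::col_character(),
      section = readr::col_character(),
      question_id = readr::col_character(),
      response = readr::col_character()
    )
  )
  need <- c("patient_id", "date", "section", "question_id", "response")
  if (!all(need %in% names(tab))) {
    stop("survey CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  dates <- as.Date(tab$date, format = "%Y-%m-%d")
  bad_date <- which(is.na(dates) & !is.na(tab$date))
  if (length(bad_date)) {
    stop("unparseable date(s) at data row(s): ",
         paste(utils::head(bad_date, 5), collapse = ", "), call. = FALSE)
  }
  resp_chr <- trimws(tab$response)
  resp_chr[resp_chr %in% c("", "NA")] <- NA_character_
  resp <- suppressWarnings(as.integer(resp_chr))
  bad_resp <- which(is.na(resp) & !is.na(resp_chr))
  if (length(bad_resp)) {
    stop("non-integer response(s) at data row(s): ",
         paste(utils::head(bad_resp, 5), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    patient_id = tab$patient_id,
    date = dates,
    section = tab$section,
    question_id = tab$question_id,
    response = resp
  )
  validate_survey(out, schema, dedupe = TRUE)
}

#' Validate a survey table against a schema
#'
#' @param table Tibble with survey columns as in [read_survey()].
#' @param schema A [survey_schema()].
#' @param dedupe Collapse duplicate keys keeping the last occurrence
#'   (warning) rather than erroring.
#' @return The validated (possibly deduplicated) tibble, sorted by key.
#' @export
validate_survey <- function(table, schema, dedupe = FALSE) {
  stopifnot(inherits(schema, "survey_schema"))
  bad_sec <- setdiff(unique(table$section), schema$sections)
  if (length(bad_sec)) {
    stop("section(s) not in schema: ", paste(bad_sec, collapse = ", "),
         call. = FALSE)
  }
  expect_sec <- question_section(schema, table$question_id)
  bad_q <- is.na(expect_sec) | expect_sec != table$section
  if (any(bad_q)) {
    stop(sum(bad_q), " row(s) with question_id absent from its section; e.g. ",
         table$question_id[which(bad_q)[1]], " in section ",
         table$section[which(bad_q)[1]], call. = FALSE)
  }
  ok_level <- vapply(seq_len(nrow(table)), function(i) {
    r <- table$response[i]
    is.na(r) || r %in% schema$levels[[table$question_id[i]]]
  }, logical(1))
  if (!all(ok_level)) {
    bad <- which(!ok_level)
    stop(length(bad), " response(s) outside declared levels; e.g. row ",
         bad[1], ": ", table$question_id[bad[1]], " = ",
         table$response[bad[1]], call. = FALSE)
  }
  key <- paste(table$patient_id, table$date, table$section, table$question_id,
               sep = "\r")
  if (anyDuplicated(key)) {
    if (!dedupe) {
      stop(sum(duplicated(key)), " duplicate (patient, date, section, question) row(s)",
           call. = FALSE)
    }
    warning(sum(duplicated(key)),
            " duplicate survey row(s) collapsed, keeping the last occurrence",
            call. = FALSE)
    keep <- !duplicated(key, fromLast = TRUE)
    table <- table[keep, , drop = FALSE]
  }
  dplyr::arrange(table, .data$patient_id, .data$date, .data$section,
                 .data$question_id)
}

#' Write a survey table to CSV
#' @param table Survey tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(table, path) {
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' Read and validate a GPS ping table
#'
#' Expects CSV columns `patient_id,timestamp,latitude,longitude` with
#' ISO-8601 timestamps (assumed UTC when no offset is given). Coordinates
#' are range-checked and rows sorted by (patient, timestamp).
#'
#' @param path CSV file path.
#' @param tz Timezone used to interpret timestamps and to bucket pings into
#'   local calendar days downstream.
#' @return Tibble `patient_id`, `timestamp` (POSIXct), `latitude`,
#'   `longitude`.
#' @export
read_gps <- function(path, tz = "UTC") {
  tab <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      timestamp = readr::col_character(),
      latitude = readr::col_double(),
      longitude = readr::col_double()
    )
  )
  need <- c("patient_id", "timestamp", "latitude", "longitude")
  if (!all(need %in% names(tab))) {
    stop("gps CSV must have columns ", paste(need, collapse = ","), call. = FALSE)
  }
  ts <- tryCatch(
    as.POSIXct(tab$timestamp, tz = tz,
               tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                              "%Y-%m-%d")),
    error = function(e) rep(as.POSIXct(NA), nrow(tab))
  )
  if (nrow(tab) > 0 && anyNA(ts)) {
    stop("unparseable timestamp(s) at data row(s): ",
         paste(utils::head(which(is.na(ts)), 5), collapse = ", "), call. = FALSE)
  }
  validate_gps(tibble::tibble(
    patient_id = tab$patient_id, timestamp = ts,
    latitude = tab$latitude, longitude = tab$longitude
  ))
}

#' Validate a GPS table (coordinate ranges, per-patient time order)
#' @param table GPS tibble as in [read_gps()].
#' @return Sorted, validated tibble.
#' @export
validate_gps <- function(table) {
  bad_lat <- !is.na(table$latitude) & abs(table$latitude) > 90
  bad_lon <- !is.na(table$longitude) & abs(table$longitude) > 180
  if (any(bad_lat) || any(bad_lon)) {
    stop(sum(bad_lat), " latitude and ", sum(bad_lon),
         " longitude value(s) out of range", call. = FALSE)
  }
  if (anyNA(table$latitude) || anyNA(table$longitude) || anyNA(table$timestamp)) {
    stop("missing coordinates or timestamps in GPS table", call. = FALSE)
  }
  dplyr::arrange(table, .data$patient_id, .data$timestamp)
}

#' Write a GPS table to CSV
#' @param table GPS tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gps <- function(table, path) {
  out <- table
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read relapse annotations from JSON or CSV
#'
#' JSON form: a single object or array of objects
#' `{"patient_id": ..., "relapse_dates": [...]}`. CSV form: columns
#' `patient_id,relapse_date`, one row per relapse.
#'
#' @param path File path (.json or .csv).
#' @param span Optional Date vector of length 2; relapse dates outside the
#'   span raise an error.
#' @return Named list mapping patient_id to a sorted Date vector of distinct
#'   relapse dates (possibly empty).
#' @export
read_relapse <- function(path, span = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    if (!is.null(raw$patient_id)) raw <- list(raw)
    ann <- lapply(raw, function(x) {
      as.Date(unlist(x$relapse_dates), format = "%Y-%m-%d")
    })
    names(ann) <- vapply(raw, function(x) as.character(x$patient_id), character(1))
  } else if (ext == "csv") {
    tab <- readr::read_csv(path, col_types = readr::cols(
      patient_id = readr::col_character(),
      relapse_date = readr::col_character()
    ))
    ann <- lapply(split(as.Date(tab$relapse_date), tab$patient_id), identity)
  } else {
    stop("unsupported relapse annotation format: .", ext, call. = FALSE)
  }
  ann <- lapply(ann, function(d) {
    d <- sort(unique(d))
    if (anyNA(d)) stop("unparseable relapse date", call. = FALSE)
    if (!is.null(span) && length(d) &&
        (min(d) < span[1] || max(d) > span[2])) {
      stop("relapse date outside study span", call. = FALSE)
    }
    d
  })
  ann
}

#' Write relapse annotations to JSON
#' @param annotations Named list patient_id -> Date vector.
#' @param path Output .json path.
#' @return `path`, invisibly.
#' @export
write_relapse <- function(annotations, path) {
  payload <- lapply(names(annotations), function(p) {
    list(patient_id = p,
         relapse_dates = format(annotations[[p]], "%Y-%m-%d"))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a labeled numeric matrix to CSV
#'
#' Square matrices (e.g. coassociation matrices) are written with their
#' labels as both header and first column; score matrices with row labels in
#' the first column and one column per component. Values are written at 15
#' significant digits and round-trip through [read_matrix()] to within
#' 1e-9.
#'
#' @param matrix Numeric matrix with dimnames.
#' @param path Output path.
#' @param allow_missing Permit `NA`/`NaN` entries (written as empty cells).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, allow_missing = FALSE) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (!allow_missing && !all(is.finite(matrix))) {
    stop("matrix contains missing or non-finite entries; set allow_missing = TRUE to write them",
         call. = FALSE)
  }
  rn <- rownames(matrix)
  cn <- colnames(matrix)
  if (is.null(rn)) rn <- as.character(seq_len(nrow(matrix)))
  if (is.null(cn)) cn <- paste0("c", seq_len(ncol(matrix)))
  body <- apply(matrix, 2, function(col) {
    out <- trimws(formatC(col, format = "g", digits = 15))
    out[!is.finite(col)] <- ""
    out
  })
  body <- matrix(body, nrow = nrow(matrix))
  lines <- c(
    paste(c("label", cn), collapse = ","),
    vapply(seq_len(nrow(matrix)),
           function(i) paste(c(rn[i], body[i, ]), collapse = ","),
           character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a labeled numeric matrix written by [write_matrix()]
#' @param path CSV path.
#' @return Numeric matrix with dimnames restored.
#' @export
read_matrix <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    label = readr::col_character(), .default = readr::col_double()
  ))
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$label
  m
}
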