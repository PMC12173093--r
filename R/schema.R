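#' Construct a survey schema
#'
#' A schema declares the ordered survey sections, the ordered question ids
#' within each section, and the legal ordinal levels of every question.
#' All downstream vectorization (indicator matrices, aggregate and complete
#' date vectors) uses the schema order, so results are reproducible across
#' runs and input row orders.
#'
#' @param sections Named list. Names are section names; each element is a
#'   named list mapping question id to an integer vector of legal ordinal
#'   levels (at least 2 levels per question).
#' @return An object of class `survey_schema` with fields `sections`
#'   (character vector), `questions` (named list section -> question ids) and
#'   `levels` (named list question id -> sorted integer levels).
#' @examples
#' sch <- survey_schema(list(
#'   mood  = list(mood_q1 = 0:3, mood_q2 = 0:3),
#'   sleep = list(sleep_q1 = 0:2)
#' ))
#' sch$sections
#' @export
survey_schema <- function(sections) {
  if (!is.list(sections) || length(sections) == 0 || is.null(names(sections)) ||
      any(names(sections) == "")) {
    stop("`sections` must be a non-empty named list", call. = FALSE)
  }
  if (anyDuplicated(names(sections))) {
    stop("duplicate section names in schema", call. = FALSE)
  }
  questions <- list()
  levels <- list()
  for (sec in names(sections)) {
    qs <- sections[[sec]]
    if (!is.list(qs) || length(qs) == 0 || is.null(names(qs)) || any(names(qs) == "")) {
      stop("section '", sec, "' must be a non-empty named list of questions",
           call. = FALSE)
    }
    if (anyDuplicated(names(qs))) {
      stop("duplicate question ids in section '", sec, "'", call. = FALSE)
    }
    for (q in names(qs)) {
      lv <- qs[[q]]
      if (!is.numeric(lv) || length(lv) < 2 || anyDuplicated(lv) ||
          any(lv != round(lv))) {
        stop("question '", q, "' needs >= 2 distinct integer levels", call. = FALSE)
      }
      if (q %in% names(levels)) {
        stop("question id '", q, "' appears in more than one section", call. = FALSE)
      }
      levels[[q]] <- sort(as.integer(lv))
    }
    questions[[sec]] <- names(qs)
  }
  structure(
    list(sections = names(sections), questions = questions, levels = levels),
    class = "survey_schema"
  )
}

#' Default five-section schema
#'
#' Mood, sleep, social, anxiety and psychosis sections with 3-5 questions
#' each, all answered on a 0-3 ordinal scale. This mirrors the structure of
#' ecological momentary assessment questionnaires used in smartphone studies
#' of schizophrenia.
#'
#' @param levels Integer vector of legal levels shared by all questions.
#' @return A `survey_schema`.
#' @export
default_schema <- function(levels = 0:3) {
  nq <- c(mood = 4L, sleep = 3L, social = 4L, anxiety = 5L, psychosis = 5L)
  survey_schema(lapply(stats::setNames(names(nq), names(nq)), function(sec) {
    qs <- paste0(sec, "_q", seq_len(nq[[sec]]))
    stats::setNames(rep(list(levels), length(qs)), qs)
  }))
}

#' @export
print.survey_schema <- function(x, ...) {
  cat("<survey_schema> ", length(x$sections), " sections, ",
      length(x$levels), " questions\n", sep = "")
  for (sec in x$sections) {
    cat("  ", sec, ": ", paste(x$questions[[sec]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' All question ids of a schema in schema order
#' @param schema A `survey_schema`.
#' @return Character vector of question ids.
#' @export
schema_questions <- function(schema) {
  stopifnot(inherits(schema, "survey_schema"))
  unlist(schema$questions[schema$sections], use.names = FALSE)
}

#' Read a schema from YAML or JSON
#'
#' The file maps section name -> question id -> vector of levels.
#'
#' @param path File path ending in .yaml/.yml or .json.
#' @return A `survey_schema`.
#' @export
read_schema <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported schema format: .", ext, call. = FALSE)
  )
  survey_schema(lapply(raw, function(qs) lapply(qs, as.integer)))
}

#' Write a schema to YAML or JSON
#' @param schema A `survey_schema`.
#' @param path Output path ending in .yaml/.yml or .json.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "survey_schema"))
  raw <- lapply(stats::setNames(schema$sections, schema$sections), function(sec) {
    lapply(stats::setNames(schema$questions[[sec]], schema$questions[[sec]]),
           function(q) schema$levels[[q]])
  })
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml  = yaml::write_yaml(raw, path),
    json = jsonlite::write_json(raw, path, auto_unbox = FALSE, digits = NA),
    stop("unsupported schema format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Section of a question id under a schema
#' @param schema A `survey_schema`.
#' @param question_id Character vector of question ids.
#' @return Character vector of section names.
#' @export
question_section <- function(schema, question_id) {
  stopifnot(inherits(schema, "survey_schema"))
  map <- rep(schema$sections, lengths(schema$questions[schema$sections]))
  names(map) <- schema_questions(schema)
  unname(map[question_id])
}
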