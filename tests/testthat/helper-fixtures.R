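# Small schemas and table builders used across tests.

tiny_schema <- function() {
  survey_schema(list(
    mood  = list(mood_q1 = 0:3, mood_q2 = 0:3),
    sleep = list(sleep_q1 = 0:2)
  ))
}

one_q_schema <- function(levels = 0:5) {
  survey_schema(list(mood = list(mood_q1 = levels)))
}

# Long survey tibble from a dates x questions response matrix (NA = missing).
survey_from_matrix <- function(m, schema, section, patient_id = "P01",
                               start = as.Date("2022-01-01")) {
  dates <- start + seq_len(nrow(m)) - 1
  qs <- colnames(m)
  tibble::tibble(
    patient_id = patient_id,
    date = rep(dates, times = ncol(m)),
    section = section,
    question_id = rep(qs, each = nrow(m)),
    response = as.integer(m)
  )
}

# Well-separated Gaussian blobs: centers on a scaled simplex, within-SD 1.
make_blobs <- function(n_per, centers, sep = 10, dim = 2, seed = 1) {
  withr::with_seed(seed, {
    pts <- do.call(rbind, lapply(seq_len(centers), function(c) {
      mu <- rep(0, dim)
      mu[(c - 1) %% dim + 1] <- sep * c
      sweep(matrix(stats::rnorm(n_per * dim), ncol = dim), 2, mu, "+")
    }))
    rownames(pts) <- sprintf("d%03d", seq_len(nrow(pts)))
    list(points = pts, truth = rep(seq_len(centers), each = n_per))
  })
}

write_tmp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
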