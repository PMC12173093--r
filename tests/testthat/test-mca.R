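test_that("indicator matrices are built in schema order with constant row sums", {
  sch <- survey_schema(list(sec = list(q1 = 0:2, q2 = 0:1)))
  tab <- tibble::tibble(
    patient_id = "P01", date = as.Date("2022-01-01"),
    section = "sec", question_id = c("q1", "q2"), response = c(1L, 0L)
  )
  Z <- build_indicator(tab, sch, "sec")
  expect_equal(unname(Z[1, ]), c(0, 1, 0, 1, 0))
  expect_equal(colnames(Z), c("q1:0", "q1:1", "q1:2", "q2:0", "q2:1"))
  expect_equal(rowSums(Z), c(`2022-01-01` = 2))

  # identical dates give identical rows; unused levels stay as zero columns
  tab3 <- dplyr::bind_rows(lapply(0:2, function(d) {
    dplyr::mutate(tab, date = date + d)
  }))
  Z3 <- build_indicator(tab3, sch, "sec")
  expect_equal(nrow(Z3), 3)
  expect_true(all(apply(Z3, 2, function(col) length(unique(col)) == 1)))
  expect_true(all(colSums(Z3)[c("q1:0", "q1:2", "q2:1")] == 0))

  # incomplete tables are rejected: imputation must run first
  expect_error(build_indicator(dplyr::mutate(tab, response = c(NA, 0L)),
                               sch, "sec"), "imputation")
})

test_that("a 2-date opposite-answer binary question gives the textbook CA", {
  # frozen from the closed form: S = 0.5*[[1,-1],[-1,1]], eigenvalues {1,0},
  # row principal coordinates +/-1
  Z <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
              dimnames = list(c("2022-01-01", "2022-01-02"), c("q:0", "q:1")))
  attr(Z, "mean_response") <- c(0, 1)
  fit <- fit_mca(Z)
  expect_equal(fit$eigenvalues, 1, tolerance = 1e-12)
  expect_equal(sort(unname(fit$row_scores[, 1])), c(-1, 1), tolerance = 1e-12)
  # sign convention: correlation with mean raw response is positive,
  # so the higher-response date carries the positive score
  expect_gt(fit$row_scores["2022-01-02", 1], 0)
  tr <- mca_trend(fit)
  expect_equal(tr$score, unname(fit$row_scores[, 1]))
})

test_that("fit_mca matches the brute-force eigendecomposition oracle", {
  for (s in 1:25) {
    q <- sample(2:4, 1)
    n_levels <- sample(2:4, q, replace = TRUE)
    n <- sample(4:10, 1)
    Z <- random_indicator(n, q, n_levels, seed = s)
    fit <- fit_mca(Z)
    oracle <- mca_oracle(Z)
    k <- length(fit$eigenvalues)
    expect_lt(max(abs(fit$eigenvalues - oracle$eigenvalues[seq_len(k)])), 1e-8)
    expect_lt(max(abs(fit$eigenvalues - oracle$eigen_lambda[seq_len(k)])), 1e-7)
    # tied eigenvalues leave the score basis undetermined; compare only
    # components with an isolated eigenvalue
    iso <- which(isolated_components(oracle$eigenvalues)[seq_len(k)])
    if (length(iso)) {
      expect_lt(max(abs(abs(fit$row_scores[, iso, drop = FALSE]) -
                          oracle$abs_scores[, iso, drop = FALSE])), 1e-8)
    }
    expect_true(all(diff(fit$eigenvalues) <= 1e-12))
    if (!fit$degenerate) {
      expect_equal(sum(fit$inertia_proportions), 1, tolerance = 1e-8)
      # uniform row masses: mass-weighted column means of scores are 0
      expect_lt(max(abs(colMeans(fit$row_scores))), 1e-8)
    }
  }
})

test_that("total inertia equals (J - Q)/Q when all levels are realized", {
  for (s in 1:10) {
    q <- sample(2:4, 1)
    n_levels <- sample(2:3, q, replace = TRUE)
    Z <- random_indicator(30, q, n_levels, seed = 1000 + s)
    if (any(colSums(Z) == 0)) next
    fit <- fit_mca(Z)
    expect_equal(sum(fit$eigenvalues), (ncol(Z) - q) / q, tolerance = 1e-8)
  }
})

test_that("fit_mca is invariant to row order up to the same permutation", {
  Z <- random_indicator(8, 3, c(3, 2, 4), seed = 77)
  perm <- withr::with_seed(7, sample(nrow(Z)))
  f1 <- fit_mca(Z)
  f2 <- fit_mca(Z[perm, ])
  expect_equal(f2$eigenvalues, f1$eigenvalues, tolerance = 1e-10)
  expect_equal(abs(f2$row_scores[rownames(Z), ]), abs(f1$row_scores),
               tolerance = 1e-10)
  # permuting input date order permutes the trend identically
  t1 <- mca_trend(f1)
  t2 <- mca_trend(f2)
  expect_equal(t2[order(t2$date), ], t1[order(t1$date), ], tolerance = 1e-10)
})

test_that("zero-inertia sections degrade gracefully", {
  sch <- survey_schema(list(sec = list(q1 = 0:2, q2 = 0:1)))
  tab <- dplyr::bind_rows(lapply(0:3, function(d) tibble::tibble(
    patient_id = "P01", date = as.Date("2022-01-01") + d,
    section = "sec", question_id = c("q1", "q2"), response = c(1L, 0L)
  )))
  fit <- fit_mca(build_indicator(tab, sch, "sec"))
  expect_true(fit$degenerate)
  expect_true(all(fit$eigenvalues == 0))
  expect_true(all(mca_trend(fit)$score == 0))
  expect_equal(eigengaps(fit), list(first = 0, second = 0))
})

test_that("eigengaps follow the stated arithmetic on inertia proportions", {
  fake <- function(props) {
    structure(list(inertia_proportions = props, degenerate = FALSE),
              class = "mca_result")
  }
  expect_equal(eigengaps(fake(c(0.6, 0.3, 0.1))),
               list(first = 0.3, second = 0.2))
  expect_equal(eigengaps(fake(1)), list(first = 1, second = 0))  # zero-padded
  g <- eigengaps(fake(rep(1 / 3, 3)))
  expect_equal(g$first, 0)
  expect_equal(g$second, 0)
})

test_that("more erratic responses flatten the spectrum (first eigengap)", {
  # Monte-Carlo trend: raising within-section question noise (inconsistent
  # answers across a section's questions) never raises the mean first
  # eigengap, from the coherent regime upward
  gap_at <- function(qn, seeds) {
    vapply(seeds, function(s) {
      cfg <- synth_config(n_patients = 1, span_days = 45, missing_rate = 0,
                          question_noise_sd = qn, seed = s,
                          relapse_spec = list(integer(0)))
      p <- generate_patient(cfg, 1)
      fit <- fit_mca(build_indicator(p$survey, cfg$schema, "mood"), "mood")
      eigengaps(fit)$first
    }, numeric(1))
  }
  seeds <- 1:35
  means <- c(mean(gap_at(0.5, seeds)), mean(gap_at(1, seeds)),
             mean(gap_at(2, seeds)))
  expect_true(all(diff(means) < 0))
})

test_that("the Benzecri option rescales proportions without touching scores", {
  Z <- random_indicator(12, 3, c(3, 3, 2), seed = 5)
  raw <- fit_mca(Z)
  adj <- fit_mca(Z, benzecri = TRUE)
  expect_equal(adj$row_scores, raw$row_scores)
  expect_equal(adj$eigenvalues, raw$eigenvalues)
  expect_gte(adj$first_eigengap, raw$first_eigengap - 1e-12)
})
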