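test_that("aggregate vectors are per-section means in schema order", {
  sch <- default_schema()
  days <- as.Date("2022-01-01")
  rows <- list()
  for (sec in sch$sections) {
    qs <- sch$questions[[sec]]
    resp <- if (sec == "mood") c(1L, 2L, 3L, 2L) else rep(0L, length(qs))
    rows[[sec]] <- tibble::tibble(patient_id = "P01", date = days,
                                  section = sec, question_id = qs,
                                  response = resp)
  }
  tab <- dplyr::bind_rows(rows)
  av <- make_av(tab, sch)
  expect_equal(dim(av), c(1, 5))
  expect_equal(unname(av[1, ]), c(2, 0, 0, 0, 0))
  expect_equal(colnames(av), sch$sections)

  zero <- dplyr::mutate(tab, response = 0L)
  expect_true(all(make_av(zero, sch) == 0))
})

test_that("complete vectors concatenate responses with schema-block structure", {
  sch <- survey_schema(list(a = list(a_q1 = 0:3, a_q2 = 0:3),
                            b = list(b_q1 = 0:3, b_q2 = 0:3)))
  tab <- tibble::tibble(
    patient_id = "P01", date = as.Date("2022-01-01"),
    section = c("a", "a", "b", "b"),
    question_id = c("a_q1", "a_q2", "b_q1", "b_q2"),
    response = c(1L, 2L, 3L, 0L)
  )
  cv <- make_cv(tab, sch)
  expect_equal(unname(cv[1, ]), c(1, 2, 3, 0))
  expect_equal(ncol(cv), length(schema_questions(sch)))

  # permuting schema section order permutes CV blocks identically
  sch_rev <- survey_schema(list(b = list(b_q1 = 0:3, b_q2 = 0:3),
                                a = list(a_q1 = 0:3, a_q2 = 0:3)))
  cv_rev <- make_cv(tab, sch_rev)
  expect_equal(unname(cv_rev[1, ]), c(3, 0, 1, 2))
})

test_that("predefined clustering separates separated masses and handles edges", {
  pts <- rbind(matrix(0, 5, 2), matrix(10, 5, 2)) +
    withr::with_seed(1, matrix(rnorm(20, 0, 0.01), 10, 2))
  rownames(pts) <- paste0("d", 1:10)
  for (m in c("kmeans", "agglomerative")) {
    part <- cluster_predefined(pts, 2, m, seed = 4)
    expect_length(unique(part$labels), 2)
    expect_length(unique(part$labels[1:5]), 1)
    expect_length(unique(part$labels[6:10]), 1)
    expect_false(part$labels[1] == part$labels[10])
  }
  # k = n gives all singletons
  part_n <- cluster_predefined(pts, 10, "kmeans", seed = 4)
  expect_length(unique(part_n$labels), 10)
  # identical vectors still terminate with <= k clusters
  same <- matrix(1, 6, 2, dimnames = list(paste0("d", 1:6), NULL))
  part_s <- cluster_predefined(same, 2, "kmeans", seed = 4)
  expect_lte(length(unique(part_s$labels)), 2)
  expect_error(cluster_predefined(pts, 11, "kmeans"), "exceeds")
})

test_that("natural clustering picks k by silhouette and matches the brute-force oracle", {
  blobs <- make_blobs(8, 2, seed = 3)
  part <- cluster_natural(blobs$points, k_max = 5, seed = 1)
  expect_equal(part$method, "natural_k2")
  expect_equal(length(unique(part$labels)), 2)

  blobs3 <- make_blobs(8, 3, seed = 4)
  part3 <- cluster_natural(blobs3$points, k_max = 6, seed = 1)
  expect_equal(part3$method, "natural_k3")

  # the selected k maximizes the independently computed mean silhouette
  sils <- vapply(2:5, function(k) {
    brute_silhouette(blobs3$points,
                     cluster_predefined(blobs3$points, k, "kmeans", 1)$labels)
  }, numeric(1))
  expect_equal(which.max(sils) + 1L, 3L)

  same <- matrix(2, 5, 3, dimnames = list(paste0("d", 1:5), NULL))
  deg <- cluster_natural(same, k_max = 4)
  expect_true(deg$degenerate)
  expect_length(unique(deg$labels), 1)
})

test_that("ensembles have the promised size and are seed-reproducible", {
  blobs <- make_blobs(6, 2, seed = 9)
  vectors <- list(AV = blobs$points)
  ens <- build_ensemble(vectors, kinds = "AV", strategies = "predefined",
                        k_list = c(2, 3), methods = "kmeans", restarts = 3,
                        seed = 5)
  expect_length(ens, 2 * 3)  # |methods x k| x restarts
  single <- build_ensemble(vectors, kinds = "AV", strategies = "natural",
                           restarts = 1, seed = 5)
  expect_length(single, 1)
  ens2 <- build_ensemble(vectors, kinds = "AV", strategies = "predefined",
                         k_list = c(2, 3), methods = "kmeans", restarts = 3,
                         seed = 5)
  expect_identical(lapply(ens, `[[`, "labels"), lapply(ens2, `[[`, "labels"))
})

test_that("coassociation equals direct pair counting and its invariances hold", {
  lab <- function(x) stats::setNames(as.integer(x), paste0("d", seq_along(x)))
  p1 <- phenovis:::new_partition(lab(c(1, 1, 2)), "m1")
  p2 <- phenovis:::new_partition(lab(c(1, 2, 2)), "m2")

  co_same <- coassociation(list(p1, p1))
  expect_equal(unname(co_same["d1", "d2"]), 1)
  expect_equal(unname(co_same["d1", "d3"]), 0)

  co <- coassociation(list(p1, p2))
  expect_equal(unname(co["d1", "d2"]), 0.5)
  expect_equal(unname(co["d2", "d3"]), 0.5)
  expect_equal(unname(co["d1", "d3"]), 0)

  # relabeling clusters inside a member partition changes nothing
  p2_relab <- phenovis:::new_partition(lab(c(9, 4, 4)), "m2r")
  expect_equal(unclass(coassociation(list(p1, p2_relab))), unclass(co))

  # all-singleton ensemble gives the identity matrix
  singl <- phenovis:::new_partition(lab(1:4), "s")
  expect_equal(unclass(coassociation(list(singl, singl))),
               diag(4) |> `dimnames<-`(list(paste0("d", 1:4), paste0("d", 1:4))))
})

test_that("coassociation matches the oracle on random ensembles", {
  for (s in 1:15) {
    n <- withr::with_seed(s, sample(4:10, 1))
    E <- withr::with_seed(s + 100, sample(1:5, 1))
    parts <- lapply(seq_len(E), function(e) {
      labs <- withr::with_seed(s * 100 + e,
                               sample.int(3, n, replace = TRUE))
      phenovis:::new_partition(stats::setNames(labs, paste0("d", 1:n)), "rnd")
    })
    co <- coassociation(parts)
    expect_equal(unname(unclass(co)), coassoc_oracle(parts))
    expect_equal(unclass(co), t(unclass(co)))
    expect_true(all(diag(co) == 1))
    expect_true(all(abs(co * E - round(co * E)) < 1e-12))  # multiples of 1/E
  }
})

test_that("two response regimes produce block structure in the coassociation matrix", {
  # dates from a calm baseline and a variance-inflated relapse month should
  # co-cluster within regime more than across
  hits <- vapply(1:10, function(s) {
    cfg <- synth_config(n_patients = 1, span_days = 90, missing_rate = 0,
                        relapse_spec = list(75L), seed = s)
    p <- generate_patient(cfg, 1)
    av <- make_av(p$survey, cfg$schema)
    ens <- build_ensemble(list(AV = av), kinds = "AV", restarts = 2, seed = s)
    co <- coassociation(ens)
    dates <- as.Date(rownames(co))
    rel <- dates >= p$relapse_dates - 30 & dates < p$relapse_dates
    within <- mean(c(co[rel, rel][lower.tri(co[rel, rel])],
                     co[!rel, !rel][lower.tri(co[!rel, !rel])]))
    between <- mean(co[rel, !rel])
    within > between
  }, logical(1))
  expect_gte(sum(hits), 9)
})
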