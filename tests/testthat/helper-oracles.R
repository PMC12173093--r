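# Independent brute-force oracles. These deliberately avoid the package's
# computational paths: the MCA oracle builds the standardized residual
# matrix with explicit loops and diagonalizes S S^T with eigen() (the
# implementation uses svd()); the coassociation oracle counts pairs
# directly; the silhouette oracle evaluates the definition with loops.

mca_oracle <- function(Z) {
  N <- sum(Z)
  P <- Z / N
  r <- rowSums(P)
  cc <- colSums(P)
  keep <- which(cc > 0)
  S <- matrix(0, nrow(Z), length(keep))
  for (i in seq_len(nrow(Z))) {
    for (jj in seq_along(keep)) {
      j <- keep[jj]
      S[i, jj] <- (P[i, j] - r[i] * cc[j]) / sqrt(r[i] * cc[j])
    }
  }
  sv <- svd(S)
  lambda <- sv$d^2
  scores <- matrix(0, nrow(Z), length(lambda))
  for (k in seq_along(lambda)) {
    scores[, k] <- sv$u[, k] * sv$d[k] / sqrt(r)
  }
  # second, fully independent eigenvalue route
  eig_lambda <- pmax(eigen(S %*% t(S), symmetric = TRUE,
                           only.values = TRUE)$values, 0)
  list(eigenvalues = lambda, abs_scores = abs(scores),
       eigen_lambda = eig_lambda)
}

# components whose eigenvalue is isolated from its neighbours; only these
# have a well-defined one-dimensional score direction
isolated_components <- function(lambda, tol = 1e-6) {
  n <- length(lambda)
  vapply(seq_len(n), function(k) {
    left <- if (k > 1) abs(lambda[k - 1] - lambda[k]) else Inf
    right <- if (k < n) abs(lambda[k] - lambda[k + 1]) else lambda[k]
    min(left, right) > tol
  }, logical(1))
}

# Random indicator matrix: n dates, each of q questions gets one level of
# n_levels indicated.
random_indicator <- function(n, q, n_levels, seed) {
  withr::with_seed(seed, {
    cols <- sum(n_levels)
    Z <- matrix(0L, n, cols)
    offset <- c(0, cumsum(n_levels))
    for (j in seq_len(q)) {
      lv <- sample.int(n_levels[j], n, replace = TRUE)
      Z[cbind(seq_len(n), offset[j] + lv)] <- 1L
    }
    rownames(Z) <- format(as.Date("2022-01-01") + seq_len(n) - 1, "%Y-%m-%d")
    colnames(Z) <- paste0("c", seq_len(cols))
    Z
  })
}

coassoc_oracle <- function(partitions) {
  labs <- lapply(partitions, function(p) unname(p$labels))
  n <- length(labs[[1]])
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      cnt <- 0
      for (l in labs) if (l[i] == l[j]) cnt <- cnt + 1
      M[i, j] <- cnt / length(labs)
    }
  }
  M
}

brute_silhouette <- function(points, labels) {
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
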