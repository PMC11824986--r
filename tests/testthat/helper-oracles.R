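# Independent brute-force oracles. These deliberately avoid the package's
# vectorized code paths: scalar double loops and a generic numeric optimizer,
# so agreement is evidence rather than tautology.

# Ridge solution by generic quadratic minimization of
# ||H B - T||_F^2 + (1/C) ||B||_F^2 via optim(BFGS) with analytic gradient.
oracle_ridge <- function(H, T, C) {
  p <- ncol(H); m <- ncol(T)
  obj <- function(b) {
    B <- matrix(b, p, m)
    R <- H %*% B - T
    sum(R^2) + sum(B^2) / C
  }
  grad <- function(b) {
    B <- matrix(b, p, m)
    as.vector(2 * crossprod(H, H %*% B - T) + 2 * B / C)
  }
  par <- rep(0, p * m)
  # restarted BFGS: each restart resets the Hessian approximation, which
  # pushes convergence well past a single run on ill-conditioned systems
  for (k in 1:8) {
    fit <- stats::optim(par, obj, grad, method = "BFGS",
                        control = list(maxit = 5000, reltol = 1e-16))
    if (max(abs(fit$par - par)) < 1e-10) { par <- fit$par; break }
    par <- fit$par
  }
  matrix(par, p, m)
}

# Ridge solution by the explicit normal equations, assembled entry-by-entry
# with scalar loops (an independent dense-solve route).
oracle_ridge_dense <- function(H, T, C) {
  p <- ncol(H)
  G <- matrix(0, p, p)
  for (a in seq_len(p)) for (b in seq_len(p)) G[a, b] <- sum(H[, a] * H[, b])
  solve(G + diag(p) / C, t(H) %*% T)
}

# Scalar kernel evaluations, one pair at a time.
oracle_kernel <- function(family, x, r, sigma = NULL) {
  switch(family,
    rbf = exp(-sum((x - r)^2) / (2 * sigma^2)),
    euclidean_sq = sum((x - r)^2),
    manhattan = sum(abs(x - r)),
    cosine_printed = sum(x * r) / (sum(x^2) * sum(r^2)),
    cosine_standard = sum(x * r) / sqrt(sum(x^2) * sum(r^2))
  )
}

oracle_kernel_matrix <- function(family, X, R, sigma = NULL) {
  out <- matrix(0, nrow(X), nrow(R))
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(nrow(R))) {
      out[i, j] <- oracle_kernel(family, X[i, ], R[j, ], sigma)
    }
  }
  out
}

oracle_sigmoid <- function(z) 1 / (1 + exp(-z))

# Explicit per-row random map: loops, no matrix algebra.
oracle_random_map <- function(layer, X) {
  n <- nrow(X); L <- nrow(layer$weights)
  out <- matrix(0, n, L)
  for (i in seq_len(n)) {
    for (j in seq_len(L)) {
      z <- sum(layer$weights[j, ] * X[i, ]) + layer$biases[j]
      out[i, j] <- if (layer$activation == "sigmoid") oracle_sigmoid(z) else z
    }
  }
  out
}

# Exhaustive risk enumeration for one posterior row.
oracle_min_risk <- function(post, costs) {
  m <- length(post)
  risks <- vapply(seq_len(m), function(j) sum(post * costs[, j]), numeric(1))
  which(risks == min(risks))[1]
}

expect_close <- function(actual, expected, tol = 1e-8) {
  expect_lt(max(abs(actual - expected)), tol)
}

# Small reproducible matrix fixture.
rmat <- function(n, p, seed) {
  withr::with_seed(seed, matrix(stats::rnorm(n * p), n, p))
}
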