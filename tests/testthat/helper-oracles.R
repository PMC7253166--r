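# Shared fixtures and independent oracles. The oracles deliberately use
# eigendecomposition-based matrix exponentials and brute-force
# sums/quadrature so they share no code path with the package's Van Loan /
# doubling / Stein machinery.

random_stable <- function(n, seed, margin = 0.5) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(n * n), n, n)
    A - diag(n) * (max(Re(eigen(A, only.values = TRUE)$values)) + margin)
  })
}

random_stable_symmetric <- function(n, seed, margin = 0.5) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(n * n), n, n)
    A <- (A + t(A)) / 2
    A - diag(n) * (max(eigen(A, symmetric = TRUE, only.values = TRUE)$values) + margin)
  })
}

random_psd <- function(n, seed, unit_trace = FALSE) {
  withr::with_seed(seed, {
    F <- matrix(rnorm(n * n), n, n)
    S <- tcrossprod(F)
    if (unit_trace) S / sum(diag(S)) else S
  })
}

# eigen-based matrix exponential (oracle-side, independent of Matrix::expm)
expm_eigen <- function(A, t) {
  e <- eigen(A)
  Re(e$vectors %*% (exp(e$values * t) * solve(e$vectors)))
}

# composite-Simpson quadrature of the observability integrand
obs_gramian_quadrature <- function(A, C, window, panels = 2000) {
  n <- nrow(A)
  CtC <- crossprod(C)
  ts <- seq(0, window, length.out = 2 * panels + 1)
  h <- ts[2] - ts[1]
  w <- c(1, rep(c(4, 2), panels - 1), 4, 1)
  total <- matrix(0, n, n)
  for (i in seq_along(ts)) {
    Et <- expm_eigen(A, ts[i])
    total <- total + w[i] * (t(Et) %*% CtC %*% Et)
  }
  total * h / 3
}

# truncated-series oracle for the discrete controllability Gramian
ctrl_gramian_series <- function(A, B, Sigma, window, tol = 1e-14, kmax = 100000) {
  E <- expm_eigen(A, window)
  G <- B %*% Sigma %*% t(B)
  X <- G
  Term <- G
  for (k in seq_len(kmax)) {
    Term <- E %*% Term %*% t(E)
    X <- X + Term
    if (max(abs(Term)) <= tol * max(abs(X))) break
  }
  X
}

# brute-force power allocation over a step-delta simplex grid for diagonal
# A with B = C = I (independent scalar subchannels)
simplex_grid_capacity <- function(a, sigma2, window, step = 0.01) {
  stopifnot(length(a) == 3)
  best <- -Inf
  g <- seq(0, 1, by = step)
  for (p1 in g) for (p2 in seq(0, 1 - p1, by = step)) {
    p <- c(p1, p2, 1 - p1 - p2)
    ee <- exp(-2 * a * window)
    v <- sum(0.5 * log2((2 * a * sigma2 + p) / (2 * a * sigma2 + p * ee)))
    if (v > best) best <- v
  }
  best
}

fast_opts <- function(n_restarts = 3, seed = 1, ...) {
  optimizer_options(n_restarts = n_restarts, seed = seed, ...)
}
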