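test_that("scalar Gramians match their closed forms", {
  a <- 1.3; Tw <- 0.8
  expect_equal(observability_gramian(matrix(-a), matrix(1), Tw)[1, 1],
               (1 - exp(-2 * a * Tw)) / (2 * a), tolerance = 1e-12)
  p <- 0.6
  expect_equal(controllability_gramian(matrix(-a), matrix(1), matrix(p), Tw)[1, 1],
               p / (1 - exp(-2 * a * Tw)), tolerance = 1e-12)
  # T -> infinity observability limit is 1/(2a)
  expect_equal(observability_gramian(matrix(-1), matrix(1), 50)[1, 1], 0.5,
               tolerance = 1e-12)
})

test_that("zero readout or zero input gives a zero Gramian", {
  A <- random_stable(3, 31)
  expect_equal(observability_gramian(A, matrix(0, 1, 3), 1), matrix(0, 3, 3))
  expect_equal(controllability_gramian(A, Sigma = matrix(0, 3, 3), window = 1),
               matrix(0, 3, 3))
})

test_that("observability Gramian matches Simpson quadrature on random systems", {
  for (seed in 1:3) {
    A <- random_stable(3, 300 + seed)
    C <- withr::with_seed(400 + seed, matrix(rnorm(6), 2, 3))
    O <- observability_gramian(A, C, 1.3)
    Oq <- obs_gramian_quadrature(A, C, 1.3)
    expect_lt(max(abs(O - Oq)) / max(abs(Oq)), 1e-8)
  }
})

test_that("all three observability methods agree, including non-normal chains", {
  cases <- list(random_stable(4, 77), chain_network(6, alpha = 7))
  for (A in cases) {
    n <- nrow(A)
    C <- diag(n)[1:2, , drop = FALSE]
    Od <- observability_gramian(A, C, 2, method = "doubling")
    Ol <- observability_gramian(A, C, 2, method = "lyapunov")
    Oo <- observability_gramian(A, C, 2, method = "ode")
    scale <- max(abs(Od))
    expect_lt(max(abs(Od - Ol)) / scale, 1e-8)
    expect_lt(max(abs(Od - Oo)) / scale, 1e-6)
  }
})

test_that("discrete controllability Gramian matches the truncated series", {
  for (seed in 1:3) {
    A <- random_stable(4, 500 + seed)
    B <- diag(4)[, 1:2]
    Sigma <- random_psd(2, 600 + seed, unit_trace = TRUE)
    W <- controllability_gramian(A, B, Sigma, 0.9)
    Ws <- ctrl_gramian_series(A, B, Sigma, 0.9)
    expect_lt(max(abs(W - Ws)) / max(abs(Ws)), 1e-8)
  }
})

test_that("controllability requires a contractive sampled propagator", {
  expect_error(controllability_gramian(matrix(0.2), window = 1), "spectral radius")
})

test_that("interference covariance is the Gramian minus the packet term and is PSD", {
  for (seed in 1:5) {
    A <- random_stable(5, 700 + seed)
    Sigma <- random_psd(5, 800 + seed, unit_trace = TRUE)
    W <- controllability_gramian(A, NULL, Sigma, 1.2)
    V <- interference_covariance(A, NULL, Sigma, 1.2)
    expect_equal(V, W - Sigma, tolerance = 1e-9)
    expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
  # geometric tail: scalar interference at long windows
  v <- interference_covariance(matrix(-1), matrix(1), matrix(1), 20)[1, 1]
  expect_equal(v, exp(-40) / (1 - exp(-40)), tolerance = 1e-6 * exp(-40) + 1e-15)
})

test_that("Lyapunov residuals are small and O(T) is monotone in the PSD order", {
  worst_c <- 0; worst_d <- 0
  for (seed in 1:30) {
    n <- 3 + seed %% 4
    A <- random_stable(n, 900 + seed)
    C <- withr::with_seed(950 + seed, matrix(rnorm(2 * n), 2, n))
    CtC <- crossprod(C)
    Q <- netcapacity:::lyap_continuous(A, CtC)
    worst_c <- max(worst_c, norm(t(A) %*% Q + Q %*% A + CtC, "F") / norm(CtC, "F"))
    Sigma <- random_psd(n, 970 + seed, unit_trace = TRUE)
    E <- netcapacity:::mat_exp(A * 0.7)
    W <- netcapacity:::lyap_discrete(E, Sigma)
    worst_d <- max(worst_d, norm(W - E %*% W %*% t(E) - Sigma, "F") / norm(Sigma, "F"))
  }
  expect_lt(worst_c, 1e-8)
  expect_lt(worst_d, 1e-8)
  A <- random_stable(4, 999)
  Ts <- c(0.2, 0.5, 1, 2, 5)
  Os <- lapply(Ts, function(Tw) observability_gramian(A, NULL, Tw))
  for (i in seq_len(length(Ts) - 1)) {
    d <- Os[[i + 1]] - Os[[i]]
    expect_gte(min(eigen(d, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("normal dynamics decouple into scalar modes for O and W", {
  A <- random_stable_symmetric(5, 1234)
  eg <- eigen(A, symmetric = TRUE)
  a <- -eg$values
  Tw <- 0.9
  O <- observability_gramian(A, NULL, Tw)
  Od <- t(eg$vectors) %*% O %*% eg$vectors
  expect_equal(diag(Od), (1 - exp(-2 * a * Tw)) / (2 * a), tolerance = 1e-10)
  expect_lt(max(abs(Od - diag(diag(Od)))), 1e-10)
  p <- c(0.4, 0.3, 0.15, 0.1, 0.05)
  Sigma <- eg$vectors %*% (p * t(eg$vectors))
  W <- controllability_gramian(A, NULL, Sigma, Tw)
  Wd <- t(eg$vectors) %*% W %*% eg$vectors
  expect_equal(diag(Wd), p / (1 - exp(-2 * a * Tw)), tolerance = 1e-10)
  expect_lt(max(abs(Wd - diag(diag(Wd)))), 1e-10)
})
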