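# Internal linear-algebra workhorses: symmetrization/PSD hygiene, stable
# log-determinants, and the Lyapunov/Stein solvers everything else builds on.

sym <- function(X) (X + t(X)) / 2

#' @noRd
frob <- function(X) sqrt(sum(X^2))

# Clip tiny negative eigenvalues arising from round-off; anything below
# -tol relative to the largest eigenvalue is a genuine failure upstream.
psd_clip <- function(X, tol = 1e-10) {
  X <- sym(X)
  e <- eigen(X, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  sym(e$vectors %*% (lam * t(e$vectors)))
}

# Cholesky factor of a symmetric positive definite matrix. Gramian-based
# matrices here are strongly "graded" (diagonal entries spanning tens of
# orders of magnitude under transient amplification), so the matrix is
# Jacobi-balanced to unit diagonal before factoring; the returned upper
# triangle R still satisfies R'R = S. A jitter relative to the *balanced*
# scale is added only if factorisation still fails.
chol_factor <- function(S, jitter = 1e-12) {
  S <- sym(S)
  d <- sqrt(pmax(diag(S), .Machine$double.xmin))
  Sb <- S / tcrossprod(d)
  ch <- tryCatch(chol(Sb), error = function(e) NULL)
  j <- jitter
  while (is.null(ch) && j <= 1e-4) {
    ch <- tryCatch(chol(Sb + j * diag(nrow(S))), error = function(e) NULL)
    j <- j * 1e3
  }
  if (is.null(ch)) stop("Cholesky failed: matrix is not positive definite", call. = FALSE)
  sweep(ch, 2, d, "*")  # scale columns back: R = chol(Sb) %*% diag(d)
}

spectral_abscissa <- function(A) {
  max(Re(eigen(A, only.values = TRUE)$values))
}

spectral_radius <- function(A) {
  max(Mod(eigen(A, only.values = TRUE)$values))
}

assert_square <- function(A, arg = "A") {
  if (!is.matrix(A) || nrow(A) != ncol(A) || !is.numeric(A))
    stop(sprintf("`%s` must be a square numeric matrix", arg), call. = FALSE)
  if (!all(is.finite(A)))
    stop(sprintf("`%s` contains non-finite entries", arg), call. = FALSE)
  invisible(A)
}

# Eigenvalue real parts must clear this threshold (from below) for a matrix
# to count as stable; guards the Lyapunov solvers against marginal modes.
STABILITY_TOL <- -1e-12

is_stable <- function(A, tol = STABILITY_TOL) {
  spectral_abscissa(A) < tol
}

mat_exp <- function(A) as.matrix(Matrix::expm(Matrix::Matrix(A, sparse = FALSE)))

## ---- continuous Lyapunov: A'Q + QA + M = 0 --------------------------------

# Eigen-based solve with iterative defect correction; falls back to a dense
# Kronecker solve when A's eigenbasis is too ill-conditioned (strongly
# non-normal A at small n). M need not be symmetric; the result is returned
# as computed (symmetric M yields symmetric Q up to round-off).
lyap_continuous <- function(A, M, tol = 1e-10, max_refine = 3L) {
  assert_square(A)
  n <- nrow(A)
  if (spectral_abscissa(A) >= 0)
    stop("continuous Lyapunov solve requires a stable matrix", call. = FALSE)

  nrmM <- frob(M)
  if (nrmM == 0) return(matrix(0, n, n))

  e <- tryCatch(eigen(A), error = function(err) NULL)
  Q <- NULL
  if (!is.null(e)) {
    V <- e$vectors
    rc <- tryCatch(rcond(abs(V)), error = function(err) 0)
    if (is.finite(rc) && rc > 1e-13) {
      Vi <- tryCatch(solve(V), error = function(err) NULL)
      if (!is.null(Vi)) {
        den <- outer(e$values, e$values, `+`)
        solve_once <- function(Rhs) {
          Y <- -(t(V) %*% Rhs %*% V) / den
          Re(t(Vi) %*% Y %*% Vi)
        }
        Q <- solve_once(M)
        # defect correction: residual of the current iterate feeds back in
        for (k in seq_len(max_refine)) {
          R <- t(A) %*% Q + Q %*% A + M
          if (frob(R) <= tol * nrmM) break
          Q <- Q + solve_once(R)
        }
        if (frob(t(A) %*% Q + Q %*% A + M) > tol * nrmM) Q <- NULL
      }
    }
  }

  if (is.null(Q)) {
    if (n > 70)
      stop("continuous Lyapunov solve failed: eigenbasis ill-conditioned and the dense fallback is limited to n <= 70", call. = FALSE)
    K <- kronecker(diag(n), t(A)) + kronecker(t(A), diag(n))
    Q <- matrix(solve(K, -as.vector(M)), n, n)
    R <- t(A) %*% Q + Q %*% A + M
    # one step of refinement on the dense path too
    if (frob(R) > tol * nrmM)
      Q <- Q + matrix(solve(K, -as.vector(R)), n, n)
  }
  Q
}

## ---- discrete Lyapunov (Stein): X - E X E' = M ----------------------------

# Doubling iteration: X_j = sum_{k < 2^j} E^k M E'^k, E_j = E^(2^j).
# Quadratically convergent for spectral radius < 1 and backward stable even
# for strongly non-normal E (transient growth passes through harmlessly).
lyap_discrete <- function(E, M, tol = 1e-14, max_double = 80L) {
  assert_square(E, "E")
  if (spectral_radius(E) >= 1)
    stop("discrete Lyapunov solve requires spectral radius < 1 (unstable sampled dynamics)", call. = FALSE)
  X <- M
  Ej <- E
  for (j in seq_len(max_double)) {
    Tm <- Ej %*% X %*% t(Ej)
    X <- X + Tm
    if (frob(Tm) <= tol * max(frob(X), .Machine$double.xmin)) return(X)
    Ej <- Ej %*% Ej
    if (max(abs(Ej)) < .Machine$double.xmin) return(X)
  }
  warning("discrete Lyapunov doubling hit the iteration cap; result may be inaccurate")
  X
}

# QR-based row compression: returns R with crossprod(R) == crossprod(X)
# and nrow(R) = min(dim(X)). Uses LAPACK's pivoted Householder QR (dgeqp3)
# and undoes the column pivot, so the result is a plain (not necessarily
# triangular) factor. The LINPACK default is avoided: its qr.R output can
# contain non-finite entries on rank-deficient input.
qr_rows <- function(X) {
  qq <- qr(X, LAPACK = TRUE)
  R <- qr.R(qq)
  R[, order(qq$pivot), drop = FALSE]
}

# Pivoted triangular factor: crossprod(X)[pivot, pivot] == crossprod(R)
# with R upper triangular — use alongside the pivot for permuted
# backsolves.
qr_tri <- function(X) {
  qq <- qr(X, LAPACK = TRUE)
  list(R = qr.R(qq), pivot = qq$pivot)
}

# Column factor J (p x r) of a symmetric PSD matrix with M = J J',
# rank-revealing via symmetric eigendecomposition.
psd_factor_cols <- function(M, rtol = 1e-28) {
  eg <- eigen(sym(M), symmetric = TRUE)
  mx <- max(eg$values, 0)
  if (mx == 0) return(matrix(0, nrow(M), 1L))
  keep <- eg$values > mx * rtol
  eg$vectors[, keep, drop = FALSE] *
    rep(sqrt(eg$values[keep]), each = nrow(M))
}

# Factored Stein accumulation: returns F with
#   F F' = sum_{k >= 0} E^k F0 F0' E'^k
# by doubling on the factor (column-stacking + LQ re-compression). The
# explicit-sum version loses the small-scale entries of graded solutions
# to cancellation; the factored recursion keeps every scale.
stein_factor <- function(E, F0, tol = 1e-14, max_double = 80L) {
  n <- nrow(E)
  if (spectral_radius(E) >= 1)
    stop("factored Stein accumulation requires spectral radius < 1", call. = FALSE)
  compress <- function(F) {
    if (ncol(F) <= n) return(F)
    t(qr_rows(t(F)))
  }
  F <- F0
  Ej <- E
  for (j in seq_len(max_double)) {
    Fnew <- Ej %*% F
    if (frob(Fnew) <= tol * max(frob(F), .Machine$double.xmin)) return(F)
    F <- compress(cbind(F, Fnew))
    Ej <- Ej %*% Ej
    if (max(abs(Ej)) < .Machine$double.xmin) return(F)
  }
  warning("factored Stein accumulation hit the iteration cap")
  F
}

## ---- simplex projection ----------------------------------------------------

# Euclidean projection onto the probability simplex {p >= 0, sum p = 1}.
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}
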