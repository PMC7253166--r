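# Network families and graph manipulations: directed chains whose departure
# from normality is a single dial, an inverse-Wishart random ensemble, and
# the edge-level operations used in the connectome comparisons.
#
# Orientation convention (used package-wide): A[i, j] is the weight of the
# edge j -> i, so dx/dt = A x acts on column state vectors.

#' Directed chain network
#'
#' Builds the tridiagonal connectivity matrix of a linear chain with node
#' decay `gamma` on the diagonal, forward coupling `alpha * beta` on the
#' subdiagonal and backward coupling `beta / alpha` on the superdiagonal.
#' The directionality strength `alpha` controls departure from normality
#' without changing the spectrum (a diagonal similarity rescales it away);
#' `alpha = 1` gives a symmetric, hence normal, graph. Stability requires
#' `gamma < -2 * beta`.
#'
#' Passing a vector for `n` builds a block-diagonal set of shorter chains
#' sharing the same parameters ("chopping" a chain into segments).
#'
#' @param n Chain length (positive integer), or an integer vector of segment
#'   lengths for a block-diagonal set of chains.
#' @param alpha Directionality strength, `> 0`.
#' @param beta Coupling strength, `> 0`.
#' @param gamma Node self-decay (diagonal entry); must satisfy
#'   `gamma < -2 * beta`.
#' @return A stable `sum(n) x sum(n)` connectivity matrix.
#' @examples
#' chain_network(3, alpha = 2, beta = 1, gamma = -2.5)
#' chain_network(c(4, 4), alpha = 7)   # two length-4 segments
#' @export
chain_network <- function(n, alpha = 1, beta = 1, gamma = -2.5) {
  if (any(n < 1) || any(n != round(n))) stop("`n` must be positive integer(s)", call. = FALSE)
  if (alpha <= 0 || beta <= 0) stop("`alpha` and `beta` must be positive", call. = FALSE)
  if (gamma >= -2 * beta)
    stop("stability requires gamma < -2 * beta", call. = FALSE)
  one_chain <- function(len) {
    A <- diag(gamma, len)
    if (len > 1) {
      idx <- seq_len(len - 1)
      A[cbind(idx + 1, idx)] <- alpha * beta   # forward (down the chain)
      A[cbind(idx, idx + 1)] <- beta / alpha   # backward
    }
    A
  }
  blocks <- lapply(as.integer(n), one_chain)
  block_diag(blocks)
}

block_diag <- function(blocks) {
  sizes <- vapply(blocks, nrow, integer(1))
  N <- sum(sizes)
  A <- matrix(0, N, N)
  at <- 0L
  for (b in blocks) {
    ix <- at + seq_len(nrow(b))
    A[ix, ix] <- b
    at <- at + nrow(b)
  }
  A
}

#' Random non-normal network ensemble
#'
#' Draws a stable connectivity matrix `A = (-I + S) P`, where `S` is
#' skew-symmetric with independent `N(0, sigma_S^2)` entries above the
#' diagonal (reflected with a sign flip) and `P` is positive definite drawn
#' from an inverse-Wishart distribution with scale `omega^-2 I` and `nu`
#' degrees of freedom. The defaults `nu = 24 + n` and
#' `omega_sq_inv = nu - n - 1` make `E[P] = I` while leaving the eigenvalues
#' of `P` heterogeneous. `sigma_S` sets the degree of non-normality:
#' `sigma_S = 0` gives the symmetric (normal) matrix `-P`.
#'
#' @param n Network size.
#' @param sigma_S Standard deviation of the skew part's entries (`>= 0`).
#' @param nu Wishart degrees of freedom; must exceed `n + 1`.
#' @param omega_sq_inv Inverse squared scale, `> 0`.
#' @param seed Integer seed; the draw is fully reproducible.
#' @param max_retries Resampling budget should a draw fail positive
#'   definiteness numerically.
#' @return A stable `n x n` matrix.
#' @examples
#' A <- random_nonnormal(8, sigma_S = 2, seed = 1)
#' max(Re(eigen(A)$values)) < 0
#' @export
random_nonnormal <- function(n, sigma_S, nu = 24 + n, omega_sq_inv = nu - n - 1,
                             seed = NULL, max_retries = 10L) {
  if (n < 1) stop("`n` must be positive", call. = FALSE)
  if (sigma_S < 0) stop("`sigma_S` must be nonnegative", call. = FALSE)
  if (nu <= n + 1) stop("`nu` must exceed n + 1 for the inverse-Wishart mean to exist", call. = FALSE)
  if (omega_sq_inv <= 0) stop("`omega_sq_inv` must be positive", call. = FALSE)
  draw <- function() {
    L <- matrix(0, n, n)
    if (n > 1) L[upper.tri(L)] <- stats::rnorm(n * (n - 1) / 2, sd = sigma_S)
    S <- L - t(L)
    P <- NULL
    for (k in seq_len(max_retries)) {
      # inverse-Wishart(scale = omega^-2 I, nu): invert a Wishart draw with
      # the inverted scale
      Wdraw <- stats::rWishart(1, df = nu, Sigma = diag(n) / omega_sq_inv)[, , 1]
      P_try <- tryCatch(chol2inv(chol(Wdraw)), error = function(e) NULL)
      if (!is.null(P_try)) { P <- sym(P_try); break }
    }
    if (is.null(P)) stop("failed to draw a positive definite scale matrix after retries", call. = FALSE)
    (-diag(n) + S) %*% P
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Symmetrize a connectivity matrix
#'
#' Returns `(A + t(A)) / 2`, the normal surrogate used when asking how much
#' of a network's communication performance is owed to directionality.
#'
#' @param A Square matrix.
#' @export
symmetrize <- function(A) {
  assert_square(A)
  sym(A)
}

#' Randomly swap edge directions
#'
#' For each unordered node pair `{i, j}`, exchanges the entries `A[i, j]`
#' and `A[j, i]` independently with probability `p`. The diagonal and the
#' multiset of off-diagonal values are preserved exactly; only directionality
#' is scrambled. With `p = 0.5` this is the direction-randomized null used
#' against real directed networks.
#'
#' @param A Square matrix.
#' @param p Swap probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @export
randomize_directions <- function(A, p = 0.5, seed = NULL) {
  assert_square(A)
  if (p < 0 || p > 1) stop("`p` must lie in [0, 1]", call. = FALSE)
  n <- nrow(A)
  do_swap <- function() {
    out <- A
    ut <- which(upper.tri(A), arr.ind = TRUE)
    if (nrow(ut) == 0) return(out)
    flips <- stats::runif(nrow(ut)) < p
    for (r in which(flips)) {
      i <- ut[r, 1]; j <- ut[r, 2]
      tmp <- out[i, j]; out[i, j] <- out[j, i]; out[j, i] <- tmp
    }
    out
  }
  if (is.null(seed)) do_swap() else withr::with_seed(seed, do_swap())
}

#' Stabilize a matrix by spectral shift
#'
#' Returns the dynamics matrix `(A - gamma I) / tau` together with the shift
#' `gamma = max Re eig(A) - target * tau`, chosen so the slowest mode of the
#' shifted, time-rescaled dynamics decays at exactly `target` (a negative
#' rate). This is the standard way to place an empirical adjacency matrix
#' into a stable linear-dynamics model.
#'
#' @param A Square matrix (any spectrum).
#' @param tau Time constant, `> 0`.
#' @param target Desired largest eigenvalue real part, `< 0`.
#' @return A list with `A_dyn` (the stabilized dynamics matrix) and `gamma`.
#' @export
stabilize_spectrum <- function(A, tau = 0.5, target = -0.1) {
  assert_square(A)
  if (tau <= 0) stop("`tau` must be positive", call. = FALSE)
  if (target >= 0) stop("`target` must be negative", call. = FALSE)
  gamma <- spectral_abscissa(A) - target * tau
  list(A_dyn = (A - gamma * diag(nrow(A))) / tau, gamma = gamma)
}

#' Test matrix normality
#'
#' A matrix is normal when it commutes with its transpose
#' (`A A' == A' A`), equivalently when it is unitarily diagonalizable and
#' the network decomposes into independent scalar channels. The test is
#' relative: the commutator's Frobenius norm must not exceed
#' `tol * ||A||_F^2`.
#'
#' @param A Square matrix.
#' @param tol Relative tolerance.
#' @export
is_normal_matrix <- function(A, tol = 1e-10) {
  assert_square(A)
  nrm <- frob(A)
  if (nrm == 0) return(TRUE)
  comm <- A %*% t(A) - t(A) %*% A
  frob(comm) <= tol * nrm^2
}
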