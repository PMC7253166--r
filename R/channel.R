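# The network communication channel: stable linear dynamics (A), input and
# output node selections (B, C), a transmission window and readout noise.

#' Construct a network communication channel
#'
#' Bundles the pieces of the impulsive communication model: continuous-time
#' stable linear dynamics `dx/dt = A x`, packets injected every `window`
#' time units through the columns of `B`, readout `y = C x` corrupted by
#' independent Gaussian noise of variance `sigma2` per output node.
#'
#' `B` and `C` may be given as full matrices or as integer index vectors
#' (columns/rows of the identity selecting input and output nodes);
#' `NULL` means all nodes (identity).
#'
#' @param A Stable square dynamics matrix (`n x n`).
#' @param B Input matrix (`n x m`), integer node indices, or `NULL`.
#' @param C Output matrix (`p x n`), integer node indices, or `NULL`.
#' @param window Transmission window `T > 0` (time units of `A`).
#' @param sigma2 Readout noise variance, `> 0`. The noiseless regime is not
#'   representable here (the capacity diverges); see [low_noise_rate()].
#' @return An object of class `net_channel`.
#' @examples
#' ch <- net_channel(chain_network(8, alpha = 7), window = 1, sigma2 = 1)
#' @export
net_channel <- function(A, B = NULL, C = NULL, window, sigma2 = 1) {
  assert_square(A)
  n <- nrow(A)
  if (window <= 0) stop("`window` must be positive", call. = FALSE)
  if (sigma2 <= 0) stop("`sigma2` must be positive (the noiseless limit is handled analytically)", call. = FALSE)
  if (!is_stable(A)) stop("`A` must be stable (all eigenvalue real parts < 0)", call. = FALSE)
  B <- selector_matrix(B, n, side = "input")
  C <- selector_matrix(C, n, side = "output")
  if (qr(B)$rank < ncol(B)) warning("`B` is column rank deficient; some input directions are redundant")
  if (qr(C)$rank < nrow(C)) warning("`C` is row rank deficient; some outputs are redundant")
  structure(list(A = A, B = B, C = C, window = window, sigma2 = sigma2,
                 n = n, m = ncol(B), p = nrow(C)),
            class = "net_channel")
}

# Accepts NULL (identity), an index vector, or a matrix. Inputs are columns
# of I, outputs are rows of I.
selector_matrix <- function(X, n, side = c("input", "output")) {
  side <- match.arg(side)
  if (is.null(X)) return(diag(n))
  if (is.matrix(X)) {
    ok <- if (side == "input") nrow(X) == n else ncol(X) == n
    if (!ok) stop(sprintf("selector matrix has wrong %s dimension", side), call. = FALSE)
    return(X)
  }
  idx <- as.integer(X)
  if (any(idx < 1 | idx > n)) stop("selector indices out of range", call. = FALSE)
  I <- diag(n)
  if (side == "input") I[, idx, drop = FALSE] else I[idx, , drop = FALSE]
}

#' @export
print.net_channel <- function(x, ...) {
  cat(sprintf("<net_channel> n = %d nodes, m = %d inputs, p = %d outputs\n",
              x$n, x$m, x$p))
  cat(sprintf("  window T = %g, readout noise sigma^2 = %g\n", x$window, x$sigma2))
  cat(sprintf("  spectral abscissa = %.4g, normal: %s\n",
              spectral_abscissa(x$A), is_normal_matrix(x$A)))
  invisible(x)
}

is_identity <- function(X, tol = 0) {
  is.matrix(X) && nrow(X) == ncol(X) && all(X == diag(nrow(X)))
}

# validate an input covariance against the trace-one PSD constraint set
check_input_covariance <- function(Sigma, m, tol = 1e-9) {
  if (!is.matrix(Sigma)) Sigma <- matrix(Sigma, m, m)
  if (nrow(Sigma) != m || ncol(Sigma) != m)
    stop(sprintf("`Sigma` must be %d x %d", m, m), call. = FALSE)
  Sigma <- sym(Sigma)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("`Sigma` must be positive semidefinite", call. = FALSE)
  Sigma
}
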