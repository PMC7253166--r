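# Diagnostics: effective dimensionality of a covariance and a scalar index
# of matrix non-normality.

#' Participation ratio (effective dimensionality)
#'
#' For a symmetric PSD matrix with eigenvalues `lambda_i`, returns
#' `(sum lambda_i)^2 / sum lambda_i^2`, a number between 1 (rank one) and
#' `n` (all eigenvalues equal). Applied to a covariance it measures how many
#' directions the underlying random vector effectively occupies; the
#' capacity optimizer reports it for the optimal input covariance, which
#' collapses toward 1 in the high-noise regime.
#'
#' @param M Symmetric PSD matrix (nonzero).
#' @return A real in `[1, n]`.
#' @examples
#' participation_ratio(diag(4))          # 4
#' participation_ratio(diag(c(3, 1)))    # 1.6
#' @export
participation_ratio <- function(M) {
  assert_square(M, "M")
  lam <- eigen(sym(M), symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  s2 <- sum(lam^2)
  if (s2 == 0) stop("participation ratio is undefined for the zero matrix", call. = FALSE)
  sum(lam)^2 / s2
}

#' Henrici departure from normality
#'
#' A standard scalar index of non-normality:
#' `sqrt(||A||_F^2 - sum |lambda_i|^2) / ||A||_F`, zero exactly on normal
#' matrices (where the Schur form is diagonal) and growing with the weight
#' of the Schur form's off-diagonal (hidden feedforward) part. Reported as
#' the `"henrici"` index so alternatives can be added later.
#'
#' @param A Square matrix.
#' @return Nonnegative real; 0 iff `A` is normal.
#' @examples
#' nonnormality_index(diag(c(-1, -2)))            # 0
#' nonnormality_index(chain_network(8, alpha = 7)) # > 0
#' @export
nonnormality_index <- function(A) {
  assert_square(A)
  nrm2 <- sum(A^2)
  if (nrm2 == 0) return(0)
  lam <- eigen(A, only.values = TRUE)$values
  dep2 <- max(nrm2 - sum(Mod(lam)^2), 0)
  sqrt(dep2) / sqrt(nrm2)
}
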