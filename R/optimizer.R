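# Maximisation of a smooth objective over the spectraplex
# {Sigma PSD, tr(Sigma) = 1} via the factor parameterisation
# Sigma = F F' / tr(F F'), with multi-restart gradient ascent.

#' Optimizer options
#'
#' @param n_restarts Number of restarts for the nonconvex case (the first
#'   starts from the maximum-entropy covariance `I/m`, the rest from random
#'   factors). The default 20 is a desk-scale setting; raise it (hundreds)
#'   for hard nonconvex instances.
#' @param max_iters Iteration cap per restart.
#' @param rel_tol Relative objective-change stopping tolerance.
#' @param seed Integer seed driving the random restarts; restart `k` uses
#'   `seed + k` so ensembles can derive disjoint streams by offsetting.
#' @param method `"factor-gradient"` (ascent on the factor `F`) is the only
#'   implemented backend; the argument is kept so alternative backends can
#'   sit behind the same contract.
#' @return A list of options.
#' @export
optimizer_options <- function(n_restarts = 20L, max_iters = 400L,
                              rel_tol = 1e-8, seed = 1L,
                              method = "factor-gradient") {
  stopifnot(n_restarts >= 1, max_iters >= 1, rel_tol > 0)
  list(n_restarts = as.integer(n_restarts), max_iters = as.integer(max_iters),
       rel_tol = rel_tol, seed = as.integer(seed),
       method = match.arg(method, "factor-gradient"))
}

#' Maximise an objective over trace-one PSD matrices
#'
#' Each restart parameterises `Sigma = F F' / tr(F F')` with a dense `m x m`
#' factor `F` (feasibility is automatic), ascends the objective by gradient
#' steps with backtracking line search, and stops when the relative
#' objective change falls below `opts$rel_tol`. The best restart wins; ties
#' within `1e-10` go to the lower restart index, making results
#' deterministic given the seed.
#'
#' @param objective Function of an `m x m` symmetric PSD `Sigma` returning a
#'   scalar to maximise. Must be smooth on the interior of the constraint
#'   set.
#' @param m Input dimension.
#' @param opts [optimizer_options()].
#' @param gradient Optional function of `Sigma` returning
#'   `list(value=, grad=)` with the euclidean gradient with respect to
#'   `Sigma`. When absent, central finite differences on the factor are
#'   used (step `1e-6 * max(1, ||F||)`).
#' @return `list(Sigma, value, diagnostics)`; diagnostics carry per-restart
#'   values, iteration counts and convergence flags. Non-convergence in all
#'   restarts yields a flagged best-so-far result, never an error.
#' @examples
#' # linear objective: all mass moves to the dominant direction
#' D <- diag(c(3, 1))
#' out <- optimize_input_covariance(function(S) sum(diag(D %*% S)), m = 2,
#'                                  opts = optimizer_options(n_restarts = 2))
#' out$Sigma
#' @export
optimize_input_covariance <- function(objective, m, opts = optimizer_options(),
                                      gradient = NULL) {
  if (m < 1) stop("`m` must be at least 1", call. = FALSE)
  if (m == 1) {
    S <- matrix(1, 1, 1)
    return(list(Sigma = S, value = objective(S),
                diagnostics = list(n_restarts = 0L, converged = TRUE,
                                   restart_values = numeric(0), iterations = 0L)))
  }

  inits <- vector("list", opts$n_restarts)
  inits[[1]] <- diag(m) / sqrt(m)
  if (opts$n_restarts > 1) {
    for (k in 2:opts$n_restarts) {
      inits[[k]] <- withr::with_seed(opts$seed + k,
                                     matrix(stats::rnorm(m * m), m, m))
    }
  }

  runs <- lapply(inits, function(F0)
    ascend_factor(objective, gradient, F0, opts))
  values <- vapply(runs, function(r) r$value, numeric(1))
  best <- which(values >= max(values) - 1e-10)[1]

  list(Sigma = runs[[best]]$Sigma,
       value = runs[[best]]$value,
       diagnostics = list(
         n_restarts = opts$n_restarts,
         converged = runs[[best]]$converged,
         any_converged = any(vapply(runs, function(r) r$converged, logical(1))),
         restart_values = values,
         best_restart = best,
         iterations = runs[[best]]$iterations))
}

# Gradient ascent on the factor F (normalised to unit Frobenius norm each
# iteration so Sigma = F F' exactly). The Sigma-gradient G maps to the
# factor gradient 2 (G - tr(G Sigma) I) F, the projection of the ambient
# gradient onto the trace-one constraint.
ascend_factor <- function(objective, gradient, F0, opts) {
  F <- F0 / max(frob(F0), .Machine$double.eps)
  sigma_of <- function(F) sym(tcrossprod(F))
  eval_at <- function(F) {
    S <- sigma_of(F)
    if (is.null(gradient)) {
      list(value = objective(S), grad = NULL)
    } else {
      gradient(S)
    }
  }
  fd_factor_grad <- function(F, fval) {
    h <- 1e-6 * max(1, frob(F))
    G <- matrix(0, nrow(F), ncol(F))
    for (i in seq_len(nrow(F))) for (j in seq_len(ncol(F))) {
      Fp <- F; Fp[i, j] <- Fp[i, j] + h
      Fm <- F; Fm[i, j] <- Fm[i, j] - h
      G[i, j] <- (objective(sigma_of(Fp / frob(Fp))) -
                  objective(sigma_of(Fm / frob(Fm)))) / (2 * h)
    }
    G
  }
  cur <- eval_at(F)
  f <- cur$value
  step <- 1
  converged <- FALSE
  it <- 0L
  while (it < opts$max_iters) {
    it <- it + 1L
    GF <- if (is.null(gradient)) {
      fd_factor_grad(F, f)
    } else {
      S <- sigma_of(F)
      G <- cur$grad
      2 * (G %*% F - sum(G * S) * F)
    }
    gnorm <- frob(GF)
    if (gnorm <= 1e-14 * max(1, abs(f))) { converged <- TRUE; break }
    improved <- FALSE
    for (bt in 1:40) {
      F_new <- F + step * GF
      F_new <- F_new / frob(F_new)
      cand <- eval_at(F_new)
      if (cand$value > f + 1e-14) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }
    df <- cand$value - f
    F <- F_new; cur <- cand; f <- cand$value
    step <- step * 1.6
    if (df <= opts$rel_tol * max(abs(f), 1e-12)) { converged <- TRUE; break }
  }
  list(Sigma = sigma_of(F), value = f, converged = converged, iterations = it)
}

#' Convexity certificate for the capacity objective
#'
#' The capacity maximisation is a convex problem whenever
#' `C'C >= exp(A'T) C'C exp(A T)` in the PSD order (the one-window
#' propagator does not amplify output energy). When the certificate holds a
#' single ascent from the maximum-entropy initialisation reaches the global
#' maximum; otherwise multiple restarts are used. The test accepts minimum
#' eigenvalues of the difference down to `-1e-10`.
#'
#' @param A Stable square matrix.
#' @param C Output matrix (`NULL` for identity).
#' @param window Transmission window.
#' @return Logical.
#' @export
convexity_certificate <- function(A, C = NULL, window) {
  assert_square(A)
  n <- nrow(A)
  if (is.null(C)) C <- diag(n)
  if (!is.matrix(C)) C <- matrix(C, ncol = n)
  CtC <- crossprod(C)
  E <- mat_exp(A * window)
  Dm <- sym(CtC - t(E) %*% CtC %*% E)
  min(eigen(Dm, symmetric = TRUE, only.values = TRUE)$values) >= -1e-10
}
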