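# The capacity engine: log-determinant evaluation of the per-packet mutual
# information for a fixed Gaussian input covariance, its maximisation over
# the trace-one PSD set, the scalar closed form, the normal-network rate
# bound, and the low- and high-noise asymptotics.

LN2 <- log(2)

#' Capacity of a scalar (single-node) channel
#'
#' Closed form for one node with decay rate `a` (`A = -a`), unit input and
#' output, input power `power` and readout noise `sigma2`:
#' `C_T = 0.5 * log2((2 a sigma2 + p) / (2 a sigma2 + p exp(-2 a T)))` bits.
#' With `power = 1` this is the basic single-node capacity; it grows with
#' `T`, saturating at `0.5 * log2(1 + p / (2 a sigma2))`, and vanishes as
#' `a -> 0` or `a -> Inf` (interference- and SNR-limited extremes).
#'
#' @param a Decay rate, `> 0`.
#' @param sigma2 Readout noise variance, `> 0`.
#' @param window Transmission window `T > 0`.
#' @param power Input power allocated to the node (trace share), `> 0`.
#' @return Capacity in bits.
#' @examples
#' scalar_capacity(1, 1, 1)   # about 0.245 bits
#' @export
scalar_capacity <- function(a, sigma2, window, power = 1) {
  if (any(a <= 0) || any(sigma2 <= 0) || any(window <= 0) || any(power <= 0))
    stop("`a`, `sigma2`, `window`, `power` must be positive", call. = FALSE)
  0.5 * log2((2 * a * sigma2 + power) / (2 * a * sigma2 + power * exp(-2 * a * window)))
}

#' Rate ceiling for normal networks
#'
#' No normal network with trace `trace_A < 0` can exceed the rate
#' `(1 / ln 2) * tr(A) / (2 sigma2 tr(A) - 1)` bits per unit time, whatever
#' its detailed wiring; the bound is approached with all nodes transmitting
#' and receiving in the small-window limit. In the low-SNR regime it
#' degenerates to `1 / (2 ln 2 sigma2)`, independent of the network.
#'
#' @param trace_A Trace of the (stable, normal) connectivity matrix, `< 0`.
#' @param sigma2 Readout noise variance, `> 0`.
#' @return Bound in bits per unit time.
#' @export
normal_rate_bound <- function(trace_A, sigma2) {
  if (any(trace_A >= 0)) stop("`trace_A` must be negative", call. = FALSE)
  if (any(sigma2 <= 0)) stop("`sigma2` must be positive", call. = FALSE)
  (1 / LN2) * trace_A / (2 * sigma2 * trace_A - 1)
}

#' Low-noise information rate
#'
#' In the low-noise regime the rate of any stable network approaches
#' `-tr(A) / ln 2` bits per unit time: only the spectrum matters, and
#' non-normality brings no advantage. The same value is the large-
#' directionality limit of the chain family at any noise level.
#'
#' @param A Stable square matrix.
#' @return Bits per unit time.
#' @export
low_noise_rate <- function(A) {
  assert_square(A)
  -sum(diag(A)) / LN2
}

#' High-noise information rate asymptotic
#'
#' As `sigma2 -> Inf` the rate decays as
#' `lambda_max(B' O B) / (2 ln 2 T sigma2)`, where `lambda_max(B' O B)` is
#' the maximum energy the network can autonomously generate at the outputs
#' over one window from a unit input — the quantity transient amplification
#' in non-normal networks inflates. The optimal input is then effectively
#' one-dimensional, aligned with the top eigenvector of `B' O B`.
#'
#' @param ch A [net_channel()].
#' @return Bits per unit time.
#' @export
high_noise_rate <- function(ch) {
  stopifnot(inherits(ch, "net_channel"))
  O <- observability_gramian(ch$A, ch$C, ch$window)
  M <- sym(t(ch$B) %*% O %*% ch$B)
  lmax <- max(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  lmax / (2 * LN2 * ch$window * ch$sigma2)
}

## ---- objective evaluation --------------------------------------------------

# Precompute the Sigma-independent pieces of the objective for one channel.
# O is carried as a factor O = Ro' Ro (balanced Cholesky, eigen fallback for
# singular O): under strong transient amplification O is heavily graded
# (entries spanning tens of orders of magnitude) and its symmetric square
# root loses the small-scale directions entirely, while a balanced
# triangular factor keeps every scale at full relative accuracy.
capacity_workspace <- function(ch) {
  E <- mat_exp(ch$A * ch$window)
  Ro <- obs_gramian_factor(ch$A, crossprod(ch$C), ch$window)
  list(E = E, O = crossprod(Ro), Ro = Ro, n = ch$n, m = ch$m,
       B = ch$B, sigma2 = ch$sigma2)
}

# Objective value: 0.5 * log2 det(s2 I + O W) / det(s2 I + O (W - G)).
#
# Numerics: the interference covariance W - G equals E W E' exactly (the
# Stein recursion shifted by one window), so it is computed directly as the
# solution of X - E X E' = E G E' rather than by subtraction; and with
# O = Ro' Ro the ratio of determinants is evaluated in one pass as
#   det(I + L^-T (Ro G Ro') L^-1),  L'L = s2 I + Ro (W-G) Ro'
# (det(s2 I + O X) = det(s2 I + Ro X Ro') by the push-through identity)
# via symmetric eigenvalues and log1p. This stays accurate both under
# strong transient amplification and in the high-noise regime (capacity
# ~ 1e-7 bits), where subtracting two large log-determinants loses
# everything.
objective_value <- function(ws, Sigma) {
  parts <- objective_parts(ws, Sigma)
  val <- sum(log1p(parts$lambda)) / (2 * LN2)
  if (!is.finite(val)) stop("capacity objective is non-finite (pathological conditioning)", call. = FALSE)
  val
}

# Everything stays in factored (square-root) form: with Sigma = Js Js',
# Jg = B Js, the interference covariance W - G = Fw Fw' accumulates on the
# factor, the denominator s2 I + Ro (W-G) Ro' gets its triangular factor
# Rd from a QR of stacked factors (square-root filtering), and the
# objective eigenvalues are squared singular values of Rd^-T (Ro Jg).
# Explicit Gram products of graded factors would lose the weakly amplified
# directions to cancellation.
objective_parts <- function(ws, Sigma) {
  Js <- psd_factor_cols(Sigma)
  Jg <- ws$B %*% Js
  Fw <- stein_factor(ws$E, ws$E %*% Jg)
  ro <- nrow(ws$Ro)
  Mw <- ws$Ro %*% Fw
  Mh <- ws$Ro %*% Jg
  den <- qr_tri(rbind(sqrt(ws$sigma2) * diag(ro), t(Mw)))
  # denS[pv, pv] = R'R, so the whitened signal factor is R^-T Mh[pv, ]
  X <- backsolve(den$R, Mh[den$pivot, , drop = FALSE], transpose = TRUE)
  lam <- svd(X, nu = 0, nv = 0)$d^2
  list(lambda = lam, Mh = Mh, den = den)
}

# Value and analytic gradient with respect to Sigma. The gradient of each
# log-determinant passes through the Stein equation for W; the chain rule
# collapses into two adjoint Stein solves:
#   d logdet(s2 I + O W)        = tr(Phi dG),  Phi  - E' Phi  E = M_N
#   d logdet(s2 I + O (W - G))  = tr(Psi dG),  Psi = Psi0 - M_D,
#                                 Psi0 - E' Psi0 E = M_D
# with M_N = (s2 I + O W)^-1 O = Ro' (s2 I + Ro W Ro')^-1 Ro by the
# push-through identity (SPD middle solve, accurate for graded O), M_D
# likewise, and grad_Sigma = B' (Phi - Psi) B / (2 ln 2).
objective_value_grad <- function(ws, Sigma) {
  parts <- objective_parts(ws, Sigma)
  val <- sum(log1p(parts$lambda)) / (2 * LN2)
  den <- parts$den
  # numerator factor in the denominator's pivoted coordinates:
  # numS[pv, pv] = Rd'Rd + Mh[pv, ] Mh[pv, ]'
  num <- qr_tri(rbind(den$R, t(parts$Mh[den$pivot, , drop = FALSE])))
  num_pivot <- den$pivot[num$pivot]

  # solve S Y = B through a pivoted triangular factor S[pv, pv] = R'R
  tri_solve2 <- function(R, pv, B) {
    Z <- backsolve(R, backsolve(R, B[pv, , drop = FALSE], transpose = TRUE))
    out <- Z
    out[pv, ] <- Z
    out
  }
  MN <- sym(t(ws$Ro) %*% tri_solve2(num$R, num_pivot, ws$Ro))
  MD <- sym(t(ws$Ro) %*% tri_solve2(den$R, den$pivot, ws$Ro))
  Phi <- lyap_discrete(t(ws$E), MN)
  Psi <- lyap_discrete(t(ws$E), MD) - MD
  grad <- sym(t(ws$B) %*% (Phi - Psi) %*% ws$B) / (2 * LN2)
  list(value = val, grad = grad)
}

#' Mutual information for a fixed input covariance
#'
#' Evaluates the per-packet mutual information (in bits) transmitted by the
#' channel when packets are zero-mean Gaussian with covariance `Sigma`:
#' half the base-2 log-ratio of the output covariance determinant with and
#' without the current packet, where intersymbol interference
#' (`W - B Sigma B'`) and readout noise make up the denominator.
#'
#' @param ch A [net_channel()].
#' @param Sigma Input covariance (`m x m` PSD). The trace-one constraint is
#'   not enforced here, so sub-unit powers can be explored directly.
#' @return Nonnegative mutual information in bits.
#' @examples
#' ch <- net_channel(matrix(-1), window = 1, sigma2 = 1)
#' capacity_given_input(ch, matrix(1))  # equals scalar_capacity(1, 1, 1)
#' @export
capacity_given_input <- function(ch, Sigma) {
  stopifnot(inherits(ch, "net_channel"))
  Sigma <- sym(as.matrix(Sigma))
  objective_value(capacity_workspace(ch), Sigma)
}

## ---- capacity optimisation -------------------------------------------------

#' Information capacity of a network channel
#'
#' Maximises the per-packet mutual information over all zero-mean Gaussian
#' encodings with `tr(Sigma) = 1` (the input power constraint binds at the
#' optimum because the objective is nondecreasing in power). Dispatch:
#'
#' * `m = 1`: the constraint fixes `Sigma = 1`; no search.
#' * symmetric `A` with `B = C = I`: the network decomposes into independent
#'   scalar channels along the eigenmodes; the capacity reduces to a concave
#'   power-allocation problem on the probability simplex, solved by
#'   projected gradient ascent (globally optimal).
#' * otherwise: multi-restart factor-gradient ascent over `Sigma = FF'/tr(FF')`
#'   (see [optimize_input_covariance()]); a single restart is used when the
#'   convexity certificate holds.
#'
#' @param ch A [net_channel()].
#' @param opts Optimizer options from [optimizer_options()].
#' @return A `capacity_result` with fields `capacity_bits`,
#'   `rate_bits_per_time`, `Sigma_opt`, `n_restarts_used`, `converged`,
#'   `convex_certificate`, `input_dimensionality` (participation ratio of
#'   the optimal covariance) and `method`.
#' @examples
#' ch <- net_channel(diag(c(-0.5, -1)), window = 1, sigma2 = 1)
#' res <- capacity(ch)
#' res$capacity_bits
#' @export
capacity <- function(ch, opts = optimizer_options()) {
  stopifnot(inherits(ch, "net_channel"))
  ws <- capacity_workspace(ch)
  cert <- convexity_certificate(ch$A, ch$C, ch$window)

  if (ch$m == 1) {
    Sigma <- matrix(1, 1, 1)
    val <- objective_value(ws, Sigma)
    return(new_capacity_result(val, Sigma, ch, n_restarts_used = 0L,
                               converged = TRUE, cert = cert, method = "scalar"))
  }

  if (is_identity(ch$B) && is_identity(ch$C) &&
      frob(ch$A - t(ch$A)) <= 1e-12 * max(frob(ch$A), 1)) {
    out <- capacity_symmetric_identity(ch, opts)
    return(new_capacity_result(out$value, out$Sigma, ch, n_restarts_used = 1L,
                               converged = out$converged, cert = cert,
                               method = "eigenmode-allocation"))
  }

  n_restarts <- if (cert) 1L else opts$n_restarts
  run_opts <- opts
  run_opts$n_restarts <- n_restarts
  out <- optimize_input_covariance(
    objective = function(S) objective_value(ws, S),
    m = ch$m, opts = run_opts,
    gradient = function(S) objective_value_grad(ws, S)
  )
  new_capacity_result(out$value, out$Sigma, ch,
                      n_restarts_used = out$diagnostics$n_restarts,
                      converged = out$diagnostics$converged, cert = cert,
                      method = "factor-gradient",
                      diagnostics = out$diagnostics)
}

#' @rdname capacity
#' @details `information_rate()` returns the same object; the rate
#'   `R_T = C_T / T` is a field of every `capacity_result`.
#' @export
information_rate <- function(ch, opts = optimizer_options()) {
  capacity(ch, opts)
}

# Power allocation over eigenmodes of a symmetric A with B = C = I:
# maximize sum_i scalar_capacity(a_i, s2, T, p_i) over the simplex. The
# per-mode objective is concave in p, so projected gradient ascent from the
# uniform allocation finds the global optimum.
capacity_symmetric_identity <- function(ch, opts) {
  eg <- eigen(sym(ch$A), symmetric = TRUE)
  a <- -eg$values            # decay rates, all > 0 by stability
  s2 <- ch$sigma2
  Tw <- ch$window
  ee <- exp(-2 * a * Tw)
  fval <- function(p) sum(0.5 * log2((2 * a * s2 + p) / (2 * a * s2 + p * ee)))
  fgrad <- function(p) (1 / (2 * LN2)) * (1 / (2 * a * s2 + p) - ee / (2 * a * s2 + p * ee))
  n <- length(a)
  p <- rep(1 / n, n)
  f <- fval(p)
  step <- 1
  converged <- FALSE
  for (it in seq_len(opts$max_iters)) {
    g <- fgrad(p)
    improved <- FALSE
    for (bt in 1:40) {
      p_new <- project_simplex(p + step * g)
      f_new <- fval(p_new)
      if (f_new > f + 1e-14) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }
    if (f_new - f <= opts$rel_tol * max(abs(f), 1e-12) && it > 3) {
      p <- p_new; f <- f_new; converged <- TRUE; break
    }
    p <- p_new; f <- f_new
    step <- step * 1.8
  }
  Sigma <- sym(eg$vectors %*% (p * t(eg$vectors)))
  list(value = f, Sigma = Sigma, converged = converged)
}

new_capacity_result <- function(value, Sigma, ch, n_restarts_used, converged,
                                cert, method, diagnostics = NULL) {
  structure(list(
    capacity_bits = value,
    rate_bits_per_time = value / ch$window,
    Sigma_opt = Sigma,
    window = ch$window,
    sigma2 = ch$sigma2,
    n_restarts_used = n_restarts_used,
    converged = converged,
    convex_certificate = cert,
    input_dimensionality = if (frob(Sigma) > 0) participation_ratio(Sigma) else NA_real_,
    method = method,
    diagnostics = diagnostics
  ), class = "capacity_result")
}

#' @export
print.capacity_result <- function(x, ...) {
  cat(sprintf("<capacity_result> C_T = %.6g bits, R_T = %.6g bits/time (T = %g, sigma^2 = %g)\n",
              x$capacity_bits, x$rate_bits_per_time, x$window, x$sigma2))
  cat(sprintf("  method: %s, restarts: %d, converged: %s, convex certificate: %s\n",
              x$method, x$n_restarts_used, x$converged, x$convex_certificate))
  cat(sprintf("  effective input dimensionality: %.3g\n", x$input_dimensionality))
  invisible(x)
}

## ---- rate over windows -----------------------------------------------------

#' Maximum information rate over transmission windows
#'
#' Evaluates `R_T = C_T / T` on a grid of windows, then refines around the
#' best interior grid point by golden-section search. Normal networks peak
#' at the boundary (smallest window); sufficiently non-normal ones attain an
#' interior maximum at a finite, realistic window — the result is flagged
#' accordingly.
#'
#' @param ch A [net_channel()]; its own `window` is ignored.
#' @param windows Strictly positive, sorted grid of windows `T`.
#' @param opts Optimizer options.
#' @param refine_tol Relative window tolerance of the golden-section
#'   refinement.
#' @return A list with `R_max`, `T_opt`, `boundary` (`TRUE` when the
#'   maximum sits at the smallest grid point) and `curve`, a tibble with
#'   one row per grid point (`window`, `capacity_bits`, `rate`, `n_eff`,
#'   `converged`).
#' @export
max_rate <- function(ch, windows = exp(seq(log(0.05), log(10), length.out = 15)),
                     opts = optimizer_options(), refine_tol = 1e-4) {
  stopifnot(inherits(ch, "net_channel"))
  windows <- sort(windows)
  if (any(windows <= 0)) stop("`windows` must be strictly positive", call. = FALSE)
  rate_at <- function(Tw) {
    res <- capacity(channel_with_window(ch, Tw), opts)
    res
  }
  results <- lapply(windows, rate_at)
  rates <- vapply(results, function(r) r$rate_bits_per_time, numeric(1))
  curve <- tibble::tibble(
    window = windows,
    capacity_bits = vapply(results, function(r) r$capacity_bits, numeric(1)),
    rate = rates,
    n_eff = vapply(results, function(r) r$input_dimensionality, numeric(1)),
    converged = vapply(results, function(r) r$converged, logical(1))
  )
  i <- which.max(rates)
  boundary <- i == 1L
  T_opt <- windows[i]
  R_max <- rates[i]
  if (!boundary && i < length(windows)) {
    gs <- golden_section(function(Tw) rate_at(Tw)$rate_bits_per_time,
                         windows[i - 1], windows[i + 1], tol = refine_tol)
    if (gs$value > R_max) { R_max <- gs$value; T_opt <- gs$x }
  }
  list(R_max = R_max, T_opt = T_opt, boundary = boundary, curve = curve)
}

channel_with_window <- function(ch, window) {
  ch$window <- window
  ch
}

golden_section <- function(f, lo, hi, tol = 1e-4, max_iter = 60L) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- f(x1); f2 <- f(x2)
  for (i in seq_len(max_iter)) {
    if ((hi - lo) <= tol * max(abs(lo), abs(hi))) break
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- f(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- f(x1)
    }
  }
  if (f1 >= f2) list(x = x1, value = f1) else list(x = x2, value = f2)
}
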