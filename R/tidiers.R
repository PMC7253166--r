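# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a capacity result
#'
#' One row per eigenmode of the optimal input covariance: the power
#' allocated to each orthogonal input direction, in decreasing order, with
#' its cumulative share. This is the spectral view of how the optimizer
#' distributes the unit input power.
#'
#' @param x A `capacity_result`.
#' @param ... Unused.
#' @return A tibble with columns `mode`, `power`, `cumulative_share`.
#' @method tidy capacity_result
#' @export
tidy.capacity_result <- function(x, ...) {
  lam <- pmax(eigen(sym(x$Sigma_opt), symmetric = TRUE, only.values = TRUE)$values, 0)
  tibble::tibble(mode = seq_along(lam), power = lam,
                 cumulative_share = cumsum(lam) / sum(lam))
}

#' Glance at a capacity result
#'
#' @param x A `capacity_result`.
#' @param ... Unused.
#' @return A one-row tibble with the capacity (bits), rate (bits per unit
#'   time), window, noise variance, effective input dimensionality and
#'   optimizer diagnostics.
#' @method glance capacity_result
#' @export
glance.capacity_result <- function(x, ...) {
  tibble::tibble(capacity_bits = x$capacity_bits,
                 rate_bits_per_time = x$rate_bits_per_time,
                 window = x$window, sigma2 = x$sigma2,
                 input_dimensionality = x$input_dimensionality,
                 n_restarts_used = x$n_restarts_used,
                 converged = x$converged,
                 convex_certificate = x$convex_certificate,
                 method = x$method)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a rate curve
#'
#' @param object A `rate_curve` from [rate_sweep()] (several curves with
#'   distinct labels may be row-bound and plotted together).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rate_curve
#' @export
autoplot.rate_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$window, y = .data$rate,
                                       colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "transmission window T", y = "information rate (bits / time)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an ensemble curve with its confidence band
#'
#' @param object An `ensemble_curve` from [randomized_ensemble()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ensemble_curve
#' @export
autoplot.ensemble_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$window, y = .data$mean_rate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         fill = "lightblue", alpha = 0.6) +
    ggplot2::geom_line(linetype = "dotdash") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "transmission window T",
                  y = "mean information rate (bits / time)") +
    ggplot2::theme_minimal()
}
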