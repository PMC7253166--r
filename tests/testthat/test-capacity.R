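test_that("the full pipeline reduces to the scalar closed form on 1x1 channels", {
  worst <- 0
  for (a in c(0.5, 1, 2)) for (s2 in c(0.1, 1, 10)) for (Tw in c(0.1, 1, 5)) {
    ch <- net_channel(matrix(-a), window = Tw, sigma2 = s2)
    worst <- max(worst, abs(capacity_given_input(ch, matrix(1)) -
                            scalar_capacity(a, s2, Tw)))
  }
  expect_lt(worst, 1e-9)
})

test_that("scalar capacity has the expected limits", {
  expect_equal(scalar_capacity(1, 1, 1), 0.5 * log2(3 / (2 + exp(-2))))
  # saturation at long windows
  expect_equal(scalar_capacity(1, 1, 200, power = 0.7),
               0.5 * log2(1 + 0.7 / 2), tolerance = 1e-12)
  # vanishing at both extremes of the decay rate
  expect_lt(scalar_capacity(1e-8, 1, 1), 1e-7)
  expect_lt(scalar_capacity(1e8, 1, 1), 1e-7)
})

test_that("mutual information vanishes for zero input and decomposes over diagonal modes", {
  ch <- net_channel(diag(c(-1, -2)), window = 1, sigma2 = 1)
  expect_equal(capacity_given_input(ch, matrix(0, 2, 2)), 0)
  p <- c(0.7, 0.3)
  expect_equal(capacity_given_input(ch, diag(p)),
               sum(scalar_capacity(c(1, 2), 1, 1, p)), tolerance = 1e-10)
})

test_that("identical uncoupled nodes get equal power and additive capacity", {
  ch <- net_channel(diag(-1, 4), window = 1, sigma2 = 1)
  res <- capacity(ch, fast_opts())
  expect_equal(res$Sigma_opt, diag(4) / 4, tolerance = 1e-6)
  expect_equal(res$capacity_bits, 4 * scalar_capacity(1, 1, 1, 1 / 4),
               tolerance = 1e-9)
  expect_equal(res$input_dimensionality, 4, tolerance = 1e-6)
})

test_that("optimized capacity matches the simplex-grid oracle for diagonal dynamics", {
  a <- c(0.5, 1, 2)
  ch <- net_channel(diag(-a), window = 1, sigma2 = 1)
  res <- capacity(ch, fast_opts())
  oracle <- simplex_grid_capacity(a, 1, 1, step = 0.01)
  expect_gte(res$capacity_bits + 1e-9, oracle)   # grid can only undershoot
  expect_lt(res$capacity_bits - oracle, 1e-4)
  # the generic factor-gradient path lands on the same optimum
  gen <- optimize_input_covariance(
    function(S) capacity_given_input(ch, S), m = 3,
    opts = fast_opts(n_restarts = 2, seed = 5),
    gradient = NULL)
  expect_equal(gen$value, res$capacity_bits, tolerance = 1e-5)
})

test_that("capacity grows with SNR and with additional output nodes", {
  A <- random_stable(4, 1301)
  caps <- vapply(c(4, 1, 0.25), function(s2)
    capacity(net_channel(A, window = 1, sigma2 = s2), fast_opts())$capacity_bits,
    numeric(1))
  expect_true(all(diff(caps) > 0))
  for (p in 1:3) {
    c_small <- capacity(net_channel(A, C = 1:p, window = 1, sigma2 = 1),
                        fast_opts())$capacity_bits
    c_big <- capacity(net_channel(A, C = 1:(p + 1), window = 1, sigma2 = 1),
                      fast_opts())$capacity_bits
    expect_gte(c_big + 1e-7, c_small)
  }
})

test_that("single-input channels skip the search and rate relates to capacity", {
  A <- random_stable(3, 1401)
  ch <- net_channel(A, B = 2, window = 0.7, sigma2 = 1)
  res <- capacity(ch)
  expect_identical(res$n_restarts_used, 0L)
  expect_equal(res$Sigma_opt, matrix(1))
  expect_equal(res$rate_bits_per_time * ch$window, res$capacity_bits)
  r2 <- information_rate(ch)
  expect_equal(r2$rate_bits_per_time, res$rate_bits_per_time)
})

test_that("single-node rate declines with the window toward the short-window optimum", {
  ch <- net_channel(matrix(-1), window = 1, sigma2 = 1)
  mr <- max_rate(ch, windows = exp(seq(log(0.01), log(5), length.out = 12)))
  expect_true(mr$boundary)
  expect_true(all(diff(mr$curve$rate) < 0))
  # short-window limit a / (ln 2 (1 + 2 a sigma2))
  expect_equal(mr$R_max, (1 / log(2)) / 3, tolerance = 0.01)
})

test_that("non-normal chains peak at an interior window above the normal chain", {
  grid <- exp(seq(log(0.05), log(10), length.out = 12))
  mr1 <- max_rate(net_channel(chain_network(8, alpha = 1), window = 1, sigma2 = 1),
                  windows = grid, opts = fast_opts())
  mr7 <- max_rate(net_channel(chain_network(8, alpha = 7), window = 1, sigma2 = 1),
                  windows = grid, opts = fast_opts())
  expect_true(mr1$boundary)
  expect_false(mr7$boundary)
  expect_gt(mr7$R_max, mr1$R_max)
})

test_that("normal-network rate bound evaluates correctly and caps symmetric channels", {
  expect_equal(normal_rate_bound(-20, 1), (1 / log(2)) * 20 / 41)
  # large-noise collapse: bound ~ 1/(2 ln2 sigma2), connectivity-independent
  expect_equal(normal_rate_bound(-5, 1e3), 1 / (2 * log(2) * 1e3), tolerance = 1e-3)
  expect_equal(normal_rate_bound(-50, 1e3), 1 / (2 * log(2) * 1e3), tolerance = 1e-3)
  for (seed in 1:5) {
    A <- random_stable_symmetric(5, 1500 + seed)
    bound <- normal_rate_bound(sum(diag(A)), 1)
    for (Tw in c(0.2, 1, 3)) {
      r <- capacity(net_channel(A, window = Tw, sigma2 = 1), fast_opts())
      expect_lte(r$rate_bits_per_time, bound + 1e-9)
    }
  }
})

test_that("low-noise rate equals -tr(A)/ln2 and the chain evaluates to gamma*n", {
  expect_equal(low_noise_rate(chain_network(8, gamma = -2.5)), 20 / log(2))
  A <- random_stable(5, 1601)
  expect_equal(low_noise_rate(A), -sum(diag(A)) / log(2))
})

test_that("high-noise asymptotic reduces to the scalar energy formula", {
  a <- 0.8; Tw <- 1.1; s2 <- 50
  ch <- net_channel(matrix(-a), window = Tw, sigma2 = s2)
  expect_equal(high_noise_rate(ch),
               (1 - exp(-2 * a * Tw)) / (4 * a * log(2) * Tw * s2),
               tolerance = 1e-10)
})

test_that("chain rate is invariant to the coupling strength in the high-noise regime", {
  grid <- exp(seq(log(0.1), log(5), length.out = 8))
  r1 <- max_rate(net_channel(chain_network(6, alpha = 4, beta = 0.6), window = 1,
                             sigma2 = 1e5), windows = grid, opts = fast_opts())$R_max
  r2 <- max_rate(net_channel(chain_network(6, alpha = 4, beta = 1.2), window = 1,
                             sigma2 = 1e5), windows = grid, opts = fast_opts())$R_max
  expect_equal(r1, r2, tolerance = 0.15)
})

test_that("channel constructor validates inputs", {
  expect_error(net_channel(matrix(1), window = 1), "stable")
  expect_error(net_channel(matrix(-1), window = 0), "window")
  expect_error(net_channel(matrix(-1), window = 1, sigma2 = 0), "sigma2")
  expect_warning(net_channel(diag(-1, 3), B = matrix(c(1, 1, 0, 1, 1, 0), 3, 2),
                             window = 1), "rank deficient")
})

test_that("capacity results tidy and glance into well-formed tibbles", {
  res <- capacity(net_channel(diag(c(-0.5, -1)), window = 1, sigma2 = 1), fast_opts())
  td <- generics::tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2)
  expect_equal(sum(td$power), 1, tolerance = 1e-9)
  gl <- generics::glance(res)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("capacity_bits", "rate_bits_per_time", "converged") %in% names(gl)))
})
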