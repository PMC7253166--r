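test_that("the synthetic fixture satisfies the connectome schema invariants", {
  cn <- synthetic_connectome(30, seed = 1)
  expect_s3_class(cn, "connectome")
  expect_length(cn$node_ids, 30)
  expect_setequal(unique(cn$node_class), c("sensory", "inter", "motor"))
  counts <- table(cn$node_class)
  expect_equal(as.numeric(counts[c("sensory", "inter", "motor")]) / 30,
               c(88, 82, 107) / 277, tolerance = 0.06)
  inh <- cn$node_ids %in% cn$inhibitory
  expect_true(all(cn$A_signed[, inh] <= 0))
  expect_true(all(cn$A_signed[, !inh] >= 0))
  expect_true(all(cn$A_signed == round(cn$A_signed)))
  expect_identical(synthetic_connectome(30, seed = 1)$A_signed, cn$A_signed)
})

test_that("edge and class files round-trip through load_connectome", {
  cn <- synthetic_connectome(25, seed = 7, directionality = 2)
  ed <- tempfile(fileext = ".csv"); cl <- tempfile(fileext = ".csv")
  write_connectome(cn, ed, cl)
  cn2 <- load_connectome(ed, cl)
  ord <- match(cn$node_ids, cn2$node_ids)
  expect_equal(unname(cn2$A_signed[ord, ord]), unname(cn$A_signed))
  expect_setequal(cn2$inhibitory, cn$inhibitory)
})

test_that("loading applies orientation, signs, duplicate-summing and validation", {
  ed <- tempfile(); cl <- tempfile()
  writeLines(c("pre,post,weight", "a,b,3"), ed)
  writeLines(c("id,class,gabaergic", "a,sensory,0", "b,motor,0"), cl)
  cn <- load_connectome(ed, cl)
  expect_equal(cn$A_signed["b", "a"], 3)
  expect_equal(cn$A_signed["a", "b"], 0)

  writeLines(c("id,class,gabaergic", "a,sensory,1", "b,motor,0"), cl)
  cn_inh <- load_connectome(ed, cl)
  expect_equal(cn_inh$A_signed["b", "a"], -3)

  writeLines(c("pre,post,weight", "a,b,3", "a,b,2"), ed)
  expect_message(cn_dup <- load_connectome(ed, cl), "summed")
  expect_equal(cn_dup$A_signed["b", "a"], -5)

  writeLines(c("pre,post,weight", "a,zz,3"), ed)
  expect_error(load_connectome(ed, cl), "missing from the class table")
  writeLines(c("pre,post,weight", "a,b,-3"), ed)
  expect_error(load_connectome(ed, cl), "nonnegative")
})

test_that("stabilized dynamics hit the spectral target for fixtures and manipulations", {
  for (seed in 1:5) {
    cn <- synthetic_connectome(20, seed = seed)
    st <- stabilized_dynamics(cn)
    expect_equal(max(Re(eigen(st$A_dyn, only.values = TRUE)$values)), -0.1,
                 tolerance = 1e-9)
    sw <- randomize_directions(cn$A_signed, p = 0.5, seed = seed)
    st2 <- stabilize_spectrum(sw)
    expect_equal(max(Re(eigen(st2$A_dyn, only.values = TRUE)$values)), -0.1,
                 tolerance = 1e-9)
  }
})

test_that("class selectors build unit selectors; random selectors are disjoint", {
  cn <- synthetic_connectome(24, seed = 3)
  sel <- class_selectors(cn, "sensory", "motor")
  m <- sum(cn$node_class == "sensory"); p <- sum(cn$node_class == "motor")
  expect_equal(dim(sel$B), c(24, m))
  expect_equal(dim(sel$C), c(p, 24))
  expect_true(all(colSums(sel$B) == 1) && all(sel$B %in% c(0, 1)))
  expect_true(all(rowSums(sel$C) == 1))
  # sensory inputs and motor outputs touch disjoint node sets
  expect_equal(sum(rowSums(sel$B) * colSums(sel$C)), 0)
  all_sel <- class_selectors(cn, "all", "all")
  expect_equal(all_sel$B, diag(24))
  expect_equal(all_sel$C, diag(24))
  rs <- random_selectors(cn, 8, 10, seed = 2)
  expect_equal(sum(rowSums(rs$B) * colSums(rs$C)), 0)
  expect_identical(random_selectors(cn, 8, 10, seed = 2)$B, rs$B)
})

test_that("rate sweeps are nonnegative and dominated by the full communication setting", {
  cn <- synthetic_connectome(18, seed = 9, directionality = 3)
  st <- stabilized_dynamics(cn)
  grid <- c(0.2, 0.7, 2)
  opts <- fast_opts(n_restarts = 2)
  full <- rate_sweep(st$A_dyn, NULL, NULL, grid, 1, opts, "full")
  expect_s3_class(full, "rate_curve")
  expect_true(all(full$rate >= 0))
  sel <- class_selectors(cn, "sensory", "motor")
  sub <- rate_sweep(st$A_dyn, sel$B, sel$C, grid, 1, opts, "sensory-motor")
  expect_true(all(full$rate + 1e-9 >= sub$rate))
})

test_that("strong feedforward structure is destroyed by symmetrization", {
  cn <- synthetic_connectome(22, seed = 12, directionality = 6, density = 0.15)
  grid <- exp(seq(log(0.1), log(4), length.out = 6))
  opts <- fast_opts(n_restarts = 2)
  dir_curve <- rate_sweep(stabilized_dynamics(cn)$A_dyn, NULL, NULL, grid, 1, opts)
  sym_curve <- rate_sweep(stabilize_spectrum(symmetrize(cn$A_signed))$A_dyn,
                          NULL, NULL, grid, 1, opts)
  expect_gt(max(dir_curve$rate), max(sym_curve$rate))
})

test_that("randomized ensembles aggregate curves with sane confidence bands", {
  cn <- synthetic_connectome(16, seed = 5, directionality = 3, density = 0.12)
  grid <- c(0.3, 1, 3)
  opts <- fast_opts(n_restarts = 2)
  ens <- randomized_ensemble(cn, "direction-swap", n_real = 4, windows = grid,
                             seed = 8, opts = opts)
  expect_s3_class(ens, "ensemble_curve")
  expect_true(all(ens$ci_low <= ens$mean_rate & ens$mean_rate <= ens$ci_high))
  expect_length(attr(ens, "gammas"), 4)
  # zero swap probability: all realizations identical, zero-width band
  ens0 <- randomized_ensemble(cn, "direction-swap", n_real = 3, windows = grid,
                              seed = 8, swap_prob = 0, opts = opts)
  expect_equal(ens0$ci_high - ens0$ci_low, rep(0, 3), tolerance = 1e-12)
  ens_bc <- randomized_ensemble(cn, "random-BC", n_real = 3, windows = grid,
                                seed = 9, opts = opts)
  expect_true(all(is.finite(ens_bc$mean_rate)))
})

test_that("confidence bands shrink with the number of realizations", {
  cn <- synthetic_connectome(14, seed = 21, directionality = 2, density = 0.15)
  grid <- c(0.5, 1.5)
  opts <- fast_opts(n_restarts = 1)
  w <- function(n_real) {
    e <- randomized_ensemble(cn, "random-BC", n_real = n_real, windows = grid,
                             seed = 31, opts = opts)
    mean(e$ci_high - e$ci_low)
  }
  w10 <- w(10); w40 <- w(40)
  # 1/sqrt(n) scaling: expected ratio 2, allow the sd-estimate noise of
  # small ensembles
  expect_lt(w40, w10)
  expect_gt(w10 / w40, 1.2)
  expect_lt(w10 / w40, 3.5)
})
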