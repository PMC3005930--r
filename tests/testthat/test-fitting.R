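test_that("derivative error is near zero at the generating parameters", {
  # densely sampled noiseless simulation: spline derivatives track the model
  bench <- generate_benchmark(synthetic_spec(
    n_genes = 3, n_series = 4, n_timepoints = 50, seed = 11))
  sp <- fit_splines(bench$data)
  cfg <- fit_config()
  duration <- 6 * 4  # t_end * n_series
  for (gm in bench$model$genes) {
    expect_lt(derivative_error(gm, sp, cfg), 1e-3 * duration)
  }
})

test_that("derivative error vanishes exactly for a null model on constant data", {
  d <- make_series(list(a = function(t) rep(5, length(t)),
                        b = function(t) rep(2, length(t))), times = 0:5)
  sp <- fit_splines(d)
  params <- gene_model("a", 0, 0, 0, c(b = 0))
  expect_identical(derivative_error(params, sp, fit_config()), 0)
})

test_that("quadrature is converged at the default density", {
  # generic (non-optimal) parameters give a smooth O(1) residual, the regime
  # the integral accuracy matters in; at the truth E0 is dominated by
  # sub-grid spline wiggle and its relative error is uninformative
  rb <- recovery_benchmark()
  gm <- gene_model("g1", 5, 1, -2, c(g2 = 0.05, g3 = -0.1))
  e5 <- derivative_error(gm, rb$splines, fit_config(quadrature_points_per_interval = 5))
  e10 <- derivative_error(gm, rb$splines, fit_config(quadrature_points_per_interval = 10))
  expect_lt(abs(e10 - e5) / e5, 1e-3)
})

test_that("L1 error obeys its defining identities", {
  rb <- recovery_benchmark()
  sp <- rb$splines
  params <- gene_model("g1", 5, 1, -2, c(g2 = 0.05, g3 = -0.1))
  cfg0 <- fit_config(penalty_c = 0)
  expect_identical(l1_error(params, sp, cfg0), derivative_error(params, sp, cfg0))
  nopen <- gene_model("g1", 5, 1, -2, c(g2 = 0, g3 = 0))
  cfg2 <- fit_config(penalty_c = 2)
  expect_identical(l1_error(nopen, sp, cfg2), derivative_error(nopen, sp, cfg2))
  # hand arithmetic: c = 2, |weights| sum to 0.15, so E1 = E0 + 0.3
  e0 <- derivative_error(params, sp, cfg2)
  expect_equal(l1_error(params, sp, cfg2), e0 + 2 * 0.15, tolerance = 1e-12)
})

test_that("trajectory error is zero for the generator and grows when perturbed", {
  ring <- ring_fixture()
  e_true <- trajectory_error(ring$model, ring$data)
  expect_lt(e_true, 1e-8 * nrow(ring$data))
  zero_model <- network_model("g", list(gene_model("g", 0, 0, 0)))
  zero_data <- make_series(list(g = function(t) rep(0, length(t))), times = 0:5)
  expect_equal(trajectory_error(zero_model, zero_data), 0)
  perturbed <- ring$model
  gm <- perturbed$genes[["g1"]]
  gm$decay <- gm$decay * 1.5
  perturbed$genes[["g1"]] <- gm
  expect_gt(trajectory_error(perturbed, ring$data), e_true)
})

test_that("fit_gene recovers a one-regulator gene from noiseless data", {
  ring <- ring_fixture()
  cfg <- fit_config(n_starts = 25, seed = 5)
  fit <- fit_gene(ring$splines, "g2", "g1", cfg)
  true_w <- ring$model$genes[["g2"]]$weights[["g1"]]
  expect_equal(sign(fit$params$weights[["g1"]]), sign(true_w))
  expect_lt(fit$error_E0,
            derivative_error(ring$model$genes[["g2"]], ring$splines, cfg) + 1e-6)
})

test_that("an unregulated fit recovers the decay rate of pure-decay data", {
  d <- make_series(list(g = function(t) 4 * exp(-t)),
                   times = seq(0, 3, length.out = 16))
  sp <- fit_splines(d)
  cfg <- fit_config(n_starts = 25, seed = 2)
  fit <- fit_gene(sp, "g", character(0), cfg)
  expect_equal(fit$params$decay, 1, tolerance = 0.05)
  expect_lt(fit$params$production * sigmoid(fit$params$bias), 0.05)
})

test_that("fitting is deterministic given the seed", {
  ring <- ring_fixture()
  cfg <- fit_config(n_starts = 10, seed = 99)
  f1 <- fit_gene(ring$splines, "g1", c("g2", "g3"), cfg)
  f2 <- fit_gene(ring$splines, "g1", c("g2", "g3"), cfg)
  expect_identical(tidy(f1), tidy(f2))
  expect_identical(f1$start_errors, f2$start_errors)
  expect_identical(f1$best_start_index, f2$best_start_index)
})

test_that("the joint error decomposes exactly into per-gene errors", {
  rb <- recovery_benchmark()
  joint <- network_derivative_error(rb$fit$model, rb$splines, rb$config)
  per_gene <- sum(vapply(rb$fit$fits, `[[`, numeric(1), "error_E0"))
  expect_equal(joint, per_gene, tolerance = 1e-12)
  # and for the generating model too
  joint_true <- network_derivative_error(rb$bench$model, rb$splines, rb$config)
  sum_true <- sum(vapply(rb$bench$model$genes, derivative_error,
                         numeric(1), splines = rb$splines, config = rb$config))
  expect_equal(joint_true, sum_true, tolerance = 1e-12)
})

test_that("per-gene fits are independent of target order", {
  ring <- ring_fixture()
  cfg <- fit_config(n_starts = 8, seed = 3)
  f_fwd <- fit_network(ring$splines, targets = c("g1", "g2", "g3"), config = cfg)
  f_rev <- fit_network(ring$splines, targets = c("g3", "g1", "g2"), config = cfg)
  for (g in c("g1", "g2", "g3")) {
    expect_identical(tidy(f_fwd$fits[[g]]), tidy(f_rev$fits[[g]]))
  }
})

test_that("the optimizer at least matches the truth on its own objective", {
  rb <- recovery_benchmark()
  for (g in names(rb$fit$fits)) {
    e_truth <- derivative_error(rb$bench$model$genes[[g]], rb$splines, rb$config)
    expect_lte(rb$fit$fits[[g]]$error_E0, e_truth + 1e-6)
  }
})

test_that("fit_gene beats or ties an 11-point parameter lattice", {
  ring <- ring_fixture()
  b <- parameter_bounds(weight = c(-0.2, 0.2), production = c(0, 25),
                        decay = c(0, 10), bias = -1.0)  # fixed bias
  cfg <- fit_config(bounds = b, n_starts = 25, seed = 4)
  fit <- fit_gene(ring$splines, "g2", "g1", cfg)
  grid_vals <- function(r) seq(r[1], r[2], length.out = 11)
  best_lattice <- Inf
  for (R in grid_vals(b$production)) {
    for (lam in grid_vals(b$decay)) {
      for (w in grid_vals(b$weight)) {
        e <- derivative_error(gene_model("g2", R, lam, -1.0, c(g1 = w)),
                              ring$splines, cfg)
        best_lattice <- min(best_lattice, e)
      }
    }
  }
  expect_lte(fit$error_E0, best_lattice)
})

test_that("weight thresholding follows the strict magnitude rule", {
  m <- network_model(c("a", "b", "c", "t"), list(
    gene_model("t", 1, 1, 0, c(a = 0.005, b = -0.006, c = 0.1))
  ))
  adj <- threshold_weights(m, threshold = 0.006, regulators = c("a", "b", "c"))
  expect_equal(unname(adj[c("a", "b", "c"), "t"]), c(0L, -1L, 1L))
  adj0 <- threshold_weights(m, threshold = 0, regulators = c("a", "b", "c"))
  expect_equal(unname(adj0[c("a", "b", "c"), "t"]), c(1L, -1L, 1L))
  mzero <- network_model(c("a", "t"), list(gene_model("t", 1, 1, 0, c(a = 0))))
  expect_true(all(threshold_weights(mzero, 0.006, regulators = "a") == 0L))
})

test_that("the regularization path reduces to the plain fit at c = 0 and prunes links", {
  expect_length(default_c_grid(), 101)
  expect_equal(default_c_grid()[2] - default_c_grid()[1], 0.1)
  ring <- ring_fixture()
  cfg <- fit_config(n_starts = 8, seed = 6)
  rp <- regularization_path(ring$splines, config = cfg, c_grid = c(0, 10))
  plain <- fit_network(ring$splines, config = cfg)
  expect_equal(rp$path$fit[[1]]$total_E0, plain$total_E0, tolerance = 1e-12)
  for (g in names(plain$fits)) {
    expect_identical(tidy(rp$path$fit[[1]]$fits[[g]]), tidy(plain$fits[[g]]))
  }
  n0 <- rp$path$n_links[rp$path$c == 0]
  n10 <- rp$path$n_links[rp$path$c == 10]
  expect_lte(n10, n0)
  # links surviving the heaviest penalty carry the top confidence ranking
  expect_true(all(diff(rp$link_confidence$max_c) <= 0))
})

test_that("derivative error evaluation never solves the ODE and is faster", {
  rb <- recovery_benchmark()
  gm <- rb$bench$model$genes[[1]]
  reset_ode_solve_count()
  for (i in 1:5) derivative_error(gm, rb$splines, rb$config)
  expect_identical(ode_solve_count(), 0L)
  t_deriv <- system.time({
    for (i in 1:10) derivative_error(gm, rb$splines, rb$config)
  })[["elapsed"]] / 10
  t_traj <- system.time({
    for (i in 1:2) trajectory_error(rb$bench$model, rb$bench$data)
  })[["elapsed"]] / 2
  expect_gt(ode_solve_count(), 0L)  # trajectory error does integrate
  expect_lt(t_deriv, t_traj)
})
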