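test_that("sigmoid forms have the right shape and closed-form values", {
  expect_equal(sigmoid(0, "logistic"), 0.5)
  expect_equal(sigmoid(0, "algebraic"), 0.5)
  for (u in c(0.5, 2, 10)) {
    expect_equal(sigmoid(u, "logistic") + sigmoid(-u, "logistic"), 1)
    expect_equal(sigmoid(u, "algebraic") + sigmoid(-u, "algebraic"), 1)
  }
  expect_equal(sigmoid(1, "logistic"), 0.7310585786, tolerance = 1e-9)
  # saturates without over/underflow in the far tails, stays positive below 1
  expect_gt(sigmoid(-700, "logistic"), 0)
  expect_gt(sigmoid(-700, "algebraic"), 0)
  expect_lte(sigmoid(700, "logistic"), 1)
  # strictly monotone over the numerically responsive range, nondecreasing beyond
  u <- seq(-30, 30, length.out = 301)
  for (kind in c("logistic", "algebraic")) {
    s <- sigmoid(u, kind)
    expect_true(all(s > 0 & s < 1))
    expect_true(all(diff(s) > 0))
    expect_true(all(diff(sigmoid(seq(-700, 700, length.out = 201), kind)) >= 0))
  }
})

test_that("model derivatives match hand evaluation", {
  # production balancing decay: R*sigmoid(0)*... at steady state
  m1 <- network_model("g", list(gene_model("g", 1, 0.5, 0)))
  expect_equal(unname(model_dxdt(m1, c(g = 1))), 0)
  expect_equal(steady_state_residual(m1, c(g = 1)), 0)
  # pure decay
  m2 <- network_model("g", list(gene_model("g", 0, 2, 0)))
  expect_equal(unname(model_dxdt(m2, c(g = 3))), -6)
  # one regulator, u = 0.2*5 - 1 = 0 so dx/dt = 10*0.5 - 1*2 = 3
  m3 <- network_model(c("r", "g"),
                      list(gene_model("g", 10, 1, -1, c(r = 0.2))))
  expect_equal(unname(model_dxdt(m3, c(r = 5, g = 2))), 3)
  expect_error(model_dxdt(m3, c(g = 2)), "one value per gene")
})

test_that("simulation reproduces closed-form decay and constant dynamics", {
  m <- network_model("g", list(gene_model("g", 0, 1, 0)))
  sim <- simulate_model(m, c(g = 4), times = c(0, 1, 2))
  expect_equal(sim$value, 4 * exp(-c(0, 1, 2)), tolerance = 1e-6)
  m0 <- network_model("g", list(gene_model("g", 0, 0, 0)))
  sim0 <- simulate_model(m0, c(g = 4), times = c(0, 1, 2))
  expect_equal(sim0$value, rep(4, 3))
})

test_that("fixed-step integration agrees with a hand-coded RK4 oracle", {
  model <- mutual_repression_model()
  x0 <- c(a = 2, b = 7)
  sim <- simulate_model(model, x0, times = c(0, 5), method = "rk4", step = 0.01)
  terminal <- sim$value[sim$time == 5]
  names(terminal) <- sim$gene[sim$time == 5]
  oracle <- rk4_oracle(mutual_repression_rhs(), unname(x0), 5, step = 0.001)
  expect_lt(max(abs(terminal[c("a", "b")] - oracle)), 1e-4)
})

test_that("halving the RK4 step shrinks terminal error at 4th order", {
  model <- mutual_repression_model()
  x0 <- c(a = 2, b = 7)
  ref <- rk4_oracle(mutual_repression_rhs(), unname(x0), 4, step = 0.0005)
  terminal <- function(step) {
    sim <- simulate_model(model, x0, times = c(0, 4), method = "rk4", step = step)
    sim$value[sim$time == 4]
  }
  e_coarse <- max(abs(terminal(0.2) - ref))
  e_fine <- max(abs(terminal(0.1) - ref))
  expect_gte(e_coarse / e_fine, 8)
})

test_that("trajectories stay bounded by production/decay balance", {
  bench <- recovery_benchmark()$bench
  xmax <- vapply(bench$model$genes, function(gm) gm$production / gm$decay,
                 numeric(1))
  by_gene <- dplyr::summarise(dplyr::group_by(bench$data, .data$gene),
                              mx = max(.data$value), mn = min(.data$value))
  expect_true(all(by_gene$mn >= 0))
  # bounded by max(x0, R/lambda); x0 was drawn within [0, R/lambda]
  expect_true(all(by_gene$mx <= xmax[by_gene$gene] + 1e-6))
})

test_that("perturbed steady states relax back toward rest", {
  model <- mutual_repression_model()
  sim <- simulate_model(model, c(a = 5, b = 5), times = seq(0, 30, by = 5))
  end_state <- stats::setNames(sim$value[sim$time == 30], sim$gene[sim$time == 30])
  expect_lt(steady_state_residual(model, end_state), 1e-4)
  pert <- end_state + c(2, -1)
  r0 <- steady_state_residual(model, pert)
  expect_gt(r0, 0.1)
  relax <- simulate_model(model, pert, times = c(0, 2, 4))
  mid <- stats::setNames(relax$value[relax$time == 4], relax$gene[relax$time == 4])
  expect_lt(steady_state_residual(model, mid), r0)
})

test_that("exogenous genes follow their supplied trajectories exactly", {
  model <- network_model(c("r", "g"),
                         list(gene_model("g", 5, 1, -1, c(r = 0.1))))
  exo <- list(r = function(t) 3 + sin(t))
  tms <- seq(0, 4, length.out = 9)
  sim <- simulate_model(model, c(g = 1), tms, exogenous = exo)
  expect_equal(sim$value[sim$gene == "r"], 3 + sin(tms))
  expect_error(simulate_model(model, c(g = 1), tms), "exogenous")
})

test_that("model YAML serialization round-trips", {
  model <- mutual_repression_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_yaml(model, path)
  back <- read_model_yaml(path)
  expect_equal(back$gene_names, model$gene_names)
  expect_equal(back$sigmoid_kind, model$sigmoid_kind)
  expect_equal(tidy(back), tidy(model))
})
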