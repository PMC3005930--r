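# shared fixtures, built once per test run and cached

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# expression tibble from a named list of functions of t
make_series <- function(fns, times, series_id = "s1") {
  purrr::map_dfr(names(fns), function(g) {
    tibble::tibble(gene = g, series = series_id, time = times,
                   value = fns[[g]](times))
  })
}

# the package's standard recovery benchmark: 5 genes, sparse, 20 noiseless
# series, fit with 50 starts and thresholded at 0.006
recovery_benchmark <- function() {
  cached("recovery", {
    bench <- generate_benchmark(synthetic_spec(seed = 101))
    splines <- fit_splines(bench$data)
    config <- fit_config(n_starts = 50, seed = 1)
    fit <- fit_network(splines, config = config)
    adjacency <- threshold_weights(fit, threshold = 0.006)
    list(bench = bench, splines = splines, config = config,
         fit = fit, adjacency = adjacency,
         metrics = compare_networks(bench$gold, adjacency))
  })
}

# a hand-built 3-gene repressilator-style ring (g1 -| g2 -| g3 -| g1),
# every gene with exactly one regulator, parameters inside irma_gnw bounds
ring_fixture <- function() {
  cached("ring", {
    genes <- c("g1", "g2", "g3")
    model <- network_model(genes, list(
      gene_model("g1", 12, 1.2, -1.5, c(g3 = -0.12)),
      gene_model("g2", 10, 1.0, -1.0, c(g1 = -0.10)),
      gene_model("g3", 14, 1.5, -2.0, c(g2 = 0.15))
    ))
    data <- withr::with_seed(7, purrr::map_dfr(1:8, function(i) {
      x0 <- stats::setNames(stats::runif(3, 0, 10), genes)
      simulate_model(model, x0, seq(0, 6, length.out = 16),
                     series_id = sprintf("r%d", i))
    }))
    gold <- signed_adjacency(
      matrix(c(0L, 0L, -1L, -1L, 0L, 0L, 0L, 1L, 0L), 3, 3,
             dimnames = list(genes, genes)),
      autoregulation = FALSE)
    list(model = model, data = data, gold = gold,
         splines = fit_splines(data))
  })
}

# brute-force not-a-knot cubic spline: solves the full 4(n-1)-unknown linear
# system (interpolation + C1/C2 continuity + third-derivative continuity at
# the second and penultimate knots) directly — independent of the package's
# tridiagonal construction
brute_force_nak <- function(x, y) {
  n <- length(x)
  np <- n - 1
  A <- matrix(0, 4 * np, 4 * np)
  b <- numeric(4 * np)
  row <- 0
  idx <- function(j) (j - 1) * 4 + 1:4   # coefficients a0..a3 of piece j
  for (j in seq_len(np)) {
    h <- x[j + 1] - x[j]
    row <- row + 1; A[row, idx(j)] <- c(1, 0, 0, 0); b[row] <- y[j]
    row <- row + 1; A[row, idx(j)] <- c(1, h, h^2, h^3); b[row] <- y[j + 1]
  }
  for (j in seq_len(np - 1)) {
    h <- x[j + 1] - x[j]
    row <- row + 1
    A[row, idx(j)] <- c(0, 1, 2 * h, 3 * h^2)
    A[row, idx(j + 1)] <- c(0, -1, 0, 0)
    row <- row + 1
    A[row, idx(j)] <- c(0, 0, 2, 6 * h)
    A[row, idx(j + 1)] <- c(0, 0, -2, 0)
  }
  row <- row + 1
  A[row, idx(1)] <- c(0, 0, 0, 6); A[row, idx(2)] <- c(0, 0, 0, -6)
  row <- row + 1
  A[row, idx(np - 1)] <- c(0, 0, 0, 6); A[row, idx(np)] <- c(0, 0, 0, -6)
  coef <- solve(A, b)
  function(t, deriv = 0) {
    j <- pmin(pmax(findInterval(t, x, rightmost.closed = TRUE), 1), np)
    vapply(seq_along(t), function(i) {
      a <- coef[idx(j[i])]
      dt <- t[i] - x[j[i]]
      switch(as.character(deriv),
             "0" = a[1] + a[2] * dt + a[3] * dt^2 + a[4] * dt^3,
             "1" = a[2] + 2 * a[3] * dt + 3 * a[4] * dt^2)
    }, numeric(1))
  }
}

# classical fixed-step RK4, hand-coded
rk4_oracle <- function(f, x0, t_end, step) {
  x <- x0
  t <- 0
  n <- round(t_end / step)
  for (i in seq_len(n)) {
    k1 <- f(t, x)
    k2 <- f(t + step / 2, x + step / 2 * k1)
    k3 <- f(t + step / 2, x + step / 2 * k2)
    k4 <- f(t + step, x + step * k3)
    x <- x + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + step
  }
  x
}

# the 2-gene mutual-repression model used by the integrator tests
mutual_repression_model <- function() {
  network_model(c("a", "b"), list(
    gene_model("a", 10, 1, -1, c(b = -0.15)),
    gene_model("b", 8, 0.8, -0.5, c(a = -0.12))
  ))
}

mutual_repression_rhs <- function() {
  model <- mutual_repression_model()
  function(t, x) {
    names(x) <- c("a", "b")
    unname(model_dxdt(model, x))
  }
}
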