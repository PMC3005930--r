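#' Parameter bounds for the sigmoid gene model
#'
#' Box constraints used both to bound the optimizer and to draw its random
#' starts. Two presets reflect the two data conventions: `"drosophila"`
#' (protein data on the native 0-255 scale: weights in \[-0.1, 0.1\],
#' production in \[0, 25\], decay in \[0, 10\], bias fixed at -3.5) and
#' `"irma_gnw"` (mRNA data rescaled to \[0, 100\]: weights in \[-0.2, 0.2\],
#' production in \[0, 25\], decay in \[0, 10\], bias in \[-25, 25\]).
#'
#' @param weight,production,decay Length-2 numeric ranges.
#' @param bias Length-2 range, or a single number to fix the bias.
#' @return A `parameter_bounds` list.
#' @export
parameter_bounds <- function(weight = c(-0.2, 0.2), production = c(0, 25),
                             decay = c(0, 10), bias = c(-25, 25)) {
  chk <- function(r, nm) {
    if (length(r) == 2 && r[1] > r[2]) stop("invalid ", nm, " range: lo > hi")
    r
  }
  structure(list(weight = chk(weight, "weight"),
                 production = chk(production, "production"),
                 decay = chk(decay, "decay"),
                 bias = chk(bias, "bias")),
            class = "parameter_bounds")
}

#' @rdname parameter_bounds
#' @param preset `"irma_gnw"` or `"drosophila"`.
#' @export
bounds_preset <- function(preset = c("irma_gnw", "drosophila")) {
  preset <- match.arg(preset)
  switch(preset,
    irma_gnw = parameter_bounds(weight = c(-0.2, 0.2), production = c(0, 25),
                                decay = c(0, 10), bias = c(-25, 25)),
    drosophila = parameter_bounds(weight = c(-0.1, 0.1), production = c(0, 25),
                                  decay = c(0, 10), bias = -3.5)
  )
}

#' Fitting configuration
#'
#' Collects every tunable of the gradient-matching fit. Defaults follow the
#' method's standard settings: 1000 random multi-starts, weight-zero
#' threshold 0.006 on the fitted scale, trapezoid quadrature with 5
#' subdivisions per knot interval, no L1 penalty.
#'
#' @param preset Bounds preset name (see [bounds_preset()]), used when
#'   `bounds` is not given.
#' @param bounds A `parameter_bounds` (overrides `preset`).
#' @param n_starts Number of random optimizer starts per gene (>= 1).
#' @param seed Integer seed governing all start draws.
#' @param quadrature_points_per_interval Trapezoid subdivisions per knot
#'   interval (>= 1).
#' @param penalty_c Nonnegative L1 penalty constant `c`.
#' @param weight_zero_threshold Magnitude below which a fitted weight is
#'   called zero.
#' @param autoregulation Allow self-links when choosing default regulator
#'   sets.
#' @param sigmoid_kind `"logistic"` or `"algebraic"`.
#' @return A `fit_config` list.
#' @export
fit_config <- function(preset = "irma_gnw", bounds = NULL, n_starts = 1000,
                       seed = 1, quadrature_points_per_interval = 5,
                       penalty_c = 0, weight_zero_threshold = 0.006,
                       autoregulation = FALSE,
                       sigmoid_kind = c("logistic", "algebraic")) {
  sigmoid_kind <- match.arg(sigmoid_kind)
  bounds <- bounds %||% bounds_preset(preset)
  stopifnot(n_starts >= 1, quadrature_points_per_interval >= 1,
            penalty_c >= 0, weight_zero_threshold >= 0)
  bias_fixed <- if (length(bounds$bias) == 1) bounds$bias else NULL
  structure(list(bounds = bounds, n_starts = as.integer(n_starts),
                 seed = as.integer(seed),
                 quadrature_points_per_interval =
                   as.integer(quadrature_points_per_interval),
                 penalty_c = penalty_c,
                 weight_zero_threshold = weight_zero_threshold,
                 bias_fixed = bias_fixed,
                 autoregulation = isTRUE(autoregulation),
                 sigmoid_kind = sigmoid_kind),
            class = "fit_config")
}

# Precompute the quadrature design from fitted splines: a stacked grid over
# all series with trapezoid weights, spline values X and spline derivatives D
# (rows = grid points, columns = genes). The fitting objective touches only
# these matrices — no ODE solving.
fit_design <- function(splines, config) {
  if (inherits(splines, "fit_design")) return(splines)
  stopifnot(inherits(splines, "spline_fit"))
  q <- config$quadrature_points_per_interval
  genes <- splines$fits[[1]]$genes
  parts <- lapply(splines$fits, function(sfit) {
    knots <- sfit$knots
    grid <- sort(unique(unlist(
      lapply(seq_len(length(knots) - 1L), function(i) {
        seq(knots[i], knots[i + 1], length.out = q + 1L)
      })
    )))
    d <- diff(grid)
    w <- c(d / 2, 0) + c(0, d / 2)
    list(w = w,
         X = spline_eval_matrix(sfit, grid, deriv = 0),
         D = spline_eval_matrix(sfit, grid, deriv = 1))
  })
  structure(list(genes = genes,
                 w = unlist(lapply(parts, `[[`, "w")),
                 X = do.call(rbind, lapply(parts, `[[`, "X")),
                 D = do.call(rbind, lapply(parts, `[[`, "D"))),
            class = "fit_design")
}

# objective + analytic gradient for one gene's derivative-based error,
# optionally L1-penalized. Parameter vector: (R, lambda, [h], T_1..T_k).
make_objective <- function(design, target, regulators, config) {
  if (!target %in% design$genes) stop("no trajectory for target '", target, "'")
  missing_reg <- setdiff(regulators, design$genes)
  if (length(missing_reg) > 0) {
    stop("no trajectory for regulator(s): ", paste(missing_reg, collapse = ", "))
  }
  w <- design$w
  xg <- design$X[, target]
  dg <- design$D[, target]
  Xr <- design$X[, regulators, drop = FALSE]
  kind <- config$sigmoid_kind
  cpen <- config$penalty_c
  free_h <- is.null(config$bias_fixed)
  k <- length(regulators)
  off <- 2L + as.integer(free_h)

  unpack <- function(p) {
    list(R = p[1], lam = p[2],
         h = if (free_h) p[3] else config$bias_fixed,
         Tw = if (k > 0) p[(off + 1L):(off + k)] else numeric(0))
  }
  e0 <- function(p) {
    q <- unpack(p)
    u <- if (k > 0) as.vector(Xr %*% q$Tw) + q$h else rep(q$h, length(xg))
    r <- dg - (q$R * sigmoid(u, kind) - q$lam * xg)
    sum(w * r * r)
  }
  fn <- function(p) {
    q <- unpack(p)
    e0(p) + cpen * sum(abs(q$Tw))
  }
  gr <- function(p) {
    q <- unpack(p)
    u <- if (k > 0) as.vector(Xr %*% q$Tw) + q$h else rep(q$h, length(xg))
    s <- sigmoid(u, kind)
    r <- dg - (q$R * s - q$lam * xg)
    common <- 2 * w * r
    g <- c(-sum(common * s), sum(common * xg))
    if (free_h || k > 0) sp <- sigmoid_deriv(u, kind)
    if (free_h) g <- c(g, -q$R * sum(common * sp))
    if (k > 0) {
      gT <- -q$R * as.vector(crossprod(Xr, common * sp)) + cpen * sign(q$Tw)
      g <- c(g, gT)
    }
    g
  }
  b <- config$bounds
  lower <- c(b$production[1], b$decay[1],
             if (free_h) b$bias[1], rep(b$weight[1], k))
  upper <- c(b$production[2], b$decay[2],
             if (free_h) b$bias[2], rep(b$weight[2], k))
  list(fn = fn, gr = gr, e0 = e0, lower = lower, upper = upper,
       free_h = free_h, k = k, unpack = unpack)
}

#' Derivative-based (gradient-matching) error of one gene model
#'
#' The squared discrepancy, integrated over each trajectory and summed over
#' trajectories, between the spline-estimated derivative of the target gene
#' and the model's dynamics function evaluated along the spline
#' trajectories:
#' `E0 = sum_i int (dyhat_g/dt - f_g(yhat(t)))^2 dt`.
#' The integral uses composite trapezoid quadrature on a uniform subgrid of
#' each knot interval. No ODE is solved.
#'
#' @param params A [gene_model()].
#' @param splines A `spline_fit` (or precomputed internal design).
#' @param config A [fit_config()].
#' @return Nonnegative scalar `E0`.
#' @export
derivative_error <- function(params, splines, config = fit_config()) {
  design <- fit_design(splines, config)
  regs <- names(params$weights)
  obj <- make_objective(design, params$target, regs, config)
  p <- c(params$production, params$decay,
         if (obj$free_h) params$bias, unname(params$weights))
  if (!obj$free_h && !isTRUE(all.equal(params$bias, config$bias_fixed))) {
    # honour the model's own bias even under a fixed-bias config
    cfg2 <- config
    cfg2$bias_fixed <- params$bias
    obj <- make_objective(design, params$target, regs, cfg2)
  }
  obj$e0(p)
}

#' L1-regularized error of one gene model
#'
#' `E1 = E0 + c * sum |T_gg'|`: the derivative-based error plus an L1
#' penalty on the regulatory weights only (production, decay and bias are
#' not penalized).
#'
#' @inheritParams derivative_error
#' @param penalty_c Optional override of `config$penalty_c`.
#' @return Nonnegative scalar `E1`.
#' @export
l1_error <- function(params, splines, config = fit_config(), penalty_c = NULL) {
  cpen <- penalty_c %||% config$penalty_c
  derivative_error(params, splines, config) + cpen * sum(abs(params$weights))
}

#' Trajectory-based error of a network model
#'
#' The classical ODE-fitting criterion: each series is simulated from its
#' first observation (`x(t_0) = y(t_0)`) and the squared difference between
#' simulated and observed expression of the modeled genes is summed over all
#' observation times and series. Requires one numerical integration per
#' series, which is what the derivative-based error avoids.
#'
#' @param model A `network_model`.
#' @param data Expression tibble covering all model genes.
#' @param splines Optional `spline_fit` of `data`, used for exogenous-gene
#'   trajectories (fitted on the fly if absent).
#' @return Nonnegative scalar.
#' @export
trajectory_error <- function(model, data, splines = NULL) {
  data <- check_expression(data)
  mg <- modeled_genes(model)
  exo <- setdiff(model$gene_names, mg)
  if (length(exo) > 0 && is.null(splines)) splines <- fit_splines(data)
  total <- 0
  for (sid in unique(data$series)) {
    sub <- data[data$series == sid, ]
    tms <- sort(unique(sub$time))
    obs <- tidyr::pivot_wider(sub, id_cols = "time", names_from = "gene",
                              values_from = "value")
    obs <- obs[order(obs$time), ]
    x0 <- stats::setNames(as.numeric(obs[1, model$gene_names]), model$gene_names)
    exf <- if (length(exo) > 0) exogenous_from_splines(splines, sid, exo) else NULL
    sim <- simulate_model(model, x0, tms, exogenous = exf, series_id = sid)
    simw <- tidyr::pivot_wider(sim, id_cols = "time", names_from = "gene",
                               values_from = "value")
    simw <- simw[order(simw$time), ]
    total <- total +
      sum((as.matrix(simw[, mg]) - as.matrix(obs[, mg]))^2)
  }
  total
}

# deterministic per-(target, regulator-set) start seed so that per-gene fits
# are independent of execution order and identical whether run alone, inside
# fit_network, or inside an enumeration
start_seed <- function(seed, target, regulators) {
  key <- paste(c(target, sort(regulators)), collapse = "|")
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  (as.integer(seed) * 10007L + as.integer(h %% 100003L)) %% 2147483647L
}

#' Fit one gene's model by multi-start bounded optimization
#'
#' Minimizes the (optionally L1-penalized) derivative-based error over
#' `(R, lambda, h, T)` within the configured bounds, from `n_starts`
#' random starts drawn uniformly within the bounds; the lowest-error start
#' wins (ties to the lowest start index). Weights of genes outside
#' `regulators` are structurally zero. With a fixed-bias preset, `h` is not
#' optimized.
#'
#' @param splines A `spline_fit` (or precomputed design).
#' @param target Target gene label.
#' @param regulators Character vector of candidate regulators (possibly
#'   empty).
#' @param config A [fit_config()].
#' @return A `gene_fit`: the fitted [gene_model()] plus `error_E0`,
#'   `error_E1`, per-start errors, the winning start index and the fraction
#'   of starts that converged.
#' @export
fit_gene <- function(splines, target, regulators = character(0),
                     config = fit_config()) {
  design <- fit_design(splines, config)
  regulators <- as.character(regulators)
  if (!config$autoregulation && target %in% regulators) {
    stop("autoregulation is disabled but '", target, "' regulates itself")
  }
  obj <- make_objective(design, target, regulators, config)
  np <- length(obj$lower)
  ns <- config$n_starts
  starts <- withr::with_seed(
    start_seed(config$seed, target, regulators),
    matrix(stats::runif(ns * np, min = rep(obj$lower, each = ns),
                        max = rep(obj$upper, each = ns)), nrow = ns)
  )
  values <- rep(NA_real_, ns)
  conv <- rep(NA, ns)
  pars <- vector("list", ns)
  for (i in seq_len(ns)) {
    res <- tryCatch(
      stats::optim(starts[i, ], fn = obj$fn, gr = obj$gr, method = "L-BFGS-B",
                   lower = obj$lower, upper = obj$upper,
                   control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    values[i] <- res$value
    conv[i] <- res$convergence == 0
    pars[[i]] <- res$par
  }
  ok <- which(!is.na(values))
  if (length(ok) == 0) stop("all optimizer starts failed for gene '", target, "'")
  best <- ok[which.min(values[ok])]
  p <- pars[[best]]
  q <- obj$unpack(p)
  gm <- gene_model(target, q$R, q$lam, q$h,
                   stats::setNames(q$Tw, regulators))
  structure(list(
    target = target, regulators = regulators, params = gm,
    error_E0 = obj$e0(p), error_E1 = values[best],
    n_starts_used = ns, best_start_index = best,
    converged_fraction = mean(conv[ok]),
    start_errors = values, config = config
  ), class = "gene_fit")
}

#' @export
print.gene_fit <- function(x, ...) {
  cat("<gene_fit> ", x$target, " ~ {", paste(x$regulators, collapse = ", "),
      "}  E0 = ", format(x$error_E0, digits = 6),
      "  (", x$n_starts_used, " starts)\n", sep = "")
  invisible(x)
}

#' Fit a full network gene-by-gene
#'
#' Because each gene's parameters enter only its own derivative equation,
#' the joint fit decomposes into independent per-gene regressions; this runs
#' [fit_gene()] for every target and assembles the results into a
#' `network_model`. Results are independent of target order.
#'
#' @param splines A `spline_fit`.
#' @param targets Character vector of modeled genes (default: all genes).
#' @param regulator_sets Named list of candidate-regulator vectors per
#'   target; default: all genes, excluding self unless
#'   `config$autoregulation`.
#' @param config A [fit_config()].
#' @return A `network_fit` with elements `fits` (per-gene `gene_fit`s),
#'   `model` (assembled `network_model`), and `total_E0`.
#' @export
fit_network <- function(splines, targets = NULL, regulator_sets = NULL,
                        config = fit_config()) {
  design <- fit_design(splines, config)
  targets <- targets %||% design$genes
  regulator_sets <- regulator_sets %||%
    stats::setNames(lapply(targets, function(g) {
      if (config$autoregulation) design$genes else setdiff(design$genes, g)
    }), targets)
  fits <- lapply(targets, function(g) {
    fit_gene(design, g, regulator_sets[[g]], config)
  })
  names(fits) <- targets
  model <- network_model(design$genes, lapply(fits, `[[`, "params"),
                         sigmoid_kind = config$sigmoid_kind)
  structure(list(fits = fits, model = model,
                 total_E0 = sum(vapply(fits, `[[`, numeric(1), "error_E0")),
                 total_E1 = sum(vapply(fits, `[[`, numeric(1), "error_E1")),
                 config = config),
            class = "network_fit")
}

#' @export
print.network_fit <- function(x, ...) {
  cat("<network_fit> ", length(x$fits), " genes, total E0 = ",
      format(x$total_E0, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Joint derivative-based error of a network model
#'
#' Sums the squared derivative mismatch over all modeled genes on the
#' quadrature grid in one pass; equals the sum of per-gene
#' [derivative_error()] values (the gene-wise decomposition).
#'
#' @inheritParams derivative_error
#' @param model A `network_model`.
#' @return Nonnegative scalar.
#' @export
network_derivative_error <- function(model, splines, config = fit_config()) {
  design <- fit_design(splines, config)
  total <- 0
  for (gm in model$genes) {
    u <- rep(gm$bias, nrow(design$X))
    if (length(gm$weights) > 0) {
      u <- u + as.vector(design$X[, names(gm$weights), drop = FALSE] %*%
                           unname(gm$weights))
    }
    fg <- gm$production * sigmoid(u, model$sigmoid_kind) -
      gm$decay * design$X[, gm$target]
    r <- design$D[, gm$target] - fg
    total <- total + sum(design$w * r * r)
  }
  total
}

#' Threshold fitted weights into a signed adjacency
#'
#' Weights with magnitude strictly below `threshold` are called zero;
#' otherwise the link takes the sign of the weight.
#'
#' @param model A `network_model` or `network_fit`.
#' @param threshold Nonnegative magnitude threshold (default 0.006).
#' @param regulators Candidate regulators (rows); default all model genes.
#' @param autoregulation Whether self-links are considered pairs.
#' @return A [signed_adjacency()] with targets = modeled genes.
#' @export
threshold_weights <- function(model, threshold = 0.006,
                              regulators = NULL, autoregulation = NULL) {
  if (inherits(model, "network_fit")) {
    autoregulation <- autoregulation %||% model$config$autoregulation
    model <- model$model
  }
  stopifnot(threshold >= 0)
  autoregulation <- autoregulation %||% TRUE
  regulators <- regulators %||% model$gene_names
  targets <- modeled_genes(model)
  m <- matrix(0L, length(regulators), length(targets),
              dimnames = list(regulators, targets))
  for (gm in model$genes) {
    w <- gm$weights[names(gm$weights) %in% regulators]
    keep <- abs(w) >= threshold
    m[names(w)[keep], gm$target] <- as.integer(sign(w[keep]))
  }
  signed_adjacency(m, autoregulation = autoregulation)
}

#' Default L1 regularization grid
#'
#' `c` from 0 to 10 in increments of 0.1 (101 values).
#' @return Numeric vector.
#' @export
default_c_grid <- function() seq(0, 10, by = 0.1)

#' L1 regularization path
#'
#' Refits the network at each penalty constant `c` in `c_grid` and records
#' the thresholded signed adjacency and nonzero-link count. Links that stay
#' nonzero at large `c` are the strongest predictors of the derivatives and
#' carry the highest confidence; `link_confidence` reports, per link, the
#' largest `c` at which it survives.
#'
#' @inheritParams fit_network
#' @param c_grid Nondecreasing nonnegative penalty grid
#'   (default [default_c_grid()]).
#' @return A `regularization_path`: tibble `path` (per-c link counts with
#'   fit and adjacency list-columns) and tibble `link_confidence`.
#' @export
regularization_path <- function(splines, targets = NULL, regulator_sets = NULL,
                                config = fit_config(),
                                c_grid = default_c_grid()) {
  stopifnot(all(c_grid >= 0), !is.unsorted(c_grid))
  design <- fit_design(splines, config)
  rows <- purrr::map(c_grid, function(cc) {
    cfg <- config
    cfg$penalty_c <- cc
    nf <- fit_network(design, targets, regulator_sets, cfg)
    adj <- threshold_weights(nf, threshold = config$weight_zero_threshold)
    tibble::tibble(c = cc, n_links = sum(adj != 0),
                   fit = list(nf), adjacency = list(adj))
  })
  path <- dplyr::bind_rows(rows)
  edges <- purrr::map_dfr(seq_along(c_grid), function(i) {
    dplyr::mutate(tidy(path$adjacency[[i]]), c = c_grid[i])
  })
  conf <- edges |>
    dplyr::filter(.data$sign != 0) |>
    dplyr::group_by(.data$regulator, .data$target) |>
    dplyr::summarise(max_c = max(.data$c), n_c = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$max_c))
  structure(list(path = path, link_confidence = conf, c_grid = c_grid),
            class = "regularization_path")
}

#' @export
print.regularization_path <- function(x, ...) {
  cat("<regularization_path> ", length(x$c_grid), " penalty values in [",
      min(x$c_grid), ", ", max(x$c_grid), "]\n", sep = "")
  print(dplyr::select(x$path, "c", "n_links"))
  invisible(x)
}
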