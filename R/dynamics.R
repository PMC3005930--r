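#' Sigmoidal regulation function
#'
#' The regulation function maps the summed, weighted regulator input
#' `u = sum_g' T_gg' x_g' + h_g` to a production fraction in (0, 1).
#' Two standard forms: the logistic `1 / (1 + exp(-u))` (default) and the
#' algebraic `(u / sqrt(u^2 + 1) + 1) / 2` common in gene-circuit models.
#'
#' @param u Numeric vector of regulatory inputs.
#' @param kind `"logistic"` or `"algebraic"`.
#' @return Values in (0, 1), strictly increasing in `u`.
#' @export
sigmoid <- function(u, kind = c("logistic", "algebraic")) {
  kind <- match.arg(kind)
  switch(kind,
    # split form avoids overflow of exp(-u) for large negative u
    logistic = ifelse(u >= 0, 1 / (1 + exp(-u)), exp(u) / (1 + exp(u))),
    algebraic = 0.5 * (u / sqrt(u^2 + 1) + 1)
  )
}

# derivative of sigmoid() with respect to u
sigmoid_deriv <- function(u, kind) {
  switch(kind,
    logistic = {
      s <- 1 / (1 + exp(-u))
      s * (1 - s)
    },
    algebraic = 0.5 / (u^2 + 1)^1.5
  )
}

#' Construct a single-gene dynamics model
#'
#' One target gene's parameters in the sigmoid production/decay model
#' `dx_g/dt = R_g * sigmoid(sum T_gg' x_g' + h_g) - lambda_g * x_g`:
#' maximum production rate `R_g` (expression units per time), regulatory
#' weights `T_gg'` (per expression unit; absent regulator = structural zero),
#' bias `h_g` (dimensionless) and first-order decay rate `lambda_g`
#' (per time).
#'
#' @param target Gene label.
#' @param production Nonnegative `R_g`.
#' @param decay Nonnegative `lambda_g`.
#' @param bias `h_g`.
#' @param weights Named numeric vector of regulatory weights (may be empty).
#' @return A `gene_model` list.
#' @export
gene_model <- function(target, production, decay, bias, weights = numeric(0)) {
  stopifnot(production >= 0, decay >= 0)
  if (length(weights) > 0 && is.null(names(weights))) {
    stop("weights must be named by regulator")
  }
  structure(
    list(target = target, production = production, decay = decay,
         bias = bias, weights = weights),
    class = "gene_model"
  )
}

#' Construct a network model
#'
#' A collection of [gene_model()]s over a common gene list. Genes without an
#' entry in `genes` are exogenous inputs: observed but not modeled, their
#' trajectories are supplied from data when simulating.
#'
#' @param gene_names Ordered character vector of all genes (modeled and
#'   exogenous).
#' @param genes List of `gene_model`s for the modeled targets.
#' @param sigmoid_kind `"logistic"` or `"algebraic"`.
#' @return A `network_model`.
#' @export
network_model <- function(gene_names, genes, sigmoid_kind = c("logistic", "algebraic")) {
  sigmoid_kind <- match.arg(sigmoid_kind)
  genes <- stats::setNames(genes, vapply(genes, `[[`, character(1), "target"))
  for (gm in genes) {
    bad <- setdiff(c(gm$target, names(gm$weights)), gene_names)
    if (length(bad) > 0) {
      stop("gene_model for '", gm$target, "' references unknown gene(s): ",
           paste(bad, collapse = ", "))
    }
  }
  structure(
    list(gene_names = gene_names, genes = genes, sigmoid_kind = sigmoid_kind),
    class = "network_model"
  )
}

#' @export
print.network_model <- function(x, ...) {
  cat("<network_model> ", length(x$gene_names), " genes (",
      length(x$genes), " modeled), ", x$sigmoid_kind, " sigmoid\n", sep = "")
  invisible(x)
}

modeled_genes <- function(model) names(model$genes)

#' Model derivatives at a state
#'
#' Evaluates the right-hand side of the network ODE at an expression state:
#' for each modeled gene `g`,
#' `R_g * sigmoid(sum T_gg' x_g' + h_g) - lambda_g * x_g`.
#'
#' @param model A `network_model`.
#' @param state Named numeric vector with one finite value per gene in
#'   `model$gene_names`.
#' @return Named numeric vector of derivatives for the modeled genes.
#' @export
model_dxdt <- function(model, state) {
  if (length(state) != length(model$gene_names) ||
      !all(model$gene_names %in% names(state))) {
    stop("state must supply one value per gene in the model")
  }
  if (!all(is.finite(state))) stop("state must be finite")
  vapply(model$genes, function(gm) {
    u <- gm$bias + sum(gm$weights * state[names(gm$weights)])
    gm$production * sigmoid(u, model$sigmoid_kind) - gm$decay * state[[gm$target]]
  }, numeric(1))
}

#' Steady-state residual
#'
#' Infinity norm of the model derivative at a state; zero at a fixed point.
#'
#' @inheritParams model_dxdt
#' @return Nonnegative scalar `max |dx/dt|`.
#' @export
steady_state_residual <- function(model, state) {
  max(abs(model_dxdt(model, state)))
}

# package-level counter of ODE solver invocations, used to assert that the
# derivative-based error performs no integration
.fdagrn_env <- new.env(parent = emptyenv())
.fdagrn_env$ode_solves <- 0L

#' ODE-solve counter
#'
#' `ode_solve_count()` returns the number of numerical ODE integrations the
#' package has performed this session; `reset_ode_solve_count()` zeroes it.
#' Used to verify that derivative-based error evaluation never integrates
#' the model.
#'
#' @return Integer count.
#' @export
ode_solve_count <- function() .fdagrn_env$ode_solves

#' @rdname ode_solve_count
#' @export
reset_ode_solve_count <- function() {
  .fdagrn_env$ode_solves <- 0L
  invisible(0L)
}

#' Simulate a network model
#'
#' Numerically integrates the modeled genes from an initial state; exogenous
#' (unmodeled) genes follow supplied trajectories exactly. The default
#' integrator is an adaptive Runge-Kutta pair (ode45, absolute tolerance
#' 1e-8, relative 1e-6); a fixed-step classical RK4 is available for
#' convergence studies.
#'
#' @param model A `network_model`.
#' @param x0 Named initial expression vector; must cover the modeled genes
#'   (values for exogenous genes are ignored in favour of `exogenous`).
#' @param times Increasing numeric vector of output times.
#' @param exogenous Named list of functions of time, one per unmodeled gene
#'   (required if the model has unmodeled genes).
#' @param series_id Label for the returned series.
#' @param method `"adaptive"` (default) or `"rk4"`.
#' @param step Fixed step size for `method = "rk4"`.
#' @return Expression tibble (`gene`, `series`, `time`, `value`) sampled at
#'   `times`, covering modeled and exogenous genes.
#' @export
simulate_model <- function(model, x0, times, exogenous = NULL,
                           series_id = "sim", method = c("adaptive", "rk4"),
                           step = NULL) {
  method <- match.arg(method)
  stopifnot(all(diff(times) > 0))
  mg <- modeled_genes(model)
  exo <- setdiff(model$gene_names, mg)
  if (length(exo) > 0) {
    if (is.null(exogenous) || !all(exo %in% names(exogenous))) {
      stop("exogenous trajectories required for unmodeled gene(s): ",
           paste(setdiff(exo, names(exogenous)), collapse = ", "))
    }
  }
  y0 <- unlist(x0)[mg]
  if (any(!is.finite(y0))) stop("x0 must supply finite values for modeled genes")

  rhs <- function(t, y, parms) {
    state <- y
    if (length(exo) > 0) {
      ex <- vapply(exo, function(g) exogenous[[g]](t), numeric(1))
      state <- c(y, stats::setNames(ex, exo))
    }
    list(model_dxdt(model, state[model$gene_names] |>
                      stats::setNames(model$gene_names)))
  }

  .fdagrn_env$ode_solves <- .fdagrn_env$ode_solves + 1L
  if (method == "adaptive") {
    sol <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                        method = "ode45", atol = 1e-8, rtol = 1e-6)
  } else {
    if (is.null(step)) stop("method 'rk4' requires a step size")
    grid <- sort(unique(c(seq(times[1], times[length(times)], by = step), times)))
    sol <- deSolve::ode(y = y0, times = grid, func = rhs, parms = NULL,
                        method = "rk4")
    sol <- sol[match(times, sol[, "time"]), , drop = FALSE]
  }
  if (any(!is.finite(sol))) {
    bad <- which(rowSums(!is.finite(sol)) > 0)[1]
    stop("simulation produced non-finite state at t = ", sol[bad, "time"])
  }

  out <- tibble::tibble(
    gene = rep(mg, each = length(times)),
    series = series_id,
    time = rep(times, length(mg)),
    value = as.vector(sol[, mg, drop = FALSE])
  )
  if (length(exo) > 0) {
    exo_tbl <- purrr::map_dfr(exo, function(g) {
      tibble::tibble(gene = g, series = series_id, time = times,
                     value = vapply(times, exogenous[[g]], numeric(1)))
    })
    out <- dplyr::bind_rows(out, exo_tbl)
  }
  out
}

#' Build exogenous-input functions from fitted splines
#'
#' @param fit A `spline_fit`.
#' @param series Series id within `fit`.
#' @param genes Genes to extract.
#' @return Named list of functions of time.
#' @export
exogenous_from_splines <- function(fit, series, genes) {
  sfit <- fit$fits[[series]]
  if (is.null(sfit)) stop("unknown series '", series, "'")
  stats::setNames(lapply(genes, function(g) {
    force(g)
    function(t) spline_eval_matrix(sfit, t, deriv = 0)[, g]
  }), genes)
}

#' Serialize / load a network model (YAML)
#'
#' @param model A `network_model`.
#' @param path File path.
#' @export
write_model_yaml <- function(model, path) {
  obj <- list(
    gene_names = as.list(model$gene_names),
    sigmoid_kind = model$sigmoid_kind,
    genes = lapply(model$genes, function(gm) {
      list(R = gm$production, lambda = gm$decay, h = gm$bias,
           weights = as.list(gm$weights))
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  genes <- lapply(names(obj$genes), function(g) {
    gm <- obj$genes[[g]]
    w <- unlist(gm$weights)
    if (is.null(w)) w <- numeric(0)
    gene_model(g, gm$R, gm$lambda, gm$h, w)
  })
  network_model(unlist(obj$gene_names), genes, obj$sigmoid_kind)
}

#' Model parameters as a tibble
#'
#' @param x A `network_model`.
#' @param ... Unused.
#' @return Tibble with one row per (target, term): terms `production`,
#'   `decay`, `bias` and `w:<regulator>` for each regulatory weight.
#' @method tidy network_model
#' @export
tidy.network_model <- function(x, ...) {
  purrr::map_dfr(x$genes, function(gm) {
    dplyr::bind_rows(
      tibble::tibble(target = gm$target,
                     term = c("production", "decay", "bias"),
                     estimate = c(gm$production, gm$decay, gm$bias)),
      if (length(gm$weights) > 0) {
        tibble::tibble(target = gm$target,
                       term = paste0("w:", names(gm$weights)),
                       estimate = unname(gm$weights))
      }
    )
  })
}
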