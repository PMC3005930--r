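#' Interpolating cubic splines for expression series
#'
#' Converts discrete expression series into continuous, differentiable
#' trajectories by interpolating each gene's values with a cubic spline.
#' The default end condition is "not-a-knot": the third derivative is
#' continuous across the second and next-to-last knots, so the first and
#' last two polynomial pieces coincide. A natural variant (zero second
#' derivative at the ends) is available; both have only small effects on
#' the interpolated curves for well-sampled series.
#'
#' Derivatives are obtained by differentiating the piecewise-polynomial
#' coefficients, never by finite differences, so the derivative of the
#' smooth is available at no extra cost — the property the gradient-matching
#' estimator depends on.
#'
#' @param data Expression tibble (see [check_expression()]).
#' @param end_condition `"notaknot"` (default) or `"natural"`.
#' @return An object of class `spline_fit`: per series, the knot vector and
#'   a coefficient array (interval x 4 x gene, ascending powers of `t - knot`).
#' @export
fit_splines <- function(data, end_condition = c("notaknot", "natural")) {
  end_condition <- match.arg(end_condition)
  data <- check_expression(data)
  series_ids <- unique(data$series)
  fits <- lapply(series_ids, function(sid) {
    sub <- data[data$series == sid, ]
    genes <- unique(sub$gene)
    tms <- sort(unique(sub$time))
    coefs <- array(NA_real_, dim = c(length(tms) - 1L, 4L, length(genes)),
                   dimnames = list(NULL, NULL, genes))
    for (g in genes) {
      y <- sub$value[sub$gene == g][order(sub$time[sub$gene == g])]
      coefs[, , g] <- cubic_spline_coefs(tms, y, end_condition)
    }
    list(series_id = sid, genes = genes, knots = tms, coefs = coefs)
  })
  names(fits) <- series_ids
  structure(list(fits = fits, end_condition = end_condition), class = "spline_fit")
}

# Piecewise-cubic coefficients on [x_i, x_{i+1}]:
#   p_i(t) = a0 + a1 dt + a2 dt^2 + a3 dt^3,  dt = t - x_i.
# Solves the standard tridiagonal system in the half-second-derivatives c_i;
# end rows impose not-a-knot (third-derivative continuity at the second and
# penultimate knots) or natural (c = 0 at both ends).
cubic_spline_coefs <- function(x, y, end_condition = "notaknot") {
  n <- length(x)
  if (n < 4) stop("cubic spline requires at least 4 points")
  h <- diff(x)
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    b[i] <- 3 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  if (end_condition == "notaknot") {
    A[1, 1] <- h[2]; A[1, 2] <- -(h[1] + h[2]); A[1, 3] <- h[1]
    A[n, n - 2] <- h[n - 1]; A[n, n - 1] <- -(h[n - 2] + h[n - 1]); A[n, n] <- h[n - 2]
  } else {
    A[1, 1] <- 1
    A[n, n] <- 1
  }
  cc <- solve(A, b)
  i <- seq_len(n - 1)
  a1 <- (y[i + 1] - y[i]) / h[i] - h[i] / 3 * (2 * cc[i] + cc[i + 1])
  a3 <- (cc[i + 1] - cc[i]) / (3 * h[i])
  cbind(y[i], a1, cc[i], a3, deparse.level = 0)
}

# Evaluate one series' splines (or their deriv-th derivative) at times `t`.
# Returns a |t| x n_genes matrix. No extrapolation: t must lie in the domain
# up to a small relative tolerance.
spline_eval_matrix <- function(sfit, t, deriv = 0) {
  knots <- sfit$knots
  lo <- knots[1]; hi <- knots[length(knots)]
  tol <- 1e-9 * max(1, abs(hi - lo))
  if (any(t < lo - tol | t > hi + tol)) {
    stop("evaluation point outside spline domain [", lo, ", ", hi,
         "] for series '", sfit$series_id, "' (no extrapolation)")
  }
  t <- pmin(pmax(t, lo), hi)
  idx <- findInterval(t, knots, rightmost.closed = TRUE)
  idx[idx < 1] <- 1L
  idx[idx >= length(knots)] <- length(knots) - 1L
  dt <- t - knots[idx]
  ng <- length(sfit$genes)
  out <- matrix(NA_real_, length(t), ng, dimnames = list(NULL, sfit$genes))
  for (k in seq_len(ng)) {
    cf <- sfit$coefs[idx, , k, drop = FALSE]
    dim(cf) <- c(length(t), 4L)
    out[, k] <- switch(as.character(deriv),
      "0" = cf[, 1] + dt * (cf[, 2] + dt * (cf[, 3] + dt * cf[, 4])),
      "1" = cf[, 2] + dt * (2 * cf[, 3] + dt * 3 * cf[, 4]),
      "2" = 2 * cf[, 3] + 6 * dt * cf[, 4],
      "3" = 6 * cf[, 4],
      stop("deriv must be 0, 1, 2 or 3")
    )
  }
  out
}

#' Evaluate spline trajectories and their derivatives
#'
#' `eval_spline()` evaluates the interpolated trajectories, and
#' `eval_derivative()` their exact first derivatives (from the polynomial
#' coefficients), at arbitrary times within each series' domain.
#'
#' @param fit A `spline_fit` from [fit_splines()].
#' @param times Numeric vector of evaluation times (must lie within the
#'   series domain; extrapolation is refused).
#' @param series Optional character vector of series ids (default: all).
#' @return A tibble with columns `series`, `gene`, `time`, `value` (or
#'   `deriv` for `eval_derivative()`).
#' @export
eval_spline <- function(fit, times, series = NULL) {
  eval_spline_long(fit, times, series, deriv = 0, col = "value")
}

#' @rdname eval_spline
#' @export
eval_derivative <- function(fit, times, series = NULL) {
  eval_spline_long(fit, times, series, deriv = 1, col = "deriv")
}

eval_spline_long <- function(fit, times, series, deriv, col) {
  stopifnot(inherits(fit, "spline_fit"))
  ids <- series %||% names(fit$fits)
  purrr::map_dfr(ids, function(sid) {
    sfit <- fit$fits[[sid]]
    if (is.null(sfit)) stop("unknown series '", sid, "'")
    m <- spline_eval_matrix(sfit, times, deriv)
    tibble::tibble(
      series = sid,
      gene = rep(sfit$genes, each = length(times)),
      time = rep(times, length(sfit$genes)),
      "{col}" := as.vector(m)
    )
  })
}

#' @export
print.spline_fit <- function(x, ...) {
  ns <- length(x$fits)
  ng <- length(x$fits[[1]]$genes)
  cat("<spline_fit> ", ns, " series x ", ng, " genes, ",
      x$end_condition, " cubic splines\n", sep = "")
  invisible(x)
}

#' Spline coefficient table
#'
#' @param x A `spline_fit`.
#' @param ... Unused.
#' @return Tibble of per-gene, per-interval polynomial coefficients
#'   (ascending powers of `t - interval start`).
#' @method tidy spline_fit
#' @export
tidy.spline_fit <- function(x, ...) {
  purrr::map_dfr(x$fits, function(sfit) {
    ni <- length(sfit$knots) - 1L
    purrr::map_dfr(sfit$genes, function(g) {
      tibble::tibble(
        series = sfit$series_id, gene = g,
        interval = seq_len(ni),
        t_start = sfit$knots[-length(sfit$knots)],
        t_end = sfit$knots[-1],
        c0 = sfit$coefs[, 1, g], c1 = sfit$coefs[, 2, g],
        c2 = sfit$coefs[, 3, g], c3 = sfit$coefs[, 4, g]
      )
    })
  })
}
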