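#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-gene fit summary as a tibble
#'
#' @param x A `gene_fit` or `network_fit`.
#' @param ... Unused.
#' @return `tidy()`: parameter estimates (one row per term);
#'   `glance()`: one row per gene with errors and optimizer diagnostics.
#' @method tidy gene_fit
#' @export
tidy.gene_fit <- function(x, ...) {
  gm <- x$params
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
}

#' @rdname tidy.gene_fit
#' @method glance gene_fit
#' @export
glance.gene_fit <- function(x, ...) {
  tibble::tibble(
    target = x$target,
    n_regulators = length(x$regulators),
    error_E0 = x$error_E0, error_E1 = x$error_E1,
    n_starts_used = x$n_starts_used,
    best_start_index = x$best_start_index,
    converged_fraction = x$converged_fraction
  )
}

#' @rdname tidy.gene_fit
#' @method tidy network_fit
#' @export
tidy.network_fit <- function(x, ...) {
  purrr::map_dfr(x$fits, tidy)
}

#' @rdname tidy.gene_fit
#' @method glance network_fit
#' @export
glance.network_fit <- function(x, ...) {
  purrr::map_dfr(x$fits, glance)
}

#' Enumeration entries as a tibble
#'
#' @param x An `enumeration_result`.
#' @param ... Unused.
#' @method tidy enumeration_result
#' @export
tidy.enumeration_result <- function(x, ...) {
  lattice_table(x)
}

#' Regularization path as a tibble
#'
#' @param x A `regularization_path`.
#' @param ... Unused.
#' @return One row per penalty value with the nonzero-link count.
#' @method tidy regularization_path
#' @export
tidy.regularization_path <- function(x, ...) {
  dplyr::select(x$path, "c", "n_links")
}

#' Plot expression series and optional spline smooths
#'
#' @param data Expression tibble.
#' @param splines Optional `spline_fit` to overlay as curves.
#' @param genes,series Optional subsets to display.
#' @param n_curve Evaluation points per curve.
#' @return A ggplot.
#' @export
plot_series <- function(data, splines = NULL, genes = NULL, series = NULL,
                        n_curve = 101) {
  data <- check_expression(data)
  if (!is.null(genes)) data <- dplyr::filter(data, .data$gene %in% genes)
  if (!is.null(series)) data <- dplyr::filter(data, .data$series %in% series)
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$time, y = .data$value,
                                          group = .data$series)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::facet_wrap(~gene, scales = "free_y") +
    ggplot2::labs(x = "time", y = "expression")
  if (!is.null(splines)) {
    ids <- series %||% names(splines$fits)
    curves <- purrr::map_dfr(ids, function(sid) {
      kn <- splines$fits[[sid]]$knots
      eval_spline(splines, seq(kn[1], kn[length(kn)], length.out = n_curve),
                  series = sid)
    })
    if (!is.null(genes)) curves <- dplyr::filter(curves, .data$gene %in% genes)
    p <- p + ggplot2::geom_line(data = curves, alpha = 0.5, linewidth = 0.3)
  }
  p
}

#' Plot an enumeration's error-versus-subset-size profile
#'
#' Each point is one regulator subset; the label above each column names the
#' regulator whose addition gives the best subset of that size.
#'
#' @param object An `enumeration_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot enumeration_result
#' @export
autoplot.enumeration_result <- function(object, ...) {
  e <- object$entries
  b <- object$best_per_size
  ggplot2::ggplot(tibble::tibble(size = e$size, error = e$error_E0),
                  ggplot2::aes(x = .data$size, y = .data$error)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = tibble::tibble(size = b$size, error = b$error_E0),
                       colour = "red") +
    ggplot2::geom_text(data = tibble::tibble(
      size = b$size, error = max(e$error_E0),
      lab = dplyr::coalesce(b$added_regulator, b$subset_label)),
      ggplot2::aes(label = .data$lab), angle = 90, hjust = 1, size = 3) +
    ggplot2::labs(x = "number of regulators", y = "derivative-based error E0",
                  title = object$target)
}

#' Plot link counts along a regularization path
#'
#' @param object A `regularization_path`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot regularization_path
#' @export
autoplot.regularization_path <- function(object, ...) {
  ggplot2::ggplot(object$path, ggplot2::aes(x = .data$c, y = .data$n_links)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "L1 penalty constant c", y = "nonzero links")
}
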