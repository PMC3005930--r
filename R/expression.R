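#' Validate a long-format expression table
#'
#' The package's primary data container is an ordinary tibble in long format
#' with columns `gene`, `series`, `time`, `value`: one row per observed
#' expression measurement, grouped into series (one series per trajectory,
#' e.g. one per embryo space point or per experimental time course).
#'
#' `check_expression()` validates the invariants every downstream operation
#' relies on: within a series, all genes share one strictly increasing time
#' grid of at least four points (the cubic-spline minimum), and all values
#' are finite and nonnegative.
#'
#' @param data A data frame with columns `gene`, `series`, `time`, `value`.
#' @return The input as a tibble, invisibly usable in a pipe; errors if any
#'   invariant fails, naming the offending series.
#' @export
check_expression <- function(data) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c("gene", "series", "time", "value"), names(data))
  if (length(missing_cols) > 0) {
    stop("expression data lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- tibble::as_tibble(data)
  if (!all(is.finite(data$value))) stop("expression values must be finite")
  if (any(data$value < 0)) stop("expression values must be nonnegative")
  for (sid in unique(data$series)) {
    sub <- data[data$series == sid, ]
    grids <- split(sub$time, sub$gene)
    tms <- grids[[1]]
    if (length(tms) < 4) {
      stop("series '", sid, "' has fewer than 4 time points; cubic splines need at least 4")
    }
    if (any(diff(tms) <= 0)) {
      stop("series '", sid, "' has non-increasing times")
    }
    same <- vapply(grids, function(g) length(g) == length(tms) && all(g == tms), logical(1))
    if (!all(same)) {
      stop("series '", sid, "': genes do not share a common time grid")
    }
  }
  data
}

#' Read and write long-format expression tables
#'
#' Tab-separated files with header `gene  series  time  value`.
#'
#' @param path File path.
#' @return `read_expression()` returns a validated tibble.
#' @export
read_expression <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(),
    series = readr::col_character(),
    time = readr::col_double(),
    value = readr::col_double()
  ))
  check_expression(out)
}

#' @rdname read_expression
#' @param data Expression tibble.
#' @export
write_expression <- function(data, path) {
  readr::write_tsv(check_expression(data), path)
  invisible(path)
}

#' Centered moving-average pre-smoothing
#'
#' Optional smoothing applied before spline interpolation. Each gene's values
#' within each series are replaced by a centered moving average of odd width
#' `window`, with edge replication at the series boundaries. `window = 1` is
#' the identity. Times are unchanged.
#'
#' @param data Expression tibble.
#' @param window Odd positive integer window width.
#' @return Expression tibble of the same shape.
#' @export
presmooth <- function(data, window = 1) {
  if (length(window) != 1 || window < 1 || window %% 2 == 0) {
    stop("window must be a positive odd integer")
  }
  data <- check_expression(data)
  if (window == 1) return(data)
  half <- (window - 1) / 2
  data |>
    dplyr::group_by(.data$series, .data$gene) |>
    dplyr::arrange(.data$time, .by_group = TRUE) |>
    dplyr::mutate(value = moving_average(.data$value, half)) |>
    dplyr::ungroup()
}

moving_average <- function(v, half) {
  n <- length(v)
  padded <- c(rep(v[1], half), v, rep(v[n], half))
  vapply(seq_len(n), function(i) mean(padded[i:(i + 2 * half)]), numeric(1))
}

#' Rescale expression data to a target range
#'
#' Multiplies all values by a single global factor so that the maximum equals
#' `hi` (the convention used for mRNA data fitted on a 0-100 scale). The
#' factor is attached as attribute `"scale_factor"`.
#'
#' @param data Expression tibble with nonnegative values, not all zero.
#' @param hi Target maximum, positive.
#' @return Rescaled tibble with attribute `scale_factor`.
#' @export
normalize_to_range <- function(data, hi = 100) {
  stopifnot(hi > 0)
  data <- check_expression(data)
  mx <- max(data$value)
  if (mx <= 0) stop("cannot rescale all-zero expression data")
  fac <- hi / mx
  out <- dplyr::mutate(data, value = .data$value * fac)
  attr(out, "scale_factor") <- fac
  out
}
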