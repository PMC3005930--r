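#' Signed regulatory adjacency
#'
#' A regulator-by-target matrix over \{-1, 0, +1\}: -1 repression, 0 no
#' effect, +1 activation. Row names are regulators, column names targets.
#' When `autoregulation = FALSE`, diagonal pairs (regulator == target) are
#' excluded from every comparison denominator and forced to zero.
#'
#' @param m Integer-valued matrix with dimnames, entries in \{-1, 0, 1\}.
#' @param autoregulation Are self-links considered candidate pairs?
#' @return A `signed_adjacency` matrix.
#' @export
signed_adjacency <- function(m, autoregulation = TRUE) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  if (!all(m %in% c(-1L, 0L, 1L))) stop("entries must be -1, 0 or +1")
  storage.mode(m) <- "integer"
  if (!autoregulation) {
    shared <- intersect(rownames(m), colnames(m))
    m[cbind(shared, shared)] <- 0L
  }
  structure(m, class = c("signed_adjacency", "matrix", "array"),
            autoregulation = isTRUE(autoregulation))
}

#' @export
print.signed_adjacency <- function(x, ...) {
  cat("<signed_adjacency> ", nrow(x), " regulators x ", ncol(x),
      " targets (autoregulation ",
      if (attr(x, "autoregulation")) "allowed" else "excluded", ")\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Signed adjacency as an edge tibble
#'
#' @param x A `signed_adjacency`.
#' @param ... Unused.
#' @return Tibble with columns `regulator`, `target`, `sign`, one row per
#'   considered pair.
#' @method tidy signed_adjacency
#' @export
tidy.signed_adjacency <- function(x, ...) {
  out <- tibble::tibble(
    regulator = rep(rownames(x), times = ncol(x)),
    target = rep(colnames(x), each = nrow(x)),
    sign = as.integer(x)
  )
  if (!attr(x, "autoregulation")) {
    out <- dplyr::filter(out, .data$regulator != .data$target)
  }
  out
}

#' Read and write signed edge lists
#'
#' Tab-separated files with header `regulator  target  sign`,
#' sign in \{-1, 0, 1\}; pairs omitted from the file default to 0.
#'
#' @param path File path.
#' @param regulators,targets Label vectors fixing the matrix frame; default:
#'   all labels seen in the file (regulators from column 1, targets from
#'   column 2).
#' @param autoregulation Passed to [signed_adjacency()].
#' @return A `signed_adjacency`.
#' @export
read_edges <- function(path, regulators = NULL, targets = NULL,
                       autoregulation = TRUE) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    regulator = readr::col_character(),
    target = readr::col_character(),
    sign = readr::col_integer()
  ))
  regulators <- regulators %||% unique(tbl$regulator)
  targets <- targets %||% unique(tbl$target)
  m <- matrix(0L, length(regulators), length(targets),
              dimnames = list(regulators, targets))
  keep <- tbl$regulator %in% regulators & tbl$target %in% targets
  tbl <- tbl[keep, ]
  m[cbind(tbl$regulator, tbl$target)] <- tbl$sign
  signed_adjacency(m, autoregulation = autoregulation)
}

#' @rdname read_edges
#' @param adj A `signed_adjacency`.
#' @param nonzero_only Write only nonzero links.
#' @export
write_edges <- function(adj, path, nonzero_only = FALSE) {
  tbl <- tidy(adj)
  if (nonzero_only) tbl <- dplyr::filter(tbl, .data$sign != 0)
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Score an estimated signed network against a gold standard
#'
#' Over all considered (regulator, target) pairs (excluding the diagonal
#' when autoregulation is disallowed):
#' * `Corr` / `CF` — number / fraction of pairs whose -/0/+ call matches;
#' * `TP` — pairs nonzero in both networks (sign-blind); `TN` — pairs zero
#'   in both; `FP` — estimated link absent from the gold standard; `FN` —
#'   gold link missed;
#' * `PPV = TP / (TP + FP)`; `Sens = TP / (TP + FN)`;
#' * `CSF` — among the TP pairs, the fraction with matching sign.
#'
#' Fractions with zero denominators are `NA` (undefined), never 0.
#'
#' @param gold,estimate `signed_adjacency` objects with identical regulator
#'   and target labels and the same autoregulation flag.
#' @return A `grn_metrics` list; see [tidy.grn_metrics()].
#' @export
compare_networks <- function(gold, estimate) {
  stopifnot(inherits(gold, "signed_adjacency"),
            inherits(estimate, "signed_adjacency"))
  if (!identical(rownames(gold), rownames(estimate)) ||
      !identical(colnames(gold), colnames(estimate))) {
    stop("label mismatch between gold and estimate: gold has regulators {",
         paste(rownames(gold), collapse = ","), "} and targets {",
         paste(colnames(gold), collapse = ","), "}; estimate has {",
         paste(rownames(estimate), collapse = ","), "} and {",
         paste(colnames(estimate), collapse = ","), "}")
  }
  if (!identical(attr(gold, "autoregulation"), attr(estimate, "autoregulation"))) {
    stop("gold and estimate disagree on the autoregulation flag")
  }
  g <- tidy(gold)$sign
  e <- tidy(estimate)$sign
  n <- length(g)
  corr <- sum(g == e)
  tp <- sum(g != 0 & e != 0)
  tn <- sum(g == 0 & e == 0)
  fp <- sum(g == 0 & e != 0)
  fn <- sum(g != 0 & e == 0)
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(
    n_links_considered = n, correct = corr, correct_fraction = frac(corr, n),
    true_positives = tp, true_negatives = tn,
    false_positives = fp, false_negatives = fn,
    ppv = frac(tp, tp + fp), sensitivity = frac(tp, tp + fn),
    csf = frac(sum(g != 0 & e != 0 & g == e), tp)
  ), class = "grn_metrics")
}

#' @export
print.grn_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else format(v, digits = 4)
  cat("<grn_metrics> over ", x$n_links_considered, " candidate links\n",
      "  Corr = ", x$correct, "  CF = ", fmt(x$correct_fraction), "\n",
      "  TP = ", x$true_positives, "  TN = ", x$true_negatives,
      "  FP = ", x$false_positives, "  FN = ", x$false_negatives, "\n",
      "  PPV = ", fmt(x$ppv), "  Sens = ", fmt(x$sensitivity),
      "  CSF = ", fmt(x$csf), "\n", sep = "")
  invisible(x)
}

#' Comparison metrics as a one-row tibble
#'
#' @param x A `grn_metrics`.
#' @param ... Unused.
#' @return One-row tibble; undefined fractions are `NA`.
#' @method tidy grn_metrics
#' @export
tidy.grn_metrics <- function(x, ...) {
  tibble::as_tibble(x[c("n_links_considered", "correct", "correct_fraction",
                        "true_positives", "true_negatives", "false_positives",
                        "false_negatives", "ppv", "sensitivity", "csf")])
}

#' Expected correct fraction under random signing
#'
#' A uniformly random -/0/+ call matches any fixed gold sign with
#' probability 1/3, so chance-level CF is 1/3 regardless of the number of
#' links or the gold network's density.
#'
#' @param n_links Number of candidate links (>= 1).
#' @return 1/3.
#' @export
random_baseline_cf <- function(n_links) {
  stopifnot(n_links >= 1)
  1 / 3
}
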