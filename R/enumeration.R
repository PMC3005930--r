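# subset members for bitmask `mask` over `candidates` (bit i = candidate i)
mask_members <- function(mask, candidates) {
  candidates[bitwAnd(mask, bitwShiftL(1L, seq_along(candidates) - 1L)) != 0L]
}

#' Plan an exhaustive enumeration
#'
#' Pure combinatorics of regulator-subset enumeration: each target with `K`
#' candidate regulators admits `2^K` subsets (including the empty set), and
#' the per-gene decomposition of the derivative-based error means the whole
#' architecture space is covered by `sum_target 2^K_target` independent
#' fits.
#'
#' @param targets Character vector of target genes.
#' @param candidates Character vector of shared candidate regulators, or a
#'   named list per target.
#' @return Tibble with one row per target (`target`, `n_candidates`,
#'   `n_subsets`) and attribute `total_fits`.
#' @export
enumeration_plan <- function(targets, candidates) {
  if (!is.list(candidates)) {
    candidates <- stats::setNames(rep(list(candidates), length(targets)), targets)
  }
  nk <- vapply(targets, function(g) length(candidates[[g]]), integer(1))
  out <- tibble::tibble(
    target = targets,
    n_candidates = nk,
    n_subsets = as.integer(2^nk)
  )
  attr(out, "total_fits") <- sum(out$n_subsets)
  out
}

#' Exhaustively fit every regulator subset of one gene
#'
#' Fits the target's sigmoid model under every subset of the candidate
#' regulators (all `2^K`, including the empty set) and ranks subsets by
#' derivative-based error. The best subset of each size is annotated with
#' the regulator whose addition produced it when it extends the best
#' (k-1)-subset; non-nested optima are reported as the full subset.
#'
#' @param splines A `spline_fit`.
#' @param target Target gene.
#' @param candidates Candidate regulators (must respect the autoregulation
#'   flag in `config`).
#' @param config A [fit_config()]; `n_starts` is the per-subset budget.
#' @return An `enumeration_result` with tibbles `entries` (one row per
#'   subset: `mask`, `size`, `subset` list-column, `error_E0`, `fit`
#'   list-column) and `best_per_size`.
#' @export
enumerate_gene <- function(splines, target, candidates, config = fit_config()) {
  candidates <- as.character(candidates)
  if (!config$autoregulation && target %in% candidates) {
    stop("autoregulation is disabled but '", target, "' is its own candidate")
  }
  design <- fit_design(splines, config)
  k <- length(candidates)
  masks <- if (k > 0) 0:(2L^k - 1L) else 0L
  fits <- lapply(masks, function(m) {
    fit_gene(design, target, mask_members(m, candidates), config)
  })
  entries <- tibble::tibble(
    mask = as.integer(masks),
    size = vapply(masks, function(m) length(mask_members(m, candidates)), integer(1)),
    subset = lapply(masks, mask_members, candidates = candidates),
    error_E0 = vapply(fits, `[[`, numeric(1), "error_E0"),
    fit = fits
  )
  entries <- dplyr::arrange(entries, .data$size, .data$error_E0, .data$mask)
  best <- entries |>
    dplyr::group_by(.data$size) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  added <- rep(NA_character_, nrow(best))
  for (i in seq_len(nrow(best))[-1]) {
    prev <- best$subset[[i - 1]]
    cur <- best$subset[[i]]
    if (all(prev %in% cur) && length(setdiff(cur, prev)) == 1) {
      added[i] <- setdiff(cur, prev)
    }
  }
  best$added_regulator <- added
  best$subset_label <- vapply(best$subset, function(s) {
    if (length(s) == 0) "(none)" else paste(s, collapse = "+")
  }, character(1))
  structure(list(target = target, candidates = candidates,
                 entries = entries, best_per_size = best),
            class = "enumeration_result")
}

#' @export
print.enumeration_result <- function(x, ...) {
  cat("<enumeration_result> ", x$target, ": ", nrow(x$entries),
      " subsets of {", paste(x$candidates, collapse = ", "), "}\n", sep = "")
  print(dplyr::select(x$best_per_size, "size", "subset_label",
                      "error_E0", "added_regulator"))
  invisible(x)
}

#' Enumerate regulator subsets for every target
#'
#' Independent per-target enumerations (order-invariant); the total fit
#' count is the sum of `2^K` over targets.
#'
#' @inheritParams enumerate_gene
#' @param targets Character vector of targets.
#' @param candidates Shared candidate vector or named per-target list; by
#'   default self is removed per target unless `config$autoregulation`.
#' @return A `network_enumeration`: named list `results` of
#'   `enumeration_result`s plus `total_fits`.
#' @export
enumerate_network <- function(splines, targets, candidates = NULL,
                              config = fit_config()) {
  design <- fit_design(splines, config)
  if (is.null(candidates)) candidates <- design$genes
  if (!is.list(candidates)) {
    candidates <- stats::setNames(lapply(targets, function(g) {
      if (config$autoregulation) candidates else setdiff(candidates, g)
    }), targets)
  }
  plan <- enumeration_plan(targets, candidates)
  results <- lapply(targets, function(g) {
    enumerate_gene(design, g, candidates[[g]], config)
  })
  names(results) <- targets
  structure(list(results = results, plan = plan,
                 total_fits = attr(plan, "total_fits")),
            class = "network_enumeration")
}

#' @export
print.network_enumeration <- function(x, ...) {
  cat("<network_enumeration> ", length(x$results), " targets, ",
      x$total_fits, " total fits\n", sep = "")
  invisible(x)
}

#' Assemble the best size-k architecture
#'
#' Takes, for every target, the minimum-error subset of size `k` from an
#' enumeration, assembles the corresponding network model, and thresholds
#' its weights into a signed adjacency.
#'
#' @param enumeration A `network_enumeration`.
#' @param k Subset size, `0 <= k <= min K` over targets.
#' @param gene_names All network genes (default: union of targets and
#'   candidates).
#' @param threshold Weight-zero threshold (default 0.006).
#' @param autoregulation Flag for the returned adjacency; default from the
#'   enumeration's candidate structure.
#' @return List with `model` (`network_model`) and `adjacency`
#'   (`signed_adjacency` over all candidate regulators).
#' @export
best_k_architecture <- function(enumeration, k, gene_names = NULL,
                                threshold = 0.006, autoregulation = NULL) {
  results <- enumeration$results
  kmax <- min(vapply(results, function(r) length(r$candidates), integer(1)))
  if (k < 0 || k > kmax) stop("k must lie in [0, ", kmax, "]")
  picks <- lapply(results, function(r) {
    row <- r$best_per_size[r$best_per_size$size == k, ]
    row$fit[[1]]$params
  })
  regulators <- sort(unique(unlist(lapply(results, `[[`, "candidates"))))
  gene_names <- gene_names %||% sort(unique(c(names(results), regulators)))
  autoregulation <- autoregulation %||%
    any(vapply(results, function(r) r$target %in% r$candidates, logical(1)))
  model <- network_model(gene_names, picks)
  adj <- threshold_weights(model, threshold = threshold,
                           regulators = regulators,
                           autoregulation = autoregulation)
  list(model = model, adjacency = adj)
}

#' Subset ranking table for export
#'
#' Flattens an enumeration into one row per regulator subset with its
#' error, rank within its size class, overall rank, and an inverse-error
#' score convenient for lattice-style plotting (larger = better fit).
#'
#' @param result An `enumeration_result`.
#' @return Tibble with columns `subset`, `members`, `size`, `error_E0`,
#'   `rank_in_size`, `overall_rank`, `score`.
#' @export
lattice_table <- function(result) {
  stopifnot(inherits(result, "enumeration_result"))
  e <- result$entries
  tibble::tibble(
    subset = vapply(e$subset, function(s) {
      if (length(s) == 0) "(none)" else paste(s, collapse = "+")
    }, character(1)),
    members = e$subset,
    size = e$size,
    error_E0 = e$error_E0
  ) |>
    dplyr::group_by(.data$size) |>
    dplyr::mutate(rank_in_size = rank(.data$error_E0, ties.method = "first")) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      overall_rank = rank(.data$error_E0, ties.method = "first"),
      score = 1 / pmax(.data$error_E0, .Machine$double.eps)
    )
}
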