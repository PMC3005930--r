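#' Specification for a synthetic benchmark
#'
#' Describes the study conditions for generating model-class data with a
#' known gold standard. Generated parameters are drawn strictly inside the
#' `irma_gnw` fitting bounds so the truth is always attainable by the
#' optimizer. Defaults describe the package's standard recovery benchmark:
#' 5 genes, sparse signed topology, 20 noiseless series of 16 time points
#' over 6 time units — a sampling interval of 0.4 that resolves the fastest
#' decay timescale (`1/lambda >= 0.5`) so spline derivatives are accurate.
#'
#' @param n_genes Number of genes (all modeled).
#' @param topology `"sparse"` (1-2 regulators per gene) or `"dense"`
#'   (up to `n_genes - 1`).
#' @param n_series Number of independent series.
#' @param n_timepoints Observations per series (>= 4).
#' @param t_end Duration of each series.
#' @param noise_sd Standard deviation of additive Gaussian observation
#'   noise (0 = noiseless; noisy values are clipped at 0).
#' @param seed Integer seed; fully determines the output.
#' @param protocol `"varied_initial_conditions"` (each series starts from a
#'   random state) or `"perturb_relax"` (transient overexpression of one
#'   gene from the steady state; only the relaxation half is returned).
#' @param sigmoid_kind Passed to the generating model.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 5, topology = c("sparse", "dense"),
                           n_series = 20, n_timepoints = 16, t_end = 6,
                           noise_sd = 0, seed = 42,
                           protocol = c("varied_initial_conditions", "perturb_relax"),
                           sigmoid_kind = "logistic") {
  topology <- match.arg(topology)
  protocol <- match.arg(protocol)
  stopifnot(n_genes >= 2, n_series >= 1, n_timepoints >= 4, t_end > 0,
            noise_sd >= 0)
  structure(list(n_genes = n_genes, topology = topology, n_series = n_series,
                 n_timepoints = n_timepoints, t_end = t_end,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 protocol = protocol, sigmoid_kind = sigmoid_kind),
            class = "synthetic_spec")
}

# draw a random signed topology and in-bounds parameters; autoregulation-free
draw_generator <- function(spec) {
  genes <- paste0("g", seq_len(spec$n_genes))
  n_reg <- function() {
    if (spec$topology == "sparse") sample(1:2, 1)
    else sample(seq(2, spec$n_genes - 1), 1)
  }
  gms <- lapply(genes, function(g) {
    regs <- sample(setdiff(genes, g), n_reg())
    w <- stats::setNames(
      sample(c(-1, 1), length(regs), replace = TRUE) *
        stats::runif(length(regs), 0.05, 0.15),
      regs
    )
    gene_model(g, production = stats::runif(1, 8, 20),
               decay = stats::runif(1, 0.8, 2),
               bias = stats::runif(1, -3, -1), weights = w)
  })
  model <- network_model(genes, gms, sigmoid_kind = spec$sigmoid_kind)
  m <- matrix(0L, spec$n_genes, spec$n_genes, dimnames = list(genes, genes))
  for (gm in gms) m[names(gm$weights), gm$target] <- as.integer(sign(gm$weights))
  list(model = model, gold = signed_adjacency(m, autoregulation = FALSE))
}

find_steady_state <- function(model, t_relax = 60) {
  genes <- model$gene_names
  x0 <- vapply(model$genes, function(gm) {
    gm$production * sigmoid(gm$bias, model$sigmoid_kind) / max(gm$decay, 1e-3)
  }, numeric(1))
  sim <- simulate_model(model, stats::setNames(x0, genes),
                        times = c(0, t_relax / 2, t_relax))
  last <- sim[sim$time == t_relax, ]
  stats::setNames(last$value[match(genes, last$gene)], genes)
}

#' Generate a synthetic benchmark
#'
#' Draws a signed topology and parameters from the seeded generator,
#' simulates series under the spec's protocol, optionally adds observation
#' noise, and returns the data together with the generating model and its
#' gold-standard signed adjacency.
#'
#' For `protocol = "perturb_relax"`, each series transiently overexpresses
#' one gene (rotating over genes) starting from the network steady state;
#' only the relaxation half — the return to rest after the perturbation is
#' removed — is returned, so the data describe wild-type dynamics. Specs
#' whose relaxation does not decay (steady-state residual not shrinking)
#' are redrawn from the next sub-seed, up to 5 retries.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `data` (expression tibble), `model`
#'   (generating `network_model`), `gold` ([signed_adjacency()]) and `spec`.
#' @export
generate_benchmark <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  for (attempt in 0:5) {
    out <- withr::with_seed((spec$seed + attempt * 1009L) %% 2147483647L,
                            generate_benchmark_once(spec))
    if (!is.null(out)) return(out)
  }
  stop("could not generate a relaxing system after 6 attempts")
}

generate_benchmark_once <- function(spec) {
  gen <- draw_generator(spec)
  model <- gen$model
  genes <- model$gene_names
  times <- seq(0, spec$t_end, length.out = spec$n_timepoints)
  xmax <- vapply(model$genes, function(gm) gm$production / gm$decay, numeric(1))

  if (spec$protocol == "perturb_relax") {
    ss <- find_steady_state(model)
    if (steady_state_residual(model, ss) > 1e-4 * max(ss, 1)) return(NULL)
  }

  series <- lapply(seq_len(spec$n_series), function(i) {
    sid <- sprintf("s%02d", i)
    if (spec$protocol == "varied_initial_conditions") {
      x0 <- stats::setNames(stats::runif(length(genes), 0, xmax), genes)
      sim <- simulate_model(model, x0, times, series_id = sid)
    } else {
      boosted_gene <- genes[(i - 1) %% length(genes) + 1]
      boosted <- model
      gm <- boosted$genes[[boosted_gene]]
      gm$production <- min(25, gm$production * 2.5)
      boosted$genes[[boosted_gene]] <- gm
      ss <- find_steady_state(model)
      pert <- simulate_model(boosted, ss, c(0, spec$t_end / 2, spec$t_end))
      xp <- pert[pert$time == spec$t_end, ]
      x0 <- stats::setNames(xp$value[match(genes, xp$gene)], genes)
      sim <- simulate_model(model, x0, times, series_id = sid)
      r0 <- steady_state_residual(model, x0)
      xl <- sim[sim$time == times[length(times)], ]
      rT <- steady_state_residual(
        model, stats::setNames(xl$value[match(genes, xl$gene)], genes))
      if (!(rT < r0)) return(NULL)
    }
    sim
  })
  if (any(vapply(series, is.null, logical(1)))) return(NULL)
  data <- dplyr::bind_rows(series)
  if (spec$noise_sd > 0) {
    data$value <- pmax(0, data$value + stats::rnorm(nrow(data), 0, spec$noise_sd))
  }
  list(data = data, model = model, gold = gen$gold, spec = spec)
}

#' Gap-gene-shaped synthetic fixture
#'
#' A synthetic stand-in with the shape of the Drosophila trunk gap-gene
#' protein data: 7 genes (Hb, Kr, Gt, Kni modeled; Bcd, Cad, Tll exogenous
#' inputs with smooth spatial profiles), 8 time points, 58 independent
#' series corresponding to positions along the anterior-posterior axis —
#' 3248 expression values in total, on the native 0-255 intensity scale.
#' The companion gold standard is a consensus-shaped signed 7 x 4 matrix
#' (28 candidate regulator-target pairs, 22 nonzero) with all gap-gap
#' cross-interactions repressive, Hb autoactivation, and the three
#' maternal/terminal inputs signed per the consensus picture. These are
#' synthetic data with the real data set's dimensions and conventions, not
#' the real measurements.
#'
#' @param seed Integer seed.
#' @return List with `data` (3248-row expression tibble), `gold`
#'   (7-regulator x 4-target [signed_adjacency()], autoregulation allowed),
#'   `model`, `targets`, `exogenous_genes`.
#' @export
gap_gene_shaped_fixture <- function(seed = 1) {
  targets <- c("Hb", "Kr", "Gt", "Kni")
  inputs <- c("Bcd", "Cad", "Tll")
  genes <- c(targets, inputs)
  gold <- matrix(0L, 7, 4, dimnames = list(genes, targets))
  for (r in targets) for (tg in targets) if (r != tg) gold[r, tg] <- -1L
  gold["Hb", "Hb"] <- 1L
  gold["Bcd", c("Hb", "Kr", "Gt")] <- 1L
  gold["Cad", c("Kni", "Kr")] <- 1L
  gold["Tll", "Hb"] <- 1L
  gold["Tll", c("Kr", "Gt", "Kni")] <- -1L
  gold <- signed_adjacency(gold, autoregulation = TRUE)

  withr::with_seed(seed, {
    gms <- lapply(targets, function(tg) {
      regs <- rownames(gold)[gold[, tg] != 0L]
      w <- stats::setNames(
        as.numeric(gold[regs, tg]) * stats::runif(length(regs), 0.01, 0.04),
        regs)
      gene_model(tg, production = stats::runif(1, 15, 25),
                 decay = stats::runif(1, 0.08, 0.12), bias = -3.5, weights = w)
    })
    model <- network_model(genes, gms)
    times <- seq(0, 56, by = 8)
    pos <- seq_len(58)
    bcd <- 255 * exp(-pos / 20)
    cad <- 255 / (1 + exp(-(pos - 30) / 8))
    tll <- 220 * exp(-(pos - 55)^2 / 60)
    data <- purrr::map_dfr(pos, function(s) {
      exo <- list(Bcd = local({ v <- bcd[s]; function(t) v }),
                  Cad = local({ v <- cad[s]; function(t) v }),
                  Tll = local({ v <- tll[s]; function(t) v }))
      x0 <- stats::setNames(stats::runif(4, 0, 150), targets)
      simulate_model(model, x0, times, exogenous = exo,
                     series_id = sprintf("pos%02d", s))
    })
    data$value <- pmin(pmax(data$value, 0), 255)
    list(data = data, gold = gold, model = model,
         targets = targets, exogenous_genes = inputs)
  })
}

#' IRMA-shaped synthetic fixture
#'
#' A synthetic stand-in with the shape of the IRMA in-vivo benchmark data:
#' the 5 genes SWI5, CBF1, GAL4, GAL80 and ASH1, 5 switch-on time series
#' sampled every 20 minutes over 5 hours (16 points each). The canonical
#' gold standard has exactly 7 signed links: SWI5 activates CBF1, GAL80 and
#' ASH1; CBF1 activates GAL4; GAL4 activates SWI5; ASH1 represses CBF1; and
#' GAL80 represses SWI5 (GAL80's protein-level repression of GAL4 is
#' invisible at the mRNA level, so GAL80 -> GAL4 is 0 and the effect is
#' placed on SWI5). Autoregulation is excluded. Synthetic data with the
#' real network's topology and dimensions, not the real measurements.
#'
#' @param seed Integer seed.
#' @return List with `data` (5 series x 5 genes x 16 times), `gold`
#'   (5 x 5 [signed_adjacency()], autoregulation excluded), `model`.
#' @export
irma_shaped_fixture <- function(seed = 1) {
  genes <- c("SWI5", "CBF1", "GAL4", "GAL80", "ASH1")
  edges <- list(
    c("SWI5", "CBF1", 1), c("SWI5", "GAL80", 1), c("SWI5", "ASH1", 1),
    c("CBF1", "GAL4", 1), c("GAL4", "SWI5", 1),
    c("ASH1", "CBF1", -1), c("GAL80", "SWI5", -1)
  )
  m <- matrix(0L, 5, 5, dimnames = list(genes, genes))
  for (e in edges) m[e[1], e[2]] <- as.integer(e[3])
  gold <- signed_adjacency(m, autoregulation = FALSE)

  withr::with_seed(seed, {
    gms <- lapply(genes, function(tg) {
      regs <- rownames(gold)[gold[, tg] != 0L]
      w <- stats::setNames(
        as.numeric(gold[regs, tg]) * stats::runif(length(regs), 1.0, 2.0),
        regs)
      gene_model(tg, production = stats::runif(1, 0.02, 0.05),
                 decay = stats::runif(1, 0.01, 0.02),
                 bias = stats::runif(1, -2, -1), weights = w)
    })
    model <- network_model(genes, gms)
    times <- seq(0, 300, by = 20)
    data <- purrr::map_dfr(seq_len(5), function(i) {
      x0 <- stats::setNames(stats::runif(5, 0, 0.5), genes)
      x0["SWI5"] <- stats::runif(1, 1, 2)  # galactose switch-on
      simulate_model(model, x0, times, series_id = sprintf("irma%d", i))
    })
    list(data = data, gold = gold, model = model)
  })
}

#' Write a benchmark to disk
#'
#' Emits the long-format expression TSV, the gold-standard signed edge-list
#' TSV, and the generating model YAML side by side.
#'
#' @param bench Result of [generate_benchmark()] or a fixture function.
#' @param prefix Path prefix; files get suffixes `_expression.tsv`,
#'   `_gold.tsv`, `_model.yaml`.
#' @return The three paths, invisibly.
#' @export
write_benchmark <- function(bench, prefix) {
  paths <- c(expression = paste0(prefix, "_expression.tsv"),
             gold = paste0(prefix, "_gold.tsv"),
             model = paste0(prefix, "_model.yaml"))
  write_expression(bench$data, paths["expression"])
  write_edges(bench$gold, paths["gold"])
  write_model_yaml(bench$model, paths["model"])
  invisible(paths)
}
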