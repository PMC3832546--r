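#' The hypothetical two-isoform cassette-exon gene used in simulations
#'
#' Three exons of lengths 1200, 60 and 600 bp; isoform A includes all
#' three (1860 bp), isoform B skips the 60-bp middle exon (1800 bp).
#'
#' @return A [gene_model()].
#' @export
default_sim_gene <- function() {
  gene_model("sim_gene",
             exons = cbind(c(0, 2000, 3000), c(1200, 2060, 3600)),
             isoforms = list(A = 1:3, B = c(1L, 3L)),
             strand = "+")
}

#' Abundance matrix for a simulation scenario
#'
#' Maps a total gene expression level G (RPKM-like units) to the K x I
#' abundance matrix of one of the three generating models: model 0 splits
#' G identically in every condition; model 1 multiplies a shared split by
#' the per-condition fold vector tau (sum(tau) = K, so G stays the average
#' gene level); model 2 uses distinct per-condition splits.
#'
#' @param true_model 0, 1 or 2.
#' @param G Positive total gene abundance.
#' @param split Baseline isoform proportions (models 0 and 1), summing
#'   to 1; default 50/50.
#' @param tau Per-condition fold vector for model 1 (recycled/validated to
#'   sum to K); default `c(2/3, 4/3)`.
#' @param splits2 List of K per-condition isoform proportion vectors for
#'   model 2; default `list(c(0.8, 0.2), c(0.2, 0.8))`.
#' @param K Number of conditions.
#' @return K x I abundance matrix.
#' @export
theta_from_scenario <- function(true_model, G, split = c(0.5, 0.5),
                                tau = c(2 / 3, 4 / 3),
                                splits2 = list(c(0.8, 0.2), c(0.2, 0.8)),
                                K = 2L) {
  stopifnot(G > 0, K >= 2L)
  true_model <- as.integer(true_model)
  if (!true_model %in% 0:2) stop("true_model must be 0, 1 or 2")
  if (true_model %in% c(0L, 1L)) {
    if (abs(sum(split) - 1) > 1e-8) stop("'split' must sum to 1")
    base <- G * split
    if (true_model == 0L) return(matrix(rep(base, each = K), K))
    if (length(tau) != K) stop("'tau' must have length K")
    if (abs(sum(tau) - K) > 1e-8) stop("'tau' must sum to K")
    return(outer(tau, base))
  }
  if (length(splits2) != K) stop("'splits2' must have one split per condition")
  if (any(vapply(splits2, function(s) abs(sum(s) - 1) > 1e-8, logical(1))))
    stop("each model-2 split must sum to 1")
  th <- do.call(rbind, lapply(splits2, function(s) G * s))
  if (all(apply(th / rowSums(th), 2L, function(x) diff(range(x)) < 1e-12)))
    stop("identical splits in every condition: not a model-2 scenario")
  th
}

#' Precompute per-condition sampling machinery for simulation
#'
#' Builds the sampling-rate matrices (depth scale `depth / 1e9`, making
#' abundances RPKM-like) and the full category partition once, so that
#' replicate simulation only draws Poisson counts.
#'
#' @param gene A [gene_model()].
#' @param depths Per-condition total mapped read counts.
#' @param read_length Single-end read length (bp), default 50.
#' @return List of per-condition setups (sampling rates + category
#'   partition), class `"sim_setup"`.
#' @export
sim_setup <- function(gene, depths = c(50e6, 55e6), read_length = 50) {
  stopifnot(all(depths > 0))
  out <- lapply(seq_along(depths), function(k) {
    sr <- build_sampling_rates(gene, read_length,
                               depth_scale_rpkm(depths[k]),
                               condition_id = paste0("cond", k))
    list(rates = sr, partition = category_partition(sr))
  })
  structure(out, class = "sim_setup", gene_id = gene$gene_id)
}

#' Simulate per-condition read-category counts
#'
#' Draws independent Poisson counts for every read category with mean
#' `sum_i a_ij theta_ki`. Simulating at category level is equivalent in
#' distribution to simulating each read type and reducing, by Poisson
#' thinning/superposition.
#'
#' @param theta K x I abundance matrix.
#' @param gene A [gene_model()] (ignored when `setup` is given).
#' @param depths Per-condition total mapped reads.
#' @param read_length Read length (bp).
#' @param setup Optional precomputed [sim_setup()] (recommended inside
#'   replicate loops).
#' @return List of K [read_category_table()].
#' @export
simulate_counts <- function(theta, gene = default_sim_gene(),
                            depths = c(50e6, 55e6), read_length = 50,
                            setup = NULL) {
  theta <- as.matrix(theta)
  if (is.null(setup)) setup <- sim_setup(gene, depths, read_length)
  if (length(setup) != nrow(theta))
    stop("theta must have one row per condition")
  lapply(seq_along(setup), function(k) {
    part <- setup[[k]]$partition
    mu <- as.numeric(part$rates %*% theta[k, ])
    counts <- stats::rpois(length(mu), mu)
    read_category_table(setup[[k]]$rates$condition_id, counts, part$rates,
                        setup[[k]]$rates$isoform_totals)
  })
}

#' Configuration of a model-classification simulation study
#'
#' @param gene Gene model; default the three-exon cassette gene of
#'   [default_sim_gene()].
#' @param depths Total mapped reads per condition; default 50 and 55
#'   million.
#' @param G_grid Positive gene expression levels to scan.
#' @param true_model Generating model (0, 1 or 2).
#' @param n_reps Replicate pairs per G (default 1000).
#' @param alpha Significance level of the hierarchical LRT (default 0.05).
#' @param seed Integer RNG seed.
#' @param read_length Read length (bp), default 50.
#' @param ... Scenario parameters passed to [theta_from_scenario()]
#'   (`split`, `tau`, `splits2`).
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(gene = default_sim_gene(), depths = c(50e6, 55e6),
                       G_grid = c(1, 5, 10, 20), true_model = 0,
                       n_reps = 1000L, alpha = 0.05, seed = 1L,
                       read_length = 50, ...) {
  stopifnot(all(G_grid > 0), n_reps >= 1L, alpha > 0, alpha < 1)
  structure(
    list(gene = gene, depths = depths, G_grid = G_grid,
         true_model = as.integer(true_model), n_reps = as.integer(n_reps),
         alpha = alpha, seed = as.integer(seed), read_length = read_length,
         scenario_args = list(...)),
    class = "sim_config")
}

#' Run the model-classification simulation study
#'
#' For each expression level G: simulate `n_reps` replicate pairs of
#' conditions under the generating model, fit models 0/1/2 by EM, apply
#' the hierarchical LRT, and tally selections. The true classification
#' rate is the proportion of (non-failed) replicates selecting the
#' generating model; under model 0 its complement is the empirical type-I
#' error.
#'
#' @param config A [sim_config()].
#' @return Object of class `"sim_study"`: a data.frame with one row per G
#'   (`G`, `n_model0/1/2`, `n_failed`, `true_rate`, `se`), the config as
#'   attribute `"config"`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  setup <- sim_setup(config$gene, config$depths, config$read_length)
  K <- length(config$depths)
  rows <- lapply(config$G_grid, function(G) {
    theta <- do.call(theta_from_scenario,
                     c(list(true_model = config$true_model, G = G, K = K),
                       config$scenario_args))
    tally <- c(`0` = 0L, `1` = 0L, `2` = 0L)
    failed <- 0L
    for (rep in seq_len(config$n_reps)) {
      tables <- simulate_counts(theta, setup = setup)
      ## warnings (boundary fits, sub-tolerance clamps) are routine in a
      ## bulk simulation and are reflected in the tallies instead
      sel <- tryCatch(suppressWarnings({
        fits <- fit_all_models(tables)
        hlrt(fits, alpha = config$alpha)$selected_model
      }), error = function(e) NA_integer_)
      if (is.na(sel)) failed <- failed + 1L
      else tally[as.character(sel)] <- tally[as.character(sel)] + 1L
    }
    n_ok <- sum(tally)
    rate <- if (n_ok > 0) tally[[as.character(config$true_model)]] / n_ok
            else NA_real_
    data.frame(G = G, n_model0 = tally[["0"]], n_model1 = tally[["1"]],
               n_model2 = tally[["2"]], n_failed = failed,
               true_rate = rate,
               se = if (n_ok > 0) sqrt(rate * (1 - rate) / n_ok) else NA_real_)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "config") <- config
  class(out) <- c("sim_study", class(out))
  out
}
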