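# Independent oracles and instance generators shared across test files.

# Full-resolution Poisson log-likelihood over individual read types
# (including the log(n!) terms), for checking that category reduction
# changes the likelihood only by a theta-free constant.
full_loglik_readtypes <- function(rates, counts_by_key, theta) {
  R <- rates$rates
  n <- stats::setNames(numeric(ncol(R)), colnames(R))
  n[names(counts_by_key)] <- counts_by_key
  mu <- as.numeric(theta %*% R)
  sum(stats::dpois(n, mu, log = TRUE))
}

# Generic box-constrained optimizer oracle for the three models, kept
# independent of the EM path: direct numerical maximization of the
# reduced log-likelihoods with analytic gradients.
oracle_loglik_grad <- function(theta_k, table) {
  mu <- as.numeric(table$rates %*% theta_k)
  w <- ifelse(mu > 0, table$counts / mu, 0)
  as.numeric(crossprod(table$rates, w)) - table$isoform_totals
}

oracle_fit_condition <- function(table, n_starts = 3L) {
  I <- ncol(table$rates)
  best <- -Inf
  tot <- max(sum(table$counts), 1)
  for (s in seq_len(n_starts)) {
    init <- rep(tot / max(sum(table$isoform_totals), 1) / I, I) *
      stats::runif(I, 0.3, 3)
    fit <- try(stats::optim(
      pmax(init, 1e-6),
      fn = function(th) -loglik(th, table),
      gr = function(th) -oracle_loglik_grad(th, table),
      method = "L-BFGS-B", lower = 1e-12,
      control = list(maxit = 500, factr = 1e4)), silent = TRUE)
    if (!inherits(fit, "try-error")) best <- max(best, -fit$value)
  }
  best
}

oracle_model2 <- function(tables) {
  sum(vapply(tables, oracle_fit_condition, numeric(1)))
}

oracle_model0 <- function(tables, n_starts = 3L) {
  I <- ncol(tables[[1L]]$rates)
  joint <- function(th) sum(vapply(tables, function(t) loglik(th, t),
                                   numeric(1)))
  gr <- function(th) Reduce(`+`, lapply(tables, oracle_loglik_grad,
                                        theta_k = th))
  best <- -Inf
  tot <- max(sum(vapply(tables, function(t) sum(t$counts), numeric(1))), 1)
  a <- max(sum(vapply(tables, function(t) sum(t$isoform_totals),
                      numeric(1))), 1)
  for (s in seq_len(n_starts)) {
    init <- rep(tot / a / I, I) * stats::runif(I, 0.3, 3)
    fit <- try(stats::optim(pmax(init, 1e-6),
                            fn = function(th) -joint(th),
                            gr = function(th) -gr(th),
                            method = "L-BFGS-B", lower = 1e-12,
                            control = list(maxit = 500, factr = 1e4)),
               silent = TRUE)
    if (!inherits(fit, "try-error")) best <- max(best, -fit$value)
  }
  best
}

# Model 1: optimize over (theta~, tau_1..tau_K) with every tau free; the
# scale redundancy does not change the maximum value, and leaving all tau
# free lets boundary optima (a condition with no reads, tau_k -> 0) be
# represented regardless of which component hits zero.
oracle_model1 <- function(tables, n_starts = 3L) {
  K <- length(tables); I <- ncol(tables[[1L]]$rates)
  joint <- function(par) {
    th <- par[seq_len(I)]
    tau <- par[I + seq_len(K)]
    sum(vapply(seq_len(K), function(k) loglik(tau[k] * th, tables[[k]]),
               numeric(1)))
  }
  grad <- function(par) {
    th <- par[seq_len(I)]
    tau <- par[I + seq_len(K)]
    gk <- lapply(seq_len(K), function(k)
      oracle_loglik_grad(tau[k] * th, tables[[k]]))
    g_th <- Reduce(`+`, lapply(seq_len(K), function(k) tau[k] * gk[[k]]))
    g_tau <- vapply(seq_len(K), function(k) sum(th * gk[[k]]), numeric(1))
    c(g_th, g_tau)
  }
  best <- -Inf
  tot <- max(sum(vapply(tables, function(t) sum(t$counts), numeric(1))), 1)
  a <- max(sum(vapply(tables, function(t) sum(t$isoform_totals),
                      numeric(1))), 1)
  for (s in seq_len(n_starts)) {
    init <- c(rep(tot / a / I, I) * stats::runif(I, 0.3, 3),
              stats::runif(K, 0.5, 2))
    fit <- try(stats::optim(pmax(init, 1e-6),
                            fn = function(p) -joint(p),
                            gr = function(p) -grad(p),
                            method = "L-BFGS-B", lower = 1e-12,
                            control = list(maxit = 1000, factr = 1e4)),
               silent = TRUE)
    if (!inherits(fit, "try-error")) best <- max(best, -fit$value)
  }
  best
}

# Random small estimation instance: I isoforms, K conditions, <= 6
# categories per condition, counts drawn from the model itself so that
# likelihood surfaces are well behaved but zeros still occur.
random_instance <- function(I = sample(1:3, 1), K = sample(1:3, 1),
                            true_model = sample(0:2, 1)) {
  n_cat <- sample(2:6, 1)
  rates <- matrix(stats::rexp(n_cat * I, rate = 0.5), n_cat, I)
  rates[stats::runif(n_cat * I) < 0.3] <- 0
  for (c_ix in seq_len(n_cat))       # no dead categories
    if (all(rates[c_ix, ] == 0)) rates[c_ix, sample(I, 1)] <- stats::rexp(1)
  totals <- colSums(rates) * stats::runif(I, 1, 1.6) + 0.1
  base <- stats::rexp(I, rate = 1 / 5)
  theta <- switch(as.character(if (K == 1) 2 else true_model),
                  "0" = matrix(rep(base, each = K), K),
                  "1" = outer(stats::runif(K, 0.3, 3), base),
                  "2" = matrix(stats::rexp(K * I, rate = 1 / 5), K))
  tables <- lapply(seq_len(K), function(k) {
    counts <- stats::rpois(n_cat, as.numeric(rates %*% theta[k, ]))
    read_category_table(paste0("cond", k), counts, rates, totals)
  })
  list(tables = tables, theta = theta, I = I, K = K)
}

# The three-exon cassette gene with a directly authored structure,
# independent of default_sim_gene(), for cross-checks.
make_cassette_gene <- function() {
  gene_model("cassette",
             exons = cbind(c(0, 2000, 3000), c(1200, 2060, 3600)),
             isoforms = list(A = 1:3, B = c(1L, 3L)))
}
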