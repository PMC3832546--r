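# Fake fits with prescribed log-likelihoods, for exercising the test
# procedure in isolation from the EM.
fake_fits <- function(l0, l1, l2, K = 2L, I = 2L) {
  mk <- function(id, ll, df) {
    structure(list(model_id = id, theta = matrix(1, K, I),
                   theta_tilde = rep(1, I), tau = rep(1, K), loglik = ll,
                   df = df, n_iter = 1L, converged = TRUE, boundary = FALSE,
                   loglik_path = ll),
              class = "abundance_fit")
  }
  list(m0 = mk(0L, l0, I), m1 = mk(1L, l1, I + K - 1L),
       m2 = mk(2L, l2, K * I))
}

test_that("low-count filter drops only genes weak in every condition", {
  mk <- function(n) read_category_table("c", n, matrix(1, 1, 1), 1)
  expect_false(filter_low_count(list(mk(4), mk(4)), min_reads = 5))
  expect_true(filter_low_count(list(mk(4), mk(100)), min_reads = 5))
  expect_true(filter_low_count(list(mk(5), mk(0)), min_reads = 5))
})

test_that("hierarchical LRT reproduces the worked two-round decisions", {
  ## all likelihoods equal: null case, model 0, p-values 1
  r <- hlrt(fake_fits(-100, -100, -100), alpha = 0.05)
  expect_equal(r$selected_model, 0L)
  expect_equal(unname(r$pvalues[c("p01", "p02")]), c(1, 1))
  expect_true(is.na(r$pvalues[["p12"]]))
  expect_equal(r$T, 0)

  ## K=2, I=2: L01 = 20 > 5.024 (chi2_1 at 0.975), L02 = 22 > 7.378
  ## (chi2_2 at 0.975), second round L12 = 2 < 3.841 (chi2_1 at 0.95)
  r1 <- hlrt(fake_fits(-100, -90, -89), alpha = 0.05)
  expect_equal(r1$selected_model, 1L)
  expect_equal(unname(r1$lrt), c(20, 22, 2))
  expect_false(is.na(r1$pvalues[["p12"]]))

  ## L01 = 2 not significant, L02 = 40 significant: model 2 directly,
  ## without a second round
  r2 <- hlrt(fake_fits(-100, -99, -80), alpha = 0.05)
  expect_equal(r2$selected_model, 2L)
  expect_true(is.na(r2$pvalues[["p12"]]))
  expect_true(is.na(r2$T))

  ## strong second round: model 2
  r3 <- hlrt(fake_fits(-100, -90, -70), alpha = 0.05)
  expect_equal(r3$selected_model, 2L)

  ## chi-squared reference quantiles against standard-table values
  expect_equal(qchisq(0.975, 1), 5.0239, tolerance = 1e-4)
  expect_equal(qchisq(0.975, 2), 7.3778, tolerance = 1e-4)
  expect_equal(qchisq(0.95, 1), 3.8415, tolerance = 1e-4)
})

test_that("single-isoform genes resolve the 1-vs-2 tie to model 1", {
  r <- hlrt(fake_fits(-100, -80, -80, I = 1L), alpha = 0.05)
  expect_equal(r$selected_model, 1L)
  expect_true(is.na(r$pvalues[["p12"]]))
})

test_that("degrees of freedom follow the (K-1), (K-1)I, (K-1)(I-1) rule", {
  for (K in 2:4) for (I in 2:4) {
    ## choose likelihood gaps around the alpha/2 thresholds so that the
    ## selection flips exactly where the chi-squared quantiles sit
    q01 <- qchisq(1 - 0.025, K - 1)
    q02 <- qchisq(1 - 0.025, (K - 1) * I)
    just_over <- hlrt(fake_fits(-100, -100 + (q01 + 0.01) / 2,
                                -100 + (q01 + 0.01) / 2,
                                K = K, I = I), alpha = 0.05)
    just_under <- hlrt(fake_fits(-100, -100 + (q01 - 0.01) / 2,
                                 -100 + (q01 - 0.01) / 2,
                                 K = K, I = I), alpha = 0.05)
    expect_equal(just_over$selected_model, 1L)
    expect_equal(just_under$selected_model, 0L)
    over02 <- hlrt(fake_fits(-100, -100, -100 + (q02 + 0.01) / 2,
                             K = K, I = I), alpha = 0.05)
    expect_equal(over02$selected_model, 2L)
  }
})

test_that("selection is monotone in alpha for fixed likelihoods", {
  fits <- fake_fits(-100, -97.4, -94.1)
  sel <- vapply(c(0.001, 0.01, 0.05, 0.10, 0.25, 0.5),
                function(a) hlrt(fits, alpha = a)$selected_model, integer(1))
  expect_true(all(diff(sel) >= 0))
})

test_that("negative LRT statistics are clamped with a warning", {
  w <- capture_warnings(r <- hlrt(fake_fits(-100, -100.001, -100.002)))
  expect_length(w, 3L)
  expect_true(all(grepl("clamped", w)))
  expect_equal(unname(r$lrt), c(0, 0, 0))
  expect_equal(r$selected_model, 0L)
})

test_that("run_all_genes handles filtering, failures and validation", {
  set.seed(5)
  g <- make_cassette_gene()
  setup <- sim_setup(g, c(20e6, 20e6), 50)
  strong <- simulate_counts(matrix(c(40, 10, 10, 40), 2, 2, byrow = TRUE),
                            setup = setup)
  weak <- lapply(strong, function(t)
    read_category_table(t$condition_id, rep(1, nrow(t$rates)), t$rates,
                        t$isoform_totals))
  dataset <- list(gA = list(gene = g, tables = strong),
                  gB = list(gene = g, tables = weak))
  res <- run_all_genes(dataset, alpha = 0.05, min_reads = 5)
  tab <- results_table(res)
  expect_equal(tab$status, c("tested", "filtered"))
  expect_equal(tab$selected_model[1L], 2L)
  expect_equal(tab$T[1L],
               t_statistic(res$gA$fits$m2$theta[1L, ],
                           res$gA$fits$m2$theta[2L, ]))
  expect_false(is.na(tab$ci_hat[1L]))
  expect_true(is.na(tab$p01[2L]))

  names(dataset) <- c("gA", "gA")
  expect_error(run_all_genes(dataset), "duplicate gene_id: gA")
  expect_warning(empty <- run_all_genes(list()), "empty")
  expect_length(empty, 0L)
})

test_that("null simulation keeps the type-I error near alpha", {
  set.seed(88)
  g <- make_cassette_gene()
  cfg <- sim_config(gene = g, G_grid = 20, true_model = 0, n_reps = 120,
                    alpha = 0.05, seed = 88)
  study <- run_study(cfg)
  ## 0.05 plus 3 binomial SEs at 120 reps
  expect_lte(1 - study$true_rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 120))
})
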