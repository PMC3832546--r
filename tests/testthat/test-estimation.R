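test_that("log-likelihood evaluates the linear Poisson model", {
  tab <- read_category_table("c1", 3, matrix(1, 1, 1), isoform_totals = 1)
  expect_equal(loglik(1, tab), 3 * log(1) - 1)
  expect_equal(loglik(2, tab), 3 * log(2) - 2)
  expect_error(loglik(-1, tab), "negative")

  ## all counts zero: only the linear penalty remains, zero at theta = 0
  tab0 <- read_category_table("c1", numeric(0), matrix(0, 0, 2),
                              isoform_totals = c(3, 4))
  expect_equal(loglik(c(0, 0), tab0), 0)
  expect_equal(loglik(c(1, 1), tab0), -7)

  ## positive count with zero expected rate is impossible under the model
  tab2 <- read_category_table("c1", c(4, 2),
                              matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE),
                              isoform_totals = c(2, 2))
  expect_equal(loglik(c(1, 0), tab2), -Inf)

  ## matches the full Poisson pmf up to the dropped log(n!) constant
  set.seed(7)
  for (rep in 1:5) {
    inst <- random_instance(I = 2, K = 1)
    tab <- inst$tables[[1L]]
    theta <- stats::rexp(2, 1 / 5)
    direct <- sum(stats::dpois(tab$counts,
                               as.numeric(tab$rates %*% theta), log = TRUE)) -
      (sum(tab$isoform_totals * theta) -
         sum(as.numeric(tab$rates %*% theta)))
    offset <- sum(lfactorial(tab$counts))
    expect_equal(loglik(theta, tab), direct + offset, tolerance = 1e-10)
  }
})

test_that("model 2 EM recovers closed forms for isoform-specific data", {
  ## categories that each touch a single isoform: theta_i = n_i / a_i
  rates <- matrix(c(2, 0, 0, 3), 2, 2, byrow = TRUE,
                  dimnames = list(NULL, c("i1", "i2")))
  tab1 <- read_category_table("c1", c(10, 9), rates, isoform_totals = c(4, 6))
  tab2 <- read_category_table("c2", c(40, 3), rates, isoform_totals = c(4, 6))
  fit <- fit_model2(list(tab1, tab2))
  expect_equal(fit$theta[1L, ], c(10 / 4, 9 / 6), tolerance = 1e-7)
  expect_equal(fit$theta[2L, ], c(40 / 4, 3 / 6), tolerance = 1e-7)
  expect_equal(fit$df, 4L)
  expect_true(fit$converged)

  ## zero reads in a condition: zero vector, boundary flagged
  tab0 <- read_category_table("c1", numeric(0), matrix(0, 0, 2),
                              isoform_totals = c(4, 6))
  fit0 <- fit_model2(list(tab0))
  expect_equal(fit0$theta[1L, ], c(0, 0))
  expect_true(fit0$boundary)

  ## K = 1: model 0 and model 2 coincide
  f2 <- fit_model2(list(tab1))
  f0 <- fit_model0(list(tab1))
  expect_equal(f0$loglik, f2$loglik, tolerance = 1e-8)
  expect_equal(f0$theta_tilde, f2$theta[1L, ], tolerance = 1e-6)
})

test_that("model 0 pools conditions and model 1 nests between 0 and 2", {
  ## identical tables in both conditions: shared fit equals the
  ## single-condition MLE and tau stays flat
  set.seed(11)
  inst <- random_instance(I = 2, K = 1, true_model = 2)
  tab <- inst$tables[[1L]]
  single <- fit_model2(list(tab))
  joint <- fit_model0(list(tab, tab))
  expect_equal(joint$theta_tilde, single$theta[1L, ], tolerance = 1e-5)

  m1 <- fit_model1(list(tab, tab))
  expect_equal(m1$tau, c(1, 1), tolerance = 1e-5)
  expect_equal(m1$loglik, joint$loglik, tolerance = 1e-6)
  expect_equal(m1$df, 2L + 2L - 1L)

  ## model 1 identity: theta rows are tau_k * theta~ and sum(tau) = K
  expect_equal(m1$theta, outer(m1$tau, m1$theta_tilde))
  expect_equal(sum(m1$tau), 2)
})

test_that("model 1 recovers a pure fold change", {
  set.seed(23)
  g <- make_cassette_gene()
  setup <- sim_setup(g, c(50e6, 55e6), 50)
  theta <- outer(c(0.5, 1.5), c(10, 10))   # condition 2 at 3x condition 1
  tables <- simulate_counts(theta, setup = setup)
  m1 <- fit_model1(tables)
  expect_true(m1$converged)
  expect_equal(m1$tau[2L] / m1$tau[1L], 3, tolerance = 0.1)
  ## the alternating EM reaches the optimizer-oracle maximum
  set.seed(24)
  expect_equal(m1$loglik, oracle_model1(tables), tolerance = 1e-4)
})

test_that("EM optima match the box-constrained optimizer and nest", {
  set.seed(101)
  for (rep in 1:12) {
    inst <- random_instance()
    tables <- inst$tables
    fits <- fit_all_models(tables, tol = 1e-12, max_iter = 50000)
    scale <- abs(fits$m2$loglik) + 1
    expect_lte(fits$m0$loglik, fits$m1$loglik + 1e-6 * scale)
    expect_lte(fits$m1$loglik, fits$m2$loglik + 1e-6 * scale)
    expect_equal(fits$m2$loglik, oracle_model2(tables),
                 tolerance = 1e-4)
    expect_equal(fits$m0$loglik, oracle_model0(tables),
                 tolerance = 1e-4)
    if (inst$K >= 2)
      expect_gte(fits$m1$loglik, oracle_model1(tables) -
                   1e-4 * scale)
  }
})

test_that("EM log-likelihood is monotone over iterations", {
  set.seed(202)
  for (rep in 1:8) {
    inst <- random_instance()
    for (fit in fit_all_models(inst$tables)) {
      path <- fit$loglik_path
      if (length(path) > 1L)
        expect_gte(min(diff(path)), -1e-8 * (abs(path[1L]) + 1))
    }
  }
})

test_that("rate/abundance rescaling invariance holds", {
  set.seed(33)
  inst <- random_instance(I = 2, K = 2, true_model = 2)
  c0 <- 3.7
  scaled <- lapply(inst$tables, function(t)
    read_category_table(t$condition_id, t$counts, t$rates * c0,
                        t$isoform_totals * c0))
  f <- fit_model2(inst$tables)
  fs <- fit_model2(scaled)
  ## category means a*theta are invariant, so the optima coincide and the
  ## estimates scale by 1/c
  expect_equal(fs$theta, f$theta / c0, tolerance = 1e-5)
  expect_equal(fs$loglik, f$loglik, tolerance = 1e-6)
})

test_that("Wald intervals match the Poisson closed form and flag zeros", {
  ## one isoform, unit rate: theta-hat = n, se = sqrt(n)
  n <- 47
  tab <- read_category_table("c1", n, matrix(1, 1, 1), isoform_totals = 1)
  fit <- fit_model2(list(tab))
  ci <- confidence_intervals(fit, list(tab), level = 0.95)
  z <- qnorm(0.975)
  expect_equal(ci$estimate, n, tolerance = 1e-6)
  expect_equal(ci$lower, n - z * sqrt(n), tolerance = 1e-4)
  expect_equal(ci$upper, n + z * sqrt(n), tolerance = 1e-4)

  ## zero-count isoform: one-sided [0, upper] with the exact Poisson bound
  rates <- matrix(c(1, 0), 1, 2)
  tab2 <- read_category_table("c1", 5, rates, isoform_totals = c(1, 2))
  fit2 <- fit_model2(list(tab2))
  ci2 <- confidence_intervals(fit2, list(tab2))
  expect_equal(ci2$estimate[2L], 0)
  expect_equal(ci2$lower[2L], 0)
  expect_equal(ci2$upper[2L], -log(0.05) / 2, tolerance = 1e-8)
})

test_that("interval coverage is near nominal at moderate depth", {
  set.seed(77)
  g <- make_cassette_gene()
  setup <- sim_setup(g, c(50e6, 55e6), 50)
  theta <- matrix(c(12, 6, 4, 14), 2, 2, byrow = TRUE)
  hits <- 0L; total <- 0L
  for (rep in 1:150) {
    tables <- simulate_counts(theta, setup = setup)
    fit <- fit_model2(tables)
    ci <- confidence_intervals(fit, tables, level = 0.95)
    truth <- as.numeric(t(theta))
    ok <- !is.na(ci$lower)
    hits <- hits + sum(ci$lower[ok] <= truth[ok] & truth[ok] <= ci$upper[ok])
    total <- total + sum(ok)
  }
  expect_gt(hits / total, 0.90)
  expect_lt(hits / total, 0.99)
})
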