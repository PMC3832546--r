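#' Poisson log-likelihood of one condition's read categories
#'
#' Evaluates the linear Poisson model log-likelihood
#' `sum_j n_j log(sum_i a_ij theta_i) - sum_i a_i theta_i`, dropping the
#' theta-independent `log(n_j!)` terms. A category with positive count but
#' zero expected rate makes the likelihood `-Inf`.
#'
#' @param theta_k Length-I non-negative abundance vector.
#' @param table A [read_category_table()].
#' @return The log-likelihood (up to the dropped constant).
#' @export
loglik <- function(theta_k, table) {
  stopifnot(inherits(table, "read_category_table"))
  theta_k <- as.numeric(theta_k)
  if (length(theta_k) != ncol(table$rates))
    stop("theta has wrong length")
  if (any(theta_k < 0)) stop("negative isoform abundance")
  penalty <- sum(table$isoform_totals * theta_k)
  if (length(table$counts) == 0L) return(-penalty)
  mu <- as.numeric(table$rates %*% theta_k)
  if (any(mu == 0 & table$counts > 0)) return(-Inf)
  pos <- table$counts > 0
  sum(table$counts[pos] * log(mu[pos])) - penalty
}

.check_tables <- function(tables) {
  if (inherits(tables, "read_category_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "read_category_table")))
  I <- unique(vapply(tables, function(t) ncol(t$rates), integer(1)))
  if (length(I) != 1L) stop("conditions disagree on the number of isoforms")
  tables
}

## one EM sweep's expected per-isoform read counts E_i = sum_j n_j r_ij for
## a single condition at mean vector mu_j = sum_i a_ij theta_i
.expected_counts <- function(table, theta_k) {
  I <- ncol(table$rates)
  if (length(table$counts) == 0L) return(numeric(I))
  mu <- as.numeric(table$rates %*% theta_k)
  w <- ifelse(mu > 0, table$counts / mu, 0)
  as.numeric(crossprod(table$rates, w)) * theta_k
}

.em_defaults <- list(tol = 1e-8, max_iter = 2000L)

.new_fit <- function(model_id, theta, theta_tilde, tau, ll, df, n_iter,
                     converged, boundary, loglik_path) {
  structure(
    list(model_id = model_id, theta = theta, theta_tilde = theta_tilde,
         tau = tau, loglik = ll, df = df, n_iter = n_iter,
         converged = converged, boundary = boundary,
         loglik_path = loglik_path),
    class = "abundance_fit")
}

#' @export
print.abundance_fit <- function(x, ...) {
  cat("abundance_fit model ", x$model_id, ": loglik ",
      format(x$loglik), ", df ", x$df, ", ", x$n_iter, " EM iterations",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Fit model 2 (independent abundances per condition)
#'
#' Each condition has its own free abundance vector; the maximum likelihood
#' estimate is computed per condition by EM. The E-step distributes each
#' category count over compatible isoforms in proportion to
#' `a_ij theta_i`; the M-step sets `theta_i` to expected count over total
#' sampling rate. Isoforms with zero total sampling rate in a condition are
#' fixed at 0 and flagged.
#'
#' @param tables List of [read_category_table()], one per condition.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap; non-convergence is reported, not raised.
#' @return An `"abundance_fit"` with `model_id = 2`, `theta` (K x I),
#'   `loglik = l2`, `df = K * I`.
#' @export
fit_model2 <- function(tables, tol = .em_defaults$tol,
                       max_iter = .em_defaults$max_iter) {
  tables <- .check_tables(tables)
  K <- length(tables); I <- ncol(tables[[1L]]$rates)
  theta <- matrix(0, K, I)
  ll_k <- numeric(K); iters <- 0L; conv <- TRUE
  path <- numeric(0); boundary <- FALSE
  for (k in seq_len(K)) {
    tab <- tables[[k]]
    a <- tab$isoform_totals
    live <- a > 0
    if (!any(live) || sum(tab$counts) == 0) {
      ll_k[k] <- loglik(numeric(I), tab)
      boundary <- boundary || sum(tab$counts) == 0
      next
    }
    th <- numeric(I)
    th[live] <- sum(tab$counts) / (sum(a[live]) * sum(live))
    ll_old <- loglik(th, tab)
    path_k <- ll_old
    for (it in seq_len(max_iter)) {
      E <- .expected_counts(tab, th)
      th[live] <- E[live] / a[live]
      ll_new <- loglik(th, tab)
      path_k <- c(path_k, ll_new)
      if (is.finite(ll_old) &&
          abs(ll_new - ll_old) <= tol * (abs(ll_old) + 1)) break
      ll_old <- ll_new
    }
    iters <- max(iters, it)
    conv <- conv && (it < max_iter)
    ll_k[k] <- loglik(th, tab)
    theta[k, ] <- th
    path <- if (length(path)) path else path_k
    boundary <- boundary || any(th[live] == 0)
  }
  .new_fit(2L, theta, theta_tilde = NULL, tau = NULL, ll = sum(ll_k),
           df = K * I, n_iter = iters, converged = conv,
           boundary = boundary, loglik_path = path)
}

.joint_loglik <- function(theta, tables) {
  sum(vapply(seq_along(tables),
             function(k) loglik(theta[k, ], tables[[k]]), numeric(1)))
}

#' Fit model 0 (one shared abundance vector)
#'
#' All conditions share a single abundance vector; the joint likelihood is
#' the product over conditions and the EM update pools expected counts and
#' total sampling rates across conditions.
#'
#' @inheritParams fit_model2
#' @return An `"abundance_fit"` with `model_id = 0`, `theta_tilde`
#'   (length I), `theta` with identical rows, `loglik = l0`, `df = I`.
#' @export
fit_model0 <- function(tables, tol = .em_defaults$tol,
                       max_iter = .em_defaults$max_iter) {
  tables <- .check_tables(tables)
  K <- length(tables); I <- ncol(tables[[1L]]$rates)
  a_pool <- Reduce(`+`, lapply(tables, `[[`, "isoform_totals"))
  live <- a_pool > 0
  n_tot <- sum(vapply(tables, function(t) sum(t$counts), numeric(1)))
  th <- numeric(I)
  theta_of <- function(v) matrix(rep(v, each = K), K, I)
  if (!any(live) || n_tot == 0) {
    ll <- .joint_loglik(theta_of(th), tables)
    return(.new_fit(0L, theta_of(th), th, NULL, ll, I, 0L, TRUE,
                    boundary = TRUE, loglik_path = ll))
  }
  th[live] <- n_tot / (sum(a_pool[live]) * sum(live))
  ll_old <- .joint_loglik(theta_of(th), tables)
  path <- ll_old
  for (it in seq_len(max_iter)) {
    E <- Reduce(`+`, lapply(tables, .expected_counts, theta_k = th))
    th[live] <- E[live] / a_pool[live]
    ll_new <- .joint_loglik(theta_of(th), tables)
    path <- c(path, ll_new)
    if (is.finite(ll_old) &&
        abs(ll_new - ll_old) <= tol * (abs(ll_old) + 1)) break
    ll_old <- ll_new
  }
  .new_fit(0L, theta_of(th), th, NULL, ll_new, I, it, it < max_iter,
           boundary = any(th[live] == 0), loglik_path = path)
}

#' Fit model 1 (proportional abundances: common splicing, free gene level)
#'
#' The abundance matrix is the outer product `theta_k = tau_k * theta_tilde`
#' of a per-condition fold vector tau and a basic isoform vector; the
#' relative isoform mix is shared while the overall gene level varies.
#' For identifiability tau is constrained to `sum(tau) = K`, so
#' `tau = (1, ..., 1)` recovers model 0. Fitting alternates conditional
#' EM updates of theta_tilde and tau (each a closed form given the expected
#' isoform-condition counts) and rescales tau to the constraint at the end,
#' which leaves the likelihood unchanged.
#'
#' @inheritParams fit_model2
#' @return An `"abundance_fit"` with `model_id = 1`, `theta_tilde`, `tau`,
#'   `theta = outer(tau, theta_tilde)`, `loglik = l1`, `df = I + K - 1`.
#'   A condition driven to `tau_k = 0` (no reads) sets the boundary flag.
#' @export
fit_model1 <- function(tables, tol = .em_defaults$tol,
                       max_iter = .em_defaults$max_iter) {
  tables <- .check_tables(tables)
  K <- length(tables); I <- ncol(tables[[1L]]$rates)
  if (K < 2L)
    stop("model 1 needs at least two conditions (it equals model 0 at K = 1)")
  a_mat <- do.call(rbind, lapply(tables, `[[`, "isoform_totals"))  # K x I
  tau <- rep(1, K)
  live <- colSums(a_mat) > 0
  n_k <- vapply(tables, function(t) sum(t$counts), numeric(1))
  th <- numeric(I)
  if (!any(live) || sum(n_k) == 0) {
    ll <- .joint_loglik(outer(tau, th), tables)
    return(.new_fit(1L, outer(tau, th), th, tau, ll, I + K - 1L, 0L, TRUE,
                    boundary = TRUE, loglik_path = ll))
  }
  th[live] <- sum(n_k) / (sum(a_mat[, live]) * sum(live))
  ll_old <- .joint_loglik(outer(tau, th), tables)
  path <- ll_old
  for (it in seq_len(max_iter)) {
    ## E-step: expected isoform-condition counts at current (tau, theta~);
    ## responsibilities depend only on the isoform mix, so tau cancels
    E <- do.call(rbind, lapply(seq_len(K), function(k)
      .expected_counts(tables[[k]], tau[k] * th)))          # K x I
    denom <- as.numeric(crossprod(a_mat, tau))              # sum_k tau_k a_ki
    ok <- live & denom > 0
    th[ok] <- colSums(E)[ok] / denom[ok]
    gene_rate <- as.numeric(a_mat %*% th)                   # sum_i a_ki th_i
    tau <- ifelse(gene_rate > 0, rowSums(E) / gene_rate, 0)
    ll_new <- .joint_loglik(outer(tau, th), tables)
    path <- c(path, ll_new)
    if (is.finite(ll_old) &&
        abs(ll_new - ll_old) <= tol * (abs(ll_old) + 1)) break
    ll_old <- ll_new
  }
  ## absorb the scale into theta~ so that sum(tau) = K
  s <- sum(tau)
  if (s > 0) { th <- th * s / K; tau <- tau * K / s }
  ll <- .joint_loglik(outer(tau, th), tables)
  .new_fit(1L, outer(tau, th), th, tau, ll, I + K - 1L, it, it < max_iter,
           boundary = any(tau == 0) || any(th[live] == 0), loglik_path = path)
}

#' Fit all three nested models of a gene
#'
#' Convenience wrapper running [fit_model0()], [fit_model1()] and
#' [fit_model2()] on the same per-condition tables. Enforces the nesting
#' `l0 <= l1 <= l2` up to numerical tolerance.
#'
#' @inheritParams fit_model2
#' @return Named list `list(m0, m1, m2)` of `"abundance_fit"` objects.
#' @export
fit_all_models <- function(tables, tol = .em_defaults$tol,
                           max_iter = .em_defaults$max_iter) {
  tables <- .check_tables(tables)
  m0 <- fit_model0(tables, tol, max_iter)
  m2 <- fit_model2(tables, tol, max_iter)
  m1 <- if (length(tables) >= 2L) fit_model1(tables, tol, max_iter) else m0
  list(m0 = m0, m1 = m1, m2 = m2)
}

## observed Fisher information of theta for one condition at the fit:
## I[i,l] = sum_j n_j a_ij a_lj / mu_j^2 (the linear penalty term drops out)
.cond_information <- function(table, theta_k) {
  I <- ncol(table$rates)
  if (length(table$counts) == 0L) return(matrix(0, I, I))
  mu <- as.numeric(table$rates %*% theta_k)
  ok <- mu > 0
  if (!any(ok)) return(matrix(0, I, I))
  W <- table$rates[ok, , drop = FALSE] / mu[ok]
  crossprod(W * sqrt(table$counts[ok]))
}

.wald_bounds <- function(est, var, level) {
  n <- length(est)
  lo <- rep(NA_real_, n); up <- rep(NA_real_, n)
  z2 <- stats::qnorm((1 + level) / 2)
  z1 <- stats::qnorm(level)
  for (i in seq_len(n)) {
    if (is.na(var[i]) || var[i] < 0) next
    se <- sqrt(var[i])
    if (est[i] > 0) {
      lo[i] <- max(0, est[i] - z2 * se); up[i] <- est[i] + z2 * se
    } else {
      lo[i] <- 0; up[i] <- z1 * se      # one-sided at the zero boundary
    }
  }
  cbind(lower = lo, upper = up)
}

## variance vector from an information matrix restricted to usable rows;
## singular blocks yield NA
.var_from_info <- function(info, est, zero_rate) {
  p <- nrow(info)
  v <- rep(NA_real_, p)
  use <- diag(info) > 0
  if (any(use)) {
    V <- try(solve(info[use, use, drop = FALSE]), silent = TRUE)
    if (!inherits(V, "try-error") && all(is.finite(diag(V))))
      v[use] <- diag(V)
  }
  ## parameter with no information but a positive total rate: exact
  ## one-sided Poisson bound for zero observed counts, expressed as a
  ## pseudo-variance so that qnorm(level) * sqrt(v) reproduces it
  v
}

#' Wald confidence intervals for a fitted model
#'
#' Intervals come from the observed Fisher information of the fitted
#' model's free parameters, truncated below at zero. Parameters estimated
#' exactly at the zero boundary get a one-sided interval `[0, upper]`; a
#' zero-count isoform with no Fisher information uses the exact Poisson
#' zero-count bound `upper = -log(1 - level) / a_i`. A singular
#' information block yields `NA` bounds rather than an error.
#'
#' @param est An `"abundance_fit"`.
#' @param tables The per-condition tables the model was fitted to.
#' @param level Coverage level, typically 0.95.
#' @return A data.frame with columns `parameter`, `condition`, `isoform`,
#'   `estimate`, `lower`, `upper`. For model 0 the free parameters are the
#'   shared abundances; for model 1 the basic abundances and the fold
#'   vector tau; for model 2 the per-condition abundances.
#' @export
confidence_intervals <- function(est, tables, level = 0.95) {
  stopifnot(inherits(est, "abundance_fit"), level > 0, level < 1)
  tables <- .check_tables(tables)
  K <- length(tables); I <- ncol(tables[[1L]]$rates)
  iso <- colnames(tables[[1L]]$rates)
  if (is.null(iso)) iso <- paste0("iso", seq_len(I))
  zero_bound <- function(a_i) {
    ifelse(a_i > 0, -log(1 - level) / a_i, NA_real_)
  }
  if (est$model_id == 2L) {
    out <- lapply(seq_len(K), function(k) {
      th <- est$theta[k, ]
      info <- .cond_information(tables[[k]], th)
      v <- .var_from_info(info, th, NULL)
      b <- .wald_bounds(th, v, level)
      nofi <- th == 0 & is.na(v)
      b[nofi, 1L] <- 0
      b[nofi, 2L] <- zero_bound(tables[[k]]$isoform_totals[nofi])
      data.frame(parameter = paste0("theta[", k, ",", seq_len(I), "]"),
                 condition = tables[[k]]$condition_id, isoform = iso,
                 estimate = th, lower = b[, 1L], upper = b[, 2L])
    })
    return(do.call(rbind, out))
  }
  if (est$model_id == 0L) {
    th <- est$theta_tilde
    info <- Reduce(`+`, lapply(tables, .cond_information, theta_k = th))
    v <- .var_from_info(info, th, NULL)
    b <- .wald_bounds(th, v, level)
    nofi <- th == 0 & is.na(v)
    a_pool <- Reduce(`+`, lapply(tables, `[[`, "isoform_totals"))
    b[nofi, 1L] <- 0; b[nofi, 2L] <- zero_bound(a_pool[nofi])
    return(data.frame(parameter = paste0("theta_tilde[", seq_len(I), "]"),
                      condition = "all", isoform = iso,
                      estimate = th, lower = b[, 1L], upper = b[, 2L]))
  }
  ## model 1: free parameters phi = (theta~, tau_1..tau_{K-1}); the linear
  ## constraint sum(tau) = K eliminates tau_K, and since it is linear the
  ## constrained Hessian is J' H J exactly
  th <- est$theta_tilde; tau <- est$tau
  a_mat <- do.call(rbind, lapply(tables, `[[`, "isoform_totals"))
  H_tt <- -Reduce(`+`, lapply(seq_len(K), function(k)
    .cond_information(tables[[k]], tau[k] * th) * tau[k]^2))
  n_k <- vapply(tables, function(t) sum(t$counts), numeric(1))
  H_tau <- diag(ifelse(tau > 0, -n_k / tau^2, 0), K)
  H_cross <- -t(a_mat)                                     # d2l/dth_i dtau_k
  H <- rbind(cbind(H_tt, H_cross), cbind(t(H_cross), H_tau))
  J <- rbind(cbind(diag(I), matrix(0, I, K - 1L)),
             cbind(matrix(0, K - 1L, I), diag(K - 1L)),
             c(numeric(I), rep(-1, K - 1L)))
  Hc <- t(J) %*% H %*% J
  info <- -Hc
  phi <- c(th, tau[-K])
  v <- .var_from_info(info, phi, NULL)
  v_tauK <- {                                   # var of tau_K = K - sum
    idx <- I + seq_len(K - 1L)
    use <- diag(info) > 0
    if (all(use[idx])) {
      V <- try(solve(info[use, use, drop = FALSE]), silent = TRUE)
      if (!inherits(V, "try-error")) {
        sub <- which(which(use) %in% idx)
        sum(V[sub, sub])
      } else NA_real_
    } else NA_real_
  }
  bt <- .wald_bounds(th, v[seq_len(I)], level)
  nofi <- th == 0 & is.na(v[seq_len(I)])
  bt[nofi, 1L] <- 0
  bt[nofi, 2L] <- zero_bound(colSums(a_mat)[nofi])
  btau <- .wald_bounds(tau, c(v[I + seq_len(K - 1L)], v_tauK), level)
  rbind(
    data.frame(parameter = paste0("theta_tilde[", seq_len(I), "]"),
               condition = "all", isoform = iso,
               estimate = th, lower = bt[, 1L], upper = bt[, 2L]),
    data.frame(parameter = paste0("tau[", seq_len(K), "]"),
               condition = vapply(tables, `[[`, "", "condition_id"),
               isoform = NA_character_,
               estimate = tau, lower = btau[, 1L], upper = btau[, 2L]))
}
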