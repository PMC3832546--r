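#' Low-count gene filter
#'
#' A gene is dropped only when every condition has fewer than `min_reads`
#' mapped reads; a single adequately covered condition keeps it.
#'
#' @param tables List of [read_category_table()] for one gene.
#' @param min_reads Threshold (default 5); a condition with exactly
#'   `min_reads` reads passes.
#' @return `TRUE` to keep the gene, `FALSE` to drop it.
#' @export
filter_low_count <- function(tables, min_reads = 5) {
  tables <- .check_tables(tables)
  tot <- vapply(tables, function(t) sum(t$counts), numeric(1))
  any(tot >= min_reads)
}

#' Hierarchical likelihood ratio test for model selection
#'
#' Two-round procedure over the nested models. First round, each test at
#' level `alpha / 2`: model 0 vs model 1 with `-2(l0 - l1)` against
#' chi-squared on `K - 1` degrees of freedom, and model 0 vs model 2 with
#' `-2(l0 - l2)` against `(K - 1) * I` degrees of freedom. If neither is
#' significant model 0 is selected; exactly one significant selects that
#' model. If both are significant, the second round compares model 1 vs
#' model 2 at level `alpha` with `-2(l1 - l2)` against
#' `(K - 1) * (I - 1)` degrees of freedom, selecting model 2 when
#' significant and model 1 otherwise.
#'
#' For a single-isoform gene (`I = 1`) models 1 and 2 coincide; when both
#' first-round tests fire the lower-complexity model 1 is selected and
#' `p12` is `NA`.
#'
#' Small negative statistics from numerical noise are clamped to zero; a
#' deficit beyond `1e-6` triggers a warning since it indicates
#' non-convergence of an EM fit.
#'
#' @param fits List `list(m0, m1, m2)` of `"abundance_fit"` objects (see
#'   [fit_all_models()]).
#' @param alpha Overall significance level in (0, 1).
#' @param gene_id Identifier carried into the result.
#' @return Object of class `"gene_result"`: fields `gene_id`,
#'   `selected_model` (0, 1 or 2), `lrt` (named vector L01, L02, L12),
#'   `pvalues` (p01, p02, p12; p12 `NA` unless the second round ran),
#'   `alpha`, `fits`, `T` (filled by [run_all_genes()]; 0 here for models
#'   0/1, `NA` otherwise), `boundary`.
#' @export
hlrt <- function(fits, alpha = 0.05, gene_id = "gene") {
  stopifnot(alpha > 0, alpha < 1,
            all(c("m0", "m1", "m2") %in% names(fits)))
  m0 <- fits$m0; m1 <- fits$m1; m2 <- fits$m2
  K <- nrow(m2$theta); I <- ncol(m2$theta)
  if (K < 2L) stop("model selection needs at least two conditions")
  clamp <- function(x, label) {
    if (x < -1e-6)
      warning("negative LRT statistic ", format(x), " for ", label,
              " in gene '", gene_id, "' (non-convergence?); clamped to 0")
    max(x, 0)
  }
  L01 <- clamp(-2 * (m0$loglik - m1$loglik), "model 0 vs 1")
  L02 <- clamp(-2 * (m0$loglik - m2$loglik), "model 0 vs 2")
  L12 <- clamp(-2 * (m1$loglik - m2$loglik), "model 1 vs 2")
  df01 <- K - 1L
  df02 <- (K - 1L) * I
  df12 <- (K - 1L) * (I - 1L)
  p01 <- stats::pchisq(L01, df01, lower.tail = FALSE)
  p02 <- stats::pchisq(L02, df02, lower.tail = FALSE)
  sig01 <- p01 < alpha / 2
  sig02 <- p02 < alpha / 2
  p12 <- NA_real_
  if (!sig01 && !sig02) {
    sel <- 0L
  } else if (sig01 && !sig02) {
    sel <- 1L
  } else if (!sig01 && sig02) {
    sel <- 2L
  } else if (I == 1L) {
    sel <- 1L                         # models 1 and 2 identical at I = 1
  } else {
    p12 <- stats::pchisq(L12, df12, lower.tail = FALSE)
    sel <- if (p12 < alpha) 2L else 1L
  }
  structure(
    list(gene_id = gene_id, selected_model = sel,
         lrt = c(L01 = L01, L02 = L02, L12 = L12),
         pvalues = c(p01 = p01, p02 = p02, p12 = p12),
         alpha = alpha, fits = fits,
         T = if (sel %in% c(0L, 1L)) 0 else NA_real_,
         boundary = m0$boundary || m1$boundary || m2$boundary),
    class = "gene_result")
}

#' @export
print.gene_result <- function(x, ...) {
  cat("gene_result '", x$gene_id, "': ",
      if (identical(x$selected_model, "filtered")) "filtered"
      else paste0("model ", x$selected_model),
      "  (p01 = ", format(x$pvalues[["p01"]], digits = 3),
      ", p02 = ", format(x$pvalues[["p02"]], digits = 3), ")\n", sep = "")
  invisible(x)
}

.filtered_result <- function(gene_id, alpha) {
  structure(
    list(gene_id = gene_id, selected_model = "filtered",
         lrt = c(L01 = NA_real_, L02 = NA_real_, L12 = NA_real_),
         pvalues = c(p01 = NA_real_, p02 = NA_real_, p12 = NA_real_),
         alpha = alpha, fits = NULL, T = NA_real_, boundary = FALSE),
    class = "gene_result")
}

.failed_result <- function(gene_id, alpha, msg) {
  r <- .filtered_result(gene_id, alpha)
  r$selected_model <- NA
  attr(r, "error") <- msg
  r
}

#' Classify every gene of a dataset
#'
#' Runs the low-count filter, the three EM fits and the hierarchical LRT
#' over all genes, in input (annotation) order. Per-gene numerical
#' failures are caught, logged and reported with `selected_model = NA`
#' rather than aborting the run. For two-condition analyses the T
#' differential-splicing statistic is filled in for model-2 genes.
#'
#' @param dataset Named list, one element per gene, each a list with
#'   `gene` (a [gene_model()], optional) and `tables` (list of
#'   [read_category_table()], one per condition, same conditions for all
#'   genes).
#' @param alpha Significance level of the hierarchical LRT.
#' @param min_reads Low-count filter threshold (see [filter_low_count()]).
#' @return Object of class `"gene_result_list"`: list of
#'   [hlrt()] results (or filtered/failed placeholders) named by gene.
#' @export
run_all_genes <- function(dataset, alpha = 0.05, min_reads = 5) {
  if (length(dataset) == 0L) {
    warning("empty dataset")
    return(structure(list(), class = "gene_result_list"))
  }
  ids <- names(dataset)
  if (is.null(ids) || any(ids == ""))
    stop("dataset elements must be named by gene_id")
  if (anyDuplicated(ids))
    stop("duplicate gene_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  K <- unique(vapply(dataset, function(g) length(g$tables), integer(1)))
  if (length(K) != 1L || K < 2L)
    stop("every gene needs the same set of >= 2 conditions")
  out <- vector("list", length(dataset))
  names(out) <- ids
  for (gid in ids) {
    tables <- dataset[[gid]]$tables
    if (!filter_low_count(tables, min_reads)) {
      out[[gid]] <- .filtered_result(gid, alpha)
      next
    }
    out[[gid]] <- tryCatch({
      fits <- fit_all_models(tables)
      res <- hlrt(fits, alpha = alpha, gene_id = gid)
      if (length(tables) == 2L && identical(res$selected_model, 2L))
        res$T <- t_statistic(fits$m2$theta[1L, ], fits$m2$theta[2L, ])
      res$ci <- tryCatch(
        confidence_intervals(fits[[paste0("m", res$selected_model)]], tables),
        error = function(e) NULL)
      res
    }, error = function(e) {
      message("gene '", gid, "' failed: ", conditionMessage(e))
      .failed_result(gid, alpha, conditionMessage(e))
    })
  }
  structure(out, class = "gene_result_list")
}

#' Tabulate gene results
#'
#' Flattens a result list into the standard output table: status, selected
#' model, the three log-likelihoods and p-values, T, and the per-isoform
#' abundance estimates of the selected model per condition. A
#' Benjamini-Hochberg adjusted `p02` column (`padj02`) is added across the
#' tested genes as a convenience extension; per-gene selection itself uses
#' only the fixed-level hierarchical LRT.
#'
#' @param results A `"gene_result_list"` from [run_all_genes()].
#' @return A data.frame, one row per gene.
#' @export
results_table <- function(results) {
  stopifnot(inherits(results, "gene_result_list"))
  rows <- lapply(results, function(r) {
    sel <- r$selected_model
    status <- if (identical(sel, "filtered")) "filtered"
              else if (is.na(sel[1L]) && !is.numeric(sel)) "failed"
              else "tested"
    ll <- if (is.null(r$fits)) rep(NA_real_, 3)
          else vapply(r$fits, `[[`, numeric(1), "loglik")
    theta <- if (status == "tested") {
      fit <- r$fits[[paste0("m", sel)]]
      paste(apply(fit$theta, 1L, function(row)
        paste(signif(row, 6), collapse = ",")), collapse = ";")
    } else NA_character_
    ci <- if (status == "tested" && !is.null(r$ci)) {
      paste(sprintf("%s[%s,%s]", r$ci$parameter,
                    signif(r$ci$lower, 6), signif(r$ci$upper, 6)),
            collapse = ";")
    } else NA_character_
    data.frame(
      gene_id = r$gene_id, status = status,
      selected_model = if (status == "tested") as.integer(sel) else NA_integer_,
      l0 = ll[1L], l1 = ll[2L], l2 = ll[3L],
      p01 = r$pvalues[["p01"]], p02 = r$pvalues[["p02"]],
      p12 = r$pvalues[["p12"]], T = r$T,
      boundary = r$boundary, theta_hat = theta, ci_hat = ci)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$padj02 <- NA_real_
  tested <- out$status == "tested"
  if (any(tested)) out$padj02[tested] <- stats::p.adjust(out$p02[tested], "BH")
  out
}
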