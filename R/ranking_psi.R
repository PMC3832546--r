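#' T statistic for differential splicing magnitude
#'
#' Half the L1 distance between the two conditions' L1-normalized isoform
#' abundance vectors,
#' `T = 0.5 * || theta1/||theta1||_1 - theta2/||theta2||_1 ||_1`.
#' The half bounds T in \[0, 1\]: 0 when the isoform mix is identical
#' (proportional vectors, i.e. any model-0 or model-1 gene) and 1 when the
#' two conditions express disjoint sets of isoforms.
#'
#' @param theta_1,theta_2 Non-negative abundance vectors of equal length.
#' @return T in \[0, 1\], or `NA` (with a warning) if either vector is
#'   all zero.
#' @examples
#' t_statistic(c(3, 1), c(1, 3))   # 0.5
#' t_statistic(c(5, 5), c(15, 15)) # 0: proportional
#' @export
t_statistic <- function(theta_1, theta_2) {
  theta_1 <- as.numeric(theta_1); theta_2 <- as.numeric(theta_2)
  if (length(theta_1) != length(theta_2))
    stop("abundance vectors must have the same length")
  if (any(theta_1 < 0) || any(theta_2 < 0))
    stop("abundances must be non-negative")
  s1 <- sum(theta_1); s2 <- sum(theta_2)
  if (s1 == 0 || s2 == 0) {
    warning("all-zero abundance vector; T undefined")
    return(NA_real_)
  }
  0.5 * sum(abs(theta_1 / s1 - theta_2 / s2))
}

#' Rank genes by differential-splicing evidence
#'
#' Orders gene results either by the T statistic (descending; defined only
#' for two-condition analyses) or by the model-0-vs-model-2 p-value
#' (ascending; any number of conditions). Model-0, filtered and failed
#' genes sink to the bottom, as do `NA` ranking keys; ties break by
#' `gene_id` so the order is fully deterministic.
#'
#' @param results A `"gene_result_list"` from [run_all_genes()].
#' @param by `"T"` or `"pvalue"`.
#' @return The [results_table()] data.frame reordered, with a `rank`
#'   column prepended.
#' @export
rank_genes <- function(results, by = c("T", "pvalue")) {
  by <- match.arg(by)
  stopifnot(inherits(results, "gene_result_list"))
  tab <- results_table(results)
  if (by == "T") {
    K <- unique(unlist(lapply(results, function(r)
      if (!is.null(r$fits)) nrow(r$fits$m2$theta))))
    if (length(K) && any(K != 2L))
      stop("T-ranking is defined for exactly two conditions")
    key <- tab$T
    key[is.na(key)] <- -Inf
    ord <- order(-key, tab$gene_id)
  } else {
    key <- tab$p02
    key[is.na(key)] <- Inf
    ## significance ranking still puts untested genes last
    key[tab$status != "tested"] <- Inf
    ord <- order(key, tab$gene_id)
  }
  out <- tab[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Exon inclusion level from junction read counts
#'
#' For a cassette (skipped) exon, builds the two-isoform representation of
#' the local junction evidence: the inclusion isoform carries the upstream
#' and downstream junction regions (each `junction_length` bp), the
#' skipping isoform carries the single skipping junction region. Under the
#' linear Poisson model each junction region is one read category whose
#' sampling rate is common to all regions, so the MLE has the closed form
#' `theta_long = (UJC + DJC) / 2`, `theta_short = SJC` (per junction
#' region, up to the common rate constant), giving
#' `psi = (UJC + DJC) / ((UJC + DJC) + 2 * SJC)`.
#'
#' @param ujc,djc,sjc Non-negative integer read counts on the upstream,
#'   downstream and skipping junctions.
#' @param junction_length Junction region length in bp (default 84);
#'   common to all three regions, so it cancels from psi.
#' @return List with `theta_long`, `theta_short` (abundances in units of
#'   reads per junction region) and `psi` (inclusion level in \[0, 1\],
#'   `NA` when all three counts are zero).
#' @examples
#' psi_from_junctions(30, 30, 20)$psi  # 0.6
#' @export
psi_from_junctions <- function(ujc, djc, sjc, junction_length = 84) {
  counts <- c(ujc, djc, sjc)
  if (any(is.na(counts)) || any(counts < 0))
    stop("junction counts must be non-negative")
  if (sum(counts) == 0)
    return(list(theta_long = 0, theta_short = 0, psi = NA_real_))
  theta_long <- (ujc + djc) / 2
  theta_short <- sjc
  list(theta_long = theta_long, theta_short = theta_short,
       psi = theta_long / (theta_long + theta_short))
}

#' Read category table of the two-isoform junction model
#'
#' The explicit linear Poisson representation whose EM fit the closed form
#' of [psi_from_junctions()] reproduces: three categories (upstream,
#' downstream, skipping junction regions), each with unit sampling rate
#' for its isoform; the inclusion isoform totals 2 regions, the skipping
#' isoform 1.
#'
#' @inheritParams psi_from_junctions
#' @param condition_id Condition label.
#' @return A [read_category_table()] with isoforms `long`, `short`.
#' @export
junction_category_table <- function(ujc, djc, sjc, condition_id = "cond1") {
  rates <- matrix(c(1, 0,
                    1, 0,
                    0, 1), 3, 2, byrow = TRUE,
                  dimnames = list(NULL, c("long", "short")))
  read_category_table(condition_id, c(ujc, djc, sjc), rates,
                      isoform_totals = c(2, 1))
}

#' Difference of exon inclusion levels between two conditions
#'
#' @param psi_cond1,psi_cond2 Inclusion levels in \[0, 1\] (or `NA`).
#' @return `psi_cond1 - psi_cond2`, `NA`-propagating.
#' @export
delta_psi <- function(psi_cond1, psi_cond2) {
  chk <- function(p) {
    if (!is.na(p) && (p < 0 || p > 1)) stop("psi must lie in [0, 1]")
    p
  }
  chk(psi_cond1) - chk(psi_cond2)
}

#' Exon inclusion level from full-length isoform abundances
#'
#' The inclusion level of an exon is the abundance fraction of the
#' isoforms containing it, summed over ALL of the gene's isoforms (not
#' only the pair flanking the local event), so evidence from every read of
#' the gene enters through the fitted abundances.
#'
#' @param gene A [gene_model()].
#' @param exon_index Index of the exon (row of `gene$exons`).
#' @param theta Length-I abundance vector for one condition.
#' @return psi in \[0, 1\], or `NA` if the exon is in every isoform or in
#'   none (not an inclusion event) or all abundances are zero.
#' @export
psi_from_isoforms <- function(gene, exon_index, theta) {
  stopifnot(inherits(gene, "gene_model"))
  exon_index <- as.integer(exon_index)
  if (exon_index < 1L || exon_index > nrow(gene$exons))
    stop("exon_index out of range")
  theta <- as.numeric(theta)
  if (length(theta) != length(gene$isoforms))
    stop("theta has wrong length")
  if (any(theta < 0)) stop("abundances must be non-negative")
  has <- vapply(gene$isoforms, function(ix) exon_index %in% ix, logical(1))
  if (all(has) || !any(has)) return(NA_real_)
  tot <- sum(theta)
  if (tot == 0) return(NA_real_)
  sum(theta[has]) / tot
}
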