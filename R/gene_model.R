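#' Construct a gene model
#'
#' A gene model holds the exon structure of one gene together with the
#' exon composition of each annotated isoform. It is the object from which
#' read-sampling rates are derived under the single-end uniform sampling
#' model.
#'
#' Coordinates are 0-based half-open (BED convention): an exon `(start, end)`
#' covers bases `start, ..., end - 1` and has length `end - start`.
#'
#' @param gene_id Character scalar identifier.
#' @param exons Two-column numeric matrix (or data.frame) of exon
#'   `(start, end)` intervals, 0-based half-open, in genomic order.
#' @param isoforms Named list; each element an integer vector of exon
#'   indices (into rows of `exons`), strictly increasing.
#' @param strand One of `"+"`, `"-"`, `"*"` (unknown). Recorded for
#'   reporting only; sampling rates depend solely on exon structure.
#'
#' @return An object of class `"gene_model"` with fields `gene_id`,
#'   `exons`, `isoforms`, `strand`, plus derived `exon_lengths` and
#'   `isoform_lengths`.
#' @examples
#' g <- gene_model("g1", cbind(c(0, 1300, 1400), c(1200, 1360, 2000)),
#'                 list(A = 1:3, B = c(1L, 3L)))
#' isoform_lengths(g)
#' @export
gene_model <- function(gene_id, exons, isoforms, strand = "*") {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L) stop("'exons' must have two columns (start, end)")
  storage.mode(exons) <- "double"
  colnames(exons) <- c("start", "end")
  if (nrow(exons) < 1L) stop("gene '", gene_id, "' has no exons")
  if (any(exons[, "end"] <= exons[, "start"]))
    stop("gene '", gene_id, "': every exon must have end > start")
  if (!is.list(isoforms) || length(isoforms) == 0L)
    stop("gene '", gene_id, "' must have at least one isoform")
  if (is.null(names(isoforms)))
    names(isoforms) <- paste0("iso", seq_along(isoforms))
  isoforms <- lapply(isoforms, function(ix) {
    ix <- as.integer(ix)
    if (length(ix) == 0L) stop("isoform with no exons in gene '", gene_id, "'")
    if (any(ix < 1L | ix > nrow(exons)))
      stop("isoform exon index out of range in gene '", gene_id, "'")
    if (any(diff(ix) <= 0L))
      stop("isoform exon indices must be strictly increasing in gene '",
           gene_id, "'")
    ix
  })
  if (!strand %in% c("+", "-", "*")) strand <- "*"
  exon_len <- exons[, "end"] - exons[, "start"]
  iso_len <- vapply(isoforms, function(ix) sum(exon_len[ix]), numeric(1))
  structure(
    list(gene_id = gene_id, exons = exons, isoforms = isoforms,
         strand = strand, exon_lengths = unname(exon_len),
         isoform_lengths = iso_len),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model '", x$gene_id, "' (", x$strand, "): ",
      nrow(x$exons), " exons, ", length(x$isoforms), " isoforms\n", sep = "")
  for (nm in names(x$isoforms))
    cat("  ", nm, ": exons {", paste(x$isoforms[[nm]], collapse = ","),
        "}, length ", x$isoform_lengths[[nm]], "\n", sep = "")
  invisible(x)
}

#' Isoform lengths of a gene model
#' @param gene A `gene_model`.
#' @return Named numeric vector of transcript lengths (bp).
#' @export
isoform_lengths <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  gene$isoform_lengths
}

## genomic footprint of the transcript window [s, s + len) (0-based,
## transcript coordinates) of isoform `ix` (vector of exon indices);
## returns "start-end;start-end;..." with book-ended blocks merged so that
## identical genomic footprints always serialize identically
.footprint_key <- function(exons, ix, s, len) {
  blocks_s <- numeric(0); blocks_e <- numeric(0)
  t0 <- 0
  for (e in ix) {
    el <- exons[e, 2L] - exons[e, 1L]
    lo <- max(s, t0); hi <- min(s + len, t0 + el)
    if (hi > lo) {
      gs <- exons[e, 1L] + (lo - t0)
      ge <- gs + (hi - lo)
      n <- length(blocks_s)
      if (n > 0L && blocks_e[n] == gs) {
        blocks_e[n] <- ge            # merge book-ended exons
      } else {
        blocks_s <- c(blocks_s, gs); blocks_e <- c(blocks_e, ge)
      }
    }
    t0 <- t0 + el
    if (t0 >= s + len) break
  }
  paste(blocks_s, blocks_e, sep = "-", collapse = ";")
}

#' Enumerate read types of a gene
#'
#' A read type is the equivalence class of single-end reads with the same
#' genomic footprint: the projection to the genome of a contiguous
#' `read_length`-bp window in transcript coordinates. Two isoforms share a
#' read type exactly when both contain that footprint contiguously in their
#' own transcript coordinates. Isoforms shorter than the read length
#' contribute no read types.
#'
#' @param gene A [gene_model()].
#' @param read_length Positive integer read length (bp).
#' @return A list with `keys` (character vector of genomic footprint keys,
#'   one per read type) and `compat` (I x J logical matrix; `compat[i, j]`
#'   is `TRUE` if isoform i can generate read type j).
#' @export
enumerate_read_types <- function(gene, read_length) {
  stopifnot(inherits(gene, "gene_model"))
  read_length <- as.integer(read_length)
  if (read_length < 1L) stop("'read_length' must be >= 1")
  I <- length(gene$isoforms)
  if (all(gene$isoform_lengths < read_length))
    stop("gene '", gene$gene_id, "' unquantifiable at this read length: ",
         "all isoforms shorter than ", read_length, " bp")
  key_sets <- vector("list", I)
  for (i in seq_len(I)) {
    L <- gene$isoform_lengths[i]
    if (L < read_length) { key_sets[[i]] <- character(0); next }
    n_start <- L - read_length + 1
    keys_i <- character(n_start)
    ix <- gene$isoforms[[i]]
    for (s in seq_len(n_start))
      keys_i[s] <- .footprint_key(gene$exons, ix, s - 1, read_length)
    key_sets[[i]] <- keys_i
  }
  keys <- unique(unlist(key_sets))
  compat <- matrix(FALSE, nrow = I, ncol = length(keys),
                   dimnames = list(names(gene$isoforms), keys))
  for (i in seq_len(I)) compat[i, key_sets[[i]]] <- TRUE
  list(keys = keys, compat = compat)
}

#' Build the read sampling rate matrix for one condition
#'
#' Under the uniform sampling model every possible read type of a
#' transcript is generated at the same rate. The rate of read type j from
#' isoform i is therefore `depth_scale` if the footprint is contained in
#' the isoform and 0 otherwise, and the total sampling rate of isoform i is
#' `depth_scale * (L_i - read_length + 1)`.
#'
#' `depth_scale` is the per-condition constant converting abundance units
#' into expected read counts; [depth_scale_rpkm()] gives the value that
#' makes abundances RPKM-like and hence comparable across conditions of
#' different sequencing depth.
#'
#' @param gene A [gene_model()].
#' @param read_length Positive integer read length (bp).
#' @param depth_scale Positive per-condition scale (expected reads per read
#'   type per unit abundance).
#' @param condition_id Label for the condition.
#' @return An object of class `"sampling_rates"`: fields `condition_id`,
#'   `rates` (I x J matrix, columns named by footprint key),
#'   `isoform_totals` (length I), `read_length`, `depth_scale`, `gene_id`.
#' @export
build_sampling_rates <- function(gene, read_length, depth_scale,
                                 condition_id = "cond1") {
  if (!is.numeric(depth_scale) || depth_scale <= 0)
    stop("'depth_scale' must be a positive real")
  rt <- enumerate_read_types(gene, read_length)
  rates <- rt$compat * depth_scale
  totals <- pmax(gene$isoform_lengths - read_length + 1, 0) * depth_scale
  structure(
    list(condition_id = condition_id, rates = rates,
         isoform_totals = unname(totals), read_length = read_length,
         depth_scale = depth_scale, gene_id = gene$gene_id),
    class = "sampling_rates")
}

#' Depth scale giving RPKM-like abundance units
#'
#' With `depth_scale = total_mapped_reads / 1e9`, a transcript of length
#' ~1 kb at abundance theta = 1 is expected to yield about one read per
#' million mapped reads, so theta estimates are comparable across
#' conditions sequenced at different depths.
#'
#' @param total_mapped_reads Total number of mapped reads in the condition.
#' @return The per-condition `depth_scale`.
#' @export
depth_scale_rpkm <- function(total_mapped_reads) {
  stopifnot(total_mapped_reads > 0)
  total_mapped_reads / 1e9
}

#' Construct a read category table
#'
#' The reduced form of the per-condition read evidence: read types sharing
#' an isoform-compatibility pattern are merged into categories, and only
#' the per-isoform total sampling rates are kept besides the category
#' rates. The Poisson log-likelihood over categories equals the one over
#' read types up to an additive constant free of theta, so maximum
#' likelihood estimates are unchanged.
#'
#' Zero-count categories are dropped; duplicate rate rows are merged
#' defensively (counts summed).
#'
#' @param condition_id Condition label.
#' @param counts Numeric vector of category read counts.
#' @param rates C x I matrix of category sampling rates (row c = summed
#'   rate vector of the read types merged into category c).
#' @param isoform_totals Length-I vector of per-isoform total sampling
#'   rates over ALL read types (including unobserved ones).
#' @param total_reads_mapped Total assignable reads for this gene and
#'   condition (defaults to `sum(counts)`).
#' @return Object of class `"read_category_table"`.
#' @export
read_category_table <- function(condition_id, counts, rates, isoform_totals,
                                total_reads_mapped = sum(counts)) {
  rates <- as.matrix(rates)
  counts <- as.numeric(counts)
  if (length(counts) != nrow(rates))
    stop("length(counts) must equal nrow(rates)")
  if (any(counts < 0)) stop("negative category count")
  if (any(rates < 0)) stop("negative sampling rate")
  if (length(isoform_totals) != ncol(rates))
    stop("isoform_totals length must equal number of isoforms")
  keep <- counts > 0
  counts <- counts[keep]
  rates <- rates[keep, , drop = FALSE]
  if (nrow(rates) > 1L) {
    pat <- apply(rates, 1L, paste, collapse = "\r")
    if (anyDuplicated(pat)) {
      counts <- as.numeric(tapply(counts, pat, sum)[unique(pat)])
      rates <- rates[!duplicated(pat), , drop = FALSE]
    }
  }
  structure(
    list(condition_id = condition_id, counts = counts, rates = rates,
         isoform_totals = as.numeric(isoform_totals),
         total_reads_mapped = total_reads_mapped),
    class = "read_category_table")
}

#' @export
print.read_category_table <- function(x, ...) {
  cat("read_category_table [", x$condition_id, "]: ",
      length(x$counts), " categories, ", ncol(x$rates), " isoforms, ",
      x$total_reads_mapped, " reads\n", sep = "")
  invisible(x)
}

#' Reduce observed read-type counts to read categories
#'
#' Groups read types with identical compatibility patterns into maximal
#' categories, summing counts and rate vectors. Read types never observed
#' contribute only through the per-isoform totals. Observed reads on a
#' read type compatible with no isoform are reported as unassignable (with
#' a warning) and excluded.
#'
#' @param rates A `"sampling_rates"` object.
#' @param observed_counts Named numeric vector of read counts, names being
#'   read-type footprint keys present in `rates`.
#' @return A [read_category_table()]. The number of unassignable reads is
#'   attached as attribute `"unassignable"`.
#' @export
reduce_to_categories <- function(rates, observed_counts) {
  stopifnot(inherits(rates, "sampling_rates"))
  if (length(observed_counts) &&
      (is.null(names(observed_counts)) ||
       !all(names(observed_counts) %in% colnames(rates$rates))))
    stop("every observed read type must exist in the sampling rate matrix")
  R <- rates$rates
  full_counts <- stats::setNames(numeric(ncol(R)), colnames(R))
  full_counts[names(observed_counts)] <-
    full_counts[names(observed_counts)] + as.numeric(observed_counts)
  unassignable <- 0
  dead <- colSums(R) == 0
  if (any(dead & full_counts > 0)) {
    unassignable <- sum(full_counts[dead])
    warning(sum(full_counts[dead]), " reads on read types compatible with ",
            "no isoform; excluded as unassignable")
    full_counts[dead] <- 0
  }
  obs <- full_counts > 0
  if (!any(obs)) {
    tab <- read_category_table(rates$condition_id, numeric(0),
                               matrix(0, 0, nrow(R)), rates$isoform_totals,
                               total_reads_mapped = 0)
  } else {
    Ro <- R[, obs, drop = FALSE]
    pat <- apply(Ro > 0, 2L, paste, collapse = "")
    grp <- split(seq_along(pat), pat)
    grp <- grp[order(vapply(grp, min, integer(1)))]   # deterministic order
    cat_counts <- vapply(grp, function(j) sum(full_counts[obs][j]), numeric(1))
    cat_rates <- t(vapply(grp, function(j)
      rowSums(Ro[, j, drop = FALSE]), numeric(nrow(R))))
    tab <- read_category_table(rates$condition_id, cat_counts, cat_rates,
                               rates$isoform_totals)
  }
  attr(tab, "unassignable") <- unassignable
  tab
}

#' Full category partition of a sampling-rate matrix
#'
#' Partitions ALL read types (observed or not) by compatibility pattern,
#' returning the per-category summed rate matrix. This is the natural
#' resolution at which to simulate Poisson counts: thinning makes a draw
#' per category equivalent in distribution to a draw per read type
#' followed by reduction.
#'
#' @param rates A `"sampling_rates"` object.
#' @return List with `rates` (C x I matrix) and `members` (list of
#'   read-type indices per category).
#' @export
category_partition <- function(rates) {
  stopifnot(inherits(rates, "sampling_rates"))
  R <- rates$rates
  live <- colSums(R) > 0
  Ro <- R[, live, drop = FALSE]
  pat <- apply(Ro > 0, 2L, paste, collapse = "")
  grp <- split(seq_along(pat), pat)
  grp <- grp[order(vapply(grp, min, integer(1)))]
  cat_rates <- t(vapply(grp, function(j)
    rowSums(Ro[, j, drop = FALSE]), numeric(nrow(R))))
  rownames(cat_rates) <- NULL
  list(rates = cat_rates, members = unname(grp))
}
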