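#' Read gene models from an annotation file
#'
#' GTF input is parsed with rtracklayer (exon features grouped by
#' `transcript_id` within `gene_id`, 1-based coordinates converted to the
#' package's 0-based half-open convention). The refFlat fallback is the
#' UCSC tab-separated format (geneName, name, chrom, strand, txStart,
#' txEnd, cdsStart, cdsEnd, exonCount, exonStarts, exonEnds), already
#' 0-based half-open.
#'
#' Exons are deduplicated per gene and stored in genomic order; a
#' transcript with no exons is skipped with a warning. Gene order is the
#' order of first appearance, making downstream iteration deterministic.
#'
#' @param path Annotation file path.
#' @param format `"gtf"` or `"refflat"`.
#' @return Named list of [gene_model()].
#' @export
read_annotation <- function(path, format = c("gtf", "refflat")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "gtf") .read_gtf(path) else .read_refflat(path)
}

.assemble_genes <- function(tx) {
  ## tx: data.frame gene_id, transcript_id, start, end (0-based half-open)
  if (nrow(tx) == 0L) {
    warning("annotation contains no exons")
    return(list())
  }
  out <- list()
  for (gid in unique(tx$gene_id)) {
    sub <- tx[tx$gene_id == gid, , drop = FALSE]
    exons <- unique(sub[, c("start", "end")])
    exons <- exons[order(exons$start, exons$end), , drop = FALSE]
    key <- paste(exons$start, exons$end)
    isoforms <- list()
    for (tid in unique(sub$transcript_id)) {
      e <- sub[sub$transcript_id == tid, , drop = FALSE]
      if (nrow(e) == 0L) next
      ix <- sort(match(paste(e$start, e$end), key))
      isoforms[[tid]] <- unique(ix)
    }
    if (length(isoforms) == 0L) {
      warning("gene '", gid, "' has no usable transcripts; skipped")
      next
    }
    strand <- unique(sub$strand)
    out[[gid]] <- gene_model(gid, as.matrix(exons), isoforms,
                             strand = if (length(strand) == 1L) strand
                                      else "*")
  }
  out
}

.read_gtf <- function(path) {
  if (!any(nzchar(trimws(readLines(path))))) {
    warning("annotation contains no exons")
    return(list())
  }
  gr <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(gr)
  if (!"type" %in% names(md)) stop("malformed GTF: no feature type column")
  ex <- md[md$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0L) {
    warning("annotation contains no exons")
    return(list())
  }
  if (!all(c("gene_id", "transcript_id") %in% names(ex)))
    stop("GTF exons must carry gene_id and transcript_id attributes")
  .assemble_genes(data.frame(
    gene_id = ex$gene_id, transcript_id = ex$transcript_id,
    start = ex$start - 1L, end = ex$end,        # GTF is 1-based inclusive
    strand = as.character(ex$strand)))
}

.read_refflat <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("annotation contains no exons")
    return(list())
  }
  rows <- lapply(seq_along(lines), function(ln) {
    f <- strsplit(lines[[ln]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 11L)
      stop("malformed refFlat line ", ln, ": expected 11 fields, got ",
           length(f))
    starts <- as.numeric(strsplit(f[10L], ",")[[1L]])
    ends <- as.numeric(strsplit(f[11L], ",")[[1L]])
    n <- as.integer(f[9L])
    if (length(starts) != n || length(ends) != n || anyNA(starts) ||
        anyNA(ends))
      stop("malformed refFlat line ", ln, ": exon list does not match ",
           "exonCount")
    data.frame(gene_id = f[1L], transcript_id = f[2L],
               start = starts, end = ends, strand = f[4L])
  })
  .assemble_genes(do.call(rbind, rows))
}

#' Write per-gene read category tables to TSV
#'
#' One `category` row per read category (count + per-isoform rates) and
#' one `totals` row per gene/condition carrying the per-isoform total
#' sampling rates (in the rate columns) and the total mapped reads (in the
#' count column). The header declares the number of isoforms via the
#' `rate_i` columns.
#'
#' @param tables_by_gene Named list (gene) of named lists (condition) of
#'   [read_category_table()]; all genes must share the isoform count.
#' @param path Output file.
#' @export
write_category_table_tsv <- function(tables_by_gene, path) {
  I <- max(vapply(tables_by_gene, function(g)
    max(vapply(g, function(t) ncol(t$rates), integer(1))), integer(1)))
  rate_names <- paste0("rate_", seq_len(I))
  pad <- function(v) {
    v <- unname(as.numeric(v))
    stats::setNames(as.list(c(v, rep(NA_real_, I - length(v)))), rate_names)
  }
  rows <- list()
  for (gid in names(tables_by_gene)) {
    for (cid in names(tables_by_gene[[gid]])) {
      tab <- tables_by_gene[[gid]][[cid]]
      for (c_ix in seq_along(tab$counts))
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, condition = cid, record = "category",
          count = tab$counts[c_ix],
          pad(signif(tab$rates[c_ix, ], 6)))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, condition = cid, record = "totals",
        count = tab$total_reads_mapped,
        pad(signif(tab$isoform_totals, 6)))
    }
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read per-gene, per-condition read category tables from TSV
#'
#' Inverse of [write_category_table_tsv()]. Duplicate category rows (same
#' rate vector) are merged defensively with summed counts; negative counts
#' or missing totals rows are errors.
#'
#' @param path Input TSV.
#' @param genes Optional named list of [gene_model()]; when given, each
#'   gene's rate-vector length is checked against its isoform count.
#' @return Named list (gene) of named lists (condition) of
#'   [read_category_table()].
#' @export
read_category_table_tsv <- function(path, genes = NULL) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "condition", "record", "count")
  if (!all(need %in% names(df)))
    stop("category table must have columns: ", paste(need, collapse = ", "))
  rate_cols <- grep("^rate_[0-9]+$", names(df), value = TRUE)
  if (length(rate_cols) == 0L) stop("no rate_<i> columns found")
  rate_cols <- rate_cols[order(as.integer(sub("rate_", "", rate_cols)))]
  if (any(df$count < 0, na.rm = TRUE)) stop("negative count in ", path)
  out <- list()
  for (gid in unique(df$gene_id)) {
    sub <- df[df$gene_id == gid, , drop = FALSE]
    R <- as.matrix(sub[, rate_cols, drop = FALSE])
    I <- max(which(colSums(!is.na(R)) > 0))
    if (!is.null(genes)) {
      if (!gid %in% names(genes))
        stop("gene '", gid, "' absent from annotation")
      if (I != length(genes[[gid]]$isoforms))
        stop("gene '", gid, "': rate vector length ", I,
             " does not match annotation (", length(genes[[gid]]$isoforms),
             " isoforms)")
    }
    conds <- list()
    for (cid in unique(sub$condition)) {
      s2 <- sub[sub$condition == cid, , drop = FALSE]
      tot <- s2[s2$record == "totals", , drop = FALSE]
      if (nrow(tot) != 1L)
        stop("gene '", gid, "', condition '", cid,
             "': expected exactly one totals row")
      cat_rows <- s2[s2$record == "category", , drop = FALSE]
      conds[[cid]] <- read_category_table(
        cid, cat_rows$count,
        as.matrix(cat_rows[, rate_cols[seq_len(I)], drop = FALSE]),
        isoform_totals = as.numeric(tot[1L, rate_cols[seq_len(I)]]),
        total_reads_mapped = tot$count[1L])
    }
    out[[gid]] <- conds
  }
  out
}

#' Assemble an analysis dataset from annotation and tables
#'
#' @param genes Named list of [gene_model()] (annotation order is kept).
#' @param tables_by_gene Output of [read_category_table_tsv()].
#' @return Dataset for [run_all_genes()]: per gene, `gene` + `tables`.
#' @export
build_dataset <- function(genes, tables_by_gene) {
  ids <- intersect(names(genes), names(tables_by_gene))
  if (length(ids) == 0L) stop("no genes shared between annotation and counts")
  out <- lapply(ids, function(gid)
    list(gene = genes[[gid]], tables = unname(tables_by_gene[[gid]])))
  names(out) <- ids
  out
}

#' Write the per-gene results table to TSV
#'
#' Floats are printed with 6 significant digits and `NA` spelled "NA", so
#' identical runs produce byte-identical files.
#'
#' @param results A `"gene_result_list"` or its [results_table()].
#' @param path Output file.
#' @export
write_results_tsv <- function(results, path) {
  tab <- if (inherits(results, "gene_result_list")) results_table(results)
         else results
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = 6)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
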