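#' Reduce mapped reads to read-type counts for one gene
#'
#' Optional ingestion path for SAM/BAM alignments (the canonical input is
#' the pre-computed read-category TSV, which keeps the core free of
#' alignment-format edge cases). Primary alignments of single-end reads
#' are projected to genomic footprints — M/=/X and D operations extend the
#' current block, N opens a new one — and matched against the read types
#' of the gene's sampling-rate matrix. Paired-end alignments are rejected:
#' only the uniform single-end sampling model is implemented, so there is
#' no sampling rate under which paired reads could be scored. Soft- or
#' hard-clipped (partially mapped) reads are excluded.
#'
#' Alignments are assumed to be pre-filtered to the gene's locus; the
#' reference name is not checked.
#'
#' @param path SAM or BAM file. SAM text input is converted on the fly.
#' @param rates A `"sampling_rates"` object for the gene.
#' @return Named numeric vector of counts per read-type footprint key,
#'   restricted to read types present in `rates`. Reads whose footprint
#'   matches no read type are dropped with a warning (count attached as
#'   attribute `"unassignable"`), as are clipped reads (attribute
#'   `"clipped"`).
#' @export
read_alignments <- function(path, rates) {
  stopifnot(inherits(rates, "sampling_rates"))
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(
    path, param = Rsamtools::ScanBamParam(
      what = c("flag", "pos", "cigar")))[[1L]]
  keep <- !is.na(b$pos)
  flag <- b$flag[keep]; pos <- b$pos[keep]; cigar <- b$cigar[keep]
  if (any(bitwAnd(flag, 0x1L) > 0L))
    stop("paired-end alignments: unsupported sampling model ",
         "(only single-end uniform sampling is implemented)")
  primary <- bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L &
    bitwAnd(flag, 0x4L) == 0L
  flag <- flag[primary]; pos <- pos[primary]; cigar <- cigar[primary]
  clipped <- grepl("[SH]", cigar)
  if (any(clipped))
    warning(sum(clipped), " clipped/partially mapped reads excluded")
  pos <- pos[!clipped]; cigar <- cigar[!clipped]
  if (length(pos) == 0L) {
    out <- numeric(0)
    attr(out, "unassignable") <- 0L
    attr(out, "clipped") <- sum(clipped)
    return(out)
  }
  ## alignment blocks on the reference: N opens a new block, D stays
  ## inside the current one
  blocks <- GenomicAlignments::extractAlignmentRangesOnReference(
    cigar, pos = pos, drop.D.ranges = FALSE)
  keys <- vapply(seq_along(blocks), function(i) {
    r <- blocks[[i]]
    paste(BiocGenerics::start(r) - 1L, BiocGenerics::end(r),
          sep = "-", collapse = ";")
  }, character(1))
  counts <- table(keys)
  known <- names(counts) %in% colnames(rates$rates)
  if (any(!known))
    warning(sum(counts[!known]), " reads with footprints matching no ",
            "read type of gene '", rates$gene_id, "'; excluded")
  out <- stats::setNames(as.numeric(counts[known]), names(counts)[known])
  attr(out, "unassignable") <- sum(counts[!known])
  attr(out, "clipped") <- sum(clipped)
  out
}
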