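# normalize any strand-tagged alignment input (strand_calls or a plain
# fragment alignment frame) to chrom / midpoint / strand for counting.
# The fragment midpoint convention is start + floor(len/2) of the 0-based
# half-open fragment interval.
.aln_frame <- function(aln) {
  df <- as.data.frame(aln)
  if ("call" %in% names(df)) df <- df[df$call %in% c("plus", "minus"), ]
  if (!all(c("chrom", "strand") %in% names(df))) {
    stopf("alignments must carry 'chrom' and 'strand' (or strand calls)")
  }
  if (!"midpoint" %in% names(df)) {
    if (!all(c("start", "end") %in% names(df))) {
      stopf("alignments must have 'midpoint' or 'start'/'end'")
    }
    df$midpoint <- df$start + (df$end - df$start) %/% 2L
  }
  df[c("chrom", "midpoint", "strand")]
}

# counts of midpoints within [starts, ends) per interval, stratified by
# chromosome and strand; intervals may overlap each other
.interval_counts <- function(aln, chroms, strands, starts, ends) {
  n <- length(starts)
  out <- integer(n)
  key_a <- paste(aln$chrom, aln$strand)
  key_g <- paste(chroms, strands)
  for (k in unique(key_g)) {
    mids <- sort(aln$midpoint[key_a == k])
    gi <- which(key_g == k)
    if (length(mids) == 0L) next
    out[gi] <- findInterval(ends[gi] - 0.5, mids) -
      findInterval(starts[gi] - 0.5, mids)
  }
  out
}

#' Count strand-aware fragments per gene
#'
#' A fragment is counted for a gene when its midpoint lies in
#' `[start, end)` and its called strand matches the gene's strand (sense) or
#' the opposite strand (antisense).  Each pair counts once.
#'
#' @param aln Strand-tagged alignments: a [resolve_library()] result or any
#'   data frame with `chrom`, `start`, `end` (or `midpoint`) and `strand`.
#' @param genes A `gene_models` table (must be non-empty).
#' @param orientation `"sense"` or `"antisense"`.
#' @return A named integer vector of per-gene fragment counts.
#' @export
count_fragments <- function(aln, genes, orientation = c("sense", "antisense")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(genes, "gene_models"))
  if (nrow(genes) == 0L) stopf("gene list is empty")
  df <- .aln_frame(aln)
  gstrand <- if (orientation == "sense") genes$strand else
    ifelse(genes$strand == "+", "-", "+")
  cnt <- .interval_counts(df, genes$chrom, gstrand, genes$start, genes$end)
  setNames(cnt, genes$gene_id)
}

#' Compute FPKM from fragment counts
#'
#' FPKM (fragments per kilobase of transcript per million mapped fragments):
#' `fpkm = count / (length/1000) / (library/1e6)`.
#'
#' @param counts Named per-gene fragment counts (from [count_fragments()]).
#' @param gene_lengths Gene lengths in bases, recycled/matched to `counts`.
#' @param total_mapped_fragments Library size in mapped fragments (> 0).
#' @return An `fpkm_records` data frame: `gene_id`, `sense_fragments`,
#'   `length`, `fpkm`.
#' @examples
#' compute_fpkm(c(geneA = 10), 2000, 1e6)  # FPKM 5
#' @export
compute_fpkm <- function(counts, gene_lengths, total_mapped_fragments) {
  if (total_mapped_fragments <= 0) stopf("library size must be > 0")
  if (any(gene_lengths <= 0)) stopf("gene lengths must be > 0")
  gene_lengths <- rep_len(gene_lengths, length(counts))
  fpkm <- counts / (gene_lengths / 1000) / (total_mapped_fragments / 1e6)
  structure(data.frame(
    gene_id = if (is.null(names(counts))) as.character(seq_along(counts))
              else names(counts),
    sense_fragments = as.integer(counts),
    length = as.integer(gene_lengths),
    fpkm = as.numeric(fpkm),
    stringsAsFactors = FALSE, row.names = NULL
  ), class = c("fpkm_records", "data.frame"))
}

#' Stratify genes into expression classes by FPKM
#'
#' Genes within `(0, range[2]]` are split into four ordered classes (`low`,
#' `mid1`, `mid2`, `high`) by three strictly increasing boundaries using
#' left-closed right-open intervals; genes with FPKM 0 or above the upper
#' range are assigned to the excluded class `not_expressed`.
#'
#' @param records An `fpkm_records` data frame.
#' @param boundaries Three strictly increasing class boundaries.
#' @param range Plotting range; only genes with `0 < fpkm <= range[2]` are
#'   classed.  The default `c(0.3, 500)` puts `low` below 0.3.
#' @return `records` with an added ordered factor column `expr_class` with
#'   levels `not_expressed, low, mid1, mid2, high`.
#' @export
stratify_fpkm <- function(records, boundaries = c(0.3, 5, 50),
                          range = c(0.3, 500)) {
  if (length(boundaries) != 3L || any(diff(boundaries) <= 0)) {
    stopf("'boundaries' must be 3 strictly increasing values")
  }
  if (boundaries[1] < range[1] || boundaries[3] > range[2]) {
    stopf("'boundaries' must lie within 'range'")
  }
  f <- records$fpkm
  cls <- findInterval(f, boundaries) + 1L  # 1..4
  lv <- c("not_expressed", "low", "mid1", "mid2", "high")
  out <- lv[cls + 1L]
  out[f <= 0 | f > range[2]] <- "not_expressed"
  records$expr_class <- factor(out, levels = lv, ordered = TRUE)
  records
}
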