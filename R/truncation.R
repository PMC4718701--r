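#' Sense-read counts in the 5' and 3' kilobase of each gene
#'
#' Counts sense-strand fragment midpoints in the first 1000 bases downstream
#' of the TSS (the 5' region) and the last 1000 bases upstream of the TES
#' (the 3' region), both taken in the direction of transcription, and
#' normalizes them to region length (1 kb) and library depth (per million
#' mapped fragments).
#'
#' @param aln Strand-tagged alignments (see [count_fragments()]).
#' @param genes A `gene_models` table; genes must be >= 3000 bases so that
#'   the two regions are disjoint.
#' @param library_size Mapped-fragment library size; defaults to the number
#'   of alignments.  Set the `normalize` argument to `"length"` to skip
#'   depth normalization and report per-kilobase raw counts.
#' @param region_len Region length in bases (default 1000).
#' @param genome Optional `toy_genome`; when given, regions extending past a
#'   chromosome end raise an error.
#' @param normalize `"depth"` (length and per-million depth normalization,
#'   default) or `"length"` (length only).
#' @return A `region_counts` data frame: `gene_id`, `raw5`, `raw3`
#'   (fragment counts) and `r5`, `r3` (normalized); the library size used is
#'   attached as attribute `library_size`.
#' @export
region_counts <- function(aln, genes, library_size = NULL,
                          region_len = 1000L, genome = NULL,
                          normalize = c("depth", "length")) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(genes, "gene_models"))
  if (nrow(genes) == 0L) stopf("gene list is empty")
  if (any(genes$end - genes$start < 3L * region_len)) {
    stopf("all genes must be >= %d bases for disjoint regions",
          3L * region_len)
  }
  df <- .aln_frame(aln)
  if (is.null(library_size)) library_size <- nrow(df)
  plus <- genes$strand == "+"
  s5 <- ifelse(plus, genes$start, genes$end - region_len)
  e5 <- s5 + region_len
  s3 <- ifelse(plus, genes$end - region_len, genes$start)
  e3 <- s3 + region_len
  if (!is.null(genome)) {
    L <- chrom_lengths(genome)[genes$chrom]
    if (any(s5 < 0L | s3 < 0L | e5 > L | e3 > L)) {
      stopf("gene region extends past a chromosome end")
    }
  }
  raw5 <- .interval_counts(df, genes$chrom, genes$strand, s5, e5)
  raw3 <- .interval_counts(df, genes$chrom, genes$strand, s3, e3)
  f <- (region_len / 1000)
  depth <- if (normalize == "depth") library_size / 1e6 else 1
  out <- data.frame(gene_id = genes$gene_id,
                    raw5 = raw5, raw3 = raw3,
                    r5 = raw5 / f / depth, r3 = raw3 / f / depth,
                    stringsAsFactors = FALSE)
  structure(out, class = c("region_counts", "data.frame"),
            library_size = library_size, normalize = normalize)
}

#' Screen for genes accumulating 5'-truncated sense transcripts under CPT
#'
#' Implements the four-filter selection for CPT-induced 5' sense-read
#' accumulation: a gene is selected when (i) the CPT-minus-control increase
#' of normalized sense reads in the 5' region is at least `theta5`, (ii) the
#' CPT-minus-control change in the 3' region is at most `theta3` (reduced or
#' equal 3' signal), (iii) the 5' fold change exceeds `fc_min`, and (iv) the
#' raw 5' read count in the CPT library exceeds `min_raw5`.  The fold change
#' divides by `max(r5_ctrl, pseudocount)` (pseudocount expressed in raw
#' reads and scaled to normalized units) so that unexpressed control regions
#' do not produce division by zero.
#'
#' @param ctrl,cpt [region_counts()] results for the control and CPT
#'   libraries over the same genes.
#' @param theta5 Minimum normalized 5' delta (CPT - control).
#' @param theta3 Maximum normalized 3' delta.
#' @param fc_min Minimum 5' fold change (exclusive).
#' @param min_raw5 Minimum raw 5' sense reads in the CPT library
#'   (exclusive).
#' @param pseudocount Pseudocount in raw reads used in the fold-change
#'   denominator.
#' @return A `truncation_screen` data frame with per-gene audit columns
#'   (`r5_ctrl`, `r5_cpt`, `r3_ctrl`, `r3_cpt`, `raw5_cpt`, `delta5`,
#'   `delta3`, `fc5`, `selected`); thresholds are kept as attributes.
#' @export
truncation_screen <- function(ctrl, cpt, theta5 = 10, theta3 = 5,
                              fc_min = 2, min_raw5 = 5, pseudocount = 1) {
  if (is.null(ctrl) || is.null(cpt)) stopf("both conditions are required")
  stopifnot(inherits(ctrl, "region_counts"), inherits(cpt, "region_counts"))
  if (!identical(ctrl$gene_id, cpt$gene_id)) {
    stopf("control and CPT tables must cover the same genes in order")
  }
  lib_ctrl <- attr(ctrl, "library_size")
  pc_norm <- if (identical(attr(ctrl, "normalize"), "depth")) {
    pseudocount / (lib_ctrl / 1e6)
  } else pseudocount
  rec <- data.frame(
    gene_id = ctrl$gene_id,
    r5_ctrl = ctrl$r5, r5_cpt = cpt$r5,
    r3_ctrl = ctrl$r3, r3_cpt = cpt$r3,
    raw5_cpt = cpt$raw5,
    stringsAsFactors = FALSE
  )
  rec$delta5 <- rec$r5_cpt - rec$r5_ctrl
  rec$delta3 <- rec$r3_cpt - rec$r3_ctrl
  rec$fc5 <- rec$r5_cpt / pmax(rec$r5_ctrl, pc_norm)
  rec$selected <- rec$delta5 >= theta5 & rec$delta3 <= theta3 &
    rec$fc5 > fc_min & rec$raw5_cpt > min_raw5
  structure(rec, class = c("truncation_screen", "data.frame"),
            thresholds = list(theta5 = theta5, theta3 = theta3,
                              fc_min = fc_min, min_raw5 = min_raw5,
                              pseudocount = pseudocount))
}

#' @export
print.truncation_screen <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "truncation screen: %d / %d genes selected (delta5 >= %g, delta3 <= %g, FC > %g, raw 5' > %g)\n",
    sum(x$selected), nrow(x), th$theta5, th$theta3, th$fc_min, th$min_raw5))
  invisible(x)
}

#' Genes selected by a truncation screen
#' @param screen A [truncation_screen()] result.
#' @return Character vector of selected gene ids.
#' @export
selected_genes <- function(screen) {
  stopifnot(inherits(screen, "truncation_screen"))
  screen$gene_id[screen$selected]
}
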