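#' Generate a toy reference genome
#'
#' Draws i.i.d. nucleotides with a chosen GC content.  The toy genome stands
#' in for a real assembly so that every downstream statistic can be checked
#' against planted truth; chromosomes are plain ACGT strings.
#'
#' @param seed Integer seed; regeneration with the same seed and parameters
#'   is byte-identical.
#' @param n_chrom Number of chromosomes.
#' @param lengths Integer vector of chromosome lengths (each >= 10000);
#'   recycled to `n_chrom`.
#' @param gc_fraction Target GC fraction, strictly between 0 and 1.  The
#'   empirical GC content of each chromosome concentrates tightly around this
#'   value (binomial sampling).
#' @return An object of class `toy_genome`: a list with `chromosomes` (named
#'   character vector) and `seed`.
#' @examples
#' g <- generate_genome(seed = 1, n_chrom = 1, lengths = 50000)
#' nchar(g$chromosomes)
#' @export
generate_genome <- function(seed, n_chrom = 1L, lengths = 100000L,
                            gc_fraction = 0.5) {
  lengths <- rep_len(as.integer(lengths), n_chrom)
  if (any(is.na(lengths)) || any(lengths <= 0L)) {
    stopf("chromosome lengths must be positive integers")
  }
  if (any(lengths < 10000L)) {
    stopf("chromosome lengths must be >= 10000 (got %d)", min(lengths))
  }
  if (!is.numeric(gc_fraction) || gc_fraction <= 0 || gc_fraction >= 1) {
    stopf("'gc_fraction' must lie strictly between 0 and 1")
  }
  prob <- c((1 - gc_fraction) / 2, gc_fraction / 2,
            gc_fraction / 2, (1 - gc_fraction) / 2)
  chroms <- with_seed(seed, {
    vapply(lengths, function(L) {
      paste(sample(DNA_BASES, L, replace = TRUE, prob = prob), collapse = "")
    }, character(1))
  })
  names(chroms) <- paste0("chr", seq_len(n_chrom))
  structure(list(chromosomes = chroms, seed = as.integer(seed)),
            class = "toy_genome")
}

#' @export
print.toy_genome <- function(x, ...) {
  L <- nchar(x$chromosomes)
  gc <- vapply(x$chromosomes, function(s) {
    r <- charToRaw(s)
    mean(r == charToRaw("G") | r == charToRaw("C"))
  }, numeric(1))
  cat(sprintf("toy genome: %d chromosome(s), %d bp total (seed %d)\n",
              length(L), sum(L), x$seed))
  for (i in seq_along(L)) {
    cat(sprintf("  %s  %8d bp  GC %.3f\n", names(L)[i], L[i], gc[i]))
  }
  invisible(x)
}

chrom_lengths <- function(genome) nchar(genome$chromosomes)

#' Construct and validate a gene annotation table
#'
#' Builds the `gene_models` table used as the coordinate frame for all
#' profiling.  Coordinates are 0-based half-open; the TSS is the first and
#' the TES the last transcribed base, so `tss = start` on the plus strand and
#' `tss = end - 1` on the minus strand.  The `non_overlapping` flag is
#' recomputed by brute-force pairwise comparison of the 2 kb flank-extended
#' spans, regardless of what the input claims.
#'
#' @param df A data frame with columns `gene_id`, `chrom`, `strand` (`"+"` or
#'   `"-"`), `start`, `end` and optionally `sense_level`.
#' @param flank Flank (bases) used when testing for overlap between
#'   flank-extended gene spans.
#' @param min_len Minimum allowed gene length; the default keeps the 1 kb 5'
#'   and 3' regions of the truncation screen disjoint.
#' @return A `gene_models` data frame with derived `tss`, `tes` and
#'   `non_overlapping` columns.
#' @export
gene_models <- function(df, flank = 2000L, min_len = 3000L) {
  need <- c("gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("missing column(s): %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (!all(df$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  len <- df$end - df$start
  if (any(len < min_len)) {
    stopf("gene length must be >= %d (offending: %s)", min_len,
          paste(df$gene_id[len < min_len], collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) stopf("duplicated gene_id")
  df$tss <- ifelse(df$strand == "+", df$start, df$end - 1L)
  df$tes <- ifelse(df$strand == "+", df$end - 1L, df$start)
  df$non_overlapping <- .flag_non_overlapping(df, flank)
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  df
}

# brute-force pairwise intersection of [start - flank, end + flank) spans
.flag_non_overlapping <- function(df, flank) {
  n <- nrow(df)
  s <- df$start - flank
  e <- df$end + flank
  ok <- rep(TRUE, n)
  if (n < 2L) return(ok)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (df$chrom[i] == df$chrom[j] && s[i] < e[j] && s[j] < e[i]) {
        ok[i] <- ok[j] <- FALSE
      }
    }
  }
  ok
}

#' Plant a non-overlapping gene annotation on a toy genome
#'
#' Places `n_genes` genes with random lengths and strands so that their
#' flank-extended spans (`[start - 2000, end + 2000)`) are pairwise disjoint
#' and lie fully inside a chromosome.  Genes are apportioned to chromosomes
#' by capacity; free space is distributed as random gaps.
#'
#' @param genome A [generate_genome()] result.
#' @param n_genes Number of genes to place (0 gives an empty annotation).
#' @param min_len,max_len Gene length bounds in bases (`min_len >= 3000`).
#' @param flank Reserved flank on both sides of every gene, in bases.
#' @param seed Integer seed.
#' @return A `gene_models` data frame (see [gene_models()]).
#' @export
plant_annotation <- function(genome, n_genes, min_len = 3000L,
                             max_len = 2L * min_len, flank = 2000L, seed = 1L) {
  stopifnot(inherits(genome, "toy_genome"))
  n_genes <- as.integer(n_genes)
  if (n_genes < 0L) stopf("'n_genes' must be non-negative")
  if (min_len < 3000L) stopf("'min_len' must be >= 3000")
  if (max_len < min_len) stopf("'max_len' must be >= 'min_len'")
  empty <- data.frame(gene_id = character(0), chrom = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0))
  if (n_genes == 0L) return(gene_models(empty, flank = flank))
  L <- chrom_lengths(genome)
  with_seed(seed, {
    # apportion genes to chromosomes by capacity at worst-case gene size
    cap <- pmax(0L, L %/% (max_len + 2L * flank))
    if (sum(cap) < n_genes) {
      stopf("cannot place %d genes of up to %d bp (+%d bp flanks) on %s",
            n_genes, max_len, flank, paste(names(L), collapse = ", "))
    }
    alloc <- integer(length(L))
    ord <- order(cap, decreasing = TRUE)
    left <- n_genes
    for (i in ord) {
      take <- min(cap[i], left)
      alloc[i] <- take
      left <- left - take
      if (left == 0L) break
    }
    rows <- vector("list", length(L))
    gid <- 0L
    for (ci in seq_along(L)) {
      k <- alloc[ci]
      if (k == 0L) next
      lens <- as.integer(round(runif(k, min_len, max_len)))
      used <- sum(lens + 2L * flank)
      if (used > L[ci]) {
        stopf("infeasible packing on %s: need %d bp, have %d",
              names(L)[ci], used, L[ci])
      }
      free <- L[ci] - used
      gaps <- as.integer(rmultinom(1L, free, rep(1, k + 1L))[, 1L])
      starts <- integer(k)
      pos <- 0L
      for (g in seq_len(k)) {
        pos <- pos + gaps[g] + flank
        starts[g] <- pos
        pos <- pos + lens[g] + flank
      }
      rows[[ci]] <- data.frame(
        gene_id = sprintf("gene_%04d", gid + seq_len(k)),
        chrom = names(L)[ci],
        strand = sample(c("+", "-"), k, replace = TRUE),
        start = starts,
        end = starts + lens,
        stringsAsFactors = FALSE
      )
      gid <- gid + k
    }
    gene_models(do.call(rbind, rows), flank = flank, min_len = min_len)
  })
}

#' Define a transcription program over an annotation
#'
#' A transcription program assigns to every gene an expected sense fragment
#' density, an optional divergent antisense component upstream of the TSS
#' (emulating CpG-island promoter aRNAs), and an optional CPT-induced 5'
#' truncation effect: under the `"CPT"` condition, genes flagged `truncated`
#' have their sense fragment density multiplied by `truncation_5prime_gain`
#' over the first 1000 bases downstream of the TSS.
#'
#' @param genes A `gene_models` table.
#' @param sense_level Expected sense fragments per kilobase, recycled per
#'   gene; relative weights only (absolute depth is set at simulation time).
#' @param antisense_level Expected antisense fragments per kilobase over the
#'   `antisense_window` upstream of the TSS, recycled per gene.
#' @param antisense_length_median Median antisense transcript length (bases);
#'   lengths are lognormal.
#' @param antisense_length_sdlog Lognormal sdlog of antisense lengths.
#' @param antisense_window Window upstream of the TSS (bases) in which
#'   antisense transcription initiates.
#' @param truncated Logical, recycled per gene: does this gene show the
#'   CPT-induced 5' sense-read accumulation?
#' @param truncation_5prime_gain Multiplicative gain (>= 1) applied to the
#'   sense density over `[TSS, TSS + 1000)` when `condition = "CPT"` and the
#'   gene is `truncated`.
#' @param condition `"control"` or `"CPT"`.
#' @return A `transcription_program` data frame, one row per gene, with the
#'   condition stored as an attribute.
#' @export
transcription_program <- function(genes, sense_level = 10,
                                  antisense_level = 0,
                                  antisense_length_median = 800,
                                  antisense_length_sdlog = 0.5,
                                  antisense_window = 1500L,
                                  truncated = FALSE,
                                  truncation_5prime_gain = 1,
                                  condition = c("control", "CPT")) {
  stopifnot(inherits(genes, "gene_models"))
  condition <- match.arg(condition)
  n <- nrow(genes)
  p <- data.frame(
    gene_id = genes$gene_id,
    sense_level = rep_len(sense_level, n),
    antisense_level = rep_len(antisense_level, n),
    truncated = rep_len(truncated, n),
    truncation_5prime_gain = rep_len(truncation_5prime_gain, n),
    stringsAsFactors = FALSE
  )
  if (any(p$sense_level < 0) || any(p$antisense_level < 0)) {
    stopf("expression levels must be >= 0")
  }
  if (any(p$truncation_5prime_gain < 1)) {
    stopf("'truncation_5prime_gain' must be >= 1")
  }
  if (antisense_length_median <= 0 || antisense_window <= 0) {
    stopf("antisense length and window must be positive")
  }
  structure(p, class = c("transcription_program", "data.frame"),
            condition = condition,
            antisense_length_median = antisense_length_median,
            antisense_length_sdlog = antisense_length_sdlog,
            antisense_window = as.integer(antisense_window))
}
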