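#' Map a gene to metagene bin coordinates
#'
#' Builds the flank-body-flank bin scheme used for metagene profiling over
#' the window from 2000 bases upstream of the TSS to 2000 bases downstream
#' of the TES: fixed-width upstream bins, a gene body rescaled into
#' `body_bins` near-equal bins (widths differ by at most 1 base), and
#' fixed-width downstream bins.  For minus-strand genes the mapping is
#' reflected so that bin 0 always starts 2000 bases upstream of the
#' biological TSS.
#'
#' @param gene A one-row slice of a `gene_models` table.
#' @param flank Flank size in bases on each side.
#' @param flank_bin Width of each flank bin (must divide `flank`).
#' @param body_bins Number of gene-body bins.
#' @return A data frame with one row per bin (`bin` 0-based meta index,
#'   `zone`, genomic `start`/`end`, `width`), or `NULL` as the skip signal
#'   for genes shorter than two bases per body bin.
#' @examples
#' g <- gene_models(data.frame(gene_id = "g", chrom = "chr1", strand = "+",
#'                             start = 10000, end = 20000))
#' head(meta_coordinates(g[1, ]), 2)  # bin 0 = [8000, 8100)
#' @export
meta_coordinates <- function(gene, flank = 2000L, flank_bin = 100L,
                             body_bins = 100L) {
  flank <- as.integer(flank); flank_bin <- as.integer(flank_bin)
  body_bins <- as.integer(body_bins)
  if (flank %% flank_bin != 0L) stopf("'flank_bin' must divide 'flank'")
  nf <- flank %/% flank_bin
  L <- gene$end - gene$start
  if (L < 2L * body_bins) return(NULL)  # skip signal: gene too short to bin
  body_edges <- as.integer(round(seq(0, L, length.out = body_bins + 1L)))
  if (gene$strand == "+") {
    up <- gene$start - flank + flank_bin * (0:nf)
    body <- gene$start + body_edges
    down <- gene$end + flank_bin * (0:nf)
    edges <- c(up[-(nf + 1L)], body, down[-1L])
    starts <- edges[-length(edges)]
    ends <- edges[-1L]
  } else {
    # reflected: walk right-to-left from end + flank
    up <- gene$end + flank - flank_bin * (0:nf)
    body <- gene$end - body_edges
    down <- gene$start - flank_bin * (0:nf)
    edges <- c(up[-(nf + 1L)], body, down[-1L])
    starts <- edges[-1L]
    ends <- edges[-length(edges)]
  }
  data.frame(
    bin = seq_len(2L * nf + body_bins) - 1L,
    zone = rep(c("upstream", "body", "downstream"), c(nf, body_bins, nf)),
    start = as.integer(starts), end = as.integer(ends),
    width = as.integer(ends - starts)
  )
}

#' Metagene sense-tag density profile
#'
#' Computes the mean normalized sense-fragment density over genes mapped to
#' the common flank-body-flank coordinate frame.  Per gene, sense fragments
#' are assigned to bins by midpoint; the per-bin density is
#' `count / bin_width_kb / (library_size / 1e6)` (fragments per kilobase per
#' million); the profile is by default the unweighted mean over genes, so
#' long or highly expressed genes do not dominate.
#'
#' @param aln Strand-tagged alignments (see [count_fragments()]).
#' @param genes A `gene_models` table; only `non_overlapping` genes are
#'   profiled.  Must be non-empty after filtering.
#' @param condition Condition label stored with the profile.
#' @param expr_class Expression-class label stored with the profile.
#' @param flank,flank_bin,body_bins Bin scheme, see [meta_coordinates()].
#' @param library_size Mapped-fragment library size for depth normalization;
#'   defaults to the number of alignments in `aln`.
#' @param method `"mean"` (per-gene mean, default) or `"pooled"` (densities
#'   computed from pooled counts over genes).
#' @param keep_gene_matrix Keep the per-gene density matrix (genes x bins)
#'   in the result, for auditing.
#' @return An object of class `metagene_profile`: `density` (per-bin
#'   vector), `bins` (meta bin table), `n_genes`, `n_skipped`, `gene_ids`,
#'   labels and parameters.
#' @export
metagene_profile <- function(aln, genes, condition = NA_character_,
                             expr_class = NA_character_, flank = 2000L,
                             flank_bin = 100L, body_bins = 100L,
                             library_size = NULL,
                             method = c("mean", "pooled"),
                             keep_gene_matrix = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(genes, "gene_models"))
  genes <- genes[genes$non_overlapping, , drop = FALSE]
  if (nrow(genes) == 0L) stopf("no non-overlapping genes to profile")
  df <- .aln_frame(aln)
  if (is.null(library_size)) library_size <- nrow(df)
  if (library_size <= 0) stopf("library size must be > 0")
  nf <- as.integer(flank) %/% as.integer(flank_bin)
  nbins <- 2L * nf + as.integer(body_bins)

  # pre-sort midpoints per chromosome+strand for binary-search counting
  key_a <- paste(df$chrom, df$strand)
  mids_by <- lapply(split(df$midpoint, key_a), sort)

  dens <- matrix(0, nrow = nrow(genes), ncol = nbins)
  counts <- matrix(0L, nrow = nrow(genes), ncol = nbins)
  skipped <- 0L
  used <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    b <- meta_coordinates(genes[i, ], flank, flank_bin, body_bins)
    if (is.null(b)) { skipped <- skipped + 1L; next }
    used[i] <- TRUE
    mids <- mids_by[[paste(genes$chrom[i], genes$strand[i])]]
    if (!is.null(mids) && length(mids)) {
      # genomic edges ascending regardless of strand, then re-orient
      asc <- genes$strand[i] == "+"
      gstart <- if (asc) b$start else rev(b$start)
      gend <- if (asc) b$end else rev(b$end)
      edges <- c(gstart, gend[length(gend)])
      inw <- mids[mids >= edges[1] & mids < edges[length(edges)]]
      if (length(inw)) {
        cnt <- tabulate(findInterval(inw, edges), nbins = nbins)
        if (!asc) cnt <- rev(cnt)
        counts[i, ] <- cnt
        dens[i, ] <- cnt / (b$width / 1000) / (library_size / 1e6)
      }
    }
  }
  keep <- which(used)
  density <- if (method == "mean") {
    colMeans(dens[keep, , drop = FALSE])
  } else {
    # pooled: total counts over genes / total bin widths
    widths <- matrix(0, nrow = nrow(genes), ncol = nbins)
    for (i in keep) {
      b <- meta_coordinates(genes[i, ], flank, flank_bin, body_bins)
      widths[i, ] <- b$width
    }
    colSums(counts[keep, , drop = FALSE]) /
      (colSums(widths[keep, , drop = FALSE]) / 1000) / (library_size / 1e6)
  }
  bins <- data.frame(
    bin = seq_len(nbins) - 1L,
    zone = rep(c("upstream", "body", "downstream"),
               c(nf, body_bins, nf))
  )
  structure(list(
    density = as.numeric(density), bins = bins,
    n_genes = length(keep), n_skipped = skipped,
    gene_ids = genes$gene_id[keep],
    expr_class = expr_class, condition = condition, method = method,
    library_size = library_size,
    params = list(flank = flank, flank_bin = flank_bin,
                  body_bins = body_bins),
    gene_density = if (keep_gene_matrix) dens[keep, , drop = FALSE],
    gene_counts = if (keep_gene_matrix) counts[keep, , drop = FALSE]
  ), class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf(
    "metagene profile (%s): %d genes (%d skipped), %d bins, condition %s\n",
    x$method, x$n_genes, x$n_skipped, length(x$density), x$condition))
  cat(sprintf("  mean body density %.3f FPKM-equivalents\n",
              mean(x$density[x$bins$zone == "body"])))
  invisible(x)
}

#' @export
plot.metagene_profile <- function(x, ..., col = "black") {
  b <- x$bins
  plot(b$bin, x$density, type = "l", col = col,
       xlab = "meta position (bins: 5' flank | body | 3' flank)",
       ylab = "sense-tag density (per kb per million)", ...)
  abline(v = range(b$bin[b$zone == "body"]) + c(-0.5, 0.5),
         lty = 3, col = "grey50")
  invisible(x)
}

#' Per-bin difference of two metagene profiles
#'
#' Elementwise `a - b`; the two profiles must come from identical bin
#' schemes and gene sets (e.g. CPT minus control over the same class).
#'
#' @param a,b `metagene_profile` objects.
#' @return A numeric per-bin difference vector with the bin table attached
#'   as attribute `bins`.
#' @export
profile_difference <- function(a, b) {
  stopifnot(inherits(a, "metagene_profile"), inherits(b, "metagene_profile"))
  if (!identical(a$params, b$params) ||
      length(a$density) != length(b$density)) {
    stopf("profiles use different bin schemes")
  }
  if (!identical(a$gene_ids, b$gene_ids)) {
    stopf("profiles were computed over different gene sets")
  }
  structure(a$density - b$density, bins = a$bins)
}
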