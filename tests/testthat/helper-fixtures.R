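# small fixtures built in code, shared across test files

# wrap raw chromosome strings as a toy genome (bypasses the length floor of
# generate_genome for hand-crafted sequences)
make_genome <- function(...) {
  chroms <- c(...)
  structure(list(chromosomes = chroms, seed = NA_integer_),
            class = "toy_genome")
}

# a single gene on a random 50 kb chromosome, with its exact sequence known
fixture_one_gene <- function(seed = 11, strand = "+", start = 20000,
                             len = 5000, chrom_len = 50000) {
  g <- generate_genome(seed, 1, chrom_len)
  genes <- gene_models(data.frame(
    gene_id = "g1", chrom = "chr1", strand = strand,
    start = start, end = start + len))
  list(genome = g, genes = genes)
}

# extract the bisulfite-free transcript sequence of a fragment interval
transcript_seq <- function(genome, chrom, start, end, strand) {
  s <- substring(genome$chromosomes[[chrom]], start + 1, end)
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

# build a minimal strand-tagged alignment frame from fragment coordinates
make_aln <- function(chrom, start, end, strand) {
  data.frame(pair_id = sprintf("p%04d", seq_along(start)),
             chrom = chrom, start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

# alignment frame whose fragment midpoints are exactly `mids`
aln_at_midpoints <- function(mids, strand = "+", chrom = "chr1", flen = 200) {
  make_aln(chrom, mids - flen %/% 2, mids + flen - flen %/% 2, strand)
}
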