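#' Write a toy genome as FASTA
#' @param genome A `toy_genome`.
#' @param path Output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(genome$chromosomes), filepath = path)
  invisible(path)
}

#' Read a FASTA genome
#' @param path FASTA path.
#' @param seed Seed to record on the object (provenance only).
#' @return A `toy_genome`.
#' @export
read_genome_fasta <- function(path, seed = NA_integer_) {
  ss <- Biostrings::readDNAStringSet(path)
  chroms <- as.character(ss)
  names(chroms) <- sub("\\s.*$", "", names(ss))
  structure(list(chromosomes = chroms, seed = seed), class = "toy_genome")
}

#' Write a gene annotation as BED6
#'
#' The score column carries the program's sense level when a
#' [transcription_program()] is supplied, 0 otherwise.
#' @param genes A `gene_models` table.
#' @param path Output BED path.
#' @param program Optional `transcription_program` matched to `genes`.
#' @export
write_genes_bed <- function(genes, path, program = NULL) {
  score <- if (is.null(program)) rep(0, nrow(genes)) else {
    stopifnot(identical(genes$gene_id, program$gene_id))
    program$sense_level
  }
  bed <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                    score, genes$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 gene annotation
#' @param path BED6 path (chrom, start, end, name, score, strand).
#' @return A `gene_models` table; the BED score is kept as `sense_level`.
#' @export
read_genes_bed <- function(path) {
  bed <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 6L) stopf("BED6 requires 6 columns, found %d", ncol(bed))
  df <- data.frame(gene_id = bed[[4]], chrom = bed[[1]], strand = bed[[6]],
                   start = bed[[2]], end = bed[[3]],
                   sense_level = bed[[5]], stringsAsFactors = FALSE)
  gene_models(df)
}

#' Write simulated reads as paired FASTQ
#' @param sim A [simulate_reads()] result.
#' @param r1,r2 Output FASTQ paths for mate 1 and mate 2.
#' @export
write_fastq <- function(sim, r1, r2) {
  stopifnot(inherits(sim, "read_simulation"))
  ids <- sim$truth$pair_id
  q <- Biostrings::BStringSet(rep(sim$quality, length(ids)))
  for (m in 1:2) {
    reads <- Biostrings::DNAStringSet(if (m == 1) sim$mate1 else sim$mate2)
    names(reads) <- ids
    Biostrings::writeXStringSet(reads, filepath = if (m == 1) r1 else r2,
                                format = "fastq", qualities = q)
  }
  invisible(c(r1, r2))
}

#' Read a pair of FASTQ files
#' @param r1,r2 FASTQ paths; records must be in matched order.
#' @return List with `mate1`, `mate2` (character vectors) and `ids`.
#' @export
read_paired_fastq <- function(r1, r2) {
  a <- Biostrings::readDNAStringSet(r1, format = "fastq")
  b <- Biostrings::readDNAStringSet(r2, format = "fastq")
  if (length(a) != length(b)) {
    stopf("mate count mismatch: %d vs %d reads (first unmatched record: %d)",
          length(a), length(b), min(length(a), length(b)) + 1L)
  }
  list(mate1 = unname(as.character(a)), mate2 = unname(as.character(b)),
       ids = sub("\\s.*$", "", names(a)))
}

#' Write the truth table of a simulation as TSV
#' @param truth A `fragment_truth` table (or `sim$truth`).
#' @param path Output TSV path.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
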