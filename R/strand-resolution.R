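#' Build a fully converted reference genome
#'
#' Produces the C->T ("CT") or G->A ("GA") converted copy of a genome used
#' to map bisulfite-treated reads while retaining strand information: reads
#' from plus-strand transcripts align to the CT reference, reads from
#' minus-strand transcripts to the GA reference.  Sequence lengths are
#' unchanged, so converted coordinates map back to the original genome
#' one-to-one.
#'
#' @param genome A `toy_genome`.
#' @param mode `"CT"` (every C replaced by T) or `"GA"` (every G by A).
#' @return An object of class `converted_reference`: list with `mode` and
#'   `chromosomes`.
#' @examples
#' g <- generate_genome(1, lengths = 10000)
#' ct <- convert_reference(g, "CT")
#' @export
convert_reference <- function(genome, mode = c("CT", "GA")) {
  stopifnot(inherits(genome, "toy_genome"))
  mode <- match.arg(mode)
  chroms <- if (mode == "CT") {
    chartr("C", "T", genome$chromosomes)
  } else {
    chartr("G", "A", genome$chromosomes)
  }
  structure(list(mode = mode, chromosomes = chroms),
            class = "converted_reference")
}

# In-silico read conversion follows the library chemistry: mate 1 carries
# the bisulfite-read (RNA-sense) sequence and is C->T converted; mate 2 is
# its genomic reverse complement and is G->A converted.  Each converted
# reference is then searched in both concordant orientations, as a genome
# aligner would:
#   orientation "F": mate1 forward and leftmost, mate2 reverse-complemented;
#   orientation "R": mate1 reverse-complemented and rightmost, mate2 forward.
# A plus-strand transcript matches the CT reference in orientation F, a
# minus-strand transcript the GA reference in orientation R; a fragment
# whose CT- and GA-converted forms coincide (no C and no G) matches both
# references and is later discarded as ambiguous.
.mode_hits <- function(mate1, mate2, ref, max_mismatch, seed_len,
                       insert_max) {
  m1c <- chartr("C", "T", mate1)
  m2c <- chartr("G", "A", mate2)
  if (any(c(nchar(m1c), nchar(m2c)) < seed_len)) {
    stopf("read length below 'seed_len'")
  }
  hf <- .scan_concordant(left = m1c, right = revcomp(m2c), ref,
                         max_mismatch, seed_len, insert_max)
  hr <- .scan_concordant(left = m2c, right = revcomp(m1c), ref,
                         max_mismatch, seed_len, insert_max)
  hf$mate1_forward <- rep(TRUE, nrow(hf))
  hr$mate1_forward <- rep(FALSE, nrow(hr))
  res <- rbind(hf, hr)
  res$reference_mode <- rep(ref$mode, nrow(res))
  res$proper <- rep(TRUE, nrow(res))
  if (nrow(res) == 0L) return(res)
  # one locus can in principle be reached through both orientations
  res <- res[!duplicated(res[c("pair", "chrom", "start", "end")]), ]
  rownames(res) <- NULL
  res
}

# Concordant-pair seed-and-extend scan in one orientation: the left read is
# seeded by its exact-match prefix, the right read by its exact-match
# suffix (both are the biological 5' ends of the mates), candidates are
# joined per pair, and full ungapped mismatch counts are computed.
.scan_concordant <- function(left, right, ref, max_mismatch, seed_len,
                             insert_max) {
  lL <- nchar(left); lR <- nchar(right)
  seedL <- substr(left, 1L, seed_len)
  seedR <- substring(right, lR - seed_len + 1L, lR)
  # the Aho-Corasick PDict pays off for whole libraries; for a handful of
  # pairs plain matchPattern calls are much cheaper
  use_pdict <- length(left) > 32L
  pdL <- if (use_pdict) Biostrings::PDict(Biostrings::DNAStringSet(seedL))
  pdR <- if (use_pdict) Biostrings::PDict(Biostrings::DNAStringSet(seedR))
  out <- list()
  for (chrom in names(ref$chromosomes)) {
    refstr <- ref$chromosomes[[chrom]]
    subj <- Biostrings::DNAString(refstr)
    clen <- length(subj)
    candL <- if (use_pdict) .pdict_starts(pdL, subj) else
      .pattern_starts(seedL, subj)
    candR <- if (use_pdict) .pdict_starts(pdR, subj) else
      .pattern_starts(seedR, subj)
    if (nrow(candL) == 0L || nrow(candR) == 0L) next
    candL$p <- candL$m - 1L                              # read start, 0-based
    candR$p <- candR$m - 1L - (lR[candR$id] - seed_len)
    cj <- merge(candL[c("id", "p")], candR[c("id", "p")],
                by = "id", suffixes = c("L", "R"))
    if (nrow(cj) == 0L) next
    wL <- lL[cj$id]; wR <- lR[cj$id]
    fs <- cj$pL; fe <- cj$pR + wR
    keep <- cj$pL >= 0L & cj$pR >= 0L & fe <= clen &
      (fe - fs) >= pmax(wL, wR) & (fe - fs) <= insert_max
    cj <- cj[keep, ]; wL <- wL[keep]; wR <- wR[keep]
    fs <- fs[keep]; fe <- fe[keep]
    if (nrow(cj) == 0L) next
    mm <- hamming_vec(left[cj$id],
                      substring(refstr, cj$pL + 1L, cj$pL + wL)) +
          hamming_vec(right[cj$id],
                      substring(refstr, cj$pR + 1L, cj$pR + wR))
    keep <- mm <= max_mismatch
    if (!any(keep)) next
    out[[chrom]] <- data.frame(
      pair = cj$id[keep], chrom = chrom, start = fs[keep], end = fe[keep],
      mismatches = mm[keep], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(pair = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.pdict_starts <- function(pd, subj) {
  m <- Biostrings::matchPDict(pd, subj)
  st <- Biostrings::startIndex(m)
  lens <- lengths(st)
  data.frame(id = rep.int(seq_along(st), lens),
             m = as.integer(unlist(st, use.names = FALSE)))
}

.pattern_starts <- function(seeds, subj) {
  uq <- unique(seeds)
  hits <- lapply(uq, function(s) {
    Biostrings::start(Biostrings::matchPattern(s, subj))
  })
  ids <- integer(0); ms <- integer(0)
  for (i in seq_along(uq)) {
    who <- which(seeds == uq[i])
    if (length(hits[[i]])) {
      ids <- c(ids, rep(who, each = length(hits[[i]])))
      ms <- c(ms, rep.int(hits[[i]], length(who)))
    }
  }
  data.frame(id = ids, m = as.integer(ms))
}

#' Align one bisulfite read pair against both converted references
#'
#' Toy ungapped seed-and-extend aligner: an exact-match seed of `seed_len`
#' bases at each mate's biological 5' end, full-length ungapped mismatch
#' counting, and a concordant-mate requirement within `insert_max`.  Before
#' comparison the remaining unconverted cytosines are neutralized in silico:
#' mate 1 is C->T converted and mate 2 G->A converted, then compared to the
#' CT reference in mate1-forward orientation and to the GA reference in
#' mate1-reverse orientation.  The aligner sits behind this small contract
#' so a spliced genome-scale aligner could be substituted.
#'
#' @param pair List with `mate1` and `mate2` (single sequences).
#' @param ct_ref,ga_ref [convert_reference()] results of modes CT and GA.
#' @param max_mismatch Maximum total mismatches over both mates.
#' @param seed_len Exact-match seed length (bases).
#' @param insert_max Maximum fragment (outer insert) length.
#' @return List with `hits_CT` and `hits_GA`: data frames of concordant hit
#'   loci (`chrom`, 0-based half-open `start`/`end` of the fragment,
#'   `mismatches`, `reference_mode`, `proper`).
#' @export
align_pair <- function(pair, ct_ref, ga_ref, max_mismatch = 3L,
                       seed_len = 20L, insert_max = 1000L) {
  stopifnot(identical(ct_ref$mode, "CT"), identical(ga_ref$mode, "GA"))
  hc <- .mode_hits(pair$mate1, pair$mate2, ct_ref, max_mismatch, seed_len,
                   insert_max)
  hg <- .mode_hits(pair$mate1, pair$mate2, ga_ref, max_mismatch, seed_len,
                   insert_max)
  list(hits_CT = hc[setdiff(names(hc), "pair")],
       hits_GA = hg[setdiff(names(hg), "pair")])
}

#' Call the strand of origin from dual-reference hits
#'
#' Plus-strand transcripts align only to the CT reference, minus-strand
#' transcripts only to the GA reference; a pair with hits on both references
#' is uninformative and discarded, as is a pair with several equally good
#' loci within one reference.
#'
#' @param hits_CT,hits_GA Hit data frames from [align_pair()].
#' @return An object of class `strand_call`: list with `call` (`"plus"`,
#'   `"minus"`, `"ambiguous_discarded"` or `"unmapped"`) and `best_hit` (a
#'   one-row data frame, or `NULL`).
#' @export
call_strand <- function(hits_CT, hits_GA) {
  n_ct <- NROW(hits_CT); n_ga <- NROW(hits_GA)
  res <- if (n_ct > 0L && n_ga > 0L) {
    list(call = "ambiguous_discarded", best_hit = NULL)
  } else if (n_ct == 0L && n_ga == 0L) {
    list(call = "unmapped", best_hit = NULL)
  } else {
    hits <- if (n_ct > 0L) hits_CT else hits_GA
    best <- which(hits$mismatches == min(hits$mismatches))
    if (length(best) > 1L) {
      list(call = "ambiguous_discarded", best_hit = NULL)
    } else {
      list(call = if (n_ct > 0L) "plus" else "minus",
           best_hit = hits[best, , drop = FALSE])
    }
  }
  structure(res, class = "strand_call")
}

#' @export
print.strand_call <- function(x, ...) {
  cat("strand call:", x$call, "\n")
  if (!is.null(x$best_hit)) print(x$best_hit)
  invisible(x)
}

#' Strand-resolve a whole paired library
#'
#' Runs the dual-reference alignment and strand calling over every read
#' pair of a library.  Input can be a [simulate_reads()] object, a list with
#' `mate1`/`mate2` (and optionally `ids`), or a length-2 character vector of
#' paired FASTQ paths.
#'
#' @param reads Library input (see Details above).
#' @param genome The original (unconverted) `toy_genome`.
#' @param max_mismatch,seed_len,insert_max Aligner parameters, see
#'   [align_pair()].
#' @return A `strand_calls` data frame: `pair_id`, `call`, and for called
#'   pairs `chrom`, `start`, `end`, `mismatches`, `reference_mode`.  Summary
#'   counts per call class are in `attr(, "summary")`.
#' @export
resolve_library <- function(reads, genome, max_mismatch = 3L,
                            seed_len = 20L, insert_max = 1000L) {
  if (inherits(reads, "read_simulation")) {
    lib <- list(mate1 = reads$mate1, mate2 = reads$mate2,
                ids = reads$truth$pair_id)
  } else if (is.character(reads) && length(reads) == 2L) {
    lib <- read_paired_fastq(reads[1], reads[2])
  } else if (is.list(reads) && all(c("mate1", "mate2") %in% names(reads))) {
    if (length(reads$mate1) != length(reads$mate2)) {
      stopf("mate count mismatch: %d vs %d (first unmatched record: %d)",
            length(reads$mate1), length(reads$mate2),
            min(length(reads$mate1), length(reads$mate2)) + 1L)
    }
    lib <- reads
    if (is.null(lib$ids)) lib$ids <- sprintf("pair_%07d", seq_along(lib$mate1))
  } else {
    stopf("'reads' must be a read_simulation, a mate1/mate2 list, or two FASTQ paths")
  }
  n <- length(lib$mate1)
  call <- rep("unmapped", n)
  chrom <- rep(NA_character_, n); start <- rep(NA_integer_, n)
  end <- rep(NA_integer_, n); mism <- rep(NA_integer_, n)
  refmode <- rep(NA_character_, n)
  if (n > 0L) {
    ct_ref <- convert_reference(genome, "CT")
    ga_ref <- convert_reference(genome, "GA")
    hc <- .mode_hits(lib$mate1, lib$mate2, ct_ref, max_mismatch, seed_len,
                     insert_max)
    hg <- .mode_hits(lib$mate1, lib$mate2, ga_ref, max_mismatch, seed_len,
                     insert_max)
    # per-pair hit summaries: hit count, unique-best row (vectorized
    # equivalent of call_strand over the whole library)
    pstats <- function(h) {
      cnt <- tabulate(h$pair, nbins = n)
      best <- rep(NA_integer_, n)
      nmin <- integer(n)
      if (nrow(h)) {
        o <- order(h$pair, h$mismatches)
        ho_pair <- h$pair[o]; ho_mm <- h$mismatches[o]
        first <- !duplicated(ho_pair)
        minmm <- rep(NA_integer_, n)
        minmm[ho_pair[first]] <- ho_mm[first]
        best[ho_pair[first]] <- o[first]
        nmin <- tabulate(ho_pair[ho_mm == minmm[ho_pair]], nbins = n)
      }
      list(cnt = cnt, best = best, nmin = nmin)
    }
    sc <- pstats(hc); sg <- pstats(hg)
    amb <- (sc$cnt > 0L & sg$cnt > 0L) |
      (sc$cnt > 0L & sg$cnt == 0L & sc$nmin > 1L) |
      (sg$cnt > 0L & sc$cnt == 0L & sg$nmin > 1L)
    plus <- !amb & sc$cnt > 0L & sg$cnt == 0L
    minus <- !amb & sg$cnt > 0L & sc$cnt == 0L
    call[amb] <- "ambiguous_discarded"
    call[plus] <- "plus"; call[minus] <- "minus"
    fill <- function(sel, h, best) {
      i <- which(sel); b <- best[i]
      chrom[i] <<- h$chrom[b]; start[i] <<- h$start[b]
      end[i] <<- h$end[b]; mism[i] <<- h$mismatches[b]
      refmode[i] <<- h$reference_mode[b]
    }
    fill(plus, hc, sc$best)
    fill(minus, hg, sg$best)
  }
  calls <- data.frame(pair_id = lib$ids, call = call, chrom = chrom,
                      start = start, end = end, mismatches = mism,
                      reference_mode = refmode, stringsAsFactors = FALSE)
  calls$strand <- c(plus = "+", minus = "-")[calls$call]
  smry <- table(factor(calls$call, levels = c("plus", "minus",
                                              "ambiguous_discarded",
                                              "unmapped")))
  structure(calls, class = c("strand_calls", "data.frame"),
            summary = smry,
            params = list(max_mismatch = max_mismatch, seed_len = seed_len,
                          insert_max = insert_max))
}

#' @export
print.strand_calls <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("strand calls for %d pairs:\n", nrow(x)))
  for (k in names(s)) cat(sprintf("  %-20s %d\n", k, s[[k]]))
  invisible(x)
}

#' Write strand calls as a minimal SAM file
#'
#' Emits one ungapped alignment record per mate for every pair called plus
#' or minus, with the strand of origin in an `XS:A` tag.  Coordinates are
#' converted to SAM's 1-based convention.
#'
#' @param calls A `strand_calls` table.
#' @param reads The same library the calls were made from (a
#'   `read_simulation` or `mate1`/`mate2` list).
#' @param genome The `toy_genome` (for header `@SQ` lines).
#' @param path Output SAM path.
#' @export
write_strand_sam <- function(calls, reads, genome, path) {
  if (inherits(reads, "read_simulation")) {
    reads <- list(mate1 = reads$mate1, mate2 = reads$mate2)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  L <- chrom_lengths(genome)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(L), L), con)
  called <- which(calls$call %in% c("plus", "minus"))
  for (i in called) {
    plus <- calls$call[i] == "plus"
    m1 <- reads$mate1[i]; m2 <- reads$mate2[i]
    l1 <- nchar(m1); l2 <- nchar(m2)
    xs <- if (plus) "+" else "-"
    if (plus) {
      pos1 <- calls$start[i] + 1L; pos2 <- calls$end[i] - l2 + 1L
      f1 <- 99L; f2 <- 147L
      seq1 <- m1; seq2 <- revcomp(m2)
    } else {
      pos1 <- calls$end[i] - l1 + 1L; pos2 <- calls$start[i] + 1L
      f1 <- 83L; f2 <- 163L
      seq1 <- revcomp(m1); seq2 <- m2
    }
    writeLines(sprintf(
      "%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s\tXS:A:%s",
      calls$pair_id[i], f1, calls$chrom[i], pos1, l1, pos2,
      if (plus) calls$end[i] - calls$start[i] else
        -(calls$end[i] - calls$start[i]),
      seq1, strrep("I", l1), xs), con)
    writeLines(sprintf(
      "%s\t%d\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s\tXS:A:%s",
      calls$pair_id[i], f2, calls$chrom[i], pos2, l2, pos1,
      if (plus) -(calls$end[i] - calls$start[i]) else
        calls$end[i] - calls$start[i],
      seq2, strrep("I", l2), xs), con)
  }
  invisible(path)
}

#' Write strand calls as TSV
#' @param calls A `strand_calls` table.
#' @param path Output TSV path.
#' @export
write_strand_tsv <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
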