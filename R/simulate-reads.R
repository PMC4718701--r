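#' Simulate sequencing fragments with truth labels
#'
#' Draws `n_fragments` cDNA fragments from the transcripts implied by a
#' [transcription_program()].  The total is fixed (multinomial over
#' transcript components weighted by level x length), which reproduces the
#' compositional behaviour of a library sequenced to fixed depth: planting
#' extra 5' signal in some genes slightly dilutes every other region.
#' Fragment midpoints are uniform along a transcript (with the 5' kilobase
#' up-weighted by `truncation_5prime_gain` for truncated genes under CPT);
#' antisense fragments come from divergent transcripts initiating uniformly
#' within the program's upstream window, with lognormal lengths (median 800
#' bases by default), running opposite to the mRNA.
#'
#' @param genome A [generate_genome()] result.
#' @param genes A `gene_models` table.
#' @param program A [transcription_program()].
#' @param n_fragments Total number of fragments to draw.
#' @param fragment_len_mean,fragment_len_sd Normal fragment length
#'   parameters (bases); lengths are truncated below at `read_len`.
#' @param read_len Read length (bases), the lower bound on fragment length.
#' @param seed Integer seed.
#' @return A `fragment_truth` data frame: `pair_id`, `gene_id`, `origin`
#'   (`"sense"`/`"antisense"`), `chrom`, `strand` (strand of the originating
#'   transcript), `frag_start`, `frag_end` (0-based half-open).
#' @export
simulate_fragments <- function(genome, genes, program, n_fragments,
                               fragment_len_mean = 250,
                               fragment_len_sd = 30,
                               read_len = 75L, seed = 1L) {
  with_seed(seed, .simulate_fragments_impl(
    genome, genes, program, n_fragments,
    fragment_len_mean, fragment_len_sd, read_len))
}

.simulate_fragments_impl <- function(genome, genes, program, n_fragments,
                                     fragment_len_mean, fragment_len_sd,
                                     read_len) {
  stopifnot(inherits(genome, "toy_genome"), inherits(genes, "gene_models"),
            inherits(program, "transcription_program"))
  if (!identical(genes$gene_id, program$gene_id)) {
    stopf("'genes' and 'program' must describe the same genes in order")
  }
  n_fragments <- as.integer(n_fragments)
  if (n_fragments < 1L) stopf("'n_fragments' must be >= 1")
  condition <- attr(program, "condition")
  win <- attr(program, "antisense_window")
  mlen <- attr(program, "antisense_length_median")
  sdlog <- attr(program, "antisense_length_sdlog")
  L <- chrom_lengths(genome)

  glen_kb <- (genes$end - genes$start) / 1000
  gain_on <- condition == "CPT" & program$truncated &
    program$truncation_5prime_gain > 1
  eff_kb <- glen_kb +
    ifelse(gain_on, (program$truncation_5prime_gain - 1) * pmin(1, glen_kb), 0)
  w_sense <- program$sense_level * eff_kb
  w_anti <- program$antisense_level * (win / 1000)
  w <- c(w_sense, w_anti)
  if (sum(w) <= 0) stopf("program has zero total expression")

  counts <- as.integer(rmultinom(1L, n_fragments, w)[, 1L])
  nG <- nrow(genes)
  n_s <- counts[seq_len(nG)]
  n_a <- counts[nG + seq_len(nG)]

  # sense fragment midpoints: piecewise-uniform over the gene body, the 5'
  # kilobase weighted by the truncation gain where active
  mids <- integer(0); gidx <- integer(0); ori <- character(0)
  if (sum(n_s) > 0L) {
    gi <- rep.int(seq_len(nG), n_s)
    glen <- genes$end[gi] - genes$start[gi]
    seg1 <- pmin(1000L, glen)
    gainv <- ifelse(gain_on[gi], program$truncation_5prime_gain[gi], 1)
    p5 <- gainv * seg1 / (gainv * seg1 + (glen - seg1))
    in5 <- runif(length(gi)) < p5
    off <- integer(length(gi))
    off[in5] <- as.integer(floor(runif(sum(in5)) * seg1[in5]))
    off[!in5] <- seg1[!in5] +
      as.integer(floor(runif(sum(!in5)) * (glen[!in5] - seg1[!in5])))
    # offset is measured from the TSS in the direction of transcription
    m <- ifelse(genes$strand[gi] == "+",
                genes$start[gi] + off,
                genes$end[gi] - 1L - off)
    mids <- c(mids, as.integer(m)); gidx <- c(gidx, gi)
    ori <- c(ori, rep("sense", length(gi)))
  }
  # antisense: initiation site uniform in the upstream window, transcript
  # runs away from the gene on the opposite strand, midpoint uniform on it
  if (sum(n_a) > 0L) {
    gi <- rep.int(seq_len(nG), n_a)
    u <- floor(runif(length(gi)) * win)
    tl <- pmax(1, round(rlnorm(length(gi), log(mlen), sdlog)))
    moff <- floor(runif(length(gi)) * tl)
    m <- ifelse(genes$strand[gi] == "+",
                genes$tss[gi] - 1L - u - moff,
                genes$tss[gi] + 1L + u + moff)
    mids <- c(mids, as.integer(m)); gidx <- c(gidx, gi)
    ori <- c(ori, rep("antisense", length(gi)))
  }

  chrom <- genes$chrom[gidx]
  gstrand <- genes$strand[gidx]
  strand <- ifelse(ori == "sense", gstrand,
                   ifelse(gstrand == "+", "-", "+"))
  flen <- pmax(as.integer(round(rnorm(length(mids), fragment_len_mean,
                                      fragment_len_sd))),
               as.integer(read_len))
  fs <- mids - flen %/% 2L
  cl <- unname(L[chrom])
  fs <- pmax(0L, pmin(fs, cl - flen))
  truth <- data.frame(
    pair_id = sprintf("pair_%07d", seq_along(mids)),
    gene_id = genes$gene_id[gidx],
    origin = ori,
    chrom = chrom,
    strand = strand,
    frag_start = as.integer(fs),
    frag_end = as.integer(fs + flen),
    stringsAsFactors = FALSE
  )
  class(truth) <- c("fragment_truth", "data.frame")
  truth
}

#' Perfect-alignment view of simulated fragments
#'
#' Converts a `fragment_truth` table into the strand-tagged alignment frame
#' consumed by [count_fragments()], [metagene_profile()] and
#' [region_counts()], i.e. the result of an idealized error-free strand
#' resolution.  Useful for exercising the downstream statistics at depths
#' where full read simulation and alignment would be beside the point.
#'
#' @param truth A `fragment_truth` table (or a `read_simulation`'s `$truth`).
#' @return A data frame with `pair_id`, `chrom`, `start`, `end`, `strand`.
#' @export
fragments_to_alignments <- function(truth) {
  data.frame(pair_id = truth$pair_id, chrom = truth$chrom,
             start = truth$frag_start, end = truth$frag_end,
             strand = truth$strand, stringsAsFactors = FALSE)
}

#' Simulate bisulfite-converted strand-specific paired reads
#'
#' Extends [simulate_fragments()] to full paired reads.  The fragment
#' sequence is taken in transcript orientation (reverse complement of the
#' genome for minus-strand transcripts); every cytosine of that transcript
#' sequence is independently deaminated C->T with probability
#' `conversion_rate` (bisulfite acting on the RNA, read out as T); mate 1 is
#' the first `read_len` bases of the converted fragment (RNA-sense
#' orientation) and mate 2 the reverse complement of its last `read_len`
#' bases; uniform substitution sequencing errors are then applied to the
#' reads at `error_rate` per base.  Qualities are constant.
#'
#' @inheritParams simulate_fragments
#' @param conversion_rate Per-cytosine C->T conversion probability in
#'   `[0, 1]` (1 = complete bisulfite conversion).
#' @param error_rate Per-base substitution sequencing error rate in `[0, 1]`.
#' @param quality_char Single character used for all base qualities.
#' @return An object of class `read_simulation`: list with `mate1`, `mate2`
#'   (character vectors), `quality` (one string, recycled), `truth` (the
#'   `fragment_truth` table plus a `conversion_events` count per pair), and
#'   `params`.
#' @export
simulate_reads <- function(genome, genes, program, n_fragments,
                           fragment_len_mean = 250, fragment_len_sd = 30,
                           read_len = 75L, conversion_rate = 0.99,
                           error_rate = 0.001, quality_char = "I",
                           seed = 1L) {
  if (conversion_rate < 0 || conversion_rate > 1) {
    stopf("'conversion_rate' must be in [0, 1]")
  }
  if (error_rate < 0 || error_rate > 1) stopf("'error_rate' must be in [0, 1]")
  read_len <- as.integer(read_len)
  if (read_len < 1L) stopf("'read_len' must be >= 1")
  if (read_len > fragment_len_mean) {
    stopf("'read_len' must not exceed the mean fragment length")
  }
  with_seed(seed, {
    truth <- .simulate_fragments_impl(genome, genes, program, n_fragments,
                                      fragment_len_mean, fragment_len_sd,
                                      read_len)
    n <- nrow(truth)
    fragseq <- substring(genome$chromosomes[truth$chrom],
                         truth$frag_start + 1L, truth$frag_end)
    neg <- truth$strand == "-"
    if (any(neg)) fragseq[neg] <- revcomp(fragseq[neg])

    # bisulfite conversion on the transcript sequence, via one raw buffer
    wid <- nchar(fragseq)
    ends <- cumsum(wid)
    raw <- charToRaw(paste(fragseq, collapse = ""))
    cpos <- which(raw == charToRaw("C"))
    conv <- cpos[runif(length(cpos)) < conversion_rate]
    raw[conv] <- charToRaw("T")
    truth$conversion_events <- if (length(conv)) {
      tabulate(findInterval(conv - 1L, ends) + 1L, nbins = n)
    } else integer(n)
    big <- rawToChar(raw)
    starts <- ends - wid + 1L
    conv_frag <- substring(big, starts, ends)

    mate1 <- substring(conv_frag, 1L, read_len)
    mate2 <- revcomp(substring(conv_frag, wid - read_len + 1L, wid))
    if (error_rate > 0) {
      mate1 <- .apply_seq_errors(mate1, error_rate)
      mate2 <- .apply_seq_errors(mate2, error_rate)
    }
    structure(list(
      mate1 = mate1, mate2 = mate2,
      quality = strrep(quality_char, read_len),
      truth = truth,
      params = list(read_len = read_len, conversion_rate = conversion_rate,
                    error_rate = error_rate,
                    condition = attr(program, "condition"))
    ), class = "read_simulation")
  })
}

.apply_seq_errors <- function(reads, rate) {
  raw <- charToRaw(paste(reads, collapse = ""))
  pos <- which(runif(length(raw)) < rate)
  if (length(pos)) {
    cur <- raw[pos]
    repl <- charToRaw(paste(sample(DNA_BASES, length(pos), replace = TRUE),
                            collapse = ""))
    same <- repl == cur
    while (any(same)) {  # redraw collisions so an error always changes the base
      repl[same] <- charToRaw(paste(
        sample(DNA_BASES, sum(same), replace = TRUE), collapse = ""))
      same <- repl == cur
    }
    raw[pos] <- repl
  }
  wid <- nchar(reads)
  ends <- cumsum(wid)
  substring(rawToChar(raw), ends - wid + 1L, ends)
}

#' @export
print.read_simulation <- function(x, ...) {
  cat(sprintf(
    "read simulation: %d pairs, 2 x %d bp, conversion %.2f, error %.4f (%s)\n",
    length(x$mate1), x$params$read_len, x$params$conversion_rate,
    x$params$error_rate, x$params$condition))
  print(table(origin = x$truth$origin, strand = x$truth$strand))
  invisible(x)
}
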