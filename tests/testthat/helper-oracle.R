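# Exhaustive all-positions alignment oracle, independent of the package's
# indexed seed search: every reference position is examined directly with
# vectorized substring comparison.  Shares only the hit *contract* with the
# implementation (exact 5'-end seeds, ungapped mismatch bound, concordant
# insert window), not its code path.

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

oracle_char_mismatches <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# all 0-based start positions where `read`'s seed region matches exactly;
# seed at the prefix (side = "left") or suffix (side = "right")
oracle_seed_positions <- function(read, refstr, seed_len, side) {
  L <- nchar(read)
  clen <- nchar(refstr)
  if (clen < L) return(integer(0))
  starts <- 1:(clen - L + 1)                     # candidate read starts, 1-based
  if (side == "left") {
    seed <- substr(read, 1, seed_len)
    hit <- substring(refstr, starts, starts + seed_len - 1) == seed
  } else {
    seed <- substring(read, L - seed_len + 1, L)
    hit <- substring(refstr, starts + L - seed_len, starts + L - 1) == seed
  }
  starts[hit] - 1L
}

# all concordant hits of one converted pair against one converted reference,
# scanning both orientations
oracle_pair_hits <- function(mate1, mate2, ref, max_mismatch, seed_len,
                             insert_max) {
  m1c <- chartr("C", "T", mate1)
  m2c <- chartr("G", "A", mate2)
  frames <- list(
    F = list(left = m1c, right = oracle_revcomp(m2c)),
    R = list(left = m2c, right = oracle_revcomp(m1c))
  )
  hits <- list()
  for (chrom in names(ref$chromosomes)) {
    refstr <- ref$chromosomes[[chrom]]
    clen <- nchar(refstr)
    for (orient in names(frames)) {
      fr <- frames[[orient]]
      lL <- nchar(fr$left); lR <- nchar(fr$right)
      pL <- oracle_seed_positions(fr$left, refstr, seed_len, "left")
      pR <- oracle_seed_positions(fr$right, refstr, seed_len, "right")
      for (a in pL) for (b in pR) {
        fs <- a; fe <- b + lR
        if (fe - fs < max(lL, lR) || fe - fs > insert_max || fe > clen) next
        mm <- oracle_char_mismatches(fr$left,
                                     substring(refstr, a + 1, a + lL)) +
              oracle_char_mismatches(fr$right,
                                     substring(refstr, b + 1, b + lR))
        if (mm <= max_mismatch) {
          hits[[length(hits) + 1L]] <- data.frame(
            chrom = chrom, start = fs, end = fe, mismatches = mm,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- unique(out)
  out[order(out$chrom, out$start, out$end), , drop = FALSE]
}

# canonical form for hit-set comparison
hit_key <- function(h) {
  if (NROW(h) == 0L) return(character(0))
  sort(sprintf("%s:%d-%d:%d", h$chrom, h$start, h$end, h$mismatches))
}
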