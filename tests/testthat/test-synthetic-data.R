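test_that("genome generation hits the GC target, is seed-deterministic, and validates input", {
  g <- generate_genome(seed = 1, n_chrom = 1, lengths = 50000,
                       gc_fraction = 0.5)
  expect_equal(unname(nchar(g$chromosomes)), 50000)
  r <- charToRaw(g$chromosomes[[1]])
  gc <- mean(r == charToRaw("G") | r == charToRaw("C"))
  expect_gt(gc, 0.48)
  expect_lt(gc, 0.52)
  expect_true(all(strsplit(g$chromosomes[[1]], "")[[1]] %in%
                    c("A", "C", "G", "T")))
  g2 <- generate_genome(seed = 1, n_chrom = 1, lengths = 50000,
                        gc_fraction = 0.5)
  expect_identical(g$chromosomes, g2$chromosomes)
  g3 <- generate_genome(seed = 2, n_chrom = 1, lengths = 50000)
  expect_false(identical(g$chromosomes, g3$chromosomes))
  expect_error(generate_genome(1, 1, 50000, gc_fraction = 0), "gc_fraction")
  expect_error(generate_genome(1, 1, -5), "positive")
  expect_error(generate_genome(1, 1, 5000), ">= 10000")
})

test_that("planted genes keep disjoint flank-extended spans and crafted overlaps are flagged", {
  g <- generate_genome(3, 1, 200000)
  genes <- plant_annotation(g, 10, min_len = 5000, seed = 4)
  expect_equal(nrow(genes), 10)
  expect_true(all(genes$end - genes$start >= 5000))
  # brute-force interval-intersection check on [start-2000, end+2000)
  s <- genes$start - 2000; e <- genes$end + 2000
  for (i in 1:9) for (j in (i + 1):10) {
    expect_true(s[i] >= e[j] || s[j] >= e[i])
  }
  expect_true(all(genes$non_overlapping))
  expect_true(all(s >= 0 & e <= 200000))
  # TSS/TES derive from strand
  plus <- genes$strand == "+"
  expect_equal(genes$tss[plus], genes$start[plus])
  expect_equal(genes$tss[!plus], genes$end[!plus] - 1L)

  expect_equal(nrow(plant_annotation(g, 0)), 0)
  expect_error(plant_annotation(g, 100, min_len = 5000, seed = 1), "chr1")

  crafted <- gene_models(data.frame(
    gene_id = c("a", "b", "c"), chrom = "chr1", strand = "+",
    start = c(1000, 4000, 50000), end = c(5000, 9000, 55000)))
  expect_equal(crafted$non_overlapping, c(FALSE, FALSE, TRUE))
})

test_that("fragment counts follow program levels and totals are fixed", {
  g <- generate_genome(5, 1, 100000)
  genes <- gene_models(data.frame(
    gene_id = c("hi", "lo"), chrom = "chr1", strand = c("+", "-"),
    start = c(10000, 50000), end = c(20000, 60000)))
  prog <- transcription_program(genes, sense_level = c(3, 1))
  fr <- simulate_fragments(g, genes, prog, 10000, seed = 6)
  expect_equal(nrow(fr), 10000)
  n_hi <- sum(fr$gene_id == "hi")
  ci <- qbinom(c(0.005, 0.995), 10000, 0.75)
  expect_gte(n_hi, ci[1])
  expect_lte(n_hi, ci[2])
  # determinism and seed sensitivity
  expect_identical(fr, simulate_fragments(g, genes, prog, 10000, seed = 6))
  expect_false(identical(fr$frag_start,
                         simulate_fragments(g, genes, prog, 10000,
                                            seed = 7)$frag_start))
  zero <- transcription_program(genes, sense_level = 0)
  expect_error(simulate_fragments(g, genes, zero, 100), "zero total")
})

test_that("per-gene fragment counts pass a multinomial calibration across seeds", {
  g <- generate_genome(8, 1, 500000)
  genes <- plant_annotation(g, 20, min_len = 4000, max_len = 8000, seed = 9)
  lev <- seq(1, 5, length.out = 20)
  prog <- transcription_program(genes, sense_level = lev)
  p <- lev * (genes$end - genes$start) / 1000
  p <- p / sum(p)
  rejections <- 0L
  for (s in 1:20) {
    fr <- simulate_fragments(g, genes, prog, 20000, seed = 100 + s)
    obs <- table(factor(fr$gene_id, levels = genes$gene_id))
    pval <- suppressWarnings(chisq.test(as.integer(obs), p = p)$p.value)
    if (pval < 0.01) rejections <- rejections + 1L
  }
  # allow the nominal 1% false-positive rate (P(>3 of 20) < 1e-5)
  expect_lte(rejections, 3L)
})

test_that("bisulfite conversion identities hold at the rate extremes", {
  fx <- fixture_one_gene(seed = 11, strand = "+")
  prog <- transcription_program(fx$genes, sense_level = 10)
  full <- simulate_reads(fx$genome, fx$genes, prog, 300,
                         conversion_rate = 1, error_rate = 0, seed = 12)
  expect_false(grepl("C", paste(full$mate1, collapse = "")))
  # at full conversion every transcript C is an event
  tseq <- mapply(function(s, e) transcript_seq(fx$genome, "chr1", s, e, "+"),
                 full$truth$frag_start, full$truth$frag_end)
  nC <- vapply(tseq, function(s) sum(strsplit(s, "")[[1]] == "C"),
               integer(1))
  expect_equal(full$truth$conversion_events, unname(nC))
  # mate1 equals the C->T-converted genome forward strand at its locus
  expect_equal(full$mate1,
               unname(substr(chartr("C", "T", tseq), 1, 75)))

  none <- simulate_reads(fx$genome, fx$genes, prog, 200,
                         conversion_rate = 0, error_rate = 0, seed = 13)
  tseq0 <- mapply(function(s, e) transcript_seq(fx$genome, "chr1", s, e, "+"),
                  none$truth$frag_start, none$truth$frag_end)
  expect_equal(none$mate1, unname(substr(tseq0, 1, 75)))
  expect_equal(none$truth$conversion_events, rep(0L, 200))
  # mates are reverse-complement-consistent with one fragment
  flen <- none$truth$frag_end - none$truth$frag_start
  tail75 <- substring(tseq0, flen - 74, flen)
  expect_equal(none$mate2,
               unname(as.character(Biostrings::reverseComplement(
                 Biostrings::DNAStringSet(tail75)))))
})

test_that("antisense transcripts run opposite to the mRNA upstream of the TSS", {
  for (strand in c("+", "-")) {
    fx <- fixture_one_gene(seed = 14, strand = strand)
    prog <- transcription_program(fx$genes, sense_level = 0,
                                  antisense_level = 5)
    fr <- simulate_fragments(fx$genome, fx$genes, prog, 500, seed = 15)
    expect_true(all(fr$origin == "antisense"))
    expect_true(all(fr$strand == if (strand == "+") "-" else "+"))
    mids <- fr$frag_start + (fr$frag_end - fr$frag_start) %/% 2
    tss <- fx$genes$tss[1]
    if (strand == "+") expect_true(all(mids < tss))
    else expect_true(all(mids > tss))
  }
})

test_that("DRIVE fixtures are additive and recover planted enrichment in expectation", {
  fx <- simulate_drive_fixture(c(RPL13A = 2), background = 0.5,
                               noise_sd = 0, n_reps = 1,
                               condition = "CPT 2 min", seed = 1)
  expect_equal(fx$percent_input[fx$aliquot == "IP"], 2.5)
  expect_equal(fx$percent_input[fx$aliquot == "IP_RNaseH"], 0.5)
  fx0 <- simulate_drive_fixture(c(SNRPN = 0), background = 0.5,
                                noise_sd = 0, n_reps = 1, seed = 1)
  expect_equal(fx0$percent_input[fx0$aliquot == "IP"] -
                 fx0$percent_input[fx0$aliquot == "IP_RNaseH"], 0)
  expect_error(simulate_drive_fixture(c(a = 1), n_reps = 0), "n_reps")
  expect_error(simulate_drive_fixture(c(a = -1)), ">= 0")

  mc <- simulate_drive_fixture(c(TAF4 = 2), background = 0.5,
                               noise_sd = 0.1, n_reps = 100, seed = 2)
  sub <- mc$percent_input[mc$aliquot == "IP"] -
    mc$percent_input[mc$aliquot == "IP_RNaseH"]
  sem <- sd(sub) / sqrt(length(sub))
  expect_lt(abs(mean(sub) - 2), 3 * sem)
})

test_that("decay fixtures follow exp(-kt) in expectation, including the half-life identity", {
  k <- log(2) / 30
  fx <- simulate_decay_fixture(c(x = k), times = c(0, 30), noise_cv = 0,
                               seed = 1)
  expect_equal(fx$level[fx$time_min == 30], 0.5)
  fx0 <- simulate_decay_fixture(c(x = 0), noise_cv = 0, seed = 1)
  expect_equal(fx0$level, rep(1, 4))
  expect_error(simulate_decay_fixture(c(x = k), times = c(0, -5)), "negative")
  expect_error(simulate_decay_fixture(c(x = k), times = c(20, 40)), "time 0")

  mc <- simulate_decay_fixture(c(x = k), noise_cv = 0.05, n_courses = 100,
                               seed = 3)
  for (t in c(0, 20, 40, 60)) {
    m <- mean(mc$level[mc$time_min == t])
    expect_lt(abs(m / exp(-k * t) - 1), 0.02)
  }
})
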