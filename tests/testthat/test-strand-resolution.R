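test_that("reference conversion is the definitional substitution", {
  g <- make_genome(chr1 = "ACGTACGT", chr2 = "TTTT")
  expect_equal(unname(convert_reference(g, "CT")$chromosomes),
               c("ATGTATGT", "TTTT"))
  expect_equal(unname(convert_reference(g, "GA")$chromosomes),
               c("ACATACAT", "TTTT"))
  noc <- make_genome(chr1 = "AGTTGA")
  expect_equal(unname(convert_reference(noc, "CT")$chromosomes[1]), "AGTTGA")
  expect_error(convert_reference(g, "XY"))
})

test_that("a fully converted pair from a unique plus-strand locus hits CT only", {
  fx <- fixture_one_gene(seed = 21, strand = "+")
  prog <- transcription_program(fx$genes, sense_level = 10)
  sim <- simulate_reads(fx$genome, fx$genes, prog, 5,
                        conversion_rate = 1, error_rate = 0, seed = 22)
  ct <- convert_reference(fx$genome, "CT")
  ga <- convert_reference(fx$genome, "GA")
  for (i in 1:5) {
    h <- align_pair(list(mate1 = sim$mate1[i], mate2 = sim$mate2[i]), ct, ga)
    expect_equal(nrow(h$hits_CT), 1)
    expect_equal(nrow(h$hits_GA), 0)
    expect_equal(h$hits_CT$start, sim$truth$frag_start[i])
    expect_equal(h$hits_CT$end, sim$truth$frag_end[i])
    expect_equal(h$hits_CT$mismatches, 0)
  }
})

test_that("a template with neither C nor G hits both references; foreign reads hit none", {
  set.seed(23)
  base <- paste(sample(c("A", "C", "G", "T"), 50000, TRUE), collapse = "")
  at <- paste(sample(c("A", "T"), 300, TRUE), collapse = "")
  chrom <- paste0(substr(base, 1, 20000), at, substr(base, 20301, 50000))
  g <- make_genome(chr1 = chrom)
  ct <- convert_reference(g, "CT")
  ga <- convert_reference(g, "GA")
  frag <- substr(chrom, 20051, 20250)
  pair <- list(mate1 = substr(frag, 1, 75),
               mate2 = oracle_revcomp(substring(frag, 126, 200)))
  h <- align_pair(pair, ct, ga)
  expect_gte(nrow(h$hits_CT), 1)
  expect_gte(nrow(h$hits_GA), 1)
  expect_equal(call_strand(h$hits_CT, h$hits_GA)$call, "ambiguous_discarded")

  rnd <- list(mate1 = paste(sample(c("A", "C", "G", "T"), 75, TRUE),
                            collapse = ""),
              mate2 = paste(sample(c("A", "C", "G", "T"), 75, TRUE),
                            collapse = ""))
  h2 <- align_pair(rnd, ct, ga)
  expect_equal(nrow(h2$hits_CT), 0)
  expect_equal(nrow(h2$hits_GA), 0)
  # matches the exhaustive scan on the same inputs
  expect_equal(hit_key(oracle_pair_hits(rnd$mate1, rnd$mate2, ct, 3, 20,
                                        1000)),
               character(0))
})

test_that("strand calling maps hit patterns per the discard rules and is symmetric", {
  hit <- function(mm) data.frame(chrom = "chr1", start = 0L,
                                 end = 150L + mm, mismatches = mm,
                                 reference_mode = "CT", proper = TRUE)
  none <- hit(0)[0, ]
  expect_equal(call_strand(hit(0), none)$call, "plus")
  expect_equal(call_strand(none, hit(0))$call, "minus")
  expect_equal(call_strand(hit(0), hit(1))$call, "ambiguous_discarded")
  expect_equal(call_strand(none, none)$call, "unmapped")
  # equal-score multi-mapping within one reference is discarded
  two <- rbind(hit(1), hit(1))
  expect_equal(call_strand(two, none)$call, "ambiguous_discarded")
  # a unique best among worse hits is kept
  best <- rbind(hit(0), hit(2))
  cs <- call_strand(best, none)
  expect_equal(cs$call, "plus")
  expect_equal(cs$best_hit$mismatches, 0)
  # symmetry: swapping hit lists maps plus<->minus and fixes the rest
  cases <- list(list(hit(0), none), list(none, hit(0)),
                list(hit(0), hit(0)), list(none, none), list(two, none))
  flip <- c(plus = "minus", minus = "plus",
            ambiguous_discarded = "ambiguous_discarded",
            unmapped = "unmapped")
  for (cs2 in cases) {
    a <- call_strand(cs2[[1]], cs2[[2]])$call
    b <- call_strand(cs2[[2]], cs2[[1]])$call
    expect_equal(unname(flip[a]), b)
  }
})

test_that("toy aligner hit sets equal the exhaustive scan, with and without errors", {
  g <- generate_genome(24, 1, 30000)
  genes <- gene_models(data.frame(gene_id = "g", chrom = "chr1",
                                  strand = "-", start = 9000, end = 14000))
  prog <- transcription_program(genes, sense_level = 5, antisense_level = 2)
  sim <- simulate_reads(g, genes, prog, 15, conversion_rate = 0.98,
                        error_rate = 0.01, seed = 25)
  ct <- convert_reference(g, "CT")
  ga <- convert_reference(g, "GA")
  for (i in seq_len(15)) {
    pair <- list(mate1 = sim$mate1[i], mate2 = sim$mate2[i])
    h <- align_pair(pair, ct, ga, max_mismatch = 4)
    expect_equal(hit_key(h$hits_CT),
                 hit_key(oracle_pair_hits(pair$mate1, pair$mate2, ct,
                                          4, 20, 1000)))
    expect_equal(hit_key(h$hits_GA),
                 hit_key(oracle_pair_hits(pair$mate1, pair$mate2, ga,
                                          4, 20, 1000)))
  }
})

test_that("raising max_mismatch never shrinks a hit set", {
  fx <- fixture_one_gene(seed = 26, strand = "+")
  prog <- transcription_program(fx$genes, sense_level = 10)
  sim <- simulate_reads(fx$genome, fx$genes, prog, 10,
                        conversion_rate = 0.99, error_rate = 0.02, seed = 27)
  ct <- convert_reference(fx$genome, "CT")
  ga <- convert_reference(fx$genome, "GA")
  for (i in 1:10) {
    pair <- list(mate1 = sim$mate1[i], mate2 = sim$mate2[i])
    prev <- character(0)
    for (mm in 0:5) {
      h <- align_pair(pair, ct, ga, max_mismatch = mm)
      cur <- c(hit_key(h$hits_CT), hit_key(h$hits_GA))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("whole-library resolution matches truth exactly on clean reads", {
  g <- generate_genome(28, 1, 100000)
  genes <- plant_annotation(g, 8, min_len = 4000, seed = 29)
  prog <- transcription_program(genes, sense_level = 10, antisense_level = 1)
  sim <- simulate_reads(g, genes, prog, 400, conversion_rate = 1,
                        error_rate = 0, seed = 30)
  calls <- resolve_library(sim, g)
  expect_equal(nrow(calls), 400)
  called <- calls$call %in% c("plus", "minus")
  expect_gte(mean(called), 0.99)
  expect_true(all(calls$strand[called] == sim$truth$strand[called]))
  expect_true(all(calls$start[called] == sim$truth$frag_start[called]))
  smry <- attr(calls, "summary")
  expect_equal(sum(smry), 400)
})

test_that("an AT-rich genome yields more ambiguous discards than a balanced one", {
  amb_frac <- function(gc) {
    g <- generate_genome(31, 1, 80000, gc_fraction = gc)
    genes <- plant_annotation(g, 4, min_len = 4000, seed = 32)
    prog <- transcription_program(genes, sense_level = 10)
    sim <- simulate_reads(g, genes, prog, 400, conversion_rate = 1,
                          error_rate = 0, seed = 33)
    calls <- resolve_library(sim, g)
    mean(calls$call == "ambiguous_discarded")
  }
  expect_gt(amb_frac(0.02), amb_frac(0.5))
})

test_that("library I/O round-trips and mismatched mates are rejected", {
  fx <- fixture_one_gene(seed = 34)
  prog <- transcription_program(fx$genes, sense_level = 10)
  sim <- simulate_reads(fx$genome, fx$genes, prog, 20, seed = 35)
  d <- withr::local_tempdir()
  r1 <- file.path(d, "r1.fq"); r2 <- file.path(d, "r2.fq")
  write_fastq(sim, r1, r2)
  lib <- read_paired_fastq(r1, r2)
  expect_equal(lib$mate1, unname(sim$mate1))
  expect_equal(lib$ids, sim$truth$pair_id)
  calls_file <- resolve_library(c(r1, r2), fx$genome)
  calls_mem <- resolve_library(sim, fx$genome)
  expect_equal(calls_file$call, calls_mem$call)
  expect_error(
    resolve_library(list(mate1 = sim$mate1, mate2 = sim$mate2[-1]),
                    fx$genome),
    "mate count mismatch")
  empty <- resolve_library(list(mate1 = character(0), mate2 = character(0)),
                           fx$genome)
  expect_equal(nrow(empty), 0)
  expect_equal(sum(attr(empty, "summary")), 0)
  # SAM output: two records per called pair, 1-based POS, strand tag
  sam <- file.path(d, "out.sam")
  write_strand_sam(calls_mem, sim, fx$genome, sam)
  lines <- readLines(sam)
  body <- lines[!startsWith(lines, "@")]
  called <- sum(calls_mem$call %in% c("plus", "minus"))
  expect_equal(length(body), 2 * called)
  f <- strsplit(body[1], "\t")[[1]]
  expect_equal(as.integer(f[4]), calls_mem$start[1] + 1L)
  expect_true(any(grepl("^XS:A:[+-]$", f)))
})
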