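---
title: "Methods: strand-resolved analysis of Top1-perturbed transcription"
author: "camptoseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strand-resolved analysis of Top1-perturbed transcription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camptoseq)
```

## Scientific background

Camptothecin (CPT) poisons DNA topoisomerase I (Top1) by trapping its
covalent cleavage complex on DNA. At active divergent (CpG-island-like)
promoters this perturbs the local transcription balance: promoter-associated
antisense RNAs (aRNAs, median length around 800 bases) accumulate, R-loops
(DNA:RNA hybrids with a displaced single strand) are transiently stabilized,
and under persistent treatment a subset of genes accumulates 5'-truncated
sense transcripts — reads pile up in the first kilobase downstream of the
TSS while the 3' end of the gene shows equal or reduced signal.

Three measurement modalities feed the analysis:

1. **Strand-specific bisulfite RNA-seq.** Cellular RNA is bisulfite treated
   so that cytosines read as thymines; because conversion acts on the RNA,
   the strand of origin of each cDNA fragment is recoverable by mapping
   against two converted genome copies (all C→T, "CT"; all G→A, "GA").
2. **DRIVE qPCR** (DNA:RNA in vitro enrichment): hybrids are pulled down
   with catalytically dead RNase H1 and quantified as percent of input, with
   an RNase H1-pretreated aliquot providing the hybrid-specific background.
3. **rtqPCR** relative quantification of aRNA levels and their turnover
   after transcription blockade.

Every module is exercised on synthetic data with known ground truth; the
generators are part of the package, not test scaffolding.

## The synthetic-data model

`generate_genome()` draws i.i.d. ACGT sequence at a chosen GC content, and
`plant_annotation()` places genes so that their 2 kb flank-extended spans
are pairwise disjoint (the "non-overlapping genes" used for profiling).
`transcription_program()` assigns per-gene expected fragment densities:

* **Sense transcription** covers the gene body uniformly.
  `simulate_fragments()` draws a *fixed total* of `n_fragments` from a
  multinomial over transcript components weighted by level × length. The
  fixed total reproduces the compositional behaviour of a library sequenced
  to fixed depth: planting extra 5' signal in some genes dilutes every
  other region slightly. This is deliberate — the 3' arm of the truncation
  screen ("reduced or equal" 3' signal) only behaves realistically under
  compositional sampling.
* **Antisense transcription** initiates uniformly within 1500 bases
  upstream of the TSS and runs in the opposite orientation, with lognormal
  transcript lengths (median 800 bases, sdlog 0.5 — the median is the
  observed aRNA size; the spread is a modelling choice).
* **CPT truncation effect**: under the `"CPT"` condition, genes flagged
  `truncated` have their sense density multiplied by
  `truncation_5prime_gain` over `[TSS, TSS + 1000)`.

Fragment midpoints are uniform along a transcript (piecewise-uniform when
the 5' gain is active); fragment lengths are normal (mean 250 bp, sd 30,
floored at the read length). Midpoint-uniform placement means annotated
boundaries see no artificial edge depletion, which keeps the uniform
profile genuinely flat; real libraries place whole fragments inside
transcripts and show mild edge tapering — one of the ways the generator is
simpler than reality.

`simulate_reads()` adds sequence: the fragment is taken in transcript
orientation, every transcript cytosine is independently converted C→T with
probability `conversion_rate` (default 0.99 — bisulfite conversion is
allowed to be incomplete), mate 1 is the first `read_len` bases (RNA-sense
orientation), mate 2 the reverse complement of the last `read_len` bases,
and uniform substitution errors are applied at `error_rate`. Qualities are
constant; quality trimming is out of scope. Transcripts are unspliced and
the aligner ungapped: none of the implemented statistics depend on splice
structure.

What the generator does **not** emulate: splicing, PCR duplicates,
coverage biases (GC, position), overdispersion between biological
replicates, R-loop structure itself. Passing tests therefore demonstrate
correctness of the statistics under the stated sampling model, not
robustness to every artefact of real libraries.

qPCR fixtures are constructed additively: `simulate_drive_fixture()` sets
the IP recovery to enrichment + background (+ Gaussian noise) and the
RNase H1 aliquot to the background alone, so background subtraction
recovers the planted value in expectation. `simulate_decay_fixture()`
multiplies `exp(-k t)` by lognormal noise with mean exactly 1 (meanlog
`-sdlog²/2`), so sample means estimate the decay curve without bias.

## Strand resolution

`convert_reference()` builds the CT and GA genome copies.  The toy aligner
(`align_pair()` / `resolve_library()`) is an exact-seed, ungapped,
concordant-pair matcher: reads are in-silico converted once per the library
chemistry (mate 1 C→T, mate 2 G→A), and each converted reference is
searched in both concordant orientations, exactly as a genome aligner
would treat a double-stranded reference. A 20-base exact seed at each
mate's biological 5' end generates candidates (Biostrings `PDict` for
libraries, `matchPattern` for single pairs); candidates are joined into
concordant pairs within `insert_max` and verified by full ungapped
mismatch counting with a pair-level bound (default 3).

The calling rule (`call_strand()`): a unique best CT-only hit → `plus`; a
unique best GA-only hit → `minus`; hits on both references, or equal-score
multi-mapping within one reference → `ambiguous_discarded`; nothing →
`unmapped`. Both-reference ambiguity arises exactly for fragments whose
template contains neither C nor G (their converted forms coincide), so
ambiguity is a property of local base composition, not of the library's
conversion rate — in-silico read conversion makes alignment invariant to
the realized conversion level. Tie handling (equal-score multi-mappers
discarded) is a declared choice; the alignment contract is small enough
that a spliced genome-scale aligner could be substituted behind it.

The aligner is validated against an exhaustive all-positions scan (an
independent substring-comparison oracle) on genomes up to 100 kb, and for
exactness: error-free fully converted pairs from unique loci must be
called 100% correctly, not merely accurately.

## Expression quantification and stratification

`count_fragments()` assigns each pair once, by fragment midpoint
(`start + floor(len/2)`) within `[start, end)` and matching called strand;
midpoint assignment avoids double counting at gene boundaries (an
any-overlap rule would not). FPKM is fragments per kilobase per million
*mapped fragments* — the unit produced by the standard quantifiers — via
`count / (length/1000) / (library/1e6)`.

`stratify_fpkm()` splits genes with FPKM in `(0, 500]` into four ordered
classes by boundaries `{0.3, 5, 50}` (log-spaced over the plotted range;
left-closed right-open intervals), with FPKM 0 and FPKM > 500 in the
excluded class. The published analysis prints only the range and the
number of groups; the boundaries are configurable, and whether "below 0.3"
is the lowest plotted group or the exclusion floor is likewise a
configuration choice (the default treats `(0, 0.3)` as the `low` class).

## Metagene profiles

`meta_coordinates()` maps each gene onto a fixed 140-bin frame: 20 × 100 bp
upstream bins from 2000 bases upstream of the TSS, 100 body bins of equal
width ±1 base, 20 × 100 bp downstream bins past the TES; minus-strand
genes are reflected so bin 0 is always the far upstream end. Genes shorter
than two bases per body bin are skipped and reported. The 20/100/20 scheme
mirrors the common default of metagene plotting tools and is configurable.

`metagene_profile()` computes per-gene per-bin densities
(`count / bin_kb / (library/1e6)`) and averages **per gene** (unweighted)
by default, so long or highly expressed genes do not dominate; pooled
counting is available (`method = "pooled"`) since the original tooling
does not state which it used. Two exact invariants are tested: per-gene
conservation (`sum(density × bin width)` equals the gene's normalized
in-window count) and invariance under reflecting the genome and
annotation.

## The truncation screen

`region_counts()` takes sense fragment midpoints in `[TSS, TSS + 1000)`
and `[TES - 1000, TES)` (transcription direction), normalized to region
length (1 kb) and library depth (per million). `truncation_screen()`
selects genes passing all four filters:

* `delta5 = r5_CPT - r5_ctrl >= theta5` (default 10, normalized units) —
  the printed criterion is typographically corrupt ("10 ≥ 100"), so the
  threshold is explicit and configurable;
* `delta3 = r3_CPT - r3_ctrl <= theta3` (default 5);
* fold change `r5_CPT / max(r5_ctrl, pseudocount) > 2` (pseudocount 1 raw
  read, scaled to normalized units, entering only as a denominator floor);
* raw 5' CPT reads > 5.

Depth normalization before the deltas makes the thresholds comparable
across library sizes; whether the original deltas were depth-normalized is
not recoverable, so `region_counts(normalize = "length")` exposes the raw
mode too.

Screen validation plants a 5× gain in 50 of 500 genes. The study-scale
conditions — genes 3–6 kb, 2 × 10⁶ fragments per condition — were fixed by
an a-priori power analysis of the 3' filter: under compositional sampling
the expected 3' dilution grows linearly with depth while counting noise
grows as its square root, so at this depth the `delta3 <= 5` arm passes
with per-gene probability ≈ 0.97, giving median sensitivity ≈ 0.98 with
essentially zero false discoveries; the fold-change filter alone keeps the
null screen below 1% selections.

## DRIVE quantification

`percent_input()` uses the standard Ct arithmetic
`efficiency^(ct_input - log_eff(dilution) - ct_ip) × 100` with efficiency
2 by default (the published analysis never prints its Ct arithmetic; these
are declared choices, overridable per assay). `subtract_background()`
floors negative differences at zero with an audit flag.
`normalize_to_reference()` divides by the 2-min CPT RPL13A cell *within
each experiment* before `summarize_enrichment()` pools across experiments
(mean ± SEM, with single-replicate SEM flagged as 0) — matching the
"of the same experiment" normalization order. Normalization is idempotent
and invariant to rescaling any single experiment, and on noiseless
fixtures the pipeline returns planted enrichment ratios exactly.

## Relative quantification and turnover

`ddct()` implements ΔΔCt (the published normalization — to cytochrome b or
β-actin mRNA and to untreated cells or time 0 — states the references but
not the arithmetic; ΔΔCt with efficiency 2 is the declared default). It is
exactly invariant to plate-wide Ct shifts and gives the calibrator fold
change 1.

`fit_decay()` models a time course as a single exponential through 1 at
time 0, fitting on log levels (`k = -Σ t·log y / Σ t²`) — the constrained
least-squares solution under multiplicative noise, matching the lognormal
fixture. Non-positive levels are excluded with a flag; at least three
usable points are required; `half_life = ln 2 / k` (infinite at k = 0).
`compare_turnover()` reports the rate ratio with the convention that a
ratio below 1 means slower degradation (aRNA stabilization under CPT).
A single exponential is a modelling choice: multiphasic decay or
transcriptional leakage after blockade would bias k toward the late
time points' behaviour.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open throughout; SAM output converts to
  1-based. Fragment midpoint: `start + floor(len/2)`.
* All generators are pure functions of `(seed, parameters)`; the RNG state
  of the caller is saved and restored.
* Problem sizes used by the validation suite: 10⁴ read pairs for
  strand-call exactness, 10⁶ fragments for profile flatness, 2 × 10⁶ per
  condition × 20 seeds for screen operating characteristics, 100 courses
  for decay recovery — sizes at which the binomial/lognormal error bars
  sit comfortably inside the tested tolerances.
* Degenerate inputs error early and specifically: zero-expression
  programs, infeasible gene packing (naming the chromosome), missing
  aliquots or reference cells (naming the experiment), mate-count
  mismatches (naming the record), non-positive library sizes.

## Known limitations

* The aligner is ungapped and unspliced by design; it is a contract
  stand-in for a genome-scale spliced aligner, not a replacement.
* FPKM here is per million mapped fragments; analyses built on a
  "per million sequenced nucleotides" reading would differ by a constant
  factor per library.
* The screen's operating characteristics are quoted under the generator's
  sampling model; overdispersed real replicates would need wider
  thresholds or replicate-aware testing.
* DRIVE efficiency is fixed at 2 unless overridden; no primer-efficiency
  estimation from dilution series is performed.

## Worked example

```{r example}
g <- generate_genome(seed = 1, n_chrom = 1, lengths = 200000)
genes <- plant_annotation(g, 10, min_len = 4000, max_len = 8000, seed = 2)
prog <- transcription_program(genes, sense_level = 10, antisense_level = 1)
sim <- simulate_reads(g, genes, prog, 5000, seed = 3)
calls <- resolve_library(sim, g)
calls
cnt <- count_fragments(calls, genes)
head(stratify_fpkm(compute_fpkm(cnt, genes$end - genes$start,
                                sum(attr(calls, "summary")[c("plus", "minus")]))))
```
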