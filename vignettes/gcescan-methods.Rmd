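---
title: "Detecting dual genetic code expansion: models, parameters and design choices"
author: "gcescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dual genetic code expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcescan)
```

## The problem

A small number of bacteria naturally use more than twenty amino acids.
Pyrrolysine (Pyl, one-letter code `O`) is inserted at in-frame UAG (amber)
codons and forms the active site of methylamine methyltransferases;
selenocysteine (Sec, `U`) is inserted at in-frame UGA (opal) codons when a
SECIS element — in bacteria a hairpin of roughly 50 nt immediately
downstream of the recoded codon — follows. Standard gene callers terminate
at these codons and truncate or fragment the recoded genes, so detecting
genetic code expansion (GCE) in genome assemblies and MAGs requires a
coordinated set of non-standard analyses:

1. gene calling under readthrough translation tables,
2. recognition of the structurally atypical Pyl and Sec tRNAs,
3. hairpin detection downstream of in-frame UGA codons,
4. alignment-based verification of the Pyl active site,
5. an inventory of the dedicated translation machinery
   (selA/selB/selC/selD; pylB/pylC/pylD/pylS/pylT), and
6. genome relatedness metrics (ANI, AAI) to place the organism.

`gcescan` implements this pipeline with a seeded synthetic-genome
generator so that every stage is testable against a machine-readable
truth table, without downloading any external data.

## Readthrough-aware ORF calling

`translation_table()` builds the bacterial code with optional
reassignments: amber mode maps TAG to `O`, opal maps TGA to `U`, dual maps
both; TAA is never reassigned (no natural TAA reassignment is known in
this clade). `find_orfs()` enumerates, on all six frames, ORFs that begin
at a bacterial start codon (ATG/GTG/TTG), end at a non-readthrough stop,
and pass through at most `max_readthrough` (default 2) readthrough codons,
which are recorded as events. One ORF is reported per terminal stop — the
leftmost qualifying start — which makes the output deterministic and
checkable against a brute-force six-frame oracle, unlike trained
gene-scoring models. The default minimum protein length is 60 aa; the
proteins of interest here (a 485-aa methyltransferase, ~240-aa
selenoproteins) are far longer. Contigs are treated as linear fragments;
codons containing `N` translate to `X`.

## tRNA recognition

`fold_cloverleaf()` does an exhaustive search over cloverleaf arm-length
windows chosen to bracket canonical tRNA dimensions plus the documented
deviations of the Pyl and Sec tRNAs: acceptor stem 6–9 bp,
acceptor-to-D spacer 1–3 nt, D stem 3–4 bp, D loop 4–12 nt, anticodon
stem 5–6 bp, anticodon loop fixed at 7 nt (anticodon at positions 3–5),
variable region 3–23 nt, T stem 4–5 bp, T loop 5–9 nt. A layout is legal
only when *every* stem position closes with a Watson–Crick or G·U wobble
pair, and `pair_score` counts the paired nucleotides of the four canonical
stems (2 per bp, wobble included).

Two calibration choices matter and were measured, not guessed:

* **The variable-arm stem is flagged but not scored.** A ≥3-bp stem
  somewhere inside a 10–23 nt window exists in random sequence with high
  probability, so awarding it points floods a genome scan with spurious
  arm-bearing layouts (measured: ~3.75 false cloverleafs per 100 kb at a
  threshold of 48 when the arm is scored; none in 2 Mb when it is not).
  The arm still determines Sec-tRNA classification.
* **The reporting threshold is `pair_score >= 48`**, i.e. fully paired
  maximal stems (9 + 4 + 6 + 5 bp). This keeps pure random sequence
  essentially free of calls (no hits in 2 Mb at 41% GC) while planted
  tRNAs, constructed with perfect stems, score exactly 48.

Classification then follows the anticodon plus its structural hallmark:
Pyl = CUA anticodon with a 6-bp anticodon stem (the "extra nucleotide")
or a single-nucleotide acceptor-to-D spacer; Sec = UCA anticodon with a
variable arm (≥10 nt containing a ≥3-bp stem) in place of the usual short
variable loop. A reassigned anticodon without its hallmark is reported
`ambiguous`, never silently promoted. `scan_genome_trnas()` slides 60–120
nt windows over both strands and reports non-overlapping candidates
greedily by descending score (ties: fewer wobble pairs, then leftmost).

## SECIS detection

`find_hairpin()` scans every (start, stem, loop) placement of a stem-loop
in a window, scoring `2*WC + 1*GU − 2*mismatch` with at most one
mismatched stem position by default; bulges are not modeled, which keeps
the search exhaustive and oracle-checkable. `scan_secis()` extracts, for
each `U` readthrough event, the 75-nt window downstream of the UGA in
reading direction (strand-aware) and requires the best hairpin to start
within 40 nt of the codon.

The score threshold (32) is the most consequential number in the module
and was calibrated against two null requirements. First, fewer than 5% of
decoy UGA genes (in-frame UGA, no planted hairpin) may produce a hit; the
measured null on random 75-nt windows gives P(score ≥ 18) ≈ 2.8%. Second
— much stricter — a 200-kb genome scanned in opal mode contains on the
order of a thousand background UGA windows, and exact recovery of planted
counts needs the *genome-wide* expectation of false hairpins to be well
below one; the measured null tail (P(score ≥ 28) ≈ 5×10⁻⁵, no score ≥ 30
observed in 20,000 windows) places the threshold at 32. The synthetic
generator plants perfect 18-bp stems (score 36) with a 6-nt loop 18 nt
downstream of the UGA, comfortably above threshold while still inside the
            ~50-nt envelope of natural bacterial SECIS elements. A strict
consensus-pattern flag is deliberately not imposed by default; the
threshold, stem, loop and mismatch parameters are all exposed.

## Calling recoded proteins

`call_selenoproteins()` requires both lines of evidence: at least one `U`
event *and* at least one passing SECIS hit. Calls split into the two
groups seen in nature: `known_family` when the best reference alignment
reaches 30% identity over 50% of the reference, else `novel`.

`call_pyl_proteins()` verifies candidates against pyrrolysine-containing
references (e.g. an archaeal methylamine methyltransferase with Pyl at
334 of 483). Verification needs three gates, and the package's own
benchmark shows why one is not enough:

* `site_aligned` — the candidate's `O` column must pair with the
  reference `O`. Alone this is nearly vacuous: when a global alignment
  must place a large length-difference gap somewhere, it will pair the
  two rare `O` residues almost for free (53 spurious calls on one 200-kb
  benchmark).
* downstream conservation — identity ≥50% over the 20 residues after the
  site, the machine-checkable version of "the region containing and
  following the recoded codon is conserved".
* reference coverage ≥50% — genuine Pyl methyltransferases are
  full-length homologs; short chance-readthrough ORFs whose tails align
  to one corner of the reference must not qualify.

With all three gates the benchmark yields exactly the planted calls, and
glycine-betaine methyltransferase decoys — homologs without the amber
codon, a known annotation trap — are never called because they have no
`O` event at all.

The alignment engine is an affine-gap Needleman–Wunsch (open 10,
extend 1) over BLOSUM62 extended with `O`, `U`, `X`: `O–O` and `U–U`
score as the maximum BLOSUM62 diagonal (11), `O–K` and `U–C` at half that
(Pyl is a lysine derivative; Sec is the selenium analog of cysteine),
other `O`/`U` pairings −4, and `X` 0 against everything. Identity is
computed over residue–residue columns, so terminal overhangs and internal
gaps never dilute it. Tie-breaking in the traceback is deterministic
(substitution before gap, gap-in-second before gap-in-first).
`consensus_sequence()` and `conserved_columns()` use strict-majority
rules (a tie at exactly the threshold emits `X` / is excluded), and
`dereplicate()` implements greedy length-sorted clustering at 90% global
identity.

## Machinery inventory and neighborhoods

Functional annotation is consumed, never computed: `inventory()` maps
family accessions or free labels to machinery components through an
editable `default_component_map()`, takes the tRNA components (selC,
pylT) from the tRNA scan classes, and reports completeness and copy
counts. `neighborhood()` implements the "<10 genes" locus criterion as a
strict gene-index inequality on the same contig, and
`cluster_conservation()` renders per-genome presence/order of a component
set around an anchor.

## ANI and AAI

`ani()` follows the fragment-based convention implemented by the widely
used online calculators: consecutive 1020-nt fragments, best match in the
other genome, a fragment counting when it reaches 70% identity over at
least 70% of its length, direction values averaged with hit-count
weights. The search uses exact 15-mer seeds on a 60-nt stride with
diagonal voting and a gapped global(fragment)–local(window) extension; an
`exhaustive = TRUE` flag scans every position and is used as the oracle
in tests. Undefined comparisons are reported as `NA`, never as 0, because
0% identity is not a meaningful ANI. `aai()` computes reciprocal best
hits by global alignment identity (qualifying: ≥30% identity over ≥70% of
the shorter sequence) and averages identity over RBHs.

## The synthetic benchmark

`plant_spec()` defaults define the study conditions: a 200-kb contig at
41% GC carrying 10 selenoprotein genes (U at residue 120 of 240, perfect
18-bp stem 18 nt downstream), 5 Pyl methyltransferase genes with `O` at
residue 327 of 485 (verified against a generated archaeal-style reference
with `O` at 334 of 483, built by placing 7 insertions before and 9
deletions after the conserved site region), 5 decoy UGA genes with random
downstream windows, 3 glycine-betaine-style decoys with the `O` replaced
by `K`, one Sec tRNA, one Pyl tRNA, three standard tRNAs, and an
annotation table carrying the full machinery cassette with the cognate
corrinoid gene 7 genes from the methyltransferase anchor and two CysA
(TIGR00968) copies.

Constructional details that matter for exact recovery:

* every planted coding gene is preceded by an in-frame TAA barrier so the
  leftmost-start rule recovers exactly the planted span;
* random codons inside planted genes are sense codons only, so the only
  readthrough events are the planted ones;
* stem-loops are strand-symmetric, so the generator validates that the
  only UGA trigger near a planted hairpin is the planted codon (no
  off-frame TGA within 43 nt upstream on the coding strand, no TCA — a
  reverse-strand TGA — within 44 nt downstream); without this,
  opposite-strand ORFs occasionally claim planted hairpins;
* reverse translation draws synonymous codons weighted toward the target
  GC, and planted tRNAs/hairpins are re-validated with the package's own
  detectors at construction time (deterministic bounded retries under the
  spec seed).

What the generator does *not* emulate: real codon-usage structure,
ribosome-binding signals, sequencing error, assembly fragmentation, and
natural SECIS sequence consensus beyond the hairpin. Passing the
benchmark therefore demonstrates the pipeline's logic and calibration on
idealized signals, not field performance on real MAGs, where the hairpin
model in particular is permissive by design.

## Problem sizes and numerical choices

The shipped tests run the full pipeline on 60-kb and 200-kb benchmarks,
check the ORF caller against a brute-force six-frame oracle on 100+
random contigs (1–10 kb) in every table mode, the aligner against an
independent dynamic-programming oracle on 200 random pairs, the hairpin
search against an exhaustive placement oracle, ANI/AAI against closed
form expectations (100·(1−µ) within ±0.5 / ±1.0) on 60-kb genomes and
8-protein proteomes, and decoy rates over 100–130 seeded replicates.
These sizes were chosen so the whole suite completes in minutes on one
core while keeping every estimate's Monte-Carlo error well inside the
asserted tolerances. All randomness flows from explicit seeds; reports
embed the effective configuration; ties everywhere break
deterministically (score, then fewer wobble pairs/mismatches, then
leftmost coordinate).

## Known limitations

* The hairpin model scores mismatches but not bulges or asymmetric
  internal loops, and applies no thermodynamic model; a natural SECIS
  with a large bulge would need a lower threshold or the strict flag off.
* The tRNA scanner is not a general annotator: it recognizes
  standard/Pyl/Sec classes by rule, without covariance models, isotype
  prediction, intron handling or CCA tails.
* The ORF caller reports the longest ORF per stop rather than scoring
  coding potential; on real genomes it will over-call short spurious
  ORFs, which downstream gates (SECIS evidence, reference verification)
  are designed to absorb.
* Selenoprotein and Pyl-gene counts reported for real recoded MAGs depend
  on the underlying metagenome assembly and on tool-specific SECIS
  consensus models, and cannot be reproduced from synthetic data; the
  package reproduces the *procedures* and their measurable properties
  (recovery, false-positive rates, divergence estimates) instead.
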