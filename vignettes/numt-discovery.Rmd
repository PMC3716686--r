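---
title: "Discovering and characterizing nuclear mitochondrial insertions with numtscape"
author: "numtscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and characterizing nuclear mitochondrial insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numtscape)
```

## The problem

Fragments of mitochondrial DNA are continually integrated into nuclear
chromosomes, where they decay as pseudogenes. These nuclear mitochondrial
insertions (NUMTs) are discovered by local alignment of the mitochondrial
genome against the nuclear assembly, and then characterized along four
axes: post-insertion duplication, interruption by mobile or low-complexity
elements, genomic context (gene density and intronic localization), and
expression evidence from transcript (EST) data. Cnidarian genomes are a
particularly interesting setting because mitochondrial genome architecture
varies within the phylum: hydrozoans carry two short *linear* mitochondrial
chromosomes with identical inverted terminal repeats (ITRs), while
anthozoans carry a single *circular* molecule, sometimes with a group-I
intron in *ND5*. NUMT content differs by orders of magnitude between such
genomes, so the pipeline must handle both topologies natively.

`numtscape` implements the full analysis as a tested R package. Because the
multi-hundred-megabase source assemblies are impractical for routine
validation, the package ships a first-class synthetic-genome module: every
downstream stage is exercised against genomes in which the complete truth
is known and machine-readable.

## The alignment engine

The search stage is an owned BLASTN-like engine (C++ via Rcpp):

1. **Seeding** — every exact `word_size`-mer shared between query
   (mitochondrial chromosome) and subject (nuclear scaffold) triggers an
   extension (one-hit seeding; sensitivity is preferred over speed at this
   scale). `N` never seeds and always scores as a mismatch. A per-diagonal
   high-water mark suppresses redundant seeds inside an already-extended
   region.
2. **Ungapped X-drop extension** outward from the seed, followed by
   **gapped affine X-drop extension** (Gotoh recurrences with an adaptive
   band) from the midpoint of the ungapped segment.
3. **Re-alignment** of the extension region with a banded global aligner
   with traceback, which yields the reported alignment statistics
   (identity, mismatches, gap openings, columns).
4. **Statistics** — raw scores are converted to bit scores and E-values
   with Karlin–Altschul parameters: `lambda` is the positive root of
   $\sum_{ij} p_i p_j e^{\lambda s(i,j)} = 1$ (solved to a residual below
   $10^{-9}$), and `E = K m n e^{-\lambda S}` with raw search-space lengths
   (no edge-effect correction; at the thresholds used here the correction
   is immaterial).

Both strands are searched by reverse-complementing the query; subject
coordinates are always reported on the plus strand.

Default scoring is the classic blastn-style `+1/-2` with gap open 5 and
gap extend 2, word size 11. The filtering contract applied to hits is
`E <= 1e-4` (inclusive) and a nuclear span of at least 50 bp ("shorter
than 50" is excluded, so a 50-bp hit at exactly `E = 1e-4` is retained —
the convention consistent with a smallest retained hit of 51 bp in
published per-hit tables).

Numerical choices worth knowing:

* **K** is estimated once per scoring scheme by a deterministic
  Monte-Carlo calibration: the best ungapped local scores of seeded random
  background pairs are fitted to the Gumbel mean formula. This is a
  documented approximation (the lattice correction is ignored and the same
  `K` is reused for gapped scores); `scoring_params(K = ...)` overrides it.
  At `E <= 1e-4` a factor-two error in `K` moves the score threshold by
  less than one match, so no downstream call is sensitive to it.
* The engine applies a loose internal reporting floor corresponding to
  `E <= 10` (the conventional report threshold) so that score-minimal junk
  extensions are never materialized; the strict filter is applied
  explicitly and separately by `filter_hits()`.
* **Circular topology** is handled by extending the query with a prefix
  copy (`circularize()`); reported intervals are folded back modulo the
  molecule length, origin-crossing hits carry `wraps_origin = TRUE`, and
  cyclic duplicates are removed.

An exact Smith–Waterman oracle (`smith_waterman()`, full-matrix Gotoh in
pure R, deterministic tie-breaking) is part of the package so the engine
is continuously validated against the true optimum: on random pairs
containing a shared word, the engine equals the optimum in well over 95%
of cases and never exceeds it.

## The synthetic world

`sim_config()` states the simulated world once; its defaults emulate a
scaled-down hydrozoan-like genome:

* mitochondrial genome: linear, two chromosomes of 8,194 and 7,686 bp
  (15,880 bp total) with identical ITRs at both ends of both chromosomes.
  The ITR length is not published for this architecture; the default of
  150 bp is a fixed package choice. A circular single-molecule
  configuration (optionally with an *ND5* group-I intron) models the
  anthozoan case.
* nuclear background: i.i.d. nucleotides at GC 0.276 (the published
  AT-rich nuclear composition); no higher-order structure, which is
  exactly the model under which the alignment statistics hold.
* gene models: 2–8 exons of 100–400 bp separated by introns of 200–2,000
  bp — introns large enough to host insertions.
* insertions: lengths uniform 100–2,000 bp by default; per-insertion
  substitution rate uniform on [0, 0.15] (published identities span
  roughly 79–100%, and no divergence model is published, so the default is
  illustrative, not fitted); indels at 1/10 the substitution rate with
  geometric lengths (p = 0.5, capped at 10 bp).
* duplication families copy one mutated insertion to several loci;
  interrupted insertions are split by either a dyad-repeat low-complexity
  element or a copy of a small simulated TE library; intronic insertions
  are placed wholly inside introns with one orientation per host gene
  (mirroring the published observation that all insertions within a gene
  share orientation); insertions supporting chimeric 5'-UTR transcripts
  are placed 50–200 bp upstream of genes.
* ESTs: pure mitochondrial contaminants, chimeric 5'-UTR and internal
  transcripts, and plain nuclear transcripts, each with a 0.5% per-base
  error (a sequencing-error stand-in).

All randomness derives from one master seed through fixed sub-streams:
identical configuration gives byte-identical output. The truth ledger
records every insertion (nuclear and mitochondrial intervals, strand,
divergence, realized substitutions, family id, interruption element,
host gene/feature, supporting EST ids).

What a green test on this world does *not* establish: recovery under real
repeat landscapes, assembly gaps/fragmentation, codon structure, or
heterozygosity. The simulator is a correctness harness for the pipeline's
logic and statistics, not a realism claim.

## Calling and summarizing

`call_numts()` supports two conventions: `per_hit` (one call per
alignment, mirroring per-alignment supplementary tables) and `merged`
(overlapping nuclear intervals unioned, best E-value kept). Summary
statistics follow the published conventions:

* **cumulative percentage** uses the *sum* of call lengths over the genome
  size — the only reading consistent with published totals alongside
  possibly-overlapping per-hit calls; the union is also reported.
* **mtDNA fraction transferred** is computed on the *union* of
  mitochondrial origin intervals (the only reading that can produce 100%
  coverage), with origin-wrapping intervals split at the circular origin.
* length variance is reported with the population denominator `n`
  (matching published variance figures) and the sample `n-1` alongside.
* genome size is taken from the assembly FASTA unless overridden — the
  published genome-size constants are never hard-coded.

## Characterization rules

* **Duplication families** — two calls are copies of one insertion when
  their mitochondrial origins reciprocally overlap at least 0.8 on the
  same mitochondrial chromosome while their nuclear loci differ; families
  are connected components of this relation. The 0.8 threshold
  operationalizes "same location in mtDNA" (no published threshold):
  loose enough to tolerate end erosion, tight enough to separate
  duplication from mere origin overlap. Note the rule is a *definition*:
  with many insertions in a 16-kb mitochondrial genome, independent
  origins occasionally satisfy it by chance, so recovery is validated
  against the same rule applied to the truth intervals.
* **Split pairs** — same scaffold, same strand, collinear in the
  mitochondrial genome, origin gap at most 100 bp (small negative gaps to
  -20 bp tolerate end erosion), nuclear gap at least 50 bp and at most
  50 kb. "Closely spaced" and "located away" are not quantified in the
  source; these bounds are configurable package choices.
* **Interruption classification** — the extracted gap is
  `transposable_element` if it aligns to the repeat library under the
  standard hit filter, else `low_complexity` if at least half of the
  64-bp windows have trinucleotide Shannon entropy below 1.2 bits, else
  `other`. The entropy detector replaces an external repeat-masking tool;
  1.2 bits flags dyad/homopolymer-like repeats (an AT dyad repeat scores
  exactly 1 bit) while random uniform sequence sits near 6 bits.
* **Genic context** — gene density counts genes (not transcripts)
  intersecting the call interval padded by 5 kb per side ("a 10-kbp
  window around each NUMT" is ambiguous between total 10 kb and ±10 kb;
  total 10 kb is the default, configurable), mapped to empty / 1–2 /
  more-than-2 categories. In-gene localization gives exon overlap
  priority, numbers introns in transcription order, and assigns a call
  spanning two genes to the larger overlap with lexicographic tie-break —
  a deterministic single host per call.
* **Expression** — an EST is a pure mitochondrial contaminant when
  mitochondrial alignments cover ≥ 95% of it at ≥ 98% identity (published
  filtering criteria are unspecified; these tolerate sequencing error
  while excluding genuine chimeras), chimeric when a passing
  mitochondrial block leaves ≥ 50 bp of contiguous non-mitochondrial
  sequence. Chimeric ESTs are placed by whole-EST alignment (≥ 90% of the
  EST at one locus), linked to overlapping calls, and classified `utr5`
  when the mitochondrial block maps 5' of the host gene's coding start.
  Stop-codon screening uses the universal code and NCBI translation
  table 4 (the coelenterate-appropriate mitochondrial code, where TGA
  encodes tryptophan) — so per frame, universal stops always dominate
  mitochondrial-code stops.

## Statistics utilities

`students_t_test()` is the classical pooled-variance form (`df =
n_a + n_b - 2`) because that is the named test in the comparative
analysis; Welch is available behind `var_equal = FALSE`. It is implemented
as the closed-form formula (validated against `stats::t.test` in the test
suite) so that zero-variance degenerate inputs return flagged `p = 1` /
`p = 0` instead of erroring. `pearson_loglog()` correlates
`log10(genome size)` with `log10(cumulative percentage)` with the t-based
two-sided p-value on `n - 2` df, excluding non-positive pairs with a
logged count.

## Known limitations

* Translated (protein-space) searches, tRNA structure folding, and de
  novo repeat-family discovery are out of scope; repeat classification
  requires a user-supplied library to go beyond the entropy detector.
* Gapped `K` is approximated by the ungapped calibration (override
  available).
* The per-hit convention double-reports insertions of sequence shared
  between mitochondrial chromosomes (identical ITRs) — deliberately, to
  mirror per-chromosome reporting; use `merged` mode for a non-redundant
  view.
* EST placement is not splice-aware; a chimeric transcript whose blocks
  span a long intron may fall below the single-locus coverage threshold.
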