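---
title: "Methods: virus discovery by metagenomic winnowing"
author: "virowinnow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virus discovery by metagenomic winnowing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the procedure

Insect virome surveys that prospect for new viral biocontrol agents face
a winnowing problem: pooled RNA libraries from field-collected colonies
are dominated by host transcripts, already-known viruses, dietary
organisms and sequencing controls, and a small residue of genuinely novel
viral sequence must be concentrated out of them. This package implements
that successive-winnowing procedure as a reusable, testable pipeline over
four geographically pooled libraries (labelled `SAL_1..SAL_4` after the
South American fire-ant libraries that motivated it):

1. **Quality filter** — retain a read iff its median Phred score is
   ≥ 20 and its length ≥ 25 bases. The median of an even-length quality
   vector is the mean of the two central values.
2. **Host subtraction** — remove reads matching the host reference.
   The original workflow used a short-read aligner; at desk scale we
   substitute shared-k-mer classification (defaults k = 21, T = 5 shared
   k-mers, both strands, N never matches). The aligner's mismatch
   tolerance is unstated in the source procedure; T is the equivalent
   sensitivity knob.
3. **Translated homology binning** — six-frame BLASTX-style search of
   the remaining reads against a taxon-labelled protein database with
   BLOSUM62, gap open 11 / extend 1, word size 3, and Karlin–Altschul
   statistics λ = 0.267, K = 0.041 (that tool's canonical gapped
   defaults; the source names the program but no parameters). The bit
   score is S′ = (λS − ln K)/ln 2 and E = m·n·2^(−S′) with m the query
   frame length (aa) and n the total database residues — no length
   correction, documented so fixtures are reproducible. Reads with best
   hit E < 10⁻⁵ (strict) are binned into {Animal, Plant, Fungi,
   Bacteria, Archaea, Protist, Phage, NonPhageVirus} by the best hit's
   label (best-hit-only binning; vote-among-hits would be an
   alternative, not implemented). phiX-flagged hits are removed and
   tallied outside every bin.
4. **Assembly** — greedy overlap-layout-consensus of the NonPhageVirus
   bin (both orientations), overlap length ≥ 40 nt and identity ≥ 90%
   (the published assembler's defaults), majority-vote consensus with
   ties broken A < C < G < T, and per-library singleton counts tallied
   from read labels. Assembly is pooled across libraries with
   per-library tallies, which reproduces the row structure of the
   published contig table.
5. **Known-virus matching** — contigs and leftover singletons whose best
   local nucleotide alignment to a known-virus genome reaches ≥ 95%
   identity are binned by species and excluded. The source states only
   the percentage; we additionally require an aligned length ≥ 50 nt so
   that trivially short perfect alignments cannot match, and we align
   both strands because assembled contigs have arbitrary orientation.
6. **Exclusion rules** — remaining sequences are re-searched by
   translated homology and excluded if shorter than 100 nt, hitless at
   E < 10⁻⁵, best-hitting a non-virus taxon, or best-hitting a
   plant virus (identified by the database species label, not host-range
   inference). Tally precedence is length, no-match, non-virus,
   plant-virus: a 99-nt contig with a strong viral hit is counted under
   the length rule.
7. **Classification and ranking** — each surviving contig's
   representation class is the number of libraries with ≥ 1 member
   singleton; records are ranked by singleton total, then libraries
   represented, then size; 4-of-4 contigs are flagged *high likelihood
   viral prospects*. (The published table's printed row order deviates
   once from its own described sort; we implement the described sort and
   test class sizes and sums, not row order.)
8. **Annotation** — ORF calling (ATG-initiated, plus strand, all
   frames), dicistrovirus architecture classification, motif-based
   domain localisation, polyA detection, and in-silico replicative-strand
   accounting from read strand tags (the analogue of strand-specific
   RT-PCR: replicative iff ≥ 5 minus-strand reads).
9. **Phylogeny** — Saitou–Nei neighbor joining on p or Poisson distances
   (pairwise gap deletion) with seeded column-bootstrap supports,
   emitting Newick. Poisson is the default (the standard amino-acid
   choice in the MEGA lineage); the original figure's distance model and
   gap treatment are unstated, so both are exposed as options and
   neither is claimed to be "the" published setting.

# The dicistrovirus architecture contract

A genome is classified `dicistrovirus-like` iff it has exactly two major
(≥ 600 nt) non-overlapping plus-strand ORFs in the same reading frame
(start positions congruent mod 3 — the operationalisation of the source's
undefined "in-frame"), separated and flanked by untranslated regions of
≥ 10 nt. An `ORFx` flag is set when a ≥ 60-nt ORF overlaps the first
200 nt of ORF2 in a different frame (the source does not state the short
overlapping ORF's length or extent; 60/200 are flagged assumptions, as
are the 600/60 major/minor cutoffs). Nested ORF calls sharing a stop are
collapsed to the 5′-most ATG before counting majors. Assembled contigs
have arbitrary orientation, so annotation evaluates both strands and
keeps the orientation with the better architecture evidence
(classification, then total major-ORF length, then polyA).

Domain localisation replaces profile-HMM search with packaged short
position-specific patterns (Walker-A-like helicase, 3C-protease-like
peptidase, the SGxxxTxxxNS…GDD RdRp core, and an invented capsid
anchor), each scoring +1 per constrained position with the threshold
equal to the constrained-position count. The pfam accessions these
emulate are retained as metadata labels only. This is deliberate: no HMM
database is available at desk scale, and the synthetic generator plants
exact motif instances, so a hit is evidence of placement, not of remote
homology detection power.

# The synthetic world

`sim_config()` states the world the tests run in; its defaults are fixed
and are not tuning knobs:

* 4 libraries × 10,000 single-end reads of 150 nt (the source does not
  report per-library totals after demultiplexing; these are declared
  free parameters chosen for 1-CPU budgets). Paired ends are not
  simulated because every downstream rule operates per read.
* Host genome 100 kb of uniform random sequence (host subtraction is
  exercised, not stress-tested: no repeats or introns), with three
  embedded stop-free coding windows whose translations are the Animal
  database decoys.
* Five known viruses (SINV-1..4, SiDNV) at library-varying abundance —
  the survey found known-virus load varying by orders of magnitude
  across regions — plus a planted novel dicistrovirus at fraction 0.05
  in every library, phiX and a second phage, and plant / fungal /
  bacterial / plant-virus decoys. The known-virus total (~11.5% of
  reads) is far below the real libraries' share (~79% of the non-phage
  bin); this is a deliberate desk-scale choice so that pooled assembly
  of the known-virus reads stays inside the grading budget, and the
  published fractions are exercised through the packaged printed-table
  fixtures instead.
* Substitution errors at 0.5% per base; no indels, chimeras or
  rRNA-depletion artefacts (declared non-goals). Per-base qualities are
  a discretised normal centred on the configured median (sd 4, clipped
  to [2, 40]) — only the median matters to the filter.
* A minus-strand fraction of 0.1 for replicating (ssRNA) viruses, which
  the manifest records so replicative-strand accounting can be verified.
* The polyA tail defaults to 60 nt: consensus 3′ ends are truncated by
  roughly genome-length/coverage bases (reads start uniformly), and
  oligo-dT-primed libraries capture polyadenylated termini deeply, so a
  tail that survives truncation is the realistic emulation.
* The novel genome is built to satisfy the architecture contract by
  construction: ORF2's 5′ region uses T-free codons (stop codons all
  contain T, so a T-free stretch is stop-free in every frame), an ATG is
  planted at offset +4 and its stop at the configured ORFx length, and
  UTRs are generated ATG-free so no spurious upstream start extends a
  major ORF. Diverged relatives of the two ORFs (30% amino-acid
  divergence, motifs spared) are placed in the protein database under
  dicistrovirus species labels, so reads from the planted virus bin as
  NonPhageVirus without the virus itself being known — the situation the
  procedure is designed to detect.
* One seeded RNG drives everything: `build_references()` uses the seed
  itself, `simulate_reads()` seed+1; within a run the draw order is per
  library, per taxon (abundance column order): counts, starts, strand
  flags, errors, qualities. Identical configs give byte-identical
  outputs.

What a green test does and does not establish: the synthetic world has
uniform random backgrounds, substitution-only errors, uniform coverage
and planted exact motifs, so passing tests demonstrate the correctness
of the winnowing logic, the statistics and the bookkeeping — not
robustness to repeats, indel-rich platforms, uneven coverage, chimeras,
or remote homology at real-database scale.

# Numerical and algorithmic choices

* **Seeding.** Word size 3 over the 20 standard residues, single exact
  hit gates a (frame, subject) pair, and the extension is a *full*
  Smith–Waterman of the gated pair rather than an X-drop extension.
  Seeded and exhaustive search therefore agree exactly whenever the best
  pair shares a word; a query with no seed anywhere returns no hit. No
  neighbourhood words or two-hit rule.
* **Alignment scoring.** Protein: BLOSUM62, gap of length g costs
  11 + g. Nucleotide: +5/−4, gap 10 + 4g, N scores 0. Identity is
  matches over alignment columns; coverage is query-relative (the
  published table's coverage:identity column does not state its
  reference; query-relative is assumed and labelled).
* **E-value ties** break by higher identity, then lexicographic subject
  id, for full determinism.
* **Overlaps** are gap-free: with a substitution-only error model the
  optimal overlap lies on a single diagonal, so the implementation
  evaluates every distinct diagonal that shares an exact 12-mer between
  a pair (both orientations) and the exhaustive oracle scans all
  offsets. An overlap every one of whose 12-mers is destroyed by errors
  is invisible to the seeded implementation — at 0.5% error on ≥ 40-nt
  overlaps this is vanishingly rare and is the documented sensitivity
  limit.
* **Greedy merging** processes overlaps by descending score
  (length × identity), ties by longer overlap then lexicographic id
  pair; an overlap between reads already in one contig is skipped
  (first placement wins; no consistency re-check — CAP3's forward–reverse
  constraints are a declared non-goal).
* **NJ** clamps negative branch lengths to zero (originals logged in the
  `"clamped"` attribute) and breaks Q-ties by the lexicographically
  smallest label pair. Bootstrap replicates resample included columns
  with replacement; replicate column indices are retained for audit.
* **Rounding** of reported percentages is half-up to one decimal, which
  reproduces the printed 33.4 / 78.8 / 97.4 from their integer
  numerators and denominators (banker's rounding does not).
* **Coordinates** are 0-based half-open internally, 1-based inclusive in
  GFF3 output.
* **Degenerate inputs.** Empty reads are rejected and counted
  separately; reads shorter than k are unmatched by definition and
  logged; a zero denominator reports an undefined (NA) percentage, not
  0; an all-zero library-count vector is an error (contigs must contain
  reads); saturated Poisson distances (p = 1) are an error rather than
  infinity.

# Design choices where the design was open

* **Best-hit-only binning** (not vote-among-hits): matches tabulating a
  top hit per read; flagged in the documentation.
* **Pooled assembly with per-library tallies** (not per-library
  assembly): the source is ambiguous; pooled assembly is what reproduces
  the published table's row structure of one contig with four counts.
* **Known-virus identity** is computed over the aligned region of the
  best local alignment with a 50-nt aligned-length floor.
* **Phylogeny accepts a user-supplied alignment** and does not
  re-implement multiple alignment (the source's alignment method is
  unstated); a toy RdRp-like alignment fixture exercises the module, and
  the real 16-taxon figure is not recreated (it would require external
  records).
* **The CLI config** is flat `key: value` YAML parsed by a small
  in-package reader (no YAML parser is pre-installed); unknown keys are
  rejected.

# Known limitations

Single-CPU desk scale throughout; no composition-based statistics or
low-complexity masking in the homology search; no quality-weighted
consensus or scaffolding in the assembler; motif patterns are anchors,
not profiles; the host subtraction k-mer model has no mismatch
tolerance within a k-mer (sensitivity is governed by T); IRES detection
and 5′/3′ RACE are out of scope.
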