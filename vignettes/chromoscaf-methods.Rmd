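---
title: "Methods: curation, reference-guided scaffolding, gap closing and rearrangement counting"
author: "chromoscaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, reference-guided scaffolding, gap closing and rearrangement counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chromoscaf implements the bespoke computational stages of a four-step
chromosome-scale assembly workflow for long-read data: contig curation,
reference-guided scaffolding, gap-targeted local reassembly and stitching, and
counting of large-scale structural discrepancies against a reference. The
alignments it consumes are pluggable — any long-read or whole-genome aligner
producing PAF can feed every stage, and the built-in synthetic generator can
produce exact truth alignments instead, so the complete pipeline is testable
on a laptop without downloads. This vignette explains each model and
procedure, its assumptions, the tunable parameters, and the design choices
made where the problem is genuinely open.

```{r setup, message = FALSE}
library(chromoscaf)
```

## Data model and coordinates

Sequence collections (contigs, reads, scaffolds) are tibbles with columns
`id`, `seq`, `length`; alignments are PAF tibbles; scaffold structure is a
`scaffold_plan` (an AGP-expressible component table with an attached set of
unplaced contigs). All internal coordinates are 0-based half-open, matching
PAF; AGP's 1-based inclusive convention is produced only at serialization.
Sequences are uppercase-normalized over `{A,C,G,T,N}`; characters outside
that alphabet are replaced by `N` and counted, never dropped, because length
conservation underpins every downstream interval computation.

## Step 1 — contig curation

Three independent evidence streams mark positions where a primary contig
should be split or a read recovered:

* **Dual-assembly reconciliation** (`reconcile_assemblies()`). Two
  assemblies of the same reads built with slightly different parameters
  rarely repeat the same misassembly. Aligning assembly A to its companion
  B, an internal stretch of an A-contig covered by no alignment marks a
  discrepancy. "Discrepancy" needs an operational definition, which the
  package fixes as: a maximal internal coverage gap longer than
  `coverage_tolerance` (default 100 bp), with abutting alignments merged
  regardless of which B-contig they hit (partner identity is irrelevant — a
  contiguity confirmation by any companion contig counts). The split lands
  at the gap midpoint: with no signal about the true breakpoint inside the
  gap, the midpoint is the unbiased choice.
* **Zero-coverage splitting** (`coverage_from_alignments()`,
  `find_zero_coverage_splits()`). Depth is the count of retained read
  alignments covering a base. Internal runs of zero depth of at least
  `min_zero_run` bases (default 1: the rule is taken literally — any
  truly uncovered internal base splits) yield one split at the run midpoint.
  Runs touching a contig end are reported as trim intervals instead of
  splits, since mapping end effects would otherwise shatter every contig
  terminus. Coverage evidence from raw reads and from 500-bp read-end pairs
  (`make_read_end_pairs()`) is summed into one combined profile by default
  (`combine_coverage()`); whether the two profiles should instead be
  consulted separately is not determined by the workflow's description, so
  both routes are exposed.
* **Partial-mapping rescue** (`classify_partially_mapped_reads()`). A read
  whose aligned query intervals cover, in union, less than 10% of its length
  is written to a rescue list for independent re-assembly; completely
  unmapped reads are rescued too. The threshold is strict: exactly 10%
  mapped is not rescued.

`apply_splits()` materializes all split points, naming fragments
`<id>.1, <id>.2, …` left to right; concatenating the fragments always
reproduces the parent sequence exactly.

## Step 2/4 — reference-guided scaffolding

A synteny-based scaffolder is re-implemented here as transparent
weighted-anchor placement rather than a synteny-block graph: the role —
ordering and orienting curated contigs along one or more possibly diverged
reference genomes — is the same, but every decision is a weighted majority
that can be verified by hand.

1. `build_anchor_blocks()` turns MQ-filtered contig-to-reference alignments
   into anchor blocks: records on the same (contig, chromosome, strand) are
   chained when collinear with query and target gaps at most `max_chain_gap`
   (default 100 kb), and merged blocks spanning less than `min_block`
   (default 5 kb) are discarded as likely repeat anchors. Both defaults are
   exposed; 5 kb is chosen to sit well above common interspersed-repeat
   lengths while keeping small contigs placeable.
2. `place_contigs()` assigns each contig to the chromosome with the largest
   summed anchor weight (matching bases). Orientation is the weight majority
   of anchor strands; the ordering key is the weight-weighted median of
   anchor midpoints, which is robust to a minority of stray anchors. The
   runner-up/winner weight ratio is reported as `ambiguity`. All ties break
   lexicographically (chromosome) or to `+` (strand), so plans are
   deterministic and byte-identical across runs.
3. `order_and_gap()` sorts each chromosome's contigs by ordering key and
   estimates each gap as the reference distance between facing anchors minus
   the unaligned contig tails that project into the gap, floored at
   `min_gap` (default 100 bp). The reference distance is the only available
   gap signal; the floor keeps estimated-negative gaps (anchor overlap on a
   diverged reference) representable in AGP.

Multiple references are consumed sequentially in the user's stated
precedence order (closest relative first): contigs still unplaced after
reference *k*, or placed with ambiguity above 0.8, are offered to reference
*k+1*; a confident earlier placement is never overridden. How disagreeing
references should be reconciled is an open design question; strict
precedence is this package's answer because it is predictable and mirrors
how a user orders the reference list.

`detect_scaffold_conflicts()` guards the opposite direction: after local
reassembly has improved the contigs, aligning them back to the prior
scaffold plan exposes contigs that bridge two scaffolds or jump more than
`max_jump` (default 1 Mb) within one — likely chimeras introduced by
reassembly. Junctions need `min_side` (default 50 kb) aligned bases on both
sides so that repeat-induced stray alignments cannot trigger splits.

## Step 3/4 — gap closing and stitching

Reads mapping within 20-kb windows around each scaffold gap (and scaffold
termini) are extracted per window (`extract_gap_windows()`; a read may serve
several windows). Each window is locally assembled by
`greedy_overlap_assemble()`, a deliberately transparent overlap assembler:
it repeatedly merges the pair of sequences, in either orientation, with the
longest end-overlap passing `min_overlap` (default 1 kb) and `min_identity`
(default 0.95), with ties broken by identity then lexicographic id. Exactly
contained sequences are absorbed first. The interface is pluggable: any
external assembler's FASTA output can be substituted per window. Because the
input to this stage is pre-assembled sequence (consensus accuracy around
98–99%), the conservative identity default is appropriate; for raw noisy
reads an external assembler should be plugged in instead.

Overlap detection is k-mer seeded (default k = 15): exact seed matches
between the tail of one sequence and the head of the other propose candidate
overlap lengths, which are verified longest-first by edit distance over the
implied overlap region (identity ≈ 1 − distance/overlap). Overlaps beyond
20 kb are verified on spaced chunks along the diagonal instead of the full
region — an approximation that only affects very long overlaps, where chunked
identity is an unbiased estimate under the i.i.d. error model. Seeding means
a true overlap whose every sampled seed is disrupted by errors can be
missed; at the default identity floor of 0.95 and 64 seed positions this
probability is negligible.

`close_gaps()` walks each scaffold left to right and tries, per gap:

1. **patch-mediated closure** — a window contig whose prefix overlaps the
   left flank's end and whose suffix overlaps the right flank's start (each
   by at least `min_overlap` at `min_identity`) replaces the gap with its
   inter-flank sequence;
2. **direct stitching** (`stitch_gap()`) — the flanks themselves overlap;
   the longest suffix–prefix alignment within `max_search` (default 100 kb)
   of each flanking end closes the gap. The junction sequence is taken from
   the left flank by convention: deterministic, and consensus choices belong
   to polishing, which is out of scope.

Each closure merges two components into one, so the contig N50 can only
grow; re-running `close_gaps()` on its own output closes nothing further.
Contigs can also be re-chunked into overlapping pseudo-reads
(`chunk_pseudo_reads()`, 250 kb chunks stepping 200 kb) to re-feed an
assembler whose read length is capped at 256 kb; the 50 kb (20%) overlap is
a package choice — large enough that every junction is spanned, small
enough to keep the chunk count near the minimum.

## Rearrangement counting

`classify_events()` audits an assembly against a reference using chained,
MQ-60-filtered whole-genome alignments. Filtering at mapping quality 60
keeps only uniquely placed alignments; `chain_alignments()` re-joins split
neighbouring records (same chromosome and strand, collinear, gaps at most
300 kb — deliberately equal to the event-size threshold so that splits
smaller than a countable event never fragment a chain). Chains whose query
span is below `min_event_size` (default 300 kb) are ignored outright. Three
event classes are counted per query scaffold:

* **fusion/fission (f)** — each adjacent pair of chains on different
  reference chromosomes is one junction; the two directions are
  indistinguishable from alignment alone and are counted as one class.
* **inversion (i)** — within each chromosome's chains, the dominant strand
  is the weight majority; each maximal run of opposite-strand chains whose
  query span reaches the threshold is one inversion. A scaffold aligned
  entirely on the minus strand is therefore *not* an inversion — the
  dominant strand defines the expected orientation.
* **intra-chromosomal translocation (t)** — among the dominant-strand chains
  of one chromosome, the weight-maximal monotone subsequence of reference
  starts (increasing for `+`, decreasing for `-`) defines the collinear
  backbone; every excluded chain is one displaced segment. The
  weight-maximal criterion is deterministic and verifiable by brute force on
  small instances.

Dominance is computed per (query, chromosome) pair rather than once per
query: a fused scaffold legitimately spans two chromosomes, and events on
its smaller half must not be silenced by the larger one. A segment that is
both displaced and inverted is counted once in each class; with alignment
evidence only, there is no principled way to privilege one reading, so the
two counters are kept independent and documented as such.

`dotplot_data()` exports the chains in cumulative coordinates (chromosomes
and scaffolds concatenated in sorted name order) for plotting with
`plot_dotplot()`.

## Synthetic truth generator

The generator exists so that every stage above is exercised against known
truth. `simulate_reference()` draws i.i.d. bases at a requested GC content.
`plant_rearrangements()` derives a sample genome by editing an ordered
segment map per chromosome (segments of reference coordinates with strand);
inversions reverse and flip a segment range in place, intra-chromosomal
translocations excise and reinsert a range, fusions concatenate two maps.
Because sequences are materialized from the segment maps, the recorded truth
and the sample genome cannot disagree, and `truth_alignments()` can emit
exact PAF (mapq 60, matches = segment length) by composing any interval on
the sample genome through the maps — replacing an external aligner for tests
and desk-scale runs. Event sites are drawn uniformly, at least 1 Mb from
chromosome ends and previously planted events, so that window and threshold
logic never meets degenerate overlaps.

`fragment_into_contigs()` tiles each chromosome with exponential fragment
lengths calibrated so the achieved N50 is close to the target (the N50 of
exponential fragments is about 1.68× their mean — the solution of
(1+x)e^{−x} = 1/2), assigns random orientations, and shuffles ids.
`simulate_reads()` draws Poisson-positioned reads with normal lengths and
i.i.d. per-base substitution/insertion/deletion errors. The error model is
deliberately instrument-agnostic: no homopolymer structure, no quality
values. Consequently, passing tests demonstrate the correctness of the
interval logic, thresholds and bookkeeping — not robustness to real
instrument error profiles, which enter only through the pluggable aligner
and assembler interfaces.

## Verification strategy and problem sizes

The test suite checks exact recovery end to end on a 30 Mb, 4-chromosome
genome: six planted events of at least 600 kb (twice the counting threshold)
are recovered as exactly f:1, t:2, i:3 across 20 generator seeds, with
classification performed on chromosome-scale coordinates
(`plan_from_provenance()` + `project_paf_to_scaffolds()` lift the ~1 Mb
contigs' truth alignments onto their scaffolds, equivalent to re-aligning
the assembled scaffolds). Planting the same events at 200 kb yields zero
counts, and counts are monotone non-increasing in the threshold. The same
genome, fragmented into ≥50 shuffled and randomly oriented contigs (each at
least 10 kb so that every contig can carry an anchor above `min_block`), is
restored to 100% contig order and orientation, and the reconstructed
scaffolds equal the reference up to the N gap runs. Twenty read-tiled gaps
close 20/20 with byte-exact junctions, idempotently. The greedy assembler is
checked for equivalence against an exhaustive all-pairs, both-strands
overlap oracle on 50 instances of up to 12 sequences, and N50 against an
enumeration oracle on 1000 random length multisets. These sizes are chosen
to exercise every rule at realistic scale while keeping the whole suite
runnable in minutes on one core.

## Known limitations

* Consensus polishing, BUSCO-style completeness and k-mer QV are out of
  scope; junction base-calling at stitches simply keeps the left flank.
* The greedy assembler is a desk-scale stand-in with k-mer-seeded overlap
  detection; identity-level (non-exact) containments are not absorbed, and
  repeat-heavy windows should use an external assembler via the pluggable
  interface.
* Gap estimates inherit reference structure: on a structurally diverged
  reference, the projected distance can misestimate true gap sizes (the
  floor at `min_gap` bounds the error from below only).
* Breakpoints are reported at chain boundaries; base-pair-resolution
  refinement and events below 300 kb are out of scope.
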