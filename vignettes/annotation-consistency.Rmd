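---
title: "Auditing pan-genome annotation consistency with whole-genome multiple alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing pan-genome annotation consistency with whole-genome multiple alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When many isolates of one bacterial species are sequenced and annotated, the
annotations rarely agree. Different gene callers, different annotation dates
and different amounts of manual curation produce orthologous genes whose
annotated structures differ even where the underlying DNA is nearly
identical. The most frequent disagreement is the translation initiation site
(TIS): prokaryotic gene finders locate stop codons reliably but routinely
pick different in-frame start codons. Draft assemblies add further artifacts:
genes truncated at contig boundaries, and genes split into fragments by
sequencing errors that introduce spurious frameshifts.

`panann` audits a set of annotated genomes against a reference-independent
whole-genome multiple alignment (WGA, in MAF format, one aligned segment per
genome per block). Because closely related genomes align almost everywhere,
the alignment provides a shared coordinate system — the alignment *column* —
in which annotated start and stop codons can be compared directly, without
BLAST and without a reference genome. The package does three things:

1. builds **positional ortholog groups** from the alignment,
2. **classifies** each group's annotation consistency, and
3. proposes **ranked alternative gene structures** that would restore
   consistency, including single-frameshift repairs of fragmented genes and
   suggestions for missing annotations.

The package deliberately stops short of declaring any annotation correct:
consistency is evidence, not proof, and the reports are meant to direct a
curator's attention.

## Ortholog grouping

Genes (CDS features) are processed greedily in order of decreasing length.
The longest unassigned gene becomes the *query* of a new group; genes from
*other* genomes join the group when the alignment links them to the query:

* the aligned overlap (columns where both rows carry a base) must cover at
  least `cov_match` of the candidate gene's length (default 0.5), and
* the alignment must cover at least `cov_query` of the query's length
  (default 0.5), evaluated once per query over the union of its blocks.

Joined genes are removed from the pool, so every gene lands in exactly one
group. A query with no qualifying partner forms a singleton group. Because
the query is the longest member, a single intact gene can capture several
short fragments from one genome — that is precisely how disrupted genes
surface (the fragmentation class below).

Coverage is counted in aligned (non-gap) bases after projection, making the
cutoffs insensitive to indels. The query-side cutoff is evaluated against
the union of the query's aligned blocks; a query failing it still seeds a
singleton group rather than disappearing. Ties in the length sort are broken
by genome id then gene id, so grouping is fully deterministic.

All interval queries (aligned segments and gene intervals) go through
`IRanges` nested containment lists; position/column projection uses
precomputed per-row lookup vectors, so projection is O(1) per base.

## Anomaly classes

For every non-singleton group the package projects each member's start codon
(biological 5' base) and stop codon (3' terminal base) to alignment columns
and applies an exact decision table:

| condition | class |
|---|---|
| all starts equal, all stops equal, ≤1 gene/genome | `consistent` |
| stops equal, starts differ | `inconsistent_starts` |
| starts equal, stops differ | `inconsistent_stops` |
| both differ, or members on different strands | `combination` |
| any genome contributes ≥2 members | `fragmentation` |

Fragmentation takes precedence as the primary class (a fragmented gene
necessarily perturbs the boundary comparison); the boundary verdict is kept
in `secondary_classes`. Column equality is exact — same block, same column.
Genes anchored in different blocks are never guessed equal: such groups are
classified `combination` and flagged `block_split`. A gene split across
blocks is anchored at the block containing its stop codon (ties: most
covered bases, then lowest block id).

Two further annotations accompany the class:

* **sole outlier** — the genome whose removal would make the rest of the
  group consistent, when exactly one such genome exists. Summed over groups
  this gives the per-genome inconsistency table, which exposes isolates
  annotated with a divergent protocol.
* **contig boundary** — set when a member is marked partial (5' or 3') or a
  member terminus lies within `W` bp (default 10) of a contig end. These
  anomalies usually reflect draft-assembly truncation, not annotation
  error.

Singletons are excluded from all anomaly denominators: a gene with no
aligned partner has nothing to be inconsistent with.

**Missing annotations.** A group whose aligned region spans a genome that
contributes no gene is a candidate missing annotation, reported only when
no annotated gene of any kind overlaps the projected interval, and only for
groups whose region aligns at least `min_genome_frac` (default 0.9) of all
genomes — accessory regions aligned in a few isolates otherwise flood the
report.

## Alternative gene structures

For each anomalous group the package enumerates the Cartesian product of the
distinct annotated start loci and stop loci observed in the group
(strand-consistent, start 5' of stop) and evaluates every pair in every
aligned genome: project both columns into the genome, extract the sequence
on the gene strand, and test it as an ORF under the bacterial genetic code —
first codon in `start_codons`, last codon in `stop_codons`, no internal
in-frame stop. The default start set is `{ATG, GTG, TTG}`; the bacterial
code formally admits rarer initiators (ATT, CTG, ...), so the set is a
`codon_config()` parameter rather than a constant.

**Frameshift repair.** When the direct test fails and the genome's row has
gap columns inside the candidate span, the evaluator tries a single frame
change at a gap-adjacent position (within one codon of the gap's left
anchor). The model: the 5' segment is read in the start-anchored frame, the
3' segment in the stop-anchored frame, and up to two bases straddling the
junction are left unchecked — the indel makes the junction codon ambiguous,
and fabricating it (e.g. by duplicating a neighbouring base) could invent a
stop codon that is not in the genome. `max_frameshifts` defaults to 1: one
un-annotated indel is the common, repairable case; anything more complex
deserves a curator, not an automatic edit.

**Ranking and filters.** Candidates shorter than `min_len_frac` (default
0.5) of the annotated gene length in any annotated genome are dropped.
Survivors are ordered by the number of genomes with a valid ORF, then by
length (both descending; the order is configurable via `sort_order`), with
deterministic locus-based tie-breaks. Each candidate also carries an
`overlap_flag` — true when the proposed interval would overlap an annotated
gene outside the group, a known hazard when moving a TIS upstream.

For missing-annotation records, the group's rank-1 pair (its own annotated
pair, for a consistent group) is evaluated in the unannotated genome and
reported only if it is a valid ORF there.

## Gap anchoring and degenerate inputs

A gap column projects to the nearest non-gap position on the *left of the
row text* (and reports `is_gap`), with −1 when no base lies to the left.
This left-anchor rule is what makes ORF extraction across indels
deterministic; its fixed orientation also means the planted-indel junction
is recovered exactly in the frameshift tests. Other conventions: internal
coordinates are 0-based half-open on the forward strand everywhere, with
conversion only at the GFF3/MAF boundary; MAF `src` fields are split at the
first `.` into genome and contig id (the common MAF convention); a MAF
block with two rows for one genome is skipped with a warning (duplications
are out of scope); a MAF row that disagrees with the FASTA sequence at any
base is a fatal error, because every codon decision depends on it; an empty
alignment degrades gracefully to all-singleton groups.

## The synthetic pan-genome

Real pan-genomes with curated ground truth do not exist at testable scale,
so the package ships a simulator whose defaults define its validation
conditions: 5 isolates, a 1 Mb ancestor carrying 800 non-overlapping ORFs of
300–1200 bp on both strands (packed with ≥20 bp intergenic spacers),
substitutions at 0.005 per base, and intergenic indels of 1–3 bp at 1e-4
per base. Substitution and indel rates are in the range observed between
closely related bacterial isolates; the gene density (~60% coding) and
length distribution match typical prokaryotic genomes.

Two constraints keep the ground truth exact. In-gene substitutions are
rejection-sampled so they never create a premature stop or destroy the
annotated start/stop codon, and indels are restricted to intergenic
sequence — an in-gene indel always frameshifts, which would plant an anomaly
the truth table does not know about. Consequently, at these rates the only
anomalies in a simulated data set are the planted ones, and the expected
test outcome is *exact* recovery, not approximate.

The truth alignment is star-aligned to the ancestor: every isolate is
aligned through its known mutation log, so indels become gap columns at
exactly the recorded positions. This is what the aligner *should* produce;
using it decouples validation of this package from the behaviour of any
particular WGA tool, at the cost of not exercising aligner errors
(misalignment, split blocks in repeats). Passing tests therefore demonstrate
correctness of the grouping/classification/repair logic, not robustness to
alignment noise.

Planted anomalies mirror the anomaly classes:

* `tis_shift` — one isolate's annotated start moves in frame to an existing
  downstream in-frame start codon (within the first 40% of the gene). The
  ancestral TIS remains valid in all genomes and longer, so the expected
  rank-1 alternative is the ancestral pair.
* `gene_split_indel` — 1 bp is deleted from the *sequence* mid-gene and the
  gene re-annotated as two fragments: the 5' fragment ends at the premature
  stop induced by the frameshift, the 3' fragment starts at a downstream
  in-frame start codon. The expected rank-1 alternative is the ancestral
  pair repaired by one frameshift at the planted gap column.
* `deleted_annotation` — the GFF3 record is dropped, sequence untouched;
  expected to surface as a missing-annotation record with a valid suggested
  ORF.
* `contig_break` — one isolate's contig is split inside a gene; both
  fragments are marked partial, and the truth alignment splits into blocks
  at the break. Expected to surface as a contig-boundary-flagged anomaly.

Each planted anomaly targets a distinct ancestral gene; genes unsuitable for
a plant (e.g. no internal start codon) are skipped in favour of the next
gene in a shuffled pool. A single RNG stream seeded from `sim_config(seed=)`
drives ancestor, isolates and plants in a fixed order, so outputs are
byte-reproducible.

## Problem sizes used in validation

The shipped test-suite exercises the full default conditions (5 × 1 Mb ×
800 genes) for the end-to-end recovery checks, randomized 5-genome
instances of up to ~50 genes against a naive quadratic grouping oracle, and
exhaustive projection round-trips on 10 kb blocks on both strands. Unit
tests use 20–40 kb pan-genomes with 10–25 genes, which are large enough to
contain every planted-anomaly configuration. `scripts/acceptance.R` re-runs
the two full-scale conditions from scratch and reports the measured counts.

## Known limitations

* One aligned segment per genome per block: segmental duplications are not
  interpreted; extra rows are skipped with a warning (and paralogy in
  general is out of scope — the method is positional).
* Spliced gene structures are not supported.
* Column comparisons across different blocks are conservative
  (`combination` + `block_split`), never inferred equal; genes straddling
  many block boundaries in fragmented alignments will inflate that class.
* Consistency is relative: an error propagated to every genome is invisible
  by construction.
* The frameshift search is restricted to gap-adjacent positions and at most
  `max_frameshifts` (≤2) changes; heavily degraded pseudogenes are reported
  but not repaired.
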