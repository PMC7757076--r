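---
title: "Assembly-gap forensics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembly-gap forensics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Draft genome assemblies fragment at repeats and at regions of extreme base
composition, and the resulting scaffold gaps hide exactly the sequence that
was hardest to assemble. Given a draft and a curated reference assembly of
the same genome, `gapscope` answers two questions per gap:

1. **What broke the assembly here?** — which repeat class sits immediately
   next to the gap (the *adjacency* analysis).
2. **What does the gap hide?** — which annotated sequence occupies the
   region of the reference that the gap corresponds to, found by aligning
   the gap's flanking sequence onto the reference (the *content* analysis,
   a flank-anchored liftover).

Around this core sit the completeness metrics used for "genomic dark
matter" in avian-like genomes: a GC-rich window census, a canonical
G-quadruplex (G4) motif scan, per-class repeat recovery, a census of a
multicopy exon family via six-frame translated search, gene
presence/absence calls, a simplified LTR Assembly Index, and sex-linkage
calling from female/male read-depth ratios.

Everything is verifiable without external data: a seeded simulator
generates an avian-like truth genome, derives a fragmented draft from it
with *known* gap causes, and the pipeline's output is compared against that
ground truth.

## Coordinates and gap definitions

All internal coordinates are 0-based half-open on the forward strand.
Conversions happen only at the file boundary: RepeatMasker `.out` and
blast-tabular input are 1-based inclusive, BED output is 0-based half-open.
A single convention internally removes the usual off-by-one drift.

A *gap* is a maximal run of N. Terminal N-runs (touching a scaffold end)
count in the whole-assembly gap census — the census definition does not
exclude ends — but are excluded from the cause analyses, which need flanks
on both sides. The cause analyses further keep only gaps longer than 10 bp
(`min_gap_len_analysis = 11`), because 1–5 bp N runs are typically
base-calling artefacts rather than assembly breaks. Contigs are scaffold
segments between N-runs of at least `contig_split_n = 25` bp (the
assemblathon convention; the threshold is configurable because published
tables rarely print it).

## Adjacency analysis

For each gap, repeats within `adjacency_window = 100` bp are collected.
Distance is the number of bases strictly between the two intervals, so
overlap *and* abutment count as distance 0, a repeat ending 101 bases
before the gap does not qualify, and one ending exactly 100 bases before
does. With no adjacent repeat the gap is `NoRepeat`; with one class, that
class; with several classes the repeat nearest to the gap edge wins, ties
broken by larger overlap with the gap and then by a fixed class order
(LINE, SINE, LTR, DNA, Satellite, SimpleRepeat, LowComplexity, rRNA,
Unknown, Other). Published gap-cause figures assign each gap to one group
without stating a tie rule, so the nearest-repeat choice here is a declared
convention — the full class multiset per gap is kept in the output so any
alternative tabulation can be recomputed.

## Flank liftover and content classification

500 bp flanks are taken immediately left and right of each gap. Gaps are
skipped (`NotScorable`, reason `terminal_gap`) when a side is shorter than
the flank or when a flank is more than half N (an adjacent second gap — a
pathology real drafts do produce).

Both flanks are aligned to the reference and filtered at **98% identity,
90% query coverage, e-value ≤ 1e-20**; all three thresholds are inclusive,
matching blastn-style cutoff flags. The liftover is accepted only when it
is unambiguous:

* zero passing hits on both flanks → `no_homology`;
* exactly one flank with hits → `one_flank_only`;
* two or more passing hits on either flank → `ambiguous`;
* unique hits on different reference sequences → `different_scaffolds`;
* strand disagreement, or flank order on the reference inconsistent with
  the strand → `orientation_conflict`;
* flanks more than `max_projected_span = 100` kb apart →
  `span_exceeded`. No published bound exists for this; 100 kb guards
  against paralogous flank pairings and every triggering is logged.

The projected interval runs between the gap-proximal *ends* of the two
flank hits, exclusive of the hits themselves; flanks that abut on the
reference give a zero-length projection, classified `NoRepeat` (a
"collapsed-to-zero" join rather than missing sequence). A projection
overlapping a reference N-run is `NotScorable`
(`maps_to_reference_gap`); otherwise one overlapping repeat class labels
the gap with that class, two or more label it `Complex`, none `NoRepeat`.
Both the all-gaps and the scorable-gaps denominators are reported in the
tabulation, since published proportions do not state which was used.

## The built-in aligner

Liftover and censusing run with no external binaries. The aligner is a
classic seed-and-extend design: exact k-mer seeding (k = 15 for DNA,
configurable down to 11 for diverged inputs; k = 4 on protein), seeds
grouped per target diagonal, ungapped X-drop extension, then a full
affine-gap Smith–Waterman with traceback inside a window around each
extended cluster. Scores: match +2 / mismatch −3, gap open −5, gap extend
−2 (a gap of length L costs 5 + 2L, the BLAST convention); proteins use
BLOSUM62 with −11/−1, and stop codons are made impassable so reading
frames effectively break at stops.

Design points that matter for correctness:

* **One window per cluster, never merged.** Nearby but distinct placements
  — tandem exon paralogs in the same reading frame, duplicated flanks —
  must each surface their own best local alignment. Hits whose target
  spans substantially overlap a better hit are deduplicated afterwards.
* **Cluster pruning.** Clusters scoring below half of the best ungapped
  cluster are not extended by DP. Hits they could produce are partial-
  coverage hits that the 90%-coverage filter discards, while genuinely
  ambiguous near-equal placements stay above the cut; this keeps the
  full analysis of a ~2.85 Mb run in tens of seconds.
* **E-values** follow Karlin–Altschul, `E = K·m·n·exp(−λS)`, with constants
  fixed per scoring scheme (K = 0.41, λ = 0.625 for the DNA scores;
  K = 0.041, λ = 0.267 for gapped BLOSUM62). These differ numerically from
  blastn's estimates by up to about an order of magnitude, which is
  immaterial against a 1e-20 cutoff for 500 bp flanks.
* **Determinism.** Equal-score hits are ordered by ascending e-value, then
  lowest target coordinate, then `+` before `-`.

On sequences up to 2 kb the best raw score is tested for equality against
an independent full Smith–Waterman implementation
(`Biostrings::pairwiseAlignment`) with identical scoring, over hundreds of
random pairs with planted, mutated homology.

## Base-composition metrics

GC windows are consecutive, non-overlapping, `gc_window = 1000` bp; the
final partial window is kept when it is at least half a window (small
synthetic microchromosomes would otherwise lose their tails). GC is
`(G+C)/(A+C+G+T)` in the window; windows more than half N are excluded and
counted separately; "above threshold" is strict (`>`), with 58.8% as the
default and 70% as the stricter alternative.

The G4 scan matches the canonical quadruplex motif
`G{3,}(N{1,7}G{3,}){3,}` (loop cap 7, the classic Quadparser convention,
configurable 1–12; loops admit A/C/G/T only) on the forward strand and the
analogous C-pattern reported as the minus strand, greedily left to right
with overlapping candidates resolved by earliest start then longest.
Machine-learned G4 propensity scores require a trained model and are not
reproducible from a motif definition, so outputs are labelled
`g4_canonical` to prevent silent conflation: counts from this scan are not
comparable to score-filtered totals from such tools.

## Multicopy-exon census and gene presence

The census runs every protein query of the set through the translated
search, keeps hits whose *insertion-free* length (alignment columns where
the query has a residue, × 3) is **strictly greater** than `min_hit_len`
(240 bp for a 270 bp exon-2-like query — the printed thresholds, ~90% of
the query alignment length, are the operative rule and the boundary is
excluded), merges strictly-overlapping hit intervals across queries
(abutting intervals stay separate), and counts merged intervals. A
back-validation hook (a caller-supplied predicate per merged interval,
e.g. a reciprocal-best check) is applied before counting when provided;
the full screen used with public databases is not reproducible offline, so
the hook preserves the pipeline position with default off. Exon-2-like
and exon-3-like query sets are censused separately.

Gene presence chains translated hits greedily (colinear on one scaffold
and strand, introns up to 20 kb — a stand-in for splice-aware alignment,
which is out of scope). A gene is `Complete` when ≥ 95% of the protein
aligns with similarity > 90%, `Partial` when it aligns short of either
bar, `Absent` with no alignment. Similarity is the fraction of
positive-scoring aligned columns — the usual "similarity" of protein
aligners, stated here because published methods rarely define it.

## Sex linkage

In a female-heterogametic ZW system, Z-linked sequence shows half female
coverage and full male coverage; W-linked sequence shows half female
coverage and essentially no male coverage; pseudoautosomal (PAR) sequence
is diploid in both sexes. The classifier consumes a per-contig depth table
(read mapping itself is upstream), computes per-sex ratios against an
autosomal baseline — the median over contigs that are *not* Z-homologous
and at least 5 kb long, keeping sex chromosomes out of the baseline — and
calls: W when the female ratio is within 0.5 ± t and the male ratio below
0.1; Z when the Z-homology fraction strictly exceeds 0.60 or the coverage
pattern is half-female/full-male; PAR-or-autosome when both ratios are
within 1 ± t; otherwise Unclassified. W is tested before Z so
female-specific contigs are never absorbed by the Z window. The 60%
homology rule is established practice; the numeric windows (t = 0.25,
male ceiling 0.1) are this package's declared defaults — no published
numeric windows exist — and are surfaced in every report header. A
scaffold mixing Z/W-called contigs with autosomal-called contigs is
flagged as chimeric (Unclassified members are ignored).

## The simulator

The generator emulates the structure that makes avian genomes hard to
assemble, at desk scale (defaults, all configurable): four 500 kb
macrochromosomes at GC 42%, four 100 kb GC-rich microchromosomes at
GC 60%, a 300 kb Z, and a 150 kb W at ~70% repeat density dominated by
satellites — about 2.85 Mb in total. Planted features:

* LTR retrotransposons, 8 kb with two 800 bp terminal repeats ≥ 99%
  identical (the self-similar ends that break assemblers), plus sized
  fragments (`full_length = FALSE`) so the simplified LAI is meaningful;
* 5′-truncated LINE copies of one consensus (geometric truncation from
  the 3′ end, p = 0.4), diverged 3–10% — old, heterogeneous copies;
* satellite arrays of a ~170 bp monomer, per-copy divergence uniform in
  [0, 2]% — low enough that collapse, not divergence, drives assembly
  difficulty; each array has its own monomer;
* simple repeats (2–6 bp motifs) and DNA transposons;
* a tandem cluster of 12 exon paralogs (270 nt, 2–8% protein divergence,
  alternating strands) on a microchromosome;
* five single-copy genes; one duplicated 500 bp segment planted on two
  macrochromosomes to create an ambiguous-flank liftover case; and
  adjacent-feature compounds that become `Complex` gap causes.
* Z and W share a verbatim 10 kb PAR prefix, kept free of planted repeats.

Per-class repeat targets are hit within about ±2 percentage points by
sizing the final element of each class to the remaining deficit; features
are interleaved with random background gaps of at least 250 bp that sum
exactly to the free space.

The draft is derived by sampling breaks over planted features with
class-biased odds. At each break the feature is excised — satellite arrays
collapse to two monomers, LINE/DNA elements may lose their interior, other
features are deleted whole or keep a short stub at the gap edge — and the
flanking contigs are rejoined with 100 Ns in truth order. Excisions keep
at least 1.3 kb apart so flanks stay clean, and the excision always covers
the feature's self-similar parts (e.g. both terminal repeats of an LTR),
which is what keeps flanks uniquely placeable at zero divergence: the
identity-liftover property (every non-terminal gap scorable, every
projection exact, every cause recovered) is a designed invariant, not an
accident. One W contig is moved into the first macrochromosome scaffold as
the planted chimeric scaffold; its join gap, like the duplication gap, is
recorded in the ground truth as *expected* not-scorable. Background breaks
avoid the PAR, whose sequence exists verbatim on both sex chromosomes and
can never lift over uniquely. Optional per-base substitutions (draft only)
model draft-versus-reference divergence.

Coverage is simulated per contig as `Poisson(length × depth × ploidy) /
length` with ploidy 1 for autosomes/PAR in both sexes, 0.5/1.0 (F/M) for
Z and 0.5/0 for W, at a 30× baseline.

Every stage draws from its own RNG stream derived from `(seed, stage
name)`, so adding a stage never perturbs earlier stages' draws and all
outputs are byte-reproducible from the configuration.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: read-level errors and platform error profiles,
haplotypic variation, segmental duplications beyond the single planted
pair, nested/fragmented repeat structure from deep TE archaeology,
translocations (scaffold order is preserved so `different_scaffolds`
arises only from the planted chimera), GC-dependent coverage bias, and
genome sizes within two orders of magnitude of real birds. The problem
sizes (2.85 Mb genome, ~250 gaps, 200-pair aligner cross-checks) were
chosen so the full verification cycle runs in a couple of minutes on one
CPU while still exercising every code path at realistic densities.

## Numerical and degenerate-input choices

* The missing-assembly fraction `100 × (1 − draft/reference)` over N-free
  sizes may be negative (draft larger than reference); it is reported
  as-is with a warning, never clamped.
* The simplified LAI is undefined (NA with a warning, never 0) without LTR
  intervals. The `full_length` flag comes from the annotation — the
  simulator emits it; intact-LTR structure detection (as in the full LAI
  algorithm) is out of scope, so values are comparable between assemblies
  annotated the same way, not to published LAI scores.
* Repeat recovery ratios above 1 (haplotype duplication) are reported and
  flagged, not truncated.
* All-N scaffolds contribute zero contigs, with a warning.
* IUPAC ambiguity codes other than N fold to N on input with a logged
  count; established pipelines tolerate them silently and erroring out
  would reject otherwise usable assemblies.
* An `--ambiguity`-style relaxation (accepting one best hit with others
  far worse) was considered for the liftover and deliberately not made the
  default: "only one alignment of both flanks" is read strictly as exactly
  one passing hit per flank.

## Limitations

The aligner aims at correctness on flank-scale queries, not heuristic
performance parity with blastn on gigabase databases. Gene presence uses
greedy colinear chaining, not splice modelling. The sex-linkage windows
are threshold-sensitive and should be re-examined for taxa with unusual
coverage structure. The pipeline consumes RepeatMasker `.out`, BED,
FASTA, outfmt-6 tables and depth TSVs; it does not run assemblers,
scaffolders, repeat annotators or read mappers, and read-level formats
(FASTQ/SAM/VCF) are out of scope.
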