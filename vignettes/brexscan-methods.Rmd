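---
title: "Mapping BREX and BREX-related defense systems: methods and design"
author: "brexscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping BREX and BREX-related defense systems: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brexscan)
```

# The problem

BREX (BacteRiophage EXclusion) systems are multi-gene prokaryotic
defense systems that methylate self-DNA and restrict phage DNA without
classical restriction digestion. They come in several subtypes built
around a shared tripartite core (a large ORC/Cdc6-clade AAA+ ATPase,
an N6-adenine methyltransferase, and the alkaline-phosphatase-family
PglZ, recently shown to act as a nicking nuclease). Closely related
DUF499-ATPase-anchored systems (here "BR", BREX-related) form an
RM-like tripartite family in three subtypes, and a rare seven-component
hybrid ("BRC", BREX-related capture) combines BREX homologs with a
HerA/FtsK translocase and GNAT/TGT modification enzymes.

Identifying these systems in annotated genomes is a gene-neighborhood
problem: candidate loci are reconstructed around anchor proteins,
member proteins are assigned domain architectures and canonical
component names, the component composition is classified into a
subtype by explicit rules, and occurrence is summarized per
species-level taxonomy identifier (TaxID) rather than per assembly.
brexscan implements that pipeline as a tested, reusable package,
together with a synthetic-cohort generator that provides exact ground
truth for every stage.

# Locus reconstruction

Three contextual filters define a neighborhood:

1. **Genomic proximity.** Adjacent genes separated by at most
   `max_gap_nt` nucleotides (default 100 nt) are considered operonic.
   The customary proximity rule of "approximately 100 nt" is
   unquantified, so the threshold is an exact, configurable
   parameter with 100 as its default. Coordinates are stored 0-based
   half-open internally, so the gap is simply `start2 - end1`;
   overlapping genes get a negative gap and always co-block, because
   overlap is stronger evidence of operonic linkage than any positive
   gap.
2. **Orientation conservation.** Blocks are maximal same-strand runs.
   Real neighborhoods, however, include divergently transcribed
   members, so `extractLocus()` admits a neighboring block of either
   orientation when its nearest edge lies within `max_gap_nt` of the
   growing locus span. A strict same-strand locus would contradict the
   drawn neighborhoods of the systems themselves.
3. **Cross-phyla occurrence.** Loci are grouped by archetype (the
   sorted multiset of component names); archetypes seen in fewer than
   `min_phyla` (default 2) distinct phyla are *flagged*, not deleted —
   the criterion is a curation confidence filter, and downstream users
   may want the near-misses.

The retrieval window is `window_genes` (default 10) genes on each side
of the anchor. No standard retrieval window exists for this kind of
analysis; 10 covers the largest described system (BRC, seven
components) with margin.
Replicons are treated as linear; loci never span replicons.

# Annotation

In **synthetic mode**, each protein is scanned for the registry's
signature blocks (120-aa unique amino-acid strings, one per domain,
shipped as a versioned JSON resource). Matching is seed-and-verify:
exact 8-mer seeds propose placements, which are verified by counting
mismatches across the block at a configurable tolerance (default 10%
of block length). Overlapping hits are resolved best-score-first. This
matcher is deliberately *not* claimed to work on real proteins; in
**real mode** domain hits are imported from an externally computed
table (`readDomainTable()`), whose vocabulary can be remapped by the
user — real-data discrimination of, for example, the three
methyltransferase variants depends on the external annotator.

Component calling walks an ordered rule table (most-specific rules
first): a rule's mandatory domains must appear in order as a
subsequence of the architecture, tolerating extra uncalled segments,
because lineage-specific insertions are common. Optional domains set
fusion flags (e.g. `BrxL:HKD`, `DUF499:HEPN_fused`, `PglZ:minimal`).
Architectures matching no rule fully fall back to a *partial* call
when at least half of some rule's mandatory domains are present; the
best-covered rule wins that pass so degraded architectures are not
captured by superset rules. BrxA and DUF4007 share one architecture
(two to three HTH/wHTH modules and nothing else) and are emitted as a
single component name with synonym handling in the classifier.

# Classification

`classifyLocus()` applies a fixed decision list, first match wins:

1. HerA/FtsK + PglZ + a BrxC-like ATPase → **BRC**;
2. DUF499 ATPase → **BR**, split Type-3 (PglZ in locus), Type-2
   (standalone DUF3780 or HKD-fused helicase), else Type-1;
3. PAPS-reductase (BrxP) with no methyltransferase → **BREX Type-4**;
4. PglW, or the BrxD + BrxHI dyad → **Type-2**;
5. BrxXI, or BrxF + BrxHII without a Type-1 core → **Type-3**;
6. BrxC + BrxX + PglZ → the **Type-1 family**, inside which BrxE marks
   Type-6, an extra BrxHII-class helicase Type-5, else Type-1;
7. otherwise unassigned.

BRC and BR are tested before BREX because their anchors are uniquely
diagnostic, whereas PglZ and BrxC are shared across systems. Types 1,
5 and 6 always carry the family group `Type-1-family`, reflecting the
phylogenetic collapse of those subtypes into one clade. A locus with
both BrxE and an extra helicase resolves Type-6-first and is flagged
for review. Completeness is `complete` when all mandatory components
of the matched subtype are present, `partial` with at least three
components including a system anchor (three spans the minimal
tripartite core of every described system — incomplete neighborhoods
are conventionally discarded, but no standard count exists), else
`discarded`.

Effector roles are a fixed ontology, not a computation: PglZ is the
primary effector of every BREX subtype and of Type-3 BR; the
helicase-fused REase and HKD-endoDNase are the primaries of Type-1 and
Type-2 BR. DNase-class domains are auxiliary; RNase-class and abortive
modules, and any OLD-ABC-paired nuclease dyad, are backup. Provenance
records whether an effector is fused into a core component, standalone
inside the locus, or flanking — flanking genes are admitted by
chaining the intergenic gap rule outward from the locus, so an
effector pair sitting just beyond the locus edge is taken whole.

# Clustering

Neighborhood proteins can be pooled before annotation with either of
two modes that mirror the tools whose semantics they reproduce:
single-linkage over all pairs (coverage L on both sequences, default
0.5 from the customary 0.2–0.5 range, and score threshold S, default
50 from the 20–50 range), and greedy-incremental deduplication
(identity c, default 0.9 from 0.4–0.9; word length n, default 5 from
2–5). The native scorer is an end-gap-free global alignment under
BLOSUM62 with gap open 11 / extend 1; identity uses alignment columns
excluding terminal gaps as denominator — stated explicitly because the
tools being mirrored only approximate this and no standard
definition exists. Following the original tool's documented dual semantics, an
S above 3 is interpreted as percent score density and S of at most 3
as bits per column; the customary 20–50 range for S is only attainable under
the percent reading (a BLOSUM62 column cannot reach 20 bits), which is
why the default S = 50 acts on the percent scale. The greedy mode's
k-mer prefilter only ever skips pairs provably below the identity
threshold (a pair at identity c over shorter length m shares at least
m − k + 1 − k·⌊(1 − c)m⌋ k-mers), so clustering with and without the
prefilter is identical. No fixed parameter values exist to recover —
in practice these thresholds are tuned per protein family — so the
defaults here are
deliberate mid-range choices.

# Phyletic profiling

To avoid redundancy from multiple assemblies of one organism, all
counts are over unique TaxIDs: a TaxID counts once per subtype no
matter how many assemblies or loci carry it, and may count for several
subtypes. Matrices are grouped strictly at a single chosen rank
(default phylum, with an "unclassified" bucket); heatmap groupings
seen in the literature mix ranks, so custom rollups are left to a user-supplied
grouping of the long-format table. Retention of a component within a
subtype is reported against the taxa carrying the subtype's anchor
component (BrxC for the Type-1 family, the DUF499 ATPase for BR,
HerA/FtsK for BRC).

# Entropy profiles

Per-column Shannon entropy of protein alignments is computed as
H = −Σ pᵢ log₂ pᵢ under two alphabets: the 20-letter identity alphabet
(range 0 to log₂20 = 4.32 bits) and a reduced 8-class chemical
alphabet. The conventional negative sum is used throughout — the 0–4.32 range
is attainable only with it — and log base 2 is fixed by that stated
maximum. No single 8-class partition is canonical; the shipped default is the Murphy-style partition
{LVIMC}{AG}{ST}{P}{FWY}{EDNQ}{KR}{H}, overridable via a two-column map
file. Gaps are excluded from the probabilities rather than treated as
a 21st symbol (the stated maximum implies a 20-symbol support);
nonstandard residues are excluded and tallied. Whether the original
analysis weighted sequences or filtered gappy columns is unstated;
both are off by default (columns above a 50% gap fraction are only
flagged). Output tables sign the 8-class track negative to mirror the
above/below-zero dual-track bar layout.

# The synthetic cohort generator

The generator is first-class, tested code; it emulates exactly the
features the pipeline's logic depends on:

* **per-subtype operon grammars** for all ten subtypes, with ordered
  component slots, presence probabilities and fusion-variant mixes.
  Diagnostic core slots have probability 1 so a planted locus is
  classifiable from composition alone; variable slots use the
  retention and fusion fractions reported for the mined genome set
  (HKD replaces LonP in ~35% of BrxL; 56% of Type-1 BR ATPases carry
  the HEPN fusion; 64% of Type-4 PglZ carry the iSTAND fusion; 83% of
  Type-2 BR helicases the HKD fusion; cysteine desulfurase in 56% of
  Type-4 loci; and so on);
* **signature-block proteins**: each planted protein is a
  concatenation of its architecture's 120-aa signature blocks joined
  by low-complexity linkers, so noiseless annotation recovers the
  architecture exactly and acceptance tests can be sharp. This
  replaces sampling from real sequence profiles, whose construction is
  outside this package's scope;
* **decoys and isolation**: decoy genes share no 12-mer with any
  signature (checked by construction), and planted loci are separated
  from decoys by five times the gap threshold, keeping truth loci
  unambiguous under any configured threshold up to that margin;
* **taxonomy structure**: one taxon per planted locus, lineages
  assigned so each subtype spans at least two phyla (single-phylum
  requests are recorded as truth warnings), and optionally several
  assemblies per taxon — assemblies of one taxon share the taxon's
  RNG substream, so they replicate the same organism's locus and
  exercise TaxID deduplication;
* **alignments with prescribed column distributions**, carrying both
  the expected entropy of the generating distribution and the plug-in
  entropy of the realized counts, evaluated by direct formula
  independently of the entropy module.

The noise model is i.i.d. residue substitution at a configurable rate
plus optional component dropout — the simplest controls for
robustness experiments. What passing tests show is therefore
recoverability of *composition and arrangement*, not tolerance to
real-world annotation noise: the generator does not simulate sequence
evolution, codon structure, pseudogenes, contig breaks mid-operon, or
realistic domain sequence variation, and results on synthetic cohorts
do not certify detection performance on real genomes (real-mode
annotation depends on the quality of imported domain tables).

Reproducibility: each genome derives its seed from the cohort seed and
taxon index, so cohorts are byte-identical for a fixed seed and
independent of generation order.

# Numerical and engineering choices

* Internal coordinates are 0-based half-open everywhere; conversion to
  and from the 1-based inclusive convention happens only at the
  GenBank/TSV boundary. Compound (join) locations are collapsed to
  their outer span with a warning — defense operons are single-exon,
  and gap logic needs one interval per gene.
* The signature matcher's seed length (8) and block length (120) make
  the per-block miss probability at the default 10% mismatch
  tolerance negligible for substitution noise up to ~5%; ties in
  overlap resolution go to the longer hit, then the smaller start.
* Tie-breaks elsewhere are deterministic by construction:
  representatives are the longest member with lexicographic id
  tie-break; rule evaluation order within a specificity tier does not
  affect calls (tested); tables are written with sorted stable keys.
* Degenerate inputs: empty genomes yield empty block lists; empty
  cohorts yield zeroed reports; an all-gap alignment column yields NA
  entropy; zero anchored taxa yield NA retention.
* Typical problem sizes: the shipped acceptance experiments use
  cohorts of 200 planted loci (20 per subtype, ~3,500 proteins) for
  recovery, 1,000 random layouts for the neighborhood oracle, 100–200
  seeded instances (n ≤ 40) for the clustering oracles, and 10,000
  random columns for the entropy properties — sizes chosen so the
  whole suite runs comfortably on a laptop while keeping every
  estimate's sampling error far from the acceptance margins.

# Known limitations

* Real-mode component discrimination is bounded by the imported
  annotation vocabulary (e.g. distinguishing nested-TRD
  methyltransferase variants, or inactive vs active STAND NTPases,
  which is a registry property here, not a sequence test).
* The classifier cannot discover novel subtypes; unassigned loci are
  reported with reasons, not clustered.
* Clustering does not reproduce the mirrored tools bit-for-bit (no
  e-value statistics, different alignment engine); the modes reproduce
  their documented semantics, which the oracle tests pin down.
* Circular replicons are treated as linear; a locus spanning the
  origin would be split.
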