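---
title: "Methods: annotation, viRNA profiling and statistics in virnatools"
author: "virnatools authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation, viRNA profiling and statistics in virnatools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virnatools)
```

# Scope

virnatools implements the computational workflow used to characterize a
natural bipartite RNA virus of *Caenorhabditis* and the host's small-RNA
response: genome-organization annotation, a small-RNA read-processing
pipeline, exact unambiguous mapping, per-position viRNA profiling with 22G
signature summaries, distance-based phylogenetics, and symptom-scoring
statistics. A seeded synthetic-data module generates genomes, a host
stand-in and sequencing libraries with full truth records, so every stage
is validated end to end without external data.

# Genome annotation

## ORF model

An ORF is an ATG-initiated, stop-terminated codon run; alternative
(non-ATG) starts are not considered. For each in-frame stop the 5′-most
compatible ATG is reported, i.e. one maximal ORF per stop codon. This is
the standard prediction convention, and the published product sizes of the
nematode viruses (a 982-aa polymerase, a 332-aa second ORF on RNA2) are
well-defined under it: the initiator methionine is counted, the stop codon
is not. Optionally, ATG-initiated runs that reach the segment end without
a stop are reported as 3′-partial calls.

ORF calls are stored as `GRanges` and therefore use Bioconductor's
1-based, closed coordinate convention; the range of a complete call
includes its stop codon. (The exact mapper's hit positions, in contrast,
are reported as 0-based plus-strand offsets, a deliberate echo of
short-read mapper conventions; each table documents its convention.)
Minus-strand ORFs are reported in plus-strand coordinates with strand `-`;
their `frame` is the reading-frame offset on the reverse complement.

## Organization classification

`classifyOrganization()` annotates a 1–2 segment genome against the
bipartite nodavirus convention:

* role assignment: the segment carrying the longest plus-strand ORF
  becomes RNA1 (tie broken by segment length); user-assigned roles are
  respected;
* the RdRP candidate is RNA1's longest plus-strand ORF;
* a B2-like call is the longest plus-strand ORF in frame
  `(RdRP frame + 1) mod 3` intersecting the final `ctermWindow`
  nucleotides of the RdRP ORF. The overlap region is described
  qualitatively in the nodavirus literature ("overlaps the C-terminus")
  rather than by a number, so the window is a parameter; the default of
  300 nt generously covers known B2 overlaps while staying within the
  polymerase ORF;
* the capsid candidate is the longest plus-strand ORF starting in the 5′
  half of RNA2; the δ candidate is the longest ORF starting 3′ of the
  capsid start;
* `rna2Oversize` is true when RNA2 exceeds the conventional 1.4 kb by at
  least `oversizeMargin` (default 500 nt — the nematode viruses exceed it
  by ~1 kb, while ordinary nodavirus length variation stays within a few
  hundred nt).

The default ORF floor of `minAa = 50` suppresses spurious micro-ORFs
(random sequence is rich in sub-50-codon open runs) while retaining every
real product of interest, the smallest being B2 proteins at ~60–130 aa.

Input sequences are normalized (U→T, uppercase); ambiguity codes are
rejected rather than interpreted, because the downstream mapper requires
exact matching over {A,C,G,T}.

# Small-RNA pipeline

Reads are processed in the order: parse → demultiplex → trim → collapse →
size-select.

* **Demultiplexing** assigns a read to a library by exact match of its
  first four bases against the configured barcodes; reads containing any
  N, anywhere, are excluded, as are reads with an unmatched prefix. The
  N rule is applied to the whole read, the strictest reading of "missing
  bases".
* **Trimming** removes the first four nucleotides, then the maximal run of
  trailing A's. The A rule is unconditional: genuine terminal A's of an
  insert are removed too. This is a known bias of the scheme and is why
  the synthetic generator never plants inserts ending in A (see below).
* **Collapsing** merges identical (barcode, sequence) pairs, summing read
  counts, per barcode (libraries are distinct biological samples; a
  `pool` flag merges them). Output order is deterministic (barcode, then
  sequence), so identical input yields byte-identical tables.
* **Size selection** keeps inserts of 18–30 nt inclusive, applied *after*
  trimming, in pipeline order.

Read conservation holds at every stage: parsed = assigned + excluded(N) +
excluded(barcode), and assigned = in-range + out-of-range.

# Exact unambiguous mapping

The mapper replaces a production short-read aligner at desk scale with a
transparent, exactly verifiable rule. The index stores every plus-strand
k-mer start (k = 12 by default, safely below the 18-nt minimum insert
length) in sorted order; a query is seeded by its first k-mer via binary
search and every candidate is verified by full string comparison, so
reported matches are exact by construction. Minus-strand occurrences are
found by looking up the reverse complement of the query and reported as
`-` strand hits at their plus-strand position.

Classification implements the "perfect and unambiguous" rule: an insert is
`virus_sense`, `virus_antisense` or `host` only when it has exactly one
hit — one (record, position, strand) — in the entire host+virus union.
Two or more hits of any kind make it `ambiguous`: a sequence hitting both
a viral segment and the host, both viral segments, two host loci, or its
own reverse complement (palindromes, whose orientation is undefinable) is
excluded from the viral profiles. Any host co-hit therefore removes a
sequence from the viral counts. This is the strictest reproducible reading
of "unambiguously mapped"; a production aligner may resolve multi-hits
differently, which is the main caveat when comparing absolute viral counts
against published figures.

# viRNA profiles and the 22G signature

Profiles count **unique sequences**, not reads, matching the display unit
of published viral small-RNA coverage panels; a read-weighted mode is a
flag away. Each virus-assigned unique sequence adds 1 to every position it
covers in the vector of its orientation (coverage mode, the default); a
5′-end mode counts only the 5′-most position of each small RNA, which for
an antisense read is the right-hand edge of its hit range. Whether
published coverage panels plot full coverage or 5′ ends is generally not
stated; both are provided.

The length × first-nucleotide matrix counts each unique sequence once at
(length, first base), with the first base reported in the RNA alphabet
(U for T) as in figure convention. The signature summary reports the
viral fraction of unambiguously mapped unique sequences, the antisense
modal length, the antisense length-22 and 5′ G fractions, and a `flag22G`
that is true exactly when the antisense modal length is 22 *and* G is the
modal antisense first base — the hallmark of the worm's 22G secondary
siRNA class. With zero antisense sequences the modal fields are NA and the
flag is false; no error is raised.

# Phylogenetics

The MSA is an input (alignment construction is out of scope). Distances
default to the uncorrected p-distance with pairwise gap deletion —
mismatches over columns where neither row is gapped — the simplest
defensible choice when no model is specified; a Poisson correction is
available. A pair with no shared gap-free column is an error naming the
pair.

Neighbor joining follows Saitou–Nei exactly: Q-matrix minimization with
deterministic tie-breaking (lowest index pair in current matrix order),
standard branch-length formulas, and agglomeration down to the final
trifurcation. Negative branch lengths, which NJ can produce on non-additive
input, are clamped to zero with the deficit moved to the sibling branch,
preserving the joined pair's path length. On additive matrices NJ is
consistent, and the test suite verifies exact recovery of seeded random
trees (4–12 leaves) through path-length identity.

Bootstrap supports resample alignment columns with replacement, rebuild
the NJ tree per replicate, and score each internal branch of the
full-data tree by the fraction of replicates containing the same leaf
bipartition (splits are canonicalized by the side not containing the
alphabetically first taxon). Supports live in [0, 1] as internal node
labels; the full-data topology is independent of the seed. 1,000
replicates is the conventional choice; tests use fewer only because their
purpose is correctness of the counting, not precision of the support.

# Symptom statistics

`symptomProportions()` scores the four intestinal-cell symptoms
(gut-granule loss, nuclear degeneration, cytoplasm liquefaction, cell
fusion) as cumulative proportions: the fraction of animals with at least
k symptoms, k = 1..4, non-increasing in k by construction, plus the 2×2
table (≥1 symptom vs none, by condition).

`fisherExactTwoSided()` is a from-scratch exact conditional test. The
two-sided rule sums the hypergeometric probabilities of all tables with
the observed margins whose probability does not exceed the observed
table's — the convention of mainstream implementations; conventions
differ, so it is stated explicitly. Probabilities use exact
binomial-coefficient arithmetic for table totals up to 170 and log-gamma
accumulation above; a relative tolerance of 1e-7 absorbs floating-point
ties in the "≤ observed" comparison.

A calibration worth knowing: because the conditional distribution is
discrete, Fisher's test is conservative. At 20 animals per arm the null
rejection rate at nominal α = 0.05, computed by the acceptance
simulation, is about 0.02 — no null prevalence brings it near 0.05. Small
cohorts buy exactness at the price of effective size well below nominal.

# The synthetic-data generator

The generator's defaults are the study conditions the analysis assumes:

* genome dimensions 3,628 nt (RNA1) and 2,653 nt (RNA2) with planted ORFs
  of 982 aa (polymerase), 400 aa (capsid surrogate — a typical nodavirus
  capsid size) and 332 aa (δ); no B2 by default, matching the nematode
  viruses;
* a 50-kb uniform-random host stand-in;
* an infected library of 20,000 unique inserts with 300 antisense +
  100 sense viral inserts (viral fraction 0.02, mirroring the "almost 2%"
  scale of a real infected library) and a control library with zero viral
  inserts;
* antisense lengths concentrated at 22 nt (probability 0.8, spill 0.1
  each to 21/23) with 5′ G probability 0.6 — a clear but not degenerate
  bias, chosen once as a realistic strength for a 22G population;
* sense inserts uniform over 18–30 nt with uniform first base and no
  orientation bias, emulating degradation-like fragments;
* per-read 3′ A-tail artifacts with probability 0.3 (1–4 nt) and read
  counts of 1 + geometric(0.5) per unique insert, exercising trimming and
  collapsing.

Three constructions make truth labels exact rather than approximate:

* **k-mer safety**: the host (jointly with the viral segments) is
  rejection-sampled until no 18-mer occurs twice on the plus strands or at
  all on the minus strands of the union, so every planted window of
  ≥ 18 nt maps exactly once;
* **5′ G by placement**: an antisense insert's first base is forced by
  choosing the window position (the source base complementing to G), never
  by mutating a base, so reads remain exact genome substrings. The
  constraint (G or explicitly non-G) is drawn once per insert and only the
  position is resampled, making the realized 5′ G fraction an unbiased
  Bernoulli realization of the configured probability;
* **no terminal A**: planted inserts never end in A, so the unconditional
  3′ A-trim reconstructs every insert exactly and the planted length
  distribution survives the pipeline.

Genome planting uses rejection too: background regions are resampled until
the package's own scanner recovers exactly the planted truth (the planted
ORFs are the longest on their segments; B2-like and δ calls match the
planted flags and coordinates). All draws derive from one seed; every
output is a pure function of the configuration.

What the generator does *not* emulate: sequencing errors and quality
variation, adapter read-through, PCR duplication structure, the base
composition and repeat structure of a real genome, and hot/cold-spot
structure of real viRNA coverage. Passing tests therefore demonstrate the
correctness of the pipeline's logic under clean, unambiguous data — not
robustness to real-data artifacts, nor that a real aligner's ambiguity
conventions would yield identical absolute counts.

# Problem sizes and determinism

The validation suite runs entirely from generated data at desk scale,
chosen so the full suite completes in a few minutes on a single core:
oracle comparisons use 1,000 random ≤ 1-kb sequences for the ORF scanner
and 500 queries against 10 kb of reference for the mapper; NJ recovery
uses 100 random additive trees; the exact test is checked against full
enumeration on 200 random tables; libraries of 2 × 10^4 unique inserts
(≈ 4 × 10^4 reads) validate the pipeline end to end. All stochastic steps
are seeded; reruns are bit-identical.

# Known limitations

* The mapper's strict ambiguity rule can only under-count relative to
  aligners that keep multi-segment hits; absolute viral counts are
  convention-dependent.
* Published branch lengths from other software embed their own distance
  corrections; only topology-level statements (e.g. sister relationships)
  are comparable across implementations.
* The unconditional 3′ A-trim removes genuine terminal A's; profiles of
  A-rich 3′ ends are biased by design, as in the original scheme.
* GenBank import is sequence-only; feature annotations are ignored.
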