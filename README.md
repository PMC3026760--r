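# virnatools

Analysis toolkit for characterizing natural RNA virus infections of
*Caenorhabditis* nematodes from sequence data. The package covers the
computational side of identifying a bipartite nodavirus-like virus and the
host's antiviral small-RNA response:

* **Genome annotation** — ORF scanning of viral segments and classification
  of the genome organization against the bipartite nodavirus convention:
  RNA1 (~3.1 kb) carrying the RNA-dependent RNA polymerase (RdRP) ORF,
  optionally with a B2-like ORF in the +1 frame overlapping the RdRP
  C-terminus, and RNA2 (~1.4 kb) carrying a single 5′ capsid ORF. The
  annotator flags the two organization novelties of the nematode viruses:
  a second 3′ ORF on RNA2 ("ORF δ") and an oversized RNA2.
* **Small-RNA pipeline** — FASTQ parsing, exact 4-nt barcode demultiplexing
  with N-exclusion, trimming (barcode + unconditional 3′ A-tail removal),
  collapsing to unique inserts with read counts, 18–30 nt size selection.
* **Exact unambiguous mapper** — a seed-and-verify exact matcher over a
  host + virus reference union. A unique insert is assigned to the virus
  (sense/antisense) or host only when it has *exactly one* perfect hit —
  one (record, position, strand) — in the whole union.
* **viRNA profiling** — per-position sense/antisense unique-sequence
  coverage profiles, 13×4 length × 5′-nucleotide signature matrices, and a
  summary of the 22G secondary-siRNA hallmark (antisense reads concentrated
  at 22 nt with a 5′ G bias).
* **Phylogenetics** — uncorrected p-distances with pairwise gap deletion
  from a protein MSA, a from-scratch Saitou–Nei neighbor-joining
  implementation with deterministic tie-breaking, column-resampling
  bootstrap supports, newick I/O.
* **Infection statistics** — cumulative symptom-proportion scoring of the
  four intestinal-cell symptoms and a from-scratch two-sided Fisher's exact
  test (sum of hypergeometric probabilities ≤ the observed table's).
* **Synthetic data** — a fully seeded generator of genomes, a host
  stand-in, small-RNA libraries and symptom tables, with complete truth
  records, so that every stage of the analysis is testable end to end
  without any external data.

## Core quantities

For a library of unique inserts mapped to the reference union, the
signature summary reports

* the viral fraction `(n_sense + n_antisense) / n_unambiguous`,
* the antisense length mode and the fraction of antisense inserts of
  length 22,
* the antisense and sense 5′ G fractions, and
* the 22G flag: antisense modal length 22 **and** modal first base G.

Fisher's two-sided exact p-value for a 2×2 table with fixed margins is
`p = Σ P(T)` over all tables `T` with those margins such that
`P(T) ≤ P(observed)`, with `P` the hypergeometric probability.

Neighbor joining repeatedly joins the pair `(i, j)` minimizing
`Q(i,j) = (m − 2) d(i,j) − Σ_k d(i,k) − Σ_k d(j,k)` with the standard
branch-length formulas; bootstrap support of an internal branch is the
fraction of column-resampled replicate trees containing the same leaf
bipartition.

## Worked example

```r
library(virnatools)

cfg <- simConfig(seed = 1)                     # study-condition defaults
gen <- simulateViralGenome(cfg)                # bipartite genome stand-in
classifyOrganization(gen$segments)
#> Genome organization report
#>   RNA1 -> RNA1 (3628 nt)
#>   RNA2 -> RNA2 (2653 nt)
#>   RdRP candidate: RNA1:21-2969 (982 aa)
#>   B2-like +1 overlap: none
#>   capsid candidate: RNA2:21-1223 (400 aa)
#>   3' ORF (delta) candidate: RNA2:1254-2252 (332 aa)
#>   RNA2 oversize vs 1.4 kb convention: TRUE

host <- simulateHostGenome(cfg, gen$segments)
lib  <- simulateSmallRnaLibrary(cfg, gen, host, "infected")
fq   <- tempfile(fileext = ".fq"); writeFastq(lib$reads, fq)

pp   <- processSmallRnaFastq(fq, cfg$barcodes) # demux, trim, collapse, 18-30
idx  <- buildReferenceIndex(referenceSet(gen$segments, host))
mapped <- classifySequences(pp$collapsed, idx)
categoryTally(mapped)
#>     virus_sense virus_antisense            host       ambiguous   unmapped
#>             100             300           19600               0          0

signatureSummary(mapped)
#> Viral small-RNA signature summary
#>   unique unambiguous sequences: 20000 (viral fraction 0.02)
#>   virus sense / antisense: 100 / 300
#>   antisense modal length: 22; len-22 fraction 0.770
#>   5'G fraction antisense / sense: 0.673 / 0.210
#>   22G signature: present
```

The annotation report reads: a 3,628-nt RNA1 whose longest ORF encodes a
982-aa polymerase with no B2-like +1-frame overlap, and a 2,653-nt RNA2 —
about 1 kb larger than a conventional nodavirus RNA2 — with a 5′ capsid ORF
followed by a second, 332-aa 3′ ORF. The mapped library shows the antiviral
response signature: 2% of unambiguously mapped unique sequences are viral,
and the antisense population peaks at 22 nt with a 5′ G bias.

`positionProfile()` and `lengthFirstNtMatrix()` produce the per-position
coverage vectors and length × first-nucleotide matrices behind such a
summary; `plot()` on a profile draws sense coverage upward and antisense
downward.

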