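---
title: "Methods and design of rhodoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of rhodoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhodoquant)
```

`rhodoquant` quantifies proteorhodopsin (PR) genes and transcripts in marine
microbial communities from three kinds of evidence: assembled-metagenome
protein sets, per-gene read/transcript count tables, and qPCR runs. This
vignette is the package's own account of the models behind each estimator,
the parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the design was open.

## Reference numbering and residue classification

PR biology is usually summarised by four residues in a common reference
numbering: the proton-pumping triad — aspartate-97 (the proton acceptor),
threonine-101, and glutamate-108 (the proton donor) — and the spectral tuning
residue at position 105, where leucine or methionine indicates a
green-absorbing pigment and glutamine a blue-absorbing one. The literature
cites these positions without fixing a coordinate template, so the package
anchors them explicitly: it ships a *synthetic* canonical-like reference
protein (249 aa, `inst/extdata/pr_reference_synthetic.fasta`) whose residue
indices *are* the package's reference numbering, with D/T/L/E planted at
97/101/105/108. The reference is constructed, not a natural sequence; any
user-supplied reference with the canonical triad can replace it through
`annotated_reference()`.

Queries are mapped onto this numbering by **pairwise global alignment** to the
reference rather than through a multiple sequence alignment. For the residues
of interest the two are equivalent in practice, and the pairwise route is
deterministic, dependency-free and independently testable; an MSA-based
screen is what a full phylogenetic workflow would use upstream.

Classification is deliberately conservative:

* `classify_pump()`: `functional` iff the mapped residues are exactly (D, T,
  E); `non_canonical` when all three are mapped but any differs (e.g. a
  lysine in place of E108, a variant that does occur in nature and must not
  be silently discarded); `undetermined` when any position maps to a gap.
* `classify_color()`: L/M → `green`, Q → `blue`, any other residue →
  `unknown` — never coerced to a color, because only those three residues
  have established spectral assignments — and a gap → `undetermined`.

## Screening and curation

Candidate identification in a real workflow uses an external similarity
search (DIAMOND/BLASTP against a rhodopsin database) plus HMM domain scans;
the package consumes such hit tables through `import_external_hits()`
(retaining rows with E ≤ 10⁻⁷, best hit per query by lowest E value then
highest bitscore) and also offers `search_candidates()`, an internal
local-alignment search against a reference panel, as a self-contained
stand-in. When an external table is supplied it takes precedence.

Curation then applies two rules, both explicit and logged per record:

1. **Length**: strictly greater than 100 aa ("larger than" read literally —
   a 100-aa protein fails).
2. **C-helix coverage**: the global alignment to the annotated reference must
   place non-gap query residues at ≥ 3 of the 4 key positions. Coverage, not
   residue identity, is the criterion: a protein with a non-canonical triad
   is retained and flagged downstream, because pump-variant sequences are a
   finding, not noise.

## Alignment engine

Screening, position mapping and clustering all rest on one exact affine-gap
pairwise aligner (C++): global (Needleman–Wunsch/Gotoh) and local
(Smith–Waterman) modes, substitution matrix pluggable with BLOSUM62 as the
default and X scored 0 against everything (neutral ambiguity). Gap penalties
follow BLASTP's convention — the first column of a gap costs `gap_open`
(default 11) and each further column `gap_extend` (default 1). Traceback ties
are broken deterministically: diagonal, then gap-in-target, then
gap-in-query, so outputs are byte-reproducible. A local alignment with no
positive-scoring pair is the empty alignment with score 0 and `NA` spans.
Scores are validated two independent ways in the test suite: against a
brute-force enumeration over all edit paths (small inputs), and against
`Biostrings::pairwiseAlignment` (longer random pairs). No heuristic seeding
or E-value statistics are provided; at the scale of curated PR sets the exact
DP is fast enough.

## OTU clustering

PR protein OTUs are defined by greedy incremental clustering at 82 %
identity, the convention used for PR diversity units. `cluster_greedy()`
reimplements the cd-hit strategy with the exact aligner: records sorted by
length (descending, ties by id lexicographically), each record joins the
first existing cluster whose *representative* it matches at ≥ threshold
identity (identity = matching columns / length of the shorter sequence),
otherwise it founds a new cluster. Because order is derived from the records
themselves, the partition is invariant to input order. Exact tie-breaking
among equal-length sequences varies between cd-hit versions; the
lexicographic rule here is declared for determinism. OTU labels (OTU01,
OTU02, …) are assigned after clustering by descending cluster size, matching
the prevalence-ordered naming used in field studies.

## Metagenomic abundance model

The estimator converts read counts into the *fraction of cells carrying PR*
using single-copy housekeeping genes as internal standards. With coverage
defined as count/length, the expected coverage of a gene is proportional to
(per-cell copy number) × (abundance of carrying cells) × depth. Since every
genome carries exactly one copy of recA, rplB, rpoB and EF-Tu, and PR-bearing
genomes one PR copy,

> f̂ = mean over the four families h of [ Σ_PR coverage / Σ_h coverage ]

estimates the PR-bearing cell fraction, with depth cancelling exactly (the
statistic is invariant to multiplying all counts by a constant). Two readings
of the averaging were possible; the package pools PR coverage before each
ratio (rather than averaging per-PR-gene ratios), because only the pooled
form estimates the community-level fraction. Coverage of a family sums over
all assembled variants of that family, full gene length is used as the
denominator, and estimates above 1 are *flagged, never clamped* — clamping
would bias the recovery tests. A housekeeping family with zero coverage is a
degenerate normaliser and raises an error naming the family.

Per-OTU relative abundances are coverage shares among PR genes (corrected for
gene size), summing to 1.

## Metatranscriptomic expression model

Relative expression of a target (PR, blh, crtB, crtY, or a single gene) is
its length-normalised transcript coverage divided by the mean coverage of the
housekeeping families rplB, rpoB and EF-Tu. recA is excluded from RNA
normalisation because it is not constitutively expressed in these waters; the
package rejects it as an RNA normaliser outright. Under this statistic the
three housekeeping families themselves average to exactly 1 — a built-in
self-check — and the quantity is depth-invariant. The blue/green transcript
partition divides colored PR coverage only; unknown-color mass is reported
separately rather than distorting the denominator.

## qPCR model

Standard curves are fit by least squares as Cq = intercept + slope·log₁₀
copies over a dilution series (≥ 3 distinct dilutions required; the usual
series is 10⁸ down to 10² copies). Efficiency is E = 10^(−1/slope) − 1, so
slope −3.3219 means perfect doubling; slopes outside [−3.9, −3.0] warn
(efficiency roughly outside 80–115 %). Copy numbers invert the curve at the
*mean Cq* of the replicates — standard qPCR practice — with a CV reported
from per-replicate back-calculated copies. The genome-normalised fraction of
PR-bearing bacteria is (PR copies / 1) / (16S copies / 1.9), using the
assumed 1.9 16S copies and 1 PR copy per genome; both constants are
configurable. "Below detection" is a missing Cq and propagates as a missing
measurement, never as zero — no limit-of-detection model is invented. No
per-sample DNA-input normalisation is applied: the fraction is a ratio of
copies from the same extract, so template amount cancels (template-amount
invariance is tested).

## The synthetic community generator

`community_spec()`/`generate_community()` define a mock community in which
every taxon carries one copy of each housekeeping gene and PR-bearing taxa
carry one PR gene (of known color) plus blh, crtB and crtY. Counts are
independent Poisson: count ~ Poisson(abundance × length × depth), times an
expression multiplier for transcripts. This keeps every truth analytic —
PR-bearing fraction, OTU shares, color shares, relative expression =
multiplier mass ratios — so recovery tests compare estimates against closed
forms, never against a second simulation.

The default community (`default_community_spec()`) fixes the study
conditions: ten taxa, three PR carriers at abundances 0.07 + 0.05 (green) and
0.05 (blue), hence a true PR-bearing fraction of 0.17 — the scale of a
typical coastal summer estimate and the regime the estimator is meant for.
Green PR genes dominate the DNA (share ≈ 0.71) while the blue carrier's PR
multiplier (30 vs 5) makes blue-PR dominate the transcript pool (share
≈ 0.71): the ecologically interesting "green-abundant DNA, blue-dominant
RNA" regime. Retinal-gene multipliers are set so PR:blh expression is exactly
15:1, a plant comfortably above the 10-fold threshold of interest. Gene
lengths are typical bacterial values (PR 750 nt; recA 1065, rplB 830, rpoB
4100, EF-Tu 1185, blh 900, crtB 930, crtY 1150 nt).

What the generator does **not** emulate: overdispersion beyond Poisson, GC or
mappability bias, sequencing error, chimeras, assembly artifacts, multi-copy
housekeeping deviations, primer-coverage bias in qPCR assays, and read-level
effects (counts are generated at the gene level; read mapping is upstream of
this package). Passing recovery tests therefore demonstrates correctness of
the estimators *under their stated model*, not robustness to every artifact
of real libraries — with real data, those effects enter through the count
tables this package consumes.

Synthetic protein panels derive PR-like sequences from the bundled reference
by random substitution (default rate 0.1) that never touches positions
97/101/108, with 105 set by the intended color. Decoys are heavily mutated
C-terminal fragments of the reference that *lack the C-helix region
entirely*, so their failure of the coverage rule is guaranteed by
construction rather than left to chance alignment behaviour of random
sequences.

## Numerical and validation choices

* All generators are pure functions of (spec, seed); the demo pipeline run
  twice from the same seed is byte-identical.
* Validation problem sizes: 500 random pairs (length ≤ 8) for the
  alignment-vs-enumeration oracle; a 120-protein panel (50 green, 50 blue,
  20 decoys) for screening/classification; 30 sequences × 20 seeds for the
  clustering oracle; 200 Poisson replicates per planted fraction
  {0.05, 0.17, 0.30, 0.60} at depth 1 (expected housekeeping counts ≈
  830–4100 per family) for abundance recovery; 200 replicates at depth 2 for
  transcription recovery; 200 noisy runs (Cq noise SD 0.15) for qPCR
  recovery. These sizes give Monte-Carlo standard errors small enough that a
  3-SE unbiasedness check is meaningful while keeping the full suite quick.
* Ratio-of-Poisson estimators carry an O(1/μ) small-sample bias from the
  random denominator; at the housekeeping coverages above it is an order of
  magnitude below the Monte-Carlo 3-SE band, which is why recovery is tested
  at these depths rather than sparser ones.
* Floating-point identities that hold by construction (housekeeping
  self-normalisation = 1, OTU shares summing to 1) are asserted at 1e-12 or
  exactly; statistical recoveries at 3 Monte-Carlo SEs.

## Limitations

The package does not perform read QC, assembly, gene prediction, read
mapping, rRNA removal, HMM/profile domain scoring, multiple sequence
alignment, tree inference or phylogenetic placement — all standard upstream
or downstream steps with mature external tools; their outputs are this
package's inputs. Curation implements exactly the two stated rules; a human
curator applying additional judgment may retain or drop borderline sequences
differently. The green/blue rule is binary by residue 105 and does not
predict absorption maxima.
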