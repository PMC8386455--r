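# rhodoquant

Proteorhodopsin (PR) is a single-protein, retinal-binding, light-driven proton
pump and the simplest phototrophic strategy in marine bacteria. Surveys of
coastal seawater ask three quantitative questions about it: *what fraction of
the bacterial community carries a PR gene*, *which spectral variants (blue- vs
green-absorbing) are present and transcribed*, and *how strongly the gene and
its retinal biosynthesis pathway are expressed*. `rhodoquant` implements the
full desk-side analysis behind those questions for meta-omic and qPCR data:

- **Screening** of predicted proteins for PR candidates (internal
  local-alignment search or import of DIAMOND/BLAST hit tables filtered at
  E ≤ 10⁻⁷), with curation rules: length > 100 aa and coverage of the
  proton-pumping C-helix region.
- **Residue annotation** on a fixed reference numbering: the proton-pumping
  triad D97/T101/E108 (functional vs non-canonical pump) and the spectral
  tuning residue at position 105 (L/M → green-PR, Q → blue-PR), plus
  per-position residue frequency profiles.
- **Protein OTU clustering**: cd-hit-style greedy incremental clustering at
  82 % identity (shorter-sequence denominator) using an exact affine-gap
  aligner instead of word filtering.
- **Metagenomic abundance**: the fraction of PR-bearing bacteria, estimated as
  the mean over four single-copy housekeeping genes *h* ∈ {recA, rplB, rpoB,
  EF-Tu} of the length-normalised coverage ratio

  &nbsp;&nbsp;&nbsp;&nbsp;*f* = mean₍ₕ₎ ( Σ PR counts/length ) / ( Σ *h* counts/length ),

  plus per-OTU relative abundances corrected for gene size.
- **Metatranscriptomic expression**: relative expression of PR and the retinal
  genes *blh*, *crtB*, *crtY* as the ratio of each gene's transcript coverage
  to the mean coverage of the housekeeping genes rplB/rpoB/EF-Tu (recA is
  excluded as an RNA normaliser), and the blue/green partition of PR
  transcripts.
- **qPCR quantification**: standard-curve fitting (Cq = a + b·log₁₀ copies,
  efficiency E = 10^(−1/b) − 1), triplicate copy quantification, and the
  genome-normalised relative abundance of PR-bearing bacteria assuming 1.9
  16S rRNA copies and 1 PR copy per genome.
- **A synthetic community generator** that produces ground-truthed panels,
  Poisson read/transcript counts and simulated qPCR runs, so every estimator
  is validated by parameter recovery against analytic truths.

The alignment core (global Needleman–Wunsch and local Smith–Waterman with
affine gaps, BLOSUM62 + neutral X by default, BLASTP-style penalties 11/1) is
implemented in C++ and checked against an exhaustive-enumeration oracle.

## Worked example

Simulate a ten-taxon community in which three taxa carry PR (true PR-bearing
fraction 0.17, two green and one blue carrier), estimate the fraction from
Poisson metagenome counts, partition transcripts by color, and run a qPCR
quantification:

```r
library(rhodoquant)

comm <- generate_community(default_community_spec())
comm
#> <pr_community> 10 taxa, 52 genes; true PR-bearing fraction 0.170

dna <- simulate_gene_counts(comm, depth = 1, seed = 42)
fr <- pr_bearing_fraction(dna$counts, "metaG")
round(fr$per_housekeeping_ratio, 4)
#>   recA   rplB   rpoB  EF-Tu
#> 0.1866 0.2015 0.1920 0.1958
fr$pr_fraction
#> [1] 0.1939862        # one noisy replicate; unbiased around 0.17

rna <- simulate_transcript_counts(comm, depth = 2, seed = 43)
color_transcript_partition(rna$counts, "metaT")$blue_fraction
#> [1] 0.6985448        # blue-PR dominates transcripts despite green DNA excess

cv <- fit_standard_curve(data.frame(known_copies = 10^(2:8),
                                    cq = 38 - 3.5 * (2:8)))
cv
#> <standard_curve> Cq = 38.0000 -3.5000 * log10(copies)
#>   r^2 = 1.00000, efficiency = 93.1%, 7 dilution points

pr  <- quantify_copies(cv, c(24.02, 23.97, 24.01),
                       assay_id = "SAR11_PR", sample_id = "st1")
pr
#> <qpcr_measurement> SAR11_PR / st1: 1e+04 copies (CV 1.7%, mean Cq 24.00, n=3)
s16 <- quantify_copies(cv, predict(cv, 1.9e5), assay_id = "16S", sample_id = "st1")
pr_relative_abundance(pr, s16)$fraction
#> [1] 0.1              # 1e4 PR copies vs 1.9e5 16S copies = 1e5 genomes
```

The four housekeeping ratios each independently estimate the PR-bearing
fraction; their spread is the Poisson sampling noise the simulator plants. The
qPCR fraction of 0.10 follows from the 1.9-copy 16S correction: 1.9×10⁵ 16S
copies represent 10⁵ genomes, of which 10⁴ carry PR.

An end-to-end run over generated demo inputs (screen → annotate → cluster →
abundance → transcription → qPCR):

```r
run <- run_pipeline(write_demo_inputs("demo", seed = 7))
cat(pipeline_report(run), sep = "\n")
```

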