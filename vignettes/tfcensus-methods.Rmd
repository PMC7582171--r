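---
title: "Methods: a testable AP2/ERF census and MeJA-responsiveness pipeline"
author: "tfcensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a testable AP2/ERF census and MeJA-responsiveness pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and design

`tfcensus` re-implements, as a reusable and fully tested pipeline, the
standard workflow for a genome-wide census of the AP2/ERF
transcription-factor superfamily and its jasmonate-responsiveness
analysis: PSSM domain scanning with exact p-values, domain-architecture
family rules, neighbour-joining (NJ) phylogeny anchored to labelled
references, exon–intron structure statistics, ZOOPS-EM motif discovery,
reciprocal-best-hit (RBH) orthology, FPKM-based responsiveness calls,
and the qPCR (2^−ΔΔCt) and dual-luciferase assay statistics.

Because the genomes such a census is run on are large and external, the
package ships a synthetic-genome generator with complete truth labels.
Every downstream stage is validated against that truth, and the
computational kernels (NJ, the exact p-value convolution, Smith–
Waterman) are validated against independent brute-force oracles.

# The synthetic genome generator

`generate_genome()` plants genes whose protein products carry the
domain architecture that defines each family:

* **AP2**: two AP2 domains separated by a linker (a configurable
  fraction, default 25%, carries a single domain and must be rescued
  through the tree, mimicking the single-domain AP2 members a real
  census recovers phylogenetically);
* **RAV**: one AP2 domain plus one B3 domain;
* **DREB/ERF**: a single AP2 domain carrying the group's four
  diagnostic columns;
* **Soloist**: a strongly diverged AP2 variant embedded in conserved
  family-specific flanks, so that Soloists are recognizable by
  full-length homology rather than by clade.

The AP2 (60 columns) and B3 (40 columns) seed alignments shipped under
`inst/extdata` are small hand-built synthetic stand-ins for curated
domain models (marked `_synthetic` in their file names); their
consensus sequences seed both the scanning PSSMs and the planted
domains. Each DREB/ERF group owns four fixed diagnostic columns of the
AP2 consensus (groups differ pairwise at eight columns). Diagnostic
columns are exempt from the divergence process, so group identity
remains recoverable by construction; everything else mutates per site
with probability `domain_divergence` (default 0.05; at ≥ 0.5 the
generator warns that truth may be unrecoverable).

Structural realism follows the regularities censuses of this
superfamily report: groups III, VI, VI-L and IX are intronless, every
group VII gene has at least one intron, AP2 genes carry 1–9 introns and
Soloists 4–5. Introns are inserted at codon boundaries with canonical
`GT..AG` ends, which keeps CDS extraction unambiguous. Every CDS ends
in a stop codon, so a CDS of `L` bp encodes `L/3 − 1` residues.

A single seed drives all generators; each stage derives a substream by
a fixed offset, making all outputs byte-identical under a fixed
configuration.

**What the generator does not emulate**: read-level noise (it produces
counts, not FASTQ), codon-usage bias, alternative splicing, UTRs,
paralogous duplication structure, and realistic inter-family sequence
homology beyond the shared consensus scaffold. Tests passing on this
generator therefore demonstrate the correctness of the pipeline's
logic and numerics, not its sensitivity on any real genome.

## The count model

Counts are negative binomial with `var = mu·(1 + nb_dispersion)`
(`nb_dispersion = 0` is Poisson). This "NB1" convention makes the
dispersion the *relative* extra-Poisson variance, so at the default
baseline mean of 500 and dispersion 0.05 the per-sample coefficient of
variation is ≈ 5% — the regime in which a single-replicate time course
(the design this analysis targets) can support a fold-change cut-off
without false calls. Induced genes (default: groups IX, X and III,
fold 8) have their mean multiplied in MeJA samples at times > 0; the
mock series and the 0 h samples are never induced.

The returned matrix carries a `total_fragments` attribute: per-sample
totals including 10^6 background fragments for the rest of the
transcriptome. FPKM computed with totals restricted to one gene family
would suffer a strong composition bias whenever many members are
induced (the induced genes would inflate the denominator and largely
cancel their own fold change); real libraries are dominated by the
remainder of the transcriptome, which the background term emulates.

# Domain scanning and exact p-values

`build_pssm()` drops columns with > 50% gaps, smooths foreground
frequencies with `pseudocount × background` (default background:
add-one-smoothed training-set residue frequencies) and stores log2
odds. Scores are discretized to `eps = 0.01`-bit bins; the binned
matrix *defines* the score scale: the scanner scores windows with it,
and `exact_score_pvalue()` computes `P(score ≥ s)` under the background
by position-wise convolution of the per-column binned distributions —
exact for that scale, and within `width · eps` of the continuous-score
tail. Tails for every model prefix and suffix are accumulated in one
forward and one backward pass and memoized, so end-truncated
candidates (the model overhanging a protein end by ≥ 6 retained
columns) get honest p-values at negligible cost.

A hit's `coverage` is the structural fraction of model columns aligned
(1 for interior windows); `complete` requires coverage ≥ 0.9, which
tolerates ragged ends while excluding half-domains. Overlapping hits
are reduced greedily best-first, suppressing overlaps above 50% of the
shorter hit. The default per-window threshold is `1e-5`.

No gapped matching is attempted: presence/absence plus completeness is
what the census consumes, and an ungapped scan keeps the p-value
exactly computable.

# Alignment, distances, NJ and bootstrap

`progressive_align()` merges profiles along a UPGMA guide tree built on
3-mer count distances; profile–profile columns are scored as the
frequency-weighted BLOSUM62 expectation and aligned by an affine-gap
dynamic program (gap of length L costs `open + L·ext`, default 10/1)
implemented once in C++ and shared with the local aligner.

Distances use pairwise deletion of gapped sites; `p` is the mismatch
proportion and the Poisson correction is `−ln(1 − p)`. The
maximum-likelihood amino-acid model often used for such trees is
deliberately replaced by the Poisson-corrected p-distance: the census
needs relative placement, not absolute branch lengths, and the
group-assignment machinery relies only on topology and path lengths.
A saturated pair (`p = 1`) is assigned twice the maximum finite
distance, with a warning.

`nj_tree()` is the Saitou–Nei agglomeration with the standard two-point
branch-length formula, negative lengths clamped to zero, and equal-Q
ties broken by the lexicographically smallest id pair — NJ is exact on
additive matrices and fully deterministic here. `bootstrap_nj()`
resamples columns with replacement and reports, per internal edge,
the percentage of replicates containing the same leaf bipartition; all
values are recorded, including those below 50.

# Classification

Architecture first: two complete AP2 domains → AP2; one AP2 + one B3 →
RAV; no complete AP2 → excluded from the census; a single AP2 leaves a
candidate. Candidates' best domain windows are aligned jointly with the
reference panel, an NJ tree is built, and:

1. **Soloist** if the best full-length global-alignment similarity to a
   Soloist anchor reaches the threshold. Similarity is BLOSUM62
   positives per alignment column (gaps in the denominator). The
   default threshold is 60%: measured on synthetic data, true Soloists
   score ≈ 97% while any other single-domain protein — which still
   shares the conserved domain block — scores 30–44%, so the
   conventional 40% would not separate; 60% sits in the wide gap.
2. **AP2 rescue** if the nearest reference by patristic distance is an
   AP2 anchor.
3. Otherwise the group of the nearest group reference (DREB for I–IV,
   ERF for V–X/VI-L/Xb-L), except that
4. when the nearest and second-nearest references belong to different
   groups and their patristic distances differ by < 10% (relative), the
   protein is assigned the **single** group with `ambiguous_sister`
   evidence — modelling the near-tie placement a census occasionally
   reports next to, but not inside, a group clade.

Xb-L remains a legal label throughout; a census with no Xb-L members
prints 0. `census()` enforces the identities: total = Σ families,
DREB = Σ groups I–IV, ERF = Σ groups V–X, VI-L, Xb-L, single.

# Structure statistics and density

Percentages are rounded half-up at 1 decimal and densities at 3
decimals (`round_half_up()`), matching how such tables are printed; no
minimum intron length is imposed. `gene_density(total, Mb)` is a plain
ratio: 134 genes in a 502-Mb assembly gives 0.267 per Mb.

# Motif discovery

`discover_motifs()` implements ZOOPS EM (zero or one site per
sequence): deterministic seedings from the subwords of the first three
sequences (one EM iteration each), the best seed run to convergence
(ΔLLR < 1e-6 or 200 iterations; monotonicity of the likelihood is
asserted at every iteration), width chosen by the penalized ratio
`LLR − 0.5 · 19w · ln N`, and discovered sites masked before the next
motif, so site intervals never overlap. The penalty is conservative:
it prefers the shortest width whose columns carry signal, so a planted
8-mer is typically reported as its best 6-column core — site recovery,
which is what the census consumes, is unaffected. Site p-values reuse
the exact PSSM machinery on the motif's log-odds, and display heights
are capped at `−log10(p) = 10`.

# Orthology

`local_align()` is Smith–Waterman with BLOSUM62 and the conventional
gapped parameters (open 11, extend 1); bit scores use the standard
first-order Karlin–Altschul constants (λ = 0.267, K = 0.041) and
`e = m·n·2^−S′`. "Similarity" is positives (BLOSUM62 > 0), the
conventional reading of percent similarity, and coverage is measured on
the query. `rbh()` selects best hits by bit score *before* applying the
similarity ≥ 45% / coverage > 50% / e ≤ 1e-20 gates, in both
directions. `combine_with_tree()` marks a call tree-supported when the
pair is sisters or the partner is the nearest cross-proteome leaf;
pairs added on tree evidence alone must be genuine sisters, which keeps
the `tree_only` set meaningful (a nearest leaf always exists and would
otherwise admit every protein).

# Expression and assays

FPKM is `counts · 1e9 / (total · length)`. Responsiveness compares
`log2(FPKM + 1)` of every sample against the mock 0 h baseline mean;
a gene is up-regulated when its maximum over MeJA samples strictly
exceeds 1 (a change of exactly 1.0 is not called) and down-regulated
symmetrically. The +1 offset is the common log-transform convention
for expression heat maps and is configurable; as the pseudocount
shrinks the rule converges to the plain FPKM ratio. Hierarchical
clustering is average linkage on `1 − Pearson` row distance
(zero-variance rows get the maximal distance 1, with a warning).

`ddct()` computes per-replicate `ΔCt = Ct_target − Ct_ref`, calibrates
against the mock 0 h mean, reports `RQ = 2^−ΔΔCt` with replicate SD,
and compares each treated group to its matched mock with a two-sided
*equal-variance* Student's t-test (the convention in these assays),
starring p < 0.05 and p < 0.01; no multiple-testing correction is
applied, matching practice. Note that `2^−ΔΔCt` of noisy Ct values is
log-normally biased upward by ≈ `(σ ln 2)²/2`; at the default
`ct_sd = 0.2` this is ≈ 1%, which the parameter-recovery test bounds
at 5%. `luc_relative()` normalizes firefly/renilla ratios by the
vector-control mean (VC ≡ 1) and tests effectors against VC the same
way; a zero-variance comparison is degenerate and reported as p = 0
with a warning.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen
as the smallest sizes at which every property is informative: 100
random 4–8-leaf additive trees for the NJ oracle; exhaustive
enumeration up to width 3 (8000 words) for p-values and length 8 for
Smith–Waterman; 200 genes at divergence 0.05 for classification
recovery; 20 seeds × 10 sequences for motif recovery; 20 seeds × 21
genes for responsiveness. Bootstrap replicate counts default to 1000
in `bootstrap_nj()` but the examples and pipeline use ~100, which is
ample for the synthetic clades' saturated supports.

Tie-breaking is deterministic everywhere (lexicographic pairs in NJ,
diagonal-first alignment traceback, first-index maxima); all RNG flows
from one seed via fixed substream offsets.

# Known limitations

* Ungapped PSSM scanning cannot model insertions within a domain.
* The p-distance/Poisson tree is not a substitution-model phylogeny;
  supports and lengths should not be interpreted evolutionarily.
* ZOOPS only; no OOPS/ANR motif models, and no motif-database
  comparison.
* RBH is one-to-one; paralogous many-to-many orthogroups are out of
  scope.
* The responsiveness caller is a fold-change rule for replicate-free
  designs, not a differential-expression test.
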