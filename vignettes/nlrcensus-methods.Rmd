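---
title: "Methods: motif-based NLR classification, census statistics and drought differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-based NLR classification, census statistics and drought differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlrcensus)
```

# Scope

`nlrcensus` analyses the repertoire of NLR (nucleotide-binding,
leucine-rich-repeat) immune receptors in predicted proteomes, with conifer
transcriptomes as the motivating use case. It covers five linked stages:

1. **Subfamily classification** of peptides into CNL, CNL2, RNL and TNL
   (plus truncated, atypical, undetermined and excluded forms) from domain
   architecture and NB-ARC motif signatures.
2. **Redundancy removal and identity clustering** (CD-HIT-style greedy
   clustering on global-alignment identity).
3. **RPW8 phylogeny**: extraction of full-length RPW8 domains, a
   neighbor-joining tree with reference anchors, and assignment to the four
   RNL groups.
4. **Cross-species census statistics**: per-species architecture-row counts,
   subfamily distribution percentages, transcriptome ratios, chi-square
   homogeneity, and an RNL-versus-TNL regression across species.
5. **Drought differential expression**: count filtering, median-of-ratios
   normalization, a simplified per-gene negative-binomial likelihood-ratio
   test with BH FDR control, and Ward.D2/manhattan expression grouping.

A seed-deterministic synthetic-data module generates every input the
pipeline consumes, together with machine-readable truth tables, and is the
basis of the package's tests.

# The classification model

## Domain evidence

A sequence qualifies as an NLR candidate if it carries at least one of the
canonical TIR, RPW8 or NB-ARC domains. Coiled-coil-only and LRR-only
sequences are excluded: they may be mispredicted and are not specific to
NLRs. Domain intervals come from an hmmscan-style per-domain table
(`read_domain_table()`, with the e-value threshold applied per hit;
defaults: broad pre-filter 1.0, model 0.01, hit 0.03 — all three are
separate configuration values because they attach to different steps of an
annotation workflow) or are planted by the synthetic generator. Overlapping
hits of the same domain are merged to union intervals before architecture
calling, because repeat domains (LRR especially) produce tiled hits.

## NB-ARC motif signatures

The NB-ARC domain carries conserved motifs (P-loop, Kinase-2/3, RNBS-C,
GLPL) shared by all subfamilies, and three discriminative motifs — RNBS-A,
RNBS-D and MHD — whose residue variants track the N-terminal domain
identity. The package models each motif as a degenerate consensus: a string
of exact residues, `h` (hydrophobic: A, V, L, I, M, F, W, Y) and `x` (any),
with a subset of *discriminant* positions that must match exactly and are
never relaxed. Non-discriminant positions tolerate `max_mismatch`
substitutions (default 1). An `X` in a sequence matches nothing, so heavily
masked sequences fall through to the undetermined class rather than being
forced into a subfamily.

`locate_nbarc()` anchors the domain by the best chain
P-loop < Kinase-2 < GLPL < MHD-variant in sequence order, with each
adjacent gap (end of one motif to start of the next) inside a configurable
window (default 20–180 residues, the span expected inside one NB-ARC
domain). Among competing chains the fewest total mismatches win; ties break
by leftmost position, making the scan deterministic. The RNBS-A slot is
then scanned between P-loop and Kinase-2, and RNBS-D between GLPL and the
MHD variant. Each slot yields a subfamily call, `ambiguous` (variants of
two subfamilies match) or `absent`.

Key residue signatures carried in the packaged configuration
(`motifs_default.yaml`):

* RNL RNBS-D is `CFLDLGxFP` (discriminants C1, D4, G6) — RNLs carry a
  glycine at position 6 where the other subfamilies carry a cysteine
  (position 5 in CNL, 6 in CNL2, 7 in TNL, after the conserved D4).
* The RNL MHD variant is `QHD`: a glutamine strictly replaces the usual
  methionine/hydrophobic first residue. CNL2 carries `VHD`.
* CNL2 has no scannable RNBS-A variant (it is polymorphic in that motif);
  CNL2 is therefore called by the agreement of its RNBS-D (C6) and VHD
  signatures.
* There is no TNL-specific MHD variant: TNLs share the M1 form with CNLs,
  so a TNL's MHD slot resolves to the CNL-tagged variant and TNL
  classification rests on RNBS-A/RNBS-D plus the TIR domain.

The configuration is data, not code: the hydrophobic set, mismatch budget,
spacing window and every consensus string can be replaced via
`load_motif_config()` without touching the engine. Where a published
consensus exists only as a figure, the packaged strings are curated
transcriptions built around the discriminant residues above; they are the
package's operating definitions rather than verbatim database patterns.

## The decision procedure

`call_category()` applies, in order:

1. No TIR, no RPW8, no NB-ARC evidence → **excluded**.
2. NB-ARC absent: TIR (with or without LRR) → truncated **TNL**-related;
   RPW8 only → truncated **RNL**-related.
3. NB-ARC present: the three signature slots vote; a 2-of-3 majority
   assigns the subfamily unless the N-terminal domain contradicts it (for
   example a TIR over an RNL-voting NB-ARC), which is **atypical**. No
   majority, or all slots ambiguous/absent → **undetermined**.
4. NB-ARC fused to a non-canonical extra domain (e.g. a kinase) →
   **atypical**, regardless of the vote.

The 2-of-3 rule is this package's operationalization: published category
systems do not state a tie rule, and routing contradictions to the atypical
class mirrors how atypical rows are reported in cross-species census
tables. Coiled-coil detection is deliberately not implemented — the non-TIR
N-terminus is highly polymorphic — so CNL is defined negatively
(non-TIR, non-RPW8 N-terminus), as census tables do. When NB-ARC presence
comes only from an external domain hit and no motif chain can be found, the
sequence is undetermined rather than being rescued by its N-terminus; this
keeps step 3 a pure function of the signature vote.

# Identity, clustering and deduplication

`global_identity()` computes a Needleman–Wunsch global alignment under
BLOSUM62 with affine gaps (open 11, extend 1; a gap of length $L$ costs
$11 + L$). Identity is the number of identical aligned pairs divided by the
length of the *shorter* sequence — the CD-HIT global-identity convention,
chosen because the clustering cutoffs quoted for such tools assume it.
Because co-optimal alignments can differ in their match counts, the
alignment core (in C++) maximizes the pair (score, matches)
lexicographically, which makes the reported identity deterministic and
traceback-independent. All scores are integer sums, so exact floating-point
comparison is safe.

`greedy_cluster()` is CD-HIT-style incremental clustering: records are
processed longest-first (ties by id), each joins the first representative
with identity at or above the cutoff, otherwise founds a new cluster. The
deterministic order replaces the tool's internal order for
reproducibility. A length-ratio short-circuit skips alignments that cannot
reach the cutoff under the shorter-sequence denominator; it is a pure
optimization and cannot change results. Deduplication at 0.97 identity
(allelic variants and alternative transcripts) keeps the longest member per
cluster, ties broken by smallest id; deduplication runs on full-length
peptides. Default cutoffs: 0.97 (redundancy), 0.60 (RPW8 representative
sets), 0.80 (within-group structure).

# RPW8 groups

Full-length RPW8 domains are extracted from RPW8 hits strictly longer than
100 residues. Pairwise distances are $1 - \mathrm{identity}$, and trees are
built by Saitou–Nei neighbor joining, which recovers additive distance
matrices exactly; on non-additive input any negative branch is clamped to
zero with the deficit moved to its sibling. Neighbor joining on alignment
distances replaces maximum-likelihood tree search here as a deliberate
design choice: the downstream quantity is the *group assignment* of each
domain (nearest anchor by patristic or raw distance), which is robust to
this substitution, and the substitution is visible in all outputs. Group 2
is anchored by ADR1 and group 4 by NRG1/RPW8.1/RPW8.2; groups 1 and 3 are
conifer-specific and anchored by packaged exemplars. The packaged anchor
FASTA is a **synthetic stand-in** (generated, seed-fixed sequences named
after the real references; see the file header) because the package ships
no third-party sequence data; users analysing real data should supply real
anchors via `load_rpw8_anchors(path)`. Queries equidistant (within 1e-12)
from two groups stay unassigned. Subgroup structure within group 1 is not
modelled.

# Census statistics

`build_census()` reproduces the standard census layout: one row per
architecture form (`NB_CNL-(LRR)`, `RPW8`, `RPW8-NB_RNL-(LRR)`,
`TIR-NB_TNL-(LRR)`, …, with truncated forms counted inside their related
subfamily), per-species NLR totals and percentage ratios to the assembled
transcriptome size (rounded half-up to 2 decimals), and the distribution of
each subfamily as a percentage of all *assigned* sequences across species
(half-up to integers; atypical and undetermined count in totals but not in
the distribution denominator). Half-up rounding and the
truncated-forms-included distribution are the conventions that reproduce
the packaged seven-conifer table's printed percentages from its own counts.

`chi_square_homogeneity()` is a Pearson chi-square without continuity
correction on a species × subfamily count table (columns CNL, CNL2,
RNL-related, TNL-related), with an error on any zero expected cell.
`ols_regression()` fits ordinary least squares with intercept on raw
per-species counts and reports the overall F test on $(1, n-2)$ degrees of
freedom; raw counts are used because they reproduce printed cross-species
regression statistics at the reported precision.

# Differential expression

The drought design has three clonally propagated genotypes, two conditions
(well-watered control, unwatered drought) and five sampling days
(0, 7, 14, 18, 22), with two replicates — 60 libraries by default
(`make_sample_sheet()`). Genes are kept when their count strictly exceeds 5
in at least two libraries. Size factors are median-of-ratios against a
zero-free geometric-mean pseudo-reference, then rescaled to geometric mean
1 so log size factors sum to zero exactly.

The per-gene test is a deliberately simplified negative-binomial GLM owned
by this package: the gene-wise dispersion is estimated by method of moments
on normalized counts, $\hat\alpha = \max((v - m)/m^2, 10^{-8})$, with no
shrinkage across genes and no outlier refitting; the mean model is then
fitted at fixed dispersion under the full design (day × treatment,
optionally plus genotype) and the reduced design (day only), and
$2(\ell_{\mathrm{full}} - \ell_{\mathrm{red}})$ is referred to a chi-square
with the difference in parameter counts as degrees of freedom. BH
adjustment is applied over all tested genes at FDR 0.05. The reported
log2 fold change is drought versus control at day 22 (the end of the time
course), averaged over genotypes when they are in the model. Because the
published analysis this emulates did not print its design formula, both the
plain and the genotype-covariate designs are provided and neither is
asserted as "the" original; the moment-dispersion simplification is
recorded in the result's `model` attribute. Moment dispersion estimated
ignoring the mean structure is slightly inflated for genuinely DE genes,
which costs a little power but never anti-conservatively.

Expression groups are built from per-gene z-scores of
$\log_2(\text{normalized count} + 1)$, clustered with manhattan distance
and Ward.D2 linkage and cut into $k = 14$ groups by default. Profiles are
z-scored because heatmap-style grouping conventions rarely state their
transform; z-scoring makes the groups reflect shape rather than level.

# The synthetic generators

`synth_proteome()` plants category-correct architectures: an N-terminal
TIR block (five TIR motifs), an RPW8 block (115 residues, above the
full-length threshold), or a neutral region; the NB-ARC block with the
category's motif chain at realistic spacings (25-residue linkers, all gaps
inside the 20–180 window); and optional LRR repeats emitted as tiled hits.
Linkers use a reduced "neutral" alphabet (A, E, N, R, S, T) that cannot
complete any discriminant residue combination, so the planted signal is the
only signal — a deliberate idealisation. Truncated forms are emitted at
fixed fractions inside the RNL (20% RPW8-only, 20% NB-only) and TNL
(15% TIR-only, 10% TIR-LRR, 20% NB-only) categories; atypical forms are
kinase fusions; excluded decoys are LRR-only. Point mutations spare
discriminant positions (unless corruption is requested) and are driven by
per-position uniform draws made independently of the rate, so for a fixed
seed the mutation set at rate $\varepsilon_1 < \varepsilon_2$ is nested in
the $\varepsilon_2$ set — classification recall is then structurally
non-increasing in the mutation rate, which is what the recall tests assert.

What the generator does **not** emulate: indel evolution, compositional
bias, coiled-coil N-termini, paralog families with shared ancestry, or
annotation noise in domain boundaries. Passing tests therefore demonstrate
the correctness of the decision procedure and its monotone degradation
under substitutions, not classifier performance on real proteomes.

`synth_species_panel()` draws per-species TNL counts from a negative
binomial (mu 150, size 2 — matching the spread of real cross-species TNL
counts, single digits to ~400), sets
$\mathrm{RNL} = \max(0, \mathrm{round}(0.1\,\mathrm{TNL} + \mathcal{N}(0, 6)))$
and independent CNL counts. The noise SD of 6 puts $R^2$ near 0.7, the
level reported for real cross-species panels; the default panel size is 49
species, the $n$ of the published regression. `synth_counts()` draws NB
counts (default dispersion 0.05, a typical bulk RNA-seq value) with planted
size factors and treatment effects that ramp from day 14 (half effect) to
full effect at days 18–22, mirroring a response that builds with water
deprivation.

# Numerical choices and degenerate inputs

* Alignment scores are integer-valued; ties in the greedy clustering and
  NJ are broken deterministically (processing order; smallest label pair).
* `round_half_up()` implements the half-away-from-zero rounding used by the
  census; base R's banker's rounding does not reproduce printed tables.
* Chi-square tables with a zero expected cell, distance matrices with
  fewer than 3 labels, clustering cutoffs outside (0, 1], counts that are
  not non-negative integers, and `k` larger than the gene set are all
  rejected with errors rather than silently handled.
* All-zero genes are excluded from the LRT with a log message; the LRT
  statistic is floored at 0 against tiny negative numerical residues.
* All generator randomness flows through a single explicit seed; the
  expression module's default seed is 20190812.

# Problem sizes used in the tests

The packaged tests and the acceptance script run at desk scale, chosen as
the package's own test design: 300 sequences (50 per category) for
classification recall across mutation rates {0, 0.02, 0.05, 0.1}; 1000
random motif instances against the exhaustive oracle; 300 RPW8 domains
from 45 planted families for the clustering census; 200 random additive
matrices (4–8 leaves) for NJ; 1000 null genes and 100 planted DE genes
(|log2FC| = 2, 60 libraries) for DE calibration and power. Full-size
repertoire numbers reported for real transcriptomes (thousands of NLRs,
hundreds of RPW8 domains, hundreds of DE genes) require the deposited
sequencing data and are out of scope; the desk-scale runs mirror their
structure, not their magnitudes.

# Known limitations

* CNL is a negative definition; genuine CC motifs are not detected.
* The NJ tree is a distance-based stand-in for likelihood methods; branch
  supports are not computed.
* The DE model's moment dispersion is noisier than shrinkage estimators at
  small replicate counts; calibration was verified at the packaged design
  size (60 libraries), not for very small designs.
* The packaged RPW8 anchors are synthetic stand-ins suitable for testing
  the machinery, not for biological inference on real data.
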