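---
title: "Methods: a desk-scale coral holobiont RNA-seq workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale coral holobiont RNA-seq workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holotrx)
```

# Overview

Bulk RNA-seq of a reef coral sequences the whole holobiont: host,
dinoflagellate symbionts (*Symbiodinium*), and everything else living in
the tissue. holotrx implements the chain of analyses such a dataset
supports — separating host from symbiont transcripts, typing the symbiont
community from ITS2 marker reads, testing host differential expression and
coexpression structure against site, symbiont clade and disease status,
and estimating host genetic differentiation from transcriptome SNPs — as
small, individually testable functions, together with a synthetic-data
module that generates every input with known ground truth.

The package deliberately contains no aligner, assembler or variant caller:
those stages are consumed through their standard outputs (FASTA, FASTQ,
BLAST tabular, SAM-derived alignment tables, VCF). What it does implement
in full are the decision rules and statistics between those files and the
biological conclusions.

# The synthetic-data generator

The generator's defaults describe the study conditions the workflow is
meant for, and are fixed: tests and the acceptance checks run at these
settings.

**Meta-transcriptome.** Host and symbiont transcripts draw per-transcript
GC targets from truncated normals — host mean 0.40, symbiont mean 0.55,
common sd 0.04 (fractions of bases). These place the 0.47 partition cutoff
near the optimal decision boundary between the two pools, so the GC rule's
misclassification behaviour is actually exercised: about 4% of host
transcripts exceed the cutoff and about 2% of symbiont transcripts fall
below it. Each transcript is one full open reading frame (ATG ... TAA,
98–398 interior codons, so 300–1,200 bases), built to hit its GC target
exactly up to integer base counts: G+C positions are placed by count, and
in-frame stop codons are removed by composition-preserving A/T swaps. A
configurable fraction of transcripts (default 0.5) receives an ortholog
hit to the correct reference in the homology-evidence table.

**ITS2 reads.** Two synthetic references stand in for the clade C (C31)
and clade D (D1a) marker transcripts: 400 bases, 15% diverged, with a
panel of within-clade type variants at 2% divergence. They mimic only the
length and divergence structure of the real marker panel, not its
sequence. Read pairs (75 bp, inward-facing, fragment 150–250 bp) are drawn
from the D reference with the sample's mixture probability and carry
uniform substitution errors (default 0.003/base). Indels are not
simulated; at this read length the mappers of interest rarely need gapped
alignment, and the internal aligner penalises gaps heavily.

**Counts.** Gene counts are gamma-Poisson: negative binomial with
dispersion 0.1 around `library size x relative abundance`, with a base
log2-abundance spread of sd 2 across genes. Planted differentially
expressed genes shift the log2 mean by ±2 (default) in one site or clade
group, half up and half down. Planted modules share a per-sample latent
Gaussian factor (sd 1 on the log2 scale) times the module loading; a
module may instead be tied to a trait, in which case the factor is the
standardized trait indicator plus N(0, 0.3) noise. FPKM is the naive
count/(kilobase x million-mapped) arithmetic. Because abundances are
renormalized per sample, strong planted factors induce a small
compositional coupling between modules — exactly the distortion TMM exists
to correct.

**Genotypes.** The Balding–Nichols beta model: ancestral frequency
p ~ Uniform(0.1, 0.9), two group frequencies from
Beta(p(1−F)/F, (1−p)(1−F)/F), diploid genotypes binomial, depth
Poisson (mean 40). This is a closed-form equilibrium approximation, not a
coalescent: it is directly parameterized by the differentiation F that the
Weir–Cockerham estimator targets, which is what parameter-recovery tests
need. When transcripts are supplied, SNPs are planted at four-fold
degenerate third codon positions (synonymous by construction) or at
second positions chosen to change the amino acid, so the synonymous
annotation step has a controlled truth.

**What passing tests do not show.** The generator has no isoforms, no
indels, no GC-coverage bias, no batch effects, no phylogenetic structure
within clades, and independent samples (no colony-level correlation).
Recovery results here bound what the code does under its stated model, not
what the field data can support.

# Host/symbiont partition

Rules are applied in precedence order: ortholog evidence to the coral
reference → host; to the symbiont reference → symbiont; a reciprocal best
hit against the cnidarian database → host; otherwise GC ≤ 0.47 → host
(inclusive boundary, per the printed "≤47%"); otherwise discarded.
Transcripts with ortholog evidence to both references are discarded — the
source narrative never describes dual-evidence transcripts, and dropping
them is the conservative resolution. Low-expression (summed FPKM < 0.5;
a sum exactly at the threshold is kept) and ORF-less transcripts are
removed before any homology rule, matching the narrative order.

RBH ties break to the lexicographically smallest subject id, and
reciprocity is checked against that single tie-broken subject; this keeps
the rule deterministic under score ties.

*Accuracy definition.* The workflow's purpose is a clean host set. A call
is therefore scored correct when a true host transcript is labelled host,
and when a true symbiont transcript is *not* labelled host — a symbiont
transcript discarded by the GC rule has been handled correctly, because
no evidence could have rescued it. Under a strict three-label scoring the
95% accuracy bound would be unreachable by construction at 50% evidence
coverage.

# Symbiont typing

Marker discovery is a seeded ungapped local search (shared 11-mers, X-drop
10, +1/−1 scoring) with a Karlin–Altschul e-value
`E = K m n exp(−lambda S)` using the ungapped parameters for +1/−1 scoring
on uniform composition (lambda = ln 3, K ≈ 0.33). The approximation is
crude in K, but the cutoff (0.001) sits orders of magnitude away from the
exact-copy regime, so only the extremes matter; a permutation control
(shuffled same-composition transcripts) shows false hits in ≤1 of 100
trials. A BLAST outfmt-6 table can be supplied instead.

Quantification aligns each mate semi-globally against both references
(+1/−1, gap open 4 / extend 2); a mate maps when its score implies an edit
fraction ≤ 0.1. A read pair counts once — whether both mates or only one
aligned — for the reference whose pair-combined score *strictly* exceeds
the other's; ties count for nothing. "Uniquely mapped" is thus a
deterministic best-score margin rather than a mapper-specific flag.
Phylogenetic type placement is simplified to nearest global-alignment
identity against the type panel, with exact ties reporting all tied
labels.

Per-sample clade proportions are unique-pair counts per clade over the
total; a sample is a mixed-clade outlier when two clades each reach 0.25.
Any nonzero unique count makes a clade "present"; the 0.25 threshold is
used only for outlier flagging. Zero mapped pairs flags the sample as
having no ITS2 signal rather than producing proportions. Mismatch
profiles (fraction of mapped pairs with ≥1 substitution, and the
mismatch-count histogram) are computed from alignment scores, which under
substitution-only scoring convert exactly to mismatch counts.

# Differential expression

The stack is the standard count pipeline, implemented here from its
published definitions and cross-checked in the test suite against the
edgeR/limma implementations (which agree to numerical precision but are
never called by the package code):

* count filter: keep genes with count ≥ 1 in ≥ 3 samples;
* TMM factors: reference sample by 75th-percentile count fraction closest
  to the mean; M and A over genes positive in both; double trim (30% each
  tail on M, 5% on A); inverse-delta-method weights; factors scaled to
  geometric mean 1;
* logCPM: `log2((count + 0.5) / (lib x factor + 1) x 1e6)`;
* MDS: pairwise "leading logFC" distances (RMS of the 500 largest absolute
  logCPM differences per pair, genes chosen pairwise) into classical
  Torgerson MDS;
* voom: lowess (span 0.5) of sqrt residual sd on average log2 count from
  an unweighted fit, evaluated at each observation's fitted log2 count,
  weights = trend^−4, clipped to the trend's range;
* moderation: moment matching of log s² via digamma/trigamma (the inverse
  trigamma solved by Newton iteration); moderated t with d + d0 degrees of
  freedom; d0 = ∞ collapses the variance to s0², a single gene falls back
  to the ordinary t (d0 = 0);
* BH-FDR calls at 0.05, split by sign of the contrast.

Contrasts are three separate binary comparisons (site, clade, disease
status) rather than one multi-factor model, and lesioned plus
morphologically unaffected tissue pool into "diseased". Samples from the
same diseased colony are treated as independent — a deliberate
simplification, flagged as a statistical caveat, since the source design
did not model colony identity either. Outlier exclusion is config input:
the clustering helper (`flag_expression_outliers`, Euclidean distance on
logCPM, average linkage, median + 2 MAD join-height rule) flags and never
drops.

# Coexpression networks

Unsigned weighted network: adjacency `|cor|^beta` on log2(FPKM + 1) after
an FPKM ≥ 1 in ≥ 3 samples filter. The soft power is the smallest
candidate whose signed scale-free fit reaches 0.8 (argmax with a warning
if none does). The fit index bins connectivity into 10 *equal-width* bins
and regresses log10(frequency) on log10(mean k), signed by the slope;
equal-occupancy binning would make the frequency constant by construction
and the index meaningless, so the canonical equal-width form is used.

Module detection is average-linkage clustering of 1 − TOM with a static
cut at 0.995 x the maximum merge height, minimum module size 30, and
iterative merging of modules whose eigengenes correlate above 0.85. A
static cut is a deliberate simplification of the unstated "default"
dynamic tree cut: at the exponents in use (≥ 12) between-module TOM is
driven to ~0, all between-cluster merges happen just below the maximum
height, and the static cut separates them cleanly; at soft exponents it
under-splits, which is why exponent selection matters. Eigengenes are
first right singular vectors of the gene-standardized module submatrix,
sign-fixed to correlate positively with mean module expression.
Module–trait association is OLS of eigengene on trait with BH adjustment
across modules within a trait. Connectivity (kTotal, kWithin) sums
adjacency excluding self.

# Population genetics

SNP handling: depth < 20 calls are set missing first; sites need call rate
≥ 0.95 ("maximum allowable missing data threshold of 0.95" read in the
vcftools sense) and minor allele frequency ≥ 0.1. Synonymous status
substitutes the alternate allele into its codon (standard code, both
strands supported); SNPs outside every ORF are undetermined and excluded.
Thinning keeps the first SNP (smallest position) on each gene's longest
isoform, ties on length breaking to the smallest isoform id.

The estimator is the group-level multi-locus Weir–Cockerham (1984)
theta: per-locus variance components a, b, c summed over loci,
`theta = sum(a) / sum(a + b + c)`. Negative estimates are retained.
Confidence intervals are percentile bootstrap over loci (default 1,000
replicates, seeded). The 2x2 association tests default to the uncorrected
Pearson chi-square — the printed statistics match the uncorrected values
exactly, despite being labelled Yates-corrected in the source — with the
Yates mode available.

For recovery experiments, a two-deme symmetric island model at
migration–drift equilibrium is mapped to its Balding–Nichols
approximation through `F = 1/(1 + 4Nm (d/(d−1))²)`, i.e. `1/(1 + 16Nm)`
for two demes; `simulate_island_fst()` draws 2,524 post-MAF-filter SNPs
at that F and returns the WC84 estimate.

# GO enrichment

pfam2go lines are parsed into a domain → GO multimap (comment lines
skipped, malformed lines warn and skip); terms transfer to genes through
Pfam domain assignments with no GO-graph ancestor propagation, matching
the flat mapping the reported term sizes derive from. The test is the
hypergeometric upper tail including the observed count, with the odds
ratio of the implied 2x2 table. Reported terms need p < 0.05 (strict) and
count ≥ ceiling(0.02 x test-set size); the ceiling is a documented choice,
the source's rounding being unstated. The annotated universe is the gene
background restricted to genes with ≥ 1 GO annotation (configurable), so
printed p-values from unknown universes are not treated as exact targets.

Because the hypergeometric tail is discrete, null p-values are
*super-uniform*: P(p ≤ alpha) ≤ alpha with equality only at support
points. Calibration tests therefore check that the empirical CDF of null
p-values never exceeds the uniform CDF beyond Monte-Carlo slack — a
two-sided uniformity test would reject for every correct implementation.

# Problem sizes and numerical choices

Tests and the acceptance checks run at: 2,000 + 2,000 transcripts for
partition; 10,000 read pairs per sample over six mixtures for typing;
2,000 genes x 24 samples for expression (10 null seeds, 20 power seeds)
and networks (10 seeds, five 100-gene modules at loading 0.8, exponent
14); 2,524 post-filter SNPs x 50 seeds per island-model scenario; 100
bootstrap-coverage runs at 300 replicates. These sizes give Monte-Carlo
error comfortably inside the tolerances being asserted while keeping the
whole suite in a few minutes.

Numerical details worth knowing: the inverse trigamma uses Newton steps
from the asymptotic start 0.5 + 1/x; zero-variance genes error in
adjacency (and are excluded with a warning in soft-threshold search, or
dropped from eigengenes); `rnorm_trunc` rejects and finally clamps into
(0, 1); RNG streams are derived per generator from the config seed, so
generators are deterministic, order-independent, and leave the caller's
RNG state untouched.

# Known limitations

Single-end and gapped alignment paths are not implemented; the e-value
model is approximate in K; module detection is static-cut (no dynamic
tree cut variants); only two groups are supported in the FST estimator;
GO semantic-redundancy reduction is out of scope; and the exact module
counts or DEG lists of any real dataset are not reproduction targets —
they depend on data the package does not ship.
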