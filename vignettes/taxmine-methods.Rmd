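---
title: "Methods and models behind taxmine"
author: "taxmine authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and models behind taxmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxmine)
```

taxmine re-implements, at desk scale, the comparative-genomic and
expression analyses used to dissect paclitaxel biosynthesis in the yew
(*Taxus*) genome: dating whole-genome duplication from synonymous
divergence of paralogues, dating LTR retrotransposon insertions with a
molecular clock, detecting the physical grouping of CYP450 genes on
pseudochromosomes, scoring group-level jasmonate responses, screening
candidate pathway genes by three rounds of subtraction, building an
anchor-gene coregulation network, and fitting taxadiene synthase
kinetics. Because the original sequencing data are far too large for a
test suite, every stage is paired with a generator that simulates input
with known truth; this vignette records the models, the defaults, and
the design decisions that were genuinely open.

## Synonymous divergence and WGD detection

Ka/Ks is estimated by Nei–Gojobori (1986) counting. Synonymous sites are
counted fractionally per codon position, with mutations to stop codons
removed from the per-position denominator, and averaged over the two
sequences; N is defined as `3L - S` so sites are conserved exactly.
Codons differing at *k* positions are scored by averaging the
synonymous/nonsynonymous assignments over all *k*! orderings of single
steps, excluding orderings that pass through a stop codon (if every
ordering does, the average falls back to all orderings and the codon is
flagged — this cannot arise for sense-codon endpoints in the standard
code). Proportions are corrected with the one-parameter Jukes–Cantor
formula, `Ks = -(3/4) log(1 - (4/3) pS)`; a proportion at or past the
3/4 bound is reported as saturated (NA), never as a silent zero. The
original study ran the YN (Yang–Nielsen) model in KaKs_Calculator; we
deliberately implement NG86 instead because it is fully specified,
exhaustively checkable against a brute-force pathway oracle, and
adequate for peak-location inference; the substitution is a documented
difference, and estimates here should not be compared number-for-number
with YN output at high divergence.

4DTv is the proportion of transversion-differing third positions among
sites where both codons share an identical fourfold-degenerate prefix.
It is reported uncorrected, since the source analysis states no
correction; an HKY-style correction was considered and rejected as an
undocumented extra degree of freedom.

Peak detection for Ks and 4DTv cohorts uses a Gaussian KDE with the
Silverman rule-of-thumb bandwidth on a 512-point grid; peaks are sign
changes of the density derivative, reported in descending density
order. The display histogram bin width (default 0.05) is cosmetic and
never enters peak inference. Cohorts with fewer than 10 finite values
are refused rather than smoothed.

Reciprocal-best-hit paralogue pairs use the published filters: e-value
at most 1e-5, alignment length at least 100 amino acids, and c-score
(bitscore over the query's best bitscore) at least 0.3. Self-hits are
excluded from the c-score denominator — the one point the one-line
published definition leaves open — so the best non-self hit of a query
always has c-score 1 and the threshold bites only on externally
supplied, weaker pair tables. Ties are broken by e-value and then by
subject identifier so results are reproducible. Syntenic pair tables
from collinearity tools can be supplied as plain data frames;
collinearity detection itself is out of scope.

## The codon-pair generator

`simulateCodonPair()` provides pairs whose *expected* NG86 Ks equals a
requested target — the property every recovery test and the planted
2.1-peak check rest on. Only synonymous third positions mutate, so the
true Ka is exactly zero. Within a codon whose synonymous third-position
class has *m* members, the substitution probability is calibrated as
`p_m = ((m-1)/3) p*`, where `p*` is the Jukes–Cantor forward transform
of the target; each class then contributes differences in exact
proportion to its NG86 site weight, making `E[pS | ancestor] = p*` for
*every* ancestral sequence, not just on average. For this identity to
hold the ancestor is drawn uniformly from the 45 sense codons whose
synonymous variation is purely third-position with regular site
fractions — this excludes the leucine and arginine families (synonymous
first-position changes) and the Tyr/Cys codons (stop-adjacent third
positions). The exclusion is a deliberate idealisation: real coding
sequences contain those codons, and on real data NG86 saturates
noticeably earlier at high Ks. What the passing tests show is that the
estimator and peak machinery recover a known synonymous divergence;
they do not certify NG86 against the additional biases of real codon
composition.

## LTR insertion dating

The two long terminal repeats of a retrotransposon are identical at
insertion and diverge afterwards, so the insertion age is `T = D/(2
mu)` with `D` the repeat-pair distance and `mu` the neutral rate per
site per year (default 7.34573e-10, the slow gymnosperm rate used
throughout; the rice rate 1.8e-8 is bundled as `RICE_MU` to illustrate
how strongly the clock rescales). The distance correction was not
stated by the source; we default to Kimura's two-parameter model, the
convention of the LTR_retriever pipeline it relied on, with a
Jukes–Cantor fallback behind an argument. Sites with N in either repeat
are excluded pairwise. The generator evolves both repeats independently
under K2P with a transition:transversion rate ratio of 2.0 (a typical
plant value; the source states none) for a known number of years, so
estimated ages can be checked against planted truth; recovery is
unbiased to first order for D < 0.1. Repeats are assumed pre-aligned
with gap columns dropped; alignment construction is out of scope.

Age histograms bin `[0, binWidth)` upward to `maxAge`, with overflow
and saturated elements counted separately so that fractions over all
classes sum to one, and `ageWindowFraction()` reports the share of a
cohort inside an age window such as 8–24 Ma.

## Physical gene groups

`detectGroups()` chains family-filtered genes along a chromosome while
the intergenic gap (next start minus previous end, floored at zero for
overlapping genes) stays within `maxGap`, and keeps chains of at least
`minSize` genes; defaults are the published criteria, 5.26 Mb and 7
genes. Two readings were reconciled: the methods text says "less than"
while the figure caption says "<=" — we use `<=`, and the comparison is
recorded here so either convention can be audited. The gap endpoints
(end-to-start rather than start-to-start) are likewise a choice the
source leaves open. Grouping ignores strand (published groups contain
mixed orientations) and is invariant to input order. Labels are
`<chromosome>.<k>` in coordinate order, matching the published 9.1–9.4
naming. Internal coordinates stay 1-based inclusive (GFF3 native);
BED-like output converts to 0-based half-open, a length-preserving
conversion.

Classification against named references uses the conventional
cytochrome-P450 identity cutoffs — 97% allelic, 55% subfamily, 40%
family — taking the best-identity reference with deterministic
tie-breaks, and leaving sub-40% queries unclassified as candidate new
families.

## Expression responses and the subtraction screen

Expression is quantified as RPKM with the library size taken as the
column sum of the count table (total mapped reads are not available to
a reanalysis). The group response score sums per-gene calls of +1/-1/0;
calls threshold the pseudocounted log2 RPKM ratio at a 1.5-fold change
with pseudocount 0.1. The source states no fold-change cutoff for these
calls; 1.5-fold with a small pseudocount avoids calling noise on
near-zero RPKM, and both knobs are arguments. Replicates (n = 3 in the
emulated design) are averaged before calling.

The three-round screen proceeds by set subtraction. Round 1 keeps genes
with mean RPKM higher in root or bark than in leaf, with a floor of 1
RPKM on the maximal tissue mean ("more highly expressed" is read as
strict inequality of replicate means; no threshold is stated). Round 2
contrasts the high- and low-paclitaxel cell lines. The original used
edgeR; to keep the statistical contribution self-contained we implement
the analogous exact machinery directly: counts are scaled to the
geometric-mean library size, a common negative-binomial dispersion is
estimated by pooled method of moments (least squares on the quadratic
mean–variance relation, which we found markedly less biased at n = 3
than a median of per-gene ratios), and each gene is tested with the
exact conditional double-tail test on group sums — the conditional
binomial when the dispersion estimate is ~0. Survivors need a signed
log2 fold change above 1 (high-yield line over low) and a
Benjamini–Hochberg FDR below 0.05. This is not edgeR: there is no
empirical-Bayes dispersion shrinkage or TMM normalisation, and with
many strongly up-regulated genes CPM scaling introduces a composition
bias that pushes measured fold changes toward the cutoff — visible in
the recovery test, where specificity is perfect but a minority of
planted genes fall under the fold-change line. Round 3 averages
replicates at each of the five jasmonate time points (0, 2, 4, 8, 24
h), computes Pearson correlations between anchor genes and candidates
over those n = 5 values, and keeps pairs with two-sided t-test p <
0.05 (df = 3, so the minimal surviving |r| is 0.878). "Pearce
correlation" in the source methods is read as the Pearson correlation
its results section names. Zero-variance series are skipped and
reported, not silently kept.

The expression generator plants this entire structure: log-normal
relative abundances, negative-binomial counts (dispersion 0.1 by
default), tissue and cell-line log2 effects on the planted pathway
genes, and a shared latent jasmonate trajectory (plus independent
per-gene log2 noise, sd 0.25) for anchors and their designated
partners. Null designs (all effects zero) are used to verify type-I
control of both testing rounds.

## Trees and kinetics

Family trees use p-distances (mismatches over compared sites, pairwise
deletion of gap/ambiguity columns — the source does not state its gap
treatment) and our own Saitou–Nei neighbour-joining implementation:
Q-matrix agglomeration with lexicographic tie-breaks for determinism,
standard branch-length formulas, three-point resolution of the final
trifurcation, and negative branch estimates clamped to zero with a
recorded count (mirroring common phylogenetics-GUI behaviour). On
additive matrices the implementation provably recovers the generating
topology and all leaf-to-leaf path lengths, which the suite checks
against randomly generated trees and against an independent NJ
implementation. Newick output single-quotes labels containing
metacharacters and round-trips branch lengths to six decimals.

Michaelis–Menten parameters are fit by Levenberg–Marquardt least
squares of `v = Vmax S/(Km + S)` (unweighted, as the original
regression settings are unknown), initialised deterministically at
`Vmax0 = max(v)` and `Km0` = the substrate concentration at half-max by
linear interpolation, with tolerance 1e-10 and at most 500 iterations.
On noiseless data from the published eight-point GGPP grid (0.2–50 µM)
the fit recovers Km to better than 1e-6 relative error; with 5%
multiplicative noise the median Km bias stays under 5%. kcat is
reported only when an enzyme concentration is supplied. qPCR fold
changes are `2^-ddCt`.

## Problem sizes and reproducibility

The test suite and acceptance checks run at sizes chosen to make
sampling error negligible relative to the tested tolerances while
keeping a full run in the low minutes on one core: codon-pair cohorts
of 100–300 pairs at 500–2,000 codons, LTR cohorts of 200 five-kilobase
elements, 500 random layouts against the brute-force grouping oracle,
expression studies of 400–2,000 genes with three replicates, and 30–45
random additive matrices of up to 12 taxa. All generators take explicit
integer seeds and restore the caller's RNG state, so every reported
number is reproducible from a seed. `scripts/acceptance.R` recomputes
the package's headline quantities (annotation-support percentages, the
CYP450 census, and the taxadiene-synthase kinetic constants and
ratios, the latter through actual model fits on the printed assay
grid) and writes them as JSON.

## Known limitations

NG86 rather than YN means Ks values at high divergence are not
comparable number-for-number with maximum-likelihood estimates; the
4DTv statistic is uncorrected; the screen's count test is not edgeR and
inherits composition bias from CPM scaling; the LTR generator does not
simulate indels, nested insertions, or rate variation among sites; the
layout generator plants rectangular gene models without overlaps or
nested genes; and the synthetic expression model is negative-binomial
with a single common dispersion, which understates the mean-dispersion
trend of real RNA-seq. Collinearity detection, HMM-based gene-family
discovery, alignment construction, and maximum-likelihood phylogenies
are intentionally out of scope.
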