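---
title: "Methods: classifying drought stress memory from expression and methylome data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying drought stress memory from expression and methylome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memoryseq)
```

## The biological question

Plants exposed to repeated mild drought can respond differently to a later
stress than to the first one — a *stress memory*. The experimental design
behind this package samples rice leaves at four states along a cycle of
drought (S) and re-watering (R): the untreated control **R0**, the first
stress **S1**, a late re-watering **R3** and a late stress **S4**, each with
three biological replicates. A *memory gene* is a stress-responsive gene
whose transcript level at S4 or R3 differs significantly from its level at
S1: it "remembers" the earlier exposure instead of repeating the same
response. The package classifies such genes by trajectory shape, calls
differentially methylated regions (DMRs) from bisulfite counts, and asks
whether methylation changes track memory-gene expression.

## Trajectory profiles

With four ordered conditions there are three transitions; discretising each
transition into down / flat / up gives $3^3 = 27$ candidate shapes, of which
the all-flat one is excluded, leaving **26 profiles**. `enumerate_profiles()`
numbers them by the lexicographic rank of the step vector ($-1 < 0 < +1$)
with the flat slot removed, so profile 0 is monotone down $(0,-1,-2,-3)$ and
profile 25 monotone up $(0,1,2,3)$. This numbering reproduces the semantics
of the published profile ids used for the memory categories (e.g. 18 is
"respond at S1, return and hold", 25 is monotone accumulation); the original
clustering tool's internal numbering is not documented, so the canonical
rank is the package's own convention.

Genes are matched to profiles in three steps:

1. replicate FPKM values are averaged per condition (one value per condition
   per gene, the unit the clustering operates on);
2. the trajectory is log-ratio transformed,
   $v_t = \log_2\frac{x_t + 1}{x_1 + 1}$, anchoring R0 at 0 (pseudocount 1
   avoids infinities for genes silent in some state);
3. the profile maximising the centred Pearson correlation with $v$ wins;
   ties break toward the lower profile id for determinism, and a constant
   $v$ is reported unassignable rather than forced.

Because correlation is scale-free, a gene with a weak but consistently
shaped response gets the same profile as a strong one; the *memory* decision
is made separately from significance tests, not from the shape.

FPKM used here is computed with **median-ratio effective library sizes**
rather than raw column sums. Raw library sizes are badly distorted when a
substantial share of transcription shifts between conditions (composition
bias); the median ratio to the gene-wise geometric mean is the conventional
robust replacement and is essential for trajectory fidelity when strong
multi-fold changes are present.

## Memory definition and categories

`flag_memory()` implements the definition: a gene is memory if it is
differentially expressed versus R0 in at least one of S1/R3/S4 (the
responsiveness gate) **and** differs from S1 at R3 or S4. The default rule
is the inclusive OR (`rule = "any"`); the AND variant is a switch. Neither
rule reproduces exactly the published list of 16 memory profiles out of the
26 — that list appears partly curated — so the package ships it verbatim as
`memory_profile_preset()` and does not guess the curation rule.

Memory genes are then categorised from their assigned profile. The default
map is the published explicit lists (stable {21, 24}, accumulated {22},
lineage {25}, initial {7, 18}, dosage {9, 10, 12, 13, 15, 16}; anything else
flagged memory is "other-memory"). An alternative `scheme = "shape"` derives
sign-symmetric predicates (dosage = flat at S1; initial = respond once then
return; lineage = strictly monotone; stable = respond and hold; accumulated
= respond, plateau, respond again), which agrees with the published lists on
every listed profile and extends them symmetrically to down-regulated
shapes. Dosage-dependent memory genes — silent at the first stress,
responsive only after repeated cycles — are the category the memory
definition is specifically designed not to miss.

## Differential expression

The screen is the published criterion: $|\log_2 FC| > 1$ and BH FDR
$< 0.05$, per contrast. The test behind it is an **exact conditional count
test** authored in the package: replicates are pooled per group after
median-ratio scaling, and, conditional on the pooled total $t$,

* dispersion $\alpha = 0$: the group-A total is Binomial$(t, 1/2)$ under the
  null; the two-sided $p$ sums all outcomes no more likely than the observed
  one (minimum-likelihood region);
* $\alpha > 0$: each pooled group of $n$ replicates is negative binomial
  with dispersion $\alpha / n$ (variance $\mu + \alpha\mu^2$ at replicate
  level), and the conditional split distribution is renormalised over all
  splits of $t$.

For $\alpha = 0$ the test has a closed brute-force oracle (direct binomial
summation); for $\alpha > 0$ it agrees with edgeR's small-p exact test to
machine precision, which the test suite checks — edgeR is used only as a
cross-check, never as the implementation. The common dispersion, when not
supplied, is the across-gene *mean* of per-gene moment estimates
$(s^2 - \bar x)/\bar x^2$ (genes with mean below 5 excluded): the per-gene
moment is unbiased but extremely noisy at $n = 3$, so a robust location
(median) would be biased low and make the test anti-conservative; the mean
is not. Fold changes use pseudocount 1 on normalised means so dosage-type
genes silent in one condition stay finite.

## DMR calling

Methylation differences are tested per context (CG, CHG, CHH) on a sliding
grid of 200 bp windows at 50 bp steps. Each window pools methylated and
unmethylated counts over both strands, needs at least 5 reads per condition
(Fisher on near-empty tables is uninformative), and is tested by the
two-sided Fisher exact test (minimum-likelihood hypergeometric tail). The
implementation is a vectorised `dhyper()` summation because tens of
thousands of windows are tested; it is verified against `fisher.test()` and
against an independent binomial-coefficient enumeration over *all* tables
with margins up to 30. BH correction is applied within context.

A single 200 bp window is a noisy unit, so the caller reports *regions*:

1. **candidates** — maximal runs of overlapping/bookended raw-significant
   windows ($p \le 0.05$, same direction), at least two windows long (an
   isolated window is not a region), containing at least one FDR-significant
   window ($q \le 0.05$) as a seed;
2. **boundary refinement** — a window union systematically overstates the
   extent by up to window − step per side (a window overlapping a true
   region by a fraction of its width can still be significant). With a
   fine-grained tiling (25 bp bins) supplied, each region is re-fit by a
   two-segment binomial changepoint model: every candidate pair of bin
   edges (region ± a margin) is scored by the binomial log-likelihood with
   segment-wise MLE levels per condition, and the maximising segment becomes
   the DMR;
3. **effect filter** — the refined region must show an absolute pooled
   methylation-level difference of at least 0.2, a conventional
   minimal-biological-effect cut in WGBS practice that suppresses
   FDR-permitted false windows with trivially small differences.

These region rules (merge, refinement, minimum difference) are the package's
own design; the study describes the window test and FDR control but not how
windows become reported DMRs. Window-level $p$, $q$ and significance flags
are always reported alongside, so the raw procedure remains fully visible.

## Methylation–expression linkage

Called DMRs are associated with genes when they overlap the gene body or a
strand-aware 2 kb promoter window (the association rule is unspecified in
the study; 2 kb upstream of the TSS is the common plant convention). Each
DMR–gene pair is scored independently by the Pearson correlation between
per-sample methylation level and expression. The shipped link thresholds
are the published $r > 0.04$ / $r < -0.04$. These are unusually permissive:
with 12 samples a *null* pair exceeds $|r| = 0.04$ with probability
$\approx 0.90$ (the $t$-distribution of a null correlation), which the test
suite verifies empirically. They are kept as defaults for fidelity; for any
real analysis a conventional $|r| > 0.4$ is recommended via the
`pos_thr`/`neg_thr` knobs. Term enrichment of memory-gene sets is a
standard upper-tail hypergeometric test with BH correction across terms —
a generic replacement for web-tool enrichment.

## Physiological indices

Two closed-form indices monitor drought severity: relative water content
$\mathrm{RWC} = (FW - DW)/(RW - DW) \times 100\%$ and the maximum quantum
yield of photosystem II $F_v/F_m = (F_m - F_0)/F_m$. Values outside their
physical ranges are returned with a warning rather than clipped —
measurement error should be visible. Steady-state fluorescence is recorded
in the measurement schema but enters no formula.

## The synthetic-data generator

Every stage is testable against planted truth without sequencing data.
Defaults were chosen once to be realistic for the rice system:

| parameter | default | rationale |
|---|---|---|
| conditions × replicates | R0,S1,R3,S4 × 3 | the sequenced design |
| baseline mean count | 100 | moderately expressed gene |
| NB dispersion α | 0.05 | typical bulk RNA-seq biological CV (~22%) |
| effect size | 2 log2-units per unit step | clear 4-fold response per transition |
| profile mixture | 60% flat, rest uniform over the 26 shapes | most genes unresponsive |
| gene length | log-uniform 500–5000 bp | exercises FPKM normalisation |
| cytosines per Mb | CG 85k, CHG 60k, CHH 250k | C density implied by ~44% GC rice-like sequence |
| context baseline levels | CG 0.50, CHG 0.25, CHH 0.05 | rice-like genome-wide averages |
| WGBS depth | Poisson mean 30 | common WGBS coverage |
| DMR delta / width | 0.3 / 200 bp | moderate, window-scale regions |

Counts are NB($\mu$, $\alpha$) with $\alpha = 0$ degenerating to Poisson;
per-cytosine methylated counts are Binomial(depth, level), with condition-B
levels shifted by the planted delta inside DMRs. Planted DMRs are disjoint
and spaced by at least three widths so merged calls cannot bridge them.
Coupled linkage data makes per-sample methylation an affine function of
standardised log2 expression (configurable sign and Gaussian noise), with
amplitude chosen so noise-free levels are never clipped at [0, 1] — so
noise-free correlations are exactly ±1.

What the generator does **not** emulate: read-level error and mapping bias,
replicate-specific library composition artefacts, spatially autocorrelated
methylation, gene-length–expression coupling, lncRNA biology, and real
genomic sequence (cytosine positions are uniform, strands alternate). Tests
passing on this generator therefore validate the statistical machinery and
its calibration, not robustness to alignment or sequence-context artefacts.

## Problem sizes and numerical choices in the test suite

The suite runs at desk scale, chosen so the whole suite completes in well
under a minute: null calibration uses 5,000 genes and ~60,000 windows
(empirical $p < 0.05$ rates within $0.05 \pm 0.01$ and essentially nothing
passing BH); recovery runs use 2,000 genes (effect 2, dispersion 0.05,
$n=3$) and 40–60 planted DMRs at delta 0.3, depth 20–30, asking ≥90% of
planted memory genes flagged, ≥85% correct shapes, and ≥90% DMR sensitivity
and precision with boundaries within one 50 bp step. Oracle-equivalence
tests enumerate all 2×2 tables with margins ≤ 30 and 1,000 random BH
vectors. Seeds are fixed in the tests; all generator randomness flows from a
single seed per simulated dataset.

## Known limitations

* The exact count test pools replicates; it does not model per-replicate
  outliers the way a GLM with observation weights would.
* The changepoint refinement assumes one contiguous level change per
  candidate region; two planted DMRs closer than a window width would be
  fused.
* The published ±0.04 linkage thresholds accept ~90% of null pairs at
  $n = 12$; results at those defaults are screening candidates, not
  discoveries.
* Profile assignment is purely nearest-profile; no profile-significance
  permutation test is attempted, as none is described for the study design.
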