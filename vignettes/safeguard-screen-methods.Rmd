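---
title: "Methods: the safeguard-repressor screen and activity analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the safeguard-repressor screen and activity analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(safeguardR)
```

## The model

Cell identity is maintained not only by lineage-specific activators but
also by *safeguard repressors*: transcription factors (TFs) that are
specifically and continuously expressed in a cell type and silence the
gene programs of alternative lineages. Such a TF leaves a recognizable
statistical footprint in reference atlases: it is expressed far above its
cross-tissue average in its home cell type, while its DNA-binding motif is
*depleted* at the promoters of that same cell type's signature genes (it
has no business repressing its own program) and present at the signatures
of other lineages.

The screen quantifies both signals per TF $t$ and cell type $c$:

* $E_{tc}$ — mean expression of $t$ in cells of type $c$, on
  median-library-size CPM units;
* $D_{tc}$ — mean motif density of $t$: the average number of motif hits
  of $t$ in the ±2 kb promoter windows of type $c$'s signature genes.

Each TF's row is standardized across cell types (sample s.d.),

$$Z^{\mathrm{expr}}_{tc} = \frac{E_{tc} - \bar E_{t\cdot}}{s(E_{t\cdot})},
\qquad
Z^{\mathrm{motif}}_{tc} = \frac{D_{tc} - \bar D_{t\cdot}}{s(D_{t\cdot})},$$

and combined with equal weighting after dividing each matrix by its global
maximum absolute value ($Z_{\max}$ normalization):

$$S_{tc} = \frac{Z^{\mathrm{expr}}_{tc}}{\max|Z^{\mathrm{expr}}|}
        - \frac{Z^{\mathrm{motif}}_{tc}}{\max|Z^{\mathrm{motif}}|}
        \in [-2, 2].$$

A high $S_{tc}$ marks a TF that is specifically expressed in $c$ *and*
whose motifs avoid $c$'s own signature genes — the safeguard-repressor
profile. Activators of $c$'s program score near 0: their expression term
is equally positive but their motif term is positive too, and it is
subtracted.

Candidates are annotated as *lifelong expressed* by two filters:

1. **Aged-atlas filter** — mean expression in the aged atlas is at least
   50% of the young mean in the same type, and the young type mean
   exceeds the TF's mean across all cell types;
2. **Developmental filter** — within each developmental sample
   (time point × replicate) a TF is "high" if it lies in the top quartile
   of all TFs; a TF passes if it is high in strictly more than 70% of
   samples. Both the quantile level and the persistence threshold are
   parameters (`quantile_level`, `min_fraction`).

## Signature genes

Signatures are the top `n_top` (default 1,000) genes enriched in each
cell type by a one-sided one-vs-rest Wilcoxon rank-sum test, ranked by
Benjamini–Hochberg-adjusted p, ties broken by log2 fold change of group
means (pseudocount 1) and then gene id. The rank-sum p-value uses the
exact distribution (`stats::pwilcox`) for tie-free pooled samples of at
most 20 cells and a tie-corrected, continuity-corrected normal
approximation otherwise, vectorised across genes. Genes appearing in two
or more signatures are removed from *all* of them, making signatures
pairwise disjoint before any motif density is computed; no keep-winner
rule is applied because expression shared between two lineages is
uninformative about either one's specific program.

One numerical consequence worth knowing: adjusted p-values come in large
tie groups, and the fold-change tie-break (pseudocount 1) is not
invariant to a global rescaling of the expression matrix, so the genes
sitting exactly at the `n_top` boundary can change if all values are
multiplied by a constant. The z-scores and safeguard scores themselves
are exactly scale-invariant for a fixed signature set, and that is how
the invariance is asserted in the test suite.

## Intervals and counting rules

All intervals are 0-based half-open. Promoter windows are
$[\max(0, \mathrm{TSS} - 2000),\ \mathrm{TSS} + 2000)$ and
strand-independent (the window is symmetric, so strand cannot change it).
A motif hit belongs to a promoter iff its midpoint lies inside the
window; the midpoint rule prevents a hit straddling a window edge from
being counted in neither or both of two abutting windows, while a hit
whose midpoint genuinely lies in two *overlapping* gene windows is
counted once per gene. Whether the original analyses counted
edge-overlapping instances in or out is not documented anywhere we could
follow; the midpoint rule is this package's documented choice.

For regulon construction, binding peaks are first filtered for motif
support: each motif hit is extended symmetrically to a total width of
50 bp (left pad $\lfloor (50-\ell)/2 \rfloor$, remainder right) and peaks
must overlap an extended hit by ≥ 1 base. Surviving peaks are assigned to
every gene whose $[\mathrm{TSS}-1\,\mathrm{kb}, \mathrm{TSS}+1\,\mathrm{kb})$
window they overlap. A target enters the regulon if it additionally shows
a significant expression response (adjusted p < `de_alpha`) under the
declared contrast; the *high-confidence repressed* subset further
requires the promoter to close in accessibility (control-vs-OE log2 fold
change > 1). The contrast orientation is a required configuration field
and never inferred from the data.

## Module scores, activity and the transduction filter

The per-cell module score of a gene set is its mean expression minus the
mean expression of control genes matched on average expression: genes are
placed into 24 equal-frequency bins by mean expression, and for each set
gene up to 100 controls are drawn (seeded, without replacement) from its
bin; the controls are pooled as a unique set. The score is invariant to
adding a per-cell constant and identically zero on constant-expression
data. Repressor-mode TF activity is the *negated* module score of the
high-confidence repressed subset — a sign flip, not a reciprocal, which
would be undefined at zero.

The transduction filter compares, for each overexpression (OE) cell, the
fraction of control cells with strictly lower activity
(`gfp_prop`) against the fraction of the other OE cells with strictly
higher activity (`prox1_prop`; self excluded, ties count toward
neither). The published rule excludes a cell when
`gfp_prop > prox1_prop`. Combined with inverted (repressor) activity
this removes the *highest*-activity OE cells — the opposite of its
stated purpose of discarding untransduced cells. Either the inequality
or the inversion must differ from what was actually run; since the
original code is not available to us, both orientations are implemented
(`rule = "as_published"` and `rule = "flipped"`) and only the flipped
orientation is asserted against planted ground truth. On simulated data
the flipped rule keeps essentially all transduced cells and nearly every
cell it excludes is truly untransduced; note that its *specificity* in
the textbook sense is bounded near 77% at transduction rate 0.7, because
an untransduced OE cell whose activity sits at control-quantile $u$ is
excluded iff $u < 1/1.3$ — a property of the rank rule itself, not of
the data.

Identity–activity association is the plain Pearson correlation between
per-cell identity module scores and TF activity, restricted to kept
cells; zero-variance vectors yield a missing value with a warning rather
than an error.

## Enrichment statistics

Gene-set enrichment uses the one-tailed (upper) hypergeometric test with
BH adjustment across all sets tested together; set sizes are counted
after intersection with the universe. The Fisher overlap test reports
the sample odds ratio $ad/bc$ (infinite when $bc = 0$, undefined for an
empty margin) with the same upper-tail p-value; depletion tails are
deliberately not offered. Printed count ratios are formatted by
`fraction_percent()`, which rounds half-up (so 6.25% prints as 6.3, not
banker's 6.2).

## The synthetic-data generator

The generator produces every input the pipelines consume, with planted
ground truth, so each stage is testable end to end without external
atlases. Defaults define the reference conditions used throughout the
package's validation: 8 cell types × 200 cells, 2,000 genes plus 60 TFs,
100 markers per type, one safeguard and one activator TF per type, an
8-fold marker effect, promoter motif rates 0.2 (depleted) vs 3.0
(enriched) mean hits, negative-binomial counts with dispersion 0.3
(variance $\mu + 0.3\mu^2$, a typical UMI overdispersion), transduction
rate 0.7 and repression factor 0.2. Where a choice was free we took the
simplest realistic option and fixed it once: lognormal baseline means
(meanlog 0, sdlog 1, giving libraries of a few thousand counts over
2,060 features), 11-base motif-hit intervals placed uniformly in the
promoter window, one synthetic chromosome per 1,000 features with TSSs
10 kb apart on the + strand, and the midpoint rate
$(\mathrm{low}+\mathrm{high})/2$ for neutral TFs and non-marker
promoters, which the density computation never touches. Every generator
is bit-reproducible given (config, seed); stages draw from independent
derived seeds so adding one stage never perturbs another.

What the generator does *not* emulate — and therefore what passing tests
cannot show about real data: no nucleotide sequence or PWM scanning (motif
presence is planted at the hit-count level), no doublets, ambient RNA,
batch effects or cell-cycle structure, no correlated gene programs beyond
the planted markers, and marker effects that are cleanly multiplicative.
The parameter-recovery results (the planted safeguard ranking first in
essentially every simulated cell type) demonstrate that the scoring
machinery recovers the signal it formalizes, not that real atlases carry
a signal this clean.

## Problem sizes and numerical conventions

Validation runs use the reference simulation for parameter recovery and
transduction filtering (20 replicate seeds each) and a reduced
3-type × 30-cell configuration for property checks; these sizes give
stable Monte-Carlo estimates while keeping the whole suite quick on a
laptop. Zero-variance rows z-score to zero with a warning rather than
NaN; empty signatures yield density 0 with a warning; sample (n−1)
standard deviations are used throughout; BH adjustment is
`stats::p.adjust`; and the exact hypergeometric tail is
`stats::phyper`, cross-checked in the tests against exhaustive subset
enumeration up to universe size 20.

## Known limitations

* The screen's candidate lists on real atlases depend on atlas
  composition (which cell types are included changes every z-score); the
  package reproduces the method, not any particular published candidate
  list.
* The `as_published` transduction rule is retained verbatim for
  transparency but cannot be validated against ground truth (see above).
* Shortlisting is a parameterized top-k per cell type; no claim is made
  about how published candidate counts were curated.
* Motif hits are consumed as precomputed intervals; questions about
  motif-calling thresholds live upstream of this package.
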