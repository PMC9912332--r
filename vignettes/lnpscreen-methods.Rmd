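---
title: "Methods: pooled barcode screen analysis with lnpscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled barcode screen analysis with lnpscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lnpscreen)
```

# The experimental design this package models

In a pooled lipid-nanoparticle (LNP) screen, each chemically distinct LNP is
formulated to carry a reporter mRNA together with a unique DNA barcode. The
whole library is injected into reporter mice as a single pool; days later,
functionally transfected cells of many types are sorted and their barcodes
sequenced. The abundance of each barcode in a sorted population, relative to
its abundance in the injected pool, reports which chemistries delivered mRNA
to which cells — many chemistries are screened in one animal.

`lnpscreen` implements the full desk-side analysis of such a screen:

1. **Library design** — full-factorial enumeration of helper lipids ×
   molar-ratio arms × PEG-lipid arms, with chemical annotation and
   Hamming-separated barcode assignment (`enumerate_library()`,
   `assign_barcodes()`).
2. **Barcode quantification** — demultiplexing reads into a barcodes ×
   samples count table (`count_barcodes()`).
3. **Normalized delivery** — the per-LNP delivery score per sorted sample
   (`normalized_delivery_table()`, `aggregate_mice()`).
4. **Decile enrichment** — chemical-property enrichment among top/bottom
   performers with a permutation test (`enrich_all()`).
5. **Single-cell delivery** — percent reporter-positive cells per cluster,
   rank-sum differential expression, hypergeometric overrepresentation
   (`percent_positive()`, `differential_expression()`,
   `ora_hypergeometric()`).
6. **Synthetic data** — generators with ground truth for every stage
   (`simulate_screen_counts()`, `simulate_screen_fastq()`,
   `simulate_sc_matrix()`).

# Library design

The shipped default library crosses 18 helper lipids (3 cationic, 8 neutral,
7 anionic) with 4 molar-ratio arms and 2 PEG-lipids: 144 designs, of which
137 enter the default injected pool (charge-wise 23/59/55). Three of the
four helper-lipid mole fractions (12%, 27.5%, 44.5%) are the standard
titration set for this design; the fourth arm is not uniquely determined by
any published table, so the default uses an intermediate 20% placeholder and
the whole arm table is an ordinary data frame the user can replace. The same
holds for the headgroup molecular weights in `default_lipid_table()`: they
are approximate catalogue values, present so that the headgroup-size
property has sensible defaults, and clearly replaceable.

Which designs fail pooling criteria (oversized or polydisperse particles) is
an experimental measurement, so `pooled` is an input flag (`set_pooled()`);
`default_screen_library()` marks one cationic, five neutral and one anionic
design — a synthetic choice that reproduces the standard 137-of-144 pool
shape.

Barcodes are drawn by rejection sampling so that every pair differs at
`min_hamming` ≥ 3 positions (default length 8 nt). With
`max_mismatch < min_hamming / 2` during demultiplexing, every single-base
sequencing error still has a unique nearest barcode, so assignment is
provably unambiguous. Assignment is deterministic under its seed and fails
loudly (rather than truncating) when the requested number of barcodes cannot
be placed.

# Normalized delivery

For sorted sample $s$ with barcode proportions $p_{is}$ and input-pool
proportions $q_i$, the normalized delivery of LNP $i$ is

$$\mathrm{ND}_{is} = 100 \cdot
  \frac{p_{is}/q_i}{\sum_{j \in \mathrm{retained}} p_{js}/q_j}.$$

This ratio-then-renormalize form is the minimal procedure consistent with
the term "normalized delivery" and its conventional 0–100 display scale;
retained LNP scores sum to exactly 100 per sample, an invariant asserted
throughout the package. Two consequences worth knowing:

* **Scale invariance** — multiplying a raw counts column by any positive
  constant leaves ND unchanged, so sequencing depth differences between
  samples do not bias the score.
* **Relative score** — ND is a within-sample composition; comparisons across
  samples compare *shares* of delivery, not absolute delivery.

The naked (unencapsulated) barcode control is scored against the same input
pool but **excluded from the renormalization denominator** and reported
separately (`naked_control_nd`, and `naked_control_pct` on the LNP scale for
display). Including the control would inflate every LNP score by a constant
factor wherever the control performs poorly — which it is designed to do; it
serves as a floor, not a competitor.

QC precedes normalization: barcodes whose input-pool proportion falls below
half the uniform expectation (default, configurable) are dropped before
rescaling — a barcode underrepresented in the pool has an unstable
denominator — and samples with fewer than $10^4$ assigned reads (default)
are excluded. Both bounds are inclusive at the threshold. Normalization is
per sample; mouse averaging (`aggregate_mice()`: mean, SEM $= s/\sqrt{n}$,
and $n$ per LNP × cell type) happens afterwards. SEM is reported as missing
for a single mouse rather than 0.

# Decile enrichment

For a chemical property value $v$ with library frequency $f_v$, enrichment
in a subset $S$ is

$$e_v(S) = \frac{\text{freq of } v \text{ in } S}{f_v},$$

so $e = 1$ is chance level, and fold enrichment is
$e_v(\mathrm{top}) - e_v(\mathrm{bottom})$ over the top and bottom
$\lceil 0.1 N \rceil$ LNPs by normalized delivery. The identity
$\sum_v f_v\, e_v(S) = 1$ holds exactly for any subset and any partition
into property values, and $|{\rm fold}| \le 1/f_v$; both are exercised as
properties in the test suite. A difference version of enrichment
(subset frequency minus library frequency) was considered and rejected as
the default because the ratio makes "relative to chance" read directly as
$e = 1$.

**Ties and set sizes.** Scores are passed through one stable descending sort
(ties broken by design order); the top decile is the head and the bottom
decile the tail of that single ordering. This keeps the two sets disjoint
even when all scores tie, and makes results reproducible without
randomness. Per-tissue summaries (`tissue_fold()`) average per-cell-type
folds with equal weight per cell type.

**Permutation test.** Significance comes from permuting property labels
against the (fixed) decile membership. The fold statistic is discrete — it
counts labels in two small sets — so ties between permuted and observed
statistics are routine, and the conservative tie-inclusive p-value
$(1 + \#\{|{\rm fold}^\ast| \ge |{\rm fold}|\})/(1 + B)$ is **super-uniform**
under the null: its distribution has substantial atoms (e.g. at $p = 1$
whenever the observed fold is exactly 0), which is valid for type-I control
but visibly non-uniform. `permutation_pvalue(..., ties = "random")` instead
resolves the observed statistic's rank within its tie group uniformly at
random, which is the standard construction giving an exactly
discrete-uniform p under exchangeability. The conservative form is the
default (it never understates evidence); the randomized form is what should
be used when calibration matters, e.g. when comparing p-values across many
properties. The test suite verifies the randomized form is KS-uniform under
an independent-label null and that the conservative form dominates it.

# Single-cell delivery readout

The reporter transcript (an anchored-VHH pseudogene, `aVHH` by default) is
carried as an ordinary gene row in a sparse genes × cells matrix with
cluster and treatment-group labels supplied as inputs — clustering and
embedding are upstream, out of scope. `percent_positive()` reports the
percentage of cells with reporter count ≥ `min_count` (default 1; a
detection threshold, deliberately permissive for shallow single-cell
libraries) per cluster × group, omitting empty strata rather than reporting
0 for them.

`differential_expression()` standardizes on the most common scRNA-seq
default: counts are scaled to a fixed per-cell total ($10^4$) and
log1p-transformed, each gene gets a two-sided Wilcoxon rank-sum p-value, a
Benjamini–Hochberg q-value over the tested genes, and a log2 fold change of
group means with pseudocount 1. Genes expressed in fewer than 5% of the
filtered cells (default) are excluded and reported, which protects the
rank-sum test from all-tie degeneracy. Both raw p and q are emitted because
volcano-style gene selections conventionally filter on raw p < 0.05 while
formal claims should use q. `top_upregulated()` ranks positive-fold genes by
ascending p, breaking ties by descending |log2FC|.

`ora_hypergeometric()` is a plain upper-tail hypergeometric
overrepresentation test of a query list against GMT gene sets intersected
with a user-supplied background. No pathway database is bundled: database
content and versioning are outside reproducibility control, so the "pathway
universe" is whatever GMT the user provides. The default enrichment flag
threshold is p < 0.001.

# The synthetic-data generators

The generators exist so that every downstream stage can be scored against a
known truth; all are pure functions of their configuration and seed.

**Screen counts.** Per-LNP potency in a cell type is
`baseline × charge_tissue_effect[charge, tissue] × lipid_effect[lipid] ×
exp(N(0, lnp_noise_sd))`, with one lognormal factor per LNP. The default
effect table encodes the qualitative tropism a charge-varied screen is
designed to detect — cationic × lung ≫ 1 (default 50), neutral/anionic ×
liver > 1 (default 10) — and the default `lipid_effect` makes one cationic
lipid (the DDAB analog) uniformly ×3 stronger, so lipid-level enrichment has
a recoverable planted truth even within a single-charge library, where the
charge × tissue term alone cancels out of within-library comparisons. The
naked control's multiplier is 0.01. These magnitudes are synthetic modelling
choices, not measured estimates. Input-pool proportions are drawn
near-uniform (Dirichlet, concentration 100/barcode; `Inf` = exactly
uniform). Each sorted sample draws proportions from a Dirichlet centred on
the potency-weighted input proportions (concentration 200 by default) and
counts from a multinomial at the configured depth — a Dirichlet-multinomial,
chosen over a plain multinomial because replicate mice are a design feature
and mouse-to-mouse overdispersion is the noise the aggregation step must
absorb. `overdispersion = Inf` recovers the multinomial limit used in
convergence tests. Default scale: 4 mice, 19 sorted cell types across 5
tissues, $10^5$ reads per sorted sample.

**FASTQ reads.** One read per counted barcode occurrence, laid out as
upstream anchor + barcode + downstream anchor (8 nt each by default — the
true amplicon architecture of barcode screens varies, so the layout is a
`barcode_spec()` the user controls), with i.i.d. per-base substitution
errors. No quality-score realism, indels, or paired ends are simulated;
demultiplexing ignores qualities by design, so these would exercise nothing.

**Cell-by-gene matrices.** Negative-binomial background genes (lognormal
per-gene means, size 2 by default), a planted block of fold-changed genes
per treatment group, and a reporter row drawn
`Bernoulli(capture_prob) × (1 + Poisson(1))` per cell with cluster ×
group-specific capture probabilities (endothelial clusters 0.6 under the
cationic treatment, 0.05 elsewhere, 0.02 under neutral/anionic, 0 under
PBS — synthetic magnitudes mirroring endothelial-first lung delivery).

**What passing on synthetic data does and does not show.** The generators
reproduce the *statistical shape* of a screen — compositional counts,
overdispersed replicates, a potency-ranked truth, planted DE — so passing
tests demonstrate the estimators are correct and calibrated under that
model. They do not emulate amplification bias, barcode cross-talk,
index hopping, doublets, ambient RNA, or cell-type-specific library size,
so agreement here does not certify behaviour on real sequencing data with
those artefacts.

# Numerical and scale choices

Default problem sizes were chosen so the whole validation suite runs in
well under a minute of simulation per stage while leaving comfortable
statistical margins: convergence checks use depth $10^6$ (multinomial noise
≈ 0.1 ND units, against a 1-unit tolerance), demultiplexing accuracy uses
$10^5$ reads (per-barcode loss at 1% substitution error ≈ 0.8–1.3%, against
a 2% bound), null calibrations use ≥ 1000 genes or 200 repetitions.
Degenerate inputs fail explicitly rather than propagating: all-zero count
columns, empty groups, infeasible barcode designs, unknown genes, and
queries outside the ORA background all raise errors naming the problem.

# Known limitations

* ND is compositional; treating it as an absolute delivery measurement is a
  user error the package cannot prevent.
* The enrichment statistic conditions on fixed decile membership; an
  alternative that propagates score uncertainty into set membership (e.g.
  bootstrap over mice) is out of scope.
* The rank-sum DE test treats cells as independent; with few mice per group
  a pseudobulk analysis would guard against pseudoreplication, but per-mouse
  identity is not part of the single-cell container here.
* Barcode demultiplexing handles substitutions only; indel-tolerant matching
  would require alignment and is not implemented.
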