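---
title: "Methods: plasticity, thermal tolerance, and selection in urban heat islands"
author: "plastisel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasticity, thermal tolerance, and selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(plastisel)
```

# The inference chain

`plastisel` connects four questions that together test whether urban
lineages of a heat-stressed ectotherm evolved by reducing or reversing
maladaptive expression plasticity:

1. *Which genes underlie heat tolerance?* Genes whose expression correlates
   with the critical thermal maximum (CT_MAX) across all animals, selected
   at FDR 0.05 applied within co-expression modules.
2. *Is the ancestral plastic response to heat adaptive or maladaptive?*
   Each candidate's common-garden 25→32 °C response is scored against the
   sign of its CT_MAX association.
3. *Did urban lineages evolve away from that response?* The correlation
   between ancestral plasticity and evolved divergence, judged against a
   permutation null that reproduces the statistical artifact inherent in
   the design.
4. *Is there genomic evidence of selection?* F_ST, LD, Hardy–Weinberg and
   annotation-class contrasts between plasticity classes and the
   transcriptome background.

The stages are exposed as standalone functions and orchestrated by
`run_pipeline()`, which takes a single `plastisel_config()` and is
reproducible bit-for-bit under a fixed seed.

# The co-expression screen

Expression is library-size normalized to
`log2(count / libsize × 1e6 + prior)` with the prior (default 1) added
*after* CPM scaling: a zero count maps to 0 and normalization is strictly
increasing within a sample. No TMM or quantile step is applied — the
downstream statistics are correlations and group-mean differences, which
only require a monotone within-sample transform and comparable scales
across samples. Genes with all-zero counts are dropped (with a warning)
because zero-variance rows are undefined under correlation.

The network is unsigned — adjacency `|cor|^β` with Pearson correlation and
default `β = 6`, the long-standing convention for unsigned weighted
networks — while the *sign* of the gene–trait relationship is kept in the
gene-significance table, where the positive/negative regulator distinction
lives. `choose_soft_power()` implements the usual scale-free-fit scan
(smallest power whose fit R² ≥ 0.8 over ≥ 10 connectivity bins, falling
back with a warning to the best-fitting power) for users who prefer a
data-driven β.

Topological overlap uses the standard formula with the shared-neighbour sum
over `u ∉ {i, j}` and connectivity excluding the diagonal; the matrix
identity used in the implementation is checked in the test suite against a
literal triple loop at 1e-12. Modules are branches of average-linkage
clustering on `1 − TOM`, obtained by a static cut at height 0.99 with a
30-gene minimum size — the deterministic "tree" variant of dynamic tree
cutting, chosen over the hybrid PAM-like variant because it is exactly
reproducible and directly testable; branches below the minimum size get
label 0 (unassigned) and are treated as their own group in the FDR step.
Eigengenes are unit-norm first principal components of the gene-standardized
module expression, sign-oriented along the module's mean standardized
profile (a single-gene module yields its standardized profile). Modules
whose eigengenes satisfy `r² ≥ 0.75` (`|r| ≥ 0.866`) merge iteratively,
most-correlated pair first, with eigengenes recomputed after every merge.

Gene significance is the signed Pearson correlation with CT_MAX, with
two-sided p-values from the t distribution on `n − 2` df. Correction is
Benjamini–Hochberg *within* each module: modular expression structure makes
the global BH assumption (exchangeable hypotheses) questionable, and the
within-module variant conditions the correction on the regulatory
architecture. Candidates are genes with `q < 0.05`.

# Plasticity classification

The decision rule is a pure sign comparison: adaptive iff
`sign(LFC_25→32) == regulator sign`. The indeterminate band `ε` defaults to
0 — every non-zero LFC is classified, so the adaptive and maladaptive
fractions sum to 1 over determinate calls, and exact-zero LFCs are recorded
as indeterminate rather than silently assigned. Urban calls reuse the
regulator classes estimated from the full cohort (not urban-specific GS):
the question is how the *same* regulators behave in the derived lineage.

Within-lineage imbalance is tested by the exact binomial against 0.5;
between lineages both the exact binomial (urban adaptive count against the
forest adaptive proportion) and the two-proportion χ² with continuity
correction are reported, since both phrasings are current in the
literature. The magnitude contrast is Welch's t on |LFC|; if both groups
are degenerate (zero variance) the function warns and returns p = 0 or 1
by the sign of the mean difference rather than dividing by zero.

# The plasticity–divergence correlation and its null

Ancestral plasticity is the forest common-garden 25→32 °C LFC; evolved
divergence is urban − forest at 32 °C. Because both contrasts contain the
forest-32 group with opposite signs, independent noise alone produces a
negative correlation (regression toward the mean): with group sizes
(3, 4, 4) the expected artifact correlation on pure noise is about −0.45.
The null distribution must therefore reproduce the artifact rather than
center on zero. The randomization permutes each gene's expression values
independently across the common-garden samples: each gene's value multiset
is preserved (so the null keeps every gene's marginal distribution) while
the gene–group association is destroyed. Among the alternatives (global
matrix shuffle, within-sample shuffle) this is the scheme under which the
shared-group artifact survives in the null, which is exactly what the test
requires; the choice is recorded here because the community-ecology
randomization utilities this mirrors offer several null models without a
single canonical default.

Spearman's ρ is the Pearson correlation of mid-ranks; the p-value uses the
t approximation. The empirical p is one-sided ("more negative than the
artifact") with the add-one rule `p = (1 + #[ρ_null ≤ ρ_obs]) / (B + 1)`,
so p can never be exactly 0; B defaults to 1000. The test suite verifies
(i) that on pure-noise matrices both observed and null ρ are negative and
the rejection rate at α = 0.05 stays within the binomial 95 % interval over
100 replicates, and (ii) that ρ with ties matches a rank-enumeration
oracle.

# Population genomics

Filters follow the conventional RNA-seq genotyping thresholds: quality ≥ 20
(inclusive), minor allele frequency ≥ 0.05 (inclusive, computed from
non-missing genotypes across all samples), missingness strictly below 0.20.

F_ST is the two-population Weir–Cockerham single-locus θ (the
variance-components estimator of the AMOVA family), computed per SNP from
sample sizes, allele frequencies and observed heterozygosity, dropping
missing genotypes per SNP. Negative estimates are *retained*: clamping at
zero would bias upward every mean-F_ST contrast between SNP sets. θ is NA
when a population has no called genotypes, fewer than three genotypes are
called in total, or the locus is monomorphic. Per-SNP θ feeds the outlier
and contrast analyses (as per-SNP scans do); for recovering a planted
divergence parameter the multi-locus ratio-of-sums estimator
(`fst_overall()`) is the right tool — the mean of per-SNP ratios is biased
downward at realistic sample sizes (≈ 0.10 for a true 0.12 at n = 40/40),
a known property of ratio estimators, and the test suite checks the
multi-locus estimator against the planted Balding–Nichols parameters to
±0.01 at 10,000 SNPs.

Kernel smoothing is a Gaussian-weighted mean along each scaffold
(`w = exp(−d²/2σ²)`, truncated at 4σ); σ → 0 returns the raw track and
σ → ∞ the scaffold mean, both asserted numerically. The genome-scale
convention of σ = 5 Mb is available as a flag; on the compact synthetic
scaffold (genes tiled every 100 kb) the pipeline default is σ = 50 kb so
that smoothing is actually exercised at the data's own scale.

Outliers are SNPs beyond the `1 − α` empirical quantile (type-7 linear
interpolation, the stats::quantile default, recorded here deliberately) of
the *background* θ distribution; set-vs-background outlier proportions and
class enrichments use the two-proportion χ² with continuity correction,
with a Wilson 95 % CI on the focal proportion.

LD is the squared Pearson correlation of unphased genotype dosages
(RNA-seq genotypes are unphased; dosage r² is the standard surrogate for
haplotype r²), over all SNP pairs inside the same non-overlapping 10 kb
window, binned at 1 kb (left-closed, right-open: 999 bp → bin 0, 1000 bp →
bin 1). Pairs with an undefined correlation (a SNP monomorphic within the
jointly-called samples) are skipped and counted. The candidate-vs-background
contrast is tested by *gene-block* permutation of gene labels with the
two-sided empirical p on the mean-r² difference: permuting whole genes
preserves the strong non-independence of pairs within a gene exactly,
which a naive pair-level test would ignore; the crossed-random-effects
mixed model used elsewhere for this contrast is recorded in the report
metadata as the alternative (fitting it adds an iterative REML solver and
no exactness guarantee, so the permutation is the package's default).

Hardy–Weinberg deviations use the 1-df χ² against expectations from the
population allele frequency; expected cells below 5 are flagged
`low_count` but still computed (transcriptome-scale scans involve thousands
of SNPs where the flag, not an error, is the useful behaviour). In the
pipeline, populations are the municipalities (urban + forest pooled), so
divergent SNPs show Wahlund-effect heterozygote deficits — which is why
candidate genes show more deviations when habitat divergence is planted.

# The synthetic-data generator

The generator is first-class, tested code: its role is to produce datasets
whose ground truth is known so that every downstream stage can be judged by
parameter recovery.

**Design emulated.** 114 wild animals across four municipality pairs
(11/16, 18/16, 12/9, 11/21 forest/urban — the 12/9 pair plus the 16-animal
common-garden colony brings that municipality to 19/18 genotyped animals),
three acclimation treatments (night 15 °C, day 25 °C, day 32 °C; the
common garden uses only the day treatments, split 3/4 forest and 5/4
urban), CT_MAX from a truncated normal (mean 39 °C, sd 1.5 °C, bounds
35–43 °C).

**Expression model.** Counts are negative binomial with lognormal gene-wise
dispersion (meanlog log 0.1, sdlog 0.5) and lognormal library-size factors —
the standard bulk RNA-seq noise model. On the log2 scale a gene's mean is
`baseline + loading·module factor + b·z(CT_MAX)·sign + reaction norm +
noise`:

* Seven latent module factors with loadings of sd 1.1 log2 units give
  within-module correlations near 0.55 — strong enough for module detection
  at the default static cut, weak enough that module-level noise does not
  dominate individual reaction norms.
* Candidates couple to standardized CT_MAX at `b = 0.8` log2 units per SD
  with the planted regulator sign; realized gene-significance correlations
  land near 0.4, typical of reported expression–phenotype candidates.
* The reaction norm displaces the 32 °C treatment by ±2.5 log2 units
  (heat-shock-scale swings) in the forest direction, which opposes the
  regulator sign with probability 0.8; the urban norm is attenuated ×0.5
  and flips direction with probability 0.5, planting forest ≈ 80 % and
  urban ≈ 50 % maladaptive fractions.
* Common-garden animals draw CT_MAX with half the wild sd (0.75 °C):
  shared rearing removes most environmental variance in thermal tolerance.
  This matters statistically as well as biologically — with 3–5 animals per
  treatment group, wild-scale CT_MAX variance would leak through the
  coupling term into the group LFCs and blur the planted reaction-norm
  directions.

**Genotype model.** Genes tile one synthetic scaffold at 100 kb spacing
with 10 kb spans; SNPs (20,000 by default) fall uniformly within spans.
Allele frequencies follow the Balding–Nichols construction: ancestral
frequency Uniform(0.1, 0.9), habitat-specific frequencies Beta-distributed
around it with the divergence parameter equal to the planted F_ST of the
SNP's set (background 0.02, adaptive 0.06, maladaptive 0.12), drawn
independently per municipality — so each urban–forest pair has expected
Weir–Cockerham θ equal to the planted parameter. A planted divergence of 1
fixes the habitats for alternate alleles. Haplotypes (two per animal)
follow a latent Gaussian autoregression along each gene with per-kb
autocorrelation 0.5 (background) or 0.9 (candidate genes), giving
distance-decaying within-gene LD and the planted candidate LD elevation;
genotypes are Hardy–Weinberg within populations by construction.
Functional classes are drawn per set (noncoding 0.5 background / 0.7
maladaptive; nonsynonymous 0.25 background / 0.45 adaptive). Genotypes are
masked at 5 % missingness.

**What the generator does not emulate.** No read-level noise or mapping
bias; no sequence content (REF/ALT are placeholders); library composition
is stable except for the planted reaction norms; no linkage between genes
(100 kb spacing, independent draws); no shared demography beyond the
municipality structure; CT_MAX is generated first and expression
conditioned on it, so the causal arrow is fixed by construction. Passing
the recovery suite therefore demonstrates that the estimators and decision
rules are correct and well-calibrated under the assumed noise model — not
that the pipeline is robust to alignment artifacts, batch structure, or
expression-phenotype feedback in real data.

# Problem sizes and runtime choices

The default configuration (5,000 genes × 130 samples, 600 candidates,
20,000 SNPs, 1000 permutations) runs the full pipeline in well under a
minute on a single core and is the size at which the recovery suite and the
acceptance script operate. Unit fixtures are much smaller (tens to hundreds
of genes; ≤ 10-sample genotype tables for the estimator oracles). The dense
adjacency/TOM path refuses more than 20,000 genes unless the guard is
raised explicitly, since memory grows quadratically.

# Known limitations

* Module detection uses the static-cut tree variant; very nested module
  structures that the hybrid dynamic cut would split are returned as single
  branches.
* The per-SNP θ estimator carries the usual small-sample downward bias in
  set means; contrasts between sets at equal sample sizes are unaffected,
  but absolute per-SNP means should not be read as unbiased estimates of
  the divergence parameter (use `fst_overall()` for that).
* The LD contrast's gene-block permutation tests exchangeability of whole
  genes between sets; it does not model distance explicitly (the per-bin
  summaries are descriptive).
* With ε = 0 the classifier assigns a direction to arbitrarily small LFCs;
  the indeterminate band exists for robustness analyses but is not part of
  the default decision rule.
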