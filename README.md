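# plastisel

Multi-stage inference linking heat-induced gene-expression plasticity to
thermal-tolerance adaptation across paired urban–forest populations.

Urban heat islands expose ectotherm populations to a novel selective
environment. A recurring question in evolutionary physiology is whether the
expression plasticity ancestral (forest) lineages deploy under heat stress
helps or hurts — and which kind of plasticity selection acts on as urban
lineages diverge. `plastisel` implements, as tested reusable R functions,
the full analysis chain this question requires, for researchers working with
bulk RNA-seq, a continuous thermal-tolerance phenotype (CT_MAX, the critical
thermal maximum), and RNA-seq-derived SNP genotypes:

1. **Candidate screen.** A signed weighted co-expression network
   (adjacency `a_ij = |cor(x_i, x_j)|^β`, topological overlap
   `TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
   average-linkage clustering of `1 − TOM` with a dynamic tree cut and
   eigengene merging at `r² ≥ 0.75`), gene significance
   `GS_g = cor(x_g, CT_MAX)`, and Benjamini–Hochberg FDR applied **within
   each module** (candidates at `q < 0.05`; positive/negative regulators by
   the sign of GS).
2. **Plasticity classification.** Per lineage, each candidate's
   common-garden 25→32 °C log₂ fold change is scored against its regulator
   class: a positive regulator that rises with heat (or a negative regulator
   that falls) shows *adaptive* plasticity; the opposite pairings are
   *maladaptive*. Exact binomial and equality-of-proportions tests compare
   the forest and urban call fractions; Welch's t compares |LFC| magnitudes.
3. **Plasticity vs. evolved divergence.** Spearman's ρ between ancestral
   plasticity (forest common-garden 25→32 °C LFC) and evolved divergence
   (urban − forest LFC at 32 °C), tested against a 1000-permutation
   matrix-randomization null (independent within-gene permutation) that
   absorbs the regression-toward-the-mean artifact created by the shared
   forest-32 °C group.
4. **Population-genomic battery.** SNP filtering (quality ≥ 20, MAF ≥ 5 %,
   < 20 % missing), per-SNP two-population Weir–Cockerham θ with optional
   Gaussian-kernel smoothing, empirical-percentile F_ST outlier enrichment
   by plasticity class, Welch contrasts of mean F_ST, pairwise genotypic
   r² in non-overlapping 10 kb windows binned at 1 kb with a gene-block
   permutation test, Hardy–Weinberg χ² scans, and continuity-corrected
   two-proportion tests of nonsynonymous/noncoding class enrichment.

A seeded synthetic-data generator (`sim_config()`, `simulate_expression()`,
`simulate_variants()`) reproduces the study design — 114 wild animals from
four municipality pairs, a 16-animal common-garden colony, negative-binomial
counts with planted CT_MAX coupling and reaction norms, Balding–Nichols
habitat divergence, haplotype-block LD — so every stage is verifiable by
parameter recovery without any external download.

## Worked example

```r
library(plastisel)
config <- plastisel_config(sim = sim_config(), n_perm = 200, seed = 7)
report <- run_pipeline(config, quiet = TRUE)
print(report)
```

```
plastisel pipeline report (seed 7, config 66894858)
  5000 genes x 130 samples; 8 modules (beta = 6)
  candidates: 601
  maladaptive plasticity: forest 79.0%, urban 54.9%
  ancestral vs evolved rho = -0.803 (null 95% [-0.502, -0.374], empirical p = 0.0050)
  Aguadilla: mean FST bg 0.016 / adaptive 0.048 / maladaptive 0.098
  Arecibo: mean FST bg 0.016 / adaptive 0.050 / maladaptive 0.091
  Mayaguez: mean FST bg 0.017 / adaptive 0.039 / maladaptive 0.099
  SanJuan: mean FST bg 0.018 / adaptive 0.049 / maladaptive 0.103
  LD contrast: diff = 0.0681, empirical p = 0.0050
```

Reading the report: the screen recovered 601 candidate genes (600 were
planted); the forest lineage's heat response is predominantly maladaptive
(79 %, planted 80 %) while the urban lineage's is attenuated toward 50 %;
ancestral plasticity and evolved divergence are strongly negatively
correlated and the observed ρ falls below the entire randomization null
(which is itself negative — the shared-group artifact the null is built to
absorb); and per-SNP F_ST recovers the planted divergence ladder
(background 0.02 < adaptive 0.06 < maladaptive 0.12, attenuated by the
per-SNP estimator's small-sample bias) in every municipality, with elevated
within-gene LD at candidate genes.

Each stage is also callable on its own (`normalize_counts()`,
`build_adjacency_tom()`, `gene_significance()`, `classify_cohort()`,
`randomization_null_test()`, `weir_cockerham_fst()`, `pairwise_ld()`,
`hwe_scan()`, ...); `write_dataset()` / `read_dataset()` round-trip the
counts TSV / metadata TSV / VCF v4.2 / BED / truth JSON file set, and
`inst/cli/plastisel.R` wraps simulation and the full run for shell use.

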