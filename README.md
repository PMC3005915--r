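# diseasome

Cross-comparison of gene age, regulation, tissue specificity and disease
association in hereditary-disease gene sets.

## The problem

Human disease genes (the "diseasome") differ systematically from the rest of
the genome: they tend to be evolutionarily old, broadly expressed or
conspicuously tissue-specific, long, well connected in interaction networks,
and enriched for regulatory function. Disentangling which of these
associations are direct and which are mediated by expression breadth
requires comparing *all* attributes against each other in one framework.
This package implements that framework for gene sets annotated with:

- **phylostratum of origin** `ps ∈ {1..19}` — OLD = originating in ps1–ps2
  (up to eukaryotes, before fungi), NEW = ps3–ps19;
- **expression breadth** over a 32-tissue panel — tissue-specific (TSP,
  expressed in < 14 tissues) vs housekeeping (HKP, ≥ 14); genes without
  expression data carry no tissue label;
- **expression level** (EXL/EXH, median split of per-gene summary
  abundance);
- **interaction status** (INT/NIN, membership in an undirected interaction
  network);
- **disease** (DIS/NDI), **transcription factor** (TFA/NTF), **PTM**
  (PTM/NPT), and their union the **regulator** class
  (REG = TFA ∪ PTM, via inclusion–exclusion |TFA ∪ PTM| = |TFA| + |PTM| −
  |TFA ∩ PTM|);
- **length** (SHO/LON at 24 kb).

The statistical core:

- the **unpooled two-proportion z-test**
  `z = (p₁ − p₂) / sqrt(p₁(1−p₁)/n₁ + p₂(1−p₂)/n₂)` with two-tailed normal
  p-values, fold changes and odds ratios, scanned over every
  level-vs-dichotomy pair of the contingency matrix;
- **Pearson and first-order partial correlations**
  `r_xy·z = (r_xy − r_xz r_yz)/sqrt((1−r_xz²)(1−r_yz²))` for testing whether
  associations with gene age survive conditioning on expression breadth;
- **least-squares means** of network degree from an additive factorial
  linear model (age × regulator × specificity × disease), with two-sided
  t-tests on contrasts;
- **age-assortative mixing**: observed old–old/old–new/new–new edge
  fractions against the degree-weighted proportionate-mixing expectation,
  with a label-permutation test; partner-phylostratum profiles and
  within-class cohesion (edge density);
- per-phylostratum regulator profiles with genome-wide 95 % bands,
  per-tissue attribute profiles, chromosome age×disease class maps, and
  deterministic two-way hierarchical clustering (UPGMA with an explicit
  lowest-index tie-break) of the chromosome-by-tissue expression matrix.

A seeded **synthetic-data generator** (`generator_config()`,
`generate_gene_table()`, `generate_interactions()`) emulates the
statistical structure of the merged 12,753-gene human dataset such studies
are built on (age-dependent disease enrichment, breadth structure,
stratum-dependent TF/PTM rates, age/regulator-dependent connectivity with
age homophily), and the published summary contingency table ships as an
embedded fixture (`load_table1_fixture()`).

## Worked example

```r
library(diseasome)

# the embedded 12,753-gene summary table
cm <- load_table1_fixture()
rd <- regulator_disease_comparison(cm)
rd
#> two-proportion z-test (unpooled): 797/2556 (0.312) vs 1725/10197 (0.169)
#>   z = 14.4290, two-tailed p = 3.402e-47, fold = 1.843, OR = 2.225

round(crosstab_summary(cm)$tfa_overall_pct, 1)
#> [1] 7.8
```

Disease genes make up 31.2 % of regulators but only 16.9 % of
non-regulators — the regulator class reconstructed by inclusion–exclusion
from the TF (999) and PTM (1785) totals and their overlap (228).

A full synthetic run:

```r
cfg <- generator_config(seed = 1)          # 12,753 genes, 55,606 edges
bundle <- run_pipeline(generator = cfg, out_dir = "out", seed = 1)
subset(bundle$lsmeans$means, factor == "age")
#>   factor level    lsmean        se    n
#> 1    age   OLD 11.829273 0.2307374 4278
#> 2    age   NEW  7.583153 0.2912879 2155
bundle$mixing
#>          oldold oldnew newnew
#> observed 0.5882 0.3466 0.0652
#> expected 0.5799 0.3632 0.0569
#> within-class excess = 0.0166, permutation p = 0.000999 (1000 shuffles)
```

Old genes carry ~50 % more connections than new genes after adjusting for
regulator status, specificity and disease, and same-age edges exceed the
degree-weighted mixing expectation — the structure the generator plants and
the pipeline recovers.

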