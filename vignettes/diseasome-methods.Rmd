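---
title: "Methods: cross-comparing gene attributes in the diseasome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-comparing gene attributes in the diseasome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diseasome)
```

## The analysis in one paragraph

Each gene carries a phylostratum of origin (1–19), a vector of per-tissue
abundances over a 32-tissue panel, a length, a chromosome, and disease /
transcription-factor / PTM annotations. `derive_attributes()` turns these
into nine binary dichotomies; `build_contingency()` cross-tabulates all 18
level codes against each other; `enrichment_scan()` tests every
level-vs-dichotomy comparison with the unpooled two-proportion z-test;
`correlation_matrix()` measures the same associations as (point-biserial)
Pearson correlations and re-measures them as partial correlations
conditional on expression breadth; `lsmeans_connectivity()`, `age_mixing()`,
`partner_stratum_profile()` and `cohesion()` analyse the interaction
network; `stratum_regulator_profile()`, `tissue_profiles()`,
`chromosome_class_distribution()` and `hierarchical_cluster()` profile the
attributes across phylostrata, tissues and chromosomes. `run_pipeline()`
chains all of it and writes TSV/JSON artifacts whose metadata headers record
the seed and every choice the input data do not fix.

## Dichotomisation thresholds

All cuts are parameters of `attribute_thresholds()`; the defaults are the
conventional ones for this kind of dataset:

* `age_ps_max = 2` — OLD means originating in phylostrata 1–2 (up to
  eukaryotes, before fungi); everything later is NEW.
* `hk_min_tissues = 14` (of 32) — housekeeping means expressed in at least
  14 tissues; fewer is tissue-specific. Breadth counts tissues with
  abundance strictly above zero. Genes with an all-zero abundance vector
  have *no expression data*, not breadth-0 expression: they are labelled
  MISSING on both tissue-based dichotomies and excluded from any
  tissue-involving denominator.
* `long_min_kb = 24` — the length split. The convention leaves genes of
  exactly 24 kb unplaced ("shorter/longer than"); we class them SHO
  (≤ 24 kb). The choice is configurable and recorded in output headers.
* Expression level (EXL/EXH) has no established cutoff at all. We use a
  median split of each gene's summary abundance, computed over expressed
  genes only, with the summary statistic configurable (`max` across
  tissues by default, `mean` available). A median split is the only rule
  that reproduces the near-equal class sizes such tables show; outputs
  flag it as an implementation choice.
* REG is the union TFA ∪ PTM; when only marginal totals and the overlap
  are known, `regulator_union()` applies inclusion–exclusion, and
  `regulator_disease_comparison()` extends it to the disease×regulator
  joint count via the three-way overlap.

## The statistical machinery

**Two-proportion z-test.** `two_proportion_ztest()` uses the unpooled
standard error `sqrt(p1(1-p1)/n1 + p2(1-p2)/n2)`, two-tailed normal tails,
no continuity correction — the plain "unequal group variances" test. When
both proportions are equal and the SE degenerates to zero, z = 0 and p = 1.
The informal guide that two proportions on 1,000+ records differing by more
than two points are significant is carried as a report column
(`guide_2pct`), never as the decision rule. The scan reports raw p-values
at α = 0.05 by default because that is how such analyses were originally
run; a Benjamini–Hochberg switch (`bh = TRUE`) is provided for modern
practice. Comparisons with unrecorded cells or empty denominators are
returned flagged `evaluable = FALSE` rather than dropped.

**Correlations.** Dichotomies are coded 0/1 (OLD, DIS, REG, INT, TFA, PTM,
HKP, EXH = 1), so the Pearson coefficient is the point-biserial/phi special
case; p-values come from the t transform on n−2 (n−3 when conditioned)
degrees of freedom. The first-order partial correlation uses the standard
closed form; tests verify it against residualisation to 1e-10. Genes with
MISSING tissue status are dropped listwise from any computation involving
breadth. One degenerate corner is worth spelling out: when x or y is
exactly collinear with the conditioning variable, the closed form is 0/0 —
but its numerator vanishes identically, so the value "fully explained,
r = 0" is returned; a blow-up with a non-vanishing numerator (only possible
numerically) raises a degenerate-conditioning error.

**Least-squares means.** Degree is modelled by an additive linear model on
the crossed factors (age, regulator, specificity, disease by default),
because per-factor adjusted means "after adjusting for the other
variables" are exactly what main-effects adjustment produces; two-way
interactions are available (`two_way = TRUE`). The LS mean of a level is
the model prediction averaged over an equally-weighted grid of the other
factors' levels — under perfect balance this collapses to the raw group
mean, and on a saturated 2×2 it is the plain average of the level's cell
means, which is what the tests pin down (and cross-check against emmeans).
Degree enters untransformed by default for fidelity to how such models are
usually reported; `log1p_response = TRUE` exists because count responses
are skewed. Only interacting genes enter by default (degree-0 genes are a
structural zero class, not a low-connectivity one). Aliased coefficients
from empty design cells raise an explicit inestimability error.

**Age mixing.** Expected edge-class fractions come from degree-weighted
proportionate mixing: with `s` the old-class share of edge stubs, expected
old–old = s², old–new = 2s(1−s), new–new = (1−s)². The within-class excess
(observed − expected summed over the two diagonal classes) is tested by
shuffling age labels over genes; the expectation is recomputed inside every
shuffle, so the p-value is exact for the label-assignment null given the
graph. "Cohesion" has no canonical formula; we operationalise it as
within-class edge density (within-edges / C(n,2)), reported alongside the
between-class density and their ratio, and the definition is printed in
the output.

## Stratum profiles and the flagging rule

`stratum_regulator_profile()` draws the genome-wide TF and PTM proportions
with the normal-approximation band `p ± 1.96·sqrt(p(1−p)/N)` (N = all
genes) — the flat reference lines of the classic stratum-profile figure; a
Wilson band is available. Flagging a stratum as over/under-represented is
a different question from drawing the band: a stratum proportion computed
on n_s genes fluctuates with standard deviation `sqrt(p(1−p)/n_s)`, far
wider than the N-based band, so comparing it to the band would flag most
strata on pure noise. The default flag therefore tests the stratum against
the genome-wide estimate using the exact null standard error of their
difference, `sqrt(p̂(1−p̂)(1/n_s − 1/N))` (the 1/N term accounts for the
stratum's own contribution to p̂), which calibrates the flag rate to the
nominal 5 % under a uniform-rate null — the acceptance suite verifies this
over 200 simulations. `flag_method = "band"` restores the figure-literal
rule for display purposes. Empty strata report NA, never zero.

For tissue profiles, the "share of other tissues where a tissue's genes
are also expressed" panel is ambiguous in the source phrasing; we compute
mean breadth of the tissue's expressed genes divided by the tissue count,
and record that reading in the output metadata.

## Chromosome maps and clustering

`chromosome_class_distribution()` tallies the four age×disease classes per
chromosome with binomial SEs on the disease proportion and sample-SD/√n
SEs on mean length. The chromosome-by-tissue count matrix is clustered
with an in-package agglomerative routine rather than `stats::hclust`
because the contract here includes an explicit deterministic tie-break
(merge the pair whose smallest original indices are lexicographically
least), which makes the merge tree invariant to input row permutation even
on tied distances (identical rows, constant matrices — the latter are
flagged degenerate). On tie-free data it reproduces `hclust` exactly, and
the tests check both. Defaults: UPGMA (average linkage) on Euclidean
distances of row-standardised counts — standardisation because heat-map
comparisons of this kind are relative, not absolute; raw counts and other
linkages are flags away, and every choice lands in the output metadata.
Trees export as Newick via ape.

## The synthetic generator

`generator_config()` defaults describe the study conditions the package is
meant to emulate, chosen once from the magnitudes such merged datasets
exhibit: 12,753 genes; 55,606 interactions; phylostratum weights putting
65.1 % of genes in ps1–2 with ~2 % at ps3 and a metazoan bump at ps5;
~45 % of genes without expression data (the gap between 12,753 genes and
the 6,976 covered by tissue dichotomies — the source tables themselves
leave that gap unreconciled, and `unexpressed_fraction` lets either total
be emulated); beta-binomial expression breadth, broader for old genes;
log-normal lengths with medians near 24 kb, longer for old genes; TF/PTM
stratum rates elevated at ps3/ps5 (TF) and ps5/ps11 (PTM) with a log-odds
overlap boost creating the TF∩PTM set; logistic disease probability with
positive OLD, TSP and REG effects; Chung–Lu-style edges whose propensities
multiply by configured OLD and REG effects, with an `age_homophily`
mixture parameter (0 = proportionate mixing, 1 = within-class only).
Everything is driven by one seed; the edge stream offsets it by one so the
table and network are jointly reproducible.

One generative detail is deliberate: `disease_breadth_slope` adds a
*linear-in-probability* breadth term to disease risk. Partial correlation
removes only linear structure, so constructing "disease depends on age
only through expression breadth" with a logistic step in TSP would leave a
small nonlinearity-induced residual association; the linear-probability
pathway makes the conditional independence exact, which is what the
mediation recovery check exercises (raw r(age, disease) strongly positive,
partial r given breadth within ±3 standard errors of zero at n = 20,000).

What the generator does *not* emulate: real marginals beyond order of
magnitude, MPSS tag structure, gene families or linkage disequilibrium,
chromosome-specific gene density (chromosome assignment is uniform unless
weighted), or any correlation structure it is not explicitly given.
Passing tests therefore demonstrate that the pipeline recovers planted
structure and stays calibrated under planted nulls — not that any
particular biological claim holds in real data. The published real-data
connectivity LS means (9.227 vs 6.1245 and kin) and per-chromosome
percentages require the external datasets and are format references only.

## Problem sizes and runtime choices

The test suite runs its heaviest checks at sizes chosen to make the
statistics decisive while keeping the whole suite interactive: parameter
recovery at 100 replicates of 2,000 genes / 8,000 edges; null calibration
of stratum flags at 200 replicates of 4,000 genes; mediation at 20,000
genes; mixing power at 10,000 genes / 40,000 edges with 199 permutations;
permutation-uniformity at 60 small replicates. The acceptance script runs
the full 12,753-gene / 55,606-edge configuration (a few seconds) plus the
mediation configuration.

## Known limitations

* The pairwise contingency matrix cannot represent three-way joint counts;
  quantities needing them (e.g. disease enrichment among tissue-specific
  old genes) are computed from the attribute table directly, and are
  simply unavailable from a printed pairwise fixture.
* The z-test and the LS-means t-tests assume large-sample normality;
  degrees are skewed counts, so small-sample contrasts should be read with
  the `log1p` option in hand.
* Permutation and bootstrap intervals are seeded and replicate-count
  configurable, but remain Monte-Carlo estimates.
* The package ingests prepared TSVs; mapping raw OMIM/HPRD/MPSS resources
  into the gene-table schema is out of scope.
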