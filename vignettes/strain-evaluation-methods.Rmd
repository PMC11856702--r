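---
title: "Methods: composite fermentation scoring and group-discriminating variant contrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite fermentation scoring and group-discriminating variant contrast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermentrank)
```

# The problem

A strain-selection experiment measures a panel of product-quality indicators
for each candidate yeast strain — for leavened wheat products typically pH,
total titratable acidity (TTA, mL of 0.1-N NaOH per 10 g sample), specific
volume (mL/g) and texture-profile analysis outputs (hardness in N,
springiness, cohesiveness, gumminess, chewiness). Three features of such
panels motivate the pipeline implemented here:

* indicators are **redundant** (pH and TTA both track organic-acid
  production; hardness, gumminess and chewiness all track crumb firmness);
* indicators point in **different directions** (high volume is good, high
  hardness is bad);
* the end goal is a **single ranking** from which extreme strains are chosen
  for downstream comparative genomics.

# Indicator pruning

`correlation_matrix()` computes all pairwise Pearson correlations with
two-sided p-values from the t-transform on n − 2 degrees of freedom.
`prune_redundant()` then performs a greedy sweep in a user-supplied priority
order: an indicator is kept iff its |r| with every already-kept indicator is
below the threshold.

Two design choices were genuinely open:

* **Threshold 0.6 on |r|.** The 0.6–1.0 band is the conventional
  "interchangeable" range for these indicator families. We apply it to the
  absolute value: a strong negative correlation carries the same information
  as a strong positive one, so sign should not rescue an indicator from
  pruning.
* **An explicit priority list rather than an automatic representative
  rule.** Which member of a correlated block survives (TTA over pH; hardness
  over cohesiveness/gumminess/chewiness) is a judgment about measurement
  reliability and interpretability, not something the correlation matrix
  determines. Encoding it as a priority list makes the judgment visible and
  overridable; the default order (TTA, Volume, Hardness, Springiness, pH,
  Cohesiveness, Gumminess, Chewiness) reproduces the conventional four-
  indicator evaluation panel. Significance (p < 0.05) is reported but not
  used as a pruning criterion; redundancy is about effect size, not
  detectability.

# The composite score

After direction correction (`apply_directionality()`; by default only
hardness is flipped, since it is the only indicator whose "lower is better"
reading is uncontroversial across product types) and column z-scoring with
sample standard deviation (denominator n − 1), `pca_correlation()`
eigendecomposes the Pearson correlation matrix of the indicators. For
standardized data this is the natural PCA scale: eigenvalues sum to the
number of indicators, so λ > 1 (the Kaiser criterion, `kaiser_select()`,
strict inequality) reads as "this component carries more variance than one
original variable".

Loadings are scaled to variable–component correlations, so their squares —
the **Cos2** of each variable on each component — column-sum to the
eigenvalue and row-sum to 1. The composite coefficient for indicator j is

$$w_j = \sum_{i \in \text{retained}} \lambda_i \cdot \mathrm{cos}^2(x_j, \mathrm{PC}_i),$$

a non-negative weight that rewards indicators well represented on the
dominant retained components, and the score is the weighted sum of z-scores,
$y_s = \sum_j w_j z_{sj}$. This eigenvalue-weighted Cos2 definition is
identifiable from its own arithmetic: each component's weight vector sums to
that component's eigenvalue, which is exactly the behaviour the per-component
weight vectors of the published formula display (0.35 + 0.57 + 0.02 + 0.55 =
1.49 ≈ λ₁ and 0.17 + 0.09 + 0.81 + 0.03 = 1.10 ≈ λ₂ on the packaged table).

Numerical conventions:

* **Component sign** is fixed by flipping each eigenvector so its loading
  sum is non-negative. Cos2 weights are squares and therefore sign-invariant;
  the convention only makes intermediate loadings reproducible across
  eigen-solvers.
* **Ties in ranking** are broken by ascending strain ID, making ranks a
  deterministic permutation.
* **Degenerate inputs** (constant columns, singular correlation matrices,
  missing cells) are hard errors rather than silently imputed: scoring input
  is expected complete, and an imputation policy would be a scientific choice
  the caller should make explicitly.
* If no eigenvalue exceeds 1, `composite_coefficients()` refuses; the
  pipeline falls back to the top component alone, the only defensible
  single-component summary.

## The scale of the published scores

On the packaged 36-strain table the published per-strain scores are not the
raw y of the two-decimal published coefficients: they are c·y for the
*unrounded* coefficients (0.7002, 0.9599, 0.9168, 0.8610) with a single
positive factor fitted at c = 25.000, matching every published score to
within 0.5 %. With the two-decimal coefficients the fit degrades to ~100 %
relative error for near-zero scores, which is pure cancellation noise: a
score near 0 is a difference of similar-magnitude terms and inherits the
rounding of the coefficients at full strength. `score_strains()` therefore
reports the least-squares positive scale factor against any reference score
column as a diagnostic (`attr(scores, "scale_fit")`) and never hard-codes
it; rank order, which is scale-invariant, is the quantity the pipeline
consumes downstream.

# Group-discriminating variants

`discriminating_sites()` implements a deliberately strict contrast for small
groups (default 3 vs 3): a site discriminates in direction A→B iff **all**
members of A share one identical non-reference state s ∈ {HOM, HET} and
**no** member of B carries s. Both directions are evaluated and unioned.
Conventions, each of which was an open reading of the rule:

* **HET is a state, not half a mutation.** A group uniformly heterozygous
  contrasts against a group with no heterozygous calls even if the latter is
  homozygous-alternate: the genotype states are matched exactly, mirroring
  how heat-map genotype classes (reference-consistent / hom-alt /
  heterozygous / low-quality) are compared visually.
* **"Does not contain this type of mutation"** is read as "no member of the
  other group has state s"; members may be reference-consistent or carry the
  other non-reference state.
* **Low-quality cells** (missing GT, or depth below threshold after
  `quality_filter()`) exclude the whole site when `require_full_groups =
  TRUE` (default): with groups of three, a rule that demands unanimity
  cannot be evaluated honestly on partial data. Setting it to FALSE instead
  drops the NO calls from the group before testing.
* **Multi-allelic records** are decomposed one row per alternate allele;
  genotypes carrying a *different* alternate become the bookkeeping state
  OTH, which can neither serve as the shared state nor block one (it is not
  s), and a strict mode drops such sites entirely.
* **A majority variant** (`min_share` < 1) relaxes "all members" to a
  fraction, for users who want the looser "some loci differed" behaviour on
  larger groups; the default stays strict.

Site-level filters follow standard short-read variant-calling practice:
QUAL ≥ 20, mapping quality ≥ 30, per-call depth ≥ 10, all boundary-inclusive.

`filter_nonsynonymous()` restricts to amino-acid-changing variants (the
annotation is consumed, not computed — alignment, calling and functional
annotation are upstream tools' jobs), and `aggregate_genes()` counts
discriminating sites per gene.

# Overrepresentation

`overrepresentation_test()` is a self-contained implementation of the
classical one-sided (upper-tail) hypergeometric overrepresentation test with
fold enrichment (k/n)/(K/N) and Benjamini–Hochberg FDR:

* the tail sum is accumulated in log space (log-binomials via `lchoose`,
  log-sum-exp reduction) so p-values far below double-precision underflow of
  the individual factorials remain accurate;
* BH is the step-up q(i) = min over j ≥ i of m·p(j)/j, capped at 1;
* terms with zero query overlap are excluded from the output and from the
  FDR family by default (the behaviour of the common web overrepresentation
  tools), with `include_zero_k = TRUE` to include them;
* only overrepresentation is tested; depletion is out of scope.

The FDR procedure attached to published enrichment tables of this kind is
often unstated; BH is the default here and the choice is visible in the
column name. No ontology graph propagation is performed: the annotation
table is taken literally, and the background universe is user-supplied
rather than bundled, which keeps results database-version-explicit.

# What the synthetic generators emulate

The generators exist so that every stage has planted ground truth.

**Phenotypes** (`simulate_phenotypes()`): one latent fermentation ability
per strain, a ~ N(0,1), drives four informative indicators (TTA weakly,
+0.3; volume and springiness +0.8; hardness −0.8) with independent Gaussian
noise (default sd 0.3) and realistic raw-unit offsets; redundant indicators
are affine functions of their parents (pH tracking TTA at r ≈ 0.99;
cohesiveness, gumminess, chewiness tracking hardness at r ≈ 0.75–0.9).
Defaults: 36 strains, matching the evaluation-panel scale this package
targets. Note one deliberate difference from real panels: because a single
latent factor drives all informative indicators, those indicators correlate
with *each other* (|r| up to ≈ 0.88 at the default noise), whereas the real
four-indicator panel is nearly uncorrelated. Recovery tests therefore score
the informative indicators directly (`redundant = FALSE`); pruning tests use
the redundant block, where the planted structure is the point.

**Genotypes** (`simulate_genotypes()`): 500 sites across 36 strains, with 33
planted discriminating sites spread over 19 genes between groups
{S1, S25, S33} and {S18, S20, S35} — the configuration the downstream
contrast is designed for — with an 80/12/8 % REF/HOM/HET background state
mix, optional missingness and planted quality failures. Because the strict
rule fires on i.i.d. background with probability ≈ 3·10⁻³ per site, a few
accidental discriminating sites would otherwise contaminate the planted
truth; by default the generator rejection-samples background sites until
none discriminates for the configured groups (`exclude_accidental = TRUE`),
so the planted list *is* the complete truth. Analyses of the strict rule's
false-positive rate set the flag to FALSE and compare against the
closed-form probability. What passing recovery tests shows is that the
machinery is exact on data that obey the rule's assumptions; it does not
show robustness to linkage, shared ancestry between groups, or genotyping
error correlated with group membership, none of which the generator
emulates.

**Annotations** (`simulate_annotations()`): a 1000-gene universe, 50 random
terms, and one planted term with fixed query overlap (defaults K = 10,
n = 20, k = 8, i.e. fold 40).

All generators are deterministic under a seed; the synthetic VCF writer
serializes QUAL/MQ at one decimal so identical matrices produce
byte-identical files, and round-trips through `read_vcf_genotypes()`.

# Problem sizes used in the tests

The packaged checks run the full published-table analysis (36 × 4), an
exhaustive 4³ × 4³ enumeration of the contrast rule (4096 single-site
configurations against a brute-force oracle), hypergeometric enumeration up
to N = 12, a 10 000-strain draw for generator-convergence checks, and 100
seeded enrichment replicates — sizes chosen so the whole suite exercises
every code path in well under a minute.

# Known limitations

* The composite score is linear in z-scores; strongly non-elliptical
  phenotype distributions would call for rank-based or rotated alternatives
  (no varimax/promax rotation is offered).
* The strict contrast rule is designed for very small groups; for larger
  groups it becomes overwhelmingly conservative, and `min_share` is a blunt
  relaxation rather than a calibrated statistic.
* Enrichment p-values are conditional on the user's annotation table and
  background; no correction for gene length, linkage between variants in the
  same gene, or ontology structure is attempted.
* The pipeline consumes annotated VCFs; nothing upstream of them (alignment,
  calling, consequence annotation) is validated here.
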