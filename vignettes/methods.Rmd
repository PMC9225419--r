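---
title: "Methods: compositional ordinal testing with a taxonomy-gated stepdown"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional ordinal testing with a taxonomy-gated stepdown}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taxgate)
```

## Scope and model

`taxgate` analyses a samples-by-taxa count table against an ordered
clinical-severity outcome with three levels, `HC < ASYM_UAS < SS_SLE`
(healthy controls, asymptomatic/undifferentiated autoimmunity, overt
Sjögren's/lupus). The package treats counts as compositional: only
log-ratio information is interpreted, never absolute counts.

**Transforms.** For a sample with counts $x$ and pseudocount $c$, the
centered log-ratio is $\mathrm{clr}(x)_i=\ln\frac{x_i+c}{g(x+c)}$ with $g$
the geometric mean of the closed vector; rows sum to zero by construction.
For multivariate analyses, a bifurcating taxon tree defines one balance
per internal node: with left/right leaf sets $L,R$ of sizes $r,s$,

$$b = \sqrt{\tfrac{rs}{r+s}}\,\ln\frac{g(x_L)}{g(x_R)}.$$

With uniform weights this is an orthonormal ilr basis, so Euclidean
distance between balance rows equals the Aitchison distance between the
compositions — an identity the test suite checks to $10^{-8}$. A
`mean_descendants` weighting is also offered, multiplying each taxon's
contribution by its mean relative abundance across samples (weighted
geometric means, weighted node normalizer). This soft down-weighting of
rare parts follows the spirit of abundance-weighted balance transforms in
the phylogenetic ilr literature; since weighted variants differ across
implementations, the uniform transform is the tested contract and the
weighted one is an option with the weight definition documented here.

**Per-taxon tests.** clr values within a taxon are replaced by midranks
across samples before model fitting, because clr-transformed counts
routinely violate conditional normality; rank-based trend tests keep type-I
error near nominal without distributional assumptions. Each taxon is fit by
least squares on a shared design:

* `ordinal3` — rank on the trend score $(-1,0,+1)$ plus batch dummies;
  two-sided t-test of the trend coefficient (the spectrum has documented
  effects in both directions, so a one-sided test would be wrong);
* `discrete3` — rank on two group indicators plus batch; 2-df F-test,
  agnostic to ordering;
* `two_group` — rank on a pooled indicator (default healthy vs all
  antibody-positive) plus batch.

Taxa whose ranks are constant get $p=1$ (not `NA`) so multiple-testing
families keep a fixed size. All taxa at a level share one design matrix, so
the fits are vectorised (one QR per level, not per taxon).

**Taxonomy-gated stepdown (TSD).** Flat BH across hundreds of taxa spends
its budget on lineages with no signal. TSD instead tests levels top-down:
all phyla are tested as one BH family; each node with adjusted $p<\alpha$
opens a gate, and only its children are tested at the next rank,
BH-adjusted *within that sibling set*; recursion stops at species or when
no gate opens. Child tests use counts re-aggregated at the child's own
level (not parent residuals): this mirrors level-wise reporting tables and
keeps each level's test exactly the level-wise rank GLM. Two structural
invariants are asserted on every run: no emitted node has a closed
ancestor gate, and the number of tested hypotheses never exceeds flat
testing's count.

**Alpha diversity.** Shannon entropy $H=-\sum p_i\ln p_i$ in nats on raw
counts (zeros contribute nothing; no pseudocount, since $0\log 0=0$ is the
correct limit), with the effective number $e^H$. Group comparisons use a
Welch t-test (or a batch-adjusted linear model) and the same ordinal trend
GLM as the taxon tests.

**Global test.** One-way PERMANOVA on the balance (Aitchison) distance
matrix: Anderson's pseudo-F from the among/within decomposition of squared
distances, $p$ by unrestricted label permutation with the add-one rule
$p=(1+\#\{F_\pi\ge F\})/(1+n_\pi)$. An exhaustive mode enumerates all
relabelings for small $n$ and is verified against independent enumeration.
PCA on the column-centered balances reports per-component explained
variance; single components can be tested against sample covariates with a
Bonferroni report for the number of components examined.

**Interaction models.** For taxa discovered by the differential stage,
effect modification is tested on the clr scale (so coefficients are per
clr unit, interpretable as per e-fold change relative to the sample's
geometric mean):

* HLA: logistic regression of overt disease vs milder autoimmunity among
  antibody-positive mothers on `clr + carrier + clr:carrier`; the Wald
  test of the product term gives the interaction p, and
  $\mathrm{OR}=e^{\hat\beta}$ with Wald 95% CI. Carrier status is
  dominant-coded (any copy = 1). A proportional-odds coding over all three
  groups is offered; when controls are ungenotyped it degenerates to the
  logistic model and the code falls back explicitly. Quasi-separation is
  reported as non-estimable (huge Wald SE, non-convergence) rather than
  crashing a screen.
* Titers: linear model `titer ~ clr + group + clr:group` among
  antibody-positive mothers, returning per-group fitted lines for
  interaction plots.

The screen applies no multiplicity adjustment by default — it is an
exploratory second tier over an already FDR-controlled candidate set — but
a BH column is one flag away.

## The synthetic cohort generator

Real cohorts of this design are access-controlled, so validation runs on
synthetic cohorts whose generative model matches what the estimators
assume, with ground truth returned for recovery checks.

Default conditions (`default_cohort_spec()`): groups of 23/43/82; 300
ASV-like leaf taxa under a 13-phylum, 150-genus taxonomy (a desk-scale
reduction of a 233-genus inventory, with ~65% of leaves species-assigned,
matching reference databases that leave many leaves unassigned at species
rank); expected depth 32,000 reads/sample (Poisson across samples); three
sequencing batches.

Generation: per-taxon baselines $\mu_j\sim N(0, 1.5^2)$ (a heavy-tailed
abundance distribution on the log scale); per-sample log abundance
$\eta_{ij}=\mu_j + \text{batch}_{b(i),j} + s_i\,\delta_j\,\mathrm{sign}_j
+ \varepsilon_{ij}$ with batch offsets $N(0,0.25^2)$, noise
$N(0,1)$, and $s_i$ the severity score; compositions are the softmax of
$\eta_i$ and counts are multinomial. The logistic-normal/multinomial
choice (over Dirichlet-multinomial) makes planted log-scale effects map
directly onto clr expectations, so recovery tests are analytically
interpretable. The default plants 13 monotone genera at $\delta=1$
log-unit per severity step, seven increasing and six decreasing, mirroring
a reporting table with effects in both directions.

HLA interactions are planted on the *outcome* scale: carrier flags are
drawn Bernoulli (default frequency 0.25 per allele, a realistic carrier
frequency for these Class II alleles in a European-ancestry autoimmune
cohort), then disease state among antibody-positive mothers is re-drawn
from a logistic model whose linear predictor includes the planted
$\log\mathrm{OR}\times\mathrm{clr}\times\mathrm{carrier}$ term, with the
intercept set to preserve the marginal group balance. This matches the
regression direction of the interaction estimator. A consequence worth
knowing: re-drawing labels partially mixes the two antibody-positive
groups relative to the abundance effects planted earlier, attenuating the
middle-vs-top severity step; the healthy-vs-positive contrast, which
carries most of the trend information, is untouched. Titers are linear in
the planted taxa's clr values with per-group slopes, noise SD 1, floored
at zero; controls have missing genotypes and titers, as in real registries
where controls are not assayed.

Determinism: each generation stage draws from its own deterministically
derived sub-seed, so adding a planted effect never perturbs draws in
unrelated stages, and identical spec + seed gives bit-identical cohorts.

**What the generator does not emulate.** Overdispersion beyond
logistic-normal (no zero-inflation mechanism beyond sampling zeros), PCR
and primer bias, strain-level variation, covariates such as age, race,
medication, and any phylogenetic signal in the planted effects (the tree
is taxonomy-derived with unit branch lengths and seeded random resolution
of multifurcations). Passing recovery tests therefore demonstrates
correctness of the estimators under their assumed model, not robustness to
every artefact of real 16S data.

## Numerical and design choices

* **Pseudocount** 0.5 added to counts before closure (the conventional
  half-count zero replacement); exposed everywhere as `pseudocount`.
  Diversity uses none.
* **Ties** in ranking take midranks, matching standard rank-test
  behaviour.
* **Rare-taxon filter**: taxa with mean relative abundance below $10^{-4}$
  are removed before per-level testing (configurable; 0 disables). The
  filtered family is the multiple-testing family.
* **Aggregation**: counts sum over member taxa; taxa unassigned at a level
  are excluded from that level (no "unclassified" pseudo-taxon), and each
  level's family contains only named taxa.
* **Gating threshold**: BH-adjusted $p<\alpha$, default $\alpha=0.05$;
  $\alpha=0$ is accepted as a degenerate "report nothing" setting so a
  pipeline dry-run completes.
* **PERMANOVA defaults**: 19,999 permutations with the add-one rule
  (resolution $5\times10^{-5}$), unrestricted permutation (batch enters
  the univariate models as a covariate instead). Exhaustive enumeration is
  limited to $n\le 8$.
* **Trees**: a user Newick tree overrides the taxonomy-derived one; the
  derived tree resolves multifurcations by seeded random left-combining,
  so same seed means same topology.
* **Degenerate inputs** error early with the offending record named:
  negative or fractional counts, duplicated identifiers, lineage gaps
  (a missing rank with a present lower rank), unknown group labels,
  all-zero tables, constant covariates, empty strata.

## Problem sizes used in validation

The shipped validation suite uses: 1000 random tables for the clr
zero-sum identity and 100 random trees for the isometry; 1000 random
vectors against an independently coded BH step-up; 2000 null simulations
(90 samples, 50 taxa) for ordinal-test calibration; 500 null cohorts for
the TSD species-level error rate; 100 default cohorts for planted-genus
recovery; 1000 reduced cohorts (30 genera, 125 antibody-positive mothers)
for interaction bias, coverage and power. These sizes give Monte-Carlo
standard errors comfortably below the margins being checked while keeping
a full run in the order of a minute or two.

## Known limitations

* The weighted (`mean_descendants`) balance variant is a documented
  best-effort definition, not an isometry; only the uniform variant
  carries the distance-preservation guarantee.
* TSD inherits the resolution of the taxonomy: signals split across
  many sibling lineages of a non-significant parent are invisible to it
  (the flat genus-level BH summary runs alongside for exactly this
  reason).
* The interaction stage models one taxon at a time; correlated planted
  effects on a shared titer are partially absorbed into each other's
  single-taxon slopes, as the generator's default cohort illustrates.
* Logistic interaction estimates carry the usual finite-sample MLE bias
  away from zero at modest carrier counts; at 125 samples and carrier
  frequency 0.25 the bias on a planted log-OR of 0.5 is about +0.05 with
  Wald CI coverage near 0.96, as the recovery checks report.
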