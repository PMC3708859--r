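---
title: "Network determinants of drug side-effect burden: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network determinants of drug side-effect burden: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

Most drugs bind several proteins, and perturbing those proteins propagates
through the cellular interaction network. `sidefxnet` asks which properties
of a drug's protein targets predict how many distinct side effects the drug
causes: whether the targets are *essential* (their loss is lethal), how
*central* they are in the protein–protein interactome (degree and
betweenness), whether they bind their interaction partners through a
*shared interface* (so that one bound drug can disrupt many interactions at
once), and how *close* the targets sit to the genes of the disease the drug
is indicated for. The package provides the full analysis battery — count
regressions, rank tests, a bootstrap comparison of distance-defined drug
classes, and randomization nulls — together with a synthetic-data generator
with known ground truth, so every stage can be validated end to end without
access to proprietary database snapshots.

## Data model

Six tab-separated inputs describe a study: a drug table (group label,
side-effect count or term list, fatal-effect flag, approval year, and
in-cell semicolon lists of targets and indicated diseases), a long-format
drug–target map, target essentiality flags, interaction-evidence records,
a (target, partner) → interacting-domain interface table, and a
disease → gene map. Interaction evidence is canonicalized to unordered
pairs (duplicates merged by OR on flags and max on publication counts —
a conservative union of evidence) and filtered by the quality rule: an
interaction is kept iff it comes from a high-throughput high-quality
experiment **or** is supported by at least two independent publications.
The structurally resolved sub-network further restricts to binary-evidence
edges that carry an interface annotation; co-complex evidence is excluded
there because an interaction interface is meaningless without direct
binding.

## The count model

Side-effect counts are overdispersed, so the headline model is a negative
binomial GLM with log link,

$$\log \mu = \beta_0 + \beta x, \qquad
  \mathrm{Var}(Y) = \mu + \mu^2/\theta,$$

with a single covariate per analysis (number of targets, number of
essential targets, standardized log target degree, number of bottleneck
targets, or the interface-sharing score). The fit alternates iteratively
reweighted least squares for $(\beta_0, \beta)$ with profile maximum
likelihood for the shape $\theta$ (golden-section search on $\log\theta$
over $[\log 10^{-4}, \log 10^{8}]$) until the joint log-likelihood changes
by less than $10^{-8}$ (relative), capped at 100 outer iterations; the fit
is flagged, never silently accepted, if that cap is hit. Inference on
$\beta$ is a two-sided Wald test, $z = \hat\beta/\mathrm{SE}$, with the
standard error from the Fisher information at the optimum (conditional on
$\hat\theta$, as is conventional). The suite verifies the optimizer against
a direct numeric maximizer of the same likelihood to $10^{-6}$ in
log-likelihood and against an independent implementation, and checks that
$\theta = 10^6$ reproduces the Poisson fit to $10^{-4}$.

Family choice is automatic: a Poisson GLM is fitted to the raw data and the
Pearson $\chi^2/\mathrm{df}$ statistic computed; above 1.5 the negative
binomial is used, otherwise Poisson. The threshold is deliberately
permissive — mild overdispersion barely moves Wald tests, and strata with
few drugs are better served by the one-parameter family.

### Median binning

To damp extreme observations, each regression is fitted on per-level
**medians**: drugs are grouped by unique covariate value, the median count
taken per level, and sparse levels at the upper margin merged downward —
sweeping from the largest level, any level with fewer than `min_bin_size`
(default 5) observations is merged into the next lower level and the
combined level re-checked, so thin margins cascade into bins of at least
five drugs. A merged level sits at the observation-weighted mean of its
member values; half-integral medians are rounded half-up so the count
likelihood stays well defined. Two choices here were genuinely open:

* **Level weighting.** The median of a 400-drug level and the median of a
  5-drug level are estimates of very different precision. The default fit
  therefore weights each level's likelihood contribution by its drug
  count; `weight_levels = FALSE` restores strictly unweighted fitting.
  With 4–7 levels (typical for discrete covariates) the unweighted fit is
  dominated by its noisiest bins and is demonstrably unstable.
* **Raw-mode fitting.** `binning = FALSE` fits the drug-level counts
  directly; the recovery and oracle tests use this mode because binned
  medians estimate a slightly different (attenuated) slope.

### Rank tests

Group contrasts (nutraceutical vs approved, withdrawn vs approved,
fatal vs non-fatal) use the two-sided Wilcoxon rank-sum test: exact
enumeration when both samples have at most 20 observations and no ties,
otherwise the normal approximation with tie correction. A fully tied
comparison returns p = 1 by convention (no evidence either way).

## Centrality and bottlenecks

Betweenness uses the fractional geodesic convention: node $v$ receives
$\sum_{\{s,t\}} \sigma_{st}(v)/\sigma_{st}$ over unordered pairs. When
several shortest paths exist, "the number of shortest paths through a
node" is ambiguous; the fractional form is the standard centrality and
preserves the ranking that the top-$k$% cutoff consumes. *Bottlenecks* are
the nodes whose betweenness ranks in the top 20% (ties broken by protein
id for determinism; exactly $\lceil fN \rceil$ nodes returned), with a
sensitivity sweep over 5/10/20/40% run by the pipeline. Betweenness is
computed on the full quality-filtered interactome, not a drug-target
sub-network: targets are mapped onto the global network context.

The degree covariate is standardized **on the log scale**. Interactome
degree distributions are heavy-tailed; a z-score of raw degree puts hubs
at +8 SD and, inside an exponential mean model, turns them into
order-of-magnitude count multipliers that no real side-effect table
exhibits. The z-score of log degree keeps multipliers bounded and the
generated counts in the tens-to-hundreds range that the model is meant to
describe. The fitted slope is therefore "per SD of log target degree".

## Interface sharing

For a target $T$ with annotated partners $A, B$, the shared-interface
score of the pair is the Jaccard similarity of the target-side domain
sets, $|D_A \cap D_B| / |D_A \cup D_B|$, and a target's score is the
unweighted mean over all unordered partner pairs (undefined below two
annotated partners, and such targets are excluded). A target is
*single-interface* when all partners bind identical domain sets —
equivalently, when its sharing score is exactly 1. Domain sets are treated
as sets, without multiplicity. The sharing regression runs on drugs with
exactly one non-essential target, so essentiality and target count cannot
confound the interface effect; the degree regression uses the same subset
for the same reason.

## Distance classes and the bootstrap

For each drug with mapped targets, the pipeline computes the average
shortest distance between its targets and (a) the genes of its indicated
diseases and (b) all other disease genes (the set difference — a gene
shared with an indicated disease is not "other"). Identical protein pairs
count distance 0; pairs in different components are excluded from the
mean rather than set to infinity (a finite network mean distance is the
reference quantity), and a drug with no finite pair is excluded and
logged. Drugs are split at an average indicated-distance of 3: strictly
below is *near*, at or above is *far*.

Because the near class is small and the variances unequal, medians are
compared by bootstrap: from each class independently, 1000 resamples of
size 10 with replacement, the median recorded each time (even-sized
resamples: mean of the central pair), and the two median distributions
compared by Wilcoxon rank-sum. The two classes draw from independent seed
substreams, so class-A draws are unaffected by the size of class B, and
the whole procedure is bit-reproducible given the seed.

## Randomization nulls

Three null models probe whether the distance-class gap is
association-driven: degree-preserving edge swaps of the interactome
(double-edge swaps, rejected when they would create a self-loop or
duplicate edge; 10×|E| attempts by default), permutation of the pooled
drug–target incidence list, and permutation of the pooled disease–gene
incidence list (both preserve every entity's set size and re-draw
collisions). The trial runner re-executes the distance classification
under each null and records the far-minus-near median side-effect gap per
trial.

Interpretation deserves care. Under the configured conditions the
randomized near class is dominated by drugs with highly central targets
(hubs are close to every gene set), and since target centrality itself
carries a count effect, the null gap is typically *negative*, not merely
shrunk toward zero. The package therefore reports attenuation as
*non-reproduction*: the observed positive gap exceeds the null mean in
every model. The stronger zero-mean property holds when the distance
effect is the only active one, and the suite checks it there — averaged
across generated datasets, because within one dataset the randomized near
class is nearly the same set of central-target drugs in every trial, so
per-trial standard errors understate the dataset-level noise.

## The synthetic study generator

The generator emulates the six inputs at study scale with known ground
truth. Defaults: a 3,000-protein preferential-attachment network with 3
edges per node (heavy-tailed degrees; quality flags drawn so that
$1 - 0.4e^{-0.8} \approx 82\%$ of records pass the evidence filter), 996
drugs of which ~35% have no mapped target (mirroring the ratio of
analyzable to cataloged drugs), truncated-geometric target counts with
mean ~2, 15% essential proteins, negative binomial counts with shape
$\theta = 2$, and effects injected on the linear predictor exactly as the
fitted model assumes: 0.17 per essential target, 0.31 per SD of log mean
target degree, 0.21 per bottleneck target, 1.5 per unit sharing score
(centered), plus a 0.8 log-scale excess for drugs *far* from their
indicated-disease genes. Confounding between covariates (degree vs
bottleneck membership) is left natural; individual effects can be isolated
by zeroing the other coefficients.

Interfaces: each protein carries 1–4 domains; each binary interaction uses
the first domain with probability `iface_reuse_prob` (default 0.5) and a
uniform draw over all its domains otherwise, which makes the expected
sharing score increase monotonically in the reuse probability; 10% of
binary edges are left unannotated so the structural-network drop rule is
exercised. Diseases are breadth-first network neighbourhoods (5–25 genes)
around random seed proteins. A drug carries a latent near flag with
probability `p_near_module` (default 0.05, matching the observed rarity of
module-proximal drugs); its indicated disease is then seeded inside the
2-neighbourhood of one of its targets, which guarantees an average
distance below 3 for single-target drugs (multi-target near drugs use a
shrinking fallback and can rarely land at 3 or above). Far drugs' diseases
are re-drawn (up to 10 attempts) when a draw accidentally falls within the
cutoff, so the realized classes follow the latent flags; drugs whose
targets are central enough that *every* disease is nearby keep their last
draw and form a small genuine residual of the near class. Withdrawn drugs
are sampled from the top count tercile and nutraceuticals from the bottom
one; fatal flags follow a logistic model in the count; approval years are
a noisy increasing function of the count, reproducing the rising trend of
recorded side effects for recent approvals.

What the generator does *not* emulate: real side-effect vocabularies and
their correlation structure, non-uniform target sampling (real targets
cluster in druggable families), literature-curation biases in the
interaction evidence, and disease modules with realistic gene-set overlap.
Passing tests therefore demonstrate that the pipeline recovers effects of
the stated form and magnitude from data of the stated shape — not that
the real-data effect sizes are correct.

## Numerical choices and degenerate inputs

* IRLS converges on relative coefficient change $< 10^{-10}$ (50-iteration
  cap); the linear predictor is clipped at ±30 to avoid overflow.
* Regression requires ≥ 3 distinct covariate levels; analyses that cannot
  meet this on a stratum are skipped with a message, never fabricated.
* Self-interactions are dropped with a warning; unannotated targets,
  interface entries referencing absent edges, and negative counts are
  hard validation errors naming the offender.
* Bottleneck ties break lexicographically; `ceiling(fraction * N)` nodes
  are always returned.
* Seed handling: one master seed fans out to named substreams (generator
  stages, bootstrap, each null trial), so changing the number of bootstrap
  replicates does not perturb the generated data or the other analyses.

## Problem sizes used by the test suite

The suite validates oracle equivalence on 50 random graphs of ≤ 8 nodes
and 10 regression datasets of n = 500; parameter recovery on 200
replicates of 600-drug studies; bootstrap symmetry on 200 seeds; and the
end-to-end battery on 20 seeded studies at the default scale (996 drugs,
3,000 proteins) with 8 randomization trials per null model. The
acceptance script runs one full study at default scale with 100 trials
per null model, the setting the pipeline defaults to.

## Known limitations

Single-covariate models only (the confound-control strategy is subsetting,
not adjustment); no multiple-testing correction across the analysis
battery (deliberately, to mirror the analysis design the package
implements); the edge-swap null samples degree-preserving graphs by
rejection rather than exactly uniformly; and binned-median regression
estimates a slope that is attenuated relative to the drug-level slope when
within-level heterogeneity is large — raw-mode fitting exists precisely to
quantify that attenuation.
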