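---
title: "Methods: pathway classification and co-occurrence networks for digester metaproteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pathway classification and co-occurrence networks for digester metaproteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`biogasnet` analyses protein-group relative-abundance tables from
anaerobic digester (biogas plant) metaproteomes. This vignette documents
the statistical procedures, the tunable parameters, the synthetic data
model used to validate them, and the numerical and design choices a
maintainer should know about.

## 1. Data model

The central container (`abundance_matrix`) is a nonnegative feature x
sample matrix of relative abundances with the sampling design (plant,
replicate) attached to the columns. Absence is encoded as zero, never as
a missing value; no imputation is done anywhere. A feature annotation
table maps protein groups to species, family, KEGG orthology (KO) and EC
identifiers.

Preprocessing follows common metaproteomics practice:

* **Replicate-presence filter** (`filter_replicate_presence`): a feature
  is kept when it is nonzero in at least `min_present` (default 3) of
  some plant's replicates. "Observed" means strictly positive abundance,
  which is the only available definition for intensity data. The filter
  keeps a feature *globally* if any plant passes, so that cross-plant
  comparisons stay on one feature universe; a per-plant masking variant
  is available (`per_plant = TRUE`) because the alternative reading is
  equally plausible.
* **Normalization** (`normalize_relative`): each sample column is scaled
  to sum 100 (percent). The operation is idempotent and errors on
  all-zero columns rather than producing NaN.
* **Aggregation** (`aggregate_features`): features are summed to
  species, family or KO level. A feature annotated with k KO ids
  contributes its full abundance to each of the k KO rows by default
  (`multi_ko = "full"`), because published per-KO abundance tables add
  the complete protein-group signal to every function the protein group
  serves; an even split (`multi_ko = "split"`) is available. Consequence:
  species- and family-level aggregation conserve column totals exactly
  (an `unassigned` row collects unannotated features), while KO-level
  totals may exceed the sample total when multi-function protein groups
  exist. This is intentional and tested.

## 2. Methanogenic pathway classification (factor F)

Methanogenesis can run acetoclastically (acetate split), hydrogenotrophically
(H2 + CO2) or methylotrophically. The classifier quantifies the balance
between the first two routes from protein abundance alone:

* KO sets (`methanogenesis_ko_sets`): six KOs unique to the acetoclastic
  route (ackA, pta, ACSS, cdh beta/gamma/delta), eleven unique to the
  hydrogenotrophic route (fmd A-E, the uncharacterized K00205, ftr, mch,
  mtd, hmd, mer), the shared mtr complex, KOs common to all routes
  (mcr, hdr, mvh, fdh) and the methylotrophic MtaABC set. The five sets
  are pairwise disjoint; only the two *unique* sets enter F, the others
  are reported for context. A user override file is accepted and checked
  for overlaps.
* F = (sum of acetoclastic-unique KO abundances) / (sum of
  hydrogenotrophic-unique KO abundances). F >= 2.5 is called
  acetoclastic, F <= 0.4 hydrogenotrophic, anything between "both"
  (both thresholds inclusive, following the written rule rather than a
  strict reading). Zero hydrogenotrophic signal with positive
  acetoclastic signal gives F = infinity (acetoclastic); zero on both
  sides is treated as a data error ("no methanogenesis signal"), not as
  a "both" call, since the complete absence of methanogenesis proteins
  in a digester sample indicates a processing problem.
* `classify_units` classifies either every replicate (the input
  partition for network inference) or per-plant means (plant means are
  renormalized to 100 first). Because the mean of ratios is not the
  ratio of means, replicates can disagree with the plant-mean call; in
  per-plant mode the replicate-majority label is reported alongside,
  and no silent reconciliation happens.

The package ships the reference per-plant KO abundance table for the
16-plant study design it targets (`load_reference_ko_table`); the
16 published plant labels (8 hydrogenotrophic, 5 acetoclastic, 3 mixed)
are reproduced from it in the test suite.

## 3. Ensemble co-occurrence network inference

Networks are inferred separately for each pathway class, over the
species-level table of that class's replicates, with an ensemble of five
association measures — Pearson, Spearman and Kendall correlation,
Bray-Curtis dissimilarity (via `vegan`) and symmetrized Kullback-Leibler
divergence — following the CoNet-style consensus design:

1. **Prevalence filter**: species must be nonzero in at least 60% of the
   replicate set (`ceiling(0.6 n)`, e.g. 24 of 40, 15 of 25, 9 of 15).
2. **Per-method candidate selection**: the 2,500 strongest co-presence
   and 2,500 strongest exclusion pairs per method (all pairs when fewer
   exist, as in the small tables of the test suite). For correlations,
   sign gives the direction; for dissimilarities, a pair is co-presence
   when its dissimilarity lies below the mean over random permutations
   of one member (the least-assumption null point). Rank ties at the
   candidate boundary break lexicographically by pair id so results are
   reproducible.
3. **Support filter**: an edge must be selected by at least
   `min_support = 3` of the 5 methods in the same direction; the
   direction is the majority among selecting methods and a tie drops
   the edge (sign disagreement means no consensus interaction type).
4. **Bootstrap significance**: for each surviving (pair, method), the
   replicate columns are resampled with replacement 100 times, the
   score recomputed, and a normal distribution fitted to the bootstrap
   scores. The p-value is the two-sided tail beyond the method's null
   value (0 for correlations, the permutation-mean for dissimilarities):
   twice the tail probability on the side opposite the observed effect,
   capped at 1. The two-sided form is used because it is the calibrated
   one — under independence the opposite-tail probability alone
   concentrates on (0, 0.5) and cannot be uniform — and matches CoNet's
   convention. A degenerate bootstrap (zero spread) yields p = 0 when
   the observed score differs from the null value. Every (pair, method)
   unit draws its own random stream from a stable hash of the master
   seed, so evaluation order cannot change results.
5. **Brown's method** merges the five dependent per-method p-values:
   with X = -2 sum log p over k methods, X is referred to a scaled
   chi-square with c = Var/(2E), f = 2E^2/Var, E = 2k,
   Var = 4k + 2 sum cov(-2 log p_i, -2 log p_j). The covariances are
   estimated empirically, pooled across all tested edges (they are not
   identifiable per edge), and clamped to [0, 4] — the theoretical range
   from independence to perfect dependence — because the pooled sample
   covariance mixes signal heterogeneity into the estimate and can
   otherwise produce invalid degrees of freedom. At zero covariance the
   merge reduces exactly to Fisher's method; at the upper clamp with
   identical p-values it returns the shared p.
6. **Benjamini-Hochberg** control at alpha = 0.05 (edges kept at
   q < 0.05).

The result is an undirected simple graph whose edges carry a
co-presence/exclusion sign, the support count, per-method p-values, the
Brown-merged p and the BH q.

Known limitation: the bootstrap-normal p-value is anti-conservative in
the far tail (the fitted normal uses the bootstrap spread, which for a
bounded statistic like a correlation is narrower than the null sampling
spread), so with hundreds of tested pairs a small number of
sampling-noise edges can survive BH. The calibration tests quantify
this: near-uniform p-values under the null, and well under 5% of tested
candidates retained on independent-feature tables.

## 4. Topology: modules and Guimera-Amaral roles

Module detection uses deterministic greedy modularity maximization
(igraph's fast-greedy algorithm) on the unsigned, unweighted skeleton;
edge signs never influence community structure, only the summary
counts. Module counts from any modularity heuristic depend on the
algorithm, so downstream checks are property-based rather than
count-matching.

For each node, the within-module degree z-score
(z_i = (k_i,own - mean) / sd over the node's module, with z = 0 when the
module's spread is zero so role assignment stays total) and the
participation coefficient (P_i = 1 - sum_s (k_is/k_i)^2, P = 0 for
isolated nodes) are computed, and roles assigned with the standard
thresholds: peripheral (z <= 2.5, P <= 0.62), connector (z <= 2.5,
P > 0.62), module hub (z > 2.5, P <= 0.62), network hub (z > 2.5,
P > 0.62). The 0.62 participation threshold is applied to network hubs
as well — the standard cut and the only value consistent with the other
three rules — and both thresholds are exposed as arguments.
`summarize_network` reports the node/edge/module/role counts per
network (positive and negative edges, in-module vs module-crossing
edges, role tallies).

## 5. Environmental association screens

* `abundance_floor` keeps rows with mean relative abundance >= 0.1%
  (inclusive) before correlation screening, reducing multiplicity.
* `spearman_screen` rank-correlates every remaining feature with every
  numeric process parameter (temperature, pH, VFA, substrate fractions,
  C/N). Replicates inherit their plant's metadata; the default runs
  across all replicate samples, with a plant-mean mode available since
  either choice is defensible. Significance is a raw p <= 0.01 by
  default, reproducing the screening convention this mirrors; a BH
  option exists but is off by default. Constant features or variables
  are excluded, not reported as NaN.
* `vif_screen` computes VIF_j = 1/(1 - R^2_j) from least-squares
  regressions of each metadata variable on the others and, in iterative
  mode, removes the worst offender at or above 10 and recomputes until
  all remaining VIFs are below the threshold. Perfect collinearity
  (R^2 = 1) is reported as infinite VIF and removed first. The kept
  variable list is what a constrained ordination (e.g. CCA) would
  consume; the ordination itself is out of scope.

## 6. Synthetic data generator

`simulate_dataset` produces replicate-level protein-group tables with
known ground truth so every stage has a recovery test without any
external download. The generative model, and what it does and does not
emulate:

* **Community**: `n_species` focal background species (log-normal base
  abundances, base log-sd 1) each with 1-4 protein groups (uniform
  weights), two methanogen species, and a "bulk" pool (default 12
  species holding 200 abundance units with individual log-sd 0.5)
  representing the hundreds of community members outside any focal
  panel. The bulk pool's statistical role is to make the column total
  stable relative to any single species, as in real tables; without it,
  compositional closure at a 30-species scale induces spurious
  correlations that no real-data analysis would face.
* **Biological variation**: each background species varies with a
  plant-level effect (log-sd `plant_sd`, default 0.6) plus a
  replicate-level effect (log-sd `rep_sd`, default 0.7, roughly 2-fold
  typical variation). Planted pairs share a latent factor in both
  components so the latent correlation is `rho` (sign +1 for
  co-presence, -1 for exclusion); each species participates in at most
  one planted pair, keeping realized correlations interpretable.
* **Methanogens**: an acetoclastic species carrying the six
  acetoclastic-unique KOs and a hydrogenotrophic species carrying the
  eleven hydrogenotrophic-unique KOs (plus common mcr-type protein
  groups on each). Per plant, the hydrogenotrophic side holds
  `hydro_mass` (10) pre-closure units and the acetoclastic side
  `F_true * hydro_mass`, so the unique-KO ratio equals `F_true` exactly
  before noise; per-replicate whole-species activity variation and
  per-protein-group measurement noise are both governed by `noise_sd`
  (default 0.3) and vanish when it is 0. Closure rescales both sides
  identically and therefore never changes F.
* **Noise and missingness**: per-protein-group log-normal measurement
  noise (`noise_sd`); left-censored dropout (`dropout_prob`, default
  0.05 mean rate) whose probability declines with the value's
  within-feature rank, emulating LC-MS detection limits. Columns are
  closed to 100, re-closed after dropout.
* **Metadata**: per-plant temperature, pH, VFA, C/N and six substrate
  fractions (normalized gamma draws). Planted monotone links replace a
  variable by a noisy monotone transform of a species' plant-level
  latent abundance.
* **Reported truth**: per-plant `F_true` and label, the planted edge
  list with signs, and the metadata links; `recovery_report` scores
  pipeline outputs against them (label accuracy, sign-aware edge
  recall/precision, link recall).

Planted correlations are specified on the latent scale; realized
(post-noise, post-closure) correlations are attenuated by the
protein-group noise (about 10% at the defaults) and by sampling
variation, so recovery tests compare against realized behaviour at
fixed seeds. What the generator does *not* emulate: peptide-level
quantification, shared peptides between species, batch effects,
phylogenetic correlation among background species, and
plant-level confounding between pathway design and community structure.
Passing recovery tests therefore demonstrate the pipeline's correctness
under exchangeable replicates with planted pairwise structure, not
robustness to every real-data pathology.

## 7. Validation design and problem sizes

The test-suite benchmarks use sizes that keep the full suite fast while
exercising every code path: the planted-structure benchmark pools one
pathway class of 40 exchangeable replicates (matching how a class's
replicates enter network inference) over 30 focal species with 10
co-presence and 5 exclusion pairs at latent rho 0.9; calibration uses
200 independent pairs at n = 40 plus a no-structure table of the same
benchmark size; pathway-label recovery simulates 100 independent
6-plant datasets with noise_sd 0.3 and F_true drawn log-uniformly from
(0.02, 0.3) and (3, 30) — outside the uninformative middle band.
Association measures, the Spearman screen and the z/P statistics are
checked against brute-force reference implementations written from the
formulas, on a thousand random instances.

## 8. Numerical choices

* KL divergence uses a pseudocount of 1e-6 on every cell before
  normalizing each species vector to a distribution, and is symmetrized
  as the average of the two directed divergences; zeros otherwise give
  infinities.
* p-values of exactly 0 (degenerate bootstrap) are clamped to the
  smallest positive double before entering Brown's log-sum.
* Candidate ranking ties break lexicographically by pair id; module
  detection and all bootstraps run under derived seeds, so a pipeline
  rerun with the same master seed is bit-identical.
* Within-module sd of 0 yields z = 0 (not NaN); isolated nodes get
  z = 0, P = 0. Roles are therefore defined for every node.
* The replicate-presence and prevalence filters use strict positivity;
  the abundance floor and both F thresholds are inclusive.
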