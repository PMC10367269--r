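---
title: "Comorbidity networks and multiplex disease-gene propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comorbidity networks and multiplex disease-gene propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
```

## The problem

Comorbidity-driven syndromes are better described by the *pattern* of
diseases a patient accumulates than by any single diagnosis. This package
operationalizes that view in four stages: (i) turn a binary
patient×diagnosis matrix into a weighted disease co-occurrence network and
its clusters; (ii) summarize patients and subtypes on that network
(covariate-attributed variance, discriminative comorbidity profiles,
patient-to-cluster similarity); (iii) embed the disease network in a
multiplex-heterogeneous disease–gene graph and propagate subtype profiles
to genes by random walk with restart; (iv) quantify how well the resulting
rankings recover known or planted disease genes, against informative
nulls.

Everything can be exercised on synthetic data with planted ground truth;
nothing in the package downloads or requires proprietary cohorts or
database snapshots.

## The comorbidity network

For diseases $i,j$ with 2×2 co-occurrence table $(a,b,c,d)$ over $n$
patients, edges are screened by the two-sided Fisher exact test —
computed exactly from the hypergeometric distribution, with the
conventional "tables no more probable than the observed" two-sided sum —
and kept when the Benjamini–Hochberg adjusted p-value is below $\alpha$
(default $10^{-4}$) *and* the $\phi$ correlation
$\phi = (ad-bc)/\sqrt{(a+b)(c+d)(a+c)(b+d)}$ is positive. Only diseases
with at least 5 affected patients enter testing (a configurable floor; a
test on a handful of patients can only produce unstable estimates).

Because $\phi$ between frequent diseases is systematically larger, edge
weights rescale $\phi_{ij}$ by the endpoint diseases' mean retained
correlation. The reference description of this scaling ("divide by the
mean correlation of each disease") does not fix the combination rule, so
both are implemented: the default geometric form
$W_{ij} = \phi_{ij}/\sqrt{\bar m_i\,\bar m_j}$ (symmetric, damps hubs
multiplicatively) and an arithmetic variant
$W_{ij} = \phi_{ij}/((\bar m_i+\bar m_j)/2)$ via the `scaling` argument.
Means are computed over the *retained* positive edges (post-filter);
computing them pre-filter would mix in noise correlations whose sign and
magnitude the filter was designed to exclude. For distance-based
centralities every edge gets the score $S = \max(W) - W$, so the
strongest association is the shortest link; zero-length edges (the argmax)
are replaced by a vanishing epsilon because shortest-path routines require
positive lengths. Closeness is reported as *harmonic* centrality, which
remains defined on disconnected networks; betweenness uses the same $S$
lengths; degree is unweighted and strength sums $W$.

Clusters are found by weighted modularity optimization (Louvain by
default, fast-greedy and walktrap as alternatives), with the random seed
fixed by the caller; the partition, algorithm name and modularity are
returned together.

Two networks are compared by the unweighted edge Jaccard index and by
DeltaCon similarity $1/(1+d)$, where $d$ is the Matusita distance between
the exact fast-belief-propagation affinity matrices
$(I + \epsilon^2 D - \epsilon A)^{-1}$, $\epsilon = 1/(1+\max \deg)$ per
graph. Disease networks are small, so the exact dense solve is used
rather than the approximate algorithm.

Subtype dependence of individual disease pairs is tested by the
Breslow–Day chi-square for odds-ratio homogeneity across two strata
(Tarone-corrected by default), with a +0.5 continuity correction applied
to all four cells of any table containing a zero (and flagged); pairs
with a zero margin in a stratum are skipped with a reason rather than
producing a spurious statistic.

## Cohort profiles

Multiple correspondence analysis uses the complete disjunctive coding
(presence and absence both coded, the convention of the standard MCA
implementations) and the SVD of the standardized residual matrix of the
indicator table. Patient coordinates are principal row coordinates;
per-dimension inertia is reported as a percentage of the indicator-matrix
total inertia, and the decomposition conserves that total to numerical
precision. Up to `min(50, rank)` dimensions are examined by default.
Covariate-explained variance is the sum of inertia percentages over
dimensions whose OLS regression on the covariate is significant at
p < 0.05 (factors use the overall F-test), following the
regress-and-sum convention.

The subtype classifier is an elastic-net logistic regression
(`glmnet`, mixing 0.5 by default, 20-value log-scale penalty grid,
5-fold stratified CV maximizing AUROC). Forward selection then grows the
feature set along the nonzero coefficients ordered by magnitude, refits
an L1 model per size, and selects the smallest size within 0.002 AUROC
of the maximum — a plateau rule standing in for a visual choice of model
size. Assignments inherit the coefficient sign (positive pulls towards
the second factor level).

Patient-to-cluster similarity is the Jaccard index between the patient's
disease set (restricted, by default, to diseases covered by the
partition) and the cluster members. Cohort contrasts use the unpaired
two-sided Wilcoxon rank-sum test per cluster, reported as
$-\log_{10}(p)$ signed by the Hodges–Lehmann location shift of the first
cohort minus the second (for very large cohorts the sign of the
Mann-Whitney U displacement is used, which agrees in direction); both raw
and BH-adjusted p-values are emitted because the corresponding published
contrasts do not state an adjustment.

## The multiplex-heterogeneous network and the walk

The heterogeneous graph joins a disease multiplex (comorbidity +
phenotype-similarity layers by default) and a gene multiplex (up to four
layers: pathway co-membership with evidence-count weights, protein
interactions, two ontology-similarity layers) through a bipartite
disease–gene table filtered at confidence strictly greater than 0.29 —
the threshold at which one curated source or several experimental ones
are required on the DisGeNET-style score scale. Gene layers can be
restricted to an expression whitelist (the union of whatever expression
evidence applies). Each layer's weights are normalized to a maximum of 1
before propagation so that no layer dominates transitions by units
alone; layer node sets are declared explicitly, so nodes isolated in one
layer (but real members of the network) stay in the universe.

The walk follows the multiplex-heterogeneous random-walk-with-restart
scheme: from a node replica, probability $\lambda$ crosses the bipartite
links (only at nodes that have them; proportional to association score,
split uniformly over the target's layer replicas); of the mass staying in
the multiplex, $1-\delta$ moves along the current layer's weighted edges
and $\delta$ jumps uniformly to the node's other replicas. Dangling
nodes pass their within-layer share to their replicas; nodes isolated
everywhere keep a self-loop (with a warning). The stationary vector
solves $p = (1-r)\,T p + r\,p_0$ by power iteration (L1 tolerance
$10^{-10}$, cap 1000 iterations, mass conservation asserted every step);
$r=1$ returns the restart vector exactly, and the iterative solution is
validated against the direct linear solve in the tests. Defaults
$r = 0.7$, $\delta = 0.5$, $\lambda = 0.5$, uniform layer restart
weights $\tau$ follow the published multiplex-RWR method, since the
analysis that motivated this package does not state its values; all are
exposed in `rwr_params()`. Seed profiles weight diseases uniformly by
default (coefficient-weighted seeding is available), and restart mass is
spread over disease layers by $\tau$.

A gene's score aggregates its replica probabilities by sum (mean
optional); ranks break ties lexicographically by gene id so results are
reproducible to the last position. Subtype prioritization scores the
top-500 genes of profile A (the published analyses observed about 500
genes with non-zero probability) as $G_i = P_i\,|\Delta R_i|$ with
$\Delta R_i = R_i(B) - R_i(A)$; genes ranked *worse* in A are retained
but flagged, because $|\Delta R|$ is sign-blind while the interpretation
usually wants genes close to A.

## Evaluation

Leave-one-out link prediction: for each disease with ≥ 2 bipartite
links, those links are removed, the transition rebuilt, the walk run from
the disease alone, and the held-out genes scored within the genome-wide
ranking by AUROC (computed by the Mann–Whitney identity with midranks),
average precision (the step-wise formulation, stable for positive
fractions of a percent), and rank ratio (median target rank over number
of genes). The candidate set is all genes by default — the alternative of
excluding directly-connected genes is selectable. The operation is pure:
the input network is untouched.

Nulls: (i) a degree-preserving rewired comorbidity layer
(double-edge swaps, 10·|E| attempts, weights travelling with edges),
implemented in-package because the swaps must preserve edge weights and
be reproducible under a seed; (ii) random seed profiles of matched size
(optionally degree-matched), summarized as z-scores of AUROC and average
precision.

Pre-ranked GSEA uses the weighted Kolmogorov–Smirnov running sum (weight
exponent 1 by default; 0 gives the classic KS), evaluated analytically at
hit positions. Significance comes from plain same-size gene-set
resampling (default 10,000 draws) with add-one smoothing, and
NES = ES / mean(|null ES| of matching sign); the adaptive multilevel
estimation of very small p-values is out of scope, because the decisions
taken downstream only require p at conventional thresholds. Positive
extrema win exact-magnitude ties, with a small tolerance so that
floating-point rounding cannot flip the reported sign.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes,
with every effect planted and recorded in a ground-truth object:

* **Cohort.** Patients get a balanced subtype A/B, an age group
  (30/45/25% for 40–59/60–79/80+), a sex, and one disease cluster
  (two with probability 0.3, giving the overlapping-comorbidity texture
  of real cohorts). Disease baseline prevalences are log-uniform on
  [0.02, 0.25] — the frequent-disease panel of a hospitalized cohort,
  mimicking heavy-tailed code prevalence. A disease's occurrence odds are
  multiplied by `within_cluster_odds` (default 6) when the patient
  carries its cluster, and by `marker_odds^{±1/2}` per subtype for the
  marker diseases (default 10 markers at odds ratio 3). The 80+ age group
  tilts cluster 1 and female sex cluster 2 (odds 2), enabling age/sex
  contrasts. Everything is reproducible from one integer seed.
* **Gene layers.** Preferential-attachment graphs over a shared universe
  (heavy-tailed degrees; labels permuted per layer so hubs differ);
  weighted layers carry integer evidence counts 1–5. Gene modules — one
  per disease cluster — are breadth-first neighborhoods of random anchors
  in the layer-union graph, of size `n_genes / n_clusters`, giving the
  network-local structure that guilt-by-association needs.
* **Bipartite map.** Each disease draws `genes_per_disease` genes from
  its cluster's module with probability `module_locality`, else
  uniformly; confidence scores are uniform on [0.05, 1] so the strict
  0.29 filter bites (retaining ≈ 75%).
* **Phenotype layer.** Same-cluster disease pairs connect with
  probability `concordance`, cross-cluster pairs at a tenth of it.
* **Signature.** Standard-normal t-statistics with the planted genes
  (a slice of cluster 1's module) shifted by `signature_shift`.

What the generator does *not* emulate: diagnosis-code semantics, visit
timing and longitudinal sequence (the analysis is cross-sectional),
age-dependent prevalence trajectories, and any real phenotype-ontology
structure — the phenotype layer is a structural stand-in driven by the
planted clusters, not a reconstruction of an ontology network. Passing
tests therefore demonstrate that the machinery recovers *planted*
structure of realistic shape and strength, not that any particular
biological claim holds on real data.

## Study sizes and benchmark conditions

Unit tests use toy objects with closed-form answers. The simulation
studies use these sizes, chosen once as realistic for the scale of the
problem:

* **Null false-discovery control:** 20 cohorts of 20,000 patients × 120
  diseases with all effects off; retained edges are counted against
  $2\alpha$ × pairs tested.
* **Cluster recovery:** 5,000 patients, 60 diseases, 6 clusters at the
  default within-cluster odds; adjusted Rand index vs the planted
  partition.
* **Classifier:** 5,000 patients, 10 markers at odds ratio 3; marker
  recovery in the forward-selected profile and chance-level AUROC under
  label permutation.
* **Propagation/evaluation benchmark** (`hetnet_study_config()`): 1,600
  patients, 60 diseases in 6 clusters, 600 genes in two layers, 50
  associations per disease at 90% module locality, phenotype concordance
  0.3. The cohort size is deliberately modest so that the comorbidity
  layer is informative but incomplete — the regime in which an auxiliary
  phenotype layer genuinely complements co-occurrence data (with a
  saturated comorbidity layer any extra disease layer is redundant and
  its cross-cluster noise can only dilute). Under these conditions the
  leave-one-out ordering *full ≥ no-phenolayer ≥ rewired* reflects the
  method's true behaviour, with full recovery above and rewired recovery
  below an AUROC of 0.75.

## Numerical choices and edge cases

* Fisher p-values use the unimodality of the hypergeometric pmf to find
  the opposite-tail boundary by bisection (exact, no normal
  approximation), with the conventional $1+10^{-7}$ relative tolerance on
  the point-probability comparison.
* Degenerate diseases (prevalence 0 or n) get `NA` statistics and are
  never edge-eligible; an empty network is a warning, not an error.
* MCA drops constant disease columns with a warning (they carry no
  inertia); eigendecomposition is done on the category-space
  cross-product, so cost scales with diseases, not patients.
* Breslow–Day expected cells solve the common-OR quadratic by a
  bracketed root on the admissible interval, robust for the
  continuity-corrected non-integer tables.
* All-tied Wilcoxon contrasts report p = 1 and sign 0; patients with no
  qualifying disease get zero similarity and are flagged.
* Rewiring skips (and counts) swap attempts that would create self-loops
  or duplicate edges, keeping the degree sequence exact.

## Known limitations

* The walk's transition matrix is built densely per leave-one-out
  disease (sparse in storage, full rebuild in time); for universes far
  beyond ~10⁴ supra-nodes an incremental update would be preferable.
* The forward-selection plateau rule (0.002 AUROC) is a reasonable
  default but, like any plateau rule, can select slightly different sizes
  under CV noise; the full size-vs-AUROC path is returned for inspection.
* Permutation GSEA p-values are floored at 1/(n_perm+1); for
  leading-edge-sensitive analyses at extreme significance a larger
  permutation budget is needed.
* The phenotype-similarity generator ties phenotypic relatedness to the
  planted comorbidity clusters; real ontology-derived similarity carries
  information (shared-gene structure) that this stand-in represents only
  through cluster concordance.
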