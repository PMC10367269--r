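# comorbnet

Comorbidity-network medicine in R: from a binary patient×diagnosis matrix
to prioritized disease genes.

Complex syndromes — heart failure with preserved ejection fraction is the
motivating example — are driven by their comorbidity spectrum as much as by
any single lesion. `comorbnet` implements a full analysis chain for that
idea:

1. **Comorbidity network construction.** For every disease pair, a
   two-sided Fisher exact test on the 2×2 co-occurrence table with
   Benjamini–Hochberg correction (default q < 1e-4) selects edges; the φ
   correlation (Pearson correlation of the binary indicators,
   φ = (ad − bc)/√((a+b)(c+d)(a+c)(b+d))) gives edge strength. Retained
   positive correlations are rescaled by the endpoint diseases' mean φ
   (W = φᵢⱼ/√(m̄ᵢ·m̄ⱼ)) to reduce hub bias, and the distance score
   S = max(W) − W supports shortest-path centralities. Weighted Louvain
   clustering yields disease clusters (DCs).
2. **Cohort profiling.** Multiple correspondence analysis of the
   disjunctive-coded diagnosis matrix attributes comorbidity variance to
   clinical covariates; an elastic-net classifier plus L1 forward selection
   derives a compact subtype-discriminative comorbidity profile; per-patient
   Jaccard similarity to each DC supports signed Wilcoxon cohort contrasts.
3. **Multiplex-heterogeneous network propagation.** The disease multiplex
   (comorbidity + phenotype-similarity layers) is joined to a multilayer
   gene network through confidence-filtered disease–gene associations
   (score > 0.29). A random walk with restart on the multiplex-heterogeneous
   graph (restart r, inter-layer jump δ, inter-network jump λ) turns a
   comorbidity profile into a stationary probability over genes; candidates
   specific to one profile are scored Gᵢ = Pᵢ·|ΔRᵢ|, the walk probability
   times the absolute rank difference between the two profiles' rankings.
4. **Evaluation.** Leave-one-out link prediction (AUROC, average precision,
   rank ratio) against rewired-network and random-seed nulls, plus
   pre-ranked GSEA of the predicted genes in a transcriptomic signature.

A synthetic-data module generates all inputs with planted ground truth
(disease clusters, subtype markers, gene modules, shifted signatures), so
the whole pipeline is testable end to end without any external database.

## Worked example

```r
library(comorbnet)

st  <- generate_synthetic_study(hetnet_study_config(seed = 1))
net <- build_network(pairwise_association(st$dm))
net
#> disease_network: 60 diseases, 40 retained comorbidity edges (BH q < 1e-04 , phi > 0)
#>   weight W in [0.867, 1.221], geometric endpoint-mean scaling

cl <- detect_clusters(net, seed = 1)
cl
#> disease_clusters: 8 clusters over 36 diseases ( louvain , modularity 0.807 )

hn <- assemble_hetnet(list(as_layer(net), st$phenolayer), st$gene_layers,
                      filter_bipartite(st$bipartite, 0.29))
hn
#> hetnet: 60 diseases x 2 layers; 600 genes x 2 layers; 1953 bipartite links

pars <- rwr_params()                       # r = 0.7, delta = lambda = 0.5
tr   <- build_transition(hn, pars)
prof <- seed_profile(names(which(st$truth$cluster_of_disease == 1)), "DC1")
res  <- rwr(tr, prof, pars)
res
#> rwr_result ('DC1'): 600 genes ranked; converged in 16 iterations
#>   top genes: g0497, g0125, g0435, g0519, g0423

loo <- loo_recovery(hn, pars)
median(loo$auroc)
#> [1] 0.8162826
```

The network print shows how many disease pairs survive the exact-test
screen at this deliberately modest cohort size; the cluster modularity
(0.81) reflects the planted community
structure; the leave-one-out median AUROC (~0.82) says that held-out
disease genes rank in the top fifth of the genome-wide ranking when
predicted purely from network context.

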