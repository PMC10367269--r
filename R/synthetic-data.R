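#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data module. The generator plants
#' known structure — disease clusters, subtype-discriminative marker
#' diseases, modular disease-gene associations, scale-free gene layers, a
#' partially concordant phenotype-similarity layer and a shifted
#' transcriptomic signature — so that every downstream stage of the
#' pipeline can be exercised and validated against ground truth without
#' any external data.
#'
#' @param n_patients,n_diseases,n_clusters cohort dimensions; diseases are
#'   split evenly over clusters.
#' @param base_prevalence_range range of per-disease baseline prevalence;
#'   prevalences are drawn log-uniformly to mimic the heavy-tailed
#'   prevalence distribution of aggregated diagnosis codes.
#' @param within_cluster_odds odds multiplier (>= 1) applied to a disease
#'   when the patient carries the disease's cluster.
#' @param p_two_clusters probability that a patient samples two clusters
#'   instead of one (overlapping comorbidity texture).
#' @param n_subtype_markers number of marker diseases whose odds differ
#'   between subtypes A and B (half favour each subtype).
#' @param marker_odds odds ratio (>= 1) of a marker disease between the
#'   favoured and the other subtype.
#' @param covariate_bias_odds odds multiplier tilting cluster 1 towards
#'   the 80+ age group and cluster 2 towards female patients, enabling
#'   age/sex cohort contrasts.
#' @param n_genes size of the shared gene universe.
#' @param gene_layers list of layer specs, each a list with `name`,
#'   `mean_degree` and `weighted`; layers are preferential-attachment
#'   graphs over the shared universe, weighted layers carry integer
#'   evidence counts in 1..5.
#' @param genes_per_disease bipartite associations drawn per disease.
#' @param module_locality probability that a disease's gene is drawn from
#'   its cluster's gene module rather than uniformly.
#' @param phenolayer_concordance probability that a same-cluster disease
#'   pair is connected in the phenotype-similarity layer (cross-cluster
#'   pairs connect at a tenth of that rate).
#' @param signature_shift mean shift added to planted signature genes'
#'   t-statistics.
#' @param seed integer seed; all generators derive their randomness from
#'   it and are fully reproducible.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 5000, n_diseases = 60, n_clusters = 6,
                         base_prevalence_range = c(0.02, 0.25),
                         within_cluster_odds = 6, p_two_clusters = 0.3,
                         n_subtype_markers = 10, marker_odds = 3,
                         covariate_bias_odds = 2,
                         n_genes = 600,
                         gene_layers = list(
                           list(name = "pathway", mean_degree = 6, weighted = TRUE),
                           list(name = "ppi", mean_degree = 4, weighted = FALSE),
                           list(name = "go_bp", mean_degree = 8, weighted = FALSE),
                           list(name = "go_mf", mean_degree = 8, weighted = FALSE)),
                         genes_per_disease = 50, module_locality = 0.9,
                         phenolayer_concordance = 0.3,
                         signature_shift = 3, seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_diseases = as.integer(n_diseases),
              n_clusters = as.integer(n_clusters),
              base_prevalence_range = as.numeric(base_prevalence_range),
              within_cluster_odds = within_cluster_odds,
              p_two_clusters = p_two_clusters,
              n_subtype_markers = as.integer(n_subtype_markers),
              marker_odds = marker_odds,
              covariate_bias_odds = covariate_bias_odds,
              n_genes = as.integer(n_genes), gene_layers = gene_layers,
              genes_per_disease = as.integer(genes_per_disease),
              module_locality = module_locality,
              phenolayer_concordance = phenolayer_concordance,
              signature_shift = signature_shift, seed = as.integer(seed))
  stopifnot(cfg$n_patients > 0, cfg$n_diseases > 0, cfg$n_clusters > 0,
            cfg$n_clusters <= cfg$n_diseases,
            length(cfg$base_prevalence_range) == 2,
            all(cfg$base_prevalence_range >= 0),
            all(cfg$base_prevalence_range <= 1),
            cfg$within_cluster_odds >= 1, cfg$marker_odds >= 1,
            cfg$p_two_clusters >= 0, cfg$p_two_clusters <= 1,
            cfg$module_locality >= 0, cfg$module_locality <= 1,
            cfg$phenolayer_concordance >= 0, cfg$phenolayer_concordance <= 1,
            cfg$n_subtype_markers >= 0, cfg$genes_per_disease >= 0,
            cfg$n_genes > 0)
  class(cfg) <- "synth_config"
  cfg
}

disease_codes <- function(cfg) sprintf("d%03d", seq_len(cfg$n_diseases))
gene_ids <- function(cfg) sprintf("g%04d", seq_len(cfg$n_genes))

#' Generate a synthetic patient cohort with planted structure
#'
#' Every patient is assigned a subtype (A/B, balanced), an age group and a
#' sex, then samples one cluster (or two, with probability
#' `p_two_clusters`). Disease occurrence is Bernoulli with a log-odds
#' equal to the disease's logit baseline prevalence, raised by
#' `log(within_cluster_odds)` when the disease belongs to one of the
#' patient's clusters, and shifted by `±log(marker_odds)/2` for marker
#' diseases according to the patient's subtype, so that the A-vs-B odds
#' ratio of a `+1` marker equals `marker_odds` (and its inverse for `-1`
#' markers). Cluster 1 membership odds rise with the 80+ age group and
#' cluster 2 with female sex (factor `covariate_bias_odds`).
#'
#' @param cfg a [synth_config()].
#' @return list with `dm` (a [diagnosis_matrix()] whose covariates carry
#'   `subtype`, `age_group`, `sex`) and `truth` (a `synth_truth` list with
#'   `cluster_of_disease`, `subtype_marker_sign`, and slots for gene
#'   modules and planted signature genes filled by the later generators).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (all(cfg$base_prevalence_range == 0))
    stop("expected disease count per patient is zero (all base prevalences 0)")
  set.seed(cfg$seed)
  n <- cfg$n_patients; d <- cfg$n_diseases; k <- cfg$n_clusters
  dis <- disease_codes(cfg)

  cluster_of_disease <- stats::setNames(sort(rep(seq_len(k), length.out = d)),
                                        dis)
  marker_sign <- stats::setNames(integer(d), dis)
  if (cfg$n_subtype_markers > 0) {
    idx <- sample.int(d, min(cfg$n_subtype_markers, d))
    marker_sign[idx] <- rep(c(1L, -1L), length.out = length(idx))
  }

  pr <- cfg$base_prevalence_range
  base_prev <- exp(stats::runif(d, log(max(pr[1], 1e-6)), log(max(pr[2], 1e-6))))

  subtype <- sample(rep(c("A", "B"), length.out = n))
  age_group <- sample(c("40-59", "60-79", "80+"), n, replace = TRUE,
                      prob = c(0.30, 0.45, 0.25))
  sex <- sample(c("F", "M"), n, replace = TRUE)

  # per-patient cluster draws; covariates tilt clusters 1 and 2
  cl1 <- integer(n); cl2 <- rep(NA_integer_, n)
  two <- k >= 2 & stats::rbinom(n, 1, cfg$p_two_clusters) == 1
  w0 <- rep(1, k)
  strata <- interaction(age_group == "80+", sex == "F", drop = FALSE)
  for (s in levels(strata)) {
    ii <- which(strata == s)
    if (!length(ii)) next
    w <- w0
    if (grepl("^TRUE", s)) w[1] <- w[1] * cfg$covariate_bias_odds
    if (grepl("TRUE$", s) && k >= 2) w[2] <- w[2] * cfg$covariate_bias_odds
    cl1[ii] <- sample.int(k, length(ii), replace = TRUE, prob = w)
  }
  if (any(two)) {
    cl2[two] <- sample.int(k, sum(two), replace = TRUE)
    while (any(bad <- !is.na(cl2) & cl2 == cl1))
      cl2[bad] <- sample.int(k, sum(bad), replace = TRUE)
  }

  logit <- matrix(stats::qlogis(base_prev), n, d, byrow = TRUE)
  bump <- log(cfg$within_cluster_odds)
  if (bump != 0) {
    for (c in seq_len(k)) {
      cols <- which(cluster_of_disease == c)
      rows <- which(cl1 == c | (!is.na(cl2) & cl2 == c))
      if (length(cols) && length(rows)) logit[rows, cols] <-
          logit[rows, cols] + bump
    }
  }
  if (cfg$marker_odds > 1 && any(marker_sign != 0)) {
    subt <- ifelse(subtype == "A", 1, -1)
    for (j in which(marker_sign != 0))
      logit[, j] <- logit[, j] +
        0.5 * log(cfg$marker_odds) * marker_sign[j] * subt
  }
  x <- stats::runif(n * d) < stats::plogis(as.vector(logit))
  hit <- which(x)
  occ <- Matrix::sparseMatrix(
    i = (hit - 1L) %% n + 1L, j = (hit - 1L) %/% n + 1L, x = 1,
    dims = c(n, d),
    dimnames = list(sprintf("p%05d", seq_len(n)), dis))
  cov <- data.frame(subtype = subtype, age_group = age_group, sex = sex,
                    cluster1 = cl1, cluster2 = cl2,
                    row.names = rownames(occ))
  truth <- structure(
    list(cluster_of_disease = cluster_of_disease,
         subtype_marker_sign = marker_sign,
         gene_module_of_cluster = NULL,
         planted_signature_genes = NULL,
         genes = NULL),
    class = "synth_truth")
  list(dm = diagnosis_matrix(occ, cov), truth = truth)
}

#' Generate scale-free gene layers and assign cluster gene modules
#'
#' Each configured layer is an independent preferential-attachment graph
#' over the shared gene universe (labels permuted per layer so hubs
#' differ); weighted layers carry integer evidence counts in 1..5,
#' emulating the number of resources reporting a relationship. Gene
#' modules — one per disease cluster, the substrate of guilt-by-association
#' structure — are breadth-first neighborhoods of random anchor genes in
#' the union graph, of size `n_genes / n_clusters`, disjoint across
#' clusters. The first cluster's module also seeds the planted signature
#' genes (up to 30).
#'
#' @param cfg a [synth_config()].
#' @param truth the `synth_truth` from [generate_cohort()].
#' @return list with `layers` (list of [layer_spec()] of kind `"gene"`)
#'   and `truth` (updated with `gene_module_of_cluster`,
#'   `planted_signature_genes`, `genes`).
#' @export
generate_gene_layers <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed + 1000L)
  genes <- gene_ids(cfg)
  n <- cfg$n_genes
  layers <- lapply(cfg$gene_layers, function(ls) {
    m <- max(1L, round(ls$mean_degree / 2))
    g <- igraph::sample_pa(n, m = m, directed = FALSE)
    g <- igraph::simplify(g)
    perm <- sample.int(n)
    el <- igraph::as_edgelist(g, names = FALSE)
    ed <- data.frame(from = genes[perm[el[, 1]]], to = genes[perm[el[, 2]]])
    ed$weight <- if (isTRUE(ls$weighted))
      sample(1:5, nrow(ed), replace = TRUE,
             prob = c(0.45, 0.25, 0.15, 0.10, 0.05)) else rep(1, nrow(ed))
    layer_spec(ls$name, "gene", ed, weighted = isTRUE(ls$weighted),
               nodes = genes)
  })

  union_el <- unique(do.call(rbind, lapply(layers, function(l)
    l$edges[, c("from", "to")])))
  gu <- igraph::graph_from_data_frame(union_el, directed = FALSE,
                                      vertices = genes)
  msize <- max(1L, floor(n / cfg$n_clusters))
  assigned <- character(0)
  modules <- vector("list", cfg$n_clusters)
  for (c in seq_len(cfg$n_clusters)) {
    free <- setdiff(genes, assigned)
    anchor <- sample(free, 1)
    ord <- igraph::bfs(gu, root = anchor, unreachable = FALSE)$order
    ord <- names(ord)[!is.na(ord)]
    pick <- setdiff(ord, assigned)
    if (length(pick) < msize) pick <- c(pick, setdiff(free, pick))
    modules[[c]] <- sort(utils::head(pick, msize))
    assigned <- c(assigned, modules[[c]])
  }
  names(modules) <- as.character(seq_len(cfg$n_clusters))
  truth$gene_module_of_cluster <- modules
  truth$planted_signature_genes <- utils::head(modules[[1]], 30)
  truth$genes <- genes
  list(layers = layers, truth = truth)
}

#' Generate the synthetic disease-gene bipartite table
#'
#' Each disease draws `genes_per_disease` genes: with probability
#' `module_locality` from its cluster's gene module, otherwise uniformly
#' from the universe. Confidence scores are uniform on \[0.05, 1\] so a
#' downstream confidence filter is exercised. Duplicate (disease, gene)
#' pairs keep the maximum score.
#'
#' @param cfg a [synth_config()].
#' @param truth a `synth_truth` with gene modules assigned.
#' @return data.frame with columns `disease`, `gene`, `score`.
#' @export
generate_bipartite <- function(cfg, truth) {
  stopifnot(inherits(cfg, "synth_config"),
            !is.null(truth$gene_module_of_cluster))
  set.seed(cfg$seed + 2000L)
  genes <- truth$genes
  rows <- lapply(names(truth$cluster_of_disease), function(d) {
    mod <- truth$gene_module_of_cluster[[
      as.character(truth$cluster_of_disease[[d]])]]
    inmod <- stats::runif(cfg$genes_per_disease) < cfg$module_locality
    g <- character(cfg$genes_per_disease)
    if (any(inmod)) g[inmod] <- sample(mod, sum(inmod), replace = TRUE)
    if (any(!inmod)) g[!inmod] <- sample(genes, sum(!inmod), replace = TRUE)
    data.frame(disease = d, gene = g)
  })
  tab <- do.call(rbind, rows)
  tab$score <- stats::runif(nrow(tab), 0.05, 1)
  tab <- tab[order(tab$disease, tab$gene, -tab$score), ]
  tab <- tab[!duplicated(tab[, c("disease", "gene")]), ]
  rownames(tab) <- NULL
  tab
}

#' Generate the synthetic phenotype-similarity disease layer
#'
#' Same-cluster disease pairs connect with probability `concordance`,
#' cross-cluster pairs with `concordance / 10`, producing a disease layer
#' partially concordant with the planted comorbidity clusters.
#'
#' @param truth a `synth_truth`.
#' @param concordance probability in \[0, 1\].
#' @param seed integer seed.
#' @return a [layer_spec()] of kind `"disease"` (possibly empty).
#' @export
generate_phenolayer <- function(truth, concordance, seed = 1L) {
  stopifnot(concordance >= 0, concordance <= 1)
  set.seed(seed + 3000L)
  dis <- names(truth$cluster_of_disease)
  cl <- truth$cluster_of_disease
  idx <- which(upper.tri(matrix(0, length(dis), length(dis))), arr.ind = TRUE)
  same <- cl[idx[, 1]] == cl[idx[, 2]]
  p <- ifelse(same, concordance, concordance / 10)
  keep <- stats::runif(nrow(idx)) < p
  ed <- data.frame(from = dis[idx[keep, 1]], to = dis[idx[keep, 2]],
                   weight = rep(1, sum(keep)))
  layer_spec("phenotype_similarity", "disease", ed, weighted = FALSE,
             nodes = dis)
}

#' Generate a ranked synthetic transcriptomic signature
#'
#' One t-statistic per gene, standard normal, with
#' `truth$planted_signature_genes` shifted by `+shift`; the table is
#' sorted by decreasing t.
#'
#' @param truth a `synth_truth` with genes assigned.
#' @param shift real effect size.
#' @param seed integer seed.
#' @return data.frame with columns `gene`, `t`.
#' @export
generate_signature <- function(truth, shift, seed = 1L) {
  stopifnot(!is.null(truth$genes))
  set.seed(seed + 4000L)
  t <- stats::rnorm(length(truth$genes))
  names(t) <- truth$genes
  t[truth$planted_signature_genes] <- t[truth$planted_signature_genes] + shift
  out <- data.frame(gene = names(t), t = unname(t))
  out <- out[order(-out$t), ]
  rownames(out) <- NULL
  out
}

#' Generate the complete synthetic study
#'
#' Convenience wrapper running every generator with a single
#' configuration.
#'
#' @param cfg a [synth_config()].
#' @return list with `dm`, `truth`, `gene_layers`, `bipartite`,
#'   `phenolayer`, `signature`.
#' @export
generate_synthetic_study <- function(cfg = synth_config()) {
  co <- generate_cohort(cfg)
  gl <- generate_gene_layers(cfg, co$truth)
  bip <- generate_bipartite(cfg, gl$truth)
  pheno <- generate_phenolayer(gl$truth, cfg$phenolayer_concordance,
                               seed = cfg$seed)
  sig <- generate_signature(gl$truth, cfg$signature_shift, seed = cfg$seed)
  list(dm = co$dm, truth = gl$truth, gene_layers = gl$layers,
       bipartite = bip, phenolayer = pheno, signature = sig)
}

#' Benchmark conditions for the propagation-evaluation study
#'
#' The synthetic study configuration used throughout the package to
#' benchmark multiplex propagation and leave-one-out disease-gene
#' recovery: a modest cohort (1600 patients) so the comorbidity layer is
#' informative but incomplete — the regime in which an auxiliary
#' phenotype-similarity layer is complementary rather than redundant — a
#' 60-disease panel in 6 clusters, a DisGeNET-density bipartite map (50
#' associations per disease, 90% module-local), and a two-layer gene
#' multiplex (weighted pathway layer, unweighted interaction layer) over
#' 600 genes.
#'
#' @param seed integer seed.
#' @return a [synth_config()].
#' @export
hetnet_study_config <- function(seed = 1L) {
  synth_config(n_patients = 1600, n_diseases = 60, n_clusters = 6,
               n_genes = 600, gene_layers = list(
                 list(name = "pathway", mean_degree = 6, weighted = TRUE),
                 list(name = "ppi", mean_degree = 4, weighted = FALSE)),
               genes_per_disease = 50, module_locality = 0.9,
               phenolayer_concordance = 0.3, seed = seed)
}

#' Write all synthetic study inputs as plain-text files
#'
#' Emits the long-format cohort TSV, covariates TSV, one edge-list TSV per
#' gene layer, the phenotype-similarity layer TSV, the bipartite
#' disease-gene TSV, the ranked signature TSV, and the ground truth as
#' JSON (requires jsonlite).
#'
#' @param study result of [generate_synthetic_study()].
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of written paths.
#' @export
write_synthetic_inputs <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "diagnoses.tsv"), file.path(dir, "covariates.tsv"))
  write_diagnosis_matrix(study$dm, paths[1], paths[2])
  wtsv <- function(x, f) {
    utils::write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }
  for (l in study$gene_layers)
    paths <- c(paths, wtsv(l$edges, file.path(dir, paste0("layer_", l$name, ".tsv"))))
  paths <- c(paths,
             wtsv(study$phenolayer$edges, file.path(dir, "phenolayer.tsv")),
             wtsv(study$bipartite, file.path(dir, "disease_gene.tsv")),
             wtsv(study$signature, file.path(dir, "signature.tsv")))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    gt <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(
      list(cluster_of_disease = as.list(study$truth$cluster_of_disease),
           subtype_marker_sign = as.list(study$truth$subtype_marker_sign),
           gene_module_of_cluster = study$truth$gene_module_of_cluster,
           planted_signature_genes = study$truth$planted_signature_genes),
      gt, auto_unbox = TRUE)
    paths <- c(paths, gt)
  }
  invisible(paths)
}
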