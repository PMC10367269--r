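test_that("degenerate parameters reduce to the classic weighted walk", {
  gl <- layer_spec("l1", "gene",
                   data.frame(from = c("g1", "g2", "g1"),
                              to = c("g2", "g3", "g3"),
                              weight = c(1, 2, 3)))
  dl <- layer_spec("como", "disease",
                   data.frame(from = "d1", to = "d2", weight = 1))
  hn <- assemble_hetnet(list(dl), list(gl),
                        data.frame(disease = character(0),
                                   gene = character(0),
                                   score = numeric(0)))
  pars <- rwr_params(interlayer_delta = 0, internetwork_lambda = 0)
  tr <- build_transition(hn, pars)
  # gene block: classic column-normalized weighted adjacency
  gidx <- which(tr$index$kind == "gene")
  Tg <- as.matrix(tr$T[gidx, gidx])
  W <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  W["g1", "g2"] <- W["g2", "g1"] <- 1 / 3
  W["g2", "g3"] <- W["g3", "g2"] <- 2 / 3
  W["g1", "g3"] <- W["g3", "g1"] <- 1  # weights normalized to max 1
  Tw <- sweep(W, 2, colSums(W), "/")
  expect_equal(unname(Tg), unname(Tw), tolerance = 1e-12)
})

test_that("every transition column sums to one on assorted hetnets", {
  for (two in c(FALSE, TRUE)) {
    hn <- toy_hetnet(two_gene_layers = two)
    for (delta in c(0, 0.5)) for (lambda in c(0, 0.5, 1)) {
      tr <- build_transition(hn, rwr_params(interlayer_delta = delta,
                                            internetwork_lambda = lambda))
      expect_equal(max(abs(Matrix::colSums(tr$T) - 1)), 0,
                   tolerance = 1e-12)
    }
  }
})

test_that("two-layer toy multiplex matches hand-computed transition entries", {
  # gene multiplex: layer A path g1-g2 (w 1), layer B edge g2-g3 (w 1);
  # no bipartite crossing from genes (lambda irrelevant at genes without
  # links); disease side minimal
  glA <- layer_spec("A", "gene", data.frame(from = "g1", to = "g2",
                                            weight = 1),
                    nodes = paste0("g", 1:3))
  glB <- layer_spec("B", "gene", data.frame(from = "g2", to = "g3",
                                            weight = 1),
                    nodes = paste0("g", 1:3))
  dl <- layer_spec("como", "disease",
                   data.frame(from = "d1", to = "d2", weight = 1))
  hn <- suppressWarnings(
    assemble_hetnet(list(dl), list(glA, glB),
                    data.frame(disease = character(0),
                               gene = character(0), score = numeric(0))))
  delta <- 0.4
  tr <- build_transition(hn, rwr_params(interlayer_delta = delta,
                                        internetwork_lambda = 0.3))
  ix <- tr$index
  at <- function(layer, node) which(ix$layer == layer & ix$node == node)
  Tm <- tr$T
  # from (A, g1): within-layer to g2 gets 1-delta, replica (B, g1) delta
  expect_equal(Tm[at("A", "g2"), at("A", "g1")], 1 - delta)
  expect_equal(Tm[at("B", "g1"), at("A", "g1")], delta)
  # from (A, g3): dangling in layer A -> all mass to replica (B, g3)
  expect_equal(Tm[at("B", "g3"), at("A", "g3")], 1)
  # from (B, g2): within to g3 1-delta, replica (A, g2) delta
  expect_equal(Tm[at("A", "g2"), at("B", "g2")], delta)
  expect_equal(Tm[at("B", "g3"), at("B", "g2")], 1 - delta)
})

test_that("restart-only walk returns the seed distribution exactly", {
  hn <- toy_hetnet(two_gene_layers = TRUE)
  pars <- rwr_params(restart_r = 1)
  tr <- build_transition(hn, pars)
  res <- rwr(tr, seed_profile(c("da", "dc")), pars)
  p <- res$probabilities
  expect_equal(sum(p$p[p$node %in% c("da", "dc")]), 1)
  expect_equal(p$p[p$node == "da" & p$layer == "comorbidity"], 0.5)
  expect_equal(sum(p$p), 1, tolerance = 1e-12)
})

test_that("mirror-symmetric network spreads probability symmetrically", {
  # path da-db-dc with equal weights, symmetric bipartite: seed at center
  dl <- layer_spec("como", "disease",
                   data.frame(from = c("da", "db"), to = c("db", "dc"),
                              weight = 1))
  gl <- layer_spec("ppi", "gene",
                   data.frame(from = c("g1", "g2"), to = c("g2", "g3"),
                              weight = 1))
  bip <- data.frame(disease = c("da", "dc"), gene = c("g1", "g3"),
                    score = 1)
  hn <- assemble_hetnet(list(dl), list(gl), bip)
  pars <- rwr_params()
  res <- rwr(build_transition(hn, pars), seed_profile("db"), pars)
  expect_equal(res$gene_scores[["g1"]], res$gene_scores[["g3"]],
               tolerance = 1e-9)
  p <- res$probabilities
  expect_equal(p$p[p$node == "da"], p$p[p$node == "dc"], tolerance = 1e-9)
})

test_that("power iteration agrees with the closed-form linear solve", {
  set.seed(14)
  cfg <- synth_config(n_patients = 400, n_diseases = 12, n_clusters = 3,
                      n_genes = 60, genes_per_disease = 6,
                      gene_layers = list(
                        list(name = "pathway", mean_degree = 4,
                             weighted = TRUE),
                        list(name = "ppi", mean_degree = 4,
                             weighted = FALSE)), seed = 14)
  st <- generate_synthetic_study(cfg)
  net <- suppressWarnings(build_network(pairwise_association(st$dm),
                                        alpha = 0.05))
  hn <- assemble_hetnet(list(as_layer(net), st$phenolayer),
                        st$gene_layers,
                        filter_bipartite(st$bipartite, 0.29))
  for (r in c(0.3, 0.7)) {
    pars <- rwr_params(restart_r = r, tol = 1e-14)
    tr <- suppressWarnings(build_transition(hn, pars))
    expect_lte(nrow(tr$index), 200)
    seeds <- seed_profile(hn$disease_universe[c(1, 5)])
    res <- rwr(tr, seeds, pars)
    p0 <- numeric(nrow(tr$index))
    D <- length(tr$disease_universe)
    pos <- match(seeds$diseases, tr$disease_universe)
    for (l in seq_len(tr$LD))
      p0[(l - 1) * D + pos] <- 0.5 / tr$LD
    expect_equal(res$probabilities$p, oracle_rwr_solve(tr$T, p0, r),
                 tolerance = 1e-8)
  }
})

test_that("gene ranking is a deterministic permutation with lexical ties", {
  hn <- toy_hetnet(two_gene_layers = TRUE)
  pars <- rwr_params()
  res <- rwr(build_transition(hn, pars), seed_profile("da"), pars)
  expect_setequal(res$gene_ranks, seq_along(res$gene_ranks))
  expect_error(rwr(build_transition(hn, pars), seed_profile("zz"), pars),
               "absent")
})

test_that("removing all bipartite links starves the gene side", {
  hn <- toy_hetnet()
  hn$bipartite <- hn$bipartite[0, ]
  pars <- rwr_params()
  tr <- suppressWarnings(build_transition(hn, pars))
  res <- rwr(tr, seed_profile("da"), pars)
  expect_equal(sum(res$gene_scores), 0)
})

test_that("prioritization score is P times absolute rank difference", {
  mk <- function(scores) {
    ord <- order(-scores, names(scores))
    rk <- stats::setNames(integer(length(scores)), names(scores)[ord])
    rk[] <- seq_along(rk)
    structure(list(gene_scores = scores, gene_ranks = rk[names(scores)],
                   converged = TRUE, n_iter = 1, seed_label = "x"),
              class = "rwr_result")
  }
  sA <- stats::setNames(c(0.05, 0.03, 0.01, 0.002), paste0("g", 1:4))
  sB <- stats::setNames(c(0.001, 0.04, 0.03, 0.02), paste0("g", 1:4))
  out <- prioritize(mk(sA), mk(sB), top_n = 4)
  # g1: P 0.05, rank 1 in A, rank 4 in B -> G = 0.05 * 3
  expect_equal(out$score_G[out$gene == "g1"], 0.05 * 3)
  expect_false(out$worse_in_a[out$gene == "g1"])
  same <- prioritize(mk(sA), mk(sA), top_n = 4)
  expect_true(all(same$score_G == 0))
  # the worked arithmetic from the prioritization definition
  expect_equal(0.01 * abs(50 - 3), 0.47)
  sC <- stats::setNames(runif(3), paste0("h", 1:3))
  expect_error(prioritize(mk(sA), mk(sC)), "universes")
})

test_that("seeds directly linked to genes outrank distant modules", {
  st <- generate_synthetic_study(hetnet_study_config(2))
  net <- suppressWarnings(build_network(pairwise_association(st$dm)))
  hn <- assemble_hetnet(list(as_layer(net), st$phenolayer),
                        st$gene_layers,
                        filter_bipartite(st$bipartite, 0.29))
  pars <- rwr_params()
  tr <- suppressWarnings(build_transition(hn, pars))
  cl <- st$truth$cluster_of_disease
  res <- rwr(tr, seed_profile(names(cl)[cl == 1]), pars)
  direct <- unique(hn$bipartite$gene[hn$bipartite$disease %in%
                                       names(cl)[cl == 1]])
  far_mod <- setdiff(st$truth$gene_module_of_cluster[["4"]], direct)
  expect_lt(median(res$gene_ranks[direct]),
            median(res$gene_ranks[far_mod]))
})
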