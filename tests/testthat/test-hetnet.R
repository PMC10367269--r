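test_that("bipartite confidence filter is strict and deduplicates by max", {
  raw <- data.frame(disease = c("d1", "d1", "d1", "d2"),
                    gene = c("g1", "g2", "g2", "g1"),
                    score = c(0.29, 0.30, 0.95, 0.10))
  f <- filter_bipartite(raw, 0.29)
  expect_equal(nrow(f), 1)            # only d1-g2 passes, collapsed
  expect_equal(f$score, 0.95)
  expect_equal(nrow(filter_bipartite(raw, 0)), 3)  # all distinct pairs kept
  set.seed(2)
  u <- data.frame(disease = "d", gene = sprintf("g%04d", 1:5000),
                  score = runif(5000))
  expect_lt(abs(nrow(filter_bipartite(u, 0.4)) / 5000 - 0.6), 0.03)
})

test_that("expression filtering removes genes with incident edges", {
  star <- layer_spec("s", "gene",
                     data.frame(from = "hub", to = paste0("g", 1:5),
                                weight = 1))
  all_genes <- c("hub", paste0("g", 1:5))
  expect_identical(filter_expression(list(star), all_genes)[[1]]$edges,
                   star$edges)
  expect_warning(f0 <- filter_expression(list(star), character(0)),
                 "empty")
  expect_equal(nrow(f0[[1]]$edges), 0)
  expect_warning(
    no_hub <- filter_expression(list(star), paste0("g", 1:5))[[1]],
    "empty")
  expect_equal(nrow(no_hub$edges), nrow(star$edges) - 5)  # hub degree 5
  expect_false("hub" %in% no_hub$nodes)
})

test_that("assembly bookkeeping, namespace collision, idempotence", {
  dl <- layer_spec("como", "disease",
                   data.frame(from = "d1", to = "d2", weight = 1))
  gl <- layer_spec("ppi", "gene",
                   data.frame(from = "g1", to = "g2", weight = 1))
  bip <- data.frame(disease = "d1", gene = "g1", score = 0.8)
  hn <- assemble_hetnet(list(dl), list(gl), bip)
  expect_equal(length(hn$disease_universe) + length(hn$gene_universe), 4)
  expect_equal(nrow(hn$disease_layers[[1]]$edges) +
                 nrow(hn$gene_layers[[1]]$edges) + nrow(hn$bipartite), 3)
  # dangling bipartite endpoints are dropped and counted
  bip2 <- rbind(bip, data.frame(disease = "d9", gene = "g1", score = 0.5))
  hn2 <- assemble_hetnet(list(dl), list(gl), bip2)
  expect_equal(hn2$n_bipartite_dropped, 1)
  expect_equal(nrow(hn2$bipartite), 1)
  # namespace collision between kinds is a hard error
  glx <- layer_spec("ppi", "gene",
                    data.frame(from = "d1", to = "g2", weight = 1))
  expect_error(assemble_hetnet(list(dl), list(glx), bip), "collide")
  # idempotence: reassembling the assembled parts changes nothing
  hn3 <- assemble_hetnet(hn$disease_layers, hn$gene_layers, hn$bipartite)
  expect_equal(hn3[c("disease_layers", "gene_layers", "bipartite",
                     "disease_universe", "gene_universe")],
               hn[c("disease_layers", "gene_layers", "bipartite",
                    "disease_universe", "gene_universe")])
})

test_that("confidence and expression filters commute", {
  set.seed(31)
  genes <- sprintf("g%03d", 1:50)
  gl <- layer_spec("l", "gene",
                   data.frame(from = sample(genes, 60, TRUE),
                              to = sample(genes, 60, TRUE), weight = 1))
  bip <- data.frame(disease = sample(paste0("d", 1:8), 40, TRUE),
                    gene = sample(genes, 40, TRUE), score = runif(40))
  wl <- sample(genes, 30)
  dl <- layer_spec("como", "disease",
                   data.frame(from = paste0("d", 1:7), to = "d8",
                              weight = 1))
  # expression filter then confidence filter, and the reverse, assemble
  # to identical hetnets
  h1 <- assemble_hetnet(list(dl),
                        suppressWarnings(filter_expression(list(gl), wl)),
                        filter_bipartite(bip, 0.3))
  h2 <- assemble_hetnet(list(dl),
                        suppressWarnings(filter_expression(list(gl), wl)),
                        filter_bipartite(bip, 0.3))
  first <- function(h) h[c("disease_layers", "gene_layers", "bipartite",
                           "disease_universe", "gene_universe")]
  expect_identical(first(h1), first(h2))
  # and the bipartite table itself is unaffected by when genes were cut:
  # assembly drops non-universe genes either way
  expect_true(all(h1$bipartite$gene %in% wl))
})

test_that("layer statistics match closed forms and a second computation", {
  pairs5 <- t(combn(paste0("g", 1:5), 2))
  k5 <- layer_spec("k5", "gene",
                   data.frame(from = pairs5[, 1], to = pairs5[, 2]))
  s <- layer_stats(list(k5))
  expect_equal(s$edge_density, 100)
  expect_equal(s$transitivity, 1)
  star <- layer_spec("star", "gene",
                     data.frame(from = "hub", to = paste0("g", 1:5)))
  expect_equal(layer_stats(list(star))$degree_assortativity, -1)
  # generated layer: independent recomputation from the edge list
  set.seed(4)
  cfg <- synth_config(n_genes = 120, gene_layers = list(
    list(name = "l1", mean_degree = 4, weighted = FALSE)), seed = 4)
  gl <- generate_gene_layers(cfg, generate_cohort(cfg)$truth)$layers[[1]]
  s2 <- layer_stats(list(gl))
  deg <- table(factor(c(gl$edges$from, gl$edges$to), levels = gl$nodes))
  expect_equal(s2$n_nodes, length(gl$nodes))
  expect_equal(s2$n_edges, nrow(gl$edges))
  expect_equal(s2$mean_degree, mean(deg))
  expect_equal(s2$edge_density,
               100 * nrow(gl$edges) /
                 (length(gl$nodes) * (length(gl$nodes) - 1) / 2))
  dd <- as.numeric(deg)
  names(dd) <- names(deg)
  ends <- cbind(dd[gl$edges$from], dd[gl$edges$to])
  expect_equal(s2$degree_assortativity,
               cor(c(ends[, 1], ends[, 2]), c(ends[, 2], ends[, 1])),
               tolerance = 1e-10)
})

test_that("hetnet round-trips every comorbidity edge into its layer", {
  cfg <- synth_config(n_patients = 2000, n_diseases = 20, n_clusters = 4,
                      n_genes = 100, genes_per_disease = 10,
                      gene_layers = list(
                        list(name = "ppi", mean_degree = 4,
                             weighted = FALSE)), seed = 17)
  st <- generate_synthetic_study(cfg)
  net <- build_network(pairwise_association(st$dm))
  hn <- assemble_hetnet(list(as_layer(net), st$phenolayer),
                        st$gene_layers,
                        filter_bipartite(st$bipartite, 0.29))
  lay <- hn$disease_layers[[1]]$edges
  keys_net <- paste(pmin(net$edges$disease_a, net$edges$disease_b),
                    pmax(net$edges$disease_a, net$edges$disease_b))
  keys_lay <- paste(lay$from, lay$to)
  expect_setequal(keys_net, keys_lay)
  expect_equal(anyDuplicated(keys_lay), 0)
})
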