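test_that("pairwise association matches enumeration oracle and closed-form phi", {
  set.seed(42)
  X <- matrix(rbinom(40 * 6, 1, 0.4), 40, 6)
  X[, 2] <- X[, 1]  # identical pair
  colnames(X) <- sprintf("d%02d", 1:6)
  dm <- toy_dm(X)
  assoc <- pairwise_association(dm, min_prevalence = 1)
  n <- 40
  for (i in seq_len(nrow(assoc))) {
    a <- assoc$n11[i]; b <- assoc$n10[i]; c <- assoc$n01[i]; d <- assoc$n00[i]
    expect_equal(assoc$p_fisher[i],
                 oracle_fisher_p(a, a + b, a + c, n), tolerance = 1e-12)
    expect_equal(assoc$phi[i], oracle_phi(a, b, c, d), tolerance = 1e-12)
    # phi equals the Pearson correlation of the binary columns
    expect_equal(assoc$phi[i],
                 cor(X[, assoc$disease_a[i] == colnames(X)],
                     X[, assoc$disease_b[i] == colnames(X)]),
                 tolerance = 1e-12)
  }
  ident <- assoc[assoc$disease_a == "d01" & assoc$disease_b == "d02", ]
  expect_equal(ident$phi, 1)
})

test_that("worked 2x2 examples: independence table and [[10,10],[10,70]]", {
  # balanced independent table: phi 0, p 1
  expect_equal(oracle_phi(25, 25, 25, 25), 0)
  expect_equal(fisher_exact_p(25, 50, 50, 100), 1, tolerance = 1e-12)
  # [[10,10],[10,70]]: closed-form phi and enumerated p
  expect_equal(fisher_exact_p(10, 20, 20, 100),
               oracle_fisher_p(10, 20, 20, 100), tolerance = 1e-12)
  expect_equal(oracle_phi(10, 10, 10, 70),
               (10 * 70 - 10 * 10) / sqrt(20 * 80 * 20 * 80))
})

test_that("association table is symmetric in the pair ordering", {
  set.seed(1)
  X <- matrix(rbinom(30 * 4, 1, 0.5), 30, 4)
  colnames(X) <- paste0("d0", 1:4)
  dm1 <- toy_dm(X)
  dm2 <- toy_dm(X[, 4:1])  # same diseases, reversed column order
  a1 <- pairwise_association(dm1, min_prevalence = 1)
  a2 <- pairwise_association(dm2, min_prevalence = 1)
  key <- function(a) {
    k <- paste(pmin(a$disease_a, a$disease_b),
               pmax(a$disease_a, a$disease_b))
    a <- a[order(k), ]; rownames(a) <- NULL; a
  }
  expect_equal(key(a1)$p_fisher, key(a2)$p_fisher, tolerance = 1e-12)
  expect_equal(key(a1)$phi, key(a2)$phi, tolerance = 1e-12)
})

test_that("degenerate diseases yield missing phi and are never edges", {
  X <- cbind(rep(1, 20), rbinom(20, 1, 0.5), rbinom(20, 1, 0.5))
  dm <- toy_dm(X)
  assoc <- pairwise_association(dm, min_prevalence = 1)
  expect_true(all(is.na(assoc$phi[assoc$disease_a == "d01" |
                                    assoc$disease_b == "d01"])))
  net <- suppressWarnings(build_network(assoc, alpha = 1))
  expect_false(any(net$edges$disease_a == "d01" |
                     net$edges$disease_b == "d01"))
})

test_that("BH adjustment matches its literal step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(9)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("network weights: equal phi collapses to W = 1, S = 0", {
  assoc <- data.frame(disease_a = c("a", "a", "b"),
                      disease_b = c("b", "c", "c"),
                      p_fisher = c(1e-9, 1e-9, 1e-9),
                      phi = c(0.2, 0.2, 0.2))
  for (sc in c("geometric", "arithmetic")) {
    net <- build_network(assoc, alpha = 1e-4, scaling = sc)
    expect_equal(net$edges$weight_W, rep(1, 3))
    expect_equal(net$edges$score_S, rep(0, 3))
  }
})

test_that("edge retention is monotone in alpha and S is zero exactly at max W", {
  set.seed(7)
  cfg <- synth_config(n_patients = 2000, n_diseases = 20, n_clusters = 4,
                      seed = 7)
  dm <- generate_cohort(cfg)$dm
  assoc <- pairwise_association(dm)
  key <- function(net) paste(net$edges$disease_a, net$edges$disease_b)
  n1 <- build_network(assoc, alpha = 1e-6)
  n2 <- build_network(assoc, alpha = 1e-3)
  expect_true(all(key(n1) %in% key(n2)))
  expect_true(all(n2$edges$score_S >= 0))
  expect_identical(which(n2$edges$score_S == 0),
                   which(n2$edges$weight_W == max(n2$edges$weight_W)))
})

test_that("centralities: star, triangle and brute-force path lengths", {
  star <- data.frame(disease_a = "hub", disease_b = paste0("leaf", 1:4),
                     p_fisher = 1e-9, phi = 0.5)
  snet <- build_network(star, alpha = 1e-4)
  # make all weights equal so S = 0 uniformly: distances all equal
  cs <- centralities(snet)
  expect_equal(cs$betweenness[cs$disease == "hub"], 6)
  expect_equal(cs$betweenness[cs$disease != "hub"], rep(0, 4))
  expect_equal(cs$degree[cs$disease == "hub"], 4)

  tri <- data.frame(disease_a = c("a", "a", "b"),
                    disease_b = c("b", "c", "c"),
                    p_fisher = 1e-9, phi = 0.4)
  expect_equal(attr(centralities(build_network(tri, 1e-4)), "transitivity"), 1)

  # 5-node path graph with distinct S: betweenness by exhaustive check
  # (on a path, shortest routes are forced; node i intermediates all
  # pairs that straddle it)
  path <- data.frame(disease_a = c("v1", "v2", "v3", "v4"),
                     disease_b = c("v2", "v3", "v4", "v5"),
                     p_fisher = 1e-9, phi = c(0.1, 0.3, 0.2, 0.25))
  pnet <- build_network(path, 1e-4)
  cp <- centralities(pnet)
  expect_equal(cp$betweenness[match(paste0("v", 1:5), cp$disease)],
               c(0, 3, 4, 3, 0))
  expect_equal(cp$strength, as.numeric(tapply(
    c(pnet$edges$weight_W, pnet$edges$weight_W),
    c(pnet$edges$disease_a, pnet$edges$disease_b), sum)[cp$disease]))
})

test_that("cluster detection recovers disjoint cliques and is deterministic", {
  cl1 <- t(combn(paste0("a", 1:4), 2))
  cl2 <- t(combn(paste0("b", 1:4), 2))
  assoc <- data.frame(disease_a = c(cl1[, 1], cl2[, 1]),
                      disease_b = c(cl1[, 2], cl2[, 2]),
                      p_fisher = 1e-9, phi = 0.5)
  net <- build_network(assoc, 1e-4)
  cl <- detect_clusters(net, seed = 3)
  expect_equal(max(cl$membership), 2)
  expect_equal(length(unique(cl$membership[paste0("a", 1:4)])), 1)
  expect_equal(length(unique(cl$membership[paste0("b", 1:4)])), 1)
  expect_identical(cl$membership, detect_clusters(net, seed = 3)$membership)
  expect_error(detect_clusters(net, algorithm = "nope"), "supported")
})

test_that("planted clusters are recovered with high adjusted Rand index", {
  skip_if_not_installed("mclust")
  cfg <- synth_config(n_patients = 5000, n_diseases = 36, n_clusters = 6,
                      seed = 13)
  co <- generate_cohort(cfg)
  net <- build_network(pairwise_association(co$dm))
  cl <- detect_clusters(net, seed = 13)
  ari <- mclust::adjustedRandIndex(
    cl$membership, co$truth$cluster_of_disease[names(cl$membership)])
  expect_gt(ari, 0.8)
  expect_gt(igraph::modularity(
    comorbnet:::network_igraph(net),
    co$truth$cluster_of_disease[net$nodes$disease]), 0.2)
})
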