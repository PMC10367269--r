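#' Two-sided Fisher exact p-values for 2x2 tables, vectorized
#'
#' Exact hypergeometric computation (no normal approximation): with `a`
#' co-occurrences, margins `m1`, `m2` and total `n`, the two-sided p is
#' the sum of hypergeometric point probabilities of all tables with the
#' same margins that are no more probable than the observed one (the
#' standard two-sided convention, with a 1e-7 relative tolerance on the
#' comparison). Unimodality of the hypergeometric pmf lets the opposite
#' tail boundary be found by bisection, so the whole computation is
#' O(log support) per table and vectorized over tables.
#'
#' @param a count of patients with both diseases.
#' @param m1,m2 disease margins (patients with disease 1 resp. 2).
#' @param n total patients.
#' @return numeric vector of two-sided p-values.
#' @export
fisher_exact_p <- function(a, m1, m2, n) {
  stopifnot(length(m1) == length(a), length(m2) == length(a))
  n <- rep_len(n, length(a))
  lo <- pmax(0, m1 + m2 - n)
  hi <- pmin(m1, m2)
  dobs <- stats::dhyper(a, m1, n - m1, m2)
  relerr <- 1 + 1e-7
  mode <- floor((m1 + 1) * (m2 + 1) / (n + 2))
  p <- numeric(length(a))

  left <- a <= mode   # observed in lower tail (or at mode)
  # lower-tail tables: all k <= a
  p_low <- stats::phyper(a, m1, n - m1, m2)
  # upper-tail tables: all k >= a
  p_up <- stats::phyper(a - 1, m1, n - m1, m2, lower.tail = FALSE)

  # find, on the opposite side of the mode, the boundary of tables with
  # pmf <= dobs * relerr; pmf is non-increasing moving away from the mode
  bisect <- function(lower, upper, pred) {
    # smallest k in [lower, upper] with pred(k) TRUE, assuming pred is
    # monotone FALSE -> TRUE; returns upper + 1 when never TRUE
    lo_ <- lower; hi_ <- upper + 1
    while (any(lo_ < hi_)) {
      mid <- (lo_ + hi_) %/% 2
      ok <- pred(mid) | lo_ >= hi_
      hi_ <- ifelse(lo_ < hi_ & ok, mid, hi_)
      lo_ <- ifelse(lo_ < hi_ & !ok, mid + 1, lo_)
    }
    lo_
  }

  if (any(left)) {
    i <- which(left)
    # smallest k > mode with pmf <= dobs (pmf decreasing for k >= mode)
    kk <- bisect(mode[i], hi[i], function(k)
      stats::dhyper(pmin(k, hi[i]), m1[i], n[i] - m1[i], m2[i]) <=
        dobs[i] * relerr | k > hi[i])
    other <- stats::phyper(kk - 1, m1[i], n[i] - m1[i], m2[i],
                           lower.tail = FALSE)
    p[i] <- p_low[i] + other
  }
  if (any(!left)) {
    i <- which(!left)
    # largest k < mode with pmf <= dobs  <=>  smallest k with pmf > dobs,
    # minus one (pmf increasing for k <= mode)
    kk <- bisect(lo[i], mode[i], function(k)
      stats::dhyper(pmax(k, lo[i]), m1[i], n[i] - m1[i], m2[i]) >
        dobs[i] * relerr | k < lo[i])
    other <- stats::phyper(kk - 1, m1[i], n[i] - m1[i], m2[i])
    p[i] <- p_up[i] + other
  }
  pmin(p, 1)
}

#' Pairwise disease co-occurrence statistics
#'
#' For every unordered pair of diseases above the prevalence floor,
#' computes the 2x2 co-occurrence contingency table, the two-sided Fisher
#' exact p-value, and the phi correlation (Pearson correlation of the two
#' binary columns, `(ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`). Pairs
#' involving a degenerate disease (prevalence 0 or n) get `phi = NA` and
#' are never edge-eligible.
#'
#' @param dm a [diagnosis_matrix()].
#' @param min_prevalence smallest patient count for a disease to enter
#'   pair testing (default 5).
#' @return data.frame with columns `disease_a`, `disease_b`, `n11`,
#'   `n10`, `n01`, `n00`, `p_fisher`, `phi`.
#' @export
pairwise_association <- function(dm, min_prevalence = 5) {
  stopifnot(inherits(dm, "diagnosis_matrix"))
  n <- length(dm$patients)
  if (n < 2 || length(dm$diseases) < 2)
    stop("need at least 2 patients and 2 diseases")
  prev <- Matrix::colSums(dm$occurrence)
  keep <- which(prev >= min_prevalence)
  if (length(keep) < 2) stop("fewer than 2 diseases above prevalence floor")
  occ <- dm$occurrence[, keep, drop = FALSE]
  co <- as.matrix(Matrix::crossprod(occ))
  m <- prev[keep]
  idx <- which(upper.tri(co), arr.ind = TRUE)
  a <- co[idx]
  m1 <- m[idx[, 1]]; m2 <- m[idx[, 2]]
  b <- m1 - a; c_ <- m2 - a; d_ <- n - m1 - m2 + a
  denom <- sqrt((a + b) * (c_ + d_)) * sqrt((a + c_) * (b + d_))
  phi <- ifelse(m1 == 0 | m1 == n | m2 == 0 | m2 == n, NA_real_,
                (a * d_ - b * c_) / denom)
  p <- fisher_exact_p(a, m1, m2, n)
  p[is.na(phi)] <- NA_real_
  out <- data.frame(disease_a = colnames(co)[idx[, 1]],
                    disease_b = colnames(co)[idx[, 2]],
                    n11 = a, n10 = b, n01 = c_, n00 = d_,
                    p_fisher = p, phi = phi)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH q-values (`p.adjust(method = "BH")`), exposed as the
#' pipeline's multiple-testing step. Order is preserved; an empty input
#' yields an empty output.
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (NA allowed and
#'   propagated).
#' @return numeric vector of adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  stopifnot(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)))
  stats::p.adjust(pvals, method = "BH")
}

#' Build the weighted disease comorbidity network
#'
#' Retains disease pairs with BH-adjusted Fisher p below `alpha` and
#' positive phi correlation. Because phi of frequent diseases is biased,
#' retained correlations are rescaled by the endpoint diseases' mean
#' retained phi: with `mbar_i` the mean phi of disease i over its
#' retained positive edges, the edge weight is
#' `W_ij = phi_ij / sqrt(mbar_i * mbar_j)` (`scaling = "geometric"`,
#' default) or `phi_ij / ((mbar_i + mbar_j) / 2)`
#' (`scaling = "arithmetic"`). The distance score used for shortest-path
#' centralities is `S = max(W) - W`, so the strongest edge has length 0.
#'
#' @param assoc association table from [pairwise_association()].
#' @param alpha BH threshold on q-values (default 1e-4).
#' @param scaling `"geometric"` or `"arithmetic"` endpoint-mean scaling.
#' @param prevalence optional named per-disease patient counts attached
#'   to nodes.
#' @return an object of class `disease_network`: list with `nodes`
#'   (data.frame `disease`, `prevalence`), `edges` (the retained
#'   association rows plus `q_bh`, `weight_W`, `score_S`), `alpha`,
#'   `scaling`.
#' @export
build_network <- function(assoc, alpha = 1e-4,
                          scaling = c("geometric", "arithmetic"),
                          prevalence = NULL) {
  scaling <- match.arg(scaling)
  stopifnot(is.data.frame(assoc),
            all(c("disease_a", "disease_b", "p_fisher", "phi") %in% names(assoc)))
  assoc$q_bh <- bh_adjust(assoc$p_fisher)
  keep <- !is.na(assoc$phi) & !is.na(assoc$q_bh) &
    assoc$q_bh < alpha & assoc$phi > 0
  edges <- assoc[keep, , drop = FALSE]
  all_dis <- sort(unique(c(assoc$disease_a, assoc$disease_b)))
  if (!nrow(edges)) {
    warning("no edges retained at alpha = ", alpha)
    edges$weight_W <- numeric(0)
    edges$score_S <- numeric(0)
  } else {
    phi_by_dis <- tapply(c(edges$phi, edges$phi),
                         c(edges$disease_a, edges$disease_b), mean)
    ma <- phi_by_dis[edges$disease_a]
    mb <- phi_by_dis[edges$disease_b]
    edges$weight_W <- as.numeric(if (scaling == "geometric")
      edges$phi / sqrt(ma * mb) else edges$phi / ((ma + mb) / 2))
    edges$score_S <- max(edges$weight_W) - edges$weight_W
  }
  rownames(edges) <- NULL
  nodes <- data.frame(disease = all_dis,
                      prevalence = if (is.null(prevalence)) NA_real_
                      else unname(prevalence[all_dis]))
  structure(list(nodes = nodes, edges = edges, alpha = alpha,
                 scaling = scaling),
            class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  cat("disease_network:", nrow(x$nodes), "diseases,", nrow(x$edges),
      "retained comorbidity edges (BH q <", format(x$alpha), ", phi > 0)\n")
  if (nrow(x$edges))
    cat(sprintf("  weight W in [%.3f, %.3f], %s endpoint-mean scaling\n",
                min(x$edges$weight_W), max(x$edges$weight_W), x$scaling))
  invisible(x)
}

#' @export
summary.disease_network <- function(object, ...) {
  g <- network_igraph(object)
  cat("disease_network summary\n")
  print(object)
  iso <- sum(igraph::degree(g) == 0)
  cat("  isolated diseases:", iso, "\n")
  cat("  global transitivity:",
      round(igraph::transitivity(g, type = "global"), 4), "\n")
  invisible(object)
}

# igraph view of a disease_network; edge attrs weight (W) and length (S)
network_igraph <- function(net) {
  stopifnot(inherits(net, "disease_network"))
  if (!nrow(net$edges))
    return(igraph::make_empty_graph(directed = FALSE) +
             igraph::vertices(net$nodes$disease))
  igraph::graph_from_data_frame(
    data.frame(from = net$edges$disease_a, to = net$edges$disease_b,
               weight = net$edges$weight_W, length = net$edges$score_S),
    directed = FALSE, vertices = net$nodes$disease)
}

#' Node centralities and global transitivity of a comorbidity network
#'
#' Degree is unweighted; strength sums the scaled-phi weights W;
#' betweenness and closeness use shortest paths under the distance score
#' `S = max(W) - W`. Closeness is the harmonic variant, which is
#' well-defined on disconnected graphs (unreachable pairs contribute 0);
#' the variant used is recorded in the result attributes. Transitivity is
#' the global (unweighted) clustering coefficient.
#'
#' @param net a `disease_network` with at least one edge.
#' @return data.frame (`disease`, `degree`, `strength`, `betweenness`,
#'   `closeness`) with attributes `transitivity` and `closeness_variant`.
#' @export
centralities <- function(net) {
  stopifnot(inherits(net, "disease_network"))
  if (!nrow(net$edges)) stop("network has no edges")
  g <- network_igraph(net)
  s <- igraph::E(g)$length
  # the argmax-W edge has length S = 0; shortest-path routines need
  # strictly positive weights, so zero lengths become a vanishing epsilon
  eps <- if (any(s > 0)) min(s[s > 0]) * 1e-9 else 1
  s[s == 0] <- eps
  out <- data.frame(
    disease = igraph::V(g)$name,
    degree = as.numeric(igraph::degree(g)),
    strength = as.numeric(igraph::strength(g,
                                           weights = igraph::E(g)$weight)),
    betweenness = as.numeric(igraph::betweenness(g, weights = s)),
    closeness = as.numeric(igraph::harmonic_centrality(g, weights = s,
                                                       normalized = TRUE)))
  attr(out, "transitivity") <- igraph::transitivity(g, type = "global")
  attr(out, "closeness_variant") <- "harmonic"
  rownames(out) <- NULL
  out
}

#' Detect disease clusters by weighted modularity optimization
#'
#' Partitions the comorbidity network using the scaled-phi weights W.
#' Supported algorithms: `"louvain"` (default), `"fast_greedy"`,
#' `"walktrap"`. Deterministic under the given seed.
#'
#' @param net a `disease_network` with at least one edge.
#' @param algorithm clustering algorithm name.
#' @param seed integer seed.
#' @return an object of class `disease_clusters`: list with `membership`
#'   (named integer, contiguous ids, only non-isolated nodes), `algorithm`,
#'   `modularity`.
#' @export
detect_clusters <- function(net, algorithm = "louvain", seed = 1L) {
  stopifnot(inherits(net, "disease_network"))
  if (!nrow(net$edges)) stop("network has no edges")
  supported <- c("louvain", "fast_greedy", "walktrap")
  if (!algorithm %in% supported)
    stop("unknown algorithm '", algorithm, "'; supported: ",
         paste(supported, collapse = ", "))
  g <- network_igraph(net)
  g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  w <- igraph::E(g)$weight
  set.seed(seed)
  cm <- switch(algorithm,
               louvain = igraph::cluster_louvain(g, weights = w),
               fast_greedy = igraph::cluster_fast_greedy(g, weights = w),
               walktrap = igraph::cluster_walktrap(g, weights = w))
  memb <- igraph::membership(cm)
  memb <- stats::setNames(as.integer(factor(memb)), names(memb))
  structure(list(membership = memb, algorithm = algorithm,
                 modularity = igraph::modularity(g, memb, weights = w)),
            class = "disease_clusters")
}

#' @export
print.disease_clusters <- function(x, ...) {
  cat("disease_clusters:", max(x$membership), "clusters over",
      length(x$membership), "diseases (", x$algorithm, ", modularity",
      round(x$modularity, 3), ")\n")
  invisible(x)
}

#' Write a disease network as an edge-list TSV (and optionally GraphML)
#' @param net a `disease_network`.
#' @param edges_tsv output TSV path.
#' @param graphml optional GraphML output path.
#' @return invisibly, `net`.
#' @export
write_disease_network <- function(net, edges_tsv, graphml = NULL) {
  stopifnot(inherits(net, "disease_network"))
  utils::write.table(net$edges, edges_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml))
    igraph::write_graph(network_igraph(net), graphml, format = "graphml")
  invisible(net)
}
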