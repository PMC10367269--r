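# Independent oracles used across tests. Each is a direct, literal
# implementation of a definition, kept free of the package's code paths.

# two-sided Fisher exact p by full enumeration of the hypergeometric
# support: sum the point probabilities (computed from choose()) of all
# tables no more probable than the observed one
oracle_fisher_p <- function(a, m1, m2, n) {
  lo <- max(0, m1 + m2 - n); hi <- min(m1, m2)
  k <- lo:hi
  pmf <- choose(m1, k) * choose(n - m1, m2 - k) / choose(n, m2)
  sum(pmf[pmf <= pmf[k == a] * (1 + 1e-7)])
}

# BH step-up applied literally: q_(i) = min_{k >= i} p_(k) * m / k
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# phi correlation from the 2x2 table, by the closed form
oracle_phi <- function(a, b, c, d) {
  (a * d - b * c) / sqrt((a + b) * (c + d) * (a + c) * (b + d))
}

# DeltaCon from first principles on a node-aligned pair of adjacency
# matrices: dense affinity solve and Matusita distance
oracle_deltacon <- function(A1, A2) {
  aff <- function(A) {
    d <- rowSums(A)
    eps <- 1 / (1 + max(d))
    solve(diag(nrow(A)) + eps^2 * diag(d, nrow(A)) - eps * A)
  }
  S1 <- aff(A1); S2 <- aff(A2)
  1 / (1 + sqrt(sum((sqrt(S1) - sqrt(S2))^2)))
}

# GSEA enrichment score by stepping the full running sum over every
# position of the ranked list
oracle_gsea_es <- function(t_sorted, hit_idx, weight_p = 1) {
  n <- length(t_sorted)
  inset <- seq_len(n) %in% hit_idx
  w <- abs(t_sorted)^weight_p
  if (sum(w[inset]) == 0) w[inset] <- 1
  step <- ifelse(inset, w / sum(w[inset]), -1 / (n - sum(inset)))
  rs <- cumsum(step)
  # extremum of larger magnitude; positive wins ties (to rounding)
  if (max(rs) >= -min(rs) - 1e-9) max(rs) else min(rs)
}

# RWR stationary distribution by direct linear solve
oracle_rwr_solve <- function(Tm, p0, r) {
  n <- length(p0)
  as.numeric(solve(diag(n) - (1 - r) * as.matrix(Tm), r * p0))
}

# small diagnosis matrix from an explicit binary matrix
toy_dm <- function(X, covariates = NULL) {
  if (is.null(rownames(X))) rownames(X) <- sprintf("p%02d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("d%02d", seq_len(ncol(X)))
  diagnosis_matrix(X, covariates)
}

# small assembled hetnet: one disease layer (path a-b-c), one or two gene
# layers, and a bipartite table; sizes kept tiny for closed-form checks
toy_hetnet <- function(two_gene_layers = FALSE, bip_scores = c(1, 1, 1)) {
  dl <- layer_spec("comorbidity", "disease",
                   data.frame(from = c("da", "db"), to = c("db", "dc"),
                              weight = c(1, 2)))
  gl1 <- layer_spec("pathway", "gene",
                    data.frame(from = c("g1", "g2"), to = c("g2", "g3"),
                               weight = 1))
  gls <- list(gl1)
  if (two_gene_layers)
    gls <- c(gls, list(layer_spec("ppi", "gene",
                                  data.frame(from = "g1", to = "g3",
                                             weight = 1))))
  bip <- data.frame(disease = c("da", "db", "dc"),
                    gene = c("g1", "g2", "g3"), score = bip_scores)
  assemble_hetnet(list(dl), gls, bip)
}
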