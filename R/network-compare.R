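canonical_edges <- function(x) {
  # unordered edge keys from a disease_network, layer_spec, or edge df
  ed <- if (inherits(x, "disease_network"))
    data.frame(from = x$edges$disease_a, to = x$edges$disease_b)
  else if (inherits(x, "layer_spec")) x$edges
  else as.data.frame(x)
  if (!nrow(ed)) return(character(0))
  unique(paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to), sep = "\r"))
}

deltacon_affinity <- function(A) {
  # exact fast-belief-propagation node affinity: (I + eps^2 D - eps A)^-1
  # with eps = 1 / (1 + max degree)
  deg <- rowSums(A)
  eps <- 1 / (1 + max(deg))
  n <- nrow(A)
  solve(diag(n) + eps^2 * diag(deg, n) - eps * A)
}

#' Compare two disease networks (edge Jaccard and DeltaCon)
#'
#' Both networks are mapped onto the union of their node sets and treated
#' as unweighted. The edge Jaccard is `|E_a int E_b| / |E_a un E_b|`.
#' DeltaCon similarity is `1 / (1 + d)` where `d` is the Matusita
#' (root-euclidean) distance between the two exact fast-belief-propagation
#' node-affinity matrices `(I + eps^2 D - eps A)^-1`,
#' `eps = 1 / (1 + max degree)` per graph. Affinities are computed by a
#' dense solve, appropriate for disease-network sizes.
#'
#' @param a,b `disease_network` objects, [layer_spec()]s, or edge
#'   data.frames with `from`/`to` columns.
#' @return list with `edge_jaccard` (NA when the edge union is empty) and
#'   `deltacon`.
#' @export
compare_networks <- function(a, b) {
  ea <- canonical_edges(a); eb <- canonical_edges(b)
  uni <- union(ea, eb)
  edge_jaccard <- if (!length(uni)) NA_real_ else
    length(intersect(ea, eb)) / length(uni)
  nodes <- sort(unique(unlist(strsplit(uni, "\r", fixed = TRUE))))
  if (!length(nodes)) return(list(edge_jaccard = edge_jaccard,
                                  deltacon = NA_real_))
  adj <- function(keys) {
    A <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    if (length(keys)) {
      pr <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
      A[cbind(match(pr[, 1], nodes), match(pr[, 2], nodes))] <- 1
      A[cbind(match(pr[, 2], nodes), match(pr[, 1], nodes))] <- 1
    }
    A
  }
  Sa <- deltacon_affinity(adj(ea))
  Sb <- deltacon_affinity(adj(eb))
  d <- sqrt(sum((sqrt(pmax(Sa, 0)) - sqrt(pmax(Sb, 0)))^2))
  list(edge_jaccard = edge_jaccard, deltacon = 1 / (1 + d))
}

breslow_day_expected <- function(or, r1, c1, n) {
  # expected a-cell under a common odds ratio, given margins; root of
  # a (n - r1 - c1 + a) = or (r1 - a)(c1 - a) on the admissible range
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  f <- function(a) a * (n - r1 - c1 + a) - or * (r1 - a) * (c1 - a)
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Breslow-Day test of odds-ratio homogeneity across two strata
#'
#' For each disease pair, builds the 2x2 co-occurrence table within each
#' level of a two-level stratifying covariate and tests whether the odds
#' ratio is the same in both strata: the Mantel-Haenszel common odds
#' ratio is estimated, the expected `a` cell under that common OR is
#' solved per stratum, and the chi-square statistic sums squared
#' deviations over their asymptotic variances (1 df for two strata; the
#' Tarone correction term is subtracted when `tarone = TRUE`). Tables
#' with any zero cell receive a +0.5 continuity correction to every cell
#' (flagged in the output). P-values are BH-adjusted across pairs.
#'
#' @param dm a [diagnosis_matrix()].
#' @param stratum name of a two-level covariate column.
#' @param pairs data.frame with columns `disease_a`, `disease_b`.
#' @param tarone apply the Tarone correction (default TRUE).
#' @return data.frame per pair: `disease_a`, `disease_b`, `or_stratum1`,
#'   `or_stratum2`, `statistic`, `p_bd`, `q_bh`, `continuity`, `skipped`
#'   (with a reason when a stratum has a zero margin).
#' @export
or_homogeneity <- function(dm, stratum, pairs, tarone = TRUE) {
  stopifnot(inherits(dm, "diagnosis_matrix"),
            stratum %in% names(dm$covariates))
  sv <- dm$covariates[[stratum]]
  lev <- unique(stats::na.omit(as.character(sv)))
  if (length(lev) != 2) stop("stratum must have exactly 2 levels")
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    da <- pairs$disease_a[i]; db <- pairs$disease_b[i]
    xa <- dm$occurrence[, da]; xb <- dm$occurrence[, db]
    tabs <- lapply(lev, function(l) {
      sel <- !is.na(sv) & as.character(sv) == l
      a <- sum(xa[sel] * xb[sel]); r1 <- sum(xa[sel]); c1 <- sum(xb[sel])
      n <- sum(sel)
      c(a = a, b = r1 - a, c = c1 - a, d = n - r1 - c1 + a)
    })
    base <- data.frame(disease_a = da, disease_b = db,
                       or_stratum1 = NA_real_, or_stratum2 = NA_real_,
                       statistic = NA_real_, p_bd = NA_real_,
                       continuity = FALSE, skipped = NA_character_)
    degen <- vapply(tabs, function(t)
      any(c(t["a"] + t["b"], t["c"] + t["d"],
            t["a"] + t["c"], t["b"] + t["d"]) == 0), logical(1))
    if (any(degen)) {
      base$skipped <- "zero margin in a stratum"
      return(base)
    }
    cont <- any(vapply(tabs, function(t) any(t == 0), logical(1)))
    if (cont) tabs <- lapply(tabs, function(t) t + 0.5)
    ors <- vapply(tabs, function(t)
      (t["a"] * t["d"]) / (t["b"] * t["c"]), numeric(1))
    # Mantel-Haenszel common OR
    num <- sum(vapply(tabs, function(t) t["a"] * t["d"] / sum(t), numeric(1)))
    den <- sum(vapply(tabs, function(t) t["b"] * t["c"] / sum(t), numeric(1)))
    or_mh <- num / den
    stat <- 0; vsum <- 0; devsum <- 0
    for (t in tabs) {
      r1 <- t["a"] + t["b"]; c1 <- t["a"] + t["c"]; n <- sum(t)
      ea <- breslow_day_expected(or_mh, r1, c1, n)
      v <- 1 / (1 / ea + 1 / (r1 - ea) + 1 / (c1 - ea) +
                  1 / (n - r1 - c1 + ea))
      stat <- stat + (t["a"] - ea)^2 / v
      vsum <- vsum + v
      devsum <- devsum + (t["a"] - ea)
    }
    if (tarone) stat <- stat - devsum^2 / vsum
    stat <- max(0, unname(stat))
    base$or_stratum1 <- unname(ors[1]); base$or_stratum2 <- unname(ors[2])
    base$statistic <- stat
    base$p_bd <- stats::pchisq(stat, df = length(tabs) - 1,
                               lower.tail = FALSE)
    base$continuity <- cont
    base
  })
  out <- do.call(rbind, res)
  out$q_bh <- NA_real_
  ok <- !is.na(out$p_bd)
  out$q_bh[ok] <- bh_adjust(out$p_bd[ok])
  rownames(out) <- NULL
  out
}
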