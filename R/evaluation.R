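#' AUROC of a binary membership against scores
#'
#' Rank-based (Mann-Whitney) computation with midranks for ties:
#' `AUROC = (sum of positive ranks - n1 (n1 + 1) / 2) / (n1 n0)`.
#'
#' @param scores numeric scores (higher = more likely positive).
#' @param positive logical vector, same length.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("need both positives and negatives")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision (step-wise AUC-PR)
#'
#' Average of precision at each positive's position in the
#' decreasing-score ordering — the step-wise formulation, stable for the
#' tiny positive fractions typical of disease-gene recovery. Ties are
#' broken deterministically by element name/index.
#'
#' @inheritParams auroc
#' @return AUC-PR in (0, 1\].
#' @export
auc_pr <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  if (!sum(positive)) stop("need at least one positive")
  nm <- if (!is.null(names(scores))) names(scores) else seq_along(scores)
  ord <- order(-scores, nm)
  pos <- positive[ord]
  hits <- cumsum(pos)
  mean((hits / seq_along(pos))[pos])
}

loo_metrics <- function(gene_scores, gene_ranks, targets) {
  pos <- names(gene_scores) %in% targets
  list(auroc = auroc(gene_scores, pos),
       auc_pr = auc_pr(gene_scores, pos),
       rank_ratio = stats::median(gene_ranks[targets]) /
         length(gene_ranks))
}

#' Leave-one-out disease-gene recovery
#'
#' For every disease with at least `min_targets` bipartite gene links,
#' removes those links, rebuilds the supra-transition, runs the walk
#' seeded at the disease alone, and scores how highly the held-out
#' target genes rank among all genes: AUROC, average precision, and the
#' rank ratio (median target rank over the number of ranked genes). The
#' input hetnet is never modified.
#'
#' @param net a `hetnet`.
#' @param params an [rwr_params()].
#' @param min_targets eligibility threshold (default 2).
#' @return data.frame per eligible disease: `disease`, `n_targets`,
#'   `auroc`, `auc_pr`, `rank_ratio`.
#' @export
loo_recovery <- function(net, params = rwr_params(), min_targets = 2) {
  stopifnot(inherits(net, "hetnet"), min_targets >= 2)
  tcount <- table(net$bipartite$disease)
  eligible <- names(tcount)[tcount >= min_targets]
  rows <- lapply(eligible, function(d) {
    targets <- net$bipartite$gene[net$bipartite$disease == d]
    net2 <- net
    net2$bipartite <- net$bipartite[net$bipartite$disease != d, ,
                                    drop = FALSE]
    tr <- suppressWarnings(build_transition(net2, params))
    res <- rwr(tr, seed_profile(d, label = d), params)
    m <- loo_metrics(res$gene_scores, res$gene_ranks, unique(targets))
    data.frame(disease = d, n_targets = length(unique(targets)),
               auroc = m$auroc, auc_pr = m$auc_pr,
               rank_ratio = m$rank_ratio)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Degree-preserving rewiring of a disease layer
#'
#' Double-edge swaps on the named disease layer: two edges (a-b, c-d)
#' are replaced by (a-d, c-b) unless that would create a self-loop or a
#' duplicate edge, in which case the attempt is skipped and counted.
#' Weights travel with the surviving edge records, the degree sequence
#' is invariant, and all other layers are untouched.
#'
#' @param net a `hetnet`.
#' @param layer name of the disease layer to rewire (default: the first).
#' @param n_swaps_factor attempted swaps as a multiple of the edge count
#'   (default 10).
#' @param seed integer seed.
#' @return the rewired `hetnet`, with attribute `n_swaps_skipped`.
#' @export
rewire_disease_layer <- function(net, layer = NULL, n_swaps_factor = 10,
                                 seed = 1L) {
  stopifnot(inherits(net, "hetnet"))
  nms <- vapply(net$disease_layers, `[[`, "", "name")
  if (is.null(layer)) layer <- nms[1]
  li <- match(layer, nms)
  if (is.na(li)) stop("no disease layer named '", layer, "'")
  ed <- net$disease_layers[[li]]$edges
  if (nrow(ed) < 2) stop("layer needs at least 2 edges to rewire")
  set.seed(seed)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  present <- new.env(hash = TRUE, parent = emptyenv())
  for (k in key(ed$from, ed$to)) assign(k, TRUE, envir = present)
  n_att <- ceiling(n_swaps_factor * nrow(ed))
  skipped <- 0L
  pick <- matrix(sample.int(nrow(ed), 2 * n_att, replace = TRUE),
                 ncol = 2)
  flip <- stats::runif(n_att) < 0.5
  for (s in seq_len(n_att)) {
    i <- pick[s, 1]; j <- pick[s, 2]
    if (i == j) { skipped <- skipped + 1L; next }
    a <- ed$from[i]; b <- ed$to[i]; c_ <- ed$from[j]; d_ <- ed$to[j]
    if (flip[s]) { tmp <- c_; c_ <- d_; d_ <- tmp }
    # propose (a, d_) and (c_, b)
    if (a == d_ || c_ == b) { skipped <- skipped + 1L; next }
    k1 <- key(a, d_); k2 <- key(c_, b)
    if (k1 == k2 || exists(k1, envir = present) ||
        exists(k2, envir = present)) { skipped <- skipped + 1L; next }
    rm(list = c(key(a, b), key(c_, d_)), envir = present)
    assign(k1, TRUE, envir = present); assign(k2, TRUE, envir = present)
    ed$from[i] <- pmin(a, d_); ed$to[i] <- pmax(a, d_)
    ed$from[j] <- pmin(c_, b); ed$to[j] <- pmax(c_, b)
  }
  out <- net
  out$disease_layers[[li]]$edges <- ed[order(ed$from, ed$to), ]
  rownames(out$disease_layers[[li]]$edges) <- NULL
  attr(out, "n_swaps_skipped") <- skipped
  out
}

#' Recovery z-scores against random seed profiles
#'
#' Runs the walk for the observed seed profile and for `n_null` random
#' disease sets of matched size drawn from the disease universe, scoring
#' a reference gene set's AUROC and average precision under each;
#' reports `z = (observed - null mean) / null sd` per metric.
#'
#' @param net a `hetnet`.
#' @param params an [rwr_params()].
#' @param profile a [seed_profile()].
#' @param gene_set character vector of genes (subset of the universe).
#' @param n_null number of random profiles (>= 2).
#' @param seed integer seed.
#' @param degree_matched draw null diseases with probability proportional
#'   to their bipartite degree instead of uniformly (default FALSE).
#' @return data.frame per metric (`auroc`, `auc_pr`): `observed`,
#'   `null_mean`, `null_sd`, `z_score`, `n_null` (z is NA when the null
#'   sd is 0).
#' @export
seed_null_zscores <- function(net, params, profile, gene_set, n_null = 100,
                              seed = 1L, degree_matched = FALSE) {
  stopifnot(inherits(net, "hetnet"), inherits(profile, "seed_profile"))
  if (n_null < 2) stop("n_null must be at least 2")
  extra <- setdiff(gene_set, net$gene_universe)
  if (length(extra)) stop("gene_set contains genes outside the universe")
  tr <- build_transition(net, params)
  score_profile <- function(pr) {
    res <- rwr(tr, pr, params)
    pos <- names(res$gene_scores) %in% gene_set
    c(auroc = auroc(res$gene_scores, pos),
      auc_pr = auc_pr(res$gene_scores, pos))
  }
  obs <- score_profile(profile)
  set.seed(seed)
  k <- length(profile$diseases)
  w <- if (degree_matched) {
    dg <- table(factor(net$bipartite$disease,
                       levels = net$disease_universe))
    as.numeric(dg) + 0.5
  } else NULL
  nulls <- vapply(seq_len(n_null), function(i)
    score_profile(seed_profile(sample(net$disease_universe, k, prob = w),
                               label = "null")),
    numeric(2))
  mu <- rowMeans(nulls); sdv <- apply(nulls, 1, stats::sd)
  data.frame(metric = c("auroc", "auc_pr"), observed = unname(obs),
             null_mean = unname(mu), null_sd = unname(sdv),
             z_score = ifelse(sdv > 0, (obs - mu) / sdv, NA_real_),
             n_null = n_null)
}

#' Recovery of reference gene sets in a walk ranking
#'
#' @param res an `rwr_result`.
#' @param reference_sets named list of gene vectors.
#' @return data.frame per set: `gene_set`, `n_in_universe`, `auroc`,
#'   `auc_pr`.
#' @export
recover_reference_sets <- function(res, reference_sets) {
  stopifnot(inherits(res, "rwr_result"), length(reference_sets) > 0,
            !is.null(names(reference_sets)))
  rows <- lapply(names(reference_sets), function(nm) {
    gs <- intersect(reference_sets[[nm]], names(res$gene_scores))
    if (!length(reference_sets[[nm]])) stop("empty reference set: ", nm)
    if (!length(gs))
      return(data.frame(gene_set = nm, n_in_universe = 0,
                        auroc = NA_real_, auc_pr = NA_real_))
    pos <- names(res$gene_scores) %in% gs
    data.frame(gene_set = nm, n_in_universe = length(gs),
               auroc = auroc(res$gene_scores, pos),
               auc_pr = auc_pr(res$gene_scores, pos))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
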