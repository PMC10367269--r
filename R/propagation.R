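#' Parameters of the multiplex-heterogeneous random walk with restart
#'
#' @param restart_r restart probability r in (0, 1].
#' @param interlayer_delta probability delta of jumping between a node's
#'   layer replicas within a multiplex (ignored for single-layer
#'   multiplexes).
#' @param internetwork_lambda probability lambda of crossing the
#'   bipartite connections at nodes that have them.
#' @param tau_disease,tau_gene per-layer restart weights within each
#'   multiplex (recycled/normalized; default uniform).
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter iteration cap.
#' @param aggregate how a gene's probability is aggregated over its layer
#'   replicas: `"sum"` (default) or `"mean"`.
#' @return list of class `rwr_params`.
#' @export
rwr_params <- function(restart_r = 0.7, interlayer_delta = 0.5,
                       internetwork_lambda = 0.5, tau_disease = NULL,
                       tau_gene = NULL, tol = 1e-10, max_iter = 1000,
                       aggregate = c("sum", "mean")) {
  stopifnot(restart_r > 0, restart_r <= 1,
            interlayer_delta >= 0, interlayer_delta <= 1,
            internetwork_lambda >= 0, internetwork_lambda <= 1,
            tol > 0, max_iter >= 1)
  structure(list(restart_r = restart_r,
                 interlayer_delta = interlayer_delta,
                 internetwork_lambda = internetwork_lambda,
                 tau_disease = tau_disease, tau_gene = tau_gene,
                 tol = tol, max_iter = as.integer(max_iter),
                 aggregate = match.arg(aggregate)),
            class = "rwr_params")
}

# supra index bookkeeping: disease layers first (layer-major), then genes
supra_index <- function(net) {
  D <- length(net$disease_universe); G <- length(net$gene_universe)
  LD <- length(net$disease_layers); LG <- length(net$gene_layers)
  list(D = D, G = G, LD = LD, LG = LG, n = D * LD + G * LG,
       dis_at = function(layer, pos) (layer - 1L) * D + pos,
       gene_at = function(layer, pos) D * LD + (layer - 1L) * G + pos)
}

#' Build the column-stochastic supra-transition matrix of a hetnet
#'
#' Encodes the multiplex-heterogeneous walk: from a node replica, a
#' fraction `lambda` of the transition mass crosses the bipartite
#' disease-gene connections (only at nodes that have them; split over
#' association scores, then uniformly over the target node's layer
#' replicas); of the mass staying in the current multiplex, `1 - delta`
#' moves along the current layer's weighted edges and `delta` jumps
#' uniformly to the node's other layer replicas. Nodes dangling in a
#' layer redistribute their within-layer mass to their replicas; nodes
#' isolated in every layer and in the bipartite table get a self-loop
#' (with a warning). Every column sums to 1 exactly.
#'
#' @param net a `hetnet` from [assemble_hetnet()].
#' @param params an [rwr_params()].
#' @return list of class `rwr_transition` with `T` (sparse
#'   column-stochastic dgCMatrix), `index` (data.frame `kind`, `layer`,
#'   `node` per supra row), and the originating `net` dimensions.
#' @export
build_transition <- function(net, params = rwr_params()) {
  stopifnot(inherits(net, "hetnet"), inherits(params, "rwr_params"))
  ix <- supra_index(net)
  delta <- params$interlayer_delta
  lambda <- params$internetwork_lambda

  bip <- net$bipartite
  dpos_b <- match(bip$disease, net$disease_universe)
  gpos_b <- match(bip$gene, net$gene_universe)
  bipsum_d <- numeric(ix$D); bipsum_g <- numeric(ix$G)
  if (nrow(bip)) {
    agg_d <- rowsum(bip$score, dpos_b)
    bipsum_d[as.integer(rownames(agg_d))] <- agg_d
    agg_g <- rowsum(bip$score, gpos_b)
    bipsum_g[as.integer(rownames(agg_g))] <- agg_g
  }
  lam_d <- ifelse(bipsum_d > 0, lambda, 0)
  lam_g <- ifelse(bipsum_g > 0, lambda, 0)

  ti <- list(); tj <- list(); tx <- list()
  push <- function(i, j, x) {
    k <- length(ti) + 1
    ti[[k]] <<- i; tj[[k]] <<- j; tx[[k]] <<- x
  }

  add_multiplex <- function(layers, universe, lam, at, L) {
    size <- length(universe)
    any_edge <- logical(size)
    for (l in seq_len(L)) {
      ed <- layers[[l]]$edges
      if (nrow(ed)) {
        i <- c(match(ed$from, universe), match(ed$to, universe))
        j <- c(match(ed$to, universe), match(ed$from, universe))
        w <- c(ed$weight, ed$weight)
        s <- numeric(size)
        agg <- rowsum(w, j)
        s[as.integer(rownames(agg))] <- agg
        has <- s > 0
      } else {
        i <- integer(0); j <- integer(0); w <- numeric(0)
        has <- rep(FALSE, size)
      }
      any_edge <- any_edge | has
      stay <- 1 - lam                       # mass staying in this multiplex
      win <- ifelse(has, stay * (if (L > 1) 1 - delta else 1), 0)
      if (length(j)) push(at(l, i), at(l, j), w / s[j] * win[j])
      # replica jumps: delta share, plus the within share of dangling nodes
      if (L > 1) {
        rep_mass <- ifelse(has, stay * delta, stay)
        nz <- which(rep_mass > 0)
        for (l2 in setdiff(seq_len(L), l))
          push(at(l2, nz), at(l, nz), rep_mass[nz] / (L - 1))
      } else {
        dang <- which(!has & stay > 0)      # self-loop: sole replica
        if (length(dang)) push(at(l, dang), at(l, dang), stay[dang])
      }
    }
    any_edge
  }

  d_has_edge <- add_multiplex(net$disease_layers, net$disease_universe,
                              lam_d, ix$dis_at, ix$LD)
  g_has_edge <- add_multiplex(net$gene_layers, net$gene_universe,
                              lam_g, ix$gene_at, ix$LG)
  iso_d <- !d_has_edge & bipsum_d == 0
  iso_g <- !g_has_edge & bipsum_g == 0
  if (any(iso_d) || any(iso_g))
    warning(sum(iso_d) + sum(iso_g),
            " node(s) isolated in all layers and bipartite links; ",
            "their walk mass stays on their own replicas")

  if (nrow(bip)) {
    # disease -> gene crossings, from every disease layer column
    for (l in seq_len(ix$LD)) for (l2 in seq_len(ix$LG))
      push(ix$gene_at(l2, gpos_b), ix$dis_at(l, dpos_b),
           lambda * bip$score / bipsum_d[dpos_b] / ix$LG)
    # gene -> disease crossings
    for (l in seq_len(ix$LG)) for (l2 in seq_len(ix$LD))
      push(ix$dis_at(l2, dpos_b), ix$gene_at(l, gpos_b),
           lambda * bip$score / bipsum_g[gpos_b] / ix$LD)
  }

  Tm <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj),
                             x = unlist(tx), dims = c(ix$n, ix$n))
  # exact column-stochastic renormalization (guards rounding only)
  cs <- Matrix::colSums(Tm)
  if (any(abs(cs - 1) > 1e-8))
    stop("internal error: transition columns do not sum to 1")
  Tm <- Tm %*% Matrix::Diagonal(x = 1 / cs)

  index <- data.frame(
    kind = c(rep("disease", ix$D * ix$LD), rep("gene", ix$G * ix$LG)),
    layer = c(rep(vapply(net$disease_layers, `[[`, "", "name"),
                  each = ix$D),
              rep(vapply(net$gene_layers, `[[`, "", "name"), each = ix$G)),
    node = c(rep(net$disease_universe, ix$LD),
             rep(net$gene_universe, ix$LG)))
  structure(list(T = Tm, index = index,
                 disease_universe = net$disease_universe,
                 gene_universe = net$gene_universe,
                 LD = ix$LD, LG = ix$LG),
            class = "rwr_transition")
}

#' A seed profile of diseases
#' @param diseases disease codes, optionally named numeric weights
#'   (normalized to sum 1; default uniform).
#' @param label free-text profile label.
#' @return list of class `seed_profile`.
#' @export
seed_profile <- function(diseases, label = "profile") {
  if (is.numeric(diseases)) {
    w <- diseases / sum(diseases)
    d <- names(diseases)
  } else {
    d <- as.character(diseases)
    w <- rep(1 / length(d), length(d))
  }
  stopifnot(length(d) > 0, !anyDuplicated(d), all(w > 0))
  structure(list(diseases = d, weights = stats::setNames(w, d),
                 label = label),
            class = "seed_profile")
}

#' Random walk with restart from a disease seed profile
#'
#' Power iteration `p <- (1 - r) T p + r p0`, with the restart vector
#' `p0` spread over the seed diseases' layer replicas according to the
#' per-layer restart weights tau (uniform by default). Stops when the L1
#' change drops below `tol`; probability mass is conserved at every
#' iteration. Gene scores aggregate each gene's probability over its
#' layer replicas; the gene ranking is by decreasing score with ties
#' broken lexicographically by gene id.
#'
#' @param transition an [build_transition()] result.
#' @param seeds a [seed_profile()] (or a character vector of diseases).
#' @param params the [rwr_params()] used (restart, tolerance,
#'   aggregation).
#' @return object of class `rwr_result`: list with `probabilities`
#'   (data.frame `kind`, `layer`, `node`, `p`), `gene_scores` (named,
#'   aggregated), `gene_ranks` (named integer, 1 = highest), `converged`,
#'   `n_iter`, `seed_label`.
#' @export
rwr <- function(transition, seeds, params = rwr_params()) {
  stopifnot(inherits(transition, "rwr_transition"),
            inherits(params, "rwr_params"))
  if (!inherits(seeds, "seed_profile")) seeds <- seed_profile(seeds)
  miss <- setdiff(seeds$diseases, transition$disease_universe)
  if (length(miss))
    stop("seed diseases absent from disease universe: ",
         paste(utils::head(miss, 3), collapse = ", "))
  D <- length(transition$disease_universe)
  LD <- transition$LD
  tau <- params$tau_disease
  if (is.null(tau)) tau <- rep(1, LD)
  tau <- rep_len(tau, LD); tau <- tau / sum(tau)
  p0 <- numeric(nrow(transition$index))
  pos <- match(seeds$diseases, transition$disease_universe)
  for (l in seq_len(LD))
    p0[(l - 1L) * D + pos] <- seeds$weights * tau[l]
  r <- params$restart_r
  p <- p0
  converged <- FALSE; it <- 0L
  if (r < 1) {
    Tm <- transition$T
    for (it in seq_len(params$max_iter)) {
      pn <- as.numeric((1 - r) * (Tm %*% p)) + r * p0
      if (abs(sum(pn) - 1) > 1e-10)
        stop("probability mass not conserved at iteration ", it)
      if (sum(abs(pn - p)) < params$tol) {
        p <- pn; converged <- TRUE; break
      }
      p <- pn
    }
  } else converged <- TRUE
  if (!converged)
    warning("RWR did not converge within ", params$max_iter, " iterations")

  gu <- transition$gene_universe
  gmask <- transition$index$kind == "gene"
  gs <- rowsum(p[gmask], transition$index$node[gmask])
  gene_scores <- stats::setNames(numeric(length(gu)), gu)
  gene_scores[rownames(gs)] <- gs[, 1]
  if (params$aggregate == "mean") gene_scores <- gene_scores / transition$LG
  ord <- order(-gene_scores, names(gene_scores))
  gene_ranks <- stats::setNames(integer(length(gu)), names(gene_scores)[ord])
  gene_ranks[] <- seq_along(gene_ranks)
  gene_ranks <- gene_ranks[names(gene_scores)]
  structure(list(
    probabilities = data.frame(transition$index, p = p),
    gene_scores = gene_scores, gene_ranks = gene_ranks,
    converged = converged, n_iter = it, seed_label = seeds$label),
    class = "rwr_result")
}

#' @export
print.rwr_result <- function(x, ...) {
  cat("rwr_result ('", x$seed_label, "'): ", length(x$gene_scores),
      " genes ranked; ", if (x$converged) paste0("converged in ", x$n_iter,
                                                 " iterations")
      else "NOT converged", "\n", sep = "")
  top <- names(sort(x$gene_ranks)[seq_len(min(5, length(x$gene_ranks)))])
  cat("  top genes:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Prioritize genes specific to one seed profile over another
#'
#' Restricted to the `top_n` genes of profile A by walk probability, the
#' prioritization score is `G_i = P_i * |dR_i|` with
#' `dR_i = R_i(B) - R_i(A)` the rank difference between the two
#' rankings. Genes ranked worse in A than in B (negative `dR`) are
#' retained but flagged, since the absolute rank difference is
#' sign-blind.
#'
#' @param resA,resB `rwr_result`s over the identical gene universe.
#' @param top_n candidate pool size (default 500).
#' @return data.frame sorted by decreasing `score_G`: `gene`, `p`,
#'   `rank_a`, `rank_b`, `delta_rank`, `score_G`, `worse_in_a`.
#' @export
prioritize <- function(resA, resB, top_n = 500) {
  stopifnot(inherits(resA, "rwr_result"), inherits(resB, "rwr_result"))
  if (!identical(sort(names(resA$gene_scores)),
                 sort(names(resB$gene_scores))))
    stop("gene universes differ between the two results")
  g <- names(resA$gene_ranks)[resA$gene_ranks <= top_n]
  dr <- resB$gene_ranks[g] - resA$gene_ranks[g]
  out <- data.frame(gene = g, p = unname(resA$gene_scores[g]),
                    rank_a = unname(resA$gene_ranks[g]),
                    rank_b = unname(resB$gene_ranks[g]),
                    delta_rank = unname(dr),
                    score_G = unname(resA$gene_scores[g] * abs(dr)),
                    worse_in_a = unname(dr < 0))
  out <- out[order(-out$score_G, out$gene), ]
  rownames(out) <- NULL
  out
}
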