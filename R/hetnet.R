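#' A single network layer (disease or gene)
#'
#' @param name layer name.
#' @param kind `"disease"` or `"gene"`.
#' @param edges data.frame with columns `from`, `to` and optionally
#'   `weight` (default 1). Self-loops and duplicate (unordered) edges are
#'   removed, keeping the maximum weight.
#' @param weighted whether weights are meaningful (informational flag).
#' @param nodes optional declared node set (ids); defaults to the edge
#'   endpoints. Declaring nodes keeps isolated ones in the layer (and in
#'   assembled universes), as a real network's node set does.
#' @return an object of class `layer_spec`.
#' @export
layer_spec <- function(name, kind = c("disease", "gene"), edges,
                       weighted = TRUE, nodes = NULL) {
  kind <- match.arg(kind)
  edges <- as.data.frame(edges)
  stopifnot(all(c("from", "to") %in% names(edges)))
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  if (nrow(edges)) {
    if (any(edges$weight <= 0)) stop("layer weights must be positive")
    a <- pmin(edges$from, edges$to); b <- pmax(edges$from, edges$to)
    edges$from <- a; edges$to <- b
    edges <- edges[order(a, b, -edges$weight), ]
    edges <- edges[!duplicated(edges[, c("from", "to")]),
                   c("from", "to", "weight")]
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0))
  }
  rownames(edges) <- NULL
  ep <- unique(c(edges$from, edges$to))
  nodes <- if (is.null(nodes)) ep else union(as.character(nodes), ep)
  structure(list(name = name, kind = kind, edges = edges,
                 weighted = weighted, nodes = sort(nodes)),
            class = "layer_spec")
}

#' @export
print.layer_spec <- function(x, ...) {
  cat("layer_spec '", x$name, "' (", x$kind, "): ", nrow(x$edges),
      " edges over ", length(layer_nodes(x)), " nodes",
      if (x$weighted) ", weighted" else "", "\n", sep = "")
  invisible(x)
}

layer_nodes <- function(layer) {
  if (!is.null(layer$nodes)) layer$nodes
  else unique(c(layer$edges$from, layer$edges$to))
}

#' Comorbidity network as a hetnet disease layer
#' @param net a `disease_network`.
#' @param name layer name (default "comorbidity").
#' @return a [layer_spec()] of kind `"disease"` carrying the scaled-phi
#'   weights W; all network nodes are declared, including isolated ones.
#' @export
as_layer <- function(net, name = "comorbidity") {
  stopifnot(inherits(net, "disease_network"))
  layer_spec(name, "disease",
             data.frame(from = net$edges$disease_a,
                        to = net$edges$disease_b,
                        weight = net$edges$weight_W),
             weighted = TRUE, nodes = net$nodes$disease)
}

#' Filter disease-gene associations by confidence
#'
#' Retains rows with score strictly above `min_conf` (the default 0.29
#' keeps associations backed by at least one curated source or several
#' experimental ones on the DisGeNET-style score scale). Duplicate
#' (disease, gene) rows collapse to the maximum score.
#'
#' @param raw data.frame with columns `disease`, `gene`, `score`.
#' @param min_conf strict lower threshold (default 0.29).
#' @return the filtered, deduplicated data.frame.
#' @export
filter_bipartite <- function(raw, min_conf = 0.29) {
  stopifnot(is.data.frame(raw),
            all(c("disease", "gene", "score") %in% names(raw)),
            all(raw$score >= 0 & raw$score <= 1))
  out <- raw[raw$score > min_conf, , drop = FALSE]
  out <- out[order(out$disease, out$gene, -out$score), ]
  out <- out[!duplicated(out[, c("disease", "gene")]), ]
  rownames(out) <- NULL
  out
}

#' Restrict gene layers to an expression whitelist
#'
#' Removes genes outside the whitelist together with their incident
#' edges, mirroring a tissue-expression filter (the whitelist is supplied
#' as the union of whatever expression evidence sources apply).
#'
#' @param layers list of gene [layer_spec()]s.
#' @param whitelist character vector of gene ids.
#' @return the filtered layer list (empty layers kept, with a warning).
#' @export
filter_expression <- function(layers, whitelist) {
  stopifnot(length(whitelist) >= 0)
  lapply(layers, function(l) {
    stopifnot(inherits(l, "layer_spec"), l$kind == "gene")
    keep <- l$edges$from %in% whitelist & l$edges$to %in% whitelist
    out <- l
    out$edges <- l$edges[keep, , drop = FALSE]
    rownames(out$edges) <- NULL
    out$nodes <- intersect(layer_nodes(l), whitelist)
    if (!nrow(out$edges))
      warning("layer '", l$name, "' is empty after expression filtering")
    out
  })
}

#' Assemble the multiplex-heterogeneous disease-gene network
#'
#' Joins one or more disease layers and gene layers (each a multiplex
#' over its own node universe) with a bipartite disease-gene association
#' table. Universes are the unions of layer nodes per kind; disease and
#' gene namespaces must be disjoint. Bipartite edges with an endpoint in
#' neither universe are dropped (and counted). Layer weights are
#' normalized per layer to a maximum of 1 so no layer dominates the walk.
#'
#' @param disease_layers,gene_layers lists of [layer_spec()]s.
#' @param bipartite data.frame `disease`, `gene`, `score` (already
#'   confidence-filtered).
#' @return an object of class `hetnet`: list with `disease_layers`,
#'   `gene_layers`, `bipartite`, `disease_universe`, `gene_universe`,
#'   `n_bipartite_dropped`.
#' @export
assemble_hetnet <- function(disease_layers, gene_layers, bipartite) {
  if (inherits(disease_layers, "layer_spec"))
    disease_layers <- list(disease_layers)
  if (inherits(gene_layers, "layer_spec")) gene_layers <- list(gene_layers)
  stopifnot(length(disease_layers) >= 1, length(gene_layers) >= 1,
            all(vapply(disease_layers, function(l)
      inherits(l, "layer_spec") && l$kind == "disease", logical(1))),
    all(vapply(gene_layers, function(l)
      inherits(l, "layer_spec") && l$kind == "gene", logical(1))))
  du <- sort(unique(unlist(lapply(disease_layers, layer_nodes))))
  gu <- sort(unique(unlist(lapply(gene_layers, layer_nodes))))
  if (length(intersect(du, gu)))
    stop("disease and gene namespaces collide: ",
         paste(utils::head(intersect(du, gu), 3), collapse = ", "))
  norm1 <- function(l) {
    if (nrow(l$edges)) l$edges$weight <- l$edges$weight / max(l$edges$weight)
    l
  }
  disease_layers <- lapply(disease_layers, norm1)
  gene_layers <- lapply(gene_layers, norm1)
  bipartite <- as.data.frame(bipartite)
  stopifnot(all(c("disease", "gene", "score") %in% names(bipartite)))
  ok <- bipartite$disease %in% du & bipartite$gene %in% gu
  dropped <- sum(!ok)
  bipartite <- bipartite[ok, , drop = FALSE]
  rownames(bipartite) <- NULL
  structure(list(disease_layers = disease_layers,
                 gene_layers = gene_layers, bipartite = bipartite,
                 disease_universe = du, gene_universe = gu,
                 n_bipartite_dropped = dropped),
            class = "hetnet")
}

#' @export
print.hetnet <- function(x, ...) {
  cat("hetnet:", length(x$disease_universe), "diseases x",
      length(x$disease_layers), "layers;",
      length(x$gene_universe), "genes x", length(x$gene_layers),
      "layers;", nrow(x$bipartite), "bipartite links\n")
  if (x$n_bipartite_dropped)
    cat("  (", x$n_bipartite_dropped,
        "bipartite links dropped: endpoint outside universes )\n")
  invisible(x)
}

layer_igraph <- function(layer, universe = NULL) {
  verts <- if (is.null(universe)) layer_nodes(layer) else universe
  igraph::graph_from_data_frame(layer$edges, directed = FALSE,
                                vertices = verts)
}

#' Per-layer topology statistics
#'
#' Node/edge counts, edge density (as a percentage of possible edges),
#' mean degree, global transitivity, and degree assortativity (Pearson
#' correlation of endpoint degrees over edges), each computed on the
#' layer's own node set.
#'
#' @param net a `hetnet` (or a list of [layer_spec()]s).
#' @return data.frame, one row per layer.
#' @export
layer_stats <- function(net) {
  layers <- if (inherits(net, "hetnet"))
    c(net$disease_layers, net$gene_layers) else net
  rows <- lapply(layers, function(l) {
    g <- layer_igraph(l)
    n <- igraph::vcount(g); m <- igraph::ecount(g)
    data.frame(
      layer = l$name, kind = l$kind, n_nodes = n, n_edges = m,
      edge_density = if (n > 1) 100 * m / (n * (n - 1) / 2) else NA_real_,
      mean_degree = if (n > 0) 2 * m / n else NA_real_,
      transitivity = igraph::transitivity(g, type = "global"),
      degree_assortativity = suppressWarnings(
        igraph::assortativity_degree(g)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a hetnet as a single long edge table
#'
#' One row per edge with a `layer` column (`bipartite` rows carry the
#' confidence score as weight), the standard exchange shape for
#' multiplex-heterogeneous edge lists.
#'
#' @param net a `hetnet`.
#' @param path output TSV path.
#' @return invisibly, the edge table.
#' @export
write_hetnet <- function(net, path) {
  stopifnot(inherits(net, "hetnet"))
  tabs <- lapply(c(net$disease_layers, net$gene_layers), function(l)
    cbind(l$edges, layer = l$name, kind = l$kind))
  bip <- data.frame(from = net$bipartite$disease, to = net$bipartite$gene,
                    weight = net$bipartite$score, layer = "bipartite",
                    kind = "bipartite")
  out <- rbind(do.call(rbind, tabs), bip)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
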