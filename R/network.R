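#' Build a molecular network from a pair-score table
#'
#' Spectra become nodes and significant pairwise alignments become edges,
#' then the topology is constrained to keep the network interpretable:
#'
#' 1. edges with `score < score_min` or `pvalue > p_max` are dropped
#'    (defaults 1.0 and 0.05 -- stricter than the hit-filtering score cutoff);
#' 2. each node keeps only its `top_k` highest-scoring incident edges, and an
#'    edge survives only if it is in the top k of *both* endpoints (the
#'    mutual top-k convention used by molecular-networking pipelines);
#' 3. while any connected component exceeds `max_component` nodes, that
#'    component's lowest-scoring edge is removed (ties broken by
#'    lexicographic edge id for determinism).
#'
#' @param table an edge table (columns `id_a`, `id_b`, `score`, `pvalue`);
#'   `nodes` not incident to a surviving edge are kept as isolated nodes.
#' @param score_min minimum score for a network edge; default 1.0.
#' @param p_max maximum p-value; default 0.05.
#' @param top_k per-node edge budget; default 10.
#' @param max_component maximum connected-component size; default 100.
#' @param nodes optional character vector of all node ids (defaults to the
#'   ids appearing in `table`).
#' @return An object of class `simile_network`: a list with `graph` (an
#'   [igraph::graph][igraph] with `score` and `pvalue` edge attributes),
#'   `edges` (the surviving edge table), and `components` (a named integer
#'   vector of component membership).
#' @export
build_network <- function(table, score_min = 1.0, p_max = 0.05,
                          top_k = 10L, max_component = 100L, nodes = NULL) {
  stopifnot(is.data.frame(table), top_k >= 1L, max_component >= 1L)
  if (is.null(nodes)) {
    nodes <- sort(unique(c(table$id_a, table$id_b)))
  }
  edges <- table[table$score >= score_min & table$pvalue <= p_max, ,
                 drop = FALSE]
  edges <- edges[order(edges$id_a, edges$id_b), , drop = FALSE]
  if (nrow(edges) > 0L) {
    edges <- edges[.mutual_top_k(edges, top_k), , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges[, c("id_a", "id_b",
                               setdiff(names(edges), c("id_a", "id_b")))]
    else data.frame(id_a = character(), id_b = character(),
                    score = numeric(), pvalue = numeric()),
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  g <- .prune_components(g, max_component)
  keep_ids <- igraph::as_data_frame(g, what = "edges")
  if (nrow(edges)) {
    edge_key <- paste(edges$id_a, edges$id_b, sep = "\t")
    keep_key <- paste(pmin(keep_ids$from, keep_ids$to),
                      pmax(keep_ids$from, keep_ids$to), sep = "\t")
    edges <- edges[edge_key %in% keep_key, , drop = FALSE]
  }
  rownames(edges) <- NULL
  comp <- igraph::components(g)$membership
  structure(list(graph = g, edges = edges, components = comp),
            class = "simile_network")
}

# Logical index of edges that are within the top-k highest-scoring incident
# edges of BOTH endpoints. Ties in score are broken by edge id so the result
# is deterministic.
.mutual_top_k <- function(edges, top_k) {
  edge_id <- paste(edges$id_a, edges$id_b, sep = "\t")
  ord <- order(-edges$score, edge_id)
  # walk edges in score order, tracking each node's running incident-edge
  # rank; an edge is kept iff it ranks < top_k at both endpoints
  counts <- new.env(parent = emptyenv())
  keep <- logical(nrow(edges))
  for (e in ord) {
    a <- edges$id_a[[e]]
    b <- edges$id_b[[e]]
    ca <- if (is.null(counts[[a]])) 0L else counts[[a]]
    cb <- if (is.null(counts[[b]])) 0L else counts[[b]]
    counts[[a]] <- ca + 1L
    counts[[b]] <- cb + 1L
    keep[[e]] <- ca < top_k && cb < top_k
  }
  keep
}

# Iteratively removes the lowest-scoring edge (ties by lexicographic edge id)
# from any connected component larger than max_component.
.prune_components <- function(g, max_component) {
  repeat {
    comp <- igraph::components(g)
    big <- which(comp$csize > max_component)
    if (length(big) == 0L) break
    member_names <- igraph::V(g)$name[comp$membership == big[[1]]]
    ends <- igraph::ends(g, igraph::E(g))
    in_big <- which(ends[, 1] %in% member_names)
    scores <- igraph::E(g)$score[in_big]
    key <- paste(pmin(ends[in_big, 1], ends[in_big, 2]),
                 pmax(ends[in_big, 1], ends[in_big, 2]), sep = "\t")
    worst <- in_big[order(scores, key)[[1]]]
    g <- igraph::delete_edges(g, worst)
  }
  g
}

#' @export
print.simile_network <- function(x, ...) {
  cat(sprintf(
    "simile_network: %d nodes, %d edges, %d component(s), largest %d\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph),
    length(unique(x$components)),
    if (length(x$components)) max(table(x$components)) else 0L
  ))
  invisible(x)
}

#' Write a molecular network to GraphML or edge-list TSV
#'
#' @param network a `simile_network` from [build_network()].
#' @param path output file path.
#' @param format `"graphml"` or `"tsv"` (edge list with score and p-value).
#' @return The path, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "tsv")) {
  stopifnot(inherits(network, "simile_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network$graph, path, format = "graphml")
  } else {
    write_score_table(network$edges, path)
  }
  invisible(path)
}
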