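#' Build a scored protein-protein interaction network
#'
#' Constructs a simple undirected graph from a canonical scored edge list,
#' keeping only edges at or above a combined-score confidence threshold
#' (inclusive, on the STRING 0-1000 integer scale; the default 400 is the
#' conventional "medium confidence" cutoff).
#'
#' @param edges Data frame `node_a`, `node_b`, `combined_score` as returned
#'   by [read_edge_list()].
#' @param min_combined_score Inclusive score threshold.
#' @param isolated_nodes Optional symbols to include as edge-less nodes.
#' @return An object of class `context_network`: list with `nodes` (sorted
#'   character vector), `edges` (canonical data frame) and
#'   `min_combined_score`.
#' @export
build_network <- function(edges, min_combined_score = 400,
                          isolated_nodes = character()) {
  keep <- edges$combined_score >= min_combined_score
  e <- edges[keep, , drop = FALSE]
  e <- e[order(e$node_a, e$node_b), , drop = FALSE]
  rownames(e) <- NULL
  nodes <- sort(unique(c(e$node_a, e$node_b, isolated_nodes)))
  structure(list(nodes = nodes, edges = e,
                 min_combined_score = min_combined_score),
            class = "context_network")
}

#' @export
print.context_network <- function(x, ...) {
  cat("Context PPI network: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges (combined_score >= ", x$min_combined_score, ")\n", sep = "")
  invisible(x)
}

#' Restrict a network to a context gene set
#'
#' Induced subgraph on the intersection of the network's nodes with a set of
#' context symbols (e.g. the targets associated with both diseases under
#' study): an edge survives iff both endpoints are in the context.
#'
#' @param network A `context_network`.
#' @param context_symbols Character vector of normalized symbols.
#' @return A `context_network`.
#' @export
restrict_to_context <- function(network, context_symbols) {
  stopifnot(inherits(network, "context_network"))
  ctx <- unique(as.character(context_symbols))
  nodes <- intersect(network$nodes, ctx)
  e <- network$edges
  e <- e[e$node_a %in% nodes & e$node_b %in% nodes, , drop = FALSE]
  rownames(e) <- NULL
  structure(list(nodes = sort(nodes), edges = e,
                 min_combined_score = network$min_combined_score),
            class = "context_network")
}

#' Drug-anchored vertex degrees
#'
#' Reduces the network's edge set to interactions involving at least one drug
#' target, then reports, for every drug target, the number of edges incident
#' to it in that reduced set (an edge between two drug targets contributes 1
#' to each endpoint). Drug targets absent from the network are reported with
#' degree 0 rather than dropped, so the ranking is not silently biased.
#'
#' @param network A `context_network` (already context-restricted).
#' @param drug_targets Character vector of normalized drug-target symbols.
#' @param affinity Optional data frame `symbol`, `best_activity_nM`,
#'   `interaction_mode` (e.g. `filter_by_potency(...)$retained`) used to
#'   annotate the result.
#' @return Data frame `symbol`, `vertex_degree`, `activity_nM`,
#'   `interaction_mode`, one row per drug target.
#' @export
drug_anchored_degrees <- function(network, drug_targets, affinity = NULL) {
  stopifnot(inherits(network, "context_network"))
  drug <- sort(unique(as.character(drug_targets)))
  e <- network$edges
  anchored <- e[e$node_a %in% drug | e$node_b %in% drug, , drop = FALSE]
  deg <- table(factor(c(anchored$node_a, anchored$node_b), levels = drug))
  out <- data.frame(symbol = drug,
                    vertex_degree = as.integer(deg[drug]),
                    activity_nM = rep(NA_real_, length(drug)),
                    interaction_mode = rep(NA_character_, length(drug)),
                    stringsAsFactors = FALSE)
  if (!is.null(affinity)) {
    idx <- match(out$symbol, affinity$symbol)
    out$activity_nM <- affinity$best_activity_nM[idx]
    out$interaction_mode <- affinity$interaction_mode[idx]
  }
  rownames(out) <- NULL
  out
}

#' Rank drug targets by vertex degree
#'
#' Sorts a degree table by descending vertex degree, ties broken
#' alphabetically by symbol; deterministic for any input order.
#'
#' @param targets Data frame as returned by [drug_anchored_degrees()].
#' @return The same data frame, reordered.
#' @export
rank_targets <- function(targets) {
  out <- targets[order(-targets$vertex_degree, targets$symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert a context network to an igraph object
#' @param network A `context_network`.
#' @param degrees Optional degree table; attached as `vertex_degree` vertex
#'   attribute (0 where absent).
#' @return An igraph graph with a `combined_score` edge attribute.
#' @export
as_igraph <- function(network, degrees = NULL) {
  stopifnot(inherits(network, "context_network"))
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = data.frame(name = network$nodes))
  vd <- rep(0L, length(network$nodes))
  if (!is.null(degrees)) {
    idx <- match(network$nodes, degrees$symbol)
    vd[!is.na(idx)] <- degrees$vertex_degree[idx[!is.na(idx)]]
  }
  igraph::V(g)$vertex_degree <- vd
  g
}

#' Export a network to GraphML and TSV
#'
#' Writes a GraphML file with `combined_score` edge attributes and
#' `vertex_degree` node attributes, plus a plain TSV edge dump. Output is
#' byte-identical across runs for identical input.
#'
#' @param network A `context_network`.
#' @param degrees Optional degree table (see [as_igraph()]).
#' @param path GraphML output path.
#' @param tsv_path Optional TSV edge-dump path (default: `path` with a
#'   `.tsv` extension).
#' @return Invisibly, `path`.
#' @export
export_graph <- function(network, degrees = NULL, path,
                         tsv_path = sub("\\.graphml$", ".tsv", path)) {
  g <- as_igraph(network, degrees)
  igraph::write_graph(g, path, format = "graphml")
  write_edge_list(network$edges, tsv_path)
  invisible(path)
}

#' Re-import a GraphML network written by [export_graph()]
#' @param path GraphML file.
#' @return A `context_network` (with `min_combined_score = NA`).
#' @export
import_graph <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  nodes <- sort(igraph::V(g)$name)
  if (nrow(el) > 0L) {
    e <- data.frame(node_a = pmin(el$from, el$to),
                    node_b = pmax(el$from, el$to),
                    combined_score = as.integer(el$combined_score),
                    stringsAsFactors = FALSE)
    e <- e[order(e$node_a, e$node_b), , drop = FALSE]
    rownames(e) <- NULL
  } else {
    e <- data.frame(node_a = character(), node_b = character(),
                    combined_score = integer(), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = e, min_combined_score = NA),
            class = "context_network")
}
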