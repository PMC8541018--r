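#' Markov clustering of a context network
#'
#' Clusters the network by the Markov Cluster (MCL) algorithm: a
#' column-stochastic random-walk matrix over the weighted graph (weights =
#' combined_score / 1000) is alternately expanded (matrix power) and inflated
#' (element-wise power followed by column renormalization) until the flow
#' stabilizes; clusters are read off the attractor structure of the converged
#' matrix. Before normalization every node receives a self-loop weighted by
#' its maximum incident edge weight (1 for isolated nodes), the standard
#' regularization that prevents period-2 oscillation. The procedure is fully
#' deterministic for fixed input and parameters, and nodes in different
#' connected components are never co-clustered.
#'
#' @param network A non-empty `context_network`.
#' @param inflation Inflation exponent (> 1 sharpens flow; default 2).
#' @param expansion Expansion power (integer >= 2; default 2).
#' @param tolerance Convergence threshold on the maximum absolute change of
#'   the matrix between iterations.
#' @param max_iterations Iteration cap; non-convergence yields a warning and
#'   a result flagged `converged = FALSE`.
#' @return An object of class `cluster_assignment`: list with `clusters`
#'   (named integer vector, symbol -> cluster id; ids contiguous from 1,
#'   ordered by decreasing cluster size, ties by alphabetically smallest
#'   member), `n_clusters`, `converged`, `iterations` and `parameters`.
#' @export
mcl_cluster <- function(network, inflation = 2, expansion = 2L,
                        tolerance = 1e-6, max_iterations = 100L) {
  stopifnot(inherits(network, "context_network"))
  nodes <- network$nodes
  n <- length(nodes)
  if (n == 0L) stop("mcl_cluster requires a non-empty network")
  stopifnot(inflation > 1, expansion >= 2, tolerance > 0, max_iterations >= 1)

  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(network$edges) > 0L) {
    ia <- match(network$edges$node_a, nodes)
    ib <- match(network$edges$node_b, nodes)
    w <- network$edges$combined_score / 1000
    W[cbind(ia, ib)] <- w
    W[cbind(ib, ia)] <- w
  }
  self <- apply(W, 2L, max)
  self[self == 0] <- 1
  diag(W) <- self

  normalize_cols <- function(M) sweep(M, 2L, colSums(M), "/")
  M <- normalize_cols(W)

  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    Mp <- M
    for (k in seq_len(expansion - 1L)) Mp <- Mp %*% M   # expansion: M^e
    Mp <- Mp ^ inflation                                # inflation
    Mp[Mp < 1e-12] <- 0                                 # prune numerical dust
    Mp <- normalize_cols(Mp)
    delta <- max(abs(Mp - M))
    M <- Mp
    if (delta < tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within ", max_iterations,
            " iterations; returning current assignment")
  }

  # Clusters: connected components of the support of the converged matrix.
  support <- (M > 1e-7) | (t(M) > 1e-7)
  g <- igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  names(comp) <- nodes

  # Relabel: ids contiguous from 1, decreasing size, ties by smallest member.
  sizes <- table(comp)
  first_member <- vapply(names(sizes), function(cid) {
    min(nodes[comp == as.integer(cid)])
  }, "")
  ord <- order(-as.integer(sizes), first_member)
  relabel <- integer(length(sizes))
  relabel[as.integer(names(sizes))[ord]] <- seq_along(ord)
  clusters <- relabel[comp]
  names(clusters) <- nodes

  structure(list(clusters = clusters,
                 n_clusters = max(clusters),
                 converged = converged,
                 iterations = iter,
                 parameters = list(inflation = inflation,
                                   expansion = as.integer(expansion),
                                   tolerance = tolerance,
                                   max_iterations = as.integer(max_iterations))),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("MCL cluster assignment: ", length(x$clusters), " nodes in ",
      x$n_clusters, " clusters (inflation ", x$parameters$inflation,
      if (!x$converged) ", NOT converged" else "", ")\n", sep = "")
  for (cid in seq_len(min(x$n_clusters, 8L))) {
    mem <- sort(names(x$clusters)[x$clusters == cid])
    cat("  ", cid, ": ", paste(utils::head(mem, 12L), collapse = ", "),
        if (length(mem) > 12L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Write a cluster assignment to TSV
#' @param x A `cluster_assignment`.
#' @param path Output path (columns `symbol`, `cluster`).
#' @export
write_clusters <- function(x, path) {
  stopifnot(inherits(x, "cluster_assignment"))
  out <- data.frame(symbol = names(x$clusters), cluster = unname(x$clusters),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cluster, out$symbol), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
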