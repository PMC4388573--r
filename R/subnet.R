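# Triangle-based subnetwork extraction and centrality analysis.
#
# The analysis graph holds the miRNAs and their direct targets after target
# addition: a directed arc miRNA -> target per regulatory edge, and both
# directions of every PPI edge whose endpoints are in-network targets.
# Around each seed node, the subnetwork keeps exactly the neighbours that
# close at least one triangle with the seed (neighbour sets are taken in
# the undirected view), with the induced directed arcs; a seed without
# triangles yields the singleton subnetwork.

.node_types <- function(graph) {
  nm <- igraph::V(graph)$name
  ty <- igraph::vertex_attr(graph, "type")
  if (is.null(ty)) ty <- ifelse(is_mirna_id(nm), "mirna", "gene")
  stats::setNames(ty, nm)
}

#' Build the analysis graph from an (extended) regulatory network
#'
#' @param net `regnet` object (normally after [add_targets()]).
#' @param ppi PPI edge list from [read_ppi()]; edges between in-network
#'   targets are imported in both directions.
#' @return a directed `igraph` with a `type` vertex attribute
#'   (`"mirna"`/`"gene"`) and a `relation` edge attribute.
#' @export
build_analysis_graph <- function(net, ppi) {
  stopifnot(inherits(net, "regnet"))
  nodes <- data.frame(name = c(net$mirnas, net$targets),
                      type = c(rep("mirna", length(net$mirnas)),
                               rep("gene", length(net$targets))),
                      stringsAsFactors = FALSE)
  reg <- data.frame(from = net$edges$mirna, to = net$edges$gene,
                    relation = "targets", stringsAsFactors = FALSE)
  pp <- ppi[ppi$a %in% net$targets & ppi$b %in% net$targets, , drop = FALSE]
  arcs <- rbind(reg,
                data.frame(from = c(pp$a, pp$b), to = c(pp$b, pp$a),
                           relation = "interacts", stringsAsFactors = FALSE))
  arcs <- unique(arcs)
  igraph::graph_from_data_frame(arcs, directed = TRUE, vertices = nodes)
}

#' Undirected neighbour set of a node
#'
#' Union of in- and out-neighbours, excluding the node itself; this is the
#' neighbourhood used for triangle finding.
#'
#' @param graph an `igraph`.
#' @param node a node name.
#' @return character vector of neighbour names.
#' @export
node_neighbours <- function(graph, node) {
  if (!node %in% igraph::V(graph)$name) {
    stop("node '", node, "' is not in the graph")
  }
  nb <- igraph::as_ids(igraph::neighbors(graph, node, mode = "all"))
  setdiff(sort(unique(nb)), node)
}

#' Extract the triangle subnetwork of a seed
#'
#' For each neighbour `u` of the seed, the triangle partners are the
#' members of `N(seed)` that also lie in `N(u)` minus the seed; the
#' subnetwork keeps the seed plus every neighbour participating in at least
#' one such triangle, with all induced arcs. The per-neighbour
#' intersections are returned for inspection.
#'
#' @param graph an `igraph` (typically from [build_analysis_graph()]).
#' @param seed a node name present in the graph.
#' @return object of class `subnetwork`: list with `seed`, `nodes`,
#'   `graph` (induced directed subgraph), `node_types`, and
#'   `intersections` (named list, one entry per neighbour of the seed).
#' @export
extract_subnetwork <- function(graph, seed) {
  if (!seed %in% igraph::V(graph)$name) {
    stop("seed '", seed, "' is not in the graph")
  }
  n1 <- node_neighbours(graph, seed)
  inter <- lapply(n1, function(u) {
    intersect(n1, setdiff(node_neighbours(graph, u), seed))
  })
  names(inter) <- n1
  partners <- sort(unique(unlist(inter, use.names = FALSE)))
  nodes <- c(seed, partners)
  sub <- igraph::induced_subgraph(graph, nodes)
  types <- .node_types(graph)[nodes]
  structure(list(seed = seed, nodes = nodes, graph = sub,
                 node_types = types, intersections = inter),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("Subnetwork of seed '", x$seed, "': ", length(x$nodes), " nodes, ",
      igraph::ecount(x$graph), " arcs\n", sep = "")
  invisible(x)
}

#' Eigenvector centrality by power iteration
#'
#' Iterates `x <- (A + I) x / ||(A + I) x||_1` from the uniform vector,
#' where `A` is the directed adjacency matrix read row-wise (a node
#' accumulates the values of its out-neighbours). The identity shift leaves
#' the eigenvectors of `A` unchanged while preventing oscillation on
#' bipartite or periodic structures. The dominant eigenvalue is reported as
#' the Rayleigh quotient of `A` at the converged vector.
#'
#' @param graph a non-empty `igraph`.
#' @param tol L1 convergence tolerance on successive iterates.
#' @param max_iter iteration cap; non-convergence raises an error condition
#'   carrying the last iterate and residual.
#' @return list with `values` (named, non-negative, summing to 1),
#'   `lambda`, and `iterations`.
#' @export
power_method <- function(graph, tol = 1e-10, max_iter = 1e5) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("graph is empty")
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  x <- rep(1 / n, n)
  delta <- Inf
  for (it in seq_len(max_iter)) {
    y <- as.vector(A %*% x) + x
    y <- y / sum(y)
    delta <- sum(abs(y - x))
    x <- y
    if (delta < tol) {
      lambda <- sum(x * as.vector(A %*% x)) / sum(x * x)
      return(list(values = stats::setNames(x, rownames(A)),
                  lambda = lambda, iterations = it))
    }
  }
  stop(errorCondition(
    sprintf("power iteration did not converge in %d iterations (residual %.3e)",
            max_iter, delta),
    iterate = stats::setNames(x, rownames(A)), residual = delta,
    class = c("power_method_error", "error", "condition")))
}

#' Node centrality indices of a directed graph
#'
#' Betweenness on directed shortest paths; closeness in the harmonic form
#' that is well defined on directed, possibly disconnected graphs
#' (unreachable pairs contribute 0); eccentricity as the longest shortest
#' path over the reachable set (0 for a node that reaches nothing); and the
#' power-method eigenvector index.
#'
#' @param graph an `igraph`.
#' @param tol,max_iter passed to [power_method()].
#' @return data.frame with columns `node`, `betweenness`, `closeness`,
#'   `eccentricity`, `power`.
#' @export
centrality_indices <- function(graph, tol = 1e-10, max_iter = 1e5) {
  nm <- igraph::V(graph)$name
  d <- igraph::distances(graph, mode = "out")
  inv <- 1 / d
  inv[!is.finite(d)] <- 0
  diag(inv) <- 0
  clo <- rowSums(inv)
  dd <- d
  dd[!is.finite(dd)] <- NA
  diag(dd) <- NA
  ecc <- apply(dd, 1L, function(r) if (all(is.na(r))) 0 else max(r, na.rm = TRUE))
  btw <- igraph::betweenness(graph, directed = TRUE)
  pw <- power_method(graph, tol = tol, max_iter = max_iter)$values
  data.frame(node = nm,
             betweenness = unname(btw[nm]),
             closeness = unname(clo[nm]),
             eccentricity = unname(ecc[nm]),
             power = unname(pw[nm]),
             stringsAsFactors = FALSE)
}

#' Build the meta-network over subnetworks
#'
#' Nodes are subnetwork seeds; a directed arc A -> B is present when B's
#' seed belongs to A's subnetwork. The trivial self-membership of a seed in
#' its own subnetwork never creates a self-loop.
#'
#' @param subnets list of `subnetwork` objects with distinct seeds.
#' @return a directed `igraph` whose vertices are the seeds.
#' @export
build_meta_network <- function(subnets) {
  stopifnot(length(subnets) > 0L,
            all(vapply(subnets, inherits, logical(1), "subnetwork")))
  seeds <- vapply(subnets, `[[`, character(1), "seed")
  if (anyDuplicated(seeds)) stop("subnetwork seeds must be distinct")
  memb <- lapply(subnets, `[[`, "nodes")
  arcs <- do.call(rbind, lapply(seq_along(subnets), function(i) {
    to <- seeds[seeds %in% memb[[i]] & seeds != seeds[i]]
    if (length(to)) data.frame(from = seeds[i], to = to,
                               stringsAsFactors = FALSE)
  }))
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(seeds)
  if (!is.null(arcs) && nrow(arcs)) {
    g <- igraph::add_edges(g, as.vector(rbind(match(arcs$from, seeds),
                                              match(arcs$to, seeds))))
  }
  g
}
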