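# Guilt-by-association network extension. The base targets are expanded
# over the protein-protein interaction graph by breadth-first closure;
# genes one PPI step away from a base target (depth 1) become candidate
# new targets, gated on carrying a disease background function and then
# admitted only if (a) they are predicted targets of a network miRNA and
# (b) strongly anticorrelated (p <= alpha_add) with at least one of those
# miRNAs. The admission procedure runs exactly once.

#' Extend the regulatory network over a PPI graph
#'
#' Breadth-first closure from the base target set. Base targets sit at depth
#' 0; depth-1 genes have a direct PPI edge to a base target. With
#' `max_depth = Inf` (default) the closure reaches the whole connected
#' component of each target, the natural stopping point when no further
#' interactor can be imported.
#'
#' @param net `regnet` object from [build_regulatory_network()].
#' @param ppi PPI edge list from [read_ppi()].
#' @param max_depth maximum import depth, `Inf` for full closure.
#' @return object of class `extended_regnet`: list with `base`, `imported`
#'   (named integer vector of depths, all >= 1) and `ppi_edges_used` (PPI
#'   edges with both endpoints reached).
#' @export
extend_network <- function(net, ppi, max_depth = Inf) {
  stopifnot(inherits(net, "regnet"))
  nbrs <- split(c(ppi$b, ppi$a), c(ppi$a, ppi$b))
  visited <- net$targets
  frontier <- intersect(net$targets, names(nbrs))
  depth <- integer(0)
  d <- 0L
  while (length(frontier) && d < max_depth) {
    d <- d + 1L
    nxt <- setdiff(unique(unlist(nbrs[frontier], use.names = FALSE)),
                   visited)
    if (!length(nxt)) break
    depth[nxt] <- d
    visited <- c(visited, nxt)
    frontier <- intersect(nxt, names(nbrs))
  }
  used <- ppi[ppi$a %in% visited & ppi$b %in% visited, , drop = FALSE]
  rownames(used) <- NULL
  structure(list(base = net, imported = depth, ppi_edges_used = used),
            class = "extended_regnet")
}

#' @export
print.extended_regnet <- function(x, ...) {
  cat("Extended network:", length(x$base$targets), "base targets,",
      length(x$imported), "imported genes (max depth",
      if (length(x$imported)) max(x$imported) else 0, ")\n")
  invisible(x)
}

#' Admit new targets among direct interactors of base targets
#'
#' Candidates are the imported genes at depth exactly 1 that carry at least
#' one background function. A candidate is admitted iff (a) it is a
#' predicted target of at least one miRNA already in the network and (b) it
#' is anticorrelated with at least one of those miRNAs at `p <= alpha_add`;
#' it is then connected to every miRNA of its qualifying set M. The
#' procedure is not iterated: calling it on an already-extended network is
#' an error.
#'
#' @param ext `extended_regnet` from [extend_network()].
#' @param bf background functions from [background_functions()].
#' @param ann annotation map from [read_go_annotations()].
#' @param preds prediction table.
#' @param mrna,mirna expression matrices (same samples as the base network).
#' @param alpha_add anticorrelation p-value cutoff for admission.
#' @return a new `regnet` with `extended = TRUE`; added targets are tagged
#'   `origin = "added"` and the base network is a subgraph of the result.
#' @export
add_targets <- function(ext, bf, ann, preds, mrna, mirna,
                        alpha_add = 0.01) {
  stopifnot(inherits(ext, "extended_regnet"))
  net <- ext$base
  if (isTRUE(net$extended)) {
    stop("target addition has already been applied to this network; ",
         "the procedure runs exactly once")
  }
  if (alpha_add <= 0 || alpha_add >= 1) stop("alpha_add must be in (0, 1)")
  cand <- names(ext$imported)[ext$imported == 1L]
  cand <- setdiff(cand, net$targets)
  has_bf <- vapply(cand, function(g) {
    any(ann$gene_to_terms[[g]] %in% bf$term)
  }, logical(1))
  cand <- cand[has_bf]
  skipped_expr <- 0L
  new_edges <- vector("list", length(cand))
  for (i in seq_along(cand)) {
    g <- cand[i]
    if (!g %in% rownames(mrna)) {
      skipped_expr <- skipped_expr + 1L
      next
    }
    ms <- intersect(predicted_mirnas(preds, g), net$mirnas)  # condition (a)
    ms <- ms[ms %in% rownames(mirna)]
    if (!length(ms)) next
    rows <- lapply(ms, function(mi) {
      r <- pearson_cor(mrna[g, ], mirna[mi, ])
      if (r$ok && r$rho < 0 && r$p_value <= alpha_add) {  # condition (b)
        data.frame(mirna = mi, gene = g, rho = r$rho, p = r$p_value,
                   origin = "added", stringsAsFactors = FALSE)
      }
    })
    rows <- do.call(rbind, rows)
    if (!is.null(rows) && nrow(rows)) new_edges[[i]] <- rows
  }
  added <- do.call(rbind, new_edges)
  edges <- rbind(net$edges, added)
  origin <- net$origin
  if (!is.null(added)) {
    for (g in unique(added$gene)) origin[g] <- "added"
  }
  .new_regnet(edges, origin, net$min_corr, net$alpha, net$n_samples,
              extended = TRUE,
              log = c(net$log, list(
                candidates_depth1 = sum(ext$imported == 1L),
                candidates_with_background = length(cand),
                candidates_without_expression = skipped_expr,
                targets_added = if (is.null(added)) 0L else
                  length(unique(added$gene)),
                alpha_add = alpha_add)))
}
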