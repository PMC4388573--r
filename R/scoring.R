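# Subnetwork scoring and seed ranking. Each subnetwork is scored by a
# Fisher-combined-probability style sum over the disease background
# functions: for every background term, the enrichment p-value of the
# subnetwork's gene set is computed (raw, no BH at this stage) and the
# score is S = sum of -log10 p over terms with a positive p-value.

#' Combine enrichment p-values into a subnetwork score
#'
#' `S = sum(-log10(p))` over positive p-values; a p-value of exactly 1
#' contributes 0 and an underflowed p is floored at 1e-320 before the log.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return non-negative score.
#' @export
#' @examples
#' fisher_combine_score(c(0.1, 0.01))  # 1 + 2 = 3
fisher_combine_score <- function(p) {
  stopifnot(is.numeric(p))
  if (!length(p)) return(0)
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) {
    stop("p-values must lie in [0, 1]")
  }
  p <- pmax(p, 1e-320)
  sum(-log10(p))
}

#' Score a subnetwork against the background functions
#'
#' For each background term, computes the enrichment p-value of the
#' subnetwork's gene nodes (miRNA nodes are excluded: the annotation covers
#' genes) against the annotation universe, then combines the p-values with
#' [fisher_combine_score()]. An empty background set scores 0.
#'
#' @param subnet `subnetwork` object.
#' @param bf background functions from [background_functions()].
#' @param ann annotation map.
#' @param universe character vector of universe gene IDs (normally
#'   `names(ann$gene_to_terms)`).
#' @param mode enrichment mode, as in [background_functions()].
#' @return the regulatory subnetwork score, a non-negative real.
#' @export
subnetwork_score <- function(subnet, bf, ann, universe,
                             mode = c("paper", "standard")) {
  mode <- match.arg(mode)
  stopifnot(inherits(subnet, "subnetwork"))
  if (!nrow(bf)) return(0)
  genes <- subnet$nodes[subnet$node_types[subnet$nodes] != "mirna"]
  q <- intersect(genes, universe)
  n <- length(q)
  m <- length(universe)
  k <- vapply(bf$term,
              function(f) sum(ann$term_to_genes[[f]] %in% q), integer(1))
  j <- lengths(ann$term_to_genes[bf$term])
  p <- switch(mode,
              paper = fisher_paper(k, unname(j), n, m),
              standard = fisher_standard(k, unname(j), n, m))
  fisher_combine_score(p)
}

#' Rank subnetwork seeds
#'
#' Primary key: regulatory subnetwork score (RSs), descending; ties broken
#' by subnetwork size (descending) then seed ID (ascending). The seed's
#' literature disease score fills the Ds column, with a -1.00 sentinel for
#' miRNA seeds and for genes with fewer than `min_pubs` supporting disease
#' publications (or none on record). PMs is the power-method value of the
#' seed in the meta-network.
#'
#' @param subnets list of `subnetwork` objects (distinct seeds).
#' @param scores numeric vector of subnetwork scores, aligned with
#'   `subnets`.
#' @param meta_pm result of [power_method()] on the meta-network from
#'   [build_meta_network()].
#' @param lit_records literature score table from [literature_scores()]
#'   (columns `gene`, `ds`, `k`).
#' @param min_pubs minimum supporting disease publications for a reportable
#'   disease score.
#' @return data.frame with columns `seed`, `nr_nodes`, `RSs`, `Ds`, `PMs`
#'   in rank order.
#' @export
rank_seeds <- function(subnets, scores, meta_pm, lit_records,
                       min_pubs = 9) {
  stopifnot(length(subnets) == length(scores))
  seeds <- vapply(subnets, `[[`, character(1), "seed")
  nr_nodes <- lengths(lapply(subnets, `[[`, "nodes"))
  seed_type <- vapply(subnets, function(s) s$node_types[[s$seed]],
                      character(1))
  ds <- vapply(seq_along(seeds), function(i) {
    if (seed_type[i] == "mirna") return(-1)
    row <- match(seeds[i], lit_records$gene)
    if (is.na(row) || lit_records$k[row] < min_pubs) return(-1)
    lit_records$ds[row]
  }, numeric(1))
  pm <- meta_pm$values[seeds]
  out <- data.frame(seed = seeds, nr_nodes = as.integer(nr_nodes),
                    RSs = scores, Ds = ds, PMs = unname(pm),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$RSs, -out$nr_nodes, out$seed), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a ranking table as CSV
#'
#' The presentation columns round RSs, Ds and PMs to two decimals; the
#' machine-readable `*_full` columns keep full precision.
#'
#' @param ranking data.frame from [rank_seeds()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  out <- data.frame(seed = ranking$seed,
                    nr_nodes = ranking$nr_nodes,
                    RSs = sprintf("%.2f", ranking$RSs),
                    Ds = sprintf("%.2f", ranking$Ds),
                    PMs = sprintf("%.2f", ranking$PMs),
                    RSs_full = ranking$RSs,
                    Ds_full = ranking$Ds,
                    PMs_full = ranking$PMs,
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
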