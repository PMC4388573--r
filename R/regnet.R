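# Construction of the base bipartite regulatory network: miRNA-target pairs
# that are (i) sequence-predicted, (ii) targeted at a literature-selected
# disease gene, and (iii) significantly negatively correlated in paired
# expression. miRNAs repress their targets, so only anticorrelation counts
# as supporting evidence.

.new_regnet <- function(edges, origin, min_corr, alpha, n_samples,
                        extended = FALSE, log = list()) {
  edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(
    edges = edges,
    mirnas = sort(unique(edges$mirna)),
    targets = sort(unique(edges$gene)),
    origin = origin,
    min_corr = min_corr,
    alpha = alpha,
    n_samples = n_samples,
    extended = extended,
    log = log
  ), class = "regnet")
}

#' @export
print.regnet <- function(x, ...) {
  cat("Regulatory network:", length(x$mirnas), "miRNAs,",
      length(x$targets), "targets,", nrow(x$edges), "edges",
      if (x$extended) "(extended)" else "", "\n")
  cat(sprintf("  |rho| >= %.4f at alpha = %g, %d samples\n",
              x$min_corr, x$alpha, x$n_samples))
  invisible(x)
}

#' Pearson correlation with a two-sided significance test
#'
#' Thin wrapper around the exact two-sided t transform of the sample
#' correlation (n - 2 degrees of freedom). A zero-variance vector makes the
#' coefficient undefined; the pair is then flagged rather than scored, and
#' it fails every downstream filter.
#'
#' @param x,y numeric vectors of equal length (at least 3), finite values.
#' @return list with `ok`, `rho`, `p_value`, `n`, and `reason` when not ok.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired samples")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(ok = FALSE, reason = "undefined correlation",
                rho = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(ok = TRUE, rho = unname(ct$estimate), p_value = ct$p.value,
       n = length(x))
}

#' Minimum significant absolute correlation at a given sample size
#'
#' The smallest `|r|` whose two-sided p-value reaches `alpha` with
#' `n_samples` observations; it solves `r = t / sqrt(n - 2 + t^2)` at the
#' critical t value and decreases as the sample size grows.
#'
#' @param n_samples number of paired samples (at least 4).
#' @param alpha two-sided significance level in (0, 1).
#' @return threshold in (0, 1).
#' @export
#' @examples
#' min_significant_corr(111, 0.05)
min_significant_corr <- function(n_samples, alpha = 0.05) {
  if (n_samples < 4L) stop("n_samples must be at least 4")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  tc <- qt(1 - alpha / 2, df = n_samples - 2)
  tc / sqrt(n_samples - 2 + tc^2)
}

#' Build the base regulatory network
#'
#' Retains every predicted miRNA-target pair whose target belongs to the
#' disease gene set and whose expression correlation is negative with
#' absolute value at or above the significance threshold (ties retained).
#' Nodes are exactly the endpoints of retained edges. Genes or miRNAs
#' without an expression row cannot be scored and are skipped; their counts
#' are kept in the network's `log`.
#'
#' @param genes character vector of disease gene IDs (the literature set).
#' @param preds prediction table from [read_predictions()].
#' @param mrna,mirna expression matrices sharing identical sample columns in
#'   identical order.
#' @param alpha two-sided significance level for the correlation filter.
#' @return object of class `regnet`.
#' @export
build_regulatory_network <- function(genes, preds, mrna, mirna,
                                     alpha = 0.05) {
  if (!identical(colnames(mrna), colnames(mirna))) {
    stop("mRNA and miRNA matrices must share identical samples in identical order")
  }
  n <- ncol(mrna)
  thr <- min_significant_corr(n, alpha)
  genes <- unique(genes)
  genes_expr <- genes[genes %in% rownames(mrna)]
  cand <- preds[preds$gene %in% genes_expr, , drop = FALSE]
  cand_expr <- cand[cand$mirna %in% rownames(mirna), , drop = FALSE]
  keep <- logical(nrow(cand_expr))
  rho <- p <- rep(NA_real_, nrow(cand_expr))
  for (i in seq_len(nrow(cand_expr))) {
    r <- pearson_cor(mrna[cand_expr$gene[i], ], mirna[cand_expr$mirna[i], ])
    if (r$ok) {
      rho[i] <- r$rho
      p[i] <- r$p_value
      keep[i] <- r$rho < 0 && abs(r$rho) >= thr
    }
  }
  edges <- data.frame(mirna = cand_expr$mirna[keep],
                      gene = cand_expr$gene[keep],
                      rho = rho[keep], p = p[keep],
                      origin = rep("literature", sum(keep)),
                      stringsAsFactors = FALSE)
  origin <- stats::setNames(rep("literature", length(unique(edges$gene))),
                            unique(edges$gene))
  .new_regnet(edges, origin, thr, alpha, n,
              log = list(
                genes_without_expression = sum(!genes %in% rownames(mrna)),
                mirnas_without_expression =
                  length(setdiff(unique(cand$mirna), rownames(mirna))),
                pairs_tested = nrow(cand_expr),
                pairs_retained = sum(keep)))
}
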