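# Background-function selection: per-GO-term enrichment of a gene set with
# Benjamini-Hochberg control. Two enrichment p-value modes are provided.
#
# "paper" evaluates the closed form
#     C(k+j, k) * C(n-k+m-j, n-k) / C(n+m, n)
# on the counts k (query genes with the term), j (universe genes with the
# term), n (query size), m (universe size). Note this contingency layout
# double-counts: j includes the k query genes and m includes the whole
# query, so the expression is not a standard Fisher exact test. It is kept
# as the default mode for fidelity to the published procedure.
#
# "standard" is the conventional one-sided Fisher exact enrichment test,
# i.e. the hypergeometric upper tail of k on the corrected 2x2 table
# [k, j-k; n-k, m-j-(n-k)].

#' Enrichment p-value, literal closed-form mode
#'
#' Evaluates the printed closed form in log space. An inconsistent argument
#' combination can push the expression outside `[0, 1]`; such results are
#' clamped to 1 with a warning.
#'
#' @param k query genes annotated with the term.
#' @param j universe genes annotated with the term.
#' @param n query-set size.
#' @param m universe size.
#' @return probability in `[0, 1]`.
#' @export
fisher_paper <- function(k, j, n, m) {
  if (any(c(k, j, n, m) < 0)) stop("counts must be non-negative")
  logp <- lchoose(k + j, k) + lchoose(n - k + m - j, n - k) -
    lchoose(n + m, n)
  p <- exp(logp)
  bad <- !is.finite(p) | p > 1
  if (any(bad)) {
    warning("closed-form enrichment value outside [0, 1]; clamped to 1")
    p[bad] <- 1
  }
  p
}

#' Enrichment p-value, one-sided Fisher exact mode
#'
#' Hypergeometric upper tail of the overlap `k` given `j` annotated genes in
#' a universe of `m`, with a query of size `n`.
#'
#' @inheritParams fisher_paper
#' @return probability in `(0, 1]`.
#' @export
fisher_standard <- function(k, j, n, m) {
  if (any(c(k, j - k, n - k, m - j - (n - k)) < 0)) {
    stop("counts do not form a consistent 2x2 contingency table")
  }
  pmin(pmax(phyper(k - 1, j, m - j, n, lower.tail = FALSE), 0), 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of raw p-values in (0, 1].
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  if (length(p) && (any(p <= 0) || any(p > 1))) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Select the disease background functions
#'
#' Tests every GO term annotating at least one query gene for enrichment of
#' the query set against the full annotation universe, BH-adjusts across the
#' tested terms, and keeps terms with adjusted p at or below `alpha`.
#' Annotations are used as given; no ontology-hierarchy propagation is
#' performed.
#'
#' @param query character vector of gene IDs (typically the literature-
#'   selected disease genes).
#' @param ann annotation map from [read_go_annotations()].
#' @param alpha BH-adjusted significance cutoff.
#' @param mode `"paper"` (default, literal closed form) or `"standard"`
#'   (one-sided Fisher exact).
#' @return data.frame with columns `term`, `k`, `j`, `n`, `m`, `p_raw`,
#'   `p_adj`, restricted to selected terms and sorted by `p_adj`.
#' @export
background_functions <- function(query, ann, alpha = 0.05,
                                 mode = c("paper", "standard")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ann, "go_annotation"))
  empty <- data.frame(term = character(0), k = integer(0), j = integer(0),
                      n = integer(0), m = integer(0), p_raw = numeric(0),
                      p_adj = numeric(0), stringsAsFactors = FALSE)
  universe <- names(ann$gene_to_terms)
  m <- length(universe)
  if (m == 0L) stop("annotation universe is empty")
  q <- intersect(unique(query), universe)
  if (!length(q)) {
    warning("query set shares no genes with the annotation universe")
    return(empty)
  }
  n <- length(q)
  terms <- sort(unique(unlist(ann$gene_to_terms[q], use.names = FALSE)))
  if (!length(terms)) return(empty)
  k <- vapply(terms,
              function(f) sum(ann$term_to_genes[[f]] %in% q), integer(1))
  j <- lengths(ann$term_to_genes[terms])
  p_raw <- switch(mode,
                  paper = fisher_paper(k, j, n, m),
                  standard = fisher_standard(k, j, n, m))
  p_raw <- pmax(p_raw, .Machine$double.xmin)  # keep BH input in (0, 1]
  out <- data.frame(term = terms, k = k, j = unname(j), n = n, m = m,
                    p_raw = p_raw, p_adj = bh_adjust(p_raw),
                    stringsAsFactors = FALSE)
  out <- out[out$p_adj <= alpha, , drop = FALSE]
  out <- out[order(out$p_adj, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
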