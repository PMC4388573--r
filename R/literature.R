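# Literature-based disease scoring.
#
# A gene's relevance to a disease is measured by how surprisingly often its
# publications fall inside the disease publication corpus. With m articles
# carrying human gene information, n of them disease-related, j articles
# about the gene and k of those also disease-related, the tail probability
#
#   H(m, n, j, k) = sum_{i=k}^{min(n,j)} C(m-j, n-i) C(j, i) / C(m, n)
#
# is the chance of observing an overlap of at least k by drawing the disease
# corpus at random, and the disease score is ds = -log10 H. Scores are
# computed in log space so that extremely enriched genes (ds in the
# hundreds) remain finite; only a tail of exactly zero maps to the cap.

#' Cap returned for a disease score whose tail probability is exactly zero
#' @export
DS_CAP <- 320

.check_lit_counts <- function(m, n, j, k) {
  if (any(c(m, n, j, k) < 0)) stop("literature counts must be non-negative")
  if (any(n > m)) stop("n (disease articles) cannot exceed m (all articles)")
  if (any(j > m)) stop("j (gene articles) cannot exceed m (all articles)")
}

#' Hypergeometric upper-tail probability of a literature overlap
#'
#' Probability of drawing at least `k` of the `j` gene-related articles when
#' `n` disease-related articles are sampled from a corpus of `m`.
#'
#' @param m total articles with gene information.
#' @param n disease-related articles among the `m`.
#' @param j articles about the gene.
#' @param k articles about the gene that are also disease-related. `k >
#'   min(n, j)` is permitted and yields an empty sum (probability 0).
#' @return probability in `[0, 1]`.
#' @export
#' @examples
#' hypergeom_tail(20, 8, 5, 3)
hypergeom_tail <- function(m, n, j, k) {
  .check_lit_counts(m, n, j, k)
  out <- numeric(length(k))
  empty <- k > pmin(n, j)
  full <- k <= 0
  mid <- !empty & !full
  out[empty] <- 0
  out[full] <- 1
  if (any(mid)) {
    p <- phyper(k[mid] - 1, j[mid], m[mid] - j[mid], n[mid],
                lower.tail = FALSE)
    out[mid] <- pmin(pmax(p, 0), 1)
  }
  out
}

#' Literature disease score ds = -log10 H(m, n, j, k)
#'
#' Computed in log space, so very small tails give large finite scores; a
#' tail of exactly zero (empty sum) returns [DS_CAP].
#'
#' @inheritParams hypergeom_tail
#' @return non-negative disease score.
#' @export
disease_score <- function(m, n, j, k) {
  .check_lit_counts(m, n, j, k)
  out <- numeric(length(k))
  empty <- k > pmin(n, j)
  full <- k <= 0
  mid <- !empty & !full
  out[empty] <- DS_CAP
  out[full] <- 0
  if (any(mid)) {
    logp <- phyper(k[mid] - 1, j[mid], m[mid] - j[mid], n[mid],
                   lower.tail = FALSE, log.p = TRUE)
    ds <- -logp / log(10)
    ds[!is.finite(logp)] <- DS_CAP
    out[mid] <- pmax(ds, 0)
  }
  out
}

#' Disease scores for every gene in a publication corpus
#'
#' Derives the global counts from the supplied corpus itself: `m` is the
#' number of distinct publications across all genes, `n` the number of those
#' that belong to the disease corpus; per gene, `j` is its publication count
#' and `k` the disease-related part.
#'
#' @param gene_pubs named list mapping gene IDs to publication-ID vectors,
#'   as returned by [read_gene2pubmed()].
#' @param disease_pmids character vector of disease-corpus publication IDs.
#' @return data.frame with columns `gene`, `m`, `n`, `j`, `k`, `H`, `ds`,
#'   sorted by decreasing score.
#' @export
literature_scores <- function(gene_pubs, disease_pmids) {
  if (!length(disease_pmids)) {
    stop("disease publication corpus is empty; the disease score is undefined")
  }
  if (!length(gene_pubs)) {
    return(data.frame(gene = character(0), m = integer(0), n = integer(0),
                      j = integer(0), k = integer(0), H = numeric(0),
                      ds = numeric(0)))
  }
  disease <- unique(disease_pmids)
  all_pubs <- unique(unlist(gene_pubs, use.names = FALSE))
  m <- length(all_pubs)
  n <- sum(all_pubs %in% disease)
  j <- lengths(gene_pubs)
  k <- vapply(gene_pubs, function(p) sum(unique(p) %in% disease), integer(1))
  mv <- rep(m, length(j)); nv <- rep(n, length(j))
  df <- data.frame(gene = names(gene_pubs), m = mv, n = nv, j = j, k = k,
                   H = hypergeom_tail(mv, nv, j, k),
                   ds = disease_score(mv, nv, j, k),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$ds, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Select the disease gene set by the ds threshold
#'
#' Retains exactly the genes whose disease score is strictly greater than
#' the threshold (default 4, i.e. a tail probability below 1e-4).
#'
#' @inheritParams literature_scores
#' @param threshold minimum disease score, exclusive.
#' @return the [literature_scores()] data.frame restricted to selected genes.
#' @export
select_disease_genes <- function(gene_pubs, disease_pmids, threshold = 4) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0)
  scores <- literature_scores(gene_pubs, disease_pmids)
  out <- scores[scores$ds > threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
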