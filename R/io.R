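# Readers and writers for the pipeline's tab-separated external formats.
# Shared conventions: UTF-8 text, "#"-prefixed comment lines and blank lines
# are skipped, structures use set semantics (row order and duplicate rows
# never matter), and a malformed row is a hard error naming the line.

.read_rows <- function(path, n_cols, what, exact = TRUE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  trimmed <- trimws(lines)
  keep <- which(nzchar(trimmed) & !startsWith(trimmed, "#"))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- if (exact) which(lengths(fields) != n_cols) else
    which(lengths(fields) < n_cols)
  if (length(bad)) {
    stop(sprintf(
      "malformed %s row at line %d of '%s': expected %s%d tab-separated fields, found %d",
      what, keep[bad[1L]], path, if (exact) "" else "at least ",
      n_cols, lengths(fields)[bad[1L]]), call. = FALSE)
  }
  list(fields = fields, lines = keep)
}

.field <- function(fields, i) trimws(vapply(fields, `[[`, character(1), i))

#' Read a gene2pubmed-style publication mapping
#'
#' Parses a three-column tab-separated file (`tax_id`, `gene`, `publication`)
#' and returns, for the requested taxon only, the set of distinct publication
#' IDs supporting each gene.
#'
#' @param path path to the TSV file.
#' @param taxon taxon filter value (e.g. `"9606"` for human); only rows whose
#'   first column equals it are retained.
#' @return named list mapping each gene ID to a character vector of distinct
#'   publication IDs. An empty file yields an empty list.
#' @export
read_gene2pubmed <- function(path, taxon) {
  stopifnot(is.character(taxon), length(taxon) == 1L)
  rows <- .read_rows(path, 3L, "gene2pubmed")
  if (!length(rows$fields)) return(stats::setNames(list(), character(0)))
  tax <- .field(rows$fields, 1L)
  gene <- .field(rows$fields, 2L)
  pub <- .field(rows$fields, 3L)
  sel <- tax == taxon
  if (!any(sel)) return(stats::setNames(list(), character(0)))
  lapply(split(pub[sel], gene[sel]), function(p) sort(unique(p)))
}

#' Read a plain list of publication IDs
#'
#' One ID per line; used for the disease corpus returned by a literature
#' query.
#'
#' @param path path to the file.
#' @return character vector of distinct publication IDs.
#' @export
read_pmid_list <- function(path) {
  rows <- .read_rows(path, 1L, "publication list", exact = FALSE)
  sort(unique(.field(rows$fields, 1L)))
}

#' Read an expression matrix (features x samples)
#'
#' The first non-comment line is the sample header; every following row is a
#' feature identifier followed by one numeric value per sample. A header with
#' one extra leading cell (a feature-column title) is also accepted.
#'
#' @param path path to the TSV file.
#' @param dedup policy for duplicate feature rows: `"error"` (default; silent
#'   aggregation can mask probe-level issues) or `"mean"` (element-wise mean).
#' @return numeric matrix with feature rownames and sample colnames; at least
#'   3 samples are required because downstream correlation is undefined below
#'   that.
#' @export
read_expression <- function(path, dedup = c("error", "mean")) {
  dedup <- match.arg(dedup)
  rows <- .read_rows(path, 1L, "expression", exact = FALSE)
  if (!length(rows$fields)) stop("expression file '", path, "' has no header row")
  header <- rows$fields[[1L]]
  data <- rows$fields[-1L]
  data_lines <- rows$lines[-1L]
  widths <- lengths(data)
  samples <- if (length(data) && all(widths == length(header))) {
    trimws(header[-1L])  # header carries a leading feature-column title
  } else {
    trimws(header)
  }
  if (length(samples) < 3L) {
    stop("expression file '", path, "' has ", length(samples),
         " samples; at least 3 are required for correlation")
  }
  bad <- which(widths != length(samples) + 1L)
  if (length(bad)) {
    stop(sprintf("malformed expression row at line %d of '%s': expected %d fields, found %d",
                 data_lines[bad[1L]], path, length(samples) + 1L, widths[bad[1L]]),
         call. = FALSE)
  }
  ids <- vapply(data, function(f) trimws(f[[1L]]), character(1))
  vals <- matrix(NA_real_, nrow = length(data), ncol = length(samples),
                 dimnames = list(ids, samples))
  for (i in seq_along(data)) {
    v <- suppressWarnings(as.numeric(data[[i]][-1L]))
    if (anyNA(v) || !all(is.finite(v))) {
      stop(sprintf("non-numeric or non-finite expression value at line %d of '%s'",
                   data_lines[i], path), call. = FALSE)
    }
    vals[i, ] <- v
  }
  if (anyDuplicated(ids)) {
    if (dedup == "error") {
      dup <- unique(ids[duplicated(ids)])
      stop("duplicate expression feature(s): ", paste(dup, collapse = ", "),
           " (use dedup = \"mean\" to aggregate)")
    }
    sums <- rowsum(vals, group = ids, reorder = FALSE)
    counts <- as.vector(table(ids)[rownames(sums)])
    vals <- sums / counts
  }
  vals
}

#' Read a miRNA-target prediction table
#'
#' Two tab-separated columns: miRNA ID, gene ID. Duplicate pairs collapse.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `mirna`, `gene`, one row per distinct pair.
#' @export
read_predictions <- function(path) {
  rows <- .read_rows(path, 2L, "prediction")
  df <- unique(data.frame(mirna = .field(rows$fields, 1L),
                          gene = .field(rows$fields, 2L),
                          stringsAsFactors = FALSE))
  df <- df[order(df$mirna, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Look up the miRNAs predicted to target a gene
#'
#' @param preds prediction table from [read_predictions()].
#' @param gene a single gene ID.
#' @return character vector of miRNA IDs (empty if the gene is unseen).
#' @export
predicted_mirnas <- function(preds, gene) {
  sort(unique(preds$mirna[preds$gene == gene]))
}

#' Read a protein-protein interaction edge list
#'
#' Two tab-separated gene columns. Edges are unordered: `(A,B)` and `(B,A)`
#' collapse to one edge, and self-loops are dropped (their count is reported
#' as a message).
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `a`, `b` (`a < b` lexicographically), one
#'   row per distinct undirected edge.
#' @export
read_ppi <- function(path) {
  rows <- .read_rows(path, 2L, "PPI")
  x <- .field(rows$fields, 1L)
  y <- .field(rows$fields, 2L)
  loops <- x == y
  if (any(loops)) message("read_ppi: dropped ", sum(loops), " self-loop(s)")
  x2 <- pmin(x[!loops], y[!loops])
  y2 <- pmax(x[!loops], y[!loops])
  df <- unique(data.frame(a = x2, b = y2, stringsAsFactors = FALSE))
  df <- df[order(df$a, df$b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read gene-to-GO-term annotations
#'
#' GAF-like tab-separated file with designated gene and term columns (by
#' default the first two). Extra columns are ignored.
#'
#' @param path path to the TSV file.
#' @param gene_col,term_col 1-based column indices of the gene and term IDs.
#' @return object of class `go_annotation`: a list with `gene_to_terms` and
#'   `term_to_genes`, exact inverses of each other.
#' @export
read_go_annotations <- function(path, gene_col = 1L, term_col = 2L) {
  rows <- .read_rows(path, max(gene_col, term_col), "GO annotation",
                     exact = FALSE)
  if (!length(rows$fields)) {
    return(structure(list(gene_to_terms = stats::setNames(list(), character(0)),
                          term_to_genes = stats::setNames(list(), character(0))),
                     class = "go_annotation"))
  }
  gene <- .field(rows$fields, gene_col)
  term <- .field(rows$fields, term_col)
  structure(list(
    gene_to_terms = lapply(split(term, gene), function(x) sort(unique(x))),
    term_to_genes = lapply(split(gene, term), function(x) sort(unique(x)))
  ), class = "go_annotation")
}

#' @export
print.go_annotation <- function(x, ...) {
  cat("GO annotation map:", length(x$gene_to_terms), "genes,",
      length(x$term_to_genes), "terms\n")
  invisible(x)
}

#' Write a regulatory subnetwork in Cytoscape SIF format
#'
#' Emits one `source<TAB>relation<TAB>target` line per interaction, with
#' relation `targets` for miRNA-to-gene regulatory arcs and `interacts` for
#' (undirected) protein-protein interactions. A subnetwork reduced to its
#' seed is written as a single node line, which SIF permits.
#'
#' @param subnet a `subnetwork` object from [extract_subnetwork()].
#' @param path output file path.
#' @return the path, invisibly.
#' @seealso [read_sif()] for the round-trip reader.
#' @export
write_subnetwork_sif <- function(subnet, path) {
  stopifnot(inherits(subnet, "subnetwork"))
  if (!length(subnet$nodes)) stop("cannot write an empty subnetwork")
  el <- igraph::as_edgelist(subnet$graph)
  lines <- character(0)
  if (nrow(el)) {
    from_mirna <- subnet$node_types[el[, 1L]] == "mirna"
    reg <- el[from_mirna, , drop = FALSE]
    lines <- c(lines, sprintf("%s\ttargets\t%s", reg[, 1L], reg[, 2L]))
    pp <- el[!from_mirna & subnet$node_types[el[, 2L]] != "mirna", ,
             drop = FALSE]
    if (nrow(pp)) {
      und <- unique(data.frame(a = pmin(pp[, 1L], pp[, 2L]),
                               b = pmax(pp[, 1L], pp[, 2L])))
      und <- und[order(und$a, und$b), , drop = FALSE]
      lines <- c(lines, sprintf("%s\tinteracts\t%s", und$a, und$b))
    }
  }
  mentioned <- if (nrow(el)) unique(as.vector(el)) else character(0)
  lines <- c(lines, setdiff(subnet$nodes, mentioned))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a SIF interaction file
#'
#' @param path path written by [write_subnetwork_sif()].
#' @return list with `edges` (data.frame `source`, `relation`, `target`) and
#'   `isolated` (character vector of node-only lines).
#' @export
read_sif <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(!n %in% c(1L, 3L))) {
    stop("malformed SIF line: ", lines[which(!n %in% c(1L, 3L))[1L]])
  }
  trip <- fields[n == 3L]
  list(
    edges = data.frame(source = vapply(trip, `[[`, "", 1L),
                       relation = vapply(trip, `[[`, "", 2L),
                       target = vapply(trip, `[[`, "", 3L),
                       stringsAsFactors = FALSE),
    isolated = vapply(fields[n == 1L], `[[`, "", 1L)
  )
}
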