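#' Classify identifiers as miRNA or gene
#'
#' Node identifiers live in two disjoint namespaces: mature miRNA names are
#' recognised by prefix (miRBase-style, e.g. `"hsa-miR-494"`), and every other
#' token is treated as a gene identifier (symbol or numeric NCBI-style ID).
#' The prefix list is configurable because public resources mix naming
#' conventions.
#'
#' @param ids character vector of identifiers.
#' @param prefixes character vector of miRNA name prefixes.
#' @return logical vector, `TRUE` where the identifier is a miRNA.
#' @export
#' @examples
#' is_mirna_id(c("hsa-miR-494", "ESR1", "hsa-let-7a"))
is_mirna_id <- function(ids, prefixes = c("hsa-miR", "hsa-let")) {
  stopifnot(is.character(ids))
  out <- rep(FALSE, length(ids))
  for (p in prefixes) out <- out | startsWith(ids, p)
  out
}
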