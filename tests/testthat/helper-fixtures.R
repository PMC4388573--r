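# Shared fixture builders. All data is generated in code at test time.

# Toy graph whose seed-1 neighbourhood walkthrough is fully specified:
# node 1 adjacent to 2, 4, 5; node 2 additionally to 3, 4, 9, 11; node 4
# additionally to 2, 3, 6; node 5 additionally to 6, 7, 8.
toy_triangle_graph <- function() {
  edges <- rbind(c("1", "2"), c("1", "4"), c("1", "5"),
                 c("2", "3"), c("2", "4"), c("2", "9"), c("2", "11"),
                 c("4", "3"), c("4", "6"),
                 c("5", "6"), c("5", "7"), c("5", "8"))
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

# A reduced fixture spec that keeps module-level tests fast while retaining
# detectable planted signal.
small_fixture_spec <- function(rng_seed = 1L, ...) {
  fixture_spec(rng_seed = rng_seed, n_genes = 120L, n_mirnas = 5L,
               n_samples = 50L, n_disease_genes = 25L,
               n_planted_pairs = 20L, n_decoy_pairs = 20L,
               n_go_terms = 20L, ...)
}

fixture_paths <- function(dir) {
  list(gene2pubmed = file.path(dir, "gene2pubmed.tsv"),
       disease_pmids = file.path(dir, "disease_pmids.txt"),
       predictions = file.path(dir, "predictions.tsv"),
       mrna = file.path(dir, "mrna.tsv"),
       mirna = file.path(dir, "mirna.tsv"),
       ppi = file.path(dir, "ppi.tsv"),
       go = file.path(dir, "go_annotations.tsv"))
}

fixture_config <- function(dir, out_dir = file.path(dir, "out"), ...) {
  p <- fixture_paths(dir)
  pipeline_config(gene2pubmed = p$gene2pubmed,
                  disease_pmids = p$disease_pmids,
                  predictions = p$predictions, mrna = p$mrna,
                  mirna = p$mirna, ppi = p$ppi, go = p$go,
                  out_dir = out_dir, ...)
}

# Generate fixtures into a fresh temp dir; returns list(dir, manifest).
make_fixtures <- function(spec) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  manifest <- generate_fixtures(spec, dir)
  list(dir = dir, manifest = manifest)
}

# Minimal hand-built annotation map.
tiny_annotation <- function(pairs) {
  # pairs: data.frame(gene, term)
  structure(list(
    gene_to_terms = lapply(split(pairs$term, pairs$gene),
                           function(x) sort(unique(x))),
    term_to_genes = lapply(split(pairs$gene, pairs$term),
                           function(x) sort(unique(x)))
  ), class = "go_annotation")
}
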