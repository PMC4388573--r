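# End-to-end pipeline driver. Stages communicate via files in the output
# directory so every intermediate is re-runnable and inspectable, and the
# run log records every threshold, every filter's before/after counts and
# an md5 digest of each artifact (the pipeline is deterministic given its
# inputs, so reruns must reproduce the digests byte for byte).

#' Pipeline configuration
#'
#' Bundles the five input paths with every tunable threshold. Thresholds
#' are validated here; input files are checked at run time.
#'
#' @param gene2pubmed,disease_pmids,predictions,mrna,mirna,ppi,go input file
#'   paths (formats as in the corresponding readers).
#' @param out_dir artifact directory.
#' @param taxon taxon filter for the gene2pubmed file.
#' @param ds_threshold disease-score selection threshold (strict, >= 0).
#' @param alpha_corr significance level of the correlation filter.
#' @param alpha_add anticorrelation cutoff for target admission.
#' @param alpha_bf BH-adjusted cutoff for background functions.
#' @param mode enrichment mode (`"paper"` or `"standard"`).
#' @param dedup duplicate-feature policy for expression files.
#' @param min_pubs publication sentinel threshold for the ranking report.
#' @param power_tol,power_max_iter power-iteration controls.
#' @param write_sif write one SIF file per seed under `subnetworks/`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(gene2pubmed, disease_pmids, predictions, mrna,
                            mirna, ppi, go, out_dir, taxon = "9606",
                            ds_threshold = 4, alpha_corr = 0.05,
                            alpha_add = 0.01, alpha_bf = 0.05,
                            mode = c("paper", "standard"),
                            dedup = c("error", "mean"), min_pubs = 9,
                            power_tol = 1e-10, power_max_iter = 1e5,
                            write_sif = TRUE) {
  mode <- match.arg(mode)
  dedup <- match.arg(dedup)
  if (ds_threshold < 0) stop("ds_threshold must be >= 0")
  for (a in c(alpha_corr, alpha_add, alpha_bf)) {
    if (a <= 0 || a >= 1) stop("alpha thresholds must lie in (0, 1)")
  }
  structure(list(gene2pubmed = gene2pubmed, disease_pmids = disease_pmids,
                 predictions = predictions, mrna = mrna, mirna = mirna,
                 ppi = ppi, go = go, out_dir = out_dir, taxon = taxon,
                 ds_threshold = ds_threshold, alpha_corr = alpha_corr,
                 alpha_add = alpha_add, alpha_bf = alpha_bf, mode = mode,
                 dedup = dedup, min_pubs = min_pubs, power_tol = power_tol,
                 power_max_iter = power_max_iter, write_sif = write_sif),
            class = "pipeline_config")
}

.sanitize <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)

#' Run the full pipeline
#'
#' Executes literature scoring, regulatory-network construction,
#' background-function selection, PPI extension with target addition,
#' subnetwork extraction with centrality computation, and seed ranking,
#' writing one artifact per stage into `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the final `ranking` data.frame, the
#'   `paths` of all artifacts and the run `log` lines.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  inputs <- c(config$gene2pubmed, config$disease_pmids, config$predictions,
              config$mrna, config$mirna, config$ppi, config$go)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  paths <- list()
  art <- function(name) {
    paths[[sub("\\..*$", "", name)]] <<- file.path(config$out_dir, name)
    file.path(config$out_dir, name)
  }

  ## Stage 1a: literature scoring -----------------------------------------
  gene_pubs <- read_gene2pubmed(config$gene2pubmed, config$taxon)
  disease_pmids <- read_pmid_list(config$disease_pmids)
  lit <- literature_scores(gene_pubs, disease_pmids)
  selected <- lit[lit$ds > config$ds_threshold, , drop = FALSE]
  write.csv(lit, art("literature.csv"), row.names = FALSE, quote = FALSE)
  note("literature\tgenes_scored=", nrow(lit),
       "\tselected_ds_gt_", config$ds_threshold, "=", nrow(selected))

  ## Stage 1b: regulatory network -----------------------------------------
  preds <- read_predictions(config$predictions)
  mrna <- read_expression(config$mrna, dedup = config$dedup)
  mirna <- read_expression(config$mirna, dedup = config$dedup)
  net <- build_regulatory_network(selected$gene, preds, mrna, mirna,
                                  alpha = config$alpha_corr)
  write.table(net$edges, art("edges.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  note("regnet\tmin_corr=", format(net$min_corr, digits = 10),
       "\tpairs_tested=", net$log$pairs_tested,
       "\tedges=", nrow(net$edges),
       "\tgenes_without_expression=", net$log$genes_without_expression)

  ## Stage 2a: background functions ---------------------------------------
  ann <- read_go_annotations(config$go)
  bf <- background_functions(selected$gene, ann, alpha = config$alpha_bf,
                             mode = config$mode)
  write.csv(bf, art("background.csv"), row.names = FALSE, quote = FALSE)
  note("background\tmode=", config$mode, "\tterms_selected=", nrow(bf))

  ## Stage 2b: PPI extension and target addition --------------------------
  ppi <- read_ppi(config$ppi)
  ext <- extend_network(net, ppi)
  net2 <- add_targets(ext, bf, ann, preds, mrna, mirna,
                      alpha_add = config$alpha_add)
  write.table(net2$edges, art("edges_extended.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("extension\timported=", length(ext$imported),
       "\tdepth1=", sum(ext$imported == 1L),
       "\ttargets_added=", net2$log$targets_added,
       "\talpha_add=", config$alpha_add)

  ## Stage 3: subnetworks, centralities, ranking --------------------------
  graph <- build_analysis_graph(net2, ppi)
  seeds <- igraph::V(graph)$name
  if (length(seeds)) {
    subnets <- lapply(seeds, function(s) extract_subnetwork(graph, s))
    if (config$write_sif) {
      sif_dir <- file.path(config$out_dir, "subnetworks")
      dir.create(sif_dir, showWarnings = FALSE)
      for (s in subnets) {
        write_subnetwork_sif(s, file.path(sif_dir,
                                          paste0(.sanitize(s$seed), ".sif")))
      }
    }
    cent <- centrality_indices(graph, tol = config$power_tol,
                               max_iter = config$power_max_iter)
    write.csv(cent, art("centralities.csv"), row.names = FALSE, quote = FALSE)
    universe <- names(ann$gene_to_terms)
    scores <- vapply(subnets, subnetwork_score, numeric(1), bf = bf,
                     ann = ann, universe = universe, mode = config$mode)
    meta <- build_meta_network(subnets)
    meta_pm <- power_method(meta, tol = config$power_tol,
                            max_iter = config$power_max_iter)
    ranking <- rank_seeds(subnets, scores, meta_pm, lit,
                          min_pubs = config$min_pubs)
    note("subnetworks\tseeds=", length(seeds),
         "\tmeta_arcs=", igraph::ecount(meta))
  } else {
    ranking <- rank_seeds(list(), numeric(0),
                          list(values = numeric(0)), lit)
    note("subnetworks\tseeds=0\tmeta_arcs=0")
  }
  write_ranking(ranking, art("ranking.csv"))

  for (p in unlist(paths)) {
    note("artifact\t", basename(p), "\tmd5=", unname(tools::md5sum(p)))
  }
  writeLines(log, file.path(config$out_dir, "run_log.txt"))
  paths$run_log <- file.path(config$out_dir, "run_log.txt")
  invisible(list(ranking = ranking, paths = paths, log = log))
}
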