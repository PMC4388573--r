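# Deterministic synthetic-data generator. Produces all five input files of
# the pipeline with planted, recoverable signal:
#
# * a publication corpus in which the designated disease genes draw their
#   publications from the disease articles at an elevated rate, so their
#   hypergeometric disease scores clear the selection threshold;
# * miRNA "modules": each planted miRNA targets a block of disease genes
#   whose expression is generated as effect_rho * miRNA + Gaussian noise,
#   while decoy predicted pairs are expression-independent;
# * a PPI graph containing a ring among each module's co-targets (so the
#   analysis graph has triangles), a random background at ppi_density,
#   three planted depth-1 interactors of base targets (predicted,
#   anticorrelated, annotated with the planted term: admissible new
#   targets) and one depth-2 twin with the same endowments that must never
#   be considered;
# * a GO annotation in which one planted term covers a fixed fraction of
#   the disease genes (whole modules at a time) against a sparse random
#   background.
#
# A single integer seed drives every draw; the same spec and seed give
# byte-identical files.

.N_ARTICLES <- 6000L
.N_DISEASE_ARTICLES <- 300L
.J_PLANTED <- 40L
.J_BACKGROUND <- 15L
.N_ADD1 <- 3L

#' Specification of a synthetic fixture set
#'
#' Defaults encode the validation conditions used throughout the package:
#' 100 samples, planted anticorrelation of -0.8, 50 planted and 50 decoy
#' predicted pairs. A power check at construction refuses specs whose
#' planted effect would be undetectable (two-sided test at alpha = 0.05,
#' required power > 0.9 via the Fisher z approximation).
#'
#' @param rng_seed integer seed driving every draw.
#' @param n_genes total genes (must leave room for disease genes plus the
#'   four reserved planted-interactor genes).
#' @param n_mirnas number of miRNAs; planted pairs are dealt to miRNAs in
#'   round-robin blocks ("modules").
#' @param n_samples paired expression samples (>= 10).
#' @param n_disease_genes genes given literature disease signal.
#' @param pub_enrichment fold-change over the 5% base disease-article rate
#'   for planted genes' publications.
#' @param n_planted_pairs anticorrelated predicted pairs (each with its own
#'   target gene, `<= n_disease_genes`).
#' @param effect_rho population correlation of planted pairs, in (-1, 0).
#' @param n_decoy_pairs predicted pairs with independent expression.
#' @param ppi_density background PPI edge probability, in (0, 1).
#' @param n_go_terms number of GO terms (term 1 is the planted one).
#' @param planted_term_coverage fraction of disease genes carrying the
#'   planted term, assigned module-wise so modules are either enriched or
#'   decoy.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(rng_seed = 1L, n_genes = 300L, n_mirnas = 10L,
                         n_samples = 100L, n_disease_genes = 60L,
                         pub_enrichment = 10, n_planted_pairs = 50L,
                         effect_rho = -0.8, n_decoy_pairs = 50L,
                         ppi_density = 0.02, n_go_terms = 40L,
                         planted_term_coverage = 0.8) {
  if (n_samples < 10L) stop("n_samples must be at least 10")
  if (effect_rho >= 0 || effect_rho <= -1) stop("effect_rho must be in (-1, 0)")
  if (ppi_density <= 0 || ppi_density >= 1) stop("ppi_density must be in (0, 1)")
  if (planted_term_coverage <= 0 || planted_term_coverage > 1) {
    stop("planted_term_coverage must be in (0, 1]")
  }
  if (n_planted_pairs > n_disease_genes) {
    stop("each planted pair needs its own disease gene: n_planted_pairs <= n_disease_genes")
  }
  if (n_disease_genes < 3L) stop("need at least 3 disease genes")
  if (n_genes < n_disease_genes + .N_ADD1 + 1L + 10L) {
    stop("n_genes too small for the requested disease genes plus reserved planted interactors")
  }
  power <- pnorm(sqrt(n_samples - 3) * atanh(abs(effect_rho)) -
                   qnorm(1 - 0.05 / 2))
  if (power <= 0.9) {
    stop(sprintf(
      "planted anticorrelation is underpowered (power %.3f at n = %d); increase n_samples or |effect_rho|",
      power, n_samples))
  }
  structure(list(rng_seed = as.integer(rng_seed), n_genes = as.integer(n_genes),
                 n_mirnas = as.integer(n_mirnas),
                 n_samples = as.integer(n_samples),
                 n_disease_genes = as.integer(n_disease_genes),
                 pub_enrichment = pub_enrichment,
                 n_planted_pairs = as.integer(n_planted_pairs),
                 effect_rho = effect_rho,
                 n_decoy_pairs = as.integer(n_decoy_pairs),
                 ppi_density = ppi_density,
                 n_go_terms = as.integer(n_go_terms),
                 planted_term_coverage = planted_term_coverage),
            class = "fixture_spec")
}

.write_tsv <- function(df, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

.write_matrix <- function(mat, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("feature", colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1L, function(v) paste(format(v, digits = 15, trim = TRUE,
                                                  scientific = FALSE),
                                           collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Generate the synthetic input files
#'
#' Writes `gene2pubmed.tsv`, `disease_pmids.txt`, `predictions.tsv`,
#' `mrna.tsv`, `mirna.tsv`, `ppi.tsv`, `go_annotations.tsv` and a
#' ground-truth `manifest.json` into `out_dir`. All randomness flows from
#' `spec$rng_seed`; the global RNG state is restored on exit.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly: planted truths plus the file paths.
#' @export
generate_fixtures <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  withr::local_seed(spec$rng_seed)

  genes <- sprintf("GENE%04d", seq_len(spec$n_genes))
  mirnas <- sprintf("hsa-miR-%03d", seq_len(spec$n_mirnas))
  samples <- sprintf("S%03d", seq_len(spec$n_samples))
  disease_genes <- genes[seq_len(spec$n_disease_genes)]
  planted_targets <- genes[seq_len(spec$n_planted_pairs)]
  add1 <- genes[spec$n_genes - seq_len(.N_ADD1)]
  add2 <- genes[spec$n_genes]
  anchors <- if (spec$n_planted_pairs >= .N_ADD1) planted_targets[seq_len(.N_ADD1)]
             else disease_genes[seq_len(.N_ADD1)]

  ## ---- literature -------------------------------------------------------
  pmids <- sprintf("PM%06d", seq_len(.N_ARTICLES))
  disease_pmids <- pmids[seq_len(.N_DISEASE_ARTICLES)]
  other_pmids <- pmids[-seq_len(.N_DISEASE_ARTICLES)]
  base_rate <- .N_DISEASE_ARTICLES / .N_ARTICLES
  p_dis <- min(0.95, base_rate * spec$pub_enrichment)
  gene_pub_rows <- vector("list", spec$n_genes)
  for (i in seq_len(spec$n_genes)) {
    g <- genes[i]
    pubs <- if (g %in% disease_genes) {
      kk <- rbinom(1L, .J_PLANTED, p_dis)
      c(sample(disease_pmids, min(kk, length(disease_pmids))),
        sample(other_pmids, .J_PLANTED - min(kk, length(disease_pmids))))
    } else if (g %in% c(add1, add2)) {
      sample(other_pmids, .J_BACKGROUND)  # never published with the disease
    } else {
      sample(pmids, .J_BACKGROUND)
    }
    gene_pub_rows[[i]] <- data.frame(tax = "9606", gene = g,
                                     pub = unique(pubs),
                                     stringsAsFactors = FALSE)
  }
  g2p <- do.call(rbind, gene_pub_rows)
  # rows from another taxon exercise the reader's filter
  alt <- data.frame(tax = "10090",
                    gene = sample(genes, 50L, replace = TRUE),
                    pub = sample(pmids, 50L, replace = TRUE),
                    stringsAsFactors = FALSE)
  g2p <- rbind(g2p, alt)

  ## ---- predictions ------------------------------------------------------
  module_of <- function(i) ((i - 1L) %% spec$n_mirnas) + 1L
  planted_pairs <- if (spec$n_planted_pairs) {
    data.frame(mirna = mirnas[module_of(seq_len(spec$n_planted_pairs))],
               gene = planted_targets, stringsAsFactors = FALSE)
  } else {
    data.frame(mirna = character(0), gene = character(0))
  }
  all_combos <- expand.grid(mirna = mirnas, gene = disease_genes,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(df) paste(df$mirna, df$gene)
  pool <- all_combos[!key(all_combos) %in% key(planted_pairs), , drop = FALSE]
  decoy_pairs <- pool[sample(nrow(pool), min(spec$n_decoy_pairs, nrow(pool))), ,
                      drop = FALSE]
  bg_genes <- setdiff(genes, c(disease_genes, add1, add2))
  bg_pairs <- data.frame(mirna = sample(mirnas, 100L, replace = TRUE),
                         gene = sample(bg_genes, 100L, replace = TRUE),
                         stringsAsFactors = FALSE)
  add_mirna <- mirnas[module_of(match(anchors, genes))]
  add_pairs <- data.frame(mirna = c(add_mirna, mirnas[1L]),
                          gene = c(add1, add2), stringsAsFactors = FALSE)
  preds <- unique(rbind(planted_pairs, decoy_pairs, bg_pairs, add_pairs))

  ## ---- expression -------------------------------------------------------
  rho <- spec$effect_rho
  noise_sd <- sqrt(1 - rho^2)
  Xm <- matrix(rnorm(spec$n_mirnas * spec$n_samples), nrow = spec$n_mirnas,
               dimnames = list(mirnas, samples))
  Xg <- matrix(rnorm(spec$n_genes * spec$n_samples), nrow = spec$n_genes,
               dimnames = list(genes, samples))
  for (i in seq_len(spec$n_planted_pairs)) {
    Xg[planted_targets[i], ] <- rho * Xm[mirnas[module_of(i)], ] +
      noise_sd * rnorm(spec$n_samples)
  }
  for (i in seq_len(.N_ADD1)) {
    Xg[add1[i], ] <- rho * Xm[add_mirna[i], ] + noise_sd * rnorm(spec$n_samples)
  }
  Xg[add2, ] <- rho * Xm[1L, ] + noise_sd * rnorm(spec$n_samples)

  ## ---- PPI --------------------------------------------------------------
  modules <- split(planted_targets, module_of(seq_len(spec$n_planted_pairs)))
  ring_edges <- do.call(rbind, lapply(modules, function(ts) {
    if (length(ts) < 2L) return(NULL)
    nxt <- c(ts[-1L], ts[1L])
    e <- data.frame(a = ts, b = nxt, stringsAsFactors = FALSE)
    if (length(ts) == 2L) e <- e[1L, , drop = FALSE]
    e
  }))
  eligible <- setdiff(genes, add2)  # random edges must not touch the depth-2 twin
  ne <- length(eligible)
  pair_idx <- which(upper.tri(matrix(TRUE, ne, ne)), arr.ind = TRUE)
  n_rand <- round(spec$ppi_density * nrow(pair_idx))
  sel <- sample(nrow(pair_idx), n_rand)
  rand_edges <- data.frame(a = eligible[pair_idx[sel, 1L]],
                           b = eligible[pair_idx[sel, 2L]],
                           stringsAsFactors = FALSE)
  planted_edges <- data.frame(a = c(anchors, add1[1L]),
                              b = c(add1, add2), stringsAsFactors = FALSE)
  ppi <- rbind(ring_edges, rand_edges, planted_edges)
  ppi <- unique(data.frame(a = pmin(ppi$a, ppi$b), b = pmax(ppi$a, ppi$b),
                           stringsAsFactors = FALSE))
  ppi <- ppi[ppi$a != ppi$b, , drop = FALSE]

  ## ---- GO ---------------------------------------------------------------
  terms <- sprintf("GO:%07d", seq_len(spec$n_go_terms))
  planted_term <- terms[1L]
  n_enriched_modules <- floor(spec$planted_term_coverage * spec$n_mirnas)
  enriched_targets <- unlist(modules[seq_len(min(n_enriched_modules,
                                                 length(modules)))],
                             use.names = FALSE)
  n_term_genes <- round(spec$planted_term_coverage * spec$n_disease_genes)
  extra <- setdiff(disease_genes, planted_targets)
  term_genes <- c(enriched_targets,
                  extra[seq_len(max(0L, min(length(extra),
                                            n_term_genes - length(enriched_targets))))])
  bg_term_carriers <- sample(bg_genes, round(0.05 * length(bg_genes)))
  planted_ann <- data.frame(gene = c(term_genes, add1, add2, bg_term_carriers),
                            term = planted_term, stringsAsFactors = FALSE)
  random_ann <- data.frame(gene = rep(genes, each = 3L),
                           term = sample(terms[-1L], 3L * spec$n_genes,
                                         replace = TRUE),
                           stringsAsFactors = FALSE)
  go <- unique(rbind(planted_ann, random_ann))

  ## ---- write ------------------------------------------------------------
  paths <- list(
    gene2pubmed = file.path(out_dir, "gene2pubmed.tsv"),
    disease_pmids = file.path(out_dir, "disease_pmids.txt"),
    predictions = file.path(out_dir, "predictions.tsv"),
    mrna = file.path(out_dir, "mrna.tsv"),
    mirna = file.path(out_dir, "mirna.tsv"),
    ppi = file.path(out_dir, "ppi.tsv"),
    go = file.path(out_dir, "go_annotations.tsv"),
    manifest = file.path(out_dir, "manifest.json"))
  .write_tsv(g2p, paths$gene2pubmed)
  writeLines(disease_pmids, paths$disease_pmids)
  .write_tsv(preds, paths$predictions)
  .write_matrix(Xg, paths$mrna)
  .write_matrix(Xm, paths$mirna)
  .write_tsv(ppi, paths$ppi)
  .write_tsv(go, paths$go)

  manifest <- list(
    spec = unclass(spec),
    files = paths,
    planted = list(
      disease_genes = disease_genes,
      planted_pairs = planted_pairs,
      decoy_pairs = decoy_pairs[order(decoy_pairs$mirna, decoy_pairs$gene), ],
      planted_term = planted_term,
      term_genes = sort(unique(term_genes)),
      enriched_targets = sort(enriched_targets),
      decoy_targets = sort(setdiff(planted_targets, enriched_targets)),
      depth1_interactors = data.frame(gene = add1, mirna = add_mirna,
                                      anchor = anchors,
                                      stringsAsFactors = FALSE),
      depth2_gene = add2))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, dataframe = "columns")
  invisible(manifest)
}
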