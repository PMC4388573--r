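# Helpers building a minimal network-plus-PPI scenario by hand.
micro_net <- function() {
  withr::local_seed(21, .local_envir = parent.frame())
  n <- 60
  m1 <- rnorm(n); m2 <- rnorm(n)
  mirna <- rbind("hsa-miR-1" = m1, "hsa-miR-2" = m2)
  mrna <- rbind(T1 = -0.85 * m1 + 0.4 * rnorm(n),
                T2 = -0.85 * m2 + 0.4 * rnorm(n),
                ADD1 = -0.85 * m2 + 0.4 * rnorm(n),  # admissible interactor
                FARGENE = -0.85 * m1 + 0.4 * rnorm(n),  # same signal, depth 2
                NOPRED = -0.85 * m1 + 0.4 * rnorm(n),
                POSCOR = 0.85 * m1 + 0.4 * rnorm(n))
  colnames(mirna) <- colnames(mrna) <- sprintf("S%02d", 1:n)
  preds <- data.frame(mirna = c("hsa-miR-1", "hsa-miR-2", "hsa-miR-2",
                                "hsa-miR-1", "hsa-miR-1"),
                      gene = c("T1", "T2", "ADD1", "FARGENE", "POSCOR"))
  net <- build_regulatory_network(c("T1", "T2"), preds, mrna, mirna)
  ann <- tiny_annotation(data.frame(
    gene = c("T1", "T2", "ADD1", "FARGENE", "NOPRED", "POSCOR"),
    term = "GO:BF"))
  bf <- data.frame(term = "GO:BF", k = 2L, j = 6L, n = 2L, m = 6L,
                   p_raw = 0.01, p_adj = 0.01)
  list(net = net, preds = preds, mrna = mrna, mirna = mirna,
       ann = ann, bf = bf)
}

test_that("PPI closure records breadth-first depths", {
  net <- micro_net()$net
  none <- extend_network(net, data.frame(a = "X", b = "Y"))
  expect_identical(length(none$imported), 0L)

  chain <- data.frame(a = c("T1", "A", "B"), b = c("A", "B", "C"))
  ext <- extend_network(net, chain)
  expect_identical(ext$imported, c(A = 1L, B = 2L, C = 3L))
  capped <- extend_network(net, chain, max_depth = 1)
  expect_identical(capped$imported, c(A = 1L))
})

test_that("unlimited closure equals the connected-component union", {
  withr::local_seed(33)
  net <- micro_net()$net
  nodes <- c("T1", "T2", paste0("N", 1:48))
  idx <- t(combn(length(nodes), 2))
  pick <- idx[sample(nrow(idx), 80), ]
  ppi <- data.frame(a = nodes[pick[, 1]], b = nodes[pick[, 2]])
  ppi <- ppi[ppi$a != ppi$b, ]
  ext <- extend_network(net, ppi)
  # oracle: union of the PPI connected components containing a base target
  g <- igraph::graph_from_data_frame(ppi, directed = FALSE)
  comp <- igraph::components(g)$membership
  targets_in <- intersect(net$targets, names(comp))
  reach <- names(comp)[comp %in% comp[targets_in]]
  expect_setequal(names(ext$imported), setdiff(reach, net$targets))
  expect_true(all(ext$imported >= 1))
})

test_that("target admission enforces both conditions at depth 1 only", {
  mc <- micro_net()
  ppi <- data.frame(a = c("T2", "ADD1", "T1", "T1"),
                    b = c("ADD1", "FARGENE", "NOPRED", "POSCOR"))
  ext <- extend_network(mc$net, ppi)
  expect_identical(ext$imported[["ADD1"]], 1L)
  expect_identical(ext$imported[["FARGENE"]], 2L)
  net2 <- add_targets(ext, mc$bf, mc$ann, mc$preds, mc$mrna, mc$mirna)
  added <- net2$edges[net2$edges$origin == "added", ]
  # ADD1: background term + predicted for a network miRNA + anticorrelated
  expect_identical(unique(added$gene), "ADD1")
  expect_identical(added$mirna, "hsa-miR-2")
  # FARGENE has identical signal and prediction but sits at depth 2
  expect_false("FARGENE" %in% net2$targets)
  # NOPRED (depth 1, background term, no prediction) fails condition (a)
  expect_false("NOPRED" %in% net2$targets)
  # POSCOR (depth 1, predicted) is positively correlated: fails (b)
  expect_false("POSCOR" %in% net2$targets)
  # base network is a subgraph of the extension
  expect_true(all(paste(mc$net$edges$mirna, mc$net$edges$gene) %in%
                    paste(net2$edges$mirna, net2$edges$gene)))
  # audit: every added edge is negative and significant at alpha_add
  for (i in seq_len(nrow(added))) {
    r <- pearson_cor(mc$mrna[added$gene[i], ], mc$mirna[added$mirna[i], ])
    expect_lt(r$rho, 0)
    expect_lte(r$p_value, 0.01)
  }
  # the procedure runs exactly once
  ext2 <- extend_network(net2, ppi)
  expect_error(add_targets(ext2, mc$bf, mc$ann, mc$preds, mc$mrna, mc$mirna),
               "exactly once")
})

test_that("an admitted gene is connected to every miRNA of its qualifying set", {
  withr::local_seed(44)
  n <- 100
  m1 <- rnorm(n); m2 <- rnorm(n); m3 <- rnorm(n)
  mirna <- rbind("hsa-miR-1" = m1, "hsa-miR-2" = m2, "hsa-miR-3" = m3)
  base <- -(m1 + m2) / sqrt(2)
  mrna <- rbind(T1 = -0.9 * m1 + 0.3 * rnorm(n),
                T2 = -0.9 * m2 + 0.3 * rnorm(n),
                T3 = -0.9 * m3 + 0.3 * rnorm(n),
                CAND = base + 0.2 * rnorm(n))
  colnames(mirna) <- colnames(mrna) <- sprintf("S%02d", 1:n)
  preds <- data.frame(mirna = c("hsa-miR-1", "hsa-miR-2", "hsa-miR-3",
                                "hsa-miR-1", "hsa-miR-2", "hsa-miR-3"),
                      gene = c("T1", "T2", "T3", "CAND", "CAND", "CAND"))
  net <- build_regulatory_network(c("T1", "T2", "T3"), preds, mrna, mirna)
  ann <- tiny_annotation(data.frame(gene = c("T1", "T2", "T3", "CAND"),
                                    term = "GO:BF"))
  bf <- data.frame(term = "GO:BF", k = 3L, j = 4L, n = 3L, m = 4L,
                   p_raw = 0.01, p_adj = 0.01)
  ext <- extend_network(net, data.frame(a = "T1", b = "CAND"))
  net2 <- add_targets(ext, bf, ann, preds, mrna, mirna)
  added <- net2$edges[net2$edges$origin == "added", ]
  # CAND anticorrelates with miR-1 and miR-2 (its construction) but not miR-3:
  # the qualifying set M has two members and both edges are created
  expect_setequal(added$mirna, c("hsa-miR-1", "hsa-miR-2"))
})
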