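test_that("neighbour sets use the undirected view and match a brute-force scan", {
  g <- toy_triangle_graph()
  expect_identical(node_neighbours(g, "1"), c("2", "4", "5"))
  expect_setequal(setdiff(node_neighbours(g, "2"), "1"),
                  c("3", "4", "9", "11"))
  iso <- igraph::make_empty_graph(directed = TRUE) + igraph::vertices("solo")
  expect_identical(node_neighbours(iso, "solo"), character(0))
  expect_error(node_neighbours(g, "zzz"), "not in the graph")

  withr::local_seed(7)
  for (i in 1:20) {
    rg <- random_digraph(sample(4:12, 1), 0.3)
    A <- igraph::as_adjacency_matrix(rg, sparse = FALSE)
    v <- sample(rownames(A), 1)
    oracle <- sort(setdiff(rownames(A)[A[v, ] > 0 | A[, v] > 0], v))
    expect_identical(node_neighbours(rg, v), oracle)
  }
})

test_that("the triangle walkthrough on the toy graph keeps {1,2,4} and drops node 5", {
  g <- toy_triangle_graph()
  s <- extract_subnetwork(g, "1")
  expect_identical(s$intersections[["2"]], "4")
  expect_identical(s$intersections[["4"]], "2")
  expect_identical(s$intersections[["5"]], character(0))
  expect_identical(s$nodes, c("1", "2", "4"))
  expect_false("5" %in% s$nodes)
  expect_error(extract_subnetwork(g, "99"), "not in the graph")
})

test_that("a star hub and any node of a triangle-free graph give singletons", {
  star <- igraph::make_star(7, mode = "undirected", center = 1)
  star <- igraph::set_vertex_attr(star, "name", value = paste0("n", 1:7))
  expect_identical(extract_subnetwork(star, "n1")$nodes, "n1")
  ring <- igraph::make_ring(6)  # 6-cycle: triangle-free
  ring <- igraph::set_vertex_attr(ring, "name", value = paste0("r", 1:6))
  for (v in paste0("r", 1:6)) {
    expect_identical(extract_subnetwork(ring, v)$nodes, v)
  }
})

test_that("subnetwork node sets equal the O(n^3) triangle oracle on random digraphs", {
  withr::local_seed(101)
  for (i in 1:40) {
    n <- sample(5:15, 1)
    g <- random_digraph(n, runif(1, 0.1, 0.5))
    seed <- sample(igraph::V(g)$name, 1)
    s <- extract_subnetwork(g, seed)
    expect_identical(sort(s$nodes), triangle_subnet_oracle(g, seed))
    # induced arcs: every arc of the subgraph exists in the parent
    el <- igraph::as_edgelist(s$graph)
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    if (nrow(el)) expect_true(all(A[el] > 0))
  }
})

test_that("path and cycle betweenness behave as expected", {
  cyc <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("b", "c"),
                                           c("c", "a")), directed = TRUE)
  cent <- centrality_indices(cyc)
  expect_true(all(cent$betweenness == cent$betweenness[1]))  # symmetry
  expect_equal(cent$eccentricity, rep(2, 3))
  # a directed path is defective (dominant eigenvalue with a Jordan block),
  # so the power iterate converges only polynomially: relax its tolerance
  path <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("b", "c")),
                                      directed = TRUE)
  pc <- centrality_indices(path, tol = 1e-8)
  expect_identical(pc$node[which.max(pc$betweenness)], "b")
  # harmonic closeness with unreachable pairs contributing zero
  expect_equal(pc$closeness[pc$node == "a"], 1 + 1 / 2)
  expect_equal(pc$closeness[pc$node == "c"], 0)   # sink reaches nothing
  expect_equal(pc$eccentricity[pc$node == "c"], 0)
})

test_that("centrality vectors match brute-force all-pairs oracles on random digraphs", {
  withr::local_seed(55)
  for (i in 1:12) {
    g <- random_digraph(10, 0.25)
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    cent <- centrality_indices(g)
    d <- floyd_warshall(A)
    inv <- 1 / d; inv[!is.finite(d)] <- 0; diag(inv) <- 0
    expect_equal(cent$closeness, unname(rowSums(inv)), tolerance = 1e-12)
    ecc <- apply(d, 1, function(r) {
      r <- r[is.finite(r) & r > 0]
      if (!length(r)) 0 else max(r)
    })
    expect_equal(cent$eccentricity, unname(ecc))
    expect_equal(cent$betweenness, unname(betweenness_oracle(A)),
                 tolerance = 1e-9)
  }
})

test_that("power iteration reproduces the dominant eigenvector", {
  # complete graph: uniform by symmetry
  k4 <- igraph::make_full_graph(4)
  k4 <- igraph::set_vertex_attr(k4, "name", value = paste0("k", 1:4))
  pm <- power_method(k4)
  expect_equal(unname(pm$values), rep(0.25, 4), tolerance = 1e-9)
  expect_equal(pm$lambda, 3, tolerance = 1e-6)
  expect_equal(sum(pm$values), 1)

  withr::local_seed(77)
  for (i in 1:15) {
    g <- random_connected_symmetric_graph(sample(3:8, 1))
    pm <- power_method(g)
    A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    ei <- eigen(A + diag(nrow(A)), symmetric = TRUE)
    v <- abs(ei$vectors[, which.max(ei$values)])
    v <- v / sum(v)
    expect_equal(unname(pm$values), v, tolerance = 1e-6)
    expect_equal(pm$lambda, max(ei$values) - 1, tolerance = 1e-6)
  }
  expect_error(power_method(igraph::make_empty_graph()), "empty")
  # a bipartite (periodic) structure still converges thanks to the shift
  bip <- igraph::make_full_bipartite_graph(3, 2)
  bip <- igraph::set_vertex_attr(bip, "name", value = paste0("b", 1:5))
  expect_silent(power_method(bip))
})

test_that("centralities are permutation-equivariant", {
  withr::local_seed(91)
  g <- random_digraph(9, 0.3)
  nm <- igraph::V(g)$name
  perm <- sample(nm)
  g2 <- igraph::permute(g, match(perm, nm))  # relabel vertices
  c1 <- centrality_indices(g)
  c2 <- centrality_indices(g2)
  for (col in c("betweenness", "closeness", "eccentricity", "power")) {
    expect_equal(c2[[col]][match(c1$node, c2$node)], c1[[col]],
                 tolerance = 1e-9)
  }
})

test_that("meta-network arcs encode seed membership without self-loops", {
  g <- toy_triangle_graph()
  subs <- lapply(c("1", "2", "4", "7"), function(s) extract_subnetwork(g, s))
  meta <- build_meta_network(subs)
  el <- igraph::as_edgelist(meta)
  # oracle: membership matrix over the stored node sets
  seeds <- vapply(subs, `[[`, "", "seed")
  expected <- do.call(rbind, lapply(seq_along(subs), function(i) {
    to <- seeds[seeds %in% subs[[i]]$nodes & seeds != seeds[i]]
    if (length(to)) cbind(seeds[i], to)
  }))
  expect_identical(sort(paste(el[, 1], el[, 2])),
                   sort(paste(expected[, 1], expected[, 2])))
  expect_false(any(el[, 1] == el[, 2]))
  # two disjoint subnetworks: no arcs
  iso <- lapply(c("7", "9"), function(s) extract_subnetwork(g, s))
  expect_identical(igraph::ecount(build_meta_network(iso)), 0)
})
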