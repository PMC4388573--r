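# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths (and where possible the library calls) of the
# implementation they check.

# Exhaustive hypergeometric tail: enumerate every size-n subset of m items
# of which the first j are marked, and count draws with at least k marks.
enum_hyper_tail <- function(m, n, j, k) {
  cmb <- utils::combn(m, n)
  marked <- colSums(matrix(cmb <= j, nrow = n))
  mean(marked >= k)
}

# Direct evaluation of the tail as the printed sum of binomial products.
sum_hyper_tail <- function(m, n, j, k) {
  hi <- min(n, j)
  if (k > hi) return(0)
  i <- k:hi
  sum(choose(m - j, n - i) * choose(j, i)) / choose(m, n)
}

# Hand-executed BH step-up: sort ascending, q_i = min_{l >= i} p_l * T / l,
# return in original order.
bh_stepup_oracle <- function(p) {
  T <- length(p)
  o <- order(p)
  q <- p[o] * T / seq_len(T)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# Triangle subnetwork by O(n^3) scan over the undirected adjacency view.
triangle_subnet_oracle <- function(g, seed) {
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  U <- (A + t(A)) > 0
  diag(U) <- FALSE
  ids <- rownames(U)
  s <- match(seed, ids)
  part <- character(0)
  n <- length(ids)
  for (u in seq_len(n)) {
    for (w in seq_len(n)) {
      if (u != w && u != s && w != s && U[s, u] && U[s, w] && U[u, w]) {
        part <- c(part, ids[u], ids[w])
      }
    }
  }
  sort(unique(c(seed, part)))
}

# All-pairs shortest-path matrix by Floyd-Warshall on the directed 0/1
# adjacency matrix.
floyd_warshall <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  d[A > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  dimnames(d) <- dimnames(A)
  d
}

# Directed betweenness via BFS shortest-path counting and a direct triple
# sum over (s, v, t).
betweenness_oracle <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    sig[s, s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(A[v, ] > 0)) {
          if (!is.finite(d[s, w])) {
            d[s, w] <- d[s, v] + 1
            nxt <- c(nxt, w)
            sig[s, w] <- sig[s, w] + sig[s, v]
          } else if (d[s, w] == d[s, v] + 1) {
            sig[s, w] <- sig[s, w] + sig[s, v]
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s != v && t != v && s != t &&
            is.finite(d[s, t]) && d[s, v] + d[v, t] == d[s, t]) {
          btw[v] <- btw[v] + sig[s, v] * sig[v, t] / sig[s, t]
        }
      }
    }
  }
  stats::setNames(btw, rownames(A))
}

# Random directed graph on n named nodes with arc probability p.
random_digraph <- function(n, p) {
  A <- matrix(stats::rbinom(n * n, 1, p), n, n)
  diag(A) <- 0
  dimnames(A) <- list(sprintf("v%02d", seq_len(n)), sprintf("v%02d", seq_len(n)))
  igraph::graph_from_adjacency_matrix(A, mode = "directed")
}

# Random connected symmetric graph (for power-method eigen checks).
random_connected_symmetric_graph <- function(n, p = 0.5) {
  repeat {
    A <- matrix(0, n, n)
    up <- upper.tri(A)
    A[up] <- stats::rbinom(sum(up), 1, p)
    A <- A + t(A)
    dimnames(A) <- list(sprintf("v%d", seq_len(n)), sprintf("v%d", seq_len(n)))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
    if (igraph::is_connected(g, mode = "weak") && sum(A) > 0) return(g)
  }
}
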