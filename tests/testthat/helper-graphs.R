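# Small named graphs used across test files, plus brute-force oracles that
# are independent of the package's implementation paths.

edge_graph <- function(u, v) {
  as_conet_igraph(data.frame(u = u, v = v))
}

triangle_pendant <- function() {
  # triangle {a, b, c} plus pendant d attached to a
  edge_graph(c("a", "a", "b", "a"), c("b", "c", "c", "d"))
}

path_graph <- function(n) {
  lab <- sprintf("n%02d", seq_len(n))
  edge_graph(lab[-n], lab[-1])
}

star_graph <- function(n_leaves) {
  edge_graph(rep("hub", n_leaves), sprintf("leaf%02d", seq_len(n_leaves)))
}

complete_graph <- function(n) {
  cmb <- utils::combn(sprintf("k%02d", seq_len(n)), 2)
  edge_graph(cmb[1, ], cmb[2, ])
}

random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  # keep the giant component so path metrics are defined
  giant_component(g)
}

# Deterministic hierarchical (iterated-clique) graph: K5 replicated 4x per
# level, peripheral nodes of the replicas wired to the original hub.
hierarchical_graph <- function(levels = 2) {
  edges <- t(utils::combn(1:5, 2))
  center <- 1L
  periph <- 2:5
  n <- 5L
  for (l in seq_len(levels)) {
    base_e <- edges
    base_n <- n
    new_periph <- integer(0)
    for (r in 1:4) {
      off <- r * base_n
      edges <- rbind(edges, base_e + off)
      new_periph <- c(new_periph, periph + off)
    }
    edges <- rbind(edges, cbind(center, new_periph))
    periph <- new_periph
    n <- 5L * base_n
  }
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

# ---- brute-force oracles ------------------------------------------------

# All-pairs shortest-path matrix by Floyd-Warshall on the adjacency matrix.
oracle_distances <- function(g) {
  n <- igraph::vcount(g)
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  d <- ifelse(a > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

oracle_path_length <- function(g) {
  d <- oracle_distances(g)
  vals <- d[upper.tri(d)]
  mean(vals[is.finite(vals)])
}

oracle_diameter <- function(g) {
  d <- oracle_distances(g)
  max(d[is.finite(d)])
}

oracle_assortativity <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  x <- c(deg[el[, 1]], deg[el[, 2]])
  y <- c(deg[el[, 2]], deg[el[, 1]])
  stats::cor(x, y)
}

oracle_clustering <- function(g) {
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  n <- nrow(a)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    ci[i] <- sum(a[nb, nb]) / 2 / (k * (k - 1) / 2)
  }
  mean(ci)
}

# Betweenness by explicit shortest-path enumeration: sigma[s, t] counts
# shortest paths, then pair dependencies are summed over interior nodes.
oracle_betweenness <- function(g) {
  n <- igraph::vcount(g)
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  d <- oracle_distances(g)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    for (t in order(d[s, ])) {
      if (t == s || !is.finite(d[s, t])) next
      pred <- which(a[, t] > 0 & d[s, ] == d[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, pred])
    }
  }
  b <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t] && sigma[s, t] > 0) {
          b[v] <- b[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  b
}

# Partial-sum zeta oracle (plain truncated series, no tail acceleration).
oracle_zeta <- function(s, q = 1, terms = 2e6) {
  sum((q + 0:(terms - 1))^(-s))
}
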