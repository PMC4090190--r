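#' Betweenness centrality
#'
#' Exact Brandes betweenness (each unordered pair counted once, edge
#' weights ignored) when `sample_sources` is `NULL`; otherwise an unbiased
#' source-sampled estimate: dependencies are accumulated from a uniform
#' sample of sources and scaled by `n / n_sources`.
#'
#' @param graph Connected graph-like object.
#' @param sample_sources Optional number of BFS sources for estimation.
#' @param seed Optional seed.
#' @return A tibble (`node`, `betweenness`).
#' @export
node_betweenness <- function(graph, sample_sources = NULL, seed = NULL) {
  g <- as_conet_igraph(graph)
  ids <- vertex_ids(g)
  if (is.null(sample_sources)) {
    b <- igraph::betweenness(g, directed = FALSE, weights = NA)
    return(tibble(node = ids, betweenness = as.numeric(b)))
  }
  n <- igraph::vcount(g)
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, as.integer)
  with_seed(seed, {
    src <- sample.int(n, min(sample_sources, n))
    score <- numeric(n)
    for (s in src) {
      score <- score + brandes_dependency(adj, n, s)
    }
    # each unordered pair appears from both endpoints in the full sum -> /2
    tibble(node = ids, betweenness = score * n / (2 * length(src)))
  })
}

# Single-source Brandes accumulation (unweighted): returns delta_s(v).
brandes_dependency <- function(adj, n, s) {
  dist <- rep(-1L, n)
  sigma <- numeric(n)
  preds <- vector("list", n)
  order_visited <- integer(n)
  dist[s] <- 0L
  sigma[s] <- 1
  queue <- integer(n)
  queue[1] <- s
  qhead <- 1L
  qtail <- 1L
  nv <- 0L
  while (qhead <= qtail) {
    v <- queue[qhead]
    qhead <- qhead + 1L
    nv <- nv + 1L
    order_visited[nv] <- v
    for (w in adj[[v]]) {
      if (dist[w] < 0L) {
        dist[w] <- dist[v] + 1L
        qtail <- qtail + 1L
        queue[qtail] <- w
      }
      if (dist[w] == dist[v] + 1L) {
        sigma[w] <- sigma[w] + sigma[v]
        preds[[w]] <- c(preds[[w]], v)
      }
    }
  }
  delta <- numeric(n)
  for (i in rev(seq_len(nv))) {
    w <- order_visited[i]
    for (v in preds[[w]]) {
      delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
    }
  }
  delta[s] <- 0
  delta
}

#' Simulate a node-removal attack
#'
#' Removes \eqn{\lceil fraction \cdot n \rceil} nodes in a single event —
#' the highest-degree nodes (`"degree"`), the highest-betweenness nodes
#' (`"betweenness"`; exact up to 2000 nodes, source-sampled above), or a
#' uniform random set (`"random"`) — and reports the surviving giant
#' component as a fraction of the initial node count. Ties in the targeted
#' strategies are broken by ascending node identifier, and centralities
#' are computed once on the intact graph (one-shot attack, no adaptive
#' recomputation).
#'
#' @param graph Connected graph-like object (pass the giant component).
#' @param strategy `"degree"`, `"betweenness"` or `"random"`.
#' @param fraction Fraction of nodes to remove, in (0, 1) (default 0.10).
#' @param seed Seed for the random strategy (and sampled betweenness).
#' @param sample_sources Betweenness source sample size on large graphs
#'   (default 200 when `n > 2000`).
#' @return One-row tibble (`strategy`, `fraction_removed`, `n_initial`,
#'   `n_removed`, `giant_fraction`, `seed`).
#' @export
attack <- function(graph, strategy = c("degree", "betweenness", "random"),
                   fraction = 0.10, seed = NULL, sample_sources = NULL) {
  strategy <- match.arg(strategy)
  g <- as_conet_igraph(graph)
  if (!igraph::is_connected(g)) {
    abort("Attack expects a connected graph; extract the giant component first.")
  }
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  n <- igraph::vcount(g)
  k <- ceiling(fraction * n)
  ids <- vertex_ids(g)
  victims <- switch(strategy,
    degree = {
      deg <- as.numeric(igraph::degree(g))
      order(-deg, ids)[seq_len(k)]
    },
    betweenness = {
      if (is.null(sample_sources) && n > 2000) sample_sources <- 200
      bt <- node_betweenness(g, sample_sources = sample_sources, seed = sub_seed(seed, 7))
      order(-bt$betweenness, ids)[seq_len(k)]
    },
    random = with_seed(seed, sample.int(n, k))
  )
  remainder <- igraph::delete_vertices(g, victims)
  giant_size <- if (igraph::vcount(remainder) == 0) 0L else max(igraph::components(remainder)$csize)
  tibble(
    strategy = strategy,
    fraction_removed = fraction,
    n_initial = n,
    n_removed = k,
    giant_fraction = giant_size / n,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
}
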