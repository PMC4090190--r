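# Edge weights are deliberately ignored by every topology metric: the
# analysis treats the reduced co-occurrence network as an unweighted simple
# graph, so igraph calls pass weights = NA throughout.

#' Local clustering coefficients
#'
#' \eqn{C_i = T_i / \binom{k_i}{2}}, the fraction of realised edges among
#' node `i`'s neighbours. Nodes with degree < 2 have no neighbour pairs
#' and contribute \eqn{C_i = 0} by convention.
#'
#' @param graph Graph-like object.
#' @param nodes Optional vector of node identifiers; defaults to all nodes.
#' @return A tibble (`node`, `degree`, `clustering`).
#' @export
local_clustering <- function(graph, nodes = NULL) {
  g <- as_conet_igraph(graph)
  ids <- vertex_ids(g)
  if (is.null(nodes)) {
    vidx <- seq_len(igraph::vcount(g))
  } else {
    vidx <- match(as.character(nodes), ids)
    if (anyNA(vidx)) {
      abort(paste0("Unknown node(s): ",
                   paste(head(nodes[is.na(vidx)], 5), collapse = ", ")))
    }
  }
  ci <- unname(igraph::transitivity(g, type = "local", vids = vidx, isolates = "NaN"))
  ci[!is.finite(ci)] <- 0
  tibble(node = ids[vidx], degree = as.integer(igraph::degree(g, v = vidx)),
         clustering = ci)
}

#' Average clustering coefficient
#'
#' Exact mean of [local_clustering()] over all nodes when `sample_nodes`
#' is `NULL`. On very large graphs, set `sample_nodes` to average over a
#' uniform node sample; each sampled high-degree node's coefficient is
#' itself estimated from `sample_pairs` uniformly drawn neighbour pairs
#' checked against the edge set, which keeps the cost independent of
#' degree. Degree < 2 nodes contribute 0 either way. By setting
#' `include_low_degree = FALSE` the mean is taken over nodes with degree
#' >= 2 only (conventions differ between libraries; the default includes
#' them).
#'
#' @param graph Graph-like object.
#' @param sample_nodes Optional number of nodes to sample.
#' @param sample_pairs Neighbour pairs sampled per node when estimating
#'   (default 1000); nodes whose total pair count is smaller are computed
#'   exactly.
#' @param seed Optional seed for the sampling.
#' @param include_low_degree Include degree < 2 nodes (as zeros) in the
#'   mean (default TRUE).
#' @return A single number in [0, 1].
#' @export
average_clustering <- function(graph, sample_nodes = NULL, sample_pairs = 1000,
                               seed = NULL, include_low_degree = TRUE) {
  g <- as_conet_igraph(graph)
  n <- igraph::vcount(g)
  if (n < 1) abort("Average clustering requires at least 1 node.")
  if (is.null(sample_nodes)) {
    lc <- local_clustering(g)
    if (!include_low_degree) lc <- filter(lc, .data$degree >= 2)
    if (nrow(lc) == 0) return(0)
    return(mean(lc$clustering))
  }
  with_seed(seed, {
    vs <- sample.int(n, min(sample_nodes, n))
    deg <- igraph::degree(g, v = vs)
    if (!include_low_degree) {
      vs <- vs[deg >= 2]
      deg <- deg[deg >= 2]
      if (length(vs) == 0) return(0)
    }
    # Hash the edge set as numeric keys for vectorised membership checks.
    el <- igraph::as_edgelist(g, names = FALSE)
    base <- as.double(n) + 1
    edge_keys <- pmin(el[, 1], el[, 2]) * base + pmax(el[, 1], el[, 2])
    nbrs <- igraph::adjacent_vertices(g, vs)
    qkeys <- vector("list", length(vs))
    qn <- integer(length(vs))
    for (i in seq_along(vs)) {
      k <- deg[i]
      if (k < 2) next
      nb <- as.integer(nbrs[[i]])
      n_pairs <- k * (k - 1) / 2
      if (n_pairs <= sample_pairs) {
        cmb <- utils::combn(nb, 2)
        a <- cmb[1, ]; b <- cmb[2, ]
      } else {
        a <- nb[sample.int(k, sample_pairs, replace = TRUE)]
        b <- nb[sample.int(k, sample_pairs, replace = TRUE)]
        dup <- a == b
        while (any(dup)) {
          b[dup] <- nb[sample.int(k, sum(dup), replace = TRUE)]
          dup <- a == b
        }
      }
      qkeys[[i]] <- pmin(a, b) * base + pmax(a, b)
      qn[i] <- length(qkeys[[i]])
    }
    hits <- unlist(qkeys, use.names = FALSE) %in% edge_keys
    per_node <- rep(0, length(vs))
    idx <- rep(seq_along(vs), qn)
    if (length(hits) > 0) {
      agg <- tapply(hits, idx, mean)
      per_node[as.integer(names(agg))] <- as.numeric(agg)
    }
    mean(per_node)
  })
}

#' Average shortest-path length
#'
#' Mean of \eqn{d_{uv}} over all connected node pairs. Exact (all-pairs
#' BFS) when `sample_sources` is `NULL`; otherwise the mean over BFS trees
#' rooted at uniformly sampled sources, which is unbiased for the pair
#' average on a connected graph.
#'
#' @param graph Graph-like object; must be connected (pass the
#'   [giant_component()]).
#' @param sample_sources Optional number of BFS sources to sample.
#' @param seed Optional seed.
#' @return A single number >= 1 (for graphs with at least one edge).
#' @export
average_path_length <- function(graph, sample_sources = NULL, seed = NULL) {
  g <- as_conet_igraph(graph)
  if (igraph::vcount(g) < 2) abort("Path length requires at least 2 nodes.")
  if (!igraph::is_connected(g)) {
    abort("Graph is disconnected; extract the giant component first with giant_component().")
  }
  if (is.null(sample_sources)) {
    return(igraph::mean_distance(g, weights = NA, directed = FALSE))
  }
  with_seed(seed, {
    n <- igraph::vcount(g)
    src <- sample.int(n, min(sample_sources, n))
    d <- igraph::distances(g, v = src, weights = NA, algorithm = "unweighted")
    mean(d[d > 0])
  })
}

#' Diameter
#'
#' Exact maximum pairwise distance when the graph is small enough
#' (`n <= exact_threshold`); on larger graphs a double-sweep BFS lower
#' bound is reported and flagged (`exact = FALSE`).
#'
#' @param graph Connected graph-like object.
#' @param exact_threshold Node count up to which the exact diameter is
#'   computed (default 5000).
#' @param seed Seed for the double-sweep start node.
#' @return One-row tibble (`diameter`, `exact`).
#' @export
graph_diameter <- function(graph, exact_threshold = 5000, seed = NULL) {
  g <- as_conet_igraph(graph)
  if (!igraph::is_connected(g)) {
    abort("Graph is disconnected; extract the giant component first with giant_component().")
  }
  n <- igraph::vcount(g)
  if (n <= exact_threshold) {
    return(tibble(diameter = as.numeric(igraph::diameter(g, weights = NA)), exact = TRUE))
  }
  with_seed(seed, {
    s <- sample.int(n, 1)
    d1 <- igraph::distances(g, v = s, weights = NA, algorithm = "unweighted")
    far <- which.max(d1)
    d2 <- igraph::distances(g, v = far, weights = NA, algorithm = "unweighted")
    tibble(diameter = max(d2), exact = FALSE)
  })
}

# Distance histogram over connected ordered pairs from all or sampled sources.
distance_histogram <- function(g, sample_sources = NULL, seed = NULL) {
  n <- igraph::vcount(g)
  if (is.null(sample_sources) && n > 4000) {
    abort("All-pairs distance histogram is infeasible at this size; set `sample_sources`.")
  }
  with_seed(seed, {
    src <- if (is.null(sample_sources)) seq_len(n) else sample.int(n, min(sample_sources, n))
    d <- igraph::distances(g, v = src, weights = NA, algorithm = "unweighted")
    d <- d[is.finite(d) & d > 0]
    tabulate(d, nbins = max(d))
  })
}

#' Effective diameter
#'
#' The smallest distance within which at least a fraction `q` (default
#' 90%) of connected node pairs can reach each other. Returned in two
#' forms: the integer `d90_int = min { d : h(d) >= q }`, where `h(d)` is
#' the cumulative fraction of connected pairs at distance <= d, and the
#' linearly interpolated real-valued
#' `d90 = (d - 1) + (q - h(d - 1)) / (h(d) - h(d - 1))`.
#'
#' @param graph Connected graph-like object.
#' @param q Reachability quantile (default 0.9).
#' @param sample_sources Optional number of BFS sources (required on
#'   graphs too large for the all-pairs histogram).
#' @param seed Optional seed.
#' @return One-row tibble (`d90`, `d90_int`, `q`).
#' @export
effective_diameter <- function(graph, q = 0.9, sample_sources = NULL, seed = NULL) {
  g <- as_conet_igraph(graph)
  if (!igraph::is_connected(g)) {
    abort("Graph is disconnected; extract the giant component first with giant_component().")
  }
  if (q <= 0 || q >= 1) abort("`q` must be in (0, 1).")
  hist <- distance_histogram(g, sample_sources, seed)
  h <- cumsum(hist) / sum(hist)
  d_int <- which(h >= q)[1]
  h_prev <- if (d_int == 1) 0 else h[d_int - 1]
  d90 <- (d_int - 1) + (q - h_prev) / (h[d_int] - h_prev)
  tibble(d90 = d90, d90_int = as.integer(d_int), q = q)
}

#' Erdős–Rényi baseline for small-world comparison
#'
#' Generates `replicates` G(n, m) graphs with the same node and edge
#' counts as the observed network and averages their giant-component path
#' length and clustering. On large graphs (`n > 2000`) both quantities are
#' estimated by sampling (defaults: 200 BFS sources, 2000 clustering
#' nodes) unless sampling parameters are given explicitly.
#'
#' @param n,m Node and edge counts of the observed network.
#' @param replicates Number of random graphs (default 10).
#' @param seed Optional seed; replicate r uses sub-stream r.
#' @param sample_sources,sample_nodes,sample_pairs Sampling controls
#'   passed to [average_path_length()] and [average_clustering()].
#' @return One-row tibble (`l_r`, `c_r`, `replicates`, `seed`) with the
#'   per-replicate values in attribute `"detail"`.
#' @export
er_baseline <- function(n, m, replicates = 10, seed = NULL,
                        sample_sources = NULL, sample_nodes = NULL,
                        sample_pairs = 1000) {
  if (replicates < 1) abort("`replicates` must be >= 1.")
  big <- n > 2000
  if (big && is.null(sample_sources)) sample_sources <- 200
  if (big && is.null(sample_nodes)) sample_nodes <- 2000
  l_vals <- numeric(replicates)
  c_vals <- numeric(replicates)
  for (r in seq_len(replicates)) {
    s <- sub_seed(seed, r)
    g <- gen_er_graph(n, m, seed = s)
    gc <- giant_component(g)
    l_vals[r] <- average_path_length(gc, sample_sources = sample_sources,
                                     seed = sub_seed(s, 1))
    c_vals[r] <- average_clustering(gc, sample_nodes = sample_nodes,
                                    sample_pairs = sample_pairs,
                                    seed = sub_seed(s, 2))
  }
  out <- tibble(l_r = mean(l_vals), c_r = mean(c_vals),
                replicates = replicates,
                seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  attr(out, "detail") <- tibble(replicate = seq_len(replicates), l = l_vals, c = c_vals)
  out
}

#' Small-world index
#'
#' \eqn{\sigma = (C / C_r) / (L / L_r)} against an equal-size random
#' graph; \eqn{\sigma > 1} indicates small-world structure (high
#' clustering at random-graph-like path lengths).
#'
#' @param clustering,clustering_random Observed and baseline average
#'   clustering coefficients.
#' @param path_length,path_length_random Observed and baseline average
#'   path lengths.
#' @return One-row tibble (`sigma`, `is_small_world`).
#' @export
small_world_index <- function(clustering, clustering_random,
                              path_length, path_length_random) {
  vals <- c(clustering, clustering_random, path_length, path_length_random)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All four inputs must be positive and finite.")
  }
  sigma <- (clustering / clustering_random) / (path_length / path_length_random)
  tibble(sigma = sigma, is_small_world = sigma > 1)
}

#' Degree assortativity
#'
#' Pearson correlation of the degrees at the two ends of each edge, with
#' both orientations of every undirected edge contributing. Regular
#' graphs have zero degree variance at the endpoints, so the coefficient
#' is undefined: `NA` is returned with a warning rather than a number.
#'
#' @param graph Graph-like object with >= 2 edges.
#' @return A number in [-1, 1], or `NA` if undefined.
#' @export
degree_assortativity <- function(graph) {
  g <- as_conet_igraph(graph)
  if (igraph::ecount(g) < 2) abort("Assortativity requires at least 2 edges.")
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  x <- deg[c(el[, 1], el[, 2])]
  if (sd(x) == 0) {
    warn("Degree variance at edge endpoints is zero (regular graph); assortativity is undefined.")
    return(NA_real_)
  }
  igraph::assortativity_degree(g, directed = FALSE)
}

#' Permutation test for degree assortativity
#'
#' The observed coefficient is compared with its distribution under random
#' re-pairing of the pooled endpoint-degree multiset (each replicate
#' shuffles all 2|E| endpoint degrees and reassembles them into edges).
#' This is one reasonable significance construction among several; treat
#' the p-value as indicative.
#'
#' @param graph Graph-like object.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional seed.
#' @return One-row tibble (`r`, `p_value`, `n_perm`).
#' @export
assortativity_test <- function(graph, n_perm = 1000, seed = NULL) {
  g <- as_conet_igraph(graph)
  r_obs <- degree_assortativity(g)
  if (is.na(r_obs)) return(tibble(r = NA_real_, p_value = NA_real_, n_perm = n_perm))
  el <- igraph::as_edgelist(g, names = FALSE)
  deg <- igraph::degree(g)
  ends <- c(deg[el[, 1]], deg[el[, 2]])
  m <- nrow(el)
  with_seed(seed, {
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      perm <- sample(ends)
      xp <- perm[seq_len(m)]
      yp <- perm[m + seq_len(m)]
      r_perm <- cor(c(xp, yp), c(yp, xp))
      if (is.finite(r_perm) && abs(r_perm) >= abs(r_obs)) exceed <- exceed + 1L
    }
    tibble(r = r_obs, p_value = (exceed + 1) / (n_perm + 1), n_perm = n_perm)
  })
}

#' Mean clustering coefficient per degree
#'
#' The C(k) curve of Ravasz-style hierarchy analysis: for each degree `k`
#' present in the graph, the mean local clustering coefficient of nodes
#' with that degree. A decaying C(k) signals hierarchical, modular
#' organisation.
#'
#' @param graph Graph-like object.
#' @return A tibble (`k`, `clustering`, `n_nodes`) of class `ck_curve`.
#' @export
clustering_by_degree <- function(graph) {
  g <- as_conet_igraph(graph)
  lc <- local_clustering(g)
  out <- lc %>%
    group_by(k = .data$degree) %>%
    summarise(clustering = mean(.data$clustering), n_nodes = dplyr::n(), .groups = "drop") %>%
    arrange(.data$k)
  class(out) <- c("ck_curve", class(out))
  out
}

#' Fit a power-law decay exponent to a C(k) curve
#'
#' Least-squares slope of `log C(k)` on `log k` over the points with
#' positive mean clustering; the returned exponent is the negated slope,
#' so C(k) ~ k^-exponent.
#'
#' @param curve A [clustering_by_degree()] result.
#' @param kmin_points Minimum number of usable points (default 3); with
#'   fewer the fit is refused with an error (the curve itself is still
#'   available).
#' @return One-row tibble (`exponent`, `intercept`, `n_points`, `r_squared`).
#' @export
fit_ck_decay <- function(curve, kmin_points = 3) {
  pts <- filter(as_tibble(curve), .data$clustering > 0, .data$k >= 1)
  if (nrow(pts) < kmin_points) {
    abort(sprintf("Need at least %d degrees with positive mean clustering to fit a decay; found %d.",
                  kmin_points, nrow(pts)))
  }
  fit <- lm(log(clustering) ~ log(k), data = pts)
  tibble(
    exponent = -unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    n_points = nrow(pts),
    r_squared = summary(fit)$r.squared
  )
}

#' Bundle of macroscopic topology metrics
#'
#' Computes node/edge counts, density, mean degree, average clustering,
#' average path length, diameter and (interpolated) effective diameter on
#' a connected graph. On graphs with more than 2000 nodes the path-based
#' quantities are sampled (see the individual functions) unless sampling
#' controls are given.
#'
#' @param graph Connected graph-like object.
#' @param sample_sources,sample_nodes,sample_pairs Sampling controls.
#' @param q Effective-diameter quantile (default 0.9).
#' @param seed Optional seed.
#' @return A one-row tibble.
#' @export
topology_summary <- function(graph, sample_sources = NULL, sample_nodes = NULL,
                             sample_pairs = 1000, q = 0.9, seed = NULL) {
  g <- as_conet_igraph(graph)
  n <- igraph::vcount(g)
  big <- n > 2000
  if (big && is.null(sample_sources)) sample_sources <- 200
  if (big && is.null(sample_nodes)) sample_nodes <- 2000
  dia <- graph_diameter(g, seed = sub_seed(seed, 3))
  eff <- effective_diameter(g, q = q, sample_sources = sample_sources,
                            seed = sub_seed(seed, 4))
  tibble(
    n = n,
    m = as.double(igraph::ecount(g)),
    density = graph_density(g),
    mean_degree = mean_degree(g),
    clustering = average_clustering(g, sample_nodes = sample_nodes,
                                    sample_pairs = sample_pairs,
                                    seed = sub_seed(seed, 1)),
    path_length = average_path_length(g, sample_sources = sample_sources,
                                      seed = sub_seed(seed, 2)),
    diameter = dia$diameter,
    diameter_exact = dia$exact,
    d90 = eff$d90,
    d90_int = eff$d90_int
  )
}
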