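#' Configuration for the synthetic corpus generator
#'
#' Describes a block-structured vocabulary: `n_blocks` topic blocks of
#' `terms_per_block` terms each, plus `n_hub_terms` near-ubiquitous "check
#' tag"-like terms that attach to documents independently of topic. Each
#' document picks a home block, draws `terms_per_doc` distinct terms from a
#' Zipf(1) popularity law over that block, and each drawn term is replaced
#' with probability `p_noise` by a term from a foreign block. The planted
#' structure gives the chi-square filter true positives (same-block pairs)
#' and true negatives (cross-block pairs) to discriminate.
#'
#' @param n_docs Number of documents.
#' @param n_blocks Number of topic blocks.
#' @param terms_per_block Terms in each block.
#' @param n_hub_terms Number of hub ("check tag"-like) terms.
#' @param terms_per_doc Distinct non-hub terms drawn per document
#'   (MEDLINE-like default: 12 descriptors per citation).
#' @param p_hub Probability that each hub term is attached to a document.
#' @param p_noise Probability that a drawn term is replaced by a uniformly
#'   chosen foreign-block term.
#' @param major_fraction Fraction of a document's terms flagged as major
#'   (rounded up).
#' @param seed Integer seed; drives per-document sub-streams so that the
#'   corpus is reproducible and invariant to generation order.
#' @return A list of class `corpus_config`.
#' @export
corpus_config <- function(n_docs = 1000, n_blocks = 5, terms_per_block = 20,
                          n_hub_terms = 3, terms_per_doc = 12, p_hub = 0.9,
                          p_noise = 0.05, major_fraction = 0.5, seed = 1) {
  cfg <- list(
    n_docs = n_docs, n_blocks = n_blocks, terms_per_block = terms_per_block,
    n_hub_terms = n_hub_terms, terms_per_doc = terms_per_doc, p_hub = p_hub,
    p_noise = p_noise, major_fraction = major_fraction, seed = seed
  )
  counts <- c("n_docs", "n_blocks", "terms_per_block", "terms_per_doc")
  for (nm in counts) {
    v <- cfg[[nm]]
    if (length(v) != 1L || !is.finite(v) || v < 1 || v != floor(v)) {
      abort(sprintf("`%s` must be a single integer >= 1.", nm))
    }
  }
  if (cfg$n_hub_terms < 0 || cfg$n_hub_terms != floor(cfg$n_hub_terms)) {
    abort("`n_hub_terms` must be a non-negative integer.")
  }
  for (nm in c("p_hub", "p_noise", "major_fraction")) {
    v <- cfg[[nm]]
    if (length(v) != 1L || !is.finite(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a probability in [0, 1].", nm))
    }
  }
  if (cfg$terms_per_doc > cfg$terms_per_block) {
    abort("`terms_per_doc` cannot exceed `terms_per_block` (documents draw distinct terms from one block).")
  }
  structure(cfg, class = "corpus_config")
}

block_vocabulary <- function(cfg) {
  lapply(seq_len(cfg$n_blocks), function(b) {
    sprintf("B%02d_T%02d", b, seq_len(cfg$terms_per_block))
  })
}

hub_vocabulary <- function(cfg) {
  if (cfg$n_hub_terms == 0) character(0) else sprintf("HUB%02d", seq_len(cfg$n_hub_terms))
}

#' Generate a synthetic term-annotated corpus with planted associations
#'
#' @param config A [corpus_config()].
#' @return A list with elements `corpus` (a doc-term tibble with columns
#'   `doc_id`, `term`, `major`) and `truth`, itself a list of two tibbles
#'   `associated_pairs` (same-block pairs, positively associated by
#'   construction) and `independent_pairs` (cross-block non-hub pairs),
#'   both with canonically ordered columns `u < v`.
#' @export
#' @examples
#' sim <- gen_corpus(corpus_config(n_docs = 50, seed = 1))
#' dplyr::n_distinct(sim$corpus$doc_id)
gen_corpus <- function(config) {
  cfg <- if (inherits(config, "corpus_config")) config else do.call(corpus_config, config)
  blocks <- block_vocabulary(cfg)
  hubs <- hub_vocabulary(cfg)
  zipf_w <- 1 / seq_len(cfg$terms_per_block)
  docs <- vector("list", cfg$n_docs)
  for (i in seq_len(cfg$n_docs)) {
    docs[[i]] <- with_seed(sub_seed(cfg$seed, i), {
      home <- sample.int(cfg$n_blocks, 1L)
      terms <- sample(blocks[[home]], cfg$terms_per_doc, prob = zipf_w)
      noisy <- which(runif(cfg$terms_per_doc) < cfg$p_noise)
      if (length(noisy) > 0 && cfg$n_blocks > 1) {
        foreign <- unlist(blocks[-home], use.names = FALSE)
        terms[noisy] <- sample(foreign, length(noisy))
      }
      if (length(hubs) > 0) {
        terms <- c(terms, hubs[runif(length(hubs)) < cfg$p_hub])
      }
      n_major <- ceiling(cfg$major_fraction * length(terms))
      major_terms <- sample(terms, n_major)
      tibble(
        doc_id = sprintf("d%06d", i),
        term = terms,
        major = terms %in% major_terms
      )
    })
  }
  corpus <- as_corpus(bind_rows(docs))
  list(corpus = corpus, truth = planted_truth(cfg, blocks))
}

planted_truth <- function(cfg, blocks) {
  pair_tbl <- function(terms_a, terms_b = NULL) {
    if (is.null(terms_b)) {
      if (length(terms_a) < 2) return(tibble(u = character(0), v = character(0)))
      cmb <- utils::combn(sort(terms_a), 2)
      tibble(u = cmb[1, ], v = cmb[2, ])
    } else {
      grid <- expand.grid(a = terms_a, b = terms_b, stringsAsFactors = FALSE)
      tibble(u = pmin(grid$a, grid$b), v = pmax(grid$a, grid$b))
    }
  }
  associated <- bind_rows(lapply(blocks, pair_tbl))
  cross <- list()
  if (cfg$n_blocks > 1) {
    idx <- utils::combn(cfg$n_blocks, 2)
    cross <- lapply(seq_len(ncol(idx)), function(j) {
      pair_tbl(blocks[[idx[1, j]]], blocks[[idx[2, j]]])
    })
  }
  independent <- if (length(cross)) arrange(bind_rows(cross), .data$u, .data$v) else
    tibble(u = character(0), v = character(0))
  list(associated_pairs = arrange(associated, .data$u, .data$v),
       independent_pairs = independent)
}

#' Sample degrees from a discrete power law
#'
#' Draws `n` integers from \eqn{P(k) \propto k^{-\alpha}}, \eqn{k \ge
#' k_{min}}, by inverse-CDF lookup against the normalised Hurwitz-zeta
#' tail. The bulk of the draws use a precomputed CDF table; draws falling
#' beyond the table (deep tail) are resolved by bisection on the zeta
#' survival function.
#'
#' @param alpha Exponent, must be > 1.
#' @param kmin Integer lower bound >= 1.
#' @param n Sample size.
#' @param seed Optional integer seed.
#' @return Integer vector of length `n`, all values >= `kmin`.
#' @export
gen_powerlaw_degrees <- function(alpha, kmin = 1, n, seed = NULL) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 1) {
    abort("`alpha` must be > 1: the discrete power law is non-normalisable otherwise.")
  }
  if (kmin < 1 || kmin != floor(kmin)) abort("`kmin` must be an integer >= 1.")
  if (n < 1) abort("`n` must be >= 1.")
  z <- hurwitz_zeta(alpha, kmin)
  with_seed(seed, {
    u <- runif(n)
    kmax <- powerlaw_quantile(max(u), alpha, kmin, z)
    ks <- kmin:kmax
    cdf <- cumsum(ks^(-alpha)) / z
    out <- kmin + findInterval(u, cdf, left.open = TRUE)
    as.integer(pmin(out, kmax))
  })
}

#' Generate an Erdős–Rényi G(n, m) random graph
#'
#' Exactly `m` distinct edges chosen uniformly without replacement among
#' the \eqn{n(n-1)/2} possible pairs.
#'
#' @param n Node count.
#' @param m Edge count; must not exceed `n * (n - 1) / 2`.
#' @param seed Optional integer seed.
#' @return An igraph object with `n` vertices and `m` edges.
#' @export
gen_er_graph <- function(n, m, seed = NULL) {
  max_m <- as.double(n) * (n - 1) / 2
  if (m > max_m) {
    abort(sprintf("`m` = %s exceeds the %s possible edges on %d nodes.",
                  format(m, big.mark = ","), format(max_m, big.mark = ","), n))
  }
  with_seed(seed, igraph::sample_gnm(n, m))
}

#' Generate a simple graph with (approximately) a given degree sequence
#'
#' Erased configuration model: stubs are matched uniformly at random, then
#' self-loops and multi-edges are deleted. Realised degrees are therefore
#' at most the requested ones; the distortion is small unless the sequence
#' is extremely heavy-tailed, and the construction always terminates.
#'
#' @param degrees Integer degree sequence with an even sum.
#' @param seed Optional integer seed.
#' @return An igraph object on `length(degrees)` vertices.
#' @export
gen_configuration_graph <- function(degrees, seed = NULL) {
  if (any(degrees < 0) || any(degrees != floor(degrees))) {
    abort("`degrees` must be non-negative integers.")
  }
  if (sum(degrees) %% 2 != 0) {
    abort("Degree sum must be even: stubs cannot be matched otherwise.")
  }
  with_seed(seed, {
    stubs <- rep(seq_along(degrees), degrees)
    stubs <- sample(stubs)
    g <- igraph::make_empty_graph(n = length(degrees), directed = FALSE)
    if (length(stubs) > 0) g <- igraph::add_edges(g, stubs)
    igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  })
}
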