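#' Count document-level term co-occurrences
#'
#' The counting unit is the document: `N` is the number of documents,
#' `doc_freq(t)` the number of documents containing term `t`, and
#' `pair_freq(u, v)` the number of documents containing both `u` and `v`
#' (each document contributes at most once per pair; pairs are unordered
#' and stored with `u < v`).
#'
#' @param corpus A corpus tibble (see [as_corpus()]).
#' @return An object of class `pair_counts`: a list with `n_docs`,
#'   `doc_freq` (tibble `term`, `n`) and `pair_freq` (tibble `u`, `v`, `n`).
#' @export
#' @examples
#' corp <- tibble::tibble(doc_id = c("d1", "d1", "d1", "d2", "d2"),
#'                        term = c("A", "B", "C", "A", "B"))
#' count_pairs(corp)
count_pairs <- function(corpus) {
  corpus <- as_corpus(corpus)
  dt <- distinct(corpus, .data$doc_id, .data$term)
  doc_freq <- count(dt, .data$term, name = "n")
  if (nrow(dt) > 0) {
    pair_freq <- inner_join(dt, dt, by = "doc_id", relationship = "many-to-many",
                            suffix = c("_u", "_v")) %>%
      filter(.data$term_u < .data$term_v) %>%
      count(u = .data$term_u, v = .data$term_v, name = "n") %>%
      arrange(.data$u, .data$v)
  } else {
    pair_freq <- tibble(u = character(0), v = character(0), n = integer(0))
  }
  structure(
    list(n_docs = n_distinct(dt$doc_id), doc_freq = doc_freq, pair_freq = pair_freq),
    class = "pair_counts"
  )
}

#' @export
print.pair_counts <- function(x, ...) {
  cat(sprintf("<pair_counts> %d documents, %d terms, %d co-occurring pairs\n",
              x$n_docs, nrow(x$doc_freq), nrow(x$pair_freq)))
  invisible(x)
}

#' @export
tidy.pair_counts <- function(x, ...) {
  x$pair_freq
}

#' Build 2x2 contingency tables for term pairs
#'
#' For each pair (`u`, `v`) the observed cells are: `o11` documents
#' containing both terms, `o12` containing `u` but not `v`, `o21`
#' containing `v` but not `u`, and `o22` containing neither. Expected
#' frequencies are the usual products of margins over the grand total,
#' `e_ij = R_i * C_j / N`.
#'
#' @param u,v Character vectors of term names (recycled to equal length).
#' @param counts A [count_pairs()] result.
#' @return A tibble with one row per pair: observed cells, margins,
#'   grand total `n` and expected cells.
#' @export
build_contingency <- function(u, v, counts) {
  stopifnot(inherits(counts, "pair_counts"))
  if (counts$n_docs == 0) abort("Cannot build contingency tables from an empty corpus (N = 0).")
  k <- max(length(u), length(v))
  u <- rep_len(as.character(u), k)
  v <- rep_len(as.character(v), k)
  df <- setNames(counts$doc_freq$n, counts$doc_freq$term)
  missing_terms <- setdiff(unique(c(u, v)), names(df))
  if (length(missing_terms) > 0) {
    abort(paste0("Term(s) not present in the corpus: ",
                 paste(head(missing_terms, 5), collapse = ", ")))
  }
  pf <- counts$pair_freq
  key <- paste(pmin(u, v), pmax(u, v), sep = "\r")
  pair_n <- setNames(pf$n, paste(pf$u, pf$v, sep = "\r"))[key]
  pair_n[is.na(pair_n)] <- 0L
  n <- counts$n_docs
  o11 <- as.double(pair_n)
  o12 <- df[u] - o11
  o21 <- df[v] - o11
  o22 <- n - o11 - o12 - o21
  r1 <- o11 + o12
  r2 <- o21 + o22
  c1 <- o11 + o21
  c2 <- o12 + o22
  tibble(
    u = u, v = v,
    o11 = o11, o12 = unname(o12), o21 = unname(o21), o22 = unname(o22),
    r1 = unname(r1), r2 = unname(r2), c1 = unname(c1), c2 = unname(c2), n = n,
    e11 = unname(r1 * c1 / n), e12 = unname(r1 * c2 / n),
    e21 = unname(r2 * c1 / n), e22 = unname(r2 * c2 / n)
  )
}

#' Chi-square test of independence for 2x2 tables
#'
#' Computes \eqn{\chi^2 = \sum_{ij} (|O_{ij} - E_{ij}| - y)^2 / E_{ij}}
#' with Yates continuity correction `y = 0.5` applied to all four cells
#' whenever any expected count falls below `yates_threshold`; the
#' corrected difference is floored at zero. Tables with a zero margin are
#' degenerate: no association is measurable and the statistic is defined
#' as 0 (not an error), so ubiquitous or vanished terms cannot crash a run.
#'
#' @param table A data frame with columns `o11`, `o12`, `o21`, `o22`
#'   (e.g. from [build_contingency()]), or a 2x2 matrix.
#' @param yates_threshold Expected-count cutoff below which the continuity
#'   correction is applied (default 5).
#' @param critical_value Significance cutoff for the statistic; the default
#'   3.84 is the 0.95 quantile of the 1-df chi-square distribution
#'   (see [chisq_critical()]).
#' @return A tibble with one row per table: `statistic`, `yates_applied`,
#'   `positive_association` (`o11 > e11`), `significant`
#'   (`statistic > critical_value`) and `degenerate`.
#' @export
#' @examples
#' chi_square(data.frame(o11 = 30, o12 = 70, o21 = 70, o22 = 830))
chi_square <- function(table, yates_threshold = 5, critical_value = 3.84) {
  if (is.matrix(table)) {
    stopifnot(identical(dim(table), c(2L, 2L)))
    table <- data.frame(o11 = table[1, 1], o12 = table[1, 2],
                        o21 = table[2, 1], o22 = table[2, 2])
  }
  o11 <- as.double(table$o11); o12 <- as.double(table$o12)
  o21 <- as.double(table$o21); o22 <- as.double(table$o22)
  if (any(c(o11, o12, o21, o22) < 0)) abort("Observed counts must be non-negative.")
  r1 <- o11 + o12; r2 <- o21 + o22; c1 <- o11 + o21; c2 <- o12 + o22
  n <- r1 + r2
  if (any(n == 0)) abort("Grand total N must be positive.")
  degenerate <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  e11 <- r1 * c1 / n; e12 <- r1 * c2 / n; e21 <- r2 * c1 / n; e22 <- r2 * c2 / n
  e_min <- pmin(e11, e12, e21, e22)
  y <- ifelse(e_min < yates_threshold, 0.5, 0)
  cell <- function(o, e) {
    out <- rep(0, length(o))
    ok <- !degenerate & e > 0
    d <- pmax(abs(o - e) - y, 0)
    out[ok] <- d[ok]^2 / e[ok]
    out
  }
  statistic <- cell(o11, e11) + cell(o12, e12) + cell(o21, e21) + cell(o22, e22)
  statistic[degenerate] <- 0
  tibble(
    statistic = statistic,
    yates_applied = !degenerate & y == 0.5,
    positive_association = !degenerate & o11 > e11,
    significant = !degenerate & statistic > critical_value,
    degenerate = degenerate
  )
}

#' Chi-square critical value
#'
#' The `1 - alpha` quantile of the chi-square distribution with `df`
#' degrees of freedom; at `alpha = 0.05` and 1 df this is the classical
#' 3.84 edge-retention cutoff.
#'
#' @param alpha Significance level (default 0.05).
#' @param df Degrees of freedom (default 1, as for a 2x2 table).
#' @return A single number.
#' @export
chisq_critical <- function(alpha = 0.05, df = 1) {
  qchisq(1 - alpha, df = df)
}

#' Reduce pair counts to a chi-square-filtered co-occurrence network
#'
#' Every term with document frequency >= 1 becomes a node. An edge
#' (`u`, `v`) is retained iff its chi-square statistic exceeds
#' `critical_value` and (when `positive_only`) the pair co-occurs more
#' often than expected under independence (`o11 > e11`). Retained edges
#' carry the co-occurrence count as weight. Nodes with no retained edges
#' are kept as isolates; extract the giant component downstream with
#' [giant_component()].
#'
#' @param counts A [count_pairs()] result.
#' @param critical_value Chi-square cutoff (default 3.84, i.e. p <= 0.05 at 1 df).
#' @param positive_only Keep only positively associated pairs (default TRUE).
#' @param yates_threshold See [chi_square()].
#' @return An object of class `cooc_network`: list with `nodes` (character)
#'   and `edges` (tibble `u`, `v`, `weight`, `chi2`).
#' @export
filter_network <- function(counts, critical_value = 3.84, positive_only = TRUE,
                           yates_threshold = 5) {
  stopifnot(inherits(counts, "pair_counts"))
  nodes <- sort(counts$doc_freq$term[counts$doc_freq$n >= 1])
  pf <- counts$pair_freq
  if (nrow(pf) > 0) {
    ct <- build_contingency(pf$u, pf$v, counts)
    cs <- chi_square(ct, yates_threshold = yates_threshold, critical_value = critical_value)
    keep <- cs$significant & (cs$positive_association | !positive_only)
    edges <- tibble(u = pf$u, v = pf$v, weight = pf$n, chi2 = cs$statistic)[keep, ]
  } else {
    edges <- tibble(u = character(0), v = character(0), weight = integer(0), chi2 = numeric(0))
  }
  structure(list(nodes = nodes, edges = edges), class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("<cooc_network> %d nodes, %d retained edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
tidy.cooc_network <- function(x, ...) {
  x$edges
}

#' Read and write weighted edge-list TSV files
#'
#' Four tab-separated columns `u`, `v`, `weight`, `chi2` (with a header
#' comment); `read_edge_tsv()` also accepts plain 2-column unweighted edge
#' lists.
#'
#' @param edges An edge tibble, a `cooc_network`, or an igraph object.
#' @param path File path.
#' @return `read_edge_tsv()` returns an edge tibble; `write_edge_tsv()`
#'   returns its input invisibly.
#' @export
write_edge_tsv <- function(edges, path) {
  if (inherits(edges, "cooc_network")) edges <- edges$edges
  if (inherits(edges, "igraph")) {
    el <- igraph::as_edgelist(edges)
    w <- if ("weight" %in% igraph::edge_attr_names(edges)) {
      igraph::E(edges)$weight
    } else {
      rep(1L, nrow(el))
    }
    edges <- tibble(u = el[, 1], v = el[, 2], weight = w, chi2 = NA_real_)
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# u\tv\tweight\tchi2", con)
  if (nrow(edges) > 0) {
    writeLines(sprintf("%s\t%s\t%s\t%s", edges$u, edges$v,
                       format(edges$weight, trim = TRUE),
                       format(edges$chi2, trim = TRUE)), con)
  }
  invisible(edges)
}

#' @rdname write_edge_tsv
#' @export
read_edge_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble(u = character(0), v = character(0), weight = numeric(0), chi2 = numeric(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (!all(nf %in% c(2L, 4L)) || length(unique(nf)) != 1L) {
    abort("Edge list must have uniformly 2 (u, v) or 4 (u, v, weight, chi2) columns.")
  }
  mat <- matrix(unlist(parts), ncol = nf[1], byrow = TRUE)
  if (nf[1] == 2L) {
    tibble(u = mat[, 1], v = mat[, 2], weight = 1, chi2 = NA_real_)
  } else {
    tibble(u = mat[, 1], v = mat[, 2],
           weight = as.numeric(mat[, 3]), chi2 = as.numeric(mat[, 4]))
  }
}
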