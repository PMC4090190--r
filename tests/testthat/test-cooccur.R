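test_that("pair counting enumerates document-level co-occurrences", {
  corp <- data.frame(doc_id = c("d1", "d1", "d1", "d2", "d2"),
                     term = c("A", "B", "C", "A", "B"))
  pc <- count_pairs(corp)
  expect_equal(pc$n_docs, 2)
  expect_equal(tibble::deframe(pc$doc_freq), c(A = 2L, B = 2L, C = 1L))
  expect_equal(pc$pair_freq,
               tibble::tibble(u = c("A", "A", "B"), v = c("B", "C", "C"),
                              n = c(2L, 1L, 1L)))

  single <- data.frame(doc_id = "d1", term = sprintf("T%02d", 1:12))
  expect_equal(nrow(count_pairs(single)$pair_freq), 66)
  expect_true(all(count_pairs(single)$pair_freq$n == 1))

  empty <- data.frame(doc_id = character(0), term = character(0))
  pc0 <- count_pairs(empty)
  expect_equal(pc0$n_docs, 0)
  expect_equal(nrow(pc0$pair_freq), 0)

  # a document contributes at most once per pair even with duplicate rows
  dup <- data.frame(doc_id = c("d1", "d1", "d1"), term = c("A", "A", "B"))
  expect_equal(count_pairs(dup)$pair_freq$n, 1L)
})

test_that("contingency tables reproduce the margin arithmetic", {
  corp <- tibble::tibble(
    doc_id = rep(sprintf("d%02d", 1:10), times = c(2, 2, 1, 1, 1, 1, 1, 1, 1, 1)),
    term = c("u", "v", "u", "v", "u", "u", "v", "x", "x", "x", "x", "x")
  )
  pc <- count_pairs(corp) # doc_freq(u)=4, doc_freq(v)=3, pair=2, N=10
  ct <- build_contingency("u", "v", pc)
  expect_equal(unlist(ct[, c("o11", "o12", "o21", "o22")], use.names = FALSE),
               c(2, 2, 1, 5))
  expect_equal(ct$e11, 4 * 3 / 10)
  expect_equal(ct$r1 + ct$r2, ct$n)
  expect_equal(ct$c1 + ct$c2, ct$n)
  expect_equal(ct$e11 + ct$e12 + ct$e21 + ct$e22, ct$n)

  # perfect co-occurrence: both terms everywhere
  all_pc <- count_pairs(tibble::tibble(doc_id = rep(sprintf("d%d", 1:4), each = 2),
                                       term = rep(c("p", "q"), 4)))
  ct2 <- build_contingency("p", "q", all_pc)
  expect_equal(unlist(ct2[, c("o11", "o12", "o21", "o22")], use.names = FALSE),
               c(4, 0, 0, 0))

  # never co-occurring pair with both terms present
  pc3 <- count_pairs(tibble::tibble(doc_id = c("d1", "d2"), term = c("p", "q")))
  ct3 <- build_contingency("p", "q", pc3)
  expect_equal(ct3$o11, 0)
  expect_equal(ct3$r1, 1)
  expect_equal(ct3$c1, 1)

  expect_error(build_contingency("p", "zzz", pc3), "not present")
  empty_pc <- count_pairs(data.frame(doc_id = character(0), term = character(0)))
  expect_error(build_contingency("p", "q", empty_pc), "N = 0")
})

test_that("chi-square matches hand-computed and shortcut values", {
  # all expected counts >= 5: no Yates correction
  res <- chi_square(data.frame(o11 = 30, o12 = 70, o21 = 70, o22 = 830))
  expect_equal(res$statistic, 1000 * (30 * 830 - 70 * 70)^2 / (100 * 900 * 100 * 900))
  expect_equal(round(res$statistic, 2), 49.38)
  expect_false(res$yates_applied)
  expect_true(res$positive_association)
  expect_true(res$significant)

  # exact independence
  res0 <- chi_square(data.frame(o11 = 25, o12 = 25, o21 = 25, o22 = 25))
  expect_equal(res0$statistic, 0)
  expect_false(res0$significant)

  # e11 = 1 < 5 triggers Yates on all four cells, floored differences
  resy <- chi_square(data.frame(o11 = 3, o12 = 7, o21 = 7, o22 = 83))
  expect_true(resy$yates_applied)
  expect_equal(resy$statistic, 2.25 / 1 + 0.25 + 0.25 + 2.25 / 81)

  # |O - E| < 0.5 is clamped to zero under Yates, never negative
  resc <- chi_square(data.frame(o11 = 1, o12 = 3, o21 = 3, o22 = 9))
  expect_gte(resc$statistic, 0)

  # zero margin: degenerate, statistic defined as 0
  resd <- chi_square(data.frame(o11 = 5, o12 = 0, o21 = 5, o22 = 0))
  expect_true(resd$degenerate)
  expect_equal(resd$statistic, 0)
  expect_false(resd$significant)
})

test_that("chi-square is invariant under transposition and term swap", {
  set.seed(71)
  for (i in 1:50) {
    o <- rpois(4, 20) + 1
    a <- chi_square(data.frame(o11 = o[1], o12 = o[2], o21 = o[3], o22 = o[4]))
    b <- chi_square(data.frame(o11 = o[1], o12 = o[3], o21 = o[2], o22 = o[4]))
    expect_equal(a$statistic, b$statistic)
  }
})

test_that("uncorrected chi-square equals the shortcut formula on random tables", {
  set.seed(72)
  for (i in 1:1000) {
    o <- rpois(4, 60) + 20 # large counts keep all expectations >= 5
    res <- chi_square(data.frame(o11 = o[1], o12 = o[2], o21 = o[3], o22 = o[4]),
                      yates_threshold = 0)
    n <- sum(o)
    shortcut <- n * (o[1] * o[4] - o[2] * o[3])^2 /
      ((o[1] + o[2]) * (o[3] + o[4]) * (o[1] + o[3]) * (o[2] + o[4]))
    expect_equal(res$statistic, shortcut, tolerance = 1e-9)
  }
})

test_that("uncorrected chi-square agrees with stats::chisq.test", {
  set.seed(73)
  for (i in 1:25) {
    o <- matrix(rpois(4, 50) + 10, 2, 2)
    res <- chi_square(o, yates_threshold = 0)
    ref <- stats::chisq.test(o, correct = FALSE)
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  }
})

test_that("network filtering keeps positive significant pairs only", {
  # 1000 docs: u&v together 30, u alone 70, v alone 70, neither 830
  docs <- c(
    lapply(1:30, function(i) c("u", "v")),
    lapply(1:70, function(i) "u"),
    lapply(1:70, function(i) "v"),
    lapply(1:830, function(i) "z")
  )
  corp <- tibble::tibble(
    doc_id = rep(sprintf("d%04d", seq_along(docs)), lengths(docs)),
    term = unlist(docs)
  )
  net <- filter_network(count_pairs(corp))
  expect_true(any(net$edges$u == "u" & net$edges$v == "v"))
  kept <- net$edges[net$edges$u == "u" & net$edges$v == "v", ]
  expect_equal(kept$weight, 30L)
  expect_equal(round(kept$chi2, 2), 49.38)
  # isolates are kept as nodes
  expect_true("z" %in% net$nodes)

  # perfectly anti-associated pair: significant but o11 < e11
  anti <- tibble::tibble(
    doc_id = rep(sprintf("a%03d", 1:100), each = 1),
    term = rep(c("p", "q"), each = 50)
  )
  # add one doc with both so the pair exists in pair_freq
  anti <- dplyr::bind_rows(anti, tibble::tibble(doc_id = "b1", term = c("p", "q")))
  pc <- count_pairs(anti)
  ct <- build_contingency("p", "q", pc)
  cs <- chi_square(ct)
  expect_true(cs$significant && !cs$positive_association)
  net_pos <- filter_network(pc, positive_only = TRUE)
  net_two <- filter_network(pc, positive_only = FALSE)
  expect_false(any(net_pos$edges$u == "p" & net_pos$edges$v == "q"))
  expect_true(any(net_two$edges$u == "p" & net_two$edges$v == "q"))
})

test_that("raising the critical value never adds edges", {
  sim <- gen_corpus(corpus_config(n_docs = 300, seed = 9))
  pc <- count_pairs(sim$corpus)
  cuts <- c(1, 3.84, 10, 30)
  n_edges <- vapply(cuts, function(cv) nrow(filter_network(pc, critical_value = cv)$edges),
                    numeric(1))
  expect_true(all(diff(n_edges) <= 0))
})

test_that("edge-list TSV round-trips and accepts 2-column lists", {
  edges <- tibble::tibble(u = c("a", "b"), v = c("b", "c"),
                          weight = c(3, 1), chi2 = c(12.5, 4.2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_tsv(edges, path)
  expect_equal(read_edge_tsv(path), edges)

  writeLines(c("a\tb", "b\tc"), path)
  two <- read_edge_tsv(path)
  expect_equal(two$u, c("a", "b"))
  expect_true(all(two$weight == 1))
})
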