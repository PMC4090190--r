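test_that("ccdf counts tail probabilities directly", {
  out <- ccdf(c(1, 1, 2, 3))
  expect_equal(out$k, c(1, 2, 3))
  expect_equal(out$p, c(1, 0.5, 0.25))

  expect_equal(ccdf(c(5, 5)), tibble::tibble(k = 5, p = 1))
  expect_error(ccdf(numeric(0)), "empty")
  # invariant to duplication of the sample
  x <- c(1, 2, 2, 7, 9)
  expect_equal(ccdf(x), ccdf(rep(x, 3)))
})

test_that("large power-law samples match the zeta-tail CCDF", {
  x <- gen_powerlaw_degrees(2.5, 1, 1e5, seed = 21)
  emp <- ccdf(x)
  p10 <- emp$p[emp$k == 10]
  model <- oracle_zeta(2.5, q = 10) / oracle_zeta(2.5)
  expect_lt(abs(p10 - model) / model, 0.2)
})

test_that("the approximate MLE matches its hand-computed closed form", {
  expect_equal(mle_alpha(c(2, 4, 8), kmin = 2, method = "approx"),
               1 + 3 / (log(4 / 3) + log(8 / 3) + log(16 / 3)))
  expect_equal(round(mle_alpha(c(2, 4, 8), 2, method = "approx"), 4), 2.0195)

  expect_error(mle_alpha(c(5, 5, 5), 5), "equal")
  expect_error(mle_alpha(c(1, 2), 5), "2 observations")
})

test_that("approximate and exact discrete MLE agree where the hybrid switches", {
  for (alpha in c(2.0, 2.5, 3.5)) {
    # exact zeta MLE recovers the truth at small kmin
    x <- gen_powerlaw_degrees(alpha, kmin = 5, n = 1e4, seed = round(100 * alpha))
    expect_lt(abs(mle_alpha(x, 5, method = "exact") - alpha), 0.1)
    # at kmin = 25 the shifted-log approximation is bias-free to ~0.02
    y <- gen_powerlaw_degrees(alpha, kmin = 25, n = 1e4, seed = round(200 * alpha))
    expect_lt(abs(mle_alpha(y, 25, method = "approx") -
                    mle_alpha(y, 25, method = "exact")), 0.02)
    # the hybrid default picks the accurate branch on both sides
    expect_equal(mle_alpha(x, 5), mle_alpha(x, 5, method = "exact"))
    expect_equal(mle_alpha(y, 25), mle_alpha(y, 25, method = "approx"))
  }
})

test_that("exponent recovery from simulated tails is unbiased", {
  alphas <- vapply(1:20, function(s) {
    mle_alpha(gen_powerlaw_degrees(2.5, 5, 1e4, seed = 500 + s), 5)
  }, numeric(1))
  expect_lt(abs(median(alphas) - 2.5), 0.05)
})

test_that("the MLE agrees with igraph's independent plfit implementation", {
  x <- gen_powerlaw_degrees(2.4, kmin = 3, n = 5000, seed = 17)
  ours <- mle_alpha(x, 3, method = "exact")
  ref <- igraph::fit_power_law(x, xmin = 3, implementation = "plfit")$alpha
  expect_lt(abs(ours - ref), 0.05)
})

test_that("KS distance reproduces the hand-computed zeta example", {
  expect_equal(round(ks_distance(c(2, 2, 4), alpha = 2, kmin = 2), 3), 0.343)
  # exact zeta arithmetic for the same case
  z <- oracle_zeta(2, q = 2)
  cdf2 <- 1 - oracle_zeta(2, q = 3) / z
  cdf4 <- 1 - oracle_zeta(2, q = 5) / z
  expect_equal(ks_distance(c(2, 2, 4), 2, 2),
               max(abs(c(2 / 3, 1) - c(cdf2, cdf4))), tolerance = 1e-5)
  # duplication invariance
  expect_equal(ks_distance(rep(c(2, 2, 4), 5), 2, 2), ks_distance(c(2, 2, 4), 2, 2))
  # consistency: KS shrinks with n for a well-specified model
  x <- gen_powerlaw_degrees(2.5, 2, 2e4, seed = 3)
  expect_lt(ks_distance(x, mle_alpha(x, 2), 2), 0.02)
})

test_that("kmin selection scans candidates and breaks ties downward", {
  # pure power law: kmin should be found near the true lower bound
  hits <- vapply(1:20, function(s) {
    x <- gen_powerlaw_degrees(2.5, 1, 1e4, seed = 600 + s)
    select_kmin(x)$kmin
  }, numeric(1))
  expect_gte(mean(hits <= 3), 0.8)

  # two distinct values only: the smaller is forced
  fit <- select_kmin(rep(c(5L, 6L), each = 10))
  expect_equal(fit$kmin, 5)

  expect_error(select_kmin(rep(3L, 20)), "distinct")
  expect_error(select_kmin(c(2L, 3L), min_tail = 10), "tail")
})

test_that("kmin selection finds the crossover in a noise + tail mixture", {
  hits <- vapply(1:10, function(s) {
    set.seed(700 + s)
    noise <- sample(1:19, 1500, replace = TRUE)
    tail_part <- gen_powerlaw_degrees(2.5, 20, 1500, seed = 701 + s)
    select_kmin(c(noise, tail_part))$kmin
  }, numeric(1))
  expect_gte(mean(hits >= 15 & hits <= 30), 0.6)
})

test_that("bootstrap GOF is calibrated on data drawn from the fitted model", {
  accept <- vapply(1:10, function(s) {
    x <- gen_powerlaw_degrees(2.5, 1, 600, seed = 800 + s)
    fit <- fit_power_law_tail(x, n_boot = 150, seed = 801 + s)
    fit$p_value > 0.1
  }, logical(1))
  expect_gte(mean(accept), 0.8) # nominal acceptance under H0 is 0.9

  x <- gen_powerlaw_degrees(2.5, 1, 200, seed = 1)
  expect_error(gof_pvalue(select_kmin(x), n_boot = 0), "n_boot")
})

test_that("power-law and exponential-tail samples are distinguishable at a common kmin", {
  # at a fixed, bulk-covering lower bound the KS distance separates the
  # families cleanly, even where the kmin-rescanning bootstrap cannot
  for (s in 1:5) {
    pl <- gen_powerlaw_degrees(2.5, 1, 1000, seed = 860 + s)
    expect_lt(ks_distance(pl, mle_alpha(pl, 1), 1), 0.05)
    set.seed(870 + s)
    geo <- rgeom(1000, 0.25) + 1L
    expect_gt(ks_distance(geo, mle_alpha(geo, 1), 1), 0.1)
  }
  # and the full procedure gives geometric data stochastically smaller p
  p_geo <- vapply(1:6, function(s) {
    set.seed(880 + s)
    fit_power_law_tail(rgeom(1000, 0.25) + 1L, n_boot = 100, seed = 881 + s)$p_value
  }, numeric(1))
  p_pl <- vapply(1:6, function(s) {
    x <- gen_powerlaw_degrees(2.5, 1, 1000, seed = 890 + s)
    fit_power_law_tail(x, n_boot = 100, seed = 891 + s)$p_value
  }, numeric(1))
  expect_lt(median(p_geo), median(p_pl))
})

test_that("gof p-values are reproducible under a fixed seed", {
  x <- gen_powerlaw_degrees(2.5, 1, 400, seed = 31)
  fit <- select_kmin(x)
  p1 <- gof_pvalue(fit, n_boot = 60, seed = 9)$p_value
  p2 <- gof_pvalue(fit, n_boot = 60, seed = 9)$p_value
  expect_identical(p1, p2)
})

test_that("full-pipeline recovery: simulate, select kmin, test plausibility", {
  res <- lapply(1:5, function(s) {
    x <- gen_powerlaw_degrees(2.5, 5, 5000, seed = 900 + s)
    fit_power_law_tail(x, n_boot = 100, seed = 901 + s)
  })
  alphas <- vapply(res, function(f) f$alpha, numeric(1))
  pvals <- vapply(res, function(f) f$p_value, numeric(1))
  expect_lt(abs(median(alphas) - 2.5), 0.1)
  expect_gt(median(pvals), 0.1)
})

test_that("alternative families recover their own parameters and fail on misfits", {
  set.seed(61)
  x <- rpois(1e4, 10)
  alt <- fit_alternatives(x[x >= 1], kmin = 1, n_boot = 60, seed = 62,
                          families = "poisson")
  expect_true(alt$converged)
  expect_lt(abs(alt$params[[1]]["lambda"] - 10), 0.2)
  expect_gt(alt$p_value, 0.1)

  pl <- gen_powerlaw_degrees(2.2, 1, 2000, seed = 63)
  alt_pl <- fit_alternatives(pl, kmin = 1, n_boot = 60, seed = 64,
                             families = "poisson")
  expect_lt(alt_pl$p_value, 0.1)

  # determinism
  a1 <- fit_alternatives(x[x >= 1], 1, n_boot = 40, seed = 65, families = "lognormal")
  a2 <- fit_alternatives(x[x >= 1], 1, n_boot = 40, seed = 65, families = "lognormal")
  expect_identical(a1$p_value, a2$p_value)
})

test_that("lognormal and exponential discretised fits are sane on their own data", {
  set.seed(66)
  xl <- pmax(1L, as.integer(round(rlnorm(5000, 2, 0.5))))
  alt <- fit_alternatives(xl, kmin = 1, n_boot = 0, families = "lognormal")
  expect_lt(abs(alt$params[[1]]["meanlog"] - 2), 0.1)
  xe <- pmax(1L, as.integer(round(rexp(5000, 0.2))))
  alte <- fit_alternatives(xe, kmin = 1, n_boot = 0, families = "exponential")
  expect_lt(abs(alte$params[[1]]["rate"] - 0.2), 0.05)
})

test_that("scale-free classification follows the 2 < alpha <= 3 convention", {
  x <- gen_powerlaw_degrees(2.5, 5, 3000, seed = 71)
  fit <- select_kmin(x)
  sf <- is_scale_free(fit)
  expect_true(sf$scale_free)
  # small-tail caveat fires when the fitted regime covers few nodes
  fit2 <- fit
  fit2$n <- fit$n_tail * 50
  expect_false(is.na(is_scale_free(fit2)$note))
})

test_that("tidy and glance methods expose the fit in broom shape", {
  x <- gen_powerlaw_degrees(2.5, 2, 1000, seed = 81)
  fit <- fit_power_law_tail(x, n_boot = 30, seed = 82)
  td <- tidy(fit)
  expect_equal(td$term, c("alpha", "kmin"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("alpha", "kmin", "ks", "p_value", "plausible") %in% names(gl)))
})

test_that("hurwitz zeta agrees with reference values", {
  expect_equal(hurwitz_zeta(2, 1), pi^2 / 6, tolerance = 1e-12)
  expect_equal(hurwitz_zeta(2, 2), pi^2 / 6 - 1, tolerance = 1e-12)
  expect_equal(hurwitz_zeta(2.5, 1), oracle_zeta(2.5), tolerance = 1e-8)
  expect_equal(hurwitz_zeta(3.5, 7), oracle_zeta(3.5, q = 7), tolerance = 1e-10)
  skip_if_not_installed("pracma")
  expect_equal(hurwitz_zeta(2.5, 1), pracma::zeta(2.5), tolerance = 1e-10)
  expect_error(hurwitz_zeta(1, 1), "non-normalisable")
})
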