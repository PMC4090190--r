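#' Complementary cumulative degree distribution
#'
#' For each distinct value `k` in the sample, the fraction of observations
#' \eqn{\ge k}. The first point always has probability 1.
#'
#' @param values Integer sample (e.g. a degree sequence); zeros and
#'   negatives are allowed in the input but excluded (they cannot appear
#'   in a CCDF over positive degrees when `positive_only = TRUE`).
#' @param positive_only Drop values < 1 before tabulating (default TRUE).
#' @return A tibble (`k`, `p`) with `p` strictly decreasing.
#' @export
#' @examples
#' ccdf(c(1, 1, 2, 3))
ccdf <- function(values, positive_only = TRUE) {
  values <- as.numeric(values)
  if (positive_only) values <- values[values >= 1]
  if (length(values) == 0) abort("Cannot compute a CCDF from an empty sample.")
  tab <- table(values)
  k <- as.numeric(names(tab))
  p <- rev(cumsum(rev(as.numeric(tab)))) / length(values)
  tibble(k = k, p = p)
}

#' Maximum-likelihood power-law exponent
#'
#' Estimates the exponent of a discrete power law from the tail
#' `k_i >= kmin`. The `"exact"` method maximises the discrete
#' (Hurwitz-zeta) likelihood numerically; `"approx"` is the closed-form
#' discrete-data approximation
#' \deqn{\hat\alpha = 1 + n \left[ \sum_i \ln \frac{k_i}{k_{min} - 1/2} \right]^{-1},}
#' whose bias is negligible for large `kmin` but noticeable below
#' `kmin` of about 10--20. The default `"hybrid"` therefore uses the
#' exact estimator for small `kmin` and the approximation above.
#'
#' @param values Integer sample.
#' @param kmin Lower bound of the fitted tail.
#' @param method `"hybrid"` (default) uses the exact estimator for
#'   `kmin < 20`, where the approximation is visibly biased, and the
#'   cheap approximation above; `"approx"` or `"exact"` force one form.
#' @return The estimated exponent (a single number > 1).
#' @export
mle_alpha <- function(values, kmin, method = c("hybrid", "approx", "exact")) {
  method <- match.arg(method)
  tail_vals <- values[values >= kmin]
  if (length(tail_vals) < 2) abort("Need at least 2 observations >= kmin.")
  if (length(unique(tail_vals)) == 1) {
    abort("All tail values are equal; the exponent estimate diverges.")
  }
  if (method == "hybrid") method <- if (kmin < 20) "exact" else "approx"
  if (method == "approx") {
    1 + length(tail_vals) / sum(log(tail_vals / (kmin - 0.5)))
  } else {
    nll <- function(a) length(tail_vals) * log(hurwitz_zeta(a, kmin)) + a * sum(log(tail_vals))
    optimize(nll, interval = c(1 + 1e-6, 25))$minimum
  }
}

#' Kolmogorov–Smirnov distance to a fitted discrete power law
#'
#' \eqn{D = \max_k |S(k) - P(k)|} over the distinct tail values, where `S`
#' is the empirical CDF of the tail and `P` the fitted discrete power-law
#' CDF (Hurwitz-zeta normalisation). Both CDFs are evaluated at the
#' observed unique values with the inclusive (\eqn{\le k}) convention;
#' KS values shift under other conventions, so this one is pinned.
#'
#' @param values Integer sample.
#' @param alpha Fitted exponent.
#' @param kmin Lower bound.
#' @return A number in [0, 1].
#' @export
ks_distance <- function(values, alpha, kmin) {
  tail_vals <- values[values >= kmin]
  if (length(tail_vals) == 0) abort("Empty tail: no observations >= kmin.")
  uk <- sort(unique(tail_vals))
  emp <- cumsum(tabulate(factor(tail_vals, levels = uk))) / length(tail_vals)
  z <- hurwitz_zeta(alpha, kmin)
  model <- 1 - hurwitz_zeta_vec(alpha, uk + 1) / z
  max(abs(emp - model))
}

# hurwitz_zeta is already vectorised over q; alias for readability
hurwitz_zeta_vec <- function(s, q) hurwitz_zeta(s, q)

#' Select the power-law lower bound by KS minimisation
#'
#' Every distinct sample value is tried as a candidate `kmin` (provided
#' the tail above it has at least `min_tail` observations and at least two
#' distinct values); for each candidate the exponent is estimated by
#' [mle_alpha()] and the [ks_distance()] computed; the candidate with the
#' smallest KS distance wins, ties going to the smallest `kmin`.
#'
#' @param values Integer sample with at least 2 distinct values.
#' @param min_tail Minimum tail size for a candidate (default 10; guards
#'   against degenerate fits on a handful of points).
#' @param method Exponent estimator, see [mle_alpha()].
#' @return An object of class `powerlaw_fit`: list with `alpha`, `kmin`,
#'   `n_tail`, `n`, `ks`, `p_value` (`NA` until [gof_pvalue()] is run),
#'   `plausible` and the input sample in `values`.
#' @export
select_kmin <- function(values, min_tail = 10, method = c("hybrid", "approx", "exact")) {
  method <- match.arg(method)
  values <- as.integer(values[values >= 1])
  uk <- sort(unique(values))
  if (length(uk) < 2) abort("Need at least 2 distinct values to select kmin.")
  best <- NULL
  for (cand in uk) {
    tail_vals <- values[values >= cand]
    if (length(tail_vals) < max(min_tail, 2)) next
    if (length(unique(tail_vals)) < 2) next
    alpha <- mle_alpha(values, cand, method = method)
    ks <- ks_distance(values, alpha, cand)
    if (is.null(best) || ks < best$ks) {
      best <- list(alpha = alpha, kmin = cand, n_tail = length(tail_vals), ks = ks)
    }
  }
  if (is.null(best)) {
    abort(sprintf("No candidate kmin leaves a tail of >= %d observations with >= 2 distinct values.",
                  min_tail))
  }
  structure(
    list(alpha = best$alpha, kmin = best$kmin, n_tail = best$n_tail,
         n = length(values), ks = best$ks, p_value = NA_real_,
         plausible = NA, n_boot = NA_integer_, min_tail = min_tail,
         method = method, values = values),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> alpha = %.3f, kmin = %d, tail %d of %d, KS = %.4f\n",
              x$alpha, x$kmin, x$n_tail, x$n, x$ks))
  if (!is.na(x$p_value)) {
    cat(sprintf("  bootstrap GOF: p = %.3f (%d replicates) -> power law %s\n",
                x$p_value, x$n_boot,
                if (isTRUE(x$plausible)) "plausible (p > 0.1)" else "rejected"))
  }
  invisible(x)
}

#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble(term = c("alpha", "kmin"), estimate = c(x$alpha, x$kmin))
}

#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(alpha = x$alpha, kmin = x$kmin, n_tail = x$n_tail, n = x$n,
         ks = x$ks, p_value = x$p_value, plausible = x$plausible,
         n_boot = x$n_boot)
}

#' Bootstrap goodness-of-fit p-value for a power-law fit
#'
#' Semi-parametric bootstrap: each replicate of size `n` draws, per
#' observation, with probability `n_tail / n` from the fitted power law
#' (values >= `kmin`) and otherwise uniformly from the empirical values
#' below `kmin`. Each replicate is re-fitted with [select_kmin()] and its
#' own KS distance computed; the p-value is the fraction of replicates
#' whose KS distance is at least the observed one. A p-value above 0.1
#' deems the power law a plausible model.
#'
#' @param fit A [select_kmin()] result.
#' @param n_boot Number of bootstrap replicates (default 2500).
#' @param seed Optional seed; replicates use independent sub-streams.
#' @return The fit, with `p_value`, `plausible` and `n_boot` filled in.
#' @export
gof_pvalue <- function(fit, n_boot = 2500, seed = NULL) {
  stopifnot(inherits(fit, "powerlaw_fit"))
  if (n_boot < 1) abort("`n_boot` must be >= 1.")
  values <- fit$values
  n <- fit$n
  body_vals <- values[values < fit$kmin]
  p_tail <- fit$n_tail / n
  ks_boot <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    rep_vals <- with_seed(sub_seed(seed, b), {
      n_tail_b <- rbinom(1, n, p_tail)
      tail_b <- if (n_tail_b > 0) {
        gen_powerlaw_degrees(fit$alpha, fit$kmin, n_tail_b)
      } else {
        integer(0)
      }
      body_b <- if (n - n_tail_b > 0) {
        sample(body_vals, n - n_tail_b, replace = TRUE)
      } else {
        integer(0)
      }
      c(tail_b, body_b)
    })
    refit <- tryCatch(select_kmin(rep_vals, min_tail = fit$min_tail, method = fit$method),
                      error = function(e) NULL)
    if (!is.null(refit)) ks_boot[b] <- refit$ks
  }
  ok <- !is.na(ks_boot)
  fit$p_value <- mean(ks_boot[ok] >= fit$ks)
  fit$plausible <- fit$p_value > 0.1
  fit$n_boot <- n_boot
  fit
}

#' Fit and test a power-law tail in one call
#'
#' Convenience wrapper: [select_kmin()] followed by [gof_pvalue()] when
#' `n_boot > 0`.
#'
#' @inheritParams select_kmin
#' @inheritParams gof_pvalue
#' @return A `powerlaw_fit`.
#' @export
fit_power_law_tail <- function(values, min_tail = 10, n_boot = 0, seed = NULL,
                               method = c("hybrid", "approx", "exact")) {
  fit <- select_kmin(values, min_tail = min_tail, method = method)
  if (n_boot > 0) fit <- gof_pvalue(fit, n_boot = n_boot, seed = seed)
  fit
}

#' Scale-free classification of a power-law fit
#'
#' Scale-free networks conventionally have exponents in (2, 3]. When the
#' fitted tail covers only a small fraction of the nodes the power law,
#' even if plausible, describes a limited range of degrees; a caveat is
#' reported in that case.
#'
#' @param fit A `powerlaw_fit`.
#' @param small_tail Tail fraction below which the caveat fires (default 0.1).
#' @return One-row tibble (`scale_free`, `alpha`, `tail_fraction`, `note`).
#' @export
is_scale_free <- function(fit, small_tail = 0.1) {
  stopifnot(inherits(fit, "powerlaw_fit"))
  frac <- fit$n_tail / fit$n
  tibble(
    scale_free = fit$alpha > 2 & fit$alpha <= 3,
    alpha = fit$alpha,
    tail_fraction = frac,
    note = if (frac < small_tail) {
      "power-law regime covers a small fraction of nodes; it may model only the extreme tail"
    } else {
      NA_character_
    }
  )
}

# ---- alternative tail models -------------------------------------------

# Discretised, kmin-truncated distribution helpers. Continuous families
# (log-normal, exponential) are discretised by the probability mass on
# [k - 1/2, k + 1/2); Poisson is discrete already. All are renormalised
# over k >= kmin so KS distances are comparable with the discrete power law.
alt_family <- function(family) {
  switch(family,
    lognormal = list(
      n_par = 2,
      init = function(tail_vals) c(mean(log(tail_vals)), log(sd(log(tail_vals)) + 0.1)),
      cdf = function(x, par) plnorm(x, meanlog = par[1], sdlog = exp(par[2])),
      untransform = function(par) c(meanlog = par[1], sdlog = exp(par[2]))
    ),
    exponential = list(
      n_par = 1,
      init = function(tail_vals) log(1 / max(mean(tail_vals), 1e-8)),
      cdf = function(x, par) pexp(x, rate = exp(par[1])),
      untransform = function(par) c(rate = exp(par[1]))
    ),
    poisson = list(
      n_par = 1,
      init = function(tail_vals) log(mean(tail_vals)),
      cdf = function(x, par) ppois(floor(x), lambda = exp(par[1])),
      untransform = function(par) c(lambda = exp(par[1]))
    ),
    abort(sprintf("Unknown family '%s'.", family))
  )
}

alt_loglik <- function(par, fam, tail_vals, kmin) {
  lower <- fam$cdf(kmin - 0.5, par)
  w <- fam$cdf(tail_vals + 0.5, par) - fam$cdf(tail_vals - 0.5, par)
  total <- 1 - lower
  # large finite penalty keeps 1-d optimisers off invalid regions quietly
  if (total <= 0 || any(!is.finite(w)) || any(w <= 0)) return(-1e12)
  sum(log(w)) - length(tail_vals) * log(total)
}

alt_cdf_at <- function(k, fam, par, kmin) {
  lower <- fam$cdf(kmin - 0.5, par)
  (fam$cdf(k + 0.5, par) - lower) / (1 - lower)
}

alt_sample <- function(n, fam, par, kmin, kmax) {
  ks <- kmin:kmax
  pmf <- fam$cdf(ks + 0.5, par) - fam$cdf(ks - 0.5, par)
  if (sum(pmf) <= 0) return(rep(kmin, n))
  sample(ks, n, replace = TRUE, prob = pmf)
}

fit_one_alternative <- function(family, tail_vals, kmin) {
  fam <- alt_family(family)
  nll <- function(par) -alt_loglik(par, fam, tail_vals, kmin)
  init <- fam$init(tail_vals)
  res <- tryCatch({
    if (fam$n_par == 1) {
      opt <- optimize(function(p) nll(p), interval = c(init - 10, init + 10))
      list(par = opt$minimum, value = opt$objective, convergence = 0)
    } else {
      optim(init, nll, method = "Nelder-Mead", control = list(maxit = 2000))
    }
  }, error = function(e) NULL)
  if (is.null(res) || !is.finite(res$value) || res$convergence != 0) {
    return(list(converged = FALSE, par = NULL, fam = fam))
  }
  list(converged = TRUE, par = res$par, fam = fam)
}

#' Fit alternative distributions to a degree tail
#'
#' Discretised log-normal, Poisson and discretised exponential models are
#' fitted to the tail `k >= kmin` by maximum likelihood, and each is
#' assessed with the same KS-statistic-plus-semi-parametric-bootstrap
#' scheme as the power law (with `kmin` held fixed when refitting
#' replicates).
#'
#' @param values Integer sample.
#' @param kmin Lower bound of the tail (typically the power-law fit's).
#' @param n_boot Bootstrap replicates per family (default 200).
#' @param seed Optional seed.
#' @param families Subset of `c("lognormal", "poisson", "exponential")`.
#' @return A tibble with one row per family: `family`, `ks`, `p_value`,
#'   `converged` and a list-column `params`.
#' @export
fit_alternatives <- function(values, kmin, n_boot = 200, seed = NULL,
                             families = c("lognormal", "poisson", "exponential")) {
  values <- as.integer(values[values >= 1])
  tail_vals <- values[values >= kmin]
  if (length(tail_vals) < 2) abort("Empty or singleton tail: nothing to fit.")
  body_vals <- values[values < kmin]
  n <- length(values)
  p_tail <- length(tail_vals) / n
  kmax <- max(2L * max(tail_vals), kmin + 10L)
  rows <- lapply(families, function(family) {
    f <- fit_one_alternative(family, tail_vals, kmin)
    if (!f$converged) {
      return(tibble(family = family, ks = NA_real_, p_value = NA_real_,
                    converged = FALSE, params = list(NULL)))
    }
    uk <- sort(unique(tail_vals))
    emp <- cumsum(tabulate(factor(tail_vals, levels = uk))) / length(tail_vals)
    ks_obs <- max(abs(emp - alt_cdf_at(uk, f$fam, f$par, kmin)))
    ks_boot <- rep(NA_real_, n_boot)
    if (n_boot > 0) {
      for (b in seq_len(n_boot)) {
        rep_vals <- with_seed(sub_seed(seed, b * 131 + match(family, families)), {
          n_tail_b <- rbinom(1, n, p_tail)
          tail_b <- if (n_tail_b > 0) alt_sample(n_tail_b, f$fam, f$par, kmin, kmax) else integer(0)
          body_b <- if (n - n_tail_b > 0) sample(body_vals, n - n_tail_b, replace = TRUE) else integer(0)
          c(tail_b, body_b)
        })
        rt <- rep_vals[rep_vals >= kmin]
        if (length(rt) < 2) next
        fb <- fit_one_alternative(family, rt, kmin)
        if (!fb$converged) next
        ukb <- sort(unique(rt))
        empb <- cumsum(tabulate(factor(rt, levels = ukb))) / length(rt)
        ks_boot[b] <- max(abs(empb - alt_cdf_at(ukb, fb$fam, fb$par, kmin)))
      }
    }
    ok <- !is.na(ks_boot)
    p_val <- if (any(ok)) mean(ks_boot[ok] >= ks_obs) else NA_real_
    tibble(family = family, ks = ks_obs, p_value = p_val, converged = TRUE,
           params = list(f$fam$untransform(f$par)))
  })
  bind_rows(rows)
}
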