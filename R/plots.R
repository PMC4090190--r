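#' Plot a complementary cumulative degree distribution
#'
#' Log-log CCDF scatter; when a `powerlaw_fit` is supplied, the fitted
#' tail CCDF (scaled by the tail fraction so it overlays the empirical
#' curve at `kmin`) is drawn as a line.
#'
#' @param values Integer sample, or a [ccdf()] tibble.
#' @param fit Optional `powerlaw_fit` overlay.
#' @return A ggplot object.
#' @export
plot_ccdf <- function(values, fit = NULL) {
  pts <- if (is.data.frame(values) && all(c("k", "p") %in% names(values))) {
    as_tibble(values)
  } else {
    ccdf(values)
  }
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$k, y = .data$p)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "P(K ≥ k)") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "powerlaw_fit"))
    kk <- exp(seq(log(fit$kmin), log(max(fit$values)), length.out = 200))
    kk <- unique(pmax(floor(kk), fit$kmin))
    tail_frac <- fit$n_tail / fit$n
    line <- tibble(k = kk, p = tail_frac * spowerlaw(kk, fit$alpha, fit$kmin))
    p <- p + ggplot2::geom_line(data = line, colour = "firebrick")
  }
  p
}

#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  plot_ccdf(object$values, fit = object)
}

#' @export
autoplot.ck_curve <- function(object, ...) {
  pts <- filter(as_tibble(object), .data$clustering > 0)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$k, y = .data$clustering)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = expression(bar(C)(k))) +
    ggplot2::theme_minimal()
}

#' Plot attack outcomes
#'
#' Bar chart of surviving giant-component fraction per attack strategy.
#'
#' @param attacks A tibble of [attack()] results (rows may be bound
#'   together).
#' @return A ggplot object.
#' @export
plot_attack <- function(attacks) {
  ggplot2::ggplot(attacks,
                  ggplot2::aes(x = .data$strategy, y = .data$giant_fraction)) +
    ggplot2::geom_col(width = 0.6, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "giant component fraction after removal") +
    ggplot2::theme_minimal()
}
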