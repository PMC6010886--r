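#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a birth-death model fit
#'
#' @param x A `bd_fit` from [fit_model()].
#' @param ... Unused.
#' @return A tibble with one row per tree and rate: columns `tree`, `term`
#'   (`"lambda"` or `"mu"`), and `estimate`.
#' @export
tidy.bd_fit <- function(x, ...) {
  est <- x$estimates
  tibble::tibble(
    tree = rep(est$tree, 2L),
    term = rep(c("lambda", "mu"), each = nrow(est)),
    estimate = c(est$lambda, est$mu)
  )
}

#' One-row summary of a birth-death model fit
#'
#' @param x A `bd_fit`.
#' @param ... Unused.
#' @return A tibble with columns `model`, `logLik`, `k`, `converged`,
#'   `n_restarts_used`.
#' @export
glance.bd_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model$name,
    logLik = x$loglik,
    k = x$k,
    converged = x$converged,
    n_restarts_used = x$n_restarts_used
  )
}

#' Tidy a likelihood-ratio test result
#'
#' @param x A `bd_lrt` from [lrt()] or [bootstrap_pvalue()].
#' @param ... Unused.
#' @return A one-row tibble: `null_model`, `alt_model`, `loglik_null`,
#'   `loglik_alt`, `statistic`, `df`, `p.value`, `method`.
#' @export
tidy.bd_lrt <- function(x, ...) {
  tibble::tibble(
    null_model = x$null_model,
    alt_model = x$alt_model,
    loglik_null = x$loglik_null,
    loglik_alt = x$loglik_alt,
    statistic = x$statistic,
    df = x$df,
    p.value = x$p,
    method = x$method
  )
}

#' Plot a simulation experiment
#'
#' For a `rates_experiment`, either the per-condition distribution of
#' likelihood-ratio-test p-values (`type = "pvalues"`; uniform under a true
#' null) or the rejection-rate curve across conditions with binomial
#' Monte-Carlo standard-error bars (`type = "power"`).
#'
#' @param object A `rates_experiment`.
#' @param type `"pvalues"` or `"power"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rates_experiment <- function(object, type = c("pvalues", "power"),
                                      ...) {
  type <- match.arg(type)
  if (type == "pvalues") {
    ggplot2::ggplot(object$per_replicate, ggplot2::aes(x = .data$p)) +
      ggplot2::geom_histogram(breaks = seq(0, 1, 0.1),
                              fill = "grey70", colour = "grey30") +
      ggplot2::facet_grid(model ~ condition) +
      ggplot2::labs(x = "likelihood-ratio test p-value", y = "replicates",
                    title = object$name) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$summary,
                    ggplot2::aes(x = .data$condition,
                                 y = .data$rejection_rate,
                                 group = .data$model,
                                 colour = .data$model)) +
      ggplot2::geom_point() +
      ggplot2::geom_line() +
      ggplot2::geom_errorbar(ggplot2::aes(
        ymin = pmax(.data$rejection_rate - 2 * .data$mc_se, 0),
        ymax = pmin(.data$rejection_rate + 2 * .data$mc_se, 1)),
        width = 0.1) +
      ggplot2::geom_hline(yintercept = 0.05, linetype = "dashed") +
      ggplot2::labs(x = "condition", y = "rejection rate at alpha = 0.05",
                    title = object$name) +
      ggplot2::theme_minimal()
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
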