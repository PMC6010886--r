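#' Likelihood-ratio test between nested rate models
#'
#' Compares a null fit to an alternative fit in which the null is a special
#' case (e.g. equal rates vs per-tree rates). The statistic is
#' `2 * (logL_alt - logL_null)`; under the null it is referred to a
#' chi-squared distribution with degrees of freedom equal to the difference
#' in free-parameter counts: `2m - 2` for the full per-tree model vs the
#' equal-rates null, `m - 1` for the shared-extinction (or shared-speciation)
#' models, and `2g - 2` for a grouped model with `g` rate classes.
#'
#' A small negative statistic (within `1e-4`) is attributed to optimizer
#' noise and clamped to zero; a larger negative value means the alternative
#' optimization failed to dominate its nested null and is reported as an
#' error rather than silently clamped.
#'
#' @param null_fit,alt_fit [fit_model()] results; `null_fit` must be nested
#'   in `alt_fit`.
#' @return An object of class `bd_lrt`: list with `statistic`, `df`, `p`
#'   (upper chi-squared tail), `method = "chisq"`, model names, and both
#'   log-likelihoods.
#' @export
lrt <- function(null_fit, alt_fit) {
  stopifnot(inherits(null_fit, "bd_fit"), inherits(alt_fit, "bd_fit"))
  if (!is_nested(null_fit$model, alt_fit$model)) {
    stop("'", null_fit$model$name, "' is not nested in '",
         alt_fit$model$name, "' (or tree counts differ)", call. = FALSE)
  }
  stat <- 2 * (alt_fit$loglik - null_fit$loglik)
  if (stat < 0) {
    if (stat > -1e-4) {
      stat <- 0
    } else {
      stop(sprintf(paste0(
        "alternative log-likelihood (%.6f) is below the null (%.6f) by more ",
        "than tolerance: optimization failure"),
        alt_fit$loglik, null_fit$loglik), call. = FALSE)
    }
  }
  df <- alt_fit$k - null_fit$k
  structure(list(
    statistic = stat,
    df = df,
    p = stats::pchisq(stat, df = df, lower.tail = FALSE),
    method = "chisq",
    null_model = null_fit$model$name,
    alt_model = alt_fit$model$name,
    loglik_null = null_fit$loglik,
    loglik_alt = alt_fit$loglik
  ), class = "bd_lrt")
}

#' @export
print.bd_lrt <- function(x, ...) {
  cat(sprintf(
    "Likelihood-ratio test: '%s' (logL = %.4f) vs '%s' (logL = %.4f)\n",
    x$null_model, x$loglik_null, x$alt_model, x$loglik_alt))
  cat(sprintf("  statistic = %.4f, df = %d, p = %.4g  [%s]\n",
              x$statistic, x$df, x$p, x$method))
  if (x$method == "bootstrap") {
    cat(sprintf("  (%d bootstrap replicates, conditioning: %s)\n",
                length(x$boot_statistics), x$conditioning))
  }
  invisible(x)
}

#' Parametric-bootstrap p-value for the likelihood-ratio test
#'
#' The chi-squared reference distribution can be unreliable when parameters
#' sit near their boundary (extinction rates near zero in particular), so the
#' null distribution of the test statistic can instead be generated by
#' simulation: the null model is fitted to the observed trees, replicate tree
#' sets are simulated under those maximum-likelihood rates, and the observed
#' statistic is ranked among the replicated ones. The add-one estimator
#' `p = (1 + #{boot >= observed}) / (n_boot + 1)` avoids p = 0.
#'
#' What to condition the simulated trees on is a genuinely open choice; both
#' schemes are exposed:
#' * `"depth-rates"` (default): each replicate tree matches the observed
#'   tree's crown age (and the fitted rates); its tip count is random.
#' * `"depth-rates-N"`: additionally, each replicate tree matches the
#'   observed tree's tip count (by exact conditioning for pure-birth nulls,
#'   otherwise by rejection).
#'
#' @param data A [multi_tree_data()] object.
#' @param null_model,alt_model [model_spec()] objects (or names).
#' @param n_boot Number of bootstrap replicates.
#' @param conditioning `"depth-rates"` or `"depth-rates-N"`.
#' @param seed Integer seed for the simulation stream.
#' @param control A [fit_control()] for the refits.
#' @return A `bd_lrt` with `method = "bootstrap"`, the bootstrap p-value, and
#'   the vector of bootstrap statistics in `boot_statistics`.
#' @export
bootstrap_pvalue <- function(data, null_model, alt_model, n_boot = 199,
                             conditioning = c("depth-rates", "depth-rates-N"),
                             seed = NULL, control = fit_control()) {
  conditioning <- match.arg(conditioning)
  if (!inherits(data, "multi_tree_data")) data <- multi_tree_data(data)
  if (is.character(null_model)) null_model <- model_spec(null_model, m = data$m)
  if (is.character(alt_model)) alt_model <- model_spec(alt_model, m = data$m)
  if (!is_nested(null_model, alt_model)) {
    stop("models are not nested", call. = FALSE)
  }
  stopifnot(n_boot >= 1)
  if (!is.null(seed)) set.seed(seed)

  obs <- .compare_pair(data, null_model, alt_model, control)
  null_fit <- obs$null_fit
  observed_stat <- obs$test$statistic

  depths <- vapply(data$trees, function(b) b$t[1], numeric(1))
  Ns <- vapply(data$trees, function(b) b$N, integer(1))
  boot_stats <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    sim_trees <- vector("list", data$m)
    for (i in seq_len(data$m)) {
      lam <- null_fit$estimates$lambda[i]
      mu <- null_fit$estimates$mu[i]
      rho <- data$rhos[i]
      sim_trees[[i]] <- .boot_sim_tree(lam, mu, rho, depths[i],
                                       n_target = if (conditioning == "depth-rates-N") Ns[i],
                                       max_redraw = 100L)
    }
    sim_data <- multi_tree_data(sim_trees, rhos = data$rhos)
    boot_stats[b] <- .compare_pair(sim_data, null_model, alt_model,
                                   control)$test$statistic
  }
  p <- (1 + sum(boot_stats >= observed_stat)) / (n_boot + 1)
  structure(list(
    statistic = observed_stat,
    df = alt_model$k - null_model$k,
    p = p,
    method = "bootstrap",
    conditioning = conditioning,
    null_model = null_model$name,
    alt_model = alt_model$name,
    loglik_null = null_fit$loglik,
    loglik_alt = obs$alt_fit$loglik,
    boot_statistics = boot_stats
  ), class = "bd_lrt")
}

# One bootstrap replicate tree under fitted null rates; exact (N, T)
# conditioning is available for pure-birth rates, otherwise N is matched by
# rejection (capped redraws).
.boot_sim_tree <- function(lam, mu, rho, depth, n_target = NULL,
                           max_redraw = 100L) {
  if (!is.null(n_target) && mu == 0 && rho == 1) {
    return(simulate_yule_NT(lam, n = n_target, depth = depth))
  }
  for (try in seq_len(max_redraw)) {
    tr <- simulate_crown_bd(lam, mu, depth = depth, rho = rho, min_tips = 2)
    if (is.null(n_target) || ape::Ntip(tr) == n_target) return(tr)
  }
  stop("could not generate a usable bootstrap replicate after ", max_redraw,
       " redraws (rates lambda=", lam, ", mu=", mu, ")", call. = FALSE)
}

# Fit null then alternative (warm-started from the null), return both fits
# and the chi-squared LRT.
.compare_pair <- function(data, null_model, alt_model, control = fit_control()) {
  null_fit <- fit_model(data, null_model, control)
  warm <- list(lambda = null_fit$estimates$lambda, mu = null_fit$estimates$mu)
  alt_fit <- fit_model(data, alt_model, control, warm_start = warm)
  list(null_fit = null_fit, alt_fit = alt_fit, test = lrt(null_fit, alt_fit))
}

#' Compare two nested rate models on a set of trees
#'
#' Convenience wrapper: fits the null and the alternative model (the
#' alternative warm-started from the null solution, so its likelihood
#' dominates) and performs the chi-squared likelihood-ratio test.
#'
#' @param data A [multi_tree_data()] object, list of trees, or single tree.
#' @param null_model,alt_model Model names or [model_spec()] objects.
#' @param control A [fit_control()].
#' @return List with `null_fit`, `alt_fit` (class `bd_fit`) and `test`
#'   (class `bd_lrt`).
#' @export
compare_models <- function(data, null_model = "equal", alt_model = "free",
                           control = fit_control()) {
  if (!inherits(data, "multi_tree_data")) data <- multi_tree_data(data)
  if (is.character(null_model)) null_model <- model_spec(null_model, m = data$m)
  if (is.character(alt_model)) alt_model <- model_spec(alt_model, m = data$m)
  .compare_pair(data, null_model, alt_model, control)
}

#' One-sided binomial test for an elevated rejection rate
#'
#' Tests whether an observed count of rejections across simulation replicates
#' significantly exceeds a nominal error rate: the exact upper binomial tail
#' `P(X >= errors)` with `X ~ Binomial(n, nominal)`.
#'
#' @param errors Number of rejections observed.
#' @param n Number of replicates.
#' @param nominal Nominal error rate (e.g. 0.05).
#' @return The one-sided p-value.
#' @export
binomial_exceedance_test <- function(errors, n, nominal = 0.05) {
  stopifnot(errors >= 0, errors <= n, n >= 1, nominal > 0, nominal < 1)
  stats::binom.test(errors, n, p = nominal, alternative = "greater")$p.value
}

#' Test a p-value sample for uniformity on [0, 1]
#'
#' Under a true null hypothesis and a well-calibrated test, p-values are
#' uniform on `[0, 1]`. This runs a one-sample Kolmogorov-Smirnov test
#' against the uniform distribution and tabulates a 10-bin histogram.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return List with `statistic` (the KS statistic), `p.value`, `n`, and
#'   `histogram` (a tibble with columns `bin`, `lower`, `upper`, `count`).
#' @export
pvalue_uniformity <- function(pvals) {
  if (length(pvals) == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  breaks <- seq(0, 1, by = 0.1)
  counts <- as.integer(table(cut(pvals, breaks, include.lowest = TRUE)))
  list(
    statistic = unname(ks$statistic),
    p.value = ks$p.value,
    n = length(pvals),
    histogram = tibble::tibble(
      bin = seq_len(10L),
      lower = breaks[-11],
      upper = breaks[-1],
      count = counts
    )
  )
}
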