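#' Birth-death rate parameters for one tree
#'
#' Bundles the per-tree parameter triple of the constant-rate birth-death
#' model: speciation rate `lambda`, extinction rate `mu` (both per lineage per
#' unit time), and the known sampling fraction `rho`, the probability that an
#' extant species appears in the tree. `mu = 0` gives the Yule (pure-birth)
#' special case. `mu > lambda` (declining diversity) is permitted — the
#' likelihood remains valid — though it is rarely optimal in practice.
#'
#' @param lambda Speciation rate, `>= 0`.
#' @param mu Extinction rate, `>= 0`. Default 0.
#' @param rho Sampling fraction in `(0, 1]`. Default 1 (complete sampling).
#' @return An object of class `bd_params`.
#' @export
bd_params <- function(lambda, mu = 0, rho = 1) {
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) || lambda < 0) {
    stop("lambda must be a single number >= 0", call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu < 0) {
    stop("mu must be a single number >= 0", call. = FALSE)
  }
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || rho <= 0 || rho > 1) {
    stop("rho must be a single number in (0, 1]", call. = FALSE)
  }
  structure(list(lambda = lambda, mu = mu, rho = rho), class = "bd_params")
}

#' @export
print.bd_params <- function(x, ...) {
  cat(sprintf("bd_params: lambda = %g, mu = %g, rho = %g\n",
              x$lambda, x$mu, x$rho))
  invisible(x)
}

# Relative threshold below which |lambda - mu| is treated as the lambda == mu
# degenerate ridge and the analytic limit formulas are used.
.EQ_RATE_TOL <- 1e-9

# Shared denominator of p0/p1:  rho*lambda + (lambda*(1-rho) - mu) * exp(-r t).
# Everything here is vectorized over t.
.bd_denom <- function(t, lambda, mu, rho) {
  r <- lambda - mu
  rho * lambda + (lambda * (1 - rho) - mu) * exp(-r * t)
}

.near_equal_rates <- function(lambda, mu) {
  abs(lambda - mu) < .EQ_RATE_TOL * pmax(lambda, 1)
}

#' Probability that a lineage leaves no sampled descendant
#'
#' `p0(t)` is the probability that a single lineage alive at time `t` before
#' the present has no descendant in the sampled reconstructed tree (it either
#' goes extinct or all its extant descendants are unsampled):
#' \deqn{p_0(t) = 1 - \frac{\rho(\lambda-\mu)}
#'   {\rho\lambda + (\lambda(1-\rho)-\mu)e^{-(\lambda-\mu)t}}}
#' On the critical ridge \eqn{\lambda = \mu} the analytic limit
#' \eqn{1 - \rho/(1+\rho\lambda t)} is used.
#'
#' @param t Age(s) before the present, `>= 0`; vectorized.
#' @param params A [bd_params()] object.
#' @return Probability value(s) in `[0, 1)`.
#' @export
p0 <- function(t, params) {
  stopifnot(inherits(params, "bd_params"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  lambda <- params$lambda; mu <- params$mu; rho <- params$rho
  if (.near_equal_rates(lambda, mu)) {
    return(1 - rho / (1 + rho * lambda * t))
  }
  1 - rho * (lambda - mu) / .bd_denom(t, lambda, mu, rho)
}

#' Probability density contribution of a surviving lineage
#'
#' `p1(t)` is the probability that a lineage alive at time `t` before the
#' present leaves exactly one sampled descendant lineage in the reconstructed
#' tree:
#' \deqn{p_1(t) = \frac{\rho(\lambda-\mu)^2 e^{-(\lambda-\mu)t}}
#'   {\left[\rho\lambda + (\lambda(1-\rho)-\mu)e^{-(\lambda-\mu)t}\right]^2}}
#' with limit \eqn{\rho/(1+\rho\lambda t)^2} at \eqn{\lambda = \mu}.
#'
#' @inheritParams p0
#' @return Probability value(s) in `(0, 1]`.
#' @export
p1 <- function(t, params) {
  stopifnot(inherits(params, "bd_params"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  exp(.log_p1(t, params$lambda, params$mu, params$rho))
}

# log p1(t), computed on the log scale so that large lambda*t never underflows
# inside an optimization.
.log_p1 <- function(t, lambda, mu, rho) {
  if (.near_equal_rates(lambda, mu)) {
    return(log(rho) - 2 * log1p(rho * lambda * t))
  }
  r <- lambda - mu
  log(rho) + 2 * log(abs(r)) - r * t - 2 * log(abs(.bd_denom(t, lambda, mu, rho)))
}

# log(1 - p0(t)) via the algebraic form rho*r/denominator, avoiding the
# catastrophic cancellation of 1 - p0 when p0 -> 1.
.log_1mp0 <- function(t, lambda, mu, rho) {
  if (.near_equal_rates(lambda, mu)) {
    return(log(rho) - log1p(rho * lambda * t))
  }
  r <- lambda - mu
  log(rho) + log(abs(r)) - log(abs(.bd_denom(t, lambda, mu, rho)))
}

#' Crown-conditioned birth-death log-likelihood of one tree
#'
#' The log-likelihood of the ordered branching times of a reconstructed,
#' ultrametric tree under a constant-rate birth-death process with sampling
#' fraction `rho`, conditioned on the crown age (the depth of the most recent
#' common ancestor) and on both crown lineages leaving sampled descendants:
#' \deqn{\log L = \log((N-1)!) + 2\log p_1(t_1) - 2\log(1-p_0(t_1))
#'   + \sum_{j=2}^{N-1}\left[\log\lambda + \log p_1(t_j)\right]}
#' The factorial term uses the log-gamma function, so tip counts in the
#' thousands do not overflow, and all probability terms are evaluated on the
#' log scale.
#'
#' @param bt A [branching_times()] object (or a `phylo`, which is reduced
#'   first).
#' @param params A [bd_params()] object.
#' @return A single finite log-likelihood value; `-Inf` when `lambda = 0`
#'   with more than two tips (no branching events are possible).
#' @export
tree_loglik <- function(bt, params) {
  if (inherits(bt, "phylo")) bt <- branching_times(bt)
  stopifnot(inherits(bt, "branching_times"), inherits(params, "bd_params"))
  lambda <- params$lambda; mu <- params$mu; rho <- params$rho
  N <- bt$N
  t1 <- bt$t[1]
  if (lambda == 0 && N > 2L) return(-Inf)
  ll <- lgamma(N) + 2 * .log_p1(t1, lambda, mu, rho) -
    2 * .log_1mp0(t1, lambda, mu, rho)
  if (N > 2L) {
    tj <- bt$t[-1]
    ll <- ll + (N - 2L) * log(lambda) + sum(.log_p1(tj, lambda, mu, rho))
  }
  if (is.nan(ll)) {
    stop(sprintf(
      "non-finite log-likelihood at lambda=%g, mu=%g, rho=%g (N=%d, t1=%g)",
      lambda, mu, rho, N, t1), call. = FALSE)
  }
  ll
}

#' Bundle several trees with their sampling fractions
#'
#' @param trees A list of [branching_times()] objects and/or `phylo` trees
#'   (trees are reduced to branching times), or a single such object.
#' @param rhos Numeric vector of per-tree sampling fractions in `(0, 1]`,
#'   recycled from length 1; default 1 for every tree.
#' @return An object of class `multi_tree_data`: list with elements `trees`
#'   (list of `branching_times`), `rhos`, and `m` (number of trees).
#' @export
multi_tree_data <- function(trees, rhos = 1) {
  if (inherits(trees, c("phylo", "branching_times"))) trees <- list(trees)
  if (!is.list(trees) || length(trees) < 1L) {
    stop("trees must be a non-empty list", call. = FALSE)
  }
  trees <- lapply(trees, function(x) {
    if (inherits(x, "phylo")) branching_times(x)
    else if (inherits(x, "branching_times")) x
    else stop("each tree must be a 'phylo' or 'branching_times' object",
              call. = FALSE)
  })
  m <- length(trees)
  if (length(rhos) == 1L) rhos <- rep(rhos, m)
  if (length(rhos) != m) {
    stop("length of rhos (", length(rhos), ") does not match number of trees (",
         m, ")", call. = FALSE)
  }
  if (any(rhos <= 0 | rhos > 1)) {
    stop("all sampling fractions must lie in (0, 1]", call. = FALSE)
  }
  structure(list(trees = trees, rhos = as.numeric(rhos), m = m),
            class = "multi_tree_data")
}

#' @export
print.multi_tree_data <- function(x, ...) {
  cat("multi_tree_data:", x$m, "tree(s)\n")
  for (i in seq_len(x$m)) {
    cat(sprintf("  tree %d: N = %d, crown age = %g, rho = %g\n",
                i, x$trees[[i]]$N, x$trees[[i]]$t[1], x$rhos[i]))
  }
  invisible(x)
}

#' Joint log-likelihood across trees
#'
#' Because the trees are modeled as independent realizations, the joint
#' log-likelihood is the sum of the per-tree crown-conditioned
#' log-likelihoods, each with its own rate parameters and sampling fraction.
#'
#' @param data A [multi_tree_data()] object.
#' @param params_list A list of [bd_params()] objects, one per tree. The
#'   `rho` stored in each `bd_params` is overridden by the data's sampling
#'   fractions if they differ is an error; supply matching `rho`s.
#' @return The summed log-likelihood.
#' @export
joint_loglik <- function(data, params_list) {
  stopifnot(inherits(data, "multi_tree_data"))
  if (inherits(params_list, "bd_params")) params_list <- list(params_list)
  if (length(params_list) != data$m) {
    stop("need one bd_params per tree: got ", length(params_list),
         " for ", data$m, " trees", call. = FALSE)
  }
  total <- 0
  for (i in seq_len(data$m)) {
    p <- params_list[[i]]
    if (!isTRUE(all.equal(p$rho, data$rhos[i]))) {
      stop("rho mismatch for tree ", i, ": params say ", p$rho,
           ", data say ", data$rhos[i], call. = FALSE)
    }
    total <- total + tree_loglik(data$trees[[i]], p)
  }
  total
}

# Fast internal joint evaluation used by the optimizer: lambda/mu vectors give
# the per-tree rates (already expanded from the model's constraint map).
# Skips class checks and rho reconciliation.
.joint_loglik_fast <- function(data, lambda, mu) {
  total <- 0
  for (i in seq_len(data$m)) {
    bt <- data$trees[[i]]
    li <- lambda[i]; mi <- mu[i]; ri <- data$rhos[i]
    if (li == 0 && bt$N > 2L) return(-Inf)
    t1 <- bt$t[1]
    ll <- lgamma(bt$N) + 2 * .log_p1(t1, li, mi, ri) - 2 * .log_1mp0(t1, li, mi, ri)
    if (bt$N > 2L) {
      ll <- ll + (bt$N - 2L) * log(li) + sum(.log_p1(bt$t[-1], li, mi, ri))
    }
    total <- total + ll
  }
  total
}
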