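#' Optimizer controls for model fitting
#'
#' @param n_restarts Number of multiplicatively jittered restarts (factor
#'   `exp(U(-1, 1))` applied to each starting rate) for the Nelder-Mead
#'   searches used by models with jointly estimated (lambda, mu) blocks.
#' @param reltol Relative convergence tolerance on the log-likelihood.
#' @param seed Optional integer seed for the restart jitter, making fits
#'   reproducible independently of the caller's RNG state.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(n_restarts = 5, reltol = 1e-8, seed = NULL) {
  stopifnot(n_restarts >= 1, reltol > 0)
  structure(list(n_restarts = as.integer(n_restarts), reltol = reltol,
                 seed = seed),
            class = "fit_control")
}

# Half-width, on the log scale, of the search bracket around the heuristic
# starting rate used by the one-dimensional golden-section searches.
.BRACKET_HALFWIDTH <- 8
# Floor for positive extinction rates on the log scale; mu = 0 itself is
# handled as an explicit boundary profile, so the floor only needs to keep
# log(mu) finite during the search.
.MU_FLOOR <- 1e-10

#' Heuristic starting rates for a model fit
#'
#' For each speciation-rate class, the start is the growth rate that a
#' pure-birth clade would need to reach the class's mean tip count in its
#' mean crown age: `lambda0 = max(log(Nbar/2)/Tbar, 1e-6)`. Extinction starts
#' at a quarter of that (`0` for Yule models), i.e. a moderate extinction
#' fraction.
#'
#' @param data A [multi_tree_data()] object.
#' @param model A [model_spec()].
#' @return List with numeric vectors `lambda0` (one per speciation-rate
#'   class) and `mu0` (one per extinction-rate class; `numeric(0)` for Yule
#'   models).
#' @export
init_params <- function(data, model) {
  stopifnot(inherits(data, "multi_tree_data"), inherits(model, "model_spec"))
  if (model$m != data$m) stop("model is for ", model$m, " trees but data have ",
                              data$m, call. = FALSE)
  Ns <- vapply(data$trees, function(b) b$N, integer(1))
  Ts <- vapply(data$trees, function(b) b$t[1], numeric(1))
  class_start <- function(classes) {
    vapply(sort(unique(classes[classes > 0L])), function(cl) {
      idx <- classes == cl
      max(log(mean(Ns[idx]) / 2) / mean(Ts[idx]), 1e-6)
    }, numeric(1))
  }
  lambda0 <- class_start(model$lambda_class)
  if (all(model$mu_class == 0L)) {
    mu0 <- numeric(0)
  } else {
    # extinction classes borrow the lambda start of the trees they cover
    mu0 <- vapply(sort(unique(model$mu_class)), function(cl) {
      idx <- model$mu_class == cl
      max(log(mean(Ns[idx]) / 2) / mean(Ts[idx]), 1e-6) / 4
    }, numeric(1))
  }
  list(lambda0 = lambda0, mu0 = mu0)
}

#' Closed-form Yule maximum-likelihood estimate
#'
#' For a completely sampled pure-birth tree, the speciation rate has the
#' closed form `lambda_hat = (N - 2) / (2 t1 + sum_{j>=2} t_j)`; the crown
#' age is counted twice because both crown lineages persist over it. Used as
#' an internal analytic oracle for the numerical optimizer.
#'
#' @param bt A [branching_times()] object (or `phylo`).
#' @return List with `lambda` (the MLE), `loglik` (log-likelihood at the
#'   MLE), and `boundary` (`TRUE` for the degenerate two-tip case, where the
#'   MLE is the boundary value `lambda = 0`).
#' @export
yule_mle <- function(bt) {
  if (inherits(bt, "phylo")) bt <- branching_times(bt)
  stopifnot(inherits(bt, "branching_times"))
  if (bt$N == 2L) {
    return(list(lambda = 0, loglik = 0, boundary = TRUE))
  }
  lam <- (bt$N - 2) / (2 * bt$t[1] + sum(bt$t[-1]))
  list(lambda = lam,
       loglik = tree_loglik(bt, bd_params(lam, 0, 1)),
       boundary = FALSE)
}

# ---- internal optimization machinery ---------------------------------------

.subset_data <- function(data, idx) {
  structure(list(trees = data$trees[idx], rhos = data$rhos[idx],
                 m = length(idx)),
            class = "multi_tree_data")
}

# Builds a fast closure computing the penalized negative joint log-likelihood
# of the trees in `idx` under one shared (lambda, mu) pair. All per-tree
# constants (factorial terms, concatenated age vectors, per-age sampling
# fractions) are precomputed so each evaluation is a handful of vectorized
# operations — the optimizers call this thousands of times per experiment.
.block_negll_fun <- function(data, idx) {
  bts <- data$trees[idx]
  rhos <- data$rhos[idx]
  Ns <- vapply(bts, function(b) b$N, integer(1))
  t1 <- vapply(bts, function(b) b$t[1], numeric(1))
  rho1 <- rhos
  tj <- unlist(lapply(bts, function(b) b$t[-1]), use.names = FALSE)
  rhoj <- rep(rhos, times = Ns - 2L)
  n_branch <- sum(Ns - 2L)
  any_big <- any(Ns > 2L)
  m_blk <- length(idx)
  sum_t1 <- sum(t1)
  sum_tj <- sum(tj)
  # the sampling fractions are data, so their log contributions are constant:
  # the crown term p1(t1)^2 / (1-p0(t1))^2 is rho-free, and each branching
  # term contributes log(rho_j) once
  const <- sum(lgamma(Ns)) + sum(log(rhoj))
  function(lambda, mu) {
    if (lambda == 0 && any_big) return(1e12)
    if (abs(lambda - mu) < .EQ_RATE_TOL * max(lambda, 1)) {
      ll <- const - 2 * sum(log1p(rho1 * lambda * t1))
      if (n_branch > 0L) {
        ll <- ll + n_branch * log(lambda) - 2 * sum(log1p(rhoj * lambda * tj))
      }
    } else {
      r <- lambda - mu
      lar <- log(abs(r))
      d1 <- rho1 * lambda + (lambda * (1 - rho1) - mu) * exp(-r * t1)
      ll <- const + 2 * (m_blk * lar - r * sum_t1 - sum(log(abs(d1))))
      if (n_branch > 0L) {
        dj <- rhoj * lambda + (lambda * (1 - rhoj) - mu) * exp(-r * tj)
        ll <- ll + n_branch * (log(lambda) + 2 * lar) - r * sum_tj -
          2 * sum(log(abs(dj)))
      }
    }
    if (!is.finite(ll)) return(1e12)
    -ll
  }
}

# 1-D maximization over log(lambda) with mu fixed, for a precompiled block
# objective. `warm` adds candidate lambda values that are evaluated and can
# beat the golden-section result (used to guarantee nested fits dominate
# their nulls).
.max_lambda_block <- function(f, mu, lambda0, warm = NULL) {
  ctr <- log(lambda0)
  opt <- stats::optimize(function(loglam) f(exp(loglam), mu),
                         interval = c(ctr - .BRACKET_HALFWIDTH,
                                      ctr + .BRACKET_HALFWIDTH),
                         tol = 1e-8)
  best <- list(lambda = exp(opt$minimum), negll = opt$objective)
  for (w in warm) {
    if (!is.null(w) && is.finite(w) && w > 0) {
      v <- f(w, mu)
      if (v < best$negll) best <- list(lambda = w, negll = v)
    }
  }
  best
}

# 1-D maximization over mu >= 0 with lambda fixed: golden section on log(mu)
# plus the explicit mu = 0 boundary.
.max_mu_block <- function(f, lambda, mu0, warm = NULL) {
  ctr <- log(max(mu0, .MU_FLOOR))
  opt <- stats::optimize(function(logmu) f(lambda, exp(logmu)),
                         interval = c(ctr - .BRACKET_HALFWIDTH,
                                      ctr + .BRACKET_HALFWIDTH),
                         tol = 1e-8)
  best <- list(mu = exp(opt$minimum), negll = opt$objective)
  v0 <- f(lambda, 0)
  if (v0 <= best$negll) best <- list(mu = 0, negll = v0)
  for (w in warm) {
    if (!is.null(w) && is.finite(w) && w >= 0) {
      v <- f(lambda, w)
      if (v < best$negll) best <- list(mu = w, negll = v)
    }
  }
  best
}

# Joint (lambda, mu) maximization for a block of trees sharing both rates:
# Nelder-Mead on (log lambda, log mu) from jittered restarts, an explicit
# mu = 0 profile, and optional warm-start candidates evaluated directly.
.fit_block <- function(fblock, lambda0, mu0, control, warm = NULL) {
  f <- function(par) fblock(exp(par[1]), exp(par[2]))
  start0 <- c(log(lambda0), log(max(mu0, .MU_FLOOR)))
  starts <- list(start0)
  if (!is.null(warm) && all(is.finite(warm)) && warm[1] > 0) {
    starts <- c(starts, list(c(log(warm[1]), log(max(warm[2], .MU_FLOOR)))))
  }
  n_extra <- max(control$n_restarts - 1L, 0L)
  for (r in seq_len(n_extra)) {
    starts <- c(starts, list(start0 + stats::runif(2, -1, 1)))
  }
  best <- NULL
  for (s in starts) {
    res <- stats::optim(s, f, method = "Nelder-Mead",
                        control = list(reltol = control$reltol, maxit = 1000))
    cand <- list(lambda = exp(res$par[1]), mu = exp(res$par[2]),
                 negll = res$value, converged = res$convergence == 0,
                 evals = res$counts[[1]])
    if (is.null(best) || cand$negll < best$negll ||
        (cand$negll == best$negll && cand$evals < best$evals)) {
      best <- cand
    }
  }
  # mu = 0 boundary profile: the extinction MLE frequently sits on the
  # boundary, which Nelder-Mead on log(mu) can only approach asymptotically
  b <- .max_lambda_block(fblock, 0, lambda0,
                         warm = list(best$lambda,
                                     if (!is.null(warm)) warm[1]))
  if (b$negll <= best$negll) {
    best <- list(lambda = b$lambda, mu = 0, negll = b$negll,
                 converged = TRUE, evals = best$evals)
  }
  # exact warm-point evaluation guarantees the fit dominates any supplied
  # nested solution
  if (!is.null(warm) && all(is.finite(warm))) {
    v <- fblock(warm[1], warm[2])
    if (v < best$negll) {
      best <- list(lambda = warm[1], mu = warm[2], negll = v,
                   converged = TRUE, evals = best$evals)
    }
  }
  best$n_restarts_used <- length(starts)
  best
}

# Profile fit for models with one shared rate and the other rate free:
# `shared` names the shared rate. The profile log-likelihood in the shared
# rate is maximized by a grid-plus-golden-section search (with an explicit
# mu = 0 boundary when mu is shared); at each profile point the free rates
# separate into independent 1-D problems per class.
.fit_profile <- function(data, model, inits, control, warm = NULL,
                         shared = c("mu", "lambda")) {
  shared <- match.arg(shared)
  if (shared == "mu") {
    free_classes <- model$lambda_class
    class_ids <- sort(unique(free_classes))
    funs <- lapply(class_ids, function(cl)
      .block_negll_fun(data, which(free_classes == cl)))
    warm_lam <- lapply(class_ids, function(cl)
      if (!is.null(warm)) warm$lambda[which(free_classes == cl)[1]])
    inner <- function(mu) {
      tot <- 0; est <- numeric(length(class_ids))
      for (ci in seq_along(class_ids)) {
        r <- .max_lambda_block(funs[[ci]], mu, inits$lambda0[ci],
                               warm = warm_lam[ci])
        tot <- tot + r$negll; est[ci] <- r$lambda
      }
      list(negll = tot, est = est)
    }
    center <- max(inits$mu0[1], 1e-6)
    grid <- center * exp(c(-6, -4, -2, 0, 2))
    if (!is.null(warm) && warm$mu[1] > 0) grid <- c(grid, warm$mu[1])
    cand <- c(0, grid)
  } else {
    free_classes <- model$mu_class
    class_ids <- sort(unique(free_classes))
    funs <- lapply(class_ids, function(cl)
      .block_negll_fun(data, which(free_classes == cl)))
    warm_mu <- lapply(class_ids, function(cl)
      if (!is.null(warm)) warm$mu[which(free_classes == cl)[1]])
    inner <- function(lam) {
      tot <- 0; est <- numeric(length(class_ids))
      for (ci in seq_along(class_ids)) {
        r <- .max_mu_block(funs[[ci]], lam, inits$mu0[ci], warm = warm_mu[ci])
        tot <- tot + r$negll; est[ci] <- r$mu
      }
      list(negll = tot, est = est)
    }
    center <- inits$lambda0[1]
    grid <- center * exp(c(-2, -1, 0, 1, 2))
    if (!is.null(warm)) grid <- c(grid, warm$lambda[1])
    cand <- grid
  }
  vals <- vapply(cand, function(x) inner(x)$negll, numeric(1))
  best_x <- cand[which.min(vals)]
  # polish around the best positive grid point
  polish_center <- if (best_x > 0) best_x else max(center, .MU_FLOOR)
  opt <- stats::optimize(function(lx) inner(exp(lx))$negll,
                         interval = log(polish_center) + c(-2.5, 2.5),
                         tol = 1e-8)
  if (opt$objective < min(vals)) {
    best_x <- exp(opt$minimum)
  }
  res <- inner(best_x)
  list(shared_value = best_x, free_values = res$est,
       class_ids = class_ids, negll = res$negll)
}

#' Fit a multi-tree birth-death rate model by maximum likelihood
#'
#' Maximizes the summed crown-conditioned birth-death log-likelihood over the
#' rates allowed to vary under `model`, with sampling fractions held fixed at
#' the values stored in `data`. Rates are optimized on the log scale;
#' extinction boundaries (`mu = 0`) are handled by explicit boundary
#' profiles, so Yule-like solutions are attainable. Models whose rate classes
#' separate (equal, free, grouped, Yule variants) are fitted blockwise;
#' models with a single shared rate (`free-speciation`, `free-extinction`)
#' are fitted by profile likelihood over the shared rate.
#'
#' @param data A [multi_tree_data()] object (or list of trees, which is
#'   wrapped with `rho = 1`).
#' @param model A [model_spec()], or a model name which is expanded with
#'   `m = data$m`.
#' @param control A [fit_control()] list.
#' @param warm_start Optional list with numeric vectors `lambda` and `mu`
#'   (length `m`, per-tree expanded rates) used as additional starting
#'   values/candidates; supplying the maximum-likelihood solution of a nested
#'   model guarantees the fitted log-likelihood is at least as high.
#' @return An object of class `bd_fit`: list with `model`, `estimates` (a
#'   tibble with one row per tree: `tree`, `lambda`, `mu`, `rho`), `loglik`,
#'   `k`, `converged`, and `n_restarts_used`.
#' @export
fit_model <- function(data, model, control = fit_control(),
                      warm_start = NULL) {
  if (!inherits(data, "multi_tree_data")) data <- multi_tree_data(data)
  if (is.character(model)) model <- model_spec(model, m = data$m)
  stopifnot(inherits(model, "model_spec"), inherits(control, "fit_control"))
  if (model$m != data$m) {
    stop("model is for ", model$m, " trees but data have ", data$m,
         call. = FALSE)
  }
  if (any(vapply(data$trees, function(b) b$N, integer(1)) < 2L)) {
    stop("every tree must have at least 2 tips", call. = FALSE)
  }
  if (!is.null(control$seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(control$seed)
  }
  inits <- init_params(data, model)
  lam_hat <- numeric(data$m)
  mu_hat <- numeric(data$m)
  converged <- TRUE
  restarts_used <- 1L

  if (all(model$mu_class == 0L)) {
    # Yule family: independent 1-D fits per speciation class
    total <- 0
    cls <- sort(unique(model$lambda_class))
    for (ci in seq_along(cls)) {
      idx <- which(model$lambda_class == cls[ci])
      r <- .max_lambda_block(.block_negll_fun(data, idx), 0,
                             inits$lambda0[ci],
                             warm = list(if (!is.null(warm_start))
                               warm_start$lambda[idx[1]]))
      lam_hat[idx] <- r$lambda
      total <- total - r$negll
    }
    loglik <- total
  } else if (identical(model$lambda_class, model$mu_class)) {
    # equal / free / grouped: independent (lambda, mu) blocks
    total <- 0
    cls <- sort(unique(model$lambda_class))
    for (ci in seq_along(cls)) {
      idx <- which(model$lambda_class == cls[ci])
      w <- if (!is.null(warm_start)) {
        c(warm_start$lambda[idx[1]], warm_start$mu[idx[1]])
      }
      r <- .fit_block(.block_negll_fun(data, idx), inits$lambda0[ci],
                      inits$mu0[ci], control, warm = w)
      lam_hat[idx] <- r$lambda
      mu_hat[idx] <- r$mu
      total <- total - r$negll
      converged <- converged && r$converged
      restarts_used <- max(restarts_used, r$n_restarts_used)
    }
    loglik <- total
  } else if (model$name == "free-speciation") {
    r <- .fit_profile(data, model, inits, control, warm = warm_start,
                      shared = "mu")
    mu_hat[] <- r$shared_value
    for (ci in seq_along(r$class_ids)) {
      lam_hat[model$lambda_class == r$class_ids[ci]] <- r$free_values[ci]
    }
    loglik <- -r$negll
  } else if (model$name == "free-extinction") {
    r <- .fit_profile(data, model, inits, control, warm = warm_start,
                      shared = "lambda")
    lam_hat[] <- r$shared_value
    for (ci in seq_along(r$class_ids)) {
      mu_hat[model$mu_class == r$class_ids[ci]] <- r$free_values[ci]
    }
    loglik <- -r$negll
  } else {
    stop("unhandled model structure: ", model$name, call. = FALSE)
  }

  # a warm start from a nested model must never beat the richer fit; keep the
  # better point if numerical search fell short
  if (!is.null(warm_start)) {
    wll <- .joint_loglik_fast(data, warm_start$lambda, warm_start$mu)
    if (is.finite(wll) && wll > loglik) {
      ok <- .warm_feasible(model, warm_start)
      if (ok) {
        lam_hat <- warm_start$lambda
        mu_hat <- warm_start$mu
        loglik <- wll
      }
    }
  }

  structure(list(
    model = model,
    estimates = tibble::tibble(tree = seq_len(data$m), lambda = lam_hat,
                               mu = mu_hat, rho = data$rhos),
    loglik = loglik,
    k = model$k,
    converged = converged,
    n_restarts_used = restarts_used
  ), class = "bd_fit")
}

# Is a per-tree expanded (lambda, mu) assignment representable under `model`?
.warm_feasible <- function(model, warm) {
  ok_lam <- all(tapply(warm$lambda, model$lambda_class,
                       function(v) diff(range(v)) == 0))
  ok_mu <- if (all(model$mu_class == 0L)) {
    all(warm$mu == 0)
  } else {
    all(tapply(warm$mu, model$mu_class, function(v) diff(range(v)) == 0))
  }
  isTRUE(ok_lam) && isTRUE(ok_mu)
}

#' @export
print.bd_fit <- function(x, ...) {
  cat(sprintf("Birth-death model fit: '%s' (k = %d), logLik = %.4f%s\n",
              x$model$name, x$k, x$loglik,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  print(x$estimates, n = Inf)
  invisible(x)
}

#' @export
logLik.bd_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' Serialize a model fit to JSON
#'
#' @param x A `bd_fit` object.
#' @return A JSON string (estimates table, log-likelihood, parameter count).
#' @export
fit_to_json <- function(x) {
  stopifnot(inherits(x, "bd_fit"))
  jsonlite::toJSON(list(
    model = x$model$name,
    k = x$k,
    loglik = x$loglik,
    converged = x$converged,
    estimates = x$estimates
  ), auto_unbox = TRUE, digits = NA)
}
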