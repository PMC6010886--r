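#' @name experiments
#' @title Simulation experiments: type-I error, power, estimation accuracy
#'
#' @description
#' Scripted simulation studies of the multi-tree rate-comparison method.
#' Each experiment simulates replicate tree sets under known rates, fits the
#' equal-rates null and one or more alternative models to every replicate,
#' performs the likelihood-ratio tests, and summarizes rejection rates at
#' `alpha = 0.05` per condition, with exact binomial tests against the
#' nominal level and Kolmogorov-Smirnov checks of p-value uniformity.
#'
#' All experiments derive one RNG stream per replicate from `seed`, so any
#' run is bit-reproducible and individual replicates can be re-examined in
#' isolation.
#'
#' @param reps Number of replicates per condition.
#' @param seed Base RNG seed.
#' @param min_tips Minimum extant tip count for accepting a simulated tree.
#' @param control A [fit_control()] passed to every fit.
#' @return An object of class `rates_experiment`: list with `name`,
#'   `conditions` (tibble of the parameter grid), `per_replicate` (tibble
#'   with one row per replicate x alternative model: seeds, per-tree tip
#'   counts, log-likelihoods, LRT statistic/df/p, and the alternative
#'   model's rate estimates), and `summary` (per condition x model:
#'   rejection rate at `alpha = 0.05` with Monte-Carlo standard error,
#'   one-sided binomial p-value against the nominal 0.05, KS uniformity
#'   p-value, and mean/SD of each rate estimate).
NULL

.ALPHA <- 0.05

# One birth-death replicate: simulate a tree per row of `grid` (columns
# lambda, mu, depth, rho), fit the null and each alternative (warm-started
# from the null), and return one result row per alternative.
.bd_replicate <- function(grid, null_name, alts, min_tips, control) {
  trees <- lapply(seq_len(nrow(grid)), function(i) {
    simulate_crown_bd(grid$lambda[i], grid$mu[i], depth = grid$depth[i],
                      rho = grid$rho[i], min_tips = min_tips)
  })
  data <- multi_tree_data(trees, rhos = grid$rho)
  .fit_and_test(data, null_name, alts, control)
}

.fit_and_test <- function(data, null_name, alts, control) {
  null_fit <- fit_model(data, null_name, control)
  warm <- list(lambda = null_fit$estimates$lambda,
               mu = null_fit$estimates$mu)
  Ns <- vapply(data$trees, function(b) b$N, integer(1))
  lapply(alts, function(alt) {
    alt_fit <- fit_model(data, alt, control, warm_start = warm)
    test <- lrt(null_fit, alt_fit)
    list(model = alt, loglik_null = null_fit$loglik,
         loglik_alt = alt_fit$loglik, statistic = test$statistic,
         df = test$df, p = test$p, n_tips = Ns,
         lambda_hat = alt_fit$estimates$lambda,
         mu_hat = alt_fit$estimates$mu)
  })
}

# Assemble replicate result rows (as produced above) into the per-replicate
# tibble; per-tree vectors become n_tips "a;b;c" strings plus wide
# lambda_hat_i / mu_hat_i columns padded with NA across conditions of
# different tree counts.
.bind_replicates <- function(rows) {
  max_m <- max(vapply(rows, function(r) length(r$res$n_tips), integer(1)))
  tibble_rows <- lapply(rows, function(r) {
    res <- r$res
    m <- length(res$n_tips)
    pad <- function(v) c(v, rep(NA_real_, max_m - m))
    est <- c(stats::setNames(as.list(pad(res$lambda_hat)),
                             paste0("lambda_hat_", seq_len(max_m))),
             stats::setNames(as.list(pad(res$mu_hat)),
                             paste0("mu_hat_", seq_len(max_m))))
    tibble::tibble(
      condition = r$condition, replicate = r$replicate, seed = r$seed,
      model = res$model, n_tips = paste(res$n_tips, collapse = ";"),
      loglik_null = res$loglik_null, loglik_alt = res$loglik_alt,
      statistic = res$statistic, df = res$df, p = res$p,
      !!!est
    )
  })
  dplyr::bind_rows(tibble_rows)
}

.summarize_experiment <- function(per_replicate) {
  est_cols <- grep("^(lambda|mu)_hat_", names(per_replicate), value = TRUE)
  per_replicate |>
    dplyr::group_by(.data$condition, .data$model) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      rejections = sum(.data$p < .ALPHA),
      rejection_rate = rejections / n_reps,
      mc_se = sqrt(rejection_rate * (1 - rejection_rate) / n_reps),
      binom_p = binomial_exceedance_test(rejections[1], n_reps[1], .ALPHA),
      ks_p = pvalue_uniformity(.data$p)$p.value,
      dplyr::across(dplyr::all_of(est_cols),
                    list(mean = ~mean(.x), sd = ~stats::sd(.x))),
      .groups = "drop"
    )
}

.new_experiment <- function(name, conditions, rows, reps, seed, min_tips) {
  per_replicate <- .bind_replicates(rows)
  structure(list(
    name = name,
    conditions = conditions,
    per_replicate = per_replicate,
    summary = .summarize_experiment(per_replicate),
    reps = reps, seed = seed, min_tips = min_tips, alpha = .ALPHA
  ), class = "rates_experiment")
}

#' @export
print.rates_experiment <- function(x, ...) {
  cat(sprintf("Simulation experiment '%s': %d replicate(s)/condition, seed %d\n",
              x$name, x$reps, x$seed))
  cat("Summary (alpha = 0.05):\n")
  print(x$summary, n = Inf)
  invisible(x)
}

#' Type-I error of the rate-comparison tests on equal-rate tree sets
#'
#' Simulates sets of trees under identical rates chosen to hit target
#' expected richnesses at a fixed extinction fraction and depth, then tests
#' each alternative model against the equal-rates null. Any rejection is a
#' type-I error.
#'
#' @rdname experiments
#' @param en Target expected tip counts `E(N)` defining the conditions.
#' @param depth Tree depth T.
#' @param extinction_fraction Shared `mu / lambda`.
#' @param n_trees Trees per replicate set.
#' @param alts Alternative models tested against the `"equal"` null.
#' @export
run_null_grid <- function(reps = 500, seed = 1,
                          en = c(20, 50, 100, 200, 500),
                          depth = 100, extinction_fraction = 0.25,
                          n_trees = 3, min_tips = 5,
                          alts = c("free", "free-speciation",
                                   "free-extinction"),
                          control = fit_control()) {
  conditions <- tibble::tibble(
    condition = paste0("EN=", en),
    en = en,
    lambda = vapply(en, function(x)
      rates_from_EN(x, depth, extinction_fraction)$lambda, numeric(1)),
    mu = extinction_fraction *
      vapply(en, function(x)
        rates_from_EN(x, depth, extinction_fraction)$lambda, numeric(1)),
    depth = depth, n_trees = n_trees
  )
  rows <- list()
  for (ci in seq_len(nrow(conditions))) {
    grid <- tibble::tibble(lambda = conditions$lambda[ci],
                           mu = conditions$mu[ci],
                           depth = depth, rho = 1)[rep(1, n_trees), ]
    for (r in seq_len(reps)) {
      rseed <- .derive_seed(seed, 1000000 * ci + r)
      set.seed(rseed)
      for (res in .bd_replicate(grid, "equal", alts, min_tips, control)) {
        rows[[length(rows) + 1L]] <- list(
          condition = conditions$condition[ci], replicate = r,
          seed = rseed, res = res)
      }
    }
  }
  .new_experiment("null-grid", conditions, rows, reps, seed, min_tips)
}

#' Type-I error with unequal tree depths
#'
#' Pairs of trees share identical rates but differ in total depth, so their
#' expected sizes differ; rejections of the equal-rates null are type-I
#' errors.
#'
#' @rdname experiments
#' @param lambda,mu Shared rates of both trees.
#' @param depths Length-2 vector of tree depths.
#' @export
run_unequal_depth <- function(reps = 500, seed = 1, lambda = 0.052,
                              mu = 0.013, depths = c(100, 141.14),
                              min_tips = 5,
                              alts = c("free", "free-speciation",
                                       "free-extinction"),
                              control = fit_control()) {
  conditions <- tibble::tibble(
    condition = "unequal-depth", lambda = lambda, mu = mu,
    depth1 = depths[1], depth2 = depths[2]
  )
  grid <- tibble::tibble(lambda = lambda, mu = mu, depth = depths, rho = 1)
  rows <- list()
  for (r in seq_len(reps)) {
    rseed <- .derive_seed(seed, r)
    set.seed(rseed)
    for (res in .bd_replicate(grid, "equal", alts, min_tips, control)) {
      rows[[length(rows) + 1L]] <- list(condition = "unequal-depth",
                                        replicate = r, seed = rseed,
                                        res = res)
    }
  }
  .new_experiment("unequal-depth", conditions, rows, reps, seed, min_tips)
}

#' Power and parameter estimation when rates genuinely differ
#'
#' Simulates pairs of trees whose speciation rate, extinction rate, or both
#' differ, fits the generating alternative model and the equal-rates null,
#' and records power (rejection rate) and the alternative model's rate
#' estimates.
#'
#' @rdname experiments
#' @param which Which rate differs between the paired trees:
#'   `"speciation"` (tree 1 at `lambda = 0.052`, tree 2 across
#'   `lambda2`, shared `mu = 0.013`; alternative `"free-speciation"`),
#'   `"extinction"` (shared `lambda = 0.075`, per-tree extinction solved
#'   from the `en2` targets; alternative `"free-extinction"`), or
#'   `"both"` (both rates solved from crossing richness targets and
#'   extinction fractions; alternative `"free"`).
#' @param lambda2 Speciation-rate grid for tree 2 (`which = "speciation"`).
#' @param en2 Expected-richness targets for tree 2 (`which = "extinction"`
#'   and `"both"`).
#' @export
run_power_sweep <- function(which = c("speciation", "extinction", "both"),
                            reps = 500, seed = 1,
                            lambda2 = c(0.045, 0.052, 0.059, 0.068, 0.075),
                            en2 = c(50, 100, 200, 500, 1000),
                            depth = 100, min_tips = 5,
                            control = fit_control()) {
  which <- match.arg(which)
  if (which == "speciation") {
    conditions <- tibble::tibble(
      condition = paste0("lambda2=", lambda2),
      lambda1 = 0.052, lambda2 = lambda2, mu1 = 0.013, mu2 = 0.013,
      depth = depth
    )
    alt <- "free-speciation"
  } else if (which == "extinction") {
    lam <- 0.075
    mu1 <- lam - log(100 / 2) / depth
    mu2 <- lam - log(en2 / 2) / depth
    if (any(mu2 < 0)) stop("infeasible extinction solution (mu < 0) for EN2 = ",
                           paste(en2[mu2 < 0], collapse = ", "), call. = FALSE)
    conditions <- tibble::tibble(
      condition = paste0("EN2=", en2),
      lambda1 = lam, lambda2 = lam, mu1 = mu1, mu2 = mu2, depth = depth
    )
    alt <- "free-extinction"
  } else {
    # tree 1 climbs the richness ladder while tree 2 descends it, with
    # crossing extinction fractions
    en1 <- en2
    en2 <- rev(en1)
    eps1 <- seq(0.35, 0.15, length.out = length(en1))
    eps2 <- rev(eps1)
    r1 <- Map(rates_from_EN, en1, depth, eps1)
    r2 <- Map(rates_from_EN, en2, depth, eps2)
    conditions <- tibble::tibble(
      condition = paste0("EN1=", en1, ",EN2=", en2),
      lambda1 = vapply(r1, `[[`, numeric(1), "lambda"),
      lambda2 = vapply(r2, `[[`, numeric(1), "lambda"),
      mu1 = vapply(r1, `[[`, numeric(1), "mu"),
      mu2 = vapply(r2, `[[`, numeric(1), "mu"),
      depth = depth
    )
    alt <- "free"
  }
  rows <- list()
  for (ci in seq_len(nrow(conditions))) {
    grid <- tibble::tibble(
      lambda = c(conditions$lambda1[ci], conditions$lambda2[ci]),
      mu = c(conditions$mu1[ci], conditions$mu2[ci]),
      depth = depth, rho = 1
    )
    for (r in seq_len(reps)) {
      rseed <- .derive_seed(seed, 1000000 * ci + r)
      set.seed(rseed)
      for (res in .bd_replicate(grid, "equal", alt, min_tips, control)) {
        rows[[length(rows) + 1L]] <- list(
          condition = conditions$condition[ci], replicate = r,
          seed = rseed, res = res)
      }
    }
  }
  .new_experiment(paste0("power-", which), conditions, rows, reps, seed,
                  min_tips)
}

#' Power as a function of the number of trees
#'
#' One tree diversifies faster (`lambda = 0.067`) than the remaining
#' `n - 1` trees (`lambda = 0.056`, shared `mu = 0.017`); the
#' variable-speciation model is tested against the equal-rates null for
#' increasing numbers of trees.
#'
#' @rdname experiments
#' @param n_trees_list Total tree counts `n` to sweep over.
#' @export
run_multitree <- function(reps = 500, seed = 1, n_trees_list = 2:11,
                          min_tips = 5, control = fit_control()) {
  stopifnot(all(n_trees_list >= 2))
  conditions <- tibble::tibble(
    condition = paste0("n=", n_trees_list),
    n_trees = n_trees_list,
    lambda1 = 0.067, lambda_rest = 0.056, mu = 0.017, depth = 100
  )
  rows <- list()
  for (ci in seq_len(nrow(conditions))) {
    n <- conditions$n_trees[ci]
    grid <- tibble::tibble(
      lambda = c(0.067, rep(0.056, n - 1L)),
      mu = 0.017, depth = 100, rho = 1
    )
    for (r in seq_len(reps)) {
      rseed <- .derive_seed(seed, 1000000 * ci + r)
      set.seed(rseed)
      for (res in .bd_replicate(grid, "equal", "free-speciation",
                                min_tips, control)) {
        rows[[length(rows) + 1L]] <- list(
          condition = conditions$condition[ci], replicate = r,
          seed = rseed, res = res)
      }
    }
  }
  .new_experiment("multitree", conditions, rows, reps, seed, min_tips)
}

#' Power for small pure-birth trees of fixed size
#'
#' Pairs of Yule trees with a two-fold speciation-rate difference
#' (`lambda = 0.04` vs `0.08`), each conditioned jointly on its tip count
#' `N` and on the depth `T_i = log(N/2) / lambda_i` that makes `N` the
#' expected richness — so every replicate has identical N and depth. The
#' Yule variable-speciation model is tested against the Yule equal-rate
#' null (df = 1).
#'
#' @rdname experiments
#' @param n_grid Tip counts N to sweep over.
#' @param lambdas Length-2 vector of the two trees' speciation rates.
#' @export
run_yule_small <- function(reps = 500, seed = 1,
                           n_grid = c(5, 10, 20, 40, 80),
                           lambdas = c(0.04, 0.08),
                           control = fit_control()) {
  stopifnot(all(n_grid >= 3), length(lambdas) == 2)
  conditions <- tibble::tibble(
    condition = paste0("N=", n_grid),
    n = n_grid,
    lambda1 = lambdas[1], lambda2 = lambdas[2],
    depth1 = log(n_grid / 2) / lambdas[1],
    depth2 = log(n_grid / 2) / lambdas[2]
  )
  rows <- list()
  for (ci in seq_len(nrow(conditions))) {
    n <- conditions$n[ci]
    for (r in seq_len(reps)) {
      rseed <- .derive_seed(seed, 1000000 * ci + r)
      set.seed(rseed)
      trees <- list(
        simulate_yule_NT(lambdas[1], n, conditions$depth1[ci]),
        simulate_yule_NT(lambdas[2], n, conditions$depth2[ci])
      )
      data <- multi_tree_data(trees)
      for (res in .fit_and_test(data, "yule-equal", "yule-free", control)) {
        rows[[length(rows) + 1L]] <- list(
          condition = conditions$condition[ci], replicate = r,
          seed = rseed, res = res)
      }
    }
  }
  .new_experiment("yule-small", conditions, rows, reps, seed, min_tips = NA)
}

#' Write an experiment's tables to disk
#'
#' Writes `<name>_replicates.csv`, `<name>_summary.csv`, and
#' `<name>_metadata.json` (software version, seed, replicate count,
#' conditions, and settings in effect) into `dir`.
#'
#' @param x A `rates_experiment`.
#' @param dir Output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
write_experiment <- function(x, dir = ".") {
  stopifnot(inherits(x, "rates_experiment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, gsub("[^a-z0-9-]", "-", x$name))
  paths <- c(
    replicates = paste0(base, "_replicates.csv"),
    summary = paste0(base, "_summary.csv"),
    metadata = paste0(base, "_metadata.json")
  )
  utils::write.csv(x$per_replicate, paths["replicates"], row.names = FALSE)
  utils::write.csv(x$summary, paths["summary"], row.names = FALSE)
  meta <- list(
    experiment = x$name,
    package_version = as.character(utils::packageVersion("ratecomp")),
    r_version = R.version.string,
    reps = x$reps, seed = x$seed, alpha = x$alpha,
    min_tips = x$min_tips,
    conditions = x$conditions
  )
  jsonlite::write_json(meta, paths["metadata"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
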