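test_that("model_spec computes free-parameter counts and constraint maps", {
  m <- 4
  expect_equal(model_spec("equal", m)$k, 2L)
  expect_equal(model_spec("free", m)$k, 8L)
  expect_equal(model_spec("free-speciation", m)$k, 5L)
  expect_equal(model_spec("free-extinction", m)$k, 5L)
  expect_equal(model_spec("yule-equal", m)$k, 1L)
  expect_equal(model_spec("yule-free", m)$k, 4L)
  gr <- model_spec("grouped", m, groups = c("a", "a", "b", "a"))
  expect_equal(gr$k, 4L)
  expect_equal(gr$lambda_class, c(1L, 1L, 2L, 1L))
  expect_error(model_spec("grouped", m), "groups")
  expect_error(model_spec("grouped", m, groups = 1:3), "length")
})

test_that("init_params uses the pure-birth growth heuristic", {
  bt <- branching_times(c(100, sort(runif(98, 0, 100), decreasing = TRUE)))
  bt$N <- 100L  # exact tip count for the heuristic check
  d <- structure(list(trees = list(bt), rhos = 1, m = 1L),
                 class = "multi_tree_data")
  ini <- init_params(d, model_spec("equal", 1))
  expect_equal(ini$lambda0, log(50) / 100, tolerance = 1e-10)
  expect_equal(ini$mu0, log(50) / 400, tolerance = 1e-10)
  expect_equal(init_params(d, model_spec("yule-equal", 1))$mu0, numeric(0))
  # floor case: N = 2, T = 1 gives log(1) = 0, floored at 1e-6
  d2 <- multi_tree_data(list(branching_times(1)))
  expect_equal(init_params(d2, model_spec("equal", 1))$lambda0, 1e-6)
})

test_that("yule_mle matches its closed form and the numerical optimizer", {
  expect_equal(yule_mle(branching_times(c(3, 2, 1)))$lambda, 2 / 9,
               tolerance = 1e-12)
  expect_equal(yule_mle(branching_times(c(2, 1)))$lambda, 1 / 5,
               tolerance = 1e-12)
  two <- yule_mle(branching_times(4))
  expect_equal(two$lambda, 0)
  expect_equal(two$loglik, 0)
  expect_true(two$boundary)

  set.seed(55)
  for (r in 1:4) {
    tr <- simulate_yule_NT(0.07, sample(5:50, 1), runif(1, 15, 60))
    d <- multi_tree_data(list(tr))
    fit <- fit_model(d, "yule-equal")
    oracle <- yule_mle(branching_times(tr))
    expect_equal(fit$estimates$lambda[1], oracle$lambda, tolerance = 1e-6)
    expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-8)
  }
})

test_that("replicated trees under the equal model reproduce the single-tree fit", {
  set.seed(77)
  tr <- simulate_crown_bd(0.07, 0.02, 40, min_tips = 5)
  one <- fit_model(multi_tree_data(list(tr)), "equal")
  three <- fit_model(multi_tree_data(list(tr, tr, tr)), "equal")
  expect_equal(three$estimates$lambda[1], one$estimates$lambda[1],
               tolerance = 1e-5)
  expect_equal(three$estimates$mu[1], one$estimates$mu[1], tolerance = 1e-4)
  expect_equal(three$loglik, 3 * one$loglik, tolerance = 1e-5)
})

test_that("the free model equals independent per-tree fits", {
  d <- bd_pair(seed = 88, lambda = c(0.05, 0.09))
  free <- fit_model(d, "free")
  sep <- lapply(1:2, function(i)
    fit_model(multi_tree_data(d$trees[i]), "equal"))
  expect_equal(free$loglik, sep[[1]]$loglik + sep[[2]]$loglik,
               tolerance = 1e-4)
  expect_equal(free$estimates$lambda,
               vapply(sep, function(f) f$estimates$lambda[1], numeric(1)),
               tolerance = 1e-3)
})

test_that("model log-likelihoods respect the nesting hierarchy", {
  for (seed in c(3, 9)) {
    d <- bd_pair(seed = seed, lambda = c(0.05, 0.08), mu = c(0.01, 0.02))
    equal <- fit_model(d, "equal")
    warm <- list(lambda = equal$estimates$lambda, mu = equal$estimates$mu)
    fs <- fit_model(d, "free-speciation", warm_start = warm)
    fe <- fit_model(d, "free-extinction", warm_start = warm)
    fr <- fit_model(d, "free", warm_start = warm)
    expect_gte(fs$loglik, equal$loglik - 1e-4)
    expect_gte(fe$loglik, equal$loglik - 1e-4)
    expect_gte(fr$loglik, fs$loglik - 1e-4)
    expect_gte(fr$loglik, fe$loglik - 1e-4)
    # constraint maps are honored exactly
    expect_equal(fs$estimates$mu[1], fs$estimates$mu[2])
    expect_equal(fe$estimates$lambda[1], fe$estimates$lambda[2])
  }
})

test_that("grouped model ties rates within groups", {
  set.seed(14)
  trees <- c(lapply(1:2, function(i) simulate_crown_bd(0.05, 0.01, 40,
                                                       min_tips = 5)),
             lapply(1:2, function(i) simulate_crown_bd(0.1, 0.02, 40,
                                                       min_tips = 5)))
  d <- multi_tree_data(trees)
  fit <- fit_model(d, model_spec("grouped", 4, groups = c(1, 1, 2, 2)))
  expect_equal(fit$estimates$lambda[1], fit$estimates$lambda[2])
  expect_equal(fit$estimates$lambda[3], fit$estimates$lambda[4])
  expect_equal(fit$k, 4L)
  equal <- fit_model(d, "equal")
  expect_gte(fit$loglik, equal$loglik - 1e-4)
})

test_that("default restarts reproduce a heavy multistart search", {
  set.seed(61)
  agree <- 0L
  n_cases <- 20L
  for (r in seq_len(n_cases)) {
    d <- multi_tree_data(list(
      simulate_crown_bd(0.08, 0.03, 30, min_tips = 5),
      simulate_crown_bd(0.08, 0.03, 30, min_tips = 5)
    ))
    f5 <- fit_model(d, "equal", fit_control(n_restarts = 5, seed = r))
    f50 <- fit_model(d, "equal", fit_control(n_restarts = 50, seed = r))
    if (abs(f5$loglik - f50$loglik) < 1e-4) agree <- agree + 1L
  }
  expect_gte(agree, n_cases - 1L)
})

test_that("fits agree with the reference implementation in phytools", {
  skip_if_not_installed("phytools")
  set.seed(8)
  tr1 <- simulate_crown_bd(0.06, 0.015, 40, min_tips = 5)
  tr2 <- simulate_crown_bd(0.06, 0.015, 40, min_tips = 5)
  trees <- list(tr1, tr2)
  class(trees) <- "multiPhylo"
  rb <- suppressWarnings(phytools::ratebytree(trees, model = "birth-death"))
  d <- multi_tree_data(list(tr1, tr2))
  equal <- fit_model(d, "equal")
  free <- fit_model(d, "free",
                    warm_start = list(lambda = equal$estimates$lambda,
                                      mu = equal$estimates$mu))
  expect_equal(equal$loglik, rb$common.rate.model$logL, tolerance = 1e-3)
  expect_gte(free$loglik, rb$multi.rate.model$logL - 1e-3)
  expect_equal(free$estimates$lambda,
               unname(rb$multi.rate.model$rates[, 1]), tolerance = 1e-2)
})

test_that("fit results serialize to JSON and tidy into tibbles", {
  d <- bd_pair(seed = 5)
  fit <- fit_model(d, "equal")
  js <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(js$model, "equal")
  expect_equal(js$loglik, fit$loglik, tolerance = 1e-9)
  expect_equal(nrow(js$estimates), 2L)

  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4L)
  expect_setequal(unique(td$term), c("lambda", "mu"))
  gl <- glance(fit)
  expect_equal(gl$k, 2L)
  expect_equal(gl$logLik, fit$loglik)
  expect_equal(unclass(logLik(fit)), fit$loglik, ignore_attr = TRUE)
})
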