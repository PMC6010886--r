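# minimal bd_fit constructor for statistic/df arithmetic checks
fake_fit <- function(model, loglik, m = 2, groups = NULL) {
  structure(list(model = model_spec(model, m, groups = groups),
                 estimates = tibble::tibble(tree = seq_len(m),
                                            lambda = 0.1, mu = 0, rho = 1),
                 loglik = loglik, k = model_spec(model, m, groups = groups)$k,
                 converged = TRUE, n_restarts_used = 1L),
            class = "bd_fit")
}

test_that("lrt computes the statistic, degrees of freedom, and chi-square tail", {
  # identical likelihoods: statistic 0, p = 1
  t0 <- lrt(fake_fit("equal", -10), fake_fit("free", -10))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$df, 2L)
  expect_equal(t0$p, 1)

  # 2 * (logL_alt - logL_null) = 4 on 1 df
  t1 <- lrt(fake_fit("equal", -12), fake_fit("free-speciation", -10))
  expect_equal(t1$statistic, 4)
  expect_equal(t1$df, 1L)
  expect_equal(t1$p, pchisq(4, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(t1$p, 0.0455, tolerance = 1e-3)

  # m trees: free vs equal has 2m - 2 df
  expect_equal(lrt(fake_fit("equal", -5, m = 3),
                   fake_fit("free", -5, m = 3))$df, 4L)
  # grouped model: df counts rate classes, not trees
  expect_equal(lrt(fake_fit("equal", -5, m = 4),
                   fake_fit("grouped", -5, m = 4,
                            groups = c(1, 1, 2, 1)))$df, 2L)
  # Yule family: m - 1 df
  expect_equal(lrt(fake_fit("yule-equal", -5, m = 3),
                   fake_fit("yule-free", -5, m = 3))$df, 2L)
})

test_that("lrt rejects non-nested pairs and flags optimization failures", {
  expect_error(lrt(fake_fit("free", -10), fake_fit("equal", -10)),
               "not nested")
  expect_error(lrt(fake_fit("free-speciation", -10),
                   fake_fit("free-extinction", -9)), "not nested")
  # small negative noise is clamped, large negatives are an error
  ok <- lrt(fake_fit("equal", -10), fake_fit("free", -10.00002))
  expect_equal(ok$statistic, 0)
  expect_error(lrt(fake_fit("equal", -10), fake_fit("free", -11)),
               "optimization failure")
})

test_that("lrt is invariant to the order of the input trees", {
  d <- bd_pair(seed = 19, lambda = c(0.05, 0.09))
  fwd <- compare_models(d, "equal", "free")$test
  rev_d <- multi_tree_data(d$trees[c(2, 1)])
  bwd <- compare_models(rev_d, "equal", "free")$test
  expect_equal(bwd$statistic, fwd$statistic, tolerance = 1e-5)
})

test_that("binomial_exceedance_test equals the exact upper binomial tail", {
  expect_equal(binomial_exceedance_test(0, 10, 0.05), 1)
  expect_equal(binomial_exceedance_test(10, 10, 0.05), 0.05^10,
               tolerance = 1e-12)
  # brute-force tail summation oracle
  expect_equal(binomial_exceedance_test(35, 500, 0.05),
               sum(dbinom(35:500, 500, 0.05)), tolerance = 1e-12)
  expect_equal(binomial_exceedance_test(3, 60, 0.05),
               sum(dbinom(3:60, 60, 0.05)), tolerance = 1e-12)
})

test_that("pvalue_uniformity computes the KS statistic and histogram", {
  even <- seq(0.05, 0.95, by = 0.1)
  res <- pvalue_uniformity(even)
  expect_equal(res$statistic, 0.05, tolerance = 1e-12)
  expect_equal(sum(res$histogram$count), 10L)

  degenerate <- pvalue_uniformity(rep(0.5, 20))
  expect_equal(degenerate$statistic, 0.5, tolerance = 1e-12)

  expect_error(pvalue_uniformity(numeric(0)), "empty")
  expect_error(pvalue_uniformity(c(0.5, 1.2)), "0, 1")

  # genuinely uniform samples rarely fail at the 0.01 level
  set.seed(99)
  passes <- sum(replicate(30, pvalue_uniformity(runif(500))$p.value > 0.01))
  expect_gte(passes, 27)
})

test_that("bootstrap p-value uses the add-one estimator and matches edge cases", {
  set.seed(120)
  tr <- simulate_yule_NT(0.08, 25, 40)
  # identical duplicated tree: observed statistic ~ 0, so p ~ 1
  d_same <- multi_tree_data(list(tr, tr))
  b0 <- bootstrap_pvalue(d_same, "yule-equal", "yule-free", n_boot = 19,
                         seed = 1)
  expect_gte(b0$p, 0.9)

  # a large observed contrast with a single bootstrap draw: p = 1/2 when the
  # draw falls below the observed statistic
  tr2 <- simulate_yule_NT(0.25, 60, 40)
  d_diff <- multi_tree_data(list(tr, tr2))
  b1 <- bootstrap_pvalue(d_diff, "yule-equal", "yule-free", n_boot = 1,
                         seed = 2)
  expect_gt(b1$statistic, 10)
  expect_equal(b1$p, 1 / 2)
})

test_that("bootstrap p-values are approximately uniform under the null", {
  # null data from the same (crown age + survival)-conditioned process the
  # likelihood describes; tip counts stay random, as the model assumes
  set.seed(7)
  pvals <- replicate(25, {
    d <- multi_tree_data(list(simulate_crown_bd(0.08, 0, 40, min_tips = 2),
                              simulate_crown_bd(0.08, 0, 40, min_tips = 2)))
    bootstrap_pvalue(d, "yule-equal", "yule-free", n_boot = 39)$p
  })
  expect_gt(pvalue_uniformity(pvals)$p.value, 0.001)
})

test_that("bootstrap and chi-square p-values broadly agree under the null", {
  set.seed(12)
  ctrl <- fit_control(n_restarts = 2)
  rates <- rates_from_EN(20, 100, 0.25)
  diffs <- replicate(12, {
    d <- multi_tree_data(list(
      simulate_crown_bd(rates$lambda, rates$mu, 100, min_tips = 5),
      simulate_crown_bd(rates$lambda, rates$mu, 100, min_tips = 5)
    ))
    chisq_p <- compare_models(d, "equal", "free", control = ctrl)$test$p
    boot_p <- bootstrap_pvalue(d, "equal", "free", n_boot = 49,
                               control = ctrl)$p
    abs(chisq_p - boot_p)
  })
  expect_lte(median(diffs), 0.05)
})

test_that("depth-rates-N conditioning matches each observed tip count", {
  set.seed(33)
  d <- multi_tree_data(list(simulate_yule_NT(0.08, 12, 40),
                            simulate_yule_NT(0.08, 15, 40)))
  b <- bootstrap_pvalue(d, "yule-equal", "yule-free", n_boot = 5,
                        conditioning = "depth-rates-N", seed = 4)
  expect_equal(b$conditioning, "depth-rates-N")
  expect_length(b$boot_statistics, 5L)
  expect_true(all(b$boot_statistics >= 0))

  td <- tidy(b)
  expect_equal(td$method, "bootstrap")
  expect_equal(td$df, 1L)
})
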