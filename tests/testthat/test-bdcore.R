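# Frozen reference values for p0/p1 computed by independent 40-digit
# arbitrary-precision evaluation (mpmath) of the closed-form expressions.
.p_oracle <- list(
  list(lambda = 0.052, mu = 0.013, rho = 1, t = 100,
       p0 = 0.246185337589233081, p1 = 0.0115021938295332278),
  list(lambda = 0.07, mu = 0.03, rho = 0.6, t = 35,
       p0 = 0.421781575814319583, p1 = 0.137410628658392482),
  list(lambda = 0.03, mu = 0.05, rho = 0.8, t = 20,  # declining diversity
       p0 = 0.615756728172238611, p1 = 0.275321640793234447)
)

test_that("p0 and p1 match high-precision oracle evaluations", {
  for (cs in .p_oracle) {
    pr <- bd_params(cs$lambda, cs$mu, cs$rho)
    expect_equal(p0(cs$t, pr), cs$p0, tolerance = 1e-12)
    expect_equal(p1(cs$t, pr), cs$p1, tolerance = 1e-12)
  }
})

test_that("p0 and p1 boundary identities hold", {
  grid <- expand.grid(lambda = c(0.02, 0.5), mu = c(0, 0.03, 0.8),
                      rho = c(0.3, 1))
  for (i in seq_len(nrow(grid))) {
    pr <- bd_params(grid$lambda[i], grid$mu[i], grid$rho[i])
    expect_equal(p0(0, pr), 1 - pr$rho, tolerance = 1e-14)
    expect_equal(p1(0, pr), pr$rho, tolerance = 1e-14)
  }
  # pure birth, complete sampling: no lineage is ever lost
  pr <- bd_params(0.3, 0, 1)
  expect_equal(p0(c(0, 1, 50), pr), c(0, 0, 0))
  expect_equal(p1(c(1, 10), pr), exp(-0.3 * c(1, 10)), tolerance = 1e-14)
})

test_that("equal-rates limit formulas agree with the full expressions", {
  # the full expressions are 0/0 at lambda = mu and cannot be evaluated
  # accurately in double precision near the ridge, so the reference values
  # for |lambda - mu| = 1e-12 were computed once by 50-digit
  # arbitrary-precision evaluation of the printed formulas and frozen here;
  # the limit branch must agree to better than 6 significant digits
  ref <- rbind(
    c(0.05, 0.5, 0.5, 0.50617283950592745, 0.48773052888303311),
    c(0.05, 0.5, 10,  0.5999999999964,     0.32000000000256),
    c(0.05, 0.5, 200, 0.91666666665694444, 0.013888888889351852),
    c(0.05, 1.0, 0.5, 0.024390243901957168, 0.95181439619320671),
    c(0.05, 1.0, 10,  0.33333333332777778, 0.44444444444740741),
    c(0.05, 1.0, 200, 0.90909090908099174, 0.0082644628100676183),
    c(1.2, 0.5, 0.5,  0.61538461538444527, 0.29585798816579426),
    c(1.2, 0.5, 10,   0.92857142857102041, 0.010204081632667638),
    c(1.2, 0.5, 200,  0.99586776859462468, 3.4150672768309982e-5),
    c(1.2, 1.0, 0.5,  0.37499999999974609, 0.39062500000012207),
    c(1.2, 1.0, 10,   0.92307692307650888, 0.0059171597633181611),
    c(1.2, 1.0, 200,  0.99585062240622234, 1.7217334412300578e-5)
  )
  for (i in seq_len(nrow(ref))) {
    pr <- bd_params(ref[i, 1], ref[i, 1], ref[i, 2])  # limit branch
    expect_equal(p0(ref[i, 3], pr), ref[i, 4], tolerance = 1e-7)
    expect_equal(p1(ref[i, 3], pr), ref[i, 5], tolerance = 1e-7)
  }
  expect_equal(p1(10, bd_params(0.05, 0.05, 0.5)), 0.32, tolerance = 1e-9)
})

test_that("p0/p1 stay within [0, 1] and are monotone where theory predicts", {
  ts <- c(0, 10^seq(-2, 4, length.out = 40))
  for (pars in list(c(0.05, 0.0125, 1), c(0.05, 0.0125, 0.4),
                    c(0.02, 0.05, 0.9), c(0.3, 0.3, 0.7))) {
    pr <- bd_params(pars[1], pars[2], pars[3])
    v0 <- p0(ts, pr); v1 <- p1(ts, pr)
    expect_true(all(v0 >= 0 & v0 <= 1))
    expect_true(all(v1 >= 0 & v1 <= 1))
    # p1 decays with age; p0 grows with age under complete sampling (with
    # rho < 1 it can decrease: older lineages have more descendants, hence
    # more chances that at least one is sampled)
    expect_true(all(diff(v1) <= 1e-12))
    if (pr$rho == 1) expect_true(all(diff(v0) >= -1e-12))
  }
})

test_that("tree_loglik matches closed-form pure-birth expressions", {
  # two tips: logL = -2 lambda T
  bt2 <- branching_times(5)
  expect_equal(tree_loglik(bt2, bd_params(0.3, 0, 1)), -2 * 0.3 * 5,
               tolerance = 1e-12)
  # four tips, t = (3, 2, 1): logL = log 6 + 2 log lambda - 9 lambda
  bt4 <- branching_times(c(3, 2, 1))
  expect_equal(tree_loglik(bt4, bd_params(2 / 9, 0, 1)),
               log(6) + 2 * log(2 / 9) - 2, tolerance = 1e-12)
  # general Yule closed form on random trees, machine precision
  set.seed(31)
  for (r in 1:5) {
    tr <- simulate_yule_NT(0.08, sample(3:60, 1), runif(1, 10, 80))
    bt <- branching_times(tr)
    lam <- runif(1, 0.01, 0.3)
    closed <- lgamma(bt$N) + (bt$N - 2) * log(lam) -
      lam * (2 * bt$t[1] + sum(bt$t[-1]))
    expect_equal(tree_loglik(bt, bd_params(lam, 0, 1)), closed,
                 tolerance = 1e-12)
  }
})

test_that("tree_loglik equals a term-by-term sum over p0/p1 calls", {
  set.seed(17)
  for (r in 1:6) {
    tr <- simulate_crown_bd(0.1, 0.04, 25, min_tips = 3)
    bt <- branching_times(tr)
    pr <- bd_params(runif(1, 0.02, 0.3), runif(1, 0, 0.2), runif(1, 0.2, 1))
    brute <- lgamma(bt$N) + 2 * log(p1(bt$t[1], pr)) -
      2 * log(1 - p0(bt$t[1], pr)) +
      sum(log(pr$lambda) + log(p1(bt$t[-1], pr)))
    expect_equal(tree_loglik(bt, pr), brute, tolerance = 1e-9)
  }
})

test_that("lambda = 0 with more than two tips gives -Inf, not an error", {
  bt <- branching_times(c(3, 2, 1))
  expect_identical(tree_loglik(bt, bd_params(0, 0, 1)), -Inf)
})

test_that("joint_loglik is an exact sum and symmetric in tree order", {
  set.seed(23)
  trees <- lapply(1:3, function(i) simulate_crown_bd(0.08, 0.02, 30,
                                                     min_tips = 3))
  prs <- lapply(1:3, function(i) bd_params(0.05 + 0.01 * i, 0.01, 1))
  d <- multi_tree_data(trees)
  total <- joint_loglik(d, prs)
  expect_equal(total,
               sum(mapply(function(tr, pr) tree_loglik(branching_times(tr), pr),
                          trees, prs)),
               tolerance = 1e-12)
  # m = 1 reduces to tree_loglik
  expect_equal(joint_loglik(multi_tree_data(trees[1]), prs[1]),
               tree_loglik(branching_times(trees[[1]]), prs[[1]]))
  # duplicated tree with identical params doubles the value exactly
  d2 <- multi_tree_data(trees[c(1, 1)])
  expect_identical(joint_loglik(d2, prs[c(1, 1)]),
                   2 * tree_loglik(branching_times(trees[[1]]), prs[[1]]))
  # joint permutation of (tree, params) pairs leaves the sum unchanged
  perm <- c(3, 1, 2)
  expect_equal(joint_loglik(multi_tree_data(trees[perm]), prs[perm]), total,
               tolerance = 1e-12)
  # length mismatch is an error
  expect_error(joint_loglik(d, prs[1:2]), "one bd_params per tree")
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(bd_params(-0.1), "lambda")
  expect_error(bd_params(0.1, -1), "mu")
  expect_error(bd_params(0.1, 0, 0), "rho")
  expect_error(bd_params(0.1, 0, 1.2), "rho")
  expect_error(multi_tree_data(list(branching_times(2)), rhos = c(1, 1)),
               "does not match")
})
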