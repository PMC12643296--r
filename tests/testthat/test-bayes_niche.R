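true_sigma <- matrix(c(2, 0.5, 0.5, 1), 2)

test_that("the conjugate posterior recovers known parameters at n = 200", {
  set.seed(31)
  m <- MASS::mvrnorm(200, c(-28, 6), true_sigma)
  ens <- fit_bivariate_posterior(m, n_draws = 4000, seed = 8)
  post_mu <- colMeans(ens$mu)
  post_sd <- apply(ens$mu, 2, sd)
  expect_true(all(abs(post_mu - c(-28, 6)) < 3 * post_sd))
  post_sigma <- apply(ens$sigma, c(1, 2), mean)
  expect_true(all(abs(post_sigma - true_sigma) / abs(true_sigma) < 0.2 |
                    abs(post_sigma - true_sigma) < 0.2))
})

test_that("ensembles are bitwise reproducible and stable in n_draws", {
  set.seed(5)
  m <- MASS::mvrnorm(40, c(0, 0), diag(2))
  e1 <- fit_bivariate_posterior(m, n_draws = 2000, seed = 99)
  e2 <- fit_bivariate_posterior(m, n_draws = 2000, seed = 99)
  expect_identical(e1$mu, e2$mu)
  expect_identical(e1$sigma, e2$sigma)
  e4 <- fit_bivariate_posterior(m, n_draws = 8000, seed = 100)
  ## doubling draws moves the posterior mean by at most Monte-Carlo error
  mc_se <- apply(e1$mu, 2, sd) / sqrt(2000)
  expect_true(all(abs(colMeans(e1$mu) - colMeans(e4$mu)) < 5 * mc_se))
})

test_that("degenerate inputs are rejected", {
  expect_error(fit_bivariate_posterior(cbind(c(1, 2), c(1, 2))), "3 points")
  m <- cbind(c(1, 2, 3, 4), rep(5, 4))
  expect_error(fit_bivariate_posterior(m), "zero variance")
})

test_that("standard ellipse area has its closed forms and rotation invariance", {
  expect_equal(standard_ellipse_area(diag(2)), pi)
  expect_equal(standard_ellipse_area(diag(c(4, 1))), 2 * pi)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(standard_ellipse_area(R %*% diag(c(4, 1)) %*% t(R)), 2 * pi)
  expect_error(standard_ellipse_area(matrix(c(1, 2, 2, 1), 2)), "positive")
})

test_that("SEAc inflates the sample-covariance SEA by (n-1)/(n-2)", {
  set.seed(3)
  for (n in c(3, 5, 20, 100)) {
    m <- MASS::mvrnorm(n, c(0, 0), true_sigma)
    expect_equal(sea_c(m),
                 standard_ellipse_area(cov(m)) * (n - 1) / (n - 2))
    expect_gte(sea_c(m), standard_ellipse_area(cov(m)))
  }
})

test_that("SEA.B brackets the truth and SEAc is close at n = 50", {
  set.seed(17)
  m <- MASS::mvrnorm(50, c(-28, 6), true_sigma)
  ens <- fit_bivariate_posterior(m, n_draws = 4000, seed = 21)
  sm <- sea_metrics(m, ensemble = ens)
  truth <- standard_ellipse_area(true_sigma)
  ci95 <- sm$credible[["95"]]
  expect_gt(truth, ci95[["lo"]])
  expect_lt(truth, ci95[["hi"]])
  expect_lt(abs(sm$sea_c - truth) / truth, 0.35)
  ## credible interval nesting
  expect_gte(sm$credible[["75"]][["lo"]], sm$credible[["95"]][["lo"]])
  expect_lte(sm$credible[["75"]][["hi"]], sm$credible[["95"]][["hi"]])
  expect_gte(sm$credible[["50"]][["lo"]], sm$credible[["75"]][["lo"]])
  expect_lte(sm$credible[["50"]][["hi"]], sm$credible[["75"]][["hi"]])
})

test_that("posterior_summary finds modes and HDIs of known shapes", {
  set.seed(2)
  ## symmetric unimodal: mode near the median
  x <- rnorm(20000, 3, 1)
  ps <- posterior_summary(x)
  expect_lt(abs(ps$mode - median(x)), 0.1)
  ## constant draws: zero-width intervals at the constant
  expect_warning(psc <- posterior_summary(rep(2.5, 10)), "1000")
  expect_equal(psc$mode, 2.5)
  expect_equal(unname(psc$credible[["95"]]), c(2.5, 2.5))
  ## lognormal HDI vs the window-search oracle
  y <- rlnorm(20000, 0, 0.5)
  ps2 <- posterior_summary(y)
  for (lv in c("50", "75", "95")) {
    o <- oracle_hdi_window(y, as.numeric(lv) / 100)
    expect_lt(abs(ps2$credible[[lv]][["lo"]] - o[["lo"]]), 0.12)
    expect_lt(abs(ps2$credible[[lv]][["hi"]] - o[["hi"]]), 0.12)
  }
})

test_that("welch_compare matches a hand-computed statistic and is antisymmetric", {
  ## identical samples: no difference
  same <- welch_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  a <- 1:5; b <- 2:6
  ## hand computation: means 3 and 4, var 2.5 each,
  ## se = sqrt(2.5/5 + 2.5/5) = 1, t = -1, Welch dof = 8
  w <- welch_compare(a, b)
  expect_equal(w$t, -1)
  expect_equal(w$dof, 8)
  expect_equal(w$p_value, 2 * pt(-1, 8))
  swapped <- welch_compare(b, a)
  expect_equal(swapped$t, 1)
  expect_equal(swapped$p_value, w$p_value)
  expect_error(welch_compare(c(1, 1), c(2, 2)), "zero variance")
})

test_that("bayes_layman concentrates at analytic values in the tight-posterior limit", {
  set.seed(23)
  diamond <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  ens <- lapply(seq_along(diamond), function(i) {
    m <- MASS::mvrnorm(400, diamond[[i]], diag(2) * 1e-6)
    fit_bivariate_posterior(m, n_draws = 1500, seed = i)
  })
  names(ens) <- paste0("g", 1:4)
  res <- bayes_layman(ens, communities = rep("pond", 4))
  modes <- res$pond$modes
  expect_lt(abs(modes[["CD"]] - 1), 0.01)
  expect_lt(abs(modes[["TA"]] - 2), 0.02)
  expect_true(all(res$pond$metric_draws >= 0))
})

test_that("a two-group community has identically zero hull area", {
  set.seed(4)
  ens <- lapply(1:2, function(i) {
    fit_bivariate_posterior(MASS::mvrnorm(30, c(i, i), diag(2)),
                            n_draws = 1200, seed = i)
  })
  names(ens) <- c("a", "b")
  res <- bayes_layman(ens, rep("ditch", 2))
  expect_true(all(res$ditch$metric_draws[, "TA"] == 0))
})

test_that("scaling a community's centroids by 2 scales the TA posterior by about 4", {
  set.seed(9)
  centers <- list(c(0, 0), c(2, 0), c(1, 2))
  ensA <- lapply(seq_along(centers), function(i) {
    fit_bivariate_posterior(MASS::mvrnorm(300, 2 * centers[[i]], diag(2) * 0.01),
                            n_draws = 1500, seed = i)
  })
  ensB <- lapply(seq_along(centers), function(i) {
    fit_bivariate_posterior(MASS::mvrnorm(300, centers[[i]], diag(2) * 0.01),
                            n_draws = 1500, seed = 10 + i)
  })
  names(ensA) <- paste0("A", 1:3); names(ensB) <- paste0("B", 1:3)
  res <- bayes_layman(c(ensA, ensB), rep(c("A", "B"), each = 3))
  ratio <- res$A$modes[["TA"]] / res$B$modes[["TA"]]
  expect_lt(abs(ratio - 4), 0.2)
})

test_that("mismatched draw counts across ensembles are fatal", {
  set.seed(6)
  e1 <- fit_bivariate_posterior(MASS::mvrnorm(20, c(0, 0), diag(2)),
                                n_draws = 1000, seed = 1)
  e2 <- fit_bivariate_posterior(MASS::mvrnorm(20, c(0, 0), diag(2)),
                                n_draws = 1500, seed = 2)
  expect_error(bayes_layman(list(a = e1, b = e2), c("x", "x")),
               "n_draws")
})
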