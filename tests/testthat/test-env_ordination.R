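test_that("zscore_env standardizes columns and is idempotent", {
  expect_equal(unname(zscore_env(cbind(a = c(1, 2, 3)))[, 1]), c(-1, 0, 1))
  set.seed(8)
  m <- matrix(rnorm(40, 5, 3), 10, 4)
  z <- zscore_env(m)
  expect_equal(unname(colMeans(z)), rep(0, 4))
  expect_equal(unname(apply(z, 2, sd)), rep(1, 4))
  expect_equal(unclass(zscore_env(z)), unclass(z), ignore_attr = TRUE)
  m2 <- cbind(x = rnorm(5), flat = rep(2, 5))
  expect_error(zscore_env(m2), "flat")
})

test_that("dissimilarity handles degenerate and whitened cases", {
  m <- rbind(c(1, 2), c(1, 2), c(1, 2))
  expect_true(all(dissimilarity(m, "euclidean") == 0))
  ## exactly uncorrelated unit-variance columns: mahalanobis == euclidean
  set.seed(3)
  raw <- matrix(rnorm(24), 12, 2)
  w <- qr.Q(qr(scale(raw, scale = FALSE))) * sqrt(nrow(raw) - 1)
  expect_equal(cov(w), diag(2), tolerance = 1e-12)
  expect_equal(as.vector(dissimilarity(w, "mahalanobis")),
               as.vector(dissimilarity(w, "euclidean")))
})

test_that("mahalanobis distances match the direct formula and vegan", {
  set.seed(19)
  m <- matrix(rnorm(30), 10, 3)
  d <- dissimilarity(m, "mahalanobis")
  expect_equal(as.vector(d), as.vector(oracle_mahalanobis(m)),
               tolerance = 1e-10)
  skip_if_not_installed("vegan")
  expect_equal(as.vector(d),
               as.vector(vegan::vegdist(m, method = "mahalanobis")),
               tolerance = 1e-8)
})

test_that("singular covariance errors in strict mode, pseudo-inverts otherwise", {
  set.seed(4)
  m <- matrix(rnorm(12), 4, 3)  # 4 sites, 3 vars: rank-deficient cov
  m <- cbind(m, m[, 1] + m[, 2]) # force exact singularity
  expect_error(dissimilarity(m, "mahalanobis", strict = TRUE), "singular")
  expect_warning(d <- dissimilarity(m, "mahalanobis"), "pseudo-inverse")
  expect_true(all(is.finite(as.vector(d))))
})

test_that("bioenv recovers a planted variable subset with rho = 1", {
  set.seed(21)
  env <- zscore_env(matrix(rnorm(10 * 5), 10, 5,
                           dimnames = list(NULL, LETTERS[1:5])))
  response <- stats::dist(env[, c("B", "D")])
  res <- bioenv_search(env, response)
  expect_setequal(res$best_subset, c("B", "D"))
  expect_equal(res$rho, 1)
  expect_equal(nrow(res$all_subsets), 2^5 - 1)
  ## single planted variable
  res1 <- bioenv_search(env, stats::dist(env[, "C", drop = FALSE]))
  expect_equal(res1$best_subset, "C")
  expect_equal(res1$rho, 1)
})

test_that("bioenv agrees with vegan's implementation on the best subset", {
  skip_if_not_installed("vegan")
  set.seed(33)
  comm <- matrix(rpois(10 * 6, 8), 10, 6)
  env <- matrix(rnorm(10 * 4), 10, 4,
                dimnames = list(NULL, c("w", "x", "y", "z")))
  response <- vegan::vegdist(comm, "bray")
  mine <- bioenv_search(zscore_env(env), response)
  ref <- vegan::bioenv(comm, as.data.frame(env), index = "bray")
  ref_best <- colnames(env)[ref$models[[which.max(
    vapply(ref$models, function(m) m$est, numeric(1)))]]$best]
  expect_setequal(mine$best_subset, ref_best)
  expect_equal(mine$rho, max(vapply(ref$models, function(m) m$est,
                                    numeric(1))), tolerance = 1e-10)
})

test_that("bioenv best rho is invariant to monotone response transforms", {
  set.seed(40)
  env <- zscore_env(matrix(rnorm(9 * 3), 9, 3,
                           dimnames = list(NULL, c("a", "b", "c"))))
  d <- stats::dist(env[, c("a", "c")]) + as.dist(matrix(runif(81, 0, .3), 9))
  d2 <- d^3 + 1  # strictly monotone transform
  r1 <- bioenv_search(env, d)
  r2 <- bioenv_search(env, d2)
  expect_equal(r1$all_subsets$rho, r2$all_subsets$rho, tolerance = 1e-12)
})

test_that("under a null response the best single-variable rho averages near zero", {
  set.seed(55)
  rhos <- replicate(60, {
    env <- zscore_env(matrix(rnorm(8 * 3), 8, 3,
                             dimnames = list(NULL, c("a", "b", "c"))))
    resp <- stats::dist(matrix(rnorm(16), 8, 2))
    res <- bioenv_search(env, resp, max_vars = 1)
    mean(res$all_subsets$rho)   # mean over the three 1-var subsets
  })
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(length(rhos)) + 0.02)
})

test_that("dbRDA spans all variance under full-rank constraints, none under orthogonal ones", {
  set.seed(61)
  Y <- matrix(rnorm(10 * 3), 10, 3)
  d <- stats::dist(Y)
  fit_full <- dbrda_fit(d, scale(Y, scale = FALSE))
  expect_equal(fit_full$constrained_prop, 1, tolerance = 1e-8)
  expect_equal(sum(fit_full$prop_explained) +
                 sum(fit_full$unconstrained_eig) / fit_full$total_inertia,
               1, tolerance = 1e-8)
  ## constraints orthogonal to the data columns
  Yc <- scale(Y, scale = FALSE)
  X <- qr.Q(qr(cbind(1, Yc)), complete = TRUE)[, 5:8, drop = FALSE]
  fit0 <- dbrda_fit(d, X)
  expect_lt(fit0$constrained_prop, 1e-8)
})

test_that("dbRDA on Euclidean distances reproduces classical RDA eigenvalues", {
  set.seed(71)
  Y <- matrix(rnorm(12 * 4), 12, 4)
  X <- matrix(rnorm(12 * 2), 12, 2, dimnames = list(NULL, c("x1", "x2")))
  fit <- dbrda_fit(stats::dist(Y), X)
  ref <- oracle_rda_eigen(Y, X)
  expect_equal(fit$constrained_eig, ref, tolerance = 1e-8)
  skip_if_not_installed("vegan")
  ## vegan scales inertia by 1/(n-1)
  vref <- vegan::dbrda(stats::dist(Y) ~ x1 + x2, data = as.data.frame(X))
  expect_equal(unname(fit$constrained_eig),
               unname(vref$CCA$eig) * (nrow(Y) - 1), tolerance = 1e-8)
  expect_equal(fit$total_inertia, vref$tot.chi * (nrow(Y) - 1),
               tolerance = 1e-8)
})

test_that("permutation test detects a planted gradient and is reproducible", {
  set.seed(81)
  n <- 20
  grad <- seq(-1, 1, length.out = n)
  Y <- cbind(3 * grad + rnorm(n, sd = 0.3), -2 * grad + rnorm(n, sd = 0.3))
  X <- cbind(gradient = grad)
  d <- stats::dist(Y)
  res <- permutation_test(d, X, n_perm = 999, seed = 7, scope = "model")
  expect_lte(res$p_value, 0.01)
  res2 <- permutation_test(d, X, n_perm = 999, seed = 7, scope = "model")
  expect_identical(res, res2)
})

test_that("terms and axes scopes return one row per component", {
  set.seed(91)
  Y <- matrix(rnorm(14 * 3), 14, 3)
  X <- matrix(rnorm(14 * 2), 14, 2, dimnames = list(NULL, c("u", "v")))
  d <- stats::dist(Y)
  tt <- permutation_test(d, X, n_perm = 99, seed = 3, scope = "terms")
  expect_equal(tt$component, c("u", "v"))
  expect_true(all(tt$p_value > 0 & tt$p_value <= 1))
  ax <- permutation_test(d, X, n_perm = 99, seed = 3, scope = "axes")
  expect_equal(nrow(ax), 2)
  expect_true(all(ax$pseudo_F >= 0))
})

test_that("permutation p-values are invariant to site relabeling", {
  set.seed(95)
  n <- 12
  Y <- matrix(rnorm(n * 2), n, 2)
  X <- cbind(x = rnorm(n))
  d <- stats::dist(Y)
  p1 <- permutation_test(d, X, n_perm = 199, seed = 11, scope = "model")
  perm <- sample.int(n)
  d2 <- stats::dist(Y[perm, , drop = FALSE])
  p2 <- permutation_test(d2, X[perm, , drop = FALSE], n_perm = 199,
                         seed = 11, scope = "model")
  expect_equal(p1$pseudo_F, p2$pseudo_F, tolerance = 1e-10)
})
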