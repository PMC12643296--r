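## Bayesian bivariate-normal niche model. Each group's (d13C, d15N) cloud
## is modelled as bivariate normal; the posterior over (mu, Sigma) under a
## conjugate Normal-Inverse-Wishart prior is sampled directly (exact,
## i.i.d. draws -- no MCMC, no burn-in).

#' Default weakly informative prior for the niche model
#'
#' Normal-Inverse-Wishart hyperparameters: `mu0` (prior mean; `NULL` means
#' use the sample centroid), `kappa0` (prior pseudo-observations for the
#' mean; small = vague), `nu0` (Inverse-Wishart degrees of freedom; 3 is
#' the smallest giving a finite covariance mean in 2-D), `Psi0` (scale
#' matrix, permil^2).
#'
#' @return named list of hyperparameters.
#' @export
niw_prior <- function() {
  list(mu0 = NULL, kappa0 = 1e-3, nu0 = 3, Psi0 = diag(2))
}

#' Sample the posterior of a bivariate-normal niche
#'
#' Fits a bivariate normal to a group's isotope cloud and draws an i.i.d.
#' sample from the conjugate Normal-Inverse-Wishart posterior of the mean
#' vector and covariance matrix. With the default vague prior the
#' posterior is dominated by the data for n of a few and upwards; groups
#' at the minimum size n = 3 are fitted but flagged as prior-influenced.
#'
#' @param x numeric vector of d13C values, or 2-column matrix.
#' @param y numeric vector of d15N values (omit when `x` is a matrix).
#' @param n_draws number of posterior draws (>= 1000 recommended).
#' @param seed integer seed; fixed seed gives a bitwise-identical ensemble.
#' @param prior hyperparameter list as from [niw_prior()].
#' @param group optional label carried through to summaries.
#' @return a `posterior_ensemble`: list with `mu` (n_draws x 2 matrix),
#'   `sigma` (2 x 2 x n_draws array), `n_draws`, `n`, `seed`, `prior`,
#'   `group`, `xbar` and `S` (sample mean and n-1 covariance of the data).
#' @export
fit_bivariate_posterior <- function(x, y = NULL, n_draws = 10000L,
                                    seed = 1L, prior = niw_prior(),
                                    group = NULL) {
  m <- .as_xy(x, y)
  n <- nrow(m)
  if (n < 3) stop("at least 3 points are required to fit a niche")
  if (any(apply(m, 2, stats::var) == 0)) {
    stop("degenerate data: zero variance on an axis")
  }
  if (n_draws < 1) stop("n_draws must be >= 1")
  xbar <- colMeans(m)
  S <- stats::cov(m)          # n-1 denominator
  SS <- S * (n - 1)           # sum of squares about the mean
  mu0 <- if (is.null(prior$mu0)) xbar else as.numeric(prior$mu0)
  kappa0 <- prior$kappa0; nu0 <- prior$nu0; Psi0 <- prior$Psi0
  kappa_n <- kappa0 + n
  mu_n <- (kappa0 * mu0 + n * xbar) / kappa_n
  nu_n <- nu0 + n
  dev <- xbar - mu0
  Psi_n <- Psi0 + SS + (kappa0 * n / kappa_n) * tcrossprod(dev)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  # Sigma ~ InvWishart(nu_n, Psi_n) via Sigma = (Wishart(nu_n, Psi_n^-1))^-1
  W <- stats::rWishart(n_draws, df = nu_n, Sigma = solve(Psi_n))
  sigma <- array(apply(W, 3, solve), dim = c(2, 2, n_draws))
  z <- matrix(stats::rnorm(2L * n_draws), nrow = n_draws)
  mu <- t(vapply(seq_len(n_draws), function(j) {
    L <- chol(sigma[, , j] / kappa_n)
    mu_n + drop(crossprod(L, z[j, ]))
  }, numeric(2)))
  colnames(mu) <- c("d13C", "d15N")
  if (n == 3) {
    message("group ", if (is.null(group)) "" else paste0("'", group, "' "),
            "has n = 3: posterior is noticeably prior-influenced")
  }
  structure(list(mu = mu, sigma = sigma, n_draws = as.integer(n_draws),
                 n = n, seed = as.integer(seed), prior = prior,
                 group = group, xbar = xbar, S = S),
            class = "posterior_ensemble")
}

#' @export
print.posterior_ensemble <- function(x, ...) {
  cat(sprintf("<posterior_ensemble> group %s: n = %d data points, %d draws (seed %d)\n",
              if (is.null(x$group)) "<unnamed>" else x$group, x$n,
              x$n_draws, x$seed))
  cat(" posterior mean mu: (", paste(sprintf("%.3f", colMeans(x$mu)),
                                     collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Standard ellipse area from a covariance matrix
#'
#' Area of the 1-standard-deviation ellipse of a bivariate normal,
#' `pi * sqrt(det(Sigma))`. Its theoretical data coverage is
#' `1 - exp(-1/2)` (about 39.35%, the conventional "40% of the data").
#'
#' @param sigma 2 x 2 covariance matrix (permil^2).
#' @return area in permil^2.
#' @export
standard_ellipse_area <- function(sigma) {
  stopifnot(is.matrix(sigma), all(dim(sigma) == 2))
  d <- det(sigma)
  if (d <= 0) stop("covariance matrix is not positive definite")
  pi * sqrt(d)
}

#' Small-sample corrected standard ellipse area (SEAc)
#'
#' Frequentist point estimate: SEA of the sample covariance (n-1
#' denominator) inflated by `(n-1)/(n-2)` to correct small-sample bias.
#'
#' @inheritParams convex_hull_area
#' @return SEAc in permil^2.
#' @export
sea_c <- function(x, y = NULL) {
  m <- .as_xy(x, y)
  n <- nrow(m)
  if (n < 3) stop("SEAc needs at least 3 points")
  standard_ellipse_area(stats::cov(m)) * (n - 1) / (n - 2)
}

#' Ellipse-area summary of a fitted niche
#'
#' Combines the frequentist SEAc with the Bayesian SEA.B: the standard
#' ellipse area evaluated on every posterior covariance draw, summarized
#' by its kernel-density mode and nested 50/75/95% highest-density
#' intervals.
#'
#' @inheritParams convex_hull_area
#' @param ensemble a `posterior_ensemble` fitted on the same points.
#' @return an `ellipse_summary`: list with `sea_c`, `sea_b` (draw vector),
#'   `sea_b_mode`, `credible` (list of `(lo, hi)` at 50/75/95), `n`.
#' @export
sea_metrics <- function(x, y = NULL, ensemble) {
  m <- .as_xy(x, y)
  stopifnot(inherits(ensemble, "posterior_ensemble"))
  if (nrow(m) != ensemble$n) {
    stop("ensemble was fitted on ", ensemble$n, " points, got ", nrow(m))
  }
  draws <- apply(ensemble$sigma, 3, function(s) pi * sqrt(det(s)))
  ps <- posterior_summary(draws)
  structure(list(sea_c = sea_c(m), sea_b = draws, sea_b_mode = ps$mode,
                 credible = ps$credible, n = nrow(m)),
            class = "ellipse_summary")
}

#' @export
print.ellipse_summary <- function(x, ...) {
  ci95 <- x$credible[["95"]]
  cat(sprintf(
    "<ellipse_summary> n = %d: SEAc = %.3f, SEA.B mode = %.3f [95%% HDI %.3f, %.3f] permil^2\n",
    x$n, x$sea_c, x$sea_b_mode, ci95[1], ci95[2]))
  invisible(x)
}

#' Mode and highest-density intervals of a posterior sample
#'
#' The mode is the argmax of a Gaussian kernel density estimate (Silverman
#' bandwidth); credible intervals are highest-density intervals obtained by
#' thresholding the same density estimate, which makes the 50/75/95%
#' intervals nested by construction.
#'
#' @param draws numeric vector of posterior draws.
#' @param levels credible levels in (0, 1).
#' @return list with `mode` and `credible` (named list of `c(lo, hi)`).
#' @export
posterior_summary <- function(draws, levels = c(0.5, 0.75, 0.95)) {
  draws <- draws[is.finite(draws)]
  if (!length(draws)) stop("no finite draws")
  if (length(draws) < 1000) {
    warning("fewer than 1000 draws: density summaries will be coarse",
            call. = FALSE)
  }
  nm <- as.character(round(levels * 100))
  if (stats::var(draws) == 0) {
    ci <- lapply(levels, function(p) c(lo = draws[1], hi = draws[1]))
    return(list(mode = draws[1], credible = stats::setNames(ci, nm)))
  }
  den <- stats::density(draws, bw = "nrd0", n = 1024)
  mode <- den$x[which.max(den$y)]
  dx <- diff(den$x[1:2])
  mass <- den$y * dx
  ord <- order(den$y, decreasing = TRUE)
  cum <- cumsum(mass[ord])
  ci <- lapply(levels, function(p) {
    k <- which(cum >= p * sum(mass))[1]
    if (is.na(k)) k <- length(ord)
    sel <- ord[seq_len(k)]
    c(lo = min(den$x[sel]), hi = max(den$x[sel]))
  })
  list(mode = mode, credible = stats::setNames(ci, nm))
}

#' Welch's unequal-variance t comparison
#'
#' Two-sided Welch t-test (Welch-Satterthwaite degrees of freedom) with a
#' 95% confidence interval for the mean difference, the standard tool for
#' comparing group-level niche statistics without assuming equal
#' variances.
#'
#' @param a,b numeric vectors (each >= 2 values).
#' @param conf_level confidence level for the mean-difference interval.
#' @return list with `t`, `dof`, `p_value`, `conf_int`, `mean_diff`.
#' @export
welch_compare <- function(a, b, conf_level = 0.95) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("both samples have zero variance; Welch statistic undefined")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE, conf.level = conf_level)
  list(t = unname(ht$statistic), dof = unname(ht$parameter),
       p_value = ht$p.value, conf_int = unname(ht$conf.int),
       mean_diff = mean(a) - mean(b))
}

#' Bayesian Layman metrics over group centroids
#'
#' For each posterior draw j, the member groups' mean-vector draws form a
#' point set of group centroids; the six Layman metrics of that set give
#' one posterior draw of the community-level metrics (the Layman.B
#' convention: geometry of group centroids, not of individuals).
#'
#' @param ensembles named list of `posterior_ensemble` objects, all with
#'   the same `n_draws`.
#' @param communities character vector (same length/names as `ensembles`)
#'   assigning each group to a community.
#' @return named list, one `bayes_layman_result` per community: list with
#'   `community`, `metric_draws` (n_draws x 6 matrix), `modes` and
#'   `credible` (per metric, from [posterior_summary()]).
#' @export
bayes_layman <- function(ensembles, communities) {
  stopifnot(length(ensembles) == length(communities))
  nd <- vapply(ensembles, function(e) e$n_draws, integer(1))
  if (length(unique(nd)) != 1) {
    stop("all ensembles must share n_draws; got ",
         paste(unique(nd), collapse = ", "))
  }
  nd <- nd[1]
  out <- lapply(split(seq_along(ensembles), communities), function(idx) {
    if (length(idx) < 2) {
      stop("community needs at least 2 groups for nearest-neighbour metrics")
    }
    mus <- lapply(ensembles[idx], function(e) e$mu)
    metric_draws <- matrix(NA_real_, nd, 6)
    colnames(metric_draws) <- c("dC_range", "dN_range", "TA", "CD", "MNND",
                                "SDNND")
    for (j in seq_len(nd)) {
      pts <- t(vapply(mus, function(m) m[j, ], numeric(2)))
      metric_draws[j, ] <- layman_metrics(pts)
    }
    sums <- apply(metric_draws, 2, posterior_summary, simplify = FALSE)
    structure(list(
      community = communities[idx][1],
      n_groups = length(idx),
      metric_draws = metric_draws,
      modes = vapply(sums, function(s) s$mode, numeric(1)),
      credible = lapply(sums, function(s) s$credible)
    ), class = "bayes_layman_result")
  })
  out
}

#' @export
print.bayes_layman_result <- function(x, ...) {
  cat(sprintf("<bayes_layman_result> community %s (%d groups)\n modes: %s\n",
              x$community, x$n_groups,
              paste(sprintf("%s = %.3f", names(x$modes), x$modes),
                    collapse = ", ")))
  invisible(x)
}

#' Fit niche ensembles for every group in a sample table
#'
#' Convenience wrapper: splits the table by a grouping scheme, fits a
#' posterior ensemble per group (skipping groups under `min_n` points) and
#' labels each ensemble with its community (water-body type).
#'
#' @param table a [sample_table()].
#' @param grouping `"site_by_ffg"` (site x FFG groups) or `"ffg_by_type"`
#'   (water-body type x FFG groups).
#' @param n_draws,seed,prior passed to [fit_bivariate_posterior()]; each
#'   group gets a distinct seed derived stably from `seed` and the group
#'   label.
#' @param min_n minimum points per fitted group.
#' @return list with `ensembles` (named list) and `communities` (named
#'   character vector of water-body types).
#' @export
fit_group_ensembles <- function(table,
                                grouping = c("site_by_ffg", "ffg_by_type"),
                                n_draws = 10000L, seed = 1L,
                                prior = niw_prior(), min_n = 3L) {
  stopifnot(inherits(table, "sample_table"))
  grouping <- match.arg(grouping)
  key <- if (grouping == "site_by_ffg") {
    paste(table$site_id, table$ffg, sep = ".")
  } else {
    paste(table$wb_type, table$ffg, sep = ".")
  }
  idx_by_group <- split(seq_len(nrow(table)), key)
  idx_by_group <- idx_by_group[vapply(idx_by_group, length, 1L) >= min_n]
  if (!length(idx_by_group)) stop("no group reaches min_n = ", min_n)
  ensembles <- list(); communities <- character(0)
  for (g in names(idx_by_group)) {
    idx <- idx_by_group[[g]]
    ensembles[[g]] <- fit_bivariate_posterior(
      table$d13C[idx], table$d15N[idx], n_draws = n_draws,
      seed = derive_seed(seed, g), prior = prior, group = g)
    communities[g] <- table$wb_type[idx[1]]
  }
  list(ensembles = ensembles, communities = communities)
}
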