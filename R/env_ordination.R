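## Linking per-site niche metrics to environmental stressors: z-scaling,
## Mahalanobis response dissimilarity, exhaustive BIOENV subset selection
## by Spearman rank correlation, distance-based redundancy analysis
## (dbRDA) via Gower double-centering, and permutation tests on the
## constrained fit.

#' Z-score an environmental matrix
#'
#' Column-wise standardization to mean 0 and unit sample variance, the
#' conventional pre-treatment before distance-based variable selection.
#'
#' @param raw numeric matrix or data frame (sites x variables).
#' @return numeric matrix of the same shape with attribute `scaled = TRUE`.
#' @export
zscore_env <- function(raw) {
  m <- as.matrix(raw)
  storage.mode(m) <- "double"
  if (nrow(m) < 2) stop("need at least 2 sites")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  }
  out <- scale(m)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "scaled") <- TRUE
  out
}

#' Site dissimilarity matrix
#'
#' Euclidean distance, or Mahalanobis distance: Euclidean distance after
#' whitening the columns by the inverse square root of their covariance,
#' which removes scale and correlation among the response variables. With
#' about as many variables as sites the covariance is near-singular; the
#' default uses a pseudo-inverse square root (eigenvalues below
#' `tol * max(eigenvalue)` dropped, with a warning), while
#' `strict = TRUE` turns singularity into an error.
#'
#' @param m numeric matrix (sites x variables), site ids as rownames.
#' @param metric `"mahalanobis"` or `"euclidean"`.
#' @param strict error (rather than pseudo-invert) on singular covariance.
#' @param tol relative eigenvalue tolerance for the pseudo-inverse.
#' @return a `dist` object with attribute `metric`.
#' @export
dissimilarity <- function(m, metric = c("mahalanobis", "euclidean"),
                          strict = FALSE, tol = 1e-8) {
  metric <- match.arg(metric)
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (nrow(m) < 2) stop("need at least 2 sites")
  if (metric == "euclidean") {
    d <- stats::dist(m)
  } else {
    S <- stats::cov(m)
    e <- eigen(S, symmetric = TRUE)
    keep <- e$values > tol * max(e$values)
    if (!all(keep)) {
      if (strict) stop("singular covariance in mahalanobis distance (",
                       sum(!keep), " null direction(s))")
      warning("near-singular covariance: using pseudo-inverse over ",
              sum(keep), " of ", length(keep), " directions", call. = FALSE)
    }
    W <- e$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(e$values[keep]), sum(keep))
    d <- stats::dist(sweep(m, 2, colMeans(m)) %*% W)
  }
  attr(d, "metric") <- metric
  d
}

#' Exhaustive BIOENV subset selection
#'
#' For every non-empty subset of the (scaled) environmental variables,
#' computes the Euclidean inter-site distance on that subset and its
#' Spearman rank correlation (average ranks for ties) with the biotic
#' response dissimilarity; returns the subset maximizing the correlation
#' together with the full ranking.
#'
#' @param env scaled environmental matrix (sites x variables), site order
#'   matching `response`.
#' @param response a `dist` of the same sites (e.g. from
#'   [dissimilarity()] on the Layman metric matrix).
#' @param max_vars restrict subsets to at most this many variables
#'   (`Inf` = all; the search is exhaustive, 2^p - 1 subsets).
#' @return a `bioenv_result`: list with `best_subset` (character),
#'   `rho`, and `all_subsets` (data frame `subset`, `size`, `rho`,
#'   sorted by decreasing `rho`).
#' @export
bioenv_search <- function(env, response, max_vars = Inf) {
  env <- as.matrix(env)
  n <- nrow(env)
  if (n != attr(response, "Size")) {
    stop("site mismatch: env has ", n, " rows, response has ",
         attr(response, "Size"))
  }
  p <- ncol(env)
  if (p > 20) stop("exhaustive search limited to 20 variables, got ", p)
  vars <- colnames(env)
  if (is.null(vars)) vars <- paste0("V", seq_len(p))
  rv <- as.vector(response)
  rows <- list()
  for (k in seq_len(min(p, max_vars))) {
    combs <- utils::combn(p, k)
    for (j in seq_len(ncol(combs))) {
      idx <- combs[, j]
      dv <- as.vector(stats::dist(env[, idx, drop = FALSE]))
      rho <- stats::cor(dv, rv, method = "spearman")
      rows[[length(rows) + 1L]] <- data.frame(
        subset = paste(vars[idx], collapse = "+"), size = k, rho = rho,
        stringsAsFactors = FALSE)
    }
  }
  all_subsets <- do.call(rbind, rows)
  all_subsets <- all_subsets[order(-all_subsets$rho), ]
  rownames(all_subsets) <- NULL
  best <- strsplit(all_subsets$subset[1], "+", fixed = TRUE)[[1]]
  structure(list(best_subset = best, rho = all_subsets$rho[1],
                 all_subsets = all_subsets),
            class = "bioenv_result")
}

#' @export
print.bioenv_result <- function(x, ...) {
  cat(sprintf("<bioenv_result> best subset {%s}, Spearman rho = %.4f (%d subsets searched)\n",
              paste(x$best_subset, collapse = ", "), x$rho,
              nrow(x$all_subsets)))
  invisible(x)
}

## Gower-centered matrix G from a dist: G = C (-0.5 D^2) C
.gower_center <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  A <- -0.5 * D^2
  C <- diag(n) - matrix(1 / n, n, n)
  C %*% A %*% C
}

## hat matrix of a centered constraint matrix
.hat_matrix <- function(X) {
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  qx <- qr(X)
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  tcrossprod(Q)
}

#' Distance-based redundancy analysis
#'
#' Constrained ordination of a dissimilarity matrix: the Gower-centered
#' matrix `G` of `-0.5 d^2` is projected onto the column space of the
#' (centered) constraints via the hat matrix `H`; eigenanalysis of `HGH`
#' gives the constrained axes and of `(I-H)G(I-H)` the residual axes.
#' Negative eigenvalues (possible for non-Euclidean dissimilarities) are
#' clipped to zero with a warning and reported.
#'
#' @param response a `dist` over the sites.
#' @param constraints numeric matrix/data frame of explanatory variables
#'   (sites x q, same site order).
#' @return a `dbrda_result`: list with `constrained_eig`,
#'   `unconstrained_eig`, `total_inertia`, `prop_explained` (per
#'   constrained axis), `constrained_prop` (sum), `site_scores`,
#'   `biplot_scores`, `rank`, `n`.
#' @export
dbrda_fit <- function(response, constraints) {
  X <- as.matrix(constraints)
  n <- attr(response, "Size")
  if (nrow(X) != n) stop("constraints have ", nrow(X), " rows, need ", n)
  if (n <= qr(scale(X, scale = FALSE))$rank) {
    stop("need more sites than independent constraint variables")
  }
  G <- .gower_center(response)
  total <- sum(diag(G))
  if (total <= 0) stop("non-positive total inertia: pathological dissimilarity")
  H <- .hat_matrix(X)
  Gc <- H %*% G %*% H
  IH <- diag(n) - H
  Gr <- IH %*% G %*% IH
  ec <- eigen((Gc + t(Gc)) / 2, symmetric = TRUE)
  er <- eigen((Gr + t(Gr)) / 2, symmetric = TRUE)
  clip <- function(v) {
    neg <- v < -1e-8 * max(abs(v), 1)
    if (any(neg)) warning(sum(neg), " negative eigenvalue(s) clipped",
                          call. = FALSE)
    pmax(v, 0)
  }
  tol <- 1e-9 * max(ec$values, 1)
  keep_c <- which(clip(ec$values) > tol)
  lam_c <- ec$values[keep_c]
  keep_r <- which(clip(er$values) > tol)
  lam_r <- er$values[keep_r]
  scores <- ec$vectors[, keep_c, drop = FALSE] %*%
    diag(sqrt(lam_c), length(lam_c))
  if (length(lam_c)) {
    dimnames(scores) <- list(attr(response, "Labels"),
                             paste0("dbRDA", seq_along(lam_c)))
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  biplot <- if (length(lam_c)) {
    suppressWarnings(stats::cor(Xc, scores))
  } else {
    NULL
  }
  structure(list(constrained_eig = lam_c, unconstrained_eig = lam_r,
                 total_inertia = total,
                 prop_explained = lam_c / total,
                 constrained_prop = sum(lam_c) / total,
                 site_scores = scores, biplot_scores = biplot,
                 rank = length(lam_c), n = n),
            class = "dbrda_result")
}

#' @export
print.dbrda_result <- function(x, ...) {
  cat(sprintf("<dbrda_result> %d sites, %d constrained axes; constrained inertia %.1f%% of total\n",
              x$n, x$rank, 100 * x$constrained_prop))
  cat(" axis proportions:",
      paste(sprintf("%.3f", x$prop_explained), collapse = ", "), "\n")
  invisible(x)
}

## traces needed for pseudo-F under a permutation of G's rows/cols
.trace_HG <- function(H, G) sum(H * G)  # = trace(HG) for symmetric H, G

#' Permutation tests for the constrained ordination
#'
#' Pseudo-F tests by free permutation of site rows of the dissimilarity
#' matrix. `scope = "model"` tests the whole constrained fit; `"terms"`
#' tests each constraint sequentially (added in column order); `"axes"`
#' tests each constrained axis marginally against the full-model
#' residual. p-values use the `(1 + #{F* >= F}) / (1 + n_perm)`
#' convention.
#'
#' @param response a `dist` over sites.
#' @param constraints explanatory matrix (sites x q).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @param scope `"model"`, `"terms"` or `"axes"`.
#' @return data frame with one row per tested component: `component`,
#'   `df`, `pseudo_F`, `p_value`.
#' @export
permutation_test <- function(response, constraints, n_perm = 999L,
                             seed = 1L, scope = c("model", "terms", "axes")) {
  scope <- match.arg(scope)
  if (n_perm < 99) stop("n_perm must be >= 99")
  X <- as.matrix(constraints)
  n <- attr(response, "Size")
  if (factorial(min(n, 170)) <= n_perm) {
    warning("only ", factorial(n), " distinct permutations exist for n = ",
            n, call. = FALSE)
  }
  G <- .gower_center(response)
  H <- .hat_matrix(X)
  q <- qr(scale(X, scale = FALSE))$rank
  df_res <- n - q - 1
  if (df_res < 1) stop("no residual degrees of freedom")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  perms <- replicate(n_perm, sample.int(n), simplify = FALSE)

  stat_model <- function(Gp) {
    con <- .trace_HG(H, Gp)
    res <- sum(diag(Gp)) - con
    (con / q) / (res / df_res)
  }
  if (scope == "model") {
    F_obs <- stat_model(G)
    F_perm <- vapply(perms, function(p) stat_model(G[p, p]), numeric(1))
    out <- data.frame(component = "model", df = q, pseudo_F = F_obs,
                      p_value = (1 + sum(F_perm >= F_obs)) / (1 + n_perm))
  } else if (scope == "terms") {
    Hs <- lapply(seq_len(ncol(X)), function(k) {
      .hat_matrix(X[, seq_len(k), drop = FALSE])
    })
    term_stats <- function(Gp) {
      tr <- vapply(Hs, .trace_HG, numeric(1), G = Gp)
      extra <- diff(c(0, tr))
      res <- sum(diag(Gp)) - tr[length(tr)]
      extra / (res / df_res)
    }
    F_obs <- term_stats(G)
    F_perm <- vapply(perms, function(p) term_stats(G[p, p]),
                     numeric(length(F_obs)))
    F_perm <- matrix(F_perm, nrow = length(F_obs))
    out <- data.frame(
      component = colnames(X) %||% paste0("term", seq_len(ncol(X))),
      df = 1,
      pseudo_F = F_obs,
      p_value = vapply(seq_along(F_obs), function(i) {
        (1 + sum(F_perm[i, ] >= F_obs[i])) / (1 + n_perm)
      }, numeric(1)))
  } else {
    fit <- dbrda_fit(response, X)
    res_ms <- (fit$total_inertia - sum(fit$constrained_eig)) / df_res
    F_obs <- fit$constrained_eig / res_ms
    nax <- length(F_obs)
    F_perm <- vapply(perms, function(p) {
      Gp <- G[p, p]
      Gc <- H %*% Gp %*% H
      lam <- sort(eigen((Gc + t(Gc)) / 2, symmetric = TRUE,
                        only.values = TRUE)$values, decreasing = TRUE)
      lam <- pmax(lam[seq_len(nax)], 0)
      res <- sum(diag(Gp)) - .trace_HG(H, Gp)
      lam / (res / df_res)
    }, numeric(nax))
    F_perm <- matrix(F_perm, nrow = nax)
    out <- data.frame(
      component = paste0("dbRDA", seq_len(nax)),
      df = 1,
      pseudo_F = F_obs,
      p_value = vapply(seq_len(nax), function(i) {
        (1 + sum(F_perm[i, ] >= F_obs[i])) / (1 + n_perm)
      }, numeric(1)))
  }
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
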