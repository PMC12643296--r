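## Maximum-likelihood niche ellipses and their pairwise overlap areas.
## An ellipse at coverage p of a bivariate normal is
##   {x : (x - c)' Sigma^-1 (x - c) <= q(p)},  q(p) = -2 log(1 - p),
## the chi-square(2) quantile; its area is pi * sqrt(det(Sigma)) * q(p).

#' Chi-square(2) radius-squared for a coverage proportion
#'
#' @param p coverage proportion in (0, 1).
#' @return `q(p) = -2 log(1 - p)`, the squared Mahalanobis radius of the
#'   ellipse containing proportion `p` of a bivariate normal.
#' @export
coverage_radius2 <- function(p) {
  stopifnot(all(p > 0), all(p < 1))
  -2 * log(1 - p)
}

#' Construct an ellipse specification
#'
#' @param center numeric 2-vector (permil).
#' @param sigma 2 x 2 symmetric positive-definite covariance (permil^2).
#' @param p coverage proportion in (0, 1).
#' @return an `ellipse_spec` with fields `center`, `sigma`, `p`, `q`
#'   (squared radius) and `area` (permil^2).
#' @export
ellipse_spec <- function(center, sigma, p = 0.95) {
  center <- as.numeric(center)
  stopifnot(length(center) == 2, is.matrix(sigma), all(dim(sigma) == 2))
  sigma <- (sigma + t(sigma)) / 2
  if (det(sigma) <= 0 || sigma[1, 1] <= 0) {
    stop("sigma must be symmetric positive definite")
  }
  q <- coverage_radius2(p)
  structure(list(center = center, sigma = sigma, p = p, q = q,
                 area = pi * sqrt(det(sigma)) * q),
            class = "ellipse_spec")
}

#' @export
print.ellipse_spec <- function(x, ...) {
  cat(sprintf("<ellipse_spec> center (%.3f, %.3f), p = %.4f, area = %.4f permil^2\n",
              x$center[1], x$center[2], x$p, x$area))
  invisible(x)
}

#' Maximum-likelihood ellipse of a point set
#'
#' Center = sample mean; covariance = maximum-likelihood estimate
#' (denominator n, not n-1); boundary at the chi-square(2) radius for
#' coverage `p`.
#'
#' @inheritParams convex_hull_area
#' @param p coverage proportion (default 0.95, the conventional interval
#'   for overlap comparisons).
#' @return an [ellipse_spec()].
#' @export
ml_ellipse <- function(x, y = NULL, p = 0.95) {
  m <- .as_xy(x, y)
  n <- nrow(m)
  if (n < 3) stop("at least 3 points required")
  ctr <- colMeans(m)
  dev <- sweep(m, 2, ctr)
  sigma_ml <- crossprod(dev) / n
  if (det(sigma_ml) <= .Machine$double.eps) {
    stop("singular ML covariance: points are (near-)collinear")
  }
  ellipse_spec(ctr, sigma_ml, p)
}

## membership test helper: squared Mahalanobis radius of points (rows) in e
.ellipse_r2 <- function(pts, e) {
  dev <- sweep(pts, 2, e$center)
  si <- solve(e$sigma)
  rowSums((dev %*% si) * dev)
}

#' Overlap area and proportion of two niche ellipses
#'
#' Computes the intersection area of two coverage ellipses by adaptive 1-D
#' quadrature: the plane is transformed so the first ellipse becomes the
#' unit disk (which conditions the integrand for eccentric ellipses), and
#' the chord-overlap length between the disk and the mapped second ellipse
#' is integrated. The summary proportion is Jaccard-style,
#' `overlap / (area1 + area2 - overlap)`; the per-ellipse fractions are
#' reported alongside so either normalization can be audited.
#'
#' @param e1,e2 [ellipse_spec()] objects.
#' @param rel_tol relative tolerance requested from the quadrature.
#' @return list with `area1`, `area2`, `overlap_area`, `proportion`
#'   (overlap over union), `prop1` (`overlap/area1`), `prop2`
#'   (`overlap/area2`).
#' @export
ellipse_overlap <- function(e1, e2, rel_tol = 1e-6) {
  stopifnot(inherits(e1, "ellipse_spec"), inherits(e2, "ellipse_spec"))
  ## map e1 to the unit disk: x = c1 + L1 u with L1 = chol(q1 * sigma1)'
  L1 <- t(chol(e1$q * e1$sigma))
  det_L1 <- abs(det(L1))
  ## e2 in u-coordinates: (u - c)' A (u - c) <= 1
  Li <- solve(L1)
  c2u <- drop(Li %*% (e2$center - e1$center))
  A <- t(L1) %*% solve(e2$sigma * e2$q) %*% L1
  A <- (A + t(A)) / 2

  ## chord of {u' A u style ellipse} at abscissa x: solve quadratic in y
  a <- A[2, 2]
  chord <- function(xs) {
    vapply(xs, function(x) {
      dx <- x - c2u[1]
      b <- 2 * A[1, 2] * dx
      cc <- A[1, 1] * dx^2 - 1
      disc <- b^2 - 4 * a * cc
      if (disc <= 0) return(0)
      r <- sqrt(disc) / (2 * a)
      ylo <- c2u[2] - b / (2 * a) - r
      yhi <- c2u[2] - b / (2 * a) + r
      dlo <- -sqrt(max(0, 1 - x^2))
      dhi <- -dlo
      max(0, min(yhi, dhi) - max(ylo, dlo))
    }, numeric(1))
  }
  ## x-range where both regions can meet
  hw2 <- sqrt(solve(A)[1, 1])          # half-width of mapped e2 along x
  lo <- max(-1, c2u[1] - hw2)
  hi <- min(1, c2u[1] + hw2)
  if (lo >= hi) {
    ov_u <- 0
  } else {
    quad <- stats::integrate(chord, lo, hi, rel.tol = rel_tol,
                             abs.tol = rel_tol * pi, subdivisions = 500L,
                             stop.on.error = FALSE)
    if (quad$message != "OK" && quad$value > 0 &&
        quad$abs.error > 1e-4 * max(quad$value, pi)) {
      stop("overlap quadrature did not reach tolerance (abs.error = ",
           format(quad$abs.error), ")")
    }
    ov_u <- max(0, quad$value)
  }
  overlap <- ov_u * det_L1
  overlap <- min(overlap, e1$area, e2$area)
  union_area <- e1$area + e2$area - overlap
  list(area1 = e1$area, area2 = e2$area, overlap_area = overlap,
       proportion = overlap / union_area,
       prop1 = overlap / e1$area, prop2 = overlap / e2$area)
}

#' Pairwise pond/ditch niche overlap per FFG
#'
#' For each FFG present with enough samples in both water-body types, fits
#' ML ellipses at coverage `p` to the pond and ditch clouds and reports
#' their overlap. Running it on differently corrected tables (d15N-only
#' vs d15N + d13C) reproduces the two-column overlap comparison layout.
#'
#' @param table a [sample_table()].
#' @param p coverage proportion.
#' @param min_n minimum samples per (type, FFG) group.
#' @return data frame with one row per FFG: areas, overlap area, and the
#'   three overlap proportions (in percent for `overlap_pct`).
#' @export
ffg_overlap_table <- function(table, p = 0.95, min_n = 3L) {
  stopifnot(inherits(table, "sample_table"))
  rows <- list()
  for (f in sort(unique(table$ffg))) {
    po <- table[table$ffg == f & table$wb_type == "pond", , drop = FALSE]
    di <- table[table$ffg == f & table$wb_type == "ditch", , drop = FALSE]
    if (nrow(po) < min_n || nrow(di) < min_n) next
    e1 <- ml_ellipse(po$d13C, po$d15N, p = p)
    e2 <- ml_ellipse(di$d13C, di$d15N, p = p)
    ov <- ellipse_overlap(e1, e2)
    rows[[f]] <- data.frame(
      ffg = f, n_pond = nrow(po), n_ditch = nrow(di),
      area_pond = ov$area1, area_ditch = ov$area2,
      overlap_area = ov$overlap_area,
      overlap_pct = 100 * ov$proportion,
      pct_of_pond = 100 * ov$prop1, pct_of_ditch = 100 * ov$prop2,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(ffg = character(0), n_pond = integer(0),
                      n_ditch = integer(0), area_pond = numeric(0),
                      area_ditch = numeric(0), overlap_area = numeric(0),
                      overlap_pct = numeric(0), pct_of_pond = numeric(0),
                      pct_of_ditch = numeric(0))
  }
  rownames(out) <- NULL
  out
}
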