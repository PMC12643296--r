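## Independent brute-force oracles used to check the package's geometry
## and statistics implementations. These deliberately use different
## algorithms from the package code.

## Convex hull area via gift wrapping (Jarvis march) + fan triangulation.
oracle_hull_area <- function(m) {
  m <- unique(m)
  n <- nrow(m)
  if (n < 3) return(0)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  start <- order(m[, 1], m[, 2])[1]
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == 1L) 2L else 1L
    for (r in seq_len(n)) {
      if (r == p || r == q) next
      cr <- cross(m[p, ], m[q, ], m[r, ])
      if (cr < 0 ||
          (cr == 0 && sum((m[r, ] - m[p, ])^2) > sum((m[q, ] - m[p, ])^2))) {
        q <- r
      }
    }
    p <- q
    if (p == start) break
    if (length(hull) > n) stop("jarvis march failed")
  }
  v <- m[hull, , drop = FALSE]
  if (nrow(v) < 3) return(0)
  ## fan triangulation from the first vertex
  area <- 0
  for (k in 2:(nrow(v) - 1)) {
    area <- area + cross(v[1, ], v[k, ], v[k + 1, ]) / 2
  }
  abs(area)
}

## Naive O(n^2) Layman metrics.
oracle_layman <- function(m) {
  n <- nrow(m)
  ctr <- c(mean(m[, 1]), mean(m[, 2]))
  cd <- mean(sqrt(rowSums(sweep(m, 2, ctr)^2)))
  nnd <- sapply(seq_len(n), function(i) {
    min(sqrt(rowSums(sweep(m[-i, , drop = FALSE], 2, m[i, ])^2)))
  })
  c(dC_range = max(m[, 1]) - min(m[, 1]),
    dN_range = max(m[, 2]) - min(m[, 2]),
    TA = oracle_hull_area(m), CD = cd, MNND = mean(nnd),
    SDNND = sd(nnd))
}

## Minimum-width sample window HDI (different algorithm from the
## KDE-threshold HDI in the package).
oracle_hdi_window <- function(draws, p) {
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(p * n)
  widths <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(widths)
  c(lo = x[i], hi = x[i + k - 1])
}

## Monte-Carlo ellipse overlap on a bounding box of both ellipses.
oracle_mc_overlap <- function(e1, e2, n_mc = 2e5) {
  bb <- function(e) {
    half <- sqrt(diag(e$sigma) * e$q)
    rbind(e$center - half, e$center + half)
  }
  b <- rbind(bb(e1), bb(e2))
  lo <- c(min(b[, 1]), min(b[, 2]))
  hi <- c(max(b[, 1]), max(b[, 2]))
  pts <- cbind(runif(n_mc, lo[1], hi[1]), runif(n_mc, lo[2], hi[2]))
  inside <- function(e) {
    dev <- sweep(pts, 2, e$center)
    rowSums((dev %*% solve(e$sigma)) * dev) <= e$q
  }
  hits <- inside(e1) & inside(e2)
  area_box <- prod(hi - lo)
  est <- mean(hits) * area_box
  se <- sd(hits) / sqrt(n_mc) * area_box
  list(est = est, se = se)
}

## Direct-formula Mahalanobis distance matrix.
oracle_mahalanobis <- function(m) {
  S <- cov(m)
  Si <- solve(S)
  n <- nrow(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- m[i, ] - m[j, ]
    d[i, j] <- sqrt(drop(t(v) %*% Si %*% v))
  }
  as.dist(d)
}

## Classical RDA constrained eigenvalues: regress coordinates on the
## constraints, then eigen-decompose the fitted cross-product.
oracle_rda_eigen <- function(Y, X) {
  Yc <- scale(Y, scale = FALSE)
  fit <- lm.fit(cbind(1, as.matrix(X)), Yc)
  Yhat <- Yc - fit$residuals
  ev <- eigen(crossprod(Yhat), symmetric = TRUE, only.values = TRUE)$values
  ev[ev > 1e-9 * max(ev)]
}

## strip a sample_table down to its bare data frame for comparisons
plain <- function(tab) {
  df <- as.data.frame(tab)
  attributes(df) <- attributes(df)[c("names", "row.names", "class")]
  rownames(df) <- NULL
  df
}

## small convenience for building validated tables in tests
make_table <- function(d13C, d15N, site_id, wb_type, ffg,
                       ids = sprintf("s%03d", seq_along(d13C))) {
  sample_table(data.frame(
    sample_id = ids, site_id = site_id, wb_type = wb_type, ffg = ffg,
    taxon = NA_character_, d13C = d13C, d15N = d15N,
    stringsAsFactors = FALSE))
}
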