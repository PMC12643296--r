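## Layman community metrics: geometric descriptors of a point cloud in
## (d13C, d15N) space. All functions take plain coordinate vectors so they
## work both on raw samples and on posterior centroid draws.

.as_xy <- function(x, y) {
  if (is.null(y)) {
    m <- as.matrix(x)
    stopifnot(ncol(m) == 2)
  } else {
    m <- cbind(x, y)
  }
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) stop("non-finite coordinates")
  m
}

#' Convex hull area of a 2-D point set
#'
#' Total area (TA) of the convex hull in permil^2, the classical measure of
#' total niche width. Computed with the planar hull ([grDevices::chull()])
#' and the shoelace formula; fewer than three non-collinear points give 0.
#'
#' @param x numeric vector of d13C values, or a 2-column matrix.
#' @param y numeric vector of d15N values (omit when `x` is a matrix).
#' @return hull area (permil^2).
#' @export
convex_hull_area <- function(x, y = NULL) {
  m <- .as_xy(x, y)
  m <- unique(m)
  if (nrow(m) < 3) return(0)
  h <- grDevices::chull(m[, 1], m[, 2])
  hx <- m[h, 1]; hy <- m[h, 2]
  # shoelace; chull returns vertices in clockwise order, take |.|
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

#' The six Layman community metrics
#'
#' Computes the standard geometric descriptors of a community's isotopic
#' niche: the d13C range, the d15N range, the convex hull area (TA,
#' permil^2), the mean Euclidean distance to the centroid (CD), the mean
#' nearest-neighbour distance (MNND) and the sample standard deviation of
#' nearest-neighbour distances (SDNND). CD measures niche width and
#' spacing, MNND density/clustering, SDNND evenness of that density.
#'
#' @inheritParams convex_hull_area
#' @return named numeric vector with elements `dC_range`, `dN_range`,
#'   `TA`, `CD`, `MNND`, `SDNND`. A single point yields all zeros with a
#'   warning; `SDNND` is 0 for two points.
#' @export
layman_metrics <- function(x, y = NULL) {
  m <- .as_xy(x, y)
  n <- nrow(m)
  metrics <- c(dC_range = 0, dN_range = 0, TA = 0, CD = 0, MNND = 0,
               SDNND = 0)
  if (n == 1) {
    warning("single point: all Layman metrics are 0", call. = FALSE)
    return(metrics)
  }
  metrics[["dC_range"]] <- diff(range(m[, 1]))
  metrics[["dN_range"]] <- diff(range(m[, 2]))
  metrics[["TA"]] <- convex_hull_area(m)
  ctr <- colMeans(m)
  metrics[["CD"]] <- mean(sqrt((m[, 1] - ctr[1])^2 + (m[, 2] - ctr[2])^2))
  d <- as.matrix(stats::dist(m))
  diag(d) <- Inf
  nnd <- apply(d, 1, min)
  metrics[["MNND"]] <- mean(nnd)
  metrics[["SDNND"]] <- if (n > 2) stats::sd(nnd) else 0
  metrics
}

#' Layman metrics for each community in a sample table
#'
#' Splits a sample table by a community key and computes the six Layman
#' metrics on each community's (d13C, d15N) cloud.
#'
#' @param table a [sample_table()].
#' @param community grouping column: `"wb_type"` (default) or `"site_id"`.
#' @return long-format data frame with columns `community`, `metric`,
#'   `value`.
#' @export
layman_by_community <- function(table, community = c("wb_type", "site_id")) {
  stopifnot(inherits(table, "sample_table"))
  community <- match.arg(community)
  keys <- table[[community]]
  res <- lapply(split(seq_len(nrow(table)), keys), function(idx) {
    layman_metrics(table$d13C[idx], table$d15N[idx])
  })
  do.call(rbind, lapply(names(res), function(k) {
    data.frame(community = k, metric = names(res[[k]]),
               value = unname(res[[k]]), stringsAsFactors = FALSE)
  }))
}

#' Per-site Layman metric matrix
#'
#' Builds the site x metric response matrix used to relate niche geometry
#' to environmental stressors: for each site, the six Layman metrics are
#' computed over the site's samples (optionally after dropping small FFG
#' groups upstream).
#'
#' @param table a [sample_table()].
#' @param by_ffg_centroids logical; when `TRUE` the metrics are computed on
#'   the FFG centroids within each site (group-level geometry) rather than
#'   on individual samples.
#' @return numeric matrix, sites in rows, the six metrics in columns, with
#'   a `wb_type` attribute giving each site's water-body type.
#' @export
site_metric_matrix <- function(table, by_ffg_centroids = TRUE) {
  stopifnot(inherits(table, "sample_table"))
  sites <- sort(unique(table$site_id))
  rows <- lapply(sites, function(s) {
    sub <- table[table$site_id == s, , drop = FALSE]
    if (by_ffg_centroids) {
      cx <- tapply(sub$d13C, sub$ffg, mean)
      cy <- tapply(sub$d15N, sub$ffg, mean)
      suppressWarnings(layman_metrics(as.numeric(cx), as.numeric(cy)))
    } else {
      suppressWarnings(layman_metrics(sub$d13C, sub$d15N))
    }
  })
  m <- do.call(rbind, rows)
  rownames(m) <- sites
  st <- unique(data.frame(site_id = table$site_id, wb_type = table$wb_type))
  attr(m, "wb_type") <- stats::setNames(st$wb_type, st$site_id)[sites]
  m
}

#' Write Layman metrics in long format
#'
#' @param df long data frame as returned by [layman_by_community()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_layman_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
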