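# Point-pattern and autocorrelation statistics: average nearest neighbour
# (ANN) ratio against the CSR null, global Moran's I with analytic and
# permutation inference, and quartic-kernel density surfaces with the
# standard-distance bandwidth rule. The cores are deliberately simple enough
# to check against O(n^2) brute force.

# Mean nearest-neighbour distance, chunked so n ~ a few thousand stays cheap
# without materialising one giant distance matrix.
mean_nn_distance <- function(pts, chunk = 512L) {
  n <- nrow(pts)
  x <- pts[, 1]; y <- pts[, 2]
  d <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    dx <- outer(x[s:e], x, "-"); dy <- outer(y[s:e], y, "-")
    m <- sqrt(dx * dx + dy * dy)
    m[cbind(seq_len(e - s + 1L), s:e)] <- Inf   # exclude self
    d[s:e] <- apply(m, 1, min)
  }
  mean(d)
}

#' Average nearest neighbour statistic
#'
#' Ratio of the observed mean nearest-neighbour distance to its expectation
#' under complete spatial randomness, with the conventional z-score:
#' \deqn{ANN = \bar D_O / \bar D_E,\quad \bar D_O = \sum_i d_i / n,\quad
#'       \bar D_E = 0.5 / \sqrt{n/A},}
#' \deqn{Z = (\bar D_O - \bar D_E)/SE,\quad SE = 0.26136 / \sqrt{n^2/A}.}
#' Ratios below 1 indicate clustering, near 1 randomness, above 1 dispersion.
#'
#' @param points two-column matrix (or data frame) of planar coordinates (m).
#' @param area study-area size in m^2; when omitted, the area of the
#'   axis-aligned minimum enclosing rectangle of the points is used.
#' @return Object of class `ann_result` with fields `d_obs`, `d_exp`, `ann`,
#'   `se`, `z`, `p`, `n`, `area`, `area_source`.
#' @export
nearest_neighbor_stat <- function(points, area = NULL) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 2) stop("at least 2 points required")
  if (!all(is.finite(pts))) stop("non-finite coordinates")
  if (is.null(area)) {
    a <- (max(pts[, 1]) - min(pts[, 1])) * (max(pts[, 2]) - min(pts[, 2]))
    if (a <= 0)
      stop("degenerate minimum enclosing rectangle (area 0); ",
           "supply the study area explicitly")
    area_source <- "min_enclosing_rect"
  } else {
    a <- as.numeric(area)
    if (a <= 0) stop("area must be positive")
    area_source <- "user"
  }
  d_obs <- mean_nn_distance(pts)
  d_exp <- 0.5 / sqrt(n / a)
  se <- 0.26136 / sqrt(n^2 / a)
  z <- (d_obs - d_exp) / se
  structure(list(d_obs = d_obs, d_exp = d_exp, ann = d_obs / d_exp,
                 se = se, z = z, p = 2 * pnorm(-abs(z)),
                 n = n, area = a, area_source = area_source),
            class = "ann_result")
}

#' @export
print.ann_result <- function(x, ...) {
  cat(sprintf("Average nearest neighbour: ANN = %.4f (z = %.3f, p = %.4g)\n",
              x$ann, x$z, x$p))
  cat(sprintf("  d_obs = %.3f m, d_exp = %.3f m, n = %d, A = %.4g m^2 (%s)\n",
              x$d_obs, x$d_exp, x$n, x$area, x$area_source))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Spatial weights

#' Build a spatial weights structure
#'
#' @param geoms either a two-column coordinate matrix (points; polygon inputs
#'   are reduced to centroids for distance-based schemes) or a
#'   [census_blocks] object (required for `rook`, which uses shared-boundary
#'   adjacency).
#' @param scheme `inverse_distance` (1/d within a cutoff; default cutoff is
#'   the maximum nearest-neighbour distance so no feature is isolated),
#'   `distance_band` (binary within `band`), `knn` (binary, `k` nearest,
#'   possibly asymmetric), or `rook` (polygons sharing a boundary segment of
#'   positive length).
#' @param cutoff,band,k scheme parameters (metres; `k` a count).
#' @param row_standardize divide each row by its sum.
#' @return Object of class `spatial_weights`: sparse triplets `i`, `j`, `w`,
#'   plus `n`, `s0` (grand sum), `scheme`, `row_standardized`.
#' @export
build_weights <- function(geoms,
                          scheme = c("inverse_distance", "distance_band",
                                     "knn", "rook"),
                          cutoff = NULL, band = NULL, k = NULL,
                          row_standardize = FALSE) {
  scheme <- match.arg(scheme)
  is_blocks <- inherits(geoms, "census_blocks")
  if (scheme == "rook") {
    if (!is_blocks) stop("rook weights need polygon (census_blocks) input")
    n <- length(geoms$block_id)
    if (n < 2) stop("need at least 2 features")
    trip <- rook_pairs(geoms)
    ii <- trip[, 1]; jj <- trip[, 2]; ww <- rep(1, nrow(trip))
  } else {
    pts <- if (is_blocks) block_centroids(geoms) else
      as.matrix(geoms)[, 1:2, drop = FALSE]
    n <- nrow(pts)
    if (n < 2) stop("need at least 2 features")
    dm <- as.matrix(stats::dist(pts))
    diag(dm) <- Inf
    if (scheme == "inverse_distance") {
      if (is.null(cutoff)) cutoff <- max(apply(dm, 1, min))
      sel <- which(dm <= cutoff & dm > 0, arr.ind = TRUE)
      ii <- sel[, 1]; jj <- sel[, 2]; ww <- 1 / dm[sel]
    } else if (scheme == "distance_band") {
      if (is.null(band)) stop("distance_band needs band")
      sel <- which(dm <= band, arr.ind = TRUE)
      ii <- sel[, 1]; jj <- sel[, 2]; ww <- rep(1, nrow(sel))
      empty <- setdiff(seq_len(n), unique(ii))
      if (length(empty))
        stop("isolated feature(s) with no neighbour within band: ",
             paste(empty, collapse = ", "))
    } else {                               # knn
      if (is.null(k)) stop("knn needs k")
      if (k >= n) stop("k must be < n")
      ii <- rep(seq_len(n), each = k)
      # apply() returns one k-column per feature; flattening column-major
      # keeps each feature's k neighbours contiguous, matching ii
      jj <- as.vector(apply(dm, 1, function(r) order(r)[seq_len(k)]))
      ww <- rep(1, length(ii))
    }
  }
  if (!length(ii)) stop("empty weights (no neighbour pairs)")
  if (row_standardize) {
    rs <- tapply(ww, ii, sum)
    ww <- ww / as.numeric(rs[as.character(ii)])
  }
  structure(list(i = as.integer(ii), j = as.integer(jj), w = as.numeric(ww),
                 n = as.integer(n), s0 = sum(ww), scheme = scheme,
                 row_standardized = isTRUE(row_standardize)),
            class = "spatial_weights")
}

# Shared-boundary (rook) adjacency: two polygons are neighbours when some pair
# of their edges is collinear with overlap of positive length.
rook_pairs <- function(blocks) {
  n <- length(blocks$block_id)
  edges_of <- lapply(blocks$rings, function(r) {
    m <- nrow(r)
    cbind(r, r[c(2:m, 1), , drop = FALSE])   # x1 y1 x2 y2
  })
  bb <- lapply(blocks$rings, geom_bbox)
  out_i <- integer(0); out_j <- integer(0)
  tol <- 1e-6
  overlap <- function(e1, e2) {
    # collinear test then 1-D overlap along the dominant axis
    d1 <- c(e1[3] - e1[1], e1[4] - e1[2])
    d2 <- c(e2[3] - e2[1], e2[4] - e2[2])
    if (abs(d1[1] * d2[2] - d1[2] * d2[1]) > tol * (sum(abs(d1)) + sum(abs(d2)))) return(FALSE)
    # e2's endpoints must lie on e1's supporting line
    cr <- function(px, py) (e1[3] - e1[1]) * (py - e1[2]) - (e1[4] - e1[2]) * (px - e1[1])
    scale <- max(abs(d1)) + tol
    if (abs(cr(e2[1], e2[2])) > tol * scale || abs(cr(e2[3], e2[4])) > tol * scale)
      return(FALSE)
    ax <- if (abs(d1[1]) >= abs(d1[2])) c(e1[1], e1[3], e2[1], e2[3]) else
      c(e1[2], e1[4], e2[2], e2[4])
    lo <- max(min(ax[1], ax[2]), min(ax[3], ax[4]))
    hi <- min(max(ax[1], ax[2]), max(ax[3], ax[4]))
    hi - lo > tol
  }
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (bb[[a]]["xmin"] > bb[[b]]["xmax"] + tol ||
          bb[[b]]["xmin"] > bb[[a]]["xmax"] + tol ||
          bb[[a]]["ymin"] > bb[[b]]["ymax"] + tol ||
          bb[[b]]["ymin"] > bb[[a]]["ymax"] + tol) next
      ea <- edges_of[[a]]; eb <- edges_of[[b]]
      hit <- FALSE
      for (p in seq_len(nrow(ea))) {
        for (q in seq_len(nrow(eb))) {
          if (overlap(ea[p, ], eb[q, ])) { hit <- TRUE; break }
        }
        if (hit) break
      }
      if (hit) { out_i <- c(out_i, a, b); out_j <- c(out_j, b, a) }
    }
  }
  if (!length(out_i)) stop("no rook neighbours found")
  cbind(out_i, out_j)
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("Spatial weights (%s): n = %d, %d nonzero pairs, S0 = %.4f%s\n",
              x$scheme, x$n, length(x$w), x$s0,
              if (x$row_standardized) ", row-standardized" else ""))
  invisible(x)
}

#' Dense matrix form of a spatial weights object
#' @param w a [spatial_weights]
#' @export
weights_matrix <- function(w) {
  m <- matrix(0, w$n, w$n)
  m[cbind(w$i, w$j)] <- w$w
  m
}

# ---------------------------------------------------------------------------
# Moran's I

#' Global Moran's I
#'
#' \deqn{I = \frac{n}{S_0}\frac{\sum_i\sum_j w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with \eqn{z_i} the deviation of the attribute from its mean and \eqn{S_0}
#' the sum of all weights. \eqn{E[I] = -1/(n-1)}; under `inference =
#' "normal"`, \eqn{V[I] = E[I^2]-E[I]^2} uses the standard
#' normality-assumption moments (S1/S2 closed form); under `"permutation"`
#' a two-sided pseudo p-value over random relabelings is added.
#'
#' @param values numeric attribute, one per feature.
#' @param w a [spatial_weights] built on the same features.
#' @param inference `"normal"` or `"permutation"` (which also reports the
#'   analytic z).
#' @param n_perm number of permutations.
#' @param seed RNG seed for the permutations.
#' @return Object of class `moran_result` with `I`, `e_i`, `v_i`, `z`,
#'   `p_analytic`, and `p_perm`/`n_perm`/`seed` when permutation inference is
#'   requested.
#' @export
morans_i <- function(values, w, inference = c("normal", "permutation"),
                     n_perm = 999L, seed = 1L) {
  inference <- match.arg(inference)
  stopifnot(inherits(w, "spatial_weights"))
  n <- w$n
  if (length(values) != n) stop("values length does not match weights")
  if (!all(is.finite(values))) stop("non-finite values")
  if (stats::var(values) == 0) stop("zero variance, I undefined")
  z <- values - mean(values)
  m2 <- sum(z * z)
  I <- (n / w$s0) * sum(w$w * z[w$i] * z[w$j]) / m2
  e_i <- -1 / (n - 1)
  # normality-assumption moments
  W <- weights_matrix(w)
  S0 <- w$s0
  S1 <- sum((W + t(W))^2) / 2
  S2 <- sum((rowSums(W) + colSums(W))^2)
  e_i2 <- (n^2 * S1 - n * S2 + 3 * S0^2) / ((n^2 - 1) * S0^2)
  v_i <- e_i2 - e_i^2
  zsc <- (I - e_i) / sqrt(v_i)
  res <- list(I = I, e_i = e_i, v_i = v_i, z = zsc,
              p_analytic = 2 * pnorm(-abs(zsc)),
              p_perm = NULL, n_perm = NULL, seed = NULL)
  if (inference == "permutation") {
    set.seed(seed)
    sims <- vapply(seq_len(n_perm), function(b) {
      zp <- sample(z)
      (n / S0) * sum(w$w * zp[w$i] * zp[w$j]) / m2
    }, numeric(1))
    p_g <- (1 + sum(sims >= I)) / (n_perm + 1)
    p_l <- (1 + sum(sims <= I)) / (n_perm + 1)
    res$p_perm <- min(1, 2 * min(p_g, p_l))
    res$n_perm <- as.integer(n_perm)
    res$seed <- as.integer(seed)
  }
  structure(res, class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Global Moran's I = %.4f (E[I] = %.4f, z = %.3f, p = %.4g)\n",
              x$I, x$e_i, x$z, x$p_analytic))
  if (!is.null(x$p_perm))
    cat(sprintf("  permutation p = %.4g (%d permutations, seed %d)\n",
                x$p_perm, x$n_perm, x$seed))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Kernel density

#' Bandwidth by the standard-distance rule
#'
#' \deqn{h = 0.9\,\min(SD,\ \sqrt{1/\ln 2}\, D_m)\, n^{-0.2}} where SD is the
#' (weighted) standard distance of the points about their mean centre, Dm the
#' (weighted) median distance to the mean centre, and n the total weight
#' (point count when unweighted).
#'
#' @param points two-column coordinate matrix.
#' @param weights optional non-negative weights (default 1 per point).
#' @return bandwidth in metres.
#' @export
kde_bandwidth <- function(points, weights = NULL) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  n_pts <- nrow(pts)
  if (n_pts < 2) stop("at least 2 points required")
  if (is.null(weights)) weights <- rep(1, n_pts)
  if (any(weights < 0) || sum(weights) <= 0) stop("weights must be non-negative")
  cx <- sum(weights * pts[, 1]) / sum(weights)
  cy <- sum(weights * pts[, 2]) / sum(weights)
  d <- sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2)
  SD <- sqrt(sum(weights * d^2) / sum(weights))
  if (SD == 0) stop("all points coincident: zero standard distance")
  Dm <- weighted_median(d, weights)
  n <- sum(weights)
  0.9 * min(SD, sqrt(1 / log(2)) * Dm) * n^(-0.2)
}

weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1]]
}

#' Quartic kernel density surface
#'
#' Each point contributes a quartic (biweight) kernel of radius `bandwidth`,
#' \deqn{K(d) = \frac{3}{\pi h^2}\left(1 - d^2/h^2\right)^2, \quad d < h,}
#' scaled by its weight, so the surface integrates to the total weight and is
#' exactly zero beyond `bandwidth` of every point.
#'
#' @param points two-column coordinate matrix.
#' @param weights per-point weights (> 0), default 1.
#' @param cell_size raster resolution in metres.
#' @param bandwidth kernel radius in metres; [kde_bandwidth()] when omitted.
#' @param extent optional `c(xmin, ymin, xmax, ymax)`; default point bbox
#'   padded by the bandwidth.
#' @return Object of class `kde_surface`: `origin` (lower-left corner),
#'   `cell_size`, `values` (matrix, rows = x index, cols = y index),
#'   `bandwidth`, `bandwidth_source`.
#' @export
kernel_density <- function(points, weights = NULL, cell_size,
                           bandwidth = NULL, extent = NULL) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  np <- nrow(pts)
  if (is.null(weights)) weights <- rep(1, np)
  if (any(weights <= 0)) stop("weights must be positive")
  if (cell_size <= 0) stop("cell_size must be positive")
  bandwidth_source <- if (is.null(bandwidth)) "rule" else "user"
  if (is.null(bandwidth)) bandwidth <- kde_bandwidth(pts, weights)
  if (bandwidth <= 0) stop("bandwidth must be positive")
  h <- bandwidth
  if (is.null(extent))
    extent <- c(min(pts[, 1]) - h, min(pts[, 2]) - h,
                max(pts[, 1]) + h, max(pts[, 2]) + h)
  nxc <- max(1L, ceiling((extent[3] - extent[1]) / cell_size))
  nyc <- max(1L, ceiling((extent[4] - extent[2]) / cell_size))
  xc <- extent[1] + (seq_len(nxc) - 0.5) * cell_size
  yc <- extent[2] + (seq_len(nyc) - 0.5) * cell_size
  vals <- matrix(0, nxc, nyc)
  for (k in seq_len(np)) {
    ix <- which(abs(xc - pts[k, 1]) < h)
    iy <- which(abs(yc - pts[k, 2]) < h)
    if (!length(ix) || !length(iy)) next
    d2 <- outer((xc[ix] - pts[k, 1])^2, (yc[iy] - pts[k, 2])^2, "+")
    u2 <- d2 / h^2
    kv <- ifelse(u2 < 1, (3 / (pi * h^2)) * (1 - u2)^2, 0)
    vals[ix, iy] <- vals[ix, iy] + weights[k] * kv
  }
  structure(list(origin = c(extent[1], extent[2]), cell_size = cell_size,
                 values = vals, bandwidth = h,
                 bandwidth_source = bandwidth_source),
            class = "kde_surface")
}

#' @export
print.kde_surface <- function(x, ...) {
  pk <- which(x$values == max(x$values), arr.ind = TRUE)[1, ]
  cat(sprintf("KDE surface: %d x %d cells of %.1f m, bandwidth %.2f m (%s)\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$bandwidth,
              x$bandwidth_source))
  cat(sprintf("  integral %.4f, peak %.6g at cell (%d, %d)\n",
              sum(x$values) * x$cell_size^2, max(x$values), pk[1], pk[2]))
  invisible(x)
}

#' Integral of a KDE surface (cell sum x cell area)
#' @param surface a [kde_surface]
#' @export
kde_integral <- function(surface) {
  sum(surface$values) * surface$cell_size^2
}

#' Write a KDE surface as an ESRI ASCII grid
#' @param surface a [kde_surface]
#' @param path output `.asc` file
#' @export
write_kde_asc <- function(surface, path) {
  v <- surface$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", nrow(v)),
               sprintf("nrows %d", ncol(v)),
               sprintf("xllcorner %s", fmt_num(surface$origin[1])),
               sprintf("yllcorner %s", fmt_num(surface$origin[2])),
               sprintf("cellsize %s", fmt_num(surface$cell_size)),
               "NODATA_value -9999"), con)
  for (row in rev(seq_len(ncol(v))))   # top row first
    writeLines(paste(sprintf("%.8g", v[, row]), collapse = " "), con)
  invisible(path)
}
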