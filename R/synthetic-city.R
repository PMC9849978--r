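# Synthetic-city generator: a jittered grid street network, census blocks with
# a log-normal population surface, a spatially autocorrelated deprivation
# field, and facility point patterns with controllable structure. The model is
# the simplest one that reproduces the qualitative structure the downstream
# statistics are meant to detect (clustered deprivation, CSR or clustered
# facilities, population density decoupled from facility density).

#' Configuration for a synthetic city
#'
#' @param seed master RNG seed; all sub-generators derive their seeds from it
#'   through a documented splitting scheme so stages are independently
#'   reproducible.
#' @param grid_nx,grid_ny number of blocks along x and y (>= 2).
#' @param block_size block edge length in metres.
#' @param road_jitter maximum node displacement in metres (< block_size/2 so
#'   blocks stay simple polygons); boundary nodes are not jittered, so blocks
#'   always tile the rectangular extent.
#' @param n_facilities number of health facilities to place.
#' @param facility_pattern `"csr"` (complete spatial randomness),
#'   `"clustered"` (Thomas-style parent/offspring) or `"custom"`.
#' @param pop_total total population, conserved exactly by integer allocation.
#' @param pop_sd_log standard deviation of block log-density.
#' @param pop_hotspot_centres list of `c(x, y, radius_m)` Gaussian density
#'   hotspots multiplying the log-normal surface.
#' @param deprivation_rho spatial-autocorrelation strength of the latent
#'   deprivation field, in `[0, 1)` (simultaneous-autoregressive coefficient
#'   on the row-standardised rook lattice).
#' @param strata_shares fractions of population in the six [STRATA] cells,
#'   summing to 1; the default is a young-city age pyramid (28% children,
#'   66% working age, 6% elderly, even sex ratio).
#' @return A validated list of class `city_config`.
#' @export
city_config <- function(seed = 1L,
                        grid_nx = 20L, grid_ny = 20L,
                        block_size = 100,
                        road_jitter = 10,
                        n_facilities = 30L,
                        facility_pattern = c("csr", "clustered", "custom"),
                        pop_total = 250000L,
                        pop_sd_log = 0.6,
                        pop_hotspot_centres = list(),
                        deprivation_rho = 0.8,
                        strata_shares = c(male_0_14 = 0.14, male_15_64 = 0.33,
                                          male_65p = 0.03, female_0_14 = 0.14,
                                          female_15_64 = 0.33, female_65p = 0.03)) {
  facility_pattern <- match.arg(facility_pattern)
  stopifnot(grid_nx >= 2, grid_ny >= 2, block_size > 0,
            n_facilities >= 1, pop_total >= 0, pop_sd_log >= 0)
  if (road_jitter < 0 || road_jitter >= block_size / 2)
    stop("road_jitter must lie in [0, block_size/2)")
  if (deprivation_rho < 0 || deprivation_rho >= 1)
    stop("deprivation_rho must lie in [0, 1)")
  if (length(strata_shares) != 6 || abs(sum(strata_shares) - 1) > 1e-9)
    stop("strata_shares must be 6 fractions summing to 1")
  names(strata_shares) <- STRATA
  structure(list(seed = as.integer(seed), grid_nx = as.integer(grid_nx),
                 grid_ny = as.integer(grid_ny), block_size = block_size,
                 road_jitter = road_jitter,
                 n_facilities = as.integer(n_facilities),
                 facility_pattern = facility_pattern,
                 pop_total = as.integer(pop_total), pop_sd_log = pop_sd_log,
                 pop_hotspot_centres = pop_hotspot_centres,
                 deprivation_rho = deprivation_rho,
                 strata_shares = strata_shares),
            class = "city_config")
}

# Rook-neighbour pairs (both directions) of an nx x ny lattice, as a 2-column
# index matrix.
lattice_rook_pairs <- function(nx, ny) {
  idx <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx), ny); j <- rep(seq_len(ny), each = nx)
  right <- i < nx; up <- j < ny
  a <- c(idx(i[right], j[right]), idx(i[up], j[up]))
  b <- c(idx(i[right] + 1L, j[right]), idx(i[up], j[up] + 1L))
  cbind(c(a, b), c(b, a))
}

# Draw one realisation of the latent deprivation field: a simultaneous
# autoregressive (SAR) Gaussian field x = (I - rho * W)^-1 e on the
# row-standardised rook lattice, standardised to mean 0 / sd 1.
sar_field <- function(nx, ny, rho) {
  n <- nx * ny
  e <- rnorm(n)
  if (rho == 0) return(as.vector(scale(e)))
  pr <- lattice_rook_pairs(nx, ny)
  W <- matrix(0, n, n)
  W[pr] <- 1
  W <- W / rowSums(W)
  x <- solve(diag(n) - rho * W, e)
  as.vector(scale(x))
}

#' Place facility points in an extent
#'
#' @param pattern `"csr"` for uniform placement, `"clustered"` for a
#'   Thomas-style parent/offspring process, `"custom"` to pass `points`
#'   through unchanged (validated against the extent).
#' @param n number of facilities (>= 1).
#' @param extent named vector `c(xmin, ymin, xmax, ymax)` in metres.
#' @param seed RNG seed.
#' @param parent_mean mean number of Thomas parents (Poisson, at least 1).
#' @param offspring_sd Gaussian spread of offspring around their parent;
#'   default 2% of the extent diagonal-scale `sqrt(area)`.
#' @param points for `pattern = "custom"`: a 2-column matrix of coordinates.
#' @param year optional census-wave tag stored on the facilities.
#' @return A [facilities] table.
#' @export
place_facilities <- function(pattern = c("csr", "clustered", "custom"), n,
                             extent, seed = 1L, parent_mean = 5,
                             offspring_sd = NULL, points = NULL, year = NA) {
  pattern <- match.arg(pattern)
  if (pattern != "custom" && n < 1) stop("n must be >= 1 (empty pattern not analysable)")
  ex <- as.numeric(extent[c("xmin", "ymin", "xmax", "ymax")])
  if (anyNA(ex)) ex <- as.numeric(extent)[1:4]
  xmin <- ex[1]; ymin <- ex[2]; xmax <- ex[3]; ymax <- ex[4]
  if (pattern == "custom") {
    if (is.null(points)) stop("custom pattern needs points")
    points <- as.matrix(points)
    out <- points[, 1] < xmin | points[, 1] > xmax |
           points[, 2] < ymin | points[, 2] > ymax
    if (any(out))
      stop("custom facility point(s) outside extent at row(s): ",
           paste(which(out), collapse = ", "))
    return(facilities(sprintf("f%03d", seq_len(nrow(points))),
                      points[, 1], points[, 2], year))
  }
  set.seed(seed)
  if (pattern == "csr") {
    x <- runif(n, xmin, xmax); y <- runif(n, ymin, ymax)
  } else {
    n_par <- max(1L, rpois(1, parent_mean))
    if (is.null(offspring_sd))
      offspring_sd <- 0.02 * sqrt((xmax - xmin) * (ymax - ymin))
    px <- runif(n_par, xmin, xmax); py <- runif(n_par, ymin, ymax)
    parent <- sample.int(n_par, n, replace = TRUE)
    x <- px[parent] + rnorm(n, 0, offspring_sd)
    y <- py[parent] + rnorm(n, 0, offspring_sd)
    for (it in 1:100) {   # resample points that fell outside; then clamp
      bad <- x < xmin | x > xmax | y < ymin | y > ymax
      if (!any(bad)) break
      x[bad] <- px[parent[bad]] + rnorm(sum(bad), 0, offspring_sd)
      y[bad] <- py[parent[bad]] + rnorm(sum(bad), 0, offspring_sd)
    }
    x <- pmin(xmax, pmax(xmin, x)); y <- pmin(ymax, pmax(ymin, y))
  }
  facilities(sprintf("f%03d", seq_len(n)), x, y, year)
}

#' Generate a synthetic city
#'
#' Streets are a jittered grid (always one connected component; connectivity
#' is nevertheless verified, with bounded regeneration); blocks are the grid
#' cells, so they tile the extent exactly; block populations are integers
#' allocated by largest remainder from a log-normal density surface modulated
#' by optional hotspot kernels; deprivation indicators are monotone transforms
#' of a latent SAR Gaussian field with neighbour correlation
#' `deprivation_rho`, plus independent measurement noise.
#'
#' @param config a [city_config].
#' @return Object of class `synthetic_city`: list with `roads`
#'   ([road_network]), `blocks` ([census_blocks]), `facilities`
#'   ([facilities]), `latent` (the deprivation field actually drawn), and
#'   `config`/`seeds` provenance.
#' @export
generate_city <- function(config) {
  stopifnot(inherits(config, "city_config"))
  seeds <- split_seed(config$seed, 4L)
  nx <- config$grid_nx; ny <- config$grid_ny; bs <- config$block_size

  # --- streets ---------------------------------------------------------------
  roads <- NULL
  for (attempt in 1:5) {
    set.seed(seeds[1] + attempt - 1L)
    gx <- rep(0:nx * bs, ny + 1)
    gy <- rep(0:ny * bs, each = nx + 1)
    interior <- rep(1:(nx + 1) > 1 & 1:(nx + 1) <= nx, ny + 1) &
                rep(1:(ny + 1) > 1 & 1:(ny + 1) <= ny, each = nx + 1)
    jx <- jy <- numeric(length(gx))
    jx[interior] <- runif(sum(interior), -config$road_jitter, config$road_jitter)
    jy[interior] <- runif(sum(interior), -config$road_jitter, config$road_jitter)
    nodes <- data.frame(id = sprintf("n%04d", seq_along(gx)),
                        x = gx + jx, y = gy + jy, stringsAsFactors = FALSE)
    nid <- function(i, j) (j - 1L) * (nx + 1L) + i     # i in 1..nx+1
    i <- rep(1:(nx + 1), ny + 1); j <- rep(1:(ny + 1), each = nx + 1)
    right <- i <= nx; up <- j <= ny
    eu <- c(nid(i[right], j[right]), nid(i[up], j[up]))
    ev <- c(nid(i[right] + 1L, j[right]), nid(i[up], j[up] + 1L))
    len <- sqrt((nodes$x[eu] - nodes$x[ev])^2 + (nodes$y[eu] - nodes$y[ev])^2)
    edges <- data.frame(edge_id = sprintf("e%04d", seq_along(eu)),
                        u = nodes$id[eu], v = nodes$id[ev], length = len,
                        stringsAsFactors = FALSE)
    net <- road_network(nodes, edges)
    if (igraph::components(net$graph)$no == 1L) { roads <- net; break }
  }
  if (is.null(roads))
    stop("road graph disconnected after ", 5, " jitter attempts; ",
         "reduce road_jitter")

  # --- blocks ----------------------------------------------------------------
  nid <- function(i, j) (j - 1L) * (nx + 1L) + i
  ids <- character(nx * ny); rings <- vector("list", nx * ny)
  k <- 0L
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    k <- k + 1L
    ids[k] <- sprintf("b%04d", k)
    c1 <- nid(i, j); c2 <- nid(i + 1L, j); c3 <- nid(i + 1L, j + 1L); c4 <- nid(i, j + 1L)
    rings[[k]] <- cbind(roads$nodes$x[c(c1, c2, c3, c4)],
                        roads$nodes$y[c(c1, c2, c3, c4)])
  }

  # --- population ------------------------------------------------------------
  set.seed(seeds[2])
  nb <- nx * ny
  loglam <- rnorm(nb, 0, config$pop_sd_log)
  if (length(config$pop_hotspot_centres)) {
    cen <- t(vapply(rings, geom_centroid, numeric(2)))
    for (h in config$pop_hotspot_centres) {
      d2 <- (cen[, 1] - h[1])^2 + (cen[, 2] - h[2])^2
      loglam <- loglam + 2 * exp(-d2 / (2 * h[3]^2))   # amplitude 2 on log scale
    }
  }
  lam <- exp(loglam)
  wts <- as.vector(outer(lam, config$strata_shares))   # blocks x strata
  cnt <- largest_remainder(wts, config$pop_total)
  pop <- matrix(cnt, nb, 6, dimnames = list(ids, STRATA))

  # --- deprivation indicators ------------------------------------------------
  set.seed(seeds[3])
  latent <- sar_field(nx, ny, config$deprivation_rho)
  noise <- function() 0.4 * rnorm(nb)
  areas_ha <- vapply(rings, function(r) abs(geom_ring_area(r)), numeric(1)) / 1e4
  ind <- data.frame(
    block_id = ids,
    unemployment_rate = round(5 + 25 * stats::plogis(1.2 * latent + noise()), 2),
    dependency_burden = round(0.4 + 0.5 * stats::plogis(latent + noise()), 3),
    literacy_rate = round(98 - 35 * stats::plogis(latent + noise()), 2),
    household_crowding = round(0.8 + 2.2 * stats::plogis(latent + noise()), 3),
    population_density = round(rowSums(pop) / areas_ha, 2),
    stringsAsFactors = FALSE)

  blocks <- census_blocks(ids, rings, pop, ind)

  # --- facilities ------------------------------------------------------------
  fac <- place_facilities(config$facility_pattern, config$n_facilities,
                          roads$bbox, seed = seeds[4])

  structure(list(roads = roads, blocks = blocks, facilities = fac,
                 latent = latent, config = config, seeds = seeds),
            class = "synthetic_city")
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat("Synthetic city:", x$config$grid_nx, "x", x$config$grid_ny,
      "blocks of", x$config$block_size, "m\n")
  cat("  population", sum(x$blocks$pop), "|", nrow(x$facilities),
      "facilities (", x$config$facility_pattern, ") | deprivation rho",
      x$config$deprivation_rho, "| seed", x$config$seed, "\n")
  invisible(x)
}

#' Write a synthetic city to an output directory
#'
#' Emits `roads.geojson`, `blocks.geojson`, `population.csv`,
#' `indicators.csv` and `facilities.geojson`. Output is byte-identical for
#' identical cities (fixed numeric formatting).
#' @param city a `synthetic_city`
#' @param dir output directory (created if needed)
#' @export
write_city <- function(city, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_roads(city$roads, file.path(dir, "roads.geojson"))
  write_blocks(city$blocks, file.path(dir, "blocks.geojson"),
               file.path(dir, "population.csv"),
               file.path(dir, "indicators.csv"))
  write_facilities(city$facilities, file.path(dir, "facilities.geojson"))
  invisible(dir)
}

#' Read a city back from the files written by [write_city()]
#' @param dir directory containing the five interchange files
#' @param assume_planar see [read_roads()]
#' @export
read_city <- function(dir, assume_planar = FALSE) {
  list(roads = read_roads(file.path(dir, "roads.geojson"), assume_planar),
       blocks = read_blocks(file.path(dir, "blocks.geojson"),
                            file.path(dir, "population.csv"),
                            file.path(dir, "indicators.csv"), assume_planar),
       facilities = read_facilities(file.path(dir, "facilities.geojson"),
                                    assume_planar))
}
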