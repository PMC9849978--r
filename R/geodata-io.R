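#' @importFrom stats median quantile rnorm runif rpois sd setNames pnorm
#' @importFrom utils read.csv write.csv head
NULL

#' Population strata used throughout the package
#'
#' Six cells: two sexes crossed with three age bands (0-14 children, 15-64
#' adults, 65+ elderly), the stratification used for access tabulation.
#' @export
STRATA <- c("male_0_14", "male_15_64", "male_65p",
            "female_0_14", "female_15_64", "female_65p")

fmt_num <- function(x) {
  # fixed formatting so identical inputs serialise byte-identically
  s <- sprintf("%.6f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

check_planar <- function(xy, what, assume_planar = FALSE) {
  if (assume_planar) return(invisible(TRUE))
  if (all(is.finite(xy)) &&
      all(abs(xy[, 1]) <= 180) && all(abs(xy[, 2]) <= 90)) {
    stop(what, ": coordinates all fall inside longitude/latitude ranges; ",
         "this package requires planar metres. Project the data to a metric ",
         "CRS first (or pass assume_planar = TRUE for genuinely small planar ",
         "extents).", call. = FALSE)
  }
  if (!all(is.finite(xy))) stop(what, ": non-finite coordinates", call. = FALSE)
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Road network

#' Construct a road network
#'
#' An undirected street graph in planar metres. Edge lengths must agree with
#' the geometric length of their polylines to within 0.1%.
#'
#' @param nodes data frame with columns `id`, `x`, `y`.
#' @param edges data frame with columns `edge_id`, `u`, `v`, `length` and a
#'   list column `geometry` of n x 2 coordinate matrices (defaults to the
#'   straight segment between the end nodes when absent).
#' @return An object of class `road_network` with the node/edge tables, the
#'   bounding box, and an [igraph][igraph::graph_from_data_frame] graph used
#'   for shortest-path queries.
#' @export
road_network <- function(nodes, edges) {
  stopifnot(all(c("id", "x", "y") %in% names(nodes)),
            all(c("edge_id", "u", "v", "length") %in% names(edges)))
  nodes$id <- as.character(nodes$id)
  edges$edge_id <- as.character(edges$edge_id)
  edges$u <- as.character(edges$u); edges$v <- as.character(edges$v)
  if (anyDuplicated(nodes$id)) stop("duplicated node ids")
  if (anyDuplicated(edges$edge_id)) stop("duplicated edge ids")
  if (!all(c(edges$u, edges$v) %in% nodes$id))
    stop("edge references unknown node id")
  xy <- cbind(nodes$x, nodes$y)
  if (!all(is.finite(xy))) stop("non-finite node coordinates")
  if (is.null(edges$geometry)) {
    iu <- match(edges$u, nodes$id); iv <- match(edges$v, nodes$id)
    edges$geometry <- lapply(seq_len(nrow(edges)), function(k)
      rbind(c(nodes$x[iu[k]], nodes$y[iu[k]]), c(nodes$x[iv[k]], nodes$y[iv[k]])))
  }
  glen <- vapply(edges$geometry, geom_polyline_length, numeric(1))
  bad <- which(edges$length <= 0 | abs(glen - edges$length) > 1e-3 * pmax(glen, 1e-9))
  if (length(bad))
    stop("edge length disagrees with geometry (>0.1%) for edge id(s): ",
         paste(edges$edge_id[bad], collapse = ", "))
  edges <- edges[order(edges$edge_id), , drop = FALSE]
  rownames(edges) <- NULL
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$u, to = edges$v, weight = edges$length,
               edge_id = edges$edge_id),
    directed = FALSE,
    vertices = nodes[, c("id", "x", "y")])
  structure(list(nodes = nodes, edges = edges, graph = g,
                 bbox = geom_bbox(xy)),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat("Road network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  cat(sprintf("  total length %.1f m, bbox [%.1f, %.1f] x [%.1f, %.1f]\n",
              sum(x$edges$length), x$bbox["xmin"], x$bbox["xmax"],
              x$bbox["ymin"], x$bbox["ymax"]))
  invisible(x)
}

#' Read a road network from GeoJSON LineString features
#'
#' Nodes are inferred by matching segment endpoints (coordinates are keyed at
#' micrometre precision). A `length` property, when present, is validated
#' against the polyline geometry; otherwise the geometric length is used.
#'
#' @param path GeoJSON file of LineString features.
#' @param assume_planar skip the longitude/latitude sanity rejection (for
#'   small planar test extents).
#' @return A [road_network].
#' @export
read_roads <- function(path, assume_planar = FALSE) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  feats <- gj$features
  coords <- list(); props <- list()
  for (k in seq_along(feats)) {
    f <- feats[[k]]
    if (is.null(f$geometry) || !identical(f$geometry$type, "LineString"))
      stop("feature ", k, " is not a LineString")
    m <- do.call(rbind, lapply(f$geometry$coordinates,
                               function(p) as.numeric(p[1:2])))
    coords[[k]] <- m
    props[[k]] <- f$properties
  }
  allxy <- do.call(rbind, coords)
  check_planar(allxy, paste0("read_roads(", path, ")"), assume_planar)
  key <- function(p) sprintf("%.6f_%.6f", p[1], p[2])
  node_key <- character(0); nx <- numeric(0); ny <- numeric(0)
  get_node <- function(p) {
    k <- key(p)
    i <- match(k, node_key)
    if (is.na(i)) {
      node_key[[length(node_key) + 1]] <<- k
      nx[[length(nx) + 1]] <<- p[1]; ny[[length(ny) + 1]] <<- p[2]
      i <- length(node_key)
    }
    i
  }
  eu <- integer(0); ev <- integer(0); elen <- numeric(0); eid <- character(0)
  for (k in seq_along(coords)) {
    m <- coords[[k]]
    u <- get_node(m[1, ]); v <- get_node(m[nrow(m), ])
    glen <- geom_polyline_length(m)
    plen <- props[[k]]$length
    len <- if (is.null(plen)) glen else as.numeric(plen)
    id <- props[[k]]$edge_id
    eid[k] <- if (is.null(id)) sprintf("e%04d", k) else as.character(id)
    eu[k] <- u; ev[k] <- v; elen[k] <- len
  }
  nodes <- data.frame(id = sprintf("n%04d", seq_along(nx)), x = nx, y = ny,
                      stringsAsFactors = FALSE)
  edges <- data.frame(edge_id = eid, u = nodes$id[eu], v = nodes$id[ev],
                      length = elen, stringsAsFactors = FALSE)
  edges$geometry <- coords
  road_network(nodes, edges)
}

#' Write a road network as GeoJSON
#' @param net a [road_network]
#' @param path output file
#' @export
write_roads <- function(net, path) {
  feat <- vapply(seq_len(nrow(net$edges)), function(k) {
    m <- net$edges$geometry[[k]]
    cs <- paste(sprintf("[%s,%s]", fmt_num(m[, 1]), fmt_num(m[, 2])),
                collapse = ",")
    sprintf(paste0('{"type":"Feature","properties":{"edge_id":"%s",',
                   '"length":%s},"geometry":{"type":"LineString",',
                   '"coordinates":[%s]}}'),
            net$edges$edge_id[k], fmt_num(net$edges$length[k]), cs)
  }, character(1))
  writeLines(sprintf('{"type":"FeatureCollection","features":[%s]}',
                     paste(feat, collapse = ",")), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Census blocks

#' Construct a set of census blocks
#'
#' @param block_id character vector of ids.
#' @param rings list of n x 2 ring matrices (open rings, planar metres).
#' @param pop integer matrix (blocks x 6 strata, columns [STRATA]); zeros when
#'   missing.
#' @param indicators optional data frame of named block-level indicators.
#' @return Object of class `census_blocks`.
#' @export
census_blocks <- function(block_id, rings, pop = NULL, indicators = NULL) {
  block_id <- as.character(block_id)
  n <- length(block_id)
  stopifnot(length(rings) == n)
  if (anyDuplicated(block_id)) stop("duplicated block_id")
  for (k in seq_len(n)) {
    r <- rings[[k]]
    if (!is.matrix(r) || ncol(r) != 2 || nrow(r) < 3 || !all(is.finite(r)))
      stop("invalid polygon ring for block_id ", block_id[k])
    if (!geom_ring_is_simple(r))
      stop("invalid (self-intersecting or degenerate) polygon for block_id ",
           block_id[k])
  }
  if (is.null(pop)) {
    pop <- matrix(0L, n, length(STRATA), dimnames = list(block_id, STRATA))
  } else {
    pop <- as.matrix(pop)
    if (!all(STRATA %in% colnames(pop)))
      stop("population matrix missing stratum column(s): ",
           paste(setdiff(STRATA, colnames(pop)), collapse = ", "))
    pop <- pop[, STRATA, drop = FALSE]
    if (any(pop < 0) || any(pop != round(pop)))
      stop("population counts must be non-negative integers")
    storage.mode(pop) <- "integer"
    rownames(pop) <- block_id
  }
  structure(list(block_id = block_id, rings = rings, pop = pop,
                 indicators = indicators),
            class = "census_blocks")
}

#' @export
print.census_blocks <- function(x, ...) {
  cat("Census blocks:", length(x$block_id), "polygons, total population",
      sum(x$pop), "\n")
  if (!is.null(x$indicators))
    cat("  indicators:", paste(setdiff(names(x$indicators), "block_id"),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Block areas (m^2)
#' @param blocks a [census_blocks]
#' @export
block_areas <- function(blocks) {
  vapply(blocks$rings, function(r) abs(geom_ring_area(r)), numeric(1))
}

#' Block centroids
#' @param blocks a [census_blocks]
#' @return two-column matrix of centroid coordinates
#' @export
block_centroids <- function(blocks) {
  t(vapply(blocks$rings, geom_centroid, numeric(2)))
}

#' Read census blocks (geometry + population + indicators)
#'
#' @param geo_path GeoJSON Polygon features with property `block_id`.
#' @param pop_path CSV with `block_id` and the six [STRATA] columns.
#' @param ind_path optional CSV with `block_id` plus one column per indicator.
#' @param assume_planar see [read_roads()].
#' @return A [census_blocks].
#' @export
read_blocks <- function(geo_path, pop_path = NULL, ind_path = NULL,
                        assume_planar = FALSE) {
  gj <- jsonlite::fromJSON(geo_path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", geo_path)
  ids <- character(0); rings <- list()
  for (k in seq_along(gj$features)) {
    f <- gj$features[[k]]
    if (is.null(f$geometry) || !identical(f$geometry$type, "Polygon"))
      stop("feature ", k, " is not a Polygon")
    id <- f$properties$block_id
    if (is.null(id)) stop("feature ", k, " lacks property block_id")
    ids[k] <- as.character(id)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) as.numeric(p[1:2])))
    # GeoJSON rings are closed; store open
    if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
      ring <- ring[-nrow(ring), , drop = FALSE]
    rings[[k]] <- ring
  }
  check_planar(do.call(rbind, rings), paste0("read_blocks(", geo_path, ")"),
               assume_planar)
  pop <- NULL
  if (!is.null(pop_path)) {
    pd <- read.csv(pop_path, stringsAsFactors = FALSE)
    if (!"block_id" %in% names(pd)) stop("population CSV lacks column block_id")
    miss <- setdiff(STRATA, names(pd))
    if (length(miss))
      stop("population CSV missing column(s): ", paste(miss, collapse = ", "))
    pd$block_id <- as.character(pd$block_id)
    unmatched <- setdiff(pd$block_id, ids)
    if (length(unmatched))
      stop("population CSV block_id not in geometry: ",
           paste(head(unmatched, 5), collapse = ", "))
    missing_blocks <- setdiff(ids, pd$block_id)
    if (length(missing_blocks))
      stop("no population row for block_id: ",
           paste(head(missing_blocks, 5), collapse = ", "))
    pop <- as.matrix(pd[match(ids, pd$block_id), STRATA])
    rownames(pop) <- ids
  }
  ind <- NULL
  if (!is.null(ind_path)) {
    ind <- read.csv(ind_path, stringsAsFactors = FALSE)
    if (!"block_id" %in% names(ind)) stop("indicators CSV lacks column block_id")
    ind$block_id <- as.character(ind$block_id)
    unmatched <- setdiff(ind$block_id, ids)
    if (length(unmatched))
      stop("indicators CSV block_id not in geometry: ",
           paste(head(unmatched, 5), collapse = ", "))
    ind <- ind[match(ids, ind$block_id), , drop = FALSE]
    rownames(ind) <- NULL
  }
  census_blocks(ids, rings, pop, ind)
}

#' Write census blocks (GeoJSON + population CSV + indicators CSV)
#'
#' @param blocks a [census_blocks]
#' @param geo_path,pop_path,ind_path output files (`NULL` to skip a file)
#' @export
write_blocks <- function(blocks, geo_path, pop_path = NULL, ind_path = NULL) {
  feat <- vapply(seq_along(blocks$block_id), function(k) {
    r <- blocks$rings[[k]]
    r <- rbind(r, r[1, ])                       # close the ring (RFC 7946)
    cs <- paste(sprintf("[%s,%s]", fmt_num(r[, 1]), fmt_num(r[, 2])),
                collapse = ",")
    sprintf(paste0('{"type":"Feature","properties":{"block_id":"%s"},',
                   '"geometry":{"type":"Polygon","coordinates":[[%s]]}}'),
            blocks$block_id[k], cs)
  }, character(1))
  writeLines(sprintf('{"type":"FeatureCollection","features":[%s]}',
                     paste(feat, collapse = ",")), geo_path)
  if (!is.null(pop_path)) {
    pd <- data.frame(block_id = blocks$block_id, blocks$pop,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.csv(pd, pop_path, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(ind_path) && !is.null(blocks$indicators)) {
    write.csv(blocks$indicators, ind_path, row.names = FALSE, quote = FALSE)
  }
  invisible(geo_path)
}

# ---------------------------------------------------------------------------
# Facilities

#' Construct a facility table
#' @param facility_id ids; `x`,`y` planar metres; `year` census-wave tag.
#' @param x,y,year see above
#' @export
facilities <- function(facility_id, x, y, year = NA) {
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite facility coordinates")
  out <- data.frame(facility_id = as.character(facility_id), x = x, y = y,
                    year = year, stringsAsFactors = FALSE)
  class(out) <- c("facilities", "data.frame")
  out
}

#' Read facilities from GeoJSON Point features (or CSV with x,y columns)
#' @param path input file; `.geojson`/`.json` parsed as GeoJSON, else CSV.
#' @param assume_planar see [read_roads()].
#' @export
read_facilities <- function(path, assume_planar = FALSE) {
  if (grepl("\\.(geo)?json$", path, ignore.case = TRUE)) {
    gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
    n <- length(gj$features)
    id <- character(n); x <- numeric(n); y <- numeric(n); yr <- rep(NA, n)
    for (k in seq_len(n)) {
      f <- gj$features[[k]]
      if (is.null(f$geometry) || !identical(f$geometry$type, "Point"))
        stop("feature ", k, " is not a Point")
      p <- as.numeric(f$geometry$coordinates[1:2])
      x[k] <- p[1]; y[k] <- p[2]
      id[k] <- if (is.null(f$properties$facility_id)) sprintf("f%03d", k) else
        as.character(f$properties$facility_id)
      if (!is.null(f$properties$year)) yr[k] <- f$properties$year
    }
  } else {
    d <- read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("x", "y") %in% names(d))) stop("facility CSV needs columns x,y")
    x <- d$x; y <- d$y
    id <- if ("facility_id" %in% names(d)) as.character(d$facility_id) else
      sprintf("f%03d", seq_along(x))
    yr <- if ("year" %in% names(d)) d$year else rep(NA, length(x))
  }
  check_planar(cbind(x, y), paste0("read_facilities(", path, ")"), assume_planar)
  facilities(id, x, y, unlist(yr))
}

#' Write facilities as GeoJSON Point features
#' @param fac a [facilities] table
#' @param path output file
#' @export
write_facilities <- function(fac, path) {
  yr <- vapply(fac$year, function(y) {
    if (is.na(y)) "null"
    else if (is.numeric(y)) as.character(y)
    else sprintf('"%s"', y)
  }, character(1))
  feat <- sprintf(paste0('{"type":"Feature","properties":{"facility_id":"%s",',
                         '"year":%s},"geometry":{"type":"Point",',
                         '"coordinates":[%s,%s]}}'),
                  fac$facility_id, yr, fmt_num(fac$x), fmt_num(fac$y))
  writeLines(sprintf('{"type":"FeatureCollection","features":[%s]}',
                     paste(feat, collapse = ",")), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Run configuration

#' Read a run configuration (YAML)
#'
#' A key-value file naming input paths, the walking model (`speed` m/s,
#' `radius` m), overlay method and pattern-statistic options, or a
#' `synthetic:` block with [city_config()] fields.
#' @param path YAML file
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
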