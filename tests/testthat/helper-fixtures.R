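# In-code fixtures shared by the test files. All geometry is planar metres;
# small extents use assume_planar readers where files are involved.

# nx x ny grid of square blocks of side `size`, ids b0001..; optional pop and
# indicator columns.
make_grid_blocks <- function(nx, ny, size = 1, pop = NULL, indicators = NULL) {
  ids <- sprintf("b%04d", seq_len(nx * ny))
  rings <- vector("list", nx * ny)
  k <- 0
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    k <- k + 1
    x0 <- (i - 1) * size; y0 <- (j - 1) * size
    rings[[k]] <- cbind(c(x0, x0 + size, x0 + size, x0),
                        c(y0, y0, y0 + size, y0 + size))
  }
  census_blocks(ids, rings, pop, indicators)
}

# Straight path network A-B-C-... along the x axis with given edge lengths.
make_path_network <- function(lengths) {
  xs <- c(0, cumsum(lengths))
  nodes <- data.frame(id = LETTERS[seq_along(xs)], x = xs, y = 0)
  edges <- data.frame(edge_id = sprintf("e%02d", seq_along(lengths)),
                      u = LETTERS[seq_along(lengths)],
                      v = LETTERS[seq_along(lengths) + 1],
                      length = lengths)
  road_network(nodes, edges)
}

# Rook pairs of an nx x ny lattice as an index matrix (both directions) --
# independent adjacency oracle for weights tests.
lattice_pairs <- function(nx, ny) {
  idx <- function(i, j) (j - 1) * nx + i
  out <- NULL
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (i < nx) out <- rbind(out, c(idx(i, j), idx(i + 1, j)))
    if (j < ny) out <- rbind(out, c(idx(i, j), idx(i, j + 1)))
  }
  rbind(out, out[, 2:1])
}

# Brute-force O(n^2) mean nearest-neighbour distance (independent oracle).
bf_mean_nn <- function(pts) {
  n <- nrow(pts)
  d <- numeric(n)
  for (i in seq_len(n)) {
    dd <- sqrt((pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2)
    d[i] <- min(dd[-i])
  }
  mean(d)
}

# Naive double-loop Moran's I (independent oracle).
bf_moran <- function(values, W) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# Exhaustive simple-path enumeration of earliest arrival times from a source
# node (independent oracle for Dijkstra-based reachability).
bf_arrival_times <- function(net, source, speed = 1) {
  ids <- net$nodes$id
  best <- setNames(rep(Inf, length(ids)), ids)
  nbrs <- function(v) {
    k1 <- which(net$edges$u == v); k2 <- which(net$edges$v == v)
    rbind(data.frame(to = net$edges$v[k1], len = net$edges$length[k1]),
          data.frame(to = net$edges$u[k2], len = net$edges$length[k2]))
  }
  recurse <- function(v, t, visited) {
    if (t < best[[v]]) best[[v]] <<- t
    nb <- nbrs(v)
    for (r in seq_len(nrow(nb))) {
      if (!(nb$to[r] %in% visited))
        recurse(nb$to[r], t + nb$len[r] / speed, c(visited, nb$to[r]))
    }
  }
  recurse(source, 0, source)
  best
}

# A small connected random planar-ish network: jittered grid nodes, grid edges.
make_test_city <- function(seed = 1, nx = 8, ny = 8, size = 150) {
  generate_city(city_config(seed = seed, grid_nx = nx, grid_ny = ny,
                            block_size = size, road_jitter = size * 0.08,
                            n_facilities = 6, pop_total = 20000))
}
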