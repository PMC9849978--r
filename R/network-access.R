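# Walking accessibility on the street network: facilities are snapped to
# their nearest edge, walking-time service areas are grown by shortest paths
# with partial-edge coverage, the covered street segments are buffered into a
# coverage region, and census-block populations are overlaid and tabulated by
# sex and age band.

#' Walking model
#'
#' @param speed walking speed in m/s (default 1).
#' @param radius network service radius in metres (default 750), so the
#'   default time budget (`cutoff = radius/speed`) is 750 s = 12.5 min.
#' @return Object of class `walk_model` with `speed`, `radius`, `cutoff` (s).
#' @export
walk_model <- function(speed = 1.0, radius = 750) {
  if (speed <= 0) stop("speed must be positive")
  if (radius <= 0) stop("radius must be positive")
  structure(list(speed = speed, radius = radius, cutoff = radius / speed),
            class = "walk_model")
}

#' @export
print.walk_model <- function(x, ...) {
  cat(sprintf("Walking model: %.2f m/s, radius %.0f m -> cutoff %.0f s (%.1f min)\n",
              x$speed, x$radius, x$cutoff, x$cutoff / 60))
  invisible(x)
}

#' Snap a facility to the road network
#'
#' Finds the foot of the perpendicular from the facility to its nearest edge;
#' ties are broken by the lowest edge id.
#'
#' @param net a [road_network].
#' @param x,y facility coordinates (or pass a one-row [facilities] table as
#'   `x`).
#' @param max_tol maximum snap distance in metres (default 200); beyond it the
#'   facility is an error, never silently dropped.
#' @param facility_id id used in diagnostics.
#' @return Object of class `net_position`: `edge_id`, end nodes `u`/`v`,
#'   `offset` (m along the edge from `u`), snapped `point`, `snap_dist`.
#' @export
snap_facility <- function(net, x, y = NULL, max_tol = 200,
                          facility_id = "facility") {
  if (is.null(y)) {
    stopifnot(inherits(x, "facilities") || is.data.frame(x))
    facility_id <- x$facility_id[1]
    y <- x$y[1]; x <- x$x[1]
  }
  best <- list(dist = Inf)
  for (k in seq_len(nrow(net$edges))) {          # edges are ordered by edge_id
    m <- net$edges$geometry[[k]]
    seg_len <- sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)
    cum <- c(0, cumsum(seg_len))
    for (s in seq_len(nrow(m) - 1)) {
      pr <- geom_point_seg(x, y, m[s, 1], m[s, 2], m[s + 1, 1], m[s + 1, 2])
      if (pr$dist < best$dist - 1e-12) {
        off_geom <- cum[s] + pr$t * seg_len[s]
        # offset in length units (edge length may differ slightly from geometry)
        off <- off_geom / max(sum(seg_len), 1e-12) * net$edges$length[k]
        best <- list(dist = pr$dist, edge = k, offset = off,
                     point = c(pr$x, pr$y))
      }
    }
  }
  if (!is.finite(best$dist) || best$dist > max_tol)
    stop("no edge within ", max_tol, " m of facility ", facility_id,
         sprintf(" (nearest %.1f m)", best$dist))
  e <- net$edges[best$edge, ]
  structure(list(edge_id = e$edge_id, u = e$u, v = e$v,
                 edge_length = e$length, offset = best$offset,
                 point = best$point, snap_dist = best$dist,
                 facility_id = facility_id),
            class = "net_position")
}

# Merge a set of [from, to] intervals on a line into disjoint intervals.
merge_intervals <- function(from, to) {
  keep <- to > from
  from <- from[keep]; to <- to[keep]
  if (!length(from)) return(cbind(from = numeric(0), to = numeric(0)))
  o <- order(from)
  from <- from[o]; to <- to[o]
  of <- from[1]; ot <- to[1]; rf <- c(); rt <- c()
  for (k in seq_along(from)[-1]) {
    if (from[k] <= ot + 1e-9) ot <- max(ot, to[k])
    else { rf <- c(rf, of); rt <- c(rt, ot); of <- from[k]; ot <- to[k] }
  }
  cbind(from = c(rf, of), to = c(rt, ot))
}

#' Walking-time service area from a network position
#'
#' Single-source shortest paths (Dijkstra, edge cost = length/speed) from the
#' snapped position, with partial-edge coverage: every edge is covered exactly
#' as far as the residual time budget reaches from each of its ends (and, on
#' the snapped edge, directly from the snap point). The covered street
#' segments buffered by `buffer_width` form the service-area footprint.
#'
#' @param net a [road_network].
#' @param position a [snap_facility()] result.
#' @param model a [walk_model].
#' @param buffer_width half-width of the street buffer forming the polygonal
#'   footprint (m).
#' @return Object of class `service_area`: `facility_id`, `cutoff`,
#'   `node_times` (named, seconds), `reached` (data frame of edge intervals in
#'   metres), `capsules` (buffered covered segments: columns x1, y1, x2, y2,
#'   r) and the snap `point`.
#' @export
service_area <- function(net, position, model = walk_model(),
                         buffer_width = 50) {
  stopifnot(inherits(position, "net_position"), inherits(model, "walk_model"))
  cutoff <- model$cutoff
  sp <- model$speed
  D <- igraph::distances(net$graph,
                         v = c(position$u, position$v),
                         weights = igraph::E(net$graph)$weight) / sp
  t_u <- position$offset / sp
  t_v <- (position$edge_length - position$offset) / sp
  node_times <- pmin(t_u + D[1, ], t_v + D[2, ])
  names(node_times) <- colnames(D)
  if (cutoff <= 0) {
    return(structure(list(facility_id = position$facility_id, cutoff = cutoff,
                          node_times = node_times,
                          reached = data.frame(edge_id = character(0),
                                               from = numeric(0), to = numeric(0)),
                          capsules = data.frame(x1 = position$point[1],
                                                y1 = position$point[2],
                                                x2 = position$point[1],
                                                y2 = position$point[2],
                                                r = buffer_width),
                          point = position$point, buffer_width = buffer_width),
                     class = "service_area"))
  }
  eid <- character(0); efrom <- numeric(0); eto <- numeric(0)
  caps <- list()
  e_id <- net$edges$edge_id; e_len <- net$edges$length
  e_geom <- net$edges$geometry
  ta_all <- node_times[net$edges$u]; tb_all <- node_times[net$edges$v]
  cand <- which((is.finite(ta_all) & ta_all < cutoff) |
                (is.finite(tb_all) & tb_all < cutoff) |
                e_id == position$edge_id)
  for (k in cand) {
    len <- e_len[k]
    iv <- matrix(numeric(0), 0, 2)
    ta <- ta_all[k]; tb <- tb_all[k]
    if (is.finite(ta) && ta < cutoff)
      iv <- rbind(iv, c(0, min(len, (cutoff - ta) * sp)))
    if (is.finite(tb) && tb < cutoff)
      iv <- rbind(iv, c(max(0, len - (cutoff - tb) * sp), len))
    if (e_id[k] == position$edge_id) {       # direct coverage from the snap point
      iv <- rbind(iv, c(max(0, position$offset - cutoff * sp),
                        min(len, position$offset + cutoff * sp)))
    }
    if (!nrow(iv)) next
    iv <- merge_intervals(iv[, 1], iv[, 2])
    if (!nrow(iv)) next
    m <- e_geom[[k]]
    glen <- geom_polyline_length(m)
    for (r in seq_len(nrow(iv))) {
      eid <- c(eid, e_id[k]); efrom <- c(efrom, iv[r, 1]); eto <- c(eto, iv[r, 2])
      # convert length-units to geometry arc length, then emit sub-segments
      s0 <- iv[r, 1] / len * glen; s1 <- iv[r, 2] / len * glen
      seg_len <- sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)
      cum <- c(0, cumsum(seg_len))
      brk <- sort(unique(c(s0, s1, cum[cum > s0 & cum < s1])))
      p <- geom_polyline_interpolate(m, brk)
      if (nrow(p) >= 2)
        caps[[length(caps) + 1]] <-
          data.frame(x1 = p[-nrow(p), 1], y1 = p[-nrow(p), 2],
                     x2 = p[-1, 1], y2 = p[-1, 2], r = buffer_width)
    }
  }
  capsules <- if (length(caps)) do.call(rbind, caps) else
    data.frame(x1 = position$point[1], y1 = position$point[2],
               x2 = position$point[1], y2 = position$point[2], r = buffer_width)
  structure(list(facility_id = position$facility_id, cutoff = cutoff,
                 node_times = node_times,
                 reached = data.frame(edge_id = eid, from = efrom, to = eto,
                                      stringsAsFactors = FALSE),
                 capsules = capsules, point = position$point,
                 buffer_width = buffer_width),
            class = "service_area")
}

#' @export
print.service_area <- function(x, ...) {
  cat(sprintf("Service area of %s: cutoff %.0f s, %.0f m of street covered, %d nodes reached\n",
              x$facility_id, x$cutoff, sum(x$reached$to - x$reached$from),
              sum(is.finite(x$node_times) & x$node_times <= x$cutoff)))
  invisible(x)
}

#' Union of service areas into one coverage region
#'
#' The coverage is the union of all buffered covered street segments, kept as
#' capsules (segment + radius) with an exact point-membership predicate; it is
#' idempotent and order-independent.
#'
#' @param areas list of [service_area] objects (or a single one); alternatively
#'   a data frame of capsules.
#' @return Object of class `coverage`.
#' @export
union_service_areas <- function(areas) {
  if (inherits(areas, "service_area")) areas <- list(areas)
  caps <- do.call(rbind, lapply(areas, function(a) a$capsules))
  caps <- unique(caps)
  rownames(caps) <- NULL
  structure(list(capsules = caps), class = "coverage")
}

#' Straight-line (Euclidean buffer) coverage baseline
#'
#' Discs of `radius` around the facility points, for comparison against the
#' network-based service areas.
#' @param fac a [facilities] table
#' @param radius disc radius (m)
#' @export
euclidean_coverage <- function(fac, radius) {
  structure(list(capsules = data.frame(x1 = fac$x, y1 = fac$y,
                                       x2 = fac$x, y2 = fac$y, r = radius)),
            class = "coverage")
}

#' @export
print.coverage <- function(x, ...) {
  cat("Coverage region:", nrow(x$capsules), "buffered segments, bbox [",
      paste(sprintf("%.1f", coverage_bbox(x)), collapse = ", "), "]\n")
  invisible(x)
}

coverage_bbox <- function(cov) {
  c(xmin = min(cov$capsules$x1 - cov$capsules$r, cov$capsules$x2 - cov$capsules$r),
    ymin = min(cov$capsules$y1 - cov$capsules$r, cov$capsules$y2 - cov$capsules$r),
    xmax = max(cov$capsules$x1 + cov$capsules$r, cov$capsules$x2 + cov$capsules$r),
    ymax = max(cov$capsules$y1 + cov$capsules$r, cov$capsules$y2 + cov$capsules$r))
}

#' Point-in-coverage predicate
#' @param cov a `coverage`
#' @param px,py coordinates (vectorised)
#' @return logical vector
#' @export
coverage_contains <- function(cov, px, py) {
  inside <- logical(length(px))
  cp <- cov$capsules
  for (k in seq_len(nrow(cp))) {
    todo <- which(!inside)
    if (!length(todo)) break
    pr <- geom_point_seg(px[todo], py[todo], cp$x1[k], cp$y1[k],
                         cp$x2[k], cp$y2[k])
    inside[todo] <- pr$dist <= cp$r[k]
  }
  inside
}

#' Approximate area of a coverage region (m^2)
#'
#' Cell-centre counting on a regular grid over the coverage bounding box.
#' @param cov a `coverage`
#' @param cell sampling cell size (m); default a 400-cell-per-axis grid capped
#'   at `r/4`.
#' @export
coverage_area <- function(cov, cell = NULL) {
  bb <- coverage_bbox(cov)
  if (is.null(cell))
    cell <- min(min(cov$capsules$r) / 4,
                max(bb["xmax"] - bb["xmin"], bb["ymax"] - bb["ymin"]) / 400)
  xs <- seq(bb["xmin"] + cell / 2, bb["xmax"], by = cell)
  ys <- seq(bb["ymin"] + cell / 2, bb["ymax"], by = cell)
  g <- expand.grid(x = xs, y = ys)
  sum(coverage_contains(cov, g$x, g$y)) * cell^2
}

#' Fraction of each census block inside a coverage region
#'
#' `method = "areal"` (default) splits every block proportionally to the share
#' of its area inside the coverage, evaluated by deterministic cell-centre
#' sampling on a `resolution` x `resolution` grid clipped to the block
#' polygon; `method = "centroid"` assigns each block all-or-nothing by
#' centroid containment. Zero-area blocks fall back to the centroid rule with
#' a warning.
#'
#' @param blocks a [census_blocks].
#' @param cov a `coverage`.
#' @param method `"areal"` or `"centroid"`.
#' @param resolution sampling grid per block side (even; default 16).
#' @return data frame `block_id`, `fraction` in `[0, 1]`.
#' @export
population_with_access <- function(blocks, cov, method = c("areal", "centroid"),
                                   resolution = 16L) {
  method <- match.arg(method)
  n <- length(blocks$block_id)
  frac <- numeric(n)
  cp <- cov$capsules
  cap_bb <- cbind(xmin = pmin(cp$x1, cp$x2) - cp$r,
                  ymin = pmin(cp$y1, cp$y2) - cp$r,
                  xmax = pmax(cp$x1, cp$x2) + cp$r,
                  ymax = pmax(cp$y1, cp$y2) + cp$r)
  for (k in seq_len(n)) {
    ring <- blocks$rings[[k]]
    a <- abs(geom_ring_area(ring))
    cen <- geom_centroid(ring)
    if (method == "centroid" || a <= 0) {
      if (method == "areal" && a <= 0)
        warning("zero-area block ", blocks$block_id[k],
                "; centroid rule applied")
      frac[k] <- as.numeric(coverage_contains(cov, cen[1], cen[2]))
      next
    }
    bb <- geom_bbox(ring)
    # only capsules whose bbox touches the block bbox can matter
    sel <- which(cap_bb[, "xmin"] <= bb["xmax"] & cap_bb[, "xmax"] >= bb["xmin"] &
                 cap_bb[, "ymin"] <= bb["ymax"] & cap_bb[, "ymax"] >= bb["ymin"])
    if (!length(sel)) { frac[k] <- 0; next }
    sub <- structure(list(capsules = cp[sel, , drop = FALSE]), class = "coverage")
    dx <- (bb["xmax"] - bb["xmin"]) / resolution
    dy <- (bb["ymax"] - bb["ymin"]) / resolution
    xs <- bb["xmin"] + (seq_len(resolution) - 0.5) * dx
    ys <- bb["ymin"] + (seq_len(resolution) - 0.5) * dy
    g <- expand.grid(x = xs, y = ys)
    inb <- geom_point_in_ring(g$x, g$y, ring)
    if (!any(inb)) { frac[k] <- as.numeric(coverage_contains(cov, cen[1], cen[2])); next }
    frac[k] <- mean(coverage_contains(sub, g$x[inb], g$y[inb]))
  }
  data.frame(block_id = blocks$block_id, fraction = frac,
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Access tabulation

# One access/no-access cell from a real-valued accessed count and an integer
# total: integers by largest remainder between the two parts (equivalently
# round-half-up, ties to access). Percentages are 100*count/total rounded
# half-up to 2 decimals (so the two shares close to 100 within 0.02). Empty
# cells report NA percentages.
access_cell <- function(access_real, total) {
  a <- max(0, min(total, access_real))
  acc <- floor(a) + as.integer((a - floor(a)) >= 0.5)
  acc <- max(0L, min(total, acc))
  list(access_n = as.integer(acc), no_access_n = as.integer(total - acc),
       total_n = as.integer(total),
       access_pct = if (total > 0) round_half_up(100 * acc / total) else NA_real_,
       no_access_pct = if (total > 0) round_half_up(100 * (total - acc) / total) else NA_real_)
}

access_row <- function(sex, age, cell, year) {
  data.frame(year = year, sex = sex, age = age,
             access_n = cell$access_n, no_access_n = cell$no_access_n,
             total_n = cell$total_n, access_pct = cell$access_pct,
             no_access_pct = cell$no_access_pct, stringsAsFactors = FALSE)
}

#' Tabulate access by sex and age band
#'
#' Applies per-block access fractions to the six stratum populations, rounds
#' to integers by largest remainder within each stratum (so access + no-access
#' equals the stratum total exactly), and derives sex totals, age totals and
#' the grand total by summation. Percentages are rounded half-up to two
#' decimals; empty cells report `NA` percentages.
#'
#' @param fractions data frame from [population_with_access()].
#' @param blocks the same [census_blocks].
#' @param year wave label stored on every row.
#' @return Object of class `access_table`: long data frame with columns
#'   `year`, `sex` (male/female/total), `age` (0_14/15_64/65p/total),
#'   `access_n`, `no_access_n`, `total_n`, `access_pct`, `no_access_pct`.
#' @export
tabulate_access <- function(fractions, blocks, year = NA) {
  stopifnot(inherits(blocks, "census_blocks"))
  if (!all(blocks$block_id %in% fractions$block_id))
    stop("fractions missing for block_id: ",
         paste(head(setdiff(blocks$block_id, fractions$block_id), 5),
               collapse = ", "))
  f <- fractions$fraction[match(blocks$block_id, fractions$block_id)]
  if (any(f < 0 | f > 1)) stop("fractions must lie in [0, 1]")
  acc_real <- colSums(blocks$pop * f)           # per stratum
  tot <- colSums(blocks$pop)
  cells <- lapply(STRATA, function(s) access_cell(acc_real[[s]], tot[[s]]))
  names(cells) <- STRATA
  access_table_from_cells(cells, year)
}

# Assemble the table (including derived totals) from the six stratum cells.
access_table_from_cells <- function(cells, year) {
  ages <- c("0_14", "15_64", "65p")
  rows <- list()
  sums <- function(sel, field) sum(vapply(cells[sel], `[[`, numeric(1), field))
  for (sex in c("male", "female")) {
    for (age in ages) {
      s <- paste(sex, age, sep = "_")
      rows[[length(rows) + 1]] <- access_row(sex, age, cells[[s]], year)
    }
    sel <- paste(sex, ages, sep = "_")
    tot_cell <- access_cell(sums(sel, "access_n"), sums(sel, "total_n"))
    rows[[length(rows) + 1]] <- access_row(sex, "total", tot_cell, year)
  }
  for (age in ages) {
    sel <- paste(c("male", "female"), age, sep = "_")
    rows[[length(rows) + 1]] <-
      access_row("total", age, access_cell(sums(sel, "access_n"),
                                           sums(sel, "total_n")), year)
  }
  rows[[length(rows) + 1]] <-
    access_row("total", "total", access_cell(sums(STRATA, "access_n"),
                                             sums(STRATA, "total_n")), year)
  out <- do.call(rbind, rows)
  class(out) <- c("access_table", "data.frame")
  out
}

#' Build an access table directly from counts
#'
#' For use when access and no-access counts are already known (for example a
#' published tabulation): percentages are recomputed from the counts.
#'
#' @param access_n,no_access_n named numeric vectors over the six [STRATA]
#'   cells, or single numbers (then only the grand-total row is returned).
#' @param year wave label.
#' @return An `access_table`.
#' @export
access_table_from_counts <- function(access_n, no_access_n, year = NA) {
  if (length(access_n) == 1 && is.null(names(access_n))) {
    cell <- access_cell(access_n, access_n + no_access_n)
    out <- access_row("total", "total", cell, year)
    class(out) <- c("access_table", "data.frame")
    return(out)
  }
  stopifnot(all(STRATA %in% names(access_n)), all(STRATA %in% names(no_access_n)))
  cells <- lapply(STRATA, function(s)
    access_cell(access_n[[s]], access_n[[s]] + no_access_n[[s]]))
  names(cells) <- STRATA
  access_table_from_cells(cells, year)
}

#' @export
print.access_table <- function(x, ...) {
  for (yr in unique(x$year)) {
    cat("Access table, wave", yr, "\n")
    sub <- x[x$year %in% yr, ]
    m <- rbind(access_n = sub$access_n, access_pct = sub$access_pct,
               no_access_n = sub$no_access_n, no_access_pct = sub$no_access_pct,
               total_n = sub$total_n)
    colnames(m) <- paste(sub$sex, sub$age, sep = ".")
    print(m)
  }
  invisible(x)
}

#' Write an access table as a Table-1-shaped CSV
#'
#' Columns are the sex x age cells plus totals; rows are access/no-access/total
#' counts and percentages per wave.
#' @param table an `access_table`
#' @param path output CSV
#' @export
write_access_table <- function(table, path) {
  cols <- paste(table$sex, table$age, sep = "_")
  out <- NULL
  for (yr in unique(table$year)) {
    sub <- table[table$year %in% yr, ]
    cn <- paste(sub$sex, sub$age, sep = "_")
    block <- data.frame(year = yr,
                        measure = c("access_n", "access_pct", "no_access_n",
                                    "no_access_pct", "total_n"),
                        stringsAsFactors = FALSE)
    vals <- rbind(sub$access_n, sub$access_pct, sub$no_access_n,
                  sub$no_access_pct, sub$total_n)
    colnames(vals) <- cn
    out <- rbind(out, cbind(block, vals))
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
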