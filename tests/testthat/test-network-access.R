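test_that("facilities snap to the nearest edge with perpendicular-foot geometry", {
  net <- make_path_network(c(400, 400))       # A(0,0) - B(400,0) - C(800,0)
  on_node <- snap_facility(net, 400, 0)
  expect_true(on_node$offset %in% c(0, 400))  # foot at node B on one of its edges
  expect_equal(on_node$snap_dist, 0)
  mid <- snap_facility(net, 200, 5)
  expect_equal(mid$edge_id, "e01")
  expect_equal(mid$offset, 200)
  expect_equal(mid$point, c(200, 0))
  expect_equal(mid$snap_dist, 5)
  expect_error(snap_facility(net, 400, 500, max_tol = 200, facility_id = "far1"),
               "far1")
})

test_that("service areas cover partial edges to the residual time budget", {
  net <- make_path_network(c(400, 400))
  pos <- snap_facility(net, 0, 0)             # at node A
  sa <- service_area(net, pos, walk_model(speed = 1, radius = 750))
  expect_equal(unname(sa$node_times[c("A", "B", "C")]), c(0, 400, 800))
  # edge B-C covered for 350 m from B; C itself unreached
  bc <- sa$reached[sa$reached$edge_id == "e02", ]
  expect_equal(bc$from, 0)
  expect_equal(bc$to, 350)
  ab <- sa$reached[sa$reached$edge_id == "e01", ]
  expect_equal(c(ab$from, ab$to), c(0, 400))  # fully covered
})

test_that("zero cutoff degenerates to the snap-point buffer", {
  net <- make_path_network(c(400))
  pos <- snap_facility(net, 100, 0)
  sa <- service_area(net, pos, walk_model(speed = 1, radius = 1e-9),
                     buffer_width = 30)
  expect_lt(sum(sa$reached$to - sa$reached$from), 1e-6)
  cov <- union_service_areas(sa)
  expect_true(coverage_contains(cov, 100, 29))
  expect_false(coverage_contains(cov, 100, 31))
})

test_that("reached times match exhaustive path enumeration on a small graph", {
  city <- make_test_city(seed = 13, nx = 3, ny = 3, size = 150)  # 16 nodes
  net <- city$roads
  src <- net$nodes$id[1]
  oracle <- bf_arrival_times(net, src, speed = 1)
  pos <- snap_facility(net, net$nodes$x[1], net$nodes$y[1])
  sa <- service_area(net, pos, walk_model(speed = 1, radius = 1e6))
  expect_equal(sa$node_times[net$nodes$id], oracle[net$nodes$id],
               tolerance = 1e-9)
})

test_that("service areas are monotone in the cutoff", {
  city <- make_test_city(seed = 4, nx = 6, ny = 6, size = 150)
  pos <- snap_facility(city$roads, city$facilities[1, , drop = FALSE])
  sa5 <- service_area(city$roads, pos, walk_model(radius = 500))
  sa7 <- service_area(city$roads, pos, walk_model(radius = 750))
  cov5 <- union_service_areas(sa5); cov7 <- union_service_areas(sa7)
  set.seed(1)
  bb <- city$roads$bbox
  px <- runif(4000, bb["xmin"], bb["xmax"])
  py <- runif(4000, bb["ymin"], bb["ymax"])
  in5 <- coverage_contains(cov5, px, py)
  expect_true(all(coverage_contains(cov7, px[in5], py[in5])))
  expect_gt(sum(coverage_contains(cov7, px, py)), sum(in5))
})

test_that("union of service areas is idempotent and additive when disjoint", {
  net <- make_path_network(c(200))
  p1 <- snap_facility(net, 0, 0)
  sa <- service_area(net, p1, walk_model(radius = 50), buffer_width = 20)
  u1 <- union_service_areas(sa)
  u2 <- union_service_areas(list(sa, sa))     # duplicated facility
  expect_identical(u1$capsules, u2$capsules)
  a1 <- coverage_area(u1, cell = 1)
  # one covered segment of 50 m buffered by 20 m: rectangle + end caps
  expect_equal(a1, 50 * 40 + pi * 20^2, tolerance = 0.02 * a1)
  # disjoint discs sum
  fac <- facilities(c("f1", "f2"), c(0, 1000), c(0, 0))
  cov <- euclidean_coverage(fac, 50)
  expect_equal(coverage_area(cov, cell = 2), 2 * pi * 50^2,
               tolerance = 0.02 * 2 * pi * 50^2)
})

test_that("areal overlay splits populations by covered area fraction", {
  pop <- matrix(100L, 1, 6, dimnames = list("b0001", STRATA))
  blocks <- make_grid_blocks(1, 1, size = 100, pop = pop)
  half <- structure(list(capsules = data.frame(
    x1 = 0, y1 = -100, x2 = 0, y2 = 200, r = 50)), class = "coverage")
  fr <- population_with_access(blocks, half, "areal")
  expect_equal(fr$fraction, 0.5)
  tab <- tabulate_access(fr, blocks, year = 2000)
  cell <- tab[tab$sex == "male" & tab$age == "0_14", ]
  expect_equal(cell$access_n, 50)
  expect_equal(cell$no_access_n, 50)
  # wholly inside and disjoint coverages
  whole <- structure(list(capsules = data.frame(
    x1 = 50, y1 = 50, x2 = 50, y2 = 50, r = 500)), class = "coverage")
  expect_equal(population_with_access(blocks, whole)$fraction, 1)
  away <- structure(list(capsules = data.frame(
    x1 = 1e4, y1 = 1e4, x2 = 1e4, y2 = 1e4, r = 50)), class = "coverage")
  expect_equal(population_with_access(blocks, away)$fraction, 0)
  # centroid method is all-or-nothing
  expect_equal(population_with_access(blocks, half, "centroid")$fraction, 1)
  expect_equal(population_with_access(blocks, away, "centroid")$fraction, 0)
})

test_that("access tables conserve population and close percentages per cell", {
  city <- make_test_city(seed = 31, nx = 6, ny = 6, size = 150)
  pos <- lapply(seq_len(3), function(i)
    snap_facility(city$roads, city$facilities[i, , drop = FALSE]))
  cov <- union_service_areas(lapply(pos, function(p)
    service_area(city$roads, p, walk_model())))
  fr <- population_with_access(city$blocks, cov)
  tab <- tabulate_access(fr, city$blocks, year = 1996)
  expect_identical(tab$access_n + tab$no_access_n, tab$total_n)
  ok <- tab$total_n > 0
  expect_true(all(abs(tab$access_pct[ok] + tab$no_access_pct[ok] - 100) <= 0.02))
  # column totals equal the sum of their strata
  for (sex in c("male", "female")) {
    sub <- tab[tab$sex == sex, ]
    expect_equal(sub$access_n[sub$age == "total"],
                 sum(sub$access_n[sub$age != "total"]))
  }
  gt <- tab[tab$sex == "total" & tab$age == "total", ]
  expect_equal(gt$total_n, sum(city$blocks$pop))
  # all blocks covered -> no_access 0 everywhere
  all_cov <- structure(list(capsules = data.frame(
    x1 = 450, y1 = 450, x2 = 450, y2 = 450, r = 5000)), class = "coverage")
  tab0 <- tabulate_access(population_with_access(city$blocks, all_cov),
                          city$blocks, 2016)
  expect_true(all(tab0$no_access_pct[tab0$total_n > 0] == 0))
  expect_true(all(tab0$no_access_n == 0L))
})

test_that("count-only tables recompute their percentages by half-up rounding", {
  t96 <- access_table_from_counts(116277, 136620, year = 1996)
  expect_equal(t96$no_access_pct, 54.02)
  expect_equal(t96$access_pct, 45.98)
  # 136685/267567 = 51.0844% -> 51.08 under half-up rounding
  t06 <- access_table_from_counts(130882, 136685, year = 2006)
  expect_equal(t06$no_access_pct,
               spaccess:::round_half_up(100 * 136685 / 267567))
  t16 <- access_table_from_counts(147229, 78276, year = 2016)
  expect_equal(t16$no_access_pct, 34.71)
  expect_equal(t16$access_pct, 65.29)
})

test_that("empty strata yield NA percentages, never division errors", {
  pop <- matrix(0L, 1, 6, dimnames = list("b0001", STRATA))
  pop[1, "male_0_14"] <- 10L
  blocks <- make_grid_blocks(1, 1, size = 100, pop = pop)
  cov <- structure(list(capsules = data.frame(x1 = 50, y1 = 50, x2 = 50,
                                              y2 = 50, r = 500)),
                   class = "coverage")
  tab <- tabulate_access(population_with_access(blocks, cov), blocks, 1)
  expect_true(is.na(tab$access_pct[tab$sex == "female" & tab$age == "65p"]))
  expect_equal(tab$access_pct[tab$sex == "male" & tab$age == "0_14"], 100)
})

test_that("access table CSV is Table-1 shaped", {
  t <- access_table_from_counts(
    setNames(as.numeric(1:6) * 10, STRATA),
    setNames(as.numeric(1:6) * 5, STRATA), year = 1996)
  f <- withr::local_tempfile(fileext = ".csv")
  write_access_table(t, f)
  d <- read.csv(f)
  expect_equal(nrow(d), 5)                     # N/% x access/no-access + total
  expect_true(all(c("male_0_14", "female_total", "total_total") %in% names(d)))
  expect_equal(d$total_total[d$measure == "total_n"], sum(1:6 * 15))
})
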