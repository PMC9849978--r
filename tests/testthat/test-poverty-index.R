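test_that("single-indicator terciles follow the raw ordering with equal class sizes", {
  ind <- data.frame(block_id = sprintf("b%02d", 1:9),
                    unemployment_rate = c(3, 9, 5, 12, 1, 7, 20, 15, 4))
  res <- composite_score(ind, indicator_spec("unemployment_rate", "deprivation_up"))
  expect_equal(as.vector(table(res$class)), c(3, 3, 3))
  # the three highest unemployment blocks are the lower class
  expect_setequal(res$block_id[res$class == "lower"],
                  ind$block_id[order(-ind$unemployment_rate)][1:3])
  expect_setequal(res$block_id[res$class == "upper"],
                  ind$block_id[order(ind$unemployment_rate)][1:3])
  # class sizes differ by at most one for any n
  for (n in 4:8) {
    r <- composite_score(data.frame(block_id = seq_len(n), v = rnorm(n)),
                         indicator_spec("v", "deprivation_up"))
    expect_lte(diff(range(table(r$class))), 1)
  }
})

test_that("scores are invariant to positive rescaling of raw indicators", {
  set.seed(12)
  ind <- data.frame(block_id = sprintf("b%02d", 1:20),
                    a = rnorm(20, 50, 10), b = runif(20))
  specs <- indicator_spec(c("a", "b"), "deprivation_up")
  r1 <- composite_score(ind, specs)
  ind2 <- transform(ind, a = a * 1000, b = b * 0.01)
  r2 <- composite_score(ind2, specs)
  expect_equal(r1$score, r2$score, tolerance = 1e-12)
  expect_identical(as.character(r1$class), as.character(r2$class))
})

test_that("flipping an indicator direction negates its contribution exactly", {
  set.seed(5)
  ind <- data.frame(block_id = 1:15, a = rnorm(15), b = rnorm(15))
  up <- composite_score(ind, indicator_spec(c("a", "b"),
                                            c("deprivation_up", "deprivation_up")))
  dn <- composite_score(ind, indicator_spec(c("a", "b"),
                                            c("deprivation_up", "deprivation_down")))
  za <- as.vector(scale(ind$a)); zb <- as.vector(scale(ind$b))
  expect_equal(up$score, (za + zb) / 2, tolerance = 1e-12)
  expect_equal(dn$score, (za - zb) / 2, tolerance = 1e-12)
})

test_that("zero-variance indicators are dropped with a warning; all-constant errors", {
  ind <- data.frame(block_id = 1:9, flat = rep(2, 9), v = 1:9)
  specs <- indicator_spec(c("flat", "v"), "deprivation_up")
  expect_warning(res <- composite_score(ind, specs), "flat")
  only_v <- composite_score(ind, indicator_spec("v", "deprivation_up"))
  expect_equal(res$score, only_v$score)
  expect_error(
    suppressWarnings(composite_score(data.frame(block_id = 1:4, flat = rep(1, 4)),
                                     indicator_spec("flat", "deprivation_up"))),
    "zero variance")
})

test_that("perfectly cancelling indicators yield a flagged tie-break classification", {
  v <- c(1, 4, 2, 9, 5, 3)
  ind <- data.frame(block_id = sprintf("b%d", 1:6), a = v, b = -v)
  expect_warning(
    res <- composite_score(ind, indicator_spec(c("a", "b"), "deprivation_up")),
    "tie-break")
  expect_true(all(abs(res$score) < 1e-12))
  expect_true(attr(res, "degenerate"))
  expect_equal(as.vector(table(res$class)), c(2, 2, 2))
})

test_that("class codings produce the vectors Moran's I expects", {
  ind <- data.frame(block_id = sprintf("b%d", 1:9), v = 1:9)
  res <- composite_score(ind, indicator_spec("v", "deprivation_up"))
  ordv <- class_to_value(res, "ordinal")
  expect_setequal(unique(ordv), c(1, 2, 3))
  expect_equal(sum(class_to_value(res, "lower_binary")), 3)
  # ordinal coding: lower (most deprived) = 3
  expect_equal(ordv[res$block_id == "b9"], 3)
  expect_equal(ordv[res$block_id == "b1"], 1)
})

test_that("clustered deprivation yields a significantly positive Moran's I on class codings", {
  cities <- lapply(1:25, function(s)
    generate_city(city_config(seed = 100 + s, grid_nx = 12, grid_ny = 12,
                              block_size = 100, deprivation_rho = 0.8,
                              n_facilities = 3, pop_total = 10000)))
  w <- build_weights(cities[[1]]$blocks, "rook")
  z <- vapply(cities, function(ct) {
    pv <- composite_score(ct$blocks, default_indicator_specs())
    morans_i(class_to_value(pv, "ordinal"), w)$z
  }, numeric(1))
  expect_gte(mean(z > 1.96), 0.9)
})
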