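test_that("bimodal log-diameter histograms give the between-mode valley", {
  cfg <- beet_config()
  set.seed(41)
  v <- c(rnorm(2500, 0.3, 0.15), rnorm(2500, 1.3, 0.25))
  thr <- small_object_threshold(v, cfg)
  # independent oracle: minimum of the closed-form mixture density between
  # the two modes
  dens <- function(t) 0.5 * dnorm(t, 0.3, 0.15) + 0.5 * dnorm(t, 1.3, 0.25)
  valley <- stats::optimize(dens, c(0.4, 1.2))$minimum
  expect_lt(abs(thr - valley), 0.12)
  expect_lte(thr, cfg$max_log_threshold)
})

test_that("unimodal samples fall back to 0.5, i.e. a 3 um diameter", {
  cfg <- beet_config()
  set.seed(42)
  expect_equal(small_object_threshold(rnorm(3000, 1.2, 0.2), cfg), 0.5)
  expect_equal(round(10^0.5), 3)
})

test_that("valleys above 0.8 are capped to protect viable cells", {
  cfg <- beet_config()
  set.seed(43)
  v <- c(rnorm(2500, 0.7, 0.1), rnorm(2500, 1.5, 0.1))  # valley near 1.1
  expect_equal(small_object_threshold(v, cfg), 0.8)
})

test_that("neighbor gating keeps symmetric rings and drops distance outliers", {
  cfg <- beet_config()
  # 6 equidistant points on a circle around a focal center: all retained
  ang <- 2 * pi * (0:5) / 6
  cells <- toy_cells(rep(20, 7), x = c(0, 10 * cos(ang)),
                     y = c(0, 10 * sin(ang)))
  nb <- gated_neighbors(cells, cfg)
  expect_equal(sort(nb$neighbors[[1]]), 2:7)
  expect_equal(nb$dist_iqr[1], 0, tolerance = 1e-9)
  # 6 near neighbors and one far point: the far one is gated out
  cells2 <- toy_cells(rep(20, 8),
                      x = c(0, 10 * cos(ang), 1000), y = c(0, 10 * sin(ang), 0))
  nb2 <- gated_neighbors(cells2[-2, ], cfg)   # drop one near so far is in k-set
  expect_false(which(cells2$order[-2] == 8) %in% nb2$neighbors[[1]])
  # two cells: each the other's single neighbor
  nb3 <- gated_neighbors(toy_cells(c(20, 20), c(0, 5), c(0, 0)), cfg)
  expect_equal(nb3$neighbors[[1]], 2L)
  expect_equal(nb3$neighbors[[2]], 1L)
})

test_that("quantile fences match a brute-force sort-based oracle", {
  set.seed(44)
  for (rep in 1:200) {
    v <- rnorm(sample(5:40, 1))
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    b <- c(brute_quantile7(v, 0.25), brute_quantile7(v, 0.5),
           brute_quantile7(v, 0.75))
    expect_equal(q, b, tolerance = 1e-12)
  }
})

test_that("diameter outliers below Q1 - 1.5 IQR of their neighborhood drop", {
  cfg <- beet_config()
  mk <- function(dlogs) {
    cells <- toy_cells(10^dlogs, x = c(0, 10 * cos(2 * pi * (0:5) / 6)),
                       y = c(0, 10 * sin(2 * pi * (0:5) / 6)))
    diameter_outlier_pass(cells, gated_neighbors(cells, cfg))
  }
  # focal 0.5 among six neighbors at 1.5: Q1 = 1.5, IQR = 0 -> removed
  r1 <- mk(c(0.5, rep(1.5, 6)))
  expect_equal(r1$removed_ids, 1L)
  # all equal: IQR = 0 but the focal equals Q1 -> kept
  r2 <- mk(rep(1.2, 7))
  expect_equal(length(r2$removed_ids), 0L)
  # spread neighborhood {1.0 .. 1.5}: focal 1.0 is inside the fence
  r3 <- mk(c(1.0, 1.1, 1.2, 1.3, 1.4, 1.5, 1.25))
  expect_false(1L %in% r3$removed_ids)
  # the quantiles in effect are recorded on the table
  expect_true(all(is.finite(r3$kept$Q1)))
  expect_true(all(r3$kept$IQR >= 0))
})

test_that("size-ordered k-means labels smallest as 1 regardless of restarts", {
  cfg <- beet_config()
  set.seed(45)
  small <- toy_cells(rnorm(40, 10, 0.5), runif(40, 0, 100), runif(40, 0, 100))
  big <- toy_cells(rnorm(40, 40, 0.5), runif(40, 0, 100), runif(40, 0, 100))
  cells <- rbind(small, big)
  lab <- kmeans_sized(cells, 2L, cfg)
  expect_true(all(lab[1:40] == 1L))
  expect_true(all(lab[41:80] == 2L))
  # three well-separated blobs recovered exactly, ordered by size
  blobs <- rbind(toy_cells(rnorm(30, 8, 0.1), 1:30, 0),
                 toy_cells(rnorm(30, 20, 0.1), 1:30, 50),
                 toy_cells(rnorm(30, 50, 0.1), 1:30, 100))
  lab3 <- kmeans_sized(blobs, 3L, cfg)
  expect_equal(lab3, rep(1:3, each = 30))
  # duplicated identical rows: single label, no crash
  dup <- toy_cells(rep(15, 10), rep(1, 10), rep(1, 10))
  expect_true(all(kmeans_sized(dup, 3L, cfg) == 1L))
  expect_error(kmeans_sized(dup[1:2, ], 3L, cfg), "at least")
})

test_that("the majority rule reproduces the worked neighbor arithmetic", {
  cfg <- beet_config()
  ang <- 2 * pi * (0:3) / 4
  cells <- toy_cells(c(8, rep(35, 4)), x = c(0, 12 * cos(ang)),
                     y = c(0, 12 * sin(ang)))
  nbrs <- gated_neighbors(cells, cfg)
  # neighbors {3,3,3,2}: SUM 11 >= MAX - MEAN = 12 - 2.75 -> intercellular
  res <- majority_rule_pass(cells, nbrs, c(1L, 3L, 3L, 3L, 2L))
  expect_equal(res$removed_ids, 1L)
  d <- res$decisions[res$decisions$order == 1, ]
  expect_equal(d$SUM, 11)
  expect_equal(d$MAX, 12)
  expect_equal(d$MEAN, 2.75)
  expect_true(d$is_intercellular)
  # all neighbors cluster 3 -> removed
  res2 <- majority_rule_pass(cells, nbrs, c(1L, 3L, 3L, 3L, 3L))
  expect_equal(res2$removed_ids, 1L)
  # neighbors all cluster 1: SUM 4 < 12 - 1 -> kept
  res3 <- majority_rule_pass(cells, nbrs, c(1L, 1L, 1L, 1L, 1L))
  expect_equal(length(res3$removed_ids), 0L)
  # non-cluster-1 focal cells are never tested
  res4 <- majority_rule_pass(cells, nbrs, c(2L, 3L, 3L, 3L, 3L))
  expect_equal(nrow(res4$decisions), 0L)
})

test_that("a focal object with zero gated neighbors is kept", {
  cfg <- beet_config()
  cells <- toy_cells(c(8, rep(35, 4)), x = c(0, 12, 24, 36, 48), y = 0)
  nbrs <- gated_neighbors(cells, cfg)
  nbrs$neighbors[[1]] <- integer()
  res <- majority_rule_pass(cells, nbrs, c(1L, 3L, 3L, 3L, 3L))
  expect_equal(length(res$removed_ids), 0L)
})

test_that("iterative filtering reaches a fixed point and logs removals", {
  cfg <- beet_config()
  # homogeneous clean table (no outliers by construction): unchanged
  ang <- 2 * pi * (0:35) / 36
  cells <- toy_cells(rep(30, 36), x = 40 * cos(ang), y = 40 * sin(ang))
  out <- iterate_filtering(cells, cfg)
  expect_equal(nrow(out), 36L)
  expect_equal(attr(out, "intercellcount"), 0)
  # chain: removing the first void exposes the second; both go over >= 2
  # passes of the neighborhood analysis
  grid <- expand.grid(x = seq(0, 150, by = 30), y = seq(0, 150, by = 30))
  host <- toy_cells(rep(35, nrow(grid)), grid$x, grid$y)
  v1 <- toy_cells(9, 75 + 15, 75, )
  v2 <- toy_cells(11, 75 + 15, 75 + 26)
  chain <- rbind(host, v1, v2)
  chain$order <- seq_len(nrow(chain))
  out2 <- iterate_filtering(chain, cfg)
  lg <- attr(out2, "removal_log")
  expect_true(all(c(nrow(host) + 1L, nrow(host) + 2L) %in% lg$order))
  expect_equal(nrow(out2), nrow(host))
  expect_equal(attr(out2, "intercellcount"),
               sum(lg$s.area[lg$stage != "size_threshold"]))
  # monotonicity: kept set shrinks weakly, removed + kept partition input
  expect_true(nrow(out2) <= nrow(chain))
  expect_setequal(c(out2$order, lg$order), chain$order)
})

test_that("filtering an all-artifact table empties it with a warning", {
  cfg <- beet_config()
  set.seed(47)
  tiny <- toy_cells(runif(30, 1.2, 2.5), runif(30, 0, 100), runif(30, 0, 100))
  expect_warning(out <- iterate_filtering(tiny, cfg), "every object")
  expect_equal(nrow(out), 0L)
})
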