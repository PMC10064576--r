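test_that("binarize recovers clean two-phase scenes and is deterministic", {
  w <- 300; h <- 200
  ctr <- cbind(c(60, 150, 240, 100, 200), c(60, 60, 60, 140, 140))
  m <- disc_mask(w, h, ctr, rep(14, 5))
  img <- as_image_record(0.2 + 0.7 * m, "discs")
  bw <- binarize(img, beet_config())
  # oracle: direct thresholding — every disc center region is foreground,
  # background stays background; opening only trims at sub-brush scale
  expect_true(all(bw[ctr]))
  expect_lt(sum(bw & !m), 5)
  expect_gt(sum(bw & m) / sum(m), 0.8)
  expect_identical(bw, binarize(img, beet_config()))
})

test_that("single-pixel salt noise is removed by the opening cycles", {
  w <- 300; h <- 200
  ctr <- cbind(c(80, 220), c(100, 100))
  m <- disc_mask(w, h, ctr, c(15, 15))
  base <- 0.2 + 0.7 * m
  noisy <- base
  set.seed(11)
  salt <- cbind(sample(seq(5, w - 5), 40), sample(seq(5, h - 5), 40))
  salt <- salt[!m[salt], , drop = FALSE]
  noisy[salt] <- 0.95
  bw0 <- binarize(as_image_record(base, "clean"), beet_config())
  bw1 <- binarize(as_image_record(noisy, "salt"), beet_config())
  expect_false(any(bw1[salt]))
  expect_identical(bw0, bw1)
})

test_that("a constant image gives an all-false mask with a warning", {
  img <- as_image_record(matrix(0.5, 50, 40), "flat")
  expect_warning(bw <- binarize(img, beet_config()), "constant")
  expect_false(any(bw))
})

test_that("peridermal-edge masking removes only the left non-tissue region", {
  cfg <- beet_config()
  w <- 2000; h <- 300   # 5% strip = 100 px
  # tissue: a lattice of cell-sized bright interiors separated by dark walls;
  # no structure survives the size-50 opening, so nothing is masked
  ctr <- as.matrix(expand.grid(seq(15, w - 15, by = 32),
                               seq(15, h - 15, by = 32)))
  tissue <- disc_mask(w, h, ctr, rep(13, nrow(ctr)))
  roi <- mask_peridermal_edge(tissue, cfg)
  expect_true(all(roi$pixels))
  expect_equal(roi$innerpixarea, w * h)
  expect_equal(roi$imagetotalpix, w * h)
  # a solid empty region at the left margin (3% of width deep): removed
  # within opening-scale boundary error (10% of its area)
  void <- matrix(FALSE, w, h)
  void[1:60, 25:275] <- TRUE
  m_void <- tissue & !void | void
  roi2 <- mask_peridermal_edge(m_void, cfg)
  removed <- sum(!roi2$pixels)
  expect_lt(abs(removed - sum(void)) / sum(void), 0.10)
  expect_gt(sum(!roi2$pixels & void) / sum(void), 0.85)
  # nothing is ever removed beyond the searched strip
  ec <- ceiling(cfg$edge_fraction * w)
  expect_true(all(roi2$pixels[(ec + 1):w, ]))
  # the same solid region placed beyond 5% of the width is untouched
  far <- matrix(FALSE, w, h)
  far[200:260, 25:275] <- TRUE
  roi3 <- mask_peridermal_edge(tissue | far, cfg)
  expect_true(all(roi3$pixels))
})

test_that("border-object removal partitions the foreground", {
  w <- 200; h <- 120
  m <- disc_mask(w, h, cbind(c(100, 195), c(60, 60)), c(20, 15))
  rb <- remove_border_objects(m)
  expect_equal(rb$n_border, 1L)
  expect_true(all((rb$interior | rb$border) == m))
  expect_false(any(rb$interior & rb$border))
  expect_true(any(rb$interior[cbind(100, 60)]))
  # a blob touching only via one corner pixel is a border object
  m2 <- matrix(FALSE, 50, 50)
  m2[1:3, 1:3] <- TRUE
  m2[1, 1] <- TRUE
  rb2 <- remove_border_objects(m2)
  expect_equal(rb2$n_border, 1L)
  expect_false(any(rb2$interior))
  # empty mask
  rb3 <- remove_border_objects(matrix(FALSE, 10, 10))
  expect_equal(rb3$n_border, 0L)
  expect_false(any(rb3$border))
})
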