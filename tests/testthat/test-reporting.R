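master_fixture <- function(datanames, n_per = 10, diam_mean = 20, seed = 71) {
  set.seed(seed)
  tabs <- lapply(seq_along(datanames), function(i) {
    cells <- toy_cells(rnorm(n_per, diam_mean, 2),
                       runif(n_per, 0, 1000), runif(n_per, 0, 300))
    cells$Cluster_zw <- rep(c("VT", "SP"), length.out = n_per)
    cells$Cluster_drei <- rep(1:3, length.out = n_per)
    cells$Imagetotalpix <- 200000L
    cells$Innerpixarea <- 180000L
    cells$Cellwallcount <- 60000L
    cells$Intercellcount <- 4000L
    cells$Dataname <- datanames[i]
    cells
  })
  assemble_master(tabs)
}

test_that("master assembly broadcasts image stats and validates columns", {
  m1 <- master_fixture("a.tif")
  expect_equal(nrow(m1), 10L)
  expect_true(all(m1$Innerpixarea == 180000L))
  m2 <- master_fixture(c("a.tif", "b.tif"), n_per = 10)
  expect_equal(nrow(m2), 20L)
  expect_setequal(unique(m2$Dataname), c("a.tif", "b.tif"))
  bad <- master_fixture("a.tif")
  bad$extra <- 1
  expect_error(assemble_master(list(bad)), "column mismatch")
})

test_that("an image with zero surviving cells still contributes accounting", {
  spec <- synthetic_spec(width = 300, height = 120, n_ring_bands = 0,
                         edge_void = FALSE, seed = 72)
  ph <- list(cells = beetmorph:::empty_object_table(),
             rings = structure(list(valley_x = numeric(), peak_x = numeric(),
                                    nmdeep = 0L, nmbpeak = 0L,
                                    smoothed_profile = data.frame()),
                               class = "beet_rings"),
             stats = list(Imagetotalpix = 36000L, Innerpixarea = 30000L,
                          Cellwallcount = 10000L, Intercellcount = 0),
             counts = list(n_watershed = 0L, n_border = 0L, n_final = 0L),
             removal_log = data.frame(), dataname = "empty.tif",
             config = beet_config())
  class(ph) <- "beet_phenotype"
  m <- assemble_master(list(ph))
  expect_equal(nrow(m), 1L)
  expect_true(is.na(m$order[1]))
  expect_equal(m$Innerpixarea[1], 30000L)
})

test_that("genotype summaries aggregate image statistics", {
  master <- master_fixture(c("a.tif", "b.tif", "c.tif", "d.tif"))
  map <- data.frame(Dataname = c("a.tif", "b.tif", "c.tif", "d.tif"),
                    genotype = c("g1", "g1", "g2", "g2"))
  s <- summarize_genotypes(master, map)
  expect_equal(nrow(s), 2L)
  expect_equal(s$n_images, c(2L, 2L))
  # per-cluster percentages each sum to 100 per genotype
  expect_equal(s$vt_cell_pct + s$sp_cell_pct, c(100, 100))
  expect_equal(s$vt_area_pct + s$sp_area_pct, c(100, 100))
  expect_error(summarize_genotypes(master, map[1:3, ]), "without genotype")
  # worked arithmetic: 4 cells {10,10,20,40} in one image
  one <- master_fixture("x.tif", n_per = 4)
  one$Meandiameterum <- c(10, 10, 20, 40)
  s1 <- summarize_genotypes(one, c(x.tif = "g"))
  expect_equal(s1$mean_diameter_mean, 20)
  expect_equal(s1$max_diameter_mean, 40)
  # two identical images: zero dispersion across images
  two <- master_fixture(c("x.tif", "y.tif"), n_per = 6, seed = 73)
  two[two$Dataname == "y.tif", setdiff(names(two), "Dataname")] <-
    two[two$Dataname == "x.tif", setdiff(names(two), "Dataname")]
  s2 <- summarize_genotypes(two, c(x.tif = "g", y.tif = "g"))
  expect_equal(s2$n_cells_sd, 0)
  expect_equal(s2$mean_diameter_sd, 0)
})

test_that("count validation reproduces R-squared identities", {
  expect_equal(validate_counts(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(validate_counts(2 * c(5, 9, 14), c(5, 9, 14)), 1)
  expect_error(validate_counts(1:3, 1:4), "length")
  expect_error(validate_counts(1:2, 1:2), "at least 3")
  # brute-force oracle: 1 - SSres/SStot on random pairs
  set.seed(74)
  for (rep in 1:20) {
    x <- rnorm(12); y <- 2 * x + rnorm(12, 0, 0.5)
    fit <- lm(y ~ x)
    r2 <- 1 - sum(residuals(fit)^2) / sum((y - mean(y))^2)
    expect_equal(validate_counts(y, x), r2, tolerance = 1e-12)
  }
})

test_that("the reference validation table gives the published precision", {
  f <- system.file("extdata", "validation_counts.csv", package = "beetmorph")
  tab <- read.csv(f)
  expect_equal(sum(tab$final_count), 16790)
  expect_equal(sum(tab$ground_truth), 15100)
  expect_equal(round(validate_counts(tab$watershed_count, tab$ground_truth), 4),
               0.9798)
  expect_equal(round(validate_counts(tab$final_count, tab$ground_truth), 4),
               0.9815)
})

test_that("the size KDE is a unit-area Gaussian estimate at bandwidth 1", {
  cfg <- beet_config()
  set.seed(75)
  d <- size_kde(rnorm(2000, 12, 2), cfg)
  expect_equal(d$bw, 1)
  expect_lt(abs(d$x[which.max(d$y)] - 12), 0.5)
  area <- sum(diff(d$x) * (d$y[-1] + d$y[-length(d$y)]) / 2)
  expect_gt(area, 0.99); expect_lt(area, 1.01)
  # two-point sample: symmetric bimodal curve
  d2 <- size_kde(c(0, 10), cfg)
  expect_equal(d2$y, rev(d2$y), tolerance = 1e-6)
  expect_error(size_kde(5, cfg), "at least 2")
})

test_that("EMD scores are symmetric, zero on identical groups, tree valid", {
  cfg <- beet_config(emd_permutations = 30, emd_n = 20)
  master <- master_fixture(rep(c("a", "b", "c", "d", "e", "f"), 1), n_per = 12,
                           seed = 76)
  # c/d duplicate a/b exactly: genotypes g1 and g2 are identical
  for (col in setdiff(names(master), "Dataname")) {
    master[master$Dataname == "c", col] <- master[master$Dataname == "a", col]
    master[master$Dataname == "d", col] <- master[master$Dataname == "b", col]
  }
  # shift genotype g3 far away in diameter
  i3 <- master$Dataname %in% c("e", "f")
  master$Meandiameterum[i3] <- master$Meandiameterum[i3] + 40
  master$Diameter_log[i3] <- log10(master$Meandiameterum[i3])
  map <- data.frame(Dataname = c("a", "b", "c", "d", "e", "f"),
                    genotype = c("g1", "g1", "g2", "g2", "g3", "g3"))
  emd <- emd_dendrogram(master, map, cfg)
  D <- as.matrix(emd$dist)
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_equal(D["g1", "g2"], 0, tolerance = 1e-9)
  expect_gt(D["g1", "g3"], D["g1", "g2"])
  # identical genotypes merge first; merge heights are non-decreasing
  expect_equal(sort(emd$hclust$merge[1, ]),
               sort(-which(rownames(D) %in% c("g1", "g2"))))
  expect_true(all(diff(emd$hclust$height) >= 0))
  expect_match(emd$newick, "^\\(.*\\);$")
  expect_error(emd_dendrogram(master, map[map$genotype == "g1", ], cfg),
               "at least 2")
})
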