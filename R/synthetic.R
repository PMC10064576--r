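#' Specification of a synthetic tissue image
#'
#' Defines a ring-structured mosaic emulating a transverse beet-root section:
#' alternating bands of small-celled (cambium ring / vascular) and
#' large-celled (storage parenchyma) zones along x, dark cell walls on light
#' interiors, intercellular voids between large cells, sub-cellular bright
#' specks (artifacts), an irregular non-tissue region at the left margin, and
#' objects truncated by the image borders. The target cell diameter follows a
#' smooth raised-cosine profile across the bands so that the loess assumption
#' of the ring detector holds.
#'
#' @param width,height image size [px].
#' @param n_ring_bands number of small-celled bands; 0 gives a uniform
#'   large-celled mosaic.
#' @param band_centers x positions of the band centers [px]; default evenly
#'   spaced at `i * width / (n + 1)`.
#' @param band_halfwidth half-width of the raised-cosine band profile [px].
#' @param small_cell_diam,large_cell_diam `c(mean, sd)` of the cell diameter
#'   in the band and parenchyma zones [um].
#' @param wall_thickness rendered cell-wall thickness [px].
#' @param intercellular_rate fraction of large cells whose junction with a
#'   neighbor is converted into a small void.
#' @param artifact_rate expected specks per 10^4 px^2.
#' @param edge_void whether to carve the irregular non-tissue region at the
#'   left margin.
#' @param edge_depth maximal depth of that region [px]; default 3.5% of width.
#' @param um_per_px pixel pitch [um/px].
#' @param seed RNG seed; the generator is fully deterministic given the seed.
#' @return A validated list of class `beet_synthetic_spec`.
#' @export
synthetic_spec <- function(width = 2000, height = 400, n_ring_bands = 5,
                           band_centers = NULL, band_halfwidth = 60,
                           small_cell_diam = c(mean = 12, sd = 2),
                           large_cell_diam = c(mean = 35, sd = 6),
                           wall_thickness = 2, intercellular_rate = 0.05,
                           artifact_rate = 0.5, edge_void = TRUE,
                           edge_depth = NULL, um_per_px = 1.015228,
                           seed = 1L) {
  if (is.null(band_centers) && n_ring_bands > 0)
    band_centers <- seq_len(n_ring_bands) * width / (n_ring_bands + 1)
  if (is.null(band_centers)) band_centers <- numeric()
  if (is.null(edge_depth)) edge_depth <- 0.035 * width
  spec <- list(width = width, height = height,
               n_ring_bands = length(band_centers),
               band_centers = band_centers, band_halfwidth = band_halfwidth,
               small_cell_diam = small_cell_diam,
               large_cell_diam = large_cell_diam,
               wall_thickness = wall_thickness,
               intercellular_rate = intercellular_rate,
               artifact_rate = artifact_rate, edge_void = edge_void,
               edge_depth = edge_depth, um_per_px = um_per_px,
               seed = as.integer(seed))
  validate_synthetic_spec(spec)
}

validate_synthetic_spec <- function(spec) {
  stopifnot(spec$width > 0, spec$height > 0, spec$um_per_px > 0,
            spec$wall_thickness >= 1)
  if (spec$intercellular_rate < 0 || spec$intercellular_rate > 1 ||
      spec$artifact_rate < 0)
    stop("rates must lie in [0, 1] (intercellular) / be non-negative (artifact)",
         call. = FALSE)
  bc <- spec$band_centers
  if (length(bc)) {
    if (any(diff(bc) <= 0) || any(bc < 0) || any(bc >= spec$width))
      stop("band_centers must be strictly increasing within [0, width)",
           call. = FALSE)
    min_gap <- min(diff(c(0, bc, spec$width)))
    if (min_gap < 2 * spec$large_cell_diam[["mean"]] / spec$um_per_px)
      stop("band spacing below twice the maximal cell diameter", call. = FALSE)
  }
  structure(spec, class = "beet_synthetic_spec")
}

# target mean diameter [um] at x positions: parenchyma baseline with
# raised-cosine dips at the band centers
target_diameter <- function(x, spec) {
  lo <- spec$small_cell_diam[["mean"]]
  hi <- spec$large_cell_diam[["mean"]]
  bump <- numeric(length(x))
  for (c0 in spec$band_centers) {
    u <- (x - c0) / spec$band_halfwidth
    w <- abs(u) <= 1
    bump[w] <- pmax(bump[w], 0.5 * (1 + cos(pi * u[w])))
  }
  hi - (hi - lo) * bump
}

# all stochastic structure of one synthetic image, drawn under the spec seed:
# seed points with classes, planted voids, artifacts, the edge curve, and the
# ground-truth object table with synthesized morphometric features
synth_structure <- function(spec) {
  with_local_seed(spec$seed, {
    W <- spec$width; H <- spec$height
    wt <- spec$wall_thickness
    mid <- (spec$small_cell_diam[["mean"]] + spec$large_cell_diam[["mean"]]) / 2

    # irregular left-margin boundary of the tissue
    if (spec$edge_void) {
      yy <- seq_len(H)
      ph <- stats::runif(3, 0, 2 * pi)
      am <- stats::runif(3, 0.2, 1)
      curve <- am[1] * sin(2 * pi * yy / H + ph[1]) +
        am[2] * sin(4 * pi * yy / H + ph[2]) +
        am[3] * sin(7 * pi * yy / H + ph[3])
      curve <- (curve - min(curve)) / max(diff(range(curve)), 1e-9)
      edge_x <- spec$edge_depth * (0.25 + 0.75 * curve)
    } else edge_x <- rep(0, H)

    # near-hexagonal column march with x-dependent spacing
    sx <- function(x) target_diameter(x, spec) / spec$um_per_px / 1.05 + wt + 1
    pts <- list(); phase <- FALSE
    x <- 2 + sx(1) / 2
    while (x < W - 2) {
      s <- sx(x)
      y0 <- 2 + if (phase) s / 2 else 0
      ys <- seq(y0, H - 2, by = s)
      if (length(ys)) {
        xj <- x + stats::rnorm(length(ys), 0, 0.10 * s)
        yj <- ys + stats::rnorm(length(ys), 0, 0.10 * s)
        ok <- xj > 2 & xj < W - 1 & yj > 2 & yj < H - 1 &
          xj > edge_x[pmin(pmax(round(yj), 1), H)] + 0.35 * s
        if (any(ok)) pts[[length(pts) + 1L]] <- cbind(xj[ok], yj[ok])
      }
      phase <- !phase
      x <- x + 0.87 * s
    }
    P <- do.call(rbind, pts)
    d_t <- target_diameter(P[, 1], spec)
    seeds <- data.frame(x = P[, 1], y = P[, 2], d_target = d_t,
                        class = ifelse(d_t < mid, "cell_VT", "cell_SP"))

    # intercellular voids at junctions between large cells: hosts are deep
    # parenchyma seeds (band profile influence < 15%), so every void is
    # smaller than all its adjacent cells, as in real beet tissue
    hi <- spec$large_cell_diam[["mean"]]; lo2 <- spec$small_cell_diam[["mean"]]
    deep <- seeds$d_target > hi - 0.15 * (hi - lo2)
    sp_idx <- which(seeds$class == "cell_SP" & deep)
    n_void <- round(spec$intercellular_rate * length(sp_idx))
    voids <- data.frame(x = numeric(), y = numeric(), r_px = numeric())
    if (n_void > 0 && length(sp_idx) > 1) {
      pick <- sample(sp_idx, n_void)
      vx <- vy <- vr <- numeric(n_void)
      for (k in seq_len(n_void)) {
        i <- pick[k]
        others <- sp_idx[sp_idx != i]
        d2 <- (seeds$x[others] - seeds$x[i])^2 + (seeds$y[others] - seeds$y[i])^2
        j <- others[which.min(d2)]
        vx[k] <- (seeds$x[i] + seeds$x[j]) / 2
        vy[k] <- (seeds$y[i] + seeds$y[j]) / 2
        vr[k] <- stats::runif(1, 4, 7)
      }
      keep <- vx > vr + 2 & vx < W - vr - 2 & vy > vr + 2 & vy < H - vr - 2
      # one void per junction neighborhood: keep voids far enough apart that
      # no void appears among another void's nearest neighbors (a void next
      # to a void has no well-defined set of surrounding cells)
      min_gap2 <- (1.8 * hi / spec$um_per_px)^2
      sel <- logical(length(vx))
      for (k in which(keep)) {
        prev <- which(sel)
        if (!length(prev) ||
            all((vx[prev] - vx[k])^2 + (vy[prev] - vy[k])^2 > min_gap2))
          sel[k] <- TRUE
      }
      voids <- data.frame(x = vx[sel], y = vy[sel], r_px = vr[sel])
    }

    # sub-cellular bright specks
    n_art <- stats::rpois(1, spec$artifact_rate * W * H / 1e4)
    artifacts <- data.frame(
      x = stats::runif(n_art, 5, W - 5), y = stats::runif(n_art, 5, H - 5),
      d_um = stats::runif(n_art, 1.5, 3))
    artifacts <- artifacts[artifacts$x >
                             edge_x[pmin(pmax(round(artifacts$y), 1), H)] + 5, ,
                           drop = FALSE]

    tab <- synth_features(seeds, voids, artifacts, spec)
    list(seeds = seeds, voids = voids, artifacts = artifacts,
         edge_x = edge_x, table = tab, band_centers = spec$band_centers)
  })
}

# ground-truth object table with synthesized morphometric features; called
# inside synth_structure's RNG scope. Cell-diameter dispersion has two parts
# with the class sd as marginal scale: a smooth spatial field (neighborhoods
# share it) and bounded local jitter — neighboring cells in real tissue are
# developmentally coherent, and an intercellular space is always smaller
# than all cells around it, which presumes locally bounded size variation.
synth_features <- function(seeds, voids, artifacts, spec) {
  upp <- spec$um_per_px
  lo <- spec$small_cell_diam; hi <- spec$large_cell_diam
  n_c <- nrow(seeds)
  sd_eff <- lo[["sd"]] + (hi[["sd"]] - lo[["sd"]]) *
    pmin(pmax((seeds$d_target - lo[["mean"]]) /
                max(hi[["mean"]] - lo[["mean"]], 1e-9), 0), 1)
  # the coherence field varies along y only, so the x diameter profile
  # carries nothing but the planted band structure
  L <- stats::runif(2, c(120, 120), c(350, 350))
  ph <- stats::runif(2, 0, 2 * pi)
  g0 <- sin(2 * pi * seeds$y / L[1] + ph[1]) +
    sin(2 * pi * seeds$y / L[2] + ph[2])   # unit variance
  u0 <- stats::runif(n_c, -sqrt(3), sqrt(3))                  # unit variance
  d_cells <- pmax(seeds$d_target + sd_eff * (0.75 * g0 + 0.66 * u0), 3.5)
  d_voids <- 2 * voids$r_px * upp
  d_art <- artifacts$d_um
  d <- c(d_cells, d_voids, d_art)
  x <- c(seeds$x, voids$x, artifacts$x)
  y <- c(seeds$y, voids$y, artifacts$y)
  cls <- c(seeds$class, rep("intercellular", nrow(voids)),
           rep("artifact", nrow(artifacts)))
  n <- length(d)
  r <- d / 2 / upp
  ecc <- ifelse(cls %in% c("cell_VT", "cell_SP"),
                stats::runif(n, 0.15, 0.65), stats::runif(n, 0.45, 0.9))
  tab <- data.frame(
    order = seq_len(n),
    s.area = pmax(pi * r^2 * (1 + stats::rnorm(n, 0, 0.05)), 1),
    s.perimeter = 2 * pi * r * (1 + stats::runif(n, 0.01, 0.08)),
    s.radius.mean = r,
    s.radius.sd = r * stats::runif(n, 0.04, 0.14),
    s.radius.max = r * (1 + stats::runif(n, 0.08, 0.25)),
    s.radius.min = r * (1 - stats::runif(n, 0.08, 0.25)),
    m.cx = x, m.cy = y,
    m.majoraxis = 2 * r * (1 + 0.3 * ecc),
    m.eccentricity = ecc,
    m.theta = stats::runif(n, -pi / 2, pi / 2),
    Meandiameterum = d,
    Diameter_log = log10(d),
    Q1 = NA_real_, Q3 = NA_real_, IQR = NA_real_,
    ring_zone = 1L, nmbpeak = 0L, nmdeep = 0L,
    Cluster_drei = NA_integer_, Cluster_zw = NA_character_
  )
  tab <- tab[, OBJECT_COLS]
  tab$true_class <- cls
  tab
}

#' Ground-truth object table of a synthetic specification
#'
#' Synthesizes the morphometric feature table of the planted objects (cells,
#' intercellular voids, artifacts) directly from the generator's geometry,
#' without rasterization. The table carries an extra `true_class` column
#' (`cell_VT`, `cell_SP`, `intercellular`, `artifact`) for recovery tests of
#' the ring-detection, filtering and tissue-typing stages. Deterministic
#' given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return Object table with `true_class`.
#' @export
synthetic_object_table <- function(spec) {
  stopifnot(inherits(spec, "beet_synthetic_spec"))
  synth_structure(spec)$table
}

#' Generate a synthetic tissue image with ground truth
#'
#' Rasterizes the planted structure: a centroidal (Voronoi) tessellation of
#' the seed points, dark walls of the configured thickness, bright cell
#' interiors, planted voids stamped at junctions between large cells, bright
#' sub-cellular specks, and the bright non-tissue region at the left margin.
#' Walls inside the small-celled bands are rendered partially washed-out
#' (fragmented), as they are in stained sections where wall thickness
#' approaches the pixel pitch. Bit-identical for a fixed seed.
#'
#' @param spec a [synthetic_spec()].
#' @return Object of class `beet_synthetic`: list with `image` (a
#'   `beet_image`), `truth` (list: `label_map` — interior-only labels,
#'   `object_class`, `true_diameter_um`, `band_centers`, `wall_pixel_count`,
#'   `seeds`, `voids`, `artifacts`, `edge_x`) and `table` (the ground-truth
#'   object table of [synthetic_object_table()]).
#' @export
generate_tissue <- function(spec) {
  stopifnot(inherits(spec, "beet_synthetic_spec"))
  st <- synth_structure(spec)
  W <- spec$width; H <- spec$height
  wt <- spec$wall_thickness

  tissue <- matrix(TRUE, W, H)
  if (spec$edge_void)
    tissue <- outer(seq_len(W), seq_len(H), function(i, j) i > st$edge_x[j])

  seed_img <- matrix(0L, W, H)
  si <- pmin(pmax(round(st$seeds$x), 1), W)
  sj <- pmin(pmax(round(st$seeds$y), 1), H)
  first <- !duplicated(cbind(si, sj))
  seed_img[cbind(si[first], sj[first])] <- which(first)

  vor <- EBImage::propagate(EBImage::Image(matrix(0, W, H)),
                            EBImage::Image(seed_img),
                            mask = EBImage::Image(tissue * 1),
                            lambda = 1e8)
  labels <- EBImage::imageData(vor)
  storage.mode(labels) <- "integer"

  # wall = pixels where the tessellation label changes (right or down)
  wall <- matrix(FALSE, W, H)
  wall[-W, ] <- labels[-W, ] != labels[-1, ]
  wall[, -H] <- wall[, -H] | (labels[, -H] != labels[, -1])
  wall <- wall & tissue
  ksize <- as.integer(wt) + (as.integer(wt) %% 2L == 0L)
  wall <- EBImage::imageData(
    EBImage::dilate(EBImage::Image(wall * 1),
                    EBImage::makeBrush(max(ksize, 3L), "box"))) > 0
  wall <- wall & tissue

  # intensity rendering (noise drawn under a derived seed so the structure
  # RNG stream is independent of raster options)
  img <- with_local_seed(spec$seed + 1L, {
    im <- matrix(0.92, W, H)                    # non-tissue margin: bright
    im[tissue] <- 0.85                          # interiors
    bump <- 1 - (target_diameter(seq_len(W), spec) -
                   spec$small_cell_diam[["mean"]]) /
      max(spec$large_cell_diam[["mean"]] - spec$small_cell_diam[["mean"]], 1e-9)
    in_band <- bump > 0.45
    wi <- which(wall)
    wx <- ((wi - 1L) %% W) + 1L
    frag <- in_band[wx] & stats::runif(length(wi)) > 0.6
    im[wi] <- ifelse(frag, 0.72, 0.15)
    im + matrix(stats::rnorm(W * H, 0, 0.03), W, H)
  })

  # stamp planted voids: dark annulus, bright interior, new labels
  n_seed <- nrow(st$seeds)
  vid <- 0L
  for (k in seq_len(nrow(st$voids))) {
    vx <- st$voids$x[k]; vy <- st$voids$y[k]; r <- st$voids$r_px[k]
    ir <- ceiling(r + wt)
    xs <- max(1, floor(vx - ir)):min(W, ceiling(vx + ir))
    ys <- max(1, floor(vy - ir)):min(H, ceiling(vy + ir))
    dd <- outer(xs, ys, function(i, j) (i - vx)^2 + (j - vy)^2)
    ann <- dd <= (r + wt)^2
    inn <- dd <= r^2
    img[xs, ys][ann] <- 0.15
    wall[xs, ys][ann] <- TRUE
    img[xs, ys][inn] <- 0.88
    wall[xs, ys][inn] <- FALSE
    labels[xs, ys][ann] <- 0L
    labels[xs, ys][inn] <- n_seed + k
    vid <- k
  }

  # stamp artifacts: tiny bright specks
  for (k in seq_len(nrow(st$artifacts))) {
    ax <- st$artifacts$x[k]; ay <- st$artifacts$y[k]
    r <- max(1, st$artifacts$d_um[k] / 2 / spec$um_per_px)
    xs <- max(1, floor(ax - r - 1)):min(W, ceiling(ax + r + 1))
    ys <- max(1, floor(ay - r - 1)):min(H, ceiling(ay + r + 1))
    dd <- outer(xs, ys, function(i, j) (i - ax)^2 + (j - ay)^2)
    inn <- dd <= r^2
    img[xs, ys][inn] <- 0.9
    labels[xs, ys][inn] <- n_seed + vid + k
  }

  img <- pmin(pmax(img, 0), 1)
  labels[wall] <- 0L
  labels[!tissue] <- 0L

  object_class <- c(st$seeds$class,
                    rep("intercellular", nrow(st$voids)),
                    rep("artifact", nrow(st$artifacts)))
  true_d <- c(st$seeds$d_target, 2 * st$voids$r_px * spec$um_per_px,
              st$artifacts$d_um)

  dataname <- sprintf("synthetic_seed%d.tif", spec$seed)
  structure(
    list(image = as_image_record(img, dataname = dataname),
         truth = list(label_map = labels, object_class = object_class,
                      true_diameter_um = true_d,
                      band_centers = st$band_centers,
                      wall_pixel_count = sum(wall),
                      seeds = st$seeds, voids = st$voids,
                      artifacts = st$artifacts, edge_x = st$edge_x),
         table = st$table,
         spec = spec),
    class = "beet_synthetic")
}

#' @export
print.beet_synthetic <- function(x, ...) {
  cls <- table(x$truth$object_class)
  cat(sprintf("<beet_synthetic> %d x %d px, %d bands, seed %d\n",
              x$spec$width, x$spec$height, x$spec$n_ring_bands, x$spec$seed))
  cat("  planted objects:",
      paste(sprintf("%s: %d", names(cls), cls), collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic image and its ground truth to disk
#'
#' Writes the rendered image as TIFF, the label map as 16-bit TIFF and the
#' ground-truth object table as CSV (all files carry a `synthetic_` prefix in
#' their names via the spec's dataname).
#'
#' @param x a `beet_synthetic`.
#' @param dir output directory (created if missing).
#' @return Character vector of the paths written, invisibly.
#' @export
write_tissue <- function(x, dir) {
  stopifnot(inherits(x, "beet_synthetic"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- tools::file_path_sans_ext(x$image$dataname)
  p_img <- file.path(dir, paste0(stem, ".tif"))
  p_lab <- file.path(dir, paste0(stem, "_labels.tif"))
  p_tab <- file.path(dir, paste0(stem, "_truth.csv"))
  EBImage::writeImage(as_ebimage(x$image), p_img, type = "tiff",
                      bits.per.sample = 8L)
  EBImage::writeImage(EBImage::Image(x$truth$label_map / 65535), p_lab,
                      type = "tiff", bits.per.sample = 16L)
  utils::write.csv(x$table, p_tab, row.names = FALSE)
  invisible(c(p_img, p_lab, p_tab))
}
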