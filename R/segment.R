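#' Watershed segmentation of the cell mask
#'
#' Cells whose shared wall was damaged during sectioning appear merged in the
#' binary mask. The Euclidean distance map of the cell interiors (foreground)
#' relative to the wall network (background) is segmented by the watershed
#' transform, which re-splits merged cells along the ridge between their
#' distance maxima — effectively re-closing the damaged wall. A plateau
#' tolerance of 1 px suppresses spurious maxima so that single convex cells
#' are not shattered.
#'
#' @param interior binary mask of complete (non-border) cells.
#' @return Integer label matrix: 0 = background, 1..N = objects. The number of
#'   objects is `max()` of the result. Disjoint connected components are never
#'   merged.
#' @export
watershed_cells <- function(interior) {
  stopifnot(is.matrix(interior), is.logical(interior))
  if (!any(interior)) {
    out <- matrix(0L, nrow(interior), ncol(interior))
    return(out)
  }
  dm <- EBImage::distmap(EBImage::Image(interior * 1))
  ws <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  out <- EBImage::imageData(ws)
  storage.mode(out) <- "integer"
  out
}

#' Extract per-object morphometric features
#'
#' One row per segmented object with the shape descriptors (area, perimeter,
#' mean/sd/max/min radius measured from the centroid to the boundary contour)
#' and the image moments (center of mass, elliptical-fit major axis,
#' eccentricity, orientation angle in radians). The mean cell diameter is
#' `2 * s.radius.mean * um_per_px`; its log10 is stored alongside. A
#' degenerate single-pixel object has zero radius and diameter; its
#' `Diameter_log` is stored as the large negative sentinel `-99` and the
#' object is removed by the small-object threshold downstream.
#'
#' @param labels integer label matrix from [watershed_cells()].
#' @param cfg a [beet_config()]; supplies the pixel pitch.
#' @return Object table (data frame) with columns `order`, `s.area`,
#'   `s.perimeter`, `s.radius.*`, `m.cx`, `m.cy`, `m.majoraxis`,
#'   `m.eccentricity`, `m.theta`, `Meandiameterum`, `Diameter_log`.
#' @export
compute_features <- function(labels, cfg = beet_config()) {
  stopifnot(is.matrix(labels))
  n <- max(labels)
  if (n < 1) return(empty_object_table())
  img <- EBImage::Image(labels)
  fs <- EBImage::computeFeatures.shape(img)
  fm <- EBImage::computeFeatures.moment(img)
  cells <- data.frame(
    order = seq_len(nrow(fs)),
    s.area = fs[, "s.area"],
    s.perimeter = fs[, "s.perimeter"],
    s.radius.mean = fs[, "s.radius.mean"],
    s.radius.sd = fs[, "s.radius.sd"],
    s.radius.max = fs[, "s.radius.max"],
    s.radius.min = fs[, "s.radius.min"],
    m.cx = fm[, "m.cx"],
    m.cy = fm[, "m.cy"],
    m.majoraxis = fm[, "m.majoraxis"],
    m.eccentricity = fm[, "m.eccentricity"],
    m.theta = fm[, "m.theta"],
    row.names = NULL
  )
  cells$Meandiameterum <- 2 * cells$s.radius.mean * cfg$um_per_px
  cells$Diameter_log <- ifelse(cells$Meandiameterum > 0,
                               log10(cells$Meandiameterum),
                               DIAMETER_LOG_SENTINEL)
  cells$Q1 <- NA_real_
  cells$Q3 <- NA_real_
  cells$IQR <- NA_real_
  cells$ring_zone <- 1L
  cells$nmbpeak <- 0L
  cells$nmdeep <- 0L
  cells$Cluster_drei <- NA_integer_
  cells$Cluster_zw <- NA_character_
  cells[, OBJECT_COLS]
}

empty_object_table <- function() {
  tmpl <- list(
    order = integer(), s.area = numeric(), s.perimeter = numeric(),
    s.radius.mean = numeric(), s.radius.sd = numeric(),
    s.radius.max = numeric(), s.radius.min = numeric(),
    m.cx = numeric(), m.cy = numeric(), m.majoraxis = numeric(),
    m.eccentricity = numeric(), m.theta = numeric(),
    Meandiameterum = numeric(), Diameter_log = numeric(),
    Q1 = numeric(), Q3 = numeric(), IQR = numeric(),
    ring_zone = integer(), nmbpeak = integer(), nmdeep = integer(),
    Cluster_drei = integer(), Cluster_zw = character()
  )
  as.data.frame(tmpl)[, OBJECT_COLS]
}

#' Count cell-wall pixels inside the ROI
#'
#' The amount of wall material is the number of background (dark) pixels of
#' the black-and-white image within the region of interest — every ROI pixel
#' that is neither cytoplasm nor intercellular space.
#'
#' @param binarized binary mask from [binarize()] (`TRUE` = cell interior).
#' @param roi a `beet_roi`, or a logical matrix of the same dimensions.
#' @return Integer pixel count (the master-table `Cellwallcount`).
#' @export
cell_wall_count <- function(binarized, roi) {
  rpx <- if (inherits(roi, "beet_roi")) roi$pixels else roi
  stopifnot(is.matrix(binarized), is.matrix(rpx))
  if (!identical(dim(binarized), dim(rpx)))
    stop("mask and ROI dimensions differ: ",
         paste(dim(binarized), collapse = "x"), " vs ",
         paste(dim(rpx), collapse = "x"), call. = FALSE)
  sum(rpx & !binarized)
}
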