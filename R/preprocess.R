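#' Binarize a micrograph
#'
#' Produces the black-and-white tissue mask: Gaussian blur (`gaussian_sigma`),
#' automatic Otsu thresholding (foreground = the lighter phase, i.e. cell
#' interiors; walls are dark), two morphological opening cycles with disc
#' brushes of size `opening_radius_1` and `opening_radius_2`, then hole
#' filling. Opening removes bright specks smaller than the brush while the
#' dark wall network, being the background, is preserved; hole filling closes
#' dark islands that are not connected to the wall network.
#'
#' A constant (zero-contrast) image yields an all-`FALSE` mask with a warning
#' rather than an error.
#'
#' @param img `beet_image` record with intensities in \[0, 1\].
#' @param cfg a [beet_config()].
#' @return Logical matrix of the same dimensions (`TRUE` = cell interior).
#' @export
binarize <- function(img, cfg = beet_config()) {
  stopifnot(inherits(img, "beet_image"))
  px <- img$pixels
  if (diff(range(px)) < 1e-9) {
    warning("constant image: Otsu threshold undefined, returning empty mask")
    return(matrix(FALSE, img$width, img$height))
  }
  x <- EBImage::gblur(as_ebimage(px), sigma = cfg$gaussian_sigma)
  thr <- EBImage::otsu(x)
  m <- EBImage::imageData(x) > thr
  m <- open_disc(m, cfg$opening_radius_1)
  m <- open_disc(m, cfg$opening_radius_2)
  m <- EBImage::imageData(EBImage::fillHull(EBImage::Image(m * 1))) > 0
  m
}

# disc opening; `size` is the brush size (diameter), rounded up to odd as in
# makeBrush, without the rounding warning
open_disc <- function(mask, size) {
  size <- as.integer(size)
  if (size %% 2L == 0L) size <- size + 1L
  kern <- EBImage::makeBrush(size, shape = "disc")
  EBImage::imageData(EBImage::opening(EBImage::Image(mask * 1), kern)) > 0
}

#' Mask the irregular peridermal edge
#'
#' The rounded periderm leaves a non-tissue region at the left margin of each
#' mosaic that tends to hold air bubbles and debris. Only the first
#' `edge_fraction` of the image width is searched: a high opening
#' (`edge_opening_radius` brush) followed by hole filling isolates connected
#' bright areas larger than any cell — the empty, non-tissue region — and
#' that area is excluded from the region of interest.
#'
#' Pixels at x-positions beyond the searched strip are never touched; a fully
#' tissue-covered strip yields an all-`TRUE` ROI.
#'
#' @param mask binary tissue mask from [binarize()].
#' @param cfg a [beet_config()].
#' @return Object of class `beet_roi`: list with `pixels` (logical matrix,
#'   `TRUE` = inside ROI), `innerpixarea` (count of `TRUE` pixels) and
#'   `imagetotalpix`.
#' @export
mask_peridermal_edge <- function(mask, cfg = beet_config()) {
  stopifnot(is.matrix(mask), is.logical(mask))
  w <- nrow(mask); h <- ncol(mask)
  ec <- ceiling(cfg$edge_fraction * w)
  roi <- matrix(TRUE, w, h)
  if (ec >= 1) {
    strip <- mask[seq_len(ec), , drop = FALSE]
    big <- open_disc(strip, cfg$edge_opening_radius)
    big <- EBImage::imageData(EBImage::fillHull(EBImage::Image(big * 1))) > 0
    roi[seq_len(ec), ] <- !big
  }
  structure(
    list(pixels = roi, innerpixarea = sum(roi), imagetotalpix = w * h),
    class = "beet_roi"
  )
}

#' @export
print.beet_roi <- function(x, ...) {
  cat(sprintf("<beet_roi> %d / %d px inside ROI (%.1f%%)\n",
              x$innerpixarea, x$imagetotalpix,
              100 * x$innerpixarea / x$imagetotalpix))
  invisible(x)
}

#' Split edge-touching objects from interior objects
#'
#' Connected components (8-connectivity) with at least one pixel on any image
#' edge are incomplete cells and must not enter size statistics. The
#' foreground is partitioned into an interior mask and a border mask.
#'
#' @param mask binary mask.
#' @return List with `interior` and `border` (logical matrices that partition
#'   the input foreground) and `n_border`, the number of edge-touching
#'   objects.
#' @export
remove_border_objects <- function(mask) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask))
    return(list(interior = mask, border = mask, n_border = 0L))
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  w <- nrow(lab); h <- ncol(lab)
  edge_labels <- unique(c(lab[1, ], lab[w, ], lab[, 1], lab[, h]))
  edge_labels <- edge_labels[edge_labels > 0]
  border <- matrix(lab %in% edge_labels, w, h) & mask
  list(interior = mask & !border, border = border,
       n_border = length(edge_labels))
}
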