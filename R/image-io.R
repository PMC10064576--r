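#' @import EBImage
NULL

# Master-table column order. `MEANDIAM_COL` carries a micro sign in the CSV
# header; inside R the ASCII alias "Meandiameterum" is used.
MEANDIAM_COL <- "Meandiameterµm"

OBJECT_COLS <- c(
  "order", "s.area", "s.perimeter", "s.radius.mean", "s.radius.sd",
  "s.radius.max", "s.radius.min", "m.cx", "m.cy", "m.majoraxis",
  "m.eccentricity", "m.theta", "Meandiameterum", "Diameter_log",
  "Q1", "Q3", "IQR", "ring_zone", "nmbpeak", "nmdeep",
  "Cluster_drei", "Cluster_zw"
)

MASTER_COLS <- c(OBJECT_COLS, "Imagetotalpix", "Innerpixarea",
                 "Cellwallcount", "Intercellcount", "Dataname")

# sentinel stored in Diameter_log for zero-diameter (degenerate) objects
DIAMETER_LOG_SENTINEL <- -99

#' Read a micrograph
#'
#' Reads a TIFF (or PNG) raster, collapses color to grayscale using standard
#' luminance weights, and rescales intensities to \[0, 1\] so that 8-bit and
#' 16-bit encodings of the same scene yield identical records. Images are
#' expected with the periderm at the left margin; the x axis runs rightward
#' from the periderm, the y axis downward.
#'
#' @param path path to a raster image file.
#' @return An object of class `beet_image` with fields `dataname` (the file's
#'   basename), `pixels` (numeric matrix in `[0, 1]`, first dimension = x /
#'   width, second = y / height, the [EBImage] layout), `width` and `height`.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: file not found: ", path, call. = FALSE)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop("cannot read image '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  px <- to_gray(img)
  as_image_record(px, dataname = basename(path))
}

to_gray <- function(img) {
  if (EBImage::colorMode(img) == EBImage::Color) {
    d <- dim(img)
    nch <- if (length(d) >= 3) d[3] else 1
    a <- EBImage::imageData(img)
    if (nch >= 3) {
      px <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
    } else if (length(d) >= 3) {
      px <- a[, , 1]
    } else px <- a
  } else {
    a <- EBImage::imageData(img)
    px <- if (length(dim(a)) > 2) a[, , 1] else a
  }
  px
}

#' Build an image record from a pixel matrix
#'
#' @param pixels numeric matrix, first dimension x (width), second y (height).
#'   Values outside \[0, 1\] are rescaled by the matrix maximum.
#' @param dataname image name recorded in output tables.
#' @return A `beet_image` object.
#' @export
as_image_record <- function(pixels, dataname = "image") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix", call. = FALSE)
  if (any(dim(pixels) == 0))
    stop("zero-area image", call. = FALSE)
  mx <- max(pixels)
  if (mx > 1) pixels <- pixels / mx
  pixels[pixels < 0] <- 0
  structure(
    list(dataname = dataname, pixels = pixels,
         width = nrow(pixels), height = ncol(pixels)),
    class = "beet_image"
  )
}

#' @export
print.beet_image <- function(x, ...) {
  cat(sprintf("<beet_image> %s  %d x %d px, intensity range [%.3f, %.3f]\n",
              x$dataname, x$width, x$height, min(x$pixels), max(x$pixels)))
  invisible(x)
}

as_ebimage <- function(x) {
  if (inherits(x, "beet_image")) x <- x$pixels
  EBImage::Image(x * 1)
}

# ---- object-table serialization --------------------------------------------

#' Write an object table as CSV
#'
#' Emits UTF-8 CSV with the master-table variable names in the header (the
#' mean-diameter column is written with the micro sign).
#'
#' @param cells object table (data frame).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_object_table <- function(cells, path) {
  stopifnot(is.data.frame(cells))
  out <- cells
  names(out)[names(out) == "Meandiameterum"] <- MEANDIAM_COL
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Read an object table written by [write_object_table()]
#'
#' @param path CSV path.
#' @return Data frame with the internal (ASCII) column names.
#' @export
read_object_table <- function(path) {
  x <- utils::read.csv(path, check.names = FALSE, encoding = "UTF-8")
  names(x)[names(x) == MEANDIAM_COL] <- "Meandiameterum"
  # all-NA columns come back typeless; restore the schema types
  char_cols <- c("Cluster_zw", "Dataname")
  for (cn in intersect(names(x), setdiff(MASTER_COLS, char_cols)))
    x[[cn]] <- as.numeric(x[[cn]])
  for (cn in intersect(names(x), char_cols))
    x[[cn]] <- as.character(x[[cn]])
  x
}

# ---- overlays ---------------------------------------------------------------

#' Write a tissue-type overlay image
#'
#' Paints surviving cells on the grayscale micrograph, vascular tissue (VT)
#' green and storage parenchyma (SP) blue.
#'
#' @param img `beet_image` record.
#' @param labels integer label matrix from [watershed_cells()].
#' @param cells final object table holding `order` and `Cluster_zw`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(img, labels, cells, path) {
  base <- img$pixels
  r <- base; g <- base; b <- base
  keep <- labels
  keep[!(labels %in% cells$order)] <- 0L
  vt <- keep %in% cells$order[cells$Cluster_zw == "VT"] & keep > 0
  sp <- keep %in% cells$order[cells$Cluster_zw == "SP"] & keep > 0
  dim(vt) <- dim(sp) <- dim(base)
  g[vt] <- pmin(1, base[vt] * 0.4 + 0.6); r[vt] <- base[vt] * 0.4; b[vt] <- base[vt] * 0.4
  b[sp] <- pmin(1, base[sp] * 0.4 + 0.6); r[sp] <- base[sp] * 0.4; g[sp] <- base[sp] * 0.4
  rgb <- EBImage::rgbImage(EBImage::Image(r), EBImage::Image(g), EBImage::Image(b))
  EBImage::writeImage(rgb, path, type = "png")
  invisible(path)
}

#' Write a binary mask as PNG (debug output for the preprocessing stages)
#'
#' @param mask logical matrix.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(mask * 1), path, type = "png")
  invisible(path)
}

stage_log <- function(stage, n_in, n_out, verbose = TRUE) {
  if (verbose)
    message(sprintf("[%s] in: %d  out: %d  removed: %d",
                    stage, n_in, n_out, n_in - n_out))
  invisible(NULL)
}
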