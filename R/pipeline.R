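#' Run the full per-image phenotyping workflow
#'
#' Chains every stage on one micrograph: binarization, peridermal-edge
#' masking, removal of border-touching objects, watershed segmentation,
#' feature extraction, cambium-ring detection and zone assignment, iterative
#' discrimination of cells from intercellular spaces and artifacts, and final
#' VT/SP tissue typing. Image-level pixel accounting (total pixels, ROI
#' pixels, wall pixels, intercellular pixels) is collected for the master
#' table.
#'
#' @param img a `beet_image` from [read_image()] / [as_image_record()].
#' @param cfg a [beet_config()].
#' @param verbose log per-stage object counts (the in/out bookkeeping of the
#'   workflow) via [message()].
#' @param keep_labels keep the watershed label matrix in the result (needed
#'   for overlays; costs memory).
#' @return Object of class `beet_phenotype`: list with
#' \describe{
#'   \item{cells}{final object table (one row per surviving cell).}
#'   \item{rings}{the `beet_rings` profile object.}
#'   \item{stats}{list: `Imagetotalpix`, `Innerpixarea`, `Cellwallcount`,
#'     `Intercellcount`.}
#'   \item{counts}{per-stage object counts: watershed objects, border objects,
#'     objects entering filtering, final cells.}
#'   \item{removal_log}{stage-by-stage removal bookkeeping.}
#'   \item{dataname, config}{provenance.}
#' }
#' @export
#' @examples
#' spec <- synthetic_spec(width = 600, height = 200, n_ring_bands = 2, seed = 7)
#' img <- generate_tissue(spec)$image
#' ph <- phenotype_image(img, verbose = FALSE)
#' ph
phenotype_image <- function(img, cfg = beet_config(), verbose = TRUE,
                            keep_labels = FALSE) {
  stopifnot(inherits(img, "beet_image"), inherits(cfg, "beet_config"))
  bw <- binarize(img, cfg)
  roi_edge <- mask_peridermal_edge(bw, cfg)
  working <- bw & roi_edge$pixels
  rb <- remove_border_objects(working)
  roi_final <- roi_edge$pixels & !rb$border
  stage_log("border_objects", rb$n_border + 0L, 0L, FALSE)

  labels <- watershed_cells(rb$interior)
  cells <- compute_features(labels, cfg)
  n_ws <- nrow(cells)
  stage_log("watershed", n_ws, n_ws, verbose)

  rings <- suppressWarnings(detect_rings(cells, cfg))
  cells <- assign_ring_zone(cells, rings)

  filtered <- iterate_filtering(cells, cfg)
  stage_log("filtering", n_ws, nrow(filtered), verbose)
  removal_log <- attr(filtered, "removal_log")
  intercell <- attr(filtered, "intercellcount")

  final <- suppressWarnings(classify_tissue(filtered, cfg))
  attr(final, "removal_log") <- NULL
  attr(final, "intercellcount") <- NULL
  attr(final, "n_pass") <- NULL

  out <- list(
    cells = final,
    rings = rings,
    stats = list(
      Imagetotalpix = roi_edge$imagetotalpix,
      Innerpixarea = sum(roi_final),
      Cellwallcount = cell_wall_count(bw, roi_final),
      Intercellcount = intercell
    ),
    counts = list(n_watershed = n_ws, n_border = rb$n_border,
                  n_final = nrow(final)),
    removal_log = removal_log,
    dataname = img$dataname,
    config = cfg
  )
  if (keep_labels) out$labels <- labels
  structure(out, class = "beet_phenotype")
}

#' @export
print.beet_phenotype <- function(x, ...) {
  cat(sprintf("<beet_phenotype> %s\n", x$dataname))
  cat(sprintf("  objects after watershed: %d (+%d edge-touching removed)\n",
              x$counts$n_watershed, x$counts$n_border))
  cat(sprintf("  final cell count:        %d\n", x$counts$n_final))
  cat(sprintf("  cambium rings (valleys): %d\n", x$rings$nmdeep))
  if (nrow(x$cells)) {
    cat(sprintf("  mean cell diameter:      %.1f µm (max %.1f µm)\n",
                mean(x$cells$Meandiameterum), max(x$cells$Meandiameterum)))
    tab <- table(x$cells$Cluster_zw)
    cat("  tissue types:           ",
        paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.beet_phenotype <- function(object, ...) {
  cl <- object$cells
  s <- object$stats
  out <- data.frame(
    Dataname = object$dataname,
    n_cells = nrow(cl),
    mean_diameter_um = if (nrow(cl)) mean(cl$Meandiameterum) else NA_real_,
    max_diameter_um = if (nrow(cl)) max(cl$Meandiameterum) else NA_real_,
    n_rings = object$rings$nmdeep,
    cellwall_frac = if (s$Innerpixarea > 0) s$Cellwallcount / s$Innerpixarea
                    else NA_real_,
    vt_cell_share = if (nrow(cl)) mean(cl$Cluster_zw == "VT") else NA_real_,
    row.names = NULL
  )
  class(out) <- c("summary.beet_phenotype", class(out))
  out
}

#' Plot a phenotyping result
#'
#' `type = "profile"` shows the diameter-vs-x profile with detected rings;
#' `type = "kde"` the Gaussian kernel density estimate of cell diameters.
#'
#' @param x a `beet_phenotype`.
#' @param type one of `"profile"`, `"kde"`.
#' @param ... passed on to the underlying plot.
#' @return `x`, invisibly.
#' @export
plot.beet_phenotype <- function(x, type = c("profile", "kde"), ...) {
  type <- match.arg(type)
  if (type == "profile") {
    plot(x$rings, main = x$dataname, ...)
  } else {
    d <- size_kde(x$cells$Meandiameterum, x$config)
    graphics::plot(d, main = x$dataname,
                   xlab = "cell diameter [µm]", ...)
  }
  invisible(x)
}

#' Build the master-table rows of one phenotyping result
#'
#' @param x a `beet_phenotype`.
#' @return Data frame in the master-table schema (object columns plus the
#'   broadcast image-level pixel accounting and the image name).
#' @export
master_rows <- function(x) {
  stopifnot(inherits(x, "beet_phenotype"))
  cl <- x$cells
  if (nrow(cl) == 0L) cl <- empty_object_table()
  n <- max(nrow(cl), 1L)
  if (nrow(cl) == 0L) cl[1L, ] <- NA   # zero-cell image: one accounting row
  cl$Imagetotalpix <- x$stats$Imagetotalpix
  cl$Innerpixarea <- x$stats$Innerpixarea
  cl$Cellwallcount <- x$stats$Cellwallcount
  cl$Intercellcount <- x$stats$Intercellcount
  cl$Dataname <- x$dataname
  rownames(cl) <- NULL
  cl[, MASTER_COLS]
}
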