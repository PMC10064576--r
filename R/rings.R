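#' Detect cambium rings from the cell-diameter profile
#'
#' Beet storage-root tissue alternates along the periderm-to-center (x) axis
#' between small-celled zones — the cambium rings with their vascular tissue —
#' and big-celled storage parenchyma. Plotting cell diameter against the
#' distance from the left (periderm) margin therefore gives an oscillating
#' profile whose local maxima mark the parenchyma band centers (peaks) and
#' whose local minima mark the cambium rings (valleys).
#'
#' Cells are ordered by their x center of mass; the diameter series is
#' smoothed by a loess local regression with span `ring_span`, and local
#' maxima of the smoothed series are detected within a sliding window of
#' `ring_window_w` consecutive samples (cells). Valleys are the maxima of the
#' negated series. Ties on plateaus resolve to the leftmost sample, and runs
#' of same-type extrema are collapsed to the strongest one so that peaks and
#' valleys strictly alternate. Rings are numbered from the left (outermost)
#' inwards, starting at 1.
#'
#' @param cells object table with `m.cx` and `Meandiameterum`.
#' @param cfg a [beet_config()].
#' @return Object of class `beet_rings`: list with `valley_x` and `peak_x`
#'   (strictly increasing x positions in px), `nmdeep = length(valley_x)`,
#'   `nmbpeak = length(peak_x)` and `smoothed_profile` (data frame `x`,
#'   `diameter`, `smooth`). Fewer than `2 * ring_window_w` cells yield an
#'   empty ring set with a warning; a flat or monotone profile yields an
#'   empty ring set silently.
#' @export
detect_rings <- function(cells, cfg = beet_config()) {
  stopifnot(is.data.frame(cells))
  w <- as.integer(cfg$ring_window_w)
  empty <- structure(
    list(valley_x = numeric(), peak_x = numeric(),
         nmdeep = 0L, nmbpeak = 0L,
         smoothed_profile = data.frame(x = numeric(), diameter = numeric(),
                                       smooth = numeric())),
    class = "beet_rings")
  n <- nrow(cells)
  if (n < 2L * w) {
    warning(sprintf(
      "ring detection needs at least %d cells (2 * ring_window_w), got %d; returning empty ring set",
      2L * w, n))
    return(empty)
  }
  ord <- order(cells$m.cx)
  x <- cells$m.cx[ord]
  d <- cells$Meandiameterum[ord]
  fit <- stats::loess(d ~ x, span = cfg$ring_span, degree = 2,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  s <- stats::predict(fit, data.frame(x = x))

  relief_floor <- cfg$ring_min_relief * mean(abs(s))
  peaks <- window_extrema(s, w, relief_floor)
  valleys <- window_extrema(-s, w, relief_floor)
  ext <- alternate_extrema(s, peaks, valleys)

  structure(
    list(valley_x = x[ext$valleys], peak_x = x[ext$peaks],
         nmdeep = length(ext$valleys), nmbpeak = length(ext$peaks),
         smoothed_profile = data.frame(x = x, diameter = d, smooth = s)),
    class = "beet_rings")
}

# indices of interior local maxima of s that also attain the maximum of the
# centered sliding window of width w; plateau runs collapse to the leftmost
# index; windows with relief below the floor (flat at the detection scale)
# yield nothing.
window_extrema <- function(s, w, relief_floor = 0) {
  n <- length(s)
  wmax <- zoo::rollapply(s, width = w, FUN = max, partial = TRUE,
                         align = "center")
  wmin <- zoo::rollapply(s, width = w, FUN = min, partial = TRUE,
                         align = "center")
  flat_tol <- max(1e-8 * max(abs(s)), relief_floor)
  i <- seq(2L, max(n - 1L, 2L))
  cand <- i[s[i] >= s[i - 1L] & s[i] >= s[i + 1L] &
              s[i] >= wmax[i] &
              (wmax[i] - wmin[i]) > flat_tol]
  if (!length(cand)) return(integer())
  # collapse consecutive candidate indices (plateaus) to the leftmost
  keep <- cand[c(TRUE, diff(cand) > 1L)]
  keep
}

# enforce strict peak/valley alternation: among consecutive extrema of the
# same type keep the strongest (highest peak / deepest valley; ties leftmost)
alternate_extrema <- function(s, peaks, valleys) {
  if (!length(peaks) && !length(valleys))
    return(list(peaks = integer(), valleys = integer()))
  ext <- rbind(
    data.frame(idx = peaks, type = rep("p", length(peaks))),
    data.frame(idx = valleys, type = rep("v", length(valleys)))
  )
  ext <- ext[order(ext$idx), , drop = FALSE]
  run <- cumsum(c(TRUE, ext$type[-1] != ext$type[-nrow(ext)]))
  pick <- vapply(split(seq_len(nrow(ext)), run), function(rows) {
    if (length(rows) == 1L) return(rows)
    v <- s[ext$idx[rows]]
    if (ext$type[rows[1]] == "p") rows[which.max(v)] else rows[which.min(v)]
  }, integer(1))
  ext <- ext[sort(pick), , drop = FALSE]
  list(peaks = ext$idx[ext$type == "p"], valleys = ext$idx[ext$type == "v"])
}

#' @export
print.beet_rings <- function(x, ...) {
  cat(sprintf("<beet_rings> %d valleys (cambium rings), %d peaks (parenchyma)\n",
              x$nmdeep, x$nmbpeak))
  if (x$nmdeep)
    cat("  ring x-positions:", paste(round(x$valley_x), collapse = ", "), "\n")
  invisible(x)
}

#' Plot the diameter profile with detected rings
#'
#' Scatter of cell diameter vs distance from the periderm, the loess-smoothed
#' profile, dashed vertical lines at the detected cambium rings (valleys) and
#' dots at the parenchyma band centers (peaks).
#'
#' @param x a `beet_rings` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.beet_rings <- function(x, ...) {
  p <- x$smoothed_profile
  if (!nrow(p)) {
    warning("empty ring set: nothing to plot")
    return(invisible(x))
  }
  graphics::plot(p$x, p$diameter, pch = 16, cex = 0.3,
                 col = grDevices::grey(0.6),
                 xlab = "distance from periderm [px]",
                 ylab = "cell diameter [µm]", ...)
  graphics::lines(p$x, p$smooth, lwd = 2)
  if (x$nmdeep)
    graphics::abline(v = x$valley_x, col = "red", lty = 2)
  if (x$nmbpeak) {
    sm <- stats::approx(p$x, p$smooth, xout = x$peak_x)$y
    graphics::points(x$peak_x, sm, col = "blue", pch = 19)
  }
  invisible(x)
}

#' Assign each cell to its ring zone
#'
#' The detected valleys (cambium rings) are numbered from the left edge
#' inwards, which partitions the x axis into contiguous zones. Each cell's
#' zone is 1 plus the number of valleys strictly left of its x center of
#' mass, so clustering can later operate between rings. The image-level
#' counts `nmbpeak` and `nmdeep` are broadcast onto all rows.
#'
#' @param cells object table.
#' @param rings a `beet_rings` from [detect_rings()].
#' @return The object table with `ring_zone`, `nmbpeak`, `nmdeep` filled in.
#'   With an empty ring set every cell is in zone 1.
#' @export
assign_ring_zone <- function(cells, rings) {
  stopifnot(is.data.frame(cells), inherits(rings, "beet_rings"))
  if (nrow(cells) == 0) return(cells)
  if (length(rings$valley_x)) {
    zone <- rowSums(outer(cells$m.cx, rings$valley_x, ">")) + 1L
  } else zone <- rep(1L, nrow(cells))
  cells$ring_zone <- as.integer(zone)
  cells$nmbpeak <- rings$nmbpeak
  cells$nmdeep <- rings$nmdeep
  cells
}
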