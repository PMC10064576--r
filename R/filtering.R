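#' Small-object threshold from the log-diameter histogram
#'
#' Artifacts of segmentation (dirt, over-segmented fragments, air bubbles)
#' are much smaller than real cells, so the frequency histogram of
#' log10(diameter) is bimodal: an artifact mode and a cell mode. The
#' threshold is the valley — the minimum-count bin strictly between the two
#' highest local-maximum bins. If the histogram is unimodal (no valley) the
#' fallback 0.5 (a 3 um diameter) is used; a valley above 0.8 is capped to
#' 0.8 to avoid dropping viable cells.
#'
#' @param diam_log numeric vector of log10 diameters (um). Sentinel values of
#'   degenerate objects (`-99`) are ignored when building the histogram.
#' @param cfg a [beet_config()]; supplies bin width, fallback and cap.
#' @return Threshold in log10 um. Objects strictly below it are dropped.
#' @export
small_object_threshold <- function(diam_log, cfg = beet_config()) {
  v <- diam_log[is.finite(diam_log) & diam_log > -10]
  if (length(v) < 2L) return(cfg$fallback_log_threshold)
  bw <- cfg$hist_binwidth
  lo <- floor(min(v) / bw) * bw
  hi <- ceiling(max(v) / bw) * bw
  if (hi <= lo) hi <- lo + bw
  breaks <- seq(lo, hi + bw / 2, by = bw)
  counts <- graphics::hist(v, breaks = breaks, plot = FALSE)$counts
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  nb <- length(counts)
  if (nb < 3L) return(cfg$fallback_log_threshold)
  # derive the continuous curve underlying the histogram: Gaussian smoothing
  # of the bin counts (2-bin kernel sd), so sampling wiggles within a single
  # mode are not mistaken for bimodality
  k <- stats::dnorm(-6:6, sd = 2)
  sm <- as.numeric(stats::filter(c(rep(counts[1], 6), counts,
                                   rep(counts[nb], 6)),
                                 k / sum(k), sides = 2))[7:(nb + 6)]
  pad <- c(-Inf, sm, -Inf)
  is_max <- sm >= pad[seq_len(nb)] & sm >= pad[seq_len(nb) + 2L] &
    sm >= 0.10 * max(sm)
  peaks <- which(is_max)
  # collapse plateau runs to their leftmost bin
  if (length(peaks) > 1L)
    peaks <- peaks[c(TRUE, diff(peaks) > 1L)]
  if (length(peaks) < 2L) return(cfg$fallback_log_threshold)
  top2 <- sort(peaks[order(sm[peaks], decreasing = TRUE)[1:2]])
  if (top2[2] - top2[1] < 2L) return(cfg$fallback_log_threshold)
  between <- (top2[1] + 1L):(top2[2] - 1L)
  valley <- between[which.min(sm[between])]
  # no clear separation between the modes -> no threshold point found
  if (sm[valley] > 0.75 * min(sm[top2]))
    return(cfg$fallback_log_threshold)
  min(mids[valley], cfg$max_log_threshold)
}

#' Neighborhood diameter-outlier pass
#'
#' For every object, quantiles of log10(diameter) over the object itself and
#' its gated neighbors are computed; an object lying below Q1 - 1.5 IQR of
#' its own neighborhood is an outlier — in beet tissue intercellular spaces
#' are always smaller than the cells surrounding them — and is removed as a
#' probable intercellular space. All decisions are taken on the same table
#' state, then applied at once. The neighborhood quantiles active at the time
#' of the test are recorded in the `Q1`, `Q3`, `IQR` columns.
#'
#' @param cells object table.
#' @param nbrs `beet_neighbors` computed on the same table.
#' @return List with `kept` (object table), `removed` (rows removed) and
#'   `removed_ids` (their `order` values).
#' @export
diameter_outlier_pass <- function(cells, nbrs) {
  stopifnot(is.data.frame(cells), inherits(nbrs, "beet_neighbors"))
  n <- nrow(cells)
  if (n == 0L)
    return(list(kept = cells, removed = cells[0, ], removed_ids = integer()))
  stopifnot(length(nbrs$neighbors) == n)
  dlog <- cells$Diameter_log
  out <- logical(n)
  for (i in seq_len(n)) {
    hood <- c(dlog[i], dlog[nbrs$neighbors[[i]]])
    qs <- stats::quantile(hood, c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- qs[2] - qs[1]
    cells$Q1[i] <- qs[1]
    cells$Q3[i] <- qs[2]
    cells$IQR[i] <- iqr
    out[i] <- dlog[i] < qs[1] - 1.5 * iqr
  }
  list(kept = cells[!out, , drop = FALSE],
       removed = cells[out, , drop = FALSE],
       removed_ids = cells$order[out])
}

# morphological feature columns used for clustering: everything from the
# feature extraction except position (m.cx, m.cy) and the ring number
KMEANS_FEATURES <- c("s.area", "s.perimeter", "s.radius.mean", "s.radius.sd",
                     "s.radius.max", "s.radius.min", "m.majoraxis",
                     "m.eccentricity", "m.theta")

#' Size-ordered k-means clustering
#'
#' Centers and scales the morphological feature columns (position and ring
#' number are excluded) and runs k-means with `kmeans_nstart` random starts
#' and at most `kmeans_max_iter` iterations, seeded from the configuration so
#' runs are reproducible. Because raw k-means label numbering is arbitrary,
#' clusters are relabeled by ascending mean cell diameter: the smallest cells
#' always get label 1 and the largest label `n_clusters`. A tie on mean
#' diameter (degenerate) is broken by cluster size, larger group first.
#'
#' @param cells object table with at least `n_clusters` rows.
#' @param n_clusters number of clusters (3 for the artifact pass, 2 for the
#'   tissue typing).
#' @param cfg a [beet_config()].
#' @return Integer vector of size-ordered cluster labels, one per row.
#' @export
kmeans_sized <- function(cells, n_clusters, cfg = beet_config()) {
  stopifnot(is.data.frame(cells))
  n <- nrow(cells)
  if (n < n_clusters)
    stop(sprintf("k-means with %d clusters needs at least %d rows, got %d",
                 n_clusters, n_clusters, n), call. = FALSE)
  X <- as.matrix(cells[, KMEANS_FEATURES])
  X <- scale(X)
  X <- X[, colSums(!is.finite(X)) == 0, drop = FALSE]
  uniq <- unique(X)
  if (nrow(uniq) <= n_clusters || ncol(X) == 0) {
    # fewer distinct points than clusters: group identical rows
    grp <- match(data.frame(t(X)), data.frame(t(uniq)))
    if (ncol(X) == 0) grp <- rep(1L, n)
    return(relabel_by_size(grp, cells$Meandiameterum))
  }
  km <- with_local_seed(cfg$random_seed,
    stats::kmeans(X, centers = n_clusters, nstart = cfg$kmeans_nstart,
                  iter.max = cfg$kmeans_max_iter))
  relabel_by_size(km$cluster, cells$Meandiameterum)
}

relabel_by_size <- function(labels, diam) {
  means <- tapply(diam, labels, mean)
  sizes <- tapply(labels, labels, length)
  o <- order(means, -sizes)
  map <- integer(length(means))
  map[as.integer(names(means))[o]] <- seq_along(o)
  map[labels]
}

#' Majority-rule intercellular-space pass
#'
#' An intercellular space is a small object (3-cluster label 1) surrounded by
#' big cells. With the gated neighbors' cluster values, let SUM and MEAN be
#' their sum and mean and MAX the sum if all neighbors were label 3
#' (3 x neighbor count). A label-1 focal object is removed when all its
#' neighbors are label 3, or — the majority criterion — when
#' `SUM >= MAX - MEAN`. A focal object with no gated neighbors is kept (no
#' evidence).
#'
#' @param cells object table.
#' @param nbrs `beet_neighbors` on the same table.
#' @param labels3 size-ordered 3-cluster labels, one per row.
#' @return List with `kept`, `removed`, `removed_ids` as in
#'   [diameter_outlier_pass()], plus `decisions`, a data frame of the SUM /
#'   MEAN / MAX arithmetic for every tested focal object.
#' @export
majority_rule_pass <- function(cells, nbrs, labels3) {
  stopifnot(is.data.frame(cells), inherits(nbrs, "beet_neighbors"),
            length(labels3) == nrow(cells))
  n <- nrow(cells)
  out <- logical(n)
  dec <- list()
  for (i in which(labels3 == 1L)) {
    labs <- labels3[nbrs$neighbors[[i]]]
    if (!length(labs)) next
    SUM <- sum(labs); MEAN <- mean(labs); MAX <- 3 * length(labs)
    drop_it <- all(labs == 3L) || SUM >= MAX - MEAN
    out[i] <- drop_it
    dec[[length(dec) + 1L]] <- data.frame(
      order = cells$order[i], n_neighbors = length(labs),
      SUM = SUM, MEAN = MEAN, MAX = MAX, is_intercellular = drop_it)
  }
  decisions <- if (length(dec)) do.call(rbind, dec) else
    data.frame(order = integer(), n_neighbors = integer(), SUM = numeric(),
               MEAN = numeric(), MAX = numeric(), is_intercellular = logical())
  list(kept = cells[!out, , drop = FALSE],
       removed = cells[out, , drop = FALSE],
       removed_ids = cells$order[out],
       decisions = decisions)
}

#' Iterative discrimination of cells from intercellular spaces and artifacts
#'
#' Repeats, until a full pass removes nothing: (1) drop objects below the
#' small-object threshold of the log-diameter histogram; (2) recompute gated
#' neighborhoods and remove neighborhood diameter outliers; (3) cluster each
#' ring zone into 3 size-ordered groups (zones with fewer than
#' `min_zone_objects` objects fall back to a global clustering); (4) remove
#' label-1 objects that the majority rule identifies as intercellular spaces,
#' with neighborhoods recomputed after step 2's removals. The kept set
#' shrinks weakly each pass, so termination is guaranteed.
#'
#' @param cells object table (ring zones already assigned; a missing or
#'   constant `ring_zone` column simply means one global zone).
#' @param cfg a [beet_config()].
#' @return The filtered object table, with attributes `removal_log` (data
#'   frame: pass, stage, order, s.area), `intercellcount` (summed pixel area
#'   of objects removed as intercellular spaces, i.e. by stages 2 and 4) and
#'   `n_pass`. If everything is removed an empty table is returned with a
#'   warning.
#' @export
iterate_filtering <- function(cells, cfg = beet_config()) {
  stopifnot(is.data.frame(cells))
  log_rows <- list()
  note <- function(pass, stage, removed) {
    if (nrow(removed))
      log_rows[[length(log_rows) + 1L]] <<- data.frame(
        pass = pass, stage = stage, order = removed$order,
        s.area = removed$s.area)
  }
  pass <- 0L
  repeat {
    pass <- pass + 1L
    n_before <- nrow(cells)
    if (n_before == 0L) break

    thr <- small_object_threshold(cells$Diameter_log, cfg)
    small <- cells$Diameter_log < thr
    note(pass, "size_threshold", cells[small, , drop = FALSE])
    cells <- cells[!small, , drop = FALSE]

    if (nrow(cells) >= 2L) {
      nbrs <- gated_neighbors(cells, cfg)
      res <- diameter_outlier_pass(cells, nbrs)
      note(pass, "neighbor_outlier", res$removed)
      cells <- res$kept
    }

    if (nrow(cells) >= 3L) {
      cells$Cluster_drei <- cluster_by_zone(cells, 3L, cfg)
      nbrs <- gated_neighbors(cells, cfg)
      res <- majority_rule_pass(cells, nbrs, cells$Cluster_drei)
      note(pass, "majority_rule", res$removed)
      cells <- res$kept
    }

    if (nrow(cells) == n_before) break
  }
  if (nrow(cells) == 0L)
    warning("iterative filtering removed every object")
  removal_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(pass = integer(), stage = character(), order = integer(),
               s.area = numeric())
  attr(cells, "removal_log") <- removal_log
  attr(cells, "intercellcount") <-
    sum(removal_log$s.area[removal_log$stage %in%
                             c("neighbor_outlier", "majority_rule")])
  attr(cells, "n_pass") <- pass
  cells
}

# 3-cluster labels per ring zone; small zones use the global solution
cluster_by_zone <- function(cells, k, cfg) {
  labels <- integer(nrow(cells))
  zones <- cells$ring_zone
  if (is.null(zones)) zones <- rep(1L, nrow(cells))
  global <- NULL
  for (z in unique(zones)) {
    rows <- which(zones == z)
    if (length(rows) >= max(cfg$min_zone_objects, k)) {
      labels[rows] <- kmeans_sized(cells[rows, , drop = FALSE], k, cfg)
    } else {
      if (is.null(global)) global <- kmeans_sized(cells, k, cfg)
      labels[rows] <- global[rows]
    }
  }
  labels
}
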