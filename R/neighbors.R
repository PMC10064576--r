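# k-nearest-neighbor search on (m.cx, m.cy), chunked brute force. Returns
# list(idx = n x k matrix of row indices, dist = n x k matrix of distances),
# neighbors ordered by increasing distance, self excluded.
knn_xy <- function(coords, k, chunk = 512L) {
  n <- nrow(coords)
  k <- min(k, n - 1L)
  idx <- matrix(NA_integer_, n, k)
  dst <- matrix(NA_real_, n, k)
  if (k < 1L) return(list(idx = idx, dist = dst))
  sq <- rowSums(coords^2)
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    d2 <- matrix(sq[rows], length(rows), n) +
      matrix(sq, length(rows), n, byrow = TRUE) -
      2 * tcrossprod(coords[rows, , drop = FALSE], coords)
    d2[cbind(seq_along(rows), rows)] <- Inf   # exclude self
    for (j in seq_along(rows)) {
      o <- order(d2[j, ])[seq_len(k)]
      idx[rows[j], ] <- o
      dst[rows[j], ] <- sqrt(pmax(d2[j, o], 0))
    }
  }
  list(idx = idx, dist = dst)
}

#' Distance-gated nearest neighborhoods
#'
#' For every object the `k_neighbors` nearest neighbors by Euclidean distance
#' between centers of mass are found; the focal object is never its own
#' neighbor. Quantiles of the k neighbor distances are then used to drop
#' neighbors across a spatial gap: objects farther than Q2 + 1.5 IQR (or
#' Q3 + 1.5 IQR with `neighbor_fence = "upper"`) are not considered direct
#' neighbors. This keeps neighborhoods local in tissue with uneven density.
#'
#' @param cells object table with `m.cx`, `m.cy`.
#' @param cfg a [beet_config()].
#' @return Object of class `beet_neighbors`: list with `neighbors` (list of
#'   integer row-index vectors into `cells`, at most `k_neighbors` each),
#'   `dist_q2`, `dist_iqr` (per focal object), and `ids` (= `cells$order`).
#'   Fewer than 2 cells give empty neighborhoods.
#' @export
gated_neighbors <- function(cells, cfg = beet_config()) {
  stopifnot(is.data.frame(cells))
  n <- nrow(cells)
  if (n < 2L) {
    return(structure(list(neighbors = rep(list(integer()), n),
                          dist_q2 = rep(NA_real_, n),
                          dist_iqr = rep(NA_real_, n),
                          ids = cells$order),
                     class = "beet_neighbors"))
  }
  nn <- knn_xy(cbind(cells$m.cx, cells$m.cy), cfg$k_neighbors)
  p <- if (identical(cfg$neighbor_fence, "upper")) 0.75 else 0.5
  q2 <- numeric(n); iqr <- numeric(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    d <- nn$dist[i, ]
    qs <- stats::quantile(d, c(0.25, p, 0.75), names = FALSE, type = 7)
    iqr[i] <- qs[3] - qs[1]
    q2[i] <- qs[2]
    keep <- d <= qs[2] + 1.5 * iqr[i]
    nbrs[[i]] <- nn$idx[i, keep]
  }
  structure(list(neighbors = nbrs, dist_q2 = q2, dist_iqr = iqr,
                 ids = cells$order),
            class = "beet_neighbors")
}

#' @export
print.beet_neighbors <- function(x, ...) {
  cat(sprintf("<beet_neighbors> %d objects, mean gated neighbors %.2f\n",
              length(x$neighbors),
              if (length(x$neighbors)) mean(lengths(x$neighbors)) else 0))
  invisible(x)
}
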