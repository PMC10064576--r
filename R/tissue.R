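#' Final two-cluster tissue typing
#'
#' After intercellular spaces and artifacts have been removed, two groups of
#' cells remain: the small cells of the vascular tissue around the cambium
#' rings and the big sugar-storing parenchyma cells between them. A final
#' size-ordered k-means with two clusters assigns every surviving cell to one
#' of the two: label 1 (the smaller cells) becomes `VT` (vascular tissue),
#' label 2 becomes `SP` (storage parenchyma). After relabeling,
#' `mean(diameter | VT) < mean(diameter | SP)` always holds; a pathological
#' tie on mean diameter resolves by cluster size, larger group = VT.
#'
#' @param cells filtered object table.
#' @param cfg a [beet_config()].
#' @return The object table with `Cluster_zw` set to `"VT"` or `"SP"` on
#'   every row. Fewer than 2 cells are all labeled `VT` with a warning.
#' @export
classify_tissue <- function(cells, cfg = beet_config()) {
  stopifnot(is.data.frame(cells))
  if (nrow(cells) < 2L) {
    if (nrow(cells))
      warning("fewer than 2 cells: all labeled VT")
    cells$Cluster_zw <- rep("VT", nrow(cells))
    return(cells)
  }
  labels2 <- kmeans_sized(cells, 2L, cfg)
  cells$Cluster_zw <- c("VT", "SP")[labels2]
  cells
}
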