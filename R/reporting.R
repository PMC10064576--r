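#' Assemble the master table
#'
#' Row-binds the per-image object tables, broadcasting each image's pixel
#' accounting (total pixels, ROI pixels, wall pixels, intercellular pixels)
#' onto its rows. An image with zero surviving cells contributes a single
#' accounting row with `NA` object columns.
#'
#' @param results list of `beet_phenotype` objects, or of data frames already
#'   in the master schema.
#' @return Master table data frame (schema: object columns + `Imagetotalpix`,
#'   `Innerpixarea`, `Cellwallcount`, `Intercellcount`, `Dataname`).
#' @export
assemble_master <- function(results) {
  stopifnot(is.list(results), length(results) >= 1L)
  tabs <- lapply(results, function(r) {
    if (inherits(r, "beet_phenotype")) return(master_rows(r))
    stopifnot(is.data.frame(r))
    missing <- setdiff(MASTER_COLS, names(r))
    extra <- setdiff(names(r), MASTER_COLS)
    if (length(missing) || length(extra))
      stop("master-table column mismatch; missing: ",
           paste(missing, collapse = ", "), "; unexpected: ",
           paste(extra, collapse = ", "), call. = FALSE)
    r[, MASTER_COLS]
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

# per-image phenotype summary used by summarize_genotypes and the EMD input
per_image_stats <- function(master) {
  split_rows <- split(master, master$Dataname)
  do.call(rbind, lapply(split_rows, function(m) {
    cells <- m[!is.na(m$order), , drop = FALSE]
    data.frame(
      Dataname = m$Dataname[1],
      n_cells = nrow(cells),
      max_diameter_um = if (nrow(cells)) max(cells$Meandiameterum) else NA_real_,
      mean_diameter_um = if (nrow(cells)) mean(cells$Meandiameterum) else NA_real_,
      n_rings = m$nmdeep[1],
      cellwall_frac = if (m$Innerpixarea[1] > 0)
        m$Cellwallcount[1] / m$Innerpixarea[1] else NA_real_,
      row.names = NULL
    )
  }))
}

#' Per-genotype phenotyping summary
#'
#' For each image the cell count, maximal and mean cell diameter, number of
#' cambium rings and the cell-wall fraction of the ROI are computed; these
#' are then aggregated as mean and standard deviation over the images of each
#' genotype. Cluster allocation is summarized per genotype as the percentage
#' of cells per tissue type, the percentage of cell area per tissue type, and
#' the mean cell diameter per tissue type (computed per image, then averaged).
#'
#' @param master master table from [assemble_master()].
#' @param mapping image-to-genotype map: a data frame with columns `Dataname`
#'   and `genotype`, or a named character vector `c(dataname = genotype)`.
#' @return Data frame, one row per genotype.
#' @export
summarize_genotypes <- function(master, mapping) {
  stopifnot(is.data.frame(master))
  map <- as_genotype_map(mapping)
  imgs <- unique(master$Dataname)
  unmapped <- setdiff(imgs, map$Dataname)
  if (length(unmapped))
    stop("image(s) without genotype mapping: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  per_img <- per_image_stats(master)
  per_img$genotype <- map$genotype[match(per_img$Dataname, map$Dataname)]
  master$genotype <- map$genotype[match(master$Dataname, map$Dataname)]

  ms <- function(x) c(mean = mean(x, na.rm = TRUE), sd = stats::sd(x))
  out <- do.call(rbind, lapply(split(per_img, per_img$genotype), function(g) {
    cells <- master[master$genotype == g$genotype[1] & !is.na(master$order), ]
    vt <- cells$Cluster_zw == "VT"
    a <- ms(g$n_cells); b <- ms(g$max_diameter_um); c_ <- ms(g$mean_diameter_um)
    d <- ms(g$n_rings); e <- ms(g$cellwall_frac)
    # per-cluster mean diameter: per image, then averaged over images
    pc <- do.call(rbind, lapply(split(cells, cells$Dataname), function(m)
      data.frame(vt = mean(m$Meandiameterum[m$Cluster_zw == "VT"]),
                 sp = mean(m$Meandiameterum[m$Cluster_zw == "SP"]))))
    data.frame(
      genotype = g$genotype[1],
      n_images = nrow(g),
      n_cells_mean = a[1], n_cells_sd = a[2],
      max_diameter_mean = b[1], max_diameter_sd = b[2],
      mean_diameter_mean = c_[1], mean_diameter_sd = c_[2],
      n_rings_mean = d[1], n_rings_sd = d[2],
      cellwall_frac_mean = e[1], cellwall_frac_sd = e[2],
      vt_cell_pct = 100 * mean(vt),
      sp_cell_pct = 100 * mean(!vt),
      vt_area_pct = 100 * sum(cells$s.area[vt]) / sum(cells$s.area),
      sp_area_pct = 100 * sum(cells$s.area[!vt]) / sum(cells$s.area),
      vt_mean_diameter = mean(pc$vt, na.rm = TRUE),
      sp_mean_diameter = mean(pc$sp, na.rm = TRUE),
      row.names = NULL
    )
  }))
  rownames(out) <- NULL
  out
}

as_genotype_map <- function(mapping) {
  if (is.data.frame(mapping)) {
    stopifnot(all(c("Dataname", "genotype") %in% names(mapping)))
    return(mapping[, c("Dataname", "genotype")])
  }
  if (!is.null(names(mapping)))
    return(data.frame(Dataname = names(mapping),
                      genotype = as.character(mapping)))
  stop("mapping must be a data frame (Dataname, genotype) or a named vector",
       call. = FALSE)
}

#' Coefficient of determination of automated vs manual counts
#'
#' Validation statistic for cell identification: the R-squared of the
#' least-squares regression of the automated per-image counts on the manual
#' ground-truth counts.
#'
#' @param auto numeric vector of automated counts.
#' @param truth numeric vector of manual counts, same length (>= 3).
#' @return R-squared in \[0, 1\].
#' @export
validate_counts <- function(auto, truth) {
  if (length(auto) != length(truth))
    stop("count vectors differ in length", call. = FALSE)
  if (length(auto) < 3L)
    stop("need at least 3 paired counts", call. = FALSE)
  fit <- stats::lm(auto ~ truth)
  ss_tot <- sum((auto - mean(auto))^2)
  if (ss_tot == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / ss_tot
}

#' Kernel density estimate of the cell-size distribution
#'
#' Gaussian kernel with a fixed bandwidth (`kde_bandwidth`, default 1 um);
#' the curve is scaled so the area under it equals one.
#'
#' @param diameters cell diameters in um (>= 2 values).
#' @param cfg a [beet_config()].
#' @return A [stats::density] object.
#' @export
size_kde <- function(diameters, cfg = beet_config()) {
  diameters <- diameters[is.finite(diameters)]
  if (length(diameters) < 2L)
    stop("need at least 2 diameters for a density estimate", call. = FALSE)
  stats::density(diameters, bw = cfg$kde_bandwidth, kernel = "gaussian")
}

# exact 1-D Earth Mover's Distance between equally weighted samples of the
# same size: mean absolute difference of the order statistics
emd_1d <- function(a, b) {
  stopifnot(length(a) == length(b))
  mean(abs(sort(a) - sort(b)))
}

#' Genotype similarity by Earth Mover's Distance
#'
#' Each image is condensed to a feature vector of the mean, standard
#' deviation, maximum and minimum of every retained master-table variable
#' (centers of mass, the neighborhood quantiles Q1/Q3/IQR, file name and the
#' original object order are excluded). Features are z-scored across images.
#' The dissimilarity of two genotypes is the average over feature dimensions
#' of the 1-D Earth Mover's Distance between their image distributions,
#' computed on bootstrap subsamples of size `emd_n` and normalized by the
#' mean of `emd_permutations` scores obtained after permuting the genotype
#' membership of the pooled images. Average-linkage hierarchical clustering
#' of the score matrix gives the similarity dendrogram.
#'
#' @param master master table.
#' @param mapping image-to-genotype map (see [summarize_genotypes()]).
#' @param cfg a [beet_config()].
#' @return Object of class `beet_emd`: list with `dist` (dist object of
#'   normalized EMD scores), `hclust`, `newick` (tree string) and `features`
#'   (the per-image summary matrix).
#' @export
emd_dendrogram <- function(master, mapping, cfg = beet_config()) {
  map <- as_genotype_map(mapping)
  genos <- unique(map$genotype)
  if (length(genos) < 2L)
    stop("need at least 2 genotypes for a similarity analysis", call. = FALSE)
  feats <- emd_features(master)
  geno_of <- map$genotype[match(rownames(feats), map$Dataname)]
  if (anyNA(geno_of))
    stop("image(s) without genotype mapping: ",
         paste(rownames(feats)[is.na(geno_of)], collapse = ", "), call. = FALSE)

  D <- matrix(0, length(genos), length(genos),
              dimnames = list(genos, genos))
  with_local_seed(cfg$random_seed, {
    for (i in seq_along(genos)) for (j in seq_len(i - 1L)) {
      D[i, j] <- D[j, i] <-
        emd_score(feats[geno_of == genos[i], , drop = FALSE],
                  feats[geno_of == genos[j], , drop = FALSE], cfg)
    }
  })
  hc <- stats::hclust(stats::as.dist(D), method = cfg$emd_linkage)
  structure(list(dist = stats::as.dist(D), hclust = hc,
                 newick = ape::write.tree(ape::as.phylo(hc)),
                 features = feats),
            class = "beet_emd")
}

# per-image {mean, sd, max, min} of every retained numeric variable, z-scored
emd_features <- function(master) {
  drop_cols <- c("m.cx", "m.cy", "Q1", "Q3", "IQR", "Dataname", "order")
  keep <- setdiff(names(master), drop_cols)
  rows <- split(master, master$Dataname)
  feats <- do.call(rbind, lapply(rows, function(m) {
    cells <- m[!is.na(m$order), keep, drop = FALSE]
    cells$Cluster_zw <- as.numeric(factor(cells$Cluster_zw,
                                          levels = c("VT", "SP")))
    unlist(lapply(cells, function(v) {
      v <- v[is.finite(v)]
      if (!length(v)) v <- 0
      c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
        max = max(v), min = min(v))
    }))
  }))
  sds <- apply(feats, 2, stats::sd)
  mns <- colMeans(feats)
  feats <- sweep(feats, 2, mns)
  feats <- sweep(feats, 2, ifelse(sds > 0, sds, 1), "/")
  feats
}

emd_score <- function(A, B, cfg) {
  n <- cfg$emd_n
  boot <- function(M) M[sample.int(nrow(M), n, replace = TRUE), , drop = FALSE]
  raw <- function(A, B) {
    a <- boot(A); b <- boot(B)
    mean(vapply(seq_len(ncol(a)), function(k) emd_1d(a[, k], b[, k]),
                numeric(1)))
  }
  obs <- raw(A, B)
  pool <- rbind(A, B)
  na <- nrow(A)
  perm <- vapply(seq_len(cfg$emd_permutations), function(b) {
    o <- sample.int(nrow(pool))
    raw(pool[o[seq_len(na)], , drop = FALSE],
        pool[o[-seq_len(na)], , drop = FALSE])
  }, numeric(1))
  m <- mean(perm)
  if (m <= 0) return(0)
  obs / m
}

#' @export
print.beet_emd <- function(x, ...) {
  cat("<beet_emd> normalized Earth Mover's Distance scores\n")
  print(round(as.matrix(x$dist), 3))
  cat("newick:", x$newick, "\n")
  invisible(x)
}

#' @export
plot.beet_emd <- function(x, ...) {
  graphics::plot(x$hclust, xlab = "", sub = "",
                 main = "Genotype similarity (EMD)", ...)
  invisible(x)
}
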