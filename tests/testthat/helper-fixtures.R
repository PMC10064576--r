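# shared fixture builders; everything is generated in code at test time

# logical mask (w x h, EBImage layout: dim1 = x) with filled discs
disc_mask <- function(w, h, centers, radii) {
  m <- matrix(FALSE, w, h)
  xs <- matrix(seq_len(w), w, h)
  ys <- matrix(seq_len(h), w, h, byrow = TRUE)
  for (k in seq_len(nrow(centers)))
    m <- m | ((xs - centers[k, 1])^2 + (ys - centers[k, 2])^2 <= radii[k]^2)
  m
}

# minimal object table for filtering/clustering tests: features derived from
# diameter (um) plus positions
toy_cells <- function(diam_um, x, y, upp = 1.015228) {
  r <- diam_um / 2 / upp
  data.frame(
    order = seq_along(diam_um),
    s.area = pi * r^2, s.perimeter = 2 * pi * r,
    s.radius.mean = r, s.radius.sd = 0.1 * r,
    s.radius.max = 1.15 * r, s.radius.min = 0.85 * r,
    m.cx = x, m.cy = y,
    m.majoraxis = 2.1 * r, m.eccentricity = 0.3, m.theta = 0,
    Meandiameterum = diam_um, Diameter_log = log10(diam_um),
    Q1 = NA_real_, Q3 = NA_real_, IQR = NA_real_,
    ring_zone = 1L, nmbpeak = 0L, nmdeep = 0L,
    Cluster_drei = NA_integer_, Cluster_zw = NA_character_
  )
}

# independent type-7 quantile: direct interpolation of the sorted sample
brute_quantile7 <- function(v, p) {
  s <- sort(v); n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# memoized default-spec recovery runs shared by the filtering and
# tissue-typing acceptance checks (10 seeds of the default generator)
.recovery_cache <- new.env(parent = emptyenv())
recovery_runs <- function(seeds = 1:10) {
  key <- paste(seeds, collapse = ",")
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  cfg <- beet_config()
  out <- lapply(seeds, function(seed) {
    tab <- synthetic_object_table(synthetic_spec(seed = seed))
    rings <- detect_rings(tab, cfg)
    tab <- assign_ring_zone(tab, rings)
    filt <- suppressWarnings(iterate_filtering(tab, cfg))
    fin <- suppressWarnings(classify_tissue(filt, cfg))
    is_void <- tab$true_class == "intercellular"
    is_cell <- tab$true_class %in% c("cell_VT", "cell_SP")
    truecl <- tab$true_class[match(fin$order, tab$order)]
    list(
      void_removed = mean(!(tab$order[is_void] %in% filt$order)),
      cell_removed = mean(!(tab$order[is_cell] %in% filt$order)),
      agree = mean((fin$Cluster_zw == "VT") == (truecl == "cell_VT")),
      vt_mean = mean(fin$Meandiameterum[fin$Cluster_zw == "VT"]),
      sp_mean = mean(fin$Meandiameterum[fin$Cluster_zw == "SP"])
    )
  })
  .recovery_cache[[key]] <- out
  out
}
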