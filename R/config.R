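#' Pipeline configuration
#'
#' Builds the configuration object that carries every numeric parameter of the
#' workflow. The defaults are the values the workflow was established with:
#' Gaussian smoothing at `sigma = 2`, two opening cycles with disc brushes of
#' size 18 and 21 px, peridermal-edge masking restricted to the first 5% of
#' image width with a size-50 brush, a pixel pitch of 1.015228 um/px (10x
#' magnification), ring detection with a 150-sample window and a loess span of
#' 0.2, k = 6 nearest neighbors, a fallback log10-diameter threshold of 0.5
#' (3 um) capped at 0.8 (6.3 um), k-means with 25 random starts and at most
#' 1000 iterations, a 1-um kernel bandwidth for the cell-size density, and an
#' Earth Mover's Distance score normalized over 100 permutations with
#' subsamples of size 40.
#'
#' @param ... named overrides for any configuration field, e.g.
#'   `beet_config(edge_fraction = 0.10)`.
#'
#' @details Fields (units in brackets):
#' \describe{
#'   \item{gaussian_sigma}{standard deviation of the Gaussian blur [px].}
#'   \item{opening_radius_1, opening_radius_2}{brush sizes of the first and
#'     second morphological opening cycle [px]. Interpreted as the *size*
#'     (diameter) of a disc structuring element, the convention of
#'     [EBImage::makeBrush()]; even values are rounded up to odd.}
#'   \item{edge_fraction}{fraction of image width, from the left margin, that
#'     is searched for the non-tissue peridermal edge region.}
#'   \item{edge_opening_radius}{brush size of the high opening used to isolate
#'     the non-tissue edge region [px].}
#'   \item{um_per_px}{pixel pitch [um/px].}
#'   \item{ring_window_w}{width of the sliding window (in profile samples,
#'     i.e. consecutive cells ordered by x) used for peak/valley detection.}
#'   \item{ring_span}{span of the loess smoother applied to the diameter
#'     profile before extrema detection.}
#'   \item{ring_min_relief}{minimum relief of an extremum's detection window,
#'     as a fraction of the mean smoothed diameter; windows with less relief
#'     are treated as flat, so residual sampling noise is never called a
#'     ring.}
#'   \item{k_neighbors}{number of nearest neighbors considered per object.}
#'   \item{fallback_log_threshold, max_log_threshold}{fallback and cap for the
#'     small-object threshold [log10 um].}
#'   \item{kmeans_nstart, kmeans_max_iter}{k-means restarts and iteration cap.}
#'   \item{kde_bandwidth}{Gaussian kernel bandwidth of the cell-size density
#'     estimate [um].}
#'   \item{emd_permutations, emd_n}{number of permuted scores and subsample
#'     size used to normalize the Earth Mover's Distance score.}
#'   \item{random_seed}{seed for every stochastic step (k-means restarts, EMD
#'     subsampling/permutations), so runs are reproducible.}
#'   \item{neighbor_fence}{`"median"` applies the distance gate
#'     Q2 + 1.5 IQR literally; `"upper"` switches to the conventional
#'     Q3 + 1.5 IQR fence.}
#'   \item{hist_binwidth}{bin width of the log10-diameter histogram used for
#'     the small-object threshold [log10 um].}
#'   \item{min_zone_objects}{ring zones with fewer objects than this fall back
#'     to the global 3-cluster solution.}
#'   \item{emd_linkage}{agglomeration method for the similarity dendrogram.}
#' }
#'
#' @return A list of class `beet_config`.
#' @seealso [load_config()], [dump_config()]
#' @export
#' @examples
#' cfg <- beet_config()
#' cfg$gaussian_sigma
#' beet_config(edge_fraction = 0.1)$edge_fraction
beet_config <- function(...) {
  cfg <- list(
    gaussian_sigma = 2,
    opening_radius_1 = 18,
    opening_radius_2 = 21,
    edge_fraction = 0.05,
    edge_opening_radius = 50,
    um_per_px = 1.015228,
    ring_window_w = 150,
    ring_span = 0.2,
    ring_min_relief = 0.05,
    k_neighbors = 6,
    fallback_log_threshold = 0.5,
    max_log_threshold = 0.8,
    kmeans_nstart = 25,
    kmeans_max_iter = 1000,
    kde_bandwidth = 1,
    emd_permutations = 100,
    emd_n = 40,
    random_seed = 1L,
    neighbor_fence = "median",
    hist_binwidth = 0.05,
    min_zone_objects = 10,
    emd_linkage = "average"
  )
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("configuration overrides must be named", call. = FALSE)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(over)] <- over
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok))
      stop(sprintf("invalid configuration: field '%s' %s", field, what),
           call. = FALSE)
  }
  num1 <- function(field) {
    v <- cfg[[field]]
    chk(is.numeric(v) && length(v) == 1 && is.finite(v), field,
        "must be a single finite number")
    v
  }
  for (f in c("gaussian_sigma", "opening_radius_1", "opening_radius_2",
              "edge_opening_radius", "ring_window_w", "k_neighbors",
              "kmeans_nstart", "kmeans_max_iter", "kde_bandwidth",
              "emd_permutations", "emd_n", "hist_binwidth",
              "min_zone_objects"))
    chk(num1(f) > 0, f, "must be strictly positive")
  chk(num1("um_per_px") > 0, "um_per_px", "must be strictly positive")
  ef <- num1("edge_fraction")
  chk(ef > 0 && ef < 1, "edge_fraction", "must lie strictly between 0 and 1")
  rs <- num1("ring_span")
  chk(rs > 0 && rs <= 1, "ring_span", "must lie in (0, 1]")
  rr <- num1("ring_min_relief")
  chk(rr >= 0 && rr < 1, "ring_min_relief", "must lie in [0, 1)")
  chk(num1("fallback_log_threshold") <= num1("max_log_threshold"),
      "fallback_log_threshold", "must not exceed max_log_threshold")
  num1("random_seed")
  chk(cfg$neighbor_fence %in% c("median", "upper"), "neighbor_fence",
      "must be 'median' or 'upper'")
  chk(is.character(cfg$emd_linkage) && length(cfg$emd_linkage) == 1,
      "emd_linkage", "must be a single string")
  structure(cfg, class = "beet_config")
}

#' Load a configuration file
#'
#' Reads a YAML-style `key: value` text file. Missing keys take the package
#' defaults of [beet_config()]; present keys override them. The result is
#' validated, so e.g. a negative smoothing sigma or an `edge_fraction` outside
#' (0, 1) raises an error naming the offending field.
#'
#' @param path path to the configuration file. An empty file yields the full
#'   default configuration.
#' @return A validated `beet_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e)
      stop("failed to parse configuration file '", path, "': ",
           conditionMessage(e), call. = FALSE)
  )
  if (is.null(raw)) raw <- list()
  if (!is.list(raw))
    stop("configuration file '", path, "' must contain key: value pairs",
         call. = FALSE)
  do.call(beet_config, raw)
}

#' Write a configuration file
#'
#' Serializes a configuration so that `load_config(dump_config(cfg, path))`
#' restores an identical object.
#'
#' @param cfg a `beet_config` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "beet_config"))
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

#' @export
print.beet_config <- function(x, ...) {
  cat("<beet_config>\n")
  for (nm in names(x))
    cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# evaluate expr under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
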