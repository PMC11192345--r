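#' Specification for a synthetic land-cover landscape
#'
#' Defines the grid geometry, class composition and (optionally) per-class
#' NDVI targets of a synthetic landscape. The default composition is the
#' eight-class Bench-Sheko mix (remnant forest 30.98%, savanna grassland
#' 24.47%, farmland 19.23%, coffee plantation 8%, disturbed forest 6.53%,
#' grassland 6.08%, wetland 4.35%, built-up 0.37%); proportions are
#' renormalized to sum to exactly 1 before sampling.
#'
#' @param n_rows,n_cols grid dimensions (positive integers).
#' @param pixel_size_m square pixel edge in metres (default 10, the
#'   Sentinel-2 visible/NIR resolution the landscapes emulate).
#' @param classes data frame with columns `code` (unique integers), `name`
#'   (text) and `proportion` (fractions summing to 1 within 1e-9). Defaults to
#'   the packaged Bench-Sheko composition.
#' @param ndvi_targets optional data frame with columns `code`, `mean`
#'   (in \[-1, 1\]) and `sd` (>= 0), one row per class, used by
#'   [generate_band_pair()]. Defaults to the packaged per-class NDVI means
#'   with sd 0.05.
#' @param seed integer seed; every generator derives its randomness from it.
#'
#' @return An object of class `landscape_spec`.
#' @seealso [generate_landcover()], [generate_band_pair()],
#'   [generate_reference_points()]
#' @export
landscape_spec <- function(n_rows, n_cols, pixel_size_m = 10,
                           classes = default_landscape_classes(),
                           ndvi_targets = default_ndvi_targets(),
                           seed = 1L) {
  stop_if_not_scalar_number(n_rows, "n_rows", lower = 1)
  stop_if_not_scalar_number(n_cols, "n_cols", lower = 1)
  stop_if_not_scalar_number(pixel_size_m, "pixel_size_m")
  if (pixel_size_m <= 0) stop("`pixel_size_m` must be > 0", call. = FALSE)
  stopifnot(is.data.frame(classes),
            all(c("code", "name", "proportion") %in% names(classes)))
  if (nrow(classes) < 1L) stop("at least one class is required", call. = FALSE)
  if (anyDuplicated(classes$code)) stop("class codes must be unique", call. = FALSE)
  if (any(classes$proportion < 0 | classes$proportion > 1)) {
    stop("class proportions must lie in [0, 1]", call. = FALSE)
  }
  s <- sum(classes$proportion)
  if (abs(s - 1) > 1e-9) {
    stop(sprintf("class proportions must sum to 1; they sum to %.12g", s),
         call. = FALSE)
  }
  if (!is.null(ndvi_targets)) {
    stopifnot(is.data.frame(ndvi_targets),
              all(c("code", "mean", "sd") %in% names(ndvi_targets)))
    if (any(abs(ndvi_targets$mean) > 1)) {
      stop("NDVI target means must lie in [-1, 1]", call. = FALSE)
    }
    if (any(ndvi_targets$sd < 0)) stop("NDVI target sd must be >= 0", call. = FALSE)
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         pixel_size_m = as.numeric(pixel_size_m),
         classes = classes, ndvi_targets = ndvi_targets,
         seed = as.integer(seed)),
    class = "landscape_spec"
  )
}

#' Default synthetic class composition
#'
#' The eight-class land-cover mix of the Bench-Sheko zone with its published
#' area proportions. As printed the proportions sum to 1.0001 (rounding); the
#' default renormalizes them so they sum to exactly 1 and satisfy the
#' [landscape_spec()] invariant.
#'
#' @param renormalize divide by the sum (default `TRUE`); set `FALSE` to get
#'   the proportions exactly as published.
#' @return data frame with columns `code`, `name`, `proportion`.
#' @export
default_landscape_classes <- function(renormalize = TRUE) {
  t <- utils::read.csv(esval_fixture("class_proportions.csv"), stringsAsFactors = FALSE)
  if (renormalize) t$proportion <- t$proportion / sum(t$proportion)
  t
}

#' Default per-class NDVI targets
#'
#' Published per-class mean NDVI values (coffee plantation 0.83 down to
#' savanna 0.53, built-up assigned 0.20). The within-class standard deviation
#' is not published; the default 0.05 is a typical within-class spread for
#' 10 m optical imagery.
#'
#' @param sd within-class NDVI standard deviation applied to every class.
#' @return data frame with columns `code`, `name`, `mean`, `sd`.
#' @export
default_ndvi_targets <- function(sd = 0.05) {
  t <- utils::read.csv(esval_fixture("ndvi_class_means.csv"), stringsAsFactors = FALSE)
  t$sd <- sd
  t
}

#' Generate a synthetic categorical land-cover raster
#'
#' By default each cell is drawn i.i.d. from the multinomial distribution
#' given by the spec's class proportions (renormalized to sum exactly to 1),
#' so realized proportions converge to the targets at the usual
#' `1/sqrt(n_cells)` rate. Setting `patch_size` instead grows Voronoi patches:
#' seed cells are placed uniformly at random (about one per `patch_size`
#' cells), each seed is labelled by an independent multinomial draw, and every
#' cell takes the label of its nearest seed. Because every cell's label is the
#' label of a multinomial seed, patching changes the spatial texture but
#' leaves the expected class proportions exactly at the targets.
#'
#' @param spec a [landscape_spec()].
#' @param patch_size expected cells per patch (`NULL`, the default, for
#'   i.i.d. cells; values > 1 give increasingly coarse patches).
#' @return An [lc_raster()]; identical spec and seed give an identical raster.
#' @examples
#' spec <- landscape_spec(50, 50, seed = 7)
#' r <- generate_landcover(spec)
#' class_proportions(class_areas(r))
#' @export
generate_landcover <- function(spec, patch_size = NULL) {
  stopifnot(inherits(spec, "landscape_spec"))
  codes <- as.integer(spec$classes$code)
  prob <- spec$classes$proportion / sum(spec$classes$proportion)
  nr <- spec$n_rows; nc <- spec$n_cols
  n <- nr * nc
  draw <- function(k) codes[sample.int(length(codes), k, replace = TRUE, prob = prob)]
  grid <- with_local_seed(spec$seed, {
    if (is.null(patch_size)) {
      matrix(draw(n), nrow = nr, ncol = nc)
    } else {
      stop_if_not_scalar_number(patch_size, "patch_size", lower = 1)
      k <- max(1L, as.integer(round(n / patch_size)))
      seed_cells <- sample.int(n, k)
      sr <- (seed_cells - 1L) %% nr + 1L
      sc <- (seed_cells - 1L) %/% nr + 1L
      labels <- draw(k)
      g <- matrix(0L, nr, nc)
      cr <- rep(seq_len(nr), times = nc)
      cc <- rep(seq_len(nc), each = nr)
      # nearest seed per cell (squared Euclidean), seeds scanned in blocks
      best_d <- rep(Inf, n); best_i <- rep(1L, n)
      for (i in seq_len(k)) {
        d <- (cr - sr[i])^2 + (cc - sc[i])^2
        upd <- d < best_d
        best_d[upd] <- d[upd]; best_i[upd] <- i
      }
      g[] <- labels[best_i]
      g
    }
  })
  lc_raster(grid, pixel_size_m = spec$pixel_size_m,
            class_names = stats::setNames(spec$classes$name, codes))
}

#' Generate paired NIR and red reflectance bands for a land-cover raster
#'
#' For every cell a per-pixel NDVI value is drawn from a Gaussian at the
#' class's target mean and sd, truncated to (-0.999, 0.999); the red
#' reflectance is fixed per class and the NIR band is solved from
#' `NIR = red (1 + v) / (1 - v)` so the pixel's NDVI is exactly the drawn
#' value. Both bands are therefore strictly positive and every NDVI value
#' lies inside (-1, 1).
#'
#' @param raster an [lc_raster()]; every class present must appear in
#'   `spec$ndvi_targets`.
#' @param spec the [landscape_spec()] carrying `ndvi_targets` and the seed.
#' @param red_reflectance fixed red-band reflectance assigned to every class
#'   (default 0.08, a typical vegetated-surface red reflectance).
#' @return A list with elements `nir` and `red`, both [band_raster()]s.
#' @export
generate_band_pair <- function(raster, spec, red_reflectance = 0.08) {
  stopifnot(inherits(raster, "lc_raster"), inherits(spec, "landscape_spec"))
  targets <- spec$ndvi_targets
  if (is.null(targets)) stop("`spec` has no ndvi_targets", call. = FALSE)
  present <- unique(as.vector(raster$grid))
  missing <- setdiff(present, targets$code)
  if (length(missing) > 0L) {
    stop("classes missing from ndvi_targets: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- match(as.vector(raster$grid), targets$code)
  mu <- targets$mean[idx]
  sd <- targets$sd[idx]
  v <- with_local_seed(derive_seed(spec$seed, 1L), {
    stats::rnorm(length(mu), mean = mu, sd = sd)
  })
  v <- pmin(pmax(v, -0.999), 0.999)
  v[sd == 0] <- mu[sd == 0]  # exact targets when no spread requested
  red <- matrix(red_reflectance, nrow(raster$grid), ncol(raster$grid))
  nir <- matrix(red_reflectance * (1 + v) / (1 - v),
                nrow(raster$grid), ncol(raster$grid))
  list(nir = band_raster(nir), red = band_raster(red))
}

#' Specification of a reference-point confusion structure
#'
#' Describes how reference (ground-truth) points of each class are mislabelled
#' by the map: row `i` of `confusion` gives the probability that a point whose
#' true class is `classes[i]` receives each map label. Used by
#' [generate_reference_points()] to emulate a field campaign with a known
#' error structure.
#'
#' @param classes ordered integer class codes.
#' @param confusion square matrix of row-stochastic label probabilities
#'   (each row sums to 1 within 1e-9). Default: identity (a perfect map).
#' @param points_per_class reference points collected per class; the default
#'   100 follows the usual minimum recommendation for large, complex areas.
#' @return An object of class `confusion_spec`.
#' @export
confusion_spec <- function(classes, confusion = diag(length(classes)),
                           points_per_class = 100L) {
  classes <- as.integer(classes)
  if (anyDuplicated(classes)) stop("class codes must be unique", call. = FALSE)
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != length(classes) || ncol(confusion) != length(classes)) {
    stop("`confusion` must be a square matrix matching `classes`", call. = FALSE)
  }
  if (any(confusion < 0)) stop("confusion probabilities must be >= 0", call. = FALSE)
  rs <- rowSums(confusion)
  bad <- which(abs(rs - 1) > 1e-9)
  if (length(bad) > 0L) {
    stop(sprintf("confusion rows must sum to 1; row %d sums to %.12g",
                 bad[1], rs[bad[1]]), call. = FALSE)
  }
  stop_if_not_scalar_number(points_per_class, "points_per_class", lower = 1)
  structure(list(classes = classes, confusion = confusion,
                 points_per_class = as.integer(points_per_class)),
            class = "confusion_spec")
}

#' Generate reference points with a prescribed confusion structure
#'
#' Samples `points_per_class` distinct cells of each class from the raster and
#' assigns each point a map label drawn from the confusion row of its true
#' class. The result feeds [build_confusion()] and the accuracy metrics.
#'
#' @param raster an [lc_raster()].
#' @param cspec a [confusion_spec()]; its classes must all occur in the raster,
#'   each with at least `points_per_class` cells.
#' @param seed integer seed.
#' @return data frame with columns `row`, `col`, `true_class`, `mapped_class`
#'   (`points_per_class` rows per class).
#' @export
generate_reference_points <- function(raster, cspec, seed = 1L) {
  stopifnot(inherits(raster, "lc_raster"), inherits(cspec, "confusion_spec"))
  raster_classes <- as.integer(names(raster$class_names))
  unknown <- setdiff(cspec$classes, raster_classes)
  if (length(unknown) > 0L) {
    stop("confusion classes absent from raster: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  with_local_seed(seed, {
    out <- vector("list", length(cspec$classes))
    for (i in seq_along(cspec$classes)) {
      cls <- cspec$classes[i]
      cells <- which(raster$grid == cls)
      if (length(cells) < cspec$points_per_class) {
        stop(sprintf("class %d has only %d cells; %d reference points requested",
                     cls, length(cells), cspec$points_per_class), call. = FALSE)
      }
      pick <- sample(cells, cspec$points_per_class)
      mapped <- sample(cspec$classes, cspec$points_per_class, replace = TRUE,
                       prob = cspec$confusion[i, ])
      out[[i]] <- data.frame(
        row = as.integer((pick - 1L) %% nrow(raster$grid)) + 1L,
        col = as.integer((pick - 1L) %/% nrow(raster$grid)) + 1L,
        true_class = cls,
        mapped_class = mapped
      )
    }
    do.call(rbind, out)
  })
}

#' Write / read a reference-point set as CSV
#'
#' @param points data frame with columns `row`, `col`, `true_class`,
#'   `mapped_class`.
#' @param path file path.
#' @return `path` invisibly (write); the data frame (read).
#' @export
write_reference_points <- function(points, path) {
  stopifnot(all(c("row", "col", "true_class", "mapped_class") %in% names(points)))
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_points
#' @export
read_reference_points <- function(path) {
  pts <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("row", "col", "true_class", "mapped_class")
  if (!all(need %in% names(pts))) {
    stop("reference point CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  pts
}
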