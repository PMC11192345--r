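#' Compute NDVI from NIR and red bands
#'
#' Cellwise normalized difference vegetation index
#' `(NIR - red) / (NIR + red)`. Cells where both bands are zero have an
#' undefined index and are returned as `NA`; they are excluded from all
#' downstream statistics rather than set to 0, which would bias class means.
#'
#' @param nir,red [band_raster()]s (or bare numeric matrices) of equal shape
#'   with nonnegative reflectances.
#' @return A numeric matrix of class `ndvi_raster` with defined values in
#'   \[-1, 1\] and `NA` where undefined.
#' @examples
#' compute_ndvi(band_raster(matrix(0.8)), band_raster(matrix(0.2)))  # 0.6
#' @export
compute_ndvi <- function(nir, red) {
  ng <- if (inherits(nir, "band_raster")) nir$grid else as.matrix(nir)
  rg <- if (inherits(red, "band_raster")) red$grid else as.matrix(red)
  check_same_shape(ng, rg, "NIR band", "red band")
  if (any(ng < 0, na.rm = TRUE) || any(rg < 0, na.rm = TRUE)) {
    stop("reflectances must be >= 0", call. = FALSE)
  }
  denom <- ng + rg
  out <- (ng - rg) / denom
  out[denom == 0] <- NA_real_
  structure(out, class = c("ndvi_raster", class(out)))
}

#' Per-class areas of a categorical raster
#'
#' Counts the cells of each declared class and converts to hectares with the
#' fixed factor 1 ha = 10,000 m2. Nodata cells are excluded. Classes declared
#' in `class_names` but absent from the grid are reported with 0 ha.
#'
#' @param raster an [lc_raster()].
#' @return data frame of class `area_table` with columns `code`, `name`,
#'   `area_ha`, and the grand total as attribute `total_area_ha`.
#' @examples
#' r <- lc_raster(matrix(1L, 100, 100), 10, c("1" = "forest"))
#' class_areas(r)  # 100 ha
#' @export
class_areas <- function(raster) {
  stopifnot(inherits(raster, "lc_raster"))
  codes <- as.integer(names(raster$class_names))
  cells <- as.vector(raster$grid)
  if (!is.null(raster$nodata_code)) cells <- cells[cells != raster$nodata_code]
  counts <- table(factor(cells, levels = codes))
  ha_per_cell <- raster$pixel_size_m^2 / 1e4
  out <- data.frame(code = codes,
                    name = unname(raster$class_names),
                    area_ha = as.numeric(counts) * ha_per_cell)
  area_table(out)
}

#' Construct / validate an area table
#'
#' An `area_table` holds per-class areas in hectares. The attribute
#' `total_area_ha` defaults to the sum of the entries but may be set larger
#' (e.g. a study area that includes classes not in the table) so proportions
#' can be taken over the full extent.
#'
#' @param df data frame with columns `code`, `area_ha` (a `name` column is
#'   kept when present).
#' @param total_area_ha total extent in hectares; default `sum(df$area_ha)`.
#' @return The validated data frame with class `area_table`.
#' @export
area_table <- function(df, total_area_ha = NULL) {
  stopifnot(is.data.frame(df), all(c("code", "area_ha") %in% names(df)))
  if (any(df$area_ha < 0)) stop("areas must be >= 0", call. = FALSE)
  if (anyDuplicated(df$code)) stop("duplicated class codes in area table", call. = FALSE)
  total <- total_area_ha %||% sum(df$area_ha)
  if (total < sum(df$area_ha) * (1 - 1e-6)) {
    stop("`total_area_ha` is smaller than the sum of class areas", call. = FALSE)
  }
  structure(df, class = c("area_table", "data.frame"), total_area_ha = total)
}

#' Total extent of an area table
#' @param areas an [area_table()].
#' @return total area in hectares.
#' @export
total_area <- function(areas) {
  attr(areas, "total_area_ha") %||% sum(areas$area_ha)
}

#' Per-class area proportions
#'
#' Fractions of the total extent occupied by each class. When the table's
#' `total_area_ha` equals the sum of its entries the fractions sum to 1
#' within 1e-9; with a larger declared extent they sum to less.
#'
#' @param areas an [area_table()].
#' @return named numeric vector of fractions, named by class code.
#' @export
class_proportions <- function(areas) {
  stopifnot(inherits(areas, "area_table"))
  total <- total_area(areas)
  if (total <= 0) stop("total area must be > 0", call. = FALSE)
  stats::setNames(areas$area_ha / total, areas$code)
}

#' Per-class NDVI statistics
#'
#' Mean, standard deviation and count of defined NDVI cells within each
#' land-cover class. Classes with no defined cells are reported with `n = 0`
#' and `NA` mean/sd.
#'
#' @param ndvi matrix returned by [compute_ndvi()].
#' @param raster the paired [lc_raster()] (same shape).
#' @return data frame with columns `code`, `name`, `mean`, `sd`, `n`.
#' @export
ndvi_class_stats <- function(ndvi, raster) {
  stopifnot(inherits(raster, "lc_raster"))
  check_same_shape(unclass(ndvi), raster$grid, "NDVI raster", "land-cover raster")
  codes <- as.integer(names(raster$class_names))
  cells <- as.vector(raster$grid)
  vals <- as.vector(ndvi)
  out <- lapply(codes, function(cl) {
    v <- vals[cells == cl & !is.na(vals)]
    data.frame(code = cl, name = raster$class_names[[as.character(cl)]],
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else if (length(v) == 1) 0 else NA_real_,
               n = length(v))
  })
  do.call(rbind, out)
}

#' Write an area table as CSV
#' @param areas an [area_table()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_area_table <- function(areas, path) {
  utils::write.csv(as.data.frame(areas), path, row.names = FALSE)
  invisible(path)
}

#' Read an area table from CSV
#'
#' @param path CSV with columns `code` (or `class`), `area_ha`.
#' @param total_area_ha optional declared total extent.
#' @return an [area_table()].
#' @export
read_area_table <- function(path, total_area_ha = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"code" %in% names(df) && "class" %in% names(df)) {
    df$code <- seq_len(nrow(df))
    df$name <- df$class
  }
  area_table(df, total_area_ha = total_area_ha)
}
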