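#' Categorical land-cover raster
#'
#' A light in-memory container for a categorical land-cover map: an integer
#' matrix of class codes plus the metadata needed for area accounting.
#' Coordinates follow the matrix convention: `grid[row, col]`, row 1 at the
#' top. The pixel is square with edge `pixel_size_m` metres; areas are flat
#' (no geodesic correction).
#'
#' @param grid integer matrix of class codes.
#' @param pixel_size_m edge length of a (square) pixel in metres; must be > 0.
#' @param class_names named character vector mapping class code (as name) to a
#'   class label. Every non-nodata code present in `grid` must appear here.
#' @param nodata_code optional integer code marking cells excluded from all
#'   statistics, or `NULL` (default) if every cell is valid.
#'
#' @return An object of class `lc_raster`.
#' @examples
#' r <- lc_raster(matrix(1L, 10, 10), pixel_size_m = 10, class_names = c("1" = "forest"))
#' class_areas(r)
#' @export
lc_raster <- function(grid, pixel_size_m, class_names, nodata_code = NULL) {
  if (!is.matrix(grid)) stop("`grid` must be a matrix", call. = FALSE)
  storage.mode(grid) <- "integer"
  stop_if_not_scalar_number(pixel_size_m, "pixel_size_m")
  if (pixel_size_m <= 0) stop("`pixel_size_m` must be > 0", call. = FALSE)
  if (is.null(names(class_names)) || anyNA(suppressWarnings(as.integer(names(class_names))))) {
    stop("`class_names` must be named by integer class codes", call. = FALSE)
  }
  codes <- as.integer(names(class_names))
  if (anyDuplicated(codes)) stop("duplicated class codes in `class_names`", call. = FALSE)
  present <- unique(as.vector(grid))
  present <- present[!is.na(present)]
  if (!is.null(nodata_code)) present <- setdiff(present, as.integer(nodata_code))
  unknown <- setdiff(present, codes)
  if (length(unknown) > 0L) {
    stop("grid contains class codes absent from `class_names`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(
    list(grid = grid, pixel_size_m = as.numeric(pixel_size_m),
         class_names = stats::setNames(as.character(class_names), codes),
         nodata_code = if (is.null(nodata_code)) NULL else as.integer(nodata_code)),
    class = "lc_raster"
  )
}

#' @export
print.lc_raster <- function(x, ...) {
  cat(sprintf("<lc_raster> %d x %d cells, %.6g m pixels, %d classes\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size_m, length(x$class_names)))
  tab <- table(factor(x$grid, levels = names(x$class_names)))
  for (code in names(x$class_names)) {
    cat(sprintf("  %s (%s): %d cells\n", code, x$class_names[[code]], tab[[code]]))
  }
  invisible(x)
}

#' Reflectance band raster
#'
#' Wraps a numeric matrix of surface reflectance values (e.g. a near-infrared
#' or red band). Values must be finite; the shape must match the paired
#' land-cover raster when used together.
#'
#' @param grid numeric matrix of reflectance values, all finite.
#' @return An object of class `band_raster`.
#' @export
band_raster <- function(grid) {
  if (!is.matrix(grid) || !is.numeric(grid)) {
    stop("`grid` must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(grid))) stop("band values must all be finite", call. = FALSE)
  structure(list(grid = grid), class = "band_raster")
}

#' @export
print.band_raster <- function(x, ...) {
  cat(sprintf("<band_raster> %d x %d, range [%.4g, %.4g]\n",
              nrow(x$grid), ncol(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

# ---- plain-text grid I/O (ESRI ASCII grid) ---------------------------------
# Written by hand: the format is 6 header lines plus whitespace-separated
# rows, and no installed package reads it.

#' Write a grid to an ESRI ASCII grid file
#'
#' Serializes an `lc_raster`, `band_raster` or bare matrix as a plain-text
#' ASCII grid (`ncols`/`nrows`/`xllcorner`/`yllcorner`/`cellsize`/
#' `NODATA_value` header followed by rows top-down).
#'
#' @param x an `lc_raster`, `band_raster`, or matrix.
#' @param path output file path.
#' @param cellsize pixel edge in metres; defaults to the raster's own size
#'   (or 1 for bare matrices/bands).
#' @param nodata value written in the `NODATA_value` header (default -9999,
#'   or the raster's `nodata_code`).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(x, path, cellsize = NULL, nodata = NULL) {
  if (inherits(x, "lc_raster")) {
    grid <- x$grid
    cellsize <- cellsize %||% x$pixel_size_m
    nodata <- nodata %||% (x$nodata_code %||% -9999L)
  } else if (inherits(x, "band_raster")) {
    grid <- x$grid
  } else if (is.matrix(x)) {
    grid <- x
  } else {
    stop("`x` must be an lc_raster, band_raster, or matrix", call. = FALSE)
  }
  cellsize <- cellsize %||% 1
  nodata <- nodata %||% -9999L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(grid)),
    sprintf("nrows %d", nrow(grid)),
    "xllcorner 0",
    "yllcorner 0",
    sprintf("cellsize %.10g", cellsize),
    sprintf("NODATA_value %.10g", as.numeric(nodata))
  ), con)
  out <- grid
  out[is.na(out)] <- as.numeric(nodata)
  utils::write.table(out, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid file
#'
#' @param path file written by [write_ascii_grid()] or any conforming ASCII
#'   grid.
#' @param class_names optional named character vector of class labels; when
#'   supplied the result is an [lc_raster()], otherwise a [band_raster()] (with
#'   the pixel size attached as the `"cellsize"` attribute).
#' @return An `lc_raster` or `band_raster`.
#' @export
read_ascii_grid <- function(path, class_names = NULL) {
  lines <- readLines(path)
  hdr <- list()
  i <- 0L
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                    "nodata_value")) break
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (k in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[k]])) stop("ASCII grid header missing `", k, "`", call. = FALSE)
  }
  vals <- scan(text = lines[(i + 1L):length(lines)], quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop(sprintf("ASCII grid body has %d values, expected %d",
                 length(vals), hdr$ncols * hdr$nrows), call. = FALSE)
  }
  grid <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(class_names)) {
    lc_raster(grid, pixel_size_m = hdr$cellsize, class_names = class_names,
              nodata_code = hdr$nodata_value)
  } else {
    b <- band_raster(grid)
    attr(b, "cellsize") <- hdr$cellsize
    b
  }
}

# shape check shared by NDVI and class statistics
check_same_shape <- function(a, b, what_a, what_b) {
  da <- dim(a); db <- dim(b)
  if (!identical(da, db)) {
    stop(sprintf("%s is %d x %d but %s is %d x %d; shapes must match",
                 what_a, da[1], da[2], what_b, db[1], db[2]), call. = FALSE)
  }
  invisible(TRUE)
}
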