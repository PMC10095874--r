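#' Categorical raster for one accounting epoch
#'
#' The spatial substrate of every account: a single-band integer raster on a
#' regular grid with nominal 1-ha pixels. Cell values are integer class codes;
#' nodata cells are `NA`. Georeferencing follows the ESRI ASCII grid
#' convention (lower-left corner, square cells, row 1 = northernmost row);
#' all layers of one analysis must share one projected CRS in metric units —
#' the package never reprojects.
#'
#' @param values Integer matrix of class codes; `NA` marks nodata.
#' @param epoch Epoch label, e.g. `"2000"`.
#' @param pixel_area_ha Area of one cell in hectares (default 1).
#' @param xll,yll Coordinates of the lower-left corner of the grid.
#' @param cellsize Cell edge length in CRS units (metres); defaults to the
#'   edge of a square `pixel_area_ha` cell.
#' @param crs CRS identifier string (not interpreted, only carried and
#'   compared).
#' @return An object of class `epoch_grid`.
#' @export
epoch_grid <- function(values, epoch = "t0", pixel_area_ha = 1,
                       xll = 0, yll = 0,
                       cellsize = sqrt(pixel_area_ha * 1e4), crs = "local") {
  if (!is.matrix(values)) stop_encar("`values` must be a matrix")
  storage.mode(values) <- "integer"
  if (pixel_area_ha <= 0) stop_encar("pixel_area_ha must be > 0")
  g <- structure(
    list(values = values, epoch = as.character(epoch),
         pixel_area_ha = pixel_area_ha,
         xll = xll, yll = yll, cellsize = cellsize, crs = crs),
    class = "epoch_grid")
  g
}

#' @export
print.epoch_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<epoch_grid '%s'> %d x %d cells, %.3g ha/pixel, crs=%s\n",
              x$epoch, nrow(v), ncol(v), x$pixel_area_ha, x$crs))
  cat(sprintf("  classes: %s | nodata cells: %d\n",
              paste(sort(unique(v[!is.na(v)])), collapse = " "),
              sum(is.na(v))))
  invisible(x)
}

#' @export
dim.epoch_grid <- function(x) dim(x$values)

#' Check that two grids share shape, georeferencing and CRS
#'
#' Any two rasters combined in an account (two epochs, a zone raster and a
#' value raster, ...) must be pixel-aligned; nothing is resampled on the fly.
#'
#' @param a,b `epoch_grid` objects.
#' @return `TRUE` if aligned, otherwise `FALSE`.
#' @export
grids_aligned <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xll, a$yll, a$cellsize, a$pixel_area_ha),
                     c(b$xll, b$yll, b$cellsize, b$pixel_area_ha))) &&
    identical(a$crs, b$crs)
}

assert_aligned <- function(a, b, what = "grids") {
  if (!grids_aligned(a, b))
    stop_encar(
      "%s are not aligned: [%d x %d, xll=%g yll=%g cell=%g crs=%s] vs [%d x %d, xll=%g yll=%g cell=%g crs=%s]",
      what, nrow(a$values), ncol(a$values), a$xll, a$yll, a$cellsize, a$crs,
      nrow(b$values), ncol(b$values), b$xll, b$yll, b$cellsize, b$crs)
  invisible(TRUE)
}

#' Class areas of a categorical raster
#'
#' @param grid An `epoch_grid`.
#' @return Named numeric vector of areas in hectares, one entry per class
#'   code present (nodata excluded).
#' @export
class_areas <- function(grid) {
  v <- grid$values[!is.na(grid$values)]
  tab <- table(v)
  out <- as.numeric(tab) * grid$pixel_area_ha
  names(out) <- names(tab)
  out
}
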