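#' Zonal statistics on aligned rasters
#'
#' Reduce a value raster over the footprint of each zone label. Nodata cells
#' of either layer are excluded. `zonal_sum()` of a per-hectare surface can
#' be converted to totals via `per_ha = FALSE`/`TRUE` handling by the
#' caller; the functions themselves are unit-agnostic.
#'
#' @param surface `epoch_grid` (numeric values allowed) or bare matrix.
#' @param zones `epoch_grid` of zone labels (or `catchment_set`).
#' @return Named numeric vector, one entry per zone id.
#' @export
zonal_sum <- function(surface, zones) zonal_stat(surface, zones, sum)

#' @rdname zonal_sum
#' @export
zonal_mean <- function(surface, zones) zonal_stat(surface, zones, mean)

zonal_stat <- function(surface, zones, fun) {
  if (inherits(zones, "catchment_set")) zones <- zones$zone_grid
  sv <- if (inherits(surface, "epoch_grid")) surface$values else surface
  zv <- zones$values
  if (!identical(dim(sv), dim(zv)))
    stop_encar("surface and zone raster differ in shape")
  ok <- !is.na(zv) & !is.na(sv)
  vapply(split(sv[ok], zv[ok]), fun, numeric(1))
}

# read a numeric (non-categorical) surface matrix out of grid-or-matrix
surface_values <- function(x) if (inherits(x, "epoch_grid")) x$values else x
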