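#' Read and write rasters as ESRI ASCII grid
#'
#' The plain-text ASCII grid interchange format (header lines `ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`, then rows
#' north to south). Categorical layers round-trip as `epoch_grid`s
#' (`read_ascii_grid`/`write_ascii_grid`, integer values); continuous
#' surfaces as bare numeric matrices (`read_ascii_surface`/
#' `write_ascii_surface`, full double precision). Round trips are
#' value-exact.
#'
#' @param path File path.
#' @param epoch,crs Metadata attached on read (not stored in the format).
#' @return `read_ascii_grid()` an `epoch_grid`; `read_ascii_surface()` a
#'   numeric matrix with attributes `xll`, `yll`, `cellsize`.
#' @export
read_ascii_grid <- function(path, epoch = "t0", crs = "local") {
  a <- read_ascii_raw(path)
  m <- a$values
  m[m == a$nodata] <- NA
  storage.mode(m) <- "integer"
  epoch_grid(m, epoch = epoch, pixel_area_ha = a$cellsize^2 / 1e4,
             xll = a$xll, yll = a$yll, cellsize = a$cellsize, crs = crs)
}

#' @rdname read_ascii_grid
#' @param grid An `epoch_grid`.
#' @param nodata Nodata code written to file.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999L) {
  v <- grid$values
  v[is.na(v)] <- nodata
  write_ascii_raw(v, path, grid$xll, grid$yll, grid$cellsize, nodata,
                  fmt = "%d")
}

#' @rdname read_ascii_grid
#' @export
read_ascii_surface <- function(path) {
  a <- read_ascii_raw(path)
  m <- a$values
  m[m == a$nodata] <- NA
  attr(m, "xll") <- a$xll; attr(m, "yll") <- a$yll
  attr(m, "cellsize") <- a$cellsize
  m
}

#' @rdname read_ascii_grid
#' @param surface Numeric matrix.
#' @param xll,yll,cellsize Georeferencing of the surface.
#' @export
write_ascii_surface <- function(surface, path, xll = 0, yll = 0,
                                cellsize = 100, nodata = -9999) {
  v <- surface
  v[is.na(v)] <- nodata
  write_ascii_raw(v, path, xll, yll, cellsize, nodata, fmt = "%.17g")
}

read_ascii_raw <- function(path) {
  if (!file.exists(path)) stop_encar("raster file not found: %s", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop_encar("%s: expected %d cells, found %d", path, nr * nc, length(vals))
  list(values = matrix(vals, nrow = nr, ncol = nc, byrow = TRUE),
       xll = hdr$xllcorner %||% 0, yll = hdr$yllcorner %||% 0,
       cellsize = hdr$cellsize, nodata = hdr$nodata_value %||% -9999)
}

write_ascii_raw <- function(v, path, xll, yll, cellsize, nodata, fmt) {
  hdr <- c(sprintf("ncols %d", ncol(v)), sprintf("nrows %d", nrow(v)),
           sprintf("xllcorner %.10g", xll), sprintf("yllcorner %.10g", yll),
           sprintf("cellsize %.10g", cellsize),
           sprintf(paste("NODATA_value", fmt), nodata))
  body <- apply(v, 1, function(row) paste(sprintf(fmt, row), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write accounting tables as CSV
#'
#' UTF-8, comma separated, period decimal mark, no row names; numeric
#' precision 15 significant digits. Fixed column orders per table make
#' outputs byte-comparable across runs.
#'
#' @param x data.frame.
#' @param path File path.
#' @return `read_table()` a data.frame; `write_table()` `path`, invisibly.
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop_encar("table not found: %s", path)
  utils::read.csv(path, fileEncoding = "UTF-8")
}

#' Write a synthetic watershed to disk as pipeline inputs
#'
#' Emits exactly the file set [run_enca()] consumes: `lc_<epoch>.asc` land
#' cover per epoch, `uzhyd.asc` zone raster, `catchments.csv`, `rivers.csv`,
#' the four surfaces (`precip_mm.asc`, `aet_mm.asc`, `npp_tc_ha.asc`,
#' `rh_tc_ha.asc`), `water_use.csv`, `carbon_use.csv`, `health.csv`,
#' `protected.asc`, `barriers.asc` and `scenario.yaml`.
#'
#' @param ws Output of [generate_watershed()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_watershed <- function(ws, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sc <- ws$scenario
  p <- function(...) file.path(dir, ...)
  write_ascii_grid(ws$grid_t0, p(sprintf("lc_%s.asc", sc$epochs[1])))
  write_ascii_grid(ws$grid_t1, p(sprintf("lc_%s.asc", sc$epochs[2])))
  write_ascii_grid(ws$catchments$zone_grid, p("uzhyd.asc"))
  write_table(ws$catchments$uzhyds, p("catchments.csv"))
  write_table(ws$reaches, p("rivers.csv"))
  write_ascii_surface(ws$precip_mm, p("precip_mm.asc"))
  write_ascii_surface(ws$aet_mm, p("aet_mm.asc"))
  write_ascii_surface(ws$npp_tc_ha, p("npp_tc_ha.asc"))
  write_ascii_surface(ws$rh_tc_ha, p("rh_tc_ha.asc"))
  write_table(ws$water_use, p("water_use.csv"))
  write_table(ws$carbon_use, p("carbon_use.csv"))
  write_table(ws$health, p("health.csv"))
  write_ascii_grid(epoch_grid(ws$protected + 0L, "protected"),
                   p("protected.asc"))
  write_ascii_grid(epoch_grid(ws$barriers + 0L, "barriers"),
                   p("barriers.asc"))
  yaml::write_yaml(list(seed = sc$seed, grid_size = sc$grid_size,
                        n_uzhyds = sc$n_uzhyds,
                        epochs = as.list(sc$epochs), n_years = sc$n_years,
                        exploitable_fraction = sc$exploitable_fraction,
                        river_thresholds = sc$river_thresholds,
                        use_levels = sc$use_levels),
                   p("scenario.yaml"))
  invisible(dir)
}
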