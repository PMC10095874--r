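#' Nested catchment hierarchy
#'
#' Catchments come at two nesting levels: accounting catchments (ENCAT) and
#' their elementary hydrological zones (UZHYD). Zone footprints are carried
#' as a label raster aligned with the land-cover grids (one integer UZHYD id
#' per cell), and the drainage topology as a downstream relation between
#' UZHYDs.
#'
#' @param uzhyds data.frame with columns `uzhyd_id`, `encat_id`,
#'   `downstream_id` (`NA` marks the outlet).
#' @param zone_grid `epoch_grid` whose cell values are UZHYD ids (`NA` =
#'   outside the accounted territory).
#' @param encats Optional data.frame with column `encat_id`; derived from
#'   `uzhyds` when omitted.
#' @return Object of class `catchment_set`.
#' @export
catchment_set <- function(uzhyds, zone_grid, encats = NULL) {
  need <- c("uzhyd_id", "encat_id", "downstream_id")
  miss <- setdiff(need, names(uzhyds))
  if (length(miss))
    stop_encar("uzhyds table lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(uzhyds$uzhyd_id))
    stop_encar("duplicate uzhyd_id in catchment table")
  if (is.null(encats))
    encats <- data.frame(encat_id = sort(unique(uzhyds$encat_id)))
  cs <- structure(list(uzhyds = uzhyds, encats = encats,
                       zone_grid = zone_grid),
                  class = "catchment_set")
  validate_catchments(cs)
  cs
}

#' Validate a catchment set
#'
#' Checks that every zone-raster label has a table row, that the downstream
#' relation stays inside the set and is acyclic, and that no UZHYD is empty.
#'
#' @param cs A `catchment_set`.
#' @return `cs` invisibly; errors describe the violated invariant.
#' @export
validate_catchments <- function(cs) {
  ids <- cs$uzhyds$uzhyd_id
  zv <- cs$zone_grid$values
  present <- sort(unique(zv[!is.na(zv)]))
  orphan <- setdiff(present, ids)
  if (length(orphan))
    stop_encar("zone raster contains uzhyd ids missing from table: %s",
               paste(orphan, collapse = ", "))
  empty <- setdiff(ids, present)
  if (length(empty))
    stop_encar("uzhyds with no raster footprint: %s",
               paste(empty, collapse = ", "))
  ds <- cs$uzhyds$downstream_id
  bad <- !is.na(ds) & !(ds %in% ids)
  if (any(bad))
    stop_encar("downstream ids outside the set: %s",
               paste(unique(ds[bad]), collapse = ", "))
  edges <- cs$uzhyds[!is.na(ds), c("uzhyd_id", "downstream_id")]
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE)
    if (!igraph::is_dag(g)) {
      cyc <- igraph::girth(igraph::as_undirected(g))$circle
      stop_encar("downstream relation contains a cycle (e.g. through %s)",
                 paste(names(cyc), collapse = " -> "))
    }
  }
  invisible(cs)
}

#' UZHYD areas from the zone raster
#' @param cs A `catchment_set`.
#' @return Named numeric vector, hectares per uzhyd_id.
#' @export
uzhyd_areas <- function(cs) {
  zv <- cs$zone_grid$values
  tab <- table(zv[!is.na(zv)])
  stats::setNames(as.numeric(tab) * cs$zone_grid$pixel_area_ha, names(tab))
}

#' Reclassify a source land-cover raster to dominant land-cover types
#'
#' Applies the scheme's total source-to-DLCT mapping cell-wise. Nodata is
#' preserved and non-nodata area is conserved exactly (pure relabelling).
#'
#' @param grid `epoch_grid` in the source nomenclature.
#' @param scheme A `classification_scheme`.
#' @return `epoch_grid` in DLCT codes, same shape and georeferencing.
#' @export
reclassify_to_dlct <- function(grid, scheme) {
  v <- grid$values
  codes <- v[!is.na(v)]
  unmapped <- setdiff(unique(codes), as.integer(names(scheme$mapping)))
  if (length(unmapped)) {
    n_aff <- sum(codes %in% unmapped)
    stop_encar("unmapped source codes %s (%d cells affected)",
               paste(unmapped, collapse = ", "), n_aff)
  }
  out <- grid
  idx <- match(as.character(v), names(scheme$mapping))
  newv <- unname(scheme$mapping[idx])
  out$values <- matrix(as.integer(newv), nrow(v), ncol(v))
  out
}

#' Dominant land-cover type per zone
#'
#' Labels each zone with the class of maximal area among its non-nodata
#' cells. Ties break to the lowest class code, so the result does not depend
#' on cell order. A zone that is more than half nodata triggers a warning; a
#' zone with no non-nodata cell is an error.
#'
#' @param dlct_grid `epoch_grid` of DLCT codes.
#' @param zones `epoch_grid` of zone labels (or a `catchment_set`).
#' @return Named integer vector: zone id -> dominant DLCT code.
#' @export
dominant_cover <- function(dlct_grid, zones) {
  if (inherits(zones, "catchment_set")) zones <- zones$zone_grid
  assert_aligned(dlct_grid, zones, "DLCT grid and zone raster")
  zv <- zones$values
  cv <- dlct_grid$values
  in_zone <- !is.na(zv)
  zone_ids <- sort(unique(zv[in_zone]))

  zsize <- table(zv[in_zone])
  ok <- in_zone & !is.na(cv)
  covered <- table(factor(zv[ok], levels = names(zsize)))
  dead <- names(zsize)[covered == 0]
  if (length(dead))
    stop_encar("zones with no non-nodata land cover: %s",
               paste(dead, collapse = ", "))
  hollow <- names(zsize)[covered / as.numeric(zsize) < 0.5]
  if (length(hollow))
    warning(sprintf("zones more than half nodata: %s",
                    paste(hollow, collapse = ", ")), call. = FALSE)

  tab <- table(zone = zv[ok], class = cv[ok])
  cls <- as.integer(colnames(tab))
  # which.max returns the first maximum; columns are in increasing code
  # order, so ties resolve to the lowest code.
  dom <- cls[apply(tab, 1, which.max)]
  stats::setNames(dom, rownames(tab))[as.character(zone_ids)]
}

#' Delineate socio-ecological landscape units (SELU)
#'
#' A SELU is an elementary catchment (UZHYD) labelled by its dominant
#' land-cover type at the reference epoch. One SELU per UZHYD keeps the
#' statistical units stable across epochs, so stocks and flows remain
#' comparable; by construction the SELUs partition the accounted territory.
#'
#' @param dlct_grid `epoch_grid` of DLCT codes for the reference epoch.
#' @param catchments A `catchment_set`.
#' @return data.frame with columns `selu_id`, `uzhyd_id`, `encat_id`,
#'   `dlct_code`, `area_ha`, plus attribute `epoch`.
#' @export
build_selus <- function(dlct_grid, catchments) {
  dom <- dominant_cover(dlct_grid, catchments)
  areas <- uzhyd_areas(catchments)
  ids <- catchments$uzhyds$uzhyd_id
  out <- data.frame(
    selu_id = ids,
    uzhyd_id = ids,
    encat_id = catchments$uzhyds$encat_id,
    dlct_code = unname(dom[as.character(ids)]),
    area_ha = unname(areas[as.character(ids)]))
  attr(out, "epoch") <- dlct_grid$epoch
  out
}

#' Classify river reaches by discharge
#'
#' Reaches are binned into small / medium / large rivers by mean annual
#' discharge using two strictly increasing cut-offs; intervals are half-open
#' with the boundary assigned to the larger class
#' (small < t1 <= medium < t2 <= large).
#'
#' @param reaches data.frame with at least `reach_id`, `length_km`,
#'   `discharge_m3s`.
#' @param thresholds Numeric length-2 vector `(t1, t2)`, strictly increasing.
#' @return `reaches` with a `size_class` factor column added/replaced.
#' @export
classify_reaches <- function(reaches, thresholds = c(5, 50)) {
  if (length(thresholds) != 2 || diff(thresholds) <= 0)
    stop_encar("thresholds must be two strictly increasing discharge cut-offs")
  q <- reaches$discharge_m3s
  if (any(q < 0, na.rm = TRUE))
    stop_encar("negative discharge for reaches: %s",
               paste(reaches$reach_id[which(q < 0)], collapse = ", "))
  if (any(reaches$length_km < 0, na.rm = TRUE))
    stop_encar("negative reach length")
  cls <- cut(q, breaks = c(-Inf, thresholds, Inf),
             labels = c("small", "medium", "large"), right = FALSE)
  reaches$size_class <- cls
  reaches
}

#' Validate a SELU table against its catchment set
#'
#' Asserts the partition property (total SELU area equals accounted
#' territory area) and positive areas.
#'
#' @param selus data.frame from [build_selus()].
#' @param catchments The `catchment_set` it was built on.
#' @return `selus` invisibly.
#' @export
validate_selus <- function(selus, catchments) {
  if (any(selus$area_ha <= 0)) stop_encar("SELU with non-positive area")
  zg <- catchments$zone_grid
  terr <- sum(!is.na(zg$values)) * zg$pixel_area_ha
  if (abs(sum(selus$area_ha) - terr) > 1e-6)
    stop_encar("SELUs do not partition the territory: %g vs %g ha",
               sum(selus$area_ha), terr)
  invisible(selus)
}
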