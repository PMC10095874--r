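#' Greenness index per SELU
#'
#' Area-weighted mean of the classification scheme's green weights over the
#' cells of each SELU: 1 for fully green land systems (e.g. closed forest),
#' 0 for fully sealed ones.
#'
#' @param dlct_grid `epoch_grid` of DLCT codes.
#' @param scheme `classification_scheme` supplying `green_weight`.
#' @param zones Zone raster or `catchment_set` (SELU footprints).
#' @return Named numeric vector in \[0, 1\] per zone id.
#' @export
green_index <- function(dlct_grid, scheme, zones) {
  w <- scheme$green_weight
  v <- dlct_grid$values
  miss <- setdiff(unique(v[!is.na(v)]), as.integer(names(w)))
  if (length(miss))
    stop_encar("green weight undefined for classes: %s",
               paste(miss, collapse = ", "))
  wm <- matrix(unname(w[as.character(v)]), nrow(v), ncol(v))
  zonal_mean(wm, zones)
}

#' Label 4-connected patches of a binary mask
#'
#' Flood-fill labelling of the `TRUE` cells of a logical matrix using
#' rook (edge) adjacency. Used by the fragmentation index; exported for
#' diagnostics.
#'
#' @param mask Logical matrix (`NA` treated as `FALSE`).
#' @return Integer matrix: 0 outside the mask, patch id >= 1 inside.
#' @export
label_patches <- function(mask) {
  mask[is.na(mask)] <- FALSE
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  stack <- integer(nr * nc)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- nxt
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      r <- ((p - 1L) %% nr) + 1L
      cpos <- ((p - 1L) %/% nr) + 1L
      for (q in c(if (r > 1L) p - 1L,
                  if (r < nr) p + 1L,
                  if (cpos > 1L) p - nr,
                  if (cpos < nc) p + nr)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- nxt
          top <- top + 1L
          stack[top] <- q
        }
      }
    }
  }
  lab
}

#' Landscape fragmentation index per SELU (effective-mesh ratio)
#'
#' Connected green patches are delineated inside each SELU with 4-neighbour
#' connectivity after removing barrier cells (roads, sealed surfaces); the
#' index is `sum(A_i^2) / A_total^2` over the patch areas `A_i`, where
#' `A_total` is the total green (non-barrier) area of the SELU. A single
#' connected patch scores 1 (unfragmented); n equal disconnected patches
#' score 1/n. A SELU with no green cell scores 0 with a warning.
#'
#' @param green_mask Logical matrix (or `epoch_grid` of 0/1): green cells.
#' @param zones Zone raster or `catchment_set`.
#' @param barriers Optional logical matrix (or 0/1 grid): cells cut out of
#'   the green fabric before patch delineation.
#' @return Named numeric vector in \[0, 1\] per zone id.
#' @export
fragmentation_index <- function(green_mask, zones, barriers = NULL) {
  if (inherits(zones, "catchment_set")) zones <- zones$zone_grid
  gm <- surface_values(green_mask) > 0
  gm[is.na(gm)] <- FALSE
  if (!is.null(barriers)) {
    bm <- surface_values(barriers) > 0
    bm[is.na(bm)] <- FALSE
    gm <- gm & !bm
  }
  zv <- zones$values
  if (!identical(dim(gm), dim(zv)))
    stop_encar("green mask and zone raster differ in shape")
  ids <- sort(unique(zv[!is.na(zv)]))
  out <- stats::setNames(numeric(length(ids)), ids)
  for (z in ids) {
    m <- gm & !is.na(zv) & zv == z
    a_tot <- sum(m)
    if (a_tot == 0) {
      warning(sprintf("SELU %s has no green cells; fragmentation index 0", z),
              call. = FALSE)
      out[as.character(z)] <- 0
      next
    }
    lab <- label_patches(m)
    sizes <- tabulate(lab[lab > 0L])
    out[as.character(z)] <- sum(sizes^2) / a_tot^2
  }
  out
}

#' Net landscape ecosystem potential (NLEP)
#'
#' Multiplicative composite of greenness, fragmentation and nature-value
#' indices; the quantity form weights the index by SELU area so potentials
#' add over disjoint territories.
#'
#' @param green,fragmentation,nature_value Indices in \[0, 1\] (vectorised).
#' @param area_ha SELU areas for the quantity form.
#' @return data.frame with `nlep` and `nlep_quantity`.
#' @export
nlep <- function(green, fragmentation, nature_value, area_ha) {
  chk01(green, "green"); chk01(fragmentation, "fragmentation")
  chk01(nature_value, "nature_value")
  v <- green * fragmentation * nature_value
  data.frame(nlep = v, nlep_quantity = v * area_ha)
}

#' Net river ecosystem potential (NREP)
#'
#' Product of the river condition potential (from ordinal ecological status)
#' and the natural conservation value index; the quantity form weights by
#' the SELU's SRKM so river potential is commensurable with the landscape
#' quantity and the two can be summed into TEIP.
#'
#' @param condition,conservation Indices in \[0, 1\]; `NA` marks SELUs
#'   without rivers (value undefined, quantity 0).
#' @param srkm_weight SRKM of the SELU's reaches.
#' @return data.frame with `nrep` and `nrep_quantity`.
#' @export
nrep <- function(condition, conservation, srkm_weight = 1) {
  chk01(condition, "condition", na_ok = TRUE)
  chk01(conservation, "conservation", na_ok = TRUE)
  v <- condition * conservation
  q <- ifelse(is.na(v), 0, v * srkm_weight)
  data.frame(nrep = v, nrep_quantity = q)
}

#' Total ecosystem infrastructure potential (TEIP)
#'
#' Sum of the NLEP and NREP quantities per SELU.
#'
#' @param nlep_quantity,nrep_quantity Non-negative quantities.
#' @return TEIP quantity.
#' @export
teip <- function(nlep_quantity, nrep_quantity) {
  if (any(nlep_quantity < 0, na.rm = TRUE) ||
      any(nrep_quantity < 0, na.rm = TRUE))
    stop_encar("potential quantities must be non-negative")
  nlep_quantity + ifelse(is.na(nrep_quantity), 0, nrep_quantity)
}

#' Yearly rate of change (linear convention)
#'
#' `((v_t1 - v_t0) / v_t0) / n_years`, as fraction per year.
#'
#' @param v_t0,v_t1 Values at the two epochs (`v_t0 > 0`).
#' @param n_years Length of the period in years (> 0).
#' @return Rate, fraction/yr.
#' @export
yearly_change <- function(v_t0, v_t1, n_years) {
  if (any(v_t0 <= 0)) stop_encar("opening value must be positive")
  if (n_years <= 0) stop_encar("n_years must be positive")
  ((v_t1 - v_t0) / v_t0) / n_years
}

#' River condition potential from ordinal ecological status
#'
#' Fixed lookup from WFD-style status classes (1 = high ... 5 = bad) to a
#' condition potential in \[0, 1\]; configurable.
#'
#' @param status Integer status class(es) in 1..5.
#' @param lookup Numeric length-5 vector, default
#'   `c(1.0, 0.8, 0.6, 0.4, 0.2)`.
#' @return Condition potential(s).
#' @export
condition_potential <- function(status, lookup = c(1, 0.8, 0.6, 0.4, 0.2)) {
  if (any(!status %in% 1:5, na.rm = TRUE))
    stop_encar("status classes must be integers 1..5")
  lookup[status]
}

#' Ecosystem health index
#'
#' Weighted arithmetic mean of the water-quality, biodiversity-change and
#' vulnerability components, each in \[0, 1\]; values below 1 signify
#' degradation. Equal weights by default.
#'
#' @param water_quality,biodiversity_change,vulnerability Components in
#'   \[0, 1\] (vectorised).
#' @param weights Length-3 non-negative weights summing to 1.
#' @return Health index in \[0, 1\].
#' @export
health_index <- function(water_quality, biodiversity_change, vulnerability,
                         weights = c(1, 1, 1) / 3) {
  chk01(water_quality, "water_quality")
  chk01(biodiversity_change, "biodiversity_change")
  chk01(vulnerability, "vulnerability")
  if (length(weights) != 3 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop_encar("weights must be three non-negative values summing to 1")
  h <- weights[1] * water_quality + weights[2] * biodiversity_change +
    weights[3] * vulnerability
  pmin(1, pmax(0, h))
}

#' Nature-value index from a protected-area share
#'
#' Maps the share of a SELU under protected / high-nature-value designation
#' through a two-point weight table: unprotected land carries the base
#' weight, protected land full weight.
#'
#' @param protected_share Share in \[0, 1\].
#' @param weight_unprotected,weight_protected Weights in \[0, 1\].
#' @return Nature-value index in \[0, 1\].
#' @export
nature_value_index <- function(protected_share, weight_unprotected = 0.5,
                               weight_protected = 1) {
  chk01(protected_share, "protected_share")
  weight_unprotected * (1 - protected_share) +
    weight_protected * protected_share
}

chk01 <- function(x, what, na_ok = FALSE) {
  bad <- x < 0 | x > 1
  if (!na_ok && any(is.na(x))) stop_encar("%s contains NA", what)
  if (any(bad, na.rm = TRUE)) stop_encar("%s must lie in [0, 1]", what)
  invisible(x)
}
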