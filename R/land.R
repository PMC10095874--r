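#' Land-cover transition matrix between two epochs
#'
#' Cross-tabulates aligned categorical rasters: entry (i, j) is the area (ha)
#' that moved from class i at the opening epoch to class j at the closing
#' epoch. Row sums are opening stocks, column sums closing stocks, and the
#' grand total the accounted area — identical for both epochs by
#' construction. With `zones` supplied the cross-tabulation is computed per
#' zone (grids masked to the zone footprint).
#'
#' @param grid_t0,grid_t1 Aligned `epoch_grid`s in the same (DLCT) codes.
#' @param scheme `classification_scheme`; defines the class universe. Codes
#'   present in the grids but absent from the scheme are an error.
#' @param zones Optional zone `epoch_grid` (or `catchment_set`); returns one
#'   matrix per zone.
#' @return A `transition_matrix` (list with `area` matrix, `classes`,
#'   `period`, `pixel_area_ha`), or a named list of them when `zones` is
#'   given.
#' @export
transition_matrix <- function(grid_t0, grid_t1, scheme = default_scheme(),
                              zones = NULL) {
  assert_aligned(grid_t0, grid_t1, "epoch grids")
  classes <- sort(as.integer(scheme$dlct_classes$code))
  v0 <- grid_t0$values; v1 <- grid_t1$values
  seen <- unique(c(v0[!is.na(v0)], v1[!is.na(v1)]))
  rogue <- setdiff(seen, classes)
  if (length(rogue))
    stop_encar("grid classes absent from scheme: %s",
               paste(sort(rogue), collapse = ", "))
  ok <- !is.na(v0) & !is.na(v1)

  tm_from <- function(sel) {
    tab <- table(factor(v0[sel], levels = classes),
                 factor(v1[sel], levels = classes))
    structure(list(area = unclass(tab) * grid_t0$pixel_area_ha,
                   classes = classes,
                   period = c(grid_t0$epoch, grid_t1$epoch),
                   pixel_area_ha = grid_t0$pixel_area_ha),
              class = "transition_matrix")
  }

  if (is.null(zones)) return(tm_from(ok))
  if (inherits(zones, "catchment_set")) zones <- zones$zone_grid
  assert_aligned(grid_t0, zones, "epoch grid and zone raster")
  zv <- zones$values
  ids <- sort(unique(zv[!is.na(zv)]))
  out <- lapply(ids, function(z) tm_from(ok & !is.na(zv) & zv == z))
  names(out) <- as.character(ids)
  out
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %s -> %s, %d classes, %.6g ha total\n",
              x$period[1], x$period[2], length(x$classes), sum(x$area)))
  print(x$area)
  invisible(x)
}

validate_tm <- function(T) {
  if (!inherits(T, "transition_matrix")) stop_encar("not a transition_matrix")
  if (any(T$area < 0)) stop_encar("negative transition areas")
  invisible(T)
}

#' Stock-and-flow account from a transition matrix
#'
#' For each class: opening stock (row sum), consumption (area lost to other
#' classes: off-diagonal row sum), formation (area gained: off-diagonal
#' column sum), net change and closing stock. The balance identity
#' `closing = opening + formation - consumption` holds per class, and net
#' changes sum to zero across classes because total area is conserved.
#'
#' @param T A `transition_matrix`.
#' @return data.frame (class `stock_flow_account`) with columns `class`,
#'   `opening_ha`, `consumption_ha`, `formation_ha`, `net_change_ha`,
#'   `closing_ha`; attribute `period`.
#' @export
stock_flow_account <- function(T) {
  validate_tm(T)
  A <- T$area
  d <- diag(A)
  opening <- rowSums(A)
  closing <- colSums(A)
  cons <- opening - d
  form <- closing - d
  out <- data.frame(class = T$classes,
                    opening_ha = as.numeric(opening),
                    consumption_ha = as.numeric(cons),
                    formation_ha = as.numeric(form),
                    net_change_ha = as.numeric(form - cons),
                    closing_ha = as.numeric(closing))
  attr(out, "period") <- T$period
  class(out) <- c("stock_flow_account", "data.frame")
  out
}

#' Percentage change of a stock
#'
#' Change relative to the opening stock; when `whole = TRUE` the result is
#' rounded to the nearest whole percent, half away from zero.
#'
#' @param opening,closing Stocks in the same unit.
#' @param whole Round to whole percents?
#' @return Percentage (e.g. `11` for +11\%).
#' @export
percent_change <- function(opening, closing, whole = TRUE) {
  if (any(opening <= 0)) stop_encar("opening stock must be positive")
  p <- (closing - opening) / opening * 100
  if (whole) round_half_away(p) else p
}

#' Driver-of-change classification scheme
#'
#' An ordered rule table mapping class-to-class conversions onto land-use
#' drivers; the first matching rule wins. `NA` in `from_code`/`to_code` is a
#' wildcard. The shipped default approximates the usual account taxonomy:
#' artificialisation, agriculture internal conversion / extension, forest &
#' shrub translation, water-glacier-wetland change, and an
#' "other changes n.e.s." catch-all.
#'
#' @param rules data.frame with columns `from_code`, `to_code`, `driver`.
#' @return Object of class `driver_scheme`.
#' @export
driver_scheme <- function(rules) {
  need <- c("from_code", "to_code", "driver")
  if (!all(need %in% names(rules)))
    stop_encar("driver rules need columns %s", paste(need, collapse = ", "))
  structure(list(rules = rules), class = "driver_scheme")
}

#' @rdname driver_scheme
#' @export
default_driver_scheme <- function() {
  agri <- c(2L, 3L, 4L)
  rules <- rbind(
    data.frame(from_code = NA, to_code = 1L, driver = "artificialisation"),
    expand.grid(from_code = agri, to_code = agri,
                driver = "agriculture internal conversion"),
    data.frame(from_code = NA, to_code = agri,
               driver = "agriculture extension"),
    expand.grid(from_code = c(5L, 6L), to_code = c(5L, 6L),
                driver = "forest & shrub translation"),
    data.frame(from_code = 10L, to_code = NA, driver = "glacier retreat"),
    data.frame(from_code = c(NA, 8L, 9L), to_code = c(9L, NA, NA),
               driver = "water body & wetland change"),
    data.frame(from_code = NA, to_code = NA, driver = "other changes n.e.s."))
  driver_scheme(rules)
}

#' Classify land-cover flows by driver
#'
#' Distributes the off-diagonal (gross change) area of a transition matrix
#' over the driver categories of an ordered rule scheme. The driver areas
#' partition gross change: their sum equals total consumption (= total
#' formation).
#'
#' @param T A `transition_matrix`.
#' @param scheme A `driver_scheme`.
#' @return Named numeric vector: driver -> area (ha), one entry per driver
#'   appearing in the scheme (zeros kept).
#' @export
classify_flows <- function(T, scheme = default_driver_scheme()) {
  validate_tm(T)
  rules <- scheme$rules
  drivers <- unique(rules$driver)
  out <- stats::setNames(numeric(length(drivers)), drivers)
  A <- T$area
  cls <- T$classes
  for (i in seq_along(cls)) for (j in seq_along(cls)) {
    if (i == j || A[i, j] == 0) next
    hit <- which((is.na(rules$from_code) | rules$from_code == cls[i]) &
                   (is.na(rules$to_code) | rules$to_code == cls[j]))
    if (!length(hit))
      stop_encar("no driver rule covers conversion %d -> %d (%.6g ha)",
                 cls[i], cls[j], A[i, j])
    out[rules$driver[hit[1]]] <- out[rules$driver[hit[1]]] + A[i, j]
  }
  out
}

#' Chain stock-flow accounts over consecutive periods
#'
#' Gross flows (consumption, formation) are summed across periods; the
#' opening stock comes from the first account and the closing stock from the
#' last, so the balance identity holds on the chained account. Periods must
#' be consecutive (closing epoch of one = opening epoch of the next) and the
#' stocks must match at the junctions.
#'
#' @param accounts List of `stock_flow_account`s in period order.
#' @param tol Stock-matching tolerance at junctions (ha).
#' @return A `stock_flow_account` spanning first opening to last closing.
#' @export
chain_periods <- function(accounts, tol = 1e-6) {
  if (!length(accounts)) stop_encar("no accounts to chain")
  if (length(accounts) == 1L) return(accounts[[1]])
  base <- accounts[[1]]
  for (k in seq_along(accounts)[-1]) {
    a <- accounts[[k]]
    p_prev <- attr(accounts[[k - 1]], "period")
    p_this <- attr(a, "period")
    if (!identical(p_prev[2], p_this[1]))
      stop_encar("periods not consecutive: %s-%s then %s-%s",
                 p_prev[1], p_prev[2], p_this[1], p_this[2])
    if (!identical(base$class, a$class))
      stop_encar("chained accounts cover different class sets")
    if (max(abs(accounts[[k - 1]]$closing_ha - a$opening_ha)) > tol)
      stop_encar("closing stocks of period %s-%s differ from next opening",
                 p_prev[1], p_prev[2])
    base$consumption_ha <- base$consumption_ha + a$consumption_ha
    base$formation_ha <- base$formation_ha + a$formation_ha
    base$closing_ha <- a$closing_ha
  }
  base$net_change_ha <- base$formation_ha - base$consumption_ha
  attr(base, "period") <- c(attr(accounts[[1]], "period")[1],
                            attr(accounts[[length(accounts)]], "period")[2])
  base
}
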