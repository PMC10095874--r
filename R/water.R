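#' Route annual water balances through the catchment topology
#'
#' Evaluates each elementary hydrological zone (UZHYD) in topological order:
#' the upstream inflow of a unit is the summed runoff of its immediate
#' upstream units. Local runoff is the non-negative part of
#' `precipitation + upstream inflow - actual ET - net abstraction`; a deficit
#' is drawn from storage instead, so the closure identity
#' `closing = opening + inflows - outflows - net abstraction` holds exactly
#' for every unit. Volumes in hm3/yr.
#'
#' @param local data.frame with columns `uzhyd_id`, `precipitation_hm3`,
#'   `evapotranspiration_hm3`, and optional `opening_stock_hm3`,
#'   `net_abstraction_hm3` (default 0).
#' @param downstream Named vector: `uzhyd_id` -> downstream `uzhyd_id`
#'   (`NA` at the outlet). Must be acyclic.
#' @return data.frame with per-unit `upstream_inflow_hm3`, `runoff_out_hm3`,
#'   `closing_stock_hm3` and the local terms.
#' @export
route_balance <- function(local, downstream) {
  ids <- as.character(local$uzhyd_id)
  if (anyDuplicated(ids)) stop_encar("duplicate uzhyd_id in balance table")
  ds <- downstream[ids]
  if (any(is.na(names(downstream))))
    stop_encar("downstream map must be named by uzhyd_id")
  edge_from <- ids[!is.na(ds)]
  edge_to <- as.character(ds[!is.na(ds)])
  if (length(setdiff(edge_to, ids)))
    stop_encar("downstream target outside the unit set: %s",
               paste(setdiff(edge_to, ids), collapse = ", "))
  order_ids <- ids
  if (length(edge_from)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = edge_from, to = edge_to),
      directed = TRUE, vertices = data.frame(name = ids))
    if (!igraph::is_dag(g)) {
      comp <- igraph::components(g, mode = "strong")
      cyc <- names(comp$membership)[comp$membership %in%
                                      which(comp$csize > 1)]
      stop_encar("cycle in downstream topology involving: %s",
                 paste(cyc, collapse = ", "))
    }
    order_ids <- names(igraph::topo_sort(g, mode = "out"))
  }

  opening <- local$opening_stock_hm3 %||% rep(0, nrow(local))
  abstraction <- local$net_abstraction_hm3 %||% rep(0, nrow(local))
  P <- stats::setNames(local$precipitation_hm3, ids)
  ET <- stats::setNames(local$evapotranspiration_hm3, ids)
  op <- stats::setNames(opening, ids)
  ab <- stats::setNames(abstraction, ids)
  if (any(P < 0) || any(ET < 0)) stop_encar("negative climate volume")

  qin <- stats::setNames(numeric(length(ids)), ids)
  qout <- qin; closing <- qin
  for (u in order_ids) {
    bal <- P[[u]] + qin[[u]] - ET[[u]] - ab[[u]]
    qout[[u]] <- max(0, bal)
    closing[[u]] <- op[[u]] + min(0, bal)
    d <- ds[[u]]
    if (!is.na(d)) qin[[as.character(d)]] <- qin[[as.character(d)]] + qout[[u]]
  }

  data.frame(uzhyd_id = local$uzhyd_id,
             opening_stock_hm3 = unname(op[ids]),
             precipitation_hm3 = unname(P[ids]),
             upstream_inflow_hm3 = unname(qin[ids]),
             evapotranspiration_hm3 = unname(ET[ids]),
             net_abstraction_hm3 = unname(ab[ids]),
             runoff_out_hm3 = unname(qout[ids]),
             closing_stock_hm3 = unname(closing[ids]))
}

#' Accessible water surplus
#'
#' The resource usable without depleting the stock: the exploitable fraction
#' of the renewable balance `precipitation + upstream inflow - actual ET`,
#' floored at zero. The correction factor reflects that not all of the
#' renewable resource is exploitable (e.g. protected-area restrictions,
#' inaccessible flood flows).
#'
#' @param balance One row of [route_balance()] output (or any list with
#'   `precipitation_hm3`, `upstream_inflow_hm3`, `evapotranspiration_hm3`).
#' @param exploitable_fraction Value in \[0, 1\].
#' @return Surplus volume, hm3/yr (vectorised over rows).
#' @export
accessible_surplus <- function(balance, exploitable_fraction = 0.5) {
  if (any(exploitable_fraction < 0 | exploitable_fraction > 1))
    stop_encar("exploitable_fraction must lie in [0, 1]")
  exploitable_fraction *
    pmax(0, balance$precipitation_hm3 + balance$upstream_inflow_hm3 -
           balance$evapotranspiration_hm3)
}

#' Municipal water use from population statistics
#'
#' @param population Inhabitant-equivalents served.
#' @param per_capita_hm3 Annual use per inhabitant-equivalent (hm3/yr);
#'   the default is 80 m3/person/yr.
#' @return Volume, hm3/yr.
#' @export
estimate_municipal_use <- function(population, per_capita_hm3 = 8e-5) {
  if (any(population < 0) || any(per_capita_hm3 < 0))
    stop_encar("population and per-capita use must be non-negative")
  population * per_capita_hm3
}

#' Sectoral water use record
#'
#' @param withdrawals Named numeric vector of sectoral withdrawals (hm3/yr),
#'   e.g. municipal, agriculture, power.
#' @param returns Named numeric vector of return flows, same sectors;
#'   `0 <= returns <= withdrawals`.
#' @return Object of class `water_use` with `net_consumption`.
#' @export
water_use <- function(withdrawals, returns = withdrawals * 0) {
  returns <- returns[names(withdrawals)]
  if (any(is.na(returns))) stop_encar("returns must cover every sector")
  if (any(returns < 0) || any(returns > withdrawals))
    stop_encar("per sector, 0 <= returns <= withdrawals must hold")
  structure(list(withdrawals = withdrawals, returns = returns,
                 net_consumption = sum(withdrawals - returns)),
            class = "water_use")
}

#' Water intensity-of-use index (raw)
#'
#' Accessible surplus divided by total net consumption. Values below 1 mean
#' use exceeds the renewable surplus; zero consumption returns `Inf` as a
#' no-depletion sentinel (capped to 1 by the capability layer).
#'
#' @param surplus Accessible surplus, hm3/yr (>= 0).
#' @param use A `water_use` object or a bare non-negative net-consumption
#'   volume.
#' @return Raw index (ratio, possibly `Inf`).
#' @export
water_intensity_index <- function(surplus, use) {
  cons <- if (inherits(use, "water_use")) use$net_consumption else use
  if (any(surplus < 0)) stop_encar("surplus must be non-negative")
  if (any(cons < 0)) stop_encar("net consumption must be non-negative")
  ifelse(cons == 0, Inf, surplus / cons)
}

#' River accounts in standard river kilometres (SRKM)
#'
#' A reach is weighted in standard river kilometres, the product of its
#' length and its mean discharge, so that reaches of different size can be
#' aggregated. Per size class (and overall) the account reports total SRKM
#' and the SRKM-weighted shares whose ordinal ecological status (1 = high
#' ... 5 = bad) degraded, improved or stayed stable between the two epochs.
#'
#' @param reaches data.frame with `reach_id`, `length_km`, `discharge_m3s`,
#'   `size_class`, `status_t0`, `status_t1`.
#' @param srkm_scale Discharge normalisation constant (SRKM per km per
#'   m3/s); configurable scale, default 1.
#' @return data.frame per size class (plus an `all` row): `srkm_total`,
#'   `share_degraded`, `share_improved`, `share_stable`.
#' @export
river_account <- function(reaches, srkm_scale = 1) {
  st <- c(reaches$status_t0, reaches$status_t1)
  if (any(!st %in% 1:5))
    stop_encar("ecological status must be an integer class 1..5")
  srkm <- srkm(reaches$length_km, reaches$discharge_m3s, srkm_scale)
  delta <- reaches$status_t1 - reaches$status_t0
  grp <- as.character(reaches$size_class)
  one <- function(sel, label) {
    tot <- sum(srkm[sel])
    if (tot == 0)
      return(data.frame(size_class = label, srkm_total = 0,
                        share_degraded = NA_real_, share_improved = NA_real_,
                        share_stable = NA_real_))
    data.frame(size_class = label, srkm_total = tot,
               share_degraded = sum(srkm[sel & delta > 0]) / tot,
               share_improved = sum(srkm[sel & delta < 0]) / tot,
               share_stable = sum(srkm[sel & delta == 0]) / tot)
  }
  classes <- unique(grp)
  out <- do.call(rbind, lapply(classes, function(k) one(grp == k, k)))
  rbind(out, one(rep(TRUE, length(srkm)), "all"))
}

#' Standard river kilometres of a reach
#' @param length_km Reach length (km).
#' @param discharge_m3s Mean discharge (m3/s).
#' @param scale Normalisation constant, default 1.
#' @return SRKM weight(s).
#' @export
srkm <- function(length_km, discharge_m3s, scale = 1) {
  if (any(length_km < 0) || any(discharge_m3s < 0))
    stop_encar("length and discharge must be non-negative")
  scale * length_km * discharge_m3s
}
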