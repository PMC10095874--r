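#' Synthetic watershed scenario
#'
#' Defines the study conditions for a fully synthetic multi-epoch watershed:
#' a categorical land-cover mosaic with a prescribed class mix, a Voronoi
#' partition into elementary catchments drained by a dendritic river
#' network, smooth positive climate and productivity surfaces, and
#' prescribed land-change processes between the two epochs. Defaults mirror
#' a large temperate river basin over a 12-year accounting period: forest
#' ~40%, pasture ~28%, arable ~15% of the territory; artificialisation of
#' 11% of the artificial-expansion-eligible arable stock, glacier retreat of
#' 13%, and forest-to-transitional-woodland conversion; bio-carbon use near
#' 35% of the accessible resource and water use a tenth of the accessible
#' surplus.
#'
#' @param seed Single integer; all randomness derives from it via fixed
#'   per-layer streams, so adding a layer never perturbs the others.
#' @param grid_size `c(nrow, ncol)` of the raster (nominal 1-ha pixels).
#' @param n_uzhyds Number of elementary catchments.
#' @param class_mix Named fractions per DLCT code (must sum to 1).
#' @param change_rates Fractions per period: `artificialisation` (arable ->
#'   artificial), `forest_transition` (forest -> transitional woodland),
#'   `glacier_retreat` (glacier -> bare).
#' @param climate Means/sds of precipitation and actual ET (mm/yr).
#' @param productivity Means/sds of NPP (tC/ha/yr); Rh is generated as a
#'   smooth 40-70% share of NPP so NEP stays positive.
#' @param use_levels Per-account use as a multiple of the accessible
#'   resource: `water`, `carbon` (length 1 or one value per epoch).
#' @param exploitable_fraction Correction factor for the accessible water
#'   surplus.
#' @param river_thresholds Discharge cut-offs (m3/s) for small/medium/large.
#' @param epochs Two epoch labels.
#' @param n_years Period length in years.
#' @return Object of class `enca_scenario`.
#' @export
enca_scenario <- function(seed = 1L,
                          grid_size = c(120L, 120L),
                          n_uzhyds = 12L,
                          class_mix = c(`1` = 0.04, `2` = 0.15, `3` = 0.28,
                                        `4` = 0.03, `5` = 0.40, `6` = 0.04,
                                        `7` = 0.02, `8` = 0.01, `9` = 0.02,
                                        `10` = 0.01),
                          change_rates = list(artificialisation = 0.11,
                                              forest_transition = 0.02,
                                              glacier_retreat = 0.13),
                          climate = list(precip_mean = 1000, precip_sd = 150),
                          productivity = list(npp_mean = 6, npp_sd = 1.2),
                          use_levels = list(water = 0.1, carbon = 0.35),
                          exploitable_fraction = 0.5,
                          river_thresholds = c(0.3, 1.0),
                          epochs = c("2000", "2012"),
                          n_years = 12) {
  if (abs(sum(class_mix) - 1) > 1e-9) stop_encar("class_mix must sum to 1")
  if (any(class_mix < 0) || any(unlist(change_rates) < 0) ||
      any(unlist(change_rates) > 1))
    stop_encar("fractions must lie in [0, 1]")
  structure(list(seed = as.integer(seed), grid_size = grid_size,
                 n_uzhyds = n_uzhyds, class_mix = class_mix,
                 change_rates = change_rates, climate = climate,
                 productivity = productivity, use_levels = use_levels,
                 exploitable_fraction = exploitable_fraction,
                 river_thresholds = river_thresholds,
                 epochs = epochs, n_years = n_years),
            class = "enca_scenario")
}

# smooth standardized random field via iterated 3x3 blur of white noise
smooth_field <- function(nr, nc, seed, iters = 20) {
  set.seed(seed)
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  for (i in seq_len(iters)) {
    up <- z[c(1, seq_len(nr - 1)), , drop = FALSE]
    down <- z[c(seq_len(nr - 1) + 1, nr), , drop = FALSE]
    left <- z[, c(1, seq_len(nc - 1)), drop = FALSE]
    right <- z[, c(seq_len(nc - 1) + 1, nc), drop = FALSE]
    z <- (z + up + down + left + right) / 5
  }
  (z - mean(z)) / stats::sd(z)
}

#' Generate the opening-epoch frame of a synthetic watershed
#'
#' Builds the epoch-0 land-cover grid (classes laid out along a smooth
#' pseudo-elevation field so realized class fractions match `class_mix`
#' exactly up to integer pixel counts), a Voronoi partition into UZHYDs with
#' an acyclic nearest-to-outlet downstream topology, and one river reach per
#' UZHYD with discharge accumulated downstream.
#'
#' @param scenario An `enca_scenario`.
#' @return List with `grid_t0` (`epoch_grid`), `catchments`
#'   (`catchment_set`), `reaches` (data.frame incl. ecological status at
#'   both epochs), `elevation` (matrix, for reuse by surfaces).
#' @export
generate_epoch0 <- function(scenario) {
  nr <- scenario$grid_size[1]; nc <- scenario$grid_size[2]
  n <- nr * nc

  # land cover: quantile slicing of a smooth field, ordered low -> high
  # "elevation": water, wetland, arable, artificial, permanent crops,
  # pasture, forest, shrub, bare, glacier
  elev <- smooth_field(nr, nc, derive_seed(scenario$seed, 1L))
  ord <- c(9L, 8L, 2L, 1L, 4L, 3L, 5L, 6L, 7L, 10L)
  frac <- scenario$class_mix[as.character(ord)]
  frac[is.na(frac)] <- 0
  bounds <- round(cumsum(frac) * n)
  bounds[length(bounds)] <- n
  r <- rank(elev, ties.method = "first")
  slot <- findInterval(r - 1, c(0, bounds), rightmost.closed = FALSE)
  v <- matrix(ord[pmin(slot, length(ord))], nr, nc)
  grid_t0 <- epoch_grid(v, epoch = scenario$epochs[1])

  # Voronoi UZHYDs around seeded points
  set.seed(derive_seed(scenario$seed, 2L))
  pts <- sample.int(n, scenario$n_uzhyds)
  pr <- ((pts - 1L) %% nr) + 1L
  pc <- ((pts - 1L) %/% nr) + 1L
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  D <- vapply(seq_len(scenario$n_uzhyds),
              function(k) as.vector((rows - pr[k])^2 + (cols - pc[k])^2),
              numeric(n))
  zone <- matrix(max.col(-D, ties.method = "first"), nr, nc)
  zone_grid <- epoch_grid(zone, epoch = "frame")

  # downstream topology: strictly decreasing distance to the outlet seed,
  # preferring raster-adjacent catchments
  outlet <- which.min(elev[pts])
  d_out <- sqrt((pr - pr[outlet])^2 + (pc - pc[outlet])^2)
  adj <- zone_adjacency(zone)
  ds <- rep(NA_integer_, scenario$n_uzhyds)
  for (u in seq_len(scenario$n_uzhyds)) {
    if (u == outlet) next
    nb <- adj[[u]]
    cand <- nb[d_out[nb] < d_out[u]]
    if (!length(cand)) cand <- which(d_out < d_out[u])
    ds[u] <- cand[which.min(d_out[cand])]
  }
  encat <- ((rank(pc, ties.method = "first") - 1L) %/% 4L) + 1L
  uz <- data.frame(uzhyd_id = seq_len(scenario$n_uzhyds),
                   encat_id = encat, downstream_id = ds)
  catchments <- catchment_set(uz, zone_grid)

  # one reach per uzhyd, specific discharge ~10 l/s/km2 accumulated
  areas <- uzhyd_areas(catchments)
  area_km2 <- unname(areas[as.character(uz$uzhyd_id)]) / 100
  set.seed(derive_seed(scenario$seed, 3L))
  local_q <- 0.01 * area_km2 * stats::runif(length(area_km2), 0.8, 1.2)
  q <- stats::setNames(local_q, uz$uzhyd_id)
  for (u in order(-d_out)) {            # headwaters first
    if (!is.na(ds[u])) q[[as.character(ds[u])]] <-
        q[[as.character(ds[u])]] + q[[as.character(u)]]
  }
  st0 <- sample(1:5, length(area_km2), replace = TRUE,
                prob = c(0.25, 0.35, 0.25, 0.10, 0.05))
  st1 <- pmin(5L, pmax(1L, st0 + sample(c(-1L, 0L, 1L), length(st0),
                                        replace = TRUE,
                                        prob = c(0.15, 0.6, 0.25))))
  reaches <- data.frame(reach_id = uz$uzhyd_id, uzhyd_id = uz$uzhyd_id,
                        length_km = round(1.5 * sqrt(area_km2), 3),
                        discharge_m3s = unname(q[as.character(uz$uzhyd_id)]),
                        status_t0 = st0, status_t1 = st1)
  reaches <- classify_reaches(reaches, scenario$river_thresholds)

  list(grid_t0 = grid_t0, catchments = catchments, reaches = reaches,
       elevation = elev)
}

zone_adjacency <- function(zone) {
  nr <- nrow(zone); nc <- ncol(zone)
  pairs <- rbind(cbind(as.vector(zone[-nr, ]), as.vector(zone[-1, ])),
                 cbind(as.vector(zone[, -nc]), as.vector(zone[, -1])))
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  pairs <- unique(rbind(pairs, pairs[, 2:1, drop = FALSE]))
  ids <- sort(unique(as.vector(zone)))
  lapply(ids, function(u) sort(unique(pairs[pairs[, 1] == u, 2])))
}

#' Apply prescribed land-change processes to the opening grid
#'
#' For each process, exactly `round(rate x eligible cells)` cells are
#' converted, chosen by seeded sampling; every other cell is unchanged.
#' Processes: artificialisation (arable 2 -> artificial 1),
#' forest degradation (forest 5 -> transitional woodland 6), glacier
#' retreat (glacier 10 -> bare 7).
#'
#' @param grid_t0 Opening `epoch_grid` (DLCT codes).
#' @param scenario The `enca_scenario` holding `change_rates`.
#' @return Closing `epoch_grid` labelled with the second epoch.
#' @export
apply_change <- function(grid_t0, scenario) {
  v <- grid_t0$values
  set.seed(derive_seed(scenario$seed, 6L))
  procs <- list(c(2L, 1L, scenario$change_rates$artificialisation),
                c(5L, 6L, scenario$change_rates$forest_transition),
                c(10L, 7L, scenario$change_rates$glacier_retreat))
  for (p in procs) {
    eligible <- which(!is.na(v) & v == p[1])
    k <- round(p[3] * length(eligible))
    if (k > 0) {
      pick <- if (length(eligible) > 1) sample(eligible, k) else eligible
      v[pick] <- as.integer(p[2])
    }
  }
  g <- grid_t0
  g$values <- v
  g$epoch <- scenario$epochs[2]
  g
}

#' Generate climate/productivity surfaces and calibrated use tables
#'
#' Precipitation and NPP are smooth positive random fields; actual ET and
#' heterotrophic respiration are smooth 40-70% shares of them, so the water
#' surplus and NEP are strictly positive everywhere. Sectoral use tables are
#' calibrated so that per SELU, total net use equals
#' `use_level x accessible resource`, which makes the expected intensity
#' indices analytically known (`min(1, 1/use_level)` after capping).
#'
#' @param scenario An `enca_scenario`.
#' @param frame Output of [generate_epoch0()].
#' @return List: `precip_mm`, `aet_mm`, `npp_tc_ha`, `rh_tc_ha` (matrices),
#'   `water_use`, `carbon_use`, `health` (data.frames, long by epoch),
#'   `protected`, `barriers` (logical matrices).
#' @export
generate_surfaces <- function(scenario, frame) {
  nr <- scenario$grid_size[1]; nc <- scenario$grid_size[2]
  cl <- scenario$climate; pr <- scenario$productivity
  z1 <- smooth_field(nr, nc, derive_seed(scenario$seed, 4L))
  z2 <- smooth_field(nr, nc, derive_seed(scenario$seed, 14L))
  z3 <- smooth_field(nr, nc, derive_seed(scenario$seed, 5L))
  z4 <- smooth_field(nr, nc, derive_seed(scenario$seed, 15L))
  precip <- pmax(cl$precip_mean + cl$precip_sd * z1, 100)
  aet <- precip * (0.4 + 0.3 * stats::pnorm(z2))
  npp <- pmax(pr$npp_mean + pr$npp_sd * z3, 0.5)
  rh <- npp * (0.4 + 0.3 * stats::pnorm(z4))

  cs <- frame$catchments
  pxa <- cs$zone_grid$pixel_area_ha
  ids <- cs$uzhyds$uzhyd_id

  # accessible water surplus per uzhyd (mm -> hm3: 1 mm on 1 ha = 1e-5 hm3)
  p_hm3 <- zonal_sum(precip, cs) * pxa * 1e-5
  et_hm3 <- zonal_sum(aet, cs) * pxa * 1e-5
  ds <- stats::setNames(cs$uzhyds$downstream_id, ids)
  bal <- route_balance(
    data.frame(uzhyd_id = ids,
               precipitation_hm3 = unname(p_hm3[as.character(ids)]),
               evapotranspiration_hm3 = unname(et_hm3[as.character(ids)])),
    ds)
  surplus <- accessible_surplus(bal, scenario$exploitable_fraction)

  # accessible carbon resource per uzhyd/SELU
  npp_tc <- zonal_sum(npp, cs) * pxa
  rh_tc <- zonal_sum(rh, cs) * pxa
  nep_acc <- nep_accessible(nep(unname(npp_tc[as.character(ids)]),
                                unname(rh_tc[as.character(ids)])))

  lv <- function(x) if (length(x) == 2) x else rep(x, 2)
  wl <- lv(scenario$use_levels$water)
  clv <- lv(scenario$use_levels$carbon)
  epochs <- scenario$epochs

  water_use <- do.call(rbind, lapply(1:2, function(e) {
    net <- wl[e] * surplus
    # uniform 30% return flow; sector split municipal/agriculture/power
    wd <- cbind(municipal = 0.5, agriculture = 0.3, power = 0.2) [rep(1, length(net)), , drop = FALSE] * net / 0.7
    data.frame(selu_id = ids, epoch = epochs[e],
               withdrawal_municipal_hm3 = wd[, 1],
               withdrawal_agriculture_hm3 = wd[, 2],
               withdrawal_power_hm3 = wd[, 3],
               return_municipal_hm3 = 0.3 * wd[, 1],
               return_agriculture_hm3 = 0.3 * wd[, 2],
               return_power_hm3 = 0.3 * wd[, 3])
  }))

  carbon_use <- do.call(rbind, lapply(1:2, function(e) {
    tot <- clv[e] * nep_acc
    data.frame(selu_id = ids, epoch = epochs[e],
               crops_harvest_tc = 0.4 * tot,
               wood_removals_tc = 0.5 * tot,
               animal_withdrawals_tc = 0.1 * tot)
  }))

  set.seed(derive_seed(scenario$seed, 7L))
  wq <- stats::runif(length(ids), 0.75, 1)
  bio <- stats::runif(length(ids), 0.75, 1)
  vul <- stats::runif(length(ids), 0.75, 1)
  drop1 <- stats::runif(length(ids), 0, 0.08)
  health <- rbind(
    data.frame(selu_id = ids, epoch = epochs[1], water_quality = wq,
               biodiversity_change = bio, vulnerability = vul),
    data.frame(selu_id = ids, epoch = epochs[2],
               water_quality = pmax(0, wq - drop1),
               biodiversity_change = pmax(0, bio - drop1),
               vulnerability = pmax(0, vul - drop1)))

  zprot <- smooth_field(nr, nc, derive_seed(scenario$seed, 8L))
  protected <- zprot > stats::quantile(zprot, 0.8)
  set.seed(derive_seed(scenario$seed, 9L))
  road_row <- sample.int(nr, 1)
  barriers <- matrix(FALSE, nr, nc)
  barriers[road_row, ] <- TRUE

  list(precip_mm = precip, aet_mm = aet, npp_tc_ha = npp, rh_tc_ha = rh,
       water_use = water_use, carbon_use = carbon_use, health = health,
       protected = protected, barriers = barriers)
}

#' Generate a complete synthetic watershed
#'
#' Convenience wrapper running [generate_epoch0()], [apply_change()] and
#' [generate_surfaces()]; the result can be written to disk with
#' [write_watershed()] in exactly the formats the pipeline consumes.
#'
#' @param scenario An `enca_scenario`.
#' @return List with all generated layers, tables and the scenario itself.
#' @export
generate_watershed <- function(scenario = enca_scenario()) {
  frame <- generate_epoch0(scenario)
  grid_t1 <- apply_change(frame$grid_t0, scenario)
  surfaces <- generate_surfaces(scenario, frame)
  c(frame[c("grid_t0", "catchments", "reaches")],
    list(grid_t1 = grid_t1), surfaces, list(scenario = scenario))
}
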