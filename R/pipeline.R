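#' Run configuration for the accounting pipeline
#'
#' Validated configuration for [run_enca()]. Unknown keys are rejected so a
#' typo never silently falls back to a default.
#'
#' @param input_dir Directory holding the input file set (see
#'   [write_watershed()] for names and formats).
#' @param out_dir Directory for the account tables (created if needed).
#' @param epochs Two epoch labels matching the `lc_<epoch>.asc` files.
#' @param n_years Period length in years.
#' @param exploitable_fraction Correction factor for accessible water.
#' @param river_thresholds Discharge cut-offs (m3/s) for river size classes.
#' @param srkm_scale SRKM normalisation constant.
#' @param w_intensity Intensity weight in the unit-value average.
#' @param health_weights Length-3 weights of the health components.
#' @param hotspot_threshold Minimum capped-index decline flagged as hotspot.
#' @param scheme Path to a classification-scheme YAML, or `NULL` for the
#'   default 10-class scheme (inputs then must already be in DLCT codes).
#' @param green_threshold Green weight at or above which a class counts as
#'   green fabric for the fragmentation index.
#' @return Object of class `enca_config` (a validated list).
#' @export
enca_config <- function(input_dir, out_dir,
                        epochs = c("2000", "2012"), n_years = 12,
                        exploitable_fraction = 0.5,
                        river_thresholds = c(0.3, 1.0), srkm_scale = 1,
                        w_intensity = 0.5, health_weights = c(1, 1, 1) / 3,
                        hotspot_threshold = 0.1, scheme = NULL,
                        green_threshold = 0.5) {
  cfg <- list(input_dir = input_dir, out_dir = out_dir,
              epochs = as.character(epochs), n_years = n_years,
              exploitable_fraction = exploitable_fraction,
              river_thresholds = river_thresholds, srkm_scale = srkm_scale,
              w_intensity = w_intensity, health_weights = health_weights,
              hotspot_threshold = hotspot_threshold, scheme = scheme,
              green_threshold = green_threshold)
  structure(cfg, class = "enca_config")
}

#' @rdname enca_config
#' @param path YAML file with any subset of the `enca_config()` arguments.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(enca_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop_encar("unknown configuration keys: %s",
               paste(unknown, collapse = ", "))
  y$epochs <- unlist(y$epochs)
  y$river_thresholds <- unlist(y$river_thresholds)
  y$health_weights <- unlist(y$health_weights %||%
                               formals(enca_config)$health_weights)
  do.call(enca_config, y)
}

#' Run the full accounting pipeline
#'
#' Executes the account production sequence frame -> land -> water ->
#' carbon -> infrastructure -> capability on an input file set, writes the
#' per-account CSV tables plus the consolidated four-table account set
#' (stocks & flows, accessible resource, use, indices) and a JSON run
#' manifest, and returns all tables invisibly. The pipeline is fully
#' deterministic: identical inputs and configuration give byte-identical
#' outputs.
#'
#' @param config An `enca_config` (or path to its YAML).
#' @param stages Character subset of
#'   `c("land", "water", "carbon", "infrastructure", "capability")` to
#'   write; the frame is always produced, and capability implies all.
#' @return Invisible named list of the computed tables.
#' @export
run_enca <- function(config, stages = c("land", "water", "carbon",
                                        "infrastructure", "capability")) {
  if (is.character(config)) config <- read_config(config)
  if ("capability" %in% stages)
    stages <- union(stages, c("land", "water", "carbon", "infrastructure"))
  ind <- config$input_dir
  outd <- config$out_dir
  dir.create(outd, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(ind, ...)
  o <- function(...) file.path(outd, ...)
  ep <- config$epochs

  scheme <- if (is.null(config$scheme)) default_scheme() else
    read_scheme(config$scheme)

  # --- frame ---------------------------------------------------------
  g0 <- read_ascii_grid(p(sprintf("lc_%s.asc", ep[1])), epoch = ep[1])
  g1 <- read_ascii_grid(p(sprintf("lc_%s.asc", ep[2])), epoch = ep[2])
  if (!is.null(config$scheme)) {
    g0 <- reclassify_to_dlct(g0, scheme)
    g1 <- reclassify_to_dlct(g1, scheme)
  }
  zones <- read_ascii_grid(p("uzhyd.asc"), epoch = "frame")
  cs <- catchment_set(read_table(p("catchments.csv")), zones)
  selus <- build_selus(g0, cs)
  validate_selus(selus, cs)
  reaches <- classify_reaches(read_table(p("rivers.csv")),
                              config$river_thresholds)
  write_table(selus, o("selu.csv"))
  out <- list(selus = selus)

  # --- land ----------------------------------------------------------
  tm <- transition_matrix(g0, g1, scheme)
  sfa <- stock_flow_account(tm)
  drivers <- classify_flows(tm, default_driver_scheme())
  tms <- transition_matrix(g0, g1, scheme, zones = cs)
  selu_flows <- do.call(rbind, lapply(names(tms), function(z) {
    a <- stock_flow_account(tms[[z]])
    data.frame(selu_id = as.integer(z),
               consumption_ha = sum(a$consumption_ha),
               formation_ha = sum(a$formation_ha))
  }))
  if ("land" %in% stages) {
    write_table(cbind(scope = "territory", sfa), o("land_stocks_flows.csv"))
    write_table(data.frame(scope = "territory", driver = names(drivers),
                           area_ha = unname(drivers)),
                o("land_drivers.csv"))
    write_table(selu_flows, o("land_selu_flows.csv"))
  }
  out$land <- list(transition = tm, account = sfa, drivers = drivers,
                   selu_flows = selu_flows)

  # --- water ---------------------------------------------------------
  pxa <- zones$pixel_area_ha
  precip <- read_ascii_surface(p("precip_mm.asc"))
  aet <- read_ascii_surface(p("aet_mm.asc"))
  ids <- cs$uzhyds$uzhyd_id
  key <- as.character(ids)
  bal <- route_balance(
    data.frame(uzhyd_id = ids,
               precipitation_hm3 = unname((zonal_sum(precip, cs) * pxa * 1e-5)[key]),
               evapotranspiration_hm3 = unname((zonal_sum(aet, cs) * pxa * 1e-5)[key])),
    stats::setNames(cs$uzhyds$downstream_id, ids))
  surplus <- accessible_surplus(bal, config$exploitable_fraction)
  wuse <- read_table(p("water_use.csv"))
  water_by_epoch <- lapply(ep, function(e) {
    u <- wuse[wuse$epoch == e, ]
    u <- u[match(ids, u$selu_id), ]
    wd <- rowSums(u[, grep("^withdrawal_", names(u))])
    rt <- rowSums(u[, grep("^return_", names(u))])
    net <- wd - rt
    data.frame(selu_id = ids, epoch = e,
               accessible_surplus_hm3 = surplus,
               withdrawals_hm3 = wd, returns_hm3 = rt,
               net_consumption_hm3 = net,
               raw_intensity = water_intensity_index(surplus, net))
  })
  names(water_by_epoch) <- ep
  riv <- river_account(reaches, config$srkm_scale)
  if ("water" %in% stages) {
    write_table(cbind(bal[, 1, drop = FALSE],
                      round(bal[, -1], 9)), o("water_balance.csv"))
    write_table(do.call(rbind, water_by_epoch), o("water_accounts.csv"))
    write_table(riv, o("river_accounts.csv"))
  }
  out$water <- list(balance = bal, accounts = water_by_epoch, rivers = riv)

  # --- carbon --------------------------------------------------------
  npp_s <- read_ascii_surface(p("npp_tc_ha.asc"))
  rh_s <- read_ascii_surface(p("rh_tc_ha.asc"))
  npp_tc <- unname((zonal_sum(npp_s, cs) * pxa)[key])
  rh_tc <- unname((zonal_sum(rh_s, cs) * pxa)[key])
  nep_raw <- nep(npp_tc, rh_tc)
  nep_acc <- nep_accessible(nep_raw)
  cuse <- read_table(p("carbon_use.csv"))
  carbon_by_epoch <- lapply(ep, function(e) {
    u <- cuse[cuse$epoch == e, ]
    u <- u[match(ids, u$selu_id), ]
    tot <- u$crops_harvest_tc + u$wood_removals_tc + u$animal_withdrawals_tc
    data.frame(selu_id = ids, epoch = e, npp_tc = npp_tc, rh_tc = rh_tc,
               nep_tc = nep_raw, nep_accessible_tc = nep_acc,
               use_total_tc = tot,
               raw_intensity = carbon_intensity_index(nep_acc, tot))
  })
  names(carbon_by_epoch) <- ep
  if ("carbon" %in% stages)
    write_table(do.call(rbind, carbon_by_epoch), o("carbon_accounts.csv"))
  out$carbon <- list(accounts = carbon_by_epoch)

  # --- infrastructure ------------------------------------------------
  protected <- read_ascii_grid(p("protected.asc"))$values
  barriers <- read_ascii_grid(p("barriers.asc"))$values
  prot_share <- zonal_mean(protected, cs)[key]
  nv <- nature_value_index(unname(prot_share))
  srkm_by_selu <- stats::setNames(
    vapply(ids, function(u) {
      r <- reaches[reaches$uzhyd_id == u, ]
      sum(srkm(r$length_km, r$discharge_m3s, config$srkm_scale))
    }, numeric(1)), key)
  infra_by_epoch <- lapply(seq_along(ep), function(e) {
    g <- list(g0, g1)[[e]]
    green <- unname(green_index(g, scheme, cs)[key])
    gw <- scheme$green_weight
    green_mask <- matrix(gw[as.character(g$values)] >= config$green_threshold,
                         nrow(g$values), ncol(g$values))
    barrier_all <- barriers > 0 | (!is.na(g$values) & g$values == 1L)
    frag <- unname(fragmentation_index(green_mask, cs, barrier_all)[key])
    nl <- nlep(green, frag, nv, selus$area_ha)
    st <- reaches[[paste0("status_t", e - 1)]]
    cond <- vapply(ids, function(u) {
      r <- reaches$uzhyd_id == u
      w <- srkm(reaches$length_km[r], reaches$discharge_m3s[r],
                config$srkm_scale)
      if (!any(r) || sum(w) == 0) return(NA_real_)
      sum(w * condition_potential(st[r])) / sum(w)
    }, numeric(1))
    nr_ <- nrep(cond, nv, unname(srkm_by_selu[key]))
    data.frame(selu_id = ids, epoch = ep[e], green_index = green,
               fragmentation_index = frag, nature_value_index = nv,
               nlep = nl$nlep, nlep_quantity = nl$nlep_quantity,
               condition_potential = cond, nrep = nr_$nrep,
               nrep_quantity = nr_$nrep_quantity,
               teip = teip(nl$nlep_quantity, nr_$nrep_quantity))
  })
  names(infra_by_epoch) <- ep
  health_tab <- read_table(p("health.csv"))
  health_by_epoch <- lapply(ep, function(e) {
    h <- health_tab[health_tab$epoch == e, ]
    h <- h[match(ids, h$selu_id), ]
    data.frame(selu_id = ids, epoch = e,
               health = health_index(h$water_quality, h$biodiversity_change,
                                     h$vulnerability, config$health_weights))
  })
  names(health_by_epoch) <- ep
  infra_all <- do.call(rbind, infra_by_epoch)
  infra_all$teip_change_per_yr <- with(
    infra_by_epoch,
    rep(yearly_change(infra_by_epoch[[1]]$teip, infra_by_epoch[[2]]$teip,
                      config$n_years), length(ep)))
  if ("infrastructure" %in% stages) {
    write_table(infra_all, o("infrastructure_accounts.csv"))
    write_table(do.call(rbind, health_by_epoch), o("health_indices.csv"))
  }
  out$infrastructure <- list(accounts = infra_by_epoch,
                             health = health_by_epoch)

  # --- capability ----------------------------------------------------
  teip_rate <- yearly_change(infra_by_epoch[[1]]$teip,
                             infra_by_epoch[[2]]$teip, config$n_years)
  cap_by_epoch <- lapply(seq_along(ep), function(e) {
    h <- health_by_epoch[[e]]$health
    # infrastructure intensity: baseline 1 at the opening epoch, then
    # 1 + yearly TEIP change (decline < 1), capped like the others
    infra_raw <- if (e == 1) rep(1, length(ids)) else
      pmax(0, 1 + teip_rate)
    capability_table(
      selus,
      water = data.frame(selu_id = ids,
                         raw_intensity = water_by_epoch[[e]]$raw_intensity,
                         health = h),
      carbon = data.frame(selu_id = ids,
                          raw_intensity = carbon_by_epoch[[e]]$raw_intensity,
                          health = h),
      infrastructure = data.frame(selu_id = ids, raw_intensity = infra_raw,
                                  health = h),
      w_intensity = config$w_intensity)
  })
  names(cap_by_epoch) <- ep
  hotspots <- hotspot_detection(cap_by_epoch[[1]], cap_by_epoch[[2]],
                                config$hotspot_threshold)
  summ <- watershed_summary(cap_by_epoch[[1]], cap_by_epoch[[2]],
                            config$n_years)
  if ("capability" %in% stages) {
    for (e in ep)
      write_table(cap_by_epoch[[e]], o(sprintf("capability_%s.csv", e)))
    write_table(hotspots, o("hotspots.csv"))
    write_table(data.frame(index = names(summ$means),
                           mean = unname(summ$means),
                           change_per_yr = unname(
                             summ$change_per_yr[names(summ$means)])),
                o("watershed_summary.csv"))
    write_account_tables(out, cap_by_epoch, water_by_epoch, carbon_by_epoch,
                         sfa, ep, outd)
  }
  out$capability <- cap_by_epoch
  out$hotspots <- hotspots
  out$summary <- summ

  manifest <- list(package = "encar",
                   version = as.character(utils::packageVersion("encar")),
                   config = unclass(config)[
                     !names(config) %in% c("input_dir", "out_dir")],
                   epochs = ep, n_selus = length(ids))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             o("run_manifest.json"))
  invisible(out)
}

# consolidated four-table account set (long format)
write_account_tables <- function(out, cap_by_epoch, water_by_epoch,
                                 carbon_by_epoch, sfa, ep, outd) {
  o <- function(...) file.path(outd, ...)
  stocks <- rbind(
    data.frame(scope = "territory", account = "land",
               item = paste0("class_", sfa$class), epoch = ep[1],
               value = sfa$opening_ha),
    data.frame(scope = "territory", account = "land",
               item = paste0("class_", sfa$class), epoch = ep[2],
               value = sfa$closing_ha),
    do.call(rbind, lapply(ep, function(e) {
      w <- carbon_by_epoch[[e]]
      data.frame(scope = w$selu_id, account = "carbon", item = "nep_tc",
                 epoch = e, value = w$nep_tc)
    })))
  accessible <- do.call(rbind, lapply(ep, function(e) rbind(
    data.frame(scope = water_by_epoch[[e]]$selu_id, account = "water",
               item = "accessible_surplus_hm3", epoch = e,
               value = water_by_epoch[[e]]$accessible_surplus_hm3),
    data.frame(scope = carbon_by_epoch[[e]]$selu_id, account = "carbon",
               item = "nep_accessible_tc", epoch = e,
               value = carbon_by_epoch[[e]]$nep_accessible_tc))))
  use <- do.call(rbind, lapply(ep, function(e) rbind(
    data.frame(scope = water_by_epoch[[e]]$selu_id, account = "water",
               item = "net_consumption_hm3", epoch = e,
               value = water_by_epoch[[e]]$net_consumption_hm3),
    data.frame(scope = carbon_by_epoch[[e]]$selu_id, account = "carbon",
               item = "use_total_tc", epoch = e,
               value = carbon_by_epoch[[e]]$use_total_tc))))
  indices <- do.call(rbind, lapply(ep, function(e) {
    d <- cap_by_epoch[[e]]
    do.call(rbind, lapply(c("water", "carbon", "infrastructure"),
                          function(a)
      data.frame(scope = d$selu_id, account = a, item = "unit_value",
                 epoch = e, value = d[[paste0("uv_", a)]])))
  }))
  write_table(stocks, o("account_stocks_flows.csv"))
  write_table(accessible, o("account_accessible.csv"))
  write_table(use, o("account_use.csv"))
  write_table(indices, o("account_indices.csv"))
  invisible(NULL)
}
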