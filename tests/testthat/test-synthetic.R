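test_that("generation is reproducible and honours the class mix", {
  sc <- enca_scenario(seed = 11)
  a <- generate_watershed(sc)
  b <- generate_watershed(sc)
  expect_identical(a$grid_t0$values, b$grid_t0$values)
  expect_identical(a$grid_t1$values, b$grid_t1$values)
  expect_identical(a$reaches, b$reaches)
  expect_identical(a$precip_mm, b$precip_mm)
  expect_identical(a$water_use, b$water_use)

  # realized class fractions within 2 percentage points of the request
  fr <- class_areas(a$grid_t0) / sum(class_areas(a$grid_t0))
  req <- sc$class_mix[names(fr)]
  expect_true(all(abs(fr - req) < 0.02))

  # degenerate mix: a single class fills the grid
  sc1 <- enca_scenario(seed = 2, class_mix = c(`5` = 1), n_uzhyds = 4,
                       grid_size = c(40L, 40L),
                       change_rates = list(artificialisation = 0,
                                           forest_transition = 0,
                                           glacier_retreat = 0))
  g <- generate_epoch0(sc1)$grid_t0
  expect_true(all(g$values == 5L))
})

test_that("generated frames pass the geoframe validators", {
  for (seed in c(3, 17)) {
    ws <- generate_watershed(enca_scenario(seed = seed,
                                           grid_size = c(60L, 60L),
                                           n_uzhyds = 8))
    expect_silent(validate_catchments(ws$catchments))
    selus <- build_selus(ws$grid_t0, ws$catchments)
    expect_silent(validate_selus(selus, ws$catchments))
    # river network drains to a single outlet with accumulating discharge
    ds <- ws$catchments$uzhyds$downstream_id
    expect_equal(sum(is.na(ds)), 1)
    outlet <- ws$catchments$uzhyds$uzhyd_id[is.na(ds)]
    q <- setNames(ws$reaches$discharge_m3s, ws$reaches$uzhyd_id)
    ups <- ws$catchments$uzhyds$uzhyd_id[!is.na(ds) & ds == outlet]
    expect_true(all(q[as.character(outlet)] > q[as.character(ups)]))
  }
})

test_that("land change converts exactly the prescribed cell counts", {
  sc <- enca_scenario(seed = 5)
  ws <- generate_watershed(sc)
  v0 <- ws$grid_t0$values; v1 <- ws$grid_t1$values
  n_arable <- sum(v0 == 2L)
  n_forest <- sum(v0 == 5L)
  n_glacier <- sum(v0 == 10L)
  expect_equal(sum(v0 == 2L & v1 == 1L),
               round(sc$change_rates$artificialisation * n_arable))
  expect_equal(sum(v0 == 5L & v1 == 6L),
               round(sc$change_rates$forest_transition * n_forest))
  expect_equal(sum(v0 == 10L & v1 == 7L),
               round(sc$change_rates$glacier_retreat * n_glacier))
  # nothing else moved
  moved <- v0 != v1
  legal <- (v0 == 2L & v1 == 1L) | (v0 == 5L & v1 == 6L) |
    (v0 == 10L & v1 == 7L)
  expect_true(all(moved == legal))
  # zero rates: identical grid
  sc0 <- enca_scenario(seed = 5,
                       change_rates = list(artificialisation = 0,
                                           forest_transition = 0,
                                           glacier_retreat = 0))
  ws0 <- generate_epoch0(sc0)
  expect_identical(apply_change(ws0$grid_t0, sc0)$values, ws0$grid_t0$values)
})

test_that("use tables are calibrated to the accessible resource", {
  # use_level 1: net use equals the accessible resource, capped index 1
  sc <- enca_scenario(seed = 8, grid_size = c(60L, 60L), n_uzhyds = 6,
                      use_levels = list(water = 1, carbon = 1))
  ws <- generate_watershed(sc)
  cu <- ws$carbon_use[ws$carbon_use$epoch == sc$epochs[1], ]
  tot <- cu$crops_harvest_tc + cu$wood_removals_tc + cu$animal_withdrawals_tc
  cs <- ws$catchments
  pxa <- cs$zone_grid$pixel_area_ha
  ids <- as.character(cu$selu_id)
  nep_acc <- nep_accessible(nep(zonal_sum(ws$npp_tc_ha, cs) * pxa,
                                zonal_sum(ws$rh_tc_ha, cs) * pxa))
  expect_equal(tot, unname(nep_acc[ids]))
  expect_equal(cap_index(carbon_intensity_index(unname(nep_acc[ids]), tot)),
               rep(1, length(tot)))
})
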