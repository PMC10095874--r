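test_that("reclassification applies the mapping and conserves area", {
  src <- data.frame(code = c(112L, 211L, 311L),
                    name = c("urban", "arable", "forest"))
  dlct <- data.frame(code = c(1L, 2L, 5L),
                     name = c("artificial", "arable", "forest"))
  sch <- classification_scheme(
    src, dlct, c(`112` = 1L, `211` = 2L, `311` = 5L),
    c(`1` = 0, `2` = 0.3, `5` = 1))

  g <- toy_grid(c(112L, 211L, 311L), 1, 3)
  expect_equal(as.vector(reclassify_to_dlct(g, sch)$values), c(1L, 2L, 5L))

  # identity scheme leaves any grid unchanged
  id <- default_scheme()
  set.seed(7)
  g2 <- toy_grid(sample(1:10, 16, replace = TRUE), 4, 4)
  expect_identical(reclassify_to_dlct(g2, id)$values, g2$values)

  # 4x4 with 7 cells of 211 and 9 of 311: areas move classwise, total kept
  g3 <- toy_grid(c(rep(211L, 7), rep(311L, 9)), 4, 4)
  out <- reclassify_to_dlct(g3, sch)
  a <- class_areas(out)
  expect_equal(unname(a[c("2", "5")]), c(7, 9))
  expect_equal(sum(a), 16)
  expect_equal(sum(class_areas(g3)), sum(a))

  # unmapped code errors, naming code and affected cells
  g4 <- toy_grid(c(112L, 999L, 999L), 1, 3)
  expect_error(reclassify_to_dlct(g4, sch), "999.*2 cells")
})

test_that("nodata survives reclassification and is excluded from areas", {
  sch <- default_scheme()
  v <- matrix(c(1L, NA, 5L, NA), 2, 2)
  out <- reclassify_to_dlct(epoch_grid(v, "t0"), sch)
  expect_identical(is.na(out$values), is.na(v))
  expect_equal(sum(class_areas(out)), 2)
})

test_that("dominant cover picks maximal area with ties to lowest code", {
  zones <- toy_grid(rep(1L, 10), 1, 10, "frame")
  expect_equal(unname(dominant_cover(toy_grid(rep(5L, 10), 1, 10), zones)),
               5L)
  # 60/40 majority
  g <- toy_grid(c(rep(2L, 6), rep(5L, 4)), 1, 10)
  expect_equal(unname(dominant_cover(g, zones)), 2L)
  # 50/50 tie breaks to the lower code
  g <- toy_grid(c(rep(5L, 5), rep(2L, 5)), 1, 10)
  expect_equal(unname(dominant_cover(g, zones)), 2L)
  # zone with no data at all is an error naming the zone
  gna <- toy_grid(rep(NA_integer_, 10), 1, 10)
  expect_error(dominant_cover(gna, zones), "zones with no non-nodata.*1")
})

test_that("dominant cover agrees with exhaustive per-pixel tabulation", {
  for (seed in 1:8) {
    pair <- random_dlct_pair(seed, 25, 25)
    zg <- random_zone_grid(seed + 100, 25, 25, 5)
    got <- dominant_cover(pair$g0, zg)
    want <- oracle_dominant(pair$g0$values, zg$values)
    expect_equal(got, want[names(got)])
  }
})

test_that("SELUs partition the territory and keep stable labels", {
  zg <- random_zone_grid(3, 30, 30, 6)
  uz <- data.frame(uzhyd_id = 1:6, encat_id = c(1, 1, 1, 2, 2, 2),
                   downstream_id = c(NA, 1, 2, 1, 4, 5))
  cs <- catchment_set(uz, zg)
  g <- random_dlct_pair(11, 30, 30)$g0
  selus <- build_selus(g, cs)
  expect_equal(nrow(selus), 6)
  expect_equal(sum(selus$area_ha), 900)
  expect_silent(validate_selus(selus, cs))
  # unchanged majorities give identical labelling at the next epoch
  selus2 <- build_selus(g, cs)
  expect_identical(selus$dlct_code, selus2$dlct_code)
})

test_that("catchment validation catches cycles and orphan zones", {
  zg <- random_zone_grid(5, 12, 12, 3)
  uz_cyc <- data.frame(uzhyd_id = 1:3, encat_id = 1,
                       downstream_id = c(2, 3, 1))
  expect_error(catchment_set(uz_cyc, zg), "cycle")
  uz_bad <- data.frame(uzhyd_id = 1:2, encat_id = 1,
                       downstream_id = c(NA, 1))
  expect_error(catchment_set(uz_bad, zg), "missing from table")
})

test_that("river reaches are classified by half-open discharge intervals", {
  r <- data.frame(reach_id = 1:3, length_km = c(1, 2, 3),
                  discharge_m3s = c(3, 5, 100))
  out <- classify_reaches(r, c(5, 50))
  expect_equal(as.character(out$size_class), c("small", "medium", "large"))
  # enumerated intervals
  r2 <- data.frame(reach_id = 1:3, length_km = 1,
                   discharge_m3s = c(1, 10, 100))
  expect_equal(as.character(classify_reaches(r2, c(5, 50))$size_class),
               c("small", "medium", "large"))
  # order invariance
  r3 <- r2[c(3, 1, 2), ]
  out3 <- classify_reaches(r3, c(5, 50))
  expect_equal(as.character(out3$size_class)[order(r3$reach_id)],
               c("small", "medium", "large"))
  expect_error(classify_reaches(data.frame(reach_id = 1, length_km = 1,
                                           discharge_m3s = -2), c(5, 50)),
               "negative discharge")
  expect_error(classify_reaches(r2, c(50, 5)), "strictly increasing")
})
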