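test_that("identical epochs give a diagonal transition matrix", {
  g <- random_dlct_pair(1, 15, 15)$g0
  g1 <- g; g1$epoch <- "t1"
  T <- transition_matrix(g, g1)
  expect_true(all(T$area[row(T$area) != col(T$area)] == 0))
  a <- stock_flow_account(T)
  expect_true(all(a$consumption_ha == 0))
  expect_true(all(a$formation_ha == 0))
})

test_that("a known conversion lands in the right matrix cell", {
  v0 <- matrix(c(2L, 2L, 2L, 5L, 5L, 5L, 3L, 3L, 3L), 3, 3)
  v1 <- v0; v1[1:2] <- 1L            # two arable cells artificialised
  T <- transition_matrix(epoch_grid(v0, "t0"), epoch_grid(v1, "t1"))
  expect_equal(T$area["2", "1"], 2)
  expect_equal(sum(T$area), 9)
  a <- stock_flow_account(T)
  arable <- a[a$class == 2, ]
  expect_equal(arable$consumption_ha, 2)
  expect_equal(arable$formation_ha, 0)
  expect_equal(arable$net_change_ha, -2)
})

test_that("transition matrix equals per-pixel enumeration; margins match stocks", {
  for (seed in 1:6) {
    pair <- random_dlct_pair(seed, 50, 50, change_frac = 0.2)
    T <- transition_matrix(pair$g0, pair$g1)
    want <- oracle_crosstab(pair$g0$values, pair$g1$values, T$classes)
    expect_equal(unname(T$area), unname(want))
    a0 <- class_areas(pair$g0); a1 <- class_areas(pair$g1)
    expect_equal(rowSums(T$area)[names(a0)], a0)
    expect_equal(colSums(T$area)[names(a1)], a1)
  }
})

test_that("misaligned or off-scheme grids are rejected", {
  g <- random_dlct_pair(2, 10, 10)$g0
  h <- random_dlct_pair(2, 11, 10)$g0
  expect_error(transition_matrix(g, h), "not aligned")
  bad <- g; bad$values[1] <- 99L
  expect_error(transition_matrix(bad, g), "absent from scheme")
})

test_that("the artificialisation worked example reports +11%", {
  # opening 4,666 km2, closing 5,163 km2 of artificial land
  expect_equal(percent_change(4666, 5163), 11)
  expect_equal(percent_change(4666, 5163, whole = FALSE), 10.6515,
               tolerance = 1e-4)
})

test_that("flow classification partitions gross change by driver", {
  v0 <- matrix(c(2L, 2L, 5L, 5L, 6L, 6L, 3L, 3L, 9L), 3, 3)
  v1 <- v0
  v1[1] <- 1L   # arable -> artificial
  v1[3] <- 6L   # forest -> shrub
  v1[5] <- 5L   # shrub -> forest
  T <- transition_matrix(epoch_grid(v0, "t0"), epoch_grid(v1, "t1"))
  d <- classify_flows(T)
  expect_equal(unname(d["artificialisation"]), 1)
  expect_equal(unname(d["forest & shrub translation"]), 2)  # gross, both ways
  a <- stock_flow_account(T)
  expect_equal(sum(d), sum(a$consumption_ha))
  expect_equal(sum(d), sum(a$formation_ha))
  # diagonal matrix: all drivers zero
  T0 <- transition_matrix(epoch_grid(v0, "t0"), epoch_grid(v0, "t1"))
  expect_true(all(classify_flows(T0) == 0))
  # a scheme that misses a conversion errors with the pair named
  part <- driver_scheme(data.frame(from_code = 2L, to_code = 1L,
                                   driver = "artificialisation"))
  expect_error(classify_flows(T, part), "5 -> 6")
})

test_that("period chaining sums gross flows and keeps the balance identity", {
  v0 <- matrix(c(2L, 2L, 2L, 2L, 5L, 5L, 5L, 5L, 3L), 3, 3)
  v1 <- v0; v1[1] <- 1L
  v2 <- v1; v2[2] <- 1L
  mk <- function(a, b, e0, e1)
    stock_flow_account(transition_matrix(epoch_grid(a, e0),
                                         epoch_grid(b, e1)))
  a01 <- mk(v0, v1, "2000", "2006")
  a12 <- mk(v1, v2, "2006", "2012")
  ch <- chain_periods(list(a01, a12))
  expect_equal(attr(ch, "period"), c("2000", "2012"))
  expect_equal(ch$closing_ha,
               ch$opening_ha + ch$formation_ha - ch$consumption_ha)
  art <- ch[ch$class == 1, ]
  expect_equal(art$net_change_ha, 2)   # +1 then +1
  # single account chains to itself; non-consecutive periods error
  expect_identical(chain_periods(list(a01)), a01)
  expect_error(chain_periods(list(a12, a01)), "not consecutive")
  # chaining with an all-zero successor changes nothing
  a22 <- mk(v2, v2, "2012", "2018")
  ch2 <- chain_periods(list(a12, a22))
  expect_equal(ch2$consumption_ha, a12$consumption_ha)
  expect_equal(ch2$formation_ha, a12$formation_ha)
})

test_that("land closure holds per class and per SELU on random pairs", {
  for (seed in 1:10) {
    pair <- random_dlct_pair(seed, 20, 20, change_frac = 0.3)
    zg <- random_zone_grid(seed + 50, 20, 20, 4)
    Ts <- transition_matrix(pair$g0, pair$g1, zones = zg)
    tot <- 0
    for (T in Ts) {
      a <- stock_flow_account(T)
      expect_equal(a$closing_ha,
                   a$opening_ha + a$formation_ha - a$consumption_ha)
      expect_equal(sum(a$net_change_ha), 0)
      tot <- tot + sum(T$area)
    }
    expect_identical(tot, 400)   # exact area conservation across zones
  }
})
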