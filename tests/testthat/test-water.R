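test_that("routing accumulates runoff in topological order", {
  # single headwater: no upstream inflow
  b <- route_balance(data.frame(uzhyd_id = 1, precipitation_hm3 = 100,
                                evapotranspiration_hm3 = 60),
                     c(`1` = NA))
  expect_equal(b$upstream_inflow_hm3, 0)
  expect_equal(b$runoff_out_hm3, 40)

  # chain A -> B passes A's runoff downstream
  b2 <- route_balance(
    data.frame(uzhyd_id = c("A", "B"), precipitation_hm3 = c(50, 10),
               evapotranspiration_hm3 = c(20, 5)),
    c(A = "B", B = NA))
  expect_equal(b2$upstream_inflow_hm3[b2$uzhyd_id == "B"], 30)

  # closure identity holds exactly for every unit
  expect_equal(b2$closing_stock_hm3,
               b2$opening_stock_hm3 + b2$precipitation_hm3 +
                 b2$upstream_inflow_hm3 - b2$evapotranspiration_hm3 -
                 b2$runoff_out_hm3 - b2$net_abstraction_hm3)
})

test_that("routing on random trees matches brute-force accumulation", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 20
    parent <- c(NA, sapply(2:n, function(i) sample.int(i - 1, 1)))
    ds <- setNames(as.character(parent), as.character(1:n))
    P <- runif(n, 50, 150)
    ET <- runif(n, 10, 40)    # ET < P so nothing floors to zero
    b <- route_balance(data.frame(uzhyd_id = as.character(1:n),
                                  precipitation_hm3 = P,
                                  evapotranspiration_hm3 = ET), ds)
    # outlet inflow equals the sum of all upstream local runoffs (tree)
    local <- P - ET
    expect_equal(b$upstream_inflow_hm3[1], sum(local[-1]))
    # cross-check the whole inflow vector with a sweep-based oracle
    want <- oracle_accumulate(setNames(local, 1:n), ds)
    expect_equal(setNames(b$upstream_inflow_hm3, b$uzhyd_id), want)
  }
})

test_that("cycles in the downstream topology are detected", {
  expect_error(route_balance(
    data.frame(uzhyd_id = c("A", "B"), precipitation_hm3 = 1,
               evapotranspiration_hm3 = 0),
    c(A = "B", B = "A")), "cycle")
})

test_that("accessible surplus applies the correction factor and floor", {
  b <- data.frame(precipitation_hm3 = 100, upstream_inflow_hm3 = 0,
                  evapotranspiration_hm3 = 60)
  expect_equal(accessible_surplus(b, 1), 40)
  expect_equal(accessible_surplus(b, 0), 0)
  b$evapotranspiration_hm3 <- 150
  expect_equal(accessible_surplus(b, 1), 0)
  expect_error(accessible_surplus(b, 1.2), "\\[0, 1\\]")
  # monotone: non-decreasing in precipitation, non-increasing in ET
  s <- sapply(seq(0, 200, 25), function(p)
    accessible_surplus(data.frame(precipitation_hm3 = p,
                                  upstream_inflow_hm3 = 10,
                                  evapotranspiration_hm3 = 80), 0.5))
  expect_true(all(diff(s) >= 0))
})

test_that("municipal use scales with population and adds over zones", {
  expect_equal(estimate_municipal_use(0), 0)
  expect_equal(estimate_municipal_use(10000, 1e-4), 1)
  expect_equal(estimate_municipal_use(3000 + 7000, 1e-4),
               estimate_municipal_use(3000, 1e-4) +
                 estimate_municipal_use(7000, 1e-4))
})

test_that("water intensity index is surplus over net consumption", {
  u <- water_use(c(municipal = 30, power = 20), c(municipal = 10, power = 15))
  expect_equal(u$net_consumption, 25)
  expect_equal(water_intensity_index(50, u), 2)
  expect_equal(water_intensity_index(25, u), 1)
  expect_identical(water_intensity_index(50, 0), Inf)   # no-use sentinel
  expect_error(water_use(c(m = 5), c(m = 6)), "returns <= withdrawals")
  expect_error(water_intensity_index(-1, 5), "non-negative")
})

test_that("river accounts aggregate SRKM and status-change shares", {
  expect_equal(srkm(10, 2), 20)
  expect_equal(srkm(0, 5), 0)
  # SRKM is additive under splitting a reach at any point
  expect_equal(srkm(7.3, 4), srkm(2.1, 4) + srkm(5.2, 4))
  r <- data.frame(reach_id = 1:2, length_km = c(10, 5),
                  discharge_m3s = c(2, 4), size_class = "small",
                  status_t0 = c(2L, 2L), status_t1 = c(3L, 2L))
  acc <- river_account(r)
  all_row <- acc[acc$size_class == "all", ]
  expect_equal(all_row$srkm_total, 40)
  expect_equal(all_row$share_degraded, 0.5)   # equal-SRKM reaches
  expect_equal(all_row$share_degraded + all_row$share_improved +
                 all_row$share_stable, 1)
  expect_error(river_account(transform(r, status_t0 = c(0L, 2L))), "1\\.\\.5")
})
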