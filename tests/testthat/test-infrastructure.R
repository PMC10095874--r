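test_that("greenness is the area-weighted mean of class weights", {
  sch <- default_scheme()
  zones <- toy_grid(rep(1L, 10), 1, 10, "frame")
  expect_equal(unname(green_index(toy_grid(rep(5L, 10), 1, 10), sch, zones)),
               1)
  expect_equal(unname(green_index(toy_grid(rep(1L, 10), 1, 10), sch, zones)),
               0)
  half <- toy_grid(c(rep(5L, 5), rep(1L, 5)), 1, 10)
  expect_equal(unname(green_index(half, sch, zones)), 0.5)
})

test_that("fragmentation follows the effective-mesh ratio", {
  zones <- epoch_grid(matrix(1L, 8, 8), "frame")
  # one patch covering the whole SELU
  expect_equal(unname(fragmentation_index(matrix(TRUE, 8, 8), zones)), 1)
  # two equal disconnected halves -> 0.5
  m <- matrix(TRUE, 8, 8); m[, 4:5] <- FALSE
  m2 <- matrix(FALSE, 8, 8); m2[, 1:3] <- TRUE; m2[, 6:8] <- TRUE
  expect_equal(unname(fragmentation_index(m2, zones)), 0.5)
  # n isolated cells -> 1/n
  iso <- matrix(FALSE, 8, 8)
  iso[cbind(c(1, 3, 5, 7), c(1, 3, 5, 7))] <- TRUE
  expect_equal(unname(fragmentation_index(iso, zones)), 1 / 4)
  # empty mask -> 0 with a warning
  expect_warning(out <- fragmentation_index(matrix(FALSE, 8, 8), zones),
                 "no green cells")
  expect_equal(unname(out), 0)
})

test_that("barriers cut patches and never increase the index", {
  zones <- epoch_grid(matrix(1L, 16, 16), "frame")
  m <- matrix(TRUE, 16, 16)
  base <- unname(fragmentation_index(m, zones))
  barrier <- matrix(FALSE, 16, 16)
  prev <- base
  for (rr in c(4, 8, 12)) {
    barrier[rr, ] <- TRUE
    cur <- unname(fragmentation_index(m, zones, barrier))
    expect_lte(cur, prev + 1e-12)
    prev <- cur
  }
  # three cuts -> four strips; check against the formula directly
  sizes <- c(3, 3, 3, 4) * 16
  expect_equal(prev, sum(sizes^2) / sum(sizes)^2)
})

test_that("patch labelling agrees with fixpoint component enumeration", {
  for (seed in 1:8) {
    set.seed(seed)
    m <- matrix(runif(24 * 24) < 0.55, 24, 24)
    lab <- label_patches(m)
    got <- sort(as.numeric(table(lab[lab > 0])))
    want <- sort(oracle_components(m))
    expect_equal(got, want)
  }
})

test_that("NLEP and NREP are bounded multiplicative composites", {
  expect_equal(nlep(1, 1, 1, 10)$nlep, 1)
  expect_equal(nlep(0.8, 0.5, 1, 10)$nlep, 0.4)
  expect_equal(nlep(0.8, 0.5, 1, 10)$nlep_quantity, 4)
  expect_equal(nlep(0, 0.5, 1, 10)$nlep, 0)      # absorbing zero
  expect_error(nlep(1.2, 1, 1, 10), "\\[0, 1\\]")

  expect_equal(nrep(1, 1, 5)$nrep, 1)
  expect_equal(nrep(0.6, 0.5, 10)$nrep, 0.3)
  no_river <- nrep(NA, 0.5, 0)
  expect_true(is.na(no_river$nrep))
  expect_equal(no_river$nrep_quantity, 0)

  expect_equal(teip(10, 5), 15)
  expect_equal(teip(7, 0), 7)
  # additivity over SELU unions
  expect_equal(teip(c(1, 2), c(3, 4)), c(4, 6))
  expect_equal(sum(teip(c(1, 2), c(3, 4))), teip(3, 7))
})

test_that("yearly change uses the linear convention", {
  expect_equal(yearly_change(5, 5, 12), 0)
  expect_equal(yearly_change(100, 88, 12), -0.01)
  expect_equal(yearly_change(1, 2, 1), 1)
  expect_error(yearly_change(0, 1, 12), "positive")
})

test_that("health index is a weighted mean, degraded iff a component is", {
  expect_equal(health_index(1, 1, 1), 1)
  expect_equal(health_index(0.6, 0.8, 1.0), 0.8)
  # identical components pass through for any weights
  expect_equal(health_index(0.7, 0.7, 0.7, c(0.5, 0.3, 0.2)), 0.7)
  # any component < 1 with positive weight drags health below 1
  set.seed(3)
  for (i in 1:25) {
    comp <- runif(3)
    w <- runif(3); w <- w / sum(w)
    low <- sample(1:3, 1)
    comp[low] <- runif(1, 0, 0.99)
    expect_lt(health_index(comp[1], comp[2], comp[3], w), 1)
  }
  expect_error(health_index(0.5, 0.5, 0.5, c(1, 1, 1)), "summing to 1")
})

test_that("status and protection map into condition and nature value", {
  expect_equal(condition_potential(1:5), c(1, 0.8, 0.6, 0.4, 0.2))
  expect_error(condition_potential(6), "1\\.\\.5")
  expect_equal(nature_value_index(0), 0.5)
  expect_equal(nature_value_index(1), 1)
  expect_equal(nature_value_index(0.5), 0.75)
})
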