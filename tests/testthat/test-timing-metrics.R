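# TimeCourse whose total substrate is a prescribed series (all other
# species zero): lets the metric layer be tested against closed forms
makeSeriesTimeCourse <- function(times, series) {
  conc <- matrix(0, length(times), 11,
                 dimnames = list(NULL, c("A", paste0("S", 0:4),
                                         paste0("AS", 0:4))))
  conc[, "S0"] <- series
  new("TimeCourse", times = times, conc = conc, params = RateParams(),
      solver = "synthetic")
}

test_that("crossing times of an exponential match the closed form", {
  t <- 0:3000
  tc <- makeSeriesTimeCourse(t, 200 * exp(-0.01 * t))
  expect_equal(crossingTime(t, 200 * exp(-0.01 * t), 0.95),
               log(1 / 0.95) / 0.01, tolerance = 1e-3)   # 5.129 s
  expect_equal(crossingTime(t, 200 * exp(-0.01 * t), 0.5),
               log(2) / 0.01, tolerance = 1e-3)          # 69.31 s
  m <- timingMetrics(tc)
  expect_equal(T95(m), 5.129, tolerance = 1e-3)
  expect_equal(T50(m), 69.31, tolerance = 1e-3)
  expect_equal(Td(m), 64.18, tolerance = 1e-3)
  expect_false(any(isCensored(m)))
})

test_that("crossings are censored or interpolated as the samples dictate", {
  t <- 0:100
  expect_true(is.na(crossingTime(t, rep(5, 101), 0.99)))

  # step drops between samples 10 and 11: crossing strictly inside
  y <- c(rep(1, 11), rep(0.2, 90))
  x <- crossingTime(t, y, 0.5)
  expect_gt(x, 10); expect_lt(x, 11)

  expect_error(crossingTime(t, rep(0, 101), 0.5), "baseline")
})

test_that("total substrate reflects the initial condition and conservation", {
  tc <- simulateDegradation(RateParams(kc = 0), horizon = 500)
  tot <- totalSubstrate(tc)
  expect_equal(tot[1], 200)
  expect_equal(tot, rep(200, length(tot)), tolerance = 1e-7)
  m <- timingMetrics(tc)
  expect_true(all(isCensored(m)))
  expect_true(is.na(Td(m)))

  zero <- makeSeriesTimeCourse(0:99, rep(0, 100))
  expect_equal(totalSubstrate(zero), rep(0, 100))
})

test_that("total substrate is non-increasing in degradation-only dynamics", {
  set.seed(5)
  for (p in randomRateParams(4)) {
    tot <- totalSubstrate(simulateDegradation(p, horizon = 1500))
    expect_true(all(diff(tot) <= 1e-7))
  }
})

test_that("maximum occupancy spans the regimes of the occupancy map", {
  # no substrate: occupancy zero
  expect_equal(maxOccupancy(simulateDegradation(RateParams(S0 = 0),
                                                horizon = 300)), 0)
  # tight, slow-catalysis binding saturates the enzyme
  occ <- maxOccupancy(simulateDegradation(
    RateParams(ka = 10, kd = 1e-3, kc = 1e-3), horizon = 1000))
  expect_gt(occ, 0.99)
  expect_lte(occ, 1)
  # no APC/C at all: undefined
  noA <- makeSeriesTimeCourse(0:99, rep(10, 100))
  expect_true(is.na(maxOccupancy(noA)))
})

test_that("occupancy agrees with the independent Euler oracle", {
  or <- eulerOneSubstrate(ka = 0.01, kd = 1, kc = 1, e = 1000, pA = 0.06,
                          horizon = 600, dt = 1e-3)
  bound <- rowSums(or$conc[, paste0("AS", 0:4)])
  totalA <- or$conc[, "A"] + bound
  occOracle <- max((bound / totalA)[totalA > 0])
  tc <- simulateDegradation(RateParams(ka = 0.01, kd = 1, kc = 1),
                            horizon = 600)
  expect_equal(maxOccupancy(tc), occOracle, tolerance = 0.01)
})

test_that("increasing kc never delays onset along a grid row", {
  kcs <- 10^seq(-1, 1, length.out = 5)
  for (kd in c(0.1, 10)) {
    t95 <- vapply(kcs, function(kc) {
      m <- timingMetrics(simulateDegradation(RateParams(kc = kc, kd = kd)))
      if (is.na(T95(m))) Inf else T95(m)
    }, numeric(1))
    expect_true(all(diff(t95) <= 1e-6 * pmax(t95[-length(t95)], 1)))
  }
})
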