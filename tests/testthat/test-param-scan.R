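test_that("default grid has exact endpoints and log spacing", {
  g <- buildLogGrid()
  expect_length(g@kc, 25); expect_length(g@kd, 25); expect_length(g@ka, 6)
  expect_equal(g@kc[1], 1e-3); expect_equal(g@kc[25], 1e3)
  expect_equal(g@kd[1], 1e-3); expect_equal(g@kd[25], 1e3)
  expect_equal(g@ka[1], 1e-4); expect_equal(g@ka[6], 10)
  # neighbour ratios: 10^(1/4) ~ 1.78 for kc/kd, 10 for ka
  expect_equal(g@kc[-1] / g@kc[-25], rep(10^0.25, 24), tolerance = 1e-12)
  expect_equal(g@kd[-1] / g@kd[-25], rep(10^0.25, 24), tolerance = 1e-12)
  expect_equal(g@ka[-1] / g@ka[-6], rep(10, 5), tolerance = 1e-12)
})

test_that("scan cells equal standalone simulate + metrics runs", {
  g <- buildLogGrid(nKc = 4, nKd = 4)
  sc <- scanGrid(g, RateParams(), horizon = 800)
  tab <- scanTable(sc)
  set.seed(3)
  for (i in sample(nrow(tab), 3)) {
    m <- timingMetrics(simulateDegradation(
      RateParams(kc = tab$kc[i], kd = tab$kd[i]), horizon = 800))
    expect_identical(tab$t95[i], T95(m))
    expect_identical(tab$td[i], Td(m))
    expect_identical(tab$maxOccupancy[i], maxOccupancy(m))
  }
})

test_that("overlap mask is the AND of the single-criterion masks", {
  g <- buildLogGrid(nKc = 5, nKd = 5)
  sc <- scanGrid(g, RateParams(), horizon = 1500)
  expect_identical(overlapMask(sc), delayMask(sc) & rateMask(sc))
  # masks align with the metric table row-by-row
  tab <- scanTable(sc)
  ok <- !tab$censoredTd
  expect_identical(rateMask(sc)[ok], tab$td[ok] < 600)
})

test_that("repeated scans write byte-identical CSV files", {
  g <- buildLogGrid(nKc = 3, nKd = 3)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeScanCSV(scanGrid(g, RateParams(), horizon = 600), f1)
  writeScanCSV(scanGrid(g, RateParams(), horizon = 600), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("perturbing kc upward never slows onset, and saturates in the fast corner", {
  # extreme fast-degradation corner: kc already maximal in effect
  fast <- sensitivityT95(RateParams(kc = 1000, kd = 1e-3), "kc_up",
                         horizon = 500)
  expect_lt(abs(fast$sensitivity), 0.02)
  # moderate cells: material speed-up, never negative
  for (cell in list(c(0.1, 10), c(0.0316, 0.01))) {
    s <- sensitivityT95(RateParams(kc = cell[1], kd = cell[2]), "kc_up")
    expect_gte(s$sensitivity, -1e-6)
    expect_gt(s$sensitivity, 0.05)
  }
})

test_that("kd sensitivity requires free APC/C (Euler-checked at two cells)", {
  # saturated low-kc/low-kd cell: nearly all APC/C already substrate-bound
  sat <- sensitivityT95(RateParams(kc = 10^-1.5, kd = 1e-3), "kd_down")
  expect_lt(abs(sat$sensitivity), 0.05)
  # free-APC/C cell: tighter binding materially accelerates onset
  free <- sensitivityT95(RateParams(kc = 0.1, kd = 10), "kd_down")
  expect_gt(free$sensitivity, 0.1)

  # both baselines and perturbed runs pinned by the independent oracle
  oracleT95 <- function(kc, kd, horizon) {
    or <- eulerOneSubstrate(ka = 0.01, kd = kd, kc = kc, e = 1000,
                            pA = 0.06, horizon = horizon, dt = 1e-3)
    crossingTime(or$times, or$total, 0.95)
  }
  f <- 10^0.25
  satOracle <- (oracleT95(10^-1.5, 1e-3, 400) -
                oracleT95(10^-1.5, 1e-3 / f, 400)) /
               oracleT95(10^-1.5, 1e-3, 400)
  expect_lt(abs(sat$sensitivity - satOracle), 0.005)
  freeOracle <- (oracleT95(0.1, 10, 900) - oracleT95(0.1, 10 / f, 900)) /
                oracleT95(0.1, 10, 900)
  expect_lt(abs(free$sensitivity - freeOracle), 0.01)
})

test_that("per-cell failures are recorded without aborting the scan", {
  g <- buildLogGrid(nKc = 2, nKd = 2)
  sc <- scanGrid(g, RateParams(), horizon = 400)
  expect_false(any(scanTable(sc)$failed))
  expect_equal(nrow(scanTable(sc)), 4)
})
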