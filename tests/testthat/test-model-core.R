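test_that("derivatives match the reaction scheme at hand-checked states", {
  p <- RateParams()   # linear mode, pA = 0.06
  zero <- initialState(p)
  zero[] <- 0
  r <- degradationRates(zero, p)
  expect_equal(unname(r["A"]), 0.06)
  expect_equal(unname(r[setdiff(names(r), "A")]), rep(0, 10))

  # constant mode has no production term
  pc <- RateParams(apcMode = "constant")
  expect_equal(unname(degradationRates(zero, pc)), rep(0, 11))

  # uncoupled system: no binding, no production, no deubiquitination
  p0 <- RateParams(ka = 0, pA = 0)
  st <- initialState(p0)
  st["A"] <- 5
  r0 <- degradationRates(st, p0)
  expect_equal(unname(r0["S0"]), 0)
  expect_equal(unname(r0["A"]), 0)
})

test_that("species not coupled to any reaction have zero rates", {
  p <- RateParams(kc = 0)          # no catalysis: AS1..AS4 unreachable
  st <- initialState(p)
  st["A"] <- 3; st["S0"] <- 100
  r <- degradationRates(st, p)
  for (sp in c("S4", "AS2", "AS3", "AS4"))
    expect_equal(unname(r[sp]), 0, info = sp)
})

test_that("summed fluxes obey mass balance symbolically at random states", {
  set.seed(42)
  for (variant in c("none", "all", "free_only", "bound_only", "mono_only")) {
    p <- RateParams(ka = 0.02, kd = 3, kc = 0.7, deubVariant = variant,
                    kdub = if (variant == "none") 0 else 0.4)
    for (rep in 1:5) {
      st <- initialState(p)
      st[] <- runif(length(st), 0, 50)
      r <- degradationRates(st, p)
      sTot <- sum(r[paste0("S", 0:4)]) + sum(r[paste0("AS", 0:4)])
      # deubiquitination moves mass between ubiquitin counts, never out
      expect_equal(sTot, -p@e * (st[["S4"]] + st[["AS4"]]),
                   tolerance = 1e-12)
      # enzyme flux: binding, dissociation and the degradation-driven
      # release all cancel; only production remains
      expect_equal(unname(r["A"]) + sum(r[paste0("AS", 0:4)]), 0.06,
                   tolerance = 1e-9)
    }
  }
})

test_that("deubiquitination variants reduce bitwise to 'none' when kdub = 0", {
  set.seed(7)
  st <- initialState(RateParams())
  st[] <- runif(length(st), 0, 100)
  base <- degradationRates(st, RateParams(deubVariant = "none"))
  for (variant in c("all", "free_only", "bound_only", "mono_only")) {
    r <- degradationRates(st, RateParams(deubVariant = variant, kdub = 0))
    expect_identical(r, base, info = variant)
  }
})

test_that("deubiquitination variants move mass from the selected species only", {
  p <- RateParams(ka = 0, pA = 0, kc = 0, kd = 0, e = 0,
                  deubVariant = "mono_only", kdub = 0.5)
  st <- initialState(p)
  st[c("S1", "S2", "AS1", "AS3")] <- c(10, 20, 8, 6)
  r <- degradationRates(st, p)
  # mono_only: only the one-ubiquitin species feed back
  expect_equal(unname(r["S0"]), 5)    # 0.5 * S1
  expect_equal(unname(r["S1"]), -5)
  expect_equal(unname(r["S2"]), 0)
  expect_equal(unname(r["AS0"]), 4)   # 0.5 * AS1
  expect_equal(unname(r["AS3"]), 0)

  pf <- RateParams(ka = 0, pA = 0, kc = 0, kd = 0, e = 0,
                   deubVariant = "free_only", kdub = 0.5)
  rf <- degradationRates(st, pf)
  expect_equal(unname(rf["S1"]), 0.5 * (20 - 10))  # gains from S2, loses own
  expect_equal(unname(rf["AS1"]), 0)               # bound species untouched
})

test_that("degenerate simulations behave as closed-form expectations", {
  # no substrate: only APC/C accumulates
  tc <- simulateDegradation(RateParams(S0 = 0), horizon = 500)
  conc <- concentrations(tc)
  expect_true(all(conc[, paste0("S", 0:4)] == 0))
  expect_true(all(conc[, paste0("AS", 0:4)] == 0))
  expect_equal(conc[, "A"], 0.06 * modelTimes(tc), tolerance = 1e-8)

  # no catalysis: substrate cannot reach four ubiquitins, total is conserved
  tc2 <- simulateDegradation(RateParams(kc = 0))
  expect_equal(totalSubstrate(tc2), rep(200, length(modelTimes(tc2))),
               tolerance = 1e-7)
})

test_that("all species stay non-negative across random parameter sets", {
  set.seed(11)
  for (p in randomRateParams(6)) {
    tc <- simulateDegradation(p, horizon = 1000)
    expect_gte(min(concentrations(tc)), 0)
  }
})

test_that("fast proteasomal step keeps four-ubiquitin species below 1% of S0", {
  cells <- list(c(0.03162278, 0.001), c(0.1, 10), c(1000, 1000),
                c(1000, 0.001), c(0.001, 1000))
  for (cell in cells) {
    tc <- simulateDegradation(RateParams(kc = cell[1], kd = cell[2]))
    four <- concentrations(tc)[, "S4"] + concentrations(tc)[, "AS4"]
    expect_lt(max(four), 0.01 * 200)
  }
})

test_that("APC/C balance holds in both input modes", {
  p <- RateParams(kc = 0.1, kd = 1, apcMode = "constant", Aconst = 100)
  tc <- simulateDegradation(p, horizon = 1000)
  conc <- concentrations(tc)
  totalA <- conc[, "A"] + rowSums(conc[, paste0("AS", 0:4)])
  expect_equal(totalA, rep(100, nrow(conc)), tolerance = 1e-6)

  pl <- RateParams(kc = 0.1, kd = 1)
  tcl <- simulateDegradation(pl, horizon = 1000)
  concl <- concentrations(tcl)
  totalAl <- concl[, "A"] + rowSums(concl[, paste0("AS", 0:4)])
  expect_equal(totalAl, 0.06 * modelTimes(tcl), tolerance = 1e-6)
})

test_that("fixed-step mode matches the adaptive solver when stable, and fails loudly when not", {
  p <- RateParams(kc = 0.5, kd = 2, e = 10)   # stability limit dt < 0.2
  ad <- simulateDegradation(p, horizon = 300)
  eu <- simulateDegradation(p, horizon = 300, method = "euler", dt = 0.01)
  expect_equal(totalSubstrate(eu), totalSubstrate(ad), tolerance = 5e-3)

  # e = 1000 with dt = 1 is far beyond the explicit stability limit
  expect_error(
    simulateDegradation(RateParams(), method = "euler", dt = 1),
    "integration failed")
})

test_that("invalid parameters are rejected at construction", {
  expect_error(RateParams(ka = -1), "non-negative")
  expect_error(RateParams(S0 = NA_real_), "non-negative")
  expect_error(new("RateParams", maxUb = 5L), "fixed at 4")
})
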