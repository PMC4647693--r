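test_that("scenario builders enforce the ten-fold rules", {
  aff <- TwoSubstrateParams(kdS = 2, kcS = 0.5, scenario = "affinity")
  expect_equal(aff@kdC, 0.2)
  expect_equal(aff@kcC, 0.5)
  cat <- TwoSubstrateParams(kdS = 2, kcS = 0.5, scenario = "catalytic")
  expect_equal(cat@kcC, 5)
  expect_equal(cat@kdC, 2)
  expect_error(new("TwoSubstrateParams", kdS = 1, kdC = 1, kcS = 1, kcC = 1,
                   ka = 0.01, e = 1000, pA = 0.06, Aconst = 100, S0 = 200,
                   C0 = 200, apcMode = "linear", scenario = "affinity"),
               "affinity scenario")
})

test_that("with no competitor the two-substrate model reduces to one substrate", {
  p2 <- TwoSubstrateParams(kdS = 1, kcS = 0.1, scenario = "custom", C0 = 0)
  tc2 <- simulateDegradation(p2, horizon = 1000)
  tc1 <- simulateDegradation(soloParams(p2), horizon = 1000)
  expect_equal(totalSubstrate(tc2, "S"), totalSubstrate(tc1, "S"),
               tolerance = 1e-6)
  expect_equal(totalSubstrate(tc2, "C"), rep(0, 1001))
})

test_that("identical substrates give mirror-image trajectories and neutral metrics", {
  p <- TwoSubstrateParams(kdS = 1, kcS = 1, scenario = "custom")
  res <- runCompetition(p, horizon = 1000)
  conc <- concentrations(res$timeCourse)
  for (i in 0:4) {
    expect_equal(conc[, paste0("S", i)], conc[, paste0("C", i)],
                 tolerance = 1e-8)
    expect_equal(conc[, paste0("AS", i)], conc[, paste0("AC", i)],
                 tolerance = 1e-8)
  }
  expect_equal(unname(res$competition["relOnsetDifference"]), 0,
               tolerance = 1e-6)
  expect_equal(unname(res$competition["tdRatio"]), 1, tolerance = 1e-6)
})

test_that("censored crossings censor the dependent ratios", {
  # no catalysis for either substrate: nothing ever degrades
  p <- TwoSubstrateParams(kdS = 1, kcS = 0, scenario = "custom", kcC = 0)
  res <- runCompetition(p, horizon = 500)
  expect_true(is.na(res$competition["tdRatio"]))
  expect_true(is.na(res$competition["relOnsetDifference"]))
  expect_true(is.na(res$competition["competitionEffect"]))
})

test_that("a high-affinity competitor materially delays S at a small-kdS overlap cell", {
  res <- runCompetition(TwoSubstrateParams(kdS = 0.01, kcS = 10^-1.5,
                                           scenario = "affinity"))
  eff <- unname(res$competition["competitionEffect"])
  expect_gt(eff, 0.2)
  # the same cell under catalytic competition shows a much weaker effect
  resCat <- runCompetition(TwoSubstrateParams(kdS = 0.01, kcS = 10^-1.5,
                                              scenario = "catalytic"))
  expect_lt(unname(resCat$competition["competitionEffect"]), eff / 2)
  # and the catalytically better C degrades faster than S
  expect_lte(unname(resCat$competition["tdRatio"]), 1)
})

test_that("catalytic competition leaves a much smaller C-bound APC/C pool (Euler-checked)", {
  maxAC <- function(tc) max(rowSums(concentrations(tc)[, paste0("AC", 0:4)]))
  aff <- simulateDegradation(TwoSubstrateParams(kdS = 1, kcS = 0.1,
                                                scenario = "affinity"),
                             horizon = 300)
  cat <- simulateDegradation(TwoSubstrateParams(kdS = 1, kcS = 0.1,
                                                scenario = "catalytic"),
                             horizon = 300)
  expect_lt(maxAC(cat), maxAC(aff) / 2)

  # both pools verified against the independent fixed-step oracle
  orAff <- eulerTwoSubstrate(ka = 0.01, kdS = 1, kcS = 0.1, kdC = 0.1,
                             kcC = 0.1, e = 1000, pA = 0.06, horizon = 300)
  orCat <- eulerTwoSubstrate(ka = 0.01, kdS = 1, kcS = 0.1, kdC = 1,
                             kcC = 1, e = 1000, pA = 0.06, horizon = 300)
  oracleMax <- function(or) max(rowSums(or$conc[, paste0("AC", 0:4)]))
  expect_equal(maxAC(aff), oracleMax(orAff), tolerance = 0.01)
  expect_equal(maxAC(cat), oracleMax(orCat), tolerance = 0.01)
})

test_that("APC/C conservation includes both substrates' bound forms", {
  p <- TwoSubstrateParams(kdS = 1, kcS = 0.1, scenario = "affinity",
                          apcMode = "constant", Aconst = 100)
  tc <- simulateDegradation(p, horizon = 1000)
  conc <- concentrations(tc)
  totalA <- conc[, "A"] + rowSums(conc[, paste0("AS", 0:4)]) +
    rowSums(conc[, paste0("AC", 0:4)])
  expect_equal(totalA, rep(100, nrow(conc)), tolerance = 1e-6)
})
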