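makeTrace <- function(y, dt = 30, id = "t")
  FluorescenceTrace(seq(0, by = dt, length.out = length(y)), y, cellId = id)

test_that("smoothing and normalization behave on canonical shapes", {
  const <- makeTrace(rep(500, 40))
  sm <- smoothNormalize(const)
  expect_equal(sm@intensities, rep(1, 40))

  # window 1 is the identity smoother (up to normalization)
  ramp <- makeTrace(seq(100, 490, by = 10))
  sm1 <- smoothNormalize(ramp, window = 1)
  expect_equal(sm1@intensities, ramp@intensities / max(ramp@intensities))

  # a moving average of a linear ramp is linear away from the edges
  sm5 <- smoothNormalize(ramp, window = 5)
  interior <- sm5@intensities[3:(length(ramp@intensities) - 2)]
  expect_equal(diff(diff(interior)), rep(0, length(interior) - 2),
               tolerance = 1e-12)

  expect_error(smoothNormalize(const, window = 4), "odd")
  expect_error(smoothNormalize(makeTrace(rep(1, 10)), window = 11),
               "shorter")
})

test_that("a noise-free plateau-then-decline trace is called at its onset", {
  tr <- generateTrace(TraceSpec(noiseSd = 0, onsetJitterSd = 0, onset = 600),
                      1)
  call <- detectOnset(tr)
  expect_true(call@found)
  expect_lte(abs(onsetTime(call) - 600), 30)
  expect_lte(onsetTime(call), call@argminTime)
})

test_that("degenerate traces are flagged or rejected as specified", {
  # monotone non-decreasing: no declining phase exists
  up <- makeTrace(seq(100, 300, length.out = 30))
  expect_false(detectOnset(up)@found)

  # decline already under way at the first sample
  down <- makeTrace(1000 * exp(-0.005 * seq(0, by = 30, length.out = 40)))
  call <- detectOnset(down)
  expect_true(call@found)
  expect_true(call@flagged)
  expect_equal(onsetTime(call), 0)

  expect_error(makeTrace(c(rep(1, 10), NA, rep(1, 9))), "finite")
})

test_that("detection is invariant to positive rescaling of the trace", {
  tr <- generateTrace(TraceSpec(noiseSd = 0.02, seed = 9), 3)
  scaled <- FluorescenceTrace(tr@times, 7.3 * tr@intensities,
                              cellId = tr@cellId)
  expect_equal(onsetTime(detectOnset(tr)), onsetTime(detectOnset(scaled)))
})

test_that("onset recovery stays within one sample at low noise", {
  absErr <- function(noiseSd, n, seed) {
    calls <- detectOnsets(generateTraces(
      TraceSpec(noiseSd = noiseSd, onsetJitterSd = 30, nCells = n,
                seed = seed)))
    abs(calls$onset - calls$trueOnset)
  }
  expect_lte(median(absErr(0, 30, 21)), 30)
  expect_lte(median(absErr(0.02, 30, 22)), 30)
})

test_that("population statistics recover a known onset gap", {
  oA <- detectOnsets(generateTraces(TraceSpec(onset = 600, noiseSd = 0.02,
                                              nCells = 30, seed = 31)))$onset
  oB <- detectOnsets(generateTraces(TraceSpec(onset = 840, noiseSd = 0.02,
                                              nCells = 30, seed = 32)))$onset
  st <- onsetStatistics(oB, oA)
  expect_lt(abs(st$meanDifference - 240), 15)
  expect_lt(st$pValue, 0.001)

  # identical groups: no difference, p = 1
  same <- onsetStatistics(oA, oA)
  expect_equal(same$meanDifference, 0)
  expect_equal(same$pValue, 1)

  # translation equivariance
  shifted <- onsetStatistics(oA + 120, oA)
  expect_equal(shifted$meanDifference, 120)
})
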