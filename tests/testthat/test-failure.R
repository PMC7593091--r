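test_that("CSA uses the smallest diameter and a circular section", {
  expect_equal(computeCSA(1.0)$csa, 0.7853981634, tolerance = 1e-9)
  expect_equal(computeCSA(c(0.52, 0.50, 0.55))$csa, 0.1963495408,
               tolerance = 1e-9)
  expect_equal(computeCSA(c(0.55, 0.52, 0.50))$csa,
               computeCSA(c(0.50, 0.55, 0.52))$csa)   # permutation-invariant
  expect_error(computeCSA(numeric()), "empty")
  expect_error(computeCSA(c(0.5, -0.1)), "> 0")
})

test_that("stress and strain are the elementary ratios", {
  geo <- list(csa = 0.5, gauge_length = 20)
  ss <- toStressStrain(1, 0.4, geo)
  expect_equal(ss$stress_MPa, 2)
  expect_equal(ss$strain_pct, 2)
  expect_equal(toStressStrain(rep(0, 5), 1:5, geo)$stress_MPa, rep(0, 5))
  expect_error(toStressStrain(1, 1, list(csa = 0, gauge_length = 20)), "csa")
})

test_that("sliding-window slopes match OLS on lines, quadratics and brute force", {
  eps <- seq(0, 0.1, length.out = 60)
  sl <- continuousSlope(eps, 500 * eps, 10)
  expect_equal(nrow(sl), 51L)                      # N - 9 windows
  expect_equal(sl$slope, rep(500, 51), tolerance = 1e-9)
  # quadratic: window slope ~ derivative at window mean, to O(span^2)
  a <- 3000
  sl2 <- continuousSlope(eps, a * eps^2, 10)
  span <- eps[10] - eps[1]
  expect_lt(max(abs(sl2$slope - 2 * a * sl2$centre_x)), a * span^2)
  expect_error(continuousSlope(eps[1:9], eps[1:9], 10), "at least 10")
  # brute-force lm oracle on an arbitrary smooth curve
  y <- sin(eps * 40) + eps * 3
  expect_equal(continuousSlope(eps, y, 10)$slope,
               oracleWindowSlopes(eps, y, 10), tolerance = 1e-9)
})

test_that("yield lands in the first max-slope window of a bilinear curve", {
  # slope 100 then 300 then plateau; max-slope windows sit in the 300 branch
  x <- seq(0, 3, by = 0.01)
  y <- ifelse(x < 1, 100 * x, ifelse(x < 2, 100 + 300 * (x - 1), 400))
  sl <- continuousSlope(x, y, 10)
  best <- which(sl$slope == max(sl$slope))[1]
  brute <- oracleWindowSlopes(x, y, 10)
  expect_equal(max(sl$slope), max(brute), tolerance = 1e-9)
  expect_gte(sl$centre_x[best], 1.0)
  expect_lte(sl$centre_x[best], 2.0)
  # ties break to the first window: an exactly representable line ties
  # everywhere (integer abscissae keep the OLS arithmetic exact)
  xi <- as.numeric(0:29)
  slLine <- continuousSlope(xi, 2 * xi, 10)
  expect_true(all(slLine$slope == 2))
  expect_equal(which(slLine$slope == max(slLine$slope))[1], 1L)
})

test_that("failure and yield recovery on simulated ramps matches truth", {
  for (i in 1:6) {
    ph <- if (i %% 2 == 0) "fascicle" else "IFM"
    p <- drawParams(i, ph, viscFraction = 0.1)
    pr <- defaultProtocol(ph)
    sim <- simSegmented(p)
    geo <- if (ph == "fascicle") computeCSA(p@diameter, p@gaugeLength) else NULL
    fm <- failureMetrics(sim$trace, pr, geo)
    dx <- tendomech:::rampRateMm(pr, p@gaugeLength) / pr@sampleRate
    expect_lt(abs(fm$failure_extension_mm - sim$truth$failureExtension),
              dx + 1e-9)
    expect_gte(sim$truth$yieldExtension, fm$yield_window_lo_mm)
    expect_lte(sim$truth$yieldExtension, fm$yield_window_hi_mm)
    expect_equal(fm$failure_force_N, sim$truth$failureForce, tolerance = 0.01)
  }
})

test_that("stiffness scales with force while the toe profile does not", {
  pr <- defaultProtocol("IFM")
  sim <- simSegmented(ifmParams(seed = 21L))
  tr <- sim$trace
  scaled <- methods::new("ForceExtensionTrace", time = traceTime(tr),
                         force = traceForce(tr) * 3,
                         extension = traceExtension(tr),
                         segment = segmentLabels(tr),
                         sampleRate = sampleRate(tr))
  a <- failureMetrics(tr, pr); b <- failureMetrics(scaled, pr)
  expect_equal(b$max_stiffness_N_mm, 3 * a$max_stiffness_N_mm,
               tolerance = 1e-9)
  toeCols <- grep("^toe_ext_", names(a))
  expect_equal(unlist(b[toeCols]), unlist(a[toeCols]), tolerance = 1e-9)
})

test_that("toe profile is proportional for a linear ramp and anchored at failure", {
  x <- seq(0, 2, by = 0.01)
  f <- 5 * x
  prof <- toeProfile(x, f, failureForce = 10, failureExtension = 2)
  expect_equal(prof, seq(0.2, 2, by = 0.2), tolerance = 1e-9)
  expect_equal(toeProfile(x, f, 10, 2, grid = 100), 2)
})

test_that("toe profiles of simulated specimens are non-decreasing and end at failure", {
  for (i in 1:8) {
    ph <- if (i %% 2 == 0) "fascicle" else "IFM"
    p <- drawParams(100 + i, ph, noiseSd = if (ph == "fascicle") 0.01 else 0.002)
    pr <- defaultProtocol(ph)
    sim <- simSegmented(p, computeTruth = FALSE)
    geo <- if (ph == "fascicle") computeCSA(p@diameter, p@gaugeLength) else NULL
    fm <- failureMetrics(sim$trace, pr, geo)
    prof <- unlist(fm[grep("^toe_ext_", names(fm))])
    expect_true(all(diff(prof) >= -1e-12))
    expect_equal(unname(prof[length(prof)]), fm$failure_extension_mm)
  }
})

test_that("max modulus equals the brute-force maximum over all windows", {
  p <- drawParams(55, "fascicle")
  pr <- defaultProtocol("fascicle")
  sim <- simSegmented(p, computeTruth = FALSE)
  geo <- computeCSA(p@diameter, p@gaugeLength)
  fm <- failureMetrics(sim$trace, pr, geo)
  idx <- which(segmentLabels(sim$trace) == "ramp")
  xx <- traceExtension(sim$trace)[idx]; ff <- traceForce(sim$trace)[idx]
  failIdx <- which.max(ff)
  fs <- sgSmooth(ff[1:failIdx], pr@frameRamp)
  strainFrac <- xx[1:failIdx] / p@gaugeLength
  stress <- fs / geo$csa
  expect_equal(fm$max_modulus_MPa,
               max(oracleWindowSlopes(strainFrac, stress, 10)),
               tolerance = 1e-8)
})
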