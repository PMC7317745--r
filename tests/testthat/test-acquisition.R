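# signal synthesis: b-values, forward model, free-diffusion oracles, symmetry

test_that("b-value follows the PGSE formula", {
  # independent hand evaluation of gamma^2 delta^2 G^2 (Delta - delta/3)
  gam <- 2.675e8
  byHand <- gam^2 * 0.015^2 * 0.64^2 * (0.017 - 0.015 / 3)
  expect_equal(bValue(0.64, 0.015, 0.017), byHand)
  expect_equal(bValue(0, 0.015, 0.017), 0)
  expect_equal(bValue(0.2, 0.015, 0.017), 4 * bValue(0.1, 0.015, 0.017))
  expect_error(bValue(0.1, 0.02, 0.017), "delta")
})

test_that("forward model matches a term-by-term summation oracle", {
  w <- matrix(c(0.5, 0.1, 0.3, 0.1), 2, 2)
  D1 <- c(1e-9, 1e-10)
  D2 <- c(8e-10, 6e-11)
  b1 <- c(0, 4e9, 1e10)
  b2 <- c(0, 2e9)
  S <- forwardSignal(w, D1, D2, b1, b2)
  oracle <- matrix(0, 3, 2)
  for (i in 1:3) for (j in 1:2)
    for (k in 1:2) for (l in 1:2)
      oracle[i, j] <- oracle[i, j] +
        w[k, l] * exp(-b1[i] * D1[k]) * exp(-b2[j] * D2[l])
  expect_equal(S, oracle)
  # one-term limits
  expect_equal(forwardSignal(matrix(1), 1e-9, 1e-9, 0, 0)[1, 1], 1)
  expect_equal(forwardSignal(matrix(1), 1e-9, 1e-9, 2e9, 3e9)[1, 1],
               exp(-(2e9 + 3e9) * 1e-9))
  expect_error(forwardSignal(matrix(c(1.2, -0.2), 1, 2),
                             1e-9, c(1e-9, 1e-10), 0, 0), "non-negative")
})

test_that("DEXSY synthesis in free diffusion matches the analytic signal", {
  ens <- fix_ens_free()
  sq <- dexsySequence(nG = 6, Gmax = 0.3)
  sm <- synthesizeDexsy(ens, sq)
  expect_equal(sm@values[1, 1], 1)
  D <- ens@params@diffusivity
  # continuum Gaussian-phase prediction
  expected <- exp(-outer(sm@b1, sm@b2, "+") * D)
  # exact discrete oracle for the step-sampled waveform: phase variance is
  # gamma^2 G^2 dt^2 * 2 D dt * sum of squared waveform suffix sums
  n <- ens@params@nSteps
  dt <- timeStep(ens@params)
  p1 <- dexsim:::.pgse_waveform(n, dt, 0.015, 0.017, 0L)
  ntm <- as.integer(round(sq@tm / dt))
  p2 <- dexsim:::.pgse_waveform(n, dt, 0.015, 0.017, p1$endStep + ntm)
  suff2 <- function(w) sum(rev(cumsum(rev(w)))^2)
  v1 <- dexsim::GAMMA_H^2 * dt^3 * 2 * D * suff2(p1$w)
  v2 <- dexsim::GAMMA_H^2 * dt^3 * 2 * D * suff2(p2$w)
  discrete <- exp(-outer(sq@G1List^2 * v1, sq@G2List^2 * v2, "+") / 2)
  # the step discretization itself is a small systematic effect
  expect_lt(max(abs(discrete - expected)), 0.03)
  # and the simulated signal matches the discrete oracle to Monte Carlo error
  expect_true(all(abs(sm@values - discrete) < 5 * pmax(sm@se, 1e-4)))
  # monotone non-increasing in each gradient, allowing Monte Carlo noise
  seTol <- 4 * pmax(sm@se, 1e-4)
  expect_true(all(diff(sm@values[, 1]) <= (seTol[-1, 1] + seTol[-6, 1])))
  expect_true(all(diff(sm@values[1, ]) <= (seTol[1, -1] + seTol[1, -6])))
})

test_that("signal symmetry holds at equilibrium with identical pair timings", {
  ens <- fix_ens_spheres_p0()
  sq <- dexsySequence(nG = 5, Gmax = 0.6)
  sm <- synthesizeDexsy(ens, sq)
  off <- abs(sm@values - t(sm@values))
  setol <- 5 * pmax(sm@se + t(sm@se), 1e-4)
  expect_true(all(off < setol))
  expect_true(all(sm@values > 0 & sm@values <= 1 + 1e-12))
})

test_that("two seeds give signal matrices equal within sampling error", {
  sub <- fix_spheres_small()
  sq <- dexsySequence(nG = 5, Gmax = 0.6)
  mats <- lapply(c(101, 202), function(s) {
    wp <- walkParams(nWalkers = 2000, nSteps = 1200, duration = 0.4,
                     transitProb = 0, seed = s)
    synthesizeDexsy(simulateWalk(sub, wp), sq)
  })
  diffs <- abs(mats[[1]]@values - mats[[2]]@values)
  se <- sqrt(mats[[1]]@se^2 + mats[[2]]@se^2)
  expect_true(all(diffs < 4.5 * pmax(se, 1e-4)))
})

test_that("sequences longer than the simulation are rejected", {
  ens <- fix_ens_free()
  expect_error(synthesizeDexsy(ens, dexsySequence(tm = 1.0)), "longer")
})

test_that("DOSY synthesis reproduces free-diffusion attenuation", {
  ens <- fix_ens_free()
  dosy <- synthesizeDosy(ens, GList = seq(0, 0.3, length.out = 32))
  expect_equal(dosy$signal[1], 1)
  D <- ens@params@diffusivity
  expect_true(all(abs(dosy$signal - exp(-dosy$b * D)) <
                    5 * pmax(dosy$se, 1e-4)))
})

test_that("FEXSY without filter or exchange reproduces the unfiltered ADC", {
  ens <- fix_ens_spheres_p0()
  fx0 <- synthesizeFexsy(ens, filterG = 0, tmList = c(0, 0.1, 0.3))
  adc0 <- adcPerTm(fx0)
  # no filter: ADC equals the plain encode-dimension ADC at every tm
  expect_equal(adc0, rep(adc0[1], 3), tolerance = 0.05)
  # p = 0 with filter: no ADC recovery over tm
  fx <- synthesizeFexsy(ens, tmList = c(0, 0.1, 0.3))
  adcs <- adcPerTm(fx)
  expect_equal(adcs / adcs[1], rep(1, 3), tolerance = 0.08)
})

test_that("signal matrix text format round-trips and validates", {
  ens <- fix_ens_free()
  sm <- synthesizeDexsy(ens, dexsySequence(nG = 5, Gmax = 0.64))
  path <- withr::local_tempfile(fileext = ".txt")
  writeSignalMatrix(sm, path)
  back <- ingestAcquired(path)
  expect_equal(back@values, sm@values, tolerance = 1e-12)
  expect_equal(back@b1, sm@b1)
  expect_equal(back@tm, sm@tm)
  # a matrix missing its G = 0 row fails with a specific parse error
  lines <- readLines(path)
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(lines[-7], bad)  # drop the first data row (G1 = 0)
  expect_error(ingestAcquired(bad), "S0|non-decreasing")
})
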