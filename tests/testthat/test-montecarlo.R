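# walker engine: permeability mapping, free-diffusion statistics, membrane
# bookkeeping

test_that("transit probability maps to the reference permeabilities", {
  dt <- 0.4 / 16000
  D <- 2e-9
  # printed correspondence: p = 1e-4 -> 0.37 um/s, 5.5e-4 -> 2.0 um/s
  expect_equal(signif(permeabilityFromProbability(1e-4, dt, D) * 1e6, 2), 0.37)
  expect_equal(signif(permeabilityFromProbability(5.5e-4, dt, D) * 1e6, 2), 2.0)
  expect_equal(transitProbability(0, dt, D), 0)
  expect_equal(permeabilityFromProbability(0, dt, D), 0)
  expect_error(transitProbability(1e-6, dt = 0, D = D), "positive")
  expect_error(transitProbability(1e-6, dt = dt, D = -1), "positive")
})

test_that("probability/permeability conversions are exact inverses", {
  dt <- 2.5e-5
  D <- 2e-9
  p <- withr::with_seed(4, runif(100))
  k <- permeabilityFromProbability(p, dt, D)
  expect_equal(transitProbability(k, dt, D), p)
})

test_that("free diffusion reproduces the Einstein relation", {
  ens <- fix_ens_free()
  t <- ens@params@duration
  D <- ens@params@diffusivity
  msd <- rowSums(ens@displacement^2)
  n <- length(msd)
  se <- sd(msd) / sqrt(n)
  expect_lt(abs(mean(msd) - 6 * D * t), 3 * se)
  # each displacement component has variance 2 D t
  for (ax in 1:3) {
    v <- var(ens@displacement[, ax])
    sev <- v * sqrt(2 / (n - 1))
    expect_lt(abs(v - 2 * D * t), 3.5 * sev)
  }
})

test_that("impermeable membranes never change compartment labels", {
  ens <- fix_ens_spheres_p0()
  expect_true(all(ens@labels == rep(ens@labels[1, ],
                                    each = nrow(ens@labels))))
  expect_true(all(ens@crossings == 0L))
  expect_equal(fractionExchanged(ens), 0)
})

test_that("fully permeable membranes recover free-diffusion displacement", {
  wp <- walkParams(nWalkers = 3000, nSteps = 400, duration = 0.1,
                   transitProb = 1, seed = 21)
  ens <- simulateWalk(fix_spheres_small(), wp, storeProj = FALSE)
  msd <- mean(rowSums(ens@displacement^2))
  wpf <- walkParams(nWalkers = 3000, nSteps = 400, duration = 0.1,
                    transitProb = 0, seed = 22)
  free <- simulateWalk(NULL, wpf, storeProj = FALSE)
  msdf <- mean(rowSums(free@displacement^2))
  se <- sqrt(var(rowSums(ens@displacement^2)) / 3000 +
               var(rowSums(free@displacement^2)) / 3000)
  expect_lt(abs(msd - msdf), 3 * se)
})

test_that("restricted walkers stay bounded and slow down with time", {
  ens <- fix_ens_spheres_p0()
  intra <- ens@labels[1, ] > 0
  # apparent diffusivity of intracellular walkers far below intrinsic D
  t <- ens@params@duration
  Dapp <- mean(rowSums(ens@displacement[intra, ]^2)) / (6 * t)
  expect_lt(Dapp, 0.1 * ens@params@diffusivity)
  # extracellular walkers remain extracellular (p = 0)
  expect_true(all(ens@labels[nrow(ens@labels), !intra] == 0))
})

test_that("exchange during a fixed window is monotone in transit probability", {
  sub <- fix_spheres_small()
  fr <- vapply(c(0, 5e-4, 2e-3, 8e-3, 3e-2), function(p) {
    wp <- walkParams(nWalkers = 1500, nSteps = 400, duration = 0.1,
                     transitProb = p, seed = 31)
    fractionExchanged(simulateWalk(sub, wp, storeProj = FALSE))
  }, numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[1], 0)
})

test_that("simulation is deterministic given the seed and conserves walkers", {
  wp <- walkParams(nWalkers = 500, nSteps = 200, duration = 0.05,
                   transitProb = 0.01, seed = 5)
  a <- simulateWalk(fix_spheres_small(), wp)
  b <- simulateWalk(fix_spheres_small(), wp)
  expect_identical(a@displacement, b@displacement)
  expect_identical(a@labels, b@labels)
  expect_identical(nrow(a@displacement), 500L)
  expect_true(all(is.finite(a@proj)))
})

test_that("stored trajectories agree with on-the-fly phase accumulation", {
  # dual-path check: phase integrals from saved projections vs accumulated
  # in the walker loop
  n <- 200
  wfm <- matrix(0, n, 2)
  wfm[5:40, 1] <- 1
  wfm[60:95, 1] <- -1
  wfm[10:30, 2] <- 1
  wfm[120:140, 2] <- -1
  wp <- walkParams(nWalkers = 300, nSteps = n, duration = 0.05,
                   transitProb = 0.005, seed = 12)
  ens <- simulateWalk(fix_spheres_small(), wp, waveforms = wfm)
  onTheFly <- accumulatedPhase(ens)
  dt <- timeStep(wp)
  fromProj <- crossprod(ens@proj[1:n, ], wfm)
  expect_equal(onTheFly, fromProj * 1 , tolerance = 1e-12)
  # and full positions projected on the direction reproduce proj
  wp2 <- walkParams(nWalkers = 40, nSteps = 100, duration = 0.02, seed = 3)
  ens2 <- simulateWalk(fix_spheres_small(), wp2, storePositions = TRUE)
  proj2 <- apply(ens2@positions, 3, function(m) m %*% ens2@direction[1, ])
  expect_equal(unname(ens2@proj), unname(proj2), tolerance = 1e-12)
})
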