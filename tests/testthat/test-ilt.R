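# inverse Laplace inversion: recovery oracles, round trips, regularization

grid64 <- diffusivityGrid()

test_that("noiseless one-component inversion concentrates on the true cell", {
  D0 <- grid64@values[40]
  sm <- synth_matrix(matrix(1), D0, D0)
  sp <- invert2D(sm, grid64, alpha = 1e-6)
  i <- which(sp@amplitudes == max(sp@amplitudes), arr.ind = TRUE)
  expect_equal(unname(i[1, ]), c(40, 40))
  near <- sp@amplitudes[39:41, 39:41]
  expect_gte(sum(near) / sum(sp@amplitudes), 0.95)
  expect_equal(sum(sp@amplitudes), 1, tolerance = 0.1)
  expect_true(all(sp@amplitudes >= 0))
})

test_that("two well-separated diagonal components are both recovered", {
  iA <- 22L; iB <- 43L   # a decade apart on the default grid
  DA <- grid64@values[iA]; DB <- grid64@values[iB]
  w <- diag(c(0.5, 0.5))
  sm <- synth_matrix(w, c(DA, DB), c(DA, DB))
  sp <- invert2D(sm, grid64, alpha = 1e-4)
  pk <- findPeaks(sp, threshold = 0.05)
  dg <- pk[pk$label %in% c("A", "B"), ]
  expect_identical(nrow(dg), 2L)
  step <- mean(diff(log10(grid64@values)))
  expect_lt(abs(log10(sort(dg$d1)[1]) - log10(DA)), step + 1e-9)
  expect_lt(abs(log10(sort(dg$d1)[2]) - log10(DB)), step + 1e-9)
})

test_that("forward-inverse round trip fits noiseless input within 1%", {
  truth <- makeGroundTruth(dIntra = 6e-11, dExtra = 1e-9, fIntra = 0.4,
                           kEx = 2, tm = 0.1)
  sm <- generateDexsySignal(truth, noiseSd = 0)
  sp <- invert2D(sm, grid64, alpha = 1e-4)
  expect_lt(sp@residual, 0.01)
  # explicit reconstruction through the forward model
  fit <- forwardSignal(sp@amplitudes / sum(sp@amplitudes),
                       grid64@values, grid64@values, sm@b1, sm@b2)
  relRms <- sqrt(mean((fit * sum(sp@amplitudes) - sm@values)^2)) /
    sqrt(mean(sm@values^2))
  expect_lt(relRms, 0.01)
})

test_that("1D inversion resolves separated components and flags degeneracy", {
  b <- bValue(seq(0, 0.9, length.out = 64), 0.015, 0.017)
  D0 <- grid64@values[40]
  sp1 <- invert1D(exp(-b * D0), b, grid64, alpha = 1e-4)
  pk1 <- findPeaks1D(sp1)
  expect_identical(nrow(pk1), 1L)
  step <- mean(diff(log10(grid64@values)))
  expect_lt(abs(log10(pk1$d) - log10(D0)), step + 1e-9)
  # two components a decade apart resolve; ratio 1.5 merges
  DA <- grid64@values[22]; DB <- grid64@values[43]
  sp2 <- invert1D(0.5 * exp(-b * DA) + 0.5 * exp(-b * DB), b, grid64,
                  alpha = 1e-4)
  expect_identical(nrow(findPeaks1D(sp2, threshold = 0.05)), 2L)
  Dc <- DA * 1.5
  sp3 <- invert1D(0.5 * exp(-b * DA) + 0.5 * exp(-b * Dc), b, grid64,
                  alpha = 1e-4)
  expect_identical(nrow(findPeaks1D(sp3, threshold = 0.05)), 1L)
  expect_error(invert1D(rep(1, 5), rep(0, 5), grid64), "under-determined")
})

test_that("degenerate unattenuated input is flagged", {
  G <- seq(0, 0.9, length.out = 8)
  S <- matrix(1, 8, 8)
  sm <- make_signal_matrix(S, G)
  expect_warning(invert2D(sm, diffusivityGrid(32), alpha = 1e-4),
                 "low-diffusivity edge")
})

test_that("alpha selection strategies behave as specified", {
  expect_identical(selectAlpha(NULL, strategy = "fixed", alpha = 0.123), 0.123)
  # discrepancy principle: residual within 10% of sqrt(N) sigma by design
  truth <- makeGroundTruth(fIntra = 0.4, kEx = 2)
  sigma <- 0.005
  sm <- generateDexsySignal(truth, noiseSd = sigma, seed = 6)
  al <- selectAlpha(sm, grid64, strategy = "discrepancy", noiseSd = sigma)
  sp <- invert2D(sm, grid64, alpha = al)
  resid <- sp@residual * sqrt(mean(sm@values^2)) * sqrt(length(sm@values))
  expect_equal(resid, sqrt(length(sm@values)) * sigma, tolerance = 0.1)
  # heavy smoothing spreads the spectrum: entropy grows with alpha
  spSmall <- invert2D(sm, grid64, alpha = 1)
  spBig <- invert2D(sm, grid64, alpha = 1e6)
  entropy <- function(s) {
    p <- s@amplitudes / sum(s@amplitudes)
    p <- p[p > 0]
    -sum(p * log(p))
  }
  expect_gt(entropy(spBig), entropy(spSmall))
})

test_that("rank-deficient truncation is reported by name", {
  g <- diffusivityGrid(16)
  b <- bValue(seq(0, 0.9, length.out = 8), 0.015, 0.017)
  expect_error(dexsim:::.kernel_svd(b, g@values, tol = 10), "truncation")
})
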