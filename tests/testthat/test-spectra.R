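# peak segmentation, labelling and the DEI statistic

# place a small Gaussian blob on a spectrum grid
blob_spectrum <- function(places, weights, grid = diffusivityGrid(),
                          width = 0.8) {
  n <- length(grid@values)
  F <- matrix(0, n, n)
  for (k in seq_along(weights)) {
    i0 <- places[[k]][1]; j0 <- places[[k]][2]
    for (i in max(1, i0 - 3):min(n, i0 + 3))
      for (j in max(1, j0 - 3):min(n, j0 + 3))
        F[i, j] <- F[i, j] +
          weights[k] * exp(-((i - i0)^2 + (j - j0)^2) / (2 * width^2))
  }
  new("Spectrum2D", amplitudes = F / sum(F), grid1 = grid, grid2 = grid,
      alpha = 0, residual = 0, rank = c(0L, 0L))
}

test_that("four constructed point masses get the A/B/C/D labels", {
  # extracellular high-D diagonal, intracellular low-D diagonal, two cross
  sp <- blob_spectrum(list(c(45, 45), c(20, 20), c(45, 20), c(20, 45)),
                      c(0.5, 0.3, 0.1, 0.1))
  pk <- findPeaks(sp)
  expect_identical(nrow(pk), 4L)
  expect_setequal(pk$label, c("A", "B", "C", "D"))
  A <- pk[pk$label == "A", ]; B <- pk[pk$label == "B", ]
  expect_gt(A$d1, B$d1)             # A is the higher-diffusivity peak
  C <- pk[pk$label == "C", ]
  expect_gt(C$d1, C$d2)             # C: first encoding high, second low
  # thresholding trims proportionally more wing mass from the short cross
  # peaks than from the tall diagonal ones, hence the loose tolerance
  expect_equal(dei(computeDEI(pk)), 0.2 / 0.8, tolerance = 0.15)
})

test_that("a single diagonal mass yields one A peak and DEI 0", {
  sp <- blob_spectrum(list(c(40, 40)), 1)
  pk <- findPeaks(sp)
  expect_identical(nrow(pk), 1L)
  expect_identical(pk$label, "A")
  expect_equal(dei(computeDEI(pk)), 0)
})

test_that("the diagonal tolerance boundary is inclusive", {
  g <- diffusivityGrid()
  # centroid exactly diagonalTol off the diagonal -> still diagonal
  l <- log10(g@values[30])
  pk <- data.frame(d1 = 10^(l + 0.15), d2 = 10^l, volume = 1)
  F <- matrix(0, 64, 64)
  i2 <- 30L
  i1 <- which.min(abs(log10(g@values) - (l + 0.15)))
  # use an exactly placed single-cell mass at the tolerance offset
  sp <- new("Spectrum2D", amplitudes = F, grid1 = g, grid2 = g,
            alpha = 0, residual = 0, rank = c(0L, 0L))
  sp@amplitudes[i1, i2] <- 1
  tol <- abs(log10(g@values[i1]) - log10(g@values[i2]))
  pk <- findPeaks(sp, diagonalTol = tol)
  expect_identical(pk$label, "A")
  pkOff <- findPeaks(sp, diagonalTol = tol * 0.99)
  expect_true(pkOff$label %in% c("C", "D"))
})

test_that("DEI arithmetic, exclusions and errors", {
  pk <- data.frame(label = c("A", "B", "C", "D"),
                   d1 = c(1e-9, 1e-10, 1e-9, 1e-10),
                   d2 = c(1e-9, 1e-10, 1e-10, 1e-9),
                   volume = c(0.5, 0.3, 0.1, 0.1))
  res <- computeDEI(pk)
  expect_equal(dei(res), 0.25)
  expect_equal(res@exchangeVolume, 0.2)
  expect_equal(res@nonExchangeVolume, 0.8)
  # unassigned (perfusion-like) peaks are excluded and reported
  pk2 <- rbind(pk, data.frame(label = "unassigned", d1 = 2e-8, d2 = 2e-8,
                              volume = 5))
  res2 <- computeDEI(pk2)
  expect_equal(dei(res2), 0.25)
  expect_identical(nrow(res2@excluded), 1L)
  expect_error(computeDEI(pk[pk$label %in% c("C", "D"), ]), "diagonal")
})

test_that("DEI is invariant to uniform rescaling of the spectrum", {
  sp <- blob_spectrum(list(c(45, 45), c(20, 20), c(45, 20), c(20, 45)),
                      c(0.45, 0.35, 0.1, 0.1))
  d1 <- dei(computeDEI(findPeaks(sp)))
  sp@amplitudes <- sp@amplitudes * 37.5
  expect_equal(dei(computeDEI(findPeaks(sp))), d1)
})

test_that("mass entirely inside the diagonal band gives DEI 0", {
  sp <- blob_spectrum(list(c(25, 25), c(45, 45)), c(0.5, 0.5))
  expect_equal(dei(computeDEI(findPeaks(sp))), 0)
})

test_that("Spearman correlation uses average-rank ties", {
  expect_equal(deiPermeabilityCurve(1:5, (1:5) * 1e-7), 1)
  expect_equal(deiPermeabilityCurve(5:1, (1:5) * 1e-7), -1)
  # rank-by-hand oracle for (1,2,2,3) vs (1,2,3,4):
  # ranks x = 1, 2.5, 2.5, 4; y = 1..4; rho = 1 - 6*sum(d^2)/(n(n^2-1))
  x <- c(1, 2, 2, 3); y <- c(1, 2, 3, 4)
  dd <- c(0, 0.5, -0.5, 0)
  byHand <- 1 - 6 * sum(dd^2) / (4 * 15)
  # Pearson-on-ranks (what average-rank Spearman computes with ties)
  rho <- deiPermeabilityCurve(x, y)
  expect_equal(rho, cor(rank(x), rank(y)))
  expect_equal(rho, byHand, tolerance = 0.02)
  expect_error(deiPermeabilityCurve(c(1, 1, 1), 1:3), "constant")
  expect_error(deiPermeabilityCurve(1:2, 1:2), "3 points")
})

test_that("the full synthetic chain recovers DEI near the weight ratio", {
  # cross mass f: DEI should come out near f / (1 - f) end to end
  truth <- makeGroundTruth(dIntra = 6e-11, dExtra = 1e-9, fIntra = 0.4,
                           kEx = -log(1 - 0.2 / (2 * 0.4 * 0.6)) / 0.1,
                           tm = 0.1)
  f <- sum(truth@weights[c("wC", "wD")])
  expect_equal(f, 0.2, tolerance = 1e-9)
  sm <- generateDexsySignal(truth, noiseSd = 0)
  sp <- invert2D(sm, diffusivityGrid(), alpha = 1e-4)
  res <- computeDEI(findPeaks(sp))
  expect_equal(dei(res), f / (1 - f), tolerance = 0.2 * f / (1 - f))
})

test_that("peak tables serialize", {
  pk <- data.frame(label = c("A", "C"), d1 = c(1e-9, 1e-9),
                   d2 = c(1e-9, 1e-10), volume = c(0.9, 0.1))
  res <- computeDEI(pk)
  path <- withr::local_tempfile(fileext = ".tsv")
  writePeakTable(res, path)
  lines <- readLines(path)
  expect_match(lines[1], "dei")
  back <- read.table(path, header = TRUE, comment.char = "#")
  expect_equal(back$volume, pk$volume)
})
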