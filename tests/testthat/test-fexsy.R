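# ADC fitting and the AXR recovery model

test_that("ADC fit recovers exact mono-exponential decay", {
  b <- seq(0, 3e9, length.out = 6)
  expect_equal(fitADC(exp(-b * 1e-9), b), 1e-9, tolerance = 1e-12)
  expect_equal(fitADC(rep(1, 4), c(0, 1e9, 2e9, 3e9)), 0)
  expect_error(fitADC(c(1, 0.5), c(0, 1e9)), "3 encode")
  expect_error(fitADC(c(1, -0.1, 0.2), c(0, 1e9, 2e9)), "non-positive")
  expect_error(fitADC(c(1, 0.9, 0.8), c(1e8, 1e9, 2e9)), "b = 0")
})

test_that("bi-exponential ADC lies between the component diffusivities", {
  b <- seq(0, 2e9, length.out = 9)
  Dfast <- 1.5e-9; Dslow <- 1e-10
  s <- 0.6 * exp(-b * Dfast) + 0.4 * exp(-b * Dslow)
  adc <- fitADC(s, b)
  expect_gt(adc, Dslow)
  expect_lt(adc, Dfast)
})

test_that("AXR parameters are recovered to 4 significant figures", {
  tm <- c(0, 0.01, 0.1, 0.2, 0.3)
  adc <- generateFexsyADC(adcEq = 1e-9, sigma = 0.3, axr = 2, tmList = tm)
  fit <- fitAXR(adc, tm)
  expect_equal(axr(fit), 2, tolerance = 1e-4)
  expect_equal(fit@sigma, 0.3, tolerance = 1e-4)
  expect_equal(fit@adcEq, 1e-9, tolerance = 1e-4)
})

test_that("flat ADC over tm is flagged as unidentifiable", {
  tm <- c(0, 0.1, 0.2, 0.3)
  expect_error(fitAXR(rep(7e-10, 4), tm), "unidentifiable")
  expect_error(fitAXR(c(1e-9, 9e-10), c(0, 0.1)), "3 distinct")
})

test_that("AXR = 0 synthetic data is constant at the filtered level", {
  adc <- generateFexsyADC(adcEq = 1e-9, sigma = 0.4, axr = 0,
                          tmList = c(0, 0.1, 0.3))
  expect_equal(adc, rep(1e-9 * 0.6, 3))
})

test_that("noisy generation is seeded and round-trips through the fit", {
  tm <- c(0, 0.01, 0.1, 0.2, 0.3)
  a1 <- generateFexsyADC(noiseSd = 2e-11, seed = 9, tmList = tm)
  a2 <- generateFexsyADC(noiseSd = 2e-11, seed = 9, tmList = tm)
  expect_identical(a1, a2)
  fit <- fitAXR(a1, tm)
  expect_equal(axr(fit), 2, tolerance = 0.5)   # noise-limited recovery
  expect_gte(fit@sigma, 0); expect_lte(fit@sigma, 1)
  expect_gte(axr(fit), 0)
})

test_that("AXR fit serializes with its ADC table", {
  tm <- c(0, 0.01, 0.1, 0.2, 0.3)
  fit <- fitAXR(generateFexsyADC(tmList = tm), tm)
  path <- withr::local_tempfile(fileext = ".txt")
  writeAxrFit(fit, path)
  lines <- readLines(path)
  expect_match(lines[1], "axr_per_s")
  tab <- read.table(path, header = TRUE, comment.char = "#")
  expect_equal(tab$adc_m2_per_s, fit@adc)
})
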