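#' @include spectra.R
NULL

#' Apparent diffusion coefficient from mono-exponential attenuation
#'
#' Least-squares slope of `-log(S/S0)` against b, where S0 is the signal at
#' the b = 0 point of the encode dimension (after any filter).
#'
#' @param signals S/S0 per encode gradient (the first entry is the b = 0
#'   reference and need not be 1).
#' @param b b-values (s/m^2), at least 3 points including b = 0.
#' @return ADC (m^2/s); can be negative only through noise.
#' @examples
#' b <- seq(0, 3e9, length.out = 5)
#' fitADC(exp(-b * 1e-9), b)  # 1e-9
#' @export
fitADC <- function(signals, b) {
  if (length(signals) != length(b)) stop("signals and b lengths differ")
  if (length(b) < 3) stop("need at least 3 encode points")
  if (!any(b == 0)) stop("the encode dimension must include b = 0")
  if (any(signals <= 0)) stop("non-positive signals cannot be log-transformed")
  s0 <- signals[which(b == 0)[1]]
  y <- -log(signals / s0)
  unname(coef(lm(y ~ b))[2])
}

#' Fit the apparent exchange rate from ADC recovery over mixing time
#'
#' Nonlinear least squares of
#' \eqn{ADC(t_m) = ADC_{eq}\,(1 - \sigma e^{-AXR\, t_m})}, the standard
#' filter-exchange parametrization, using a deterministic multi-start
#' Levenberg-Marquardt search with bounds AXR in \[0, 100\] 1/s and sigma in
#' \[0, 1\].
#'
#' @param adcPerTm fitted ADC per mixing time (m^2/s).
#' @param tmList mixing times (s), at least 3 distinct values.
#' @param adcEq optional fixed equilibrium ADC (m^2/s), typically measured
#'   from a filter-free encode sweep of the same acquisition. Fixing it
#'   removes the strong ADC_eq-AXR degeneracy of the three-parameter fit
#'   and stabilizes the AXR considerably on noisy data; `NULL` fits all
#'   three parameters.
#' @return an [AxrFit-class].
#' @examples
#' tm <- c(0, 0.01, 0.1, 0.2, 0.3)
#' adc <- 1e-9 * (1 - 0.3 * exp(-2 * tm))
#' axr(fitAXR(adc, tm))  # 2
#' @export
fitAXR <- function(adcPerTm, tmList, adcEq = NULL) {
  if (length(adcPerTm) != length(tmList)) stop("adc and tm lengths differ")
  if (length(unique(tmList)) < 3) stop("need at least 3 distinct mixing times")
  rng <- diff(range(adcPerTm))
  if (rng <= 1e-6 * max(abs(adcPerTm)))
    stop("ADC is flat over tm (sigma ~ 0): AXR is unidentifiable")
  dat <- data.frame(adc = adcPerTm, tm = tmList)
  scale <- max(adcPerTm)
  best <- NULL
  fixedEq <- !is.null(adcEq)
  if (fixedEq) dat$aeq <- adcEq
  for (axr0 in c(0.5, 2, 5, 20, 50)) {
    for (sig0 in c(0.1, 0.3, 0.6, 0.9)) {
      fit <- tryCatch(
        if (fixedEq)
          minpack.lm::nlsLM(adc ~ aeq * (1 - sigma * exp(-axr * tm)),
                            data = dat,
                            start = list(sigma = sig0, axr = axr0),
                            lower = c(sigma = 0, axr = 0),
                            upper = c(sigma = 1, axr = 100),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
        else
          minpack.lm::nlsLM(adc ~ adcEq * (1 - sigma * exp(-axr * tm)),
                            data = dat,
                            start = list(adcEq = scale, sigma = sig0, axr = axr0),
                            lower = c(adcEq = 1e-16, sigma = 0, axr = 0),
                            upper = c(adcEq = Inf, sigma = 1, axr = 100),
                            control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        ssr <- sum(residuals(fit)^2)
        if (is.null(best) || ssr < best$ssr - 1e-30 * scale^2)
          best <- list(fit = fit, ssr = ssr)
      }
    }
  }
  if (is.null(best))
    stop("AXR fit did not converge from any start")
  cf <- coef(best$fit)
  np <- length(cf)
  cv <- tryCatch(vcov(best$fit),
                 error = function(e) matrix(NA_real_, np, np))
  new("AxrFit", axr = unname(cf["axr"]), sigma = unname(cf["sigma"]),
      adcEq = if (fixedEq) adcEq else unname(cf["adcEq"]),
      adc = adcPerTm, tm = tmList, cov = cv)
}

#' Per-mixing-time ADC values of a FEXSY acquisition
#'
#' Applies [fitADC()] to the encode dimension at every mixing time.
#'
#' @param fexsy a [FexsyAcquisition-class].
#' @param dropSaturated optionally drop encode points whose signal fell below
#'   this fraction of the per-tm maximum before fitting (default keeps all 9
#'   points).
#' @return numeric vector of ADC values, one per mixing time.
#' @export
adcPerTm <- function(fexsy, dropSaturated = 0) {
  vapply(seq_along(fexsy@tmList), function(j) {
    s <- fexsy@signals[, j]
    keep <- s > dropSaturated * max(s)
    keep[which(fexsy@bEncode == 0)[1]] <- TRUE
    fitADC(s[keep], fexsy@bEncode[keep])
  }, numeric(1))
}

#' Fit the AXR directly from a FEXSY acquisition
#'
#' @param fexsy a [FexsyAcquisition-class].
#' @param adcEq optional fixed equilibrium ADC; see [fitAXR()].
#' @param ... passed to [adcPerTm()].
#' @return an [AxrFit-class].
#' @export
fitAXRFromFexsy <- function(fexsy, adcEq = NULL, ...) {
  fitAXR(adcPerTm(fexsy, ...), fexsy@tmList, adcEq = adcEq)
}

#' Serialize an AXR fit and its per-tm ADC table
#'
#' @param fit an [AxrFit-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAxrFit <- function(fit, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# axr_per_s: %.17g", fit@axr),
               sprintf("# sigma: %.17g", fit@sigma),
               sprintf("# adc_eq_m2_per_s: %.17g", fit@adcEq)), con)
  write.table(data.frame(tm_s = fit@tm, adc_m2_per_s = fit@adc), con,
              quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
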