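#' @include fexsy.R
NULL

#' Construct a synthetic two-site exchange ground truth
#'
#' Equilibrium two-site mixing during the mixing time: the exchanged fraction
#' is \eqn{f_{ex} = 1 - e^{-k_{ex} t_m}}, the symmetric cross-peak weights are
#' \eqn{w_C = w_D = f_{intra} (1 - f_{intra}) f_{ex}} (detailed balance), and
#' the diagonal weights absorb the remaining mass in proportion to
#' \eqn{(1 - f_{intra})} and \eqn{f_{intra}}. This is a synthetic statistical
#' stand-in with the structure the analysis assumes, not a physical membrane
#' model.
#'
#' @param dIntra,dExtra pool diffusivities (m^2/s).
#' @param fIntra intracellular fraction, in (0, 1).
#' @param kEx exchange rate (1/s), non-negative.
#' @param tm mixing time (s), non-negative.
#' @return an [ExchangeGroundTruth-class].
#' @examples
#' makeGroundTruth(kEx = 0)@weights          # (1 - f, f, 0, 0)
#' makeGroundTruth(fIntra = 0.5, kEx = 1e6)@weights  # wC = wD = 0.25
#' @export
makeGroundTruth <- function(dIntra = 6e-11, dExtra = 1e-9, fIntra = 0.5,
                            kEx = 2, tm = 0.1) {
  stopifnot(fIntra > 0, fIntra < 1, kEx >= 0, tm >= 0,
            dIntra > 0, dExtra > 0)
  fex <- 1 - exp(-kEx * tm)
  wC <- fIntra * (1 - fIntra) * fex
  rest <- 1 - 2 * wC
  w <- c(wA = rest * (1 - fIntra), wB = rest * fIntra, wC = wC, wD = wC)
  new("ExchangeGroundTruth", dIntra = dIntra, dExtra = dExtra,
      fIntra = fIntra, kEx = kEx, tm = tm, weights = w)
}

# four-component spectrum of a ground truth as (weights, D1, D2) triplets
.truth_components <- function(truth) {
  De <- truth@dExtra; Di <- truth@dIntra
  w <- truth@weights
  list(w = unname(w),
       d1 = c(De, Di, De, Di),
       d2 = c(De, Di, Di, De))
}

#' Generate a synthetic DEXSY signal matrix from a ground truth
#'
#' Evaluates the closed-form double-exponential forward model over the four
#' components (A, B and the two cross peaks), optionally adds zero-mean
#' Gaussian noise per cell, and renormalizes so S(0,0) = 1. Deterministic
#' given `seed`.
#'
#' @param truth an [ExchangeGroundTruth-class].
#' @param sequence a [DexsySequence-class]; its timings define the b-values.
#' @param noiseSd additive Gaussian noise standard deviation (on S/S0).
#' @param seed RNG seed for the noise.
#' @param gamma gyromagnetic ratio.
#' @return a [SignalMatrix-class] with the ground-truth parameters recorded
#'   in `meta` (labelled synthetic).
#' @export
generateDexsySignal <- function(truth, sequence = dexsySequence(),
                                noiseSd = 0, seed = 1L, gamma = GAMMA_H) {
  stopifnot(noiseSd >= 0)
  cmp <- .truth_components(truth)
  b1 <- bValue(sequence@G1List, sequence@pair1@delta, sequence@pair1@Delta, gamma)
  b2 <- bValue(sequence@G2List, sequence@pair2@delta, sequence@pair2@Delta, gamma)
  S <- matrix(0, length(b1), length(b2))
  for (k in seq_along(cmp$w))
    S <- S + cmp$w[k] * outer(exp(-b1 * cmp$d1[k]), exp(-b2 * cmp$d2[k]))
  if (noiseSd > 0)
    S <- S + with_seed(seed, matrix(rnorm(length(S), 0, noiseSd),
                                    nrow(S), ncol(S)))
  S <- S / S[1, 1]
  new("SignalMatrix", values = S, G1 = sequence@G1List, G2 = sequence@G2List,
      b1 = b1, b2 = b2,
      delta = c(sequence@pair1@delta, sequence@pair2@delta),
      Delta = c(sequence@pair1@Delta, sequence@pair2@Delta),
      tm = sequence@tm, gamma = gamma, direction = sequence@pair1@direction,
      se = if (noiseSd > 0) matrix(noiseSd, nrow(S), ncol(S)) else matrix(0, 0, 0),
      meta = list(synthetic = TRUE, dIntra = truth@dIntra,
                  dExtra = truth@dExtra, fIntra = truth@fIntra,
                  kEx = truth@kEx, weights = truth@weights,
                  noiseSd = noiseSd, seed = seed))
}

#' Generate synthetic per-tm ADC values from the AXR recovery model
#'
#' Evaluates \eqn{ADC(t_m) = ADC_{eq}(1 - \sigma e^{-AXR\, t_m})} and adds
#' Gaussian noise. Deterministic given `seed`.
#'
#' @param adcEq equilibrium ADC (m^2/s).
#' @param sigma filter efficiency in \[0, 1\].
#' @param axr apparent exchange rate (1/s).
#' @param tmList mixing times (s).
#' @param noiseSd Gaussian noise standard deviation (m^2/s).
#' @param seed RNG seed.
#' @return numeric vector of ADC values.
#' @export
generateFexsyADC <- function(adcEq = 1e-9, sigma = 0.3, axr = 2,
                             tmList = c(0, 0.01, 0.1, 0.2, 0.3),
                             noiseSd = 0, seed = 1L) {
  stopifnot(adcEq > 0, sigma >= 0, sigma <= 1, axr >= 0, noiseSd >= 0)
  adc <- adcEq * (1 - sigma * exp(-axr * tmList))
  if (noiseSd > 0)
    adc <- adc + with_seed(seed, rnorm(length(tmList), 0, noiseSd))
  adc
}
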