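#' @include montecarlo.R
NULL

#' Construct a PGSE encoding pair
#'
#' @param delta gradient pulse duration (s).
#' @param Delta pulse separation (s), at least `delta`.
#' @param G fixed gradient amplitude (T/m) or `NA` when swept.
#' @param direction gradient direction (normalized internally).
#' @return a [PgsePair-class].
#' @export
pgsePair <- function(delta = 0.015, Delta = 0.017, G = NA_real_,
                     direction = c(1, 0, 0)) {
  new("PgsePair", G = G, delta = delta, Delta = Delta,
      direction = direction / sqrt(sum(direction^2)))
}

#' Construct a DEXSY sequence
#'
#' Defaults reproduce the simulated protocol: delta = 15 ms, Delta = 17 ms,
#' tm = 100 ms, both gradients swept 0-900 mT/m in 16 linearly spaced steps.
#'
#' @param delta,Delta shared pair timings (s).
#' @param tm mixing time (s), measured from the end of the first pair's
#'   second lobe to the start of the second pair.
#' @param Gmax maximum gradient amplitude (T/m).
#' @param nG number of amplitudes per axis.
#' @param direction gradient direction.
#' @return a [DexsySequence-class].
#' @export
dexsySequence <- function(delta = 0.015, Delta = 0.017, tm = 0.1,
                          Gmax = 0.9, nG = 16L, direction = c(1, 0, 0)) {
  g <- seq(0, Gmax, length.out = nG)
  p <- pgsePair(delta, Delta, direction = direction)
  new("DexsySequence", pair1 = p, pair2 = p, tm = tm, G1List = g, G2List = g)
}

#' Diffusion weighting b-value of a PGSE pair
#'
#' \eqn{b = \gamma^2 \delta^2 G^2 (\Delta - \delta/3)}.
#'
#' @param G gradient amplitude (T/m); vectorized.
#' @param delta pulse duration (s).
#' @param Delta pulse separation (s), at least `delta`.
#' @param gamma gyromagnetic ratio (rad/s/T), default proton.
#' @return b-value (s/m^2).
#' @examples
#' bValue(0.64, 0.015, 0.017)
#' @export
bValue <- function(G, delta, Delta, gamma = GAMMA_H) {
  if (delta > Delta) stop("delta must not exceed Delta")
  if (any(G < 0)) stop("G must be non-negative")
  gamma^2 * delta^2 * G^2 * (Delta - delta / 3)
}

#' Closed-form DEXSY forward model
#'
#' \eqn{S/S_0 = \sum_{ij} p(D_{1i}, D_{2j}) e^{-b_1 D_{1i}} e^{-b_2 D_{2j}}},
#' evaluated exactly for a discrete spectrum of weights.
#'
#' @param weights non-negative matrix p(D1, D2) summing to 1 (rows = D1).
#' @param D1,D2 diffusivities (m^2/s) indexing rows and columns of `weights`.
#' @param b1,b2 b-value vectors (s/m^2) of the two encodings.
#' @return `length(b1) x length(b2)` matrix of S/S0.
#' @examples
#' forwardSignal(matrix(1), 1e-9, 1e-9, b1 = 0, b2 = 0)  # 1
#' @export
forwardSignal <- function(weights, D1, D2, b1, b2) {
  weights <- as.matrix(weights)
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1")
  K1 <- exp(-outer(b1, D1))
  K2 <- exp(-outer(b2, D2))
  K1 %*% weights %*% t(K2)
}

# ---------------------------------------------------------------------------
# waveform construction and phase integrals
# ---------------------------------------------------------------------------

# unit effective waveform of one PGSE pair as per-step amplitudes (+1 first
# lobe, -1 second lobe after the refocusing pulse), with timings rounded to
# whole steps; returns the vector plus the rounded timings
.pgse_waveform <- function(nSteps, dt, delta, Delta, startStep = 0L) {
  nd <- max(1L, as.integer(round(delta / dt)))
  nD <- as.integer(round(Delta / dt))
  if (nD < nd) stop("Delta shorter than delta after step rounding")
  endStep <- startStep + nD + nd
  if (endStep > nSteps) stop("sequence longer than the simulated duration")
  w <- numeric(nSteps)
  w[(startStep + 1):(startStep + nd)] <- 1
  w[(startStep + nD + 1):(startStep + nD + nd)] <- -1
  list(w = w, delta = nd * dt, Delta = nD * dt, endStep = endStep)
}

# per-walker phase integral per unit gradient amplitude:
# gamma * dt * sum_t w(t) x(t), using the stored projected positions at the
# start of each step
.phase_integral <- function(ensemble, w, gamma = GAMMA_H) {
  n <- ensemble@params@nSteps
  if (!nrow(ensemble@proj))
    stop("ensemble was simulated without projection storage")
  idx <- which(w != 0)
  gamma * timeStep(ensemble@params) *
    drop(crossprod(ensemble@proj[idx, , drop = FALSE], w[idx]))
}

.mean_cos <- function(phi) c(mean(cos(phi)), sd(cos(phi)) / sqrt(length(phi)))

#' Synthesize a DEXSY signal matrix from a walker ensemble
#'
#' Accumulates, per walker, the phase of the full piecewise-constant
#' effective gradient waveform (finite pulses: every simulation step during
#' the pulses contributes), and averages `cos(phase)` over the ensemble for
#' every (G1, G2) pair. Pulse timings are rounded to whole simulation steps
#' and the stored b-values are recomputed from the rounded timings.
#'
#' @param ensemble a [WalkEnsemble-class] with stored projections.
#' @param sequence a [DexsySequence-class]; its pairs must fit within the
#'   simulated duration.
#' @param gamma gyromagnetic ratio (rad/s/T).
#' @return a [SignalMatrix-class] with per-cell Monte Carlo standard errors.
#' @export
synthesizeDexsy <- function(ensemble, sequence, gamma = GAMMA_H) {
  n <- ensemble@params@nSteps
  dt <- timeStep(ensemble@params)
  p1 <- .pgse_waveform(n, dt, sequence@pair1@delta, sequence@pair1@Delta, 0L)
  ntm <- as.integer(round(sequence@tm / dt))
  p2 <- .pgse_waveform(n, dt, sequence@pair2@delta, sequence@pair2@Delta,
                       p1$endStep + ntm)
  phi1 <- .phase_integral(ensemble, p1$w, gamma)
  phi2 <- .phase_integral(ensemble, p2$w, gamma)
  G1 <- sequence@G1List; G2 <- sequence@G2List
  S <- matrix(NA_real_, length(G1), length(G2))
  SE <- S
  for (j in seq_along(G2)) {
    ph2 <- G2[j] * phi2
    for (i in seq_along(G1)) {
      mc <- .mean_cos(G1[i] * phi1 + ph2)
      S[i, j] <- mc[1]; SE[i, j] <- mc[2]
    }
  }
  S0 <- S[1, 1]
  new("SignalMatrix", values = S / S0, G1 = G1, G2 = G2,
      b1 = bValue(G1, p1$delta, p1$Delta, gamma),
      b2 = bValue(G2, p2$delta, p2$Delta, gamma),
      delta = c(p1$delta, p2$delta), Delta = c(p1$Delta, p2$Delta),
      tm = ntm * dt, gamma = gamma, direction = sequence@pair1@direction,
      se = SE / S0,
      meta = list(nWalkers = ensemble@params@nWalkers,
                  transitProb = ensemble@params@transitProb,
                  substrate = ensemble@substrateType))
}

#' Synthesize a DOSY (single PGSE) signal from a walker ensemble
#'
#' @param ensemble a [WalkEnsemble-class] with stored projections.
#' @param delta,Delta pair timings (s).
#' @param GList gradient amplitudes (T/m); default 0-900 mT/m in 256 steps.
#' @param gamma gyromagnetic ratio.
#' @return list with `signal` (S/S0), `b` (s/m^2), `G`, `se`, and the rounded
#'   `delta`, `Delta`.
#' @export
synthesizeDosy <- function(ensemble, delta = 0.015, Delta = 0.017,
                           GList = seq(0, 0.9, length.out = 256),
                           gamma = GAMMA_H) {
  n <- ensemble@params@nSteps
  dt <- timeStep(ensemble@params)
  p1 <- .pgse_waveform(n, dt, delta, Delta, 0L)
  phi <- .phase_integral(ensemble, p1$w, gamma)
  res <- vapply(GList, function(g) .mean_cos(g * phi), numeric(2))
  S0 <- res[1, 1]
  list(signal = res[1, ] / S0, b = bValue(GList, p1$delta, p1$Delta, gamma),
       G = GList, se = res[2, ] / S0, delta = p1$delta, Delta = p1$Delta)
}

#' Synthesize a FEXSY acquisition from a walker ensemble
#'
#' The first pair at fixed `filterG` suppresses fast-diffusing spins; after a
#' mixing time, a second pair sweeps `encodeList`. Defaults follow the
#' simulated protocol: filter 68 mT/m, encode 0-68 mT/m in 9 steps,
#' tm = 0, 10, 100, 200, 300 ms.
#'
#' @param ensemble a [WalkEnsemble-class] with stored projections.
#' @param filterG filter gradient amplitude (T/m).
#' @param encodeList encode amplitudes (T/m), starting at 0.
#' @param delta,Delta shared pair timings (s).
#' @param tmList mixing times (s).
#' @param gamma gyromagnetic ratio.
#' @return a [FexsyAcquisition-class].
#' @export
synthesizeFexsy <- function(ensemble, filterG = 0.068,
                            encodeList = seq(0, 0.068, length.out = 9),
                            delta = 0.015, Delta = 0.017,
                            tmList = c(0, 0.01, 0.1, 0.2, 0.3),
                            gamma = GAMMA_H) {
  n <- ensemble@params@nSteps
  dt <- timeStep(ensemble@params)
  p1 <- .pgse_waveform(n, dt, delta, Delta, 0L)
  phiF <- .phase_integral(ensemble, p1$w, gamma)
  S <- matrix(NA_real_, length(encodeList), length(tmList))
  for (j in seq_along(tmList)) {
    ntm <- as.integer(round(tmList[j] / dt))
    p2 <- .pgse_waveform(n, dt, delta, Delta, p1$endStep + ntm)
    phiE <- .phase_integral(ensemble, p2$w, gamma)
    base <- filterG * phiF
    for (i in seq_along(encodeList))
      S[i, j] <- mean(cos(base + encodeList[i] * phiE))
  }
  new("FexsyAcquisition", filterG = filterG, encodeG = encodeList,
      bEncode = bValue(encodeList, p1$delta, p1$Delta, gamma),
      tmList = tmList, signals = S, delta = p1$delta, Delta = p1$Delta)
}
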