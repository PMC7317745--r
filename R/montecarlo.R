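#' @include substrates.R
NULL

#' Membrane transit probability from permeability
#'
#' Per-encounter probability that a random walker crosses the cell membrane,
#' \eqn{p = k \sqrt{6\, dt / D}}, clipped to \[0, 1\]. With the reference
#' simulation settings (dt = 400 ms / 16000 steps, D = 2.0e-9 m^2/s) the
#' probabilities 0.0001 and 0.00055 correspond to permeabilities of 0.37 and
#' 2.0 um/s.
#'
#' @param k membrane permeability (m/s), non-negative.
#' @param dt simulation time step (s), positive.
#' @param D intrinsic diffusivity (m^2/s), positive.
#' @return transit probability in \[0, 1\].
#' @seealso [permeabilityFromProbability()] for the exact inverse.
#' @examples
#' transitProbability(0.37e-6, dt = 0.4 / 16000, D = 2e-9)
#' @export
transitProbability <- function(k, dt, D) {
  if (any(dt <= 0) || any(D <= 0)) stop("dt and D must be positive")
  if (any(k < 0)) stop("permeability must be non-negative")
  pmin(k * sqrt(6 * dt / D), 1)
}

#' Membrane permeability from transit probability
#'
#' Exact inverse of [transitProbability()] (below the clipping point):
#' \eqn{k = p \sqrt{D / (6\, dt)}}.
#'
#' @param p transit probability in \[0, 1\].
#' @param dt simulation time step (s), positive.
#' @param D intrinsic diffusivity (m^2/s), positive.
#' @return permeability (m/s).
#' @examples
#' permeabilityFromProbability(1e-4, dt = 0.4 / 16000, D = 2e-9) * 1e6  # um/s
#' @export
permeabilityFromProbability <- function(p, dt, D) {
  if (any(dt <= 0) || any(D <= 0)) stop("dt and D must be positive")
  if (any(p < 0 | p > 1)) stop("probability must lie in [0, 1]")
  p * sqrt(D / (6 * dt))
}

#' Construct walk parameters
#'
#' @param nWalkers number of walkers.
#' @param duration total simulated time (s).
#' @param nSteps number of time steps (`dt = duration / nSteps`; the step
#'   length is `sqrt(6 * diffusivity * dt)`).
#' @param diffusivity intrinsic diffusivity (m^2/s), identical inside and
#'   outside the cells.
#' @param transitProb per-encounter membrane transit probability.
#' @param permeability alternatively, a membrane permeability (m/s) converted
#'   internally with [transitProbability()] at this run's `dt`; exactly one
#'   of `transitProb`/`permeability` may be given.
#' @param seed master seed; every walker uses an independent counter-based
#'   substream, so results do not depend on batching order.
#' @return a [WalkParams-class].
#' @export
walkParams <- function(nWalkers = 1e4, duration = 0.4, nSteps = 16000L,
                       diffusivity = 2e-9, transitProb = NULL,
                       permeability = NULL, seed = 1L) {
  if (is.null(transitProb) && is.null(permeability)) transitProb <- 0
  if (!is.null(permeability)) {
    if (!is.null(transitProb))
      stop("give either transitProb or permeability, not both")
    transitProb <- transitProbability(permeability,
                                      dt = duration / nSteps, D = diffusivity)
  }
  new("WalkParams", nWalkers = as.integer(nWalkers), duration = duration,
      nSteps = as.integer(nSteps), diffusivity = diffusivity,
      transitProb = transitProb, seed = as.integer(seed))
}

#' Time step of a walk
#' @param params a [WalkParams-class].
#' @return `duration / nSteps` (s).
#' @export
timeStep <- function(params) params@duration / params@nSteps

#' Simulate random-walk diffusion with permeable membranes
#'
#' Walkers start uniformly in the periodic cell and take fixed-length steps
#' `sqrt(6 D dt)` in directions uniform on the sphere. A step intersecting a
#' membrane is transmitted with probability `transitProb` (continuing along
#' its original direction) and specularly reflected otherwise; multiple
#' membrane interactions within one step are processed iteratively, and the
#' walker is nudged 1e-12 m off the surface after each event so the same
#' membrane is not re-detected.
#'
#' @param substrate a [CylinderSubstrate-class], [SphereSubstrate-class], or
#'   `NULL` for free diffusion.
#' @param params a [WalkParams-class].
#' @param direction measurement direction(s) on which projected positions are
#'   stored: a unit vector, or a matrix with one direction per row (default
#'   x, perpendicular to cylinder axes). With several rows the synthesis
#'   functions average the signal over directions, which reduces Monte Carlo
#'   noise on isotropic substrates.
#' @param storeProj keep the per-step projected unwrapped positions needed by
#'   the signal synthesis functions.
#' @param storePositions keep full 3D unwrapped trajectories (small runs
#'   only).
#' @param labelStride record compartment labels every this many steps.
#' @param waveforms optional `nSteps x K` matrix of gradient waveform values
#'   per step; when given, per-walker sums \eqn{\sum_t w_k(t)\, x(t)} are
#'   accumulated on the fly (multiply by gamma, dt and the gradient amplitude
#'   to obtain phases). This is the low-memory alternative to `storeProj` and
#'   agrees with it exactly.
#' @return a [WalkEnsemble-class].
#' @examples
#' params <- walkParams(nWalkers = 200, nSteps = 100, duration = 0.01, seed = 2)
#' ens <- simulateWalk(NULL, params)
#' mean(rowSums(ens@displacement^2)) / (6 * 2e-9 * 0.01)  # ~ 1
#' @export
simulateWalk <- function(substrate, params, direction = c(1, 0, 0),
                         storeProj = TRUE, storePositions = FALSE,
                         labelStride = max(1L, params@nSteps %/% 100L),
                         waveforms = NULL) {
  sub <- if (is.null(substrate)) {
    list(type = "spheres", centers = matrix(numeric(0), 0, 3),
         radii = numeric(0), L = 1)
  } else geomList(substrate)
  if (is.null(dim(direction))) direction <- matrix(direction, nrow = 1)
  direction <- direction / sqrt(rowSums(direction^2))
  res <- cpp_simulate(sub, params@nWalkers, params@nSteps, timeStep(params),
                      params@diffusivity, params@transitProb, params@seed,
                      direction, storeProj, storePositions,
                      as.integer(labelStride), waveforms)
  ens <- new("WalkEnsemble", params = params,
             direction = direction,
             proj = if (storeProj) res$proj else matrix(numeric(0), 0, 0),
             displacement = res$displacement, initial = res$initial,
             labels = res$labels, labelSteps = as.integer(res$label_steps),
             crossings = as.integer(res$crossings),
             positions = if (storePositions) res$positions else NULL,
             substrateType = if (is.null(substrate)) "free" else sub$type)
  if (!is.null(waveforms)) attr(ens@proj, "phase") <- res$phase
  ens
}

#' Phase integrals accumulated on the fly during simulation
#'
#' @param ensemble a [WalkEnsemble-class] simulated with `waveforms`.
#' @return nWalkers x K matrix of raw sums (projected position times waveform
#'   value per step; multiply by gamma and dt for phase per unit gradient),
#'   or `NULL`.
#' @export
accumulatedPhase <- function(ensemble) attr(ensemble@proj, "phase")

#' Fraction of walkers that changed compartment between two checkpoints
#'
#' @param ensemble a [WalkEnsemble-class].
#' @param fromStep,toStep step indices; the nearest recorded label
#'   checkpoints are used (defaults: first and last).
#' @return proportion of walkers whose compartment label differs.
#' @export
fractionExchanged <- function(ensemble, fromStep = 0L,
                              toStep = ensemble@params@nSteps) {
  ck <- ensemble@labelSteps
  i <- which.min(abs(ck - fromStep))
  j <- which.min(abs(ck - toStep))
  mean(ensemble@labels[i, ] != ensemble@labels[j, ])
}
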