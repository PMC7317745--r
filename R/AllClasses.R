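#' @include dexsim-package.R
NULL

# ---------------------------------------------------------------------------
# substrates
# ---------------------------------------------------------------------------

#' Virtual parent of the periodic substrate geometries
#'
#' @slot seed integer seed that produced the arrangement.
#' @exportClass Substrate
setClass("Substrate", representation("VIRTUAL", seed = "integer"))

#' Periodic substrate of parallel axis-aligned cylinders
#'
#' Models a nerve-bundle geometry: parallel cylinders (axes along z) with
#' gamma-distributed radii, packed without overlap in a square periodic cell
#' of side `latticeSize`. Lengths in metres.
#'
#' @slot radii cylinder radii (m).
#' @slot centers n x 2 matrix of axis positions in the periodic cell (m).
#' @slot latticeSize side of the periodic cell (m).
#' @slot gammaShape,gammaScale parameters of the radius distribution.
#' @exportClass CylinderSubstrate
setClass("CylinderSubstrate", contains = "Substrate",
  representation(radii = "numeric", centers = "matrix",
                 latticeSize = "numeric", gammaShape = "numeric",
                 gammaScale = "numeric"))

#' Periodic substrate of equal spheres
#'
#' Models a dense cell suspension (for example yeast): `n` spheres of common
#' radius in a cubic periodic box whose side is set by the target packing
#' fraction. Lengths in metres.
#'
#' @slot centers n x 3 matrix of sphere centres (m).
#' @slot radius common sphere radius (m).
#' @slot boxSide side of the cubic periodic box (m).
#' @slot packingFraction target intracellular volume fraction.
#' @exportClass SphereSubstrate
setClass("SphereSubstrate", contains = "Substrate",
  representation(centers = "matrix", radius = "numeric", boxSide = "numeric",
                 packingFraction = "numeric"))

.min_image <- function(d, L) d - L * round(d / L)

setValidity("CylinderSubstrate", function(object) {
  n <- length(object@radii)
  if (nrow(object@centers) != n) return("centers/radii length mismatch")
  if (any(object@radii <= 0)) return("all radii must be positive")
  L <- object@latticeSize
  if (L <= 0) return("latticeSize must be positive")
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      dx <- .min_image(object@centers[(i + 1):n, 1] - object@centers[i, 1], L)
      dy <- .min_image(object@centers[(i + 1):n, 2] - object@centers[i, 2], L)
      gap <- sqrt(dx^2 + dy^2) - (object@radii[(i + 1):n] + object@radii[i])
      if (any(gap < -1e-12 * L)) return("cylinders overlap under periodic wrap")
    }
  }
  TRUE
})

setValidity("SphereSubstrate", function(object) {
  n <- nrow(object@centers)
  if (object@radius <= 0) return("radius must be positive")
  L <- object@boxSide
  if (L <= 0) return("boxSide must be positive")
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      dx <- .min_image(object@centers[(i + 1):n, 1] - object@centers[i, 1], L)
      dy <- .min_image(object@centers[(i + 1):n, 2] - object@centers[i, 2], L)
      dz <- .min_image(object@centers[(i + 1):n, 3] - object@centers[i, 3], L)
      if (any(sqrt(dx^2 + dy^2 + dz^2) < 2 * object@radius - 1e-12 * L))
        return("spheres overlap under periodic wrap")
    }
  }
  phi <- n * (4 / 3) * pi * object@radius^3 / L^3
  if (abs(phi - object@packingFraction) > 0.01)
    return("achieved packing fraction deviates from target by more than 0.01")
  TRUE
})

# ---------------------------------------------------------------------------
# random walk
# ---------------------------------------------------------------------------

#' Parameters of a random-walk simulation
#'
#' @slot nWalkers number of random walkers.
#' @slot duration total simulated time (s).
#' @slot nSteps number of time steps; `dt = duration / nSteps`.
#' @slot diffusivity intrinsic diffusivity D (m^2/s), identical in all
#'   compartments.
#' @slot transitProb per-encounter membrane transit probability in \[0, 1\].
#' @slot seed master seed; each walker derives an independent substream.
#' @exportClass WalkParams
setClass("WalkParams",
  representation(nWalkers = "integer", duration = "numeric", nSteps = "integer",
                 diffusivity = "numeric", transitProb = "numeric",
                 seed = "integer"))

setValidity("WalkParams", function(object) {
  if (object@nWalkers < 1L || object@nSteps < 1L) return("need >= 1 walker and step")
  if (object@duration <= 0 || object@diffusivity <= 0)
    return("duration and diffusivity must be positive")
  if (object@transitProb < 0 || object@transitProb > 1)
    return("transitProb must lie in [0, 1]")
  TRUE
})

#' Ensemble of simulated random walkers
#'
#' Wrapped positions live in the periodic cell; displacements are tracked
#' unwrapped. `proj` holds, per time step, the unwrapped position of every
#' walker projected on the measurement `direction`, the quantity entering
#' gradient phase integrals.
#'
#' @slot params the [WalkParams-class] used.
#' @slot direction matrix of unit row vectors on which `proj` projects
#'   positions; several rows average the signal over gradient directions
#'   (legitimate for isotropic substrates, or within the transverse plane of
#'   a cylinder substrate).
#' @slot proj (nSteps + 1) x (nWalkers * nDirections) matrix of projected
#'   unwrapped positions (m), direction-major blocks of nWalkers columns, or
#'   a 0 x 0 matrix when projection storage was disabled.
#' @slot displacement nWalkers x 3 unwrapped net displacement (m).
#' @slot initial nWalkers x 3 initial positions (m).
#' @slot labels checkpoint x nWalkers compartment labels (0 = extracellular).
#' @slot labelSteps step indices of the label checkpoints.
#' @slot crossings number of membrane transmissions per walker.
#' @slot positions optional (nSteps + 1) x 3 x nWalkers unwrapped trajectory
#'   array for small runs, else `NULL`.
#' @slot substrateType `"spheres"`, `"cylinders"` or `"free"`.
#' @exportClass WalkEnsemble
setClass("WalkEnsemble",
  representation(params = "WalkParams", direction = "matrix", proj = "matrix",
                 displacement = "matrix", initial = "matrix",
                 labels = "matrix", labelSteps = "integer",
                 crossings = "integer", positions = "ANY",
                 substrateType = "character"))

# ---------------------------------------------------------------------------
# acquisition
# ---------------------------------------------------------------------------

#' A pulsed-gradient spin-echo encoding pair
#'
#' @slot G gradient amplitude (T/m); `NA` when the amplitude is swept.
#' @slot delta gradient pulse duration \eqn{\delta} (s).
#' @slot Delta pulse separation \eqn{\Delta} (s); `delta <= Delta`.
#' @slot direction unit gradient direction.
#' @exportClass PgsePair
setClass("PgsePair",
  representation(G = "numeric", delta = "numeric", Delta = "numeric",
                 direction = "numeric"))

setValidity("PgsePair", function(object) {
  if (object@delta <= 0) return("delta must be positive")
  if (object@delta > object@Delta) return("delta must not exceed Delta")
  if (!is.na(object@G) && object@G < 0) return("G must be non-negative")
  if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-8)
    return("direction must be a unit vector")
  TRUE
})

#' A DEXSY double diffusion-encoding sequence
#'
#' Two PGSE pairs separated by a mixing time `tm` (measured from the end of
#' the first pair's second lobe to the start of the second pair), with the
#' two gradient amplitudes swept over `G1List` and `G2List`.
#'
#' @slot pair1,pair2 the two [PgsePair-class] encoding blocks.
#' @slot tm mixing time (s).
#' @slot G1List,G2List non-decreasing gradient amplitudes (T/m) starting at 0.
#' @exportClass DexsySequence
setClass("DexsySequence",
  representation(pair1 = "PgsePair", pair2 = "PgsePair", tm = "numeric",
                 G1List = "numeric", G2List = "numeric"))

setValidity("DexsySequence", function(object) {
  if (object@tm < 0) return("tm must be non-negative")
  for (g in list(object@G1List, object@G2List)) {
    if (length(g) < 1 || g[1] != 0) return("gradient lists must start at 0")
    if (is.unsorted(g)) return("gradient lists must be non-decreasing")
  }
  TRUE
})

#' A DEXSY signal matrix S/S0 on a (G1, G2) grid
#'
#' @slot values normalized signal, `values[1, 1] = 1` at G1 = G2 = 0.
#' @slot G1,G2 gradient amplitudes (T/m) of rows and columns.
#' @slot b1,b2 b-values (s/m^2) of rows and columns.
#' @slot delta,Delta per-pair timings (s), length 2.
#' @slot tm mixing time (s).
#' @slot gamma gyromagnetic ratio used (rad/s/T).
#' @slot direction gradient direction.
#' @slot se per-cell Monte Carlo standard error, or 0 x 0 when unknown.
#' @slot meta free-form provenance list.
#' @exportClass SignalMatrix
setClass("SignalMatrix",
  representation(values = "matrix", G1 = "numeric", G2 = "numeric",
                 b1 = "numeric", b2 = "numeric", delta = "numeric",
                 Delta = "numeric", tm = "numeric", gamma = "numeric",
                 direction = "numeric", se = "matrix", meta = "list"))

setValidity("SignalMatrix", function(object) {
  if (nrow(object@values) != length(object@G1) ||
      ncol(object@values) != length(object@G2))
    return("values dimensions must match gradient lists")
  if (length(object@b1) != length(object@G1) ||
      length(object@b2) != length(object@G2))
    return("b-vector lengths must match gradient lists")
  if (object@G1[1] != 0 || object@G2[1] != 0)
    return("gradient lists must include the G = 0 (S0) cell first")
  if (is.unsorted(object@G1) || is.unsorted(object@G2))
    return("gradient lists must be non-decreasing")
  if (abs(object@values[1, 1] - 1) > 1e-6)
    return("values[1,1] must equal 1 (S0 normalization)")
  if (!all(is.finite(object@values))) return("values must be finite")
  TRUE
})

#' A FEXSY (filter exchange) acquisition
#'
#' @slot filterG fixed filter gradient amplitude (T/m).
#' @slot encodeG encode gradient amplitudes (T/m).
#' @slot bEncode b-values of the encode dimension (s/m^2).
#' @slot tmList mixing times (s).
#' @slot signals S/S0, encode x tm.
#' @slot delta,Delta shared pair timings (s).
#' @exportClass FexsyAcquisition
setClass("FexsyAcquisition",
  representation(filterG = "numeric", encodeG = "numeric", bEncode = "numeric",
                 tmList = "numeric", signals = "matrix", delta = "numeric",
                 Delta = "numeric"))

# ---------------------------------------------------------------------------
# inversion and spectra
# ---------------------------------------------------------------------------

#' Log-spaced diffusivity grid for inverse Laplace inversion
#'
#' @slot values strictly increasing diffusivities (m^2/s).
#' @exportClass DiffusivityGrid
setClass("DiffusivityGrid", representation(values = "numeric"))

setValidity("DiffusivityGrid", function(object) {
  v <- object@values
  if (length(v) < 2) return("grid needs at least two points")
  if (any(v <= 0) || any(diff(v) <= 0)) return("grid must be positive and strictly increasing")
  TRUE
})

#' A 2D diffusion-diffusion spectrum
#'
#' Non-negative amplitudes over a log-spaced (D1, D2) grid, from regularized
#' inversion of a [SignalMatrix-class].
#'
#' @slot amplitudes non-negative matrix, rows indexed by D1, columns by D2.
#' @slot grid1,grid2 the [DiffusivityGrid-class] axes.
#' @slot alpha regularization weight used.
#' @slot residual relative RMS misfit of the reconstruction.
#' @slot rank singular-value truncation ranks of the two kernels.
#' @exportClass Spectrum2D
setClass("Spectrum2D",
  representation(amplitudes = "matrix", grid1 = "DiffusivityGrid",
                 grid2 = "DiffusivityGrid", alpha = "numeric",
                 residual = "numeric", rank = "integer"))

setValidity("Spectrum2D", function(object) {
  if (any(object@amplitudes < 0)) return("amplitudes must be non-negative")
  if (nrow(object@amplitudes) != length(object@grid1@values) ||
      ncol(object@amplitudes) != length(object@grid2@values))
    return("amplitude dimensions must match the grids")
  TRUE
})

#' A 1D diffusion (DOSY) spectrum
#'
#' @slot amplitudes non-negative amplitudes over the grid.
#' @slot grid the [DiffusivityGrid-class].
#' @slot alpha regularization weight.
#' @slot residual relative RMS misfit.
#' @slot rank truncation rank of the kernel.
#' @exportClass Spectrum1D
setClass("Spectrum1D",
  representation(amplitudes = "numeric", grid = "DiffusivityGrid",
                 alpha = "numeric", residual = "numeric", rank = "integer"))

#' Diffusion Exchange Index result
#'
#' @slot dei ratio of exchange (off-diagonal) to non-exchange (diagonal)
#'   spectral volume.
#' @slot exchangeVolume,nonExchangeVolume the two sums.
#' @slot peaks data.frame of all segmented peaks (label, d1, d2, volume).
#' @slot excluded peaks left out of the ratio (label `"unassigned"`).
#' @exportClass DeiResult
setClass("DeiResult",
  representation(dei = "numeric", exchangeVolume = "numeric",
                 nonExchangeVolume = "numeric", peaks = "data.frame",
                 excluded = "data.frame"))

#' Apparent exchange rate (AXR) fit
#'
#' Parameters of \eqn{ADC(t_m) = ADC_{eq} (1 - \sigma e^{-AXR\, t_m})}.
#'
#' @slot axr apparent exchange rate (1/s).
#' @slot sigma filter efficiency in \[0, 1\].
#' @slot adcEq equilibrium ADC (m^2/s).
#' @slot adc per-mixing-time ADC values fitted from the encode dimension.
#' @slot tm mixing times (s).
#' @slot cov parameter covariance matrix (may be all-NA if unavailable).
#' @exportClass AxrFit
setClass("AxrFit",
  representation(axr = "numeric", sigma = "numeric", adcEq = "numeric",
                 adc = "numeric", tm = "numeric", cov = "matrix"))

setValidity("AxrFit", function(object) {
  if (object@axr < 0) return("AXR must be non-negative")
  if (object@sigma < 0 || object@sigma > 1) return("sigma must lie in [0, 1]")
  if (object@adcEq <= 0) return("adcEq must be positive")
  TRUE
})

# ---------------------------------------------------------------------------
# synthetic ground truth
# ---------------------------------------------------------------------------

#' Two-site equilibrium exchange ground truth (synthetic)
#'
#' A synthetic stand-in for DEXSY data: two diffusivity pools with a fraction
#' of mass exchanged during the mixing time, split into four spectral
#' components A (extra/extra), B (intra/intra), C and D (cross terms).
#'
#' @slot dIntra,dExtra pool diffusivities (m^2/s).
#' @slot fIntra intracellular fraction.
#' @slot kEx exchange rate (1/s).
#' @slot tm mixing time (s).
#' @slot weights named numeric (wA, wB, wC, wD), non-negative, summing to 1.
#' @exportClass ExchangeGroundTruth
setClass("ExchangeGroundTruth",
  representation(dIntra = "numeric", dExtra = "numeric", fIntra = "numeric",
                 kEx = "numeric", tm = "numeric", weights = "numeric"))

setValidity("ExchangeGroundTruth", function(object) {
  w <- object@weights
  if (length(w) != 4 || any(w < -1e-12)) return("need 4 non-negative weights")
  if (abs(sum(w) - 1) > 1e-9) return("weights must sum to 1")
  if (abs(w[["wC"]] - w[["wD"]]) > 1e-9)
    return("detailed balance requires wC == wD")
  TRUE
})
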