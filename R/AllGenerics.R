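#' @include AllClasses.R
NULL

#' Compartment label of points in a substrate
#'
#' Maps each point (wrapped into the periodic cell) to the index of the
#' containing object, or 0 for the extracellular space.
#'
#' @param substrate a [CylinderSubstrate-class] or [SphereSubstrate-class].
#' @param points numeric matrix of coordinates (m), one point per row
#'   (2 columns suffice for cylinders), or a single point as a vector.
#' @return integer vector of labels (0 = extracellular).
#' @export
setGeneric("locate", function(substrate, points) standardGeneric("locate"))

#' Earliest membrane crossing along line segments
#'
#' Finds, for each segment, the first intersection with any object membrane
#' under the periodic wrap, together with the outward surface normal.
#'
#' @param substrate a substrate object.
#' @param start,end matrices of segment endpoints (m), one segment per row.
#' @return data.frame with `distance` (m along the segment, `NA` if no hit),
#'   `object` (1-based index, 0 if none) and normal components `nx`,`ny`,`nz`.
#' @export
setGeneric("firstIntersection",
           function(substrate, start, end) standardGeneric("firstIntersection"))

#' Analytic intracellular volume fraction of a substrate
#'
#' @param substrate a substrate object.
#' @return the fraction of the periodic cell occupied by objects.
#' @export
setGeneric("intracellularFraction",
           function(substrate) standardGeneric("intracellularFraction"))

# internal: plain list representation handed to the C++ geometry kernels
setGeneric("geomList", function(substrate) standardGeneric("geomList"))

#' @describeIn locate cylinders (third coordinate, if any, is ignored)
setMethod("locate", "CylinderSubstrate", function(substrate, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  cpp_locate(geomList(substrate), as.matrix(points))
})

#' @describeIn locate spheres
setMethod("locate", "SphereSubstrate", function(substrate, points) {
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  cpp_locate(geomList(substrate), as.matrix(points))
})

.first_intersection <- function(substrate, start, end) {
  if (is.null(dim(start))) start <- matrix(start, nrow = 1)
  if (is.null(dim(end))) end <- matrix(end, nrow = 1)
  res <- cpp_first_intersection(geomList(substrate), as.matrix(start),
                                as.matrix(end))
  as.data.frame(res)
}

#' @describeIn firstIntersection cylinders
setMethod("firstIntersection", "CylinderSubstrate", function(substrate, start, end)
  .first_intersection(substrate, start, end))

#' @describeIn firstIntersection spheres
setMethod("firstIntersection", "SphereSubstrate", function(substrate, start, end)
  .first_intersection(substrate, start, end))

setMethod("geomList", "CylinderSubstrate", function(substrate) {
  list(type = "cylinders", centers = substrate@centers,
       radii = substrate@radii, L = substrate@latticeSize)
})

setMethod("geomList", "SphereSubstrate", function(substrate) {
  list(type = "spheres", centers = substrate@centers,
       radii = rep(substrate@radius, nrow(substrate@centers)),
       L = substrate@boxSide)
})

setMethod("intracellularFraction", "CylinderSubstrate", function(substrate)
  sum(pi * substrate@radii^2) / substrate@latticeSize^2)

setMethod("intracellularFraction", "SphereSubstrate", function(substrate)
  nrow(substrate@centers) * (4 / 3) * pi * substrate@radius^3 / substrate@boxSide^3)

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "CylinderSubstrate", function(object) {
  cat(sprintf("CylinderSubstrate: %d parallel cylinders, lattice %.3g m\n",
              length(object@radii), object@latticeSize))
  cat(sprintf("  radii: mean %.3g m (gamma shape %.4g, scale %.3g)\n",
              mean(object@radii), object@gammaShape, object@gammaScale))
  cat(sprintf("  intracellular area fraction: %.3f\n",
              intracellularFraction(object)))
})

setMethod("show", "SphereSubstrate", function(object) {
  cat(sprintf("SphereSubstrate: %d spheres of radius %.3g m, box %.3g m\n",
              nrow(object@centers), object@radius, object@boxSide))
  cat(sprintf("  packing fraction: %.3f\n", intracellularFraction(object)))
})

setMethod("show", "WalkParams", function(object) {
  cat(sprintf(
    "WalkParams: %d walkers, %d steps over %.3g s (dt = %.3g s)\n",
    object@nWalkers, object@nSteps, object@duration,
    object@duration / object@nSteps))
  cat(sprintf("  D = %.3g m^2/s, transit probability = %.3g, seed = %d\n",
              object@diffusivity, object@transitProb, object@seed))
})

setMethod("show", "WalkEnsemble", function(object) {
  cat(sprintf("WalkEnsemble in %s substrate\n", object@substrateType))
  show(object@params)
  cat(sprintf("  projections stored: %s; full positions: %s\n",
              if (nrow(object@proj)) "yes" else "no",
              if (is.null(object@positions)) "no" else "yes"))
  cat(sprintf("  mean membrane crossings per walker: %.2f\n",
              mean(object@crossings)))
})

setMethod("show", "SignalMatrix", function(object) {
  cat(sprintf("SignalMatrix: %d x %d (G up to %.3g / %.3g T/m)\n",
              length(object@G1), length(object@G2),
              max(object@G1), max(object@G2)))
  cat(sprintf("  delta = %s s, Delta = %s s, tm = %.3g s\n",
              paste(signif(object@delta, 3), collapse = "/"),
              paste(signif(object@Delta, 3), collapse = "/"), object@tm))
})

setMethod("show", "Spectrum2D", function(object) {
  cat(sprintf("Spectrum2D: %d x %d grid over [%.2g, %.2g] m^2/s\n",
              nrow(object@amplitudes), ncol(object@amplitudes),
              min(object@grid1@values), max(object@grid1@values)))
  cat(sprintf("  alpha = %.3g, relative residual = %.3g, ranks = %s\n",
              object@alpha, object@residual,
              paste(object@rank, collapse = "/")))
  cat(sprintf("  total amplitude = %.4f\n", sum(object@amplitudes)))
})

setMethod("show", "DeiResult", function(object) {
  cat(sprintf("DEI = %.4g (exchange %.4g / non-exchange %.4g)\n",
              object@dei, object@exchangeVolume, object@nonExchangeVolume))
  if (nrow(object@peaks)) {
    cat("  peaks:\n")
    print(object@peaks, row.names = FALSE)
  }
})

setMethod("show", "AxrFit", function(object) {
  cat(sprintf("AxrFit: AXR = %.4g 1/s, sigma = %.3g, ADC_eq = %.4g m^2/s\n",
              object@axr, object@sigma, object@adcEq))
})

setMethod("show", "ExchangeGroundTruth", function(object) {
  w <- object@weights
  cat(sprintf(
    "ExchangeGroundTruth (synthetic two-site model): k_ex = %.3g 1/s, tm = %.3g s\n",
    object@kEx, object@tm))
  cat(sprintf("  weights: A = %.3f, B = %.3f, C = %.3f, D = %.3f\n",
              w[["wA"]], w[["wB"]], w[["wC"]], w[["wD"]]))
})

# ---------------------------------------------------------------------------
# simple accessors
# ---------------------------------------------------------------------------

#' Signal values of a SignalMatrix
#' @param x a [SignalMatrix-class].
#' @return the S/S0 matrix.
#' @export
signalValues <- function(x) {
  stopifnot(is(x, "SignalMatrix"))
  x@values
}

#' Amplitudes of a spectrum
#' @param x a [Spectrum2D-class] or [Spectrum1D-class].
#' @return the non-negative amplitude matrix or vector.
#' @export
spectrumValues <- function(x) {
  stopifnot(is(x, "Spectrum2D") || is(x, "Spectrum1D"))
  x@amplitudes
}

#' Diffusivity axis of a grid or spectrum
#' @param x a [DiffusivityGrid-class], [Spectrum2D-class] or [Spectrum1D-class].
#' @return numeric vector of diffusivities (m^2/s).
#' @export
gridValues <- function(x) {
  if (is(x, "DiffusivityGrid")) return(x@values)
  if (is(x, "Spectrum2D")) return(x@grid1@values)
  if (is(x, "Spectrum1D")) return(x@grid@values)
  stop("no diffusivity grid in this object")
}

#' The Diffusion Exchange Index of a DeiResult
#' @param x a [DeiResult-class].
#' @return the DEI value.
#' @export
dei <- function(x) {
  stopifnot(is(x, "DeiResult"))
  x@dei
}

#' The apparent exchange rate of an AxrFit
#' @param x an [AxrFit-class].
#' @return AXR in 1/s.
#' @export
axr <- function(x) {
  stopifnot(is(x, "AxrFit"))
  x@axr
}

#' Segmented peak table of a DeiResult
#' @param x a [DeiResult-class].
#' @param includeExcluded also append unassigned peaks.
#' @return data.frame with label, centroid diffusivities and volume.
#' @export
peakTable <- function(x, includeExcluded = FALSE) {
  stopifnot(is(x, "DeiResult"))
  if (includeExcluded && nrow(x@excluded)) rbind(x@peaks, x@excluded) else x@peaks
}
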