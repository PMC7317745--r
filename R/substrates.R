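#' @include AllGenerics.R
NULL

#' Build a periodic substrate of parallel cylinders with gamma radii
#'
#' Draws `nCylinders` radii from a gamma distribution and places the
#' cylinders by random sequential addition (largest first) in a square
#' periodic cell, rejecting overlapping positions. If a radius draw cannot
#' be packed within the retry budget, the radii are re-drawn from a new
#' sub-seed; after `maxRedraws` failures an error reports the achieved
#' density. The default parameters reproduce a corpus-callosum-style nerve
#' bundle: shape 5.3316, scale 1.0242e-7 m, 100 cylinders in a 1.65e-5 m
#' lattice (intracellular area fraction about 0.41).
#'
#' @param gammaShape,gammaScale gamma distribution of radii (scale in m).
#' @param nCylinders number of cylinders.
#' @param latticeSize periodic cell side (m).
#' @param seed integer seed; the build is deterministic given it.
#' @param maxAttempts placement attempts per cylinder.
#' @param maxRedraws full re-draws of the radius set before giving up.
#' @return a [CylinderSubstrate-class].
#' @examples
#' sub <- buildCylinderSubstrate(nCylinders = 20, seed = 1)
#' intracellularFraction(sub)
#' @export
buildCylinderSubstrate <- function(gammaShape = 5.3316, gammaScale = 1.0242e-7,
                                   nCylinders = 100L, latticeSize = 1.65e-5,
                                   seed = 1L, maxAttempts = 20000L,
                                   maxRedraws = 20L) {
  stopifnot(gammaShape > 0, gammaScale > 0, nCylinders >= 1, latticeSize > 0)
  L <- latticeSize
  placed <- 0L
  radii <- numeric(0)
  for (redraw in seq_len(maxRedraws)) {
    radii <- with_seed(seed + 1000L * (redraw - 1L),
                       rgamma(nCylinders, shape = gammaShape, scale = gammaScale))
    radii <- sort(radii, decreasing = TRUE)
    if (2 * max(radii) > L) next  # cannot fit the largest cylinder
    centers <- matrix(NA_real_, nCylinders, 2)
    placed <- 0L
    res <- with_seed(seed + 1000L * (redraw - 1L) + 500L, {
      ok <- TRUE
      for (i in seq_len(nCylinders)) {
        done <- FALSE
        for (att in seq_len(maxAttempts)) {
          p <- runif(2, 0, L)
          if (placed == 0L) { done <- TRUE } else {
            dx <- .min_image(centers[seq_len(placed), 1] - p[1], L)
            dy <- .min_image(centers[seq_len(placed), 2] - p[2], L)
            done <- all(dx^2 + dy^2 >=
                          (radii[seq_len(placed)] + radii[i])^2)
          }
          if (done) {
            centers[i, ] <- p
            placed <- placed + 1L
            break
          }
        }
        if (!done) { ok <- FALSE; break }
      }
      ok
    })
    if (res) {
      return(new("CylinderSubstrate", radii = radii, centers = centers,
                 latticeSize = L, gammaShape = gammaShape,
                 gammaScale = gammaScale, seed = as.integer(seed)))
    }
  }
  achieved <- sum(pi * radii[seq_len(placed)]^2) / L^2
  stop(sprintf(
    "cylinder placement failed: achieved area fraction %.3f before stalling",
    achieved))
}

#' Build a dense periodic packing of equal spheres
#'
#' The cubic box side is chosen so that `n * (4/3) pi r^3 / side^3` equals
#' the requested packing fraction; centres are then densified from a random
#' dilute start by staged radius growth with iterative overlap-relaxation
#' sweeps under the periodic wrap. The default parameters emulate a yeast
#' suspension: 500 spheres of 5 um diameter at packing fraction 0.62 (close
#' to random close packing, hence the active densification).
#'
#' @param nSpheres number of spheres.
#' @param diameter sphere diameter (m).
#' @param packingFraction target volume fraction, in (0, 0.64).
#' @param seed integer seed; deterministic given it.
#' @param nStages radius growth stages of the densification.
#' @param maxSweeps relaxation sweeps allowed per stage.
#' @return a [SphereSubstrate-class].
#' @examples
#' sub <- buildSphereSubstrate(nSpheres = 40, packingFraction = 0.3, seed = 1)
#' intracellularFraction(sub)
#' @export
buildSphereSubstrate <- function(nSpheres = 500L, diameter = 5e-6,
                                 packingFraction = 0.62, seed = 1L,
                                 nStages = 160L, maxSweeps = 6000L) {
  stopifnot(nSpheres >= 1, diameter > 0,
            packingFraction > 0, packingFraction < 0.64)
  r <- diameter / 2
  side <- (nSpheres * (4 / 3) * pi * r^3 / packingFraction)^(1 / 3)
  pk <- cpp_pack_spheres(as.integer(nSpheres), r, side, as.integer(seed),
                         as.integer(nStages), as.integer(maxSweeps))
  new("SphereSubstrate", centers = pk$centers, radius = r, boxSide = side,
      packingFraction = packingFraction, seed = as.integer(seed))
}

#' Estimate the intracellular fraction by uniform random points
#'
#' Monte Carlo companion to [intracellularFraction()]: classifies `n`
#' uniform points with [locate()] and returns the intracellular proportion.
#'
#' @param substrate a substrate object.
#' @param n number of sample points.
#' @param seed RNG seed.
#' @return estimated intracellular fraction.
#' @export
sampleIntracellularFraction <- function(substrate, n = 1e5, seed = 1L) {
  L <- if (is(substrate, "SphereSubstrate")) substrate@boxSide else substrate@latticeSize
  dim3 <- is(substrate, "SphereSubstrate")
  pts <- with_seed(seed, matrix(runif(n * (if (dim3) 3 else 2), 0, L),
                                ncol = if (dim3) 3 else 2))
  mean(locate(substrate, pts) > 0)
}

# ---------------------------------------------------------------------------
# substrate serialization: key-value header + table of centres/radii
# ---------------------------------------------------------------------------

#' Write a substrate to a structured text file
#'
#' A commented key-value header (type, lattice, distribution parameters,
#' seed) followed by a whitespace-delimited table of centres and radii, so a
#' build is reproducible and inspectable.
#'
#' @param substrate a substrate object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSubstrate <- function(substrate, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is(substrate, "CylinderSubstrate")) {
    writeLines(c("# type: cylinders",
                 sprintf("# lattice_size: %.17g", substrate@latticeSize),
                 sprintf("# gamma_shape: %.17g", substrate@gammaShape),
                 sprintf("# gamma_scale: %.17g", substrate@gammaScale),
                 sprintf("# seed: %d", substrate@seed)), con)
    tab <- data.frame(x = substrate@centers[, 1], y = substrate@centers[, 2],
                      radius = substrate@radii)
  } else {
    writeLines(c("# type: spheres",
                 sprintf("# box_side: %.17g", substrate@boxSide),
                 sprintf("# radius: %.17g", substrate@radius),
                 sprintf("# packing_fraction: %.17g", substrate@packingFraction),
                 sprintf("# seed: %d", substrate@seed)), con)
    tab <- data.frame(x = substrate@centers[, 1], y = substrate@centers[, 2],
                      z = substrate@centers[, 3])
  }
  write.table(format(tab, digits = 17), con, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_header <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (ln in hdr) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  kv
}

#' Read a substrate written by [writeSubstrate()]
#'
#' @param path file path.
#' @return a [CylinderSubstrate-class] or [SphereSubstrate-class].
#' @export
readSubstrate <- function(path) {
  kv <- .read_header(path)
  tab <- read.table(path, header = TRUE, comment.char = "#")
  if (identical(kv$type, "cylinders")) {
    new("CylinderSubstrate",
        radii = tab$radius, centers = as.matrix(tab[, c("x", "y")]),
        latticeSize = as.numeric(kv$lattice_size),
        gammaShape = as.numeric(kv$gamma_shape),
        gammaScale = as.numeric(kv$gamma_scale),
        seed = as.integer(kv$seed))
  } else if (identical(kv$type, "spheres")) {
    new("SphereSubstrate",
        centers = as.matrix(tab[, c("x", "y", "z")]),
        radius = as.numeric(kv$radius),
        boxSide = as.numeric(kv$box_side),
        packingFraction = as.numeric(kv$packing_fraction),
        seed = as.integer(kv$seed))
  } else stop("unknown substrate type in header")
}
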