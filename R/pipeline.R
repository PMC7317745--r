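#' @include io.R
NULL

.default_config <- function() {
  list(
    substrate = list(type = "spheres", nSpheres = 500L, diameter = 5e-6,
                     packingFraction = 0.62,
                     gammaShape = 5.3316, gammaScale = 1.0242e-7,
                     nCylinders = 100L, latticeSize = 1.65e-5),
    walk = list(nWalkers = 10000L, nSteps = 6000L, duration = 0.4,
                diffusivity = 2e-9),
    probabilities = NULL,
    permeabilities = permeabilityFromProbability(
      seq(1e-4, 5.5e-4, length.out = 6), dt = 0.4 / 16000, D = 2e-9),
    sequence = list(delta = 0.015, Delta = 0.017, tm = 0.1,
                    Gmax = 0.9, nG = 16L),
    # lower = NULL: bracket the expected peaks per substrate (the
    # motionally narrowed intracellular pool of thin cylinders sits near
    # 1e-12 m^2/s, well below the sphere default)
    inversion = list(nGrid = 64L, lower = NULL, upper = 1e-8,
                     alphaStrategy = "discrepancy", alpha = NULL),
    peaks = list(threshold = 0.01, diagonalTol = 0.15),
    fexsy = list(enabled = TRUE, filterG = 0.068, encodeMax = 0.068,
                 nEncode = 9L, tmList = c(0, 0.01, 0.1, 0.2, 0.3)),
    dosy = list(enabled = FALSE, nG = 256L),
    seed = 1L,
    outDir = NULL)
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys missing from the file keep their defaults; the effective (merged)
#' configuration is what [runPipeline()] executes and dumps next to its
#' outputs.
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return nested configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) cfg <- .merge_config(cfg, yaml::read_yaml(path))
  cfg
}

.build_substrate <- function(scfg, seed) {
  if (scfg$type == "spheres") {
    buildSphereSubstrate(nSpheres = scfg$nSpheres, diameter = scfg$diameter,
                         packingFraction = scfg$packingFraction, seed = seed)
  } else if (scfg$type == "cylinders") {
    buildCylinderSubstrate(gammaShape = scfg$gammaShape,
                           gammaScale = scfg$gammaScale,
                           nCylinders = scfg$nCylinders,
                           latticeSize = scfg$latticeSize, seed = seed)
  } else stop("unknown substrate type: ", scfg$type)
}

#' Run the full permeability sweep pipeline
#'
#' For each configured permeability (or transit probability): simulate the
#' random walk, synthesize the DEXSY matrix, invert it, segment peaks,
#' compute the DEI, and (optionally) synthesize FEXSY and fit the AXR. The
#' per-permeability ensembles are discarded after use to bound memory.
#'
#' @param config nested list from [readRunConfig()]; any subset of keys may
#'   be overridden. Exactly one of `config$permeabilities` (m/s) or
#'   `config$probabilities` (per-encounter, at this run's time step) drives
#'   the sweep.
#' @param verbose print per-stage progress and wall time.
#' @return list with `summary` (data.frame: probability, permeability_m_per_s,
#'   dei, axr_per_s), `rhoDei`, `rhoAxr` (Spearman correlations against
#'   permeability, `NA` when the sweep has under 3 points), `spectra`,
#'   `peaks`, `config`, and `substrate`.
#' @export
runPipeline <- function(config = list(), verbose = FALSE) {
  cfg <- .merge_config(.default_config(), config)
  if (!is.null(cfg$probabilities)) cfg$permeabilities <- NULL
  seed <- as.integer(cfg$seed)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()["elapsed"]

  substrate <- .build_substrate(cfg$substrate, seed)
  say("substrate built (%.1f s)", proc.time()["elapsed"] - t0)

  dt <- cfg$walk$duration / cfg$walk$nSteps
  D <- cfg$walk$diffusivity
  if (!is.null(cfg$probabilities)) {
    probs <- cfg$probabilities
    perms <- permeabilityFromProbability(probs, dt, D)
  } else {
    perms <- cfg$permeabilities
    probs <- transitProbability(perms, dt, D)
  }
  sq <- dexsySequence(delta = cfg$sequence$delta, Delta = cfg$sequence$Delta,
                      tm = cfg$sequence$tm, Gmax = cfg$sequence$Gmax,
                      nG = cfg$sequence$nG)
  lower <- cfg$inversion$lower
  if (is.null(lower))
    lower <- if (cfg$substrate$type == "cylinders") 1e-13 else 1e-11
  grid <- diffusivityGrid(cfg$inversion$nGrid, lower, cfg$inversion$upper)

  n <- length(probs)
  deiVals <- axrVals <- rep(NA_real_, n)
  spectra <- vector("list", n)
  peaks <- vector("list", n)
  dosy <- vector("list", n)
  for (i in seq_len(n)) {
    wp <- walkParams(nWalkers = cfg$walk$nWalkers, duration = cfg$walk$duration,
                     nSteps = cfg$walk$nSteps, diffusivity = D,
                     transitProb = probs[i], seed = seed + i)
    # average over the restriction-sensitive directions: all three axes for
    # the isotropic sphere packing, the transverse plane for cylinders
    dirs <- if (cfg$substrate$type == "spheres") diag(3) else
      rbind(c(1, 0, 0), c(0, 1, 0))
    ens <- simulateWalk(substrate, wp, direction = dirs)
    say("p = %.5g: simulated (%.1f s)", probs[i], proc.time()["elapsed"] - t0)
    sm <- synthesizeDexsy(ens, sq)
    alpha <- if (identical(cfg$inversion$alphaStrategy, "fixed"))
      cfg$inversion$alpha else NULL
    sp <- invert2D(sm, grid, alpha = alpha)
    pk <- findPeaks(sp, threshold = cfg$peaks$threshold,
                    diagonalTol = cfg$peaks$diagonalTol)
    deiVals[i] <- if (any(pk$label %in% c("A", "B"))) dei(computeDEI(pk)) else NA_real_
    spectra[[i]] <- sp
    peaks[[i]] <- pk
    if (isTRUE(cfg$fexsy$enabled)) {
      enc <- seq(0, cfg$fexsy$encodeMax, length.out = cfg$fexsy$nEncode)
      fx <- synthesizeFexsy(ens, filterG = cfg$fexsy$filterG,
                            encodeList = enc,
                            delta = cfg$sequence$delta,
                            Delta = cfg$sequence$Delta,
                            tmList = cfg$fexsy$tmList)
      # equilibrium ADC from a filter-free encode sweep of the same walk;
      # fixing it removes the ADC_eq-AXR degeneracy of the recovery fit
      fx0 <- synthesizeFexsy(ens, filterG = 0, encodeList = enc,
                             delta = cfg$sequence$delta,
                             Delta = cfg$sequence$Delta, tmList = 0)
      adcEq <- adcPerTm(fx0)[1]
      axrVals[i] <- tryCatch(axr(fitAXRFromFexsy(fx, adcEq = adcEq)),
                             error = function(e) NA_real_)
    }
    if (isTRUE(cfg$dosy$enabled))
      dosy[[i]] <- synthesizeDosy(ens, delta = cfg$sequence$delta,
                                  Delta = cfg$sequence$Delta,
                                  GList = seq(0, cfg$sequence$Gmax,
                                              length.out = cfg$dosy$nG))
    rm(ens); gc(FALSE)
    say("p = %.5g: DEI = %.4g, AXR = %.4g (%.1f s)", probs[i], deiVals[i],
        axrVals[i], proc.time()["elapsed"] - t0)
  }
  summary <- data.frame(probability = probs, permeability_m_per_s = perms,
                        dei = deiVals, axr_per_s = axrVals)
  rhoDei <- if (n >= 3 && sd(deiVals) > 0)
    deiPermeabilityCurve(deiVals, perms) else NA_real_
  rhoAxr <- if (n >= 3 && all(is.finite(axrVals)) && sd(axrVals) > 0)
    axrPermeabilityCurve(axrVals, perms) else NA_real_

  out <- list(summary = summary, rhoDei = rhoDei, rhoAxr = rhoAxr,
              spectra = spectra, peaks = peaks, dosy = dosy,
              config = cfg, substrate = substrate)
  if (!is.null(cfg$outDir)) .write_pipeline_outputs(out, cfg)
  out
}

.write_pipeline_outputs <- function(out, cfg) {
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(cfg$outDir, ...)
  cfg_dump <- cfg
  cfg_dump$outDir <- NULL
  yaml::write_yaml(cfg_dump, fp("config.yaml"))
  writeSubstrate(out$substrate, fp("substrate.txt"))
  write.table(out$summary, fp("summary.tsv"), quote = FALSE,
              row.names = FALSE, sep = "\t")
  for (i in seq_along(out$spectra)) {
    writeSpectrum(out$spectra[[i]], fp(sprintf("spectrum_%02d.txt", i)))
    writePeakTable(out$peaks[[i]], fp(sprintf("peaks_%02d.tsv", i)))
  }
  invisible(cfg$outDir)
}
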