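#' @include ilt.R
NULL

#' Segment peaks of a 2D diffusion-diffusion spectrum
#'
#' Regions of amplitude at or above `threshold * max(amplitudes)` are
#' segmented and split between their internal maxima by watershed
#' (`EBImage::watershed`; maxima closer than `watershedTol * max` to their
#' separating saddle are merged, which keeps noise ripples from
#' fragmenting a peak). Each region becomes one peak with an
#' amplitude-weighted log-diffusivity centroid and a volume equal to its
#' summed amplitude. A peak is diagonal
#' iff `|log10 D1 - log10 D2|` at its centroid is at most `diagonalTol`
#' (inclusive) or at most the peak's own amplitude-weighted RMS extent
#' across the diagonal — a broad peak straddling the identity line is
#' diagonal even where log-diffusivity resolution is poor.
#' Diagonal peaks are labelled `A` (extracellular, higher D) and
#' `B` (intracellular, lower D); split diagonal fragments whose centroids lie
#' within `mergeCells` grid cells of another diagonal peak are merged into
#' it. Off-diagonal peaks are labelled by side: `C` where D1 > D2
#' (extracellular-to-intracellular exchange) and `D` where D2 > D1. Diagonal
#' peaks more than a decade above A are labelled `"unassigned"`
#' (perfusion-like) and excluded from the DEI.
#'
#' @param spectrum a [Spectrum2D-class].
#' @param threshold amplitude threshold as a fraction of the maximum,
#'   in (0, 1). The default 0.01 suppresses the low-amplitude spurious peaks
#'   the inversion is known to produce.
#' @param diagonalTol half-width of the diagonal band (log10 units).
#' @param mergeCells merge distance for split diagonal peaks (grid cells).
#' @param watershedTol minimum height of a maximum above its saddle, as a
#'   fraction of the spectral maximum, for it to found its own peak.
#' @param minVolume discard peaks whose volume is below this fraction of the
#'   total spectral amplitude; suppresses the low-amplitude spurious peaks
#'   regularized inversion is known to produce.
#' @return data.frame with columns `label`, `d1`, `d2` (centroid m^2/s),
#'   `volume`; zero rows for an empty spectrum.
#' @export
findPeaks <- function(spectrum, threshold = 0.01, diagonalTol = 0.15,
                      mergeCells = 2L, watershedTol = 0.02,
                      minVolume = 0.01) {
  stopifnot(threshold > 0, threshold < 1)
  F <- spectrum@amplitudes
  empty <- data.frame(label = character(0), d1 = numeric(0),
                      d2 = numeric(0), volume = numeric(0))
  mx <- max(F)
  if (mx <= 0) return(empty)
  mask <- F >= threshold * mx
  Fm <- F / mx
  Fm[!mask] <- 0
  lab <- EBImage::imageData(EBImage::watershed(EBImage::as.Image(Fm),
                                               tolerance = watershedTol,
                                               ext = 1))
  nlab <- max(lab)
  if (nlab == 0) return(empty)
  l1 <- log10(spectrum@grid1@values)
  l2 <- log10(spectrum@grid2@values)
  step1 <- mean(diff(l1))
  pk <- do.call(rbind, lapply(seq_len(nlab), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    wts <- F[lab == k]
    c1 <- sum(l1[idx[, 1]] * wts) / sum(wts)
    c2 <- sum(l2[idx[, 2]] * wts) / sum(wts)
    # amplitude-weighted RMS extent across the diagonal: a broad peak that
    # straddles the identity line is diagonal even if its centroid drifts
    # (log-D resolution is poor at the slow-diffusion edge)
    v <- l1[idx[, 1]] - l2[idx[, 2]]
    sPerp <- sqrt(sum(wts * (v - (c1 - c2))^2) / sum(wts))
    data.frame(d1 = 10^c1, d2 = 10^c2, volume = sum(wts), sPerp = sPerp)
  }))
  lg1 <- log10(pk$d1); lg2 <- log10(pk$d2)
  diagonal <- abs(lg1 - lg2) <= pmax(diagonalTol, pk$sPerp) + 1e-12
  pk$label <- ifelse(diagonal, NA_character_,
                     ifelse(lg1 > lg2, "C", "D"))
  # merge split diagonal fragments lying within mergeCells grid cells
  di <- which(diagonal)
  if (length(di) > 1) {
    ord <- di[order(-pk$volume[di])]
    keep <- rep(TRUE, nrow(pk))
    for (i in seq_along(ord)[-1]) {
      a <- ord[i]
      for (j in ord[seq_len(i - 1)]) {
        if (!keep[j]) next
        dcell <- sqrt((lg1[a] - lg1[j])^2 + (lg2[a] - lg2[j])^2) / step1
        if (dcell <= mergeCells) {
          w <- pk$volume[c(a, j)]
          pk$d1[j] <- 10^(sum(log10(pk$d1[c(a, j)]) * w) / sum(w))
          pk$d2[j] <- 10^(sum(log10(pk$d2[c(a, j)]) * w) / sum(w))
          pk$volume[j] <- sum(w)
          keep[a] <- FALSE
          break
        }
      }
    }
    pk <- pk[keep, , drop = FALSE]
    lg1 <- log10(pk$d1); lg2 <- log10(pk$d2)
    diagonal <- is.na(pk$label)
  }
  # assign A (higher D) / B (lower D) among diagonal peaks; the two largest
  # anchor the assignment, the rest co-label with the nearer anchor
  di <- which(is.na(pk$label))
  if (length(di)) {
    dd <- (lg1[di] + lg2[di]) / 2
    anchors <- di[order(-pk$volume[di])][seq_len(min(2, length(di)))]
    aD <- (lg1 + lg2)[anchors] / 2
    hiA <- max(aD)
    for (q in seq_along(di)) {
      i <- di[q]
      pk$label[i] <- if (dd[q] > hiA + 1) "unassigned"
        else if (length(anchors) == 1) "A"
        else if (abs(dd[q] - max(aD)) <= abs(dd[q] - min(aD))) "A" else "B"
    }
  }
  pk <- pk[pk$volume >= minVolume * sum(F), , drop = FALSE]
  rownames(pk) <- NULL
  pk[, c("label", "d1", "d2", "volume")]
}

#' Compute the Diffusion Exchange Index from segmented peaks
#'
#' DEI = (sum of off-diagonal exchange peak volumes C + D) / (sum of diagonal
#' non-exchange peak volumes A + B). Unassigned peaks are excluded from both
#' sums and reported separately.
#'
#' @param peaks data.frame from [findPeaks()].
#' @return a [DeiResult-class].
#' @examples
#' pk <- data.frame(label = c("A", "B", "C", "D"),
#'                  d1 = c(1e-9, 1e-10, 1e-9, 1e-10),
#'                  d2 = c(1e-9, 1e-10, 1e-10, 1e-9),
#'                  volume = c(0.5, 0.3, 0.1, 0.1))
#' dei(computeDEI(pk))  # 0.25
#' @export
computeDEI <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  excl <- peaks[peaks$label == "unassigned", , drop = FALSE]
  kept <- peaks[peaks$label != "unassigned", , drop = FALSE]
  nonex <- sum(kept$volume[kept$label %in% c("A", "B")])
  exch <- sum(kept$volume[kept$label %in% c("C", "D")])
  if (!any(kept$label %in% c("A", "B")))
    stop("no diagonal (non-exchange) peaks: DEI requires at least one")
  if (nonex <= 0) stop("zero non-exchange volume: DEI undefined")
  new("DeiResult", dei = exch / nonex, exchangeVolume = exch,
      nonExchangeVolume = nonex, peaks = kept, excluded = excl)
}

#' Spearman rank correlation of an index against permeability
#'
#' Average-rank tie handling, as used for the DEI-permeability and
#' AXR-permeability monotonicity summaries.
#'
#' @param index DEI or AXR values.
#' @param permeability matching permeabilities (m/s).
#' @return Spearman's rho.
#' @export
deiPermeabilityCurve <- function(index, permeability) {
  if (length(index) != length(permeability))
    stop("index and permeability lengths differ")
  if (length(index) < 3) stop("need at least 3 points")
  if (sd(index) == 0 || sd(permeability) == 0)
    stop("constant input: rank correlation undefined")
  cor(index, permeability, method = "spearman")
}

#' @rdname deiPermeabilityCurve
#' @export
axrPermeabilityCurve <- deiPermeabilityCurve

#' Local maxima of a 1D diffusion spectrum
#'
#' @param spectrum a [Spectrum1D-class].
#' @param threshold amplitude threshold as a fraction of the maximum.
#' @return data.frame with peak positions `d` (m^2/s, amplitude-weighted
#'   centroid of each above-threshold connected run) and `volume`.
#' @export
findPeaks1D <- function(spectrum, threshold = 0.01) {
  a <- spectrum@amplitudes
  mx <- max(a)
  if (mx <= 0) return(data.frame(d = numeric(0), volume = numeric(0)))
  above <- a >= threshold * mx
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ld <- log10(spectrum@grid@values)
  out <- lapply(which(runs$values), function(i) {
    idx <- starts[i]:ends[i]
    data.frame(d = 10^(sum(ld[idx] * a[idx]) / sum(a[idx])),
               volume = sum(a[idx]))
  })
  if (!length(out)) return(data.frame(d = numeric(0), volume = numeric(0)))
  do.call(rbind, out)
}

#' Write a peak table as delimited text
#'
#' @param x a [DeiResult-class] or a peak data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePeakTable <- function(x, path) {
  tab <- if (is(x, "DeiResult")) peakTable(x, includeExcluded = TRUE) else x
  con <- file(path, "w")
  on.exit(close(con))
  if (is(x, "DeiResult"))
    writeLines(sprintf("# dei: %.17g", x@dei), con)
  write.table(tab, con, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Render a 2D spectrum as a contour plot
#'
#' @param spectrum a [Spectrum2D-class].
#' @param path optional PNG output path; when `NULL`, plots to the active
#'   device.
#' @param main plot title.
#' @return `path` (or `NULL`), invisibly.
#' @export
plotSpectrum <- function(spectrum, path = NULL, main = "diffusion-diffusion spectrum") {
  if (!is.null(path)) {
    png(path, width = 900, height = 800)
    on.exit(dev.off())
  }
  l1 <- log10(spectrum@grid1@values)
  l2 <- log10(spectrum@grid2@values)
  filled.contour(l1, l2, spectrum@amplitudes,
                 color.palette = function(n) hcl.colors(n, "YlOrRd", rev = TRUE),
                 xlab = "log10 D1 (m^2/s)", ylab = "log10 D2 (m^2/s)",
                 main = main,
                 plot.axes = { graphics::axis(1); graphics::axis(2)
                   abline(0, 1, lty = 2) })
  invisible(path)
}
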