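#' @include synthetic.R
NULL

#' Write a DEXSY signal matrix as delimited text
#'
#' Commented header (timings, mixing time, gamma, direction), then a numeric
#' block whose first row and first column hold the G2 and G1 amplitudes (T/m)
#' and whose body holds S/S0. The same format ingests real acquired DEXSY
#' matrices via [ingestAcquired()].
#'
#' @param signal a [SignalMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSignalMatrix <- function(signal, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# dexsy_signal_matrix",
               sprintf("# delta_s: %.17g %.17g", signal@delta[1], signal@delta[2]),
               sprintf("# Delta_s: %.17g %.17g", signal@Delta[1], signal@Delta[2]),
               sprintf("# tm_s: %.17g", signal@tm),
               sprintf("# gamma_rad_per_s_per_T: %.17g", signal@gamma),
               sprintf("# direction: %s",
                       paste(signal@direction, collapse = " "))), con)
  block <- rbind(c(0, signal@G2), cbind(signal@G1, signal@values))
  write.table(format(block, digits = 17), con, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a DEXSY signal matrix written by [writeSignalMatrix()]
#'
#' @param path file path.
#' @param delta,Delta,tm,gamma override or supply sequence metadata missing
#'   from the header (each pair timing may be length 1 or 2, seconds).
#' @return a validated [SignalMatrix-class]; b-values are recomputed from the
#'   header timings.
#' @export
readSignalMatrix <- function(path, delta = NULL, Delta = NULL, tm = NULL,
                             gamma = NULL) {
  kv <- .read_header(path)
  num <- function(key, override) {
    if (!is.null(override)) return(override)
    if (is.null(kv[[key]])) stop(sprintf("header is missing '%s'", key))
    as.numeric(strsplit(trimws(kv[[key]]), "\\s+")[[1]])
  }
  delta <- rep_len(num("delta_s", delta), 2)
  Delta <- rep_len(num("Delta_s", Delta), 2)
  tm <- num("tm_s", tm)[1]
  gamma <- num("gamma_rad_per_s_per_T", gamma)[1]
  direction <- if (!is.null(kv$direction))
    as.numeric(strsplit(trimws(kv$direction), "\\s+")[[1]]) else c(1, 0, 0)
  block <- as.matrix(read.table(path, comment.char = "#"))
  if (nrow(block) < 2 || ncol(block) < 2) stop("malformed signal matrix block")
  G2 <- as.numeric(block[1, -1])
  G1 <- as.numeric(block[-1, 1])
  values <- unname(block[-1, -1, drop = FALSE])
  if (G1[1] != 0 || G2[1] != 0)
    stop("signal matrix is missing the G = 0 (S0) row or column")
  if (is.unsorted(G1) || is.unsorted(G2))
    stop("gradient amplitude lists must be non-decreasing")
  if (any(!is.finite(values))) stop("non-finite signal values")
  new("SignalMatrix", values = values, G1 = G1, G2 = G2,
      b1 = bValue(G1, delta[1], Delta[1], gamma),
      b2 = bValue(G2, delta[2], Delta[2], gamma),
      delta = delta, Delta = Delta, tm = tm, gamma = gamma,
      direction = direction, se = matrix(0, 0, 0),
      meta = list(source = path))
}

#' Ingest an acquired DEXSY signal matrix
#'
#' Validation wrapper around [readSignalMatrix()] for scanner exports in the
#' documented delimited format (for example 16 x 16 grids over 0-640 mT/m,
#' delta = 15 ms, Delta = 17 ms): checks the S0 cell, grid monotonicity and
#' that S/S0 is normalized, then returns a matrix ready for [invert2D()].
#'
#' @param path file path.
#' @param ... metadata overrides passed to [readSignalMatrix()].
#' @return a [SignalMatrix-class].
#' @export
ingestAcquired <- function(path, ...) {
  sm <- readSignalMatrix(path, ...)
  if (abs(sm@values[1, 1] - 1) > 1e-6)
    stop("S(0,0) is not 1: normalize the matrix to its S0 cell")
  sm
}

#' Write a 2D spectrum as delimited text
#'
#' Header records alpha, residual and truncation ranks; the numeric block has
#' the D2 grid in its first row, the D1 grid in its first column and the
#' amplitudes in its body.
#'
#' @param spectrum a [Spectrum2D-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# spectrum2d",
               sprintf("# alpha: %.17g", spectrum@alpha),
               sprintf("# residual: %.17g", spectrum@residual),
               sprintf("# rank: %d %d", spectrum@rank[1], spectrum@rank[2])), con)
  block <- rbind(c(0, spectrum@grid2@values),
                 cbind(spectrum@grid1@values, spectrum@amplitudes))
  write.table(format(block, digits = 17), con, quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 2D spectrum written by [writeSpectrum()]
#'
#' @param path file path.
#' @return a [Spectrum2D-class].
#' @export
readSpectrum <- function(path) {
  kv <- .read_header(path)
  block <- as.matrix(read.table(path, comment.char = "#"))
  rk <- as.integer(strsplit(trimws(kv$rank), "\\s+")[[1]])
  new("Spectrum2D",
      amplitudes = unname(block[-1, -1, drop = FALSE]),
      grid1 = new("DiffusivityGrid", values = as.numeric(block[-1, 1])),
      grid2 = new("DiffusivityGrid", values = as.numeric(block[1, -1])),
      alpha = as.numeric(kv$alpha), residual = as.numeric(kv$residual),
      rank = rk)
}
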