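#' @include acquisition.R
NULL

#' Construct a log-spaced diffusivity grid
#'
#' Default: 64 points over 1e-11 to 1e-8 m^2/s, bracketing intracellular,
#' extracellular and exchange peaks; widen the upper bound (e.g. 1e-7) for
#' perfusion-dominated in vivo spectra.
#'
#' @param n number of grid points.
#' @param lower,upper bounds (m^2/s).
#' @return a [DiffusivityGrid-class].
#' @export
diffusivityGrid <- function(n = 64L, lower = 1e-11, upper = 1e-8) {
  stopifnot(lower > 0, upper > lower, n >= 2)
  new("DiffusivityGrid",
      values = exp(seq(log(lower), log(upper), length.out = n)))
}

# truncated SVD of an exponential kernel exp(-outer(b, D)); keeps singular
# values >= tol * largest
.kernel_svd <- function(b, D, tol = 1e-3) {
  K <- exp(-outer(b, D))
  sv <- svd(K)
  keep <- which(sv$d >= tol * sv$d[1])
  if (length(keep) < 1)
    stop(sprintf("kernel rank-deficient after truncation at %.1e", tol))
  list(U = sv$u[, keep, drop = FALSE], d = sv$d[keep],
       V = sv$v[, keep, drop = FALSE], K = K)
}

# solve min ||A x - d||^2 + alpha ||x||^2, x >= 0; optionally warm-started
# from a previous support (speeds up alpha sweeps considerably)
.nnls <- function(A, d, alpha, warmStart = NULL) {
  cpp_nnls_tikhonov(A, d, alpha, maxit = 5000L, warmStart)$x
}

.nnls_full <- function(A, d, alpha, warmStart = NULL) {
  cpp_nnls_tikhonov(A, d, alpha, maxit = 5000L, warmStart)
}

.edge_warning <- function(F, grid1, grid2 = NULL) {
  # mass piling onto the lowest-attenuation (smallest D) edge signals a
  # degenerate, effectively unweighted input
  tot <- sum(F)
  if (tot <= 0) return(invisible())
  if (is.null(grid2)) edge <- sum(F[1:2]) else edge <- sum(F[1:2, 1:2])
  if (edge / tot > 0.5)
    warning("spectral mass concentrated at the low-diffusivity edge: ",
            "the data carry little diffusion attenuation", call. = FALSE)
  invisible()
}

#' Regularized 2D inverse Laplace inversion of a DEXSY signal matrix
#'
#' Minimizes \eqn{\|K_1 F K_2^T - S\|^2 + \alpha \|F\|^2} subject to
#' \eqn{F \ge 0}, with \eqn{K_i[j,k] = e^{-b_i[j] D[k]}}. Both kernels are
#' compressed by truncated SVD (singular values below `truncTol` of the
#' largest dropped) before the active-set non-negative solve, the standard
#' fast approach for 2D relaxation/diffusion spectra. The S0 cell is part of
#' the fit. Deterministic.
#'
#' @param signal a [SignalMatrix-class] (b-vectors from its metadata).
#' @param grid a [DiffusivityGrid-class] (shared by both axes).
#' @param alpha regularization weight, positive. `NULL` (default) picks
#'   alpha by the discrepancy principle when a noise estimate is available
#'   (`noiseSd` or the signal's Monte Carlo standard errors), else
#'   `1e-2 * sigma_max(A)^2` of the compressed kernel.
#' @param noiseSd optional per-cell noise standard deviation for the
#'   discrepancy principle.
#' @param truncTol SVD truncation threshold, relative to the largest
#'   singular value.
#' @return a [Spectrum2D-class]; total amplitude approximates S(0,0) = 1.
#' @examples
#' sq <- dexsySequence(nG = 8, Gmax = 0.64)
#' b <- bValue(sq@G1List, 0.015, 0.017)
#' S <- forwardSignal(matrix(1), 1e-9, 1e-9, b, b)
#' sm <- new("SignalMatrix", values = S, G1 = sq@G1List, G2 = sq@G2List,
#'           b1 = b, b2 = b, delta = rep(0.015, 2), Delta = rep(0.017, 2),
#'           tm = 0.1, gamma = GAMMA_H, direction = c(1, 0, 0),
#'           se = matrix(0, 0, 0), meta = list())
#' sp <- invert2D(sm, diffusivityGrid(32), alpha = 1e-6)
#' @export
invert2D <- function(signal, grid = diffusivityGrid(), alpha = NULL,
                     noiseSd = NULL, truncTol = 1e-3) {
  D <- grid@values
  S <- signal@values
  k1 <- .kernel_svd(signal@b1, D, truncTol)
  k2 <- .kernel_svd(signal@b2, D, truncTol)
  # compressed problem: A = (S2 V2') kron (S1 V1'), d = vec(U1' S U2)
  A1 <- k1$d * t(k1$V)
  A2 <- k2$d * t(k2$V)
  A <- kronecker(A2, A1)
  d <- as.vector(t(k1$U) %*% S %*% k2$U)
  smax2 <- (k1$d[1] * k2$d[1])^2
  if (is.null(alpha)) {
    if (is.null(noiseSd) && nrow(signal@se) > 0 && any(signal@se > 0))
      noiseSd <- mean(signal@se)
    alpha <- if (!is.null(noiseSd) && noiseSd > 0) {
      .discrepancy_alpha(A, d, noiseSd, nFull = length(S),
                         fullResidual = function(x) {
                           FF <- matrix(x, length(D), length(D))
                           sqrt(sum((k1$K %*% FF %*% t(k2$K) - S)^2))
                         })
    } else 1e-2 * smax2
  }
  x <- .nnls(A, d, alpha)
  F <- matrix(x, length(D), length(D))
  fit <- k1$K %*% F %*% t(k2$K)
  resid <- sqrt(mean((fit - S)^2)) / sqrt(mean(S^2))
  .edge_warning(F, D, D)
  new("Spectrum2D", amplitudes = F, grid1 = grid, grid2 = grid,
      alpha = alpha, residual = resid,
      rank = c(length(k1$d), length(k2$d)))
}

#' Regularized 1D inverse Laplace inversion (DOSY)
#'
#' One-dimensional analogue of [invert2D()].
#'
#' @param signal numeric vector of S/S0.
#' @param b b-values (s/m^2) of the signal points; must show attenuation
#'   (all-zero b is under-determined).
#' @param grid a [DiffusivityGrid-class].
#' @param alpha regularization weight; `NULL` as in [invert2D()].
#' @param noiseSd optional noise level for the discrepancy principle.
#' @param truncTol SVD truncation threshold.
#' @return a [Spectrum1D-class].
#' @export
invert1D <- function(signal, b, grid = diffusivityGrid(), alpha = NULL,
                     noiseSd = NULL, truncTol = 1e-3) {
  if (length(signal) != length(b)) stop("signal and b lengths differ")
  if (all(b == 0)) stop("all b-values are zero: the inversion is under-determined")
  D <- grid@values
  k <- .kernel_svd(b, D, truncTol)
  A <- k$d * t(k$V)
  d <- drop(t(k$U) %*% signal)
  if (is.null(alpha)) {
    alpha <- if (!is.null(noiseSd) && noiseSd > 0) {
      .discrepancy_alpha(A, d, noiseSd, nFull = length(signal),
                         fullResidual = function(x)
                           sqrt(sum((k$K %*% x - signal)^2)))
    } else 1e-2 * k$d[1]^2
  }
  x <- drop(.nnls(A, d, alpha))
  resid <- sqrt(mean((k$K %*% x - signal)^2)) / sqrt(mean(signal^2))
  .edge_warning(x, D)
  new("Spectrum1D", amplitudes = x, grid = grid, alpha = alpha,
      residual = resid, rank = length(k$d))
}

# discrepancy principle: residual(alpha) is monotone increasing in alpha;
# bisection on log10(alpha) for ||fit - data|| = sqrt(nFull) * sigma
.discrepancy_alpha <- function(A, d, noiseSd, nFull, fullResidual) {
  target <- sqrt(nFull) * noiseSd
  smax2 <- norm(A, "2")^2
  supp <- NULL
  f <- function(la) {
    res <- .nnls_full(A, d, 10^la, supp)
    supp <<- res$support
    fullResidual(res$x) - target
  }
  lo <- log10(smax2) - 7
  hi <- log10(smax2) + 4
  fhi <- f(hi)   # evaluate from the smooth end: supports grow as alpha drops
  if (fhi < 0) return(10^hi)
  flo <- f(lo)
  if (flo > 0) return(10^lo)  # even minimal smoothing misfits above target
  u <- uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi, tol = 0.01)
  10^u$root
}

#' Choose the regularization weight for an inversion
#'
#' Strategies: `"fixed"` returns `alpha`; `"discrepancy"` matches the data
#' misfit to `sqrt(N) * noiseSd` by bisection; `"lcurve"` maximizes the
#' curvature of the (log residual, log norm) curve over a log-spaced alpha
#' sweep.
#'
#' @param signal a [SignalMatrix-class] (2D) or numeric signal vector (1D).
#' @param grid a [DiffusivityGrid-class].
#' @param strategy one of `"fixed"`, `"discrepancy"`, `"lcurve"`.
#' @param alpha the value returned by the fixed strategy.
#' @param noiseSd noise level, required for the discrepancy strategy.
#' @param b b-values, required when `signal` is a vector.
#' @param nAlpha sweep length for the L-curve.
#' @return the selected alpha (with the sweep trace as attribute
#'   `"trace"` for the L-curve).
#' @export
selectAlpha <- function(signal, grid = diffusivityGrid(),
                        strategy = c("fixed", "discrepancy", "lcurve"),
                        alpha = 1e-2, noiseSd = NULL, b = NULL,
                        nAlpha = 20L) {
  strategy <- match.arg(strategy)
  if (strategy == "fixed") return(alpha)
  is2d <- is(signal, "SignalMatrix")
  D <- grid@values
  if (is2d) {
    k1 <- .kernel_svd(signal@b1, D)
    k2 <- .kernel_svd(signal@b2, D)
    A <- kronecker(k2$d * t(k2$V), k1$d * t(k1$V))
    d <- as.vector(t(k1$U) %*% signal@values %*% k2$U)
    nFull <- length(signal@values)
    fres <- function(x) {
      FF <- matrix(x, length(D), length(D))
      sqrt(sum((k1$K %*% FF %*% t(k2$K) - signal@values)^2))
    }
  } else {
    if (is.null(b)) stop("vector signals need b-values")
    k <- .kernel_svd(b, D)
    A <- k$d * t(k$V)
    d <- drop(t(k$U) %*% signal)
    nFull <- length(signal)
    fres <- function(x) sqrt(sum((k$K %*% x - signal)^2))
  }
  if (strategy == "discrepancy") {
    if (is.null(noiseSd) || noiseSd <= 0)
      stop("the discrepancy strategy needs a positive noiseSd")
    return(.discrepancy_alpha(A, d, noiseSd, nFull, fres))
  }
  # L-curve
  smax2 <- norm(A, "2")^2
  las <- seq(log10(smax2) - 8, log10(smax2) + 2, length.out = nAlpha)
  pts <- t(vapply(las, function(la) {
    x <- .nnls(A, d, 10^la)
    c(log(fres(x) + 1e-300), log(sqrt(sum(x^2)) + 1e-300))
  }, numeric(2)))
  # discrete curvature via second differences
  k_curv <- rep(NA_real_, nAlpha)
  for (i in 2:(nAlpha - 1)) {
    d1 <- pts[i + 1, ] - pts[i, ]
    d0 <- pts[i, ] - pts[i - 1, ]
    cross <- d0[1] * d1[2] - d0[2] * d1[1]
    k_curv[i] <- cross / (sqrt(sum(d0^2)) * sqrt(sum(d1^2)) *
                            sqrt(sum((d1 + d0)^2)) + 1e-300)
  }
  if (all(is.na(k_curv))) stop("L-curve search did not produce a corner")
  best <- which.max(k_curv)
  out <- 10^las[best]
  attr(out, "trace") <- data.frame(log10alpha = las,
                                   logResidual = pts[, 1], logNorm = pts[, 2])
  out
}
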