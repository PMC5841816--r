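#' Frequency band specification
#'
#' @param name band label.
#' @param f_lo,f_hi band edges (Hz), `0 < f_lo < f_hi`.
#' @return An object of class `band_spec`.
#' @examples
#' alpha_band()   # 8-13 Hz
#' @export
band_spec <- function(name, f_lo, f_hi) {
  if (!(f_lo > 0 && f_hi > f_lo)) stop("need 0 < f_lo < f_hi")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_spec")
}

#' @rdname band_spec
#' @export
alpha_band <- function() band_spec("alpha", 8, 13)

# two-pass filtering with odd-reflection end padding to suppress the edge
# transients of zero-initial-condition filtering
filtfilt_padded <- function(bf, x, npad) {
  n <- length(x)
  npad <- min(npad, n - 1)
  left <- 2 * x[1] - x[(npad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- signal::filtfilt(bf, c(left, x, right))
  y[(npad + 1):(npad + n)]
}

#' Zero-phase Butterworth band-pass
#'
#' 4th-order Butterworth applied forward and backward (two-pass, zero net
#' phase). The spans of `1 / f_lo` seconds at each end are affected by
#' filter edge transients; their length in samples is attached as attribute
#' `edge_samples` for downstream exclusion.
#'
#' @param X channels x time matrix (or vector).
#' @param fs sampling rate (Hz).
#' @param band a [band_spec()]; must lie below Nyquist.
#' @return Filtered matrix (or vector) with attribute `edge_samples`.
#' @export
bandpass <- function(X, fs, band = alpha_band()) {
  stopifnot(inherits(band, "band_spec"))
  if (band$f_hi >= fs / 2) stop("band exceeds the Nyquist frequency")
  vec <- !is.matrix(X)
  if (vec) X <- matrix(X, 1)
  bf <- signal::butter(4, c(band$f_lo, band$f_hi) / (fs / 2), type = "pass")
  npad <- ceiling(6 * fs / band$f_lo)
  out <- t(apply(X, 1, function(x) filtfilt_padded(bf, x, npad)))
  if (vec) out <- drop(out)
  attr(out, "edge_samples") <- ceiling(fs / band$f_lo)
  out
}

#' Analytic signal via the frequency-domain Hilbert method
#'
#' Computes the discrete analytic signal `x + i H(x)` and returns its
#' envelope and phase. The caller is responsible for band-limiting the
#' input first.
#'
#' @param x numeric vector (length `>= 8`).
#' @param unwrap return the unwrapped phase.
#' @return List with `envelope` (`>= 0`), `phase` (radians) and the complex
#'   `analytic` signal.
#' @export
analytic <- function(x, unwrap = FALSE) {
  n <- length(x)
  if (n < 8) stop("input too short (< 8 samples)")
  Xf <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  xa <- stats::fft(Xf * h, inverse = TRUE) / n
  ph <- Arg(xa)
  if (unwrap) ph <- unwrap_phase(ph)
  list(envelope = Mod(xa), phase = ph, analytic = xa)
}

#' Unwrap a phase timecourse
#'
#' @param phase wrapped phase (radians).
#' @return Unwrapped phase.
#' @export
unwrap_phase <- function(phase) {
  d <- diff(phase)
  jumps <- round(d / (2 * pi))
  phase - c(0, cumsum(jumps)) * 2 * pi
}

#' Symmetric multivariate leakage-correction orthogonalisation
#'
#' Removes all zero-lag correlations between channel timecourses
#' simultaneously by finding the set of mutually orthogonal, per-channel
#' positively rescaled timecourses closest in least squares to the demeaned
#' input. The solution alternates a polar-decomposition step (closest
#' orthonormal basis given the scalings) with an optimal-rescaling step
#' until the relative Frobenius change of the reconstruction drops below
#' `tol`. Because the orthonormal basis lives in the column space of the
#' demeaned data, output channels are exactly zero-mean, so their pairwise
#' instantaneous Pearson correlations vanish (to numerical precision).
#'
#' @param X channels x time matrix; time samples must exceed channels and
#'   the demeaned channels must be linearly independent.
#' @param tol relative Frobenius-change convergence tolerance.
#' @param max_iter iteration cap.
#' @return Orthogonalised channels x time matrix; attributes `iterations`
#'   and `scalings`.
#' @export
orthogonalise <- function(X, tol = 1e-10, max_iter = 200) {
  stopifnot(is.matrix(X))
  n <- nrow(X)
  T_ <- ncol(X)
  if (T_ <= n) stop("need more time samples than channels")
  Z <- t(X)                         # time x channels
  Z <- sweep(Z, 2, colMeans(Z))
  sv <- svd(Z)
  if (min(sv$d) < 1e-10 * max(sv$d)) {
    cm <- abs(stats::cor(Z))
    diag(cm) <- 0
    ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    stop(sprintf(paste0("rank-deficient input: channels %d and %d are ",
                        "(nearly) collinear"), ij[1], ij[2]))
  }
  d <- rep(1, n)
  Y_prev <- NULL
  iter <- 0
  repeat {
    iter <- iter + 1
    s2 <- svd(Z %*% diag(d, n))
    Q <- s2$u %*% t(s2$v)           # closest orthonormal set
    d <- colSums(Z * Q)             # optimal per-channel scalings
    if (any(d <= 0))
      d <- pmax(d, 1e-12 * max(abs(d)))
    Y <- Q %*% diag(d, n)
    if (!is.null(Y_prev)) {
      rel <- norm(Y - Y_prev, "F") / norm(Y, "F")
      if (rel < tol) break
    }
    if (iter >= max_iter) {
      stop(sprintf("orthogonalisation did not converge in %d iterations ",
                   max_iter),
           sprintf("(last relative change %.3g)",
                   norm(Y - Y_prev, "F") / norm(Y, "F")))
    }
    Y_prev <- Y
  }
  out <- t(Y)
  attr(out, "iterations") <- iter
  attr(out, "scalings") <- d
  out
}

#' Downsample an amplitude envelope by block averaging
#'
#' Non-overlapping block means of length `fs / target_fs` (the final
#' partial block is dropped), the standard reduction of band-limited
#' envelopes to slow timescales before correlation.
#'
#' @param A envelope vector or channels x time matrix at rate `fs`.
#' @param fs input rate (Hz).
#' @param target_fs output rate (Hz), `<= fs`; `fs / target_fs` must be a
#'   whole number of samples.
#' @return Downsampled vector or matrix.
#' @export
downsample_envelope <- function(A, fs, target_fs = 1) {
  if (target_fs > fs) stop("target_fs must be <= fs")
  blk <- fs / target_fs
  if (abs(blk - round(blk)) > 1e-8)
    stop("fs / target_fs must be an integer block length")
  blk <- as.integer(round(blk))
  vec <- !is.matrix(A)
  if (vec) A <- matrix(A, 1)
  nb <- ncol(A) %/% blk
  if (nb < 1) stop("input shorter than one block")
  idx <- rep(seq_len(nb), each = blk)
  out <- t(apply(A[, seq_len(nb * blk), drop = FALSE], 1, function(x)
    tapply(x, idx, mean)))
  out <- matrix(out, nrow = nrow(A))
  if (vec) drop(out) else out
}
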