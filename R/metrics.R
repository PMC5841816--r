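#' Kuramoto order parameter
#'
#' `R(t) = | mean_k exp(i phi_k(t)) |`: 1 when all oscillators share a
#' phase, near 0 for uniformly scattered phases.
#'
#' @param phases n x T matrix of instantaneous phases (radians).
#' @return Length-T vector `R(t)` in \[0, 1\].
#' @export
order_parameter <- function(phases) {
  if (!is.matrix(phases)) phases <- matrix(phases, 1)
  Mod(colMeans(exp(1i * phases)))
}

#' Synchrony and metastability of an order-parameter timecourse
#'
#' Time-averaged synchrony (mean of `R(t)`) and metastability (sample
#' standard deviation of `R(t)`).
#'
#' @param R_t order-parameter timecourse.
#' @return List with `synchrony` and `metastability`.
#' @export
synchrony_metastability <- function(R_t) {
  if (!length(R_t)) stop("empty order-parameter timecourse")
  list(synchrony = mean(R_t), metastability = stats::sd(R_t))
}

#' Network synchrony from simulated activity
#'
#' Band-passes the excitatory timecourses, extracts analytic phases,
#' excludes filter edge spans, and evaluates the order parameter.
#'
#' @param X channels x time matrix of activity (e.g. `sim$E`).
#' @param fs sampling rate (Hz).
#' @param band a [band_spec()].
#' @param orthogonalise_first apply leakage-correction orthogonalisation
#'   before phase estimation (mirrors the MEG pipeline variant).
#' @return List with `R_t`, `synchrony`, `metastability`.
#' @export
network_synchrony <- function(X, fs, band = alpha_band(),
                              orthogonalise_first = FALSE) {
  Xf <- bandpass(X, fs, band)
  edge <- attr(Xf, "edge_samples")
  if (orthogonalise_first) Xf <- orthogonalise(Xf)
  ph <- t(apply(Xf, 1, function(x) analytic(x)$phase))
  keep <- seq.int(edge + 1L, ncol(ph) - edge)
  R_t <- order_parameter(ph[, keep, drop = FALSE])
  c(list(R_t = R_t), synchrony_metastability(R_t))
}

.fc_matrix <- function(values, metric, band, orthogonalised) {
  structure(list(values = values, metric = metric, band = band,
                 orthogonalised = orthogonalised),
            class = "fc_matrix")
}

#' @export
print.fc_matrix <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf("fc_matrix: %s (%s band), %d regions%s\n", x$metric,
              if (inherits(x$band, "band_spec")) x$band$name else x$band,
              nrow(x$values),
              if (x$orthogonalised) ", orthogonalised" else ""))
  cat(sprintf("  off-diagonal: mean %.3f, range [%.3f, %.3f]\n",
              mean(off), min(off), max(off)))
  invisible(x)
}

# shared front end: band-pass, optional orthogonalisation, analytic
# decomposition, edge exclusion
.analytic_pipeline <- function(X, fs, band, orthogonalise_first) {
  Xf <- bandpass(X, fs, band)
  edge <- attr(Xf, "edge_samples")
  if (orthogonalise_first) Xf <- orthogonalise(Xf)
  ana <- apply(Xf, 1, analytic)
  keep <- seq.int(edge + 1L, ncol(Xf) - edge)
  env <- do.call(rbind, lapply(ana, function(a) a$envelope[keep]))
  ph <- do.call(rbind, lapply(ana, function(a) a$phase[keep]))
  list(envelope = env, phase = ph)
}

#' Amplitude envelope correlation
#'
#' AEC pipeline: band-pass, symmetric orthogonalisation (AEC is sensitive
#' to zero-lag leakage), analytic envelope, downsampling of the envelopes
#' to `env_fs` (1 Hz by default) by block means, then pairwise Pearson
#' correlation.
#'
#' @param X channels x time matrix of raw timecourses.
#' @param fs sampling rate (Hz).
#' @param band a [band_spec()].
#' @param env_fs envelope rate (Hz) before correlation.
#' @return An `fc_matrix` (diagonal 1, entries in \[-1, 1\]).
#' @export
aec <- function(X, fs, band = alpha_band(), env_fs = 1) {
  pp <- .analytic_pipeline(X, fs, band, orthogonalise_first = TRUE)
  env <- downsample_envelope(pp$envelope, fs, env_fs)
  if (ncol(env) < 10)
    warning("fewer than 10 envelope blocks; AEC estimate is unstable")
  V <- stats::cor(t(env))
  diag(V) <- 1
  .fc_matrix(V, "AEC", band, TRUE)
}

#' Phase locking value
#'
#' `PLV_ij = | < exp(i (phi_i - phi_j)) > |` over the edge-excluded window,
#' computed on orthogonalised timecourses (PLV is inflated by zero-lag
#' leakage).
#'
#' @inheritParams aec
#' @return An `fc_matrix` (diagonal 1, entries in \[0, 1\]).
#' @export
plv <- function(X, fs, band = alpha_band()) {
  pp <- .analytic_pipeline(X, fs, band, orthogonalise_first = TRUE)
  Zp <- exp(1i * pp$phase)
  M <- (Zp %*% Conj(t(Zp))) / ncol(Zp)
  V <- Mod(M)
  diag(V) <- 1
  .fc_matrix(V, "PLV", band, TRUE)
}

#' Phase lag index
#'
#' `PLI_ij = | < sign(sin(phi_i - phi_j)) > |` on the raw
#' (non-orthogonalised) timecourses: the asymmetry of the phase-difference
#' distribution, insensitive to zero-lag mixing. `sign(0) = 0`.
#'
#' @inheritParams aec
#' @return An `fc_matrix` (diagonal 0, entries in \[0, 1\]).
#' @export
pli <- function(X, fs, band = alpha_band()) {
  pp <- .analytic_pipeline(X, fs, band, orthogonalise_first = FALSE)
  n <- nrow(pp$phase)
  V <- matrix(0, n, n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n) {
      V[i, j] <- V[j, i] <-
        abs(mean(sign(sin(pp$phase[i, ] - pp$phase[j, ]))))
    }
  .fc_matrix(V, "PLI", band, FALSE)
}

#' Similarity between two functional connectivity matrices
#'
#' Pearson correlation of the strictly-upper-triangle entries (the diagonal
#' carries no information and is excluded).
#'
#' @param A,B `fc_matrix` objects or plain symmetric matrices of equal size.
#' @return Correlation coefficient; `NA` with attribute
#'   `undefined = TRUE` if either triangle has zero variance.
#' @export
fc_similarity <- function(A, B) {
  a <- if (inherits(A, "fc_matrix")) A$values else A
  b <- if (inherits(B, "fc_matrix")) B$values else B
  stopifnot(all(dim(a) == dim(b)))
  if (inherits(A, "fc_matrix") && inherits(B, "fc_matrix") &&
      A$metric != B$metric)
    stop("similarity requires matching metrics")
  ut <- upper.tri(a)
  x <- a[ut]
  y <- b[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- NA_real_
    attr(r, "undefined") <- TRUE
    return(r)
  }
  stats::cor(x, y)
}

#' Model-vs-individual-variability Z-score
#'
#' Leave-one-out benchmark: each subject's FC is correlated with the mean
#' FC of the remaining subjects; the model's similarity to the group is
#' expressed as `Z = (model_sim - mean) / sd` of those leave-one-out
#' similarities (sample sd). `|Z| < 1.96` means the model is not
#' significantly less (or more) similar to the group than a typical
#' individual.
#'
#' @param model_sim model-to-group similarity (scalar correlation).
#' @param subject_fcs a `subject_fc_set` (see [generate_subject_fc_set()]).
#' @return List with `Z`, `mean_sim`, `sd_sim`, `loo_sims`, `rejected`.
#' @export
similarity_zscore <- function(model_sim, subject_fcs) {
  stopifnot(inherits(subject_fcs, "subject_fc_set"))
  mats <- subject_fcs$matrices
  m <- length(mats)
  if (m < 2) stop("need at least 2 subjects")
  total <- Reduce(`+`, mats)
  loo <- vapply(seq_len(m), function(s) {
    grp <- (total - mats[[s]]) / (m - 1)
    fc_similarity(mats[[s]], grp)
  }, 0)
  mu <- mean(loo)
  sdv <- stats::sd(loo)
  if (sdv == 0) stop("degenerate variability: leave-one-out sd is 0")
  Z <- (model_sim - mu) / sdv
  list(Z = Z, mean_sim = mu, sd_sim = sdv, loo_sims = loo,
       rejected = abs(Z) > 1.96)
}

#' Correlation between node strength and converged inhibition
#'
#' E/I-balance diagnostic: Pearson correlation between each region's node
#' strength (total long-range excitatory input weight) and its local
#' inhibitory weight after plasticity. A strong negative signed correlation
#' means regions receiving more excitation acquired proportionally more
#' inhibition.
#'
#' @param network a [structural_network()] (or a weight matrix).
#' @param c_ie_final length-n vector of converged signed inhibitory weights.
#' @return List with `r_signed`, `r_magnitude` and `defined` (FALSE when
#'   `c_ie_final` is constant, e.g. without any ISP run).
#' @export
balance_correlation <- function(network, c_ie_final) {
  W <- if (inherits(network, "structural_network")) network$W else network
  s <- node_strength(W)
  if (length(s) != length(c_ie_final)) stop("length mismatch")
  if (stats::sd(c_ie_final) == 0)
    return(list(r_signed = NA_real_, r_magnitude = NA_real_,
                defined = FALSE))
  r <- stats::cor(s, c_ie_final)
  list(r_signed = r, r_magnitude = abs(r), defined = TRUE)
}

#' Plasticity convergence statistic
#'
#' Standard deviation over time of each region's `c_ie` trajectory within a
#' window (chosen after allowing time to converge); persistent drift shows
#' up as a large value.
#'
#' @param cie_traj n x K matrix of coarsely sampled `c_ie`.
#' @param times length-K vector of sample times (s).
#' @param window length-2 time window `c(t0, t1)`.
#' @return List with `per_region` (sd per region) and `max` (scalar).
#' @export
convergence_stat <- function(cie_traj, times, window = range(times)) {
  stopifnot(is.matrix(cie_traj), length(times) == ncol(cie_traj))
  keep <- times >= window[1] & times <= window[2]
  if (!any(keep)) stop("empty convergence window")
  sds <- apply(cie_traj[, keep, drop = FALSE], 1, stats::sd)
  if (sum(keep) == 1L) sds <- rep(0, nrow(cie_traj))
  list(per_region = sds, max = max(sds))
}

#' Write a functional connectivity matrix as labelled CSV
#'
#' @param fc an `fc_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fc_csv <- function(fc, path) {
  stopifnot(inherits(fc, "fc_matrix"))
  utils::write.csv(fc$values, path, row.names = FALSE)
  invisible(path)
}
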