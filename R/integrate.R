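#' Simulation configuration
#'
#' @param duration length of the recorded analysis segment (s), after any
#'   ISP schedule and before transient discard.
#' @param dt integration step (s).
#' @param transient initial span of the analysis segment discarded to remove
#'   initial-condition effects (s).
#' @param out_fs output sampling rate (Hz) after anti-alias downsampling.
#' @param seed integer RNG seed governing initial conditions and noise.
#' @param isp_schedule list of `c(span_s, tau_isp_s)` stages run with
#'   plasticity on before the analysis segment; empty list means ISP off.
#' @param freeze_after_schedule freeze `c_ie` for the analysis segment
#'   (plasticity disabled while recording).
#' @param cie_record_fs rate (Hz) at which the slow `c_ie` trajectory is
#'   stored.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration = 30, dt = 1e-4, transient = 15,
                       out_fs = 300, seed = 1, isp_schedule = list(),
                       freeze_after_schedule = TRUE, cie_record_fs = 10) {
  stopifnot(dt > 0, duration > 0, out_fs <= 1 / dt, transient < duration,
            transient >= 0)
  if (length(isp_schedule))
    for (st in isp_schedule)
      stopifnot(length(st) == 2, st[1] > 0, st[2] > 0)
  structure(list(duration = duration, dt = dt, transient = transient,
                 out_fs = out_fs, seed = as.integer(seed),
                 isp_schedule = isp_schedule,
                 freeze_after_schedule = isTRUE(freeze_after_schedule),
                 cie_record_fs = cie_record_fs),
            class = "sim_config")
}

# initial conditions and history buffer shared by the entry points.
# E, I ~ Uniform(0.1, 0.3) per region (low-activity basin); past E history
# clamped to the initial value.
.init_state <- function(network, config, init = NULL) {
  n <- network$n
  set.seed(config$seed)
  if (is.null(init)) {
    E0 <- stats::runif(n, 0.1, 0.3)
    I0 <- stats::runif(n, 0.1, 0.3)
  } else {
    E0 <- rep_len(init$E, n)
    I0 <- rep_len(init$I, n)
  }
  H <- max(network$delay_steps) + 2L
  list(E_hist = matrix(E0, n, H), I = I0)
}

.cpp_params <- function(params) {
  params[c("c_ee", "c_ei", "mu", "sigma", "P", "C", "tau_e", "tau_i",
           "noise_sd")]
}

.segment <- function(network, params, state, cie, n_steps, dt,
                     isp_on = FALSE, tau_isp = 2.5, rho = 0.15,
                     record = TRUE, cie_record_every = 0L) {
  res <- wc_integrate_cpp(network$W, network$delay_steps,
                          .cpp_params(params), state$E_hist, state$I, cie,
                          as.integer(n_steps), dt, isp_on, tau_isp, rho,
                          record, as.integer(cie_record_every),
                          state$noise_e %||% numeric(0),
                          state$noise_i %||% numeric(0))
  res$state <- list(E_hist = res$E_hist_tail, I = res$I_final,
                    noise_e = res$noise_e, noise_i = res$noise_i)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.finish_sim <- function(raw, network, params, config, cie_traj, cie_times,
                        clamp_count, t0 = 0) {
  dt <- config$dt
  n_keep_from <- floor(config$transient / dt) + 1L
  E <- raw$E[, n_keep_from:ncol(raw$E), drop = FALSE]
  I <- raw$I[, n_keep_from:ncol(raw$I), drop = FALSE]
  fs_in <- 1 / dt
  Ed <- downsample_output(E, fs_in, config$out_fs)
  Id <- downsample_output(I, fs_in, config$out_fs)
  t <- t0 + config$transient + (seq_len(ncol(Ed)) - 1) / config$out_fs
  structure(list(t = t, E = Ed, I = Id,
                 cie = raw$cie_final, cie_traj = cie_traj,
                 cie_times = cie_times, fs = config$out_fs,
                 clamp_count = clamp_count,
                 meta = list(params = params, config = config,
                             n = network$n, velocity = network$velocity)),
            class = "wc_sim")
}

#' Simulate the delay-coupled Wilson-Cowan network
#'
#' Advances the full network with fixed-step RK4. Delayed inputs are read
#' from a per-edge-delay ring buffer of past excitatory activity; noise is
#' drawn once per step per population and linearly interpolated at the RK
#' stages; the history is initialised by clamping to the (seeded, uniform in
#' \[0.1, 0.3\]) initial state. The inhibitory weights stay at
#' `params$c_ie0` (no plasticity); use [run_isp_protocol()] for the staged
#' ISP run. The first `config$transient` seconds are discarded and the
#' output decimated to `config$out_fs` behind an anti-alias low-pass.
#'
#' @param network a [structural_network()].
#' @param params a [wc_params()] object.
#' @param config a [sim_config()] object.
#' @param cie optional length-n vector of fixed inhibitory weights
#'   (defaults to `params$c_ie0` everywhere); used for homogeneous or
#'   frozen-heterogeneous runs.
#' @param init optional list with `E` and `I` vectors overriding the seeded
#'   uniform initial conditions (recycled to length n).
#' @return A `wc_sim` object: fields `t`, `E`, `I` (n x T at `out_fs`),
#'   `cie` (final weights), `cie_traj`/`cie_times`, `fs`, `meta`.
#' @export
simulate_network <- function(network, params, config = sim_config(),
                             cie = NULL, init = NULL) {
  stopifnot(inherits(network, "structural_network"),
            inherits(params, "wc_params"), inherits(config, "sim_config"))
  if (network$dt != config$dt)
    network <- structural_network(network$W, network$D, network$velocity,
                                  config$dt, network$labels)
  cie <- .expand_cie(cie, params, network$n)
  state <- .init_state(network, config, init)
  n_steps <- round(config$duration / config$dt)
  raw <- .segment(network, params, state, cie, n_steps, config$dt,
                  record = TRUE)
  .finish_sim(raw, network, params, config,
              cie_traj = matrix(raw$cie_final, network$n, 1),
              cie_times = config$duration, clamp_count = raw$clamp_count)
}

.expand_cie <- function(cie, params, n) {
  if (is.null(cie)) cie <- params$c_ie0
  if (length(cie) == 1L) cie <- rep(cie, n)
  if (length(cie) != n) stop("cie must be scalar or length n")
  if (any(cie > 0)) stop("cie must be <= 0")
  cie
}

#' Run the staged ISP protocol
#'
#' Runs the plasticity schedule in `config$isp_schedule` (each stage a span
#' in seconds with its own `tau_isp`, progressively slowed to decouple
#' plasticity from the fast oscillations), updating `c_ie` each step by
#' forward Euler on [isp_derivative()] (justified by timescale separation),
#' then freezes `c_ie` and records the analysis segment of
#' `config$duration` seconds. Weights are clamped at 0 from above
#' (inhibition cannot become excitation); clamp events are counted.
#'
#' @inheritParams simulate_network
#' @return A `wc_sim` object whose `E`/`I` cover the frozen analysis
#'   segment and whose `cie_traj` spans the whole schedule.
#' @export
run_isp_protocol <- function(network, params, config) {
  stopifnot(inherits(network, "structural_network"),
            inherits(params, "wc_params"), inherits(config, "sim_config"))
  if (!length(config$isp_schedule)) stop("isp_schedule is empty")
  if (network$dt != config$dt)
    network <- structural_network(network$W, network$D, network$velocity,
                                  config$dt, network$labels)
  n <- network$n
  dt <- config$dt
  cie <- .expand_cie(NULL, params, n)
  state <- .init_state(network, config)
  rec_every <- max(1L, round(1 / (config$cie_record_fs * dt)))
  traj <- list()
  times <- list()
  t_off <- 0
  clamps <- 0
  for (st in config$isp_schedule) {
    n_steps <- round(st[1] / dt)
    seg <- .segment(network, params, state, cie, n_steps, dt,
                    isp_on = TRUE, tau_isp = st[2], rho = params$rho,
                    record = FALSE, cie_record_every = rec_every)
    cie <- seg$cie_final
    state <- seg$state
    traj[[length(traj) + 1L]] <- seg$cie_traj
    times[[length(times) + 1L]] <- t_off + seg$cie_steps * dt
    t_off <- t_off + st[1]
    clamps <- clamps + seg$clamp_count
  }
  n_steps <- round(config$duration / dt)
  fin <- .segment(network, params, state, cie, n_steps, dt,
                  isp_on = !config$freeze_after_schedule,
                  tau_isp = config$isp_schedule[[length(config$isp_schedule)]][2],
                  rho = params$rho, record = TRUE,
                  cie_record_every = rec_every)
  traj[[length(traj) + 1L]] <- fin$cie_traj
  times[[length(times) + 1L]] <- t_off + fin$cie_steps * dt
  clamps <- clamps + fin$clamp_count
  .finish_sim(fin, network, params, config,
              cie_traj = do.call(cbind, traj),
              cie_times = unlist(times), clamp_count = clamps, t0 = t_off)
}

#' Anti-aliased downsampling of simulated output
#'
#' Zero-phase 4th-order Butterworth low-pass at `0.4 * fs_out`, applied
#' forward and backward, followed by linear-interpolation resampling onto
#' the output grid. Output length is `floor(T * fs_out / fs_in)`.
#'
#' @param x numeric vector or channels x time matrix at rate `fs_in`.
#' @param fs_in input sampling rate (Hz).
#' @param fs_out output rate (Hz), `<= fs_in`.
#' @return Downsampled vector or matrix.
#' @export
downsample_output <- function(x, fs_in, fs_out) {
  if (fs_out > fs_in) stop("fs_out must be <= fs_in")
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, 1)
  if (fs_out == fs_in) return(if (vec) drop(x) else x)
  bf <- signal::butter(4, 0.4 * fs_out / (fs_in / 2), type = "low")
  T_in <- ncol(x)
  L <- floor(T_in * fs_out / fs_in)
  t_in <- (seq_len(T_in) - 1) / fs_in
  t_out <- (seq_len(L) - 1) / fs_out
  out <- matrix(NA_real_, nrow(x), L)
  npad <- ceiling(6 * fs_in / (0.4 * fs_out))
  for (i in seq_len(nrow(x))) {
    xf <- filtfilt_padded(bf, x[i, ], npad)
    out[i, ] <- stats::approx(t_in, xf, xout = t_out, rule = 2)$y
  }
  if (vec) drop(out) else out
}

#' @export
print.wc_sim <- function(x, ...) {
  cat(sprintf("wc_sim: %d regions, %.1f s at %g Hz (%d samples)\n",
              nrow(x$E), diff(range(x$t)), x$fs, ncol(x$E)))
  cat(sprintf("  mean E %.3f  mean c_ie %.3f  clamp events %g\n",
              mean(x$E), mean(x$cie), x$clamp_count))
  invisible(x)
}

#' @export
summary.wc_sim <- function(object, ...) {
  s <- list(n = nrow(object$E), fs = object$fs,
            span = range(object$t),
            mean_E = rowMeans(object$E), sd_E = apply(object$E, 1, stats::sd),
            cie = object$cie)
  class(s) <- "summary.wc_sim"
  s
}

#' @export
print.summary.wc_sim <- function(x, ...) {
  cat(sprintf("wc_sim summary: %d regions, t = [%.1f, %.1f] s at %g Hz\n",
              x$n, x$span[1], x$span[2], x$fs))
  cat(sprintf("  E: mean %.3f (range of region means %.3f-%.3f)\n",
              mean(x$mean_E), min(x$mean_E), max(x$mean_E)))
  cat(sprintf("  c_ie: mean %.3f (range %.3f-%.3f)\n",
              mean(x$cie), min(x$cie), max(x$cie)))
  invisible(x)
}

#' @export
plot.wc_sim <- function(x, regions = seq_len(min(4, nrow(x$E))),
                        span = 2, ...) {
  idx <- x$t <= min(x$t) + span
  graphics::matplot(x$t[idx], t(x$E[regions, idx, drop = FALSE]),
                    type = "l", lty = 1, xlab = "time (s)",
                    ylab = "excitatory rate", ...)
  invisible(x)
}

#' Export a simulation to CSV
#'
#' Writes the downsampled excitatory timecourses as a plain CSV (time in
#' the first column, one column per region). Intended for small runs.
#'
#' @param sim a `wc_sim` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(sim, path) {
  df <- data.frame(t = sim$t, t(sim$E))
  names(df) <- c("t", paste0("E", seq_len(nrow(sim$E))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
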