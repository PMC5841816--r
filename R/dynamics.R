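#' Sigmoid firing-rate response
#'
#' The population response function `S(x) = 1 / (1 + exp(-(x - mu)/sigma))`,
#' mapping synaptic drive to a firing rate expressed as a fraction of the
#' maximum rate. Numerically stable for large `|x|`.
#'
#' @param x synaptic drive (vectorised).
#' @param mu firing threshold.
#' @param sigma threshold spread; must be `> 0`.
#' @return Rates in (0, 1), same shape as `x`.
#' @examples
#' wc_sigmoid(1)            # threshold -> 0.5
#' wc_sigmoid(0)            # 1/(1 + e^4)
#' @export
wc_sigmoid <- function(x, mu = 1, sigma = 0.25) {
  if (sigma <= 0) stop("sigma must be > 0")
  # plogis is the numerically-stable logistic CDF
  stats::plogis((x - mu) / sigma)
}

#' Inverse sigmoid
#'
#' @param y rate in (0, 1).
#' @inheritParams wc_sigmoid
#' @return Drive `x` such that `wc_sigmoid(x, mu, sigma) = y`.
#' @export
wc_sigmoid_inv <- function(y, mu = 1, sigma = 0.25) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (any(y <= 0 | y >= 1)) stop("y must lie strictly in (0, 1)")
  mu + sigma * log(y / (1 - y))
}

#' Network right-hand side of the Wilson-Cowan equations
#'
#' Time derivatives of the excitatory and inhibitory rates for all regions,
#' given the already-assembled delayed long-range input. The delayed input
#' for region k must equal `sum_j W[k, j] * E_j(t - tau_jk)`; assembling it
#' from the history buffer is the integrator's job.
#'
#' @param E,I length-n vectors of current excitatory/inhibitory rates.
#' @param c_ie length-n vector (or scalar) of signed inhibitory weights.
#' @param delayed_E_input length-n vector of delayed, connectome-weighted
#'   excitatory input (before scaling by the global coupling `C`).
#' @param noise_e,noise_i length-n noise samples entering inside the sigmoid.
#' @param params a [wc_params()] object.
#' @return A list with elements `dE` and `dI` (rates per second).
#' @export
wc_derivatives <- function(E, I, c_ie, delayed_E_input,
                           noise_e = 0, noise_i = 0, params = wc_params()) {
  n <- length(E)
  if (length(I) != n || length(delayed_E_input) != n)
    stop("E, I and delayed_E_input must have equal length")
  if (!(length(c_ie) %in% c(1L, n))) stop("c_ie must be scalar or length n")
  drive_e <- params$c_ee * E + c_ie * I + params$P + noise_e +
    params$C * delayed_E_input
  drive_i <- params$c_ei * E + noise_i
  list(dE = (-E + wc_sigmoid(drive_e, params$mu, params$sigma)) / params$tau_e,
       dI = (-I + wc_sigmoid(drive_i, params$mu, params$sigma)) / params$tau_i)
}

#' Inhibitory synaptic plasticity update
#'
#' Rate of change of the signed local inhibitory weight. The homeostatic
#' (stabilising) form for a signed `c_ie <= 0` entering the excitatory drive
#' additively is `dc_ie/dt = -I (E - rho) / tau_isp`: inhibition strengthens
#' (c_ie decreases) when excitatory activity exceeds the target, equivalent to
#' the textbook rule applied to the inhibitory magnitude `|c_ie|`.
#'
#' @param E,I current excitatory/inhibitory rates (vectorised).
#' @param rho target excitatory activity level.
#' @param tau_isp learning timescale (s); must be `> 0`.
#' @return `dc_ie/dt` in units of weight per second.
#' @examples
#' isp_derivative(E = 0.3, I = 0.2, rho = 0.15, tau_isp = 2.5)  # -0.012
#' @export
isp_derivative <- function(E, I, rho = 0.15, tau_isp = 2.5) {
  if (tau_isp <= 0) stop("tau_isp must be > 0")
  -I * (E - rho) / tau_isp
}

#' Fixed point of an isolated Wilson-Cowan unit
#'
#' Solves the steady state of a single uncoupled, noise-free unit:
#' `E = S(c_ee E + c_ie S(c_ei E) + P + external)`, `I = S(c_ei E)`.
#' Roots are bracketed by a dense scan of the self-consistency residual on
#' \[0, 1\] and polished with [stats::uniroot()]. When several fixed points
#' coexist the low-activity branch (smallest E) is returned as the operating
#' point; the full root list is kept.
#'
#' @param params a [wc_params()] object.
#' @param c_ie signed inhibitory weight (defaults to `params$c_ie0`).
#' @param external additional constant drive added to P (e.g. long-range
#'   input treated as frozen).
#' @param grid_n resolution of the bracketing scan.
#' @param tol root-polishing tolerance on E.
#' @return A list with `E`, `I` (the low-E operating point) and `roots`, a
#'   matrix with one row per fixed point (columns `E`, `I`).
#' @export
isolated_fixed_point <- function(params = wc_params(), c_ie = params$c_ie0,
                                 external = 0, grid_n = 10000L,
                                 tol = 1e-12) {
  g <- function(E) {
    I <- wc_sigmoid(params$c_ei * E, params$mu, params$sigma)
    wc_sigmoid(params$c_ee * E + c_ie * I + params$P + external,
               params$mu, params$sigma) - E
  }
  Es <- seq(0, 1, length.out = grid_n)
  gv <- g(Es)
  roots <- numeric(0)
  sgn <- sign(gv)
  flips <- which(sgn[-1] * sgn[-grid_n] < 0)
  for (i in flips) {
    r <- stats::uniroot(g, c(Es[i], Es[i + 1]), tol = tol)
    roots <- c(roots, r$root)
  }
  exact <- Es[gv == 0]
  roots <- sort(unique(c(roots, exact)))
  if (!length(roots))
    stop("no fixed point bracketed in [0, 1]; internal failure")
  Is <- wc_sigmoid(params$c_ei * roots, params$mu, params$sigma)
  list(E = roots[1], I = Is[1],
       roots = cbind(E = roots, I = Is))
}

#' Jacobian of the isolated unit at a fixed point
#'
#' Analytic 2x2 Jacobian of the two-ODE isolated unit, using
#' `S'(x) = S(x) (1 - S(x)) / sigma`.
#'
#' @inheritParams isolated_fixed_point
#' @param E,I the fixed point at which to linearise.
#' @return A 2x2 matrix, state order (E, I).
#' @export
jacobian_isolated <- function(params = wc_params(), c_ie = params$c_ie0,
                              E, I, external = 0) {
  drive_e <- params$c_ee * E + c_ie * I + params$P + external
  drive_i <- params$c_ei * E
  Se <- wc_sigmoid(drive_e, params$mu, params$sigma)
  Si <- wc_sigmoid(drive_i, params$mu, params$sigma)
  dSe <- Se * (1 - Se) / params$sigma
  dSi <- Si * (1 - Si) / params$sigma
  matrix(c((-1 + params$c_ee * dSe) / params$tau_e, c_ie * dSe / params$tau_e,
           params$c_ei * dSi / params$tau_i,        -1 / params$tau_i),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("E", "I"), c("E", "I")))
}

#' Closed-form ISP equilibrium inhibitory weight
#'
#' At the plasticity equilibrium of a unit in a steady (non-oscillatory)
#' regime, `E = rho` and the fixed-point condition can be inverted:
#' `c_ie* = (S^{-1}(rho) - c_ee rho - P - external) / I*` with
#' `I* = S(c_ei rho)`. Valid as an oracle only where the converged state is a
#' stable steady state, not a limit cycle.
#'
#' @inheritParams isolated_fixed_point
#' @param rho target excitatory activity (defaults to `params$rho`).
#' @return The equilibrium signed inhibitory weight `c_ie*` (scalar).
#' @examples
#' isp_equilibrium_cie(wc_params(), rho = 0.10)  # ~ -2.76
#' @export
isp_equilibrium_cie <- function(params = wc_params(), rho = params$rho,
                                external = 0) {
  if (rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)")
  I_star <- wc_sigmoid(params$c_ei * rho, params$mu, params$sigma)
  if (I_star == 0) stop("degenerate input: I* = 0")
  (wc_sigmoid_inv(rho, params$mu, params$sigma) -
     params$c_ee * rho - params$P - external) / I_star
}
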