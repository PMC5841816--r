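#' Wilson-Cowan model parameters
#'
#' Construct the parameter set for the local Wilson-Cowan unit, the global
#' coupling and the inhibitory synaptic plasticity (ISP) rule. Defaults are
#' the standard rescaled parameterisation in which the sigmoid saturates at 1
#' and the firing threshold is `mu = 1`, so all rates are dimensionless
#' fractions of the maximum firing rate.
#'
#' @param c_ee local excitatory-to-excitatory coupling.
#' @param c_ei local excitatory-to-inhibitory coupling.
#' @param c_ie0 initial local inhibitory-to-excitatory coupling; signed,
#'   must be `<= 0` (inhibition enters the excitatory drive additively).
#' @param mu firing response threshold of the sigmoid.
#' @param sigma firing threshold variability (sigmoid spread); must be `> 0`.
#' @param P constant external excitatory drive.
#' @param tau_e excitatory time constant (s).
#' @param tau_i inhibitory time constant (s).
#' @param rho ISP target excitatory activity level, in (0, 1).
#' @param C global coupling scale multiplying all long-range inputs.
#' @param noise_sd standard deviation of the per-step Gaussian noise samples.
#' @param tau_isp ISP learning timescale (s); schedules may override it.
#'
#' @return An object of class `wc_params` (a validated named list).
#' @examples
#' p <- wc_params()
#' p$c_ee
#' @export
wc_params <- function(c_ee = 3.5, c_ei = 3.75, c_ie0 = -2.5,
                      mu = 1, sigma = 0.25, P = 0.31,
                      tau_e = 0.01, tau_i = 0.02, rho = 0.15,
                      C = 0, noise_sd = 0.01, tau_isp = 2.5) {
  p <- list(c_ee = c_ee, c_ei = c_ei, c_ie0 = c_ie0, mu = mu, sigma = sigma,
            P = P, tau_e = tau_e, tau_i = tau_i, rho = rho, C = C,
            noise_sd = noise_sd, tau_isp = tau_isp)
  validate_wc_params(p)
  class(p) <- "wc_params"
  p
}

validate_wc_params <- function(p) {
  stopifnot(is.numeric(unlist(p)))
  if (p$sigma <= 0) stop("sigma must be > 0")
  if (p$tau_e <= 0 || p$tau_i <= 0) stop("time constants must be > 0")
  if (p$c_ie0 > 0) stop("c_ie0 is a signed inhibitory weight and must be <= 0")
  if (p$rho <= 0 || p$rho >= 1) stop("rho must lie in (0, 1)")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (p$tau_isp <= 0) stop("tau_isp must be > 0")
  invisible(p)
}

#' @export
print.wc_params <- function(x, ...) {
  cat("Wilson-Cowan parameters\n")
  cat(sprintf("  local:  c_ee=%g  c_ei=%g  c_ie0=%g  mu=%g  sigma=%g  P=%g\n",
              x$c_ee, x$c_ei, x$c_ie0, x$mu, x$sigma, x$P))
  cat(sprintf("  time:   tau_e=%g s  tau_i=%g s\n", x$tau_e, x$tau_i))
  cat(sprintf("  global: C=%g  noise_sd=%g\n", x$C, x$noise_sd))
  cat(sprintf("  ISP:    rho=%g  tau_isp=%g s\n", x$rho, x$tau_isp))
  invisible(x)
}

#' Read or write a flat key-value parameter file
#'
#' Parameter sets serialise to a plain `key value` text file, one parameter
#' per line, using the canonical parameter names.
#'
#' @param params a `wc_params` object.
#' @param path file path.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   `wc_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "wc_params"))
  lines <- sprintf("%s %.17g", names(unclass(params)), unlist(params))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  keys <- vapply(parts, `[`, "", 1L)
  vals <- as.numeric(vapply(parts, `[`, "", 2L))
  if (anyNA(vals)) stop("non-numeric parameter value in ", path)
  known <- names(formals(wc_params))
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  do.call(wc_params, as.list(stats::setNames(vals, keys)))
}
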