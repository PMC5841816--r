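#' Whole-cortex Wilson-Cowan network model object
#'
#' Bundles a structural network with a parameter set into a model object
#' that the standard S3 generics operate on: `print`, `summary`, `coef`
#' (the flat parameter vector) and `simulate` (which runs the delay
#' integrator and returns `wc_sim` objects).
#'
#' @param network a [structural_network()].
#' @param params a [wc_params()].
#' @return An object of class `wc_model`.
#' @examples
#' \donttest{
#' net <- generate_connectome(n = 10, seed = 1)
#' m <- wc_model(net, wc_params(C = 0.1))
#' sim <- simulate(m, seed = 1, duration = 4, transient = 1)
#' }
#' @export
wc_model <- function(network, params = wc_params()) {
  stopifnot(inherits(network, "structural_network"),
            inherits(params, "wc_params"))
  structure(list(network = network, params = params), class = "wc_model")
}

#' @export
print.wc_model <- function(x, ...) {
  cat("Wilson-Cowan network model\n")
  print(x$network)
  print(x$params)
  invisible(x)
}

#' @export
coef.wc_model <- function(object, ...) unlist(unclass(object$params))

#' @export
summary.wc_model <- function(object, ...) {
  fp <- isolated_fixed_point(object$params)
  ev <- eigen(jacobian_isolated(object$params, E = fp$E, I = fp$I),
              only.values = TRUE)$values
  s <- list(n = object$network$n, params = object$params,
            strength = node_strength(object$network$W),
            fp = fp, max_re = max(Re(ev)))
  class(s) <- "summary.wc_model"
  s
}

#' @export
print.summary.wc_model <- function(x, ...) {
  cat(sprintf("wc_model: %d regions\n", x$n))
  cat(sprintf("  node strength: mean %.2f, range [%.2f, %.2f]\n",
              mean(x$strength), min(x$strength), max(x$strength)))
  cat(sprintf("  isolated unit operating point: E* = %.4f, I* = %.4f (%s)\n",
              x$fp$E, x$fp$I,
              if (x$max_re < 0) "stable" else "unstable"))
  invisible(x)
}

#' Simulate from a Wilson-Cowan network model
#'
#' `simulate` method running the fixed-step delay integrator; with an
#' `isp_schedule` it runs the staged plasticity protocol.
#'
#' @param object a [wc_model()].
#' @param nsim number of independent realisations.
#' @param seed base RNG seed (realisation `k` uses `seed + k - 1`).
#' @param duration,transient,out_fs,isp_schedule passed to [sim_config()].
#' @param ... further [sim_config()] arguments.
#' @return A `wc_sim` for `nsim = 1`, else a list of them.
#' @export
simulate.wc_model <- function(object, nsim = 1, seed = 1, duration = 30,
                              transient = 15, out_fs = 300,
                              isp_schedule = list(), ...) {
  runs <- lapply(seq_len(nsim), function(k) {
    cfg <- sim_config(duration = duration, transient = transient,
                      out_fs = out_fs, seed = seed + k - 1,
                      isp_schedule = isp_schedule, ...)
    if (length(isp_schedule))
      run_isp_protocol(object$network, object$params, cfg)
    else simulate_network(object$network, object$params, cfg)
  })
  if (nsim == 1) runs[[1]] else runs
}
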