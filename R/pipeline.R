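#' Classify the dynamical regime of a simulation
#'
#' Per region: oscillatory if the alpha-band envelope is large relative to
#' the mean activity level; otherwise a steady state, high or low according
#' to the time-mean excitatory rate. The network label is the shared region
#' label, or `"mixed"` when regions disagree.
#'
#' @param sim a `wc_sim` object.
#' @param band a [band_spec()] for the oscillation test.
#' @param osc_frac envelope-to-mean ratio above which a region counts as
#'   oscillatory.
#' @param high_thresh,low_thresh mean-rate thresholds for the steady labels.
#' @return List with `label` (network) and `regions` (per-region labels).
#' @export
classify_regime <- function(sim, band = alpha_band(), osc_frac = 0.2,
                            high_thresh = 0.5, low_thresh = 0.3) {
  E <- sim$E
  fs <- sim$fs
  Ef <- bandpass(E, fs, band)
  edge <- attr(Ef, "edge_samples")
  keep <- seq.int(edge + 1L, ncol(Ef) - edge)
  labs <- character(nrow(E))
  for (k in seq_len(nrow(E))) {
    env <- analytic(Ef[k, ])$envelope[keep]
    mE <- mean(E[k, keep])
    if (mean(env) > osc_frac * mE) {
      labs[k] <- "oscillatory"
    } else if (mE > high_thresh) {
      labs[k] <- "steady_high"
    } else if (mE < low_thresh) {
      labs[k] <- "steady_low"
    } else {
      labs[k] <- "steady_mid"
    }
  }
  u <- unique(labs)
  list(label = if (length(u) == 1L) u else "mixed", regions = labs)
}

#' Sweep configuration over global coupling and conduction velocity
#'
#' @param couplings numeric vector of global coupling values `C`.
#' @param velocities numeric vector of conduction velocities (m/s); `Inf`
#'   is the zero-delay sentinel.
#' @param mode `"no_isp"`, `"isp"` or `"homogeneous"` (uniform `c_ie` set
#'   to the spatial mean of the converged ISP weights at the same cell).
#' @param rho ISP target used in `"isp"`/`"homogeneous"` modes.
#' @param sim_template a [sim_config()] used for every cell (its seed is
#'   overridden by the seed policy).
#' @param reference_fc optional named list of reference `fc_matrix` objects
#'   (names among `"AEC"`, `"PLV"`, `"PLI"`) for similarity scoring.
#' @param base_seed per-cell seeds are `base_seed + cell_index`.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(couplings, velocities, mode = c("no_isp", "isp",
                                                         "homogeneous"),
                         rho = 0.15, sim_template = sim_config(),
                         reference_fc = NULL, base_seed = 1000L) {
  mode <- match.arg(mode)
  if (!length(couplings) || !length(velocities)) stop("empty sweep grid")
  structure(list(couplings = couplings, velocities = velocities,
                 mode = mode, rho = rho, sim_template = sim_template,
                 reference_fc = reference_fc,
                 base_seed = as.integer(base_seed)),
            class = "sweep_config")
}

#' Run a single sweep cell
#'
#' Runs one (coupling, velocity) parameter point in the requested mode and
#' computes the standard per-cell summary: FC similarity per metric (when a
#' reference is supplied), synchrony and metastability, E/I-balance
#' correlation, plasticity convergence statistic, mean converged `c_ie`,
#' and the dynamical regime label.
#'
#' @param network a [structural_network()] (its velocity is overridden).
#' @param params a [wc_params()] (its `C` is overridden).
#' @param C global coupling for this cell.
#' @param velocity conduction velocity for this cell (m/s, `Inf` allowed).
#' @param mode `"no_isp"`, `"isp"` or `"homogeneous"`.
#' @param config a [sim_config()]; for ISP modes its `isp_schedule` must be
#'   non-empty.
#' @param reference_fc optional named list of reference `fc_matrix`s.
#' @param band analysis band.
#' @param cie_homog uniform weight for `"homogeneous"` mode; if `NULL`, an
#'   ISP run is performed first and its spatial mean used.
#' @return A list record (class `wc_cell`) of summary statistics plus the
#'   `wc_sim` object.
#' @export
run_cell <- function(network, params, C, velocity, mode = "no_isp",
                     config = sim_config(), reference_fc = NULL,
                     band = alpha_band(), cie_homog = NULL) {
  net <- structural_network(network$W, network$D, velocity = velocity,
                            dt = config$dt, labels = network$labels)
  p <- params
  p$C <- C
  sim <- switch(mode,
    no_isp = simulate_network(net, p, config),
    isp = run_isp_protocol(net, p, config),
    homogeneous = {
      if (is.null(cie_homog)) {
        isp_sim <- run_isp_protocol(net, p, config)
        cie_homog <- mean(isp_sim$cie)
      }
      simulate_network(net, p, config, cie = rep(cie_homog, net$n))
    },
    stop("unknown mode: ", mode))
  sync <- tryCatch(network_synchrony(sim$E, sim$fs, band),
                   error = function(e) list(synchrony = NA_real_,
                                            metastability = NA_real_))
  sims <- list()
  if (!is.null(reference_fc)) {
    fcs <- list(AEC = function() aec(sim$E, sim$fs, band),
                PLV = function() plv(sim$E, sim$fs, band),
                PLI = function() pli(sim$E, sim$fs, band))
    for (mname in names(reference_fc)) {
      fcm <- tryCatch(fcs[[mname]](), error = function(e) NULL)
      sims[[mname]] <- if (is.null(fcm)) NA_real_
                       else fc_similarity(fcm, reference_fc[[mname]])
    }
  }
  bal <- balance_correlation(net, sim$cie)
  conv <- if (ncol(sim$cie_traj) > 1)
    convergence_stat(sim$cie_traj, sim$cie_times)$max else 0
  regime <- classify_regime(sim, band)
  structure(list(C = C, velocity = velocity, mode = mode,
                 similarity = sims, synchrony = sync$synchrony,
                 metastability = sync$metastability,
                 balance_r = bal$r_signed, convergence = conv,
                 mean_cie = mean(sim$cie), regime = regime$label,
                 cie_homog = if (mode == "homogeneous") cie_homog else NULL,
                 seed = config$seed, sim = sim),
            class = "wc_cell")
}

#' Run a (coupling x velocity) parameter sweep
#'
#' Iterates [run_cell()] over the grid with independent, reproducible
#' per-cell seeds (`base_seed + cell_index`). Integration failures are
#' recorded per cell and do not abort the sweep.
#'
#' @param network a [structural_network()].
#' @param params a [wc_params()].
#' @param sweep a [sweep_config()].
#' @param keep_sims retain each cell's `wc_sim` (memory-heavy).
#' @return An object of class `wc_sweep`: `table` (one row per cell) and
#'   `cells` (the per-cell records).
#' @export
run_sweep <- function(network, params, sweep, keep_sims = FALSE) {
  stopifnot(inherits(sweep, "sweep_config"))
  grid <- expand.grid(C = sweep$couplings, velocity = sweep$velocities,
                      KEEP.OUT.ATTRS = FALSE)
  cells <- vector("list", nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- sweep$sim_template
    cfg$seed <- sweep$base_seed + i
    p <- params
    p$rho <- sweep$rho
    rec <- tryCatch(
      run_cell(network, p, grid$C[i], grid$velocity[i], sweep$mode, cfg,
               sweep$reference_fc),
      error = function(e) structure(list(C = grid$C[i],
                                         velocity = grid$velocity[i],
                                         mode = sweep$mode,
                                         error = conditionMessage(e)),
                                    class = "wc_cell"))
    failed <- !is.null(rec$error)
    rows[[i]] <- data.frame(
      cell = i, C = grid$C[i], velocity = grid$velocity[i],
      synchrony = if (failed) NA else rec$synchrony,
      metastability = if (failed) NA else rec$metastability,
      sim_AEC = if (!failed && !is.null(rec$similarity$AEC))
        rec$similarity$AEC else NA,
      sim_PLV = if (!failed && !is.null(rec$similarity$PLV))
        rec$similarity$PLV else NA,
      sim_PLI = if (!failed && !is.null(rec$similarity$PLI))
        rec$similarity$PLI else NA,
      balance_r = if (failed) NA else rec$balance_r,
      convergence = if (failed) NA else rec$convergence,
      mean_cie = if (failed) NA else rec$mean_cie,
      regime = if (failed) "error" else rec$regime,
      seed = sweep$base_seed + i,
      error = if (failed) rec$error else "")
    if (!keep_sims) rec$sim <- NULL
    cells[[i]] <- rec
  }
  structure(list(table = do.call(rbind, rows), cells = cells,
                 config = sweep), class = "wc_sweep")
}

#' @export
print.wc_sweep <- function(x, ...) {
  cat(sprintf("wc_sweep: %d cells (%s mode)\n", nrow(x$table),
              x$config$mode))
  print(x$table[, setdiff(names(x$table), "error")], digits = 3)
  invisible(x)
}

#' Write a sweep summary table to CSV
#'
#' @param sweep_result a `wc_sweep`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep_result, path) {
  utils::write.csv(sweep_result$table, path, row.names = FALSE)
  invisible(path)
}
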