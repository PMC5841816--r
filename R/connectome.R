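#' Read a square numeric matrix from delimited text
#'
#' Reads the plain-text matrix dialect used for connectome weight and
#' distance matrices: one row per line, whitespace- or comma-delimited
#' numeric values, equal row lengths, no header.
#'
#' @param path file path.
#' @return An n x n numeric matrix.
#' @export
load_matrix_text <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file: ", path)
  rows <- lapply(strsplit(trimws(lines), "[,[:space:]]+"), function(x) {
    v <- suppressWarnings(as.numeric(x))
    v
  })
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop(sprintf("ragged input: row %d has %d columns, expected %d",
                 which(lens != lens[1])[1], lens[lens != lens[1]][1], lens[1]))
  for (i in seq_along(rows)) if (anyNA(rows[[i]]))
    stop(sprintf("non-numeric value at row %d, column %d",
                 i, which(is.na(rows[[i]]))[1]))
  m <- do.call(rbind, rows)
  if (nrow(m) != ncol(m))
    stop(sprintf("non-square matrix: %d rows x %d columns", nrow(m), ncol(m)))
  m
}

#' Write a matrix in the delimited text dialect read by [load_matrix_text()]
#'
#' @param m numeric matrix.
#' @param path file path.
#' @param digits significant digits written (default preserves doubles).
#' @return `path`, invisibly.
#' @export
write_matrix_text <- function(m, path, digits = 17) {
  stopifnot(is.matrix(m), is.numeric(m))
  lines <- apply(m, 1, function(r) paste(formatC(r, digits = digits,
                                                 format = "g"),
                                         collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Log-compress and max-normalise connectome weights
#'
#' Tractography streamline counts are heavily right-skewed; the standard
#' post-processing log-transforms the weights to counter this algorithmic
#' bias and normalises by the largest value. Zero entries (absent
#' connections) stay exactly zero; nonzero entries are rescaled so the
#' smallest nonzero maps to 1, natural-log-compressed, and divided by the
#' maximum, giving a zero-diagonal matrix with maximum entry exactly 1.
#'
#' @param W_raw nonnegative square matrix of raw weights.
#' @return Normalised weight matrix (diagonal forced to 0, max entry 1).
#' @export
log_normalize_weights <- function(W_raw) {
  stopifnot(is.matrix(W_raw), nrow(W_raw) == ncol(W_raw))
  if (any(W_raw < 0)) stop("weights must be nonnegative")
  W <- W_raw
  diag(W) <- 0
  nz <- W > 0
  if (!any(nz)) {
    warning("all-zero weight matrix; returned unchanged")
    return(W)
  }
  mn <- min(W[nz])
  V <- W
  V[nz] <- log(W[nz] / mn)
  mx <- max(V)
  if (mx == 0) {
    # all nonzero weights equal: log-compression is flat, map them to 1
    V[nz] <- 1
    return(V)
  }
  V / mx
}

#' Conduction delays from inter-region distances
#'
#' Converts a distance matrix in millimetres and a uniform conduction
#' velocity in m/s to propagation delays in seconds, plus the delays
#' discretised to integer steps of the integration grid (rounded to
#' nearest). A velocity of `Inf` is the zero-delay sentinel.
#'
#' @param D distance matrix (mm).
#' @param velocity conduction speed (m/s), `> 0` or `Inf`.
#' @param dt integration step (s).
#' @return A list with `delays` (s) and `delay_steps` (integer matrix).
#' @examples
#' delays_from_distances(matrix(c(0, 75, 75, 0), 2), velocity = 5,
#'                       dt = 1e-4)$delays[1, 2]  # 0.015 s
#' @export
delays_from_distances <- function(D, velocity, dt = 1e-4) {
  stopifnot(is.matrix(D), dt > 0)
  if (!(velocity > 0)) stop("velocity must be > 0 (Inf = zero delay)")
  delays <- (D / 1000) / velocity   # mm -> m
  if (is.infinite(velocity)) delays[] <- 0
  steps <- matrix(as.integer(round(delays / dt)), nrow = nrow(D))
  list(delays = delays, delay_steps = steps)
}

#' Node strength
#'
#' Row-sums of the structural weight matrix: the total long-range excitatory
#' input weight converging on each region.
#'
#' @param W square weight matrix.
#' @return Length-n numeric vector.
#' @export
node_strength <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  rowSums(W)
}

#' Construct a structural network object
#'
#' Bundles the normalised weight matrix, the distance matrix, the conduction
#' velocity and the derived per-edge delays, after checking the structural
#' invariants (nonnegative symmetric W with zero diagonal and max 1,
#' symmetric positive distances).
#'
#' @param W normalised weight matrix (as from [log_normalize_weights()]).
#' @param D distance matrix (mm).
#' @param velocity conduction speed (m/s); `Inf` means zero delay.
#' @param dt integration step used to discretise delays (s).
#' @param labels optional character vector of region names.
#' @return An object of class `structural_network` with fields `n`, `W`,
#'   `D`, `velocity`, `delays`, `delay_steps`, `labels`.
#' @export
structural_network <- function(W, D, velocity = 5, dt = 1e-4,
                               labels = NULL) {
  stopifnot(is.matrix(W), is.matrix(D), nrow(W) == ncol(W),
            all(dim(W) == dim(D)))
  n <- nrow(W)
  if (any(W < 0)) stop("W must be nonnegative")
  if (any(diag(W) != 0)) stop("W must have zero diagonal")
  if (max(W) > 0 && abs(max(W) - 1) > 1e-12)
    stop("W must be max-normalised (largest entry 1)")
  if (max(abs(W - t(W))) > 1e-12) stop("W must be symmetric")
  if (max(abs(D - t(D))) > 1e-9) stop("D must be symmetric")
  if (any(diag(D) != 0)) stop("D must have zero diagonal")
  off <- D[upper.tri(D)]
  if (any(off <= 0)) stop("off-diagonal distances must be > 0")
  if (!is.null(labels) && length(labels) != n)
    stop("labels length must equal n")
  del <- delays_from_distances(D, velocity, dt)
  structure(list(n = n, W = W, D = D, velocity = velocity, dt = dt,
                 delays = del$delays, delay_steps = del$delay_steps,
                 labels = labels),
            class = "structural_network")
}

#' @export
print.structural_network <- function(x, ...) {
  dens <- mean(x$W[upper.tri(x$W)] > 0)
  cat(sprintf("structural_network: %d regions, density %.2f\n", x$n, dens))
  cat(sprintf("  velocity %g m/s; delays %s-%s ms; mean node strength %.2f\n",
              x$velocity, format(min(x$delays[upper.tri(x$delays)]) * 1e3,
                                 digits = 3),
              format(max(x$delays) * 1e3, digits = 3),
              mean(node_strength(x$W))))
  invisible(x)
}

#' Generate a synthetic connectome
#'
#' Builds a synthetic stand-in for a parcellated cortical connectome.
#' Region centroids are placed uniformly inside a brain-sized ellipsoid
#' split into two mirrored hemispheres; distances are Euclidean between
#' centroids. Raw weights are sampled log-normally around an
#' exponential-decay mean in distance (short connections are stronger, the
#' dominant regularity of tractography-derived connectomes), thresholded to
#' the requested edge density, symmetrised, and passed through
#' [log_normalize_weights()]. Fully reproducible from `seed`.
#'
#' @param n region count (default 68, a standard bilateral cortical
#'   parcellation size).
#' @param seed integer RNG seed.
#' @param decay_scale e-folding length (mm) of the weight-distance decay.
#' @param density fraction of possible edges retained, in (0, 1].
#' @param velocity conduction speed (m/s) stored on the network.
#' @param dt integration step used for delay discretisation (s).
#' @param lognorm_sd dispersion (log scale) of weights around the decay mean.
#' @param semiaxes ellipsoid semi-axes (mm), anterior-posterior,
#'   left-right (per hemisphere), inferior-superior.
#' @return A [structural_network()] object.
#' @export
generate_connectome <- function(n = 68, seed = 1, decay_scale = 40,
                                density = 0.6, velocity = 5, dt = 1e-4,
                                lognorm_sd = 1.0,
                                semiaxes = c(85, 35, 60)) {
  if (n < 2) stop("n must be >= 2")
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]")
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  n_left <- ceiling(n / 2)
  pts <- matrix(NA_real_, 0, 3)
  # rejection-sample centroids in a half-ellipsoid (x: AP, y: LR, z: IS)
  while (nrow(pts) < n_left) {
    cand <- cbind(stats::runif(4 * n_left, -1, 1),
                  stats::runif(4 * n_left, 0.05, 1),
                  stats::runif(4 * n_left, -1, 1))
    keep <- rowSums(cand^2) <= 1
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  left <- pts[seq_len(n_left), , drop = FALSE]
  left <- sweep(left, 2, semiaxes, `*`)
  right <- left
  right[, 2] <- -right[, 2]
  xyz <- rbind(left, right[seq_len(n - n_left), , drop = FALSE])
  D <- as.matrix(stats::dist(xyz))
  if (any(D[upper.tri(D)] <= 0)) D[D == 0 & row(D) != col(D)] <- 0.5
  # log-normal weights around an exponential distance decay
  iu <- upper.tri(D)
  mu_w <- -D[iu] / decay_scale
  w <- exp(stats::rnorm(sum(iu), mean = mu_w, sd = lognorm_sd))
  n_keep <- max(1L, round(density * length(w)))
  thr <- sort(w, decreasing = TRUE)[n_keep]
  w[w < thr] <- 0
  W_raw <- matrix(0, n, n)
  W_raw[iu] <- w
  W_raw <- W_raw + t(W_raw)
  W <- log_normalize_weights(W_raw)
  structural_network(W, D, velocity = velocity, dt = dt)
}

#' Generate a surrogate per-subject functional connectivity set
#'
#' Produces a set of surrogate subject FC matrices as a group template plus
#' independent symmetric Gaussian noise, clipped to the metric's valid range
#' (`[-1, 1]` for correlation-type metrics, `[0, 1]` for PLV/PLI). Used to
#' exercise the leave-one-out individual-variability machinery without real
#' subject data.
#'
#' @param template symmetric n x n template FC matrix.
#' @param n_subjects number of surrogate subjects (default 55, a typical
#'   resting-state cohort); must be `>= 2`.
#' @param subject_sd standard deviation of per-subject edge noise.
#' @param seed integer RNG seed.
#' @param metric metric name; sets the clipping range and diagonal.
#' @return An object of class `subject_fc_set`: list with `matrices`
#'   (list of n x n matrices), `metric`, `band`.
#' @param band optional band label carried along.
#' @export
generate_subject_fc_set <- function(template, n_subjects = 55,
                                    subject_sd = 0.1, seed = 1,
                                    metric = c("AEC", "PLV", "PLI"),
                                    band = "alpha") {
  metric <- match.arg(metric)
  stopifnot(is.matrix(template), nrow(template) == ncol(template))
  if (max(abs(template - t(template))) > 1e-10)
    stop("template must be symmetric")
  if (subject_sd < 0) stop("subject_sd must be >= 0")
  if (n_subjects < 2) stop("n_subjects must be >= 2 (leave-one-out)")
  rng <- if (metric == "AEC") c(-1, 1) else c(0, 1)
  n <- nrow(template)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  mats <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    Nz <- matrix(0, n, n)
    Nz[upper.tri(Nz)] <- stats::rnorm(n * (n - 1) / 2, sd = subject_sd)
    Nz <- Nz + t(Nz)
    M <- template + Nz
    M[M < rng[1]] <- rng[1]
    M[M > rng[2]] <- rng[2]
    diag(M) <- diag(template)
    mats[[s]] <- M
  }
  structure(list(matrices = mats, metric = metric, band = band),
            class = "subject_fc_set")
}

# save/restore .Random.seed so generators are self-seeding but do not
# disturb the caller's RNG stream
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}
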