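test_that("matrix text I/O parses, validates and round-trips", {
  f <- withr::local_tempfile()
  writeLines(c("0 1", "1 0"), f)
  expect_equal(load_matrix_text(f), rbind(c(0, 1), c(1, 0)))

  writeLines(c("0, 1", "1, 0"), f)
  expect_equal(load_matrix_text(f), rbind(c(0, 1), c(1, 0)))

  writeLines(c("0 1 2", "1 0"), f)
  expect_error(load_matrix_text(f), "ragged")
  writeLines(c("0 1", "1 x"), f)
  expect_error(load_matrix_text(f), "non-numeric")
  writeLines(c("0 1 2", "1 0 3"), f)
  expect_error(load_matrix_text(f), "non-square")

  set.seed(42)
  for (n in c(3, 7)) {
    M <- matrix(rnorm(n * n) * 10^runif(n * n, -6, 3), n)
    write_matrix_text(M, f)
    M2 <- load_matrix_text(f)
    expect_lt(max(abs(M2 - M) / pmax(abs(M), 1e-300)), 1e-12)
  }
})

test_that("log-normalisation preserves zeros and order, max is 1", {
  set.seed(7)
  W <- matrix(runif(36, 0.1, 50), 6)
  W <- W + t(W)
  diag(W) <- 0
  W[2, 5] <- W[5, 2] <- 0
  V <- log_normalize_weights(W)
  expect_identical(V[2, 5], 0)
  expect_identical(diag(V), rep(0, 6))
  expect_equal(max(V), 1)
  expect_true(all(V >= 0))
  # order among nonzero entries is preserved
  iu <- upper.tri(W) & W > 0
  expect_equal(rank(V[iu]), rank(W[iu]))
  expect_error(log_normalize_weights(-W), "nonnegative")
  expect_warning(Vz <- log_normalize_weights(matrix(0, 3, 3)), "all-zero")
  expect_equal(Vz, matrix(0, 3, 3))
})

test_that("distance-to-delay conversion is exact and homogeneous", {
  D <- rbind(c(0, 75), c(75, 0))
  d <- delays_from_distances(D, velocity = 5, dt = 1e-4)
  expect_equal(d$delays[1, 2], 0.015)
  expect_equal(d$delay_steps[1, 2], 150L)
  # doubling velocity halves every delay
  d2 <- delays_from_distances(D, velocity = 10, dt = 1e-4)
  expect_equal(d2$delays, d$delays / 2)
  # infinite velocity sentinel: zero delay
  dz <- delays_from_distances(D, velocity = Inf, dt = 1e-4)
  expect_true(all(dz$delays == 0) && all(dz$delay_steps == 0L))
  # round-to-nearest step
  expect_equal(delays_from_distances(rbind(c(0, 6.15), c(6.15, 0)), 5,
                                     1e-4)$delay_steps[1, 2], 12L)
  expect_error(delays_from_distances(D, velocity = -1), "velocity")
})

test_that("node strength equals brute-force row sums", {
  expect_equal(node_strength(rbind(c(0, 1), c(1, 0))), c(1, 1))
  expect_equal(node_strength(matrix(0, 3, 3)), rep(0, 3))
  set.seed(3)
  W <- matrix(runif(25), 5)
  brute <- vapply(1:5, function(k) sum(W[k, ]), 0)
  expect_equal(node_strength(W), brute)
})

test_that("generated connectomes satisfy the structural invariants", {
  net <- generate_connectome(n = 20, seed = 5)
  W <- net$W
  D <- net$D
  expect_true(all(W >= 0))
  expect_identical(diag(W), rep(0, 20))
  expect_equal(max(W), 1)
  expect_equal(W, t(W))
  expect_equal(D, t(D))
  expect_true(all(D[upper.tri(D)] > 0))
  expect_true(all(net$delays >= 0))
  # determinism
  net2 <- generate_connectome(n = 20, seed = 5)
  expect_identical(net$W, net2$W)
  expect_identical(net$D, net2$D)
  # default size matches a bilateral cortical parcellation
  expect_equal(formals(generate_connectome)$n, 68)
  expect_error(generate_connectome(n = 10, density = 1.5), "density")
  expect_error(generate_connectome(n = 1), "n must be")
})

test_that("generated weights decay with distance", {
  # distance-weight anticorrelation over present edges, several seeds
  for (seed in 1:3) {
    net <- generate_connectome(n = 30, seed = seed, decay_scale = 20)
    iu <- upper.tri(net$W) & net$W > 0
    expect_lt(cor(net$W[iu], net$D[iu]), 0)
  }
})

test_that("surrogate subject FC sets behave as designed", {
  tmpl <- random_fc_template(8, seed = 11)
  # zero subject noise: every subject is the template, LOO similarity 1
  s0 <- generate_subject_fc_set(tmpl, n_subjects = 5, subject_sd = 0,
                                seed = 2)
  expect_true(all(vapply(s0$matrices, function(m) identical(m, tmpl), TRUE)))
  # larger noise -> smaller mean leave-one-out similarity (Monte-Carlo)
  mean_loo <- function(sdv, seed) {
    s <- generate_subject_fc_set(tmpl, n_subjects = 20, subject_sd = sdv,
                                 seed = seed)
    total <- Reduce(`+`, s$matrices)
    mean(vapply(seq_along(s$matrices), function(k)
      fc_similarity(s$matrices[[k]], (total - s$matrices[[k]]) / 19), 0))
  }
  for (seed in 1:3)
    expect_gt(mean_loo(0.05, seed), mean_loo(0.3, seed))
  # range clipping per metric
  sp <- generate_subject_fc_set(tmpl, 4, subject_sd = 2, seed = 3,
                                metric = "PLV")
  expect_true(all(vapply(sp$matrices, function(m) all(m >= 0 & m <= 1),
                         TRUE)))
  expect_error(generate_subject_fc_set(tmpl, n_subjects = 1), ">= 2")
  # default cohort size
  expect_equal(formals(generate_subject_fc_set)$n_subjects, 55)
})
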