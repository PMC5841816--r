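test_that("order parameter matches closed forms and a brute-force oracle", {
  expect_equal(order_parameter(matrix(c(1.3, 1.3, 1.3), 3, 1)), 1)
  expect_equal(order_parameter(matrix(c(0, pi), 2, 1)), 0)
  expect_equal(order_parameter(matrix(c(0, pi / 2), 2, 1)), sqrt(2) / 2)
  set.seed(5)
  ph <- matrix(runif(8 * 50, -pi, pi), 8)
  brute <- vapply(1:50, function(j) Mod(mean(complex(argument = ph[, j]))),
                  0)
  expect_equal(order_parameter(ph), brute, tolerance = 1e-14)
})

test_that("synchrony and metastability are the window mean and sd", {
  expect_equal(synchrony_metastability(rep(0.7, 10))$metastability, 0)
  expect_equal(synchrony_metastability(rep(c(0, 1), 20))$synchrony, 0.5)
  set.seed(6)
  r <- runif(100)
  sm <- synchrony_metastability(r)
  expect_equal(sm$synchrony, sum(r) / 100)
  expect_equal(sm$metastability, sqrt(sum((r - mean(r))^2) / 99))
  expect_error(synchrony_metastability(numeric(0)), "empty")
})

test_that("AEC tracks shared envelopes and vanishes for independent ones", {
  fs <- 300
  t <- seq(0, 120, by = 1 / fs)
  env <- 1 + 0.5 * sin(2 * pi * 0.1 * t)
  X <- rbind(env * cos(2 * pi * 9.5 * t), env * cos(2 * pi * 11.5 * t + 1))
  A <- aec(X, fs)
  expect_gt(A$values[1, 2], 0.9)
  expect_s3_class(A, "fc_matrix")
  expect_true(A$orthogonalised)
  expect_equal(A$values, t(A$values))
  expect_equal(diag(A$values), c(1, 1))
  # independent slow envelopes: AEC near zero
  e1 <- 1 + 0.5 * sin(2 * pi * 0.11 * t + 2)
  e2 <- 1 + 0.5 * sin(2 * pi * 0.23 * t + 5)
  Xi <- rbind(e1 * cos(2 * pi * 9.5 * t), e2 * cos(2 * pi * 11.5 * t))
  expect_lt(abs(aec(Xi, fs)$values[1, 2]), 2 / sqrt(100))
})

test_that("PLV is 1 for constant lag, small for uncoupled noise, offset-invariant", {
  fs <- 300
  t <- seq(0, 60, by = 1 / fs)
  X <- rbind(cos(2 * pi * 10 * t), cos(2 * pi * 10 * t - 1))
  expect_gt(plv(X, fs)$values[1, 2], 0.99)
  set.seed(3)
  Xn <- rbind(rnorm(length(t)), rnorm(length(t)))
  expect_lt(plv(Xn, fs)$values[1, 2], 0.2)
  # common time-varying phase offset cancels in the difference
  drift <- 0.5 * sin(2 * pi * 0.2 * t)
  X2 <- rbind(cos(2 * pi * 10 * t + drift), cos(2 * pi * 10 * t - 1 + drift))
  expect_equal(plv(X2, fs)$values[1, 2], plv(X, fs)$values[1, 2],
               tolerance = 0.02)
})

test_that("PLI detects lag asymmetry and ignores zero-lag identity", {
  fs <- 300
  t <- seq(0, 60, by = 1 / fs)
  ph <- 2 * pi * 10 * t
  # constant positive lag: all phase-difference signs equal
  expect_equal(pli(rbind(cos(ph), cos(ph - 0.8)), fs)$values[1, 2], 1,
               tolerance = 1e-6)
  # identical signals: sign(0) = 0 convention
  expect_lt(pli(rbind(cos(ph), cos(ph)), fs)$values[1, 2], 1e-6)
  expect_equal(diag(pli(rbind(cos(ph), cos(ph - 0.8)), fs)$values), c(0, 0))
  # symmetric +/- jitter around zero lag: distribution stays symmetric
  set.seed(9)
  jit <- sample(c(-0.6, 0.6), length(t), replace = TRUE)
  Xj <- rbind(cos(ph), cos(ph + jit))
  expect_lt(pli(Xj, fs)$values[1, 2], 0.1)
})

test_that("FC metrics are invariant under channel relabeling", {
  set.seed(12)
  fs <- 300
  t <- seq(0, 40, by = 1 / fs)
  X <- rbind(sin(2 * pi * 9 * t) + 0.3 * rnorm(length(t)),
             sin(2 * pi * 10 * t + 0.4) + 0.3 * rnorm(length(t)),
             sin(2 * pi * 12 * t + 1.1) + 0.3 * rnorm(length(t)))
  perm <- c(2, 3, 1)
  for (fun in list(aec, plv, pli)) {
    V <- fun(X, fs)$values
    Vp <- fun(X[perm, ], fs)$values
    expect_equal(Vp, V[perm, perm], tolerance = 1e-6)
  }
})

test_that("FC similarity is the upper-triangle Pearson correlation", {
  A <- matrix(0, 3, 3)
  A[upper.tri(A)] <- c(1, 2, 3)
  A <- A + t(A)
  B <- matrix(0, 3, 3)
  B[upper.tri(B)] <- c(2, 4, 5)
  B <- B + t(B)
  expect_equal(fc_similarity(A, A), 1)
  expect_equal(fc_similarity(A, -B), -fc_similarity(A, B))
  expect_equal(fc_similarity(A, B), 0.98198, tolerance = 1e-5)
  Z <- matrix(1, 3, 3)
  expect_true(is.na(fc_similarity(A, Z)))
  expect_true(attr(fc_similarity(A, Z), "undefined"))
})

test_that("individual-variability Z-scores follow the leave-one-out formula", {
  # the reported group comparison: model 0.48 vs individuals 0.60 +/- 0.17
  z <- (0.48 - 0.60) / 0.17
  expect_equal(z, -0.71, tolerance = 0.01)
  expect_lt(abs(z), 1.96)

  tmpl <- random_fc_template(8, seed = 11)
  s <- generate_subject_fc_set(tmpl, n_subjects = 30, subject_sd = 0.1,
                               seed = 7)
  res <- similarity_zscore(0.48, s)
  # model_sim equal to the mean gives Z = 0
  expect_equal(similarity_zscore(res$mean_sim, s)$Z, 0)
  # hand-rolled leave-one-out oracle
  loo <- vapply(1:30, function(k) {
    grp <- Reduce(`+`, s$matrices[-k]) / 29
    cor(s$matrices[[k]][upper.tri(tmpl)], grp[upper.tri(tmpl)])
  }, 0)
  expect_equal(res$mean_sim, mean(loo))
  expect_equal(res$Z, (0.48 - mean(loo)) / sd(loo))
})

test_that("surrogate recovery: leave-one-out similarity matches its design value", {
  # analytic prediction for template + iid edge noise:
  # r = v / sqrt((v + s^2)(v + s^2/(m-1))), v = template edge variance
  tmpl <- random_fc_template(12, seed = 21)
  v <- var(tmpl[upper.tri(tmpl)])
  m <- 40
  sdv <- 0.15
  pred <- v / sqrt((v + sdv^2) * (v + sdv^2 / (m - 1)))
  sims <- vapply(1:4, function(seed) {
    s <- generate_subject_fc_set(tmpl, m, sdv, seed = seed)
    similarity_zscore(0.5, s)$mean_sim
  }, 0)
  expect_equal(mean(sims), pred, tolerance = 0.03)
})

test_that("E/I balance correlation is -1 in the affine mean-field regime", {
  p <- wc_params()
  net <- generate_connectome(n = 12, seed = 13)
  s <- node_strength(net$W)
  # frozen mean-field external input proportional to node strength
  cie_star <- vapply(0.05 * s, function(e) isp_equilibrium_cie(p, 0.10, e),
                     0)
  b <- balance_correlation(net, cie_star)
  expect_equal(b$r_signed, -1, tolerance = 1e-6)
  expect_equal(b$r_magnitude, 1, tolerance = 1e-6)
  # constant weights: correlation undefined
  b0 <- balance_correlation(net, rep(-2.5, 12))
  expect_false(b0$defined)
  expect_true(is.na(b0$r_signed))
  # random pairs against the base correlation
  set.seed(31)
  x <- rnorm(12)
  expect_equal(balance_correlation(net, -abs(x))$r_signed,
               cor(s, -abs(x)))
})

test_that("convergence statistic: frozen weights give 0, a ramp gives |a| L / sqrt(12)", {
  times <- seq(0.01, 4, by = 0.01)
  traj <- matrix(-2, 3, length(times))
  expect_equal(convergence_stat(traj, times)$max, 0)
  a <- 0.03
  L <- diff(range(times))
  ramp <- rbind(-2 + a * times, rep(-2, length(times)))
  cs <- convergence_stat(ramp, times, window = c(0.01, 4))
  expect_equal(cs$per_region[1], abs(a) * L / sqrt(12), tolerance = 0.01)
  expect_error(convergence_stat(traj, times, window = c(10, 20)), "empty")
})
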