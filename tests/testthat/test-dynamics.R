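test_that("sigmoid values, saturation and inverse", {
  expect_equal(wc_sigmoid(1), 0.5)
  expect_equal(wc_sigmoid(0), 1 / (1 + exp(4)))
  expect_equal(wc_sigmoid(1e6), 1)
  expect_equal(wc_sigmoid(-1e6), 0)
  expect_error(wc_sigmoid(0, sigma = 0), "sigma")
  y <- seq(1e-6, 1 - 1e-6, length.out = 50)
  expect_lt(max(abs(wc_sigmoid(wc_sigmoid_inv(y)) - y)), 1e-12)
})

test_that("network derivatives vanish at the isolated fixed point and match a scalar oracle", {
  p <- wc_params()
  fp <- isolated_fixed_point(p)
  d <- wc_derivatives(E = rep(fp$E, 3), I = rep(fp$I, 3), c_ie = p$c_ie0,
                      delayed_E_input = rep(0, 3), params = p)
  expect_lt(max(abs(c(d$dE, d$dI))), 1e-10)

  # at the origin with zero input the flow is strictly inward-positive
  d0 <- wc_derivatives(0, 0, p$c_ie0, 0, params = p)
  expect_gt(d0$dE, 0)
  expect_gt(d0$dI, 0)

  # n = 1 reduces to an independently coded scalar two-ODE system
  scalar_rhs <- function(E, I, din, ne, ni, p) {
    S <- function(x) 1 / (1 + exp(-(x - p$mu) / p$sigma))
    c((-E + S(p$c_ee * E + p$c_ie0 * I + p$P + ne + p$C * din)) / p$tau_e,
      (-I + S(p$c_ei * E + ni)) / p$tau_i)
  }
  set.seed(8)
  p2 <- wc_params(C = 0.2)
  for (k in 1:10) {
    E <- runif(1); I <- runif(1); din <- runif(1)
    ne <- rnorm(1, 0, 0.01); ni <- rnorm(1, 0, 0.01)
    d1 <- wc_derivatives(E, I, p2$c_ie0, din, ne, ni, p2)
    expect_equal(c(d1$dE, d1$dI), scalar_rhs(E, I, din, ne, ni, p2),
                 tolerance = 1e-12)
  }
  expect_error(wc_derivatives(c(0, 0), 0, -2.5, 0), "equal length")
})

test_that("ISP derivative has the homeostatic sign and magnitude", {
  expect_equal(isp_derivative(E = 0.15, I = 0.3, rho = 0.15), 0)
  expect_equal(isp_derivative(E = 0.3, I = 0, rho = 0.15), 0)
  # above target with active inhibition: inhibition strengthens
  expect_lt(isp_derivative(E = 0.3, I = 0.2, rho = 0.15, tau_isp = 2.5), 0)
  expect_equal(isp_derivative(0.3, 0.2, 0.15, 2.5), -0.012)
  expect_error(isp_derivative(0.2, 0.2, tau_isp = -1), "tau_isp")
})

test_that("isolated fixed point matches a dense grid scan", {
  p <- wc_params()
  fp <- isolated_fixed_point(p)
  # residuals of both equations at the returned point
  res_E <- wc_sigmoid(p$c_ee * fp$E + p$c_ie0 * fp$I + p$P) - fp$E
  res_I <- wc_sigmoid(p$c_ei * fp$E) - fp$I
  expect_lt(abs(res_E), 1e-10)
  expect_lt(abs(res_I), 1e-10)

  # brute-force oracle: sign changes of g on a 1e-4 grid
  g <- function(E) wc_sigmoid(p$c_ee * E +
                              p$c_ie0 * wc_sigmoid(p$c_ei * E) + p$P) - E
  Es <- seq(0, 1, by = 1e-4)
  gv <- g(Es)
  brute <- Es[which(gv[-1] * gv[-length(gv)] < 0)]
  expect_equal(nrow(fp$roots), length(brute))
  expect_lt(max(abs(fp$roots[, "E"] - brute)), 1e-4)

  # strong drive saturates the excitatory population
  fp_hi <- isolated_fixed_point(wc_params(P = 50))
  expect_gt(fp_hi$E, 0.999)
})

test_that("analytic Jacobian matches finite differences and decoupled limits", {
  p <- wc_params()
  fp <- isolated_fixed_point(p)
  J <- jacobian_isolated(p, E = fp$E, I = fp$I)
  h <- 1e-6
  num <- matrix(0, 2, 2)
  f <- function(E, I) {
    d <- wc_derivatives(E, I, p$c_ie0, 0, params = p)
    c(d$dE, d$dI)
  }
  num[, 1] <- (f(fp$E + h, fp$I) - f(fp$E - h, fp$I)) / (2 * h)
  num[, 2] <- (f(fp$E, fp$I + h) - f(fp$E, fp$I - h)) / (2 * h)
  expect_lt(max(abs(J - num)), 1e-5)

  # stable operating point below the oscillatory threshold
  expect_lt(max(Re(eigen(J, only.values = TRUE)$values)), 0)

  # decoupled limit: lower-triangular with eigenvalues -1/tau
  p0 <- wc_params()
  p0$c_ee <- 0
  fp0 <- isolated_fixed_point(p0, c_ie = 0)
  J0 <- jacobian_isolated(p0, c_ie = 0, E = fp0$E, I = fp0$I)
  expect_equal(J0[1, 2], 0)
  expect_equal(sort(Re(eigen(J0)$values)),
               sort(c(-1 / p0$tau_e, -1 / p0$tau_i)))
})

test_that("closed-form ISP equilibrium weight is correct and monotone", {
  p <- wc_params()
  cie <- isp_equilibrium_cie(p, rho = 0.10)
  expect_equal(cie, -2.7592, tolerance = 1e-4)
  # self-consistency: with c_ie = cie*, rho is a fixed point
  fp <- isolated_fixed_point(p, c_ie = cie)
  expect_equal(fp$E, 0.10, tolerance = 1e-9)
  # strictly decreasing in external drive (affine, negative slope)
  ext <- seq(0, 0.3, length.out = 7)
  vals <- vapply(ext, function(e) isp_equilibrium_cie(p, 0.10, e), 0)
  expect_true(all(diff(vals) < 0))
  # numerator-vanishing target gives c_ie* = 0 (weak recurrent excitation
  # so the self-consistency root lies inside (0, 1))
  p3 <- wc_params(c_ee = 0.5)
  rho0 <- uniroot(function(r) wc_sigmoid_inv(r) - p3$c_ee * r - p3$P,
                  c(0.05, 0.5), tol = 1e-12)$root
  expect_equal(isp_equilibrium_cie(p3, rho0), 0, tolerance = 1e-7)
})

test_that("parameter validation and flat-file round trip", {
  expect_error(wc_params(sigma = -1), "sigma")
  expect_error(wc_params(c_ie0 = 1), "c_ie0")
  expect_error(wc_params(rho = 1.2), "rho")
  p <- wc_params(C = 0.12, noise_sd = 0.02)
  f <- withr::local_tempfile()
  write_params(p, f)
  expect_equal(read_params(f), p)
})
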