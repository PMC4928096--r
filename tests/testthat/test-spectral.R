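test_that("null parameters give the identity transfer pair", {
  b <- laguerre_basis(0.2, 2)
  kt <- narl_to_kernels(null_params(1500, P1 = 2, P2 = 2), b, mu_rr = 0.8)
  expect_true(all(Mod(kt$H1 - 1) < 1e-14))
  expect_true(all(Mod(kt$H2_at(c(0.1), c(0.2))) == 0))
})

test_that("single-Laguerre model equals the closed-form AR(1) transfer", {
  a <- 0.5
  b1 <- laguerre_basis(1e-30, 1, truncation = 1)
  par <- narl_parameters(shape = 1500, g0 = 0,
                         g1 = a / b1$basis_matrix[1, 1])
  f <- seq(-0.5, 0.5, by = 0.005)
  kt <- narl_to_kernels(par, b1, freq_grid = f, mu_rr = 0.8)
  closed <- 1 / Mod(1 - a * exp(-2i * pi * f))^2
  expect_lt(max(abs(Mod(kt$H1)^2 - closed) / closed), 1e-8)
})

test_that("conjugate symmetry and pole detection", {
  b <- laguerre_basis(0.2, 2)
  par <- narl_parameters(shape = 1000, g0 = 0, g1 = c(0.4, -0.2),
                         g2 = matrix(c(0.2, 0.05, 0.05, 0), 2))
  kt <- narl_to_kernels(par, b, mu_rr = 0.8)
  f <- c(0.03, 0.11, 0.27)
  expect_lt(max(Mod(kt$H1_at(-f) - Conj(kt$H1_at(f)))), 1e-12)
  expect_lt(max(Mod(kt$H2_at(-f, -rev(f)) - Conj(kt$H2_at(f, rev(f))))),
            1e-12)
  # a unit-gain lag-1 kernel has 1 - Gamma1(0) = 0
  b0 <- laguerre_basis(1e-30, 1, truncation = 1)
  bad <- narl_parameters(shape = 1000, g0 = 0,
                         g1 = 1 / b0$basis_matrix[1, 1])
  expect_error(narl_to_kernels(bad, b0, freq_grid = seq(0, 0.5, 0.01),
                               mu_rr = 0.8)$H1_at(0),
               "pole")
})

test_that("null model spectrum is flat with the bandwidth LF/HF ratio", {
  traj <- fixture_null_traj()
  sp <- instantaneous_spectrum(traj, n_freq = 256)
  i <- which(is.finite(sp$bands$lf_hf))
  expect_gt(length(i), 10)
  expect_equal(unique(round(sp$bands$lf_hf[i], 9)),
               round(0.10 / 0.35, 9), tolerance = 1e-6)
  expect_true(all(sp$h1sq >= 0))
  expect_error(instantaneous_spectrum(traj, n_freq = 2), "grid")
})

test_that("AR(1)-equivalent band powers match quadrature of the closed
          form", {
  a <- 0.4; mu <- 0.8; shape <- 1500
  b1 <- laguerre_basis(1e-30, 1, truncation = 1)
  par <- narl_parameters(shape = shape, g0 = 0,
                         g1 = a / b1$basis_matrix[1, 1])
  ev <- fixture_renewal()
  traj <- constant_parameter_trajectory(
    ev, par, fit_config(step_delta = 1, P1 = 1, P2 = 0, alpha = 1e-30,
                        truncation = 1))
  sp <- instantaneous_spectrum(traj, n_freq = 2048)
  k <- which(is.finite(sp$bands$lf))[3]
  sg2 <- traj$sigma_rr[match(sp$times[k], traj$grid_times)]^2
  closed_band <- function(lo, hi) {
    stats::integrate(function(f)
      2 * sg2 / Mod(1 - a * exp(-2i * pi * f))^2,
      lo * traj$mu_rr[1], hi * traj$mu_rr[1],
      rel.tol = 1e-10)$value
  }
  mu_k <- traj$mu_rr[match(sp$times[k], traj$grid_times)]
  lf_cf <- stats::integrate(function(f)
    2 * sg2 / Mod(1 - a * exp(-2i * pi * f))^2, 0.05 * mu_k, 0.15 * mu_k,
    rel.tol = 1e-10)$value
  hf_cf <- stats::integrate(function(f)
    2 * sg2 / Mod(1 - a * exp(-2i * pi * f))^2, 0.15 * mu_k, 0.5 * mu_k,
    rel.tol = 1e-10)$value
  expect_lt(abs(sp$bands$lf[k] - lf_cf) / lf_cf, 0.001)
  expect_lt(abs(sp$bands$hf[k] - hf_cf) / hf_cf, 0.001)
})

test_that("spectrum scales linearly with the innovation variance", {
  ev <- fixture_renewal()
  cfg <- fit_config(step_delta = 1)
  t1 <- constant_parameter_trajectory(ev, null_params(1500), cfg)
  t2 <- constant_parameter_trajectory(ev, null_params(1500 / 4), cfg)
  s1 <- instantaneous_spectrum(t1, n_freq = 64)
  s2 <- instantaneous_spectrum(t2, n_freq = 64)
  i <- which(is.finite(s1$bands$lf) & is.finite(s2$bands$lf))
  expect_equal(s2$bands$lf[i] / s1$bands$lf[i], rep(4, length(i)),
               tolerance = 1e-9)
})
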