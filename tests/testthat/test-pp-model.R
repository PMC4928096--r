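test_that("conditional mean reduces to the stated polynomial", {
  p_null <- null_params(1500)
  expect_equal(conditional_mean(p_null, rep(0, 3), last_rr = 0.8), 0.8)

  p <- narl_parameters(shape = 1000, g0 = 0.01, g1 = 0.5)
  expect_equal(conditional_mean(p, 0.02, last_rr = 0.8), 0.82)

  # quadratic symmetry: g2 enters through its symmetric part only
  g2 <- matrix(c(0.3, 0.1, 0.1, -0.2), 2, 2)
  pq <- narl_parameters(shape = 1000, g0 = 0, g1 = c(0, 0), g2 = g2)
  l <- c(0.03, -0.01)
  expect_equal(conditional_mean(pq, l, last_rr = 0.8),
               0.8 + drop(t(l) %*% g2 %*% l), tolerance = 1e-14)
  expect_error(narl_parameters(shape = 1, g2 = matrix(c(0, 1, 0, 0), 2)),
               "symmetric")
  expect_error(narl_parameters(shape = 0), "positive")
})

test_that("single-interval window reduces to one weighted log density", {
  ev <- event_series(cumsum(c(0, rep(0.8, 40))), t_end = 32.2)
  cfg <- fit_config(window_W = 0.5, weight_decay = 0, P1 = 1, P2 = 0,
                    alpha = 0.2, truncation = 12, censoring = FALSE)
  p <- narl_parameters(shape = 900, g0 = 0.0, g1 = 0)
  t <- ev$event_times[30] + 1e-9
  ll <- local_loglikelihood(ev, p, t, cfg)
  expect_equal(ll, dinvgauss(0.8, 0.8, 900, log = TRUE), tolerance = 1e-9)
  expect_error(local_loglikelihood(ev, p, 40, cfg), "no complete interval")
})

test_that("analytic gradient matches central differences", {
  ev <- simulate_ig_renewal(0.8, 1200, 60, seed = 9)
  cfg <- fit_config(window_W = 45, step_delta = 0.05, P1 = 2, P2 = 1,
                    censoring = TRUE)
  p <- narl_parameters(shape = 1000, g0 = 0.003, g1 = c(0.08, -0.04),
                       g2 = matrix(0.3, 1, 1))
  t <- 50
  out <- local_loglikelihood(ev, p, t, cfg, gradient = TRUE)
  th0 <- heartpp:::params_to_theta(p)
  pre <- heartpp:::fit_precompute(ev, cfg)
  rows <- heartpp:::window_rows(pre, t)
  num <- vapply(seq_along(th0), function(i) {
    h <- 1e-6 * max(1, abs(th0[i]))
    tp <- th0; tp[i] <- tp[i] + h
    tm <- th0; tm[i] <- tm[i] - h
    (heartpp:::local_ll_core(tp, pre, t, rows)$ll -
       heartpp:::local_ll_core(tm, pre, t, rows)$ll) / (2 * h)
  }, numeric(1))
  expect_equal(out$grad, num, tolerance = 1e-4)
})

test_that("likelihood is invariant to shifting all event times", {
  ev <- simulate_ig_renewal(0.8, 1500, 60, seed = 4)
  cfg <- fit_config(window_W = 30, P1 = 2, P2 = 0)
  p <- narl_parameters(shape = 1500, g0 = 0, g1 = c(0.05, 0))
  ev2 <- event_series(ev$event_times + 100, t_start = 100,
                      t_end = ev$t_end + 100)
  expect_equal(local_loglikelihood(ev, p, 55, cfg),
               local_loglikelihood(ev2, p, 155, cfg), tolerance = 1e-10)
})

test_that("tracking a constant-parameter recording recovers the moments", {
  ev <- simulate_ig_renewal(0.8, 1500, 420, seed = 12)
  traj <- fit_trajectory(ev, fit_config(step_delta = 0.1))
  keep <- traj$grid_times > 120          # past early partial windows
  expect_gt(mean(traj$converged), 0.95)
  expect_lt(abs(median(traj$mu_rr[keep], na.rm = TRUE) - 0.8) / 0.8, 0.05)
  sig <- sqrt(0.8^3 / 1500)
  expect_lt(abs(median(traj$sigma_rr[keep], na.rm = TRUE) - sig) / sig,
            0.15)
  # reciprocal moments are the closed forms of the fitted IG
  k <- which(keep & traj$converged)[1]
  hr <- ig_hr_moments(traj$mu_rr[k], exp(traj$theta[k, ncol(traj$theta)]))
  expect_equal(traj$mu_hr[k], hr$mu_hr)
  expect_equal(traj$sigma_hr[k], hr$sigma_hr)
})

test_that("a step change in the mean is tracked within two windows", {
  mu_fun <- function(t) if (t < 300) 0.8 else 0.7
  ev <- simulate_ig_timeline(mu_fun, 2000, 540, seed = 21)
  traj <- fit_trajectory(ev, fit_config(step_delta = 0.1))
  late <- traj$grid_times > 300 + 2 * 90
  expect_lt(abs(median(traj$mu_rr[late], na.rm = TRUE) - 0.7) / 0.7, 0.05)
  before <- traj$grid_times > 200 & traj$grid_times < 290
  expect_lt(abs(median(traj$mu_rr[before], na.rm = TRUE) - 0.8) / 0.8,
            0.05)
})

test_that("trajectory export carries every parameter and moment", {
  ev <- fixture_renewal()
  traj <- constant_parameter_trajectory(ev, null_params(1500),
                                        fit_config(step_delta = 1))
  df <- trajectory_frame(traj)
  expect_true(all(c("time", "g0", "g1_1", "g2_1_1", "log_shape", "mu_rr",
                    "sigma_rr", "mu_hr", "sigma_hr", "converged") %in%
                    names(df)))
  expect_equal(nrow(df), length(traj$grid_times))
})
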