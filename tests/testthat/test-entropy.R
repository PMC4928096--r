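# naive double-loop implementation of the template entropies, sharing
# only the scalar ks_distance with the optimized path
entropy_naive <- function(mu, shape, m, r) {
  nb <- length(mu)
  nt <- nb - m
  dist_t <- function(i, j, ord) {
    mx <- 0
    for (k in 0:(ord - 1)) {
      mx <- max(mx, ks_distance(mu[i + k], shape[i + k],
                                mu[j + k], shape[j + k]))
    }
    mx
  }
  Cm <- Cm1 <- numeric(nt)
  B <- A <- 0
  for (i in seq_len(nt)) {
    cm <- cm1 <- 0
    for (j in seq_len(nt)) {
      dm <- dist_t(i, j, m)
      dm1 <- dist_t(i, j, m + 1)
      if (dm <= r) { cm <- cm + 1; if (i != j) B <- B + 1 }
      if (dm1 <= r) { cm1 <- cm1 + 1; if (i != j) A <- A + 1 }
    }
    Cm[i] <- cm / nt; Cm1[i] <- cm1 / nt
  }
  list(approx = mean(log(Cm)) - mean(log(Cm1)),
       sample = if (B > 0 && A > 0) -log(A / B) else NA_real_)
}

test_that("closed-form KS distance matches a dense-grid evaluation", {
  cases <- list(c(0.5, 1000, 1.5, 1000),
                c(0.8, 1500, 0.82, 1500),
                c(0.8, 1500, 0.8, 300),
                c(0.75, 800, 0.85, 2500))
  for (cs in cases) {
    d <- ks_distance(cs[1], cs[2], cs[3], cs[4])
    g <- seq(1e-4, 6, length.out = 1e6)
    dg <- max(abs(pinvgauss(g, cs[1], cs[2]) - pinvgauss(g, cs[3], cs[4])))
    expect_lt(abs(d - dg), 1e-4)
    expect_gte(d, dg - 1e-12)             # closed form is the supremum
    # metric properties
    expect_equal(d, ks_distance(cs[3], cs[4], cs[1], cs[2]))
    expect_true(d >= 0 && d <= 1)
  }
  expect_equal(ks_distance(0.8, 1200, 0.8, 1200), 0)
  expect_error(ks_distance(-1, 10, 1, 10), "mean")
})

test_that("optimized entropies equal the naive double loop", {
  set.seed(31)
  nb <- 200
  mu <- 0.8 + cumsum(rnorm(nb, 0, 0.004))
  shape <- exp(log(1500) + cumsum(rnorm(nb, 0, 0.01)))
  r <- 2 * pnorm(0.1) - 1
  D <- heartpp:::ks_distance_matrix(mu, shape)
  fast <- heartpp:::entropy_from_distances(D, 2, r)
  slow <- entropy_naive(mu, shape, 2, r)
  expect_equal(fast$approx, slow$approx, tolerance = 1e-10)
  expect_equal(fast$sample, slow$sample, tolerance = 1e-10)
})

test_that("identical predictive pdfs give zero sample entropy", {
  D <- matrix(0, 30, 30)
  out <- heartpp:::entropy_from_distances(D, 2, 0.05)
  expect_equal(out$sample, 0)
  expect_equal(out$approx, 0)
})

test_that("entropies are nonnegative and shift invariant on tracked data", {
  ev <- fixture_renewal()
  traj <- fixture_null_traj()
  ent <- instantaneous_entropy(traj, ev, stride = 40, window = 45)
  i <- is.finite(ent$approx_entropy)
  expect_gt(sum(i), 5)
  expect_true(all(ent$approx_entropy[i] >= 0))
  expect_true(all(ent$sample_entropy[is.finite(ent$sample_entropy)] >= 0))

  # shifting the whole recording in time leaves the estimates unchanged
  ev2 <- event_series(ev$event_times + 50, t_start = 50,
                      t_end = ev$t_end + 50)
  traj2 <- constant_parameter_trajectory(ev2, null_params(1500),
                                         fit_config(step_delta = 0.5))
  ent2 <- instantaneous_entropy(traj2, ev2, stride = 40, window = 45)
  a1 <- ent$approx_entropy[is.finite(ent$approx_entropy)]
  a2 <- ent2$approx_entropy[is.finite(ent2$approx_entropy)]
  nn <- min(length(a1), length(a2))
  expect_equal(tail(a1, nn - 2), tail(a2, nn - 2), tolerance = 1e-9)
})

test_that("sharper predictive pdfs do not raise median sample entropy", {
  meds <- vapply(c(800, 8000), function(shp) {
    out <- numeric(3)
    for (s in 1:3) {
      ev <- simulate_ig_renewal(0.8, shp, 240, seed = 50 + s)
      traj <- constant_parameter_trajectory(ev, null_params(shp),
                                            fit_config(step_delta = 0.5))
      ent <- instantaneous_entropy(traj, ev, stride = 60, window = 45)
      out[s] <- median(ent$sample_entropy, na.rm = TRUE)
    }
    median(out)
  }, numeric(1))
  expect_lte(meds[2], meds[1] + 0.2)
})
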