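test_that("interval dialects accumulate and convert units", {
  p <- withr::local_tempfile(lines = c("0.8", "0.82", "0.79"))
  ev <- read_event_series(p, "rr_seconds")
  expect_equal(ev$rr_intervals, c(0.8, 0.82, 0.79))
  expect_equal(ev$event_times, cumsum(c(0, 0.8, 0.82, 0.79)))

  pm <- withr::local_tempfile(lines = c("800", "820"))
  evm <- read_event_series(pm, "rr_milliseconds")
  expect_equal(evm$rr_intervals, c(0.8, 0.82))
})

test_that("invariant violations are reported with their position", {
  p <- withr::local_tempfile(lines = c("0.8", "-0.1"))
  expect_error(read_event_series(p, "rr_seconds"), "line 2")
  expect_error(event_series(c(1, 2, 2)), "index 3")
  expect_error(event_series(c(1, 2), t_end = 1.5), "t_end")
})

test_that("write/read round trip preserves event times to 1e-9 s", {
  ev <- fixture_renewal()
  p <- withr::local_tempfile()
  write_event_series(ev, p)
  back <- read_event_series(p, "beat_times")
  expect_lt(max(abs(back$event_times - ev$event_times)), 1e-9)
})

test_that("annotation tables are validated and sorted", {
  p <- withr::local_tempfile(lines = c(
    "onset,offset,force,velocity,subject",
    "60,85,2,9.4,S01",
    "10,14.3,6,65,S01"))
  ann <- read_stimulus_annotations(p)
  expect_equal(ann$onset, c(10, 60))

  bad <- withr::local_tempfile(lines = c(
    "onset,offset,force,velocity,subject",
    "10,30,2,9.4,S01",
    "20,40,6,65,S01"))
  expect_error(read_stimulus_annotations(bad), "overlapping")

  empty <- withr::local_tempfile(
    lines = "onset,offset,force,velocity,subject")
  expect_equal(nrow(read_stimulus_annotations(empty)), 0)
})

test_that("QRS detection recovers planted beats and rejects bad input", {
  beats <- c(1.0, 1.8, 2.6)
  ecg <- synthetic_ecg(beats, fs = 500)
  det <- detect_r_peaks(ecg)
  expect_equal(length(det$event_times), 3)
  expect_lt(max(abs(det$event_times - beats)), 0.010)

  set.seed(5)
  # 20 dB SNR additive noise
  noisy <- synthetic_ecg(beats, fs = 500, noise_sd = 0.1)
  detn <- detect_r_peaks(noisy)
  expect_equal(length(detn$event_times), 3)
  expect_lt(max(abs(detn$event_times - beats)), 0.010)

  flat <- ecg_trace(rep(0, 2000), 500)
  expect_equal(length(detect_r_peaks(flat)$event_times), 0)
  expect_error(ecg_trace(rep(0, 2000), 0), "sampling_rate")
  expect_error(detect_r_peaks(ecg_trace(rnorm(50), 500)), "2 s")
})

test_that("longer noise-free synthetic ECG yields exactly the planted count", {
  beats <- cumsum(rep(c(0.8, 0.75, 0.85), 10))
  det <- detect_r_peaks(synthetic_ecg(beats, fs = 250))
  expect_equal(length(det$event_times), length(beats))
})

test_that("artifact correction recovers a split beat and is idempotent", {
  ev <- fixture_renewal()
  clean <- correct_artifacts(ev)
  expect_equal(clean$report$merged + clean$report$inserted, 0)
  expect_equal(clean$events$event_times, ev$event_times)

  # plant a spurious detection halfway through beat 100's interval
  tt <- ev$event_times
  fake <- sort(c(tt, (tt[100] + tt[101]) / 2))
  planted <- event_series(fake, t_end = ev$t_end)
  fixed <- correct_artifacts(planted)
  expect_equal(fixed$report$merged, 1)
  expect_lt(max(abs(fixed$events$event_times - tt)), 1e-9)

  twice <- correct_artifacts(fixed$events)
  expect_equal(twice$events$event_times, fixed$events$event_times)

  expect_error(correct_artifacts(event_series(cumsum(rep(0.8, 6)))),
               "20 beats")
})

test_that("a missed beat is reinserted by the long-interval split rule", {
  ev <- fixture_renewal()
  tt <- ev$event_times
  dropped <- event_series(tt[-150], t_end = ev$t_end)
  fixed <- correct_artifacts(dropped)
  expect_equal(fixed$report$inserted, 1)
  expect_equal(length(fixed$events$event_times), length(tt))
})
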