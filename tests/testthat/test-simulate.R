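test_that("arrival times follow straight-line propagation", {
  # mic at the origin, source 100 m overhead: 100 / 340 s
  mics <- data.frame(id = c("o", "b", "c", "d", "e"),
                     x = c(0, 10, -10, 0, 0), y = c(0, 0, 10, -10, 5),
                     z = c(0, 1, 1, 1, 9))
  arr <- array_layout(mics, 22050, sound_speed = 340)
  ev <- emission_event(c(0, 0, 100), 0, default_call_library()[["SYNTH"]])
  at <- arrival_times(ev, arr)
  expect_equal(at[["o"]], 100 / 340, tolerance = 1e-12)  # 0.294118 s

  # independent per-microphone recomputation for random sources
  set.seed(11)
  std <- std_array()
  for (k in 1:20) {
    s <- as.numeric(random_sources(1))
    t0 <- runif(1, 0, 5)
    ev <- emission_event(s, t0, default_call_library()[["SYNTH"]])
    at <- arrival_times(ev, std)
    manual <- vapply(seq_len(6), function(i) {
      m <- as.numeric(std$microphones[i, c("x", "y", "z")])
      t0 + sqrt(sum((s - m)^2)) / std$sound_speed
    }, numeric(1))
    expect_equal(unname(at), manual, tolerance = 1e-12)
  }

  # source on the vertical centroid axis: trio-symmetric arrivals
  ev <- emission_event(c(0, 0, 80), 0, default_call_library()[["SYNTH"]])
  at <- arrival_times(ev, std)
  expect_equal(at[["A_low"]], at[["B_low"]], tolerance = 1e-12)
  expect_equal(at[["A_low"]], at[["C_low"]], tolerance = 1e-12)
  expect_equal(at[["A_high"]], at[["B_high"]], tolerance = 1e-12)
})

test_that("nearest-sample rendering reproduces the rounded arrival offsets", {
  arr <- std_array()
  tpl <- default_call_library()[["SYNTH"]]
  set.seed(21)
  for (k in 1:5) {
    s <- as.numeric(random_sources(1))
    clip <- render_call_clip(s, tpl, arr, noise_rms = 0)
    at <- arrival_times(clip$event, arr)
    offs <- round(at * arr$sample_rate)
    seg <- extract_segment(clip$recording, clip$entry$time_s, 1.5, arr,
                           template_samples = length(tpl$samples))
    ids <- mic_ids(arr)
    for (j in 2:6) {
      cc <- cross_correlation_lag(seg$segments[[ids[1]]], seg$segments[[ids[j]]],
                                  pair_lag_bound(arr, ids[1], ids[j]) + 5)
      expect_identical(cc$lag, as.integer(offs[[ids[j]]] - offs[[ids[1]]]))
      # rendered lag within one sample of the rounded arrival-time difference
      expect_lte(abs(cc$lag - round((at[[ids[j]]] - at[[ids[1]]]) * arr$sample_rate)), 1)
    }
  }
})

test_that("rendering respects noise level, symmetry and spherical spreading", {
  arr <- std_array()
  # pure noise channels: RMS within 5% of the requested level at 10 s
  rec <- render_recording(list(), arr, duration = 10, noise_rms = 0.02, seed = 1)
  rms <- apply(rec$samples, 2, function(v) sqrt(mean(v^2)))
  expect_true(all(abs(rms - 0.02) / 0.02 < 0.05))

  # event at the ground centroid: zero pairwise lag among the bottom trio
  tpl <- default_call_library()[["SYNTH"]]
  ev <- emission_event(c(0, 0, 0), 1.2, tpl)
  rec <- render_recording(list(ev), arr, duration = 2.4)
  seg <- extract_segment(rec, 1.2, 1.5, arr, template_samples = length(tpl$samples))
  cc <- cross_correlation_lag(seg$segments[["A_low"]], seg$segments[["B_low"]],
                              pair_lag_bound(arr, "A_low", "B_low") + 5)
  expect_identical(cc$lag, 0L)

  # doubling the source distance halves the received peak amplitude
  mics <- data.frame(id = letters[1:5], x = c(0, 10, -10, 0, 0),
                     y = c(0, 0, 10, -10, 5), z = c(0, 1, 1, 1, 9))
  arr5 <- array_layout(mics, 22050)
  peak_at <- function(h) {
    ev <- emission_event(c(0, 0, h), 1.2, tpl)
    rec <- render_recording(list(ev), arr5, duration = 2.4)
    max(abs(rec$samples[, "a"]))
  }
  expect_equal(peak_at(50) / peak_at(100), 2, tolerance = 0.02)
})

test_that("a truncated event is rendered partially with a warning", {
  arr <- std_array()
  tpl <- default_call_library()[["SYNTH"]]
  ev <- emission_event(c(0, 0, 30), 1.9, tpl)  # call tail passes the end
  expect_warning(rec <- render_recording(list(ev), arr, duration = 2),
                 "partially")
  expect_gt(max(abs(rec$samples)), 0)
})

test_that("simulated flight tracks hit the stated schedule and bounds", {
  sim <- simulate_flight_track(300, seed = 4)
  expect_length(sim$events, 100L)          # 3-s call interval
  expect_identical(nrow(sim$track$points), 43L)  # 7-s fixes incl. t = 0

  pos <- t(vapply(sim$events, function(e) e$source, numeric(3)))
  expect_true(all(sqrt(pos[, 1]^2 + pos[, 2]^2) <= 105 + 1e-9))
  expect_true(all(pos[, 3] >= 10 - 1e-9 & pos[, 3] <= 140 + 1e-9))
  pts <- sim$track$points
  expect_true(all(sqrt(pts$x^2 + pts$y^2) <= 105 + 1e-9))
  expect_true(all(pts$z >= 10 - 1e-9 & pts$z <= 140 + 1e-9))
  expect_true(all(diff(pts$time) > 0))

  # templates are cycled in order
  labels <- vapply(sim$events, function(e) e$template$label, character(1))
  expect_identical(labels[1:11], names(default_call_library()))
  expect_identical(labels[12], labels[1])
})

test_that("identical seeds reproduce simulations bit for bit", {
  s1 <- simulate_flight_track(60, seed = 9)
  s2 <- simulate_flight_track(60, seed = 9)
  expect_identical(s1$track$points, s2$track$points)

  arr <- std_array()
  r1 <- render_recording(s1$events[2], arr, 10, noise_rms = 0.01, seed = 5)
  r2 <- render_recording(s2$events[2], arr, 10, noise_rms = 0.01, seed = 5)
  expect_identical(r1$samples, r2$samples)
})

test_that("truth perturbation matches the requested per-axis sigma", {
  pts <- data.frame(time = seq_len(10000), x = 0, y = 0, z = 50)
  track <- truth_track(pts)

  expect_identical(perturb_truth(track, sigma = 0)$points, pts)

  noisy <- perturb_truth(track, sigma = 5, seed = 8)
  for (axis in c("x", "y", "z")) {
    rms <- sqrt(mean((noisy$points[[axis]] - pts[[axis]])^2))
    expect_lt(abs(rms - 5) / 5, 0.02)
  }
  # the implied Euclidean uncertainty bound used downstream
  err <- sqrt((noisy$points$x - pts$x)^2 + (noisy$points$y - pts$y)^2 +
              (noisy$points$z - pts$z)^2)
  expect_equal(sqrt(mean(err^2)), sqrt(3) * 5, tolerance = 0.02)
  expect_equal(perturb_truth(track, 5, seed = 8)$points, noisy$points)
})

test_that("truth and schedule CSVs round-trip", {
  sim <- simulate_flight_track(60, seed = 2)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_truth_csv(sim$track, tf)
  back <- read_truth_csv(tf, per_axis_sigma = 5)
  expect_equal(back$points$x, sim$track$points$x, tolerance = 1e-5)
  expect_equal(back$per_axis_sigma, 5)

  sf <- withr::local_tempfile(fileext = ".csv")
  write_schedule_csv(sim$events, sf)
  sched <- read_schedule_csv(sf)
  expect_identical(nrow(sched), length(sim$events))
  expect_identical(sched$label[1:11], names(default_call_library()))
  expect_equal(sched$time_s, vapply(sim$events, function(e) e$t0, numeric(1)),
               tolerance = 1e-3)
})
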