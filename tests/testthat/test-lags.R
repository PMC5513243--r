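test_that("band-pass filter passes the band and rejects out-of-band energy", {
  fs <- 22050
  t <- (0:22049) / fs
  inband <- sin(2 * pi * 7000 * t)
  out <- bandpass(inband, 6000, 8000, fs)
  mid <- 5000:17000  # steady-state section, away from filter transients
  expect_lt(abs(sqrt(mean(out[mid]^2)) / sqrt(mean(inband[mid]^2)) - 1), 0.05)

  lowtone <- sin(2 * pi * 1000 * t)
  rej <- bandpass(lowtone, 6000, 8000, fs)
  atten_db <- 20 * log10(sqrt(mean(rej[mid]^2)) / sqrt(mean(lowtone[mid]^2)))
  expect_lt(atten_db, -40)

  expect_identical(bandpass(numeric(500), 6000, 8000, fs), numeric(500))
  expect_error(bandpass(inband, 8000, 6000, fs), class = "flightloc_invalid_parameter")
  expect_error(bandpass(inband, 6000, 12000, fs), class = "flightloc_invalid_parameter")
})

test_that("cross-correlation recovers constructed shifts with deterministic ties", {
  set.seed(5)
  x <- rnorm(2000)  # broadband: a unique, unambiguous correlation peak

  same <- cross_correlation_lag(x, x, 100)
  expect_identical(same$lag, 0L)
  expect_equal(same$peak, 1.0, tolerance = 1e-12)

  for (shift in c(17L, -23L, 250L)) {
    y <- if (shift >= 0) c(numeric(shift), x)[seq_along(x)]
         else c(x[(-shift + 1):length(x)], numeric(-shift))
    cc <- cross_correlation_lag(x, y, 300)
    expect_identical(cc$lag, shift)
    expect_gt(cc$peak, 0.9)
  }

  # sub-sample refinement stays within a fraction of a sample on clean shifts
  y <- c(numeric(17), x)[seq_along(x)]
  cc <- cross_correlation_lag(x, y, 50, subsample = TRUE)
  expect_lt(abs(cc$lag_fractional - 17), 0.3)

  expect_error(cross_correlation_lag(numeric(100), x[1:100], 10),
               class = "flightloc_zero_segment")
  expect_error(cross_correlation_lag(x, x[-1], 10),
               class = "flightloc_invalid_parameter")
  expect_error(cross_correlation_lag(x, x, length(x)),
               class = "flightloc_invalid_parameter")
})

test_that("rendered channel pairs yield the arrival-time lags of the geometry", {
  arr <- std_array()
  tpl <- default_call_library()[["VESP"]]
  set.seed(31)
  for (k in 1:5) {
    s <- as.numeric(random_sources(1))
    clip <- render_call_clip(s, tpl, arr, noise_rms = 0)
    seg <- extract_segment(clip$recording, clip$entry$time_s, 1.5, arr,
                           template_samples = length(tpl$samples))
    ls <- build_lag_set(seg$segments, arr, band = tpl$band)
    at <- arrival_times(clip$event, arr)
    offs <- round(at * arr$sample_rate)
    expect_true(ls$accepted)
    expect_identical(unname(ls$lags),
                     unname(as.numeric(offs - offs[["A_low"]])))
  }
})

test_that("lag sets are antisymmetric, cycle-consistent and reference-anchored", {
  arr <- std_array()
  lib <- default_call_library()
  set.seed(41)
  for (k in 1:6) {
    tpl <- lib[[(k - 1) %% length(lib) + 1]]
    clip <- render_call_clip(as.numeric(random_sources(1)), tpl, arr,
                             noise_rms = 0)
    seg <- extract_segment(clip$recording, clip$entry$time_s, 1.5, arr,
                           template_samples = length(tpl$samples))
    ls <- build_lag_set(seg$segments, arr, band = tpl$band)
    expect_identical(unname(ls$lags[ls$reference]), 0)
    expect_true(all(ls$pairwise + t(ls$pairwise) == 0))
    expect_true(all(ls$peaks >= -1 & ls$peaks <= 1))
    # cycle consistency within one sample on noise-free quantized input
    ids <- mic_ids(arr)
    for (i in 1:4) for (j in (i + 1):5) for (l in (j + 1):6) {
      dev <- abs(ls$pairwise[ids[i], ids[j]] + ls$pairwise[ids[j], ids[l]] -
                 ls$pairwise[ids[i], ids[l]])
      expect_lte(dev, 1)
    }
  }
})

test_that("an identical shift of every channel leaves the lag set unchanged", {
  arr <- std_array()
  tpl <- default_call_library()[["INBU"]]
  clip <- render_call_clip(c(40, -25, 70), tpl, arr, noise_rms = 0)
  seg <- extract_segment(clip$recording, clip$entry$time_s, 1.5, arr,
                         template_samples = length(tpl$samples))$segments
  ls1 <- build_lag_set(seg, arr, band = tpl$band)
  shift <- 37L
  shifted <- lapply(seg, function(s) c(numeric(shift), s)[seq_along(s)])
  ls2 <- build_lag_set(shifted, arr, band = tpl$band)
  expect_identical(ls1$lags, ls2$lags)
  expect_identical(ls1$pairwise, ls2$pairwise)
})

test_that("screening rejects calls missing from any channel, with diagnostics", {
  arr <- std_array()
  tpl <- default_call_library()[["BTBW"]]
  clip <- render_call_clip(c(30, 40, 100), tpl, arr, noise_rms = 0.003, seed = 2)
  seg <- extract_segment(clip$recording, clip$entry$time_s, 1.5, arr,
                         template_samples = length(tpl$samples))$segments

  ok <- build_lag_set(seg, arr, band = tpl$band)
  expect_true(ok$accepted)
  expect_true(all(ok$detected))

  set.seed(7)
  seg$B_high <- rnorm(length(seg$B_high), sd = 0.003)  # call absent
  rej <- build_lag_set(seg, arr, band = tpl$band)
  expect_false(rej$accepted)
  expect_false(rej$detected[["B_high"]])
  expect_true(all(rej$detected[setdiff(names(rej$detected), "B_high")]))

  # an all-zero channel is a rejection, not an exception
  seg$B_high <- numeric(length(seg$B_high))
  z <- build_lag_set(seg, arr, band = tpl$band)
  expect_false(z$accepted)
  expect_false(z$detected[["B_high"]])
})

test_that("peak correlation decays with increasing noise, in expectation", {
  arr <- std_array()
  tpl <- default_call_library()[["SYNTH"]]
  s <- c(20, 35, 80)
  mean_peak <- function(noise, reps, seed0) {
    mean(vapply(seq_len(reps), function(r) {
      clip <- render_call_clip(s, tpl, arr, noise_rms = noise, seed = seed0 + r)
      seg <- extract_segment(clip$recording, clip$entry$time_s, 1.5, arr,
                             template_samples = length(tpl$samples))$segments
      cross_correlation_lag(bandpass(seg$A_low, tpl$band[1], tpl$band[2], 22050),
                            bandpass(seg$B_high, tpl$band[1], tpl$band[2], 22050),
                            pair_lag_bound(arr, "A_low", "B_high") + 5)$peak
    }, numeric(1)))
  }
  p_low <- mean_peak(0.002, 12, 100)
  p_mid <- mean_peak(0.008, 12, 200)
  p_high <- mean_peak(0.03, 12, 300)
  expect_gt(p_low, p_mid)
  expect_gt(p_mid, p_high)
})
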