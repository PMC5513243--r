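test_that("lags convert to range differences at v / tau meters per sample", {
  arr <- std_array()
  ls <- list(reference = "A_low",
             lags = c(A_low = 0, A_high = 10, B_low = 0, B_high = -496,
                      C_low = 3, C_high = -3))
  delta <- range_differences(ls, arr)
  expect_equal(delta[["A_high"]], 340 * 10 / 22050, tolerance = 1e-12)
  expect_equal(delta[["A_high"]], 0.15420, tolerance = 1e-4)
  expect_identical(delta[["A_low"]], 0)
  expect_equal(delta[["B_high"]], -340 * 496 / 22050, tolerance = 1e-12)
  # the 496-sample bound corresponds to (just past) the 7.64 m separation
  expect_lt(abs(abs(delta[["B_high"]]) - 7.648), 1e-3)
})

test_that("the linear solve recovers exact sources and flags defects", {
  arr <- std_array()
  est <- linear_tdoa_solve(arr, exact_delta(c(30, 40, 100), arr))
  expect_lt(euclid_err(est, c(30, 40, 100)), 1e-6)
  expect_identical(est$method, "linear")
  expect_false(est$flags$negative_range)
  expect_equal(est$emission_time_offset, -est$reference_range / 340,
               tolerance = 1e-12)

  # all-zero range differences: a point equidistant from all six microphones
  est0 <- linear_tdoa_solve(arr, stats::setNames(numeric(6), mic_ids(arr)))
  P <- mic_positions(arr)
  d <- sqrt(rowSums(sweep(P, 2, est0$position)^2))
  expect_lt(max(d) - min(d), 1e-6)
  expect_lt(est0$residual_rms, 1e-6)

  # four microphones are underdetermined
  mics4 <- std_array()$microphones[1:4, ]
  expect_error(array_layout(mics4, 22050), class = "flightloc_invalid_parameter")

  # a range difference exceeding the pair separation is infeasible
  bad <- stats::setNames(numeric(6), mic_ids(arr))
  bad[["A_high"]] <- 9  # > 7.64 m separation
  err <- tryCatch(linear_tdoa_solve(arr, bad), error = identity)
  expect_s3_class(err, "flightloc_infeasible_input")
  expect_match(conditionMessage(err), "A_high")
})

test_that("Gauss-Newton refinement is stationary, monotone and accurate", {
  arr <- std_array()
  truth <- c(-45, 60, 90)
  dx <- exact_delta(truth, arr)

  # exact initialization is a fixed point
  init <- linear_tdoa_solve(arr, dx)
  ref <- refine_gauss_newton(init, arr, dx)
  expect_lt(euclid_err(ref, truth), 1e-8)

  # quantized lags: refinement never increases the residual
  set.seed(17)
  for (k in 1:10) {
    s <- as.numeric(random_sources(1))
    dq <- quantized_delta(s, arr)
    lin <- linear_tdoa_solve(arr, dq)
    ref <- refine_gauss_newton(lin, arr, dq)
    expect_lte(ref$residual_rms, lin$residual_rms + 1e-12)
  }

  # convergence from a remote initialization, cross-checked by the oracle
  dq <- quantized_delta(truth, arr)
  start <- linear_tdoa_solve(arr, dq)
  start$position[] <- c(0, 0, 5)  # array centroid
  start$residual_rms <- Inf
  ref <- refine_gauss_newton(start, arr, dq)
  g <- grid_oracle(arr, dq, coarse_step = 10, refine_levels = 4)
  expect_lt(euclid_err(ref, g$position), 2 * 10 / 5^4)
})

test_that("the grid oracle finds exact sources and never fails on infeasible input", {
  arr <- std_array()
  dx <- exact_delta(c(30, 40, 100), arr)
  g <- grid_oracle(arr, dx, coarse_step = 10, refine_levels = 5)
  expect_lt(euclid_err(g, c(30, 40, 100)), 0.02)

  bad <- stats::setNames(numeric(6), mic_ids(arr))
  bad[["A_high"]] <- 9
  g2 <- grid_oracle(arr, bad, coarse_step = 20, refine_levels = 2)
  expect_s3_class(g2, "source_estimate")
  expect_gt(g2$residual_rms, 0.1)
})

test_that("refined solver and grid oracle agree on random quantized lag sets", {
  arr <- std_array()
  set.seed(23)
  for (k in 1:15) {
    dq <- quantized_delta(as.numeric(random_sources(1)), arr)
    ref <- refine_gauss_newton(linear_tdoa_solve(arr, dq), arr, dq)
    g <- grid_oracle(arr, dq, coarse_step = 10, refine_levels = 4)
    expect_lt(euclid_err(ref, g$position), 2 * 10 / 5^4)
  }
})

test_that("the solver chain is translation equivariant", {
  arr <- std_array()
  shift <- c(250, -180, 40)
  mics2 <- arr$microphones
  mics2$x <- mics2$x + shift[1]
  mics2$y <- mics2$y + shift[2]
  mics2$z <- mics2$z + shift[3]
  arr2 <- array_layout(mics2, arr$sample_rate, arr$sound_speed)
  set.seed(29)
  for (k in 1:5) {
    s <- as.numeric(random_sources(1))
    dq <- quantized_delta(s, arr)
    e1 <- refine_gauss_newton(linear_tdoa_solve(arr, dq), arr, dq)
    dq2 <- quantized_delta(s + shift, arr2)
    e2 <- refine_gauss_newton(linear_tdoa_solve(arr2, dq2), arr2, dq2)
    expect_equal(unname(e2$position), unname(e1$position) + shift,
                 tolerance = 1e-6)
  }
})

test_that("full-chain localization is exact without quantization and bounded with it", {
  arr <- std_array()
  set.seed(37)
  # unquantized range differences: exact recovery (sampled version of the
  # 100-case ensemble; the full ensemble runs in the acceptance suite)
  for (k in 1:20) {
    s <- as.numeric(random_sources(1))
    dx <- exact_delta(s, arr)
    est <- refine_gauss_newton(linear_tdoa_solve(arr, dx), arr, dx)
    expect_lt(euclid_err(est, s), 1e-6)
  }
  # nearest-sample quantization leaves errors on the sample-distance scale
  errs <- vapply(1:10, function(k) {
    s <- as.numeric(random_sources(1))
    dq <- quantized_delta(s, arr)
    euclid_err(refine_gauss_newton(linear_tdoa_solve(arr, dq), arr, dq), s)
  }, numeric(1))
  expect_lt(stats::median(errs), 2)
})

test_that("localize_call reports rejections and ground-biased retrievals", {
  arr <- std_array()
  lib <- default_call_library()

  # clean call end to end
  res <- localize_clip(c(30, 40, 100), lib[["BTBW"]], arr, noise_rms = 0.002,
                       seed = 3)
  expect_identical(res$status, "ok")
  expect_lt(euclid_err(res$estimate, c(30, 40, 100)), 3)

  # heavy noise: rejected with per-channel diagnostics, no estimate
  rej <- localize_clip(c(90, 0, 120), lib[["OVEN"]], arr, noise_rms = 0.15,
                       seed = 4)
  expect_identical(rej$status, "rejected")
  expect_null(rej$estimate)
  expect_false(all(rej$lag_set$detected))

  # a dominant ground interferer drags the retrieval toward the ground:
  # the result is either rejected or visibly near-ground, never a clean
  # aerial fix
  tpl <- lib[["SYNTH"]]
  ground <- emission_event(c(10, -5, 0.5), 1.2, tpl, source_level = 400)
  adv <- render_call_clip(c(30, 40, 100), tpl, arr, noise_rms = 0.002,
                          seed = 5, ground_interferers = list(ground))
  res_g <- localize_call(adv$recording, adv$entry, arr)
  if (res_g$status == "ok") {
    expect_lt(res_g$estimate$position[["z"]], 5)
  } else {
    expect_identical(res_g$status, "rejected")
  }

  # a call scheduled too close to the recording edge is an error record
  short <- render_call_clip(c(30, 40, 100), tpl, arr, t0 = 0.1, duration = 2.4)
  res_e <- localize_call(short$recording, short$entry, arr)
  expect_identical(res_e$status, "error")
  expect_match(res_e$message, "beyond the recording")
})

test_that("retrieval errors are larger in the vertical than in the horizontal", {
  arr <- std_array()
  set.seed(53)
  n <- 60
  S <- random_sources(n)
  err <- t(vapply(seq_len(n), function(k) {
    dq <- quantized_delta(as.numeric(S[k, ]), arr)
    est <- refine_gauss_newton(linear_tdoa_solve(arr, dq), arr, dq)
    as.numeric(est$position) - as.numeric(S[k, ])
  }, numeric(3)))
  expect_gt(stats::median(abs(err[, 3])), stats::median(abs(err[, 1])))
  expect_gt(stats::median(abs(err[, 3])), stats::median(abs(err[, 2])))
})
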