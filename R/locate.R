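#' Convert lags to range differences
#'
#' A lag of `l` samples relative to the reference microphone corresponds to
#' a path-length difference `delta = sound_speed * l / sample_rate` meters:
#' the source is `delta` meters farther from that microphone than from the
#' reference.
#'
#' @param lagset a [build_lag_set()] result (or any list with `lags` and
#'   `reference`).
#' @param layout an [array_layout()].
#' @param fractional if `TRUE` and the lag set carries sub-sample lags, use
#'   them instead of the integer lags.
#' @return Named numeric vector of range differences in meters (reference
#'   entry 0).
#' @export
range_differences <- function(lagset, layout, fractional = FALSE) {
  lags <- if (fractional && !is.null(lagset$lags_fractional))
    lagset$lags_fractional else lagset$lags
  if (!lagset$reference %in% mic_ids(layout))
    fl_stop(sprintf("reference %s not in layout", lagset$reference),
            "flightloc_lookup_error")
  lags * layout$sound_speed / layout$sample_rate
}

# hyperbolic residual vector f_i = |s - m_i| - |s - m_ref| - delta_i over
# the non-reference microphones; P is the position matrix, ref the row index
tdoa_residuals <- function(s, P, ref, delta) {
  d <- row_norms(sweep(P, 2, s))
  (d - d[ref] - delta)[-ref]
}

tdoa_residual_rms <- function(s, P, ref, delta) {
  f <- tdoa_residuals(s, P, ref, delta)
  sqrt(mean(f^2))
}

new_source_estimate <- function(position, reference, reference_range,
                                residual_rms, method, sound_speed,
                                flags = list()) {
  fl <- list(below_ground = isTRUE(flags$below_ground),
             negative_range = isTRUE(flags$negative_range),
             ill_conditioned = isTRUE(flags$ill_conditioned),
             out_of_bounds = isTRUE(flags$out_of_bounds))
  structure(
    list(position = stats::setNames(as.numeric(position), c("x", "y", "z")),
         reference = reference, reference_range = reference_range,
         emission_time_offset = -reference_range / sound_speed,
         residual_rms = residual_rms, method = method, flags = fl),
    class = "source_estimate"
  )
}

#' @export
print.source_estimate <- function(x, ...) {
  on <- names(x$flags)[vapply(x$flags, isTRUE, logical(1))]
  cat(sprintf("Source estimate (%s): x = %.2f, y = %.2f, z = %.2f m\n",
              x$method, x$position[1], x$position[2], x$position[3]))
  cat(sprintf("  reference %s, range %.2f m, residual RMS %.4g m%s\n",
              x$reference, x$reference_range, x$residual_rms,
              if (length(on)) paste0(", flags: ", paste(on, collapse = ", "))
              else ""))
  invisible(x)
}

# order delta to match layout, check the reference entry, return list
prepare_delta <- function(layout, delta, reference) {
  ids <- mic_ids(layout)
  if (!reference %in% ids)
    fl_stop(sprintf("reference %s not in layout", reference),
            "flightloc_lookup_error")
  if (!is.null(names(delta))) {
    if (!all(ids %in% names(delta)))
      fl_stop("`delta` must be named with one entry per microphone",
              "flightloc_invalid_parameter")
    delta <- delta[ids]
  } else if (length(delta) != length(ids)) {
    fl_stop("`delta` must have one entry per microphone (layout order)",
            "flightloc_invalid_parameter")
  }
  list(delta = as.numeric(delta), ref = match(reference, ids), ids = ids)
}

#' Linearized TDOA least-squares solve
#'
#' The closed-form initializer of the solver chain. Writing `R` for the
#' unknown source-to-reference range, each non-reference microphone i gives
#' `|s - m_i| = R + delta_i`; squaring and subtracting the reference
#' equation yields one linear equation per microphone,
#' `2 (m_i - m_ref) . s + 2 delta_i R = |m_i|^2 - |m_ref|^2 - delta_i^2`,
#' and the resulting overdetermined system (N - 1 equations, 4 unknowns
#' `(s, R)`) is solved by least squares. With six microphones the system
#' has one redundant equation, which buys robustness against quantization
#' and noise.
#'
#' @param layout an [array_layout()] with at least 5 microphones.
#' @param delta range differences in meters (named by microphone id, or in
#'   layout order; reference entry 0), e.g. from [range_differences()].
#' @param reference reference microphone id (default: first in layout).
#' @param cond_threshold design-matrix condition number above which the
#'   estimate is flagged `ill_conditioned` (default 1e8).
#' @param feasibility_tol slack in meters allowed on the physical bound
#'   `|delta_i| <= separation(i, ref)`; defaults to one sample distance
#'   (quantization can push a measured lag one sample past the bound).
#' @return A `source_estimate` (method `"linear"`). `negative_range` is
#'   flagged when the least-squares range comes out negative (the estimate
#'   is still returned as an initializer for refinement).
#' @export
linear_tdoa_solve <- function(layout, delta, reference = NULL,
                              cond_threshold = 1e8, feasibility_tol = NULL) {
  reference <- reference %||% mic_ids(layout)[1L]
  pd <- prepare_delta(layout, delta, reference)
  P <- mic_positions(layout)
  ref <- pd$ref
  delta <- pd$delta
  feasibility_tol <- feasibility_tol %||%
    (layout$sound_speed / layout$sample_rate + 1e-9)
  seps <- row_norms(sweep(P, 2, P[ref, ]))
  bad <- which(abs(delta) > seps + feasibility_tol & seq_along(delta) != ref)
  if (length(bad))
    fl_stop(sprintf("infeasible range difference for pair (%s, %s): |%.4f| > separation %.4f m",
                    pd$ids[bad[1L]], reference, delta[bad[1L]], seps[bad[1L]]),
            "flightloc_infeasible_input")

  idx <- setdiff(seq_len(nrow(P)), ref)
  if (length(idx) < 4L)
    fl_stop("at least 5 microphones are required (4 equations for 4 unknowns)",
            "flightloc_invalid_parameter")
  A <- cbind(2 * sweep(P[idx, , drop = FALSE], 2, P[ref, ]), 2 * delta[idx])
  b <- rowSums(P[idx, , drop = FALSE]^2) - sum(P[ref, ]^2) - delta[idx]^2
  cond <- kappa(A, exact = TRUE)
  sol <- qr.coef(qr(A), b)
  s <- sol[1:3]
  R <- sol[4]
  new_source_estimate(
    position = s, reference = reference, reference_range = abs(R),
    residual_rms = tdoa_residual_rms(s, P, ref, delta),
    method = "linear", sound_speed = layout$sound_speed,
    flags = list(below_ground = s[3] < 0, negative_range = R < 0,
                 ill_conditioned = cond > cond_threshold)
  )
}

#' Gauss-Newton refinement of a TDOA estimate
#'
#' Minimizes the true hyperbolic misfit
#' `sum_i (|s - m_i| - |s - m_ref| - delta_i)^2` by damped Gauss-Newton
#' (Levenberg-style: the damping grows until a step reduces the cost). The
#' linearized solution is exact only for error-free range differences;
#' quantized or noisy lags leave a bias that this refinement removes. The
#' result never has a larger residual than the initial estimate; if no
#' descent step can be found the initial estimate is returned with the
#' `ill_conditioned` flag set.
#'
#' @param initial a `source_estimate` (typically from [linear_tdoa_solve()]).
#' @param layout an [array_layout()].
#' @param delta range differences in meters (see [linear_tdoa_solve()]).
#' @param reference reference microphone id; defaults to the initial
#'   estimate's reference.
#' @param max_iter maximum Gauss-Newton iterations (default 50).
#' @param tol stop when the step length falls below this (meters,
#'   default 1e-9).
#' @return A `source_estimate` (method `"refined"`).
#' @export
refine_gauss_newton <- function(initial, layout, delta, reference = NULL,
                                max_iter = 50, tol = 1e-9) {
  reference <- reference %||% initial$reference
  pd <- prepare_delta(layout, delta, reference)
  P <- mic_positions(layout)
  ref <- pd$ref
  delta <- pd$delta
  s <- as.numeric(initial$position)
  if (any(!is.finite(s)))
    fl_stop("initial position must be finite", "flightloc_invalid_parameter")

  cost <- function(s) sum(tdoa_residuals(s, P, ref, delta)^2)
  cur <- cost(s)
  lambda <- 1e-4
  diverged <- FALSE
  for (iter in seq_len(max_iter)) {
    d <- row_norms(sweep(P, 2, s))
    d <- pmax(d, 1e-9)
    U <- -sweep(P, 2, s) / d  # unit vectors (s - m_i)/|s - m_i|
    J <- sweep(U[-ref, , drop = FALSE], 2, U[ref, ])
    f <- tdoa_residuals(s, P, ref, delta)
    g <- crossprod(J, f)
    H <- crossprod(J)
    step_found <- FALSE
    for (k in 1:30) {
      Hd <- H + lambda * diag(3)
      step <- tryCatch(-solve(Hd, g), error = function(e) NULL)
      if (!is.null(step)) {
        s_new <- s + as.numeric(step)
        c_new <- cost(s_new)
        if (is.finite(c_new) && c_new <= cur) {
          s <- s_new
          cur <- c_new
          lambda <- max(lambda / 10, 1e-12)
          step_found <- TRUE
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!step_found) { diverged <- iter == 1L; break }
    if (sqrt(sum(step^2)) < tol) break
  }

  refined_rms <- sqrt(cur / (nrow(P) - 1L))
  if (diverged || refined_rms > initial$residual_rms) {
    out <- initial
    out$flags$ill_conditioned <- TRUE
    return(out)
  }
  new_source_estimate(
    position = s, reference = reference,
    reference_range = sqrt(sum((s - P[ref, ])^2)),
    residual_rms = refined_rms, method = "refined",
    sound_speed = layout$sound_speed,
    flags = list(below_ground = s[3] < 0,
                 negative_range = initial$flags$negative_range,
                 ill_conditioned = initial$flags$ill_conditioned)
  )
}

#' Brute-force grid search oracle
#'
#' Independent verifier for the solver chain: a multi-level exhaustive
#' search minimizing the same hyperbolic residual. Each refinement level
#' re-grids a box of one coarse cell around the current best point with a
#' 5x finer step, so the final resolution is
#' `coarse_step / 5^refine_levels`. The oracle never fails: for infeasible
#' range differences it still returns the minimum-residual grid point
#' (with a large residual).
#'
#' @param layout an [array_layout()].
#' @param delta range differences in meters (see [linear_tdoa_solve()]).
#' @param reference reference microphone id (default: first in layout).
#' @param bounds list with `x`, `y`, `z` ranges in meters (each
#'   `c(min, max)`).
#' @param coarse_step first-level grid step in meters (default 10).
#' @param refine_levels number of 5x refinement passes (default 4; final
#'   step 0.016 m with the default coarse step).
#' @param beam_width number of well-separated candidates carried through
#'   each refinement level (default 25; 1 gives a plain greedy descent,
#'   sufficient when the bounds already isolate one basin).
#' @param polish polish the grid optimum with a restarted derivative-free
#'   simplex search on the same cost (default `TRUE`).
#' @return A `source_estimate` (method `"grid"`).
#' @export
grid_oracle <- function(layout, delta, reference = NULL,
                        bounds = list(x = c(-150, 150), y = c(-150, 150),
                                      z = c(0, 150)),
                        coarse_step = 10, refine_levels = 4,
                        beam_width = 25L, polish = TRUE) {
  reference <- reference %||% mic_ids(layout)[1L]
  pd <- prepare_delta(layout, delta, reference)
  P <- mic_positions(layout)
  ref <- pd$ref
  delta_nr <- pd$delta[-ref]
  check_positive(coarse_step, "coarse_step")

  eval_grid <- function(xs, ys, zs) {
    G <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    D <- matrix(0, nrow(G), nrow(P))
    for (m in seq_len(nrow(P)))
      D[, m] <- sqrt((G[, 1] - P[m, 1])^2 + (G[, 2] - P[m, 2])^2 +
                     (G[, 3] - P[m, 3])^2)
    resid <- sweep(D[, -ref, drop = FALSE] - D[, ref], 2, delta_nr)
    list(points = G, rms = sqrt(rowMeans(resid^2)))
  }
  # keep the best candidates that are mutually at least min_sep apart;
  # the residual surface has long, nearly flat valleys (poorly constrained
  # directions), so a single greedy path can stall far from the minimum --
  # a beam of well-separated candidates refined in parallel does not
  top_candidates <- function(ev, k, min_sep) {
    ord <- order(ev$rms)
    kept <- matrix(numeric(0), 0, 3)
    rms <- numeric(0)
    for (i in ord) {
      p <- ev$points[i, ]
      if (nrow(kept) == 0L || min(row_norms(sweep(kept, 2, p))) >= min_sep) {
        kept <- rbind(kept, p)
        rms <- c(rms, ev$rms[i])
        if (nrow(kept) >= k) break
      }
    }
    list(points = kept, rms = rms)
  }

  step <- coarse_step
  beam <- top_candidates(
    eval_grid(seq(bounds$x[1], bounds$x[2], by = step),
              seq(bounds$y[1], bounds$y[2], by = step),
              seq(bounds$z[1], bounds$z[2], by = step)),
    beam_width, 2 * step)
  for (lvl in seq_len(refine_levels)) {
    half <- step
    step <- step / 5
    pts <- matrix(numeric(0), 0, 3)
    rms <- numeric(0)
    for (b in seq_len(nrow(beam$points))) {
      p <- beam$points[b, ]
      ev <- eval_grid(seq(p[1] - half, p[1] + half, by = step),
                      seq(p[2] - half, p[2] + half, by = step),
                      seq(p[3] - half, p[3] + half, by = step))
      cand <- top_candidates(ev, 3L, 2 * step)
      pts <- rbind(pts, cand$points)
      rms <- c(rms, cand$rms)
    }
    beam <- top_candidates(list(points = pts, rms = rms), beam_width, 2 * step)
  }
  k_best <- which.min(beam$rms)
  best <- list(point = beam$points[k_best, ], rms = beam$rms[k_best])

  # Final polish: the cost surface has near-degenerate (valley) directions
  # along which point sampling cannot rank positions at grid resolution, so
  # the grid optimum is polished by a restarted derivative-free simplex
  # search (Nelder-Mead) on the same cost. This keeps the oracle free of
  # the analytic Jacobian used by the Gauss-Newton solver it verifies.
  cost_at <- function(s) {
    d <- row_norms(sweep(P, 2, s))
    sum(((d - d[ref])[-ref] - delta_nr)^2)
  }
  if (polish) {
    p <- as.numeric(best$point)
    for (restart in 1:2)
      p <- stats::optim(p, cost_at, method = "Nelder-Mead",
                        control = list(maxit = 20000, reltol = 1e-15))$par
    if (cost_at(p) <= best$rms^2 * (nrow(P) - 1L))
      best <- list(point = p, rms = sqrt(cost_at(p) / (nrow(P) - 1L)))
  }
  s <- as.numeric(best$point)
  new_source_estimate(
    position = s, reference = reference,
    reference_range = sqrt(sum((s - P[ref, ])^2)),
    residual_rms = best$rms, method = "grid",
    sound_speed = layout$sound_speed,
    flags = list(below_ground = s[3] < 0)
  )
}

#' Localization configuration
#'
#' @param window segment window length in seconds (default 1.5: covers the
#'   maximum propagation delay for sources within ~250 m plus the call).
#' @param min_peak detection threshold on the normalized peak correlation
#'   (default 0.3).
#' @param reference reference microphone id (`NULL`: first in layout).
#' @param refine run Gauss-Newton refinement after the linear solve
#'   (default `TRUE`).
#' @param subsample parabolic sub-sample lag refinement (default `FALSE`).
#' @param cond_threshold condition-number flag threshold (default 1e8).
#' @param margin extra samples on each pair's lag search bound (default 5).
#' @param template_duration assumed call duration in seconds used for
#'   segment padding (default 0.15, the longest default template).
#' @param max_range estimates farther than this from the array center are
#'   flagged `out_of_bounds` (meters, default 1000).
#' @return List of class `localize_config`.
#' @export
localize_config <- function(window = 1.5, min_peak = 0.3, reference = NULL,
                            refine = TRUE, subsample = FALSE,
                            cond_threshold = 1e8, margin = 5,
                            template_duration = 0.15, max_range = 1000) {
  structure(list(window = window, min_peak = min_peak, reference = reference,
                 refine = refine, subsample = subsample,
                 cond_threshold = cond_threshold, margin = margin,
                 template_duration = template_duration, max_range = max_range),
            class = "localize_config")
}

#' Localize one scheduled call
#'
#' End-to-end composition for a single call: extract synchronized segments
#' around the scheduled time, band-pass filter and screen the channels,
#' measure the lags, convert them to range differences, solve the
#' linearized system and refine. A call that fails screening (any channel
#' undetected) yields a rejected record carrying the per-channel
#' diagnostics rather than an error. Below-ground solutions (z < 0) are
#' reported with the `below_ground` flag, not clamped: near-ground
#' retrievals are a meaningful diagnostic of ground-based interference.
#'
#' @param recording a [multichannel_recording()].
#' @param entry schedule entry: list or one-row data frame with `time_s`,
#'   `f_lo_hz`, `f_hi_hz` and optionally `call_id`, `label`.
#' @param layout an [array_layout()].
#' @param config a [localize_config()].
#' @return List of class `call_result`: `call_id`, `time_s`, `label`,
#'   `status` (`"ok"`, `"rejected"` or `"error"`), `estimate` (a
#'   `source_estimate` or `NULL`), `lag_set` (or `NULL`), `message`.
#' @export
localize_call <- function(recording, entry, layout, config = localize_config()) {
  entry <- as.list(entry)
  call_id <- entry$call_id %||% NA_integer_
  label <- entry$label %||% NA_character_
  result <- function(status, estimate = NULL, lag_set = NULL, message = "") {
    structure(list(call_id = call_id, time_s = entry$time_s, label = label,
                   status = status, estimate = estimate, lag_set = lag_set,
                   message = message),
              class = "call_result")
  }
  tpl_samples <- round(config$template_duration * layout$sample_rate)
  seg <- tryCatch(
    extract_segment(recording, entry$time_s, config$window, layout,
                    template_samples = tpl_samples),
    flightloc_truncation_error = function(e) e
  )
  if (inherits(seg, "condition"))
    return(result("error", message = conditionMessage(seg)))

  ls <- build_lag_set(seg$segments, layout, reference = config$reference,
                      band = c(entry$f_lo_hz, entry$f_hi_hz),
                      min_peak = config$min_peak, margin = config$margin,
                      subsample = config$subsample)
  if (!ls$accepted)
    return(result("rejected", lag_set = ls,
                  message = sprintf("undetected channel(s): %s",
                                    paste(names(ls$detected)[!ls$detected],
                                          collapse = ", "))))

  delta <- range_differences(ls, layout, fractional = config$subsample)
  est <- tryCatch(
    linear_tdoa_solve(layout, delta, reference = ls$reference,
                      cond_threshold = config$cond_threshold),
    flightloc_error = function(e) e
  )
  if (inherits(est, "condition"))
    return(result("error", lag_set = ls, message = conditionMessage(est)))
  if (config$refine)
    est <- refine_gauss_newton(est, layout, delta)
  center <- colMeans(mic_positions(layout))
  if (sqrt(sum((est$position - center)^2)) > config$max_range)
    est$flags$out_of_bounds <- TRUE
  result("ok", estimate = est, lag_set = ls)
}

#' Localize every call in a schedule
#'
#' Runs [localize_call()] over a schedule table and collects the results
#' into a retrievals table.
#'
#' @param recording a [multichannel_recording()].
#' @param schedule data frame with columns `call_id`, `time_s`, `label`,
#'   `f_lo_hz`, `f_hi_hz` (see [read_schedule_csv()]).
#' @param layout an [array_layout()].
#' @param config a [localize_config()].
#' @return List with `results` (list of `call_result`) and `table` (data
#'   frame `call_id, time_s, label, x_m, y_m, z_m, residual_m, flags,
#'   status`; coordinates are `NA` for rejected/errored calls).
#' @export
localize_schedule <- function(recording, schedule, layout,
                              config = localize_config()) {
  results <- lapply(seq_len(nrow(schedule)), function(i)
    localize_call(recording, schedule[i, ], layout, config))
  rows <- lapply(results, function(r) {
    if (r$status == "ok") {
      fl <- r$estimate$flags
      data.frame(call_id = r$call_id, time_s = r$time_s, label = r$label,
                 x_m = r$estimate$position[["x"]],
                 y_m = r$estimate$position[["y"]],
                 z_m = r$estimate$position[["z"]],
                 residual_m = r$estimate$residual_rms,
                 flags = paste(names(fl)[vapply(fl, isTRUE, logical(1))],
                               collapse = "|"),
                 status = r$status, stringsAsFactors = FALSE)
    } else {
      data.frame(call_id = r$call_id, time_s = r$time_s, label = r$label,
                 x_m = NA_real_, y_m = NA_real_, z_m = NA_real_,
                 residual_m = NA_real_, flags = "", status = r$status,
                 stringsAsFactors = FALSE)
    }
  })
  list(results = results, table = do.call(rbind, rows))
}

#' Read / write the retrievals CSV
#'
#' Columns: `call_id, time_s, label, x_m, y_m, z_m, residual_m, flags,
#' status`. Coordinates are written with 6 decimals so repeated runs on the
#' same inputs produce byte-identical files.
#'
#' @param table retrievals data frame (from [localize_schedule()]).
#' @param path CSV file path.
#' @return `path` invisibly / the retrievals data frame.
#' @export
write_retrievals_csv <- function(table, path) {
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
  out <- data.frame(call_id = table$call_id,
                    time_s = sprintf("%.3f", table$time_s),
                    label = table$label,
                    x_m = fmt(table$x_m), y_m = fmt(table$y_m),
                    z_m = fmt(table$z_m), residual_m = fmt(table$residual_m),
                    flags = table$flags, status = table$status)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_retrievals_csv
#' @export
read_retrievals_csv <- function(path) {
  utils::read.csv(path, colClasses = c(label = "character",
                                       flags = "character",
                                       status = "character"))
}
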