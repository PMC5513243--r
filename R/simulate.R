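#' Emission event
#'
#' One call broadcast from a known 3D position at a known time, used by the
#' propagation simulator and (through its template band) by the detection
#' filter downstream.
#'
#' @param source numeric length-3 vector `(x, y, z)` in meters, `z >= 0`.
#' @param t0 emission time in seconds since recording start, `t0 >= 0`.
#' @param template a [call_template()].
#' @param source_level linear amplitude at 1 m from the source. With
#'   spherical spreading the received peak amplitude at range r meters is
#'   `source_level / r`.
#' @return Object of class `emission_event`.
#' @export
emission_event <- function(source, t0, template, source_level = 20) {
  source <- as.numeric(source)
  if (length(source) != 3L || any(!is.finite(source)))
    fl_stop("`source` must be a finite (x, y, z) triple", "flightloc_invalid_parameter")
  if (source[3] < 0)
    fl_stop("source height z must be non-negative", "flightloc_invalid_parameter")
  check_nonnegative(t0, "t0")
  check_positive(source_level, "source_level")
  if (!inherits(template, "call_template"))
    fl_stop("`template` must be a call_template", "flightloc_invalid_parameter")
  structure(
    list(source = source, t0 = t0, template = template,
         source_level = source_level),
    class = "emission_event"
  )
}

#' Arrival times of an emission at each microphone
#'
#' Straight-line propagation at the layout's speed of sound:
#' `t_i = t0 + |source - m_i| / v`.
#'
#' @param event an [emission_event()].
#' @param layout an [array_layout()].
#' @return Named numeric vector of arrival times in seconds, one per
#'   microphone in layout order.
#' @export
arrival_times <- function(event, layout) {
  pos <- mic_positions(layout)
  d <- row_norms(sweep(pos, 2, event$source))
  stats::setNames(event$t0 + d / layout$sound_speed, rownames(pos))
}

#' Multichannel recording
#'
#' @param samples numeric matrix, one column per microphone channel; column
#'   names are the microphone ids in layout order.
#' @param sample_rate sample rate in Hz.
#' @param start_time recording start time in seconds (default 0).
#' @return Object of class `multichannel_recording`.
#' @export
multichannel_recording <- function(samples, sample_rate, start_time = 0) {
  if (is.null(dim(samples)))
    fl_stop("`samples` must be a matrix with one column per channel",
            "flightloc_invalid_parameter")
  check_positive(sample_rate, "sample_rate")
  structure(
    list(samples = samples, sample_rate = sample_rate, start_time = start_time),
    class = "multichannel_recording"
  )
}

#' @export
print.multichannel_recording <- function(x, ...) {
  cat(sprintf("Multichannel recording: %d channels, %.2f s @ %g Hz\n",
              ncol(x$samples), nrow(x$samples) / x$sample_rate, x$sample_rate))
  invisible(x)
}

# add one event's contribution to the channel matrix in place (returns matrix)
render_event <- function(mat, event, layout, quantize) {
  fs <- layout$sample_rate
  tpl <- event$template
  if (abs(tpl$sample_rate - fs) > 1e-9)
    fl_stop("template sample rate must match the layout sample rate",
            "flightloc_invalid_parameter")
  n <- nrow(mat)
  nt <- length(tpl$samples)
  pos <- mic_positions(layout)
  arr <- arrival_times(event, layout)
  ranges <- pmax(row_norms(sweep(pos, 2, event$source)), 1e-3)
  truncated <- FALSE
  for (ch in seq_len(ncol(mat))) {
    amp <- event$source_level / ranges[ch]
    if (quantize == "nearest_sample") {
      off <- round(arr[ch] * fs)  # 0-based index of the template start
      idx <- off + seq_len(nt)
      keep <- idx >= 1L & idx <= n
      if (!all(keep)) truncated <- TRUE
      mat[idx[keep], ch] <- mat[idx[keep], ch] + amp * tpl$samples[keep]
    } else {
      off <- arr[ch] * fs
      i0 <- floor(off)
      idx <- (i0 + 1L):(i0 + nt + 1L)
      keep <- idx >= 1L & idx <= n
      if (!all(keep)) truncated <- TRUE
      idx <- idx[keep]
      # template evaluated at fractional positions (linear interpolation)
      p <- (idx - 1L) - off
      vals <- stats::approx(x = 0:(nt - 1L), y = tpl$samples, xout = p,
                            yleft = 0, yright = 0)$y
      mat[idx, ch] <- mat[idx, ch] + amp * vals
    }
  }
  if (truncated)
    warning(sprintf("event at t0 = %.3f s extends beyond the recording and was rendered partially",
                    event$t0), call. = FALSE)
  mat
}

#' Render emission events into a multichannel recording
#'
#' Simulates straight-line propagation from each event source to every
#' microphone: the template is scaled by `source_level / range` (spherical
#' spreading; no atmospheric absorption) and delayed by the arrival time. In
#' `"nearest_sample"` mode each channel's arrival time is rounded to its
#' nearest sample, reproducing the integer-lag resolution model of sampled
#' recording; in `"fractional"` mode the template is placed at the exact
#' fractional delay by interpolation. Independent Gaussian noise at
#' `noise_rms` is added to every channel, and optional ground interferers
#' (ordinary events with z near 0, emulating insect noise) are rendered
#' identically.
#'
#' @param events list of [emission_event()].
#' @param layout an [array_layout()].
#' @param duration recording length in seconds.
#' @param noise_rms RMS of the additive Gaussian noise (linear amplitude);
#'   0 disables noise.
#' @param quantize `"nearest_sample"` (default) or `"fractional"`.
#' @param ground_interferers optional list of [emission_event()] rendered in
#'   addition to `events`.
#' @param seed optional integer seed making the noise reproducible.
#' @return A [multichannel_recording()] whose channels follow layout order.
#' @export
render_recording <- function(events, layout, duration, noise_rms = 0,
                             quantize = c("nearest_sample", "fractional"),
                             ground_interferers = NULL, seed = NULL) {
  quantize <- match.arg(quantize)
  check_positive(duration, "duration")
  check_nonnegative(noise_rms, "noise_rms")
  fs <- layout$sample_rate
  n <- round(duration * fs)
  ids <- mic_ids(layout)
  mat <- matrix(0, nrow = n, ncol = length(ids),
                dimnames = list(NULL, ids))
  for (ev in c(events, ground_interferers))
    mat <- render_event(mat, ev, layout, quantize)
  if (noise_rms > 0) {
    if (!is.null(seed)) set.seed(seed)
    mat <- mat + matrix(stats::rnorm(length(mat), sd = noise_rms),
                        nrow = n, dimnames = dimnames(mat))
  }
  multichannel_recording(mat, fs)
}

#' Truth track
#'
#' A sequence of timestamped 3D positions with a stated per-axis
#' measurement uncertainty, playing the role of the GPS record of a
#' validation experiment.
#'
#' @param points data frame with columns `time`, `x`, `y`, `z` (seconds and
#'   meters); times must be strictly increasing.
#' @param per_axis_sigma per-axis 1-sigma position uncertainty in meters.
#' @return Object of class `truth_track`.
#' @export
truth_track <- function(points, per_axis_sigma = 0) {
  if (!is.data.frame(points) || !all(c("time", "x", "y", "z") %in% names(points)))
    fl_stop("`points` must have columns time, x, y, z", "flightloc_invalid_parameter")
  if (nrow(points) > 1L && any(diff(points$time) <= 0))
    fl_stop("track times must be strictly increasing", "flightloc_invalid_parameter")
  check_nonnegative(per_axis_sigma, "per_axis_sigma")
  structure(
    list(points = points[c("time", "x", "y", "z")], per_axis_sigma = per_axis_sigma),
    class = "truth_track"
  )
}

#' @export
print.truth_track <- function(x, ...) {
  cat(sprintf("Truth track: %d points over %.1f s, per-axis sigma %g m\n",
              nrow(x$points), diff(range(x$points$time)), x$per_axis_sigma))
  invisible(x)
}

#' Simulate an aerial broadcast flight track
#'
#' Emulates a tethered-aloft speaker experiment: a smooth random trajectory
#' (an integrated Ornstein-Uhlenbeck velocity process, reflected at the
#' domain bounds) confined to a cylinder of radius `r_max` and heights
#' `[z_min, z_max]` around the array. Calls are emitted every
#' `call_interval` seconds, cycling through the template library; the truth
#' position is sampled every `gps_interval` seconds.
#'
#' @param duration experiment length in seconds.
#' @param call_interval seconds between call broadcasts (default 3).
#' @param gps_interval seconds between truth fixes (default 7).
#' @param r_max maximum horizontal distance from the array center in meters
#'   (default 105).
#' @param z_min,z_max height bounds in meters (defaults 10 and 140).
#' @param templates list of [call_template()] cycled through in order
#'   (default [default_call_library()]).
#' @param source_level linear source amplitude at 1 m (default 20).
#' @param seed integer seed; the trajectory is deterministic given the seed.
#' @return List with `track` (a [truth_track()], per-axis sigma 0) and
#'   `events` (list of [emission_event()]).
#' @export
#' @examples
#' sim <- simulate_flight_track(300, seed = 1)
#' length(sim$events)       # 100 calls at 3-s intervals
#' nrow(sim$track$points)   # 43 truth fixes at 7-s intervals
simulate_flight_track <- function(duration, call_interval = 3, gps_interval = 7,
                                  r_max = 105, z_min = 10, z_max = 140,
                                  templates = NULL, source_level = 20,
                                  seed = NULL) {
  check_positive(duration, "duration")
  check_positive(call_interval, "call_interval")
  check_positive(gps_interval, "gps_interval")
  check_positive(r_max, "r_max")
  if (!(z_min >= 0 && z_max > z_min))
    fl_stop("need 0 <= z_min < z_max", "flightloc_invalid_parameter")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(templates)) templates <- default_call_library()

  dt <- 0.5
  nsteps <- ceiling(duration / dt) + 1L
  tgrid <- (seq_len(nsteps) - 1L) * dt
  # OU velocity: mean-reverting, stationary sd ~2 m/s horizontal, ~1 m/s vertical
  rho <- 0.97
  sd_step <- c(2, 2, 1) * sqrt(1 - rho^2)
  pos <- matrix(0, nsteps, 3L)
  vel <- c(0, 0, 0)
  # start well inside the domain
  ang <- stats::runif(1, 0, 2 * pi)
  r0 <- sqrt(stats::runif(1)) * 0.5 * r_max
  pos[1L, ] <- c(r0 * cos(ang), r0 * sin(ang),
                 stats::runif(1, z_min + 0.3 * (z_max - z_min),
                              z_min + 0.8 * (z_max - z_min)))
  for (k in 2L:nsteps) {
    vel <- rho * vel + sd_step * stats::rnorm(3L)
    p <- pos[k - 1L, ] + vel * dt
    # reflect at the cylinder wall
    r <- sqrt(p[1]^2 + p[2]^2)
    if (r > r_max) {
      u <- p[1:2] / r
      p[1:2] <- u * (2 * r_max - r)
      vrad <- sum(vel[1:2] * u)
      vel[1:2] <- vel[1:2] - 2 * vrad * u
    }
    # reflect at the height bounds
    if (p[3] > z_max) { p[3] <- 2 * z_max - p[3]; vel[3] <- -vel[3] }
    if (p[3] < z_min) { p[3] <- 2 * z_min - p[3]; vel[3] <- -vel[3] }
    pos[k, ] <- p
  }
  interp_pos <- function(times) {
    cbind(stats::approx(tgrid, pos[, 1], times, rule = 2)$y,
          stats::approx(tgrid, pos[, 2], times, rule = 2)$y,
          stats::approx(tgrid, pos[, 3], times, rule = 2)$y)
  }

  gps_times <- seq(0, duration, by = gps_interval)
  gp <- interp_pos(gps_times)
  track <- truth_track(data.frame(time = gps_times, x = gp[, 1], y = gp[, 2],
                                  z = gp[, 3]), per_axis_sigma = 0)

  call_times <- seq(0, by = call_interval,
                    length.out = floor(duration / call_interval))
  cp <- interp_pos(call_times)
  events <- lapply(seq_along(call_times), function(i) {
    tpl <- templates[[(i - 1L) %% length(templates) + 1L]]
    emission_event(cp[i, ], call_times[i], tpl, source_level)
  })
  list(track = track, events = events)
}

#' Perturb a truth track with GPS-like noise
#'
#' Adds independent zero-mean Gaussian error with standard deviation `sigma`
#' to each axis of each point, emulating the stated accuracy of a handheld
#' GPS. The returned track records `sigma` as its `per_axis_sigma`.
#'
#' @param track a [truth_track()].
#' @param sigma per-axis error standard deviation in meters (default 5).
#' @param seed optional integer seed.
#' @return A new [truth_track()].
#' @export
perturb_truth <- function(track, sigma = 5, seed = NULL) {
  check_nonnegative(sigma, "sigma")
  pts <- track$points
  if (sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(pts)
    pts$x <- pts$x + stats::rnorm(n, sd = sigma)
    pts$y <- pts$y + stats::rnorm(n, sd = sigma)
    pts$z <- pts$z + stats::rnorm(n, sd = sigma)
  }
  truth_track(pts, per_axis_sigma = sigma)
}

#' Read / write the CSV formats of the simulator
#'
#' Truth tracks use columns `time_s,x_m,y_m,z_m`; call schedules use
#' `call_id,time_s,label,f_lo_hz,f_hi_hz`.
#'
#' @param track a [truth_track()].
#' @param path CSV file path.
#' @return Writers return `path` invisibly; readers return a
#'   [truth_track()] or a schedule data frame.
#' @export
write_truth_csv <- function(track, path) {
  pts <- track$points
  out <- data.frame(time_s = sprintf("%.3f", pts$time),
                    x_m = sprintf("%.6f", pts$x),
                    y_m = sprintf("%.6f", pts$y),
                    z_m = sprintf("%.6f", pts$z))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param per_axis_sigma sigma recorded on the track read back (meters).
#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path, per_axis_sigma = 0) {
  d <- utils::read.csv(path)
  truth_track(data.frame(time = d$time_s, x = d$x_m, y = d$y_m, z = d$z_m),
              per_axis_sigma = per_axis_sigma)
}

#' @param events list of [emission_event()] to tabulate.
#' @rdname write_truth_csv
#' @export
write_schedule_csv <- function(events, path) {
  out <- data.frame(
    call_id = seq_along(events),
    time_s = sprintf("%.3f", vapply(events, function(e) e$t0, numeric(1))),
    label = vapply(events, function(e) e$template$label, character(1)),
    f_lo_hz = vapply(events, function(e) e$template$band[["f_lo"]], numeric(1)),
    f_hi_hz = vapply(events, function(e) e$template$band[["f_hi"]], numeric(1))
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_schedule_csv <- function(path) {
  d <- utils::read.csv(path, colClasses = c(label = "character"))
  need <- c("call_id", "time_s", "label", "f_lo_hz", "f_hi_hz")
  if (!all(need %in% names(d)))
    fl_stop(sprintf("schedule CSV must contain columns: %s",
                    paste(need, collapse = ", ")), "flightloc_io_error")
  d
}
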