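#' Microphone array layout
#'
#' An `array_layout` fixes the observing system for time-difference-of-arrival
#' (TDOA) localization: the 3D coordinates of the microphones, the common
#' sample rate of the synchronized recorders, and the speed of sound assumed
#' for the deployment. Coordinates are in meters in a right-handed local
#' frame (x east, y north, z height above ground level); the conventional
#' origin is the ground-level centroid of the array.
#'
#' Three-dimensional TDOA localization needs at least five time-synchronized
#' microphones (four independent arrival-time differences for the four
#' unknowns: source position and reference range). The constructor also
#' rejects coincident microphones and fully collinear layouts, both of which
#' make the hyperbolic system degenerate.
#'
#' @param microphones data frame with columns `id`, `x`, `y`, `z`
#'   (identifiers and coordinates in meters).
#' @param sample_rate recording sample rate in Hz (samples per second).
#' @param sound_speed speed of sound in m/s. Default 340.
#' @return An object of class `array_layout`.
#' @seealso [triangle_array()] for the standard three-tower deployment,
#'   [read_array_config()] for file-based configuration.
#' @export
#' @examples
#' mics <- data.frame(
#'   id = c("a", "b", "c", "d", "e"),
#'   x = c(0, 10, 0, 10, 5), y = c(0, 0, 10, 10, 5),
#'   z = c(1, 1, 1, 1, 9))
#' array_layout(mics, sample_rate = 22050)
array_layout <- function(microphones, sample_rate, sound_speed = 340) {
  if (!is.data.frame(microphones) ||
      !all(c("id", "x", "y", "z") %in% names(microphones)))
    fl_stop("`microphones` must be a data frame with columns id, x, y, z",
            "flightloc_invalid_parameter")
  check_positive(sample_rate, "sample_rate")
  check_positive(sound_speed, "sound_speed")
  mics <- data.frame(
    id = as.character(microphones$id),
    x = as.numeric(microphones$x),
    y = as.numeric(microphones$y),
    z = as.numeric(microphones$z),
    stringsAsFactors = FALSE
  )
  if (nrow(mics) < 5L)
    fl_stop("at least 5 microphones are required for 3D TDOA localization",
            "flightloc_invalid_parameter")
  if (anyDuplicated(mics$id))
    fl_stop("microphone ids must be unique", "flightloc_invalid_parameter")
  if (any(!is.finite(as.matrix(mics[c("x", "y", "z")]))))
    fl_stop("microphone coordinates must be finite", "flightloc_invalid_parameter")
  pos <- as.matrix(mics[c("x", "y", "z")])
  if (min(stats::dist(pos)) <= 0)
    fl_stop("no two microphones may be coincident", "flightloc_invalid_parameter")
  centered <- sweep(pos, 2, colMeans(pos))
  sv <- svd(centered, nu = 0, nv = 0)$d
  if (sum(sv > 1e-9 * max(sv, 1)) < 2L)
    fl_stop("microphones must not all be collinear", "flightloc_invalid_parameter")
  structure(
    list(microphones = mics, sample_rate = sample_rate, sound_speed = sound_speed),
    class = "array_layout"
  )
}

#' @export
print.array_layout <- function(x, ...) {
  cat(sprintf("Microphone array: %d microphones, %g Hz, v = %g m/s\n",
              nrow(x$microphones), x$sample_rate, x$sound_speed))
  cat(sprintf("Sample distance v/tau = %.4f m\n",
              sample_distance(x$sound_speed, x$sample_rate)))
  print(x$microphones, row.names = FALSE)
  invisible(x)
}

#' Microphone ids in layout order
#'
#' @param layout an [array_layout()].
#' @return Character vector of microphone ids.
#' @export
mic_ids <- function(layout) layout$microphones$id

#' Microphone coordinates as a matrix
#'
#' @param layout an [array_layout()].
#' @param ids optional character vector of microphone ids to select (in the
#'   requested order); defaults to all microphones in layout order.
#' @return Numeric matrix with one row per microphone and columns x, y, z
#'   (meters); row names are the microphone ids.
#' @export
mic_positions <- function(layout, ids = NULL) {
  mics <- layout$microphones
  if (!is.null(ids)) {
    idx <- match(ids, mics$id)
    if (anyNA(idx))
      fl_stop(sprintf("unknown microphone id(s): %s",
                      paste(ids[is.na(idx)], collapse = ", ")),
              "flightloc_lookup_error")
    mics <- mics[idx, , drop = FALSE]
  }
  pos <- as.matrix(mics[c("x", "y", "z")])
  rownames(pos) <- mics$id
  pos
}

#' Separation between two microphones
#'
#' @param layout an [array_layout()].
#' @param i,j microphone ids.
#' @return Euclidean separation in meters.
#' @export
pair_separation <- function(layout, i, j) {
  p <- mic_positions(layout, c(i, j))
  sqrt(sum((p[1, ] - p[2, ])^2))
}

#' Largest physically possible lag for a microphone pair
#'
#' For any source position, the arrival-time difference between two
#' microphones is bounded by their separation divided by the speed of sound;
#' in samples the magnitude of the lag can never exceed
#' `ceiling(separation * sample_rate / sound_speed)`. This bound sets the
#' cross-correlation search window for the pair.
#'
#' @inheritParams pair_separation
#' @return Integer bound on the absolute lag, in samples.
#' @export
#' @examples
#' arr <- triangle_array()
#' pair_lag_bound(arr, "A_low", "A_high") # 7.64 m vertical pair -> 496
pair_lag_bound <- function(layout, i, j) {
  d <- pair_separation(layout, i, j)
  # subtract a relative epsilon so exact-integer ratios are not bumped up
  as.integer(ceiling(d * layout$sample_rate / layout$sound_speed - 1e-9))
}

# maximum pair_lag_bound over all pairs (segment padding uses this)
max_pair_lag_bound <- function(layout) {
  pos <- mic_positions(layout)
  d <- max(stats::dist(pos))
  as.integer(ceiling(d * layout$sample_rate / layout$sound_speed - 1e-9))
}

#' Standard three-tower triangular array
#'
#' Builds the layout of a low-cost proof-of-concept deployment for flight-call
#' localization: three vertical towers at the vertices of an equilateral
#' triangle, each carrying one microphone near the tower base (kept off the
#' ground to reduce insect and rodent interference) and one at the tower top.
#' The tall/low pairing supplies the vertical aperture that 3D retrievals
#' need; the triangle supplies the horizontal aperture.
#'
#' The origin of the local frame is the ground-level centroid of the
#' triangle, with one vertex on the +x axis; z is height above ground.
#'
#' @param side triangle side length in meters (default 20).
#' @param low_height height of the lower microphones in meters (default 1.5).
#' @param high_height height of the upper microphones in meters
#'   (default 9.14, a three-segment guyed pipe tower).
#' @param sample_rate recorder sample rate in Hz (default 22050).
#' @param sound_speed speed of sound in m/s (default 340).
#' @return An [array_layout()] with six microphones, ids `A_low`, `A_high`,
#'   `B_low`, `B_high`, `C_low`, `C_high` (tower-major order).
#' @export
#' @examples
#' arr <- triangle_array()
#' pair_separation(arr, "A_low", "B_low")  # = side
triangle_array <- function(side = 20, low_height = 1.5, high_height = 9.14,
                           sample_rate = 22050, sound_speed = 340) {
  check_positive(side, "side")
  check_nonnegative(low_height, "low_height")
  if (high_height <= low_height)
    fl_stop("`high_height` must exceed `low_height`", "flightloc_invalid_parameter")
  r <- side / sqrt(3)  # circumradius of an equilateral triangle
  ang <- c(0, 2, 4) * pi / 3
  vx <- r * cos(ang)
  vy <- r * sin(ang)
  towers <- c("A", "B", "C")
  mics <- data.frame(
    id = as.vector(rbind(paste0(towers, "_low"), paste0(towers, "_high"))),
    x = rep(vx, each = 2),
    y = rep(vy, each = 2),
    z = rep(c(low_height, high_height), times = 3),
    stringsAsFactors = FALSE
  )
  array_layout(mics, sample_rate = sample_rate, sound_speed = sound_speed)
}

#' Read / write an array configuration file
#'
#' The configuration format is YAML or JSON (chosen by file extension) with
#' keys `sample_rate_hz`, `sound_speed_mps` and `microphones`, the latter a
#' list of `{id, x_m, y_m, z_m}` records.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_array_config()` returns an [array_layout()];
#'   `write_array_config()` returns `path` invisibly.
#' @export
read_array_config <- function(path) {
  if (!file.exists(path))
    fl_stop(sprintf("array config not found: %s", path), "flightloc_io_error")
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    fl_stop("array config must be .yaml/.yml or .json", "flightloc_io_error")
  )
  need <- c("sample_rate_hz", "sound_speed_mps", "microphones")
  if (!all(need %in% names(cfg)))
    fl_stop(sprintf("array config must contain keys: %s", paste(need, collapse = ", ")),
            "flightloc_io_error")
  mics <- do.call(rbind, lapply(cfg$microphones, function(m)
    data.frame(id = as.character(m$id), x = as.numeric(m$x_m),
               y = as.numeric(m$y_m), z = as.numeric(m$z_m),
               stringsAsFactors = FALSE)))
  array_layout(mics, sample_rate = as.numeric(cfg$sample_rate_hz),
               sound_speed = as.numeric(cfg$sound_speed_mps))
}

#' @param layout an [array_layout()] to serialize.
#' @rdname read_array_config
#' @export
write_array_config <- function(layout, path) {
  cfg <- list(
    sample_rate_hz = layout$sample_rate,
    sound_speed_mps = layout$sound_speed,
    microphones = lapply(seq_len(nrow(layout$microphones)), function(i) {
      m <- layout$microphones[i, ]
      list(id = m$id, x_m = m$x, y_m = m$y, z_m = m$z)
    })
  )
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(cfg, path)
  } else if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    fl_stop("array config must be .yaml/.yml or .json", "flightloc_io_error")
  }
  invisible(path)
}
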