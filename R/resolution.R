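#' Spatial distance represented by one sample interval
#'
#' At sample rate `sample_rate` and speed of sound `sound_speed`, two
#' arrivals can only be distinguished when they are at least one sample
#' apart, i.e. when the corresponding path lengths differ by at least
#' `sound_speed / sample_rate` meters. This "sample distance" is the basic
#' spatial resolution element of lag-based localization: a higher sample
#' rate (or slower medium) resolves finer range differences.
#'
#' @param sound_speed speed of sound in m/s.
#' @param sample_rate sample rate in Hz.
#' @return Sample distance in meters.
#' @export
#' @examples
#' sample_distance(340, 22050)  # ~0.0154 m
sample_distance <- function(sound_speed, sample_rate) {
  check_positive(sound_speed, "sound_speed")
  check_positive(sample_rate, "sample_rate")
  sound_speed / sample_rate
}

#' Maximum lag between a microphone pair
#'
#' The largest integer lag a pair can record occurs when the source lies on
#' the pair axis beyond one microphone, where the path difference equals the
#' full separation: `max_lag = floor(separation / sample_dist)`. A small
#' relative tolerance keeps exact decimal ratios (e.g. 1.54 / 0.154 = 10)
#' from being rounded down by binary floating point.
#'
#' @param separation microphone separation d in meters.
#' @param sample_dist sample distance in meters (see [sample_distance()]).
#' @return Integer maximum lag in samples.
#' @export
#' @examples
#' max_lag(1.54, 0.154)  # 10
#' max_lag(3.08, 0.154)  # 20: doubling the separation doubles the lag range
max_lag <- function(separation, sample_dist) {
  check_nonnegative(separation, "separation")
  check_positive(sample_dist, "sample_dist")
  ratio <- separation / sample_dist
  as.integer(floor(ratio + 1e-9 * (ratio + 1)))
}

#' Size of the one-sided lag alphabet
#'
#' For a source anywhere on one side of a vertically separated pair, the lag
#' ranges over the integers 0..`l_max`: `l_max + 1` distinguishable values.
#' Lag 0 is the plane equidistant from the pair; lag `l_max` is the pair
#' axis beyond the nearer microphone.
#'
#' @param l_max maximum lag in samples (non-negative integer).
#' @return Integer count of possible lag values.
#' @export
#' @examples
#' lag_alphabet_size(10)  # 11
lag_alphabet_size <- function(l_max) {
  check_nonnegative(l_max, "l_max")
  as.integer(l_max) + 1L
}

#' Number of intermediate hyperboloids for a pair
#'
#' Each lag between 1 and `l_max - 1` constrains the source to a distinct
#' hyperboloid sheet between the degenerate extremes (the lag-0 plane and
#' the lag-`l_max` axis line), giving `max(l_max - 1, 0)` intermediate
#' surfaces. More surfaces means finer quantization of the airspace and
#' hence better attainable localization accuracy; the count grows with both
#' the sample rate and the microphone separation.
#'
#' @inheritParams lag_alphabet_size
#' @return Integer count of intermediate hyperboloids.
#' @export
#' @examples
#' hyperboloid_count(10)  # 9
hyperboloid_count <- function(l_max) {
  check_nonnegative(l_max, "l_max")
  max(as.integer(l_max) - 1L, 0L)
}

#' Quantization-resolution summary for a microphone pair
#'
#' Bundles the resolution quantities for one pair: the sample distance, the
#' maximum lag the separation supports, the size of the one-sided lag
#' alphabet, and the number of intermediate hyperboloid surfaces.
#'
#' @param separation microphone separation in meters.
#' @param sample_rate sample rate in Hz.
#' @param sound_speed speed of sound in m/s (default 340).
#' @return An object of class `lag_resolution` with fields `sample_distance`,
#'   `max_lag`, `lag_alphabet_size`, `hyperboloid_count`.
#' @export
#' @examples
#' lag_resolution(7.64, 22050)  # the vertical pair of triangle_array()
lag_resolution <- function(separation, sample_rate, sound_speed = 340) {
  dd <- sample_distance(sound_speed, sample_rate)
  lm <- max_lag(separation, dd)
  structure(
    list(separation = separation, sample_rate = sample_rate,
         sound_speed = sound_speed, sample_distance = dd, max_lag = lm,
         lag_alphabet_size = lag_alphabet_size(lm),
         hyperboloid_count = hyperboloid_count(lm)),
    class = "lag_resolution"
  )
}

#' @export
print.lag_resolution <- function(x, ...) {
  cat(sprintf("Pair resolution (d = %g m, tau = %g Hz, v = %g m/s):\n",
              x$separation, x$sample_rate, x$sound_speed))
  cat(sprintf("  sample distance   %.4f m\n", x$sample_distance))
  cat(sprintf("  max lag           %d samples\n", x$max_lag))
  cat(sprintf("  lag alphabet      %d values\n", x$lag_alphabet_size))
  cat(sprintf("  hyperboloids      %d intermediate surfaces\n", x$hyperboloid_count))
  invisible(x)
}
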