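#' Call template
#'
#' A short band-limited waveform standing in for a species flight call, with
#' the metadata the pipeline needs: a label (species alpha code or synthetic
#' tag), the frequency band used for detection filtering, and the duration.
#'
#' @param label short character code (e.g. a four-letter species code).
#' @param samples numeric waveform, peak absolute amplitude at most 1.
#' @param sample_rate sample rate in Hz.
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi < sample_rate / 2`.
#' @return Object of class `call_template`.
#' @export
call_template <- function(label, samples, sample_rate, f_lo, f_hi) {
  check_positive(sample_rate, "sample_rate")
  if (!(is.numeric(f_lo) && is.numeric(f_hi) &&
        f_lo > 0 && f_lo < f_hi && f_hi < sample_rate / 2))
    fl_stop("band must satisfy 0 < f_lo < f_hi < sample_rate/2",
            "flightloc_invalid_parameter")
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    fl_stop("template must contain at least 2 samples", "flightloc_invalid_parameter")
  if (max(abs(samples)) > 1 + 1e-12)
    fl_stop("template peak amplitude must not exceed 1", "flightloc_invalid_parameter")
  structure(
    list(label = as.character(label), samples = samples,
         sample_rate = sample_rate, band = c(f_lo = f_lo, f_hi = f_hi),
         duration = length(samples) / sample_rate),
    class = "call_template"
  )
}

#' @export
print.call_template <- function(x, ...) {
  cat(sprintf("Call template '%s': %.3f s (%d samples) @ %g Hz, band %g-%g Hz\n",
              x$label, x$duration, length(x$samples), x$sample_rate,
              x$band[["f_lo"]], x$band[["f_hi"]]))
  invisible(x)
}

# raised-cosine on/off ramps over a fraction of the template at each end
tukey_ramp <- function(n, fraction = 0.1) {
  w <- rep(1, n)
  nr <- max(2L, round(fraction * n))
  ramp <- 0.5 * (1 - cos(pi * seq(0, 1, length.out = nr)))
  w[seq_len(nr)] <- ramp
  w[n + 1L - seq_len(nr)] <- ramp
  w
}

#' Synthesize a band-limited call template
#'
#' Generates a deterministic surrogate flight call: a linear frequency sweep
#' (`chirp`), a constant tone at the band center (`tone`), or a band-limited
#' click (`pulse`, a windowed difference of sinc pulses whose spectrum is
#' confined to the band). All kinds carry raised-cosine on/off ramps and are
#' peak-normalized to 1.
#'
#' These templates emulate the variety of real flight calls (sweeps, tones
#' and impulse-like notes spanning roughly 1-10 kHz) without reproducing any
#' recorded audio; they are synthetic by construction.
#'
#' @param label template label.
#' @param kind one of `"chirp"`, `"tone"`, `"pulse"`.
#' @param f_lo,f_hi band edges in Hz (`f_lo < f_hi` strictly).
#' @param duration call duration in seconds.
#' @param sample_rate sample rate in Hz (default 22050).
#' @return A [call_template()].
#' @export
#' @examples
#' tpl <- synth_call_template("BTBW", "chirp", 6000, 8500, 0.05)
#' length(tpl$samples)  # ~ duration * sample_rate
synth_call_template <- function(label, kind = c("chirp", "tone", "pulse"),
                                f_lo, f_hi, duration, sample_rate = 22050) {
  kind <- match.arg(kind)
  check_positive(duration, "duration")
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < sample_rate / 2))
    fl_stop("band must satisfy 0 < f_lo < f_hi < sample_rate/2",
            "flightloc_invalid_parameter")
  n <- max(2L, round(duration * sample_rate))
  t <- (seq_len(n) - 1L) / sample_rate
  x <- switch(kind,
    chirp = {
      # instantaneous frequency sweeps f_lo -> f_hi linearly
      rate <- (f_hi - f_lo) / (2 * duration)
      sin(2 * pi * (f_lo * t + rate * t^2))
    },
    tone = sin(2 * pi * ((f_lo + f_hi) / 2) * t),
    pulse = {
      # band-limited impulse centered mid-template:
      # (sin(2 pi f_hi u) - sin(2 pi f_lo u)) / (pi u) has a flat spectrum
      # confined to [f_lo, f_hi]
      u <- t - duration / 2
      y <- ifelse(abs(u) < 1e-12,
                  2 * (f_hi - f_lo),
                  (sin(2 * pi * f_hi * u) - sin(2 * pi * f_lo * u)) / (pi * u))
      y
    }
  )
  x <- x * tukey_ramp(n)
  x <- x / max(abs(x))
  call_template(label, x, sample_rate, f_lo, f_hi)
}

#' Default synthetic call library
#'
#' Eleven synthetic templates: ten labeled with species alpha codes spanning
#' a wide range of frequencies, durations and bandwidths (the mix of sweeps,
#' tones and impulse-like notes typical of nocturnal flight calls between
#' about 1 and 10 kHz), plus one synthetic tone sequence (`SYNTH`). Bands and
#' durations are this package's choices; the waveforms are generated, not
#' recorded.
#'
#' @param sample_rate sample rate in Hz (default 22050).
#' @return Named list of [call_template()] objects.
#' @export
default_call_library <- function(sample_rate = 22050) {
  spec <- list(
    list("BTBW", "pulse", 6000, 8800, 0.040),
    list("DICK", "chirp", 5000, 7000, 0.060),
    list("INBU", "chirp", 5500, 7500, 0.055),
    list("OVEN", "pulse", 7000, 9000, 0.030),
    list("SUTA", "chirp", 4500, 6500, 0.070),
    list("SWTH", "tone",  1500, 2500, 0.090),
    list("VESP", "chirp", 6500, 8500, 0.050),
    list("WOTH", "chirp", 2000, 4000, 0.080),
    list("YBCU", "tone",  1000, 1600, 0.100),
    list("YEWA", "chirp", 5500, 8000, 0.060),
    list("SYNTH", "tone", 3000, 5000, 0.150)
  )
  out <- lapply(spec, function(s)
    synth_call_template(s[[1]], s[[2]], s[[3]], s[[4]], s[[5]], sample_rate))
  names(out) <- vapply(out, function(x) x$label, character(1))
  out
}
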