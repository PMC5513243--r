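#' Zero-phase band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), giving zero phase distortion -- essential here,
#' because any phase shift would bias the cross-correlation lags. Band edges
#' come from the call schedule; filtering to the call's band improves
#' detectability against broadband and low-frequency noise.
#'
#' @param x numeric waveform.
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi < sample_rate / 2`.
#' @param sample_rate sample rate in Hz.
#' @return Filtered waveform, same length as `x`.
#' @export
bandpass <- function(x, f_lo, f_hi, sample_rate) {
  check_positive(sample_rate, "sample_rate")
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < sample_rate / 2))
    fl_stop("band must satisfy 0 < f_lo < f_hi < sample_rate/2",
            "flightloc_invalid_parameter")
  bf <- signal::butter(4, c(f_lo, f_hi) / (sample_rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, as.numeric(x)))
}

#' Extract synchronized per-channel segments around a scheduled call
#'
#' Cuts the same sample range from every channel, centered on the scheduled
#' emission time, wide enough that the true arrivals fall inside the segment
#' on every channel: the half-window is extended by the largest pair lag
#' bound of the layout plus the template duration.
#'
#' @param recording a [multichannel_recording()].
#' @param scheduled_time known emission time in seconds.
#' @param window nominal window length in seconds (the returned segments are
#'   longer by twice the padding).
#' @param layout an [array_layout()] (used for the lag-bound padding).
#' @param template_samples template length in samples added to the padding
#'   (default 0).
#' @return List with `segments` (named list of per-channel numeric vectors)
#'   and `start_sample` (1-based index of the first sample in the recording).
#' @export
extract_segment <- function(recording, scheduled_time, window, layout,
                            template_samples = 0) {
  check_positive(window, "window")
  fs <- recording$sample_rate
  n <- nrow(recording$samples)
  pad <- max_pair_lag_bound(layout) + as.integer(template_samples)
  center <- round((scheduled_time - recording$start_time) * fs)
  half <- round(window * fs / 2)
  i0 <- center - half - pad + 1L
  i1 <- center + half + pad
  if (i0 < 1L || i1 > n)
    fl_stop(sprintf("segment for call at %.3f s extends beyond the recording (samples %d..%d of %d)",
                    scheduled_time, i0, i1, n),
            "flightloc_truncation_error")
  segs <- lapply(seq_len(ncol(recording$samples)),
                 function(ch) recording$samples[i0:i1, ch])
  names(segs) <- colnames(recording$samples)
  list(segments = segs, start_sample = i0)
}

# cross-correlation sequence r[l] = sum_n a[n] b[n+l] for l in -L..L,
# normalized by the segment energies; computed by FFT with enough padding
# that no circular wrap-around occurs.
xcorr_sequence <- function(a, b, max_abs_lag) {
  n <- length(a)
  L <- as.integer(max_abs_lag)
  N <- stats::nextn(n + L, 2)
  fa <- stats::fft(c(a, numeric(N - n)))
  fb <- stats::fft(c(b, numeric(N - n)))
  cc <- Re(stats::fft(Conj(fa) * fb, inverse = TRUE)) / N
  lags <- (-L):L
  idx <- ifelse(lags >= 0, lags + 1L, N + lags + 1L)
  r <- cc[idx] / sqrt(sum(a^2) * sum(b^2))
  # Cauchy-Schwarz bounds |r| by 1; FFT roundoff can exceed it by ~1e-15
  list(lags = lags, r = pmin(pmax(r, -1), 1))
}

#' Cross-correlation lag between two channels
#'
#' Finds the integer lag maximizing the normalized cross-correlation of two
#' equal-length segments, restricted to `|lag| <= max_abs_lag` (the physical
#' bound for the pair). A positive lag means `b` receives the signal later
#' than `a`. Exact peak ties are broken deterministically: smallest `|lag|`
#' first, then the negative lag before the positive one.
#'
#' @param a,b equal-length numeric segments.
#' @param max_abs_lag search bound in samples (must be smaller than the
#'   segment length).
#' @param subsample if `TRUE`, refine the peak by parabolic interpolation
#'   over the three samples around the maximum and also return
#'   `lag_fractional`. Off by default: the integer-sample lag is the
#'   quantized observable of the resolution model.
#' @return List with `lag` (integer samples), `peak` (normalized correlation
#'   in \[-1, 1\]) and, when `subsample = TRUE`, `lag_fractional`.
#' @export
#' @examples
#' x <- sin(2 * pi * 2000 * (0:999) / 22050) * exp(-(0:999) / 300)
#' y <- c(numeric(17), x)[1:1000]
#' cross_correlation_lag(x, y, 50)$lag  # 17
cross_correlation_lag <- function(a, b, max_abs_lag, subsample = FALSE) {
  if (length(a) != length(b))
    fl_stop("segments must have equal length", "flightloc_invalid_parameter")
  if (max_abs_lag < 0 || max_abs_lag >= length(a))
    fl_stop("`max_abs_lag` must be in [0, segment length)",
            "flightloc_invalid_parameter")
  if (sum(a^2) == 0 || sum(b^2) == 0)
    fl_stop("correlation undefined for an all-zero segment",
            "flightloc_zero_segment")
  xc <- xcorr_sequence(a, b, max_abs_lag)
  peak <- max(xc$r)
  cand <- which(xc$r == peak)
  cand <- cand[order(abs(xc$lags[cand]), xc$lags[cand])]
  best <- cand[1L]
  out <- list(lag = xc$lags[best], peak = peak)
  if (subsample && best > 1L && best < length(xc$r)) {
    ym <- xc$r[best - 1L]; y0 <- xc$r[best]; yp <- xc$r[best + 1L]
    denom <- ym - 2 * y0 + yp
    delta <- if (abs(denom) > 1e-15) 0.5 * (ym - yp) / denom else 0
    out$lag_fractional <- xc$lags[best] + delta
  } else if (subsample) {
    out$lag_fractional <- as.numeric(xc$lags[best])
  }
  out
}

#' Build the full lag set for one call
#'
#' Implements the screening and lag-measurement steps of the TDOA workflow:
#' every channel segment is band-pass filtered to the call's band, all
#' pairwise lags are measured by normalized cross-correlation within each
#' pair's physical lag bound (plus a small margin), and a channel is marked
#' undetected when its best correlation against the reference channel falls
#' below `min_peak`. Localization requires the call on every channel, so a
#' call with any undetected channel is rejected (the result carries the
#' per-channel diagnostics; no error is thrown).
#'
#' The full antisymmetric pairwise matrix is retained for diagnostics
#' (cycle-consistency checks); the solver consumes the reference-relative
#' lags.
#'
#' @param segments named list of equal-length per-channel segments (names
#'   are microphone ids), e.g. from [extract_segment()].
#' @param layout an [array_layout()].
#' @param reference reference microphone id (default: first in layout).
#' @param band numeric `(f_lo, f_hi)` detection band in Hz.
#' @param min_peak minimum normalized peak correlation against the reference
#'   for a channel to count as detected (default 0.3).
#' @param margin extra samples added to each pair's lag search bound
#'   (default 5).
#' @param subsample enable parabolic sub-sample lag refinement (default
#'   `FALSE`).
#' @return Object of class `lag_set`: fields `reference`, `lags` (named
#'   reference-relative lags, reference = 0), `pairwise` (antisymmetric
#'   matrix), `peaks` (pair peak correlations), `detected` (named logicals),
#'   `accepted` (all channels detected), `band`, `min_peak`.
#' @export
build_lag_set <- function(segments, layout, reference = NULL, band,
                          min_peak = 0.3, margin = 5, subsample = FALSE) {
  ids <- mic_ids(layout)
  if (!all(ids %in% names(segments)))
    fl_stop("`segments` must contain one segment per layout microphone",
            "flightloc_invalid_parameter")
  reference <- reference %||% ids[1L]
  if (!reference %in% ids)
    fl_stop(sprintf("unknown reference microphone: %s", reference),
            "flightloc_lookup_error")
  nch <- length(ids)
  fs <- layout$sample_rate

  filt <- lapply(ids, function(id) {
    s <- as.numeric(segments[[id]])
    if (sum(s^2) == 0) s else bandpass(s, band[1], band[2], fs)
  })
  names(filt) <- ids
  energy <- vapply(filt, function(s) sum(s^2), numeric(1))

  lag_m <- matrix(NA_real_, nch, nch, dimnames = list(ids, ids))
  frac_m <- matrix(NA_real_, nch, nch, dimnames = list(ids, ids))
  peak_m <- matrix(NA_real_, nch, nch, dimnames = list(ids, ids))
  diag(lag_m) <- 0
  diag(frac_m) <- 0
  diag(peak_m) <- 1
  for (i in seq_len(nch - 1L)) {
    for (j in (i + 1L):nch) {
      if (energy[i] == 0 || energy[j] == 0) {
        peak_m[i, j] <- peak_m[j, i] <- 0
        next
      }
      bound <- pair_lag_bound(layout, ids[i], ids[j]) + as.integer(margin)
      cc <- cross_correlation_lag(filt[[i]], filt[[j]], bound,
                                  subsample = subsample)
      lag_m[i, j] <- cc$lag
      lag_m[j, i] <- -cc$lag
      if (subsample) {
        frac_m[i, j] <- cc$lag_fractional
        frac_m[j, i] <- -cc$lag_fractional
      }
      peak_m[i, j] <- peak_m[j, i] <- cc$peak
    }
  }

  detected <- peak_m[reference, ] >= min_peak
  detected[reference] <- energy[reference] > 0
  lags <- lag_m[reference, ]
  structure(
    list(reference = reference, lags = lags,
         lags_fractional = if (subsample) frac_m[reference, ] else NULL,
         pairwise = lag_m, peaks = peak_m,
         detected = detected, accepted = all(detected),
         band = c(f_lo = band[1], f_hi = band[2]), min_peak = min_peak),
    class = "lag_set"
  )
}

#' @export
print.lag_set <- function(x, ...) {
  cat(sprintf("Lag set (reference %s, band %g-%g Hz): %s\n",
              x$reference, x$band[["f_lo"]], x$band[["f_hi"]],
              if (x$accepted) "accepted" else "REJECTED"))
  tab <- data.frame(mic = names(x$lags), lag_samples = as.vector(x$lags),
                    peak = round(x$peaks[x$reference, ], 3),
                    detected = as.vector(x$detected))
  print(tab, row.names = FALSE)
  invisible(x)
}
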