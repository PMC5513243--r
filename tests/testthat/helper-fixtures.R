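# shared fixtures: the standard six-microphone array, short rendered clips
# and exact/quantized range differences computed straight from the
# propagation geometry (independent of the lag-measurement code)

std_array <- function() triangle_array()

# random sources uniform in a cylinder (area-uniform in radius)
random_sources <- function(n, r_max = 100, z_min = 10, z_max = 130) {
  r <- sqrt(stats::runif(n)) * r_max
  ang <- stats::runif(n, 0, 2 * pi)
  cbind(x = r * cos(ang), y = r * sin(ang),
        z = stats::runif(n, z_min, z_max))
}

# exact (unquantized) range differences relative to a reference microphone
exact_delta <- function(source, layout, reference = "A_low") {
  P <- mic_positions(layout)
  d <- sqrt(rowSums(sweep(P, 2, source)^2))
  stats::setNames(d - d[reference], rownames(P))
}

# range differences after nearest-sample quantization of each arrival time
quantized_delta <- function(source, layout, reference = "A_low") {
  P <- mic_positions(layout)
  fs <- layout$sample_rate
  v <- layout$sound_speed
  t <- sqrt(rowSums(sweep(P, 2, source)^2)) / v
  o <- round(t * fs)
  stats::setNames(v * (o - o[reference]) / fs, rownames(P))
}

# render a single call into a short clip, interior to the segment window
render_call_clip <- function(source, template, layout, noise_rms = 0,
                             seed = NULL, t0 = 1.2, duration = 2.4,
                             quantize = "nearest_sample", source_level = 20,
                             ground_interferers = NULL) {
  ev <- emission_event(source, t0, template, source_level)
  rec <- render_recording(list(ev), layout, duration, noise_rms = noise_rms,
                          quantize = quantize,
                          ground_interferers = ground_interferers, seed = seed)
  entry <- list(call_id = 1L, time_s = t0, label = template$label,
                f_lo_hz = template$band[["f_lo"]],
                f_hi_hz = template$band[["f_hi"]])
  list(recording = rec, entry = entry, event = ev)
}

localize_clip <- function(source, template, layout, config = localize_config(),
                          ...) {
  clip <- render_call_clip(source, template, layout, ...)
  localize_call(clip$recording, clip$entry, layout, config)
}

euclid_err <- function(estimate, truth) {
  sqrt(sum((as.numeric(estimate$position) - as.numeric(truth))^2))
}
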