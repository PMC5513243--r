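#' Pair retrievals with a truth track
#'
#' Interpolates the truth track linearly in time to each call time and
#' pairs it with the retrieval. Calls farther than `max_gap` seconds from
#' every track point are dropped (the count of dropped calls is attached as
#' the `dropped` attribute); calls just outside the track span but within
#' `max_gap` use the nearest endpoint.
#'
#' @param retrievals data frame with columns `time_s`, `x_m`, `y_m`, `z_m`
#'   and optionally `call_id`, `label` (rows with `NA` coordinates are
#'   ignored), e.g. from [localize_schedule()].
#' @param track a [truth_track()].
#' @param max_gap maximum time gap to the nearest track point in seconds
#'   (default 10).
#' @return Data frame of class `paired_retrievals`: one row per paired
#'   call with retrieval and truth coordinates, per-axis errors `dx, dy,
#'   dz` (retrieval minus truth, meters) and `euclidean` error.
#' @export
match_to_truth <- function(retrievals, track, max_gap = 10) {
  if (nrow(track$points) == 0L)
    fl_stop("truth track is empty", "flightloc_invalid_parameter")
  r <- retrievals[!is.na(retrievals$x_m), , drop = FALSE]
  pts <- track$points
  gap <- vapply(r$time_s, function(t) min(abs(pts$time - t)), numeric(1))
  keep <- gap <= max_gap
  dropped <- sum(!keep)
  r <- r[keep, , drop = FALSE]
  tx <- stats::approx(pts$time, pts$x, r$time_s, rule = 2)$y
  ty <- stats::approx(pts$time, pts$y, r$time_s, rule = 2)$y
  tz <- stats::approx(pts$time, pts$z, r$time_s, rule = 2)$y
  out <- data.frame(
    call_id = r$call_id %||% seq_len(nrow(r)),
    label = r$label %||% NA_character_,
    time_s = r$time_s,
    x_m = r$x_m, y_m = r$y_m, z_m = r$z_m,
    truth_x = tx, truth_y = ty, truth_z = tz,
    dx = r$x_m - tx, dy = r$y_m - ty, dz = r$z_m - tz,
    stringsAsFactors = FALSE
  )
  out$euclidean <- sqrt(out$dx^2 + out$dy^2 + out$dz^2)
  attr(out, "dropped") <- dropped
  class(out) <- c("paired_retrievals", class(out))
  out
}

tukey_stats <- function(v) {
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  whisk_lo <- q[1] - 1.5 * iqr
  whisk_hi <- q[3] + 1.5 * iqr
  list(n = length(v), mean = mean(v), median = q[2], q1 = q[1], q3 = q[3],
       outliers = v[v < whisk_lo | v > whisk_hi])
}

#' Summarize localization errors
#'
#' Per-axis (signed) and Euclidean error statistics for a set of paired
#' retrievals: mean, median, quartiles, Tukey (1.5 IQR) outliers, and the
#' fraction of calls within each requested threshold. Per-axis fractions
#' use the absolute error `|d| <= threshold`; the Euclidean fraction uses
#' the distance itself.
#'
#' @param pairs a [match_to_truth()] result (non-empty).
#' @param thresholds error thresholds in meters (default `c(5, 10)`, the
#'   conventional per-axis uncertainty of a handheld GPS and twice it).
#' @return List of class `error_summary` with `n` and one component per
#'   metric (`x`, `y`, `z`, `euclidean`), each carrying the statistics and
#'   a named `fraction_within` vector.
#' @export
summarize_errors <- function(pairs, thresholds = c(5, 10)) {
  if (is.null(pairs) || nrow(pairs) == 0L)
    fl_stop("no paired retrievals to summarize", "flightloc_empty_summary")
  metrics <- list(x = pairs$dx, y = pairs$dy, z = pairs$dz,
                  euclidean = pairs$euclidean)
  out <- lapply(names(metrics), function(nm) {
    v <- metrics[[nm]]
    s <- tukey_stats(v)
    mag <- if (nm == "euclidean") v else abs(v)
    s$fraction_within <- stats::setNames(
      vapply(thresholds, function(th) mean(mag <= th), numeric(1)),
      paste0(thresholds, "m"))
    s
  })
  names(out) <- names(metrics)
  structure(c(list(n = nrow(pairs)), out), class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("Localization error summary (n = %d)\n", x$n))
  for (nm in c("x", "y", "z", "euclidean")) {
    s <- x[[nm]]
    cat(sprintf("  %-9s median %7.3f  mean %7.3f  IQR [%7.3f, %7.3f] m",
                nm, s$median, s$mean, s$q1, s$q3))
    fw <- paste(sprintf("%s: %.1f%%", names(s$fraction_within),
                        100 * s$fraction_within), collapse = ", ")
    cat(sprintf("  within %s\n", fw))
  }
  invisible(x)
}

#' Per-call-type error summaries
#'
#' Groups paired retrievals by their call-type label and summarizes each
#' group (sample size, boxplot statistics, threshold fractions). Groups
#' with differing detectability end up with differing `n`, mirroring how
#' low signal-to-noise call types yield fewer usable retrievals.
#'
#' @inheritParams summarize_errors
#' @return Named list of [summarize_errors()] results, one per label.
#' @export
per_label_summary <- function(pairs, thresholds = c(5, 10)) {
  if (all(is.na(pairs$label)))
    fl_stop("paired retrievals carry no labels", "flightloc_invalid_parameter")
  lapply(split(pairs, pairs$label), summarize_errors, thresholds = thresholds)
}

#' Euclidean uncertainty implied by a per-axis uncertainty
#'
#' Independent per-axis errors of magnitude `sigma` combine to a Euclidean
#' distance uncertainty of `sqrt(3) * sigma`: the radius within which a
#' 3D fix with the stated per-axis accuracy is indistinguishable from
#' truth.
#'
#' @param per_axis_sigma per-axis uncertainty in meters.
#' @return `sqrt(3) * per_axis_sigma` in meters.
#' @export
#' @examples
#' euclidean_uncertainty(5)  # 8.66 m
euclidean_uncertainty <- function(per_axis_sigma) {
  check_nonnegative(per_axis_sigma, "per_axis_sigma")
  sqrt(3) * per_axis_sigma
}

#' Diagnostic plots for paired retrievals
#'
#' `plot_retrieval_comparison()` draws the four-panel retrieval-vs-truth
#' scatter (Euclidean distance from the array center, height, x, y) with
#' the one-to-one line and dashed uncertainty bounds.
#' `plot_label_errors()` draws per-label Tukey boxplots of one error
#' metric.
#'
#' @param pairs a [match_to_truth()] result.
#' @param per_axis_sigma per-axis truth uncertainty drawn as dashed bounds
#'   (default 5 m).
#' @return The input, invisibly.
#' @export
plot_retrieval_comparison <- function(pairs, per_axis_sigma = 5) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  panel <- function(truth, ret, lab, sig) {
    lim <- range(c(truth, ret))
    plot(truth, ret, xlab = paste("truth", lab), ylab = paste("retrieved", lab),
         pch = 16, cex = 0.6, xlim = lim, ylim = lim)
    graphics::abline(0, 1)
    graphics::abline(sig, 1, lty = 2)
    graphics::abline(-sig, 1, lty = 2)
  }
  rt <- sqrt(pairs$truth_x^2 + pairs$truth_y^2 + pairs$truth_z^2)
  rr <- sqrt(pairs$x_m^2 + pairs$y_m^2 + pairs$z_m^2)
  panel(rt, rr, "distance (m)", euclidean_uncertainty(per_axis_sigma))
  panel(pairs$truth_z, pairs$z_m, "height (m)", per_axis_sigma)
  panel(pairs$truth_x, pairs$x_m, "x (m)", per_axis_sigma)
  panel(pairs$truth_y, pairs$y_m, "y (m)", per_axis_sigma)
  invisible(pairs)
}

#' @param metric one of `"euclidean"`, `"dx"`, `"dy"`, `"dz"` for
#'   `plot_label_errors()`.
#' @rdname plot_retrieval_comparison
#' @export
plot_label_errors <- function(pairs, metric = c("euclidean", "dx", "dy", "dz"),
                              per_axis_sigma = 5) {
  metric <- match.arg(metric)
  v <- pairs[[metric]]
  sig <- if (metric == "euclidean") euclidean_uncertainty(per_axis_sigma)
         else per_axis_sigma
  graphics::boxplot(v ~ pairs$label, range = 1.5, outcol = "red",
                    outpch = 16, xlab = "call type",
                    ylab = paste(metric, "error (m)"))
  graphics::abline(h = if (metric == "euclidean") sig else c(-sig, sig),
                   lty = 2)
  invisible(pairs)
}
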