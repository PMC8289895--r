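#' Eye-tracking preprocessing configuration
#'
#' Parameters for blink detection, between-blink segmentation, and Gaussian
#' smoothing of smooth-pursuit gaze traces.
#'
#' @param derivative_threshold blink threshold on `|dx + dy|`, in input
#'   coordinate units per sample at the native sampling grid (default 100).
#' @param guard_gap seconds trimmed from a segment boundary adjacent to a
#'   detected blink (default 0.050).
#' @param min_segment_duration minimum retained segment duration in seconds
#'   (default 10).
#' @param smoothing_sigma standard deviation of the time-domain Gaussian
#'   smoothing kernel, in seconds (default 0.021).
#' @return list of class `"eye_preprocess_config"`.
#' @export
eye_preprocess_config <- function(derivative_threshold = 100,
                                  guard_gap = 0.050,
                                  min_segment_duration = 10,
                                  smoothing_sigma = 0.021) {
  vals <- c(derivative_threshold, guard_gap, min_segment_duration,
            smoothing_sigma)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all eye preprocessing parameters must be strictly positive",
         call. = FALSE)
  }
  structure(list(derivative_threshold = derivative_threshold,
                 guard_gap = guard_gap,
                 min_segment_duration = min_segment_duration,
                 smoothing_sigma = smoothing_sigma),
            class = "eye_preprocess_config")
}

#' Detect blinks in a two-channel gaze trace
#'
#' A sample is flagged as a blink when the sensor reported no value
#' (missing mask) or when the absolute value of the summed one-step backward
#' differences of the x and y coordinates exceeds the derivative threshold.
#' The first sample has no backward difference and is tested only for
#' missingness; differences involving a missing neighbour are not evaluated
#' (the missing sample is already flagged).
#'
#' @param gaze an [mc_series] with exactly two channels (x, y).
#' @param cfg an [eye_preprocess_config].
#' @return logical vector, one entry per sample; `TRUE` = blink.
#' @export
detect_blinks <- function(gaze, cfg = eye_preprocess_config()) {
  stopifnot(inherits(gaze, "mc_series"))
  if (nrow(gaze$values) != 2L) {
    stop("gaze series must have exactly 2 channels (x, y)", call. = FALSE)
  }
  v <- gaze$values
  n <- ncol(v)
  mask <- gaze$missing_mask
  dsum <- (v[1L, -1L] - v[1L, -n]) + (v[2L, -1L] - v[2L, -n])
  over <- abs(dsum) > cfg$derivative_threshold
  over[is.na(over)] <- FALSE  # neighbour missing: missingness already flags it
  mask | c(FALSE, over)
}

#' Segment a trace between blinks
#'
#' Finds maximal blink-free runs, trims `guard_gap` seconds from any run
#' boundary adjacent to a detected blink (recording start and end receive no
#' guard), and retains runs whose duration is at least
#' `min_segment_duration`. May return zero segments.
#'
#' @param blink_mask logical per-sample blink mask from [detect_blinks()].
#' @param cfg an [eye_preprocess_config].
#' @param sample_interval seconds per sample of the underlying series.
#' @return data.frame with integer columns `start`, `end` (1-based, both
#'   inclusive) and numeric `duration_s`; zero rows if nothing is retained.
#' @export
segment_between_blinks <- function(blink_mask, cfg = eye_preprocess_config(),
                                   sample_interval) {
  stopifnot(is.logical(blink_mask), length(blink_mask) >= 1L,
            is.numeric(sample_interval), sample_interval > 0)
  guard <- as.integer(round(cfg$guard_gap / sample_interval))
  r <- rle(blink_mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- !r$values
  starts <- starts[keep]; ends <- ends[keep]
  n <- length(blink_mask)
  out_start <- integer(0); out_end <- integer(0)
  for (i in seq_along(starts)) {
    s <- starts[i]; e <- ends[i]
    if (s > 1L) s <- s + guard          # preceded by a blink
    if (e < n)  e <- e - guard          # followed by a blink
    if (s > e) next
    dur <- (e - s + 1L) * sample_interval
    if (dur >= cfg$min_segment_duration) {
      out_start <- c(out_start, s); out_end <- c(out_end, e)
    }
  }
  data.frame(start = out_start, end = out_end,
             duration_s = (out_end - out_start + 1L) * sample_interval)
}

#' Gaussian smoothing of a multichannel series
#'
#' Smooths each channel independently with a unit-gain discrete Gaussian
#' kernel of standard deviation `sigma` seconds, truncated at four standard
#' deviations and renormalized. Near the edges the kernel is renormalized
#' over the available samples, so no data is invented beyond the input.
#'
#' @param series an [mc_series] with no missing samples (smooth per segment,
#'   after segmentation).
#' @param sigma kernel standard deviation in seconds (> 0).
#' @return an [mc_series] of the same dimensions.
#' @export
smooth_gaussian <- function(series, sigma) {
  stopifnot(inherits(series, "mc_series"))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("`sigma` must be a single positive number of seconds", call. = FALSE)
  }
  if (any(series$missing_mask)) {
    stop("series contains missing samples; smooth within segments only",
         call. = FALSE)
  }
  dt <- series$sample_interval
  h <- max(1L, as.integer(ceiling(4 * sigma / dt)))
  k <- stats::dnorm((-h:h) * dt, sd = sigma)
  k <- k / sum(k)
  n <- ncol(series$values)
  sm <- series$values
  for (c in seq_len(nrow(sm))) {
    sm[c, ] <- smooth1d(series$values[c, ], k, h, n)
  }
  mc_series(sm, dt, series$channel_labels, series$missing_mask)
}

# Internal: renormalized Gaussian smoothing of one channel. Interior samples
# use full-kernel convolution; the h samples at each edge use the partial
# kernel renormalized over the available samples.
smooth1d <- function(x, k, h, n) {
  partial <- function(i) {
    j <- max(1L, i - h):min(n, i + h)
    w <- k[j - i + h + 1L]
    sum(w * x[j]) / sum(w)
  }
  if (n <= 2L * h + 1L) {
    return(vapply(seq_len(n), partial, numeric(1)))
  }
  # linear convolution by FFT, zero-padded to a highly composite length
  L <- stats::nextn(n + 2L * h)
  fx <- stats::fft(c(x, numeric(L - n)))
  fk <- stats::fft(c(k, numeric(L - 2L * h - 1L)))
  conv <- Re(stats::fft(fx * fk, inverse = TRUE)) / L
  out <- conv[(h + 1L):(h + n)]  # aligned: full kernel centered on sample i
  for (i in c(seq_len(h), (n - h + 1L):n)) out[i] <- partial(i)
  out
}

#' One-step backward difference of each channel
#'
#' Produces the discrete-time derivative series `out[i] = in[i+1] - in[i]`
#' (per-sample units), e.g. delta-formants from formant tracks. The output
#' has one fewer sample than the input.
#'
#' @param series an [mc_series] with no missing samples and at least 2
#'   samples.
#' @return an [mc_series] with `n_samples(series) - 1` samples; channel
#'   labels gain a `"d_"` prefix.
#' @export
compute_delta <- function(series) {
  stopifnot(inherits(series, "mc_series"))
  if (any(series$missing_mask)) {
    stop("series contains missing samples", call. = FALSE)
  }
  n <- ncol(series$values)
  if (n < 2L) stop("need at least 2 samples to differentiate", call. = FALSE)
  d <- series$values[, -1L, drop = FALSE] - series$values[, -n, drop = FALSE]
  mc_series(d, series$sample_interval,
            paste0("d_", series$channel_labels))
}

#' Per-channel variance summary features
#'
#' Sample variance of each raw channel over the whole series, in channel
#' order (the fMRI region-of-interest summary features).
#'
#' @param series an [mc_series] with no missing samples and at least 2
#'   samples.
#' @return named numeric vector, one variance per channel.
#' @export
channel_variance_features <- function(series) {
  stopifnot(inherits(series, "mc_series"))
  if (any(series$missing_mask)) {
    stop("series contains missing samples", call. = FALSE)
  }
  v <- apply(series$values, 1L, stats::var)
  names(v) <- series$channel_labels
  v
}

#' Blink-aware gaze preprocessing
#'
#' Runs the full gaze pipeline: blink detection, between-blink segmentation
#' with guard gaps and minimum-duration filtering, then Gaussian smoothing
#' applied independently within each retained segment (never across blink
#' gaps).
#'
#' @param gaze two-channel [mc_series] of x, y gaze coordinates.
#' @param cfg an [eye_preprocess_config].
#' @return list with `series` (the input with smoothed values inside the
#'   retained segments) and `segments` (data.frame from
#'   [segment_between_blinks()]).
#' @export
preprocess_gaze <- function(gaze, cfg = eye_preprocess_config()) {
  mask <- detect_blinks(gaze, cfg)
  segs <- segment_between_blinks(mask, cfg, gaze$sample_interval)
  out <- gaze
  for (i in seq_len(nrow(segs))) {
    idx <- segs$start[i]:segs$end[i]
    piece <- mc_series(gaze$values[, idx, drop = FALSE],
                       gaze$sample_interval, gaze$channel_labels)
    out$values[, idx] <- smooth_gaussian(piece, cfg$smoothing_sigma)$values
  }
  list(series = out, segments = segs)
}
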