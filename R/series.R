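#' Multichannel time series
#'
#' Container for a uniformly sampled, labelled multichannel signal with an
#' optional per-sample missing mask (true where the sensor reported no
#' numerical value, e.g. during blinks).
#'
#' @param values numeric matrix, channels x samples. Non-missing entries must
#'   be finite; entries at missing samples may be `NA`.
#' @param sample_interval seconds per sample (> 0).
#' @param channel_labels character vector, one label per channel. Defaults to
#'   rownames of `values` or `"ch1"`, `"ch2"`, ...
#' @param missing_mask logical vector, one entry per sample; `TRUE` marks
#'   samples with no sensor value. Defaults to all `FALSE`.
#' @return An object of class `"mc_series"`: a list with elements
#'   `values`, `sample_interval`, `channel_labels`, `missing_mask`.
#' @examples
#' s <- mc_series(rbind(x = sin(1:100 / 10), y = cos(1:100 / 10)), 0.001)
#' n_samples(s)
#' @export
mc_series <- function(values, sample_interval, channel_labels = NULL,
                      missing_mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 2L) {
    stop("need at least 1 channel and 2 samples", call. = FALSE)
  }
  if (!is.numeric(sample_interval) || length(sample_interval) != 1L ||
      !is.finite(sample_interval) || sample_interval <= 0) {
    stop("`sample_interval` must be a single positive number", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- rownames(values)
    if (is.null(channel_labels)) {
      channel_labels <- paste0("ch", seq_len(nrow(values)))
    }
  }
  if (length(channel_labels) != nrow(values)) {
    stop("one channel label per row of `values` required", call. = FALSE)
  }
  if (is.null(missing_mask)) {
    missing_mask <- rep(FALSE, ncol(values))
  }
  if (!is.logical(missing_mask) || length(missing_mask) != ncol(values) ||
      anyNA(missing_mask)) {
    stop("`missing_mask` must be a logical vector with one entry per sample",
         call. = FALSE)
  }
  if (any(!is.finite(values[, !missing_mask, drop = FALSE]))) {
    stop("non-missing samples must be finite", call. = FALSE)
  }
  rownames(values) <- channel_labels
  structure(
    list(values = values, sample_interval = sample_interval,
         channel_labels = channel_labels, missing_mask = missing_mask),
    class = "mc_series"
  )
}

#' @export
print.mc_series <- function(x, ...) {
  cat(sprintf("<mc_series> %d channel(s) x %d samples @ %g Hz (%.3f s)\n",
              nrow(x$values), ncol(x$values), 1 / x$sample_interval,
              ncol(x$values) * x$sample_interval))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  nm <- sum(x$missing_mask)
  if (nm > 0) cat(sprintf("  missing samples: %d (%.1f%%)\n", nm,
                          100 * nm / ncol(x$values)))
  invisible(x)
}

#' Number of samples in a multichannel series
#' @param x an [mc_series] object
#' @return integer sample count
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "mc_series"))
  ncol(x$values)
}

#' Number of channels in a multichannel series
#' @param x an [mc_series] object
#' @return integer channel count
#' @export
n_channels <- function(x) {
  stopifnot(inherits(x, "mc_series"))
  nrow(x$values)
}

# Internal: coerce an mc_series or plain matrix into (matrix, dt) pieces.
as_window <- function(x, sample_interval = NULL) {
  if (inherits(x, "mc_series")) {
    if (any(x$missing_mask)) {
      stop("window contains missing samples; segment before embedding",
           call. = FALSE)
    }
    list(values = x$values, dt = x$sample_interval)
  } else if (is.matrix(x) && is.numeric(x)) {
    if (is.null(sample_interval)) {
      stop("`sample_interval` required when passing a plain matrix",
           call. = FALSE)
    }
    list(values = x, dt = sample_interval)
  } else {
    stop("expected an mc_series or a numeric matrix", call. = FALSE)
  }
}
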