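#' Delay-embedding configuration
#'
#' Parameters of the channel-delay correlation analysis: number of delays,
#' spacing between successive delays, and (for framewise analysis of gaze
#' segments) frame length and overlap. Delay offsets are `0, 1, ..., N-1`
#' times `delay_spacing`, so the zero-delay diagonal of the correlation
#' matrix is unity.
#'
#' @param num_delays integer N >= 1 (default 15).
#' @param delay_spacing seconds between successive delays; must be an exact
#'   integer multiple of the series sample interval. Defaults used by the
#'   pipeline: 0.5 (gaze), 0.03 (formant and delta-formant), 2.0 (fMRI).
#' @param frame_length seconds per analysis frame, or `NULL` for a single
#'   matrix over the whole series (gaze uses 10 s frames).
#' @param frame_overlap seconds of overlap between successive frames
#'   (gaze uses 5 s); must be < `frame_length` when frames are used.
#' @return list of class `"delay_config"`.
#' @export
delay_config <- function(num_delays = 15L, delay_spacing,
                         frame_length = NULL, frame_overlap = NULL) {
  num_delays <- as.integer(num_delays)
  if (is.na(num_delays) || num_delays < 1L) {
    stop("`num_delays` must be an integer >= 1", call. = FALSE)
  }
  if (!is.numeric(delay_spacing) || delay_spacing <= 0) {
    stop("`delay_spacing` must be positive seconds", call. = FALSE)
  }
  if (!is.null(frame_length)) {
    if (is.null(frame_overlap)) frame_overlap <- 0
    if (frame_overlap >= frame_length) {
      stop("`frame_overlap` must be smaller than `frame_length`",
           call. = FALSE)
    }
  }
  structure(list(num_delays = num_delays, delay_spacing = delay_spacing,
                 frame_length = frame_length, frame_overlap = frame_overlap),
            class = "delay_config")
}

#' Default per-modality delay configurations
#'
#' The delay parameters used throughout the pipeline: N = 15 delays for all
#' modalities; spacing 0.5 s for gaze (with 10 s frames overlapping by 5 s),
#' 0.03 s for formants and delta-formants, and 2 s for subcortical and
#' cortical fMRI.
#'
#' @return named list of [delay_config] objects with entries `eye`,
#'   `formant`, `fmri`.
#' @export
default_delay_configs <- function() {
  list(
    eye = delay_config(15L, 0.5, frame_length = 10, frame_overlap = 5),
    formant = delay_config(15L, 0.03),
    fmri = delay_config(15L, 2.0)
  )
}

# Internal: delay spacing in samples, validated as an integer multiple.
spacing_samples <- function(cfg, dt) {
  step <- cfg$delay_spacing / dt
  if (abs(step - round(step)) > 1e-8) {
    stop(sprintf(
      "delay spacing %g s is not an integer multiple of the sample interval %g s",
      cfg$delay_spacing, dt), call. = FALSE)
  }
  as.integer(round(step))
}

#' Time-delay embedding of a multichannel window
#'
#' Expands an M-channel window into M*N rows, where row (c, d) is channel c
#' delayed by d * `delay_spacing` seconds (d = 0..N-1). All rows are
#' truncated to the common support of length
#' `samples - (N-1) * delay_spacing / sample_interval`.
#'
#' @param window an [mc_series] or a numeric channels x samples matrix.
#' @param cfg a [delay_config].
#' @param sample_interval seconds per sample; required when `window` is a
#'   plain matrix.
#' @return numeric (M*N) x T' matrix; row names are `<channel>.d<delay>`.
#' @export
delay_embed <- function(window, cfg, sample_interval = NULL) {
  w <- as_window(window, sample_interval)
  v <- w$values
  step <- spacing_samples(cfg, w$dt)
  N <- cfg$num_delays
  M <- nrow(v)
  S <- ncol(v)
  span <- (N - 1L) * step
  Tp <- S - span
  if (Tp < 2L) {
    stop(sprintf(
      "window too short for embedding: need at least %d samples, got %d",
      span + 2L, S), call. = FALSE)
  }
  E <- matrix(0, nrow = M * N, ncol = Tp)
  labs <- character(M * N)
  ch <- rownames(v)
  if (is.null(ch)) ch <- paste0("ch", seq_len(M))
  for (c in seq_len(M)) {
    for (d in 0:(N - 1L)) {
      r <- (c - 1L) * N + d + 1L
      # row (c,d)[j] = channel c at time j + span - d*step (delayed by d)
      E[r, ] <- v[c, (span - d * step + 1L):(S - d * step)]
      labs[r] <- sprintf("%s.d%d", ch[c], d)
    }
  }
  rownames(E) <- labs
  E
}

# Condition constructor for degenerate (zero-variance) windows.
degenerate_window_error <- function(msg) {
  structure(class = c("coordcca_degenerate", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Channel-delay correlation matrix
#'
#' Pearson correlation matrix of the time-delay-embedded rows of a window.
#' Block (c1, c2) holds the correlations of channel c1 at delays d1 = 0..N-1
#' with channel c2 at delays d2 = 0..N-1, all computed over the common
#' support (each embedded row is standardized over that support).
#'
#' @inheritParams delay_embed
#' @return (M*N) x (M*N) symmetric unit-diagonal matrix of class
#'   `"cd_matrix"` with attributes `M` and `N`.
#' @export
channel_delay_correlation <- function(window, cfg, sample_interval = NULL) {
  w <- as_window(window, sample_interval)
  E <- delay_embed(w$values, cfg, w$dt)
  sds <- apply(E, 1L, stats::sd)
  if (any(sds == 0)) {
    stop(degenerate_window_error(
      "window has a constant embedded channel; correlation undefined"))
  }
  R <- stats::cor(t(E))
  R <- (R + t(R)) / 2
  diag(R) <- 1
  structure(R, class = c("cd_matrix", class(R)),
            M = nrow(w$values), N = cfg$num_delays)
}

#' Eigenspectrum of a channel-delay correlation matrix
#'
#' Rank-ordered (descending) eigenvalues of the symmetric correlation
#' matrix; these quantify the dimensionality of the windowed multichannel
#' signal. Weight concentrated in the leading eigenvalues indicates low
#' complexity; weight spread into the small eigenvalues indicates high
#' complexity. Tiny negative eigenvalues (numerical) are clamped to zero.
#'
#' @param Rmat a square symmetric matrix, typically from
#'   [channel_delay_correlation()].
#' @return object of class `"eigenspectrum"`: list with `eigenvalues`
#'   (descending, length M*N), `n_frames` (1) and `modality` (`NA` here;
#'   set by higher-level wrappers).
#' @export
eigenspectrum <- function(Rmat) {
  if (!is.matrix(Rmat) || nrow(Rmat) != ncol(Rmat) || anyNA(Rmat) ||
      any(!is.finite(Rmat))) {
    stop("`Rmat` must be a finite square matrix", call. = FALSE)
  }
  if (max(abs(Rmat - t(Rmat))) > 1e-8) {
    stop("`Rmat` must be symmetric", call. = FALSE)
  }
  ev <- eigen((Rmat + t(Rmat)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  ev <- sort(ev, decreasing = TRUE)
  ev[ev < 0] <- 0
  structure(list(eigenvalues = ev, n_frames = 1L, modality = NA_character_),
            class = "eigenspectrum")
}

#' @export
print.eigenspectrum <- function(x, ...) {
  cat(sprintf("<eigenspectrum> %d eigenvalues (%s), %d frame(s)\n",
              length(x$eigenvalues),
              if (is.na(x$modality)) "unlabelled" else x$modality,
              x$n_frames))
  cat("  top 5:", paste(signif(utils::head(x$eigenvalues, 5), 4),
                        collapse = ", "), "\n")
  invisible(x)
}

# Internal: eigenvalues of the channel-delay correlation matrix of a window,
# via whichever Gram matrix is smaller. When the embedded dimension M*N
# exceeds the common support T', the nonzero eigenvalues equal those of the
# T' x T' Gram matrix of the standardized rows; the remainder are exact
# zeros. Mathematically identical to eigenspectrum(channel_delay_correlation(.)).
delay_eigenvalues <- function(window, cfg, sample_interval = NULL) {
  w <- as_window(window, sample_interval)
  E <- delay_embed(w$values, cfg, w$dt)
  Tp <- ncol(E)
  ctr <- rowMeans(E)
  Z <- E - ctr
  ss <- sqrt(rowSums(Z^2) / (Tp - 1L))
  if (any(ss == 0)) {
    stop(degenerate_window_error(
      "window has a constant embedded channel; correlation undefined"))
  }
  Z <- Z / ss
  p <- nrow(E)
  if (p <= Tp) {
    G <- tcrossprod(Z) / (Tp - 1L)
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  } else {
    G <- crossprod(Z) / (Tp - 1L)
    ev <- c(eigen(G, symmetric = TRUE, only.values = TRUE)$values,
            rep(0, p - Tp))
  }
  ev <- sort(ev, decreasing = TRUE)
  ev[ev < 0] <- 0
  ev
}

# Condition for sessions yielding no usable frames.
no_frames_error <- function(msg) {
  structure(class = c("coordcca_no_frames", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Framewise eigenspectrum with rank-wise averaging
#'
#' For gaze analysis: tiles each between-blink segment with frames of
#' `frame_length` seconds starting at the segment start, advancing by
#' `frame_length - frame_overlap` seconds; trailing partial frames are
#' discarded. The eigenspectrum is computed per frame and the eigenvalues at
#' each rank are averaged (unweighted) across all frames of the session.
#' Frames containing a constant channel are skipped and counted.
#'
#' @param series an [mc_series] (typically smoothed gaze).
#' @param segments data.frame with `start`, `end` sample indices (1-based,
#'   inclusive) as returned by [segment_between_blinks()].
#' @param cfg a [delay_config] with non-`NULL` `frame_length`.
#' @return an `"eigenspectrum"` object with `n_frames` set to the number of
#'   frames averaged and attribute `n_skipped` counting degenerate frames.
#' @export
framewise_eigenspectrum <- function(series, segments, cfg) {
  stopifnot(inherits(series, "mc_series"), inherits(cfg, "delay_config"))
  if (is.null(cfg$frame_length)) {
    stop("`cfg$frame_length` must be set for framewise analysis",
         call. = FALSE)
  }
  dt <- series$sample_interval
  flen <- as.integer(round(cfg$frame_length / dt))
  stride <- as.integer(round((cfg$frame_length - cfg$frame_overlap) / dt))
  stopifnot(flen >= 2L, stride >= 1L)
  acc <- NULL
  n_used <- 0L
  n_skipped <- 0L
  for (i in seq_len(nrow(segments))) {
    a <- segments$start[i]; b <- segments$end[i]
    if (b - a + 1L < flen) next
    for (s in seq.int(a, b - flen + 1L, by = stride)) {
      win <- series$values[, s:(s + flen - 1L), drop = FALSE]
      ev <- tryCatch(delay_eigenvalues(win, cfg, dt),
                     coordcca_degenerate = function(e) NULL)
      if (is.null(ev)) {
        n_skipped <- n_skipped + 1L
        next
      }
      acc <- if (is.null(acc)) ev else acc + ev
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) {
    stop(no_frames_error(
      "no usable frames: all segments too short or degenerate"))
  }
  structure(list(eigenvalues = acc / n_used, n_frames = n_used,
                 modality = NA_character_),
            class = "eigenspectrum", n_skipped = n_skipped)
}

#' Per-session feature vectors for all seven feature sets
#'
#' Orchestrates feature extraction for one session: framewise gaze
#' eigenspectrum (after blink-aware preprocessing), whole-series formant and
#' delta-formant eigenspectra, whole-series subcortical and cortical fMRI
#' eigenspectra, and subcortical/cortical per-channel variances. Sessions
#' missing any modality cannot be analyzed and raise an error with class
#' `"coordcca_missing_modality"`.
#'
#' @param session list with elements `gaze`, `formant`, `fmri_subcort`,
#'   `fmri_cort`, each an [mc_series] (see [simulate_session_signals()]).
#' @param delay_cfgs named list of [delay_config]s (`eye`, `formant`,
#'   `fmri`), as from [default_delay_configs()].
#' @param eye_cfg an [eye_preprocess_config].
#' @return named list of numeric feature vectors: `eye_eig` (2*N),
#'   `formant_eig` and `dformant_eig` (3*N), `subcort_eig` (21*N),
#'   `cort_eig` (48*N), `subcort_var` (21), `cort_var` (48).
#' @export
session_feature_vector <- function(session,
                                   delay_cfgs = default_delay_configs(),
                                   eye_cfg = eye_preprocess_config()) {
  need <- c("gaze", "formant", "fmri_subcort", "fmri_cort")
  have <- vapply(need, function(m) !is.null(session[[m]]), logical(1))
  if (!all(have)) {
    stop(structure(
      class = c("coordcca_missing_modality", "error", "condition"),
      list(message = paste("session missing modality:",
                           paste(need[!have], collapse = ", ")),
           call = NULL)))
  }
  prep <- preprocess_gaze(session$gaze, eye_cfg)
  eye_spec <- framewise_eigenspectrum(prep$series, prep$segments,
                                      delay_cfgs$eye)
  dform <- compute_delta(session$formant)
  list(
    eye_eig = eye_spec$eigenvalues,
    formant_eig = delay_eigenvalues(session$formant, delay_cfgs$formant),
    dformant_eig = delay_eigenvalues(dform, delay_cfgs$formant),
    subcort_eig = delay_eigenvalues(session$fmri_subcort, delay_cfgs$fmri),
    cort_eig = delay_eigenvalues(session$fmri_cort, delay_cfgs$fmri),
    subcort_var = unname(channel_variance_features(session$fmri_subcort)),
    cort_var = unname(channel_variance_features(session$fmri_cort))
  )
}

#' Canonical feature-set names, in fusion order
#' @return character vector of the seven feature-set names.
#' @export
feature_set_names <- function() {
  c("eye_eig", "formant_eig", "dformant_eig", "subcort_eig", "cort_eig",
    "subcort_var", "cort_var")
}

#' Feature matrices for a whole cohort
#'
#' Applies [session_feature_vector()] to every session of a simulated (or
#' loaded) cohort and stacks the results into one matrix per feature set.
#' Sessions that yield no usable gaze frames are dropped with a message
#' (mirroring sessions excluded for lack of long between-blink segments).
#'
#' @param cohort a cohort list as returned by [simulate_cohort()].
#' @param delay_cfgs,eye_cfg see [session_feature_vector()].
#' @return list with `features` (named list of n_sessions x p matrices),
#'   `meta` (data.frame `subject_id`, `session_index`) and `dropped`
#'   (character vector of dropped session labels).
#' @export
cohort_features <- function(cohort, delay_cfgs = default_delay_configs(),
                            eye_cfg = eye_preprocess_config()) {
  rows <- vector("list", length(cohort$sessions))
  keep <- logical(length(cohort$sessions))
  dropped <- character(0)
  for (i in seq_along(cohort$sessions)) {
    s <- cohort$sessions[[i]]
    res <- tryCatch(
      session_feature_vector(s, delay_cfgs, eye_cfg),
      coordcca_no_frames = function(e) NULL,
      coordcca_missing_modality = function(e) NULL
    )
    if (is.null(res)) {
      dropped <- c(dropped,
                   sprintf("%s/%d", s$subject_id, s$session_index))
      next
    }
    rows[[i]] <- res
    keep[i] <- TRUE
  }
  if (!any(keep)) stop("no analyzable sessions in cohort", call. = FALSE)
  rows <- rows[keep]
  sets <- feature_set_names()
  features <- lapply(sets, function(fs) {
    do.call(rbind, lapply(rows, `[[`, fs))
  })
  names(features) <- sets
  meta <- data.frame(
    subject_id = vapply(cohort$sessions[keep], `[[`, "", "subject_id"),
    session_index = vapply(cohort$sessions[keep], `[[`, 0L, "session_index"),
    stringsAsFactors = FALSE
  )
  list(features = features, meta = meta, dropped = dropped)
}
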