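#' Synthetic cohort configuration
#'
#' Parameters of the synthetic-cohort generator. The generator plants a
#' per-session latent cognition score z (subject trait plus within-subject
#' drift) that jointly modulates (i) the precision of smooth-pursuit gaze,
#' (ii) the high-frequency content of formant tracks, (iii) the effective
#' dimensionality of fMRI ROI series, and (iv) four of the six composite
#' scores. Defaults mirror the study conditions: 28 subjects, 68 sessions
#' with monotone attrition (40 successive-session pairs), gaze at 1000 Hz
#' for ~2 min of 35 pursuit cycles, formants at 100 Hz for ~51.5 s, and
#' 21 + 48 fMRI ROI channels at 0.5 Hz for 580 s.
#'
#' @param n_subjects number of subjects (default 28).
#' @param sessions_per_subject integer vector of per-subject session counts
#'   (default totals 68 sessions across 28 subjects with 40 pairs).
#' @param effect_size global multiplier beta (>= 0) on all planted
#'   signal-complexity links; 0 gives a null cohort.
#' @param within_subject_drift SD of the session-level deviation of z from
#'   the subject trait (default 0.3).
#' @param composite_loadings length-6 loading pattern of z on the composite
#'   scores (default equal on the first four, zero on impulse control and
#'   total symptoms).
#' @param composite_noise_sd SD of the independent noise on each composite's
#'   standardized scale (default 0.8).
#' @param eye_gain,formant_gain,fmri_gain per-modality sensitivities of the
#'   planted complexity parameters to `effect_size * z` (log scale for gaze
#'   jitter and formant fast amplitude, logit scale for the fMRI mixing
#'   weight).
#' @param eye_nuisance,formant_nuisance,fmri_nuisance SD of the per-session
#'   nuisance deviation of each complexity dial on the same (log or logit)
#'   scale. These model cognition-unrelated state variability (fatigue,
#'   recording conditions) and set the ceiling of the feature-outcome
#'   correlations; the defaults were calibrated once so that single-modality
#'   out-of-sample correlations fall in the moderate range reported for
#'   comparable human cohorts (roughly 0.2-0.5) rather than near 1.
#' @param gaze_duration,gaze_rate,pursuit_cycles,gaze_radius,jitter_base,jitter_phi,gaze_noise_sd
#'   gaze generation parameters (seconds, Hz, cycles, screen units).
#' @param blink_rate_per_min,blink_duration_range Poisson blink rate and
#'   uniform blink-gap duration range in seconds.
#' @param formant_duration_mean,formant_duration_sd,formant_rate,formant_centers,formant_slow_amp,formant_slow_phi,formant_fast_base,formant_fast_phi,formant_noise_sd
#'   formant-track generation parameters (Hz-valued tracks).
#' @param fmri_duration,fmri_rate,n_subcort,n_cort,fmri_n_factors,fmri_factor_phi,fmri_idio_phi
#'   fMRI generation parameters.
#' @param fmri_var_gain sensitivity of the session-wide subcortical signal
#'   amplitude (log scale) to `effect_size * z`; cortical amplitude carries
#'   no z link, mirroring the observation that subcortical — but not
#'   cortical — variance features track cognition.
#' @param fmri_var_nuisance SD of the per-session nuisance on the global
#'   amplitude (log scale), applied independently to the subcortical and
#'   cortical sets.
#' @param seed RNG seed making the cohort reproducible.
#' @return list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 28L,
                          sessions_per_subject = c(5L, 5L, 4L, 4L, 4L,
                                                   rep(3L, 7L), rep(2L, 9L),
                                                   rep(1L, 7L)),
                          effect_size = 1,
                          within_subject_drift = 0.3,
                          composite_loadings = c(1, 1, 1, 1, 0, 0),
                          composite_noise_sd = 0.8,
                          eye_gain = 0.5,
                          formant_gain = 0.5,
                          fmri_gain = 0.8,
                          eye_nuisance = 0.5,
                          formant_nuisance = 0.6,
                          fmri_nuisance = 0.8,
                          gaze_duration = 122.5, gaze_rate = 1000,
                          pursuit_cycles = 35, gaze_radius = 300,
                          jitter_base = 30, jitter_phi = 0.97,
                          gaze_noise_sd = 1,
                          blink_rate_per_min = 4,
                          blink_duration_range = c(0.1, 0.3),
                          formant_duration_mean = 51.5,
                          formant_duration_sd = 9.2,
                          formant_rate = 100,
                          formant_centers = c(500, 1500, 2500),
                          formant_slow_amp = c(80, 100, 120),
                          formant_slow_phi = 0.995,
                          formant_fast_base = 15,
                          formant_fast_phi = 0.6,
                          formant_noise_sd = 2,
                          fmri_duration = 580, fmri_rate = 0.5,
                          n_subcort = 21L, n_cort = 48L,
                          fmri_n_factors = 3L,
                          fmri_factor_phi = 0.9,
                          fmri_idio_phi = 0.6,
                          fmri_var_gain = 0.08,
                          fmri_var_nuisance = 0.2,
                          seed = 1L) {
  if (effect_size < 0) stop("`effect_size` must be >= 0", call. = FALSE)
  if (length(sessions_per_subject) != n_subjects) {
    stop("`sessions_per_subject` must have one entry per subject",
         call. = FALSE)
  }
  if (any(sessions_per_subject < 1L)) {
    stop("every subject needs at least one session", call. = FALSE)
  }
  if (length(composite_loadings) != 6L) {
    stop("`composite_loadings` must have length 6", call. = FALSE)
  }
  if (composite_noise_sd <= 0 || within_subject_drift < 0) {
    stop("noise SDs must be positive; drift must be non-negative",
         call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

# Internal: stationary AR(1) series with (theoretical) unit variance.
ar1_unit <- function(n, phi) {
  if (abs(phi) >= 1) {
    stop("unstable autoregressive parameter (|phi| >= 1)", call. = FALSE)
  }
  as.numeric(stats::filter(stats::rnorm(n), phi, method = "recursive")) *
    sqrt(1 - phi^2)
}

#' Planted complexity parameters as a function of z
#'
#' The generator's per-modality complexity dials, each a strictly monotone
#' function of the latent score z: gaze jitter amplitude (decreasing in z —
#' higher cognition, more precise pursuit), formant fast-component amplitude
#' (increasing — more high-frequency articulatory fluctuation), and fMRI
#' idiosyncratic mixing weight (increasing — higher effective
#' dimensionality). These are the deterministic (nuisance-free) values;
#' [simulate_session_signals()] additionally perturbs each dial by a
#' per-session nuisance draw on the same log/logit scale.
#'
#' @param z latent score (vectorized).
#' @param cfg a [cohort_config].
#' @param nuisance optional length-3 vector of nuisance deviations (eye,
#'   formant, fMRI) on the log/logit scale; default zero.
#' @return data.frame with columns `eye_jitter_sd`, `formant_fast_amp`,
#'   `fmri_mix_weight`.
#' @export
planted_complexity_params <- function(z, cfg = cohort_config(),
                                      nuisance = c(0, 0, 0)) {
  b <- cfg$effect_size
  data.frame(
    eye_jitter_sd = cfg$jitter_base *
      exp(-cfg$eye_gain * b * z + nuisance[1L]),
    formant_fast_amp = cfg$formant_fast_base *
      exp(cfg$formant_gain * b * z + nuisance[2L]),
    fmri_mix_weight = stats::plogis(cfg$fmri_gain * b * z + nuisance[3L])
  )
}

# Internal: merge possibly-overlapping integer spans (k x 2 matrix).
merge_spans <- function(sp) {
  if (nrow(sp) == 0L) return(sp)
  sp <- sp[order(sp[, 1L]), , drop = FALSE]
  out <- sp[1L, , drop = FALSE]
  for (i in seq_len(nrow(sp))[-1L]) {
    j <- nrow(out)
    if (sp[i, 1L] <= out[j, 2L] + 1L) {
      out[j, 2L] <- max(out[j, 2L], sp[i, 2L])
    } else {
      out <- rbind(out, sp[i, , drop = FALSE])
    }
  }
  out
}

#' Simulate one session's multimodal signals
#'
#' Generates gaze, formant and fMRI series whose complexity is modulated by
#' the supplied latent score. Gaze is a circular pursuit trajectory with
#' additive autocorrelated jitter (amplitude decreasing in z) and
#' Poisson-placed blink gaps marked as missing samples. Formant tracks are
#' band-limited wanders around typical formant center frequencies with a
#' fast component whose amplitude increases with z. fMRI channels mix a
#' small set of shared autoregressive factors with idiosyncratic
#' autoregressive noise; the idiosyncratic weight (and hence effective
#' dimensionality) increases with z. Autoregressive parameters with unit or
#' larger magnitude are rejected as unstable.
#'
#' @param z latent cognition score for the session.
#' @param cfg a [cohort_config].
#' @return list with elements `gaze` (2-channel [mc_series] with blink gaps
#'   as missing samples and attribute `"blink_spans"`), `formant`
#'   (3-channel), `fmri_subcort` (21-channel), `fmri_cort` (48-channel).
#' @export
simulate_session_signals <- function(z, cfg = cohort_config()) {
  for (phi in c(cfg$jitter_phi, cfg$formant_slow_phi, cfg$formant_fast_phi,
                cfg$fmri_factor_phi, cfg$fmri_idio_phi)) {
    if (abs(phi) >= 1) {
      stop("unstable autoregressive parameter (spectral radius >= 1)",
           call. = FALSE)
    }
  }
  nuis <- c(cfg$eye_nuisance, cfg$formant_nuisance, cfg$fmri_nuisance) *
    stats::rnorm(3L)
  pars <- planted_complexity_params(z, cfg, nuisance = nuis)

  ## gaze: circular pursuit + AR(1) jitter + measurement noise + blink gaps
  dt <- 1 / cfg$gaze_rate
  n <- as.integer(round(cfg$gaze_duration * cfg$gaze_rate))
  tt <- seq_len(n) * dt
  phase <- 2 * pi * cfg$pursuit_cycles * tt / cfg$gaze_duration
  a <- pars$eye_jitter_sd
  gx <- 512 + cfg$gaze_radius * cos(phase) + a * ar1_unit(n, cfg$jitter_phi) +
    stats::rnorm(n, 0, cfg$gaze_noise_sd)
  gy <- 384 + cfg$gaze_radius * sin(phase) + a * ar1_unit(n, cfg$jitter_phi) +
    stats::rnorm(n, 0, cfg$gaze_noise_sd)
  n_blinks <- stats::rpois(1L, cfg$blink_rate_per_min * cfg$gaze_duration / 60)
  spans <- matrix(integer(0), 0L, 2L)
  if (n_blinks > 0L) {
    starts <- sort(sample.int(n, n_blinks))
    durs <- as.integer(round(stats::runif(n_blinks,
                                          cfg$blink_duration_range[1L],
                                          cfg$blink_duration_range[2L]) *
                               cfg$gaze_rate))
    spans <- merge_spans(cbind(starts, pmin(n, starts + durs - 1L)))
  }
  miss <- rep(FALSE, n)
  for (i in seq_len(nrow(spans))) miss[spans[i, 1L]:spans[i, 2L]] <- TRUE
  gv <- rbind(x = gx, y = gy)
  gv[, miss] <- NA_real_
  gaze <- mc_series(gv, dt, c("x", "y"), miss)
  attr(gaze, "blink_spans") <- spans

  ## formants: slow wander + fast component (amplitude grows with z) + noise
  fdur <- min(70, max(35, stats::rnorm(1L, cfg$formant_duration_mean,
                                       cfg$formant_duration_sd)))
  fn <- as.integer(round(fdur * cfg$formant_rate))
  fv <- matrix(0, 3L, fn)
  for (i in 1:3) {
    fv[i, ] <- cfg$formant_centers[i] +
      cfg$formant_slow_amp[i] * ar1_unit(fn, cfg$formant_slow_phi) +
      pars$formant_fast_amp * ar1_unit(fn, cfg$formant_fast_phi) +
      stats::rnorm(fn, 0, cfg$formant_noise_sd)
  }
  formant <- mc_series(fv, 1 / cfg$formant_rate, c("F1", "F2", "F3"))

  ## fMRI: shared AR factors + idiosyncratic AR noise, weight w grows with z
  bn <- as.integer(round(cfg$fmri_duration * cfg$fmri_rate))
  w <- pars$fmri_mix_weight
  make_roi <- function(m, prefix, global_amp) {
    f <- t(vapply(seq_len(cfg$fmri_n_factors),
                  function(i) ar1_unit(bn, cfg$fmri_factor_phi),
                  numeric(bn)))
    L <- matrix(stats::rnorm(m * cfg$fmri_n_factors), m)
    L <- L / sqrt(rowSums(L^2))
    common <- L %*% f
    idio <- t(vapply(seq_len(m),
                     function(i) ar1_unit(bn, cfg$fmri_idio_phi),
                     numeric(bn)))
    amp <- global_amp *
      exp(stats::rnorm(m, 0, 0.2))  # per-channel amplitude heterogeneity
    v <- amp * (sqrt(1 - w) * common + sqrt(w) * idio)
    mc_series(v, 1 / cfg$fmri_rate, paste0(prefix, seq_len(m)))
  }
  # session-wide amplitude: subcortical tracks z weakly, cortical does not
  amp_sub <- exp(cfg$fmri_var_gain * cfg$effect_size * z +
                   cfg$fmri_var_nuisance * stats::rnorm(1L))
  amp_cort <- exp(cfg$fmri_var_nuisance * stats::rnorm(1L))
  list(gaze = gaze, formant = formant,
       fmri_subcort = make_roi(cfg$n_subcort, "subcort_", amp_sub),
       fmri_cort = make_roi(cfg$n_cort, "cort_", amp_cort))
}

#' Simulate composite scores for one session
#'
#' The four cognition-linked composites (verbal memory, visual memory,
#' visual speed, reaction speed) load on z with independent noise; impulse
#' control and total symptoms are independent noise. Reaction time is
#' emitted as the reciprocal of the underlying speed score, so downstream
#' code must apply the reciprocal transform.
#'
#' @param z latent cognition score.
#' @param cfg a [cohort_config].
#' @return one-row data.frame with the six composite columns
#'   (`reaction_time`, not reaction speed).
#' @export
simulate_composites <- function(z, cfg = cohort_config()) {
  lo <- cfg$composite_loadings
  s <- lo * z + stats::rnorm(6L, 0, cfg$composite_noise_sd)
  speed_score <- 1.7 + 0.12 * s[4L]
  if (speed_score <= 0.2) speed_score <- 0.2  # keep reaction time physical
  data.frame(
    verbal_memory = 85 + 8 * s[1L],
    visual_memory = 75 + 10 * s[2L],
    visual_speed = 38 + 5 * s[3L],
    reaction_time = 1 / speed_score,
    impulse_control = 5 + 2.5 * s[5L],
    total_symptoms = 6 + 5 * s[6L]
  )
}

#' Simulate a full synthetic cohort
#'
#' Draws a standard-normal trait per subject, adds within-subject drift per
#' session, and generates all three modalities plus composite scores for
#' every session. The ground-truth z per session is returned separately
#' from the pipeline-visible data for parameter-recovery testing.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [cohort_config].
#' @return list of class `"cohort"`: `sessions` (list; each has
#'   `subject_id`, `session_index`, `gaze`, `formant`, `fmri_subcort`,
#'   `fmri_cort`), `panel` (composite panel data.frame), `truth`
#'   (data.frame `subject_id`, `session_index`, `z`), `config`.
#' @export
simulate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  ids <- sprintf("S%02d", seq_len(cfg$n_subjects))
  traits <- stats::rnorm(cfg$n_subjects)
  sessions <- list()
  panel <- NULL
  truth <- NULL
  for (i in seq_len(cfg$n_subjects)) {
    for (k in seq_len(cfg$sessions_per_subject[i])) {
      z <- traits[i] + cfg$within_subject_drift * stats::rnorm(1L)
      sig <- simulate_session_signals(z, cfg)
      comp <- simulate_composites(z, cfg)
      sessions[[length(sessions) + 1L]] <- c(
        list(subject_id = ids[i], session_index = k), sig)
      panel <- rbind(panel, cbind(
        data.frame(subject_id = ids[i], session_index = k,
                   stringsAsFactors = FALSE), comp))
      truth <- rbind(truth, data.frame(
        subject_id = ids[i], session_index = k, z = z,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(sessions = sessions, panel = panel, truth = truth,
                 config = cfg),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects, %d sessions (effect size %.2f, seed %d)\n",
              x$config$n_subjects, length(x$sessions),
              x$config$effect_size, x$config$seed))
  invisible(x)
}

#' Three-sinusoid illustration configuration
#'
#' Configuration of the classic three-channel sinusoid illustration of the
#' complexity features: Case 1 uses closely spaced frequencies (4.75, 5.0,
#' 5.25 Hz), Case 2 a broader spread (4.5, 5.0, 5.5 Hz) with identical
#' phases, sampled at 1000 Hz over 0 < t <= 1 s, analyzed with N = 15
#' delays at 0.005 s spacing. The broader spread yields more variable phase
#' relationships, i.e. higher complexity, visible as larger small
#' eigenvalues.
#'
#' @param case 1 or 2.
#' @param sampling_rate Hz (default 1000).
#' @param phases shared phase offsets (radians) of the three channels.
#' @return list of class `"fig1_config"` with `case`, `frequencies`,
#'   `phases`, `sampling_rate`, and the matching [delay_config] in
#'   `delay_cfg`.
#' @export
fig1_config <- function(case = 1L, sampling_rate = 1000,
                        phases = c(0.4, 1.7, 3.1)) {
  case <- as.integer(case)
  if (!case %in% c(1L, 2L)) stop("`case` must be 1 or 2", call. = FALSE)
  freqs <- if (case == 1L) c(4.75, 5.0, 5.25) else c(4.5, 5.0, 5.5)
  structure(list(case = case, frequencies = freqs, phases = phases,
                 sampling_rate = sampling_rate,
                 delay_cfg = delay_config(15L, 0.005)),
            class = "fig1_config")
}

#' Generate the three-sinusoid illustration signals
#'
#' @param cfg a [fig1_config] (or a case number, passed through).
#' @return 3-channel [mc_series] of `sin(2 pi f_i t + phi_i)` over
#'   0 < t <= 1.
#' @export
make_fig1_sinusoids <- function(cfg = fig1_config(1L)) {
  if (is.numeric(cfg)) cfg <- fig1_config(cfg)
  stopifnot(inherits(cfg, "fig1_config"))
  dt <- 1 / cfg$sampling_rate
  tt <- seq(dt, 1, by = dt)
  v <- t(vapply(1:3, function(i) {
    sin(2 * pi * cfg$frequencies[i] * tt + cfg$phases[i])
  }, numeric(length(tt))))
  mc_series(v, dt, paste0("y", 1:3))
}
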