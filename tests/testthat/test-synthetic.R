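test_that("cohort simulation is deterministic and follows the schedule", {
  cfg <- cohort_config(n_subjects = 3L, sessions_per_subject = c(2L, 1L, 3L),
                       gaze_duration = 15, formant_duration_mean = 20,
                       formant_duration_sd = 0, fmri_duration = 100,
                       seed = 9L)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$panel, co2$panel)
  expect_identical(co1$truth$z, co2$truth$z)
  expect_identical(co1$sessions[[4]]$gaze$values,
                   co2$sessions[[4]]$gaze$values)
  # schedule bookkeeping
  expect_equal(length(co1$sessions), 6L)
  expect_equal(as.integer(table(co1$truth$subject_id)), c(2L, 1L, 3L))

  # default configuration arithmetic: 28 subjects, 68 sessions, 40 pairs
  dcfg <- cohort_config()
  expect_equal(dcfg$n_subjects, 28L)
  expect_equal(sum(dcfg$sessions_per_subject), 68L)
  expect_equal(sum(pmax(0L, dcfg$sessions_per_subject - 1L)), 40L)
  expect_equal(length(dcfg$sessions_per_subject), 28L)
})

test_that("generated signals satisfy the series invariants", {
  cfg <- cohort_config(gaze_duration = 20, formant_duration_mean = 20,
                       formant_duration_sd = 0, fmri_duration = 120)
  set.seed(10)
  sig <- simulate_session_signals(0.3, cfg)
  for (s in sig) {
    expect_s3_class(s, "mc_series")
    expect_true(all(is.finite(s$values[, !s$missing_mask])))
    expect_gte(nrow(s$values), 1L)
    expect_gte(ncol(s$values), 2L)
  }
  expect_equal(dim(sig$gaze$values), c(2L, 20000L))
  expect_equal(nrow(sig$formant$values), 3L)
  expect_equal(nrow(sig$fmri_subcort$values), 21L)
  expect_equal(nrow(sig$fmri_cort$values), 48L)
  expect_equal(sig$fmri_subcort$sample_interval, 2)

  # blink spans attribute agrees with the missing mask
  spans <- attr(sig$gaze, "blink_spans")
  mask <- rep(FALSE, ncol(sig$gaze$values))
  for (i in seq_len(nrow(spans))) mask[spans[i, 1]:spans[i, 2]] <- TRUE
  expect_identical(mask, sig$gaze$missing_mask)

  # unstable autoregression rejected
  bad <- cohort_config(fmri_factor_phi = 1.0)
  expect_error(simulate_session_signals(0, bad), "unstable")
})

test_that("segmentation recovers the planted blink layout", {
  # jitter kept far below the derivative threshold so the only blinks are
  # the planted sensor dropouts and the counting oracle stays exact
  cfg <- cohort_config(jitter_base = 10, eye_nuisance = 0.1)
  ecfg <- eye_preprocess_config()
  set.seed(14)
  for (rep in 1:3) {
    sig <- simulate_session_signals(0, cfg)
    gaze <- sig$gaze
    spans <- attr(gaze, "blink_spans")
    n <- ncol(gaze$values)
    # counting oracle from the generator's own blink bookkeeping
    bounds <- c(0L, t(spans), n + 1L)
    runs <- matrix(bounds, ncol = 2, byrow = TRUE)  # (end_prev, start_next)
    expected <- 0L
    for (i in seq_len(nrow(runs))) {
      a <- runs[i, 1] + 1L; b <- runs[i, 2] - 1L
      if (a > b) next
      if (runs[i, 1] > 0L) a <- a + 50L   # 50 ms guard at 1000 Hz
      if (runs[i, 2] <= n) b <- b - 50L
      if (a <= b && (b - a + 1L) * 0.001 >= 10) expected <- expected + 1L
    }
    seg <- segment_between_blinks(detect_blinks(gaze, ecfg), ecfg, 0.001)
    expect_equal(nrow(seg), expected)
    expect_true(nrow(spans) >= 1L)
    expect_true(all(spans[, 2] - spans[, 1] + 1L >= 1L))
  }
})

test_that("composite generator reproduces the planted block structure", {
  cfg <- cohort_config()
  # noiseless limit: perfect rank correlation of loaded composites with z
  quiet <- cohort_config(composite_noise_sd = 1e-9)
  z <- seq(-2, 2, length.out = 30)
  set.seed(16)
  p0 <- do.call(rbind, lapply(z, simulate_composites, cfg = quiet))
  expect_equal(cor(p0$verbal_memory, z, method = "spearman"), 1)
  expect_equal(cor(1 / p0$reaction_time, z, method = "spearman"), 1)

  # default noise at n = 68: loaded block correlated, unloaded block not
  set.seed(17)
  min_block <- numeric(20)
  cross_abs <- array(NA_real_, c(20, 2, 4))
  impulse_indep <- logical(20)
  for (s in 1:20) {
    zz <- rnorm(68)
    p <- do.call(rbind, lapply(zz, simulate_composites, cfg = cfg))
    m <- cbind(p$verbal_memory, p$visual_memory, p$visual_speed,
               1 / p$reaction_time)
    cc <- cor(m, method = "spearman")
    min_block[s] <- min(cc[upper.tri(cc)])
    cross_abs[s, , ] <- abs(cor(cbind(p$impulse_control, p$total_symptoms),
                                m, method = "spearman"))
    impulse_indep[s] <-
      abs(cor(p$impulse_control, zz, method = "spearman")) < 0.25
  }
  # block pattern: four loaded composites mutually correlated, the two
  # unloaded ones essentially independent of each of them
  expect_gt(median(min_block), 0.4)
  expect_true(all(apply(cross_abs, c(2, 3), median) < 0.2))
  expect_gte(mean(impulse_indep), 0.9)
})

test_that("planted complexity dials are strictly monotone in z", {
  cfg <- cohort_config()
  z <- seq(-3, 3, length.out = 25)
  pars <- planted_complexity_params(z, cfg)
  expect_true(all(diff(pars$eye_jitter_sd) < 0))
  expect_true(all(diff(pars$formant_fast_amp) > 0))
  expect_true(all(diff(pars$fmri_mix_weight) > 0))
  # effect size zero flattens every dial
  null <- planted_complexity_params(z, cohort_config(effect_size = 0))
  expect_equal(var(null$eye_jitter_sd), 0)
  expect_equal(var(null$fmri_mix_weight), 0)
})

test_that("fMRI tail eigenvalues increase with z at the default effect size", {
  cfg <- cohort_config(gaze_duration = 15, formant_duration_mean = 20,
                       formant_duration_sd = 0)
  dcfg <- default_delay_configs()$fmri
  set.seed(19)
  tail_mean <- vapply(c(-2, 0, 2), function(z) {
    mean(vapply(1:8, function(i) {
      sig <- simulate_session_signals(z, cfg)
      ev <- coordcca:::delay_eigenvalues(sig$fmri_subcort, dcfg)
      mean(ev[158:315])  # bottom half of the spectrum
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(tail_mean) > 0))
})

test_that("sinusoid illustration signals share channel 2 across cases", {
  s1 <- make_fig1_sinusoids(fig1_config(1))
  s2 <- make_fig1_sinusoids(fig1_config(2))
  expect_equal(ncol(s1$values), 1000L)
  expect_identical(s1$values[2, ], s2$values[2, ])   # f2 = 5 Hz in both
  expect_false(identical(s1$values[1, ], s2$values[1, ]))
  # channel 2 zero crossings where 5 t + phase/(2 pi) is an integer
  ph <- fig1_config(1)$phases[2]
  t0 <- (2 * pi - ph) / (2 * pi * 5)   # first zero of sin(2 pi 5 t + ph)
  i0 <- round(t0 * 1000)
  expect_lt(abs(s1$values[2, i0]), 0.04)
  expect_error(fig1_config(3), "1 or 2")
})

test_that("cohort round-trips through the CSV/JSON interchange format", {
  co <- simulate_cohort(cohort_config(
    n_subjects = 2L, sessions_per_subject = c(1L, 1L),
    gaze_duration = 12, formant_duration_mean = 15,
    formant_duration_sd = 0, fmri_duration = 80, seed = 23L))
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(length(back$sessions), 2L)
  s0 <- co$sessions[[1]]; s1 <- back$sessions[[1]]
  expect_equal(s1$gaze$values, s0$gaze$values, tolerance = 1e-6)
  expect_identical(s1$gaze$missing_mask, s0$gaze$missing_mask)
  expect_equal(s1$fmri_cort$sample_interval, 2)
  expect_equal(back$panel$verbal_memory, co$panel$verbal_memory,
               tolerance = 1e-6)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(length(manifest$feature_sets), 7L)
  unlink(dir, recursive = TRUE)
})
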