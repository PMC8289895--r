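# Brute-force oracles and small fixtures shared across the test files.
# Every oracle here is deliberately written as a direct transcription of the
# defining formula, independent of the package's implementation paths.

# Four-index channel-delay correlation oracle: correlation of channel c1 at
# delay d1 with channel c2 at delay d2, each pair computed with stats::cor on
# explicitly constructed shifted slices over the common support.
oracle_cd_correlation <- function(values, N, step) {
  M <- nrow(values); S <- ncol(values)
  span <- (N - 1L) * step
  Tp <- S - span
  slice <- function(c, d) values[c, (span - d * step + 1L):(S - d * step)]
  R <- matrix(NA_real_, M * N, M * N)
  for (c1 in seq_len(M)) for (d1 in 0:(N - 1L)) {
    for (c2 in seq_len(M)) for (d2 in 0:(N - 1L)) {
      R[(c1 - 1L) * N + d1 + 1L, (c2 - 1L) * N + d2 + 1L] <-
        stats::cor(slice(c1, d1), slice(c2, d2))
    }
  }
  R
}

# Generalized-eigenproblem CCA oracle: canonical correlations as the square
# roots of the eigenvalues of Sxx^-1 Sxy Syy^-1 Syx (same ridge on the
# covariance diagonals, different algebraic route than whitening + SVD).
oracle_cca_cors <- function(X, Y, ridge = 1e-8) {
  n <- nrow(X)
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  Sxx <- crossprod(Xc) / (n - 1) + diag(ridge, ncol(X))
  Syy <- crossprod(Yc) / (n - 1) + diag(ridge, ncol(Y))
  Sxy <- crossprod(Xc, Yc) / (n - 1)
  M <- solve(Sxx, Sxy %*% solve(Syy, t(Sxy)))
  ev <- sort(Re(eigen(M)$values), decreasing = TRUE)
  sqrt(pmax(ev[seq_len(min(ncol(X), ncol(Y)))], 0))
}

# Midrank Spearman oracle: explicit midranks, explicit Pearson formula.
oracle_midranks <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}
oracle_spearman <- function(x, y) {
  rx <- oracle_midranks(x); ry <- oracle_midranks(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Small, fast cohort for model-level and taint tests: 6 subjects x 2
# sessions, shortened recordings (full channel counts retained).
make_tiny_cohort <- function(seed = 1, effect_size = 1) {
  simulate_cohort(cohort_config(
    n_subjects = 6L, sessions_per_subject = rep(2L, 6L),
    effect_size = effect_size,
    gaze_duration = 40, blink_rate_per_min = 2,
    formant_duration_mean = 25, formant_duration_sd = 0,
    fmri_duration = 150, seed = seed
  ))
}

# Memoized tiny-cohort features (reused by several test files).
tiny_fixture_env <- new.env(parent = emptyenv())
tiny_fixture <- function() {
  if (is.null(tiny_fixture_env$fx)) {
    co <- make_tiny_cohort(seed = 11)
    tiny_fixture_env$co <- co
    tiny_fixture_env$fx <- cohort_features(co)
  }
  list(co = tiny_fixture_env$co, fx = tiny_fixture_env$fx)
}

# Memoized full-scale seeded pipeline runs shared by the parameter-recovery
# and composite-pattern acceptance checks (they are defined over the same
# 20 planted and 20 null cohorts).
accept_env <- new.env(parent = emptyenv())
acceptance_runs <- function() {
  if (!is.null(accept_env$res)) return(accept_env$res)
  res <- list(planted = NULL, null = NULL)
  for (seed in 1:20) {
    for (mode in c("planted", "null")) {
      beta <- if (mode == "planted") 1 else 0
      co <- simulate_cohort(cohort_config(seed = seed, effect_size = beta))
      fx <- cohort_features(co)
      cv <- loso_crossvalidate(fx$features, fx$meta, co$panel)
      cc <- cv$composite_cor
      res[[mode]] <- rbind(res[[mode]], data.frame(
        seed = seed, r = cv$uv$r, p = cv$uv$p,
        t(stats::setNames(cc$r, cc$composite))))
    }
  }
  accept_env$res <- res
  res
}
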