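test_that("PCA recovers dominant axes and inverts exactly at full rank", {
  set.seed(51)
  n <- 400
  # two planted correlated blocks: PC1 spans columns 1-2, PC2 columns 3-4
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- cbind(f1 + rnorm(n, 0, 0.1), f1 + rnorm(n, 0, 0.1),
             f2 + rnorm(n, 0, 0.4), f2 + rnorm(n, 0, 0.4),
             rnorm(n))
  pca <- fit_pca(X, 2)
  expect_true(all(abs(pca$loadings[1:2, 1]) > 0.6))
  expect_true(all(abs(pca$loadings[3:4, 2]) > 0.6))
  # loadings equal the correlation-matrix eigenvectors (independent oracle)
  evec <- eigen(cor(X), symmetric = TRUE)$vectors[, 1:2]
  for (j in 1:2) {
    if (sign(evec[which.max(abs(evec[, j])), j]) < 0) evec[, j] <- -evec[, j]
    expect_equal(unname(pca$loadings[, j]), evec[, j], tolerance = 1e-8)
  }

  # full-rank round trip is the identity
  set.seed(52)
  X2 <- matrix(rnorm(50 * 4), 50)
  map <- fit_pca(X2, 4)
  rec <- invert_pca(map, apply_pca(map, X2))
  expect_lt(max(abs(rec - X2)), 1e-10)

  # m = 1 reconstructions lie on a line through the mean
  map1 <- fit_pca(X2, 1)
  rec1 <- invert_pca(map1, apply_pca(map1, X2))
  dirs <- sweep(rec1, 2, colMeans(X2))
  expect_equal(qr(dirs)$rank, 1L)

  # duplicated feature columns load equally on the first component
  set.seed(53)
  base <- rnorm(60)
  Xd <- cbind(base, base, rnorm(60, 0, 0.1))
  pd <- fit_pca(Xd, 1)
  expect_equal(pd$loadings[1, 1], pd$loadings[2, 1], tolerance = 1e-10)

  expect_error(fit_pca(Xd, 4), "rank")
})

test_that("truncated PCA reconstruction error equals discarded variance", {
  set.seed(54)
  Z <- matrix(rnorm(200 * 6), 200) %*% diag(c(3, 2.5, 2, 1.5, 1, 0.5))
  map <- fit_pca(Z, 2)
  S <- apply_pca(map, Z)
  rec <- invert_pca(map, S)
  # on the z-scored scale the mean squared residual equals the mean of the
  # discarded eigenvalues (PCA optimality)
  Zs <- scale(Z, center = map$center, scale = map$scale)
  recs <- scale(rec, center = map$center, scale = map$scale)
  mse <- sum((Zs - recs)^2) / (nrow(Z) - 1)
  expect_equal(mse, sum(map$sdev[-(1:2)]^2), tolerance = 1e-8)
})

test_that("CCA agrees with Pearson in 1-D and with the eigenproblem oracle", {
  set.seed(61)
  x <- rnorm(120); y <- 0.7 * x + rnorm(120)
  cc <- fit_cca(matrix(x), matrix(y))
  expect_equal(cc$cors, abs(cor(x, y)), tolerance = 1e-6)

  # identical matrices: all canonical correlations are one
  M <- matrix(rnorm(80 * 3), 80)
  expect_equal(fit_cca(M, M)$cors, rep(1, 3), tolerance = 1e-6)

  # independent X, Y at n = 500: matches the generalized-eigenproblem oracle
  set.seed(62)
  X <- matrix(rnorm(500 * 2), 500); Y <- matrix(rnorm(500 * 2), 500)
  cc2 <- fit_cca(X, Y)
  expect_equal(cc2$cors, oracle_cca_cors(X, Y), tolerance = 1e-8)
  expect_true(all(diff(cc2$cors) <= 1e-12))
  # training-data sign convention: first pair positively correlated
  pr <- cca_project(cc2, X = X, Y = Y)
  expect_gte(cor(pr$U[, 1], pr$V[, 1]), 0)
})

test_that("canonical correlations are invariant to invertible affine maps", {
  set.seed(63)
  X <- matrix(rnorm(150 * 3), 150)
  Y <- X[, 1, drop = FALSE] %*% matrix(c(1, -0.5), 1) +
    matrix(rnorm(150 * 2), 150)
  base <- fit_cca(X, Y)$cors
  for (i in 1:5) {
    Tx <- matrix(rnorm(9), 3); while (abs(det(Tx)) < 0.1) Tx <- matrix(rnorm(9), 3)
    Ty <- matrix(rnorm(4), 2); while (abs(det(Ty)) < 0.1) Ty <- matrix(rnorm(4), 2)
    tr <- fit_cca(sweep(X %*% Tx, 2, c(1, -2, 3), "+"),
                  sweep(Y %*% Ty, 2, c(4, 5), "+"))$cors
    expect_equal(tr, base, tolerance = 1e-6)
  }
})

test_that("Spearman matches the midrank oracle and its t-approximation", {
  set.seed(64)
  for (i in 1:20) {
    n <- sample(8:40, 1)
    x <- sample(1:6, n, replace = TRUE)  # heavy ties
    y <- x + rnorm(n)
    sc <- spearman_cor(x, y)
    expect_equal(sc$r, oracle_spearman(x, y), tolerance = 1e-12)
  }
  sc <- spearman_cor(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  tval <- sc$r * sqrt(8 / (1 - sc$r^2))
  expect_equal(sc$p, 2 * pt(-abs(tval), 8))
  expect_true(is.na(spearman_cor(rep(1, 5), rnorm(5))$r))
})

test_that("nested dimensionality selection finds planted structure", {
  set.seed(71)
  n_sub <- 10; n <- n_sub * 3
  subjects <- rep(sprintf("P%02d", 1:n_sub), each = 3)
  # session-level latent score carried by a correlated block of features,
  # so its direction survives the internal z-scoring
  z <- rnorm(n); w <- rnorm(n)
  X <- cbind(z + rnorm(n, 0, 0.01), z + rnorm(n, 0, 0.01),
             z + rnorm(n, 0, 0.01), w + rnorm(n, 0, 0.01),
             w + rnorm(n, 0, 0.01), rnorm(n), rnorm(n))
  Ymat <- cbind(verbal_memory = z + rnorm(n, 0, 0.01),
                visual_memory = z, visual_speed = z, reaction_speed = z,
                impulse_control = rnorm(n), total_symptoms = rnorm(n))
  sel <- select_pca_dim_nested(X, Ymat, subjects)
  expect_true(sel$m %in% 1:7)
  expect_gte(max(sel$inner_r, na.rm = TRUE), 0.99)
  # determinism: identical rerun
  sel2 <- select_pca_dim_nested(X, Ymat, subjects)
  expect_identical(sel, sel2)
})

test_that("fusion concatenates in canonical order and guards duplicates", {
  fx <- tiny_fixture()
  Ymat <- composite_matrix(fx$co$panel)
  subj <- fx$fx$meta$subject_id
  dims <- list(eye_eig = 3L, subcort_eig = 2L)
  model <- fit_prediction_model(fx$fx$features, Ymat, subj,
                                train = seq_along(subj),
                                feature_sets = c("subcort_eig", "eye_eig"),
                                fixed_dims = dims)
  # canonical order regardless of request order; dims add up
  expect_equal(model$feature_sets, c("eye_eig", "subcort_eig"))
  expect_equal(sum(model$dims), 5L)
  expect_equal(nrow(model$cca$A), 5L)
  expect_error(
    fit_prediction_model(fx$fx$features, Ymat, subj, seq_along(subj),
                         feature_sets = c("eye_eig", "eye_eig"),
                         fixed_dims = dims),
    "duplicated")
  expect_error(
    fit_prediction_model(fx$fx$features, Ymat, subj, seq_along(subj),
                         feature_sets = "nope"),
    "unknown feature set")
})

test_that("LOSO cross-validation partitions sessions exactly once", {
  fx <- tiny_fixture()
  cv <- loso_crossvalidate(fx$fx$features, fx$fx$meta, fx$co$panel,
                           feature_sets = c("eye_eig", "subcort_eig"),
                           candidate_dims = 1:3)
  expect_false(anyNA(cv$sessions$U))
  expect_false(anyNA(cv$sessions$V))
  expect_equal(nrow(cv$sessions), nrow(fx$fx$meta))
  expect_equal(anyDuplicated(cv$sessions[c("subject_id", "session_index")]),
               0L)
  expect_equal(nrow(cv$fold_dims), length(unique(fx$fx$meta$subject_id)))
  md <- modal_dims(cv)
  expect_true(all(md >= 1 & md <= 3))
})

test_that("outcome-dimension sweep is consistent with the main analysis", {
  fx <- tiny_fixture()
  dims <- list(eye_eig = 2L, subcort_eig = 2L)
  cv1 <- loso_crossvalidate(fx$fx$features, fx$fx$meta, fx$co$panel,
                            feature_sets = c("eye_eig", "subcort_eig"),
                            fixed_dims = dims)
  sw <- sweep_impact_dims(fx$fx$features, fx$fx$meta, fx$co$panel,
                          fixed_dims = dims,
                          feature_sets = c("eye_eig", "subcort_eig"),
                          mY_values = 1:2)
  # the m_Y = 1 column of the sweep reproduces the main run exactly
  m1 <- sw[sw$m_Y == 1, c("composite", "r", "p")]
  rownames(m1) <- NULL
  expect_equal(m1, cv1$composite_cor)
  expect_error(sweep_impact_dims(fx$fx$features, fx$fx$meta, fx$co$panel,
                                 fixed_dims = dims, mY_values = 7),
               "1..6")
})

test_that("scalar outcome chains predict composites along a single line", {
  fx <- tiny_fixture()
  Ymat <- composite_matrix(fx$co$panel)
  subj <- fx$fx$meta$subject_id
  model <- fit_prediction_model(fx$fx$features, Ymat, subj,
                                train = seq_along(subj),
                                feature_sets = c("eye_eig", "subcort_eig"),
                                fixed_dims = list(eye_eig = 2L,
                                                  subcort_eig = 2L))
  pred <- predict_outcomes(model, fx$fx$features)$composites
  # with m_Y = 1 every prediction lies on one line through a common point
  dirs <- sweep(pred[-1, , drop = FALSE], 2, pred[1, ])
  expect_equal(qr(dirs)$rank, 1L)
})

test_that("no test-subject statistic leaks into training-fold fits", {
  fx <- tiny_fixture()
  feats <- fx$fx$features
  Ymat <- composite_matrix(fx$co$panel)
  subj <- fx$fx$meta$subject_id
  sets <- c("eye_eig", "subcort_eig")
  target <- unique(subj)[2]
  tr <- which(subj != target)
  m_clean <- fit_prediction_model(feats, Ymat, subj, tr,
                                  feature_sets = sets, candidate_dims = 1:3)
  # poison every statistic of the held-out subject: features AND composites
  feats_p <- feats
  Ymat_p <- Ymat
  for (fs in names(feats_p)) feats_p[[fs]][subj == target, ] <- NaN
  Ymat_p[subj == target, ] <- NaN
  m_poison <- fit_prediction_model(feats_p, Ymat_p, subj, tr,
                                   feature_sets = sets, candidate_dims = 1:3)
  expect_identical(m_clean$dims, m_poison$dims)
  expect_identical(m_clean$pcas, m_poison$pcas)
  expect_identical(m_clean$cca, m_poison$cca)
  expect_identical(m_clean$Gamma, m_poison$Gamma)
  # and predictions for the other subjects are bit-identical too
  other <- which(subj != target)
  expect_identical(predict_outcomes(m_clean, feats, idx = other),
                   predict_outcomes(m_poison, feats_p, idx = other))
})
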