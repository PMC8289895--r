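#' Fit a PCA map with internal z-scoring
#'
#' Z-scores the feature columns (so all dimensions get unit variance and
#' equal weight), then extracts the top `m` principal axes by explained
#' variance. Columns with zero variance are centered and left unscaled (they
#' contribute nothing). Loading signs are fixed deterministically: the
#' largest-magnitude element of each loading vector is positive.
#'
#' @param X numeric matrix, observations x features (n >= 2).
#' @param m number of components to retain; must not exceed the rank of the
#'   z-scored data.
#' @return list of class `"pca_map"`: `center`, `scale`, `loadings`
#'   (p x m, orthonormal columns), `sdev` (all component SDs), `rank`, `m`.
#' @export
fit_pca <- function(X, m) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  ctr <- colMeans(X)
  Z <- X - rep(ctr, each = n)
  scl <- sqrt(colSums(Z^2) / (n - 1L))
  scl[scl == 0] <- 1
  Z <- Z / rep(scl, each = n)
  if (p <= n) {
    e <- eigen(crossprod(Z) / (n - 1L), symmetric = TRUE)
    lam <- pmax(e$values, 0)
    V <- e$vectors
  } else {
    e <- eigen(tcrossprod(Z) / (n - 1L), symmetric = TRUE)
    lam <- pmax(e$values, 0)
    d <- sqrt(lam * (n - 1L))
    pos <- d > max(d) * 1e-12
    V <- crossprod(Z, e$vectors[, pos, drop = FALSE]) /
      rep(d[pos], each = p)
    lam <- lam[pos]
  }
  rank <- sum(lam > max(lam[1L], .Machine$double.eps) * 1e-9)
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("`m` must be a positive integer", call. = FALSE)
  if (m > rank) {
    stop(sprintf("m = %d exceeds the rank (%d) of the z-scored data", m, rank),
         call. = FALSE)
  }
  V <- V[, seq_len(m), drop = FALSE]
  # deterministic sign: largest-|loading| element positive
  for (j in seq_len(m)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(center = ctr, scale = scl, loadings = V,
                 sdev = sqrt(lam), rank = rank, m = m),
            class = "pca_map")
}

#' Project data through a PCA map
#'
#' Applies the stored z-scoring (training means and SDs) and projects onto
#' the retained principal axes.
#'
#' @param map a `"pca_map"` from [fit_pca()].
#' @param X numeric matrix (or vector treated as one row) with the same
#'   feature dimension the map was fitted on.
#' @return n x m matrix of component scores.
#' @export
apply_pca <- function(map, X) {
  stopifnot(inherits(map, "pca_map"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(map$center)) {
    stop(sprintf("expected %d feature columns, got %d",
                 length(map$center), ncol(X)), call. = FALSE)
  }
  n <- nrow(X)
  ((X - rep(map$center, each = n)) / rep(map$scale, each = n)) %*%
    map$loadings
}

#' Reconstruct data from PCA scores
#'
#' Back-projects component scores into feature space and undoes the
#' z-scoring. With `m` equal to the full rank this inverts [apply_pca()]
#' exactly; with truncation it yields the least-squares reconstruction.
#'
#' @param map a `"pca_map"`.
#' @param S n x m matrix of component scores.
#' @return n x p matrix on the original feature scale.
#' @export
invert_pca <- function(map, S) {
  stopifnot(inherits(map, "pca_map"))
  if (is.null(dim(S))) S <- matrix(S, ncol = map$m)
  if (ncol(S) != map$m) {
    stop(sprintf("expected %d score columns, got %d", map$m, ncol(S)),
         call. = FALSE)
  }
  Z <- S %*% t(map$loadings)
  sweep(sweep(Z, 2L, map$scale, "*"), 2L, map$center, "+")
}

#' Fit canonical correlation analysis
#'
#' Finds projections `U = (X - E[X]) A` and `V = (Y - E[Y]) B` whose
#' successive columns maximize residual correlation. Implemented by
#' whitening both sides (eigendecomposition of the covariances with a small
#' ridge added to the diagonals for numerical rank safety) and a singular
#' value decomposition of the whitened cross-covariance. The first canonical
#' pair has non-negative correlation by construction.
#'
#' @param X numeric matrix n x mx.
#' @param Y numeric matrix n x my.
#' @param ridge ridge added to covariance diagonals (default 1e-8).
#' @return list of class `"cca_map"`: `A` (mx x k), `B` (my x k),
#'   `x_center`, `y_center`, `cors` (length k, nonincreasing in [0, 1]),
#'   `k = min(mx, my)`.
#' @export
fit_cca <- function(X, Y, ridge = 1e-8) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have the same rows", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  mx <- ncol(X); my <- ncol(Y)
  xc <- colMeans(X); yc <- colMeans(Y)
  Xc <- X - rep(xc, each = n); Yc <- Y - rep(yc, each = n)
  Sxx <- crossprod(Xc) / (n - 1L); diag(Sxx) <- diag(Sxx) + ridge
  Syy <- crossprod(Yc) / (n - 1L); diag(Syy) <- diag(Syy) + ridge
  Sxy <- crossprod(Xc, Yc) / (n - 1L)
  whiten <- function(S) {
    if (ncol(S) == 1L) {
      if (S[1L] <= 0) {
        stop("covariance rank-deficient beyond ridge rescue", call. = FALSE)
      }
      return(matrix(1 / sqrt(S[1L]), 1L, 1L))
    }
    e <- eigen(S, symmetric = TRUE)
    if (any(e$values <= 0)) {
      stop("covariance rank-deficient beyond ridge rescue", call. = FALSE)
    }
    e$vectors %*% (t(e$vectors) / sqrt(e$values))
  }
  Wx <- whiten(Sxx); Wy <- whiten(Syy)
  K <- Wx %*% Sxy %*% Wy
  k <- min(mx, my)
  if (k == 1L && my == 1L) {        # closed form: rank-one cross-covariance
    d <- sqrt(sum(K^2))
    P <- K / d; Q <- matrix(1, 1L, 1L); d <- d[1L]
  } else if (k == 1L) {
    d <- sqrt(sum(K^2))
    P <- matrix(1, 1L, 1L); Q <- t(K) / d; d <- d[1L]
  } else {
    sv <- svd(K)
    P <- sv$u[, seq_len(k), drop = FALSE]
    Q <- sv$v[, seq_len(k), drop = FALSE]
    d <- sv$d[seq_len(k)]
  }
  for (j in seq_len(k)) {
    i <- which.max(abs(P[, j]))
    if (P[i, j] < 0) { P[, j] <- -P[, j]; Q[, j] <- -Q[, j] }
  }
  structure(list(A = Wx %*% P, B = Wy %*% Q, x_center = xc, y_center = yc,
                 cors = pmin(pmax(d, 0), 1), k = k),
            class = "cca_map")
}

#' Project data into the CCA latent space
#'
#' @param map a `"cca_map"` from [fit_cca()].
#' @param X,Y optional matrices on the X (feature-PC) or Y (outcome-PC)
#'   side; supply either or both.
#' @return list with `U` and/or `V` (n x k matrices).
#' @export
cca_project <- function(map, X = NULL, Y = NULL) {
  stopifnot(inherits(map, "cca_map"))
  out <- list()
  if (!is.null(X)) {
    if (!is.matrix(X)) X <- as.matrix(X)
    out$U <- (X - rep(map$x_center, each = nrow(X))) %*% map$A
  }
  if (!is.null(Y)) {
    if (!is.matrix(Y)) Y <- as.matrix(Y)
    out$V <- (Y - rep(map$y_center, each = nrow(Y))) %*% map$B
  }
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation (midranks for ties) with a two-sided p-value from the
#' t approximation `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- stats::cor(x, y, method = "spearman")
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Select the feature-PC dimensionality by inner LOSO cross-validation
#'
#' For each candidate dimensionality m, runs an inner leave-one-subject-out
#' loop over the training subjects with a one-dimensional outcome side
#' (m_Y = 1): per inner fold the feature PCA, outcome z-scoring/PCA and CCA
#' are fitted on the inner-training subjects only, U and V are computed on
#' the held-out subject's sessions, and the pooled inner-test U, V across
#' folds give a Spearman correlation per candidate. Returns the candidate
#' with the highest pooled correlation; ties break to the smallest m
#' (parsimony). Candidates exceeding an inner fold's feasible rank are
#' capped within that fold.
#'
#' @param X feature matrix (training sessions x features).
#' @param Ymat 6-column composite outcome matrix for the same sessions.
#' @param subjects subject identifier per row.
#' @param candidate_dims integer candidates (default 1:7).
#' @param ridge CCA ridge.
#' @return list with `m` (selected), `inner_r` (named vector of pooled
#'   inner correlations per candidate).
#' @export
select_pca_dim_nested <- function(X, Ymat, subjects, candidate_dims = 1:7,
                                  ridge = 1e-8) {
  X <- as.matrix(X)
  subjects <- as.character(subjects)
  uniq <- unique(subjects)
  if (length(uniq) < 3L) {
    stop("need at least 3 training subjects for inner selection",
         call. = FALSE)
  }
  cand <- sort(unique(as.integer(candidate_dims)))
  mmax <- max(cand)
  pooled_u <- rep(list(numeric(0)), length(cand))
  pooled_v <- rep(list(numeric(0)), length(cand))
  for (s in uniq) {
    te <- subjects == s
    tr <- !te
    pca <- fit_pca(X[tr, , drop = FALSE], min(mmax, NA_rank_cap(X[tr, , drop = FALSE], mmax)))
    Str <- apply_pca(pca, X[tr, , drop = FALSE])
    Ste <- apply_pca(pca, X[te, , drop = FALSE])
    ypca <- fit_pca(Ymat[tr, , drop = FALSE], 1L)
    Ytr <- apply_pca(ypca, Ymat[tr, , drop = FALSE])
    Yte <- apply_pca(ypca, Ymat[te, , drop = FALSE])
    for (ci in seq_along(cand)) {
      m <- min(cand[ci], pca$m)
      cca <- fit_cca(Str[, seq_len(m), drop = FALSE], Ytr, ridge)
      pr <- cca_project(cca, X = Ste[, seq_len(m), drop = FALSE], Y = Yte)
      pooled_u[[ci]] <- c(pooled_u[[ci]], pr$U[, 1L])
      pooled_v[[ci]] <- c(pooled_v[[ci]], pr$V[, 1L])
    }
  }
  inner_r <- vapply(seq_along(cand), function(ci) {
    spearman_cor(pooled_u[[ci]], pooled_v[[ci]])$r
  }, numeric(1))
  names(inner_r) <- as.character(cand)
  if (all(is.na(inner_r))) {
    stop("all candidate dimensionalities degenerate", call. = FALSE)
  }
  list(m = cand[which.max(inner_r)], inner_r = inner_r)
}

# Internal: rank cap for a training block without refitting (cheap bound).
NA_rank_cap <- function(X, mmax) {
  min(mmax, nrow(X) - 1L, ncol(X))
}

#' Fit the full prediction model on a training set
#'
#' Per feature set: selects the PCA dimensionality by inner LOSO (unless
#' `fixed_dims` supplies it) and fits the PCA map; the selected per-set
#' component scores are fused by concatenation (in the canonical feature-set
#' order). The outcome side is z-scored and reduced to `m_Y` components. A
#' CCA is fitted between the fused feature PCs and the outcome PCs, and a
#' least-squares regression of V on U (on the training data) provides the
#' predictive map into the outcome latent space. All statistics (means, SDs,
#' PCA axes, CCA maps, selected dimensionalities) are derived from the
#' training rows only.
#'
#' @param features named list of feature matrices (all sessions x p_set).
#' @param Ymat 6-column composite outcome matrix (all sessions).
#' @param subjects subject id per session row.
#' @param train logical or integer index of training rows.
#' @param feature_sets which sets to fuse (default all seven, in canonical
#'   order); a duplicated set is rejected.
#' @param m_Y outcome-side PCA dimensionality (default 1, the latent
#'   cognitive factor; at most 6).
#' @param candidate_dims candidates for per-set dimensionality selection.
#' @param fixed_dims optional named integer vector/list of per-set
#'   dimensionalities, bypassing inner selection.
#' @param ridge CCA ridge.
#' @return list of class `"prediction_model"`.
#' @export
fit_prediction_model <- function(features, Ymat, subjects, train,
                                 feature_sets = names(features),
                                 m_Y = 1L, candidate_dims = 1:7,
                                 fixed_dims = NULL, ridge = 1e-8) {
  if (anyDuplicated(feature_sets) > 0) {
    stop("duplicated feature set in fusion request", call. = FALSE)
  }
  miss <- setdiff(feature_sets, names(features))
  if (length(miss) > 0) {
    stop("unknown feature set(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  # canonical fusion order
  feature_sets <- intersect(feature_set_names(), feature_sets)
  if (length(feature_sets) == 0L) feature_sets <- names(features)
  m_Y <- as.integer(m_Y)
  if (m_Y < 1L || m_Y > ncol(Ymat)) {
    stop(sprintf("m_Y must be in 1..%d", ncol(Ymat)), call. = FALSE)
  }
  if (is.logical(train)) train <- which(train)
  subjects <- as.character(subjects)
  dims <- integer(length(feature_sets)); names(dims) <- feature_sets
  pcas <- vector("list", length(feature_sets)); names(pcas) <- feature_sets
  score_blocks <- vector("list", length(feature_sets))
  for (i in seq_along(feature_sets)) {
    fs <- feature_sets[i]
    Xtr <- features[[fs]][train, , drop = FALSE]
    if (!is.null(fixed_dims) && !is.null(fixed_dims[[fs]])) {
      dims[fs] <- as.integer(fixed_dims[[fs]])
    } else {
      dims[fs] <- select_pca_dim_nested(Xtr, Ymat[train, , drop = FALSE],
                                        subjects[train], candidate_dims,
                                        ridge)$m
    }
    pcas[[fs]] <- fit_pca(Xtr, dims[fs])
    score_blocks[[i]] <- apply_pca(pcas[[fs]], Xtr)
  }
  Xhat <- do.call(cbind, score_blocks)
  ypca <- fit_pca(Ymat[train, , drop = FALSE], m_Y)
  Yhat <- apply_pca(ypca, Ymat[train, , drop = FALSE])
  cca <- fit_cca(Xhat, Yhat, ridge)
  pr <- cca_project(cca, X = Xhat, Y = Yhat)
  Gamma <- solve(crossprod(pr$U), crossprod(pr$U, pr$V))
  structure(list(feature_sets = feature_sets, dims = dims, pcas = pcas,
                 ypca = ypca, cca = cca, Gamma = Gamma, m_Y = m_Y,
                 B_pinv = MASS::ginv(cca$B)),
            class = "prediction_model")
}

#' @export
print.prediction_model <- function(x, ...) {
  cat("<prediction_model>\n  feature sets:",
      paste(sprintf("%s(m=%d)", x$feature_sets, x$dims), collapse = ", "),
      "\n")
  cat(sprintf("  m_Y = %d, canonical correlations: %s\n", x$m_Y,
              paste(signif(x$cca$cors, 3), collapse = ", ")))
  invisible(x)
}

#' Predict outcomes for new sessions
#'
#' Projects the session feature vectors through the per-set PCA maps,
#' concatenates, maps into the CCA latent space (U), predicts the outcome
#' latent variables via the training regression (V-hat = U Gamma), and
#' inverts the outcome-side CCA and PCA maps (using the pseudo-inverse of B)
#' to produce predicted composite scores.
#'
#' @param model a `"prediction_model"`.
#' @param features named list of feature matrices.
#' @param idx rows of the feature matrices to predict (default all).
#' @return list with `U` (n x k), `Vhat` (n x k), `composites` (n x 6
#'   predicted composite matrix, reaction expressed as reaction speed).
#' @export
predict_outcomes <- function(model, features, idx = NULL) {
  stopifnot(inherits(model, "prediction_model"))
  miss <- setdiff(model$feature_sets, names(features))
  if (length(miss) > 0) {
    stop("missing feature set(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  blocks <- lapply(model$feature_sets, function(fs) {
    Xf <- features[[fs]]
    if (!is.null(idx)) Xf <- Xf[idx, , drop = FALSE]
    apply_pca(model$pcas[[fs]], Xf)
  })
  Xhat <- do.call(cbind, blocks)
  U <- sweep(Xhat, 2L, model$cca$x_center) %*% model$cca$A
  Vhat <- U %*% model$Gamma
  Yhat_pca <- sweep(Vhat %*% model$B_pinv, 2L, model$cca$y_center, "+")
  comps <- invert_pca(model$ypca, Yhat_pca)
  colnames(comps) <- composite_names()
  list(U = U, Vhat = Vhat, composites = comps)
}

#' Outcome-side latent variables from true composites
#'
#' Computes V for given sessions from their true composite scores using a
#' fitted model's (training-derived) outcome z-scoring, PCA and CCA maps.
#'
#' @param model a `"prediction_model"`.
#' @param Ymat 6-column composite matrix for the sessions of interest.
#' @return n x k matrix V.
#' @export
project_outcomes <- function(model, Ymat) {
  stopifnot(inherits(model, "prediction_model"))
  Yhat <- apply_pca(model$ypca, Ymat)
  sweep(Yhat, 2L, model$cca$y_center) %*% model$cca$B
}

#' Nested leave-one-subject-out cross-validation
#'
#' Outer loop: each subject's sessions in turn form the test fold; a full
#' prediction model (per-feature-set dimensionality selection by inner LOSO,
#' PCA maps, outcome-side PCA, fused CCA, predictive regression) is fitted
#' on the remaining subjects and applied frozen to the held-out sessions.
#' Out-of-sample U, V and composite predictions are pooled across folds and
#' summarized by Spearman correlations.
#'
#' @param features named list of feature matrices (sessions x p).
#' @param meta data.frame with `subject_id`, `session_index` aligned to the
#'   feature rows.
#' @param panel composite panel data.frame (matched by subject and session).
#' @inheritParams fit_prediction_model
#' @return list of class `"cv_result"`: `sessions` (per-session data.frame
#'   with `U`, `V`, `Vhat`), `predicted` / `observed` composite matrices,
#'   `fold_dims` (per-fold selected dimensionalities), `uv` (pooled Spearman
#'   r, p, n), `composite_cor` (per-composite Spearman), `m_Y`,
#'   `feature_sets`.
#' @export
loso_crossvalidate <- function(features, meta, panel,
                               feature_sets = names(features),
                               m_Y = 1L, candidate_dims = 1:7,
                               fixed_dims = NULL, ridge = 1e-8) {
  n <- nrow(meta)
  stopifnot(all(vapply(features, nrow, 0L) == n))
  key_m <- paste(meta$subject_id, meta$session_index, sep = "\r")
  key_p <- paste(panel$subject_id, panel$session_index, sep = "\r")
  rows <- match(key_m, key_p)
  if (anyNA(rows)) {
    stop("sessions present in features but absent from composite panel",
         call. = FALSE)
  }
  Ymat <- composite_matrix(panel)[rows, , drop = FALSE]
  subjects <- as.character(meta$subject_id)
  uniq <- unique(subjects)
  if (length(uniq) < 3L) stop("need at least 3 subjects", call. = FALSE)
  U <- V <- Vhat <- rep(NA_real_, n)
  pred <- matrix(NA_real_, n, 6L, dimnames = list(NULL, composite_names()))
  fold_dims <- NULL
  assigned <- rep(0L, n)
  for (s in uniq) {
    te <- which(subjects == s)
    tr <- which(subjects != s)
    stopifnot(length(intersect(te, tr)) == 0L)
    model <- fit_prediction_model(features, Ymat, subjects, tr,
                                  feature_sets = feature_sets, m_Y = m_Y,
                                  candidate_dims = candidate_dims,
                                  fixed_dims = fixed_dims, ridge = ridge)
    out <- predict_outcomes(model, features, idx = te)
    U[te] <- out$U[, 1L]
    Vhat[te] <- out$Vhat[, 1L]
    V[te] <- project_outcomes(model, Ymat[te, , drop = FALSE])[, 1L]
    pred[te, ] <- out$composites
    fold_dims <- rbind(fold_dims,
                       data.frame(subject_id = s,
                                  t(as.matrix(model$dims))))
    assigned[te] <- assigned[te] + 1L
  }
  stopifnot(all(assigned == 1L))  # every session predicted exactly once
  uv <- spearman_cor(U, V)
  composite_cor <- do.call(rbind, lapply(composite_names(), function(cn) {
    sc <- spearman_cor(pred[, cn], Ymat[, cn])
    data.frame(composite = cn, r = sc$r, p = sc$p)
  }))
  structure(list(
    sessions = data.frame(subject_id = meta$subject_id,
                          session_index = meta$session_index,
                          U = U, V = V, Vhat = Vhat,
                          stringsAsFactors = FALSE),
    predicted = pred, observed = Ymat, fold_dims = fold_dims,
    uv = uv, composite_cor = composite_cor, m_Y = m_Y,
    feature_sets = intersect(feature_set_names(), feature_sets)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d sessions, %d subjects, m_Y = %d\n",
              nrow(x$sessions), length(unique(x$sessions$subject_id)),
              x$m_Y))
  cat("  feature sets:", paste(x$feature_sets, collapse = ", "), "\n")
  cat(sprintf("  pooled out-of-sample Spearman(U, V): r = %.3f (p = %.3g)\n",
              x$uv$r, x$uv$p))
  print(transform(x$composite_cor, r = round(r, 3), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Most commonly selected dimensionality per feature set
#'
#' Summarizes a cross-validation run by the modal selected dimensionality of
#' each feature set across outer folds; ties break to the smallest value.
#'
#' @param cv a `"cv_result"`.
#' @return named integer vector.
#' @export
modal_dims <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  sets <- setdiff(names(cv$fold_dims), "subject_id")
  out <- vapply(sets, function(fs) {
    tab <- table(cv$fold_dims[[fs]])
    vals <- as.integer(names(tab))
    best <- vals[tab == max(tab)]
    min(best)
  }, integer(1))
  names(out) <- sets
  out
}

#' Sweep the outcome-side dimensionality
#'
#' Holds the per-feature-set dimensionalities fixed and varies the
#' outcome-side PCA dimensionality m_Y, reporting out-of-sample Spearman
#' correlations between predicted and true composite scores at each m_Y.
#'
#' @inheritParams loso_crossvalidate
#' @param fixed_dims named per-set dimensionalities (required), e.g. from
#'   [modal_dims()].
#' @param mY_values integer vector of outcome dimensionalities (within 1..6).
#' @return data.frame with columns `m_Y`, `composite`, `r`, `p`.
#' @export
sweep_impact_dims <- function(features, meta, panel, fixed_dims,
                              feature_sets = names(features),
                              mY_values = 1:6, ridge = 1e-8) {
  if (any(mY_values < 1L) || any(mY_values > 6L)) {
    stop("m_Y values must lie in 1..6 (six composites)", call. = FALSE)
  }
  out <- NULL
  for (m in sort(unique(as.integer(mY_values)))) {
    cv <- loso_crossvalidate(features, meta, panel,
                             feature_sets = feature_sets, m_Y = m,
                             fixed_dims = fixed_dims, ridge = ridge)
    out <- rbind(out, cbind(m_Y = m, cv$composite_cor))
  }
  out
}
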