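#' Within-subject successive-session differences
#'
#' Computes change scores `dU = U[i+1] - U[i]` and `dV = V[i+1] - V[i]`
#' between each subject's consecutive analyzed sessions (ordered by
#' `session_index`). Subjects with a single session contribute no pairs, so
#' the number of pairs is the session count minus the subject count.
#'
#' @param sessions data.frame with columns `subject_id`, `session_index`,
#'   `U`, `V` (e.g. the `sessions` element of a [loso_crossvalidate()]
#'   result or of [global_model_changes()]).
#' @return data.frame of class `"change_scores"` with one row per
#'   consecutive pair: `subject_id`, `session_from`, `session_to`, `dU`,
#'   `dV`.
#' @export
successive_differences <- function(sessions) {
  need <- c("subject_id", "session_index", "U", "V")
  miss <- setdiff(need, names(sessions))
  if (length(miss) > 0) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sessions[c("subject_id", "session_index")]) > 0) {
    stop("duplicate (subject_id, session_index) rows", call. = FALSE)
  }
  ord <- order(sessions$subject_id, sessions$session_index)
  s <- sessions[ord, , drop = FALSE]
  out <- NULL
  for (id in unique(s$subject_id)) {
    rows <- s[s$subject_id == id, , drop = FALSE]
    k <- nrow(rows)
    if (k < 2L) next
    out <- rbind(out, data.frame(
      subject_id = id,
      session_from = rows$session_index[-k],
      session_to = rows$session_index[-1L],
      dU = diff(rows$U),
      dV = diff(rows$V),
      stringsAsFactors = FALSE
    ))
  }
  if (is.null(out)) {
    out <- data.frame(subject_id = character(0), session_from = integer(0),
                      session_to = integer(0), dU = numeric(0),
                      dV = numeric(0))
  }
  class(out) <- c("change_scores", class(out))
  out
}

#' Range-restriction adjustment of a correlation
#'
#' Thorndike Case II correction: given a correlation `r` observed in a
#' sample whose predictor standard deviation `sd_restricted` is narrowed
#' relative to a reference `sd_unrestricted`, the adjusted correlation is
#' `r K / sqrt(1 - r^2 + r^2 K^2)` with `K = sd_unrestricted /
#' sd_restricted`. Used because within-subject change scores can have
#' smaller variance than the session scores they derive from.
#'
#' @param r observed correlation, `|r| < 1`.
#' @param sd_restricted,sd_unrestricted positive standard deviations of the
#'   predictor in the restricted sample and the reference range.
#' @return adjusted correlation, same sign as `r`, magnitude below 1.
#' @export
adjust_range_restriction <- function(r, sd_restricted, sd_unrestricted) {
  if (!is.finite(r) || abs(r) >= 1) {
    stop("`r` must be a correlation with |r| < 1", call. = FALSE)
  }
  if (!is.finite(sd_restricted) || !is.finite(sd_unrestricted) ||
      sd_restricted <= 0 || sd_unrestricted <= 0) {
    stop("standard deviations must be positive", call. = FALSE)
  }
  K <- sd_unrestricted / sd_restricted
  (r * K) / sqrt(1 - r^2 + r^2 * K^2)
}

#' Within-subject change analysis under a single global model
#'
#' Fits one prediction model on all supplied sessions (no cross-validation),
#' with externally supplied per-feature-set dimensionalities (typically the
#' modal per-fold selections of a cross-validation run). U and V are
#' computed for every session from this global model, differenced within
#' subject, and the dU-dV association is summarized by a Spearman
#' correlation together with its range-restriction-adjusted value (using
#' `K = sd(U) / sd(dU)` from the same sample).
#'
#' @inheritParams loso_crossvalidate
#' @param fixed_dims named per-feature-set dimensionalities (required), e.g.
#'   from [modal_dims()].
#' @return list of class `"change_result"`: `sessions` (with global-model
#'   `U`, `V`), `changes` (the [successive_differences()] table), `r`, `p`,
#'   `r_adjusted`, `K`, `n_pairs`.
#' @export
global_model_changes <- function(features, meta, panel, fixed_dims,
                                 feature_sets = names(features),
                                 m_Y = 1L, ridge = 1e-8) {
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
  model <- fit_prediction_model(features, Ymat, subjects,
                                train = seq_len(n),
                                feature_sets = feature_sets, m_Y = m_Y,
                                fixed_dims = fixed_dims, ridge = ridge)
  out <- predict_outcomes(model, features)
  V <- project_outcomes(model, Ymat)
  sessions <- data.frame(subject_id = meta$subject_id,
                         session_index = meta$session_index,
                         U = out$U[, 1L], V = V[, 1L],
                         stringsAsFactors = FALSE)
  changes <- successive_differences(sessions)
  sc <- spearman_cor(changes$dU, changes$dV)
  K <- stats::sd(sessions$U) / stats::sd(changes$dU)
  r_adj <- if (is.na(sc$r) || abs(sc$r) >= 1) sc$r else
    adjust_range_restriction(sc$r, stats::sd(changes$dU),
                             stats::sd(sessions$U))
  structure(list(sessions = sessions, changes = changes, model = model,
                 r = sc$r, p = sc$p, r_adjusted = r_adj, K = K,
                 n_pairs = nrow(changes)),
            class = "change_result")
}

#' @export
print.change_result <- function(x, ...) {
  cat(sprintf(
    "<change_result> %d successive-session pairs from %d subjects\n",
    x$n_pairs, length(unique(x$changes$subject_id))))
  cat(sprintf("  Spearman(dU, dV): r = %.3f (p = %.3g), adjusted r = %.3f (K = %.2f)\n",
              x$r, x$p, x$r_adjusted, x$K))
  invisible(x)
}
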