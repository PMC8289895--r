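#' Reaction speed from reaction time
#'
#' Reaction speed is the reciprocal of the reaction-time composite score; it
#' is used in place of reaction time so that it shares the sign of
#' correlation of the memory and speed composites (higher = better).
#'
#' @param reaction_time positive numeric vector of reaction-time scores.
#' @return numeric vector `1 / reaction_time`.
#' @export
reaction_speed <- function(reaction_time) {
  if (!is.numeric(reaction_time) || any(!is.finite(reaction_time)) ||
      any(reaction_time <= 0)) {
    stop("`reaction_time` must be strictly positive and finite",
         call. = FALSE)
  }
  1 / reaction_time
}

# Column order of the outcome matrix used throughout the model.
composite_names <- function() {
  c("verbal_memory", "visual_memory", "visual_speed", "reaction_speed",
    "impulse_control", "total_symptoms")
}

#' Composite score matrix from a panel
#'
#' Builds the n_sessions x 6 outcome matrix (verbal memory, visual memory,
#' visual speed, reaction speed, impulse control, total symptoms) from a
#' composite panel, converting reaction time to reaction speed.
#'
#' @param panel data.frame with columns `subject_id`, `session_index`,
#'   `verbal_memory`, `visual_memory`, `visual_speed`, `reaction_time`,
#'   `impulse_control`, `total_symptoms`.
#' @return numeric matrix with the six composite columns.
#' @export
composite_matrix <- function(panel) {
  need <- c("verbal_memory", "visual_memory", "visual_speed",
            "reaction_time", "impulse_control", "total_symptoms")
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0) {
    stop("panel missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(panel[c("subject_id", "session_index")]) > 0) {
    stop("duplicate (subject_id, session_index) rows in panel",
         call. = FALSE)
  }
  m <- cbind(
    verbal_memory = panel$verbal_memory,
    visual_memory = panel$visual_memory,
    visual_speed = panel$visual_speed,
    reaction_speed = reaction_speed(panel$reaction_time),
    impulse_control = panel$impulse_control,
    total_symptoms = panel$total_symptoms
  )
  m
}

#' Fit the latent cognitive factor
#'
#' Z-scores the six composite columns over all supplied sessions pooled and
#' computes their first principal component. The loading vector has unit
#' norm and its sign is fixed so that the loading on verbal memory is
#' positive; scores have mean zero by construction. On data with the
#' expected structure the factor loads near-equally on the four
#' cognition-related composites (both memory scores, visual speed, reaction
#' speed) and near zero on impulse control and total symptoms.
#'
#' @param panel composite panel data.frame (see [composite_matrix()]), or a
#'   ready-made 6-column matrix with reaction speed already applied.
#' @return list of class `"latent_factor_model"`: `center`, `scale` (per
#'   composite), `loadings` (length 6, unit norm), `scores` (per session),
#'   `sdev` (SD of the scores).
#' @export
fit_latent_factor <- function(panel) {
  m <- if (is.matrix(panel)) panel else composite_matrix(panel)
  if (nrow(m) < 3L) stop("need at least 3 sessions", call. = FALSE)
  ctr <- colMeans(m)
  scl <- apply(m, 2L, stats::sd)
  if (any(scl == 0)) {
    stop("constant composite column; latent factor undefined", call. = FALSE)
  }
  z <- scale(m, center = ctr, scale = scl)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  w <- pc$rotation[, 1L]
  if (w["verbal_memory"] < 0) w <- -w
  scores <- drop(z %*% w)
  structure(list(center = ctr, scale = scl, loadings = w,
                 scores = scores, sdev = stats::sd(scores)),
            class = "latent_factor_model")
}

#' Latent-factor scores for new sessions
#'
#' Applies a fitted latent-factor model (z-scoring parameters and loading
#' vector) to new composite data.
#'
#' @param model a `"latent_factor_model"` from [fit_latent_factor()].
#' @param panel composite panel or 6-column matrix.
#' @return numeric vector of latent scores.
#' @export
predict_latent_factor <- function(model, panel) {
  stopifnot(inherits(model, "latent_factor_model"))
  m <- if (is.matrix(panel)) panel else composite_matrix(panel)
  z <- scale(m, center = model$center, scale = model$scale)
  drop(z %*% model$loadings)
}

#' @export
print.latent_factor_model <- function(x, ...) {
  cat("<latent_factor_model>\n  loadings:\n")
  print(round(x$loadings, 3))
  cat(sprintf("  score SD: %.3f over %d sessions\n", x$sdev,
              length(x$scores)))
  invisible(x)
}

#' Group-level check of the latent factor across assessment points
#'
#' Descriptive Kruskal-Wallis rank test of whether latent-factor values
#' differ across assessment points (e.g. pre-season through post-season
#' waves). A non-significant result indicates no group-level trend over the
#' season.
#'
#' @param scores numeric latent-factor scores per session.
#' @param assessment factor or vector of assessment-point labels.
#' @return the `htest` object from [stats::kruskal.test()].
#' @export
assessment_point_test <- function(scores, assessment) {
  stats::kruskal.test(scores, as.factor(assessment))
}
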