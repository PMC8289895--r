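#' Write a cohort to a directory of CSV/JSON files
#'
#' One CSV per session per modality (columns: `time_s` plus one column per
#' channel; missing samples as empty fields) with a JSON sidecar carrying
#' `subject_id`, `session_index`, `modality` and `sample_interval`; a
#' `composites.csv` panel; and a `manifest.json` listing sessions, the
#' feature-set specification and the generator seed.
#'
#' @param cohort a `"cohort"` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mods <- c("gaze", "formant", "fmri_subcort", "fmri_cort")
  entries <- list()
  for (s in cohort$sessions) {
    base <- sprintf("%s_ses%02d", s$subject_id, s$session_index)
    for (m in mods) {
      ser <- s[[m]]
      df <- data.frame(time_s = seq_len(ncol(ser$values)) *
                         ser$sample_interval)
      for (ci in seq_along(ser$channel_labels)) {
        df[[ser$channel_labels[ci]]] <- ser$values[ci, ]
      }
      utils::write.csv(df, file.path(dir, paste0(base, "_", m, ".csv")),
                       row.names = FALSE, na = "")
      jsonlite::write_json(
        list(subject_id = s$subject_id, session_index = s$session_index,
             modality = m, sample_interval = ser$sample_interval),
        file.path(dir, paste0(base, "_", m, ".json")), auto_unbox = TRUE)
    }
    entries[[length(entries) + 1L]] <-
      list(subject_id = s$subject_id, session_index = s$session_index)
  }
  utils::write.csv(cohort$panel, file.path(dir, "composites.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n_subjects = cohort$config$n_subjects,
         n_sessions = length(cohort$sessions),
         seed = cohort$config$seed,
         effect_size = cohort$config$effect_size,
         feature_sets = feature_set_names(),
         sessions = entries),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read one session series CSV (+ JSON sidecar) back into an mc_series
#'
#' @param csv_path path to a session CSV written by [write_cohort()].
#' @return an [mc_series]; empty fields become missing samples.
#' @export
read_session_csv <- function(csv_path) {
  side <- sub("\\.csv$", ".json", csv_path)
  meta <- jsonlite::read_json(side)
  df <- utils::read.csv(csv_path)
  v <- t(as.matrix(df[, setdiff(names(df), "time_s"), drop = FALSE]))
  miss <- apply(v, 2L, function(col) any(is.na(col)))
  mc_series(v, meta$sample_interval, rownames(v), miss)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return list with `sessions` (same layout as [simulate_cohort()] minus
#'   ground truth) and `panel`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  mods <- c("gaze", "formant", "fmri_subcort", "fmri_cort")
  sessions <- lapply(manifest$sessions, function(e) {
    base <- sprintf("%s_ses%02d", e$subject_id, e$session_index)
    out <- list(subject_id = e$subject_id,
                session_index = as.integer(e$session_index))
    for (m in mods) {
      out[[m]] <- read_session_csv(file.path(dir, paste0(base, "_", m,
                                                         ".csv")))
    }
    out
  })
  panel <- utils::read.csv(file.path(dir, "composites.csv"),
                           stringsAsFactors = FALSE)
  structure(list(sessions = sessions, panel = panel, truth = NULL,
                 config = NULL), class = "cohort")
}

#' Run the full analysis pipeline on a cohort
#'
#' Convenience wrapper: extracts the seven per-session feature sets, runs
#' nested leave-one-subject-out cross-validation with all-modality fusion,
#' then the within-subject change analysis under a global model using the
#' modal per-fold dimensionalities.
#'
#' @param cohort a `"cohort"` (simulated or read from disk).
#' @param feature_sets feature sets to fuse (default all seven).
#' @param m_Y outcome-side dimensionality (default 1).
#' @param candidate_dims per-set dimensionality candidates (default 1:7).
#' @param delay_cfgs,eye_cfg see [session_feature_vector()].
#' @return list of class `"pipeline_result"`: `cv` (a `"cv_result"`),
#'   `changes` (a `"change_result"`), `dims` (modal per-set
#'   dimensionalities), `features`, `meta`.
#' @export
run_pipeline <- function(cohort, feature_sets = feature_set_names(),
                         m_Y = 1L, candidate_dims = 1:7,
                         delay_cfgs = default_delay_configs(),
                         eye_cfg = eye_preprocess_config()) {
  fx <- cohort_features(cohort, delay_cfgs, eye_cfg)
  cv <- loso_crossvalidate(fx$features, fx$meta, cohort$panel,
                           feature_sets = feature_sets, m_Y = m_Y,
                           candidate_dims = candidate_dims)
  dims <- modal_dims(cv)
  changes <- global_model_changes(fx$features, fx$meta, cohort$panel,
                                  fixed_dims = as.list(dims),
                                  feature_sets = feature_sets, m_Y = m_Y)
  structure(list(cv = cv, changes = changes, dims = dims,
                 features = fx$features, meta = fx$meta,
                 dropped = fx$dropped),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$cv)
  print(x$changes)
  invisible(x)
}
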