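# Plain-CSV interchange for the per-trial signal tables.
# Fixation CSV columns: trial_id, participant_id, onset_s, duration_s, x, y
# Pupil CSV columns:    trial_id, participant_id, t_s, left_mm, right_mm, valid
# Truth CSV columns:    participant_id, trial_id, load, criticality,
#                       Ht_true, Hs_true, Dm_true, collision

#' Write fixation sequences of a generated dataset to CSV
#'
#' @param raw_trials The `raw` component of [generate_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixations_csv <- function(raw_trials, path) {
  tabs <- lapply(raw_trials, function(tr)
    data.frame(trial_id = tr$trial_id, participant_id = tr$participant_id,
               onset_s = tr$fixations$onset, duration_s = tr$fixations$duration,
               x = tr$fixations$x, y = tr$fixations$y))
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' Read fixation sequences from CSV
#'
#' @param path CSV written by [write_fixations_csv()].
#' @return Named list of [fixation_sequence()] objects, one per trial.
#' @export
read_fixations_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$trial_id), function(d)
    fixation_sequence(d$onset_s, d$duration_s, d$x, d$y))
}

#' Write pupil traces of a generated dataset to CSV
#'
#' @inheritParams write_fixations_csv
#' @export
write_pupil_csv <- function(raw_trials, path) {
  tabs <- lapply(raw_trials, function(tr)
    data.frame(trial_id = tr$trial_id, participant_id = tr$participant_id,
               t_s = tr$pupil$t, left_mm = tr$pupil$left_mm,
               right_mm = tr$pupil$right_mm, valid = tr$pupil$valid))
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}

#' Read pupil traces from CSV
#'
#' @param path CSV written by [write_pupil_csv()].
#' @return Named list of [pupil_trace()] objects, one per trial.
#' @export
read_pupil_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$trial_id), function(d)
    pupil_trace(d$t_s, d$left_mm, d$right_mm, d$valid))
}

#' Write the per-trial truth table to CSV
#'
#' @param truth The `truth` component of [generate_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  cols <- c("participant_id", "trial_id", "load", "criticality",
            "Ht_true", "Hs_true", "Dm_true", "collision")
  utils::write.csv(truth[cols], path, row.names = FALSE)
  invisible(path)
}

#' Compute the trial feature table from raw signals
#'
#' The raw-to-features pipeline: per trial, normalised stationary and
#' transition gaze entropy over the spatial grid and the mean pupil
#' diameter after blink interpolation and zero-phase smoothing; then
#' dataset-level z-scoring of all three features.
#'
#' @param raw_trials The `raw` component of [generate_dataset()] (or any
#'   list of trials with `fixations`, `pupil`, ids and `collision`).
#' @param grid Spatial [bin_grid()] (reported with every analysis; the
#'   normalised entropies depend on it).
#' @param cutoff_hz,order Butterworth smoothing parameters.
#' @return Data frame with per-trial `Hs_norm`, `Ht_norm`, `Dm_mm`, their
#'   z-scores, metadata and `collision`.
#' @export
trial_features <- function(raw_trials, grid = bin_grid_regular(),
                           cutoff_hz = 4, order = 2) {
  rows <- lapply(raw_trials, function(tr) {
    ent <- gaze_entropy(tr$fixations, grid)
    data.frame(participant_id = tr$participant_id, trial_id = tr$trial_id,
               load = tr$load, criticality = tr$criticality,
               Hs_norm = ent$Hs_norm, Ht_norm = ent$Ht_norm,
               Dm_mm = pupil_feature(tr$pupil, cutoff_hz, order),
               n_fixations = ent$n_fixations,
               collision = as.integer(tr$collision),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$Ht_z <- zscore(out$Ht_norm, "Ht")
  out$Hs_z <- zscore(out$Hs_norm, "Hs")
  out$Dm_z <- zscore(out$Dm_mm, "Dm")
  out
}
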