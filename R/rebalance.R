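#' Assemble a labelled feature set for model fitting
#'
#' Binds the three standardised trial features to the binary collision
#' outcome (1 = collision, the minority class), carrying row identifiers,
#' participant (cluster) ids, and a `synthetic` marker that rebalancing
#' methods set on generated rows.
#'
#' @param trials Data frame with columns `Ht_z`, `Hs_z`, `Dm_z`, `collision`
#'   and optionally `trial_id`, `participant_id` (e.g. the truth table from
#'   [generate_dataset()]).
#' @return A `labelled_features` data frame with columns `Ht_z`, `Hs_z`,
#'   `Dm_z`, `collision`, `id`, `cluster`, `synthetic`.
#' @export
labelled_features <- function(trials) {
  need <- c("Ht_z", "Hs_z", "Dm_z", "collision")
  if (!all(need %in% names(trials)))
    stop("trials must contain Ht_z, Hs_z, Dm_z and collision")
  if (any(is.na(trials[need])))
    stop("labelled features must not contain missing values")
  out <- data.frame(
    Ht_z = trials$Ht_z, Hs_z = trials$Hs_z, Dm_z = trials$Dm_z,
    collision = as.integer(trials$collision),
    id = if (is.null(trials$trial_id)) paste0("row", seq_len(nrow(trials)))
         else as.character(trials$trial_id),
    cluster = if (is.null(trials$participant_id)) paste0("row", seq_len(nrow(trials)))
              else as.character(trials$participant_id),
    synthetic = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("labelled_features", "data.frame")
  out
}

feature_cols <- c("Ht_z", "Hs_z", "Dm_z")

check_rebalanceable <- function(data) {
  if (isTRUE(attr(data, "no_rebalance")))
    stop("this set is marked no-rebalance (test data must stay untouched)")
  if (length(unique(data$collision)) < 2L)
    stop("both outcome classes must be present before correction")
}

#' Mark a dataset as off-limits for rebalancing
#'
#' Test sets carry this marker so that imbalance correction can never leak
#' into evaluation data; the rebalancing operations refuse marked input.
#'
#' @param data A `labelled_features` data frame.
#' @return The data with the `no_rebalance` attribute set.
#' @export
mark_no_rebalance <- function(data) {
  attr(data, "no_rebalance") <- TRUE
  data
}

#' SMOTE: synthetic minority over-sampling
#'
#' Equalises the class counts by generating synthetic minority (collision)
#' rows: a minority row `x_i` is drawn uniformly, one of its `k` nearest
#' minority neighbours `x_zi` (Euclidean distance on the three standardised
#' features, self excluded, ties broken by row order) is drawn uniformly,
#' and the new row is the convex combination `x_i + lambda * (x_zi - x_i)`
#' with `lambda ~ Uniform[0, 1]`. Original rows are unchanged; synthetic
#' rows are labelled collisions, flagged `synthetic`, and given fresh
#' singleton cluster ids.
#'
#' @param data A `labelled_features` set (the fitting set).
#' @param k Number of nearest minority neighbours (default 5); reduced with
#'   a warning if it exceeds `minority - 1`.
#' @return The augmented set with equal class counts.
#' @export
smote <- function(data, k = 5L) {
  check_rebalanceable(data)
  min_idx <- which(data$collision == 1L)
  maj_n <- sum(data$collision == 0L)
  m <- length(min_idx)
  if (m < 2L) stop("SMOTE requires at least 2 minority rows")
  if (k < 1L) stop("k must be >= 1")
  n_new <- maj_n - m
  if (n_new <= 0L) return(data)
  if (k > m - 1L) {
    warning(sprintf("k = %d exceeds minority size - 1; reduced to %d",
                    k, m - 1L))
    k <- m - 1L
  }
  Xm <- as.matrix(data[min_idx, feature_cols])
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  # k nearest minority neighbours per minority row, ties broken by row order
  nn <- apply(D, 1L, function(d) order(d)[seq_len(k)])
  nn <- matrix(nn, nrow = k)
  i_pick <- sample.int(m, n_new, replace = TRUE)
  z_pick <- nn[cbind(sample.int(k, n_new, replace = TRUE), i_pick)]
  lambda <- stats::runif(n_new)
  Xnew <- Xm[i_pick, , drop = FALSE] +
    lambda * (Xm[z_pick, , drop = FALSE] - Xm[i_pick, , drop = FALSE])
  new_rows <- data.frame(Xnew,
                         collision = 1L,
                         id = paste0("syn", seq_len(n_new)),
                         cluster = paste0("syn", seq_len(n_new)),
                         synthetic = TRUE, stringsAsFactors = FALSE)
  names(new_rows)[1:3] <- feature_cols
  out <- rbind(data, new_rows)
  class(out) <- class(data)
  out
}

#' Random under-sampling of the majority class
#'
#' Removes random majority (no-collision) rows without replacement until the
#' classes are the same size; minority rows are untouched.
#'
#' @param data A `labelled_features` set (the fitting set).
#' @return The reduced set with equal class counts.
#' @export
undersample <- function(data) {
  check_rebalanceable(data)
  min_idx <- which(data$collision == 1L)
  maj_idx <- which(data$collision == 0L)
  if (length(maj_idx) <= length(min_idx)) return(data)
  keep <- sample(maj_idx, length(min_idx))
  out <- data[sort(c(min_idx, keep)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(data)
  out
}

#' Random over-sampling of the minority class
#'
#' Resamples minority (collision) rows with replacement until the minority
#' class matches the majority size, producing duplicate minority cases that
#' share their source row's feature values. Duplicates are flagged
#' `synthetic` and given fresh singleton cluster ids.
#'
#' @param data A `labelled_features` set (the fitting set).
#' @return The augmented set with equal class counts.
#' @export
oversample <- function(data) {
  check_rebalanceable(data)
  min_idx <- which(data$collision == 1L)
  maj_n <- sum(data$collision == 0L)
  n_new <- maj_n - length(min_idx)
  if (n_new <= 0L) return(data)
  src <- sample(min_idx, n_new, replace = TRUE)
  new_rows <- data[src, , drop = FALSE]
  new_rows$id <- paste0("dup", seq_len(n_new))
  new_rows$cluster <- paste0("dup", seq_len(n_new))
  new_rows$synthetic <- TRUE
  out <- rbind(data, new_rows)
  rownames(out) <- NULL
  class(out) <- class(data)
  out
}

#' Apply a named imbalance-correction regime
#'
#' @param data A `labelled_features` fitting set.
#' @param method One of `"uncorrected"`, `"smote"`, `"under"`, `"over"`.
#' @param k SMOTE neighbourhood size.
#' @return The (possibly) corrected set.
#' @export
rebalance <- function(data, method = c("uncorrected", "smote", "under", "over"),
                      k = 5L) {
  method <- match.arg(method)
  switch(method,
         uncorrected = data,
         smote = smote(data, k = k),
         under = undersample(data),
         over = oversample(data))
}
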