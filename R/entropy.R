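#' Construct a fixation sequence
#'
#' An ordered sequence of fixations for one trial: onset times, durations and
#' gaze coordinates. Fixation order carries the scanpath information that the
#' transition entropy summarises, so onsets must be strictly increasing.
#'
#' @param onset Numeric vector of fixation onsets in seconds, strictly
#'   increasing.
#' @param duration Numeric vector of fixation durations in seconds, all
#'   positive.
#' @param x,y Numeric vectors of fixation coordinates (screen or normalised
#'   gaze-area units).
#' @return A `fixation_sequence`: a data frame with columns `onset`,
#'   `duration`, `x`, `y`.
#' @export
fixation_sequence <- function(onset, duration, x, y) {
  n <- length(onset)
  if (length(duration) != n || length(x) != n || length(y) != n)
    stop("onset, duration, x and y must have equal length")
  if (n >= 2 && any(diff(onset) <= 0))
    stop("fixation onsets must be strictly increasing")
  if (any(duration <= 0))
    stop("fixation durations must be positive")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("fixation coordinates must be finite")
  structure(data.frame(onset = onset, duration = duration, x = x, y = y),
            class = c("fixation_sequence", "data.frame"))
}

#' Construct a rectangular spatial bin grid
#'
#' Defines the rows x cols rectangular bins that fixations are sorted into
#' before the gaze probability distributions are formed. Bins are numbered
#' row-major, starting at 1.
#'
#' @param x_edges,y_edges Strictly increasing numeric vectors of bin
#'   boundaries along each axis (`length(edges) - 1` bins per axis).
#' @return A `bin_grid` object.
#' @seealso [bin_grid_regular()] for an evenly spaced grid.
#' @export
bin_grid <- function(x_edges, y_edges) {
  if (any(diff(x_edges) <= 0) || any(diff(y_edges) <= 0))
    stop("bin edges must be strictly increasing")
  n_bins <- (length(x_edges) - 1L) * (length(y_edges) - 1L)
  if (n_bins < 2L)
    stop("grid must define at least 2 bins")
  structure(list(x_edges = as.numeric(x_edges), y_edges = as.numeric(y_edges),
                 n_rows = length(y_edges) - 1L, n_cols = length(x_edges) - 1L,
                 n_bins = n_bins),
            class = "bin_grid")
}

#' Evenly spaced bin grid over a rectangular gaze area
#'
#' The default analysis grid is 8 x 8 over the unit square; the grid geometry
#' is a reportable configuration item because normalised entropies depend on
#' the number of bins.
#'
#' @param n_rows,n_cols Number of bins along y and x.
#' @param xlim,ylim Extent of the gaze area.
#' @return A `bin_grid`.
#' @export
bin_grid_regular <- function(n_rows = 8L, n_cols = 8L,
                             xlim = c(0, 1), ylim = c(0, 1)) {
  bin_grid(seq(xlim[1], xlim[2], length.out = n_cols + 1L),
           seq(ylim[1], ylim[2], length.out = n_rows + 1L))
}

#' Assign fixations to spatial bins
#'
#' Each bin is half-open `[low, high)` on both axes except the last bin on
#' each axis, which is closed, so a point exactly on an interior edge belongs
#' to the higher-index bin. Points outside the grid are clamped to the nearest
#' edge bin and counted in the `clamped` attribute.
#'
#' @param seq A [fixation_sequence()] (or any data frame with `x`, `y`).
#' @param grid A [bin_grid()].
#' @return Integer vector of bin indices in `1:grid$n_bins` (row-major), with
#'   attribute `clamped` giving the number of out-of-grid points.
#' @export
assign_bins <- function(seq, grid) {
  if (nrow(seq) == 0L) stop("empty fixation sequence")
  if (any(!is.finite(seq$x)) || any(!is.finite(seq$y)))
    stop("fixation coordinates must be finite")
  ax <- function(v, edges) {
    k <- findInterval(v, edges, rightmost.closed = TRUE, left.open = FALSE)
    clamped <- sum(k < 1L | k > length(edges) - 1L)
    k <- pmin(pmax(k, 1L), length(edges) - 1L)
    list(idx = k, clamped = clamped)
  }
  cx <- ax(seq$x, grid$x_edges)
  cy <- ax(seq$y, grid$y_edges)
  bins <- (cy$idx - 1L) * grid$n_cols + cx$idx
  attr(bins, "clamped") <- cx$clamped + cy$clamped
  bins
}

#' Empirical stationary distribution of bin visits
#'
#' The spatial probability distribution of fixations: `p_i = count_i / N`.
#'
#' @param bins Integer bin-index sequence (1-based).
#' @param n_bins Total number of bins.
#' @return Probability vector of length `n_bins`, summing to 1.
#' @export
stationary_distribution <- function(bins, n_bins) {
  if (length(bins) < 1L) stop("empty bin sequence")
  tabulate(bins, nbins = n_bins) / length(bins)
}

#' Empirical transition matrix of the fixation-bin chain
#'
#' Row `i` holds the conditional distribution of the next bin given the
#' current bin is `i`. Rows with no outgoing transitions (bins visited only as
#' the final fixation, or never) are left `NA` and flagged, not zero-filled.
#'
#' @param bins Integer bin-index sequence of length >= 2.
#' @param n_bins Total number of bins.
#' @return A list with `T` (n_bins x n_bins row-conditional matrix, `NA` rows
#'   where undefined), `visits` (outgoing-transition counts per row) and
#'   `undefined` (logical vector flagging rows with no exits).
#' @export
transition_matrix <- function(bins, n_bins) {
  if (length(bins) < 2L)
    stop("transition matrix requires at least 2 fixations")
  from <- bins[-length(bins)]
  to <- bins[-1L]
  counts <- matrix(0, n_bins, n_bins)
  for (t in seq_along(from))
    counts[from[t], to[t]] <- counts[from[t], to[t]] + 1
  visits <- rowSums(counts)
  undefined <- visits == 0
  T <- counts / ifelse(visits > 0, visits, NA_real_)
  T[undefined, ] <- NA_real_
  list(T = T, visits = visits, undefined = undefined)
}

#' Shannon entropy of a probability vector (bits)
#'
#' Stationary gaze entropy Hs: the average uncertainty of the spatial
#' distribution of fixations, `-sum(p * log2(p))` with `0 * log 0 := 0`.
#'
#' @param p Probability vector (non-negative, sums to 1 within 1e-9).
#' @return Entropy in bits.
#' @export
stationary_entropy <- function(p) {
  if (any(p < 0)) stop("probability vector has negative entries")
  if (abs(sum(p) - 1) > 1e-9) stop("probability vector does not sum to 1")
  nz <- p > 0
  -sum(p[nz] * log2(p[nz]))
}

#' Gaze transition entropy (bits)
#'
#' Conditional entropy of the fixation-bin Markov chain: the per-row Shannon
#' entropies of the transition matrix, weighted by the stationary probability
#' of each bin. Rows flagged undefined (no outgoing transitions) contribute
#' zero, the standard plug-in convention.
#'
#' @param p Stationary probability vector.
#' @param T Row-conditional transition matrix (`NA` rows where undefined), as
#'   returned by [transition_matrix()] (either the list or the matrix).
#' @return Transition entropy Ht in bits.
#' @export
transition_entropy <- function(p, T) {
  if (is.list(T)) T <- T$T
  if (length(p) != nrow(T)) stop("stationary vector and matrix do not conform")
  row_h <- apply(T, 1L, function(r) {
    if (any(is.na(r))) return(0)
    nz <- r > 0
    -sum(r[nz] * log2(r[nz]))
  })
  sum(p * row_h)
}

#' Normalise an entropy by its maximum
#'
#' Divides by `log2(n_bins)`, the maximum entropy over `n_bins` states, so
#' that Hs and Ht land in `[0, 1]` and are comparable across grid choices.
#'
#' @param H_bits Entropy in bits.
#' @param n_bins Number of bins (>= 2).
#' @return Normalised entropy in `[0, 1]`.
#' @export
normalize_entropy <- function(H_bits, n_bins) {
  if (n_bins < 2) stop("normalisation requires at least 2 bins")
  H_bits / log2(n_bins)
}

#' Standardise a feature across trials
#'
#' z-scores with the sample standard deviation (denominator n - 1). Applied
#' across all trials of a dataset, after entropy normalisation, so model
#' coefficients are per-SD effects.
#'
#' @param values Numeric vector, length >= 2.
#' @param name Feature name used in the zero-variance error message.
#' @return Standardised vector with mean 0 and sample SD 1.
#' @export
zscore <- function(values, name = deparse(substitute(values))) {
  if (length(values) < 2L) stop("z-scoring requires at least 2 values")
  s <- stats::sd(values)
  if (s == 0) stop(sprintf("feature '%s' is constant; cannot z-score", name))
  (values - mean(values)) / s
}

#' Entropy summary of one trial's fixation sequence
#'
#' Bins the fixations, forms the stationary and transition distributions, and
#' returns raw and normalised stationary entropy (Hs) and transition entropy
#' (Ht).
#'
#' @param seq A [fixation_sequence()] with at least 2 fixations.
#' @param grid A [bin_grid()]; defaults to 8 x 8 over the unit square.
#' @return A list of class `entropy_result`: `Hs_bits`, `Ht_bits`, `Hs_norm`,
#'   `Ht_norm`, `n_fixations`, `n_occupied_bins`, `n_undefined_rows`,
#'   `n_clamped`.
#' @export
gaze_entropy <- function(seq, grid = bin_grid_regular()) {
  if (nrow(seq) < 2L)
    stop("entropy requires at least 2 fixations")
  bins <- assign_bins(seq, grid)
  p <- stationary_distribution(bins, grid$n_bins)
  tm <- transition_matrix(bins, grid$n_bins)
  Hs <- stationary_entropy(p)
  Ht <- transition_entropy(p, tm)
  structure(list(
    Hs_bits = Hs, Ht_bits = Ht,
    Hs_norm = normalize_entropy(Hs, grid$n_bins),
    Ht_norm = normalize_entropy(Ht, grid$n_bins),
    n_fixations = nrow(seq),
    n_occupied_bins = sum(p > 0),
    n_undefined_rows = sum(tm$undefined & p > 0),
    n_clamped = attr(bins, "clamped")
  ), class = "entropy_result")
}
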