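#' Default generating coefficients for the collision log-odds model
#'
#' Log-odds coefficients for the collision model on standardised features,
#' in design order: intercept, Ht, Hs, Dm, and all their interactions. The
#' defaults are the point estimates from the uncorrected-data GLM of the
#' source study (intercept -2.664, Ht 0.811, ..., three-way 0.177), so that
#' simulated datasets carry the effect structure the analysis is built for.
#'
#' @return Named numeric vector of length 8.
#' @export
default_beta <- function() {
  c("(Intercept)" = -2.664, "Ht" = 0.811, "Hs" = -0.064, "Dm" = 0.050,
    "Ht:Hs" = 0.517, "Ht:Dm" = 0.231, "Hs:Dm" = -0.063, "Ht:Hs:Dm" = 0.177)
}

#' Simulation configuration
#'
#' Parameters of the synthetic eye-tracking study. The defaults emulate the
#' source study's conditions: 38 participants with 8 analysable critical
#' takeover trials each (~304 trials), ~10% collision prevalence driven by
#' the [default_beta()] log-odds model on standardised gaze-entropy and
#' pupil features, participant-level clustering on the log-odds scale, and
#' 60 Hz raw signals over a two-minute automation period with blinks and
#' measurement noise.
#'
#' The `dispersion` dial controls the spread of the stationary fixation
#' distribution (hence Hs); `randomness` controls transition-kernel mixing
#' (hence Ht). Both are jittered per trial by `dial_sd` so features vary
#' across trials. Under high cognitive load, gaze concentrates
#' (`load_dispersion_effect` < 0) and the pupil dilates
#' (`load_pupil_effect` > 0).
#'
#' @param n_participants,trials_per_participant Study size.
#' @param grid_rows,grid_cols Spatial binning of the gaze area.
#' @param dispersion Base stationary-distribution spread, in `[0, 1]`.
#' @param randomness Base transition-kernel mixing, in `[0, 1]`.
#' @param dial_sd Per-trial SD of the jitter on both dials.
#' @param load_dispersion_effect Shift of `dispersion` under high load.
#' @param n_fixations Fixations per trial.
#' @param sample_rate Pupil sampling rate (Hz).
#' @param trace_duration Pupil trace length (s).
#' @param pupil_baseline Mean pupil diameter under no load (mm).
#' @param pupil_noise_sd SD of slow pupil measurement noise (mm).
#' @param pupil_trial_sd SD of the trial-level true mean-diameter shift (mm).
#' @param load_pupil_effect Pupil dilation under high load (mm).
#' @param blink_rate Blink events per minute.
#' @param blink_duration Blink duration (ms).
#' @param beta Length-8 generating coefficient vector ([default_beta()]
#'   order).
#' @param cluster_sd SD of the participant random shift on the log-odds
#'   scale (>= 0).
#' @param seed Integer seed; identical configurations (including seed)
#'   produce bit-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 38L, trials_per_participant = 8L,
                       grid_rows = 8L, grid_cols = 8L,
                       dispersion = 0.7, randomness = 0.35, dial_sd = 0.18,
                       load_dispersion_effect = -0.1,
                       n_fixations = 300L,
                       sample_rate = 60, trace_duration = 120,
                       pupil_baseline = 3.5, pupil_noise_sd = 0.1,
                       pupil_trial_sd = 0.15, load_pupil_effect = 0.3,
                       blink_rate = 15, blink_duration = 150,
                       beta = default_beta(), cluster_sd = 0.5,
                       seed = 1L) {
  cfg <- list(n_participants = as.integer(n_participants),
              trials_per_participant = as.integer(trials_per_participant),
              grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              dispersion = dispersion, randomness = randomness,
              dial_sd = dial_sd,
              load_dispersion_effect = load_dispersion_effect,
              n_fixations = as.integer(n_fixations),
              sample_rate = sample_rate, trace_duration = trace_duration,
              pupil_baseline = pupil_baseline,
              pupil_noise_sd = pupil_noise_sd,
              pupil_trial_sd = pupil_trial_sd,
              load_pupil_effect = load_pupil_effect,
              blink_rate = blink_rate, blink_duration = blink_duration,
              beta = beta, cluster_sd = cluster_sd, seed = as.integer(seed))
  counts <- c(cfg$n_participants, cfg$trials_per_participant,
              cfg$grid_rows, cfg$grid_cols, cfg$n_fixations)
  if (any(counts < 1L)) stop("all counts must be >= 1")
  if (cfg$dispersion < 0 || cfg$dispersion > 1 ||
      cfg$randomness < 0 || cfg$randomness > 1)
    stop("dispersion and randomness must lie in [0, 1]")
  if (cfg$sample_rate <= 0) stop("sample_rate must be positive")
  if (cfg$cluster_sd < 0) stop("cluster_sd must be >= 0")
  if (length(cfg$beta) != 8L) stop("beta must have length 8")
  names(cfg$beta) <- names(default_beta())
  structure(cfg, class = "sim_config")
}

#' Markov kernel for the fixation-bin chain
#'
#' Builds the stationary distribution and transition kernel whose entropies
#' the generator dials map onto monotonically. The stationary distribution
#' mixes a point mass on bin 1 with the uniform distribution
#' (`pi = dispersion * uniform + (1 - dispersion) * point`), so its entropy
#' (hence Hs) grows with `dispersion`. The kernel mixes the identity
#' (self-transition-dominant) with rows all equal to the stationary
#' distribution (`K = (1 - randomness) * I + randomness * 1 pi'`), so the
#' chain's conditional entropy (hence Ht) grows with `randomness`, and `pi`
#' is exactly stationary for `K`.
#'
#' @param n_bins Number of bins (>= 2).
#' @param dispersion,randomness Dials in `[0, 1]`.
#' @return List with `stationary` (probability vector) and `kernel`
#'   (row-stochastic matrix).
#' @export
make_transition_kernel <- function(n_bins, dispersion, randomness) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (dispersion < 0 || dispersion > 1 || randomness < 0 || randomness > 1)
    stop("dispersion and randomness must lie in [0, 1]")
  stationary <- rep(dispersion / n_bins, n_bins)
  stationary[1L] <- stationary[1L] + (1 - dispersion)
  kernel <- (1 - randomness) * diag(n_bins) +
    randomness * matrix(stationary, n_bins, n_bins, byrow = TRUE)
  rs <- rowSums(kernel)
  if (any(abs(rs - 1) > 1e-6))
    warning("kernel rows required renormalisation beyond 1e-6")
  kernel <- kernel / rs
  list(stationary = stationary, kernel = kernel)
}

#' Analytic entropy rate of a Markov chain (bits)
#'
#' The conditional entropy `-sum_i pi_i sum_j K_ij log2 K_ij`: the population
#' quantity that the empirical transition entropy Ht estimates.
#'
#' @param stationary Stationary probability vector.
#' @param kernel Row-stochastic transition matrix.
#' @return Entropy rate in bits.
#' @export
chain_entropy <- function(stationary, kernel) {
  row_h <- apply(kernel, 1L, function(r) {
    nz <- r > 0
    -sum(r[nz] * log2(r[nz]))
  })
  sum(stationary * row_h)
}

# Closed-form normalised entropies of the two-parameter kernel family, using
# its two-row-type structure; vectorised over (dispersion, randomness).
# Verified against chain_entropy()/make_transition_kernel() in the tests.
kernel_entropies <- function(n_bins, dispersion, randomness) {
  plog2 <- function(q) ifelse(q > 0, q * log2(q), 0)
  po <- dispersion / n_bins                 # mass on each bin other than 1
  p1 <- po + (1 - dispersion)               # mass on bin 1
  Hs <- -(plog2(p1) + (n_bins - 1) * plog2(po))
  r <- randomness
  # row 1: diagonal entry r*p1 + 1-r, off-diagonal entries r*po (n-1 of them)
  h1 <- -(plog2(r * p1 + 1 - r) + (n_bins - 1) * plog2(r * po))
  # rows i != 1: entry r*p1 at column 1, diagonal r*po + 1-r, rest r*po
  ho <- -(plog2(r * p1) + plog2(r * po + 1 - r) +
            (n_bins - 2) * plog2(r * po))
  Ht <- p1 * h1 + (1 - p1) * ho
  list(Hs_norm = Hs / log2(n_bins), Ht_norm = Ht / log2(n_bins))
}

#' Simulate a fixation sequence from a Markov chain over bins
#'
#' Realises the bin chain from its stationary distribution, places each
#' fixation uniformly inside its bin's rectangle, and attaches plausible
#' durations (gamma, mean ~0.4 s) and strictly increasing onsets.
#'
#' @param stationary,kernel As returned by [make_transition_kernel()].
#' @param n_fixations Number of fixations (>= 2; transition entropy is
#'   undefined below that).
#' @param grid A [bin_grid()] with `n_bins` matching the kernel.
#' @return A [fixation_sequence()] with attribute `bins` (the generating bin
#'   sequence).
#' @export
generate_fixation_sequence <- function(stationary, kernel, n_fixations,
                                       grid) {
  if (n_fixations < 2L)
    stop("at least 2 fixations are required (transition entropy undefined)")
  n_bins <- length(stationary)
  if (grid$n_bins != n_bins) stop("grid does not match kernel dimension")
  bins <- integer(n_fixations)
  bins[1L] <- sample.int(n_bins, 1L, prob = stationary)
  for (t in 2:n_fixations)
    bins[t] <- sample.int(n_bins, 1L, prob = kernel[bins[t - 1L], ])
  col <- (bins - 1L) %% grid$n_cols + 1L
  row <- (bins - 1L) %/% grid$n_cols + 1L
  x <- stats::runif(n_fixations, grid$x_edges[col], grid$x_edges[col + 1L])
  y <- stats::runif(n_fixations, grid$y_edges[row], grid$y_edges[row + 1L])
  duration <- stats::rgamma(n_fixations, shape = 4, rate = 10)
  onset <- cumsum(c(0, duration[-n_fixations] + 0.03))
  out <- fixation_sequence(onset, duration, x, y)
  attr(out, "bins") <- bins
  out
}

#' Simulate a raw binocular pupil trace
#'
#' Left and right diameters are a shared baseline plus workload shift plus a
#' shared slow AR(1) drift (SD `pupil_noise_sd`), with small independent
#' per-eye noise. Blink events (Poisson at `blink_rate`/min, duration
#' `blink_duration` ms) invalidate both eyes simultaneously; their samples
#' are set to `NA`, with the validity flag authoritative.
#'
#' @param cfg A [sim_config()] (fields `sample_rate`, `trace_duration`,
#'   `pupil_baseline`, `pupil_noise_sd`, `blink_rate`, `blink_duration`).
#' @param workload_shift Additive diameter shift in mm (e.g. cognitive-load
#'   dilation).
#' @return A [pupil_trace()].
#' @export
generate_pupil_trace <- function(cfg, workload_shift = 0) {
  n <- round(cfg$sample_rate * cfg$trace_duration)
  if (n < 10L) stop("trace must contain at least 10 samples")
  t <- (seq_len(n) - 1L) / cfg$sample_rate
  level <- cfg$pupil_baseline + workload_shift
  if (cfg$pupil_noise_sd > 0) {
    rho <- exp(-1 / cfg$sample_rate)         # ~1 s drift time constant (hippus-like)
    e <- stats::rnorm(n, 0, cfg$pupil_noise_sd * sqrt(1 - rho^2))
    drift <- as.numeric(stats::filter(e, rho, method = "recursive",
                                      init = stats::rnorm(1, 0, cfg$pupil_noise_sd)))
    eye_sd <- cfg$pupil_noise_sd / 5
    left <- level + drift + stats::rnorm(n, 0, eye_sd)
    right <- level + drift + stats::rnorm(n, 0, eye_sd)
  } else {
    left <- right <- rep(level, n)
  }
  valid <- rep(TRUE, n)
  if (cfg$blink_rate > 0) {
    n_blinks <- stats::rpois(1L, cfg$blink_rate * cfg$trace_duration / 60)
    span <- max(1L, round(cfg$blink_duration / 1000 * cfg$sample_rate))
    if (n_blinks > 0) {
      starts <- sort(sample.int(n, n_blinks, replace = TRUE))
      for (s in starts) valid[s:min(n, s + span - 1L)] <- FALSE
    }
    if (!any(valid)) stop("blink spans cover the entire trace")
    left[!valid] <- NA_real_
    right[!valid] <- NA_real_
  }
  pupil_trace(t, left, right, valid)
}

#' Generate a synthetic eye-tracking study
#'
#' Draws per-trial generator dials (dispersion, randomness, pupil shift) per
#' load condition, computes the *true* trial features analytically from the
#' generating kernel family (normalised Hs and Ht, mean diameter Dm),
#' standardises them across the dataset, and draws each trial's collision
#' outcome from `Bernoulli(plogis(X beta + u))` where `u` is the
#' participant's random log-odds shift. Trials that produced a collision are
#' labelled with the short time-to-collision criticality (`ttc3`; collisions
#' occur only there), and the remaining half-quota of `ttc3` labels is
#' filled at random, the rest being `ttc5`.
#'
#' With the default coefficients the overall collision prevalence is ~10%.
#' The truth table doubles as the oracle for feature-estimation tests; raw
#' fixation sequences and pupil traces matching each trial's dials are
#' generated when `raw = TRUE`.
#'
#' @param cfg A [sim_config()].
#' @param raw If `TRUE`, also generate raw per-trial signals (slower).
#' @return List with `truth` (per-trial feature/outcome data frame), `raw`
#'   (list of per-trial signal lists, or `NULL`) and `config`.
#' @export
generate_dataset <- function(cfg, raw = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  P <- cfg$n_participants
  Tn <- cfg$trials_per_participant
  n <- P * Tn
  participant_id <- rep(seq_len(P), each = Tn)
  trial_id <- paste0("p", sprintf("%02d", participant_id), "_t",
                     rep(seq_len(Tn), P))
  # one drive without load, one with; half the trials each
  load <- rep(rep(c("no_load", "high_load"),
                  c(ceiling(Tn / 2), floor(Tn / 2))), P)
  high <- load == "high_load"

  clamp01 <- function(v) pmin(pmax(v, 0.02), 1)
  disp <- clamp01(stats::rnorm(n, cfg$dispersion +
                                 cfg$load_dispersion_effect * high,
                               cfg$dial_sd))
  rand <- clamp01(stats::rnorm(n, cfg$randomness, cfg$dial_sd))
  n_bins <- cfg$grid_rows * cfg$grid_cols
  ent <- kernel_entropies(n_bins, disp, rand)
  Dm_true <- cfg$pupil_baseline + cfg$load_pupil_effect * high +
    stats::rnorm(n, 0, cfg$pupil_trial_sd)

  Ht_z <- zscore(ent$Ht_norm, "Ht")
  Hs_z <- zscore(ent$Hs_norm, "Hs")
  Dm_z <- zscore(Dm_true, "Dm")
  X <- cbind(1, Ht_z, Hs_z, Dm_z, Ht_z * Hs_z, Ht_z * Dm_z, Hs_z * Dm_z,
             Ht_z * Hs_z * Dm_z)
  u <- stats::rnorm(P, 0, cfg$cluster_sd)
  eta <- drop(X %*% cfg$beta) + u[participant_id]
  collision <- stats::rbinom(n, 1L, stats::plogis(eta))

  # collisions only on short-TTC trials; fill the ttc3 quota at random
  criticality <- rep("ttc5", n)
  quota <- ceiling(Tn / 2)
  for (p in seq_len(P)) {
    idx <- which(participant_id == p)
    hit <- idx[collision[idx] == 1L]
    criticality[hit] <- "ttc3"
    need <- quota - length(hit)
    if (need > 0) {
      pool <- idx[collision[idx] == 0L]
      criticality[sample(pool, min(need, length(pool)))] <- "ttc3"
    }
  }

  truth <- data.frame(participant_id = participant_id, trial_id = trial_id,
                      load = load, criticality = criticality,
                      dispersion = disp, randomness = rand,
                      Ht_true = ent$Ht_norm, Hs_true = ent$Hs_norm,
                      Dm_true = Dm_true,
                      Ht_z = Ht_z, Hs_z = Hs_z, Dm_z = Dm_z,
                      collision = collision,
                      stringsAsFactors = FALSE)

  raw_trials <- NULL
  if (raw) {
    grid <- bin_grid_regular(cfg$grid_rows, cfg$grid_cols)
    raw_trials <- vector("list", n)
    for (i in seq_len(n)) {
      mk <- make_transition_kernel(n_bins, disp[i], rand[i])
      raw_trials[[i]] <- list(
        participant_id = participant_id[i], trial_id = trial_id[i],
        load = load[i], criticality = criticality[i],
        fixations = generate_fixation_sequence(mk$stationary, mk$kernel,
                                               cfg$n_fixations, grid),
        pupil = generate_pupil_trace(cfg, Dm_true[i] - cfg$pupil_baseline),
        collision = collision[i] == 1L)
    }
  }
  list(truth = truth, raw = raw_trials, config = cfg)
}
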