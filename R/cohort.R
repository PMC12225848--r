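REGIONS <- c("MTL", "PFC", "OFC")
CONDITIONS <- c("identity", "spatial", "temporal")

#' Describe a planted directed coupling
#'
#' A single off-diagonal MVAR coefficient inserted into the generative model,
#' active only in the listed task conditions. It is the ground truth that the
#' DTF stage is expected to recover.
#'
#' @param source_channel,target_channel 1-based channel indices (must differ).
#' @param lag lag in samples at which the coupling acts.
#' @param gain dimensionless autoregressive coefficient; must leave the full
#'   generative model stable (checked at model-build time).
#' @param conditions character subset of `c("identity","spatial","temporal")`
#'   in which the coupling is switched on.
#' @return An object of class `planted_coupling`.
#' @export
planted_coupling <- function(source_channel, target_channel, lag = 1L,
                             gain = 0.06, conditions = "spatial") {
  if (source_channel == target_channel)
    stop("planted coupling must connect two distinct channels")
  if (lag < 1L) stop("lag must be a positive number of samples")
  if (!all(conditions %in% CONDITIONS))
    stop("conditions must be a subset of ", paste(CONDITIONS, collapse = ", "))
  structure(list(source_channel = as.integer(source_channel),
                 target_channel = as.integer(target_channel),
                 lag = as.integer(lag), gain = gain,
                 conditions = conditions),
            class = "planted_coupling")
}

#' Specify a synthetic cohort
#'
#' The cohort emulates a multi-subject working-memory iEEG session: each
#' subject contributes channels in three regions (MTL, PFC, OFC) and a set of
#' trial epochs per condition, generated from stable band-tuned MVAR models
#' with known directed couplings.
#'
#' Each channel carries a damped-oscillator AR(2) core resonating at its
#' region's node frequency; couplings add off-diagonal MVAR coefficients in
#' the conditions where they are active. Reaction times follow
#' `base_ms - effect_ms * [any coupling active in the condition] + N(0, noise_sd_ms)`,
#' truncated at 100 ms.
#'
#' @param n_subjects number of subjects.
#' @param channels_per_region named integer vector (MTL, PFC, OFC) of mean
#'   channel counts per subject; per-subject counts are drawn around these
#'   with `channel_sd` (minimum 1 per region).
#' @param channel_sd SD of the per-subject channel-count draw (0 = fixed).
#' @param trials_per_condition named (or scalar) mean trial count per
#'   condition; drawn per subject with SD `trial_sd`.
#' @param trial_sd SD of the trial-count draw.
#' @param conditions conditions to generate (default all three).
#' @param sampling_rate Hz.
#' @param window_length analysis-window length in seconds.
#' @param node_frequencies named vector of per-region AR(2) resonance (Hz).
#' @param damping AR(2) pole radius in (0, 1).
#' @param coupling_edges list of [planted_coupling()] objects (channel indices
#'   refer to the subject channel layout implied by `channels_per_region`
#'   means; subjects whose drawn layout lacks a channel drop that edge).
#' @param rt_model numeric `c(base_ms, effect_ms, noise_sd_ms)`.
#' @param accuracy probability a trial is answered correctly.
#' @param burn_in samples discarded before the analysis window (>= 500).
#' @param seed integer seed making the cohort fully reproducible.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 8L,
                        channels_per_region = c(MTL = 2L, PFC = 3L, OFC = 3L),
                        channel_sd = 0,
                        trials_per_condition = c(identity = 34, spatial = 35,
                                                 temporal = 33),
                        trial_sd = 3,
                        conditions = CONDITIONS,
                        sampling_rate = 250,
                        window_length = 0.6,
                        node_frequencies = c(MTL = 6, PFC = 6, OFC = 6),
                        damping = 0.92,
                        coupling_edges = list(
                          planted_coupling(source_channel = 1L,
                                           target_channel = 3L,
                                           lag = 1L, gain = 0.06,
                                           conditions = "spatial")),
                        rt_model = c(base_ms = 800, effect_ms = 150,
                                     noise_sd_ms = 150),
                        accuracy = 0.88,
                        burn_in = 500L,
                        seed = 1L) {
  spec <- structure(list(
    n_subjects = as.integer(n_subjects),
    channels_per_region = channels_per_region,
    channel_sd = channel_sd,
    trials_per_condition = trials_per_condition,
    trial_sd = trial_sd,
    conditions = conditions,
    sampling_rate = sampling_rate,
    window_length = window_length,
    node_frequencies = node_frequencies,
    damping = damping,
    coupling_edges = coupling_edges,
    rt_model = rt_model,
    accuracy = accuracy,
    burn_in = as.integer(burn_in),
    seed = as.integer(seed)), class = "cohort_spec")
  validate_cohort_spec(spec, warn = TRUE)
  spec
}

validate_cohort_spec <- function(spec, warn = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_subjects < 1L) stop("n_subjects must be >= 1")
  if (!all(REGIONS %in% names(spec$channels_per_region)))
    stop("channels_per_region must name MTL, PFC and OFC")
  if (any(spec$channels_per_region < 1))
    stop("at least one channel per region is required")
  if (spec$damping <= 0 || spec$damping >= 1)
    stop("damping (pole radius) must lie in (0, 1)")
  if (any(spec$node_frequencies >= spec$sampling_rate / 2))
    stop("node frequencies must be below Nyquist (fs/2)")
  if (!all(spec$conditions %in% CONDITIONS))
    stop("unknown condition name")
  if (spec$burn_in < 500L) stop("burn_in must be >= 500 samples")
  n_samples <- round(spec$sampling_rate * spec$window_length)
  k <- sum(spec$channels_per_region)
  if (n_samples <= 10 * k)
    stop("window too short: ", n_samples, " samples for ", k,
         " channels; MVAR fit not identifiable")
  if (warn && n_samples < 50 * k)
    warning("fewer than 50 samples per channel (", n_samples, " for ", k,
            " channels); MVAR estimates will be noisy", call. = FALSE)
  invisible(spec)
}

#' AR(2) coefficients of a damped oscillator
#'
#' Places a complex-conjugate pole pair at radius `r` and angle
#' `2*pi*f0/fs`, so a realization has a spectral peak near `f0`:
#' `a1 = 2 r cos(2 pi f0 / fs)`, `a2 = -r^2`.
#'
#' @param f0 resonance frequency in Hz, `0 < f0 < fs/2`.
#' @param r pole radius in (0, 1); closer to 1 means a sharper peak.
#' @param fs sampling rate in Hz.
#' @return Numeric `c(a1, a2)`.
#' @export
ar2_coefficients <- function(f0, r, fs) {
  if (f0 <= 0 || f0 >= fs / 2)
    stop("resonance frequency must satisfy 0 < f0 < fs/2 (aliasing)")
  if (r <= 0 || r >= 1)
    stop("pole radius must lie in (0, 1) for a stable AR(2)")
  c(a1 = 2 * r * cos(2 * pi * f0 / fs), a2 = -r^2)
}

companion_matrix <- function(A) {
  # A: k x k x p coefficient array
  k <- dim(A)[1]; p <- dim(A)[3]
  M <- matrix(0, k * p, k * p)
  for (m in seq_len(p)) M[1:k, ((m - 1) * k + 1):(m * k)] <- A[, , m]
  if (p > 1) M[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  M
}

spectral_radius <- function(M) max(Mod(eigen(M, only.values = TRUE)$values))

#' Build the generative MVAR for one condition
#'
#' Every channel receives an AR(2) diagonal core at its region's node
#' frequency; planted couplings active in `condition` add off-diagonal
#' coefficients. The result is checked for stability (companion spectral
#' radius < 1).
#'
#' @param spec a [cohort_spec()].
#' @param condition condition whose active couplings are inserted.
#' @param channel_regions optional per-channel region labels; defaults to the
#'   layout implied by `spec$channels_per_region`.
#' @return List with `A` (k x k x p array), `noise_cov` (identity), and
#'   `channel_regions`.
#' @export
build_generative_var <- function(spec, condition,
                                 channel_regions = NULL) {
  validate_cohort_spec(spec)
  if (is.null(channel_regions))
    channel_regions <- rep(REGIONS, times = spec$channels_per_region[REGIONS])
  k <- length(channel_regions)
  edges <- Filter(function(e) condition %in% e$conditions &&
                    e$source_channel <= k && e$target_channel <= k,
                  spec$coupling_edges)
  p <- max(2L, if (length(edges)) max(vapply(edges, `[[`, 1L, "lag")) else 2L)
  A <- array(0, dim = c(k, k, p))
  for (ch in seq_len(k)) {
    a <- ar2_coefficients(spec$node_frequencies[[channel_regions[ch]]],
                          spec$damping, spec$sampling_rate)
    A[ch, ch, 1] <- a[1]
    A[ch, ch, 2] <- a[2]
  }
  for (e in edges) A[e$target_channel, e$source_channel, e$lag] <-
    A[e$target_channel, e$source_channel, e$lag] + e$gain
  rho <- spectral_radius(companion_matrix(A))
  if (rho >= 1) {
    desc <- paste(vapply(edges, function(e)
      sprintf("%d->%d (gain %.3g)", e$source_channel, e$target_channel,
              e$gain), ""), collapse = ", ")
    stop("generative MVAR unstable (spectral radius ", signif(rho, 4),
         ") after inserting couplings: ", desc)
  }
  list(A = A, noise_cov = diag(k), channel_regions = channel_regions)
}

#' Simulate a stationary MVAR realization
#'
#' @param A k x k x p coefficient array.
#' @param n_samples samples returned after discarding `burn_in`.
#' @param burn_in initial samples dropped (zero initial condition).
#' @param noise_sd innovation standard deviation (white, uncorrelated).
#' @return k x n_samples matrix.
#' @export
simulate_var_process <- function(A, n_samples, burn_in = 500L, noise_sd = 1) {
  k <- dim(A)[1]; p <- dim(A)[3]
  total <- n_samples + burn_in
  X <- matrix(0, k, total + p)
  E <- matrix(stats::rnorm(k * total, sd = noise_sd), k, total)
  for (t in seq_len(total)) {
    tt <- t + p
    acc <- E[, t]
    for (m in seq_len(p)) acc <- acc + A[, , m] %*% X[, tt - m]
    X[, tt] <- acc
  }
  X[, (p + burn_in + 1):(p + total), drop = FALSE]
}

draw_count <- function(mean, sd, minimum = 1L) {
  max(minimum, as.integer(round(stats::rnorm(1, mean, sd))))
}

#' Generate a synthetic cohort
#'
#' Simulates every subject and trial of the cohort described by `spec`.
#' Trial counts per condition are drawn around the specified means, each
#' trial is an independent realization of the condition's generative MVAR
#' (burn-in discarded), and reaction times / correctness are drawn from the
#' spec's behavioural model. Fully reproducible from `spec$seed`.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `cohort` with elements `trials` (list of
#'   `trial_recording`), `ground_truth` (planted edges and rt model),
#'   and `spec`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  n_samples <- round(spec$sampling_rate * spec$window_length)
  tpc <- spec$trials_per_condition
  if (length(tpc) == 1L && is.null(names(tpc)))
    tpc <- stats::setNames(rep(tpc, length(spec$conditions)), spec$conditions)
  rt <- spec$rt_model
  trials <- list()
  for (s in seq_len(spec$n_subjects)) {
    counts <- vapply(REGIONS, function(rg)
      draw_count(spec$channels_per_region[[rg]], spec$channel_sd), 1L)
    channel_regions <- rep(REGIONS, times = counts)
    models <- lapply(spec$conditions, function(cond)
      build_generative_var(spec, cond, channel_regions))
    names(models) <- spec$conditions
    for (cond in spec$conditions) {
      n_tr <- draw_count(tpc[[cond]], spec$trial_sd, minimum = 5L)
      active <- any(vapply(spec$coupling_edges, function(e)
        cond %in% e$conditions, TRUE))
      for (tr in seq_len(n_tr)) {
        data <- simulate_var_process(models[[cond]]$A, n_samples,
                                     burn_in = spec$burn_in)
        rt_ms <- rt[["base_ms"]] - rt[["effect_ms"]] * as.numeric(active) +
          stats::rnorm(1, 0, rt[["noise_sd_ms"]])
        rt_ms <- max(100, rt_ms)
        trials[[length(trials) + 1L]] <- trial_recording(
          data = data, condition = cond, rt = rt_ms,
          correct = stats::runif(1) < spec$accuracy,
          subject_id = s, channel_regions = channel_regions,
          sampling_rate = spec$sampling_rate)
      }
    }
  }
  structure(list(trials = trials,
                 ground_truth = list(coupling_edges = spec$coupling_edges,
                                     rt_model = spec$rt_model),
                 spec = spec), class = "cohort")
}

#' One trial epoch
#'
#' @param data channels x samples numeric matrix (finite).
#' @param condition one of identity / spatial / temporal.
#' @param rt reaction time in ms (> 0).
#' @param correct logical.
#' @param subject_id subject identifier.
#' @param channel_regions per-channel region label (MTL / PFC / OFC).
#' @param sampling_rate Hz.
#' @return Object of class `trial_recording`.
#' @export
trial_recording <- function(data, condition, rt, correct, subject_id,
                            channel_regions, sampling_rate) {
  if (!all(is.finite(data))) stop("trial data contain NaN/Inf")
  if (nrow(data) != length(channel_regions))
    stop("channel_regions length must match the number of channels")
  if (!all(REGIONS %in% channel_regions))
    stop("each trial needs at least one channel per region")
  structure(list(data = data, condition = condition, rt = rt,
                 correct = correct, subject_id = subject_id,
                 channel_regions = channel_regions,
                 sampling_rate = sampling_rate),
            class = "trial_recording")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$trials), "trials,",
      x$spec$n_subjects, "subjects,",
      length(x$spec$conditions), "conditions @",
      x$spec$sampling_rate, "Hz\n")
  invisible(x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}
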