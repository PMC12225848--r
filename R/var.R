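#' Frequency bands (Hz)
#'
#' Canonical band edges used throughout: theta 4-8, alpha 8-12, beta 12-30,
#' low-gamma 30-80, high-gamma 80-200. Intervals are half-open
#' `[low, high)` so a shared printed edge (e.g. 8 Hz) is counted once,
#' in the upper band.
#'
#' @export
dtf_bands <- list(theta = c(4, 8), alpha = c(8, 12), beta = c(12, 30),
                  low_gamma = c(30, 80), high_gamma = c(80, 200))

#' Fit a per-trial MVAR model with SBC order selection
#'
#' Channels are mean-centered per trial, then a vector autoregression
#' `X(t) = sum_m A(m) X(t-m) + E(t)` is fitted by ordinary least squares at
#' every candidate order `1..max_order` over a common effective sample
#' (observations `max_order+1 .. N`, so criteria are comparable across
#' orders). The order minimising Schwarz's Bayesian criterion,
#' `N_e log det(Sigma_hat(p)) + log(N_e) k^2 p`, is kept.
#'
#' @param trial a [trial_recording()], or a channels x samples matrix.
#' @param max_order largest candidate order; capped so that
#'   `k * order < samples / 3`.
#' @return Object of class `var_fit` with `coefficients` (k x k x p),
#'   `noise_cov`, `order`, `sbc_trace`, `n_samples_used`, `stable`, `fs`.
#' @export
fit_var <- function(trial, max_order = 15L) {
  X <- if (inherits(trial, "trial_recording")) trial$data else trial
  fs <- if (inherits(trial, "trial_recording")) trial$sampling_rate else NA_real_
  if (!all(is.finite(X))) stop("trial data contain non-finite values")
  k <- nrow(X); N <- ncol(X)
  max_order <- min(as.integer(max_order), as.integer(floor(N / (3 * k))))
  if (max_order < 1L)
    stop("too few samples (", N, ") to fit even order 1 with ", k, " channels")
  if (N <= k * max_order + k) stop("too few samples for requested max_order")
  X <- X - rowMeans(X)
  n_eff <- N - max_order
  Y <- t(X[, (max_order + 1):N, drop = FALSE])         # n_eff x k responses
  # full lag matrix for the largest order; smaller orders use leading columns
  Z_full <- matrix(0, n_eff, k * max_order)
  for (m in seq_len(max_order))
    Z_full[, ((m - 1) * k + 1):(m * k)] <- t(X[, (max_order + 1 - m):(N - m),
                                               drop = FALSE])
  sbc <- rep(NA_real_, max_order)
  fits <- vector("list", max_order)
  for (p in seq_len(max_order)) {
    Z <- Z_full[, seq_len(k * p), drop = FALSE]
    qz <- qr(Z)
    if (qz$rank < ncol(Z))
      stop("singular MVAR fit: rank-deficient regressor matrix ",
           "(constant or collinear channel?)")
    B <- qr.coef(qz, Y)                                 # (k*p) x k
    Res <- Y - Z %*% B
    Sigma_ml <- crossprod(Res) / n_eff
    ld <- determinant(Sigma_ml, logarithm = TRUE)
    if (ld$sign <= 0) {
      sbc[p] <- Inf
    } else {
      sbc[p] <- n_eff * as.numeric(ld$modulus) + log(n_eff) * k * k * p
    }
    fits[[p]] <- list(B = B, Res = Res)
  }
  p_opt <- which.min(sbc)
  B <- fits[[p_opt]]$B
  A <- array(0, dim = c(k, k, p_opt))
  for (m in seq_len(p_opt))
    A[, , m] <- t(B[((m - 1) * k + 1):(m * k), , drop = FALSE])
  dof <- n_eff - k * p_opt
  noise_cov <- crossprod(fits[[p_opt]]$Res) / max(1L, dof)
  stable <- spectral_radius(companion_matrix(A)) < 1
  structure(list(coefficients = A, noise_cov = noise_cov,
                 order = as.integer(p_opt), sbc_trace = sbc,
                 n_samples_used = n_eff, stable = stable, fs = fs),
            class = "var_fit")
}

#' Spectral transfer matrix of a fitted MVAR
#'
#' Forms `A(f) = I - sum_m A(m) exp(-i 2 pi f m / fs)` on the requested
#' frequency grid and inverts it to the transfer matrix `H(f) = A(f)^-1`,
#' through which the innovation noise is filtered into the observed process.
#'
#' @param fit a `var_fit` (or a list with `coefficients` and `fs`).
#' @param freqs frequency grid in Hz, within `(0, fs/2]`.
#' @param fs sampling rate (taken from `fit` when present).
#' @return Object of class `transfer_spectrum` with `freqs`, `H` and `A_of_f`
#'   (both k x k x nfreq complex arrays).
#' @export
transfer_spectrum <- function(fit, freqs = NULL, fs = NULL) {
  A <- fit$coefficients
  fs <- fs %||% fit$fs
  if (is.null(fs) || is.na(fs)) stop("sampling rate unknown; pass fs")
  if (is.null(freqs)) freqs <- seq(1, fs / 2)
  if (any(freqs <= 0) || any(freqs > fs / 2))
    stop("frequencies must lie in (0, fs/2]")
  k <- dim(A)[1]; p <- dim(A)[3]; nf <- length(freqs)
  H <- array(complex(real = 0), dim = c(k, k, nf))
  Af <- array(complex(real = 0), dim = c(k, k, nf))
  for (if_ in seq_len(nf)) {
    f <- freqs[if_]
    Afreq <- diag(k) + 0i
    for (m in seq_len(p))
      Afreq <- Afreq - A[, , m] * exp(-2i * pi * f * m / fs)
    Af[, , if_] <- Afreq
    Hf <- tryCatch(solve(Afreq), error = function(e) NULL)
    if (is.null(Hf))
      stop("transfer matrix singular at f = ", f, " Hz")
    H[, , if_] <- Hf
  }
  structure(list(freqs = freqs, H = H, A_of_f = Af, fs = fs),
            class = "transfer_spectrum")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Squared directed transfer function
#'
#' Row-normalized squared transfer magnitudes: entry `(i, j)` at frequency
#' `f` is `|H_ij(f)|^2 / sum_m |H_im(f)|^2`, the directed influence of source
#' channel `j` on target channel `i`. Rows sum to one at every frequency.
#'
#' @param ts a [transfer_spectrum()].
#' @return k x k x nfreq array of DTF-squared values in `[0, 1]`.
#' @export
dtf_squared <- function(ts) {
  H2 <- Mod(ts$H)^2
  k <- dim(H2)[1]; nf <- dim(H2)[3]
  out <- H2
  for (if_ in seq_len(nf)) {
    rs <- rowSums(H2[, , if_, drop = FALSE][, , 1])
    if (any(rs == 0))
      stop("all-zero transfer row at f = ", ts$freqs[if_],
           " Hz; DTF undefined")
    out[, , if_] <- H2[, , if_] / rs
  }
  out
}

#' Band-averaged DTF connectivity matrix
#'
#' Arithmetic mean of the DTF-squared matrices over the grid frequencies in
#' the half-open band `[low, high)`.
#'
#' @param dtf k x k x nfreq array from [dtf_squared()].
#' @param freqs the frequency grid matching `dtf`'s third dimension.
#' @param band band name (see [dtf_bands]) or numeric `c(low, high)`.
#' @param fs sampling rate, used to reject bands above Nyquist.
#' @return Object of class `band_connectivity`: `C` (k x k), `band`, `edges`.
#' @export
band_average <- function(dtf, freqs, band, fs = NULL) {
  edges <- if (is.character(band)) {
    if (!band %in% names(dtf_bands)) stop("unknown band: ", band)
    dtf_bands[[band]]
  } else band
  if (!is.null(fs) && edges[2] > fs / 2)
    stop("band [", edges[1], ", ", edges[2], ") extends above Nyquist (fs/2 = ",
         fs / 2, " Hz)")
  mask <- freqs >= edges[1] & freqs < edges[2]
  if (!any(mask))
    stop("no grid frequencies inside band [", edges[1], ", ", edges[2], ")")
  C <- apply(dtf[, , mask, drop = FALSE], c(1, 2), mean)
  structure(list(C = C,
                 band = if (is.character(band)) band else
                   paste0(edges[1], "-", edges[2], "Hz"),
                 edges = edges, n_freqs = sum(mask)),
            class = "band_connectivity")
}

#' Per-trial band connectivity, end to end
#'
#' Convenience wrapper: MVAR fit, transfer spectrum on a 1-Hz grid, DTF
#' squared, and band averages.
#'
#' @param trial a [trial_recording()].
#' @param bands character vector of band names.
#' @param max_order passed to [fit_var()].
#' @return Named list of `band_connectivity` objects.
#' @export
trial_connectivity <- function(trial, bands = "theta", max_order = 15L) {
  fit <- fit_var(trial, max_order = max_order)
  fs <- trial$sampling_rate
  top <- max(vapply(bands, function(b) dtf_bands[[b]][2], 0))
  if (top > fs / 2)
    stop("band(s) above Nyquist for fs = ", fs, " Hz")
  ts <- transfer_spectrum(fit, freqs = seq(1, fs / 2), fs = fs)
  d <- dtf_squared(ts)
  out <- lapply(bands, function(b) band_average(d, ts$freqs, b, fs = fs))
  names(out) <- bands
  out
}
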