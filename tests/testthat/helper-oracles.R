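# Independent oracles used across tests. These deliberately avoid the code
# paths they check: cofactor inversion instead of solve(), matrix-power path
# counting instead of Brandes, power iteration instead of eigen().

# Adjugate (cofactor) inverse for complex matrices up to 3x3.
adjugate_inverse <- function(M) {
  k <- nrow(M)
  if (k == 1) return(matrix(1 / M[1, 1], 1, 1))
  if (k == 2) {
    det <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
    return(matrix(c(M[2, 2], -M[2, 1], -M[1, 2], M[1, 1]), 2, 2) / det)
  }
  cof <- matrix(0i, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    m <- M[-i, -j]
    cof[i, j] <- (-1)^(i + j) * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])
  }
  det <- sum(M[1, ] * cof[1, ])
  t(cof) / det
}

# Brute-force DTF^2 from a coefficient array, via cofactor inversion.
dtf_oracle <- function(A, fs, freqs) {
  k <- dim(A)[1]; p <- dim(A)[3]
  out <- array(0, dim = c(k, k, length(freqs)))
  for (fi in seq_along(freqs)) {
    Af <- diag(k) + 0i
    for (m in seq_len(p))
      Af <- Af - A[, , m] * exp(-2i * pi * freqs[fi] * m / fs)
    H2 <- Mod(adjugate_inverse(Af))^2
    out[, , fi] <- H2 / rowSums(H2)
  }
  out
}

# Shortest-path betweenness by matrix-power path counting:
# sigma_ij = (M^d(i,j))[i,j]; a shortest path i->j passes v iff
# d(i,v) + d(v,j) = d(i,j), contributing sigma_iv * sigma_vj paths.
bc_oracle <- function(mask) {
  # mask[i, j] = edge source j -> target i; build successor matrix S[i, j] =
  # 1 if edge i -> j
  S <- t(mask)
  k <- nrow(S)
  pows <- list(diag(k))
  for (L in 1:k) pows[[L + 1]] <- pows[[L]] %*% S
  dist <- matrix(Inf, k, k); diag(dist) <- 0
  sigma <- matrix(0, k, k); diag(sigma) <- 1
  for (i in 1:k) for (j in 1:k) {
    if (i == j) next
    for (L in 1:k) {
      if (pows[[L + 1]][i, j] > 0) {
        dist[i, j] <- L
        sigma[i, j] <- pows[[L + 1]][i, j]
        break
      }
    }
  }
  bc <- numeric(k)
  for (v in 1:k) for (i in 1:k) for (j in 1:k) {
    if (i == j || i == v || j == v) next
    if (is.finite(dist[i, j]) &&
        is.finite(dist[i, v]) && is.finite(dist[v, j]) &&
        dist[i, v] + dist[v, j] == dist[i, j])
      bc[v] <- bc[v] + sigma[i, v] * sigma[v, j] / sigma[i, j]
  }
  bc
}

# Local clustering on the symmetrized binary graph, by neighbor enumeration.
cc_oracle <- function(mask) {
  S <- (mask | t(mask)) * 1
  diag(S) <- 0
  k <- nrow(S)
  sapply(seq_len(k), function(i) {
    nb <- which(S[i, ] == 1)
    if (length(nb) < 2) return(0)
    links <- 0
    for (pair in utils::combn(nb, 2, simplify = FALSE))
      links <- links + S[pair[1], pair[2]]
    2 * links / (length(nb) * (length(nb) - 1))
  })
}

# Power-iteration eigenvector centrality on (W + t(W)) / 2. A positive
# spectral shift makes the Perron eigenvalue strictly dominant so the
# iteration cannot oscillate between +/- eigenpairs of equal magnitude.
ec_oracle <- function(W, tol = 1e-13, max_iter = 100000) {
  S <- (W + t(W)) / 2
  if (all(S == 0)) return(numeric(nrow(S)))
  shift <- sum(abs(S)) + 1
  Ssh <- S + diag(shift, nrow(S))
  x <- rep(1, nrow(S)) / sqrt(nrow(S))
  for (i in seq_len(max_iter)) {
    x_new <- drop(Ssh %*% x)
    x_new <- x_new / sqrt(sum(x_new^2))
    if (max(abs(x_new - x)) < tol) break
    x <- x_new
  }
  v <- abs(x_new)
  v[v < 1e-12] <- 0
  v / sqrt(sum(v^2))
}

# Random stable VAR coefficient array (rescaled until companion radius < 1).
random_stable_var <- function(k, p, sd = 0.3) {
  repeat {
    A <- array(stats::rnorm(k * k * p, sd = sd), dim = c(k, k, p))
    M <- matrix(0, k * p, k * p)
    for (m in seq_len(p)) M[1:k, ((m - 1) * k + 1):(m * k)] <- A[, , m]
    if (p > 1) M[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
    rho <- max(Mod(eigen(M, only.values = TRUE)$values))
    if (rho < 0.95) return(A)
    sd <- sd * 0.7
  }
}

# Random weighted directed graph as a thresholded_graph-compatible object.
random_digraph <- function(k, density = 0.4) {
  W <- matrix(stats::runif(k * k), k, k) *
    (matrix(stats::runif(k * k), k, k) < density)
  diag(W) <- 0
  structure(list(weights = W, mask = (W > 0) * 1L, pth = NA,
                 density = sum(W > 0) / (k * (k - 1)),
                 n_edges = sum(W > 0)),
            class = "thresholded_graph")
}

# Small deterministic cohort used by several tests.
tiny_cohort <- function(seed = 1, trials = 15, conditions = c("identity",
                                                              "spatial"),
                        gain = 0.06, accuracy = 1) {
  spec <- suppressWarnings(cohort_spec(
    n_subjects = 1, channels_per_region = c(MTL = 2, PFC = 2, OFC = 2),
    trials_per_condition = trials, trial_sd = 0, conditions = conditions,
    coupling_edges = list(planted_coupling(1, 3, 1, gain, "spatial")),
    accuracy = accuracy, seed = seed))
  generate_cohort(spec)
}
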