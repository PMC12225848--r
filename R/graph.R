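GRAPH_METRICS <- c("degree", "in_degree", "out_degree",
                   "strength", "in_strength", "out_strength",
                   "clustering_coefficient", "betweenness_centrality",
                   "eigenvector_centrality")

#' Proportional thresholding of a connectivity matrix
#'
#' Retains the `round(pth * k(k-1))` largest off-diagonal entries (ties at
#' the cutoff broken deterministically by value desc, then source index asc,
#' then target index asc) and zeroes the rest, so that every trial's graph
#' has the same edge density. Entry `(i, j)` is the edge source `j` ->
#' target `i`; the diagonal is never an edge.
#'
#' @param C a `band_connectivity` or a k x k numeric matrix.
#' @param pth retained fraction of directed edges, in `(0, 1]`.
#' @return Object of class `thresholded_graph` with `weights`, `mask`,
#'   `pth`, `density`, `n_edges`.
#' @export
proportional_threshold <- function(C, pth) {
  W <- if (inherits(C, "band_connectivity")) C$C else C
  k <- nrow(W)
  if (k < 2) stop("need at least 2 nodes")
  if (pth <= 0 || pth > 1) stop("pth must lie in (0, 1]")
  m <- k * (k - 1)
  n_keep <- floor(pth * m + 0.5)          # round half away from zero
  if (n_keep < 1) stop("pth = ", pth, " retains zero edges for k = ", k)
  off <- which(row(W) != col(W))
  tgt <- row(W)[off]; src <- col(W)[off]; val <- W[off]
  ord <- order(-val, src, tgt)
  keep <- off[ord[seq_len(n_keep)]]
  mask <- matrix(0L, k, k)
  mask[keep] <- 1L
  weights <- matrix(0, k, k)
  weights[keep] <- W[keep]
  structure(list(weights = weights, mask = mask, pth = pth,
                 density = n_keep / m, n_edges = n_keep),
            class = "thresholded_graph")
}

#' Degree metrics
#'
#' In-degree of node i counts retained edges arriving at i (row i of the
#' mask), out-degree counts edges leaving i (column i), degree is their sum.
#'
#' @param g a [proportional_threshold()] result.
#' @return List of numeric vectors `in_degree`, `out_degree`, `degree`.
#' @export
degree_metrics <- function(g) {
  ind <- rowSums(g$mask)
  outd <- colSums(g$mask)
  list(in_degree = ind, out_degree = outd, degree = ind + outd)
}

#' Strength metrics
#'
#' Same as [degree_metrics()] but summing the retained DTF weights rather
#' than counting edges.
#'
#' @param g a [proportional_threshold()] result.
#' @return List of numeric vectors `in_strength`, `out_strength`, `strength`.
#' @export
strength_metrics <- function(g) {
  ins <- rowSums(g$weights)
  outs <- colSums(g$weights)
  list(in_strength = ins, out_strength = outs, strength = ins + outs)
}

#' Clustering coefficient
#'
#' Watts-Strogatz local clustering on the binarized, symmetrized graph (an
#' undirected link exists if either direction survived thresholding): the
#' fraction of realized links among each node's neighbors. Nodes with fewer
#' than two neighbors get 0.
#'
#' @param g a [proportional_threshold()] result.
#' @return Numeric vector, one value in `[0, 1]` per node.
#' @export
clustering_coefficient <- function(g) {
  S <- (g$mask | t(g$mask)) * 1L
  diag(S) <- 0L
  k <- nrow(S)
  vapply(seq_len(k), function(i) {
    nb <- which(S[i, ] == 1L)
    n_i <- length(nb)
    if (n_i < 2) return(0)
    links <- sum(S[nb, nb]) / 2
    2 * links / (n_i * (n_i - 1))
  }, 0)
}

#' Betweenness centrality
#'
#' Directed shortest-path betweenness on the binary mask with unit edge
#' lengths (Brandes' accumulation): `BC(v) = sum over ordered pairs (s, t),
#' s != t != v, of sigma_st(v) / sigma_st`. Pairs with no connecting path
#' contribute 0. Values are raw (unnormalized) path-count ratios.
#'
#' @param g a [proportional_threshold()] result.
#' @return Numeric vector, one value per node.
#' @export
betweenness_centrality <- function(g) {
  M <- g$mask
  k <- nrow(M)
  adj <- lapply(seq_len(k), function(i) which(M[, i] == 1L)) # successors of i
  bc <- numeric(k)
  for (s in seq_len(k)) {
    sigma <- numeric(k); sigma[s] <- 1
    dist <- rep(-1L, k); dist[s] <- 0L
    preds <- vector("list", k)
    stack <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      stack <- c(stack, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(k)
    for (w in rev(stack)) {
      for (v in preds[[w]])
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the symmetrized weighted matrix
#' `(W + t(W)) / 2`, taken entrywise non-negative and scaled to unit
#' Euclidean norm. For a non-negative matrix the Perron root is the largest
#' eigenvalue, so nodes outside the dominant component score 0.
#'
#' @param g a [proportional_threshold()] result.
#' @return Numeric vector of non-negative scores with unit Euclidean norm
#'   (all zeros, with a warning, for an empty graph).
#' @export
eigenvector_centrality <- function(g) {
  S <- (g$weights + t(g$weights)) / 2
  if (all(S == 0)) {
    warning("empty graph: eigenvector centrality undefined, returning zeros")
    return(numeric(nrow(S)))
  }
  es <- eigen(S, symmetric = TRUE)
  v <- abs(es$vectors[, 1])
  v[v < 1e-12] <- 0
  v / sqrt(sum(v^2))
}

#' All nine node metrics
#'
#' @param g a [proportional_threshold()] result.
#' @return k x 9 matrix, columns in the canonical metric order (degree,
#'   in/out-degree, strength, in/out-strength, clustering coefficient,
#'   betweenness, eigenvector centrality).
#' @export
node_metrics <- function(g) {
  d <- degree_metrics(g)
  s <- strength_metrics(g)
  out <- cbind(degree = d$degree, in_degree = d$in_degree,
               out_degree = d$out_degree,
               strength = s$strength, in_strength = s$in_strength,
               out_strength = s$out_strength,
               clustering_coefficient = clustering_coefficient(g),
               betweenness_centrality = betweenness_centrality(g),
               eigenvector_centrality = suppressWarnings(
                 eigenvector_centrality(g)))
  out[, GRAPH_METRICS, drop = FALSE]
}

#' Region-averaged feature vector
#'
#' Averages each node metric over the channels of each region, yielding the
#' fixed-order 27-value feature vector (regions MTL, PFC, OFC x the nine
#' metrics), named `"<region>.<metric>"`.
#'
#' @param metrics k x 9 matrix from [node_metrics()].
#' @param channel_regions per-channel region label.
#' @return Named numeric vector of length 27.
#' @export
aggregate_regions <- function(metrics, channel_regions) {
  if (length(channel_regions) != nrow(metrics))
    stop("channel_regions length must match metric rows")
  vals <- numeric(0)
  for (rg in REGIONS) {
    idx <- which(channel_regions == rg)
    if (!length(idx)) stop("empty region: ", rg)
    m <- colMeans(metrics[idx, , drop = FALSE])
    names(m) <- paste(rg, GRAPH_METRICS, sep = ".")
    vals <- c(vals, m)
  }
  if (any(!is.finite(vals))) stop("non-finite feature value")
  vals
}

#' Per-trial 27-value feature vector
#'
#' @param C a `band_connectivity` (or k x k matrix).
#' @param channel_regions per-channel region labels.
#' @param pth proportional threshold.
#' @return Named numeric vector of length 27.
#' @export
trial_features <- function(C, channel_regions, pth = 0.2) {
  g <- proportional_threshold(C, pth)
  aggregate_regions(node_metrics(g), channel_regions)
}

#' Feature table for a whole cohort
#'
#' Computes band connectivity and the 27 region x metric features for every
#' trial of a cohort, at one or more proportional thresholds.
#'
#' @param cohort a [generate_cohort()] result.
#' @param bands band names to analyse.
#' @param pth numeric vector of proportional thresholds.
#' @param max_order passed to [fit_var()].
#' @param correct_only drop incorrect trials (the default, matching the
#'   analysis protocol).
#' @return A data.frame with columns `subject`, `trial`, `condition`,
#'   `rt_ms`, `correct`, `band`, `pth` and the 27 feature columns.
#' @export
cohort_features <- function(cohort, bands = "theta", pth = 0.2,
                            max_order = 15L, correct_only = TRUE) {
  trials <- cohort$trials
  if (correct_only) trials <- Filter(function(tr) isTRUE(tr$correct), trials)
  if (!length(trials)) stop("no (correct) trials in cohort")
  rows <- list()
  for (ti in seq_along(trials)) {
    tr <- trials[[ti]]
    conn <- trial_connectivity(tr, bands = bands, max_order = max_order)
    for (b in bands) {
      for (p in pth) {
        fv <- trial_features(conn[[b]], tr$channel_regions, pth = p)
        rows[[length(rows) + 1L]] <- c(
          list(subject = tr$subject_id, trial = ti, condition = tr$condition,
               rt_ms = tr$rt, correct = tr$correct, band = b, pth = p),
          as.list(fv))
      }
    }
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
}

#' Feature column names
#'
#' @return Character vector of the 27 canonical feature names.
#' @export
feature_names <- function() {
  as.vector(vapply(REGIONS, function(rg)
    paste(rg, GRAPH_METRICS, sep = "."), character(length(GRAPH_METRICS))))
}
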