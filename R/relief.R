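#' ReliefF feature weights
#'
#' Deterministic ReliefF for binary classes: every sample is used once; for
#' each sample the `k_neighbors` nearest same-class (hits) and nearest
#' other-class (misses) samples are found by Euclidean distance in the
#' feature space as given (callers normally pass z-scored features). Each
#' feature's weight accumulates the range-normalized absolute differences to
#' misses minus those to hits, averaged over `n * k` comparisons. Features
#' that differ across classes near decision boundaries score high; constant
#' features score exactly 0.
#'
#' @param features n x d numeric matrix.
#' @param labels binary labels (factor, logical, or two unique values).
#' @param k_neighbors neighbors per class (default 10; capped error if a
#'   class has fewer than `k_neighbors + 1` members).
#' @return Numeric vector of d feature weights.
#' @export
relief_scores <- function(features, labels, k_neighbors = 10L) {
  X <- as.matrix(features)
  y <- as.integer(factor(labels))
  if (length(unique(y)) != 2L) stop("relief_scores needs exactly two classes")
  n <- nrow(X); d <- ncol(X)
  tab <- tabulate(y, 2L)
  if (any(tab < k_neighbors + 1L))
    stop("each class needs at least k_neighbors + 1 = ", k_neighbors + 1L,
         " samples (have ", paste(tab, collapse = ", "), ")")
  rng <- apply(X, 2, function(col) diff(range(col)))
  scale <- ifelse(rng > 0, rng, Inf)     # constant features contribute 0
  D2 <- as.matrix(stats::dist(X))^2
  W <- numeric(d)
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    diff_cls <- which(y != y[i])
    hits <- same[order(D2[i, same], same)][seq_len(k_neighbors)]
    misses <- diff_cls[order(D2[i, diff_cls], diff_cls)][seq_len(k_neighbors)]
    dh <- abs(X[hits, , drop = FALSE] -
                matrix(X[i, ], k_neighbors, d, byrow = TRUE))
    dm <- abs(X[misses, , drop = FALSE] -
                matrix(X[i, ], k_neighbors, d, byrow = TRUE))
    W <- W + (colSums(dm) - colSums(dh)) / scale
  }
  W / (n * k_neighbors)
}
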