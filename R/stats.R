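#' Binomial critical selection count
#'
#' Inverts the binomial upper tail: the smallest count `k` whose probability
#' of being reached by chance, `P(X >= k)` with `X ~ Binomial(n, p)`, does
#' not exceed `alpha`. The tail is computed by exact CDF summation
#' (`pbinom`), no approximation.
#'
#' Two conventions are exposed because the literal inversion and the
#' published threshold for feature-selection stability (43 at
#' n = 100, p = 1/3, alpha = 0.05) disagree by one:
#' \describe{
#'   \item{`exact_tail`}{the literal smallest `k` with `P(X >= k) <= alpha`
#'     (42 at the parameters above, since `P(X >= 42) = 0.0434`).}
#'   \item{`paper_compat`}{`exact_tail + 1`: the strict-exceedance reading
#'     under which a count is "more frequent than chance" only when it
#'     strictly exceeds the last count attainable at level alpha; reproduces
#'     the published 43.}
#' }
#'
#' @param n number of iterations (trials of the binomial).
#' @param p null per-iteration selection probability.
#' @param alpha significance level in (0, 1]; `alpha = 1` returns 0.
#' @param convention `"exact_tail"` or `"paper_compat"`.
#' @return Integer critical count.
#' @export
binomial_critical_count <- function(n, p, alpha = 0.05,
                                    convention = c("exact_tail",
                                                   "paper_compat")) {
  convention <- match.arg(convention)
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (alpha == 1) return(0L)
  upper_tail <- function(k) 1 - stats::pbinom(k - 1, n, p)
  k <- 0L
  while (k <= n && upper_tail(k) > alpha) k <- k + 1L
  if (k > n) stop("no count reaches significance at alpha = ", alpha)
  if (convention == "paper_compat") k <- min(n, k + 1L)
  as.integer(k)
}

#' Flag significantly often-selected features
#'
#' A feature is significant when its selection count reaches the binomial
#' critical count (boundary inclusive: a count equal to the threshold is
#' significant).
#'
#' @param counts integer selection counts (e.g. `selection_counts` of a
#'   [run_decoding()] result).
#' @param n,p,alpha,convention passed to [binomial_critical_count()];
#'   defaults match 100 iterations selecting 9 of 27 features (p = 1/3)
#'   with the published-threshold convention.
#' @return Logical vector, with the critical count as attribute
#'   `"critical_k"`.
#' @export
flag_significant_features <- function(counts, n = 100L, p = 1 / 3,
                                      alpha = 0.05,
                                      convention = "paper_compat") {
  kcrit <- binomial_critical_count(n, p, alpha, convention)
  structure(counts >= kcrit, critical_k = kcrit)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic on pooled ranks with a chi-square reference
#' distribution on `groups - 1` degrees of freedom. With two groups it is
#' the rank-sum test in its large-sample form.
#'
#' @param groups list of numeric samples.
#' @return List with `statistic` (H), `df`, `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(!vapply(groups, length, 0L))) stop("empty group")
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, 0L))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) sum(ri)^2 / length(ri))) - 3 * (N + 1)
  ties <- base::table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (corr > 0) H / corr else 0
  df <- length(groups) - 1L
  p <- if (H <= 0) 1 else stats::pchisq(H, df, lower.tail = FALSE)
  list(statistic = H, df = df, p.value = min(1, p))
}

#' Dunn's pairwise comparisons with Sidak correction
#'
#' Pairwise z statistics on the pooled ranks (Dunn's test) following a
#' Kruskal-Wallis analysis, with each two-sided p adjusted as
#' `1 - (1 - p)^m` for the `m` comparisons performed.
#'
#' @param groups list of numeric samples (names used in the output).
#' @return data.frame with columns `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_sidak_pairwise <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, 0L))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  ties <- base::table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  nm <- names(groups) %||% as.character(seq_along(groups))
  pairs <- utils::combn(length(groups), 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                    z = NA_real_, p = NA_real_, p_adj = NA_real_)
  for (j in seq_len(m)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(s2 * (1 / ns[i1] + 1 / ns[i2]))
    z <- if (se > 0) (rbar[i1] - rbar[i2]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    out$z[j] <- z
    out$p[j] <- p
    out$p_adj[j] <- min(1, max(0, 1 - (1 - p)^m))
  }
  out
}

#' Wilcoxon rank-sum test
#'
#' Two-sided; exact distribution when the combined sample size is at most
#' 25 and there are no ties, normal approximation with continuity
#' correction otherwise.
#'
#' @param x,y numeric samples.
#' @return List with `statistic` (W) and `p.value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  use_exact <- (length(x) + length(y)) <= 25 &&
    !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Wilcoxon signed-rank test
#'
#' Two-sided one-sample test of symmetry about `mu`; exact for n <= 25
#' without ties/zeros, normal approximation with continuity correction
#' otherwise. All differences zero gives p = 1.
#'
#' @param x numeric sample.
#' @param mu hypothesized center.
#' @return List with `statistic` (V) and `p.value`.
#' @export
wilcoxon_signed_rank <- function(x, mu = 0) {
  d <- x - mu
  if (all(d == 0)) return(list(statistic = 0, p.value = 1))
  dn <- d[d != 0]
  use_exact <- length(dn) <= 25 && !anyDuplicated(abs(dn))
  ht <- suppressWarnings(
    stats::wilcox.test(x, mu = mu, exact = use_exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}
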