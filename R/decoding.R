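#' Train-fit z-scoring
#'
#' Per feature, subtracts the training mean and divides by the training
#' standard deviation (sample, n-1 denominator); the identical parameters
#' are applied to the test rows, so no test information leaks into scaling.
#' Zero-variance training features map to 0 in both sets.
#'
#' @param train,test numeric matrices with matching columns (`test` may be
#'   `NULL`).
#' @return List with `train`, `test`, `center`, `scale`.
#' @export
zscore_fit_apply <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2) stop("need at least 2 training rows")
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  zero <- sdv == 0 | !is.finite(sdv)
  sdv[zero] <- 1
  tr <- sweep(sweep(train, 2, mu), 2, sdv, "/")
  tr[, zero] <- 0
  te <- NULL
  if (!is.null(test)) {
    te <- sweep(sweep(as.matrix(test), 2, mu), 2, sdv, "/")
    te[, zero] <- 0
  }
  list(train = tr, test = te, center = mu, scale = ifelse(zero, 0, sdv))
}

#' Decoding configuration
#'
#' @param n_repeats random subsampling repetitions (default 100).
#' @param test_fraction held-out fraction per repetition (default 0.2).
#' @param n_selected features kept by Relief per repetition (default 9).
#' @param k_neighbors ReliefF neighbors (default 10, capped below at the
#'   size the smallest training class allows).
#' @param cost linear-SVM cost.
#' @param seed RNG seed for the subsampling.
#' @return List of class `decoding_config`.
#' @export
decoding_config <- function(n_repeats = 100L, test_fraction = 0.2,
                            n_selected = 9L, k_neighbors = 10L,
                            cost = 1, seed = 1L) {
  structure(list(n_repeats = as.integer(n_repeats),
                 test_fraction = test_fraction,
                 n_selected = as.integer(n_selected),
                 k_neighbors = as.integer(k_neighbors),
                 cost = cost, seed = as.integer(seed)),
            class = "decoding_config")
}

as_feature_matrix <- function(table) {
  if (is.data.frame(table)) {
    fn <- intersect(feature_names(), names(table))
    if (!length(fn)) stop("no recognized feature columns in table")
    as.matrix(table[, fn, drop = FALSE])
  } else as.matrix(table)
}

stratified_split <- function(y, test_fraction) {
  test <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_test <- max(1L, round(test_fraction * length(idx)))
    test <- c(test, sample(idx, n_test))
  }
  test
}

#' Repeated-subsampling Relief + SVM decoding
#'
#' Per repetition: stratified random 80/20 split, z-scoring fit on the
#' training rows only, ReliefF on the training rows only, the top
#' `n_selected` features by Relief weight (ties broken toward the lower
#' feature index), a linear maximum-margin classifier trained on the
#' selected features and scored on the held-out rows. Selection indicators
#' and test accuracies are accumulated over repetitions.
#'
#' @param table a feature table (data.frame with the 27 feature columns, or
#'   a plain numeric matrix).
#' @param labels binary class labels, one per row.
#' @param config a [decoding_config()].
#' @return Object of class `decoding_run`: `accuracies`, `mean_accuracy`,
#'   `selection_matrix` (repeats x features), `selection_counts`,
#'   `config`, `feature_names`.
#' @export
run_decoding <- function(table, labels, config = decoding_config()) {
  X <- as_feature_matrix(table)
  y <- as.character(labels)
  if (length(unique(y)) != 2L) stop("labels must contain exactly two classes")
  counts <- base::table(y)
  if (any(counts < 10L))
    stop("need at least 10 trials per class (have ",
         paste(counts, collapse = ", "), ")")
  d <- ncol(X)
  if (config$n_selected > d) stop("n_selected exceeds feature count")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed)
  R <- config$n_repeats
  acc <- numeric(R)
  sel <- matrix(0L, R, d,
                dimnames = list(NULL, colnames(X)))
  for (r in seq_len(R)) {
    test_idx <- stratified_split(y, config$test_fraction)
    train_idx <- setdiff(seq_along(y), test_idx)
    sc <- zscore_fit_apply(X[train_idx, , drop = FALSE],
                           X[test_idx, , drop = FALSE])
    ytr <- y[train_idx]
    kn <- min(config$k_neighbors, min(base::table(ytr)) - 1L)
    w <- relief_scores(sc$train, ytr, k_neighbors = kn)
    top <- order(-w, seq_along(w))[seq_len(config$n_selected)]
    fit <- linear_svm(sc$train[, top, drop = FALSE], ytr, cost = config$cost)
    pred <- predict(fit, sc$test[, top, drop = FALSE])
    acc[r] <- mean(pred == y[test_idx])
    sel[r, top] <- 1L
  }
  structure(list(accuracies = acc, mean_accuracy = mean(acc),
                 selection_matrix = sel,
                 selection_counts = colSums(sel),
                 config = config, feature_names = colnames(X)),
            class = "decoding_run")
}

#' @export
print.decoding_run <- function(x, ...) {
  cat("Decoding run:", length(x$accuracies), "repeats, mean accuracy",
      sprintf("%.3f", x$mean_accuracy), "\n")
  invisible(x)
}

#' Proportional-threshold scan
#'
#' Runs [run_decoding()] for each supplied threshold and returns the one
#' with the highest mean accuracy (ties resolved toward the smaller
#' threshold, the sparser, more conservative graph).
#'
#' @param tables named list: `tables[[as.character(pth)]]` is the feature
#'   table at that threshold. Alternatively a single data.frame with a
#'   `pth` column.
#' @param labels per-row labels (for the data.frame form, labels are taken
#'   per threshold subset via `label_col`).
#' @param config a [decoding_config()].
#' @param label_col label column name used with the data.frame form.
#' @return List with `pth` (chosen), `run` (its `decoding_run`),
#'   `scan` (data.frame of pth and mean accuracy).
#' @export
pth_scan <- function(tables, labels = NULL, config = decoding_config(),
                     label_col = "condition") {
  if (is.data.frame(tables)) {
    stopifnot("pth" %in% names(tables))
    pths <- sort(unique(tables$pth))
    tables <- stats::setNames(lapply(pths, function(p)
      tables[tables$pth == p, , drop = FALSE]), as.character(pths))
    labels <- NULL
  }
  pths <- as.numeric(names(tables))
  if (!length(pths) || any(is.na(pths)))
    stop("tables must be named by their pth value")
  runs <- vector("list", length(pths))
  for (i in seq_along(pths)) {
    tab <- tables[[i]]
    lab <- labels %||% tab[[label_col]]
    runs[[i]] <- run_decoding(tab, lab, config)
  }
  accs <- vapply(runs, `[[`, 0, "mean_accuracy")
  best <- order(-accs, pths)[1]
  list(pth = pths[best], run = runs[[best]],
       scan = data.frame(pth = pths, mean_accuracy = accs))
}

#' Permutation test of decoding accuracy
#'
#' Builds a null distribution by rerunning the entire decoding pipeline —
#' splits, scaling, Relief selection and classifier training — on
#' label-shuffled copies of the data. The primary p-value is the empirical
#' permutation probability `(1 + #{null >= observed}) / (1 + n_shuffles)`,
#' which is exactly valid when the null statistic is computed like the
#' observed one (`r_perm = n_repeats`, the default). A Wilcoxon rank-sum
#' p-value comparing the observed per-repeat accuracies with the null
#' accuracies is also reported (`p_ranksum`) for compatibility with
#' rank-based reporting conventions, but the per-repeat accuracies share
#' trials and are therefore dependent, so `p_ranksum` is descriptive, not
#' calibrated.
#'
#' @param table,labels,config as in [run_decoding()].
#' @param n_shuffles number of label permutations (default 1000).
#' @param r_perm subsampling repeats per shuffle; `NULL` (default) uses
#'   `config$n_repeats` so observed and null statistics are exchangeable;
#'   smaller values are a documented speed reduction (conservative).
#' @param observed optionally, a precomputed `decoding_run` for the true
#'   labels (must have been produced with `config`).
#' @return Object of class `permutation_null`: `observed` (run),
#'   `null_accuracies`, `p_value` (empirical), `p_ranksum`, `n_shuffles`,
#'   `r_perm`.
#' @export
permutation_test <- function(table, labels, config = decoding_config(),
                             n_shuffles = 1000L, r_perm = NULL,
                             observed = NULL) {
  X <- as_feature_matrix(table)
  y <- as.character(labels)
  if (is.null(observed)) observed <- run_decoding(X, y, config)
  r_perm <- as.integer(r_perm %||% config$n_repeats)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(config$seed + 1L)
  null_acc <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    ys <- sample(y)
    cfg_s <- config
    cfg_s$n_repeats <- r_perm
    cfg_s$seed <- config$seed + 1L + s
    null_acc[s] <- run_decoding(X, ys, cfg_s)$mean_accuracy
  }
  p_emp <- (1 + sum(null_acc >= observed$mean_accuracy)) / (1 + n_shuffles)
  p_rs <- wilcoxon_rank_sum(observed$accuracies, null_acc)$p.value
  structure(list(observed = observed, null_accuracies = null_acc,
                 p_value = p_emp, p_ranksum = p_rs,
                 n_shuffles = as.integer(n_shuffles), r_perm = r_perm),
            class = "permutation_null")
}

#' Fast/slow reaction-time classes
#'
#' Within each condition, RTs of correct trials are z-scored per subject
#' (removing between-subject speed offsets), pooled across subjects and
#' sorted; the smallest quarter (`floor(N/4)`) becomes the fast class, the
#' largest quarter the slow class, and the middle half is excluded.
#' Incorrect trials are always excluded.
#'
#' @param rt numeric reaction times (ms).
#' @param subject per-trial subject ids.
#' @param condition per-trial condition labels.
#' @param correct per-trial logical (default all `TRUE`).
#' @return Character vector (`"fast"`, `"slow"`, `"excluded"`) aligned with
#'   the input trials.
#' @export
rt_classes <- function(rt, subject, condition, correct = NULL) {
  n <- length(rt)
  correct <- correct %||% rep(TRUE, n)
  stopifnot(length(subject) == n, length(condition) == n,
            length(correct) == n)
  if (any(rt <= 0)) stop("reaction times must be positive")
  out <- rep("excluded", n)
  for (cond in unique(condition)) {
    idx <- which(condition == cond & correct)
    if (length(idx) < 8)
      stop("condition ", cond, " has fewer than 8 pooled correct trials")
    z <- numeric(length(idx))
    for (s in unique(subject[idx])) {
      si <- subject[idx] == s
      v <- rt[idx][si]
      sdv <- stats::sd(v)
      z[si] <- if (is.na(sdv) || sdv == 0) 0 else (v - mean(v)) / sdv
    }
    nq <- floor(length(idx) / 4)
    ord <- order(z, seq_along(z))     # deterministic tie-break
    out[idx[ord[seq_len(nq)]]] <- "fast"
    out[idx[ord[(length(idx) - nq + 1):length(idx)]]] <- "slow"
  }
  out
}
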