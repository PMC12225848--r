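test_that("zscore_fit_apply scales by train statistics only", {
  tr <- cbind(a = c(1, 3), b = c(5, 5))
  te <- cbind(a = c(2, 4), b = c(7, 0))
  sc <- zscore_fit_apply(tr, te)
  # sample-sd convention: sd(c(1,3)) = sqrt(2)
  expect_equal(sc$train[, "a"], c(-1, 1) / sqrt(2))
  # constant train column maps to zero in both sets
  expect_equal(sc$train[, "b"], c(0, 0))
  expect_equal(sc$test[, "b"], c(0, 0))
  # a test value equal to the train mean maps to 0
  expect_equal(unname(sc$test[1, "a"]), 0)
  expect_error(zscore_fit_apply(tr[1, , drop = FALSE]), "2 training rows")
})

test_that("relief_scores matches a manual trace and basic properties", {
  # 4-sample, 1-feature worked case, k = 1
  x <- matrix(c(0, 0.1, 0.9, 1.0), ncol = 1)
  y <- c(0, 0, 1, 1)
  w <- relief_scores(x, y, k_neighbors = 1)
  # manual ReliefF trace (range = 1): per sample (miss diff - hit diff)/(n*k)
  manual <- ((0.9 - 0.1) + (0.8 - 0.1) + (0.8 - 0.1) + (0.9 - 0.1)) / 4
  expect_equal(w, manual)
  expect_gt(w, 0)

  # a constant feature scores exactly 0
  X <- cbind(rnorm(20), 1)
  yy <- rep(c(0, 1), each = 10)
  expect_identical(relief_scores(X, yy, 3)[2], 0)

  # a perfectly separating feature beats pure-noise features
  set.seed(99)
  wins <- 0
  for (i in 1:100) {
    n <- 30
    lab <- rep(c(0, 1), each = n / 2)
    X <- cbind(sep = ifelse(lab == 1, 1, -1) + rnorm(n, sd = 0.05),
               matrix(rnorm(n * 4), n))
    w <- relief_scores(X, lab, k_neighbors = 5)
    if (which.max(w) == 1L) wins <- wins + 1
  }
  expect_equal(wins, 100)

  expect_error(relief_scores(x, y, k_neighbors = 2), "k_neighbors")
})

test_that("linear_svm separates and predicts sensibly", {
  set.seed(8)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(ifelse(y == "b", 2, -2) + rnorm(n, sd = 0.3), rnorm(n))
  fit <- linear_svm(X, y)
  expect_true(fit$converged)
  expect_equal(mean(predict(fit, X) == y), 1)
  expect_gt(abs(fit$w[1]), abs(fit$w[2]))
  expect_error(linear_svm(X, rep("a", n)), "two classes")
})

test_that("run_decoding recovers planted class structure", {
  set.seed(14)
  n <- 80
  lab <- rep(c("p", "q"), each = n / 2)
  X <- matrix(rnorm(n * 27), n, 27,
              dimnames = list(NULL, feature_names()))
  planted <- c(2, 9, 20)
  X[, planted] <- X[, planted] + ifelse(lab == "p", 1.6, -1.6)
  run <- run_decoding(X, lab, decoding_config(n_repeats = 50, seed = 5))
  expect_gt(run$mean_accuracy, 0.9)
  top3 <- order(-run$selection_counts)[1:3]
  expect_setequal(top3, planted)
  # each repeat selects exactly n_selected features
  expect_true(all(rowSums(run$selection_matrix) == 9))
  expect_equal(sum(run$selection_counts), 50 * 9)
  expect_true(all(run$accuracies >= 0 & run$accuracies <= 1))
})

test_that("run_decoding sits at chance for random labels", {
  # per-repeat accuracies within one table are dependent (shared trials),
  # so the chance-level check averages over independent tables and uses
  # the between-table SEM
  set.seed(21)
  means <- vapply(1:10, function(i) {
    X <- matrix(rnorm(60 * 27), 60, 27)
    lab <- rep(c("p", "q"), each = 30)
    run_decoding(X, lab, decoding_config(n_repeats = 20,
                                         seed = i))$mean_accuracy
  }, 0)
  sem <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.5), 3 * sem + 1e-8)
})

test_that("decoding is reproducible and leak-free", {
  set.seed(30)
  X <- matrix(rnorm(50 * 27), 50, 27)
  lab <- rep(c("p", "q"), 25)
  cfg <- decoding_config(n_repeats = 10, seed = 77)
  r1 <- run_decoding(X, lab, cfg)
  r2 <- run_decoding(X, lab, cfg)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_identical(r1$selection_matrix, r2$selection_matrix)

  # no information leak: scaling + selection depend on training rows only
  train_idx <- 1:40; test_idx <- 41:50
  sc1 <- zscore_fit_apply(X[train_idx, ], X[test_idx, ])
  w1 <- relief_scores(sc1$train, lab[train_idx], 5)
  X2 <- X; X2[test_idx, ] <- X2[test_idx, ] + 100
  sc2 <- zscore_fit_apply(X2[train_idx, ], X2[test_idx, ])
  w2 <- relief_scores(sc2$train, lab[train_idx], 5)
  expect_identical(w1, w2)
  expect_identical(sc1$center, sc2$center)
})

test_that("pth_scan picks the threshold with peak accuracy", {
  set.seed(42)
  n <- 60
  lab <- rep(c("p", "q"), each = n / 2)
  good <- matrix(rnorm(n * 27), n, 27,
                 dimnames = list(NULL, feature_names()))
  good[, 1:3] <- good[, 1:3] + ifelse(lab == "p", 1.5, -1.5)
  bad <- matrix(rnorm(n * 27), n, 27,
                dimnames = list(NULL, feature_names()))
  cfg <- decoding_config(n_repeats = 15, seed = 2)
  res <- pth_scan(list("0.1" = good, "0.2" = bad), labels = lab, config = cfg)
  expect_equal(res$pth, 0.1)
  expect_equal(res$run$mean_accuracy, max(res$scan$mean_accuracy))
  # single pth: returned as-is
  res1 <- pth_scan(list("0.15" = good), labels = lab, config = cfg)
  expect_equal(res1$pth, 0.15)
})

test_that("permutation_test separates signal from null", {
  set.seed(60)
  n <- 60
  lab <- rep(c("p", "q"), each = n / 2)
  X <- matrix(rnorm(n * 27), n, 27)
  X[, 1:3] <- X[, 1:3] + ifelse(lab == "p", 1.8, -1.8)
  cfg <- decoding_config(n_repeats = 20, seed = 4)
  pt <- permutation_test(X, lab, cfg, n_shuffles = 60, r_perm = 5)
  expect_lt(pt$p_value, 0.02)
  expect_lt(abs(mean(pt$null_accuracies) - 0.5), 0.06)
  expect_true(all(pt$null_accuracies >= 0 & pt$null_accuracies <= 1))
  expect_s3_class(pt$observed, "decoding_run")
  expect_true(is.finite(pt$p_ranksum))
})

test_that("rt_classes quarters pooled RTs after per-subject z-scoring", {
  # 8 pooled RTs: 2 fast, 2 slow, 4 excluded
  rt <- c(300, 350, 400, 450, 500, 550, 600, 650)
  cl <- rt_classes(rt, subject = rep(1, 8), condition = rep("identity", 8))
  expect_equal(sum(cl == "fast"), 2)
  expect_equal(sum(cl == "slow"), 2)
  expect_equal(sum(cl == "excluded"), 4)
  expect_equal(cl[1:2], c("fast", "fast"))
  expect_equal(cl[7:8], c("slow", "slow"))

  # 272 pooled trials: 68 fast + 68 slow = 136 classified
  set.seed(17)
  rt272 <- runif(272, 300, 1500)
  cl272 <- rt_classes(rt272, subject = rep(1:8, each = 34),
                      condition = rep("identity", 272))
  expect_equal(sum(cl272 == "fast"), 68)
  expect_equal(sum(cl272 == "slow"), 68)
  expect_equal(sum(cl272 != "excluded"), 136)

  # shift invariance: adding a constant to one subject changes nothing
  subj <- rep(1:2, each = 20)
  rts <- runif(40, 400, 900)
  cl_a <- rt_classes(rts, subj, rep("spatial", 40))
  rts_b <- rts + ifelse(subj == 2, 500, 0)
  cl_b <- rt_classes(rts_b, subj, rep("spatial", 40))
  expect_identical(cl_a, cl_b)

  # incorrect trials are excluded and too-small conditions rejected
  rt9 <- c(rt, 200)   # fastest of all, but marked incorrect
  cl_c <- rt_classes(rt9, rep(1, 9), rep("identity", 9),
                     correct = c(rep(TRUE, 8), FALSE))
  expect_equal(cl_c[9], "excluded")
  expect_equal(sum(cl_c == "fast"), 2)
  expect_error(rt_classes(rt[1:6], rep(1, 6), rep("identity", 6)),
               "fewer than 8")
})
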