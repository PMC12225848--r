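mk_graph <- function(edges, k, weights = NULL) {
  # edges: list of c(source, target); returns a thresholded_graph
  W <- matrix(0, k, k)
  for (i in seq_along(edges)) {
    e <- edges[[i]]
    W[e[2], e[1]] <- if (is.null(weights)) 1 else weights[i]
  }
  structure(list(weights = W, mask = (W > 0) * 1L, pth = NA,
                 density = sum(W > 0) / (k * (k - 1)),
                 n_edges = sum(W > 0)),
            class = "thresholded_graph")
}

test_that("proportional_threshold keeps the strongest edges at fixed density", {
  C <- matrix(0, 3, 3)
  C[1, 2] <- 0.9; C[1, 3] <- 0.8; C[2, 1] <- 0.7
  C[2, 3] <- 0.3; C[3, 1] <- 0.2; C[3, 2] <- 0.1
  g <- proportional_threshold(C, 0.5)
  expect_equal(g$n_edges, 3L)
  expect_equal(sort(g$weights[g$weights > 0], decreasing = TRUE),
               c(0.9, 0.8, 0.7))
  expect_equal(g$density, 0.5)

  g1 <- proportional_threshold(C, 1.0)
  expect_equal(g1$mask, 1 - diag(3), ignore_attr = TRUE)

  # equal densities across different matrices at the same pth
  set.seed(1)
  dens <- vapply(1:5, function(i) {
    M <- matrix(runif(25), 5, 5); diag(M) <- 0
    proportional_threshold(M, 0.2)$density
  }, 0)
  expect_length(unique(dens), 1L)

  # deterministic tie-breaking: equal values resolved by source then target
  Ct <- matrix(0.5, 4, 4); diag(Ct) <- 0
  ga <- proportional_threshold(Ct, 0.25)
  gb <- proportional_threshold(Ct, 0.25)
  expect_identical(ga$mask, gb$mask)
  expect_equal(ga$n_edges, 3L)

  expect_error(proportional_threshold(C, 0), "pth")
  expect_error(proportional_threshold(C, 0.01), "zero edges")
})

test_that("degree and strength metrics match manual enumeration", {
  g <- mk_graph(list(c(1, 2), c(1, 3), c(2, 3)), 3,
                weights = c(0.9, 0.8, 0.7))
  d <- degree_metrics(g)
  expect_equal(d$out_degree, c(2, 1, 0), ignore_attr = TRUE)
  expect_equal(d$in_degree, c(0, 1, 2), ignore_attr = TRUE)
  expect_equal(d$degree, c(2, 2, 2), ignore_attr = TRUE)
  s <- strength_metrics(g)
  expect_equal(s$out_strength, c(1.7, 0.7, 0), tolerance = 1e-12)
  expect_equal(s$in_strength, c(0, 0.9, 1.5), tolerance = 1e-12)

  # single retained edge
  g1 <- mk_graph(list(c(1, 2)), 3, weights = 0.7)
  s1 <- strength_metrics(g1)
  expect_equal(s1$out_strength, c(0.7, 0, 0))
  expect_equal(s1$in_strength, c(0, 0.7, 0))

  # empty and complete graphs
  g0 <- mk_graph(list(), 4)
  expect_true(all(unlist(degree_metrics(g0)) == 0))
  expect_true(all(unlist(strength_metrics(g0)) == 0))
  full <- expand.grid(s = 1:4, t = 1:4)
  full <- full[full$s != full$t, ]
  gf <- mk_graph(split(as.matrix(full), seq_len(nrow(full))), 4)
  expect_equal(degree_metrics(gf)$degree, rep(6, 4), ignore_attr = TRUE)
})

test_that("clustering coefficient matches worked cases", {
  # triangle
  tri <- mk_graph(list(c(1, 2), c(2, 3), c(3, 1)), 3)
  expect_equal(clustering_coefficient(tri), rep(1, 3))
  # star: no triangles anywhere
  star <- mk_graph(list(c(1, 2), c(1, 3), c(1, 4)), 4)
  expect_equal(clustering_coefficient(star), rep(0, 4))
  # a-b, a-c, b-c, a-d
  g <- mk_graph(list(c(1, 2), c(1, 3), c(2, 3), c(1, 4)), 4)
  expect_equal(clustering_coefficient(g), c(1 / 3, 1, 1, 0))
})

test_that("betweenness matches worked cases", {
  path <- mk_graph(list(c(1, 2), c(2, 3)), 3)
  expect_equal(betweenness_centrality(path), c(0, 1, 0))
  full <- expand.grid(s = 1:4, t = 1:4)
  full <- full[full$s != full$t, ]
  gf <- mk_graph(split(as.matrix(full), seq_len(nrow(full))), 4)
  expect_equal(betweenness_centrality(gf), rep(0, 4))
  # directed out-star: no leaf-to-leaf path exists at all
  ostar <- mk_graph(list(c(1, 2), c(1, 3), c(1, 4)), 4)
  expect_equal(betweenness_centrality(ostar), rep(0, 4))
})

test_that("eigenvector centrality matches worked cases", {
  pair <- mk_graph(list(c(1, 2)), 4, weights = 0.6)
  ec <- eigenvector_centrality(pair)
  expect_equal(ec, c(1, 1, 0, 0) / sqrt(2), tolerance = 1e-10)

  # undirected star: hub / leaf ratio = sqrt(4)
  star <- mk_graph(list(c(1, 2), c(2, 1), c(1, 3), c(3, 1),
                        c(1, 4), c(4, 1), c(1, 5), c(5, 1)), 5)
  ec <- eigenvector_centrality(star)
  expect_true(all(abs(ec[2:5] - ec[2]) < 1e-10))
  expect_gt(ec[1], ec[2])
  expect_equal(ec[1] / ec[2], 2, tolerance = 1e-8)

  # eigen equation holds
  g <- mk_graph(list(c(1, 2), c(2, 3), c(3, 1), c(1, 3)), 4,
                weights = c(0.5, 0.4, 0.3, 0.2))
  S <- (g$weights + t(g$weights)) / 2
  x <- eigenvector_centrality(g)
  lam <- max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  expect_lt(max(abs(S %*% x - lam * x)), 1e-8)

  empty <- mk_graph(list(), 3)
  expect_warning(ec0 <- eigenvector_centrality(empty), "empty")
  expect_equal(ec0, rep(0, 3))
})

test_that("all metrics agree with independent oracles on random digraphs", {
  set.seed(202)
  for (rep in 1:50) {
    k <- sample(3:8, 1)
    g <- random_digraph(k, density = runif(1, 0.2, 0.7))
    d <- degree_metrics(g); s <- strength_metrics(g)
    expect_identical(unname(d$in_degree), unname(rowSums(g$mask)))
    expect_identical(unname(d$out_degree), unname(colSums(g$mask)))
    expect_equal(sum(d$in_degree), g$n_edges)
    expect_equal(sum(d$out_degree), g$n_edges)
    expect_equal(sum(s$in_strength), sum(g$weights), tolerance = 1e-12)
    expect_equal(sum(s$out_strength), sum(g$weights), tolerance = 1e-12)
    expect_equal(clustering_coefficient(g), cc_oracle(g$mask),
                 tolerance = 1e-12)
    expect_equal(betweenness_centrality(g), bc_oracle(g$mask),
                 tolerance = 1e-8)
    ec <- suppressWarnings(eigenvector_centrality(g))
    expect_equal(ec, ec_oracle(g$weights), tolerance = 1e-6)
  }
})

test_that("betweenness also agrees with igraph on random digraphs", {
  skip_if_not_installed("igraph")
  set.seed(303)
  for (rep in 1:10) {
    k <- sample(4:8, 1)
    g <- random_digraph(k, density = 0.4)
    ig <- igraph::graph_from_adjacency_matrix(t(g$mask), mode = "directed")
    expect_equal(betweenness_centrality(g),
                 unname(igraph::betweenness(ig, directed = TRUE)),
                 tolerance = 1e-10)
  }
})

test_that("adding an edge never decreases degree or strength", {
  set.seed(11)
  g <- random_digraph(6, 0.3)
  d0 <- degree_metrics(g)$degree; s0 <- strength_metrics(g)$strength
  zero <- which(g$mask == 0 & row(g$mask) != col(g$mask))
  pick <- sample(zero, 1)
  g$weights[pick] <- 0.5; g$mask[pick] <- 1L; g$n_edges <- g$n_edges + 1L
  expect_true(all(degree_metrics(g)$degree >= d0))
  expect_true(all(strength_metrics(g)$strength >= s0 - 1e-12))
})

test_that("aggregate_regions produces the canonical 27-vector", {
  g <- mk_graph(list(c(1, 2), c(2, 3), c(3, 4), c(4, 1)), 4,
                weights = c(0.5, 0.4, 0.3, 0.2))
  regions <- c("MTL", "MTL", "PFC", "OFC")
  fv <- aggregate_regions(node_metrics(g), regions)
  expect_length(fv, 27)
  expect_named(fv)
  expect_equal(names(fv)[1:3], c("MTL.degree", "MTL.in_degree",
                                 "MTL.out_degree"))
  # single-channel region equals that channel's metrics
  nm <- node_metrics(g)
  expect_equal(unname(fv["PFC.degree"]), unname(nm[3, "degree"]))
  # two-channel region is the mean
  expect_equal(unname(fv["MTL.degree"]),
               mean(nm[1:2, "degree"]))
  expect_error(aggregate_regions(nm, c("MTL", "MTL", "PFC", "PFC")),
               "OFC")
})

test_that("trial_features is a finite named 27-vector", {
  coh <- tiny_cohort(seed = 6, trials = 5, conditions = "identity")
  tr <- coh$trials[[1]]
  conn <- trial_connectivity(tr, bands = "theta")
  fv <- trial_features(conn$theta, tr$channel_regions, pth = 0.2)
  expect_length(fv, 27)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), feature_names())
})
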