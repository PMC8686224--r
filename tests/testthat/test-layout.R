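# Kernel fit, spectral initialization, cross-entropy, and the SGD layout.

test_that("kernel parameters reproduce a coarse grid-search oracle", {
  ab <- fit_curve_params(min_dist = 0.1, spread = 1.0)
  r <- seq(0, 3, length.out = 300)
  target <- ifelse(r <= 0.1, 1, exp(-(r - 0.1) / 1.0))
  grid <- expand.grid(a = seq(0.5, 3, by = 0.01), b = seq(0.5, 2, by = 0.01))
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    sum((1 / (1 + grid$a[i] * r^(2 * grid$b[i])) - target)^2)
  }, numeric(1))
  best <- grid[which.min(sse), ]
  expect_equal(ab[["a"]], best$a, tolerance = 0.05)
  expect_equal(ab[["b"]], best$b, tolerance = 0.05)
  # kernel is 1 at r = 0 and strictly decreasing
  nu <- 1 / (1 + ab["a"] * r^(2 * ab["b"]))
  expect_equal(nu[[1]], 1)
  expect_true(all(diff(nu) < 0))
  expect_error(fit_curve_params(min_dist = 2, spread = 1), "min_dist")
})

test_that("cross-entropy matches direct evaluation and its limits", {
  # the divergence form: zero when the embedding memberships match the graph
  expect_equal(cross_entropy(0.5, 0.5), 0)
  expect_lt(cross_entropy(1, 1 - 1e-12), 1e-10)
  expect_equal(cross_entropy(0.9, 0.1),
               0.9 * log(9) + 0.1 * log(1 / 9), tolerance = 1e-12)
  expect_equal(cross_entropy(c(0.9, 0.5), c(0.1, 0.5)),
               0.9 * log(9) + 0.1 * log(1 / 9), tolerance = 1e-12)
  # mismatch in either direction costs loss
  expect_gt(cross_entropy(0.2, 0.9), 0)
  expect_error(cross_entropy(c(0.1, 0.2), 0.5), "length")
})

test_that("spectral initialization separates disconnected components", {
  clique <- function(n) Matrix::Matrix(1, n, n) - Matrix::Diagonal(n)
  g <- Matrix::bdiag(clique(10), clique(10))
  co <- spectral_init(g, d = 2, seed = 1)
  box1 <- apply(co[1:10, ], 2, range)
  box2 <- apply(co[11:20, ], 2, range)
  disjoint_x <- box1[2, 1] < box2[1, 1] || box2[2, 1] < box1[1, 1]
  disjoint_y <- box1[2, 2] < box2[1, 2] || box2[2, 2] < box1[1, 2]
  expect_true(disjoint_x || disjoint_y)
  # deterministic at fixed seed
  expect_identical(co, spectral_init(g, d = 2, seed = 1))
  # single point: a row of zeros
  expect_equal(spectral_init(Matrix::Matrix(0, 1, 1, sparse = TRUE), d = 2),
               matrix(0, 1, 2))
})

test_that("spectral coordinates reflect the graph's slow modes", {
  # a path graph's second Laplacian eigenvector orders the path
  n <- 40
  g <- Matrix::bandSparse(n, k = 1, diagonals = list(rep(1, n - 1)),
                          symmetric = TRUE)
  co <- spectral_init(g, d = 1, seed = 2)
  # the degree weighting of the normalized Laplacian perturbs the endpoints,
  # so the ordering is strong but not perfect
  expect_true(abs(cor(co[, 1], seq_len(n), method = "spearman")) > 0.9)
})

single_edge_graph <- function(n = 2, mu = 1, extra = 0) {
  total <- n + extra
  m <- Matrix::sparseMatrix(i = 1, j = 2, x = mu, dims = c(total, total),
                            symmetric = TRUE)
  b <- data_block(matrix(rnorm(total * 2), total, 2,
                         dimnames = list(NULL, c("f1", "f2"))), "d",
                  point_ids = sprintf("p%02d", seq_len(total)))
  idx <- coembed:::global_index(list(b))
  structure(list(membership = methods::as(m, "CsparseMatrix"),
                 index = idx[, c("dataset", "point_id")],
                 tags = list(codes = methods::as(m, "CsparseMatrix"),
                             labels = "own:d")),
            class = "multigraph")
}

test_that("a lone strong edge attracts its endpoints", {
  g <- single_edge_graph(mu = 1)
  init <- rbind(c(-3, 0), c(3, 0))
  cfg <- embed_config(epochs = 50, seed = 1, negative_sample_rate = 1e-9)
  out <- optimize_embedding(g, init, cfg)
  expect_lt(sqrt(sum((out[1, ] - out[2, ])^2)), 6)
})

test_that("negative sampling repels non-neighbors of active points", {
  set.seed(3)
  g <- single_edge_graph(mu = 1, extra = 8)
  init <- matrix(rnorm(20, sd = 0.1), 10, 2)
  cfg <- embed_config(epochs = 100, seed = 2, negative_sample_rate = 10)
  out <- optimize_embedding(g, init, cfg)
  d0 <- mean(sqrt(rowSums((init[3:10, ] - init[rep(1, 8), ])^2)))
  d1 <- mean(sqrt(rowSums((out[3:10, ] - out[rep(1, 8), ])^2)))
  expect_gt(d1, d0)
})

two_clique_fixture <- function(seed = 4) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(20, sd = 0.3), 10, 2),
             matrix(rnorm(20, sd = 0.3), 10, 2) + 5)
  colnames(x) <- c("f1", "f2")
  b <- data_block(x, "d", point_ids = sprintf("p%02d", 1:20))
  own <- fuzzy_simplicial_set(x, k = 4)
  # one weak bridge edge
  own[1, 11] <- own[11, 1] <- 0.05
  assemble_multigraph(list(d = own),
                      index = coembed:::global_index(list(b)))
}

test_that("two cliques joined by a weak edge stay internally tight", {
  g <- two_clique_fixture()
  init <- spectral_init(g, d = 2, seed = 5)
  out <- optimize_embedding(g, init, embed_config(epochs = 200, seed = 5))
  dm <- as.matrix(dist(out))
  intra <- mean(c(dm[1:10, 1:10][upper.tri(diag(10))],
                  dm[11:20, 11:20][upper.tri(diag(10))]))
  inter <- mean(dm[1:10, 11:20])
  expect_lt(intra, inter)
})

test_that("the optimizer is deterministic and loss decreases in expectation", {
  g <- two_clique_fixture()
  init <- spectral_init(g, d = 2, seed = 6)
  # monotone SGD progress needs a stable step size; the default rate spends
  # its early epochs expanding the layout before contraction
  cfg <- embed_config(epochs = 200, seed = 6, learning_rate = 0.5,
                      snapshot_epochs = c(100, 200))
  out1 <- optimize_embedding(g, init, cfg)
  out2 <- optimize_embedding(g, init, cfg)
  expect_identical(as.vector(out1), as.vector(out2))

  snaps <- attr(out1, "snapshots")
  ed <- coembed:::edge_weights(g, c(d = 1))
  ce <- function(emb) cross_entropy(
    ed$mu, coembed:::embedding_nu(emb, ed$i, ed$j, cfg$a, cfg$b))
  losses <- c(ce(init), ce(snaps[[1]]), ce(snaps[[2]]))
  # non-increasing along the run, allowing 5% stochastic slack
  expect_lt(losses[2], losses[1] * 1.05)
  expect_lt(losses[3], losses[2] * 1.05)
  expect_lt(losses[3], losses[1])
})

test_that("zero-weight datasets are inert in the layout", {
  fx <- make_two_cluster_fixture(12, seed = 7)
  idx <- coembed:::global_index(list(fx$a, fx$b))
  own <- list(a = fuzzy_simplicial_set(own_space(fx$a), k = 5),
              b = fuzzy_simplicial_set(own_space(fx$b), k = 5))
  sp <- build_shared_space(fx$a, fx$b, d = 2)
  cs <- cross_memberships(sp, idx, k = 5)
  g1 <- assemble_multigraph(own, list(s = cs), index = idx)

  g2 <- g1
  m <- g2$membership
  rows_b <- which(idx$dataset == "b")
  sub <- m[rows_b, rows_b]
  set.seed(8)
  sub@x <- runif(length(sub@x))
  m[rows_b, rows_b] <- methods::as(Matrix::forceSymmetric(sub, uplo = "U"),
                                   "generalMatrix")
  g2$membership <- m

  w <- c(a = 1, b = 0)
  cfg <- embed_config(epochs = 100, seed = 8)
  i1 <- spectral_init(coembed:::weighted_graph(g1, w), 2, seed = 8)
  i2 <- spectral_init(coembed:::weighted_graph(g2, w), 2, seed = 8)
  e1 <- optimize_embedding(g1, i1, cfg, weights = w)
  e2 <- optimize_embedding(g2, i2, cfg, weights = w)
  expect_identical(as.vector(e1), as.vector(e2))
})
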