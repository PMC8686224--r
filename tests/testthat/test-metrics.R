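# Label transfer and the four benchmark metrics.

test_that("kNN transfer follows majority and the nearest-tie rule", {
  # unanimity: all five labeled neighbors share one class
  emb <- tibble::tibble(
    point_id = sprintf("p%02d", 1:6),
    dataset = c(rep("ref", 5), "query"),
    dim_1 = c(1, 1.1, 0.9, 1.05, 0.95, 1),
    dim_2 = c(0, 0.1, -0.1, 0.05, -0.05, 0.01))
  labs <- c(rep("B", 5), NA)
  pred <- transfer_labels_knn(emb, labs, query = "query", k = 5)
  expect_equal(pred$predicted, "B")

  # k = 1: label of the single nearest labeled neighbor
  labs2 <- c("B", "T", "T", "T", "T", NA)
  pred1 <- transfer_labels_knn(emb, labs2, query = "query", k = 1)
  expect_equal(pred1$predicted, "B")  # p1 at distance 0.01 is nearest

  # constructed 2-2-1 tie: nearest tied neighbor decides
  emb3 <- tibble::tibble(
    point_id = sprintf("q%02d", 1:6),
    dataset = c(rep("ref", 5), "query"),
    dim_1 = c(1, 4, 2, 3, 5, 0),
    dim_2 = 0)
  labs3 <- c("A", "A", "B", "B", "C", NA)
  # 5-NN of the query (at 0): all five; classes A (d 1,4), B (d 2,3), C (d 5)
  # A and B tie at 2 votes; nearest tied neighbor is A at distance 1
  pred3 <- transfer_labels_knn(emb3, labs3, query = "query", k = 5)
  expect_equal(pred3$predicted, "A")

  expect_error(transfer_labels_knn(emb, rep(NA, 6), query = "query"),
               "no labeled points")
})

test_that("harmonic transfer reproduces path-graph closed forms", {
  # A -- u -- B: the middle node splits evenly
  g3 <- path_graph(3)
  out3 <- transfer_labels_harmonic(g3, c("A", NA, "B"))
  expect_equal(out3$p_A[2], 0.5, tolerance = 1e-8)
  expect_equal(out3$p_B[2], 0.5, tolerance = 1e-8)

  # A -- u1 -- u2 -- B: (2/3, 1/3) and (1/3, 2/3)
  g4 <- path_graph(4)
  out4 <- transfer_labels_harmonic(g4, c("A", NA, NA, "B"))
  expect_equal(out4$p_A[2:3], c(2 / 3, 1 / 3), tolerance = 1e-8)
  expect_equal(out4$p_B[2:3], c(1 / 3, 2 / 3), tolerance = 1e-8)

  # clamped labels survive exactly; rows sum to one
  expect_equal(out4$p_A[1], 1)
  expect_equal(rowSums(as.matrix(out4[, c("p_A", "p_B")])), rep(1, 4),
               tolerance = 1e-8)
})

test_that("harmonic transfer handles absorbing and unreachable cases", {
  # unlabeled node adjacent only to class-A nodes
  m <- Matrix::sparseMatrix(i = c(1, 2), j = c(3, 3), x = 1, dims = c(3, 3))
  m <- m + Matrix::t(m)
  b <- data_block(matrix(0, 3, 1, dimnames = list(NULL, "f")), "d",
                  point_ids = c("a1", "a2", "u"))
  g <- structure(list(membership = methods::as(m, "CsparseMatrix"),
                      index = coembed:::global_index(list(b))[, c("dataset",
                                                                  "point_id")],
                      tags = list(codes = methods::as(m, "CsparseMatrix"),
                                  labels = "own:d")),
                 class = "multigraph")
  out <- transfer_labels_harmonic(g, c("A", "A", NA))
  expect_equal(out$p_A[3], 1, tolerance = 1e-8)

  # a component with no labels is unassignable
  g2 <- path_graph(5)
  g2$membership[4, 5] <- g2$membership[5, 4] <- 0
  g2$membership <- Matrix::drop0(g2$membership)
  expect_warning(out2 <- transfer_labels_harmonic(g2, c("A", NA, "B", NA, NA)),
                 "unassignable")
  expect_true(is.na(out2$predicted[5]))
  expect_false(anyNA(out2$predicted[1:4]))
})

test_that("balanced accuracy is the unweighted mean of per-class recall", {
  expect_equal(balanced_accuracy(c("a", "b", "a", "b"),
                                 c("a", "b", "a", "b")), 1.0)
  expect_equal(balanced_accuracy(c("a", "a", "b", "b"),
                                 c("a", "a", "a", "a")), 0.5)
  truth <- c(rep("A", 10), rep("B", 5))
  pred <- c(rep("A", 8), "B", "B", rep("B", 3), "A", "A")
  expect_equal(balanced_accuracy(truth, pred), 0.7)  # (0.8 + 0.6) / 2
  expect_equal(balanced_accuracy(truth, pred),
               oracle_balanced_accuracy(truth, pred))
})

test_that("silhouette behaves at its limits and matches brute force", {
  set.seed(1)
  tight <- rbind(matrix(rnorm(100, sd = 0.01), 50, 2),
                 matrix(rnorm(100, sd = 0.01), 50, 2) + 100)
  expect_gte(silhouette_mean(tight, rep(c("x", "y"), each = 50)), 0.99)

  blob <- matrix(rnorm(1000), 500, 2)
  rand <- sample(c("x", "y"), 500, replace = TRUE)
  expect_lt(abs(silhouette_mean(blob, rand)), 0.1)

  # 6 points on a line with hand-computable a and b
  x <- matrix(c(0, 1, 2, 10, 11, 12), 6, 1)
  labs <- rep(c("l", "r"), each = 3)
  expect_equal(silhouette_mean(x, labs), oracle_silhouette(x, labs),
               tolerance = 1e-12)

  expect_warning(
    silhouette_mean(matrix(c(0, 1, 2, 10), 4, 1), c("a", "a", "a", "b")),
    "singleton")
})

test_that("alignment measures cross-dataset mixing", {
  # disjoint regions: no mixing
  co <- rbind(matrix(rnorm(40, sd = 0.1), 20, 2),
              matrix(rnorm(40, sd = 0.1), 20, 2) + 50)
  ds <- rep(c("a", "b"), each = 20)
  expect_equal(alignment_score(co, ds, k = 5), 0)
  expect_warning(a1 <- alignment_score(co, rep("a", 40), k = 5), "single")
  expect_equal(a1, 0)

  # interleaved grid against the brute-force oracle
  co2 <- cbind(seq_len(20), 0)
  ds2 <- rep(c("a", "b"), times = 10)
  expect_equal(alignment_score(co2, ds2, k = 5),
               oracle_alignment(co2, ds2, 5), tolerance = 1e-12)

  # invariance under rotation and translation
  set.seed(2)
  co3 <- matrix(rnorm(120), 60, 2)
  ds3 <- rep(c("a", "b"), 30)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(alignment_score(co3, ds3, k = 5),
               alignment_score(sweep(co3 %*% rot, 2, c(3, -4), `+`), ds3,
                               k = 5))
})

test_that("structure score is the Pearson correlation of pair distances", {
  set.seed(3)
  x <- matrix(rnorm(30), 10, 3)
  expect_equal(structure_score(x, x), 1, tolerance = 1e-12)
  expect_equal(structure_score(x, x[, 1:2] * 3.7), structure_score(x, x[, 1:2]),
               tolerance = 1e-12)

  hi <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0), c(0, 0, 3))
  lo <- rbind(c(0, 0), c(1, 1), c(2, 0), c(0, 2))
  expect_equal(structure_score(hi, lo), oracle_structure(hi, lo),
               tolerance = 1e-12)

  degenerate <- matrix(0, 4, 2)
  expect_warning(s <- structure_score(degenerate, lo), "zero-variance")
  expect_true(is.na(s))
})

test_that("pair subsampling keeps the score close to the full computation", {
  set.seed(4)
  hi <- matrix(rnorm(600 * 3), 600, 3)
  lo <- hi[, 1:2] + matrix(rnorm(1200, sd = 0.1), 600, 2)
  full <- structure_score(hi, lo)
  sub <- structure_score(hi, lo, max_pairs = 2e4, seed = 9)
  expect_equal(sub, full, tolerance = 0.02)
})

test_that("all metrics reproduce brute-force references on random fixtures", {
  set.seed(5)
  n <- 100
  co <- matrix(rnorm(n * 2), n, 2)
  ds <- sample(c("a", "b"), n, replace = TRUE)
  labs <- sample(c("c1", "c2", "c3"), n, replace = TRUE)
  expect_lt(abs(silhouette_mean(co, labs) - oracle_silhouette(co, labs)),
            1e-10)
  expect_lt(abs(alignment_score(co, ds, k = 5) - oracle_alignment(co, ds, 5)),
            1e-10)
  hi <- matrix(rnorm(n * 5), n, 5)
  expect_lt(abs(structure_score(hi, co) - oracle_structure(hi, co)), 1e-10)
})

test_that("metric_report assembles the four metrics", {
  fit <- make_small_fit(15, epochs = 60)
  emb <- fit$embedding
  labs <- ifelse(grepl("_0(0[1-9]|1[0-5])$", emb$point_id), "c1", "c2")
  spaces <- list(a = own_space(make_two_cluster_fixture(15, seed = 3)$a))
  rep <- metric_report(fit, labs, query = "b",
                       spaces = list(a = spaces$a$coords))
  expect_s3_class(rep, "tbl_df")
  expect_true(all(c("transfer", "silhouette", "alignment", "structure")
                  %in% colnames(rep)))
  expect_gte(rep$transfer, 0)
  expect_lte(rep$transfer, 1)
})
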