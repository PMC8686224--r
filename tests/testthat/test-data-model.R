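# Core types, matrix/label I/O, TF-IDF, dimensionality reduction, shared
# feature spaces.

test_that("data_block validates its fields", {
  m <- matrix(1:6, 3, 2, dimnames = list(NULL, c("a", "b")))
  b <- data_block(m, "x")
  expect_s3_class(b, "data_block")
  expect_equal(dim(b), c(3L, 2L))
  expect_error(data_block(m[0, , drop = FALSE], "x"), "at least one point")
  expect_error(data_block(m, "x", feature_names = c("a", "a")), "duplicated")
  expect_error(data_block(m, "x", labels = c("u", "v")), "labels")
  expect_error(data_block(m, "x", weight = 2), "\\[0, 1\\]")
})

test_that("dense TSV/CSV round-trips preserve matrix, names, and order", {
  m <- matrix(round(rnorm(12), 6), 4, 3,
              dimnames = list(NULL, c("gene_b", "gene_a", "gene_c")))
  b <- data_block(m, "rna", point_ids = c("c4", "c2", "c1", "c3"))
  for (fmt in c("tsv", "csv")) {
    p <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_data_block(b, p, format = fmt)
    b2 <- read_data_block(p, dataset_id = "rna")
    expect_equal(unname(as.matrix(b2$matrix)), unname(m))
    expect_identical(b2$feature_names, b$feature_names)
    expect_identical(b2$point_ids, b$point_ids)
  }
})

test_that("Matrix Market round-trip keeps every stored entry", {
  m <- Matrix::sparseMatrix(i = c(1, 2, 3, 3, 5), j = c(2, 1, 3, 1, 2),
                            x = c(1.5, 2, 3, 4, 5), dims = c(5, 3))
  colnames(m) <- c("fA", "fB", "fC")
  b <- data_block(m, "atac", point_ids = paste0("p", 1:5))
  p <- withr::local_tempfile(fileext = ".mtx")
  write_data_block(b, p, format = "mtx")
  b2 <- read_data_block(p, dataset_id = "atac")
  expect_equal(Matrix::nnzero(b2$matrix), 5)
  expect_equal(as.matrix(b2$matrix), as.matrix(m), ignore_attr = TRUE)
  expect_identical(b2$feature_names, colnames(m))
})

test_that("malformed inputs are rejected with the offending file named", {
  m <- Matrix::rsparsematrix(4, 3, 0.5)
  colnames(m) <- paste0("f", 1:3)
  b <- data_block(m, "x", point_ids = paste0("p", 1:4))
  p <- withr::local_tempfile(fileext = ".mtx")
  write_data_block(b, p, format = "mtx")
  stem <- sub("\\.mtx$", "", p)
  writeLines(c("f1", "f2"), paste0(stem, ".features.txt"))
  expect_error(read_data_block(p), "features.txt")
  expect_error(read_data_block("no/such/file.tsv"), "does not exist")
})

test_that("labels round-trip with unlabeled points as empty strings", {
  lab <- c(p1 = "B cell", p2 = NA, p3 = "T cell")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_labels(lab, p)
  expect_identical(read_labels(p), lab)
})

test_that("cross-distance tables are 0-based on disk, validated in memory", {
  tbl <- tibble::tibble(dataset_a = "x", index_a = c(1L, 3L),
                        dataset_b = "y", index_b = c(2L, 1L),
                        distance = c(0.3, 0.1))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_cross_distances(tbl, p)
  raw <- read.delim(p)
  expect_equal(raw$index_a, c(0L, 2L))
  expect_equal(read_cross_distances(p), tbl)
  bad <- tbl
  bad$dataset_b <- "x"
  bad$index_b <- bad$index_a
  expect_error(write_cross_distances(bad, p), "self-pairs")
  bad2 <- tbl
  bad2$distance[1] <- -1
  expect_error(write_cross_distances(bad2, p), "non-negative")
})

test_that("tfidf matches the smoothed formula entrywise", {
  # single present feature: tf = 1, idf = log(1 + 1/2)
  one <- matrix(1, 1, 1, dimnames = list(NULL, "f"))
  expect_equal(as.numeric(tfidf_transform(one)), log(1 + 1 / 2))

  m <- matrix(c(1, 1, 1, 1, 0, 0), 3, 2,
              dimnames = list(NULL, c("fa", "fb")))
  # hand evaluation: N = 3, df = (3, 1); idf = log(1+3/4), log(1+3/2);
  # tf rows (1/2,1/2), (1,0), (1,0)
  expected <- rbind(c(0.5 * log(1.75), 0.5 * log(2.5)),
                    c(log(1.75), 0),
                    c(log(1.75), 0))
  expect_equal(unname(tfidf_transform(m)), expected, tolerance = 1e-12)
})

test_that("tfidf rejects bad input and preserves sparsity pattern", {
  expect_error(tfidf_transform(matrix(0, 3, 3,
                                      dimnames = list(NULL, 1:3))),
               "all-zero")
  expect_error(tfidf_transform(matrix(c(1, 2, 1, 1), 2, 2,
                                      dimnames = list(NULL, 1:2))),
               "binary")
  set.seed(1)
  sp <- Matrix::rsparsematrix(30, 20, 0.3, rand.x = function(n) rep(1, n))
  sp <- sp[Matrix::rowSums(sp) > 0, ]
  out <- tfidf_transform(sp)
  expect_identical(out != 0, sp != 0)
})

test_that("reduce_dimension is a faithful, deterministic projection", {
  # rank-1 data: one component carries all variance
  u <- matrix(rnorm(20), 20, 1)
  x1 <- u %*% t(c(1, 2, 3))
  sc <- reduce_dimension(x1, 1)
  expect_equal(attr(sc, "sdev")[1]^2 / sum(apply(x1, 2, var)), 1,
               tolerance = 1e-10)

  # full-rank PCA is an isometry
  set.seed(2)
  x <- matrix(rnorm(40 * 3), 40, 3)
  sc3 <- reduce_dimension(x, 3)
  expect_equal(as.vector(dist(sc3)), as.vector(dist(x)), tolerance = 1e-8)

  # 3x2 case against the closed-form 2x2 covariance eigenproblem; the top
  # loading is (1, -1)/sqrt(2) up to sign, so compare magnitudes
  x2 <- rbind(c(1, 0), c(0, 1), c(1, 1))
  sc1 <- reduce_dimension(x2, 1)
  cv <- stats::cov(x2)
  es <- eigen(cv, symmetric = TRUE)
  centered <- scale(x2, center = TRUE, scale = FALSE)
  expect_equal(abs(as.numeric(sc1)),
               abs(as.numeric(centered %*% es$vectors[, 1])),
               tolerance = 1e-12)

  # deterministic sign convention on a tie-free example
  x3 <- cbind(c(0, 1, 2, 4), c(0, 0.5, 1.2, 1.9))
  sc_a <- reduce_dimension(x3, 2)
  sc_b <- reduce_dimension(x3[, 2:1], 2)
  expect_equal(abs(sc_a), abs(sc_b), ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(sc_a, reduce_dimension(x3, 2))

  expect_error(reduce_dimension(x2, 5), "maximum is 2")
})

test_that("truncated SVD and irlba paths agree with exact decompositions", {
  set.seed(3)
  x <- matrix(rnorm(300 * 40), 300, 40)
  exact <- reduce_dimension(x, 5, method = "truncated_svd")
  sv <- svd(x)
  ref <- sweep(sv$u[, 1:5], 2, sv$d[1:5], `*`)
  expect_equal(abs(exact), abs(ref), tolerance = 1e-8, ignore_attr = TRUE)
  # large path (irlba) reproduces the top scores up to the sign convention
  big <- matrix(rnorm(500 * 300), 500, 300)
  a <- reduce_dimension(big, 4, method = "pca", seed = 1)
  pr <- prcomp(big, rank. = 4)
  expect_equal(abs(unname(a)), abs(unname(pr$x[, 1:4])), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("shared spaces restrict to common features and stack jointly", {
  set.seed(4)
  mk <- function(id, feats) {
    m <- matrix(rnorm(10 * length(feats)), 10,
                dimnames = list(NULL, feats))
    data_block(m, id, point_ids = sprintf("%s%02d", id, 1:10))
  }
  a <- mk("a", c("A", "B", "C"))
  b <- mk("b", c("A", "B", "D"))
  sp <- build_shared_space(a, b, d = 2)
  expect_equal(sp$dim, 2)
  expect_equal(nrow(sp$coords), 20)

  d_only <- mk("d", c("X", "Y"))
  expect_error(build_shared_space(a, d_only), "no shared features")
  expect_warning(build_shared_space(a, b, d = 10), "lowering d")
})

test_that("duplicated blocks land on identical shared-space coordinates", {
  set.seed(5)
  m <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("f", 1:4)))
  a <- data_block(m, "a", point_ids = paste0("a", 1:10))
  b <- data_block(m, "b", point_ids = paste0("b", 1:10))
  sp <- build_shared_space(a, b, d = 3)
  expect_equal(sp$coords[1:10, ], sp$coords[11:20, ], ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("build_shared_space is symmetric in its arguments", {
  set.seed(6)
  mk <- function(id) {
    m <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(NULL, paste0("f", 1:5)))
    data_block(m, id, point_ids = sprintf("%s%02d", id, 1:8))
  }
  a <- mk("a")
  b <- mk("b")
  ab <- build_shared_space(a, b, d = 3)
  ba <- build_shared_space(b, a, d = 3)
  key_ab <- paste(ab$index$dataset, ab$index$point_id)
  key_ba <- paste(ba$index$dataset, ba$index$point_id)
  expect_equal(ab$coords, ba$coords[match(key_ab, key_ba), ],
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("default weights follow the reference convention", {
  fx <- make_two_cluster_fixture()
  w <- coembed:::resolve_weights(list(fx$a, fx$b), reference = "a")
  expect_equal(unname(w), c(0.8, 0.2))
  w2 <- coembed:::resolve_weights(list(fx$a, fx$b))
  expect_equal(unname(w2), c(1, 1))
  fx$b$weight <- 0.5
  w3 <- coembed:::resolve_weights(list(fx$a, fx$b), reference = "a")
  expect_equal(unname(w3), c(0.8, 0.5))
})
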