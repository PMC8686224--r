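# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals: dense
# all-pairs distances, stats::uniroot for the bandwidth, explicit loops.

brute_knn <- function(x, k) {
  n <- nrow(x)
  dm <- as.matrix(dist(x))
  idx <- matrix(0L, n, k)
  dd <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ord <- order(dm[i, -i])
    cand <- seq_len(n)[-i][ord]
    idx[i, ] <- cand[seq_len(k)]
    dd[i, ] <- dm[i, idx[i, ]]
  }
  list(idx = idx, dist = dd)
}

oracle_calibrate <- function(d, k = length(d)) {
  rho <- min(d)
  target <- log2(k)
  f <- function(s) sum(exp(-pmax(d - rho, 0) / s)) - target
  md <- mean(d)
  sigma <- stats::uniroot(f, c(1e-9 * md, 1e4 * md), tol = 1e-14)$root
  c(rho = rho, sigma = sigma)
}

# Full single-space fuzzy graph by brute force: exact kNN, uniroot
# calibration, dense directed strengths, looped t-conorm union.
oracle_fuzzy_graph <- function(x, k) {
  n <- nrow(x)
  nn <- brute_knn(x, k)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cal <- oracle_calibrate(nn$dist[i, ], k)
    for (col in seq_len(k)) {
      j <- nn$idx[i, col]
      p[i, j] <- exp(-max(nn$dist[i, col] - cal["rho"], 0) / cal["sigma"])
    }
  }
  s <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s[i, j] <- p[i, j] + p[j, i] - p[i, j] * p[j, i]
    }
  }
  diag(s) <- 0
  s
}

oracle_balanced_accuracy <- function(truth, pred) {
  cls <- unique(truth)
  mean(vapply(cls, function(cl) {
    sum(pred == cl & truth == cl) / sum(truth == cl)
  }, numeric(1)))
}

oracle_silhouette <- function(coords, labels) {
  n <- nrow(coords)
  dm <- as.matrix(dist(coords))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(dm[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(dm[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_alignment <- function(coords, datasets, k) {
  n <- nrow(coords)
  dm <- as.matrix(dist(coords))
  fr <- numeric(n)
  for (i in seq_len(n)) {
    nb <- setdiff(order(dm[i, ]), i)[seq_len(k)]
    fr[i] <- mean(datasets[nb] != datasets[i])
  }
  mean(fr)
}

oracle_structure <- function(hi, lo) {
  cor(as.vector(dist(hi)), as.vector(dist(lo)), method = "pearson")
}

# Small labeled two-dataset fixture with well-separated clusters.
make_two_cluster_fixture <- function(n_per = 20, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(10, 10))
  mk <- function(ds) {
    x <- do.call(rbind, lapply(1:2, function(cl) {
      sweep(matrix(rnorm(n_per * 2, sd = 0.5), n_per, 2), 2,
            centers[cl, ], `+`)
    }))
    colnames(x) <- c("f1", "f2")
    data_block(x, ds, point_ids = sprintf("%s_%03d", ds, seq_len(2 * n_per)),
               labels = rep(c("c1", "c2"), each = n_per))
  }
  list(a = mk("a"), b = mk("b"))
}

# Tiny multigraph over two datasets built from a shared 2-feature space.
make_small_fit <- function(n_per = 20, epochs = 80, seed = 3) {
  fx <- make_two_cluster_fixture(n_per, seed)
  suppressWarnings(integrate_datasets(
    list(fx$a, fx$b), config = embed_config(epochs = epochs, seed = seed)))
}

# Unweighted path graph wrapped as a multigraph (harmonic-transfer fixtures).
path_graph <- function(n, ids = sprintf("n%d", seq_len(n))) {
  m <- Matrix::bandSparse(n, k = 1, diagonals = list(rep(1, n - 1)),
                          symmetric = TRUE)
  b <- data_block(matrix(rnorm(n * 2), n, 2,
                         dimnames = list(NULL, c("f1", "f2"))), "d",
                  point_ids = ids)
  structure(list(membership = methods::as(m, "CsparseMatrix"),
                 index = coembed:::global_index(list(b))[, c("dataset",
                                                             "point_id")],
                 tags = list(codes = methods::as(m, "CsparseMatrix"),
                             labels = "own:d")),
            class = "multigraph")
}
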