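#' k-nearest-neighbor search within one ambient space
#'
#' Exact search uses a kd-tree; approximate search (for large spaces) uses a
#' seeded Annoy index with 50 random-projection trees. By default the search
#' is exact up to 5,000 points and approximate beyond.
#'
#' @param x Numeric coordinate matrix or [space_coords()].
#' @param k Number of neighbors (self excluded); clipped with a warning when
#'   `k >= n`.
#' @param method `"auto"`, `"exact"` or `"approx"`.
#' @param seed Seed for the approximate index.
#' @return A list of class `knn_result` with `idx` and `dist` matrices
#'   (`n` by `k`), distances sorted ascending per row, self excluded.
#' @export
knn_search <- function(x, k, method = c("auto", "exact", "approx"), seed = 0) {
  if (inherits(x, "space_coords")) x <- x$coords
  x <- as_dense(x)
  method <- match.arg(method)
  n <- nrow(x)
  if (k < 1) stopf("k must be at least 1")
  if (k >= n) {
    warnf("k = %d >= n = %d; clipping k to %d", k, n, n - 1)
    k <- n - 1
  }
  if (method == "auto") method <- if (n <= 5000) "exact" else "approx"

  if (method == "exact") {
    nn <- RANN::nn2(x, x, k = k + 1, treetype = "kd", searchtype = "standard")
    res <- drop_self(nn$nn.idx, nn$nn.dists)
  } else {
    ann <- methods::new(RcppAnnoy::AnnoyEuclidean, ncol(x))
    ann$setSeed(as.integer(seed %% .Machine$integer.max))
    for (i in seq_len(n)) ann$addItem(i - 1L, x[i, ])
    ann$build(50L)
    idx <- matrix(0L, n, k)
    dst <- matrix(0, n, k)
    for (i in seq_len(n)) {
      got <- ann$getNNsByItemList(i - 1L, k + 1L, -1L, TRUE)
      sel <- drop_self_row(got$item + 1L, got$distance, i, k)
      idx[i, ] <- sel$idx
      dst[i, ] <- sel$dist
    }
    res <- list(idx = idx, dist = dst)
  }
  structure(list(idx = res$idx, dist = res$dist, k = k), class = "knn_result")
}

# Remove each query's own row from a (k+1)-column kNN result. With duplicate
# points the self entry need not be first, so drop by index, not position.
drop_self <- function(idx, dist) {
  n <- nrow(idx)
  k <- ncol(idx) - 1L
  out_i <- matrix(0L, n, k)
  out_d <- matrix(0, n, k)
  for (i in seq_len(n)) {
    sel <- drop_self_row(idx[i, ], dist[i, ], i, k)
    out_i[i, ] <- sel$idx
    out_d[i, ] <- sel$dist
  }
  list(idx = out_i, dist = out_d)
}

drop_self_row <- function(idx, dist, self, k) {
  hit <- which(idx == self)
  keep <- if (length(hit)) seq_along(idx)[-hit[1]] else seq_len(length(idx) - 1L)
  keep <- keep[seq_len(min(k, length(keep)))]
  list(idx = idx[keep], dist = dist[keep])
}

# kNN of `query` points among `data` points (different sets; no self
# handling). Used for cross-dataset edges inside shared spaces and for
# label transfer.
knn_cross <- function(query, data, k, method = c("auto", "exact", "approx"),
                      seed = 0) {
  method <- match.arg(method)
  k <- min(k, nrow(data))
  if (method == "auto") method <- if (nrow(data) <= 5000) "exact" else "approx"
  if (method == "exact") {
    nn <- RANN::nn2(data, query, k = k, treetype = "kd",
                    searchtype = "standard")
    list(idx = nn$nn.idx, dist = nn$nn.dists, k = k)
  } else {
    ann <- methods::new(RcppAnnoy::AnnoyEuclidean, ncol(data))
    ann$setSeed(as.integer(seed %% .Machine$integer.max))
    for (i in seq_len(nrow(data))) ann$addItem(i - 1L, data[i, ])
    ann$build(50L)
    idx <- matrix(0L, nrow(query), k)
    dst <- matrix(0, nrow(query), k)
    for (i in seq_len(nrow(query))) {
      got <- ann$getNNsByVectorList(query[i, ], k, -1L, TRUE)
      idx[i, ] <- got$item + 1L
      dst[i, ] <- got$distance
    }
    list(idx = idx, dist = dst, k = k)
  }
}

#' Calibrate the local distance normalization for one point
#'
#' Given a point's sorted nearest-neighbor distances, finds the local
#' connectivity radius \eqn{\rho} (the distance to the nearest neighbor) and
#' the bandwidth \eqn{\sigma} such that
#' \deqn{\sum_j \exp\!\big(-\max(0, d_j - \rho) / \sigma\big) = \log_2 k.}
#' Together \eqn{(\rho, \sigma)} convert ambient distances into
#' manifold-normalized membership strengths: they realize a constant-radius
#' ball on the latent manifold, specific to the space being calibrated.
#'
#' \eqn{\sigma} is found by bisection on `(1e-8 m, 1e3 m]` with `m` the mean
#' neighbor distance, at most 64 iterations. If every distance is zero no
#' bandwidth satisfies the constraint and \eqn{\sigma} is set to a fixed
#' floor of `1e-3` with a warning.
#'
#' @param distances Sorted ascending neighbor distances for one point.
#' @param k Neighborhood size; defaults to `length(distances)`.
#' @return Named numeric vector `c(rho, sigma)`.
#' @export
smooth_knn_calibrate <- function(distances, k = length(distances)) {
  if (is.unsorted(distances)) stopf("distances must be sorted ascending")
  if (length(distances) < 1) stopf("need at least one distance")
  rho <- distances[1]
  mean_d <- mean(distances)
  if (mean_d <= 0) {
    warnf("all neighbor distances are zero; using bandwidth floor 1e-3")
    return(c(rho = rho, sigma = 1e-3))
  }
  target <- log2(k)
  lo <- 1e-8 * mean_d
  hi <- 1e3 * mean_d
  gap <- pmax(distances - rho, 0)
  for (iter in seq_len(64)) {
    mid <- (lo + hi) / 2
    val <- sum(exp(-gap / mid))
    if (val > target) hi <- mid else lo <- mid
  }
  c(rho = rho, sigma = (lo + hi) / 2)
}

# Vectorized calibration over the rows of a kNN distance matrix.
smooth_knn <- function(dist, k = ncol(dist)) {
  n <- nrow(dist)
  rho <- dist[, 1]
  sigma <- numeric(n)
  target <- log2(k)
  mean_d <- rowMeans(dist)
  gap <- pmax(dist - rho, 0)
  lo <- 1e-8 * mean_d
  hi <- 1e3 * mean_d
  zero <- mean_d <= 0
  if (any(zero)) {
    warnf("%d point(s) with all-zero neighbor distances; bandwidth floor 1e-3",
          sum(zero))
  }
  live <- which(!zero)
  if (length(live)) {
    g <- gap[live, , drop = FALSE]
    l <- lo[live]
    h <- hi[live]
    for (iter in seq_len(64)) {
      m <- (l + h) / 2
      val <- rowSums(exp(-g / m))
      up <- val > target
      h[up] <- m[up]
      l[!up] <- m[!up]
    }
    sigma[live] <- (l + h) / 2
  }
  sigma[zero] <- 1e-3
  tibble(rho = rho, sigma = sigma)
}

#' Directed membership strengths from calibrated neighborhoods
#'
#' Converts a kNN result plus per-point \eqn{(\rho, \sigma)} into the
#' directed fuzzy membership \eqn{\exp(-\max(0, d - \rho_p)/\sigma_p)} from
#' each point to each of its neighbors.
#'
#' @param neighbors A `knn_result` from [knn_search()].
#' @param params Tibble with per-point `rho` and `sigma` columns (from the
#'   calibration), aligned to the rows of `neighbors`.
#' @return Directed sparse matrix (`dgCMatrix`) of strengths in `(0, 1]`.
#' @export
membership_strengths <- function(neighbors, params) {
  idx <- neighbors$idx
  n <- nrow(idx)
  if (nrow(params) != n) stopf("params not aligned to neighbor lists")
  s <- exp(-pmax(neighbors$dist - params$rho, 0) / params$sigma)
  Matrix::sparseMatrix(i = rep(seq_len(n), ncol(idx)), j = as.vector(idx),
                       x = as.vector(s), dims = c(n, n))
}

#' Symmetrize directed memberships by fuzzy union
#'
#' Combines the two directed strengths of each ordered pair with the
#' probabilistic t-conorm \eqn{a + b - ab}, yielding the symmetric
#' membership matrix of the fuzzy simplicial set on one space.
#'
#' @param directed Square sparse matrix of directed strengths in `[0, 1]`.
#' @return Symmetric sparse matrix with zero diagonal.
#' @export
symmetrize_union <- function(directed) {
  tp <- Matrix::t(directed)
  out <- directed + tp - directed * tp
  Matrix::diag(out) <- 0
  Matrix::drop0(out)
}

#' Fuzzy simplicial set of one ambient space
#'
#' Convenience pipeline: kNN search, per-point calibration, directed
#' strengths, fuzzy union. This is the within-dataset edge construction of
#' the multigraph.
#'
#' @inheritParams knn_search
#' @param k Neighborhood size (default 15).
#' @return Symmetric sparse membership matrix over the points of the space.
#' @export
fuzzy_simplicial_set <- function(x, k = 15, method = "auto", seed = 0) {
  nn <- knn_search(x, k = k, method = method, seed = seed)
  params <- smooth_knn(nn$dist, k = nn$k)
  symmetrize_union(membership_strengths(nn, params))
}
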