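# Downstream consumers of the multigraph and embedding: label transfer and
# the four integration-quality metrics (transfer balanced accuracy,
# silhouette, alignment, structure preservation).

#' Label transfer by k nearest labeled neighbors
#'
#' Assigns each query point the most frequent label among its `k` nearest
#' *labeled* neighbors in the embedding (Euclidean distances; only labeled
#' points outside the query dataset are searched). Ties are broken in favor
#' of the tied class containing the nearest neighbor.
#'
#' @param embedding A `coembed_fit` or embedding tibble (with `dataset` and
#'   `dim_*` columns).
#' @param labels Character vector aligned to the embedding rows; `NA` marks
#'   unlabeled points.
#' @param query Dataset id(s) whose points should be predicted.
#' @param k Number of labeled neighbors (default 5).
#' @return Tibble `point_id`, `dataset`, `predicted` for the query points.
#' @export
transfer_labels_knn <- function(embedding, labels, query, k = 5) {
  if (inherits(embedding, "coembed_fit")) embedding <- embedding$embedding
  coords <- embedding_matrix(embedding)
  ds <- embedding$dataset
  labels <- as.character(labels)
  if (length(labels) != nrow(coords)) {
    stopf("labels not aligned to embedding rows")
  }
  is_query <- ds %in% query
  pool <- which(!is.na(labels) & !is_query)
  if (length(pool) == 0) stopf("no labeled points outside the query dataset")
  kk <- min(k, length(pool))
  qrows <- which(is_query)
  nn <- knn_cross(coords[qrows, , drop = FALSE],
                  coords[pool, , drop = FALSE], k = kk, method = "exact")
  pred <- character(length(qrows))
  for (ii in seq_along(qrows)) {
    neigh <- labels[pool[nn$idx[ii, ]]]
    tab <- table(neigh)
    best <- names(tab)[tab == max(tab)]
    if (length(best) > 1) {
      # nearest neighbor among the tied classes decides
      first_of <- vapply(best, function(cl) which(neigh == cl)[1], integer(1))
      best <- best[which.min(first_of)]
    }
    pred[ii] <- best
  }
  tibble(point_id = embedding$point_id[qrows], dataset = ds[qrows],
         predicted = pred)
}

#' Label transfer by harmonic functions on the multigraph
#'
#' Semi-supervised node classification: labeled points are clamped to their
#' class indicator vectors and every unlabeled point's class probabilities
#' satisfy the harmonic condition — each equals the membership-weighted
#' average of its neighbors'. Solved exactly by a sparse linear solve on the
#' unlabeled block. Points in connected components without any labeled
#' point cannot be reached and are returned with `NA` probabilities.
#'
#' @param graph A `multigraph` (or `coembed_fit`).
#' @param labels Character vector aligned to the graph's points; `NA` marks
#'   unlabeled points.
#' @return Tibble `point_id`, `dataset`, `predicted`, plus one probability
#'   column `p_<class>` per class; rows of labeled points carry their own
#'   label with probability 1.
#' @export
transfer_labels_harmonic <- function(graph, labels) {
  if (inherits(graph, "coembed_fit")) graph <- graph$graph
  stopifnot(inherits(graph, "multigraph"))
  w <- graph$membership
  n <- nrow(w)
  labels <- as.character(labels)
  if (length(labels) != n) stopf("labels not aligned to graph points")
  labeled <- which(!is.na(labels))
  if (length(labeled) == 0) stopf("at least one labeled point is required")
  classes <- sort(unique(labels[labeled]))
  y <- Matrix::sparseMatrix(i = labeled,
                            j = match(labels[labeled], classes),
                            x = 1, dims = c(n, length(classes)))
  probs <- matrix(NA_real_, n, length(classes))
  probs[labeled, ] <- as.matrix(y[labeled, , drop = FALSE])

  unlabeled <- setdiff(seq_len(n), labeled)
  if (length(unlabeled)) {
    ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    comp <- igraph::components(ig)$membership
    reachable <- unlabeled[comp[unlabeled] %in% unique(comp[labeled])]
    if (length(reachable) < length(unlabeled)) {
      warnf("%d point(s) in components without labels are unassignable",
            length(unlabeled) - length(reachable))
    }
    if (length(reachable)) {
      deg <- Matrix::rowSums(w)
      luu <- Matrix::Diagonal(x = deg[reachable]) -
        w[reachable, reachable, drop = FALSE]
      rhs <- w[reachable, labeled, drop = FALSE] %*%
        y[labeled, , drop = FALSE]
      sol <- tryCatch(
        as.matrix(Matrix::solve(luu, rhs)),
        error = function(e) {
          # damped Jacobi fallback for near-singular systems
          f <- matrix(1 / length(classes), length(reachable), length(classes))
          wuu <- w[reachable, reachable, drop = FALSE]
          dinv <- 1 / pmax(deg[reachable], .Machine$double.eps)
          for (it in seq_len(10000)) {
            fn <- dinv * as.matrix(wuu %*% f + rhs)
            if (max(abs(fn - f)) < 1e-8) { f <- fn; break }
            f <- fn
          }
          f
        })
      probs[reachable, ] <- sol
    }
  }
  rs <- rowSums(probs)
  ok <- !is.na(rs) & rs > 0
  probs[ok, ] <- probs[ok, , drop = FALSE] / rs[ok]
  pred <- rep(NA_character_, n)
  has <- !apply(is.na(probs), 1, any)
  pred[has] <- classes[max.col(probs[has, , drop = FALSE],
                               ties.method = "first")]
  pred[labeled] <- labels[labeled]
  out <- tibble(point_id = graph$index$point_id,
                dataset = graph$index$dataset, predicted = pred)
  colnames(probs) <- paste0("p_", classes)
  dplyr::bind_cols(out, as_tibble(probs))
}

#' Balanced accuracy of a label transfer
#'
#' The unweighted mean over classes of per-class recall, so rare classes
#' count as much as common ones. Classes with no true members are excluded
#' with a warning.
#'
#' @param truth,predicted Character vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stopf("truth and predicted differ in length")
  }
  keep <- !is.na(truth)
  truth <- truth[keep]
  predicted <- predicted[keep]
  classes <- unique(truth)
  recalls <- vapply(classes, function(cl) {
    mean(predicted[truth == cl] == cl, na.rm = FALSE)
  }, numeric(1))
  mean(recalls)
}

#' Mean silhouette of an embedding under labels
#'
#' Standard silhouette \eqn{s(i) = (b - a)/\max(a, b)} with Euclidean
#' distances, averaged over all points. Points in singleton classes score 0
#' (with a warning).
#'
#' @param embedding A `coembed_fit`, embedding tibble, or coordinate matrix.
#' @param labels Character vector of class labels aligned to the points.
#' @return Scalar in `[-1, 1]`.
#' @export
silhouette_mean <- function(embedding, labels) {
  coords <- embedding_matrix(embedding)
  labels <- as.character(labels)
  keep <- !is.na(labels)
  coords <- coords[keep, , drop = FALSE]
  labels <- labels[keep]
  f <- factor(labels)
  if (nlevels(f) < 2) stopf("silhouette needs at least two classes")
  if (any(table(f) < 2)) {
    warnf("singleton class(es) present; their points score 0")
  }
  sil <- cluster::silhouette(as.integer(f), dist(coords))
  mean(sil[, "sil_width"])
}

#' Dataset mixing (alignment) score
#'
#' The proportion of each point's `k` nearest neighbors (self excluded,
#' Euclidean distances in the embedding) that originate in a different
#' dataset, averaged over all points. 0 means the datasets occupy disjoint
#' regions; values near the inter-dataset mixing proportion of a random
#' arrangement mean thorough mixing.
#'
#' @param embedding A `coembed_fit`, embedding tibble, or coordinate matrix.
#' @param datasets Character vector of dataset ids per point (taken from the
#'   tibble/fit when omitted).
#' @param k Neighborhood size (default 5).
#' @return Scalar in `[0, 1]`.
#' @export
alignment_score <- function(embedding, datasets = NULL, k = 5) {
  if (inherits(embedding, "coembed_fit")) embedding <- embedding$embedding
  coords <- embedding_matrix(embedding)
  if (is.null(datasets)) {
    if (!is.data.frame(embedding) || !"dataset" %in% colnames(embedding)) {
      stopf("`datasets` is required when embedding is a bare matrix")
    }
    datasets <- embedding$dataset
  }
  if (length(unique(datasets)) < 2) {
    warnf("single dataset; alignment is 0 by definition")
    return(0)
  }
  nn <- knn_search(coords, k = k, method = "exact")
  other <- matrix(datasets[nn$idx], nrow(nn$idx)) != datasets
  mean(rowMeans(other))
}

#' Structure preservation score
#'
#' Pearson correlation between all pairwise distances of one dataset's
#' points in its high-dimensional ambient space and the corresponding
#' distances in the embedding. Above `max_pairs` pairs, a seeded random
#' subset of pairs is used.
#'
#' @param space High-dimensional coordinates: a [space_coords()] or matrix,
#'   one row per point.
#' @param embedding Embedded coordinates of the *same* points, same order.
#' @param max_pairs Pair-count threshold before subsampling (default 1e6).
#' @param seed Seed for pair subsampling.
#' @return Pearson correlation in `[-1, 1]`, or `NA` (with a warning) when
#'   a distance vector has zero variance.
#' @export
structure_score <- function(space, embedding, max_pairs = 1e6, seed = 0) {
  hi <- if (inherits(space, "space_coords")) space$coords else as_dense(space)
  lo <- embedding_matrix(embedding)
  n <- nrow(hi)
  if (nrow(lo) != n) stopf("space and embedding cover different point sets")
  if (n < 3) stopf("need at least three points")
  n_pairs <- n * (n - 1) / 2
  if (n_pairs <= max_pairs) {
    dh <- as.vector(dist(hi))
    dl <- as.vector(dist(lo))
  } else {
    pairs <- with_seed(seed, {
      i <- sample.int(n, max_pairs, replace = TRUE)
      j <- sample.int(n - 1, max_pairs, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)
      cbind(i, j)
    })
    dh <- sqrt(rowSums((hi[pairs[, 1], , drop = FALSE] -
                          hi[pairs[, 2], , drop = FALSE])^2))
    dl <- sqrt(rowSums((lo[pairs[, 1], , drop = FALSE] -
                          lo[pairs[, 2], , drop = FALSE])^2))
  }
  if (stats::sd(dh) == 0 || stats::sd(dl) == 0) {
    warnf("zero-variance distance vector; structure score undefined")
    return(NA_real_)
  }
  cor(dh, dl, method = "pearson")
}

#' Integration quality report
#'
#' Computes the four benchmark metrics for a fit: label-transfer balanced
#' accuracy (5 labeled nearest neighbors, predicting the query dataset from
#' the others), mean silhouette under the true labels, alignment, and the
#' per-dataset structure scores (averaged).
#'
#' @param fit A `coembed_fit`.
#' @param labels Character vector of true labels aligned to the embedding
#'   rows (`NA` allowed).
#' @param query Dataset id to predict for the transfer metric.
#' @param spaces Optional named list (by dataset id) of high-dimensional
#'   [space_coords()]/matrices for the structure score.
#' @param k Neighborhood size for transfer and alignment (default 5).
#' @return One-row tibble with `transfer`, `silhouette`, `alignment`,
#'   `structure` and the parameters used.
#' @export
metric_report <- function(fit, labels, query, spaces = NULL, k = 5) {
  emb <- if (inherits(fit, "coembed_fit")) fit$embedding else fit
  pred <- transfer_labels_knn(emb, labels, query = query, k = k)
  qmask <- emb$dataset %in% query
  transfer <- balanced_accuracy(labels[qmask], pred$predicted)
  sil <- silhouette_mean(emb, labels)
  ali <- alignment_score(emb, k = k)
  structure <- NA_real_
  if (!is.null(spaces)) {
    vals <- vapply(names(spaces), function(ds) {
      rows <- which(emb$dataset == ds)
      sp <- spaces[[ds]]
      hi <- if (inherits(sp, "space_coords")) sp$coords else as_dense(sp)
      structure_score(hi, embedding_matrix(emb)[rows, , drop = FALSE])
    }, numeric(1))
    structure <- mean(vals)
  }
  tibble(transfer = transfer, silhouette = sil, alignment = ali,
         structure = structure, k = k, query = paste(query, collapse = "+"))
}
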