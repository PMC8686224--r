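#' TF-IDF weighting of a binary accessibility matrix
#'
#' The standard preprocessing for binarized chromatin-accessibility (and
#' similar presence/absence) matrices before latent semantic indexing: each
#' entry becomes term frequency times smoothed inverse document frequency,
#' \deqn{w_{cf} = \frac{x_{cf}}{\sum_{f'} x_{cf'}} \cdot
#'       \log\!\left(1 + \frac{N}{1 + \mathrm{df}_f}\right),}
#' where \eqn{N} is the number of points and \eqn{\mathrm{df}_f} the number
#' of points in which feature \eqn{f} is present. The smoothed IDF is
#' strictly positive, so the sparsity pattern is preserved exactly.
#'
#' @param x Binary (0/1) points-by-features matrix, dense or sparse.
#' @return Weighted matrix of the same shape and class family as the input.
#' @export
tfidf_transform <- function(x) {
  if (inherits(x, "data_block")) x <- x$matrix
  vals <- if (is_sparse(x)) x@x else as.numeric(x)
  if (length(vals) && any(vals != 0 & vals != 1)) {
    stopf("tfidf_transform expects a binary (0/1) matrix")
  }
  rs <- Matrix::rowSums(x)
  if (any(rs == 0)) {
    stopf("tfidf_transform: all-zero row(s): %s",
          paste(head(which(rs == 0), 5), collapse = ", "))
  }
  n <- nrow(x)
  df <- Matrix::colSums(x != 0)
  idf <- log(1 + n / (1 + df))
  if (is_sparse(x)) {
    out <- Matrix::Diagonal(x = 1 / rs) %*% x %*% Matrix::Diagonal(x = idf)
    dimnames(out) <- dimnames(x)
    methods::as(out, "CsparseMatrix")
  } else {
    (x / rs) * rep(idf, each = n)
  }
}

# Deterministic sign convention: within each component, the loading of
# largest magnitude is made positive (first index wins ties).
fix_signs <- function(scores, loadings) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Reduce a matrix to its top component scores
#'
#' PCA (centered) or truncated SVD (uncentered, the convention for TF-IDF
#' weighted accessibility matrices). Components are ordered by decreasing
#' explained variance and carry a deterministic sign convention (the loading
#' of largest magnitude in each component is positive), so results are
#' reproducible across runs and platforms.
#'
#' Exact decompositions are used for small problems; for larger ones a
#' truncated solver (irlba) is used under the supplied seed.
#'
#' @param x Numeric matrix (or [data_block()]), points in rows.
#' @param d Number of components to keep; at most `min(dim(x))`.
#' @param method `"pca"` or `"truncated_svd"`.
#' @param seed Integer seed for the truncated solver.
#' @return Score matrix (`nrow(x)` by `d`), row names preserved, with
#'   attributes `sdev` (component standard deviations) and `method`.
#' @export
reduce_dimension <- function(x, d, method = c("pca", "truncated_svd"),
                             seed = 0) {
  if (inherits(x, "data_block")) x <- x$matrix
  method <- match.arg(method)
  n <- nrow(x)
  p <- ncol(x)
  max_d <- min(n, p)
  if (d > max_d) {
    stopf("d = %d exceeds min(n_points, n_features); maximum is %d", d, max_d)
  }
  vals <- if (is_sparse(x)) x@x else x
  if (any(!is.finite(vals))) stopf("matrix contains non-finite entries")

  small <- max_d <= 200 || d > 0.5 * max_d
  if (method == "pca") {
    if (small) {
      pc <- prcomp(as_dense(x), center = TRUE, scale. = FALSE, rank. = d)
      fixed <- fix_signs(pc$x[, seq_len(d), drop = FALSE],
                         pc$rotation[, seq_len(d), drop = FALSE])
      sdev <- pc$sdev[seq_len(d)]
    } else {
      ctr <- as.numeric(Matrix::colMeans(x))
      sv <- with_seed(seed, irlba::irlba(x, nv = d, nu = d, center = ctr,
                                         tol = 1e-9))
      fixed <- fix_signs(sweep(sv$u, 2, sv$d, `*`), sv$v)
      sdev <- sv$d / sqrt(max(1, nrow(x) - 1))
    }
  } else {
    if (small) {
      sv <- svd(as_dense(x), nu = d, nv = d)
      dvals <- sv$d[seq_len(d)]
      fixed <- fix_signs(sweep(sv$u, 2, dvals, `*`), sv$v)
      sdev <- dvals / sqrt(max(1, n - 1))
    } else {
      sv <- with_seed(seed, irlba::irlba(x, nv = d, nu = d, tol = 1e-9))
      fixed <- fix_signs(sweep(sv$u, 2, sv$d, `*`), sv$v)
      sdev <- sv$d / sqrt(max(1, n - 1))
    }
  }
  scores <- fixed$scores
  rownames(scores) <- rownames(x)
  colnames(scores) <- paste0("comp_", seq_len(d))
  attr(scores, "sdev") <- sdev
  attr(scores, "method") <- method
  scores
}

#' Coordinates of a set of points inside one ambient space
#'
#' A `space_coords` object holds the reduced coordinates of every point of
#' one or more datasets inside a single ambient space: either a dataset's
#' own space (its full feature space, reduced) or a shared feature space
#' built on the features common to several datasets.
#'
#' @param coords Numeric matrix of coordinates, one row per point.
#' @param index Tibble with columns `dataset` and `point_id`, one row per
#'   coordinate row.
#' @param space_id Character vector of the dataset ids the space covers.
#' @return A `space_coords` object.
#' @export
space_coords <- function(coords, index, space_id) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(index)) {
    stopf("coords and index disagree: %d rows vs %d", nrow(coords), nrow(index))
  }
  if (any(!is.finite(coords))) stopf("space coordinates must be finite")
  if (ncol(coords) < 1) stopf("space dimension must be at least 1")
  key <- paste(index$dataset, index$point_id)
  if (anyDuplicated(key)) stopf("each point may appear once per space")
  if (!all(index$dataset %in% space_id)) {
    stopf("index contains datasets outside space_id")
  }
  structure(list(coords = coords, index = as_tibble(index[c("dataset", "point_id")]),
                 space_id = space_id, dim = ncol(coords)),
            class = "space_coords")
}

#' @export
print.space_coords <- function(x, ...) {
  cat(sprintf("<space_coords [%s]> %d points in %d dims\n",
              paste(x$space_id, collapse = "+"), nrow(x$coords), x$dim))
  invisible(x)
}

#' Build a dataset's own ambient space
#'
#' Reduces the block's full feature space to `d` component scores (or keeps
#' the raw coordinates when the block already has `d` or fewer features).
#'
#' @param block A [data_block()].
#' @param d Target dimension (default 50, the convention for single-cell
#'   omics inputs).
#' @inheritParams reduce_dimension
#' @return A [space_coords()] covering the one dataset.
#' @export
own_space <- function(block, d = 50, method = "pca", seed = 0) {
  stopifnot(inherits(block, "data_block"))
  idx <- tibble(dataset = block$dataset_id, point_id = block$point_ids)
  d <- min(d, nrow(block$matrix))
  if (ncol(block$matrix) <= d) {
    return(space_coords(as_dense(block$matrix), idx, block$dataset_id))
  }
  sc <- reduce_dimension(block$matrix, d = d, method = method,
                         seed = child_seed(seed, block$dataset_id))
  space_coords(sc, idx, block$dataset_id)
}

#' Build a shared feature space for two or more datasets
#'
#' Restricts every block to the features present in all of them (in one
#' canonical sorted order), stacks the points, and jointly reduces the
#' stacked matrix. Inputs are assumed to be already normalized per modality;
#' set `log1p = TRUE` to apply a log(1 + x) transform to the restricted
#' matrices first.
#'
#' @param ... Two or more [data_block()] objects (or one list of them).
#' @param d Target dimension; lowered with a warning when the feature
#'   intersection is smaller.
#' @param method Reduction method passed to [reduce_dimension()].
#' @param log1p Apply `log1p` to the restricted matrices before reduction.
#' @param seed Integer seed.
#' @return A [space_coords()] covering every input dataset.
#' @export
build_shared_space <- function(..., d = 50, method = "pca", log1p = FALSE,
                               seed = 0) {
  blocks <- list(...)
  if (length(blocks) == 1 && !inherits(blocks[[1]], "data_block")) {
    blocks <- blocks[[1]]
  }
  if (length(blocks) < 2) stopf("a shared space needs at least two blocks")
  ids <- vapply(blocks, function(b) b$dataset_id, character(1))
  shared <- Reduce(intersect, lapply(blocks, function(b) b$feature_names))
  if (length(shared) == 0) {
    stopf("no shared features between blocks %s", paste(ids, collapse = ", "))
  }
  shared <- sort(shared)
  if (length(shared) < d) {
    warnf("shared space %s: intersection has %d features; lowering d from %d",
          paste(ids, collapse = "+"), length(shared), d)
    d <- length(shared)
  }
  mats <- lapply(blocks, function(b) {
    m <- b$matrix[, match(shared, b$feature_names), drop = FALSE]
    if (log1p) m <- log1p(m)
    m
  })
  stacked <- do.call(rbind, lapply(mats, as_dense))
  idx <- tibble(
    dataset = rep(ids, vapply(blocks, n_points, integer(1))),
    point_id = unlist(lapply(blocks, function(b) b$point_ids), use.names = FALSE)
  )
  d <- min(d, nrow(stacked))
  sc <- reduce_dimension(stacked, d = d, method = method,
                         seed = child_seed(seed, paste(ids, collapse = "+")))
  space_coords(sc, idx, ids)
}
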