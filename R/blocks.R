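#' Create a data block
#'
#' A data block is one dataset to be integrated: a numeric points-by-features
#' matrix (dense or sparse) together with its feature names, a short dataset
#' identifier, optional per-point labels, and an optional influence weight
#' used by the embedding loss.
#'
#' @param matrix Numeric matrix or `Matrix::sparseMatrix`, points in rows.
#' @param dataset_id Short string identifying the dataset (e.g. `"rna"`).
#' @param feature_names Character vector of feature names, one per column.
#'   Defaults to the matrix column names.
#' @param point_ids Character vector of unique point identifiers, one per
#'   row. Defaults to the matrix row names, or `"<dataset_id>_000001"` style
#'   identifiers when absent.
#' @param labels Optional character vector of per-point labels; `NA` or `""`
#'   marks an unlabeled point.
#' @param weight Optional influence weight in `[0, 1]` for the embedding
#'   cross-entropy loss. When `NULL`, a default is resolved at integration
#'   time: 0.8 for a designated reference dataset and 0.2 for the others, or
#'   1 for every dataset when no reference is named.
#'
#' @return An object of class `data_block`.
#' @examples
#' m <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("g", 1:4)))
#' b <- data_block(m, "rna")
#' b
#' @export
data_block <- function(matrix, dataset_id,
                       feature_names = colnames(matrix),
                       point_ids = rownames(matrix),
                       labels = NULL, weight = NULL) {
  if (!(is.matrix(matrix) || is_sparse(matrix))) {
    stopf("`matrix` must be a base matrix or a sparse Matrix")
  }
  n <- nrow(matrix)
  p <- ncol(matrix)
  if (n < 1) stopf("a data block needs at least one point")
  if (!is.character(dataset_id) || length(dataset_id) != 1 || !nzchar(dataset_id)) {
    stopf("`dataset_id` must be a single non-empty string")
  }
  if (is.null(feature_names)) {
    stopf("feature names are required (set colnames or pass `feature_names`)")
  }
  feature_names <- as.character(feature_names)
  if (length(feature_names) != p) {
    stopf("block '%s': %d feature names for %d columns", dataset_id,
          length(feature_names), p)
  }
  if (anyDuplicated(feature_names)) {
    stopf("block '%s': duplicated feature names", dataset_id)
  }
  if (is.null(point_ids)) {
    point_ids <- sprintf("%s_%06d", dataset_id, seq_len(n))
  }
  point_ids <- as.character(point_ids)
  if (length(point_ids) != n || anyDuplicated(point_ids)) {
    stopf("block '%s': point ids must be unique, one per row", dataset_id)
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) {
      stopf("block '%s': %d labels for %d points", dataset_id, length(labels), n)
    }
    labels[!is.na(labels) & labels == ""] <- NA_character_
  }
  if (!is.null(weight)) {
    if (!is.numeric(weight) || length(weight) != 1 || weight < 0 || weight > 1) {
      stopf("`weight` must be a single number in [0, 1]")
    }
    weight <- as.numeric(weight)
  }
  rownames(matrix) <- point_ids
  colnames(matrix) <- feature_names
  structure(
    list(matrix = matrix, dataset_id = dataset_id,
         feature_names = feature_names, point_ids = point_ids,
         labels = labels, weight = weight),
    class = "data_block"
  )
}

#' @export
print.data_block <- function(x, ...) {
  cat(sprintf("<data_block '%s'> %d points x %d features (%s)%s%s\n",
              x$dataset_id, nrow(x$matrix), ncol(x$matrix),
              if (is_sparse(x$matrix)) "sparse" else "dense",
              if (is.null(x$labels)) "" else
                sprintf(", %d labeled", sum(!is.na(x$labels))),
              if (is.null(x$weight)) "" else sprintf(", weight %.2f", x$weight)))
  invisible(x)
}

#' @export
dim.data_block <- function(x) dim(x$matrix)

n_points <- function(block) nrow(block$matrix)

# Resolve per-dataset embedding weights. Explicit per-block weights win;
# otherwise the reference dataset (if any) gets 0.8 and the rest 0.2; with no
# reference all datasets weigh 1 (equal influence at full strength).
resolve_weights <- function(blocks, reference = NULL, weights = NULL) {
  ids <- vapply(blocks, function(b) b$dataset_id, character(1))
  if (!is.null(weights)) {
    if (length(weights) != length(blocks)) {
      stopf("got %d weights for %d blocks", length(weights), length(blocks))
    }
    w <- as.numeric(weights)
  } else if (!is.null(reference)) {
    if (!reference %in% ids) stopf("reference dataset '%s' not among blocks", reference)
    w <- ifelse(ids == reference, 0.8, 0.2)
  } else {
    w <- rep(1, length(blocks))
  }
  explicit <- !vapply(blocks, function(b) is.null(b$weight), logical(1))
  w[explicit] <- vapply(blocks[explicit], function(b) b$weight, numeric(1))
  if (any(w < 0 | w > 1)) stopf("dataset weights must lie in [0, 1]")
  setNames(w, ids)
}

# Global point index: concatenation of the blocks in user-supplied order.
global_index <- function(blocks) {
  ids <- vapply(blocks, function(b) b$dataset_id, character(1))
  if (anyDuplicated(ids)) stopf("dataset ids must be unique across blocks")
  tibble(
    dataset = rep(ids, vapply(blocks, n_points, integer(1))),
    point_id = unlist(lapply(blocks, function(b) b$point_ids), use.names = FALSE)
  ) |> dplyr::mutate(row = dplyr::row_number())
}
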