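#' Integrate multiple datasets into a joint embedding
#'
#' End-to-end pipeline: build each dataset's own ambient space (top
#' principal components of its full feature space), build shared ambient
#' spaces from the features common to dataset pairs, recover
#' manifold-normalized fuzzy memberships within every space, assemble the
#' single cross-dataset multigraph, and optimize a joint low-dimensional
#' embedding by weighted fuzzy cross-entropy.
#'
#' Internally points are processed in a canonical order (sorted by point id
#' within each dataset) and restored to input order on output, so the result
#' is invariant to row permutations of the inputs.
#'
#' @param blocks List of [data_block()] objects (or a single block).
#' @param shared `"auto"` (build a shared space for every dataset pair with
#'   common features), `"none"`, or a list of pre-built [space_coords()].
#' @param cross Optional cross-distance tibble (see
#'   [read_cross_distances()]) giving explicit distances between points of
#'   different datasets.
#' @param reference Optional dataset id to treat as the reference modality;
#'   it receives weight 0.8 and the others 0.2 (the convention when one
#'   modality, typically scRNA-seq, is of higher quality).
#' @param weights Optional numeric vector of per-dataset weights in
#'   `[0, 1]`, one per block, overriding the defaults.
#' @param own_dim,shared_dim Ambient dimension for own and shared spaces
#'   (default 50 each, the single-cell convention).
#' @param n_neighbors Neighborhood size for all spaces (default 15).
#' @param knn_method `"auto"`, `"exact"` or `"approx"`, see [knn_search()].
#' @param all_datasets_space With three or more blocks, additionally build
#'   one shared space over all datasets together (default `FALSE`:
#'   pairwise spaces only).
#' @param log1p_shared Apply `log1p` when building shared spaces.
#' @param config An [embed_config()]; its seed is the seed of the whole run.
#' @param verbose Print stage progress.
#' @return An object of class `coembed_fit` with elements `embedding`
#'   (tibble: `point_id`, `dataset`, `dim_1..dim_d`, in input order),
#'   `graph` (the `multigraph`, same order), `weights`, `config`, and
#'   `loss` (final fuzzy cross-entropy over the graph edges).
#' @examples
#' sc <- make_cluster_overlap_pair(n_clusters = 4, m = 4, n_per_cluster = 30,
#'                                 seed = 1)
#' fit <- integrate_datasets(sc$blocks, config = embed_config(epochs = 50))
#' glance(fit)
#' @export
integrate_datasets <- function(blocks, shared = "auto", cross = NULL,
                               reference = NULL, weights = NULL,
                               own_dim = 50, shared_dim = 50,
                               n_neighbors = 15, knn_method = "auto",
                               all_datasets_space = FALSE,
                               log1p_shared = FALSE,
                               config = embed_config(), verbose = FALSE) {
  if (inherits(blocks, "data_block")) blocks <- list(blocks)
  if (length(blocks) == 0) stopf("at least one data block is required")
  if (!all(vapply(blocks, inherits, logical(1), "data_block"))) {
    stopf("`blocks` must be data_block objects")
  }
  seed <- config$seed
  w <- resolve_weights(blocks, reference, weights)

  # canonical internal order: sort points by id within each block
  perms <- lapply(blocks, function(b) order(b$point_ids))
  cblocks <- Map(function(b, p) {
    b$matrix <- b$matrix[p, , drop = FALSE]
    b$point_ids <- b$point_ids[p]
    if (!is.null(b$labels)) b$labels <- b$labels[p]
    b
  }, blocks, perms)
  index <- global_index(cblocks)

  log_msg("building own ambient spaces", verbose = verbose)
  own_spaces <- lapply(cblocks, own_space, d = own_dim, seed = seed)

  shared_spaces <- list()
  if (is.character(shared) && length(shared) == 1) {
    if (shared == "auto" && length(cblocks) > 1) {
      combos <- utils::combn(length(cblocks), 2, simplify = FALSE)
      if (all_datasets_space && length(cblocks) > 2) {
        combos <- c(combos, list(seq_along(cblocks)))
      }
      for (cmb in combos) {
        feats <- Reduce(intersect,
                        lapply(cblocks[cmb], function(b) b$feature_names))
        if (length(feats) == 0) next
        log_msg("building shared space for ",
                paste(vapply(cblocks[cmb], function(b) b$dataset_id,
                             character(1)), collapse = "+"),
                verbose = verbose)
        sp <- build_shared_space(cblocks[cmb], d = shared_dim,
                                 log1p = log1p_shared, seed = seed)
        shared_spaces[[paste0("shared:",
                              paste(sp$space_id, collapse = "+"))]] <- sp
      }
    } else if (!shared %in% c("auto", "none")) {
      stopf("`shared` must be \"auto\", \"none\", or a list of space_coords")
    }
  } else if (is.list(shared)) {
    for (sp in shared) {
      if (!inherits(sp, "space_coords")) {
        stopf("`shared` list entries must be space_coords")
      }
      # every point the space covers must exist in the blocks
      invisible(index_rows(index, sp$index$dataset, sp$index$point_id))
      shared_spaces[[paste0("shared:",
                            paste(sp$space_id, collapse = "+"))]] <- sp
    }
  }

  log_msg("computing within-dataset fuzzy sets", verbose = verbose)
  own_sets <- lapply(cblocks, function(b) {
    sp <- own_spaces[[match(b$dataset_id,
                            vapply(cblocks, function(x) x$dataset_id,
                                   character(1)))]]
    fuzzy_simplicial_set(sp, k = n_neighbors, method = knn_method,
                         seed = child_seed(seed, b$dataset_id))
  })
  names(own_sets) <- vapply(cblocks, function(b) b$dataset_id, character(1))

  shared_sets <- lapply(shared_spaces, function(sp) {
    cross_memberships(sp, index, k = n_neighbors, method = knn_method,
                      seed = child_seed(seed, paste(sp$space_id,
                                                    collapse = "+")))
  })

  cross_sets <- list()
  if (!is.null(cross) && nrow(cross) > 0) {
    log_msg("calibrating cross-distance table", verbose = verbose)
    # note: table indices refer to the blocks' *input* row order
    cross_sets <- list(
      "cross:table" = cross_memberships_from_table(cross, index, blocks,
                                                   k = n_neighbors))
  }

  log_msg("assembling multigraph", verbose = verbose)
  graph <- assemble_multigraph(own_sets, shared_sets, cross_sets, index)
  check_pair_coverage(graph)

  log_msg("spectral initialization", verbose = verbose)
  wg <- weighted_graph(graph, w)
  init <- spectral_init(wg, d = config$n_components,
                        seed = child_seed(seed, "spectral"))

  log_msg("optimizing embedding", verbose = verbose)
  emb <- optimize_embedding(graph, init, config, weights = w)

  ed <- edge_weights(graph, w)
  nu <- embedding_nu(emb, ed$i, ed$j, config$a, config$b)
  loss <- cross_entropy(ed$mu, nu)

  # restore input order
  back <- index_rows(
    index,
    rep(vapply(blocks, function(b) b$dataset_id, character(1)),
        vapply(blocks, n_points, integer(1))),
    unlist(lapply(blocks, function(b) b$point_ids), use.names = FALSE))
  emb_out <- emb[back, , drop = FALSE]
  graph_out <- graph
  graph_out$membership <- graph$membership[back, back, drop = FALSE]
  graph_out$tags$codes <- graph$tags$codes[back, back, drop = FALSE]
  graph_out$index <- graph$index[back, ]

  emb_tbl <- as_tibble(graph_out$index)
  colnames(emb_out) <- paste0("dim_", seq_len(ncol(emb_out)))
  emb_tbl <- dplyr::bind_cols(emb_tbl, as_tibble(emb_out))

  structure(list(embedding = emb_tbl, graph = graph_out, weights = w,
                 config = config, loss = loss,
                 n_skipped = attr(emb, "n_skipped")),
            class = "coembed_fit")
}

# Edge strengths scaled by dataset weights; used for initialization so a
# zero-weight dataset contributes no internal structure there either.
weighted_graph <- function(graph, weights) {
  ed <- edge_weights(graph, weights)
  keep <- ed$w > 0
  n <- nrow(graph$membership)
  s <- Matrix::sparseMatrix(i = ed$i[keep], j = ed$j[keep],
                            x = ed$mu[keep] * ed$w[keep], dims = c(n, n))
  Matrix::forceSymmetric(s, uplo = "U")
}

#' @export
print.coembed_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(paste0("<coembed_fit> %d points, %d dataset(s), %d-dim ",
                     "embedding\n  edges: %d; cross-entropy: %.4g\n"),
              g$n_points, g$n_datasets, g$n_components, g$n_edges, g$loss))
  invisible(x)
}

#' Tidy the joint embedding
#'
#' @param x A `coembed_fit`.
#' @param ... Unused.
#' @return Tibble with `point_id`, `dataset` and `dim_*` columns, one row
#'   per point, in input order.
#' @export
tidy.coembed_fit <- function(x, ...) x$embedding

#' One-row summary of an integration fit
#'
#' @param x A `coembed_fit`.
#' @param ... Unused.
#' @return One-row tibble: points, datasets, edges, embedding dimension,
#'   epochs, final cross-entropy.
#' @export
glance.coembed_fit <- function(x, ...) {
  tibble(
    n_points = nrow(x$embedding),
    n_datasets = length(unique(x$embedding$dataset)),
    n_edges = Matrix::nnzero(x$graph$membership) / 2,
    n_components = x$config$n_components,
    epochs = resolve_epochs(x$config$epochs, nrow(x$embedding)),
    loss = x$loss
  )
}

#' Plot a joint embedding
#'
#' @param object A `coembed_fit`.
#' @param colour_by `"dataset"` (default) or the name of a column to join
#'   from `labels`.
#' @param labels Optional tibble with `point_id`, `dataset` and extra
#'   columns to color by.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coembed_fit <- function(object, colour_by = "dataset",
                                 labels = NULL, ...) {
  df <- object$embedding
  if (!is.null(labels)) {
    df <- dplyr::left_join(df, labels, by = c("point_id", "dataset"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dim_1, y = .data$dim_2,
                                   colour = .data[[colour_by]])) +
    ggplot2::geom_point(size = 0.6, alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "dim 1", y = "dim 2", colour = colour_by)
}

# Extract the embedding coordinate matrix from a fit or tibble.
embedding_matrix <- function(embedding) {
  if (inherits(embedding, "coembed_fit")) embedding <- embedding$embedding
  if (is.matrix(embedding)) return(embedding)
  cols <- grep("^dim_", colnames(embedding), value = TRUE)
  if (length(cols) == 0) stopf("no dim_* columns found in embedding")
  as.matrix(embedding[cols])
}
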