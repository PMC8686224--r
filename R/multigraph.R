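# Cross-dataset fuzzy graph assembly.
#
# Within-dataset edges come from each dataset's own ambient space;
# cross-dataset edges come from shared feature spaces (kNN restricted to
# points of *other* datasets, calibrated per point within the shared space)
# or from a user-supplied cross-distance table. All sources are merged with
# the probabilistic t-conorm so the result is a single symmetric fuzzy graph
# over the global point index.

# Map (dataset, point_id) pairs to rows of the global index.
index_rows <- function(index, dataset, point_id) {
  key <- paste(index$dataset, index$point_id, sep = "\r")
  pos <- match(paste(dataset, point_id, sep = "\r"), key)
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    stopf("point '%s' of dataset '%s' is not in the global index",
          point_id[bad], dataset[bad])
  }
  pos
}

#' Cross-dataset memberships from a shared space
#'
#' For every point in the shared space, finds its `k` nearest neighbors
#' *belonging to a different dataset*, calibrates \eqn{(\rho, \sigma)} on
#' those cross distances (the neighborhood normalization specific to the
#' shared feature space), converts them to membership strengths, and
#' symmetrizes by fuzzy union. Same-dataset proximity inside a shared space
#' is deliberately ignored: within-dataset geometry is the business of each
#' dataset's own space.
#'
#' @param space A [space_coords()] covering two or more datasets.
#' @param index Global point index (tibble with `dataset`, `point_id`).
#' @param k Neighborhood size (default 15).
#' @param method kNN search mode, see [knn_search()].
#' @param seed Seed for approximate search.
#' @return Symmetric sparse membership matrix over the global index with
#'   cross-dataset entries only.
#' @export
cross_memberships <- function(space, index, k = 15, method = "auto", seed = 0) {
  stopifnot(inherits(space, "space_coords"))
  if (length(unique(space$index$dataset)) < 2) {
    stopf("a shared space must cover at least two datasets")
  }
  n_global <- nrow(index)
  rows_global <- index_rows(index, space$index$dataset, space$index$point_id)
  ds <- space$index$dataset
  tri <- list(i = integer(0), j = integer(0), x = numeric(0))
  for (v in unique(ds)) {
    mine <- which(ds == v)
    others <- which(ds != v)
    kk <- min(k, length(others))
    nn <- knn_cross(space$coords[mine, , drop = FALSE],
                    space$coords[others, , drop = FALSE],
                    k = kk, method = method, seed = child_seed(seed, v))
    params <- smooth_knn(nn$dist, k = kk)
    s <- exp(-pmax(nn$dist - params$rho, 0) / params$sigma)
    tri$i <- c(tri$i, rep(rows_global[mine], kk))
    tri$j <- c(tri$j, rows_global[others][as.vector(nn$idx)])
    tri$x <- c(tri$x, as.vector(s))
  }
  directed <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x,
                                   dims = c(n_global, n_global))
  symmetrize_union(directed)
}

#' Cross-dataset memberships from an explicit distance table
#'
#' Each anchored point's supplied cross distances are calibrated exactly as
#' within-space neighborhoods (with `k` clipped to the number of available
#' distances) and converted to memberships. Points absent from the table are
#' simply unanchored.
#'
#' @param table Cross-distance tibble (`dataset_a`, `index_a`, `dataset_b`,
#'   `index_b`, `distance`; 1-based indices), see [read_cross_distances()].
#' @param index Global point index.
#' @param blocks The list of [data_block()] objects the indices refer to.
#' @param k Neighborhood size cap (default 15).
#' @return Symmetric sparse membership matrix over the global index.
#' @export
cross_memberships_from_table <- function(table, index, blocks, k = 15) {
  validate_cross_distances(table)
  ids <- vapply(blocks, function(b) b$dataset_id, character(1))
  pid <- function(ds, i) {
    b <- blocks[[match(ds, ids)]]
    if (is.null(b)) stopf("cross table names unknown dataset '%s'", ds)
    b$point_ids[i]
  }
  rows_a <- index_rows(index, table$dataset_a,
                       unlist(Map(pid, table$dataset_a, table$index_a)))
  rows_b <- index_rows(index, table$dataset_b,
                       unlist(Map(pid, table$dataset_b, table$index_b)))
  # directed: both endpoints of every pair act as an anchor
  from <- c(rows_a, rows_b)
  to <- c(rows_b, rows_a)
  d <- c(table$distance, table$distance)
  n_global <- nrow(index)
  tri <- list(i = integer(0), j = integer(0), x = numeric(0))
  for (p in unique(from)) {
    sel <- which(from == p)
    ord <- sel[order(d[sel])]
    kk <- min(k, length(ord))
    ord <- ord[seq_len(kk)]
    cal <- smooth_knn_calibrate(d[ord], k = kk)
    s <- exp(-pmax(d[ord] - cal["rho"], 0) / cal["sigma"])
    tri$i <- c(tri$i, rep(p, kk))
    tri$j <- c(tri$j, to[ord])
    tri$x <- c(tri$x, s)
  }
  directed <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x,
                                   dims = c(n_global, n_global),
                                   use.last.ij = TRUE)
  symmetrize_union(directed)
}

#' Assemble the multigraph
#'
#' Merges the per-dataset fuzzy sets (within-dataset edges), the shared-space
#' cross memberships, and optional table-based cross memberships into one
#' symmetric fuzzy graph over the global point index. Edges present in
#' several sources are combined with the probabilistic t-conorm
#' \eqn{a + b - ab}; each edge is tagged with the source space contributing
#' the largest pre-merge strength.
#'
#' @param own_sets Named list (by dataset id) of symmetric membership
#'   matrices, one per dataset, each over that dataset's own points.
#' @param shared_sets List of global symmetric cross-membership matrices from
#'   [cross_memberships()]; names are used as space tags.
#' @param cross_sets Optional list of global matrices from
#'   [cross_memberships_from_table()].
#' @param index Global point index (tibble `dataset`, `point_id`).
#' @return A `multigraph`: list with `membership` (symmetric `dgCMatrix` of
#'   strengths in `(0,1]`), `index`, and `tags` (sparse integer codes plus a
#'   label vector).
#' @export
assemble_multigraph <- function(own_sets, shared_sets = list(),
                                cross_sets = list(), index) {
  datasets <- unique(index$dataset)
  if (!setequal(names(own_sets), datasets)) {
    stopf("need exactly one own-space fuzzy set per dataset; missing: %s",
          paste(setdiff(datasets, names(own_sets)), collapse = ", "))
  }
  counts <- table(factor(index$dataset, levels = datasets))
  for (v in datasets) {
    if (nrow(own_sets[[v]]) != counts[[v]]) {
      stopf("own-space set for '%s' has %d points; index has %d",
            v, nrow(own_sets[[v]]), counts[[v]])
    }
  }
  g <- methods::as(Matrix::bdiag(own_sets[datasets]), "CsparseMatrix")
  labels <- paste0("own:", datasets)
  tg <- methods::as(g, "TsparseMatrix")
  block_of <- rep(seq_along(datasets), counts)
  codes <- Matrix::sparseMatrix(i = tg@i + 1L, j = tg@j + 1L,
                                x = block_of[tg@i + 1L],
                                dims = dim(g))

  name_or <- function(lst, prefix) {
    if (length(lst) == 0) return(lst)
    nms <- names(lst) %||% rep("", length(lst))
    nms[nms == ""] <- paste0(prefix, which(nms == ""))
    setNames(lst, nms)
  }
  extra <- c(name_or(shared_sets, "shared:"), name_or(cross_sets, "cross:"))
  for (nm in names(extra)) {
    s <- extra[[nm]]
    if (!all(dim(s) == nrow(index))) {
      stopf("cross set '%s' is not over the global index", nm)
    }
    labels <- c(labels, nm)
    code_new <- length(labels)
    # tag bookkeeping: the source with the larger pre-merge strength wins
    st <- methods::as(Matrix::drop0(s), "TsparseMatrix")
    old_vals <- g[cbind(st@i + 1L, st@j + 1L)]
    stronger <- st@x > old_vals
    if (any(stronger)) {
      codes[cbind(st@i[stronger] + 1L, st@j[stronger] + 1L)] <- code_new
    }
    g <- g + s - g * s
  }
  g <- Matrix::drop0(g)
  # numerical guard: the t-conorm keeps values in (0, 1] exactly, but float
  # arithmetic can overshoot by an ulp
  g@x <- pmin(g@x, 1)

  structure(list(membership = g, index = as_tibble(index[c("dataset", "point_id")]),
                 tags = list(codes = methods::as(codes, "CsparseMatrix"),
                             labels = labels)),
            class = "multigraph")
}

#' @export
print.multigraph <- function(x, ...) {
  nd <- length(unique(x$index$dataset))
  ne <- Matrix::nnzero(x$membership) / 2
  cat(sprintf("<multigraph> %d points from %d dataset(s), %d undirected edges\n",
              nrow(x$membership), nd, ne))
  invisible(x)
}

# Warn when a dataset pair has no cross information at all (the graph is
# block-disconnected across that pair).
check_pair_coverage <- function(graph) {
  ds <- unique(graph$index$dataset)
  if (length(ds) < 2) return(invisible(NULL))
  m <- graph$membership
  rows <- split(seq_len(nrow(m)), graph$index$dataset)
  for (a in seq_along(ds)) {
    for (b in seq_len(a - 1)) {
      sub <- m[rows[[ds[a]]], rows[[ds[b]]], drop = FALSE]
      if (Matrix::nnzero(sub) == 0) {
        warnf("no cross edges between datasets '%s' and '%s'; they will not be integrated",
              ds[a], ds[b])
      }
    }
  }
  invisible(NULL)
}

# Per-edge dataset weights for the layout loss: within dataset v the edge
# weighs omega_v; a cross edge between i and j weighs (omega_i + omega_j)/2.
edge_weights <- function(graph, weights) {
  ds <- graph$index$dataset
  tg <- methods::as(graph$membership, "TsparseMatrix")
  keep <- tg@i < tg@j
  wi <- weights[ds[tg@i[keep] + 1L]]
  wj <- weights[ds[tg@j[keep] + 1L]]
  list(i = tg@i[keep] + 1L, j = tg@j[keep] + 1L, mu = tg@x[keep],
       w = ifelse(wi == wj, wi, (wi + wj) / 2))
}
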