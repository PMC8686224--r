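#' Read a data block from disk
#'
#' Supported formats: dense TSV/CSV with a header row of feature names and a
#' first column of point identifiers, or sparse Matrix Market (`.mtx`) with
#' `<stem>.features.txt` and `<stem>.points.txt` sidecar files (one name per
#' line).
#'
#' @param path Path to the matrix file.
#' @param dataset_id Dataset identifier for the block; defaults to the file
#'   stem.
#' @param format One of `"auto"`, `"tsv"`, `"csv"`, `"mtx"`. `"auto"` picks
#'   by file extension.
#' @param labels Optional path to a two-column labels TSV (see
#'   [read_labels()]).
#' @return A [data_block()].
#' @export
read_data_block <- function(path, dataset_id = NULL, format = "auto",
                            labels = NULL) {
  if (!file.exists(path)) stopf("input file does not exist: %s", path)
  format <- match.arg(format, c("auto", "tsv", "csv", "mtx"))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
                     stopf("cannot infer format from extension of %s", path))
  }
  stem <- sub("\\.[^.]*$", "", path)
  dataset_id <- dataset_id %||% basename(stem)

  if (format == "mtx") {
    m <- tryCatch(Matrix::readMM(path),
                  error = function(e) stopf("malformed Matrix Market file %s: %s",
                                            path, conditionMessage(e)))
    m <- methods::as(m, "CsparseMatrix")
    fpath <- paste0(stem, ".features.txt")
    ppath <- paste0(stem, ".points.txt")
    for (side in c(fpath, ppath)) {
      if (!file.exists(side)) stopf("missing sidecar file: %s", side)
    }
    feats <- readLines(fpath)
    pts <- readLines(ppath)
    if (length(feats) != ncol(m)) {
      stopf("feature sidecar %s has %d lines but matrix has %d columns",
            fpath, length(feats), ncol(m))
    }
    if (length(pts) != nrow(m)) {
      stopf("point sidecar %s has %d lines but matrix has %d rows",
            ppath, length(pts), nrow(m))
    }
    block <- data_block(m, dataset_id, feature_names = feats, point_ids = pts)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- tryCatch(
      read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                 stringsAsFactors = FALSE),
      error = function(e) stopf("failed to parse %s: %s", path,
                                conditionMessage(e)))
    if (ncol(df) < 2) stopf("%s: expected a point-id column plus features", path)
    pts <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stopf("%s: non-numeric entries in matrix body", path)
    block <- data_block(m, dataset_id, feature_names = colnames(df)[-1],
                        point_ids = pts)
  }
  if (!is.null(labels)) {
    lab <- read_labels(labels)
    block$labels <- unname(lab[block$point_ids])
  }
  block
}

#' Write a data block to disk
#'
#' @param block A [data_block()].
#' @param path Output path. For `"mtx"` the path names the matrix file and
#'   `<stem>.features.txt` / `<stem>.points.txt` sidecars are written next to
#'   it.
#' @param format One of `"auto"`, `"tsv"`, `"csv"`, `"mtx"`.
#' @return Invisibly, the paths written.
#' @export
write_data_block <- function(block, path, format = "auto") {
  stopifnot(inherits(block, "data_block"))
  format <- match.arg(format, c("auto", "tsv", "csv", "mtx"))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", "tsv")
  }
  stem <- sub("\\.[^.]*$", "", path)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(methods::as(block$matrix, "dMatrix"),
                                "TsparseMatrix"), path)
    writeLines(block$feature_names, paste0(stem, ".features.txt"))
    writeLines(block$point_ids, paste0(stem, ".points.txt"))
    paths <- c(path, paste0(stem, c(".features.txt", ".points.txt")))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(point_id = block$point_ids,
                     as_dense(block$matrix), check.names = FALSE)
    colnames(df) <- c("point_id", block$feature_names)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    paths <- path
  }
  invisible(paths)
}

#' Read or write per-point labels
#'
#' Labels are stored as a two-column TSV with header `point_id` and `label`;
#' an empty label marks an unlabeled point.
#'
#' @param path File path.
#' @return `read_labels()` returns a named character vector (names are point
#'   ids, `NA` for unlabeled points).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stopf("labels file does not exist: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = NULL)
  if (ncol(df) < 2) stopf("%s: expected two columns (point id, label)", path)
  lab <- as.character(df[[2]])
  lab[lab == ""] <- NA_character_
  setNames(lab, as.character(df[[1]]))
}

#' @param labels Named character vector (names are point ids) or the `labels`
#'   field of a [data_block()] together with its point ids.
#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  stopifnot(!is.null(names(labels)))
  out <- ifelse(is.na(labels), "", labels)
  write.table(data.frame(point_id = names(labels), label = out),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a cross-distance table
#'
#' Explicit cross-dataset distances for a subset of point pairs (e.g. anchor
#' points whose latent manifold position is known). On disk this is a
#' five-column TSV `dataset_a`, `index_a`, `dataset_b`, `index_b`,
#' `distance` with 0-based point indices; in R the indices are 1-based.
#'
#' @param path File path.
#' @return A tibble with columns `dataset_a`, `index_a`, `dataset_b`,
#'   `index_b`, `distance` (1-based indices).
#' @export
read_cross_distances <- function(path) {
  if (!file.exists(path)) stopf("cross-distance file does not exist: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("dataset_a", "index_a", "dataset_b", "index_b", "distance")
  if (!all(need %in% colnames(df))) {
    stopf("%s: expected columns %s", path, paste(need, collapse = ", "))
  }
  tbl <- as_tibble(df[need])
  tbl$index_a <- as.integer(tbl$index_a) + 1L
  tbl$index_b <- as.integer(tbl$index_b) + 1L
  validate_cross_distances(tbl)
  tbl
}

#' @param table Cross-distance tibble as returned by [read_cross_distances()].
#' @rdname read_cross_distances
#' @export
write_cross_distances <- function(table, path) {
  validate_cross_distances(table)
  out <- table
  out$index_a <- as.integer(out$index_a) - 1L
  out$index_b <- as.integer(out$index_b) - 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_cross_distances <- function(table) {
  if (any(!is.finite(table$distance)) || any(table$distance < 0)) {
    stopf("cross distances must be finite and non-negative")
  }
  self <- table$dataset_a == table$dataset_b & table$index_a == table$index_b
  if (any(self)) stopf("cross-distance table contains self-pairs")
  invisible(table)
}

#' Export an embedding to TSV
#'
#' Writes columns `point_id`, `dataset`, `dim_1` ... `dim_d`.
#'
#' @param embedding A `coembed_fit` or the embedding tibble from [tidy()].
#' @param path Output TSV path.
#' @export
write_embedding <- function(embedding, path) {
  if (inherits(embedding, "coembed_fit")) embedding <- embedding$embedding
  write.table(as.data.frame(embedding), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an embedding TSV written by [write_embedding()]
#' @param path TSV path.
#' @return Tibble with `point_id`, `dataset` and `dim_*` columns.
#' @export
read_embedding <- function(path) {
  if (!file.exists(path)) stopf("embedding file does not exist: %s", path)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("point_id", "dataset") %in% colnames(df))) {
    stopf("%s: expected point_id and dataset columns", path)
  }
  as_tibble(df)
}

#' Export a multigraph
#'
#' Writes the symmetric membership matrix as Matrix Market, the global point
#' index as a two-column TSV (`dataset`, 0-based `index`), and the per-edge
#' source-space tags as a three-column TSV (0-based `row`, `col`,
#' `space_tag`).
#'
#' @param graph A `multigraph` object.
#' @param stem Output path stem; `<stem>.mtx`, `<stem>.index.tsv` and
#'   `<stem>.tags.tsv` are written.
#' @export
write_multigraph <- function(graph, stem) {
  stopifnot(inherits(graph, "multigraph"))
  Matrix::writeMM(methods::as(graph$membership, "TsparseMatrix"),
                  paste0(stem, ".mtx"))
  idx <- graph$index |>
    dplyr::group_by(.data$dataset) |>
    dplyr::mutate(local = dplyr::row_number() - 1L) |>
    dplyr::ungroup()
  write.table(data.frame(dataset = idx$dataset, index = idx$local,
                         point_id = idx$point_id),
              paste0(stem, ".index.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  tg <- methods::as(graph$tags$codes, "TsparseMatrix")
  keep <- tg@i < tg@j
  write.table(data.frame(row = tg@i[keep], col = tg@j[keep],
                         space_tag = graph$tags$labels[tg@x[keep]]),
              paste0(stem, ".tags.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paste0(stem, c(".mtx", ".index.tsv", ".tags.tsv")))
}
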