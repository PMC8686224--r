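# Synthetic multimodal scenarios for controlled evaluation. Each generator
# returns a `coembed_scenario`: a list of data blocks, an optional
# cross-distance table, and per-point ground truth.

new_scenario <- function(blocks, cross = NULL, truth, params, seed) {
  structure(list(blocks = blocks, cross = cross, truth = as_tibble(truth),
                 params = params, seed = seed),
            class = "coembed_scenario")
}

#' @export
print.coembed_scenario <- function(x, ...) {
  cat(sprintf("<coembed_scenario> %d block(s): %s%s\n",
              length(x$blocks),
              paste(vapply(x$blocks, function(b)
                sprintf("%s[%dx%d]", b$dataset_id, nrow(b$matrix),
                        ncol(b$matrix)), character(1)), collapse = ", "),
              if (is.null(x$cross)) "" else
                sprintf("; %d cross distances", nrow(x$cross))))
  invisible(x)
}

# Arc length of the spiral t (cos t, sin t) from 0: (t sqrt(1+t^2) + asinh t)/2.
spiral_arc <- function(t) (t * sqrt(1 + t^2) + asinh(t)) / 2

#' Swiss-roll / rectangle multimodal pair
#'
#' One dataset of `n` points sampled from the canonical 3-D Swiss-roll
#' surface `(t cos t, y, t sin t)` with `t` uniform on `[3pi/2, 9pi/2]`, and
#' a second dataset of `n` points from the 2-D rectangle the roll unrolls
#' to (long side = arc length of the spiral, short side matching the roll's
#' height). The two datasets have disjoint feature spaces but describe the
#' same rectangular manifold. For a fraction of the points (the anchors) the
#' position along the manifold — arc length normalized to `[0, 1]` — is
#' known, and cross-dataset distances between anchors are the absolute
#' differences of these positions.
#'
#' @param n Points per dataset (default 10000).
#' @param anchored_fraction Fraction of points per dataset whose manifold
#'   position is known (default 0.01).
#' @param height Width of the roll / rectangle short side (default 21).
#' @param seed Integer seed.
#' @return A `coembed_scenario` with blocks `roll` (3-D) and `rect` (2-D),
#'   a cross-distance tibble over all anchor pairs, and `truth` holding each
#'   point's normalized manifold `position`.
#' @export
make_swiss_roll_pair <- function(n = 10000, anchored_fraction = 0.01,
                                 height = 21, seed = 0) {
  if (n < 100) stopf("n must be at least 100")
  if (anchored_fraction <= 0 || anchored_fraction > 1) {
    stopf("anchored_fraction must be in (0, 1]")
  }
  n_anchor <- round(anchored_fraction * n)
  if (n_anchor < 2) stopf("anchored fraction yields fewer than 2 anchors")
  t0 <- 3 * pi / 2
  t1 <- 9 * pi / 2
  arc0 <- spiral_arc(t0)
  arc_total <- spiral_arc(t1) - arc0

  sc <- with_seed(seed, {
    t <- runif(n, t0, t1)
    y1 <- runif(n, 0, height)
    pos1 <- (spiral_arc(t) - arc0) / arc_total
    x1 <- cbind(t * cos(t), y1, t * sin(t))
    pos2 <- runif(n)
    y2 <- runif(n, 0, height)
    x2 <- cbind(pos2 * arc_total, y2)
    anchors1 <- sample.int(n, n_anchor)
    anchors2 <- sample.int(n, n_anchor)
    list(t = t, x1 = x1, pos1 = pos1, x2 = x2, pos2 = pos2,
         anchors1 = anchors1, anchors2 = anchors2)
  })
  colnames(sc$x1) <- c("roll_x", "roll_y", "roll_z")
  colnames(sc$x2) <- c("rect_u", "rect_v")
  b1 <- data_block(sc$x1, "roll",
                   point_ids = sprintf("roll_%06d", seq_len(n)))
  b2 <- data_block(sc$x2, "rect",
                   point_ids = sprintf("rect_%06d", seq_len(n)))
  grid <- expand.grid(ia = sc$anchors1, ib = sc$anchors2)
  cross <- tibble(dataset_a = "roll", index_a = grid$ia,
                  dataset_b = "rect", index_b = grid$ib,
                  distance = abs(sc$pos1[grid$ia] - sc$pos2[grid$ib]))
  truth <- tibble(dataset = rep(c("roll", "rect"), each = n),
                  point_id = c(b1$point_ids, b2$point_ids),
                  position = c(sc$pos1, sc$pos2))
  new_scenario(list(b1, b2), cross, truth,
               params = list(n = n, anchored_fraction = anchored_fraction,
                             height = height, t_range = c(t0, t1),
                             arc_total = arc_total,
                             anchors = list(roll = sc$anchors1,
                                            rect = sc$anchors2)),
               seed = seed)
}

# Smooth high-contrast random field on a grid: coarse Gaussian noise,
# bilinearly upsampled, then pushed through a sigmoid so the marginal
# resembles the strong foreground/background contrast of glyph images.
random_prototype <- function(nrow_px, ncol_px, coarse = 7) {
  z <- matrix(rnorm(coarse * coarse), coarse, coarse)
  ri <- seq(1, coarse, length.out = nrow_px)
  ci <- seq(1, coarse, length.out = ncol_px)
  i0 <- pmin(floor(ri), coarse - 1)
  j0 <- pmin(floor(ci), coarse - 1)
  fi <- ri - i0
  fj <- ci - j0
  up <- outer(seq_len(nrow_px), seq_len(ncol_px), function(r, c) {
    z[cbind(i0[r], j0[c])] * (1 - fi[r]) * (1 - fj[c]) +
      z[cbind(i0[r] + 1, j0[c])] * fi[r] * (1 - fj[c]) +
      z[cbind(i0[r], j0[c] + 1)] * (1 - fi[r]) * fj[c] +
      z[cbind(i0[r] + 1, j0[c] + 1)] * fi[r] * fj[c]
  })
  up <- (up - mean(up)) / stats::sd(up)
  1 / (1 + exp(-3 * up))
}

#' Split-image two-modality pair
#'
#' Emulates the statistics of splitting glyph images into overlapping left
#' and right halves: `n_classes` class-prototype images (smooth
#' high-contrast random fields on a 28 x 28 grid), per-sample pixel noise,
#' values clipped to `[0, 1]`. Dataset 1 holds the flattened 28 x 15 left
#' half of each image, dataset 2 the 28 x 15 right half; the halves share a
#' 28 x 2 column overlap whose pixels carry identical feature names, so a
#' shared feature space can be recovered from them. Gaussian noise with
#' standard deviation equal to the maximum pixel value (= 1 after clipping)
#' is added to dataset 1 only.
#'
#' @param n Number of images (each contributes one point to both datasets).
#' @param n_classes Number of classes (default 10).
#' @param image_shape Image grid (default `c(28, 28)`).
#' @param half_width Columns per half (default 15, giving a 2-column
#'   overlap).
#' @param sample_noise_sd Per-pixel within-class noise before clipping
#'   (default 0.1).
#' @param seed Integer seed.
#' @return A `coembed_scenario` with blocks `left` and `right` (420
#'   features each for the defaults), no cross table (the shared pixels
#'   carry the correspondence), and `truth` holding each point's class.
#' @export
make_split_image_pair <- function(n = 2000, n_classes = 10,
                                  image_shape = c(28, 28), half_width = 15,
                                  sample_noise_sd = 0.1, seed = 0) {
  if (n < 10 * n_classes) stopf("need at least 10 points per class")
  nr <- image_shape[1]
  nc <- image_shape[2]
  if (2 * half_width <= nc) stopf("halves must overlap: 2*half_width > ncol")

  sc <- with_seed(seed, {
    protos <- lapply(seq_len(n_classes), function(cl)
      random_prototype(nr, nc))
    cls <- sort(rep_len(seq_len(n_classes), n))
    imgs <- matrix(0, n, nr * nc)
    for (i in seq_len(n)) {
      img <- protos[[cls[i]]] + rnorm(nr * nc, sd = sample_noise_sd)
      imgs[i, ] <- as.vector(img)
    }
    imgs[imgs < 0] <- 0
    imgs[imgs > 1] <- 1
    list(imgs = imgs, cls = cls,
         noise1 = matrix(rnorm(n * nr * half_width), n))
  })
  px_names <- as.vector(outer(seq_len(nr), seq_len(nc), function(r, c)
    sprintf("px_r%02d_c%02d", r, c)))
  left_cols <- which(rep(seq_len(nc), each = nr) <= half_width)
  right_cols <- which(rep(seq_len(nc), each = nr) > nc - half_width)

  max_px <- max(sc$imgs)  # = 1 after clipping
  left <- sc$imgs[, left_cols, drop = FALSE] + max_px * sc$noise1
  right <- sc$imgs[, right_cols, drop = FALSE]
  colnames(left) <- px_names[left_cols]
  colnames(right) <- px_names[right_cols]
  ids <- sprintf("img_%06d", seq_len(n))
  class_labels <- sprintf("class_%02d", sc$cls)
  b1 <- data_block(left, "left", point_ids = ids, labels = class_labels)
  b2 <- data_block(right, "right", point_ids = ids, labels = class_labels)
  truth <- tibble(dataset = rep(c("left", "right"), each = n),
                  point_id = c(ids, ids),
                  label = c(class_labels, class_labels))
  new_scenario(list(b1, b2), NULL, truth,
               params = list(n = n, n_classes = n_classes,
                             image_shape = image_shape,
                             half_width = half_width,
                             n_overlap = length(intersect(colnames(left),
                                                          colnames(right))),
                             noise_sd = max_px,
                             sample_noise_sd = sample_noise_sd),
               seed = seed)
}

#' Two datasets with partially overlapping cluster sets
#'
#' Gaussian clusters in a shared latent space: dataset A carries clusters
#' `1..n_clusters`; dataset B carries the first `m` of them (same latent
#' centroids) plus `n_clusters - m` B-only clusters. Each dataset is
#' observed through its own random linear map into its own feature space,
#' with a block of features common to both maps so a shared feature space
#' exists.
#'
#' @param n_clusters Clusters per dataset (default 10).
#' @param m Number of clusters shared between the datasets (1 to
#'   `n_clusters`).
#' @param n_per_cluster Points per cluster (default 200).
#' @param latent_dim Latent space dimension (default 10).
#' @param dims Feature-space dimension of each dataset (default 60 each).
#' @param n_overlap Number of features common to both datasets (default
#'   20).
#' @param centroid_sd Latent centroid spread (default 5).
#' @param within_sd Within-cluster latent spread (default 1).
#' @param feature_noise_sd Observation noise per feature (default 0.1).
#' @param seed Integer seed.
#' @return A `coembed_scenario` with blocks `A` and `B`, labeled points,
#'   and `truth` holding each point's cluster label (shared clusters carry
#'   the same label in both datasets).
#' @export
make_cluster_overlap_pair <- function(n_clusters = 10, m = n_clusters,
                                      n_per_cluster = 200, latent_dim = 10,
                                      dims = c(60, 60), n_overlap = 20,
                                      centroid_sd = 5, within_sd = 1,
                                      feature_noise_sd = 0.1, seed = 0) {
  if (m < 1 || m > n_clusters) stopf("m must be between 1 and n_clusters")
  n_feat_total <- sum(dims) - n_overlap
  if (n_overlap > min(dims)) stopf("n_overlap exceeds a dataset's dimension")

  sc <- with_seed(seed, {
    cent_shared <- matrix(rnorm(n_clusters * latent_dim, sd = centroid_sd),
                          n_clusters)
    cent_bonly <- matrix(rnorm(n_clusters * latent_dim, sd = centroid_sd),
                         n_clusters)
    loadings <- matrix(rnorm(latent_dim * n_feat_total, sd = 1 / sqrt(latent_dim)),
                       latent_dim)
    draw <- function(centroids, labs) {
      lat <- centroids[labs, , drop = FALSE] +
        matrix(rnorm(length(labs) * latent_dim, sd = within_sd), length(labs))
      lat
    }
    labs_a <- rep(seq_len(n_clusters), each = n_per_cluster)
    labs_b <- rep(seq_len(n_clusters), each = n_per_cluster)
    lat_a <- draw(cent_shared, labs_a)
    # B: clusters 1..m shared; the rest are B-only centroids
    cent_b <- cent_shared
    if (m < n_clusters) {
      cent_b[(m + 1):n_clusters, ] <- cent_bonly[(m + 1):n_clusters, ]
    }
    lat_b <- draw(cent_b, labs_b)
    noise <- function(nr, ncl) matrix(rnorm(nr * ncl, sd = feature_noise_sd),
                                      nr)
    list(labs_a = labs_a, labs_b = labs_b,
         xa = lat_a %*% loadings[, seq_len(dims[1])] +
           noise(nrow(lat_a), dims[1]),
         xb = lat_b %*% loadings[, (n_feat_total - dims[2] + 1):n_feat_total] +
           noise(nrow(lat_b), dims[2]))
  })
  feat_names <- sprintf("f_%04d", seq_len(n_feat_total))
  fa <- feat_names[seq_len(dims[1])]
  fb <- feat_names[(n_feat_total - dims[2] + 1):n_feat_total]
  lab_a <- sprintf("shared_%02d", sc$labs_a)
  lab_b <- ifelse(sc$labs_b <= m, sprintf("shared_%02d", sc$labs_b),
                  sprintf("bonly_%02d", sc$labs_b))
  colnames(sc$xa) <- fa
  colnames(sc$xb) <- fb
  ids_a <- sprintf("A_%06d", seq_along(lab_a))
  ids_b <- sprintf("B_%06d", seq_along(lab_b))
  ba <- data_block(sc$xa, "A", point_ids = ids_a, labels = lab_a)
  bb <- data_block(sc$xb, "B", point_ids = ids_b, labels = lab_b)
  truth <- tibble(dataset = c(rep("A", length(ids_a)), rep("B", length(ids_b))),
                  point_id = c(ids_a, ids_b), label = c(lab_a, lab_b))
  new_scenario(list(ba, bb), NULL, truth,
               params = list(n_clusters = n_clusters, m = m,
                             n_per_cluster = n_per_cluster,
                             latent_dim = latent_dim, dims = dims,
                             n_overlap = n_overlap,
                             centroid_sd = centroid_sd,
                             within_sd = within_sd,
                             feature_noise_sd = feature_noise_sd),
               seed = seed)
}

#' Export a scenario through the standard writers
#'
#' Writes each block's matrix (TSV), labels (if any), the ground truth, and
#' the cross-distance table (if any) into a directory.
#'
#' @param scenario A `coembed_scenario`.
#' @param dir Output directory (created if missing).
#' @param format Matrix format for [write_data_block()].
#' @return Invisibly, the files written.
#' @export
write_scenario <- function(scenario, dir, format = "tsv") {
  stopifnot(inherits(scenario, "coembed_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (b in scenario$blocks) {
    ext <- if (format == "mtx") "mtx" else format
    p <- file.path(dir, paste0(b$dataset_id, ".", ext))
    write_data_block(b, p, format = format)
    paths <- c(paths, p)
    if (!is.null(b$labels)) {
      lp <- file.path(dir, paste0(b$dataset_id, ".labels.tsv"))
      write_labels(setNames(b$labels, b$point_ids), lp)
      paths <- c(paths, lp)
    }
  }
  tp <- file.path(dir, "truth.tsv")
  write.table(as.data.frame(scenario$truth), tp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, tp)
  if (!is.null(scenario$cross)) {
    cp <- file.path(dir, "cross_distances.tsv")
    write_cross_distances(scenario$cross, cp)
    paths <- c(paths, cp)
  }
  invisible(paths)
}
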