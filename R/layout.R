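#' Fit the low-dimensional membership kernel
#'
#' The fuzzy membership of a pair of embedded points at distance `r` is
#' modeled as \eqn{\nu(r) = 1 / (1 + a r^{2b})}. `(a, b)` are chosen by
#' least squares so that \eqn{\nu} matches the piecewise target that is 1 up
#' to `min_dist` and decays as \eqn{\exp(-(r - \mathrm{min\_dist}) /
#' \mathrm{spread})} beyond it, over a fixed grid on `[0, 3 spread]`.
#'
#' @param min_dist Distance below which embedded points are considered
#'   fully connected (default 0.5).
#' @param spread Scale of the decay beyond `min_dist` (default 1.0).
#' @return Named numeric vector `c(a, b)`.
#' @export
fit_curve_params <- function(min_dist = 0.5, spread = 1.0) {
  if (!(min_dist > 0 && min_dist < spread)) {
    stopf("need 0 < min_dist < spread")
  }
  r <- seq(0, 3 * spread, length.out = 300)
  target <- ifelse(r <= min_dist, 1, exp(-(r - min_dist) / spread))
  fit <- tryCatch(
    nls(target ~ 1 / (1 + a * r^(2 * b)), start = list(a = 1, b = 1),
        control = stats::nls.control(maxiter = 200)),
    error = function(e) {
      stopf("kernel fit did not converge (%s)", conditionMessage(e))
    })
  res <- sqrt(mean(stats::residuals(fit)^2))
  if (!is.finite(res) || res > 0.25) {
    stopf("kernel fit did not converge; RMS residual %.3g", res)
  }
  cf <- coef(fit)
  c(a = unname(cf["a"]), b = unname(cf["b"]))
}

# Membership in the embedding space for given pairs of rows.
embedding_nu <- function(emb, i, j, a, b) {
  r2 <- rowSums((emb[i, , drop = FALSE] - emb[j, , drop = FALSE])^2)
  1 / (1 + a * r2^b)
}

#' Fuzzy cross-entropy between graph and embedding memberships
#'
#' The layout objective: for paired edge memberships \eqn{\mu} (manifold
#' graph) and \eqn{\nu} (embedding space),
#' \deqn{\sum_e \mu \log\frac{\mu}{\nu} +
#'       (1-\mu) \log\frac{1-\mu}{1-\nu},}
#' with \eqn{\nu} clamped to `[1e-12, 1 - 1e-12]`. Terms with \eqn{\mu} at 0
#' or 1 use the \eqn{0 \log 0 = 0} convention.
#'
#' @param mu,nu Numeric vectors of equal length with values in `[0, 1]`.
#' @return The scalar loss.
#' @export
cross_entropy <- function(mu, nu) {
  if (length(mu) != length(nu)) stopf("mu and nu differ in length")
  nu <- pmin(pmax(nu, 1e-12), 1 - 1e-12)
  attract <- ifelse(mu > 0, mu * log(mu / nu), 0)
  repel <- ifelse(mu < 1, (1 - mu) * log((1 - mu) / (1 - nu)), 0)
  sum(attract + repel)
}

#' Spectral initialization of the embedding
#'
#' Initial coordinates from the `d` nontrivial eigenvectors of the symmetric
#' normalized graph Laplacian, rescaled to a fixed coordinate range of 10.
#' Disconnected components are laid out independently and placed on a grid
#' so their bounding boxes do not overlap; tiny components (or an
#' eigensolver failure) fall back to a seeded random layout.
#'
#' @param graph A `multigraph` or symmetric non-negative sparse matrix.
#' @param d Embedding dimension.
#' @param seed Integer seed (solver start vector and random fallbacks).
#' @return Numeric `n` by `d` matrix.
#' @export
spectral_init <- function(graph, d = 2, seed = 0) {
  m <- if (inherits(graph, "multigraph")) graph$membership else graph
  n <- nrow(m)
  if (n == 1) return(matrix(0, 1, d))
  ig <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  comp <- igraph::components(ig)
  k_comp <- comp$no
  coords <- matrix(0, n, d)
  for (ci in seq_len(k_comp)) {
    rows <- which(comp$membership == ci)
    sub <- m[rows, rows, drop = FALSE]
    coords[rows, ] <- component_layout(sub, d, child_seed(seed, paste0("comp", ci)))
  }
  if (k_comp > 1) {
    # grid placement, largest component first, spacing 3x the layout range
    ord <- order(tabulate(comp$membership, k_comp), decreasing = TRUE)
    side <- ceiling(sqrt(k_comp))
    spacing <- 30
    for (pos in seq_len(k_comp)) {
      ci <- ord[pos]
      rows <- which(comp$membership == ci)
      off <- c(((pos - 1) %% side) * spacing,
               -((pos - 1) %/% side) * spacing)
      coords[rows, 1] <- coords[rows, 1] + off[1]
      if (d >= 2) coords[rows, 2] <- coords[rows, 2] + off[2]
    }
  }
  coords
}

component_layout <- function(sub, d, seed) {
  mcomp <- nrow(sub)
  if (mcomp <= d + 2) {
    return(with_seed(seed, matrix(runif(mcomp * d, -5, 5), mcomp, d)))
  }
  vecs <- tryCatch({
    deg <- Matrix::rowSums(sub)
    dinv <- 1 / sqrt(pmax(deg, .Machine$double.eps))
    nrm <- Matrix::Diagonal(x = dinv) %*% sub %*% Matrix::Diagonal(x = dinv)
    nrm <- methods::as(methods::as(
      Matrix::forceSymmetric((nrm + Matrix::t(nrm)) / 2), "generalMatrix"),
      "CsparseMatrix")
    if (mcomp <= 200) {
      es <- eigen(as.matrix(nrm), symmetric = TRUE)
      es$vectors[, seq(2, d + 1), drop = FALSE]
    } else {
      iv <- with_seed(seed, runif(mcomp, -1, 1))
      es <- RSpectra::eigs_sym(nrm, k = d + 1, which = "LA",
                               opts = list(initvec = iv))
      ord <- order(es$values, decreasing = TRUE)
      es$vectors[, ord[seq(2, d + 1)], drop = FALSE]
    }
  }, error = function(e) {
    warnf("eigensolver failed (%s); random initialization", conditionMessage(e))
    with_seed(seed, matrix(runif(mcomp * d, -5, 5), mcomp, d))
  })
  expand <- 10 / max(abs(vecs))
  vecs * expand
}

#' Embedding optimizer configuration
#'
#' @param n_components Embedding dimension (default 2).
#' @param min_dist,spread Parameters of the low-dimensional kernel, see
#'   [fit_curve_params()].
#' @param a,b Kernel coefficients; computed from `min_dist`/`spread` when
#'   `NULL`.
#' @param epochs Optimization epochs; when `NULL`, 500 for up to 10,000
#'   points and 200 beyond.
#' @param learning_rate Initial SGD step size, decayed linearly to 0.
#' @param negative_sample_rate Negative (repulsive) samples per positive
#'   edge sample (default 5).
#' @param repulsion_strength Multiplier on repulsive gradients (default 1).
#' @param weight_repulsion Scale repulsive updates by the edge's dataset
#'   weight, as for attractive updates (default `TRUE`); `FALSE` applies
#'   dataset weights to attraction only.
#' @param seed Integer seed.
#' @param snapshot_epochs Optional integer vector of epochs after which to
#'   record intermediate embeddings.
#' @return A list of class `embed_config`.
#' @export
embed_config <- function(n_components = 2, min_dist = 0.5, spread = 1.0,
                         a = NULL, b = NULL, epochs = NULL,
                         learning_rate = 1.0, negative_sample_rate = 5,
                         repulsion_strength = 1.0, weight_repulsion = TRUE,
                         seed = 42, snapshot_epochs = NULL) {
  if (n_components < 1) stopf("n_components must be at least 1")
  if (!is.null(epochs) && epochs < 1) stopf("epochs must be at least 1")
  if (is.null(a) || is.null(b)) {
    ab <- fit_curve_params(min_dist, spread)
    a <- a %||% ab[["a"]]
    b <- b %||% ab[["b"]]
  }
  if (a <= 0 || b <= 0) stopf("kernel parameters a, b must be positive")
  structure(list(n_components = n_components, min_dist = min_dist,
                 spread = spread, a = a, b = b, epochs = epochs,
                 learning_rate = learning_rate,
                 negative_sample_rate = negative_sample_rate,
                 repulsion_strength = repulsion_strength,
                 weight_repulsion = weight_repulsion, seed = seed,
                 snapshot_epochs = snapshot_epochs),
            class = "embed_config")
}

resolve_epochs <- function(epochs, n) {
  if (!is.null(epochs)) return(as.integer(epochs))
  if (n <= 10000) 500L else 200L
}

#' Optimize the embedding against the multigraph
#'
#' Stochastic gradient layout: each graph edge attracts its endpoints with a
#' force derived from the fuzzy cross-entropy, sampled in proportion to its
#' membership strength; uniformly sampled non-neighbors repel. Every update
#' on an edge is scaled by its dataset weight (within dataset `v`:
#' \eqn{\omega_v}; across datasets: the mean of the two weights), so
#' \eqn{\omega_v = 0} removes dataset `v`'s internal structure from the
#' layout entirely. Deterministic given the seed.
#'
#' @param graph A `multigraph`.
#' @param init Initial coordinates (`n` by `d`), e.g. from
#'   [spectral_init()].
#' @param config An [embed_config()].
#' @param weights Named per-dataset weight vector in `[0, 1]`; defaults to 1
#'   for every dataset.
#' @return Matrix of optimized coordinates with attributes `snapshots` (list
#'   of intermediate embeddings, if requested) and `n_skipped` (non-finite
#'   update steps that were skipped).
#' @export
optimize_embedding <- function(graph, init, config = embed_config(),
                               weights = NULL) {
  stopifnot(inherits(graph, "multigraph"))
  n <- nrow(graph$membership)
  if (!is.matrix(init) || nrow(init) != n || ncol(init) != config$n_components) {
    stopf("init must be a %d x %d matrix aligned to the graph", n,
          config$n_components)
  }
  ds <- unique(graph$index$dataset)
  if (is.null(weights)) weights <- setNames(rep(1, length(ds)), ds)
  if (!all(ds %in% names(weights))) stopf("weights must name every dataset")

  ed <- edge_weights(graph, weights)
  keep <- ed$w > 0
  epochs <- resolve_epochs(config$epochs, n)
  if (any(keep)) {
    # edges too weak to be sampled even once are dropped (standard
    # convention for this optimizer family)
    mu_max <- max(ed$mu[keep])
    keep <- keep & ed$mu >= mu_max / epochs
  }
  if (!any(keep)) {
    warnf("no positive-weight edges; returning initialization")
    return(init)
  }
  i <- ed$i[keep]; j <- ed$j[keep]
  mu <- ed$mu[keep]; w <- ed$w[keep]
  eps <- max(mu) / mu

  res <- optimize_layout_cpp(
    init, i, j, eps, w,
    a = config$a, b = config$b, gamma = config$repulsion_strength,
    alpha0 = config$learning_rate, n_epochs = epochs,
    negative_sample_rate = config$negative_sample_rate,
    seed = as.numeric(config$seed %% 2^31),
    weight_repulsion = config$weight_repulsion,
    snapshot_epochs = as.integer(config$snapshot_epochs %||% integer(0)))

  skipped_frac <- res$n_skipped / max(1, length(mu) * epochs)
  if (skipped_frac > 0.01) {
    warnf("%.1f%% of gradient steps were non-finite and skipped",
          100 * skipped_frac)
  }
  out <- res$embedding
  dimnames(out) <- dimnames(init)
  attr(out, "snapshots") <- res$snapshots
  attr(out, "n_skipped") <- res$n_skipped
  out
}
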