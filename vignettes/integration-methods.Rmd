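---
title: "Methods: cross-dataset manifold integration in coembed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-dataset manifold integration in coembed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coembed)
```

## The problem

Multimodal experiments measure the same underlying biology through
different feature spaces: transcript counts in scRNA-seq, chromatin
accessibility peaks in scATAC-seq, targeted panels in spatial assays. The
datasets cannot be concatenated — they have different dimensions — yet an
integrated analysis needs all cells from all assays in one coordinate
system and one neighborhood graph. `coembed` assumes the datasets sample a
single latent manifold and recovers it in three steps: normalize distances
within every ambient space onto a common manifold scale, assemble one
fuzzy neighborhood graph (the *multigraph*) spanning all datasets, and lay
all points out in a low-dimensional space by minimizing a weighted fuzzy
cross-entropy.

## Manifold-normalized memberships

Each dataset $X^v$ contributes an *own* ambient space: its full feature
matrix reduced to the top $d$ principal components (default $d = 50$, the
single-cell convention; binary accessibility matrices are TF-IDF weighted
with smoothed IDF $\log(1 + N/(1 + \mathrm{df}))$ and reduced by truncated
SVD instead). Every pair of datasets with common features additionally
contributes a *shared* space: both matrices restricted to the intersected
features, stacked, and jointly reduced.

Raw Euclidean distances in different spaces are incomparable. Within each
space, for each point $p$ with sorted neighbor distances
$d_1 \le \dots \le d_k$ (default $k = 15$), we set the local connectivity
radius $\rho_p = d_1$ and choose the bandwidth $\sigma_p$ by bisection so
that

$$\sum_{j=1}^{k} \exp\!\left(-\frac{\max(0,\, d_j - \rho_p)}{\sigma_p}\right)
  = \log_2 k .$$

This realizes a constant-radius ball on the latent manifold: every point
sees the same effective neighborhood mass regardless of its local sampling
density, and the resulting directed membership
$\mu(p \to q) = \exp(-\max(0, d(p,q) - \rho_p)/\sigma_p)$ is invariant to
rescaling the space's coordinates. Directed memberships are symmetrized
with the probabilistic t-conorm $a + b - ab$.

Within a shared space only *cross-dataset* pairs are converted to edges:
each point's $k$ nearest neighbors among the other datasets' points are
calibrated with the same $(\rho, \sigma)$ machinery, so the neighborhood
scale is specific to the shared space. Same-dataset proximity inside a
shared space is discarded — the own space, which sees every feature of
that dataset, is the better judge of within-dataset geometry, and this
choice makes within-dataset edges provably independent of which shared
spaces exist. When explicit cross-dataset distances are supplied instead
(anchor tables), each anchored point's distance list is calibrated the
same way, with $k$ clipped to the number of entries.

All sources merge into the multigraph by the same t-conorm; each edge
remembers the space that contributed its largest pre-merge strength. With
three or more datasets the default is pairwise shared spaces only; a flag
adds one space over all datasets jointly, for designs where a three-way
feature intersection is informative.

## The embedding objective

The embedding-space membership of a pair at distance $r$ is
$\nu(r) = (1 + a r^{2b})^{-1}$, with $(a, b)$ least-squares fitted so that
$\nu$ matches a plateau of width `min_dist` (default 0.5) followed by an
exponential tail of scale `spread` (default 1). The layout minimizes

$$\sum_{e} w_e \left[ \mu_e \log\frac{\mu_e}{\nu_e}
  + (1 - \mu_e) \log\frac{1 - \mu_e}{1 - \nu_e} \right],$$

by stochastic gradient descent with negative sampling: each edge is
sampled in proportion to $\mu_e$, attracts its endpoints, and draws five
uniformly random points as repulsive samples (dataset-agnostic, since the
embedding-space fuzzy set knows nothing of datasets). The per-dataset
weight $\omega^v \in [0, 1]$ enters as $w_e = \omega^v$ for an edge inside
dataset $v$ and $w_e = (\omega^i + \omega^j)/2$ for a cross edge — the
mean is symmetric and reduces correctly when the two weights agree. By
default weights scale both the attractive and repulsive updates
(`weight_repulsion = TRUE`); a flag restricts them to attraction. With no
reference dataset all weights are 1; naming a reference applies the
0.8/0.2 convention used when one modality (typically scRNA-seq) is of
visibly higher quality.

Initialization is spectral on the *assembled, weight-scaled* multigraph:
the $d$ nontrivial eigenvectors of the symmetric normalized Laplacian,
rescaled to a coordinate range of 10. Initializing on the joint graph
(rather than per dataset) avoids arbitrary relative placement of the
datasets; scaling edge strengths by $w_e$ before the eigensolve makes a
zero-weight dataset inert in the initialization exactly as it is inert in
the loss.

## Determinism and ordering

Reproducibility is treated as a contract, not an aspiration:

* every stochastic step (solver start vectors, approximate kNN forests,
  the SGD schedule) derives its seed from the single user seed;
* the optimizer runs single-threaded, and every retained edge owns an
  independent counter-based RNG stream keyed by its endpoints — dropping
  or re-weighting one edge cannot shift another edge's negative-sampling
  draws, which is what makes "$\omega^v = 0$ ignores dataset $v$'s edge
  strengths" hold bitwise rather than approximately;
* `integrate_datasets()` internally sorts each dataset's points by point
  id and restores input order at the end, so permuting input rows permutes
  the output rows and changes nothing else;
* principal components carry a deterministic sign convention (the loading
  of largest magnitude is positive).

## Numerical choices

* Bandwidth bisection runs on $(10^{-8}\bar d,\ 10^3 \bar d\,]$ for at
  most 64 iterations ($\bar d$ = mean neighbor distance), which pins the
  calibration sum to $\log_2 k$ within $10^{-5}$; a point whose neighbor
  distances are all zero has no solution and receives a bandwidth floor of
  $10^{-3}$ with a warning.
* Edges too weak to be sampled once in the epoch budget
  ($\mu < \mu_{\max}/\text{epochs}$) are dropped from the schedule, the
  standard economy of this optimizer family.
* Gradient components are clipped to $\pm 4$; non-finite updates are
  skipped and counted, with a warning above 1%.
* Exact kNN (kd-tree) is used up to 5,000 points per space, a seeded
  Annoy index (50 trees) beyond; the approximate index agrees with exact
  search on well over 95% of neighbors at the sizes where both run.
* Disconnected graph components are laid out independently and placed on
  a grid with spacing three times the per-component coordinate range, so
  unrelated components never overlap; components too small for an
  eigensolve get a seeded random layout.
* Epochs default to 500 up to 10,000 points and 200 beyond; the learning
  rate decays linearly from 1.

## Synthetic scenarios

Three generators reproduce the statistical structure of controlled
multimodal experiments and back the package's tests; the sizes quoted are
the defaults the test-suite runs at.

**Swiss roll / rectangle** (`make_swiss_roll_pair`). A 3-D roll
$(t\cos t,\, y,\, t\sin t)$, $t \sim U[3\pi/2,\, 9\pi/2]$, and an
independent 2-D rectangle whose long side equals the roll's unrolled arc
length. The manifold position of 1% of the points is known; cross
distances between anchors are absolute position differences (positions
normalized to $[0,1]$ so the rule has one scale). The roll genuinely
folds: at $n = 2000$ there are pairs whose ambient distance is far below
their along-manifold distance, which is exactly the nonlinearity the
normalization must undo. The tests integrate at $n = 2000$ per dataset and
check that the first principal coordinate of each dataset's embedding
tracks the true manifold position (|Spearman| $\ge 0.9$).

**Split images** (`make_split_image_pair`). Class prototypes are smooth
random fields on a $28 \times 28$ grid, contrast-boosted through a sigmoid
so their marginal resembles the foreground/background statistics of glyph
images; samples add per-pixel noise and are clipped to $[0,1]$. The left
and right $28 \times 15$ halves (420 features each) go to separate
datasets, overlapping in a $28 \times 2$ sliver of 56 shared pixel
features; Gaussian noise with standard deviation equal to the maximum
pixel value (= 1 after clipping) is added to the left dataset only. The
sliver is deliberately ambiguous; the point of the scenario is that
integration through it still transfers class labels across halves and
separates classes better than the sliver alone.

**Partial cluster overlap** (`make_cluster_overlap_pair`). Gaussian
clusters in a 10-D latent space observed through two random linear maps
with a 20-feature overlap; dataset B shares $m$ of A's 10 clusters and has
its own otherwise. Transfer accuracy restricted to shared clusters should
be essentially flat in $m$ — integration must not degrade when the
populations only partially overlap.

What the generators do *not* emulate: count noise (overdispersion,
dropout), batch effects within a modality, and the sparsity of real
accessibility matrices. Passing tests on them demonstrates the geometry of
the method — distance normalization, cross-space stitching, weighting —
not robustness to single-cell noise models, which enter upstream of this
package through the user's normalization.

## Known limitations

* Cross-dataset attraction exists only where cross edges exist. When only
  a small fraction of points carries cross information (the 1%-anchor
  swiss-roll setting), the negative-sampling term actively separates the
  remaining points by dataset: the manifold coordinate is recovered, but
  the datasets form parallel rather than interleaved sheets. This is a
  property of the cross-entropy/negative-sampling family itself — an
  independent optimizer of the same family produces the same layout on
  the same graph — and it disappears when shared feature spaces give
  every point cross neighbors, as in the split-image and omics settings.
* The harmonic label propagation clamps labeled points; mislabeled
  anchors are never corrected, only diluted.
* Shared spaces are built by joint PCA of the concatenated restricted
  matrices. Fitting on one dataset and projecting the other is the main
  alternative; concatenation was chosen because it treats the datasets
  symmetrically, but with grossly unequal sample sizes the larger dataset
  dominates the shared components.
* SGD progress is monotone only at stable step sizes; with the default
  learning rate of 1 the first epochs expand the layout before
  contraction, so mid-run loss can transiently exceed the initial loss on
  small graphs.

## A worked miniature

```{r example, fig.width = 6, fig.height = 4}
sc <- make_cluster_overlap_pair(n_clusters = 4, m = 4, n_per_cluster = 40,
                                seed = 1)
fit <- integrate_datasets(sc$blocks, config = embed_config(epochs = 100,
                                                           seed = 7))
glance(fit)

labs <- sc$truth$label[match(paste(tidy(fit)$dataset, tidy(fit)$point_id),
                             paste(sc$truth$dataset, sc$truth$point_id))]
metric_report(fit, labs, query = "B")
autoplot(fit)
```
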