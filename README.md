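# coembed

Integration and joint dimensionality reduction of multimodal datasets —
any number of data matrices over *different* feature spaces (scRNA-seq
genes, scATAC-seq peaks, targeted spatial panels, image halves) embedded
into one low-dimensional space with one cross-dataset neighborhood graph.
It is aimed at computational biologists who need to co-embed and
co-analyze single-cell assays that cannot be concatenated, and at anyone
benchmarking such integrations.

## The method

All datasets $X^v$ are assumed to sample one latent manifold. The package:

1. builds each dataset's **own ambient space** (top 50 principal
   components of its full feature matrix; TF-IDF + truncated SVD for
   binary accessibility) and a **shared ambient space** for every dataset
   pair with common features (intersected features, stacked, jointly
   reduced);
2. converts distances in every space to **manifold-normalized fuzzy
   memberships**: per point, $\rho$ = distance to its nearest neighbor and
   $\sigma$ solving
   $\sum_j \exp(-\max(0, d_j - \rho)/\sigma) = \log_2 k$,
   then $\mu(p \to q) = \exp(-\max(0, d - \rho_p)/\sigma_p)$, symmetrized
   and merged across spaces with the probabilistic t-conorm $a + b - ab$.
   Cross-dataset edges come from shared spaces (or user-supplied anchor
   distances); within-dataset edges come only from own spaces. The result
   is a single sparse symmetric graph over all points — the *multigraph*;
3. optimizes an embedding by **weighted fuzzy cross-entropy**
   $\sum_e w_e [\mu_e \log(\mu_e/\nu_e) + (1-\mu_e)\log((1-\mu_e)/(1-\nu_e))]$
   with $\nu(r) = (1 + a r^{2b})^{-1}$, SGD with negative sampling, and
   per-dataset weights $\omega^v$ (cross edges use the mean of the two
   weights) so the user controls each dataset's influence.

Downstream, the package provides label transfer by 5 nearest labeled
neighbors in the embedding and by harmonic-function propagation on the
multigraph, plus the four standard integration metrics: transfer balanced
accuracy, mean silhouette, alignment (cross-dataset neighbor fraction),
and structure preservation (Pearson correlation of high- vs
low-dimensional pairwise distances). Synthetic generators (swiss-roll /
rectangle pair with manifold anchors, split images with a shared pixel
sliver, partially overlapping Gaussian clusters) make every stage testable
without downloads.

## A worked example

```r
library(coembed)

sc  <- make_cluster_overlap_pair(n_clusters = 4, m = 4, n_per_cluster = 40,
                                 seed = 1)
fit <- integrate_datasets(sc$blocks, config = embed_config(epochs = 100,
                                                           seed = 7))
fit
#> <coembed_fit> 320 points, 2 dataset(s), 2-dim embedding
#>   edges: 6374; cross-entropy: 3176

labs <- sc$truth$label[match(paste(tidy(fit)$dataset, tidy(fit)$point_id),
                             paste(sc$truth$dataset, sc$truth$point_id))]
metric_report(fit, labs, query = "B")
#> # A tibble: 1 × 6
#>   transfer silhouette alignment structure     k query
#>      <dbl>      <dbl>     <dbl>     <dbl> <dbl> <chr>
#> 1        1      0.950     0.354        NA     5 B
```

Two simulated modalities observing the same four clusters integrate into
one embedding; every dataset-B cell receives its correct cluster label
from dataset A's annotations (`transfer = 1`), the true clusters are
well separated in the joint embedding (`silhouette = 0.95`), and about a
third of each cell's nearest neighbors come from the other dataset
(`alignment = 0.35`), i.e., the modalities are mixed rather than side by
side. `tidy(fit)` returns the embedding as a tibble, `autoplot(fit)`
plots it, and `fit$graph` is the multigraph for external clustering or
trajectory tools (`write_multigraph()` exports it as Matrix Market).

A thin command-line wrapper is installed with the package
(`inst/scripts/coembed.R`) with `integrate`, `simulate`, and `metrics`
subcommands writing TSV/Matrix-Market/JSON outputs.

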