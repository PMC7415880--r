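---
title: "Methods: semisupervised count autoencoding with protein gating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semisupervised count autoencoding with protein gating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The generative model and its assumptions

`scsemivae` assumes each cell is a point on a low-dimensional manifold
of cell states.  A latent code $z \in \mathbb{R}^d$ with standard
normal prior generates the observed gene counts through a
zero-inflated negative binomial (ZINB):

$$x_{j} \mid z \sim \mathrm{ZINB}(\mu_j(z),\ \theta_j,\ \pi_j(z)),$$

where $\mu_j(z)$ is the decoded mean on the raw count scale,
$\theta_j$ a per-gene inverse dispersion (variance
$\mu + \mu^2/\theta$), and $\pi_j(z)$ a per-cell, per-gene dropout
probability.  The NB component captures biological overdispersion; the
zero-inflation component absorbs the excess zeros produced by mRNA
capture inefficiency.  We use the $(\mu, \theta)$ parameterization
throughout — the classic $(r, p)$ form maps onto it as $r = \theta$,
$p = \theta / (\theta + \mu)$ — because the decoded mean is directly
interpretable as denoised expression and its gradients are well
scaled.

The posterior is approximated by an encoder network
$q(z \mid x) = N(\mu(x), \mathrm{diag}\,\sigma^2(x))$ and trained by
maximizing the evidence lower bound (ELBO) with the
reparameterization trick.  The KL term against the standard normal
prior has the closed form
$\sum_d \tfrac12 (\mu_d^2 + \sigma_d^2 - 1 - \log \sigma_d^2)$.

### Supervision by surface proteins

When CITE-seq antibody-derived tag (ADT) measurements exist for some
cells, a label head is attached to the *shared* decoder trunk and the
training objective becomes

$$\mathcal{L} = -\mathrm{ELBO}(x) + \gamma \cdot \mathcal{L}_y,$$

with $\mathcal{L}_y$ the label negative log-likelihood **averaged over
labeled cells only**, so the meaning of $\gamma$ does not drift when
the labeled fraction changes.  Two principles shape the design:

1. labels are consumed only through the training objective — encoding,
   imputation and protein prediction read the count matrix alone, so
   the model is evaluated and deployed exactly like an unsupervised
   one;
2. the supervised task is auxiliary: it regularizes the latent space
   toward biologically meaningful structure rather than replacing the
   reconstruction objective.

$\gamma = 0$ (or simply omitting the head) recovers the unsupervised
count VAE, which doubles as the in-package baseline.

### Probabilistic protein gating

Raw ADT counts are bimodal per protein — a background mode and an
"activated" mode — but heavily skewed and scale-heterogeneous across
proteins, which makes them poor direct regression targets.  We
therefore fit, per protein, a two-component Gaussian mixture on
$\log(1+\text{count})$ and use the posterior responsibility of the
larger-mean component as a *probabilized* label in $[0,1]$.  These
feed a Bernoulli head by default (an NB head on raw label counts is
available).  Probabilized labels bound the magnitude of the supervised
gradient per protein and make the targets comparable across proteins;
thresholding at 0.5 yields binary presence/absence calls when discrete
gates are wanted.

## Tunable parameters

| parameter | default | meaning / rationale |
|---|---|---|
| `n_hidden_layers`, `n_hidden_units` | 2, 128 | encoder/decoder depth and width; the tuned sweet spot for datasets of a few thousand cells |
| `n_latent` | 32 | latent dimensionality; smaller values underfit multi-lineage data |
| `gamma` | 20 | supervised weight; the smallest value at which supervision clearly outperforms the unsupervised baseline — much larger values trade gene reconstruction for protein fit |
| `label_fraction` | 1 | fraction of labeled cells whose labels are visible (seeded subset); sweeping it quantifies how much labeling a dataset needs |
| `learning_rate`, `batch_size` | 1e-3, 128 | ADAM defaults for this scale |
| `max_epochs`, `patience` | 200, 20 | early stopping on a 10% validation slice; patience `Inf` disables it for strictly reproducible epoch counts |
| GMM `threshold` | 0.5 | binarization cut on the posterior probability |
| corruption `fraction`, `keep_prob` | 0.25, 0.2 | benchmark protocol: a quarter of entries downsampled by `Binomial(n, 0.2)` |
| split `train_fraction` | 0.9 | 90/10 train/test protocol |

## Numerical choices

* **Analytic gradients.** No autodiff framework is used: the
  derivatives of the ZINB, NB and Bernoulli losses with respect to
  the decoder preactivations (log-mean, dropout logit, log-dispersion)
  are closed forms, chained through the dense stacks by standard
  backpropagation.  They are validated in development against central
  finite differences.
* **Stability.** ZINB evaluation at $x = 0$ uses log-sum-exp, never
  exponentiate-then-log.  Head preactivations are clamped to
  $\pm 13$ and log-variances to $\pm 10$ (gradients pass through), and
  dispersions live on the log scale clamped to $\pm 8$.  Gradients are
  globally norm-clipped (default 100).
* **EM for the protein gate.** Initialization is deterministic —
  component means at the 25th/75th percentiles, pooled variance, equal
  weights — and a variance floor of $10^{-6}\times$ the data variance
  prevents singular components.  The mean log-likelihood is
  non-decreasing across iterations (asserted in tests); ties in the
  "on" component (equal means) break by weight.
* **Encoder input.** Counts are library-size scaled to the training
  median and `log1p`-transformed; the decoder emits parameters on the
  raw count scale, so library size is carried implicitly by the
  network rather than by an explicit size factor.
* **Degenerate inputs.** All-identical protein values refuse to fit; a
  zero-variance vector inside a correlation contributes 0 (with a
  warning) instead of `NaN`; zero library sizes are floored at 1.
* **Determinism.** All randomness (split, label masking, weight
  initialization, shuffling, reparameterization noise, k-means
  restarts) flows from integer seeds; rerunning with the same seeds
  reproduces histories bitwise.

## The synthetic generator

`simulate_citeseq()` emulates the structure of a CITE-seq experiment
with full ground truth: cells carry one of `n_types` types; baseline
gene means are log-uniform; each type multiplies a random 30% of
genes by a 2–6x fold change; gene counts are ZINB with per-gene
dispersion and dropout; protein counts are NB (no dropout) with an
8-fold elevated mean in the type that expresses them.  Marker gene
$m$ and protein $m$ share their expressing type, so their clean
signals correlate.

Marker *transcripts* are deliberately given heavy dropout (default
0.7) while their paired proteins have none: that asymmetry — sparse
marker mRNA, clean surface readout — is precisely the regime the
semisupervised model targets, and without it the benchmark would
measure nothing interesting.  The defaults (500 cells x 100 genes x 5
proteins x 3 types) generate in well under a second and train in
seconds, which is what the test suite and the acceptance script use;
the same generator scales up by changing `sim_spec()`.

What the generator does **not** emulate: batch effects, ambient RNA,
doublets, library-size gradients within type, isotype-control
backgrounds, or correlated protein panels.  Tests passing on this
generator therefore demonstrate correctness of the machinery and the
qualitative benefit of supervision under the intended noise regime —
not performance claims on any real dataset.

## Design decisions on open points

* **Dispersion** is a free per-gene parameter shared across cells
  (not decoded per cell): fewer parameters, stabler fits at this
  scale, and standard practice in count-VAE models.
* **Supervised head target**: probabilized (not binarized) labels by
  default — the smooth target regulates how much information the
  supervised gradient injects; the NB head on raw counts is retained
  as an option.
* **CLR normalization** is per cell (compositional, `log1p`-based,
  arithmetic mean centering), the common CITE-seq convention; a
  per-protein variant sits behind `margin = "proteins"`.
* **Variable genes** are ranked by variance of `log1p` counts with
  ties broken by gene identifier.
* **Corruption order**: the benchmark corrupts the modeling matrix,
  i.e. after any gene selection, and selects exactly
  `round(0.25 * n_entries)` entries (zeros included) so the selected
  share is exact rather than expected.
* **Supervised loss composition**: a single uniformly weighted sum
  over proteins; per-protein weights are easy to add but are not part
  of the model.
* **Secondary classifier** (latent F1): multinomial logistic
  regression with weight decay `1e-3` — deterministic and fast.
  **Clustering** for ARI/NMI/UCA: k-means with `k` = number of true
  classes and 10 seeded restarts; silhouette on Euclidean latent
  distances, rescaled by $(\mathrm{ASW}+1)/2$ before pooling so all
  four components share $[0,1]$.  UCA searches all one-to-one
  cluster-label assignments exhaustively (supported up to 9 clusters).

## Known limitations

* Training is CPU-bound, minibatched dense linear algebra: fine for
  tens of thousands of cells, not for atlas-scale data.
* The ZINB is the only gene likelihood; Poisson/ZIP would be a small
  extension of the distribution layer but are not provided.
* One GMM component pair per protein: proteins whose distribution has
  more than two modes, or whose background requires isotype-control
  modeling, are gated only approximately.
* The importance-weighted marginal log-likelihood is a lower-bound
  estimator; its variance at small sample counts makes per-cell values
  noisy even though the mean is well behaved.
* k-means and logistic-regression evaluation metrics measure linear or
  spherical structure; strongly non-convex latent geometries would
  need different probes.
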