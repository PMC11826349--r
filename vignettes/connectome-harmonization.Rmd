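---
title: "Harmonizing connectome network measures with a site-conditional VAE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing connectome network measures with a site-conditional VAE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Structural connectomes — weighted, undirected graphs whose nodes are atlas
regions and whose edge weights count tractography streamlines — are estimated
through a long processing chain (diffusion acquisition, tractography,
parcellation). Every stage is sensitive to scanner hardware and protocol, so
connectomes pooled across acquisition *sites* carry systematic non-biological
differences ("site effects") that confound multi-site analyses of aging and
neurodegeneration. Graph-theoretic summaries of the connectome inherit these
biases.

`siteharm` learns a latent representation of the connectome that is minimally
informative of site while remaining predictive of biology (age, sex) and of
the network's connectivity profile, then *projects* connectomes and their
network measures into a single site domain of the user's choice, so that
downstream statistics compare like with like.

## The model

The model is a variational autoencoder over the strict upper triangle of the
connectome matrix (length $n(n-1)/2$; 3486 for the 84-region
Desikan–Killiany parcellation), with a site-conditional decoder:

* **Encoder** — two linear layers with ReLU activations, followed by two
  parallel affine maps producing the posterior mean $\mu_z$ and
  log-variance $\log\sigma_z^2$ of a diagonal Gaussian $q(z\mid x)$. The
  encoder never sees the site label.
* **Reparameterization** — during training,
  $z = \mu_z + \sigma_z \odot \varepsilon$, $\varepsilon \sim N(0, I)$. At
  test time $z = \mu_z$ (no sampling), so projection is deterministic.
* **Decoder** — $z$ concatenated with a one-hot site code $c$, through two
  linear layers (ReLU between), reconstructing the feature vector "as if
  acquired" at site $c$.
* **Prediction heads** — age and sex are affine readouts of $z$ alone
  (biology must be site-invariant); the network-measure head reads $(z, c)$,
  because the measures it predicts are themselves site-biased quantities.

The composite loss is the weighted sum of five components: conditional
reconstruction error (decoding each training subject at its *true* site), the
KL divergence $\mathrm{KL}[q(z \mid x)\,\|\,N(0,I)]$, squared error of
standardized age, binary cross entropy of sex, and squared error of the
standardized network-measure targets (site-conditional). The KL term is the
crux: together with conditional reconstruction it bounds the mutual
information between $z$ and the site variable — any site information kept in
$z$ is redundant (the decoder receives $c$ for free) and is gradually pruned
by the KL penalty, while information demanded by the age/sex/measure heads is
retained.

At test time the site code is simply set to the target domain: the same $z$
decoded under different $c$ yields the subject's connectome rendered in each
site's convention.

### Loss reductions and numerical choices

The literature states the loss as an unweighted sum but not the reduction of
each term; these choices matter numerically and are therefore fixed and
documented here:

* reconstruction: mean over batch *and* features (so its scale is comparable
  to the O(1) head losses and the KL term exerts real pressure);
* KL: sum over latent dimensions, mean over batch (the closed form
  $\tfrac12\sum_d(e^{\ell_d}+\mu_d^2-1-\ell_d)$ implemented in
  `kl_divergence()`);
* age/sex/measures: plain means; measure targets that are undefined for a
  subject (disconnected graph) are masked out of the mean.

All five weights default to 1 (an unweighted sum), with `w_kl` the main
science dial. Two standard optimization aids are built in: a linear KL
warm-up over the first `kl_warmup` epochs (the heads and reconstruction
organize the latent space before the bottleneck tightens — without it the
early sampling noise prevents the heads from ever fitting), and a step decay
of the Adam learning rate (factor 0.3 over the final third of training).
`log_var` is clamped to $[-30, 30]$ as a numerical guard; the clamp is
inactive in normal training.

Inputs are transformed $\log(1+w)$ — streamline counts span orders of
magnitude — and z-scored per feature on the training set; age and measure
targets are z-scored likewise. All statistics are stored with the model and
inverted on output, so predictions are reported in natural units (years,
streamlines). A single integer seed drives initialization, minibatch
shuffling and $\varepsilon$ draws; training is bitwise reproducible, and the
RNG state of the calling session is never touched.

### Co-learning vs individual learning

Two training schemes are provided: *co-learning* (one model whose measure
head predicts all 12 network measures simultaneously) and *individual
learning* (12 separate models, head width 1). Both share the same encoder
architecture. Co-learning is the default: a single latent space shaped by
all measures jointly.

## The twelve network measures

`all_measures()` computes, in fixed order: modularity (Louvain), average
node betweenness, degree assortativity, average participation coefficient,
average clustering (Onnela), average strength, average local efficiency,
global efficiency, density, rich-club coefficient, characteristic path
length, and the mean edge count of the characteristic paths. Conventions,
chosen to match the Brain Connectivity Toolbox where the verbal definitions
leave room:

* **Lengths** — all shortest-path measures run on lengths $\ell = 1/w$:
  stronger connections are shorter. Physical streamline lengths in
  millimeters are not recoverable from count matrices, so inverse weights
  are the stated convention throughout.
* **Normalization** — clustering and both efficiencies first normalize
  weights by the matrix maximum, keeping them in $[0,1]$; characteristic
  path length stays on raw inverse weights. Density, assortativity,
  participation and (normalized) clustering are invariant to uniform weight
  scaling; strength scales linearly.
* **Ties** — betweenness uses Brandes dependency accumulation with exact
  fractional counting of tied geodesics (relative tie tolerance $10^{-10}$);
  the edge-count measure breaks length ties toward the fewest hops, which
  makes it well defined.
* **Louvain** — weighted, resolution 1, best of 10 seeded restarts; the
  winning partition is reused for the participation coefficient. The
  reported Q always equals the direct evaluation of the modularity formula
  on the returned partition.
* **Rich club** — the weighted curve $\phi^w(k)$ (BCT convention: subgraph
  weight over the sum of the equally many strongest weights anywhere in the
  network), reduced to a scalar by the mean over defined degree levels;
  `max_k` and `fixed_k` reductions are available since the scalar reduction
  is not standardized in the literature.
* **Degenerate inputs** — disconnected pairs are excluded from path means
  and contribute zero to efficiencies; measures that are structurally
  undefined (no edges, regular graphs for assortativity, no degree-$>$1
  nodes for the rich club) return `NA` rather than raising, and propagate as
  `NA` through tables.
* **Connection filter** — edges carrying fewer streamlines than a fixed
  fraction ($10^{-7}$, i.e. 0.00001%) of the total streamline count
  (default $10^7$) are removed before any analysis; removal is strict
  (`weight < cutoff`), equality is retained. The filter is idempotent.

## Harmonization and its evaluation

`project_cohort()` encodes every subject to $\mu_z$, decodes at the chosen
target site, clips negative decoded weights to zero (streamline counts are
nonnegative), and rebuilds symmetric matrices. Network measures are produced
by **two routes** — predicted by the measure head at the target site, and
recomputed from the reconstructed connectome — and both are reported side by
side (`route` column), because they answer slightly different questions (what
the latent space knows vs what the reconstruction preserves). Reconstructions
are re-filtered with the model's connection filter before measures are
recomputed (default `rethreshold = TRUE`): the decoder emits thousands of
sub-streamline noise edges which would otherwise saturate density and distort
every topology-sensitive measure; the raw decoder output remains available
with `rethreshold = FALSE`.

The evaluation battery follows standard practice for two-site designs:

* **Demographic matching** — maximum-cardinality bipartite matching between
  sites (augmenting paths, not greedy), a pair being admissible when both
  subjects share sex and differ by at most one year of age. On matched
  samples, any remaining distributional gap is attributable to site.
* **Effect sizes** — Cohen's D with pooled SD; harmonization should reduce
  large effects ($|D| > 0.5$) to small ($|D| < 0.2$).
* **Rank tests** — Mann–Whitney U, normal approximation with midranks, tie
  correction and continuity correction (at the cohort sizes in question the
  exact distribution is unnecessary); significant ($p < 0.05$) median
  differences should become non-significant after harmonization.
* **Biology preservation** — sex accuracy (0.5 cutoff) and age MAE/R² of the
  heads on held-out subjects.
* **Bootstrap** — `bootstrap_experiments()` retrains on 80% subsamples drawn
  without replacement (iteration $i$ seeded `seed + i`), evaluates each model
  on the same fixed test set, and reports mean ± SD of every metric. The
  full-scale analysis uses 100 iterations; small `n_iter` gives quick
  stability checks.

No multiple-testing correction is applied across the 12 measures: each
measure is reported with its raw $p$, matching how such panels are read in
practice.

## The synthetic cohort generator

Because no public two-site connectome cohort can be shipped, the package
generates one with known ground truth, and every end-to-end claim in the
test suite is made against it. The generator emulates:

* a shared anatomical template of two hemisphere blocks, intra-hemispheric
  connections denser and heavier than inter-hemispheric ones; heavy-tailed
  log-normal weights (median 30 streamlines, $\sigma_{\log} = 1.5$), so that
  low-count edges genuinely flicker across subjects and topology-level
  measures (density, assortativity) have subject-level variance;
* a per-year multiplicative decline of all weights with age (default
  $-1.5\%$/year over ages 55–90), the dominant axis of biological variation;
* a sex effect on a designated edge subset (default ×1.15 for female
  subjects on a seeded random 30% of edges) — sex dimorphism has its own
  spatial signature, distinct from the hemispheric organization that site
  effects follow;
* a **site effect concentrated on intra-hemispheric edges** (default ×1.40
  at the second site), applied under a fixed total streamline budget:
  tractography generates a fixed number of streamlines per subject, so a
  site that reconstructs relatively more intra-hemispheric tracks does so at
  the expense of inter-hemispheric ones (`balance_site_mass = TRUE`
  renormalizes the bias to be mass-preserving; an explicit `gain` field
  remains available and is never balanced away). This mirrors the empirical
  signature of site differences in two-site connectome averages. The default
  deliberately contains no global site gain: a global gain is collinear with
  the aging axis and per-subject gain, and no site-blind encoder can
  attribute it to site; a pattern-shaped, mass-preserving site effect is
  both what fixed-count tractography actually produces and what makes the
  harmonization problem identifiable;
* per-subject global gain jitter ($\sigma_{\log} = 0.06$; head size and SNR
  vary between people in ways per-edge noise cannot produce) and per-edge
  log-normal noise ($\sigma_{\log} = 0.25$); weights are rounded to integer
  streamline counts.

With these defaults and 150 subjects per site, 6 of the 12 measures show a
pre-harmonization between-site $|D| > 0.5$ (modularity, participation,
clustering, both efficiencies, density), and several more show significant
median shifts. The matched test generator draws
demographic profiles and instantiates one subject per site per profile (age
jitter ≤ ±0.5 year), so full recovery by `match_cohorts()` is guaranteed by
construction.

What the generator does **not** emulate: realistic regional topology beyond
the two-hemisphere block structure, distance-dependent connection
probability, cognitive-status effects, longitudinal structure, or more than
one kind of site effect per site. Passing the test battery therefore shows
that the machinery does what it claims under controlled conditions with a
known answer — it does not certify performance on any particular real
cohort, where site effects may be entangled with biology in ways the
generator deliberately keeps identifiable.

## Problem sizes and default hyperparameters

The shipped defaults are the study conditions of the package's own test
battery: 84-node connectomes, 150 training subjects per site, 60 matched
test pairs; encoder/decoder hidden width 256, latent dimension 16, KL
weight 0.5 with a 100-epoch warm-up, 600 epochs of Adam at $10^{-3}$,
batch 64. The KL weight and latent width were chosen by a small grid on the
synthetic study itself — the operating point where the site probe fails
(small latent, real KL pressure) while the age/sex heads still fit; both
knobs trade harmonization strength against biological fidelity and are the
first thing to revisit on new data. Unit tests
use 16-node cohorts (seconds per training run); the end-to-end acceptance
battery runs the full 84-node study. The architecture dimensions, all loss
weights, epochs and seeds are configurable; hidden/latent sizes and the
optimizer settings are implementation choices — the literature this package
follows does not pin them down.

## Known limitations

* Site effects that are exactly collinear with retained biology (e.g. a pure
  global gain vs age-related global decline) cannot be separated by any
  encoder that never observes the site label; the latent bottleneck can only
  remove site information that is *redundant given the site code*, i.e.
  identifiable from pattern structure.
* Harmonization quality is a trained property, not a guarantee: a model
  stopped early, or trained with `w_kl = 0`, will leak site information (the
  package's tests verify the trained default does not).
* The individual-learning scheme harmonizes measures one model at a time and
  does not produce a single harmonized connectome per subject.
* Measures recomputed from reconstructions inherit decoder smoothing; the
  two measure routes agree in distribution but not subject by subject.
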