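---
title: "Methods: population-graph contrastive learning for multi-atlas connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-graph contrastive learning for multi-atlas connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popconn)
```

## The problem

Resting-state fMRI yields, for each subject, a BOLD time series per brain
region under a chosen parcellation (atlas). The Pearson correlations between
region time series form the subject's functional-connectivity (FC) matrix,
and connectivity differences between clinical groups (here: a binary
case/control diagnosis such as autism spectrum disorder versus typical
controls) are subtle, heterogeneous across acquisition sites, and sensitive
to the parcellation. `popconn` implements a classifier that attacks all
three difficulties at once:

* **multiple atlas views** — FC matrices are built under several
  parcellations and treated as complementary views of the same brain;
* **a population graph per view** — subjects become nodes, connected when
  their imaging features and phenotypes (site, age, ...) agree, so that a
  graph convolution can smooth information over similar subjects and absorb
  multi-site heterogeneity;
* **a dual global/local encoder with alignment losses** — a graph
  convolutional network (GCN) over the population graph produces *global*
  per-subject embeddings, an attention aggregator over each subject's own
  region-level connectivity profiles produces *local* embeddings, and
  consistency and contrastive losses pull the two (and the different atlas
  views) toward agreement before a linear classifier fuses everything.

A perturbation analysis then scores each brain region by how much held-out
accuracy drops when that region's features are masked, giving an
interpretable region ranking.

## Model components

### Connectivity views

For subject $n$ and atlas $v$ with $M_v$ regions, $S^{(n,v)} \in
\mathbb{R}^{M_v \times M_v}$ is the Pearson FC matrix (unit diagonal) and
$u^{(n,v)} \in \mathbb{R}^{d_v}$, $d_v = M_v(M_v-1)/2$, its strict upper
triangle in fixed row-major order $(1,2), (1,3), \dots$. A region with zero
temporal variance gets correlation $0$ with every other region rather than
`NaN`; this keeps $d_v$ identical across subjects, which the downstream
masking operators rely on. No Fisher transform is applied: the raw
correlation is the feature. Standardising the time series before the
correlation would not change anything (Pearson is affine-invariant), so the
columns are used as generated.

### Population graph

Per atlas, the graph over the $N$ subjects is built in four steps.

1. **Score.** $A_{ij} = \cos(u_i, u_j)\,\sum_m \varphi(P_{im}, P_{jm})$
   where $P$ holds the phenotype columns. The kernel $\varphi$ is an
   equality indicator for categorical phenotypes and
   $\mathbb{1}\{|P_{im}-P_{jm}| < \theta_2\}$ for quantitative ones — the
   boundary $|\Delta| = \theta_2$ does *not* match. Cosine similarity was
   chosen for the imaging factor because it is bounded, symmetric and
   scale-free; the kernel sum is used raw (not divided by the number of
   phenotypes) so that the default threshold below operates on the same
   scale regardless of how many phenotypes are configured.
2. **Sparsify.** $F_{ij} = \mathbb{1}\{A_{ij} \ge \theta_1\}$, diagonal
   zero. Raising $\theta_1$ monotonically removes edges.
3. **Phenotype embedding.** Each phenotype becomes a token (one-hot
   categories, cohort z-scored quantities, each mapped through a fixed
   random token embedding); one *untrained, fixed-seed* single-head
   self-attention block mixes the tokens per subject and the result is
   flattened. The graph must be static before training starts and nothing
   in the training objective reaches back into edge construction, so an
   untrained attention block computed once is the design that keeps the
   pipeline well-posed; it is still a deterministic, dimension-raising
   interaction of the phenotypes.
4. **Weights.** $W_{ij} = (\cos(E_i, E_j)+1)/2$ on kept edges, $0$
   elsewhere, so $W \in [0,1]^{N\times N}$ with zero diagonal. Self-loops
   are added only inside the graph convolution ($\tilde A = W + I$),
   never here, to avoid double self-loops.

One graph is built *per atlas*: the phenotype factor is shared, but the
imaging similarities (and hence $A$ and $F$) differ between views. Default
phenotypes are site and age — the combination that carries the most signal
in multi-site cohorts of this kind — with the full set configurable.

### Global encoder (GCN)

Starting from $H^{(0)} = X^{ut}$ (the stacked upper-triangle features), each
layer computes
$$H^{(l+1)} = \mathrm{ReLU}\!\left(\tilde D^{-1/2} \tilde A \tilde D^{-1/2}
H^{(l)} \Theta^{(l)}\right) + R\!\left(H^{(l)}\right),$$
with $\tilde A = W + I_N$, $\tilde D$ its degree matrix, and a residual map
$R$ that is the identity when input and output widths match and a learned
linear projection otherwise (the residual is required; its form was an open
choice). During training, *DropEdge* removes each undirected edge
independently with probability 0.3 (both symmetric entries together) before
normalisation, and feature dropout 0.2 is applied to the layer inputs; at
evaluation both are exact no-ops. Two layers of width 32 are the default. A
Chebyshev polynomial convolution (order configurable, default 2) is
available behind `gcn.variant = "chebyshev"` for users who prefer spectral
filters; the renormalised rule above is the default.

### Local encoder (target-aware attention aggregator)

Each subject's tokens are the rows of their FC matrix — region $i$'s
connectivity profile, the standard vector summary of a region. One
multi-head self-attention block (2 heads by default; no positional encoding,
so the block is region-permutation equivariant) is followed by three
node-centric attention aggregation (NCAA) layers. For center region $i$,
a shared two-layer perceptron scores the concatenation $[h_i \| h_j]$
against every other region $j$, a softmax over the $M-1$ neighbours gives
weights $\alpha_{ij}$, and
$$\tilde h_i = h_i + \sum_{j \ne i} \alpha_{ij} h_j.$$
Sharing one scorer across centers (rather than one scorer per center) keeps
the parameter count independent of $M$; a per-center scorer would add
$M$ separate perceptrons with no evidence of benefit. Mean-pooling over
regions and a linear map produce the local embedding; pooling makes the
final embedding invariant to region order. Three NCAA layers are the
default operating point; fewer underfit the region interactions and more
add parameters without gain.

### Losses

With $G_v, T_v$ the global/local embeddings of view $v$ (rows
L2-normalised before scoring so the sigmoid and cosine operate on a fixed
scale — unnormalised inner products make these terms vanish or saturate
with embedding scale):

* **Cross-view consistency** over ordered pairs of distinct views,
  $$L_{vc} = -\sum_{(i,j),\, i \ne j} \frac{1}{N}\sum_n \log\sigma\!\big(
  \langle G_{i,n}, G_{j,n}\rangle + \langle T_{i,n}, T_{j,n}\rangle\big),$$
  averaged over subjects (the reduction over subjects is a package choice;
  a sum would only rescale the weight $\alpha$).
* **Local/global contrastive alignment.** Both embeddings pass through one
  *shared* projection head, two linear maps around an ELU with Xavier
  initialisation. Similarities are $\mathrm{sim}(\phi_i,\phi_j) =
  \exp(\cos(\phi_i,\phi_j)/\tau)$ — the normalised-temperature form, in
  which $\tau$ genuinely controls the smoothness of the distribution;
  placing the norms and temperature multiplicatively inside the exponent
  instead is numerically explosive and deprives $\tau$ of that role. With a
  positive mask $M^p$ (default: the identity, i.e. the same subject's local
  and global projections are the positive pair; a same-label variant is
  configurable),
  $$L^{lv} = -\tfrac1N \sum_i \log\frac{\sum_j \mathrm{sim}(\phi^{lv}_i,
  \phi^{gv}_j) M^p_{ij}}{\sum_j \mathrm{sim}(\phi^{lv}_i, \phi^{gv}_j)},$$
  symmetrically $L^{gv}$, and $L_{cl} = \gamma L^{lv} + (1-\gamma) L^{gv}$.
* **Cross-entropy** $L_{ce}$ on the training-mask subjects, with predicted
  probabilities clipped to $[10^{-7}, 1-10^{-7}]$.

Total: $L = L_{ce} + \alpha L_{vc} + \beta L_{cl}$.

### Training and evaluation

Training is transductive: every subject sits in every population graph in
every forward pass, and only the loss terms are restricted to training-mask
nodes. (The practical consequence — adding new subjects requires
retraining — is inherent to population-graph methods.) The optimiser is
Adam with L2 weight decay; a stratified slice of the training mask is held
out to monitor the total loss, and early stopping starts counting at a
configurable epoch with a patience window, returning the best checkpoint.
Stratified $k$-fold cross-validation reports accuracy, precision, recall,
F1 ($2\cdot\mathrm{PRE}\cdot\mathrm{REC}/(\mathrm{PRE}+\mathrm{REC})$, with
zero denominators reported as 0 with a warning) and AUC via the
Mann–Whitney rank statistic. Fusion across atlases concatenates
$[G_v \| T_v]$ over views into one linear softmax classifier — per-atlas
ensembling is a reasonable alternative, concatenation is the package's
documented choice.

### Region importance

For a trained *single-atlas* model (multi-atlas importance conflates
parcellations and is refused), baseline accuracy $Acc^*$ is pooled over the
union of held-out folds under the frozen per-fold models. For each region
$i$, both inputs are rebuilt with $i$ masked — row and column $i$ of $S$
zeroed for the local branch, the $M-1$ pair positions of $u$ zeroed for the
node features — and the pooled accuracy $\widetilde{Acc}_i$ of the frozen
models gives $\Delta Acc_i = Acc^* - \widetilde{Acc}_i$. Masking zeroes
rather than deletes, so dimensions stay compatible with the trained
weights. Graph edges and weights are *not* rebuilt under perturbation by
default: the analysis probes a trained model's inputs, and rebuilding the
graph would mix structural with feature effects (`rebuild_graph = TRUE`
exists for the alternative reading). Held-out subjects are used for both
accuracies; ties in the ranking break by region index.

## Tunable parameters

| key | default | meaning |
|---|---|---|
| `graph.theta1` | 0.61 | edge-score threshold (unitless); larger = sparser graph |
| `graph.theta2` | 2 | quantitative phenotype window (years for age) |
| `graph.phenotypes` | site, age | columns entering score and weights |
| `taa.layers` | 3 | NCAA layers in the local encoder |
| `taa.heads` | 2 | self-attention heads (must divide $M$) |
| `gcn.layers` / `gcn.hidden` | 2 / 32 | GCN depth and width |
| `gcn.dropout` / `gcn.edge_dropout` | 0.2 / 0.3 | feature / edge dropout (training only) |
| `loss.alpha` | 0.1 | weight of the consistency term |
| `loss.beta` | 0.01 | weight of the contrastive term |
| `loss.gamma` | 0.4 | local-vs-global balance inside $L_{cl}$ |
| `loss.tau` | 0.5 | contrastive temperature (no published value; 0.5 is the common NT-Xent choice) |
| `train.lr` … | 1e-4, 200 epochs, wd 5e-5, stop 50/30, 10 folds | published operating point |

Two defaults deserve a note. The consistency weight has two published
operating points (0.1 in the experimental-setup description, 0.001 in the
sensitivity analysis); the package defaults to 0.1 and exposes the
alternative through `loss.alpha`. Likewise the convolution rule is the
renormalised one by default, with the Chebyshev variant (which the
published parameter table mentions) behind a flag.

`default_config()` reproduces the published operating point exactly.
`desk_config()` keeps every model and graph parameter identical but
shortens the optimiser schedule (lr 0.01, 60 epochs, early stopping from
epoch 20 with patience 15, 5 folds): the published schedule is tuned for
cohorts of many hundreds of subjects and thousands of connectivity
features, and underfits the package's small synthetic cohorts. All examples,
tests and the acceptance script use `desk_config()` problem sizes: 150
subjects, 4 sites, three toy atlases of 10/12/16 regions (120 subjects and
one 10-region atlas for the perturbation study) — small enough to run on a
single CPU in minutes, large enough for the planted signal to dominate
sampling noise.

## The synthetic cohort generator

Real multi-site rs-fMRI data cannot ship with a package, and no public
accession is required by the pipeline, so `popconn` generates cohorts with
*known planted structure* from a latent-factor model: every region loads on
a subject-wide signal, on a site latent through a site-specific loading
vector (drawn once per site and atlas, giving site-correlated FC structure —
the heterogeneity the population graph is designed to absorb), and, for
cases only, the two regions of each planted effect pair load jointly on an
extra latent with weight `effect_size`, raising their mutual correlation.
Unit-variance white noise completes the series. Because the data are
generated, not perturbed, every FC matrix is automatically a valid
correlation matrix — no projection to the positive-semidefinite cone is
ever needed. Ages are normal per site truncated to [6, 45], sexes are
Bernoulli with a 0.85 male fraction mirroring the strong male skew of
public autism cohorts, labels are Bernoulli at `class_balance`, and every
draw comes from a stream keyed by `(seed, subject, atlas)`, so any subject
can be regenerated alone, in any order, bit-for-bit.

What the generator does **not** emulate: hemodynamics, motion or
physiological artifacts, realistic FC spectra of 100+-region atlases,
site differences in scanner noise, or label-phenotype confounding beyond a
mild case IQ shift. Passing tests on these cohorts therefore demonstrates
that the implementation is correct and that the pipeline recovers planted
signal under controlled conditions — not that the published accuracies on
real cohorts are reproduced. All distributional choices here are package
inventions and labelled as such.

## Numerical choices and degenerate inputs

* Zero-variance regions: correlation 0, never `NaN`; zero-norm feature or
  embedding rows: similarity/weight 0 with a warning.
* Thresholds: the edge rule is $\ge \theta_1$ (equality keeps the edge),
  the phenotype window is $< \theta_2$ (equality does not match).
* Isolated nodes survive the GCN through their self-loop (degree $\ge 1$
  always).
* Softmaxes subtract the row maximum; $\log\sigma$ uses the `log1p` form;
  embeddings are L2-normalised with a $10^{-12}$ floor.
* Early stopping restores the best checkpoint; with a patience larger than
  the epoch budget training simply runs to the end.
* The trainable stack runs on a small reverse-mode tape (`R/autograd.R`)
  with the two attention kernels fused in C++; every kernel's hand-derived
  backward pass is verified against central finite differences in the test
  suite, and the fused layers are additionally checked against a
  composition of the exported, interpretable operators.
* Region masking is idempotent and the matrix- and vector-space masks are
  verified to address exactly the same entries.

## Limitations

Transductive by design (retraining needed for new subjects); no NIfTI or
volume handling (inputs are plain-text per-region time series, the format
CPAC-style pipelines export); no partial-correlation or tangent-space
connectivity; the optimiser is Adam by assumption (no optimiser is named in
the published setting); desk-scale experiment harnesses rerun the published
*designs* (ablation, phenotype and hyperparameter grids) on synthetic
cohorts and make no claim about the published absolute numbers, which would
require the original multi-site cohort and full-scale training.
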