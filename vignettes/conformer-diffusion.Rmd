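---
title: "Graph diffusion for conformer generation: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph diffusion for conformer generation: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confdiff)
```

## The model

`confdiff` generates 3D conformers of a molecule by learning to reverse a
Gaussian diffusion over atomic coordinates. The forward process corrupts
a conformation $X_0$ in $T$ steps,

$$q(X_t \mid X_{t-1}) = \mathcal{N}\!\big(\sqrt{1-\beta_t}\,X_{t-1},\ \beta_t I\big),$$

which marginalises to the closed form
$X_t = \sqrt{\bar\alpha_t}\,X_0 + \sqrt{1-\bar\alpha_t}\,\epsilon$ with
$\alpha_t = 1-\beta_t$, $\bar\alpha_t = \prod_{s\le t}\alpha_s$ and
$\epsilon \sim \mathcal{N}(0, I)$. The reverse step uses the predicted
noise $\hat\epsilon_\theta(X_t, t)$:

$$X_{t-1} = \frac{1}{\sqrt{\alpha_t}}\Big(X_t -
  \frac{\beta_t}{\sqrt{1-\bar\alpha_t}}\hat\epsilon_\theta\Big) + \sigma_t z,
\qquad \sigma_t^2 = \beta_t\,\frac{1-\bar\alpha_{t-1}}{1-\bar\alpha_t},$$

with the stochastic term dropped at the final step. Coordinates and all
injected noise are centroid-subtracted at every step: the translational
mode is unconstrained by any distance-based model, and removing it keeps
the equivariance contract ($\hat\epsilon(RX+\tau) = R\,\hat\epsilon(X)$)
well posed.

The default variance schedule is sigmoidal: $T = 5000$ values of $s$
linearly spaced on $[-6, 6]$ define
$\beta_t = \beta_{\min} + \mathrm{logistic}(s_t)\,(\beta_{\max}-\beta_{\min})$
with $\beta \in [10^{-7}, 2\times10^{-3}]$, giving
$\bar\alpha_T \approx 6.7\times10^{-3}$ — the terminal distribution is
close to a standard Gaussian. A single-step schedule takes the left
endpoint of the span.

## Architecture

The noise field is never predicted directly in Cartesian coordinates.
Each of two encoder streams produces a scalar score per directed edge,
and scores become atom vectors through

$$\hat\epsilon_i \;=\; \sum_{j:\,(i,j)\in E} s_{ij}\,
  \frac{x_i - x_j}{\lVert x_i - x_j\rVert},$$

which is rotation equivariant by construction; edges whose endpoints
coincide (length $< 10^{-8}$ Å) contribute nothing. Because the edge set
contains both directions of every pair with equal scores, pair
contributions are equal and opposite and $\sum_i \hat\epsilon_i = 0$.

Edges are typed with a fixed vocabulary — 0 single, 1 double, 2 triple,
3 aromatic, 4 two-hop, 5 three-hop, 6 spatial. Hop edges come from
shortest-path distances on the covalent graph only; a pair reachable at
both 2 and 3 hops takes the smaller count, and covalent bonds are never
re-typed. Spatial edges join all remaining pairs within an inclusive
10 Å cutoff and are rebuilt from the *current* coordinates at every
sampler step, since proximity changes as atoms move. The global stream
sees all edges; the local stream only the graph-derived ones.

* The **edge encoder** expands each length with a linear layer,
  concatenates learned type embeddings, applies a GeLU MLP, recombines
  multiplicatively with the type embedding and applies a second GeLU MLP.
  A Gaussian radial-basis expansion would be a natural alternative for
  the length pathway; the plain linear map is the default and was
  sufficient for every test in the package.
* The **global encoder** embeds atomic numbers (128 features by default)
  and applies interaction blocks. Each block runs two parallel
  continuous-filter convolutions — 128-filter and 64-filter pathways with
  separate filter-generating networks — where messages are neighbour
  features times filter outputs times a distance weight
  $w(d) = \ell(d)\cdot e^{-d^2/(2\sigma^2)}$ with $\sigma = d_\mathrm{cutoff}$,
  hard-zeroed beyond the cutoff; $\ell(d)$ is a learnable per-filter
  weighting, parameterised as $2\,\mathrm{sigmoid}(\cdot)$ and
  zero-initialised so it starts exactly at 1. The concatenated pathway
  outputs pass a learnable shifted softplus
  ($\mathrm{softplus}(x - s)\cdot c$ per channel), an attention gate
  (half-width ReLU layer, then sigmoid) that scales features atom-wise,
  and a linear projection back to the node width before the residual
  addition. After each block an adaptive-scaling module computes
  channel gates ($2\,\mathrm{sigmoid}$ again, so zeroed weights give the
  identity) from mean-pooled node features. Mean pooling was chosen for
  the global context because it is size-independent; sum pooling would
  confound molecule size with feature scale.
* The **local encoder** is a GIN stack over the local edges with
  edge-feature injection, batch normalisation + ReLU after every layer
  except the last, residual recombination and a final two-layer ReLU MLP.
  It sees coordinates only through the edge-length features.

Time conditioning is a sinusoidal embedding of $t$ passed through a small
GeLU MLP and added to the initial node embeddings of both streams.

Both score MLPs read the elementwise *sum* of the endpoint embeddings
concatenated with the edge features, which guarantees
$s_{ij} = s_{ji}$ exactly. Their output layers are zero-initialised so
the untrained model predicts the zero field — the standard stable start
for score networks.

## Two numerical choices that matter

**Conditional-score scaling.** The conditional noise implied by the
forward process is $\epsilon = (X_t - \sqrt{\bar\alpha_t}\,X_0)/
\sqrt{1-\bar\alpha_t}$: near $t = 0$ the network would need a gain of
order $10^2$ to turn ångström-scale distance deviations into unit-scale
noise. The package factors this known gain out: the learned edge scores
are multiplied by $1/\sqrt{1-\bar\alpha_t}$ before the gradient
transformation, so the MLPs regress a quantity that stays at the scale of
distance deviations across the whole schedule. Paired with it, the
`"sigma2"` loss-weight rule $\gamma_t = 1-\bar\alpha_t$ makes the
training gradient magnitude uniform over $t$; it is equivalent to
penalising the error of the *implied denoised structure* equally at every
step, which is what ancestral sampling accuracy depends on. The plain
DDPM objective ($\gamma_t = 1$) remains the default of `loss_eps` and
`diffusion_config`.

**Stream mixing.** Both streams are trained against the full noise
target, so at inference their predictions are averaged
($w_g = w_l = 0.5$). Summing them with unit weights would double-count
the prediction and bias every reverse step; setting $w_l = 0$ isolates
the global stream when wanted. The training combination is
$L = L_\mathrm{global} + \lambda L_\mathrm{local}$ with $\lambda = 1$.

## Batch normalisation on tiny graphs

The batch-normalisation modules sit on the aggregated CFConv feature
maps and between GIN layers. On the mini-batches this package trains on —
single molecules of a handful of atoms, often one element — the observed
per-channel statistics are degenerate: many channels have (near-)zero
within-batch variance, and normalising by them amplifies activations by
$1/\sqrt{\epsilon}$ and makes training- and evaluation-mode outputs
diverge by orders of magnitude (this failure was observed directly during
development: running variances around $10^{-9}$, evaluation-time
amplification around $300\times$). The package therefore normalises with
the *running* estimates in both modes — so a single molecule evaluates
deterministically and identically to the training path — and
`train_config(bn_freeze_iter = 0)` by default keeps those estimates at
their unit initialisation, reducing the module to its learnable
scale-and-shift. On large, chemically diverse batches the running
estimates can be calibrated by setting `bn_freeze_iter` to a positive
iteration count (statistics update with momentum 0.1 until then); note
that calibrated statistics re-introduce the small-variance amplification
problem on toy-sized data, which is why calibration is opt-in.

## Training procedure

Adam with learning rate $10^{-3}$, moment coefficients $(0.95, 0.999)$
and no weight decay; per iteration each molecule in the batch gets a
uniform $t$ and a fresh noise draw; the global gradient norm is clipped
(10 000 small-molecule preset, 30 000 drug-like preset); validation — the
training objective under fixed noise seeds, so values are comparable —
runs every 5 000 iterations, and a plateau scheduler multiplies the rate
by 0.6 after 10 consecutive non-improving validations (strict
improvement, floor $10^{-6}$). Checkpoints are RDS archives with a
versioned header carrying parameters, running statistics, optimiser state
and the RNG state, so an interrupted run resumes bit-exactly.

## What the toy generator emulates — and what it does not

`make_toy()` builds exact idealised geometries: tetrahedral centres
(bond angles $\arccos(-1/3)$), regular rings (optionally aromatic),
linear chains, and torsion chains placed by the internal-coordinate
construction with tetrahedral bond angles. `make_reference_ensemble()`
adds seeded isotropic Gaussian jitter. These fixtures exercise every code
path — edge typing, spatial cutoffs, automorphism-aware RMSD, training
and sampling — but they are *not* force-field conformers: there are no
competing torsional minima, no excluded-volume effects, no element
diversity beyond what a test requests. Passing the toy overfit pipeline
demonstrates that the model, objective and sampler are wired correctly
and can memorise and reproduce a geometry through 100 denoising steps; it
says nothing about generalisation across chemistry, which at the original
scale requires training on a large conformer corpus.

Problem sizes used by the test-suite pipeline run: width 32/16, two
interaction blocks, GIN depth 2, $T = 100$ with $\beta \in
[10^{-4}, 0.1]$ (chosen so $\bar\alpha_T \approx 7\times10^{-3}$ matches
the default schedule's terminal signal level), batch 8, 2 000 iterations,
20 sampled conformers. Under these conditions all twenty samples
reconstruct the 5-carbon tetrahedral toy to better than 0.12 Å
symmetry-corrected heavy-atom RMSD.

## Evaluation metrics

`min_rmsd()` computes optimal-superposition RMSD with the Kabsch
algorithm restricted to proper rotations, over heavy atoms by default.
With `symmetry = TRUE` it minimises over graph automorphisms
(vertex-coloured by element, enumerated with igraph) so chemically
indistinguishable atom relabellings do not inflate the error; the
enumeration is capped (default $10^4$) with a flagged identity fallback.
`cov_mat()` computes, from the reference-by-generated RMSD matrix,
COV-R (percentage of references within $\delta$ of some generated frame),
MAT-R (mean nearest-generated RMSD), and the precision-side COV-P/MAT-P
with the roles swapped; $\delta = 0.5$ Å is the small-molecule
convention and 1.25 Å the drug-like one, and the evaluation driver
defaults to generating twice as many conformers as the reference set.
`ramachandran_density()` builds a Gaussian product-kernel density over
the $3\times3$ periodic tiling of the dihedral samples, normalised to
integrate to one over its $[-180, 180)^2$ grid; bandwidths default to
Scott's rule, and the returned closure evaluates the identical normalised
density at arbitrary angles (periodic to $10^{-10}$, limited only by
kernel mass beyond the first tile).

## Known limitations

* No stereochemistry or chirality handling: mirror-image conformers are
  distinct only through the signed dihedral analysis.
* The neural core is a purpose-built dense-matrix autodiff engine; it is
  exact (validated against finite differences) but single-threaded and
  intended for desk-scale models, not for training on large corpora.
* The GEOM pickle dialect is not supported; SDF, SMILES and XYZ are.
* Sampling is plain ancestral DDPM; no accelerated (DDIM-style) or
  probability-flow samplers.
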