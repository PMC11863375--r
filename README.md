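# confdiff

Denoising-diffusion generation of molecular conformer ensembles in R.

Small molecules adopt many 3D shapes (conformers), and enumerating the
low-energy ones from the bond graph alone is a central task in
computational drug discovery. `confdiff` implements a denoising diffusion
probabilistic model (DDPM) over atomic coordinates: a forward process
gradually corrupts a conformation `X_0` with Gaussian noise along a
variance schedule `beta_t`, and a learned reverse process starts from pure
noise and iteratively removes it, producing new conformers conditioned on
the molecular graph.

The score network is built from three enhanced graph encoders:

* an **MLP edge encoder** that expands interatomic distances, combines
  them with learned embeddings of the edge type (single / double / triple
  / aromatic bond, 2-hop, 3-hop, spatial) and processes them with GeLU
  MLPs;
* a **global encoder**: a SchNet-style stack of interaction blocks, each
  with two parallel continuous-filter convolutions (full-width and
  reduced filter counts), a Gaussian distance envelope
  `exp(-d^2 / (2 d_cutoff^2))` with a learnable distance-weighting
  network (hard zero beyond the 10 Å cutoff), learnable shifted-softplus
  activations, an atom-wise sigmoid attention gate and adaptive feature
  scaling driven by mean-pooled global context;
* a **local encoder**: GIN-style message passing restricted to the
  covalent/2-hop/3-hop graph, with batch normalisation and ReLU between
  layers.

Each stream maps node embeddings to a scalar score `s_ij` per directed
edge; scores push and pull atoms along interparticle displacement unit
vectors,

```
eps_i = sum_j s_ij (x_i - x_j) / |x_i - x_j|,
```

which makes the predicted noise field exactly rotation equivariant
(translations are removed by centring). Training minimises the simplified
epsilon-matching objective `gamma_t * E|eps - eps_hat|^2` per stream; the
sampler is plain ancestral DDPM with the posterior variance.

Evaluation utilities cover Kabsch minimal RMSD (heavy-atom and
symmetry-corrected over graph automorphisms), the COV-R/MAT-R and
COV-P/MAT-P coverage and matching metrics, best-k RMSD lists, Pearson
correlations against molecular property tables, signed dihedrals with a
periodic Ramachandran kernel density, and per-trajectory RMSD traces. A
deterministic toy-molecule generator (tetrahedral centres, chains, rings,
torsion chains) makes the whole pipeline runnable without external data.

## Worked example

Train a small model on a rigid 5-carbon tetrahedral toy molecule and
sample it back:

```r
library(confdiff)

tet   <- make_toy("tetrahedral_center", r = 1.54, elements = "C")
sched <- make_schedule(diffusion_config(100, 1e-4, 0.1, gamma_t = "sigma2"))
model <- init_score_model(model_config(hidden = 32, reduced = 16,
                                       n_blocks = 2, gin_depth = 2), seed = 11)
fit <- train_model(model, list(tet), sched,
                   train_config(batch_size = 8, val_interval = 1e9,
                                max_iter = 2000, seed = 3))

cs <- sample_conformers(fit$model, tet, sched, n_conf = 20, seed = 5)
r  <- sapply(cs$frames, min_rmsd, b = tet$coords, mol = tet,
             mode = "heavy", symmetry = TRUE)
summary(r)
#    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
# 0.05297 0.06859 0.07348 0.07729 0.07994 0.11279
mean(r < 0.3)
# [1] 1
```

All twenty sampled conformers reconstruct the target geometry to within
0.12 Å symmetry-corrected heavy-atom RMSD; the training loss falls from
the zero-predictor baseline (~0.55) to ~0.09, essentially the irreducible
rotational component of the objective.

Evaluate any generated ensemble against references:

```r
Sr  <- make_reference_ensemble(tet, 10, jitter_sd = 0.05, seed = 41)
rep <- cov_mat(cs, Sr, delta = 0.5, mol = tet, symmetry = TRUE)
rep
# <metrics_report: delta=0.5 A | COV-R 100.0% MAT-R 0.0794 | COV-P 100.0% MAT-P 0.0947>
```

A shell front end mirrors the R API
(`inst/cli/confdiff train|sample|evaluate|analyze|make-toy`).

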