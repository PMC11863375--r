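Package: confdiff
Title: Attention-Enhanced Graph Diffusion for Molecular Conformer Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Denoising diffusion probabilistic modelling over atomic
    coordinates for generating molecular conformer ensembles. Molecules are
    represented as typed graphs (covalent, 2-hop, 3-hop and spatial edges);
    an attention-enhanced continuous-filter convolution (SchNet-style)
    global encoder, a batch-normalised GIN local encoder and an MLP edge
    encoder predict per-edge scores that are converted into rotation
    equivariant per-atom noise estimates. Includes a sigmoidal variance
    schedule, the simplified epsilon-matching training objective, an
    ancestral sampler, a training loop with plateau learning-rate
    scheduling and gradient clipping, conformer-ensemble evaluation
    (Kabsch RMSD, COV/MAT recall and precision, best-k RMSD, property
    correlations, periodic Ramachandran densities) and a deterministic
    toy-molecule generator for fully self-contained experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ChemmineOB,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
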