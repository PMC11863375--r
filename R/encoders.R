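# The three encoders driving the score model:
#  * MLP edge encoder: linear length expansion, concatenation with edge-type
#    embeddings, a GeLU MLP, elementwise recombination with the type
#    embeddings and a second MLP.
#  * Global encoder: SchNet-style stack of interaction blocks, each holding
#    two parallel continuous-filter convolutions (full-width and reduced
#    filters) whose concatenated output passes a learnable shifted-softplus,
#    an atom-wise attention gate (half-width ReLU layer, sigmoid), a
#    projection back to the node width and a residual; adaptive feature
#    scaling sits in the main loop. Distances enter only through edge
#    lengths, so node features are rotation/translation invariant.
#  * Local encoder: GIN-style message passing over covalent/2-hop/3-hop
#    edges with batch normalisation and ReLU after every layer but the
#    last, residual recombination and a final two-layer ReLU MLP.

#' Score-model architecture configuration
#'
#' Defaults are the package's repository defaults (128-wide node features,
#' 128/64 dual CFConv filter pathways, 6 interaction blocks, GIN depth 4,
#' 10 Angstrom spatial cutoff); widths can be shrunk for desk-scale
#' experiments.
#'
#' @param hidden node/edge feature width.
#' @param reduced filter count of the reduced CFConv pathway.
#' @param n_blocks number of interaction blocks.
#' @param gin_depth number of GIN layers in the local encoder.
#' @param cutoff spatial edge cutoff (Angstrom).
#' @param max_z largest atomic number in the embedding table.
#' @param w_global,w_local inference mixing weights for the two gradient
#'   streams. Both streams regress the full noise field, so the default
#'   equal-weight mixture averages them (0.5/0.5); setting one weight to
#'   zero isolates the other stream.
#' @param lambda_local weight of the local term in the training loss.
#' @return a `model_config` list.
#' @export
model_config <- function(hidden = 128L, reduced = 64L, n_blocks = 6L,
                         gin_depth = 4L, cutoff = 10, max_z = 53L,
                         w_global = 0.5, w_local = 0.5, lambda_local = 1) {
  structure(list(hidden = as.integer(hidden), reduced = as.integer(reduced),
                 n_blocks = as.integer(n_blocks),
                 gin_depth = as.integer(gin_depth), cutoff = cutoff,
                 max_z = as.integer(max_z), w_global = w_global,
                 w_local = w_local, lambda_local = lambda_local),
            class = "model_config")
}

# deterministic parameter initialisation; creation order is fixed so a
# given seed always yields the same parameter set
init_encoder_params <- function(cfg, seed = 1L) {
  set.seed(seed)
  h <- cfg$hidden
  r <- cfg$reduced
  p <- list()

  # edge encoder
  p[["edge.type_emb"]] <- glorot(N_EDGE_TYPES, h)
  p <- init_linear(p, "edge.len", 1L, h)
  p <- init_mlp(p, "edge.mlp1", 2L * h, 2L * h, h)
  p <- init_mlp(p, "edge.mlp2", h, h, h)

  # atom embeddings and time-conditioning MLPs for both streams
  p[["glob.embed"]] <- glorot(cfg$max_z, h)
  p[["loc.embed"]] <- glorot(cfg$max_z, h)
  p <- init_mlp(p, "glob.time", h, h, h)
  p <- init_mlp(p, "loc.time", h, h, h)

  # global encoder interaction blocks
  for (b in seq_len(cfg$n_blocks)) {
    for (cf in c(1L, 2L)) {
      nf <- if (cf == 1L) h else r
      pre <- sprintf("glob.b%d.cf%d", b, cf)
      p <- init_linear(p, paste0(pre, ".in"), h, nf)
      p <- init_batchnorm(p, paste0(pre, ".bn"), nf)
      p <- init_mlp(p, paste0(pre, ".filt"), h, nf, nf)
      # learnable distance weighting: zero-init so the initial weight is
      # exactly the Gaussian envelope (2 * sigmoid(0) = 1)
      p[[paste0(pre, ".dw.W")]] <- matrix(0, 1L, nf)
      p[[paste0(pre, ".dw.b")]] <- matrix(0, 1L, nf)
      p <- init_linear(p, paste0(pre, ".out"), nf, nf)
    }
    w <- h + r
    pre <- sprintf("glob.b%d", b)
    p <- init_ssp(p, paste0(pre, ".ssp"), w)
    p <- init_linear(p, paste0(pre, ".att1"), w, w %/% 2L)
    p <- init_linear(p, paste0(pre, ".att2"), w %/% 2L, w)
    p <- init_linear(p, paste0(pre, ".proj"), w, h)
    p <- init_mlp(p, paste0(pre, ".ads"), h, h %/% 2L, h)
  }

  # local (GIN) encoder
  for (l in seq_len(cfg$gin_depth)) {
    pre <- sprintf("loc.g%d", l)
    p[[paste0(pre, ".eps")]] <- matrix(0, 1L, h)
    p <- init_linear(p, paste0(pre, ".edge"), h, h)
    p <- init_mlp(p, paste0(pre, ".mlp"), h, 2L * h, h)
    # the last GIN layer skips batch-norm + ReLU, so no such params there
    if (l < cfg$gin_depth) p <- init_batchnorm(p, paste0(pre, ".bn"), h)
  }
  p <- init_mlp(p, "loc.out", h, h, h)
  p
}

check_edge_types <- function(types) {
  if (length(types) && (any(types < 0L) || any(types >= N_EDGE_TYPES))) {
    stop("vocabulary error: unknown edge type code ",
         paste(setdiff(unique(types), 0:(N_EDGE_TYPES - 1L)), collapse = ","))
  }
}

## ---- node-level (autodiff) forwards ----------------------------------------

enc_edges_node <- function(ctx, params, cfg, lengths, types) {
  check_edge_types(types)
  if (any(lengths < 0)) stop("edge lengths must be >= 0")
  temb <- ad_rows(ctx, ad_param(ctx, params, "edge.type_emb"), types + 1L)
  len <- ad_const(ctx, matrix(lengths, ncol = 1L))
  expand <- nn_linear(ctx, params, "edge.len", len)
  hmid <- nn_mlp(ctx, params, "edge.mlp1", ad_cbind(ctx, expand, temb),
                 act = ad_gelu)
  nn_mlp(ctx, params, "edge.mlp2", ad_mul(ctx, hmid, temb), act = ad_gelu)
}

# Gaussian envelope with sigma = cutoff, hard-zeroed past the cutoff,
# multiplied by the learnable per-filter weighting (2 * sigmoid(W d + b),
# equal to one at zero initialisation).
dist_weight_node <- function(ctx, params, prefix, lengths, cutoff, nf) {
  env <- exp(-lengths^2 / (2 * cutoff^2))
  env[lengths > cutoff] <- 0
  learned <- ad_scale(ctx, ad_sigmoid(ctx, nn_linear(
    ctx, params, paste0(prefix, ".dw"),
    ad_const(ctx, matrix(lengths, ncol = 1L)))), 2)
  ad_mul_cv(ctx, learned, ad_const(ctx, matrix(env, ncol = 1L)))
}

# LeakyReLU on the projected atom features before message passing; batch
# normalisation on the aggregated feature maps (which carry the distance
# information and therefore have meaningful per-channel statistics).
cfconv_node <- function(ctx, params, cfg, prefix, h, edges, edge_emb) {
  xf <- ad_leaky_relu(ctx, nn_linear(ctx, params, paste0(prefix, ".in"), h))
  if (n_edges(edges) == 0L) {
    agg <- ad_scale(ctx, xf, 0) # empty neighbourhood: zero aggregate
  } else {
    filt <- nn_mlp(ctx, params, paste0(prefix, ".filt"), edge_emb,
                   act = ad_softplus)
    dw <- dist_weight_node(ctx, params, prefix, edges$lengths, cfg$cutoff,
                           ncol(filt$val))
    msg <- ad_mul(ctx, ad_rows(ctx, xf, edges$pairs[, 2L]),
                  ad_mul(ctx, filt, dw))
    agg <- ad_scatter_sum(ctx, msg, edges$pairs[, 1L], nrow(h$val))
  }
  agg <- nn_batchnorm(ctx, params, paste0(prefix, ".bn"), agg)
  nn_linear(ctx, params, paste0(prefix, ".out"), agg)
}

interaction_block_node <- function(ctx, params, cfg, prefix, h, edges,
                                   edge_emb) {
  a1 <- cfconv_node(ctx, params, cfg, paste0(prefix, ".cf1"), h, edges,
                    edge_emb)
  a2 <- cfconv_node(ctx, params, cfg, paste0(prefix, ".cf2"), h, edges,
                    edge_emb)
  cat2 <- nn_ssp(ctx, params, paste0(prefix, ".ssp"), ad_cbind(ctx, a1, a2))
  att <- ad_sigmoid(ctx, nn_linear(ctx, params, paste0(prefix, ".att2"),
                                   ad_relu(ctx, nn_linear(
                                     ctx, params, paste0(prefix, ".att1"),
                                     cat2))))
  gated <- ad_mul(ctx, cat2, att)
  ad_add(ctx, h, nn_linear(ctx, params, paste0(prefix, ".proj"), gated))
}

adaptive_scale_node <- function(ctx, params, prefix, h) {
  pooled <- ad_colmeans(ctx, h)
  scale <- ad_scale(ctx, ad_sigmoid(ctx, nn_mlp(
    ctx, params, paste0(prefix, ".ads"), pooled, act = ad_relu)), 2)
  ad_mul_rv(ctx, h, scale)
}

global_encode_node <- function(ctx, params, cfg, z, edges, edge_emb,
                               time_node = NULL) {
  h <- ad_rows(ctx, ad_param(ctx, params, "glob.embed"), z)
  if (!is.null(time_node)) {
    h <- ad_add_rv(ctx, h, nn_mlp(ctx, params, "glob.time", time_node,
                                  act = ad_gelu))
  }
  for (b in seq_len(cfg$n_blocks)) {
    pre <- sprintf("glob.b%d", b)
    h <- interaction_block_node(ctx, params, cfg, pre, h, edges, edge_emb)
    h <- adaptive_scale_node(ctx, params, pre, h)
  }
  h
}

local_encode_node <- function(ctx, params, cfg, z, edges, edge_emb,
                              time_node = NULL) {
  h <- ad_rows(ctx, ad_param(ctx, params, "loc.embed"), z)
  if (!is.null(time_node)) {
    h <- ad_add_rv(ctx, h, nn_mlp(ctx, params, "loc.time", time_node,
                                  act = ad_gelu))
  }
  ones <- matrix(1, 1L, cfg$hidden)
  for (l in seq_len(cfg$gin_depth)) {
    pre <- sprintf("loc.g%d", l)
    epsl <- ad_add(ctx, ad_const(ctx, ones),
                   ad_param(ctx, params, paste0(pre, ".eps")))
    hs <- ad_mul_rv(ctx, h, epsl)
    if (n_edges(edges) > 0L) {
      eadj <- nn_linear(ctx, params, paste0(pre, ".edge"), edge_emb)
      m <- ad_relu(ctx, ad_add(ctx, ad_rows(ctx, h, edges$pairs[, 2L]), eadj))
      agg <- ad_scatter_sum(ctx, m, edges$pairs[, 1L], nrow(h$val))
      hs <- ad_add(ctx, hs, agg)
    }
    upd <- nn_mlp(ctx, params, paste0(pre, ".mlp"), hs, act = ad_relu)
    if (l < cfg$gin_depth) {
      upd <- ad_relu(ctx, nn_batchnorm(ctx, params, paste0(pre, ".bn"), upd))
    }
    h <- ad_add(ctx, h, upd)
  }
  nn_mlp(ctx, params, "loc.out", h, act = ad_relu)
}

## ---- matrix-level public wrappers ------------------------------------------

model_params_cfg <- function(model) {
  stopifnot(inherits(model, "score_model"))
  list(params = model$params, cfg = model$config)
}

#' Encode edges from lengths and type codes
#'
#' @param model a [init_score_model()] object.
#' @param lengths edge lengths (Angstrom, >= 0).
#' @param types integer edge-type codes (0..6).
#' @return a matrix with one feature row per edge.
#' @export
encode_edges <- function(model, lengths, types) {
  m <- model_params_cfg(model)
  ctx <- ad_ctx(FALSE)
  enc_edges_node(ctx, m$params, m$cfg, lengths, as.integer(types))$val
}

#' Cutoff-enveloped, learnable distance weight
#'
#' The fixed part is a Gaussian envelope `exp(-d^2 / (2 sigma^2))` with
#' `sigma = d_cutoff`, set to exactly zero for `d > d_cutoff`. When a model
#' and parameter prefix are given, the envelope is multiplied elementwise
#' by the learnable weighting network's output; with `model = NULL` the
#' learned factor is one and the bare envelope is returned.
#'
#' @param d distances (Angstrom).
#' @param d_cutoff cutoff (Angstrom), also the Gaussian width.
#' @param model optional score model supplying the learned weighting.
#' @param prefix parameter prefix of the CFConv whose weighting to use.
#' @return a numeric vector (no model) or matrix of per-filter weights.
#' @export
distance_weight <- function(d, d_cutoff = 10, model = NULL,
                            prefix = "glob.b1.cf1") {
  stopifnot(all(d >= 0))
  env <- exp(-d^2 / (2 * d_cutoff^2))
  env[d > d_cutoff] <- 0
  if (is.null(model)) return(env)
  m <- model_params_cfg(model)
  ctx <- ad_ctx(FALSE)
  dist_weight_node(ctx, m$params, prefix, d, d_cutoff, NULL)$val
}

#' Continuous-filter convolution layer (single pathway)
#'
#' @param model score model.
#' @param h node feature matrix (atoms x hidden).
#' @param edges `edge_set` with lengths.
#' @param edge_emb per-edge features from [encode_edges()].
#' @param prefix parameter prefix, e.g. `"glob.b1.cf1"`.
#' @return updated node features (atoms x filters).
#' @export
cfconv <- function(model, h, edges, edge_emb, prefix = "glob.b1.cf1") {
  m <- model_params_cfg(model)
  ctx <- ad_ctx(FALSE)
  emb <- if (n_edges(edges) > 0L) ad_const(ctx, edge_emb) else NULL
  cfconv_node(ctx, m$params, m$cfg, prefix, ad_const(ctx, h), edges, emb)$val
}

#' Dual-pathway interaction block with attention gating
#'
#' @inheritParams cfconv
#' @param prefix block prefix, e.g. `"glob.b1"`.
#' @return node features after the residual update (atoms x hidden).
#' @export
interaction_block <- function(model, h, edges, edge_emb, prefix = "glob.b1") {
  m <- model_params_cfg(model)
  ctx <- ad_ctx(FALSE)
  emb <- if (n_edges(edges) > 0L) ad_const(ctx, edge_emb) else NULL
  interaction_block_node(ctx, m$params, m$cfg, prefix, ad_const(ctx, h),
                         edges, emb)$val
}

#' Adaptive feature scaling from pooled global context
#'
#' Channel-wise scaling factors are computed from the mean-pooled node
#' features and applied by elementwise multiplication.
#'
#' @inheritParams cfconv
#' @param prefix block prefix owning the scaling network.
#' @return rescaled node features.
#' @export
adaptive_scale <- function(model, h, prefix = "glob.b1") {
  m <- model_params_cfg(model)
  ctx <- ad_ctx(FALSE)
  adaptive_scale_node(ctx, m$params, prefix, ad_const(ctx, h))$val
}

#' Global (SchNet-style) encoding of a molecule
#'
#' @param model score model.
#' @param graph a [molecule_graph()].
#' @param coords coordinates to use (default the graph's own).
#' @return per-atom feature matrix (atoms x hidden); depends on coordinates
#'   only through interatomic distances.
#' @export
global_encode <- function(model, graph, coords = graph$coords) {
  if (is.null(coords)) stop("input error: coordinates required")
  m <- model_params_cfg(model)
  edges <- build_all_edges(graph, coords, m$cfg$cutoff)
  ctx <- ad_ctx(FALSE)
  emb <- if (n_edges(edges) > 0L) {
    enc_edges_node(ctx, m$params, m$cfg, edges$lengths, edges$types)
  } else NULL
  global_encode_node(ctx, m$params, m$cfg, graph$atom_numbers, edges, emb)$val
}

#' Local (GIN) encoding over covalent/2-hop/3-hop edges
#'
#' @inheritParams global_encode
#' @return per-atom feature matrix (atoms x hidden).
#' @export
local_encode <- function(model, graph, coords = graph$coords) {
  m <- model_params_cfg(model)
  edges <- build_local_edges(graph)
  if (!is.null(coords)) {
    edges <- edge_lengths(coords, edges)
  } else {
    edges$lengths <- rep(0, n_edges(edges))
  }
  ctx <- ad_ctx(FALSE)
  emb <- if (n_edges(edges) > 0L) {
    enc_edges_node(ctx, m$params, m$cfg, edges$lengths, edges$types)
  } else NULL
  local_encode_node(ctx, m$params, m$cfg, graph$atom_numbers, edges, emb)$val
}
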