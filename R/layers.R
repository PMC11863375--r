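# Layer helpers on top of the autodiff primitives. Parameters live in one
# flat named list of matrices; layer constructors register entries under a
# dotted prefix and forward helpers fetch them through ad_param() so a
# tape sees each weight exactly once.

glorot <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
}

init_linear <- function(store, prefix, n_in, n_out, bias = TRUE) {
  store[[paste0(prefix, ".W")]] <- glorot(n_in, n_out)
  if (bias) store[[paste0(prefix, ".b")]] <- matrix(0, 1L, n_out)
  store
}

nn_linear <- function(ctx, params, prefix, x) {
  w <- ad_param(ctx, params, paste0(prefix, ".W"))
  out <- ad_matmul(ctx, x, w)
  bname <- paste0(prefix, ".b")
  if (!is.null(params[[bname]])) {
    out <- ad_add_rv(ctx, out, ad_param(ctx, params, bname))
  }
  out
}

# two-layer perceptron with a configurable hidden activation
init_mlp <- function(store, prefix, n_in, n_hidden, n_out) {
  store <- init_linear(store, paste0(prefix, ".l1"), n_in, n_hidden)
  init_linear(store, paste0(prefix, ".l2"), n_hidden, n_out)
}

nn_mlp <- function(ctx, params, prefix, x, act = ad_relu) {
  h <- act(ctx, nn_linear(ctx, params, paste0(prefix, ".l1"), x))
  nn_linear(ctx, params, paste0(prefix, ".l2"), h)
}

## ---- batch normalisation ---------------------------------------------------

# Learnable gamma/beta plus running mean/var. The graphs seen here are
# single molecules with a handful of atoms, often of one element, so
# within-batch feature statistics can collapse to zero variance on some
# channels; normalising by them makes training- and evaluation-mode
# activations diverge catastrophically. Normalisation therefore always
# uses the running estimates (gradients do not flow through them), while
# training passes record the observed batch statistics on the tape
# context so the trainer can fold them into the running estimates with
# momentum 0.1. Evaluation of a single molecule is thus deterministic and
# identical to the training-time path.
init_batchnorm <- function(store, prefix, k) {
  store[[paste0(prefix, ".gamma")]] <- matrix(1, 1L, k)
  store[[paste0(prefix, ".beta")]] <- matrix(0, 1L, k)
  store[[paste0(prefix, ".running_mean")]] <- matrix(0, 1L, k)
  store[[paste0(prefix, ".running_var")]] <- matrix(1, 1L, k)
  store
}

nn_batchnorm <- function(ctx, params, prefix, x, eps = 1e-5) {
  gamma <- ad_param(ctx, params, paste0(prefix, ".gamma"))
  beta <- ad_param(ctx, params, paste0(prefix, ".beta"))
  if (ctx$training && nrow(x$val) > 1L) {
    mu <- colMeans(x$val)
    ctx$bn_updates[[length(ctx$bn_updates) + 1L]] <-
      list(prefix = prefix, mean = matrix(mu, 1L),
           var = matrix(colMeans(sweep(x$val, 2L, mu)^2), 1L))
  }
  rm <- params[[paste0(prefix, ".running_mean")]]
  rv <- params[[paste0(prefix, ".running_var")]]
  xhat <- ad_mul_rv(ctx, ad_sub_rv(ctx, x, ad_const(ctx, rm)),
                    ad_const(ctx, 1 / sqrt(rv + eps)))
  ad_add_rv(ctx, ad_mul_rv(ctx, xhat, gamma), beta)
}

# names holding running statistics are state, not trainable weights
is_trainable_param <- function(name) {
  !grepl("\\.running_(mean|var)$", name)
}

## ---- learnable shifted softplus --------------------------------------------

# softplus(x - s) * c with per-channel shift s and gain c; at
# initialisation s = log(e - 1) (so softplus(x - s) crosses ~x at 0) and
# c = 1. The learnable pair lets training reshape the response curve.
init_ssp <- function(store, prefix, k) {
  store[[paste0(prefix, ".shift")]] <- matrix(log(exp(1) - 1), 1L, k)
  store[[paste0(prefix, ".gain")]] <- matrix(1, 1L, k)
  store
}

nn_ssp <- function(ctx, params, prefix, x) {
  s <- ad_param(ctx, params, paste0(prefix, ".shift"))
  cgain <- ad_param(ctx, params, paste0(prefix, ".gain"))
  ad_mul_rv(ctx, ad_softplus(ctx, ad_sub_rv(ctx, x, s)), cgain)
}

## ---- time conditioning ------------------------------------------------------

# sinusoidal embedding of the diffusion step, transformer-style
time_embedding <- function(t, t_max, dim) {
  half <- dim %/% 2L
  freq <- exp(-log(10000) * (seq_len(half) - 1L) / max(half - 1L, 1L))
  ang <- (t / t_max) * t_max * freq # position t against geometric frequencies
  emb <- c(sin(ang), cos(ang))
  if (length(emb) < dim) emb <- c(emb, 0)
  matrix(emb[seq_len(dim)], 1L)
}
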