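# Minimal tape-based reverse-mode automatic differentiation over dense
# matrices. Every network in the package (edge encoder, GIN local encoder,
# attention-enhanced CFConv global encoder, score MLPs) is expressed in
# these primitives, so one backward() pass yields exact parameter gradients.
#
# A node is an environment holding `val` (a matrix), an accumulated `grad`,
# and a `bw` closure that pushes the incoming gradient to its parents.
# Nodes are appended to a tape in creation order; backward walks it in
# reverse. Parameters are cached per tape by name so that reusing a weight
# (e.g. across molecules of a batch) accumulates gradients correctly.

ad_ctx <- function(training = FALSE) {
  ctx <- new.env(parent = emptyenv())
  ctx$tape <- vector("list", 512L)
  ctx$n <- 0L
  ctx$params <- new.env(parent = emptyenv()) # name -> node
  ctx$pnames <- character(0)
  ctx$training <- isTRUE(training)
  ctx$bn_updates <- list() # batch statistics observed during a training pass
  ctx
}

ad_node <- function(ctx, val, bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$bw <- bw
  n <- ctx$n + 1L
  if (n > length(ctx$tape)) {
    ctx$tape <- c(ctx$tape, vector("list", length(ctx$tape)))
  }
  ctx$tape[[n]] <- nd
  ctx$n <- n
  nd
}

ad_const <- function(ctx, val) {
  if (!is.matrix(val)) val <- as.matrix(val)
  ad_node(ctx, val)
}

# Fetch (and cache) the tape node for a named parameter matrix.
ad_param <- function(ctx, params, name) {
  nd <- ctx$params[[name]]
  if (is.null(nd)) {
    val <- params[[name]]
    if (is.null(val)) stop("unknown parameter: ", name)
    nd <- ad_node(ctx, val)
    assign(name, nd, envir = ctx$params)
    ctx$pnames <- c(ctx$pnames, name)
  }
  nd
}

ad_accum <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

# Run the reverse pass from a scalar (1x1) node; returns the named list of
# gradients for every parameter touched by this tape.
ad_backward <- function(ctx, loss) {
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(ctx$n, 1L)) {
    nd <- ctx$tape[[i]]
    if (!is.null(nd$bw) && !is.null(nd$grad)) nd$bw(nd$grad)
  }
  grads <- vector("list", length(ctx$pnames))
  names(grads) <- ctx$pnames
  for (nm in ctx$pnames) {
    pn <- ctx$params[[nm]]
    grads[[nm]] <- if (is.null(pn$grad)) pn$val * 0 else pn$grad
  }
  grads
}

## ---- primitive operations -------------------------------------------------

ad_matmul <- function(ctx, a, b) {
  ad_node(ctx, a$val %*% b$val, bw = function(g) {
    ad_accum(a, g %*% t(b$val))
    ad_accum(b, t(a$val) %*% g)
  })
}

ad_add <- function(ctx, a, b) {
  ad_node(ctx, a$val + b$val, bw = function(g) {
    ad_accum(a, g)
    ad_accum(b, g)
  })
}

ad_sub <- function(ctx, a, b) {
  ad_node(ctx, a$val - b$val, bw = function(g) {
    ad_accum(a, g)
    ad_accum(b, -g)
  })
}

ad_mul <- function(ctx, a, b) {
  ad_node(ctx, a$val * b$val, bw = function(g) {
    ad_accum(a, g * b$val)
    ad_accum(b, g * a$val)
  })
}

ad_scale <- function(ctx, a, k) {
  ad_node(ctx, a$val * k, bw = function(g) ad_accum(a, g * k))
}

# broadcast a 1 x k row vector across the rows of a (n x k)
ad_add_rv <- function(ctx, a, r) {
  ad_node(ctx, sweep(a$val, 2L, r$val[1L, ], "+"), bw = function(g) {
    ad_accum(a, g)
    ad_accum(r, matrix(colSums(g), 1L))
  })
}

ad_sub_rv <- function(ctx, a, r) {
  ad_node(ctx, sweep(a$val, 2L, r$val[1L, ], "-"), bw = function(g) {
    ad_accum(a, g)
    ad_accum(r, matrix(-colSums(g), 1L))
  })
}

ad_mul_rv <- function(ctx, a, r) {
  rv <- r$val[1L, ]
  ad_node(ctx, sweep(a$val, 2L, rv, "*"), bw = function(g) {
    ad_accum(a, sweep(g, 2L, rv, "*"))
    ad_accum(r, matrix(colSums(g * a$val), 1L))
  })
}

# scale each row i of a (n x k) by column-vector entry c_i (n x 1)
ad_mul_cv <- function(ctx, a, cv) {
  cc <- cv$val[, 1L]
  ad_node(ctx, a$val * cc, bw = function(g) {
    ad_accum(a, g * cc)
    ad_accum(cv, matrix(rowSums(g * a$val), ncol = 1L))
  })
}

# gather rows (embedding lookup / edge endpoint gather)
ad_rows <- function(ctx, a, idx) {
  idx <- as.integer(idx)
  ad_node(ctx, a$val[idx, , drop = FALSE], bw = function(g) {
    gp <- matrix(0, nrow(a$val), ncol(a$val))
    rs <- rowsum(g, group = idx)
    gp[as.integer(rownames(rs)), ] <- rs
    ad_accum(a, gp)
  })
}

# sum rows of a into n buckets given by idx (message aggregation)
ad_scatter_sum <- function(ctx, a, idx, n) {
  idx <- as.integer(idx)
  out <- matrix(0, n, ncol(a$val))
  if (nrow(a$val) > 0L) {
    rs <- rowsum(a$val, group = idx)
    out[as.integer(rownames(rs)), ] <- rs
  }
  ad_node(ctx, out, bw = function(g) {
    if (nrow(a$val) > 0L) ad_accum(a, g[idx, , drop = FALSE])
  })
}

ad_cbind <- function(ctx, a, b) {
  ka <- ncol(a$val)
  ad_node(ctx, cbind(a$val, b$val), bw = function(g) {
    ad_accum(a, g[, seq_len(ka), drop = FALSE])
    ad_accum(b, g[, -seq_len(ka), drop = FALSE])
  })
}

ad_colmeans <- function(ctx, a) {
  n <- nrow(a$val)
  ad_node(ctx, matrix(colMeans(a$val), 1L), bw = function(g) {
    ad_accum(a, matrix(g[1L, ], n, ncol(a$val), byrow = TRUE) / n)
  })
}

ad_mean_all <- function(ctx, a) {
  n <- length(a$val)
  ad_node(ctx, matrix(mean(a$val), 1L, 1L), bw = function(g) {
    ad_accum(a, matrix(g[1L, 1L] / n, nrow(a$val), ncol(a$val)))
  })
}

ad_sum_all <- function(ctx, a) {
  ad_node(ctx, matrix(sum(a$val), 1L, 1L), bw = function(g) {
    ad_accum(a, matrix(g[1L, 1L], nrow(a$val), ncol(a$val)))
  })
}

# subtract the column means from every row (zero center of mass)
ad_center_rows <- function(ctx, a) {
  ad_node(ctx, sweep(a$val, 2L, colMeans(a$val), "-"), bw = function(g) {
    ad_accum(a, sweep(g, 2L, colMeans(g), "-"))
  })
}

## ---- elementwise nonlinearities --------------------------------------------

ad_relu <- function(ctx, a) {
  m <- a$val > 0
  ad_node(ctx, a$val * m, bw = function(g) ad_accum(a, g * m))
}

ad_leaky_relu <- function(ctx, a, slope = 0.01) {
  m <- ifelse(a$val > 0, 1, slope)
  ad_node(ctx, a$val * m, bw = function(g) ad_accum(a, g * m))
}

ad_sigmoid <- function(ctx, a) {
  s <- 1 / (1 + exp(-a$val))
  ad_node(ctx, s, bw = function(g) ad_accum(a, g * s * (1 - s)))
}

# exact GeLU: x * Phi(x)
ad_gelu <- function(ctx, a) {
  p <- stats::pnorm(a$val)
  ad_node(ctx, a$val * p, bw = function(g) {
    ad_accum(a, g * (p + a$val * stats::dnorm(a$val)))
  })
}

ad_softplus <- function(ctx, a) {
  # numerically stable log(1 + exp(x))
  v <- ifelse(a$val > 30, a$val, log1p(exp(pmin(a$val, 30))))
  s <- 1 / (1 + exp(-a$val))
  ad_node(ctx, v, bw = function(g) ad_accum(a, g * s))
}

ad_square <- function(ctx, a) {
  ad_node(ctx, a$val^2, bw = function(g) ad_accum(a, 2 * g * a$val))
}

ad_exp <- function(ctx, a) {
  v <- exp(a$val)
  ad_node(ctx, v, bw = function(g) ad_accum(a, g * v))
}

# 1 / sqrt(x + eps), used by batch normalisation
ad_rsqrt <- function(ctx, a, eps = 1e-5) {
  v <- 1 / sqrt(a$val + eps)
  ad_node(ctx, v, bw = function(g) ad_accum(a, -0.5 * g * v^3))
}
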