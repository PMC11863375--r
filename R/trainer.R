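# Training loop: per iteration a batch of molecules each receives a
# uniformly sampled diffusion step and a fresh noise draw; the combined
# epsilon-matching loss is backpropagated, the global gradient norm is
# clipped, and Adam (beta1 = 0.95, beta2 = 0.999, no weight decay) takes a
# step. Validation runs on a fixed-noise objective every `val_interval`
# iterations and a plateau scheduler multiplies the learning rate by 0.6
# after `patience` consecutive non-improving validations.

#' Training configuration
#'
#' Defaults mirror the reference training procedure: Adam with learning
#' rate 1e-3 and moment coefficients (0.95, 0.999), no weight decay,
#' plateau factor 0.6 with patience 10 validations, validation every 5000
#' iterations, and the small-molecule presets of batch size 64 and
#' gradient-clip norm 10000 (drug-like preset: 32 / 30000).
#'
#' @param lr initial learning rate.
#' @param beta1,beta2 Adam moment coefficients.
#' @param weight_decay L2 coefficient (0 = none).
#' @param plateau_factor learning-rate decay factor.
#' @param plateau_patience consecutive non-improving validations before a
#'   decay.
#' @param min_lr learning-rate floor.
#' @param batch_size molecules per iteration.
#' @param clip_norm maximum global gradient norm.
#' @param val_interval iterations between validations.
#' @param max_iter total iterations.
#' @param n_val_draws noise draws per validation molecule.
#' @param bn_freeze_iter iteration after which batch-norm running
#'   statistics stop updating. The default 0 keeps the unit
#'   initialisation statistics throughout (the learnable scale/shift
#'   still adapts): on single-molecule mini-batches of a few atoms the
#'   observed per-channel variances collapse on many channels, and
#'   normalising by them both ill-conditions the network and moves the
#'   normalisation target under the optimiser. Set a positive value (or
#'   `Inf`) to calibrate running statistics on larger, diverse batches.
#' @param seed run seed.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-3, beta1 = 0.95, beta2 = 0.999,
                         weight_decay = 0, plateau_factor = 0.6,
                         plateau_patience = 10L, min_lr = 1e-6,
                         batch_size = 64L, clip_norm = 10000,
                         val_interval = 5000L, max_iter = 10000L,
                         n_val_draws = 4L, bn_freeze_iter = 0,
                         seed = 1L) {
  stopifnot(lr > 0, plateau_factor > 0, plateau_factor < 1, clip_norm > 0,
            batch_size >= 1, val_interval >= 1, max_iter >= 1)
  structure(as.list(environment()), class = "train_config")
}

#' Plateau learning-rate scheduler
#'
#' Tracks the best validation loss seen; after `patience` consecutive
#' validations without strict improvement the learning rate is multiplied
#' by `factor` (never below `min_lr`) and the counter resets.
#'
#' @param lr initial learning rate.
#' @param factor decay factor in (0, 1).
#' @param patience consecutive non-improving validations tolerated.
#' @param min_lr floor.
#' @return a `plateau_scheduler` state list.
#' @export
plateau_scheduler <- function(lr = 1e-3, factor = 0.6, patience = 10L,
                              min_lr = 1e-6) {
  structure(list(lr = lr, factor = factor, patience = as.integer(patience),
                 min_lr = min_lr, best = Inf, bad = 0L),
            class = "plateau_scheduler")
}

#' @param sched a [plateau_scheduler()] state.
#' @param val_loss newly observed validation loss.
#' @rdname plateau_scheduler
#' @export
plateau_step <- function(sched, val_loss) {
  if (val_loss < sched$best) {
    sched$best <- val_loss
    sched$bad <- 0L
  } else {
    sched$bad <- sched$bad + 1L
    if (sched$bad >= sched$patience) {
      sched$lr <- max(sched$lr * sched$factor, sched$min_lr)
      sched$bad <- 0L
    }
  }
  sched
}

#' Clip a gradient list to a maximum global L2 norm
#'
#' @param grads named list of gradient matrices.
#' @param max_norm clip threshold.
#' @return the (possibly rescaled) gradient list, with attribute
#'   `"grad_norm"` holding the pre-clip norm.
#' @export
clip_gradients <- function(grads, max_norm) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1L))))
  if (is.finite(total) && total > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  attr(grads, "grad_norm") <- total
  grads
}

adam_init <- function(params) {
  trainable <- names(params)[vapply(names(params), is_trainable_param,
                                    logical(1L))]
  list(step = 0L,
       m = lapply(params[trainable], function(p) p * 0),
       v = lapply(params[trainable], function(p) p * 0))
}

adam_step <- function(params, grads, state, lr, beta1, beta2,
                      weight_decay = 0, eps = 1e-8) {
  state$step <- state$step + 1L
  bc1 <- 1 - beta1^state$step
  bc2 <- 1 - beta2^state$step
  for (nm in names(grads)) {
    if (!is_trainable_param(nm)) next
    g <- grads[[nm]]
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# fold batch statistics observed during the forward pass into the running
# estimates (momentum 0.1, as in standard batch normalisation)
apply_bn_updates <- function(params, updates, momentum = 0.1) {
  for (u in updates) {
    mn <- paste0(u$prefix, ".running_mean")
    vn <- paste0(u$prefix, ".running_var")
    params[[mn]] <- (1 - momentum) * params[[mn]] + momentum * u$mean
    params[[vn]] <- (1 - momentum) * params[[vn]] + momentum * u$var
  }
  params
}

#' Validation objective with fixed noise seeds
#'
#' Mean training objective over the validation molecules, with the
#' diffusion step and noise of draw `d` for molecule `k` derived
#' deterministically from `seed`, so values are comparable across calls.
#'
#' @param model score model.
#' @param dataset list of molecules with coordinates.
#' @param sched noise schedule.
#' @param n_draws noise draws per molecule (must be >= 1).
#' @param seed seed for the fixed draws.
#' @return scalar mean loss.
#' @export
validate_model <- function(model, dataset, sched, n_draws = 4L, seed = 1L) {
  if (length(dataset) == 0L) stop("validation set is empty")
  if (n_draws < 1L) stop("n_draws must be >= 1")
  total <- 0
  count <- 0L
  for (k in seq_along(dataset)) {
    mol <- dataset[[k]]
    for (d in seq_len(n_draws)) {
      set.seed(derive_seed(seed, k * 1000L + d))
      t <- sample.int(sched$T_steps, 1L)
      eps <- matrix(stats::rnorm(3L * n_atoms(mol)), n_atoms(mol), 3L)
      total <- total + training_loss(model, mol, mol$coords, t, eps, sched)$loss
      count <- count + 1L
    }
  }
  total / count
}

#' Train a score model
#'
#' @param model a [init_score_model()] object (or a checkpoint to resume).
#' @param dataset list of training molecules (with coordinates).
#' @param sched noise schedule.
#' @param config a [train_config()].
#' @param val_dataset validation molecules (defaults to `dataset`).
#' @param checkpoint_dir if given, a checkpoint is written at every
#'   validation.
#' @param resume optional `train_state` from a previous [train_model()]
#'   call; continues bit-exactly.
#' @param verbose print progress lines.
#' @return list with the trained `model`, the final `state` (iteration,
#'   lr, best validation loss, Adam/scheduler/RNG state) and a `history`
#'   data frame (iteration, loss, lr, grad_norm).
#' @export
train_model <- function(model, dataset, sched, config = train_config(),
                        val_dataset = dataset, checkpoint_dir = NULL,
                        resume = NULL, verbose = FALSE) {
  if (length(dataset) == 0L) stop("training set is empty")
  params <- model$params
  cfg <- model$config

  if (is.null(resume)) {
    set.seed(config$seed)
    opt <- adam_init(params)
    lrs <- plateau_scheduler(config$lr, config$plateau_factor,
                             config$plateau_patience, config$min_lr)
    iter0 <- 0L
    history <- list()
  } else {
    opt <- resume$opt
    lrs <- resume$lrs
    iter0 <- resume$iteration
    history <- resume$history
    assign(".Random.seed", resume$rng, envir = globalenv())
  }

  for (iter in seq.int(iter0 + 1L, iter0 + config$max_iter)) {
    idx <- sample.int(length(dataset), config$batch_size, replace = TRUE)
    ctx <- ad_ctx(training = TRUE)
    loss_nodes <- vector("list", length(idx))
    for (b in seq_along(idx)) {
      mol <- dataset[[idx[b]]]
      t <- sample.int(sched$T_steps, 1L)
      eps <- matrix(stats::rnorm(3L * n_atoms(mol)), n_atoms(mol), 3L)
      loss_nodes[[b]] <- training_loss_node(ctx, params, cfg, mol,
                                            mol$coords, t, eps, sched)$loss
    }
    total <- loss_nodes[[1L]]
    if (length(loss_nodes) > 1L) {
      for (b in 2:length(loss_nodes)) total <- ad_add(ctx, total, loss_nodes[[b]])
    }
    total <- ad_scale(ctx, total, 1 / length(idx))
    loss_val <- total$val[1L, 1L]
    if (!is.finite(loss_val)) {
      stop("non-finite training loss at iteration ", iter)
    }
    grads <- ad_backward(ctx, total)
    grads <- clip_gradients(grads, config$clip_norm)
    upd <- adam_step(params, grads, opt, lrs$lr, config$beta1, config$beta2,
                     config$weight_decay)
    params <- upd$params
    opt <- upd$state
    if (iter <= config$bn_freeze_iter) {
      params <- apply_bn_updates(params, ctx$bn_updates)
    }

    history[[length(history) + 1L]] <-
      data.frame(iteration = iter, loss = loss_val, lr = lrs$lr,
                 grad_norm = attr(grads, "grad_norm"))

    if (iter %% config$val_interval == 0L) {
      rng_save <- get(".Random.seed", envir = globalenv())
      model_now <- structure(list(params = params, config = cfg),
                             class = "score_model")
      vloss <- validate_model(model_now, val_dataset, sched,
                              config$n_val_draws, seed = config$seed)
      lrs <- plateau_step(lrs, vloss)
      if (verbose) {
        message(sprintf("iter %d: loss %.4f, val %.4f, lr %.2e",
                        iter, loss_val, vloss, lrs$lr))
      }
      if (!is.null(checkpoint_dir)) {
        st <- list(iteration = iter, opt = opt, lrs = lrs, history = history,
                   rng = rng_save)
        save_checkpoint(model_now, file.path(checkpoint_dir,
                                             sprintf("ckpt_%07d.rds", iter)),
                        state = st)
      }
      assign(".Random.seed", rng_save, envir = globalenv())
    }
  }

  state <- list(iteration = iter0 + config$max_iter, opt = opt, lrs = lrs,
                history = history,
                rng = get(".Random.seed", envir = globalenv()),
                best_val = lrs$best)
  list(model = structure(list(params = params, config = cfg),
                         class = "score_model"),
       state = state,
       history = do.call(rbind, history))
}

#' Save / load a model checkpoint
#'
#' Checkpoints hold a versioned header, the parameter list (including
#' batch-norm running statistics), the architecture configuration and
#' optionally the full training state for bit-exact resumption.
#'
#' @param model score model.
#' @param path file path.
#' @param state optional training state.
#' @return `save_checkpoint` the path; `load_checkpoint` a list with
#'   `model` and `state`.
#' @export
save_checkpoint <- function(model, path, state = NULL) {
  obj <- list(format = "confdiff-checkpoint", version = 1L,
              params = model$params, config = model$config, state = state)
  tryCatch(saveRDS(obj, path),
           error = function(e) stop("I/O error writing checkpoint '", path,
                                    "': ", conditionMessage(e)))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "confdiff-checkpoint")) {
    stop("not a confdiff checkpoint: ", path)
  }
  list(model = structure(list(params = obj$params, config = obj$config),
                         class = "score_model"),
       state = obj$state)
}
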