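# Denoising diffusion over atomic coordinates: sigmoidal variance schedule,
# closed-form forward noising, the reverse (ancestral) update and the
# simplified epsilon-matching objective.
#
# Conventions: beta_t for t = 1..T rises sigmoidally from beta_min to
# beta_max; alpha_t = 1 - beta_t; alpha_bar_t is the running product (with
# alpha_bar_0 = 1); the posterior standard deviation is
# sigma_t^2 = beta_t * (1 - alpha_bar_{t-1}) / (1 - alpha_bar_t).
# Coordinates and injected noise are centroid-subtracted at every step so
# the unconstrained translational mode never enters.

#' Diffusion process configuration
#'
#' Defaults follow the reference setup: 5000 steps with beta rising
#' sigmoidally from 1e-7 to 2e-3 along a linearly spaced span of
#' \[-6, 6\].
#'
#' @param T_steps number of diffusion steps.
#' @param beta_min,beta_max endpoints of the variance schedule.
#' @param span sigmoid argument range (length 2).
#' @param gamma_t loss weight rule: `"one"` (the simple objective) or
#'   `"sigma2"` (`gamma_t = 1 - alpha_bar_t`, which balances the gradient
#'   magnitude of the score-scaled noise prediction across steps).
#' @return a `diffusion_config` list.
#' @export
diffusion_config <- function(T_steps = 5000L, beta_min = 1e-7,
                             beta_max = 2e-3, span = c(-6, 6),
                             gamma_t = c("one", "sigma2")) {
  gamma_t <- match.arg(gamma_t)
  if (T_steps < 1L) stop("config error: T_steps must be >= 1")
  if (beta_min >= beta_max) stop("config error: beta_min must be < beta_max")
  structure(list(T_steps = as.integer(T_steps), beta_min = beta_min,
                 beta_max = beta_max, span = span, gamma_t = gamma_t),
            class = "diffusion_config")
}

#' Build the noise schedule
#'
#' `beta_t = beta_min + logistic(s_t) * (beta_max - beta_min)` with `s_t`
#' linearly spaced over the configured span (a single-step schedule takes
#' the left endpoint). Derived arrays `alpha`, `alpha_bar` and the
#' posterior `sigma` are populated.
#'
#' @param cfg a [diffusion_config()].
#' @return a `noise_schedule` list with elements `T_steps`, `beta`,
#'   `alpha`, `alpha_bar` (length T), `sigma`, and `alpha_bar0 = 1`.
#' @export
make_schedule <- function(cfg = diffusion_config()) {
  stopifnot(inherits(cfg, "diffusion_config"))
  Tn <- cfg$T_steps
  s <- if (Tn == 1L) cfg$span[1L] else seq(cfg$span[1L], cfg$span[2L],
                                           length.out = Tn)
  beta <- cfg$beta_min + stats::plogis(s) * (cfg$beta_max - cfg$beta_min)
  alpha <- 1 - beta
  alpha_bar <- cumprod(alpha)
  alpha_bar_prev <- c(1, alpha_bar[-Tn])
  sigma2 <- beta * (1 - alpha_bar_prev) / (1 - alpha_bar)
  structure(list(T_steps = Tn, beta = beta, alpha = alpha,
                 alpha_bar = alpha_bar, sigma = sqrt(sigma2), cfg = cfg),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("<noise_schedule: T=%d, beta in [%.3g, %.3g], alpha_bar_T=%.3g>\n",
              x$T_steps, x$beta[1L], x$beta[x$T_steps],
              x$alpha_bar[x$T_steps]))
  invisible(x)
}

check_step <- function(t, sched) {
  if (length(t) != 1L || t < 1L || t > sched$T_steps) {
    stop("step error: t must be in [1, ", sched$T_steps, "]")
  }
  as.integer(t)
}

center_coords <- function(x) sweep(x, 2L, colMeans(x), "-")

#' Closed-form forward sample
#'
#' `X_t = sqrt(alpha_bar_t) X_0 + sqrt(1 - alpha_bar_t) eps`, with both
#' `X_0` and `eps` zero-centred first.
#'
#' @param X0 n x 3 reference coordinates.
#' @param t diffusion step in 1..T.
#' @param eps n x 3 noise draw (standard normal under training).
#' @param sched a [make_schedule()] result.
#' @return noised n x 3 coordinates.
#' @export
forward_sample <- function(X0, t, eps, sched) {
  t <- check_step(t, sched)
  X0 <- as.matrix(X0)
  eps <- as.matrix(eps)
  if (!all(dim(eps) == dim(X0))) stop("input error: eps shape mismatch")
  ab <- sched$alpha_bar[t]
  sqrt(ab) * center_coords(X0) + sqrt(1 - ab) * center_coords(eps)
}

#' One reverse (denoising) step
#'
#' `X_{t-1} = (X_t - beta_t/sqrt(1-alpha_bar_t) * eps_hat)/sqrt(alpha_t)
#'  + sigma_t z`; the stochastic term is dropped at the final step
#' (`t = 1`). Output is re-centred.
#'
#' @param Xt current coordinates.
#' @param eps_hat model-predicted noise, same shape.
#' @param t current step.
#' @param z noise draw for the stochastic term (ignored at `t = 1`).
#' @param sched schedule.
#' @return denoised coordinates at step `t - 1`.
#' @export
reverse_step <- function(Xt, eps_hat, t, z, sched) {
  t <- check_step(t, sched)
  Xt <- as.matrix(Xt)
  eps_hat <- as.matrix(eps_hat)
  mean_t <- (Xt - sched$beta[t] / sqrt(1 - sched$alpha_bar[t]) * eps_hat) /
    sqrt(sched$alpha[t])
  if (t > 1L) {
    mean_t <- mean_t + sched$sigma[t] * center_coords(as.matrix(z))
  }
  center_coords(mean_t)
}

#' Simplified epsilon-matching loss
#'
#' `gamma_t * mean((eps - eps_hat)^2)`; under the simple objective
#' `gamma_t = 1` for all steps.
#'
#' @param eps_hat predicted noise.
#' @param eps true noise.
#' @param t step (used only by non-trivial weight rules).
#' @param cfg a [diffusion_config()].
#' @return scalar loss.
#' @export
loss_eps <- function(eps_hat, eps, t = 1L, cfg = diffusion_config()) {
  eps_hat <- as.matrix(eps_hat)
  eps <- as.matrix(eps)
  if (!all(dim(eps_hat) == dim(eps))) stop("input error: shape mismatch")
  gamma_weight(cfg$gamma_t, t, cfg) * mean((eps - eps_hat)^2)
}

# per-step loss weight; "sigma2" needs the alpha_bar value for t, which a
# schedule-owning caller supplies via `ab`
gamma_weight <- function(rule, t, cfg = NULL, ab = NULL) {
  if (identical(rule, "sigma2")) {
    if (is.null(ab)) {
      sch <- make_schedule(cfg)
      ab <- sch$alpha_bar[t]
    }
    1 - ab
  } else {
    1
  }
}

#' Generate conformers by ancestral sampling
#'
#' Starts each conformer from a centred standard-normal prior draw and
#' applies [reverse_step()] T times with the model's predicted noise,
#' rebuilding spatial edges from the current coordinates at every step.
#' A `model` of `NULL` uses a zero noise prediction (useful for
#' schedule-only diagnostics).
#'
#' @param model a trained score model (see [init_score_model()]) or `NULL`.
#' @param graph a [molecule_graph()].
#' @param sched noise schedule.
#' @param n_conf number of conformers to draw.
#' @param seed integer seed; conformer `k` uses a sub-seed derived from
#'   `(seed, k)` so draws are independent and reproducible.
#' @param save_every if positive, keep every k-th frame of the first
#'   trajectory (plus start and end).
#' @return a `conformer_set` (role `"generated"`); if `save_every > 0` the
#'   attribute `"trajectory"` holds the saved frames of conformer 1.
#' @export
sample_conformers <- function(model, graph, sched, n_conf = 1L, seed = 1L,
                              save_every = 0L) {
  n <- n_atoms(graph)
  frames <- vector("list", n_conf)
  trajectory <- NULL
  for (k in seq_len(n_conf)) {
    set.seed(derive_seed(seed, k))
    x <- center_coords(matrix(stats::rnorm(3L * n), n, 3L))
    keep <- save_every > 0L && k == 1L
    if (keep) trajectory <- list(x)
    for (t in seq.int(sched$T_steps, 1L)) {
      eps_hat <- if (is.null(model)) {
        matrix(0, n, 3L)
      } else {
        predict_eps(model, graph, x, t, sched)$eps
      }
      z <- if (t > 1L) matrix(stats::rnorm(3L * n), n, 3L) else matrix(0, n, 3L)
      x <- reverse_step(x, eps_hat, t, z, sched)
      if (!all(is.finite(x)) || max(abs(x)) > 1e3) {
        stop("divergence error at step ", t, " of conformer ", k)
      }
      if (keep && (t == 1L || (sched$T_steps - t + 1L) %% save_every == 0L)) {
        trajectory[[length(trajectory) + 1L]] <- x
      }
    }
    frames[[k]] <- x
  }
  out <- conformer_set(graph$name, frames, role = "generated")
  if (!is.null(trajectory)) attr(out, "trajectory") <- trajectory
  out
}

# small deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483647)
}

#' Dump / load a schedule as CSV (columns t, beta, alpha_bar, sigma)
#' @param sched schedule to write.
#' @param path file path.
#' @return `write_schedule_csv` the path; `read_schedule_csv` a data frame.
#' @export
write_schedule_csv <- function(sched, path) {
  utils::write.csv(data.frame(t = seq_len(sched$T_steps), beta = sched$beta,
                              alpha_bar = sched$alpha_bar,
                              sigma = sched$sigma),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) utils::read.csv(path)
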