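test_that("sigmoidal schedule matches its closed form and config errors fire", {
  expect_error(diffusion_config(T_steps = 0), "config error")
  expect_error(diffusion_config(beta_min = 1e-3, beta_max = 1e-4),
               "config error")

  # degenerate single-step schedule takes the left endpoint of the span
  s1 <- make_schedule(diffusion_config(T_steps = 1L))
  expect_equal(s1$beta,
               1e-7 + stats::plogis(-6) * (2e-3 - 1e-7), tolerance = 1e-15)

  sch <- make_schedule(diffusion_config())
  # direct evaluation of the closed form at the mid-index; logistic(~0)
  # is ~0.5 so the value sits at ~1.00005e-3
  s_mid <- -6 + 12 * 2499 / 4999
  expect_equal(sch$beta[2500L],
               1e-7 + stats::plogis(s_mid) * (2e-3 - 1e-7), tolerance = 1e-12)
  expect_equal(sch$beta[2500L], 1.00005e-3, tolerance = 1e-3)
  # independent cumulative-product oracle in log space
  abar_oracle <- exp(cumsum(log(1 - sch$beta)))
  expect_equal(sch$alpha_bar, abar_oracle, tolerance = 1e-12)
  expect_lt(sch$alpha_bar[5000L], 0.01)
  expect_equal(sch$alpha_bar[5000L], 6.7e-3, tolerance = 0.01)
})

test_that("schedule invariants: beta bounded monotone, alpha_bar decreasing", {
  sch <- make_schedule(diffusion_config())
  expect_true(all(diff(sch$beta) >= 0))
  expect_true(all(sch$beta >= 1e-7 - 1e-12 & sch$beta <= 2e-3 + 1e-12))
  expect_true(all(diff(sch$alpha_bar) < 0))
  expect_true(all(sch$sigma >= 0))
  # posterior sigma_1 is zero (alpha_bar_0 = 1)
  expect_equal(sch$sigma[1L], 0)
})

test_that("variance propagation of the stepwise process matches 1 - alpha_bar", {
  sch <- tiny_schedule(50L)
  # symbolic recursion: v_t = alpha_t v_{t-1} + beta_t, v_0 = 0, and the
  # signal coefficient m_t = prod sqrt(alpha)
  v <- 0
  m <- 1
  for (t in seq_len(50L)) {
    v <- sch$alpha[t] * v + sch$beta[t]
    m <- m * sqrt(sch$alpha[t])
    expect_equal(v, 1 - sch$alpha_bar[t], tolerance = 1e-12)
    expect_equal(m, sqrt(sch$alpha_bar[t]), tolerance = 1e-12)
  }
})

test_that("forward_sample has the closed-form conditional mean and variance", {
  sch <- tiny_schedule(40L)
  X0 <- make_toy("tetrahedral_center", r = 1.54, elements = "C")$coords
  X0c <- sweep(X0, 2L, colMeans(X0))
  n <- nrow(X0)
  expect_error(forward_sample(X0, 0L, X0, sch), "step error")
  expect_error(forward_sample(X0, 41L, X0, sch), "step error")
  expect_equal(forward_sample(X0, 10L, matrix(0, n, 3L), sch),
               sqrt(sch$alpha_bar[10L]) * X0c, tolerance = 1e-12)

  # Monte-Carlo marginal check at t in {1, T/2, T}: per-coordinate mean
  # sqrt(ab) X0c and variance (1 - ab) (1 - 1/n) (noise is centred),
  # within 3 standard errors at 1e4 draws
  set.seed(101)
  N <- 1e4L
  for (t in c(1L, 20L, 40L)) {
    ab <- sch$alpha_bar[t]
    draws <- vapply(seq_len(N), function(k) {
      forward_sample(X0, t, matrix(stats::rnorm(3L * n), n, 3L), sch)[2L, 1L]
    }, numeric(1L))
    mu_exp <- sqrt(ab) * X0c[2L, 1L]
    v_exp <- (1 - ab) * (1 - 1 / n)
    expect_lt(abs(mean(draws) - mu_exp), 3 * sqrt(v_exp / N))
    expect_lt(abs(stats::var(draws) - v_exp), 3 * v_exp * sqrt(2 / (N - 1)))
  }
})

test_that("reverse_step evaluates the posterior-mean formula", {
  # antisymmetric two-atom configuration keeps centring inert, so the
  # per-coordinate update equals the scalar formula
  fake <- structure(list(T_steps = 1L, beta = 0.01, alpha = 0.99,
                         alpha_bar = 0.5, sigma = 0,
                         cfg = diffusion_config(1L)),
                    class = "noise_schedule")
  Xt <- rbind(c(1, 0, 0), c(-1, 0, 0))
  eh <- rbind(c(1, 0, 0), c(-1, 0, 0))
  out <- reverse_step(Xt, eh, 1L, matrix(0, 2L, 3L), fake)
  expect_equal(out[1L, 1L], 0.99082, tolerance = 1e-5)

  # eps_hat = 0, z = 0: pure rescale by 1/sqrt(alpha_t)
  sch <- tiny_schedule(10L)
  Xc <- sweep(matrix(stats::rnorm(12), 4L), 2L, colMeans(matrix(0, 1L, 3L)))
  Xc <- sweep(Xc, 2L, colMeans(Xc))
  out <- reverse_step(Xc, matrix(0, 4L, 3L), 5L, matrix(0, 4L, 3L), sch)
  expect_equal(out, Xc / sqrt(sch$alpha[5L]), tolerance = 1e-12)

  # beta -> 0 limit: identity
  fake0 <- structure(list(T_steps = 1L, beta = 1e-15, alpha = 1 - 1e-15,
                          alpha_bar = 0.5, sigma = 0,
                          cfg = diffusion_config(1L)),
                     class = "noise_schedule")
  out0 <- reverse_step(Xt, eh, 1L, matrix(0, 2L, 3L), fake0)
  expect_equal(out0, Xt, tolerance = 1e-6)
  expect_error(reverse_step(Xt, eh, 3L, matrix(0, 2L, 3L), fake), "step error")
})

test_that("forward-then-reverse with oracle noise recovers the previous mean", {
  sch <- tiny_schedule(30L)
  mol <- make_toy("tetrahedral_center", r = 1.54, elements = "C")
  X0c <- sweep(mol$coords, 2L, colMeans(mol$coords))
  set.seed(9)
  for (t in c(2L, 15L, 30L)) {
    eps <- matrix(stats::rnorm(15), 5L, 3L)
    epsc <- sweep(eps, 2L, colMeans(eps))
    Xt <- forward_sample(X0c, t, eps, sch)
    got <- reverse_step(Xt, epsc, t, matrix(0, 5L, 3L), sch)
    ab <- sch$alpha_bar[t]
    abp <- sch$alpha_bar[t - 1L]
    mu <- (sqrt(abp) * sch$beta[t] / (1 - ab)) * X0c +
      (sqrt(sch$alpha[t]) * (1 - abp) / (1 - ab)) * Xt
    expect_equal(got, sweep(mu, 2L, colMeans(mu)), tolerance = 1e-6)
  }
})

test_that("loss_eps is the (weighted) mean squared noise error", {
  e <- matrix(stats::rnorm(12), 4L)
  expect_equal(loss_eps(e, e), 0)
  expect_equal(loss_eps(matrix(0, 4L, 3L), matrix(1, 4L, 3L)), 1)
  eh <- matrix(stats::rnorm(12), 4L)
  expect_equal(loss_eps(eh, e), loss_eps(-eh, -e))
  expect_error(loss_eps(matrix(0, 3L, 3L), matrix(0, 4L, 3L)), "shape")
  # sigma2 rule scales by 1 - alpha_bar_t
  cfg <- diffusion_config(10L, 1e-4, 0.1, gamma_t = "sigma2")
  sch <- make_schedule(cfg)
  expect_equal(loss_eps(matrix(0, 4L, 3L), matrix(1, 4L, 3L), t = 10L, cfg),
               1 - sch$alpha_bar[10L], tolerance = 1e-12)
})

test_that("zero-model sampling is deterministic and matches its recursion", {
  mol <- make_toy("tetrahedral_center", r = 1.54, elements = "C")
  sch <- tiny_schedule(15L)
  a <- sample_conformers(NULL, mol, sch, n_conf = 2L, seed = 42L)
  b <- sample_conformers(NULL, mol, sch, n_conf = 2L, seed = 42L)
  expect_identical(a$frames, b$frames)

  # trajectory bookkeeping: T + 1 frames when every step is kept
  tr <- attr(sample_conformers(NULL, mol, sch, n_conf = 1L, seed = 1L,
                               save_every = 1L), "trajectory")
  expect_length(tr, sch$T_steps + 1L)

  # closed-form recursion oracle for the zero model, replaying the seeds
  n <- 5L
  set.seed(confdiff:::derive_seed(42L, 1L))
  x <- matrix(stats::rnorm(3L * n), n, 3L)
  x <- sweep(x, 2L, colMeans(x))
  for (t in seq.int(15L, 1L)) {
    z <- if (t > 1L) matrix(stats::rnorm(3L * n), n, 3L) else matrix(0, n, 3L)
    zc <- sweep(z, 2L, colMeans(z))
    x <- x / sqrt(sch$alpha[t]) + if (t > 1L) sch$sigma[t] * zc else 0
    x <- sweep(x, 2L, colMeans(x))
  }
  expect_equal(a$frames[[1L]], x, tolerance = 1e-12)
})

test_that("schedule CSV dump round-trips", {
  sch <- tiny_schedule(25L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_schedule_csv(sch, f)
  df <- read_schedule_csv(f)
  expect_equal(df$beta, sch$beta, tolerance = 1e-12)
  expect_equal(df$alpha_bar, sch$alpha_bar, tolerance = 1e-12)
  expect_equal(df$sigma, sch$sigma, tolerance = 1e-12)
})
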