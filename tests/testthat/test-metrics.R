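test_that("minimal RMSD removes rigid motion and matches hand cases", {
  set.seed(12)
  P <- matrix(stats::rnorm(24), 8L, 3L)
  expect_equal(min_rmsd(P, P, mode = "all"), 0)
  R <- random_rotation()
  expect_lt(min_rmsd(P %*% R + 5, P, mode = "all"), 1e-6)
  # symmetric centred pair stretched by 1: optimal rotation is identity
  a <- rbind(c(-1, 0, 0), c(1, 0, 0))
  b <- rbind(c(-2, 0, 0), c(2, 0, 0))
  expect_equal(min_rmsd(a, b, mode = "all"), 1, tolerance = 1e-12)
  expect_error(min_rmsd(P, P[1:4, ], mode = "all"), "mismatch")
  # symmetry of the arguments
  Q <- P + matrix(stats::rnorm(24, sd = 0.3), 8L, 3L)
  expect_equal(min_rmsd(P, Q, mode = "all"), min_rmsd(Q, P, mode = "all"),
               tolerance = 1e-9)
})

test_that("Kabsch superposition agrees with an independent reference", {
  # oracle: brute-force minimisation over Euler angles
  set.seed(3)
  P <- matrix(stats::rnorm(21), 7L, 3L)
  Q <- P + matrix(stats::rnorm(21, sd = 0.4), 7L, 3L)
  Pc <- sweep(P, 2L, colMeans(P))
  Qc <- sweep(Q, 2L, colMeans(Q))
  obj <- function(ang) {
    cz <- cos(ang[1L]); sz <- sin(ang[1L])
    cy <- cos(ang[2L]); sy <- sin(ang[2L])
    cx <- cos(ang[3L]); sx <- sin(ang[3L])
    R <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3L, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3L, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3L, byrow = TRUE)
    sqrt(mean(rowSums((Pc - Qc %*% R)^2)))
  }
  brute <- min(vapply(1:60, function(k) {
    stats::optim(stats::runif(3, -pi, pi), obj)$value
  }, numeric(1L)))
  expect_equal(min_rmsd(P, Q, mode = "all"), brute, tolerance = 1e-5)
})

test_that("heavy-atom selection and symmetry correction behave as documented", {
  # methane-like: 1 heavy atom + 4 hydrogens
  mol <- make_toy("tetrahedral_center", r = 1.09)
  a <- mol$coords
  b <- a
  # a single hydrogen swap: an odd permutation, not realisable by any
  # proper rotation of the tetrahedron
  b[2:5, ] <- b[c(3L, 2L, 4L, 5L), ]
  # heavy mode ignores the hydrogens entirely
  expect_equal(min_rmsd(a, b, mol = mol, mode = "heavy"), 0, tolerance = 1e-9)
  # all-atom without symmetry sees the swap; with symmetry it vanishes
  expect_gt(min_rmsd(a, b, mol = mol, mode = "all"), 0.5)
  expect_lt(min_rmsd(a, b, mol = mol, mode = "all", symmetry = TRUE), 1e-9)
  # automorphism cap exceeded: identity fallback flagged
  r <- min_rmsd(a, b, mol = mol, mode = "all", symmetry = TRUE, cap = 2)
  expect_true(isTRUE(attr(r, "fallback")))
})

test_that("COV/MAT reproduce the worked matrix and the identity case", {
  M <- rbind(c(0.3, 0.9, 1.1), c(1.2, 0.4, 0.8))
  rep <- cov_mat_from_matrix(M, delta = 0.5)
  expect_equal(rep$cov_r, 100)
  expect_equal(rep$mat_r, 0.35, tolerance = 1e-12)
  expect_equal(rep$cov_p, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(rep$mat_p, 0.5, tolerance = 1e-12)

  mol <- make_toy("tetrahedral_center", r = 1.54, elements = "C")
  Sr <- make_reference_ensemble(mol, 4L, jitter_sd = 0.2, seed = 5L)
  Sg <- conformer_set(mol$name, Sr$frames, role = "generated")
  same <- cov_mat(Sg, Sr, delta = 0.5, mol = mol)
  expect_equal(same$cov_r, 100)
  expect_equal(same$cov_p, 100)
  expect_equal(same$mat_r, 0, tolerance = 1e-9)
  expect_equal(same$mat_p, 0, tolerance = 1e-9)
  # all cross-RMSDs beyond delta
  expect_equal(cov_mat_from_matrix(matrix(2, 3L, 3L), 0.5)$cov_r, 0)
  expect_error(cov_mat(Sg, conformer_set("x", list(), "reference")),
               "at least one frame")
})

test_that("cov_mat matches a brute-force double loop on random matrices", {
  set.seed(77)
  for (k in 1:100) {
    nr <- sample(1:10, 1L)
    ng <- sample(1:10, 1L)
    M <- matrix(stats::runif(nr * ng, 0, 2), nr, ng)
    delta <- stats::runif(1, 0.2, 1.5)
    rep <- cov_mat_from_matrix(M, delta)
    cov_r <- 0; mat_r <- 0
    for (r in seq_len(nr)) {
      best <- Inf
      for (g in seq_len(ng)) best <- min(best, M[r, g])
      cov_r <- cov_r + (best <= delta)
      mat_r <- mat_r + best
    }
    cov_p <- 0; mat_p <- 0
    for (g in seq_len(ng)) {
      best <- Inf
      for (r in seq_len(nr)) best <- min(best, M[r, g])
      cov_p <- cov_p + (best <= delta)
      mat_p <- mat_p + best
    }
    expect_equal(rep$cov_r, 100 * cov_r / nr)
    expect_equal(rep$mat_r, mat_r / nr)
    expect_equal(rep$cov_p, 100 * cov_p / ng)
    expect_equal(rep$mat_p, mat_p / ng)
  }
})

test_that("recall metrics ignore duplicated frames and improve with coverage", {
  mol <- make_toy("tetrahedral_center", r = 1.54, elements = "C")
  Sr <- make_reference_ensemble(mol, 3L, jitter_sd = 0.3, seed = 8L)
  set.seed(9)
  gframes <- lapply(1:4, function(k) {
    mol$coords + matrix(stats::rnorm(15, sd = 0.3), 5L, 3L)
  })
  Sg <- conformer_set(mol$name, gframes, "generated")
  Sg_dup <- conformer_set(mol$name, c(gframes, gframes), "generated")
  r1 <- cov_mat(Sg, Sr, 0.5, mol = mol)
  r2 <- cov_mat(Sg_dup, Sr, 0.5, mol = mol)
  expect_equal(r2$cov_r, r1$cov_r)
  expect_equal(r2$mat_r, r1$mat_r, tolerance = 1e-12)
  # MAT-R cannot rise when generated frames are added
  extra <- conformer_set(mol$name, c(gframes, list(mol$coords)), "generated")
  expect_lte(cov_mat(extra, Sr, 0.5, mol = mol)$mat_r, r1$mat_r + 1e-12)
})

test_that("best_k returns the k smallest per-frame minima in order", {
  mol <- make_toy("tetrahedral_center", r = 1.54, elements = "C")
  Sr <- make_reference_ensemble(mol, 3L, jitter_sd = 0.1, seed = 2L)
  set.seed(3)
  gframes <- c(list(Sr$frames[[1L]]),
               lapply(1:4, function(k) {
                 mol$coords + matrix(stats::rnorm(15, sd = 0.2), 5L, 3L)
               }))
  Sg <- conformer_set(mol$name, gframes, "generated")
  b1 <- best_k(Sg, Sr, k = 1L, mol = mol)
  expect_equal(as.numeric(b1), 0, tolerance = 1e-9) # exact copy present
  ball <- best_k(Sg, Sr, k = 5L, mol = mol)
  # full-sort oracle over all per-generated minima
  minima <- vapply(gframes, function(f) {
    min(vapply(Sr$frames, function(r) min_rmsd(f, r, mol = mol),
               numeric(1L)))
  }, numeric(1L))
  expect_equal(as.numeric(ball), sort(minima), tolerance = 1e-12)
  expect_false(is.unsorted(ball))
  expect_error(best_k(Sg, Sr, k = 6L), "exceeds")
})

test_that("property correlations follow the Pearson formula and flag constants", {
  r <- c(0.2, 0.5, 0.3, 0.9, 0.6)
  props <- data.frame(same = r, neg = -r, flat = rep(1, 5L),
                      mw = c(16, 30, 44, 58, 72))
  out <- property_correlations(r, props)
  expect_equal(out$r[out$property == "same"], 1, tolerance = 1e-12)
  expect_equal(out$r[out$property == "neg"], -1, tolerance = 1e-12)
  expect_true(is.na(out$r[out$property == "flat"]))
  # textbook Pearson by hand
  mw <- props$mw
  hand <- sum((r - mean(r)) * (mw - mean(mw))) /
    sqrt(sum((r - mean(r))^2) * sum((mw - mean(mw))^2))
  expect_equal(out$r[out$property == "mw"], hand, tolerance = 1e-12)
  expect_error(property_correlations(r[1:2], props[1:2, ]), "at least 3")
  expect_error(property_correlations(r, props[1:4, ]), "aligned")
})

test_that("dihedral follows the atan2 sign convention", {
  # planar trans (anti) arrangement
  expect_equal(dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0)),
               180, tolerance = 1e-9)
  p <- list(c(1, 0.2, 0.1), c(0, 0, 0), c(0, 1.1, 0), c(-0.8, 1.2, 0.6))
  ang <- dihedral(p[[1L]], p[[2L]], p[[3L]], p[[4L]])
  mirror <- lapply(p, function(v) v * c(1, 1, -1))
  expect_equal(dihedral(mirror[[1L]], mirror[[2L]], mirror[[3L]],
                        mirror[[4L]]), -ang, tolerance = 1e-9)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("Ramachandran density is normalised and periodic", {
  set.seed(42)
  phi <- c(stats::rnorm(60, -60, 20), stats::rnorm(40, 60, 25))
  psi <- c(stats::rnorm(60, 150, 25), stats::rnorm(40, -50, 20))
  kde <- ramachandran_density(phi, psi, gridsize = 90L)
  cell <- (360 / 90)^2
  expect_equal(sum(kde$density) * cell, 1, tolerance = 1e-6)
  # periodic edges: identical density at phi = -180 and phi = +180
  psis <- seq(-170, 170, by = 40)
  expect_equal(kde$eval(rep(-180, length(psis)), psis),
               kde$eval(rep(180, length(psis)), psis), tolerance = 1e-10)
  expect_equal(kde$eval(psis, rep(-180, length(psis))),
               kde$eval(psis, rep(180, length(psis))), tolerance = 1e-10)
  expect_error(ramachandran_density(1, 1), "at least 2")
})

test_that("trajectory RMSD series match per-frame calls and average correctly", {
  mol <- make_toy("tetrahedral_center", r = 1.54, elements = "C")
  set.seed(5)
  frames <- lapply(seq(1, 0, length.out = 6L), function(s) {
    mol$coords + matrix(stats::rnorm(15, sd = s * 0.5), 5L, 3L)
  })
  frames[[6L]] <- mol$coords
  series <- trajectory_rmsd(frames, mol$coords, mol = mol)
  expect_equal(series,
               vapply(frames, min_rmsd, numeric(1L), b = mol$coords,
                      mol = mol), tolerance = 1e-12)
  expect_equal(series[6L], 0, tolerance = 1e-9)
  # constant trajectory: constant series
  const <- trajectory_rmsd(rep(list(frames[[2L]]), 4L), mol$coords, mol = mol)
  expect_equal(const, rep(const[1L], 4L))
  # multiple trajectories: elementwise mean curve
  multi <- trajectory_rmsd(list(frames, frames), mol$coords, mol = mol)
  expect_equal(multi$mean, series, tolerance = 1e-12)
})
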