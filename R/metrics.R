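# Conformer-ensemble evaluation: Kabsch minimal RMSD (optionally
# symmetry-corrected over graph automorphisms), COV/MAT recall and
# precision, best-k RMSD, property correlations, signed dihedrals with a
# periodic Ramachandran density, and per-trajectory RMSD traces.

# optimal proper-rotation superposition RMSD (Kabsch): centre both point
# sets, rotate Q onto P by the SVD solution with a determinant correction
# restricting to proper rotations
kabsch_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2L, colMeans(P))
  Qc <- sweep(Q, 2L, colMeans(Q))
  s <- svd(t(Qc) %*% Pc) # maximise tr(R' Qc' Pc) over proper rotations R
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((Pc - Qc %*% R)^2)))
}

# enumerate graph automorphisms (vertex-coloured by atomic number) of the
# subgraph induced by the selected atoms; returns a list of permutations
graph_automorphisms <- function(mol, atoms, cap = 1e4) {
  n <- length(atoms)
  b <- mol$bonds
  keep <- b$i %in% atoms & b$j %in% atoms
  remap <- match(seq_len(n_atoms(mol)), atoms)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (any(keep)) {
    g <- igraph::add_edges(g, rbind(remap[b$i[keep]], remap[b$j[keep]]))
  }
  colors <- as.integer(mol$atom_numbers[atoms])
  cnt <- igraph::count_isomorphisms(g, g, vertex.color1 = colors,
                                    vertex.color2 = colors)
  if (cnt > cap) return(NULL) # caller falls back to the identity mapping
  maps <- igraph::isomorphisms(g, g, vertex.color1 = colors,
                               vertex.color2 = colors)
  lapply(maps, as.integer)
}

#' Minimal RMSD between two conformations
#'
#' Optimal-superposition RMSD (Kabsch, proper rotations only), by default
#' over heavy atoms. With `symmetry = TRUE` and a molecular graph given,
#' the RMSD is minimised over graph automorphisms (vertex-coloured by
#' element); if more than `cap` automorphisms exist the identity mapping
#' is used and the result carries the attribute `fallback = TRUE`.
#'
#' @param a,b n x 3 coordinate matrices with identical atom ordering.
#' @param mol optional [molecule_graph()] (needed for `mode = "heavy"`
#'   element selection and for `symmetry`).
#' @param mode `"heavy"` (exclude hydrogens; requires `mol`) or `"all"`.
#' @param symmetry minimise over graph automorphisms.
#' @param cap automorphism enumeration cap.
#' @return RMSD in Angstrom.
#' @export
min_rmsd <- function(a, b, mol = NULL, mode = c("heavy", "all"),
                     symmetry = FALSE, cap = 1e4) {
  mode <- match.arg(mode)
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("atom-count mismatch between frames")
  atoms <- seq_len(nrow(a))
  if (mode == "heavy" && !is.null(mol)) {
    atoms <- which(mol$atom_numbers != 1L)
    if (length(atoms) == 0L) atoms <- seq_len(nrow(a))
  }
  if (!symmetry || is.null(mol)) {
    return(kabsch_rmsd(a[atoms, , drop = FALSE], b[atoms, , drop = FALSE]))
  }
  perms <- graph_automorphisms(mol, atoms, cap)
  if (is.null(perms)) {
    out <- kabsch_rmsd(a[atoms, , drop = FALSE], b[atoms, , drop = FALSE])
    attr(out, "fallback") <- TRUE
    return(out)
  }
  best <- Inf
  bsel <- b[atoms, , drop = FALSE]
  for (pm in perms) {
    r <- kabsch_rmsd(a[atoms[pm], , drop = FALSE], bsel)
    if (r < best) best <- r
  }
  best
}

rmsd_matrix <- function(Sg, Sr, mol = NULL, mode = "heavy",
                        symmetry = FALSE) {
  M <- matrix(0, length(Sr$frames), length(Sg$frames))
  for (r in seq_along(Sr$frames)) {
    for (g in seq_along(Sg$frames)) {
      M[r, g] <- min_rmsd(Sg$frames[[g]], Sr$frames[[r]], mol = mol,
                          mode = mode, symmetry = symmetry)
    }
  }
  M
}

#' Coverage and matching metrics from an RMSD matrix
#'
#' Rows index reference conformations, columns generated ones. COV-R is
#' the percentage of references whose nearest generated frame lies within
#' `delta`; MAT-R is the mean nearest-generated RMSD over references.
#' COV-P / MAT-P swap the roles.
#'
#' @param M reference x generated RMSD matrix (Angstrom).
#' @param delta coverage threshold delta (Angstrom).
#' @return a `metrics_report` list: `cov_r`, `mat_r`, `cov_p`, `mat_p`
#'   (COV in percent), `delta` and the matrix itself.
#' @export
cov_mat_from_matrix <- function(M, delta) {
  if (nrow(M) == 0L || ncol(M) == 0L) stop("empty RMSD matrix")
  ref_min <- apply(M, 1L, min)
  gen_min <- apply(M, 2L, min)
  structure(list(cov_r = 100 * mean(ref_min <= delta),
                 mat_r = mean(ref_min),
                 cov_p = 100 * mean(gen_min <= delta),
                 mat_p = mean(gen_min),
                 delta = delta, rmsd = M),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report: delta=%.3g A | COV-R %.1f%% MAT-R %.4f | COV-P %.1f%% MAT-P %.4f>\n",
    x$delta, x$cov_r, x$mat_r, x$cov_p, x$mat_p))
  invisible(x)
}

#' Coverage/matching between generated and reference conformer sets
#'
#' @param Sg generated [conformer_set()].
#' @param Sr reference [conformer_set()].
#' @param delta RMSD threshold (Angstrom); 0.5 is the small-molecule
#'   convention, 1.25 the drug-like one.
#' @param mol optional graph for heavy-atom / symmetry handling.
#' @param mode,symmetry passed to [min_rmsd()].
#' @return a `metrics_report`.
#' @export
cov_mat <- function(Sg, Sr, delta = 0.5, mol = NULL, mode = "heavy",
                    symmetry = FALSE) {
  if (length(Sg$frames) == 0L) stop("generated set is empty")
  if (length(Sr$frames) == 0L) stop("reference set is empty")
  cov_mat_from_matrix(rmsd_matrix(Sg, Sr, mol, mode, symmetry), delta)
}

#' The k smallest per-generated-frame minimal RMSDs
#'
#' For each generated frame, take its minimum RMSD over the references;
#' return the `k` smallest such values in ascending order (ties broken by
#' generated-frame index).
#'
#' @inheritParams cov_mat
#' @param k how many values to return (`k <= |Sg|`).
#' @return numeric vector of length `k` with attribute `"index"` giving
#'   the generated-frame indices.
#' @export
best_k <- function(Sg, Sr, k = 5L, delta = NULL, mol = NULL, mode = "heavy",
                   symmetry = FALSE) {
  if (k > length(Sg$frames)) stop("k exceeds the number of generated frames")
  M <- rmsd_matrix(Sg, Sr, mol, mode, symmetry)
  gen_min <- apply(M, 2L, min)
  ord <- order(gen_min, seq_along(gen_min))[seq_len(k)]
  structure(gen_min[ord], index = ord)
}

#' Pearson correlations between per-molecule RMSD means and properties
#'
#' @param rmsd_means named (or positional) numeric vector, one value per
#'   molecule.
#' @param properties data frame of property columns aligned with
#'   `rmsd_means` (>= 3 rows).
#' @return data frame with `property`, `r` (Pearson), `n`; a constant
#'   column yields `NA`.
#' @export
property_correlations <- function(rmsd_means, properties) {
  properties <- as.data.frame(properties)
  if (length(rmsd_means) != nrow(properties)) {
    stop("rmsd_means and properties are not aligned")
  }
  if (length(rmsd_means) < 3L) stop("need at least 3 molecules")
  r <- vapply(properties, function(p) {
    if (stats::sd(p) == 0 || stats::sd(rmsd_means) == 0) return(NA_real_)
    stats::cor(rmsd_means, p)
  }, numeric(1L))
  data.frame(property = names(properties), r = unname(r),
             n = length(rmsd_means), row.names = NULL)
}

#' Signed dihedral angle of four points
#'
#' Standard atan2 construction; result in degrees on (-180, 180].
#'
#' @param p1,p2,p3,p4 3-vectors.
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop("undefined dihedral: three consecutive points are collinear")
  }
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Periodic 2D kernel density over dihedral pairs (Ramachandran density)
#'
#' A Gaussian product-kernel density built over the 3 x 3 periodic tiling
#' of the (phi, psi) samples, evaluated on a grid over \[-180, 180)^2 and
#' normalised to integrate to one over the grid. Bandwidths default to
#' Scott's rule (`sd * n^(-1/6)` per dimension).
#'
#' @param phi,psi dihedral samples in degrees (>= 2 points).
#' @param bandwidth length-2 bandwidths in degrees (default Scott).
#' @param gridsize number of grid cells per axis.
#' @return list with `phi`, `psi` (grid centres), `density` (matrix,
#'   phi x psi), `bandwidth`, and `eval(phi, psi)`, a vectorised closure
#'   evaluating the same normalised density at arbitrary angles.
#' @export
ramachandran_density <- function(phi, psi, bandwidth = NULL, gridsize = 180L) {
  stopifnot(length(phi) == length(psi))
  n <- length(phi)
  if (n < 2L) stop("need at least 2 samples")
  if (is.null(bandwidth)) {
    bandwidth <- c(stats::sd(phi), stats::sd(psi)) * n^(-1 / 6)
    bandwidth[!is.finite(bandwidth) | bandwidth <= 0] <- 10
  }
  # periodic images at +-360 in both angles
  shifts <- as.matrix(expand.grid(s1 = c(-360, 0, 360), s2 = c(-360, 0, 360)))
  px <- rep(phi, times = nrow(shifts)) + rep(shifts[, 1L], each = n)
  py <- rep(psi, times = nrow(shifts)) + rep(shifts[, 2L], each = n)

  raw <- function(qx, qy) {
    vapply(seq_along(qx), function(i) {
      sum(stats::dnorm(qx[i], px, bandwidth[1L]) *
            stats::dnorm(qy[i], py, bandwidth[2L]))
    }, numeric(1L)) / n
  }

  cell <- 360 / gridsize
  centers <- -180 + (seq_len(gridsize) - 0.5) * cell
  gx <- stats::dnorm(outer(centers, px, "-") / bandwidth[1L]) /
    bandwidth[1L] # gridsize x points
  gy <- stats::dnorm(outer(centers, py, "-") / bandwidth[2L]) / bandwidth[2L]
  dens <- (gx %*% t(gy)) / n
  norm_const <- sum(dens) * cell^2
  dens <- dens / norm_const

  list(phi = centers, psi = centers, density = dens, bandwidth = bandwidth,
       eval = function(phi, psi) raw(phi, psi) / norm_const)
}

#' Per-frame RMSD of a trajectory against a reference structure
#'
#' @param frames list of coordinate matrices (one diffusion trajectory),
#'   or a list of such lists (several trajectories).
#' @param reference reference coordinates.
#' @param mol optional graph for heavy-atom selection.
#' @param mode,symmetry passed to [min_rmsd()].
#' @return for one trajectory, a numeric series; for several, a list with
#'   per-trajectory `series` and the elementwise `mean` curve.
#' @export
trajectory_rmsd <- function(frames, reference, mol = NULL, mode = "heavy",
                            symmetry = FALSE) {
  one <- function(tr) {
    vapply(tr, min_rmsd, numeric(1L), b = reference, mol = mol, mode = mode,
           symmetry = symmetry)
  }
  if (is.list(frames[[1L]]) && !is.matrix(frames[[1L]])) {
    series <- lapply(frames, one)
    len <- unique(vapply(series, length, integer(1L)))
    if (length(len) != 1L) stop("trajectories differ in length")
    list(series = series, mean = Reduce(`+`, series) / length(series))
  } else {
    one(frames)
  }
}
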