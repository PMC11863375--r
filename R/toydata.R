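# Deterministic toy-molecule generator. Templates produce exact idealised
# geometries (tetrahedral centres, linear chains, regular rings, torsion
# chains) so every other module can be exercised without external data.

TOY_TEMPLATES <- c("tetrahedral_center", "linear_chain", "ring", "torsion_chain")

#' Generate an idealised toy molecule
#'
#' Templates:
#' * `tetrahedral_center`: a central atom bonded to four terminals at exact
#'   tetrahedral angles (arccos(-1/3)); always 5 atoms.
#' * `linear_chain`: `n_atoms` collinear atoms with consecutive single
#'   bonds.
#' * `ring`: regular planar n-gon (n >= 3) with consecutive bonds, optionally
#'   aromatic.
#' * `torsion_chain`: a chain with tetrahedral bond angles and the requested
#'   dihedral angles (degrees), placed by the standard internal-coordinate
#'   (NeRF) construction; needs `n_atoms >= 4` and `length(torsions) ==
#'   n_atoms - 3`.
#'
#' Elements default to carbon for chain/ring atoms and hydrogens for the
#' terminals of the tetrahedral template; pass `elements` to override (a
#' vector of symbols recycled to the atom count).
#'
#' @param template template name.
#' @param n_atoms atom count (ignored for `tetrahedral_center`).
#' @param r bond length in Angstrom.
#' @param torsions dihedral angles in degrees for `torsion_chain`.
#' @param elements optional element symbols.
#' @param aromatic logical; make ring bonds aromatic.
#' @param name molecule name.
#' @return a [molecule_graph()] with exact coordinates.
#' @export
make_toy <- function(template = TOY_TEMPLATES, n_atoms = 5L, r = 1.5,
                     torsions = NULL, elements = NULL, aromatic = FALSE,
                     name = NULL) {
  template <- match.arg(template)
  out <- switch(template,
    tetrahedral_center = {
      dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
      coords <- rbind(c(0, 0, 0), r * dirs)
      bonds <- data.frame(i = 1L, j = 2:5, order = 1L)
      el <- if (is.null(elements)) c("C", rep("H", 4L)) else elements
      list(coords = coords, bonds = bonds, el = el, n = 5L)
    },
    linear_chain = {
      if (n_atoms < 2L) stop("invalid spec: linear_chain needs >= 2 atoms")
      coords <- cbind((seq_len(n_atoms) - 1L) * r, 0, 0)
      bonds <- data.frame(i = seq_len(n_atoms - 1L), j = 2:n_atoms, order = 1L)
      el <- if (is.null(elements)) "C" else elements
      list(coords = coords, bonds = bonds, el = el, n = n_atoms)
    },
    ring = {
      if (n_atoms < 3L) stop("invalid spec: ring needs >= 3 atoms")
      rad <- r / (2 * sin(pi / n_atoms))
      ang <- 2 * pi * (seq_len(n_atoms) - 1L) / n_atoms
      coords <- cbind(rad * cos(ang), rad * sin(ang), 0)
      bonds <- data.frame(i = seq_len(n_atoms),
                          j = c(2:n_atoms, 1L),
                          order = if (aromatic) 4L else 1L)
      el <- if (is.null(elements)) "C" else elements
      list(coords = coords, bonds = bonds, el = el, n = n_atoms)
    },
    torsion_chain = {
      if (n_atoms < 4L) stop("invalid spec: torsion_chain needs >= 4 atoms")
      if (is.null(torsions)) torsions <- rep(180, n_atoms - 3L)
      if (length(torsions) != n_atoms - 3L) {
        stop("invalid spec: need ", n_atoms - 3L, " torsion angles")
      }
      theta <- acos(-1 / 3) # tetrahedral bond angle
      coords <- matrix(0, n_atoms, 3L)
      coords[2L, ] <- c(r, 0, 0)
      coords[3L, ] <- coords[2L, ] + r * c(-cos(theta), sin(theta), 0)
      for (k in 4:n_atoms) {
        coords[k, ] <- nerf_place(coords[k - 3L, ], coords[k - 2L, ],
                                  coords[k - 1L, ], r, theta,
                                  torsions[k - 3L] * pi / 180)
      }
      bonds <- data.frame(i = seq_len(n_atoms - 1L), j = 2:n_atoms, order = 1L)
      el <- if (is.null(elements)) "C" else elements
      list(coords = coords, bonds = bonds, el = el, n = n_atoms)
    }
  )
  el <- rep_len(out$el, out$n)
  z <- ELEMENT_Z[el]
  if (any(is.na(z))) stop("unknown element symbol in 'elements'")
  molecule_graph(unname(z), out$bonds, out$coords,
                 name = if (is.null(name)) template else name)
}

# place atom D given A, B, C at bond length r, bond angle theta (B-C-D)
# and dihedral phi (A-B-C-D); standard natural-extension construction
nerf_place <- function(a, b, c_, r, theta, phi) {
  bc <- (c_ - b); bc <- bc / sqrt(sum(bc^2))
  ab <- (b - a)
  n <- pracma_cross(ab, bc); n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  # sign of the out-of-plane component chosen so the A-B-C-D dihedral of
  # the placed point follows the standard (IUPAC) sign convention
  d2 <- c(-r * cos(theta), r * sin(theta) * cos(phi),
          -r * sin(theta) * sin(phi))
  c_ + cbind(bc, m, n) %*% d2
}

pracma_cross <- function(u, v) {
  c(u[2L] * v[3L] - u[3L] * v[2L],
    u[3L] * v[1L] - u[1L] * v[3L],
    u[1L] * v[2L] - u[2L] * v[1L])
}

#' A conformer ensemble: coordinate frames sharing one molecular graph
#'
#' @param id molecule identifier.
#' @param frames list of n x 3 coordinate matrices.
#' @param role `"generated"` or `"reference"`.
#' @return an object of class `conformer_set`.
#' @export
conformer_set <- function(id, frames, role = c("generated", "reference")) {
  role <- match.arg(role)
  if (length(frames) < 1L) stop("conformer set needs at least one frame")
  nats <- vapply(frames, nrow, integer(1L))
  if (length(unique(nats)) != 1L) stop("frames differ in atom count")
  structure(list(id = id, frames = lapply(frames, function(x) {
    x <- as.matrix(x); dimnames(x) <- NULL; x
  }), role = role), class = "conformer_set")
}

#' @export
print.conformer_set <- function(x, ...) {
  cat(sprintf("<conformer_set '%s': %d frames x %d atoms (%s)>\n",
              x$id, length(x$frames), nrow(x$frames[[1L]]), x$role))
  invisible(x)
}

#' Reference ensemble: jittered copies of a toy geometry
#'
#' @param mol a [molecule_graph()] with coordinates.
#' @param n_frames number of frames (>= 1).
#' @param jitter_sd per-coordinate Gaussian jitter standard deviation
#'   (Angstrom); 0 gives identical frames.
#' @param seed RNG seed.
#' @return a `conformer_set` with role `"reference"`.
#' @export
make_reference_ensemble <- function(mol, n_frames, jitter_sd = 0, seed = 1L) {
  if (n_frames < 1L) stop("n_frames must be >= 1")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (is.null(mol$coords)) stop("molecule has no coordinates")
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(k) {
    mol$coords + matrix(stats::rnorm(3L * n_atoms(mol), sd = jitter_sd),
                        n_atoms(mol), 3L)
  })
  conformer_set(mol$name, frames, role = "reference")
}
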