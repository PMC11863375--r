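# Molecular graph data model, edge construction/typing, and file I/O.
#
# A molecule is a typed graph: atoms carry atomic numbers Z, undirected
# covalent bonds carry an order (single/double/triple/aromatic), and 3D
# coordinates (Angstrom) are optional. Edge sets used by the encoders are
# *directed* and typed with a fixed vocabulary:
#   0 single, 1 double, 2 triple, 3 aromatic, 4 two-hop, 5 three-hop,
#   6 spatial (within-cutoff, non-bonded).

BOND_ORDERS <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)
EDGE_TYPE_CODES <- c(single = 0L, double = 1L, triple = 2L, aromatic = 3L,
                     hop2 = 4L, hop3 = 5L, spatial = 6L)
N_EDGE_TYPES <- 7L

ELEMENT_Z <- c(H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Si = 14L,
               P = 15L, S = 16L, Cl = 17L, Br = 35L, I = 53L)

element_symbol <- function(z) {
  sym <- names(ELEMENT_Z)[match(z, ELEMENT_Z)]
  sym[is.na(sym)] <- paste0("X", z[is.na(sym)])
  sym
}

#' Construct a molecular graph
#'
#' @param atom_numbers integer atomic numbers, one per atom.
#' @param bonds data frame (or matrix) with columns `i`, `j` (1-based atom
#'   indices) and `order` (one of `"single"`, `"double"`, `"triple"`,
#'   `"aromatic"`, or the integer codes 1-4). Each undirected bond appears
#'   once.
#' @param coords optional n x 3 matrix of positions in Angstrom.
#' @param name free-text identifier.
#' @return an object of class `molecule_graph`.
#' @export
molecule_graph <- function(atom_numbers, bonds = NULL, coords = NULL,
                           name = "mol") {
  atom_numbers <- as.integer(atom_numbers)
  n <- length(atom_numbers)
  if (n < 1L) stop("molecule must have at least one atom")
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  } else {
    bonds <- as.data.frame(bonds)
    names(bonds)[1:3] <- c("i", "j", "order")
    if (is.character(bonds$order)) {
      bonds$order <- BOND_ORDERS[bonds$order]
    }
    bonds$i <- as.integer(bonds$i)
    bonds$j <- as.integer(bonds$j)
    bonds$order <- as.integer(bonds$order)
    if (any(is.na(bonds$order)) || any(bonds$order < 1L | bonds$order > 4L)) {
      stop("invalid bond order; use single/double/triple/aromatic or 1-4")
    }
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n)) {
      stop("invalid graph: bond index out of range")
    }
    if (any(bonds$i == bonds$j)) stop("invalid graph: self-bond")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("invalid graph: duplicate bond")
  }
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 3L) {
      stop("coords must be an n x 3 matrix")
    }
    if (!all(is.finite(coords))) stop("coords contain non-finite values")
    dimnames(coords) <- NULL
  }
  structure(list(atom_numbers = atom_numbers, bonds = bonds,
                 coords = coords, name = name),
            class = "molecule_graph")
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("<molecule_graph '%s': %d atoms, %d bonds, coords: %s>\n",
              x$name, length(x$atom_numbers), nrow(x$bonds),
              if (is.null(x$coords)) "none" else "present"))
  invisible(x)
}

n_atoms <- function(mol) length(mol$atom_numbers)

edge_set <- function(pairs, types, is_local, lengths = NULL) {
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  structure(list(pairs = pairs, types = as.integer(types),
                 is_local = as.logical(is_local), lengths = lengths),
            class = "edge_set")
}

#' @export
print.edge_set <- function(x, ...) {
  cat(sprintf("<edge_set: %d directed edges (%d local, %d spatial)>\n",
              nrow(x$pairs), sum(x$is_local), sum(!x$is_local)))
  invisible(x)
}

n_edges <- function(es) nrow(es$pairs)

# both directions of each undirected pair, with duplicated attributes
symmetrize_edges <- function(i, j, types, is_local) {
  edge_set(cbind(c(i, j), c(j, i)), rep(types, 2L), rep(is_local, 2L))
}

edge_set_rbind <- function(a, b) {
  lengths <- if (!is.null(a$lengths) && !is.null(b$lengths)) {
    c(a$lengths, b$lengths)
  } else NULL
  edge_set(rbind(a$pairs, b$pairs), c(a$types, b$types),
           c(a$is_local, b$is_local), lengths)
}

#' Local (graph-derived) edges: covalent bonds plus 2-hop and 3-hop pairs
#'
#' Covalent edges keep a type per bond order; atom pairs at covalent-graph
#' shortest-path distance 2 or 3 receive their own edge types. A pair
#' reachable at several hop counts is typed by the smallest, and covalent
#' bonds are never re-typed as hop edges. Hop distances are computed on the
#' covalent graph only.
#'
#' @param mol a [molecule_graph()].
#' @return an `edge_set` with both directions of every edge, all flagged
#'   local.
#' @export
build_local_edges <- function(mol) {
  stopifnot(inherits(mol, "molecule_graph"))
  n <- n_atoms(mol)
  b <- mol$bonds
  if (nrow(b) == 0L) {
    return(edge_set(matrix(integer(0), 0L, 2L), integer(0), logical(0)))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(b$i, b$j))
  d <- igraph::distances(g)
  bond_types <- b$order - 1L # codes 0..3 align with order 1..4
  ut <- which(upper.tri(d) & (d == 2 | d == 3), arr.ind = TRUE)
  hop_i <- ut[, 1L]
  hop_j <- ut[, 2L]
  hop_types <- ifelse(d[ut] == 2, EDGE_TYPE_CODES[["hop2"]],
                      EDGE_TYPE_CODES[["hop3"]])
  symmetrize_edges(c(b$i, hop_i), c(b$j, hop_j),
                   c(bond_types, hop_types),
                   rep(TRUE, nrow(b) + length(hop_i)))
}

#' Spatial edges: all atom pairs within a distance cutoff
#'
#' Pairs already present in `exclude` (typically the local edge set) are
#' skipped. The cutoff comparison is inclusive (`<=`).
#'
#' @param coords n x 3 positions (Angstrom).
#' @param cutoff distance cutoff in Angstrom (default 10).
#' @param exclude optional `edge_set` whose pairs must not be duplicated.
#' @return an `edge_set` of spatial edges (type code 6), non-local, with
#'   lengths populated.
#' @export
build_spatial_edges <- function(coords, cutoff = 10, exclude = NULL) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("invalid input: non-finite coordinates")
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- nrow(coords)
  dm <- as.matrix(stats::dist(coords))
  sel <- which(upper.tri(dm) & dm <= cutoff, arr.ind = TRUE)
  if (!is.null(exclude) && n_edges(exclude) > 0L && nrow(sel) > 0L) {
    excl_key <- paste(pmin(exclude$pairs[, 1L], exclude$pairs[, 2L]),
                      pmax(exclude$pairs[, 1L], exclude$pairs[, 2L]))
    keep <- !(paste(sel[, 1L], sel[, 2L]) %in% excl_key)
    sel <- sel[keep, , drop = FALSE]
  }
  es <- symmetrize_edges(sel[, 1L], sel[, 2L],
                         rep(EDGE_TYPE_CODES[["spatial"]], nrow(sel)),
                         rep(FALSE, nrow(sel)))
  es$lengths <- rep(dm[sel], 2L)
  es
}

#' Populate Euclidean edge lengths from coordinates
#'
#' @param coords n x 3 positions.
#' @param edges an `edge_set`.
#' @return the `edge_set` with `lengths` filled in.
#' @export
edge_lengths <- function(coords, edges) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords))) stop("invalid input: non-finite coordinates")
  if (n_edges(edges) == 0L) {
    edges$lengths <- numeric(0)
    return(edges)
  }
  d <- coords[edges$pairs[, 1L], , drop = FALSE] -
    coords[edges$pairs[, 2L], , drop = FALSE]
  edges$lengths <- sqrt(rowSums(d^2))
  edges
}

# combined edge set used by the global encoder; spatial edges are rebuilt
# from the current coordinates at every call
build_all_edges <- function(mol, coords, cutoff = 10) {
  local <- edge_lengths(coords, build_local_edges(mol))
  spatial <- build_spatial_edges(coords, cutoff, exclude = local)
  edge_set_rbind(local, spatial)
}

## ---- file I/O ---------------------------------------------------------------

#' Read molecules from SDF, SMILES or XYZ files
#'
#' SDF (V2000, possibly multi-record) and SMILES parsing are delegated to
#' ChemmineR/ChemmineOB; SMILES yields topology-only graphs (no
#' coordinates). XYZ records carry coordinates but no bonds.
#'
#' @param path input file.
#' @param format one of `"sdf"`, `"smiles"`, `"xyz"`.
#' @return a list of [molecule_graph()] objects (empty file gives an empty
#'   list).
#' @export
read_molecules <- function(path, format = c("sdf", "smiles", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) return(list())
  switch(format,
    sdf = read_sdf_file(path),
    smiles = read_smiles_file(path),
    xyz = read_xyz_file(path)
  )
}

sdfset_to_graphs <- function(sdfset, topology_only = FALSE) {
  lapply(seq_along(sdfset), function(k) {
    sdf <- sdfset[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    sym <- sub("_.*$", "", rownames(ab))
    z <- ELEMENT_Z[sym]
    if (any(is.na(z))) {
      stop("format error in record ", k, ": unknown element ",
           paste(unique(sym[is.na(z)]), collapse = ","))
    }
    bonds <- if (NROW(bb) > 0L) {
      data.frame(i = as.integer(bb[, 1L]), j = as.integer(bb[, 2L]),
                 order = as.integer(bb[, 3L]))
    } else NULL
    coords <- if (!topology_only) unname(ab[, 1:3, drop = FALSE]) else NULL
    nm <- ChemmineR::sdfid(sdf)
    molecule_graph(unname(z), bonds, coords,
                   name = if (length(nm) && nzchar(nm)) nm else paste0("mol", k))
  })
}

read_sdf_file <- function(path) {
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path, skipErrors = FALSE)),
    error = function(e) stop("format error reading SDF '", path, "': ",
                             conditionMessage(e))
  )
  sdfset_to_graphs(sdfset)
}

read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(list())
  smi <- vapply(strsplit(trimws(lines), "\\s+"), `[`, character(1L), 1L)
  nms <- vapply(strsplit(trimws(lines), "\\s+"), function(x) {
    if (length(x) > 1L) paste(x[-1L], collapse = " ") else x[1L]
  }, character(1L))
  out <- vector("list", length(smi))
  for (k in seq_along(smi)) {
    sdfset <- tryCatch(ChemmineR::smiles2sdf(smi[k]), error = function(e) {
      stop("format error in SMILES record ", k, " ('", smi[k], "'): ",
           conditionMessage(e))
    })
    g <- sdfset_to_graphs(sdfset, topology_only = TRUE)[[1L]]
    g$name <- nms[k]
    out[[k]] <- g
  }
  out
}

read_xyz_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  pos <- 1L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || pos + 1L + n > length(lines)) {
      stop("format error in XYZ record starting at line ", pos)
    }
    comment <- trimws(lines[pos + 1L])
    rows <- strsplit(trimws(lines[pos + 2L:(n + 1L)]), "\\s+")
    sym <- vapply(rows, `[`, character(1L), 1L)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3L)))
    z <- ELEMENT_Z[sym]
    if (any(is.na(z))) stop("format error: unknown element in XYZ record")
    out[[length(out) + 1L]] <- molecule_graph(
      unname(z), NULL, xyz,
      name = if (nzchar(comment)) comment else paste0("mol", length(out) + 1L))
    pos <- pos + 2L + n
  }
  out
}

#' Write conformer ensembles as a multi-record V2000 SDF
#'
#' @param path output file.
#' @param mols a [molecule_graph()] or list of them; each must carry
#'   coordinates, or be paired with `frames`.
#' @param frames optional list of coordinate matrices (one record each) to
#'   write for a single molecule's graph.
#' @return the path, invisibly.
#' @export
write_conformers <- function(path, mols, frames = NULL) {
  if (inherits(mols, "molecule_graph")) {
    mols <- if (is.null(frames)) list(mols) else {
      lapply(frames, function(x) { m <- mols; m$coords <- x; m })
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    if (is.null(mol$coords)) stop("cannot write SDF without coordinates")
    writeLines(format_sdf_record(mol), con)
  }
  invisible(path)
}

format_sdf_record <- function(mol) {
  n <- n_atoms(mol)
  nb <- nrow(mol$bonds)
  sym <- element_symbol(mol$atom_numbers)
  header <- c(mol$name, "  confdiff", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   mol$coords[, 1L], mol$coords[, 2L], mol$coords[, 3L], sym)
  bonds <- if (nb > 0L) {
    sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$i, mol$bonds$j, mol$bonds$order)
  } else character(0)
  c(header, atoms, bonds, "M  END", "$$$$")
}

#' Write coordinates as (multi-frame) XYZ
#'
#' @param path output file.
#' @param mol a [molecule_graph()] supplying elements.
#' @param frames list of n x 3 coordinate matrices; defaults to the
#'   molecule's own coordinates.
#' @param comments per-frame comment lines.
#' @return the path, invisibly.
#' @export
write_xyz <- function(path, mol, frames = NULL, comments = NULL) {
  if (is.null(frames)) frames <- list(mol$coords)
  sym <- element_symbol(mol$atom_numbers)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    x <- frames[[k]]
    writeLines(c(
      as.character(nrow(x)),
      if (is.null(comments)) paste0("frame ", k) else comments[[k]],
      sprintf("%-3s %14.8f %14.8f %14.8f", sym, x[, 1L], x[, 2L], x[, 3L])
    ), con)
  }
  invisible(path)
}
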