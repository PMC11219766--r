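# Lightweight molecule model used for ligands and fragments.
# Atoms are rows of a coordinate matrix; bonds an integer matrix (i, j, order).
# Hydrogens are implicit throughout: X-ray inputs rarely resolve them and all
# distance rules operate on heavy atoms.

#' Construct a molecule
#'
#' The package's uniform container for ligands and ligand fragments: heavy
#' atoms with 3D coordinates, a connection table with bond orders, and formal
#' charges. Hydrogens are implicit (derived from standard valences).
#'
#' @param element character vector of element symbols (heavy atoms only).
#' @param xyz numeric matrix with one row per atom and columns x, y, z (Angstrom).
#' @param bonds integer matrix with columns `i`, `j`, `order` (1, 2, 3, or 4 for
#'   aromatic as in SDF V2000); zero-row matrix for a single atom.
#' @param name molecule identifier (e.g. HET code).
#' @param charge integer vector of formal charges, one per atom (default 0).
#' @return An object of class `fbmol`.
#' @export
fbmol <- function(element, xyz, bonds = matrix(integer(0), 0, 3), name = "MOL",
                  charge = integer(length(element))) {
  xyz <- as.matrix(xyz)
  if (length(element) == 0L) stop("molecule must have at least one atom")
  if (nrow(xyz) != length(element) || ncol(xyz) != 3L)
    stop("xyz must be a length(element) x 3 matrix")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- NULL
  bonds <- matrix(as.integer(bonds), ncol = 3,
                  dimnames = list(NULL, c("i", "j", "order")))
  if (nrow(bonds) > 0 &&
      (any(bonds[, 1:2] < 1L) || any(bonds[, 1:2] > length(element))))
    stop("bond indices out of range")
  structure(
    list(name = name, element = as.character(element), xyz = xyz,
         bonds = bonds, charge = as.integer(charge)),
    class = "fbmol")
}

#' @export
print.fbmol <- function(x, ...) {
  cat(sprintf("<fbmol %s: %d heavy atoms, %d bonds, MW %.1f Da>\n",
              x$name, length(x$element), nrow(x$bonds), mol_weight(x)))
  invisible(x)
}

#' @export
n_atoms <- function(mol) length(mol$element)

# IUPAC 2021 standard atomic weights (abridged), plus H for implicit capping.
.ATOMIC_MASS <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Se = 78.971, Br = 79.904,
  I = 126.904, Na = 22.990, K = 39.098, Mg = 24.305, Ca = 40.078,
  Zn = 65.38, Fe = 55.845, Mn = 54.938, Cu = 63.546, Ni = 58.693, Co = 58.933
)

# Default valences used to infer implicit hydrogen counts on heavy atoms.
.DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, B = 3,
                      F = 1, Cl = 1, Br = 1, I = 1, Se = 2, Si = 4)

#' Per-atom heavy-bond order sums
#' @keywords internal
bond_order_sums <- function(mol) {
  s <- numeric(n_atoms(mol))
  if (nrow(mol$bonds) > 0) {
    ord <- ifelse(mol$bonds[, "order"] == 4L, 1.5, mol$bonds[, "order"])
    for (k in seq_len(nrow(mol$bonds))) {
      s[mol$bonds[k, "i"]] <- s[mol$bonds[k, "i"]] + ord[k]
      s[mol$bonds[k, "j"]] <- s[mol$bonds[k, "j"]] + ord[k]
    }
  }
  s
}

#' Implicit hydrogen count per atom
#'
#' Standard valence minus the sum of heavy-atom bond orders (aromatic bonds
#' count 1.5, rounded down over the atom), adjusted by formal charge; floored
#' at zero. Elements without a tabulated valence get zero implicit hydrogens.
#' @param mol an `fbmol`.
#' @return integer vector, one per atom.
#' @export
implicit_h <- function(mol) {
  val <- .DEFAULT_VALENCE[mol$element]
  val[is.na(val)] <- 0
  # positive charge on N adds a bonding slot; negative charge on O/S removes one
  val <- val + ifelse(mol$element == "N", pmax(mol$charge, 0), 0) + pmin(mol$charge, 0)
  h <- floor(val - bond_order_sums(mol) + 1e-9)
  as.integer(pmax(h, 0))
}

#' Molecular weight with open valences hydrogen-capped
#'
#' Heavy-atom masses plus one hydrogen mass per implicit hydrogen. This is the
#' weight used by the 50-300 Da fragment retention window.
#' @param mol an `fbmol`.
#' @return weight in Da.
#' @export
mol_weight <- function(mol) {
  m <- .ATOMIC_MASS[mol$element]
  if (anyNA(m)) stop("unknown element: ",
                     paste(unique(mol$element[is.na(m)]), collapse = ", "))
  sum(m) + .ATOMIC_MASS[["H"]] * sum(implicit_h(mol))
}

#' Adjacency list of a molecule
#' @keywords internal
adjacency <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  if (nrow(mol$bonds) > 0) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[k, "i"]; j <- mol$bonds[k, "j"]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

.mol_graph <- function(mol) {
  igraph::graph_from_edgelist(
    matrix(mol$bonds[, 1:2], ncol = 2), directed = FALSE) |>
    (\(g) if (igraph::vcount(g) < n_atoms(mol))
      igraph::add_vertices(g, n_atoms(mol) - igraph::vcount(g)) else g)()
}

#' Ring-bond membership
#'
#' A bond is a ring bond iff it is not a bridge of the molecular graph.
#' @param mol an `fbmol`.
#' @return logical vector over rows of `mol$bonds`.
#' @export
ring_bonds <- function(mol) {
  if (nrow(mol$bonds) == 0) return(logical(0))
  g <- .mol_graph(mol)
  br <- igraph::bridges(g)
  res <- rep(TRUE, nrow(mol$bonds))
  res[as.integer(br)] <- FALSE
  res
}

#' Ring-atom membership (atoms on at least one ring bond)
#' @param mol an `fbmol`.
#' @return logical vector over atoms.
#' @export
ring_atoms <- function(mol) {
  inring <- logical(n_atoms(mol))
  rb <- ring_bonds(mol)
  if (any(rb)) {
    idx <- mol$bonds[rb, 1:2, drop = FALSE]
    inring[unique(as.integer(idx))] <- TRUE
  }
  inring
}

#' Smallest rings of a molecule
#'
#' For every ring bond (i, j), the smallest cycle through it is that bond plus
#' the shortest i-j path in the graph with the bond removed. Duplicate rings
#' are merged. Covers the fused/spiro systems found in drug-like fragments.
#' @param mol an `fbmol`.
#' @return list of integer vectors, each one ring (sorted atom indices).
#' @export
mol_rings <- function(mol) {
  rb <- ring_bonds(mol)
  if (!any(rb)) return(list())
  g <- .mol_graph(mol)
  rings <- list()
  for (k in which(rb)) {
    i <- mol$bonds[k, 1]; j <- mol$bonds[k, 2]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    sp <- suppressWarnings(
      igraph::shortest_paths(g2, from = i, to = j, output = "vpath"))
    path <- as.integer(sp$vpath[[1]])
    if (length(path) < 3) next
    rings[[length(rings) + 1L]] <- sort(path)
  }
  unique(rings)
}

#' Aromatic-atom perception
#'
#' Simplified, deterministic perception adequate for drug-like fragments:
#' a ring is aromatic if (a) all its ring bonds have SDF order 4, or (b) it is
#' six-membered with three ring double bonds, or (c) five-membered with two
#' ring double bonds and at least one heteroatom. Atoms of aromatic rings are
#' aromatic.
#' @param mol an `fbmol`.
#' @return logical vector over atoms.
#' @export
aromatic_atoms <- function(mol) {
  ar <- logical(n_atoms(mol))
  rings <- mol_rings(mol)
  if (length(rings) == 0) return(ar)
  bkey <- paste(pmin(mol$bonds[, 1], mol$bonds[, 2]),
                pmax(mol$bonds[, 1], mol$bonds[, 2]))
  for (ring in rings) {
    n <- length(ring)
    if (n < 5 || n > 6) next
    inring <- mol$bonds[, 1] %in% ring & mol$bonds[, 2] %in% ring
    ords <- mol$bonds[inring, "order"]
    n_dbl <- sum(ords == 2L)
    all4 <- length(ords) > 0 && all(ords == 4L)
    het <- any(mol$element[ring] != "C")
    if (all4 || (n == 6 && n_dbl >= 3) || (n == 5 && n_dbl >= 2 && het))
      ar[ring] <- TRUE
  }
  ar
}

#' Extract a sub-molecule by atom indices
#'
#' Keeps coordinates and charges; bonds restricted to the kept set; records
#' attachment points (kept atoms that lost a neighbour).
#' @param mol an `fbmol`.
#' @param idx integer atom indices to keep.
#' @return `fbmol` with attributes `attachment_points` (indices into the new
#'   atom order) and `parent_atoms` (original indices).
#' @export
sub_molecule <- function(mol, idx) {
  idx <- sort(unique(as.integer(idx)))
  map <- integer(n_atoms(mol)); map[idx] <- seq_along(idx)
  keep <- mol$bonds[, 1] %in% idx & mol$bonds[, 2] %in% idx
  cut <- xor(mol$bonds[, 1] %in% idx, mol$bonds[, 2] %in% idx)
  b <- mol$bonds[keep, , drop = FALSE]
  if (nrow(b) > 0) { b[, 1] <- map[b[, 1]]; b[, 2] <- map[b[, 2]] }
  att <- integer(0)
  if (any(cut)) {
    ends <- mol$bonds[cut, 1:2, drop = FALSE]
    att <- sort(unique(map[ends[ends %in% idx]]))
  }
  out <- fbmol(mol$element[idx], mol$xyz[idx, , drop = FALSE], b,
               name = mol$name, charge = mol$charge[idx])
  attr(out, "attachment_points") <- att
  attr(out, "parent_atoms") <- idx
  out
}

#' Apply a rigid transform to molecule coordinates
#' @param mol an `fbmol`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector.
#' @return transformed `fbmol`.
#' @export
transform_mol <- function(mol, rotation, translation = c(0, 0, 0)) {
  mol$xyz <- sweep(mol$xyz %*% t(rotation), 2, -translation)
  mol
}

# pairwise distances between two coordinate matrices (rows = points)
cross_dist <- function(a, b) {
  a <- matrix(a, ncol = 3); b <- matrix(b, ncol = 3)
  sq <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(sq, 0))
}
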