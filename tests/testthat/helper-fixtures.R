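# Shared fixture builders and independent oracles. Everything is generated
# in code; no files ship with the tests.

hexagon_xyz <- function(r = 1.39) {
  a <- (0:5) * pi / 3
  cbind(r * cos(a), r * sin(a), 0)
}

benzene_mol <- function() {
  fbmol(rep("C", 6), hexagon_xyz(), cbind(1:6, c(2:6, 1), rep(c(2L, 1L), 3)),
        name = "BNZ")
}

# linear tetrapeptide-like ligand: four N-CA-C(=O) units, graph chemistry
# only (coordinates on a line are irrelevant to the filter rules)
tetrapeptide_mol <- function() {
  el <- character(0); bonds <- NULL
  for (u in 0:3) {
    b <- u * 4L
    el <- c(el, "N", "C", "C", "O")          # N, CA, C, O
    bonds <- rbind(bonds,
                   c(b + 1L, b + 2L, 1L),    # N-CA
                   c(b + 2L, b + 3L, 1L),    # CA-C
                   c(b + 3L, b + 4L, 2L))    # C=O
    if (u > 0) bonds <- rbind(bonds, c(b - 1L, b + 1L, 1L))  # C-N amide link
  }
  xyz <- cbind(seq_along(el) * 1.4, (seq_along(el) %% 2) * 0.8, 0)
  fbmol(el, xyz, bonds, name = "PEP4")
}

# trimethyl-phosphate-like ligand: exercises the phosphorus rule
phosphate_mol <- function() {
  el <- c("P", "O", "O", "O", "O", "C", "C", "C")
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(-0.5, 1.4, 0), c(-0.5, -0.7, 1.2),
               c(-0.5, -0.7, -1.2), c(-1.9, 2.0, 0), c(0.5, -1.6, 2.0),
               c(0.5, -1.6, -2.0))
  bonds <- rbind(c(1L, 2L, 2L), c(1L, 3L, 1L), c(1L, 4L, 1L), c(1L, 5L, 1L),
                 c(3L, 6L, 1L), c(4L, 7L, 1L), c(5L, 8L, 1L))
  fbmol(el, xyz, bonds, name = "TMP")
}

# fixed-width PDB writer for tiny synthetic entries
pdb_atom_line <- function(type, serial, name, resn, chain, resno, xyz,
                          element, occ = 1.00, alt = "") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, if (nchar(name) < 4) paste0(" ", name) else name,
          alt, resn, chain, resno, xyz[1], xyz[2], xyz[3], occ, 0.0, element)
}

# three residues around a benzene HETATM, plus a water
write_toy_pdb <- function(path, with_water = TRUE, waters_only = FALSE) {
  lines <- character(0); serial <- 0L
  res <- list(list("ALA", c(0, 6, 0)), list("GLY", c(5.2, -3, 0)),
              list("SER", c(-5.2, -3, 0)))
  for (i in seq_along(res)) {
    ca <- res[[i]][[2]]
    for (at in list(c("N", -1.46, 0, 0), c("CA", 0, 0, 0),
                    c("C", 0.55, 1.40, 0), c("O", 1.78, 1.55, 0))) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line("ATOM", serial, at[1], res[[i]][[1]],
                                      "A", i, ca + as.numeric(at[2:4]),
                                      substr(at[1], 1, 1)))
    }
  }
  if (!waters_only) {
    hx <- hexagon_xyz()
    for (k in 1:6) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line("HETATM", serial, paste0("C", k), "BNZ",
                                      "B", 90, hx[k, ], "C"))
    }
  }
  if (with_water || waters_only) {
    serial <- serial + 1L
    lines <- c(lines, pdb_atom_line("HETATM", serial, "O", "HOH", "B", 95,
                                    c(8, 8, 8), "O"))
  }
  writeLines(c(lines, "END"), path)
  path
}

# independent double-loop implementation of the interaction fingerprint
oracle_fingerprint <- function(fr) {
  lt <- type_atoms_ligand(fr$fragment)
  pt <- type_atoms_protein(fr$environment)
  f <- numeric(29 * 13)
  for (i in seq_along(lt)) {
    for (j in seq_along(pt$types)) {
      d <- sqrt(sum((fr$fragment$xyz[i, ] - pt$xyz[j, ])^2))
      w <- if (d <= 10) exp(-(d - 3)^2) else 0
      for (m in lt[[i]]) for (n in pt$types[[j]])
        f[(m - 1) * 13 + n] <- f[(m - 1) * 13 + n] + w
    }
  }
  f
}

# grid + refine oracle for the 3-point superposition residual
oracle_superpose_rmsd <- function(P, Q) {
  P0 <- sweep(P, 2, colMeans(P)); Q0 <- sweep(Q, 2, colMeans(Q))
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3) %*%
      matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3) %*%
      matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  }
  obj <- function(ang) sqrt(mean(rowSums((P0 %*% t(rot(ang)) - Q0)^2)))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a in grid) for (b in grid) for (cc in grid) {
    v <- obj(c(a, b, cc))
    if (v < best) { best <- v; best_ang <- c(a, b, cc) }
  }
  stats::optim(best_ang, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
}

# brute-force all-pairs triplet matching: two triplets match iff their
# 6-permutation fingerprint families intersect
oracle_match <- function(target_triplets, db_triplets_by_frase) {
  fam <- function(tt) triplet_key(tt)$fps
  hits <- 0L
  for (tt in target_triplets) {
    ft <- tryCatch(fam(tt), error = function(e) NULL)
    if (is.null(ft)) next
    for (fid in names(db_triplets_by_frase)) {
      for (dt in db_triplets_by_frase[[fid]]) {
        fd <- tryCatch(fam(dt), error = function(e) NULL)
        if (!is.null(fd) && length(intersect(ft, fd)) > 0) hits <- hits + 1L
      }
    }
  }
  hits
}

# connectivity check without igraph: is the bond graph minus one edge still
# connected between that edge's endpoints? (independent ring-bond oracle)
oracle_is_ring_bond <- function(mol, k) {
  from <- mol$bonds[k, 1]; to <- mol$bonds[k, 2]
  edges <- mol$bonds[-k, 1:2, drop = FALSE]
  seen <- from; frontier <- from
  while (length(frontier) > 0) {
    nxt <- unique(c(edges[edges[, 1] %in% frontier, 2],
                    edges[edges[, 2] %in% frontier, 1]))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  to %in% seen
}
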