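# Nativeness scoring: 29 ligand x 13 protein atom-type vocabularies, the
# 377-dimensional distance-weighted interaction fingerprint, decoy
# generation by fragment swapping, and the neural classifier on top.

#' Ligand atom-type vocabulary (29 types, fixed order)
#' @return character vector of length 29.
#' @export
ligand_type_vocab <- function() c(
  "Aromatic", "Hetero", "Halogen", "Negative Ionizable", "Positive Ionizable",
  "H-bond Donor", "H-bond Acceptor", "Amide Nitrogen", "Amine Nitrogen",
  "Vinyl", "Carboxylate Oxygen", "Alcohol Oxygen", "Nitro Oxygen",
  "Nitro Nitrogen", "Phosphate Oxygen", "Sulfone Sulfur", "Sulfoxide Sulfur",
  "Enol Oxygen", "Imine Nitrogen", "Enamine Nitrogen", "Aromatic Nitrogen",
  "Aromatic Oxygen", "Aromatic Sulfur", "Aromatic Carbon", "Aliphatic Carbon",
  "F", "Cl", "Br", "I")

#' Protein atom-type vocabulary (13 types, fixed order)
#' @return character vector of length 13.
#' @export
protein_type_vocab <- function() c(
  "Aromatic", "Negative Ionizable", "Positive Ionizable", "H-bond Donor",
  "H-bond Acceptor", "Amide Nitrogen", "Amine Nitrogen", "Carboxylate Oxygen",
  "Alcohol Oxygen", "Imine Nitrogen", "Aromatic Nitrogen", "Aromatic Carbon",
  "Aliphatic Carbon")

#' Type the atoms of a ligand fragment
#'
#' Many-hot assignment over the 29-type ligand vocabulary, perceived from the
#' molecular graph (elements, bond orders, rings, implicit hydrogens). An
#' atom may carry several types ("Aromatic" and "Aromatic Carbon" overlap by
#' construction); atoms matching no rule get an empty set. The perception
#' rules are deterministic and documented in the methods vignette.
#'
#' @param mol an [fbmol].
#' @return list of integer vectors (indices into [ligand_type_vocab]), one
#'   per atom.
#' @export
type_atoms_ligand <- function(mol) {
  V <- ligand_type_vocab()
  ti <- function(nm) match(nm, V)
  n <- n_atoms(mol)
  el <- mol$element
  ar <- aromatic_atoms(mol)
  h <- implicit_h(mol)
  adj <- adjacency(mol)
  b <- mol$bonds
  ord_to <- function(i, j) {
    hit <- (b[, 1] == i & b[, 2] == j) | (b[, 1] == j & b[, 2] == i)
    if (any(hit)) b[which(hit)[1], "order"] else 0L
  }
  carbonyl_c <- .carbonyl_carbons(mol)
  # vinyl carbons: non-aromatic C=C
  vinyl <- logical(n)
  if (nrow(b) > 0) {
    cc2 <- b[b[, "order"] == 2L, , drop = FALSE]
    for (k in seq_len(nrow(cc2))) {
      i <- cc2[k, 1]; j <- cc2[k, 2]
      if (el[i] == "C" && el[j] == "C" && !ar[i] && !ar[j])
        vinyl[c(i, j)] <- TRUE
    }
  }
  # nitro groups: N with >=2 O neighbours, one double-bonded
  nitro_n <- logical(n); nitro_o <- logical(n)
  for (i in which(el == "N")) {
    os <- adj[[i]][el[adj[[i]]] == "O"]
    if (length(os) >= 2 && any(vapply(os, function(o) ord_to(i, o) == 2L,
                                      logical(1)))) {
      nitro_n[i] <- TRUE; nitro_o[os] <- TRUE
    }
  }
  # carboxylate / carboxylic acid oxygens: C bonded to two O, >=1 double
  carbox_o <- logical(n)
  for (i in which(el == "C")) {
    os <- adj[[i]][el[adj[[i]]] == "O"]
    if (length(os) >= 2 && any(vapply(os, function(o) ord_to(i, o) == 2L,
                                      logical(1))))
      carbox_o[os] <- TRUE
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    t <- integer(0)
    e <- el[i]
    nb <- adj[[i]]
    if (ar[i]) t <- c(t, ti("Aromatic"))
    if (!e %in% c("C", "H")) t <- c(t, ti("Hetero"))
    if (e %in% c("F", "Cl", "Br", "I")) t <- c(t, ti("Halogen"), ti(e))
    if (e == "C") {
      t <- c(t, ti(if (ar[i]) "Aromatic Carbon" else "Aliphatic Carbon"))
      if (vinyl[i]) t <- c(t, ti("Vinyl"))
    }
    if (e == "O") {
      t <- c(t, ti("H-bond Acceptor"))
      if (h[i] > 0) t <- c(t, ti("H-bond Donor"))
      if (ar[i]) t <- c(t, ti("Aromatic Oxygen"))
      if (nitro_o[i]) t <- c(t, ti("Nitro Oxygen"))
      if (carbox_o[i]) t <- c(t, ti("Carboxylate Oxygen"),
                              ti("Negative Ionizable"))
      if (any(el[nb] == "P")) t <- c(t, ti("Phosphate Oxygen"),
                                     ti("Negative Ionizable"))
      if (!carbox_o[i] && !nitro_o[i] && h[i] > 0 && length(nb) == 1 &&
          el[nb] == "C" && !nb %in% carbonyl_c) {
        if (vinyl[nb]) t <- c(t, ti("Enol Oxygen"))
        else if (!ar[nb]) t <- c(t, ti("Alcohol Oxygen"))
      }
    }
    if (e == "N") {
      if (ar[i]) {
        t <- c(t, ti("Aromatic Nitrogen"))
        if (h[i] > 0) t <- c(t, ti("H-bond Donor")) else t <- c(t, ti("H-bond Acceptor"))
      } else {
        if (h[i] > 0) t <- c(t, ti("H-bond Donor"))
        if (nitro_n[i]) t <- c(t, ti("Nitro Nitrogen"))
        amide <- any(nb %in% carbonyl_c)
        dbl_c <- any(el[nb] == "C" & vapply(nb, function(x)
          ord_to(i, x) == 2L, logical(1)))
        if (amide && !nitro_n[i]) t <- c(t, ti("Amide Nitrogen"))
        if (dbl_c) t <- c(t, ti("Imine Nitrogen"), ti("H-bond Acceptor"))
        sp3 <- !dbl_c && !nitro_n[i]
        if (sp3 && !amide) {
          if (any(vinyl[nb])) t <- c(t, ti("Enamine Nitrogen"))
          else {
            t <- c(t, ti("Amine Nitrogen"), ti("Positive Ionizable"),
                   ti("H-bond Acceptor"))
          }
        }
      }
    }
    if (e == "S") {
      os2 <- nb[el[nb] == "O" & vapply(nb, function(x) ord_to(i, x) == 2L,
                                       logical(1))]
      if (length(os2) >= 2) t <- c(t, ti("Sulfone Sulfur"))
      else if (length(os2) == 1) t <- c(t, ti("Sulfoxide Sulfur"))
      if (ar[i]) t <- c(t, ti("Aromatic Sulfur"))
    }
    out[[i]] <- sort(unique(t))
  }
  out
}

# protein-side per-atom types by residue and PDB atom name ------------------
# backbone: N amide donor, O acceptor, C/CA aliphatic carbon.
# side chains: standard chemistry (ASP/GLU carboxylates negative, LYS/ARG
# amines positive, HIS imidazole both donor and acceptor, ring carbons
# aromatic, hydroxyls donor+acceptor alcohols).
.PROT_TYPE_TABLE <- local({
  V <- c("Aromatic", "Negative Ionizable", "Positive Ionizable",
         "H-bond Donor", "H-bond Acceptor", "Amide Nitrogen",
         "Amine Nitrogen", "Carboxylate Oxygen", "Alcohol Oxygen",
         "Imine Nitrogen", "Aromatic Nitrogen", "Aromatic Carbon",
         "Aliphatic Carbon")
  t <- function(...) match(c(...), V)
  bb <- list(N = t("H-bond Donor", "Amide Nitrogen"),
             CA = t("Aliphatic Carbon"), C = t("Aliphatic Carbon"),
             O = t("H-bond Acceptor"),
             OXT = t("H-bond Acceptor", "Carboxylate Oxygen",
                     "Negative Ionizable"))
  aroC <- t("Aromatic", "Aromatic Carbon")
  ali <- t("Aliphatic Carbon")
  side <- list(
    ALA = list(CB = ali),
    ARG = list(CB = ali, CG = ali, CD = ali, CZ = ali,
               NE = t("H-bond Donor", "Positive Ionizable", "Amine Nitrogen"),
               NH1 = t("H-bond Donor", "Positive Ionizable", "Amine Nitrogen"),
               NH2 = t("H-bond Donor", "Positive Ionizable", "Amine Nitrogen")),
    ASN = list(CB = ali, CG = ali, OD1 = t("H-bond Acceptor"),
               ND2 = t("H-bond Donor", "Amide Nitrogen")),
    ASP = list(CB = ali, CG = ali,
               OD1 = t("H-bond Acceptor", "Carboxylate Oxygen",
                       "Negative Ionizable"),
               OD2 = t("H-bond Acceptor", "Carboxylate Oxygen",
                       "Negative Ionizable")),
    CYS = list(CB = ali, SG = integer(0)),
    GLU = list(CB = ali, CG = ali, CD = ali,
               OE1 = t("H-bond Acceptor", "Carboxylate Oxygen",
                       "Negative Ionizable"),
               OE2 = t("H-bond Acceptor", "Carboxylate Oxygen",
                       "Negative Ionizable")),
    GLN = list(CB = ali, CG = ali, CD = ali, OE1 = t("H-bond Acceptor"),
               NE2 = t("H-bond Donor", "Amide Nitrogen")),
    GLY = list(),
    HIS = list(CB = ali, CG = aroC, CD2 = aroC, CE1 = aroC,
               ND1 = t("Aromatic", "Aromatic Nitrogen", "H-bond Donor",
                       "Positive Ionizable"),
               NE2 = t("Aromatic", "Aromatic Nitrogen", "H-bond Acceptor",
                       "Imine Nitrogen", "Positive Ionizable")),
    ILE = list(CB = ali, CG1 = ali, CG2 = ali, CD1 = ali),
    LEU = list(CB = ali, CG = ali, CD1 = ali, CD2 = ali),
    LYS = list(CB = ali, CG = ali, CD = ali, CE = ali,
               NZ = t("H-bond Donor", "Positive Ionizable", "Amine Nitrogen")),
    MET = list(CB = ali, CG = ali, SD = integer(0), CE = ali),
    PHE = list(CB = ali, CG = aroC, CD1 = aroC, CD2 = aroC, CE1 = aroC,
               CE2 = aroC, CZ = aroC),
    PRO = list(CB = ali, CG = ali, CD = ali),
    SER = list(CB = ali,
               OG = t("H-bond Donor", "H-bond Acceptor", "Alcohol Oxygen")),
    THR = list(CB = ali, CG2 = ali,
               OG1 = t("H-bond Donor", "H-bond Acceptor", "Alcohol Oxygen")),
    TRP = list(CB = ali, CG = aroC, CD1 = aroC, CD2 = aroC, CE2 = aroC,
               CE3 = aroC, CZ2 = aroC, CZ3 = aroC, CH2 = aroC,
               NE1 = t("Aromatic", "Aromatic Nitrogen", "H-bond Donor")),
    TYR = list(CB = ali, CG = aroC, CD1 = aroC, CD2 = aroC, CE1 = aroC,
               CE2 = aroC, CZ = aroC,
               OH = t("H-bond Donor", "H-bond Acceptor", "Alcohol Oxygen")),
    VAL = list(CB = ali, CG1 = ali, CG2 = ali))
  side$PRO$N <- t("Amide Nitrogen")  # no amide H on proline backbone N
  list(bb = bb, side = side)
})

#' Type the atoms of a residue environment
#'
#' Many-hot assignment over the 13-type protein vocabulary, from a fixed
#' residue/atom-name lookup (backbone amide, side-chain chemistry). Atoms of
#' non-standard residues or with unknown names get an empty type set with a
#' warning.
#' @param residues list of [fb_residue].
#' @return list with `types` (list of integer index vectors, one per atom,
#'   over all residues in order) and `xyz` (the stacked coordinate matrix).
#' @export
type_atoms_protein <- function(residues) {
  types <- list(); xyz <- list()
  unknown <- 0L
  for (r in residues) {
    side <- .PROT_TYPE_TABLE$side[[r$name]]
    for (a in seq_along(r$atom_names)) {
      nm <- r$atom_names[a]
      tt <- if (r$name == "PRO" && nm == "N") .PROT_TYPE_TABLE$side$PRO$N
            else .PROT_TYPE_TABLE$bb[[nm]] %||% side[[nm]]
      if (is.null(tt)) { tt <- integer(0); unknown <- unknown + 1L }
      types[[length(types) + 1L]] <- tt
      xyz[[length(xyz) + 1L]] <- r$xyz[a, ]
    }
  }
  if (unknown > 0)
    warning(unknown, " protein atom(s) with no type assignment")
  list(types = types, xyz = do.call(rbind, xyz))
}

#' Gaussian distance weight
#'
#' `exp(-(d - 3)^2)` for pair distances up to 10 A, zero beyond (the weight
#' is cut, not tapered, at the cap). Peaks at 3 A, the canonical contact
#' distance.
#' @param d distance(s) in Angstrom, non-negative.
#' @return weight(s) in `[0, 1]`.
#' @export
distance_weight <- function(d) {
  if (any(d < 0)) stop("negative distance")
  ifelse(d <= 10, exp(-(d - 3)^2), 0)
}

#' Distance-weighted interaction fingerprint of a FRASE
#'
#' For every (ligand atom i, protein atom j) heavy-atom pair, the Gaussian
#' weight of their distance is added to every cell (m, n) where i carries
#' ligand type m and j protein type n. The result is the length-377
#' (29 x 13) nonnegative vector, flattened with the protein type index
#' fastest: cell `l = (m - 1) * 13 + n`. Multi-typed atoms contribute once
#' per type pair.
#'
#' @param fr a [frase] (or any list with `fragment` and `environment`).
#' @return numeric vector of length 377 with names "ligandtype|proteintype".
#' @export
interaction_fingerprint <- function(fr) {
  ltypes <- type_atoms_ligand(fr$fragment)
  prot <- type_atoms_protein(fr$environment)
  nm <- as.vector(t(outer(ligand_type_vocab(), protein_type_vocab(),
                          paste, sep = "|")))
  f <- numeric(29 * 13)
  names(f) <- nm
  if (length(prot$types) == 0) {
    warning("empty environment: zero fingerprint")
    return(f)
  }
  A <- matrix(0, n_atoms(fr$fragment), 29)
  for (i in seq_along(ltypes)) A[i, ltypes[[i]]] <- 1
  B <- matrix(0, length(prot$types), 13)
  for (j in seq_along(prot$types)) B[j, prot$types[[j]]] <- 1
  W <- distance_weight(cross_dist(fr$fragment$xyz, prot$xyz))
  f[] <- as.vector(t(crossprod(A, W %*% B)))  # f_mn = sum_ij A_im W_ij B_jn
  f
}

#' Decoy generation settings
#' @param decoys_per_frase decoys built per true FRASE (default 2, the
#'   training-set ratio).
#' @param seed RNG seed.
#' @return object of class `decoy_spec`.
#' @export
decoy_spec <- function(decoys_per_frase = 2L, seed = 1L) {
  stopifnot(decoys_per_frase >= 1)
  structure(list(decoys_per_frase = as.integer(decoys_per_frase),
                 seed = as.integer(seed)), class = "decoy_spec")
}

# place src coordinates into the frame of ref coordinates: centroids
# coincide, principal axes aligned, deterministic sign convention (each
# mapped axis keeps a positive projection onto the reference axis ordering;
# the third axis sign is fixed to keep the rotation proper).
.principal_axes <- function(xyz) {
  c0 <- colMeans(xyz)
  X <- sweep(xyz, 2, c0)
  if (nrow(xyz) < 3) return(list(center = c0, axes = diag(3)))
  ev <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  A <- ev$vectors
  # sign convention: largest-magnitude component of each axis positive
  for (k in 1:2) {
    m <- which.max(abs(A[, k]))
    if (A[m, k] < 0) A[, k] <- -A[, k]
  }
  A[, 3] <- .cross3(A[, 1], A[, 2])
  list(center = c0, axes = A)
}

.swap_place <- function(src_xyz, ref_xyz) {
  ps <- .principal_axes(src_xyz)
  pr <- .principal_axes(ref_xyz)
  R <- pr$axes %*% t(ps$axes)
  sweep(sweep(src_xyz, 2, ps$center) %*% t(R), 2, -pr$center)
}

#' Generate decoy FRASEs by fragment swapping
#'
#' For each true FRASE, `decoys_per_frase` decoys are built by replacing its
#' fragment with one drawn at random from a different FRASE; the swapped-in
#' fragment is moved so its centroid coincides with the original fragment's
#' centroid and its principal axes align (no re-minimisation), while the
#' environment is left untouched. Deterministic for a fixed seed.
#'
#' @param frases list of true [frase] objects (at least 2).
#' @param spec a [decoy_spec].
#' @return list of `decoys_per_frase * length(frases)` FRASEs with label
#'   "decoy".
#' @export
make_decoys <- function(frases, spec = decoy_spec()) {
  n <- length(frases)
  if (n < 2) stop("cannot swap fragments with fewer than 2 FRASEs")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  out <- vector("list", n * spec$decoys_per_frase)
  k <- 0L
  for (i in seq_len(n)) {
    donors <- sample.int(n - 1L, spec$decoys_per_frase, replace = TRUE)
    donors <- ifelse(donors >= i, donors + 1L, donors)  # never self-draw
    ref_xyz <- frases[[i]]$fragment$xyz
    for (d in donors) {
      frag <- frases[[d]]$fragment
      frag$xyz <- .swap_place(frag$xyz, ref_xyz)
      k <- k + 1L
      out[[k]] <- frase(frag, frases[[i]]$environment,
                        env_radius = frases[[i]]$env_radius,
                        source = frases[[i]]$source, label = "decoy",
                        id = sprintf("%s|decoy%d<-%s", frases[[i]]$id, k,
                                     frases[[d]]$id))
    }
  }
  out
}

#' Split FRASE ids into training and validation sets
#'
#' Random, disjoint, exhaustive split; deterministic for a fixed seed. With
#' a database of 184,963 and a training draw of 38,791, the validation side
#' holds the remaining 146,172.
#' @param ids character vector of FRASE ids (must be unique).
#' @param n_train number drawn for training.
#' @param seed RNG seed.
#' @return list with `train` and `validation` id vectors.
#' @export
split_frase_ids <- function(ids, n_train, seed = 1L) {
  stopifnot(!anyDuplicated(ids), n_train >= 1, n_train < length(ids))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tr <- sample(ids, n_train)
  list(train = tr, validation = setdiff(ids, tr))
}

#' Train the nativeness classifier
#'
#' A 377-32-16-1 dense network (ReLU hidden layers, sigmoid output) trained
#' with binary cross-entropy and ADAM over mini-batches; class imbalance is
#' left unweighted. Deterministic given the seed.
#'
#' @param true_fps matrix of fingerprints of true FRASEs (rows = samples).
#' @param decoy_fps matrix of decoy fingerprints.
#' @param hidden hidden-layer widths (default `c(32, 16)`).
#' @param epochs,batch,lr training schedule (defaults 500 epochs, batch 50).
#' @param seed RNG seed for initialisation and shuffling.
#' @return object of class `nativeness_model` wrapping the trained `fb_mlp`
#'   with its training metadata.
#' @export
train_model <- function(true_fps, decoy_fps, hidden = c(32L, 16L),
                        epochs = 500L, batch = 50L, lr = 1e-3, seed = 1L) {
  true_fps <- as.matrix(true_fps); decoy_fps <- as.matrix(decoy_fps)
  if (nrow(true_fps) == 0 || nrow(decoy_fps) == 0)
    stop("need at least one example per class")
  X <- rbind(true_fps, decoy_fps)
  y <- c(rep(1, nrow(true_fps)), rep(0, nrow(decoy_fps)))
  net <- mlp_new(c(ncol(X), hidden, 1L), seed = seed)
  net <- mlp_train(net, X, y, epochs = epochs, batch = batch, lr = lr,
                   seed = seed + 1L)
  structure(list(net = net,
                 meta = list(n_true = nrow(true_fps),
                             n_decoy = nrow(decoy_fps),
                             hidden = hidden, epochs = epochs, batch = batch,
                             lr = lr, seed = seed)),
            class = "nativeness_model")
}

#' @export
print.nativeness_model <- function(x, ...) {
  cat(sprintf(
    "<nativeness model %s: trained on %d true / %d decoy, final BCE %.4f>\n",
    paste(x$net$sizes, collapse = "-"), x$meta$n_true, x$meta$n_decoy,
    utils::tail(x$net$loss, 1)))
  invisible(x)
}

#' Score the nativeness of a FRASE
#'
#' Sigmoid output of the classifier on the FRASE's interaction fingerprint:
#' close to 1 for native-like fragment poses, close to 0 for decoy-like ones.
#' A zero fingerprint (no contact within 10 A) is scored anyway and flagged.
#' @param model a [train_model] result (or a bare `fb_mlp`).
#' @param fr a [frase], or a precomputed length-377 fingerprint.
#' @return fitness score in (0, 1); attribute `zero_fingerprint` when flagged.
#' @export
score_frase <- function(model, fr) {
  fp <- if (is.numeric(fr)) fr else interaction_fingerprint(fr)
  net <- if (inherits(model, "nativeness_model")) model$net else model
  s <- mlp_predict(net, fp)
  if (all(fp == 0)) attr(s, "zero_fingerprint") <- TRUE
  s
}
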