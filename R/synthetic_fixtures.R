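# Self-contained toy inputs with known ground truth: a small-molecule
# fragment palette with geometric 3D coordinates, reduced rigid residue
# templates, planted complexes, bulk FRASE sets and separable training sets.
# Everything is generated in code -- no structure downloads, no binary
# fixtures -- and is deterministic for a fixed seed.

.hexagon <- function(r = 1.39) {
  a <- (0:5) * pi / 3
  cbind(r * cos(a), r * sin(a), 0)
}

#' Fragment palette for synthetic fixtures
#'
#' Nine small molecules with idealised planar/near-planar 3D coordinates and
#' full connection tables: benzene, phenol, toluene, pyridine, furan,
#' imidazole, cyclohexane, benzamide and benzoic acid. All fall in (or near)
#' the 50-300 Da retention window and jointly exercise the aromatic,
#' donor/acceptor, ionizable and hydrophobic perception rules.
#' @return named list of [fbmol].
#' @export
fragment_palette <- function() {
  hx <- .hexagon()
  ring_bonds6 <- cbind(1:6, c(2:6, 1), rep(c(2L, 1L), 3))
  benzene <- fbmol(rep("C", 6), hx, ring_bonds6, name = "BNZ")
  phenol <- fbmol(c(rep("C", 6), "O"),
                  rbind(hx, c(2.75, 0, 0)),
                  rbind(ring_bonds6, c(1L, 7L, 1L)), name = "PHN")
  toluene <- fbmol(c(rep("C", 6), "C"),
                   rbind(hx, c(2.90, 0, 0)),
                   rbind(ring_bonds6, c(1L, 7L, 1L)), name = "TOL")
  pyridine <- fbmol(c("N", rep("C", 5)), hx, ring_bonds6, name = "PYR")
  pent <- function(r) { a <- pi / 2 + (0:4) * 2 * pi / 5
                        cbind(r * cos(a), r * sin(a), 0) }
  furan <- fbmol(c("O", rep("C", 4)), pent(1.17),
                 cbind(1:5, c(2:5, 1), c(1L, 2L, 1L, 2L, 1L)), name = "FUR")
  imidazole <- fbmol(c("N", "C", "N", "C", "C"), pent(1.16),
                     cbind(1:5, c(2:5, 1), c(1L, 2L, 1L, 2L, 1L)),
                     name = "IMD")
  chair <- .hexagon(1.47); chair[, 3] <- rep(c(0.25, -0.25), 3)
  cyclohexane <- fbmol(rep("C", 6), chair,
                       cbind(1:6, c(2:6, 1), rep(1L, 6)), name = "CHX")
  benzamide <- fbmol(c(rep("C", 6), "C", "O", "N"),
                     rbind(hx, c(2.90, 0, 0), c(3.55, 1.05, 0),
                           c(3.55, -1.15, 0)),
                     rbind(ring_bonds6, c(1L, 7L, 1L), c(7L, 8L, 2L),
                           c(7L, 9L, 1L)), name = "BZM")
  benzoate <- fbmol(c(rep("C", 6), "C", "O", "O"),
                    rbind(hx, c(2.90, 0, 0), c(3.55, 1.05, 0),
                          c(3.55, -1.15, 0)),
                    rbind(ring_bonds6, c(1L, 7L, 1L), c(7L, 8L, 2L),
                          c(7L, 9L, 1L)), name = "BZA")
  list(benzene = benzene, phenol = phenol, toluene = toluene,
       pyridine = pyridine, furan = furan, imidazole = imidazole,
       cyclohexane = cyclohexane, benzamide = benzamide, benzoate = benzoate)
}

# Reduced rigid residue templates in a local frame (CA at origin): backbone
# N, CA, C, O plus CB and representative side-chain heavy atoms, enough for
# distance rules, triplet bits and protein atom typing. Rotamer realism is
# out of scope.
.residue_templates <- local({
  u <- c(0.38, -0.52, 0.80)  # side-chain growth direction
  bb <- rbind(N = c(-1.46, 0, 0), CA = c(0, 0, 0), C = c(0.55, 1.40, 0),
              O = c(1.78, 1.55, 0))
  grow <- function(...) {
    ds <- c(...)
    t(vapply(seq_along(ds), function(k)
      ds[k] * u + (k - 1) * c(0.25, 0.30, -0.10), numeric(3)))
  }
  tmpl <- list(
    GLY = bb,
    ALA = rbind(bb, CB = 1.53 * u),
    SER = rbind(bb, CB = 1.53 * u, OG = grow(2.9)[1, ]),
    VAL = rbind(bb, CB = 1.53 * u, CG1 = grow(2.9)[1, ],
                CG2 = 2.9 * u + c(-0.9, 0.4, 0.3)),
    LEU = rbind(bb, CB = 1.53 * u, CG = grow(2.9)[1, ], CD1 = grow(2.9, 4.1)[2, ],
                CD2 = 4.1 * u + c(-0.9, 0.5, 0.4)),
    THR = rbind(bb, CB = 1.53 * u, OG1 = grow(2.9)[1, ],
                CG2 = 2.9 * u + c(-0.9, 0.4, 0.3)),
    ASP = rbind(bb, CB = 1.53 * u, CG = grow(2.9)[1, ],
                OD1 = grow(2.9, 4.0)[2, ], OD2 = 4.0 * u + c(-0.8, 0.5, 0.3)),
    GLU = rbind(bb, CB = 1.53 * u, CG = grow(2.9)[1, ], CD = grow(2.9, 4.2)[2, ],
                OE1 = grow(2.9, 4.2, 5.3)[3, ],
                OE2 = 5.3 * u + c(-0.8, 0.5, 0.3)),
    ASN = rbind(bb, CB = 1.53 * u, CG = grow(2.9)[1, ],
                OD1 = grow(2.9, 4.0)[2, ], ND2 = 4.0 * u + c(-0.8, 0.5, 0.3)),
    LYS = rbind(bb, CB = 1.53 * u, CG = grow(2.9)[1, ], CD = grow(2.9, 4.2)[2, ],
                CE = grow(2.9, 4.2, 5.5)[3, ], NZ = grow(2.9, 4.2, 5.5, 6.8)[4, ]),
    ARG = rbind(bb, CB = 1.53 * u, CG = grow(2.9)[1, ], CD = grow(2.9, 4.2)[2, ],
                NE = grow(2.9, 4.2, 5.5)[3, ], CZ = grow(2.9, 4.2, 5.5, 6.8)[4, ],
                NH1 = 6.8 * u + c(0.9, 0.9, -0.3) * 1.2,
                NH2 = 6.8 * u + c(-0.9, 0.5, 0.4)),
    PHE = local({
      ring <- .hexagon(1.39)
      ring <- sweep(ring %*% diag(3), 2, -(3.3 * u + c(1.39, 0, 0)))
      rbind(bb, CB = 1.53 * u, CG = ring[4, ], CD1 = ring[3, ],
            CD2 = ring[5, ], CE1 = ring[2, ], CE2 = ring[6, ], CZ = ring[1, ])
    }),
    TYR = local({
      ring <- .hexagon(1.39)
      ring <- sweep(ring %*% diag(3), 2, -(3.3 * u + c(1.39, 0, 0)))
      rbind(bb, CB = 1.53 * u, CG = ring[4, ], CD1 = ring[3, ],
            CD2 = ring[5, ], CE1 = ring[2, ], CE2 = ring[6, ], CZ = ring[1, ],
            OH = ring[1, ] + c(1.36, 0, 0))
    }),
    HIS = local({
      a <- pi / 2 + (0:4) * 2 * pi / 5
      ring <- cbind(1.16 * cos(a), 1.16 * sin(a), 0)
      ring <- sweep(ring, 2, -(3.2 * u + c(1.16, 0, 0)))
      rbind(bb, CB = 1.53 * u, CG = ring[4, ], ND1 = ring[3, ],
            CD2 = ring[5, ], CE1 = ring[2, ], NE2 = ring[1, ])
    }),
    TRP = local({
      ring <- .hexagon(1.39)
      ring <- sweep(ring %*% diag(3), 2, -(3.6 * u + c(1.39, 0, 0)))
      rbind(bb, CB = 1.53 * u, CG = 2.9 * u, CD1 = 3.6 * u + c(-1.0, 0.4, 0.3),
            CD2 = ring[4, ], NE1 = 4.6 * u + c(-1.1, 0.5, 0.3),
            CE2 = ring[3, ], CE3 = ring[5, ], CZ2 = ring[2, ],
            CZ3 = ring[6, ], CH2 = ring[1, ])
    }))
  lapply(tmpl, function(m) {
    el <- substr(rownames(m), 1, 1)
    list(atom_names = rownames(m), element = el, xyz = unname(m))
  })
})

#' Residue types available as synthetic templates
#' @return character vector of 3-letter codes.
#' @export
template_residues <- function() names(.residue_templates)

# uniform random rotation (QR of a Gaussian matrix, det fixed to +1)
.rand_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# rotation taking unit vector `from` onto unit vector `to` (Rodrigues)
.rotation_to <- function(from, to) {
  from <- from / sqrt(sum(from^2)); to <- to / sqrt(sum(to^2))
  v <- .cross3(from, to); c_ <- sum(from * to)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {  # antipodal: rotate pi about any perpendicular
    p <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- .cross3(from, p); v <- v / sqrt(sum(v^2))
    return(2 * tcrossprod(v) - diag(3))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

.SIDE_DIR <- c(0.38, -0.52, 0.80) / sqrt(sum(c(0.38, -0.52, 0.80)^2))

#' Place a template residue in the lab frame
#'
#' Rigidly rotates the template and puts its Calpha at `ca`.
#' @param code template residue code.
#' @param chain,seq identifiers for the resulting residue.
#' @param ca target Calpha position.
#' @param rotation 3x3 rotation (default: random from the current RNG).
#' @return an [fb_residue].
#' @export
place_residue <- function(code, chain, seq, ca, rotation = .rand_rotation()) {
  tm <- .residue_templates[[code]]
  if (is.null(tm)) stop("no template for residue ", code)
  xyz <- sweep(tm$xyz %*% t(rotation), 2, -as.numeric(ca))
  fb_residue(code, chain, seq, tm$atom_names, tm$element, xyz)
}

#' Specification for a toy complex
#'
#' @param fragment_name palette fragment to plant (see [fragment_palette]).
#' @param n_env number of environment residues (atoms within 4.5 A).
#' @param n_far number of distant residues (all atoms beyond 8 A).
#' @param residue_codes pool of template codes to draw from.
#' @param triplet_side if non-NULL, the first three environment residues'
#'   Calpha atoms are planted as an equilateral triangle with this side (A).
#' @param env_radius environment cutoff the truth is computed against.
#' @param seed RNG seed.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(fragment_name = "phenol", n_env = 5L, n_far = 3L,
                         residue_codes = template_residues(),
                         triplet_side = 9.5, env_radius = 4.5, seed = 1L) {
  structure(list(fragment_name = fragment_name, n_env = as.integer(n_env),
                 n_far = as.integer(n_far), residue_codes = residue_codes,
                 triplet_side = triplet_side, env_radius = env_radius,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# place a residue so its closest heavy atom sits at `target_min` from the
# fragment: CA along direction `dir`, side chain pointing away from the
# fragment, then slide radially (two refinement passes; the min-distance
# field is 1-Lipschitz, so two passes land within a few hundredths of an A)
.place_at_min_dist <- function(code, chain, seq, dir, frag_xyz, target_min) {
  dir <- dir / sqrt(sum(dir^2))
  r <- place_residue(code, chain, seq, 15 * dir,
                     rotation = .rotation_to(.SIDE_DIR, dir))
  for (pass in 1:3) {
    gap <- min(cross_dist(r$xyz, frag_xyz)) - target_min
    if (abs(gap) < 0.02) break
    r$xyz <- sweep(r$xyz, 2, gap * dir)
    r$ca <- r$ca - gap * dir
  }
  r
}

#' Generate a toy complex with known ground truth
#'
#' Plants a palette fragment at the origin (random orientation) and rigid
#' residue templates around it: `n_env` residues with their closest atom
#' 3-4.4 A from the fragment, `n_far` residues beyond 8 A. When
#' `triplet_side` is set, the first three environment residues get Calpha
#' atoms on an equilateral triangle of that side, guaranteeing at least one
#' qualifying triplet. Ground truth (environment indices, exhaustive triplet
#' list, the planted FRASE) is computed by construction-independent brute
#' force.
#'
#' @param spec a [fixture_spec].
#' @return list: `complex` ([fb_complex]), `truth` with `fragment`,
#'   `env_idx`, `triplets` (brute force over all residue 3-subsets) and
#'   `frase`.
#' @export
make_toy_complex <- function(spec = fixture_spec()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  frag0 <- fragment_palette()[[spec$fragment_name]]
  if (is.null(frag0)) stop("unknown palette fragment: ", spec$fragment_name)

  residues <- list()
  frag <- NULL
  if (spec$n_env >= 3 && !is.null(spec$triplet_side)) {
    s <- spec$triplet_side
    if (s < 8 || s > 12) stop("infeasible geometry: triplet side outside [8, 12]")
    # equilateral triangle of Calpha atoms in the fragment plane, centred on
    # the fragment; circumradius s/sqrt(3). Side chains point outward so the
    # backbone faces the fragment. Retry fragment orientation until all three
    # residues sit inside the environment shell without clashing.
    rho <- s / sqrt(3)
    ang <- c(0, 2, 4) * pi / 3
    tri <- cbind(rho * cos(ang), rho * sin(ang), 0)
    codes3 <- sample(spec$residue_codes, 3, replace = TRUE)
    for (try in 1:200) {
      frag_try <- transform_mol(frag0, .rand_rotation())
      res_try <- lapply(1:3, function(i)
        place_residue(codes3[i], "A", i, tri[i, ],
                      rotation = .rotation_to(.SIDE_DIR, tri[i, ])))
      dmin <- vapply(res_try, function(r)
        min(cross_dist(r$xyz, frag_try$xyz)), numeric(1))
      if (all(dmin > 1.5 & dmin <= spec$env_radius - 0.1)) {
        frag <- frag_try; residues <- res_try; break
      }
    }
    if (is.null(frag))
      stop("infeasible geometry request: could not place the planted triplet")
  } else {
    frag <- transform_mol(frag0, .rand_rotation())
  }
  while (length(residues) < spec$n_env) {
    i <- length(residues) + 1L
    residues[[i]] <- .place_at_min_dist(sample(spec$residue_codes, 1), "A", i,
                                        stats::rnorm(3), frag$xyz,
                                        stats::runif(1, 3.0, 4.4))
  }
  for (k in seq_len(spec$n_far)) {
    i <- length(residues) + 1L
    residues[[i]] <- .place_at_min_dist(sample(spec$residue_codes, 1), "A", i,
                                        stats::rnorm(3), frag$xyz,
                                        stats::runif(1, 9, 20))
  }
  cx <- fb_complex(sprintf("TOY%04d", spec$seed), residues,
                   ligands = list(frag))

  env_idx <- environment_residues(frag, residues, spec$env_radius)
  truth <- list(
    fragment = frag,
    env_idx = env_idx,
    triplets = brute_force_triplets(residues),
    frase = if (length(env_idx) > 0)
      frase(frag, residues[env_idx], env_radius = spec$env_radius,
            source = cx$pdb_id, label = "true",
            id = paste0(cx$pdb_id, ":planted")))
  list(complex = cx, truth = truth)
}

#' Exhaustive residue-triplet oracle
#'
#' Literal check of every 3-subset of residues against the edge bounds;
#' quadratic-free reference for [enumerate_triplets].
#' @param residues list of [fb_residue].
#' @param edge_min,edge_max bounds in Angstrom.
#' @return list of integer index triples.
#' @export
brute_force_triplets <- function(residues, edge_min = 8, edge_max = 12) {
  ok <- which(vapply(residues, function(r)
    !is.null(r$ca) && r$name %in% rownames(.RESIDUE_BITS), logical(1)))
  if (length(ok) < 3) return(list())
  out <- list()
  for (cmb in utils::combn(ok, 3, simplify = FALSE)) {
    ca <- do.call(rbind, lapply(residues[cmb], `[[`, "ca"))
    e <- c(sqrt(sum((ca[1, ] - ca[2, ])^2)), sqrt(sum((ca[1, ] - ca[3, ])^2)),
           sqrt(sum((ca[2, ] - ca[3, ])^2)))
    if (all(e >= edge_min & e <= edge_max))
      out[[length(out) + 1L]] <- cmb
  }
  out
}

#' Generate a bulk set of true FRASEs
#'
#' Fast, lightweight sampler for scale tests: each FRASE gets a random
#' palette fragment (random orientation) and 3-6 template residues placed
#' with closest atoms 3-4.4 A away. Supports tens of thousands of FRASEs in
#' bounded time and memory; deterministic for a fixed seed.
#' @param n number of FRASEs.
#' @param seed RNG seed.
#' @return list of [frase] with label "true" and ids "synth000001", ...
#' @export
make_frase_set <- function(n, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pal <- fragment_palette()
  codes <- template_residues()
  tmpl <- .residue_templates
  out <- vector("list", n)
  for (i in seq_len(n)) {
    frag <- pal[[sample.int(length(pal), 1)]]
    frag <- transform_mol(frag, .rand_rotation())
    nr <- sample(3:6, 1)
    env <- vector("list", nr)
    for (j in seq_len(nr)) {
      code <- codes[sample.int(length(codes), 1)]
      env[[j]] <- .place_at_min_dist(code, "A", j, stats::rnorm(3), frag$xyz,
                                     stats::runif(1, 3.0, 4.4))
    }
    out[[i]] <- frase(frag, env, source = "synth", label = "true",
                      id = sprintf("synth%06d", i))
  }
  out
}

#' Generate a separable true/decoy fingerprint set
#'
#' Direct fingerprint-space construction for classifier tests: both classes
#' share a sparse exponential background over the 377 cells; the true class
#' adds `effect` to the mean of `n_signal` fixed signal cells (truncated at
#' zero to respect fingerprint nonnegativity). With unit-variance signal
#' cells the Bayes accuracy of the construction is
#' `pnorm(effect * sqrt(n_signal) / 2)`, reported alongside the data.
#'
#' @param n_true number of true examples; decoys are `ratio` times as many.
#' @param n_signal number of signal-carrying cells.
#' @param effect mean shift on the signal cells (0 = null construction).
#' @param ratio decoys per true example (default 2).
#' @param seed RNG seed.
#' @return list: `true` and `decoy` matrices (377 columns), `signal_cells`,
#'   `bayes_accuracy`.
#' @export
make_separable_training_set <- function(n_true, n_signal = 5L, effect = 3,
                                        ratio = 2L, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  p <- 29L * 13L
  n_decoy <- ratio * n_true
  cells <- sample.int(p, n_signal)
  bg <- function(n) {
    m <- matrix(stats::rexp(n * p, rate = 2) *
                  (stats::runif(n * p) < 0.10), n, p)
    m
  }
  true <- bg(n_true); decoy <- bg(n_decoy)
  base <- 3
  true[, cells] <- pmax(matrix(stats::rnorm(n_true * n_signal,
                                            base + effect), n_true), 0)
  decoy[, cells] <- pmax(matrix(stats::rnorm(n_decoy * n_signal, base),
                                n_decoy), 0)
  list(true = true, decoy = decoy, signal_cells = cells,
       bayes_accuracy = stats::pnorm(effect * sqrt(n_signal) / 2))
}
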