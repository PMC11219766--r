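# Turning complexes into FRASEs: drug-likeness filters on ligands,
# fragmentation over acyclic single bonds, and 4.5 A environment cut-out.

#' Ligand drug-likeness filter configuration
#'
#' Thresholds for the Lipinski-style rules, the element allow-list (no
#' phosphorus, no inorganics), the peptide-exclusion rule and the set of
#' enabled reactive-group rules. Reactive groups are matched by documented
#' graph predicates over the molecule's connection table (see
#' [reactive_group_rules]).
#'
#' @param mw_cap molecular-weight cap in Da (500 default; 600 is the common
#'   relaxation for screening libraries).
#' @param hbd_max maximum H-bond donors (N/O bearing at least one H).
#' @param hba_max maximum H-bond acceptors (any N or O).
#' @param max_amide_bonds ligands with more amide (C(=O)-N) bonds than this
#'   are rejected as peptides.
#' @param allowed_elements element allow-list.
#' @param reactive_rules names of enabled reactive-group rules, a subset of
#'   `names(reactive_group_rules())`.
#' @return object of class `ligand_filter_config`.
#' @export
ligand_filter_config <- function(mw_cap = 500, hbd_max = 5, hba_max = 10,
                                 max_amide_bonds = 2,
                                 allowed_elements = c("C", "N", "O", "S",
                                                      "F", "Cl", "Br", "I"),
                                 reactive_rules = names(reactive_group_rules())) {
  structure(list(mw_cap = mw_cap, hbd_max = hbd_max, hba_max = hba_max,
                 max_amide_bonds = max_amide_bonds,
                 allowed_elements = allowed_elements,
                 reactive_rules = reactive_rules),
            class = "ligand_filter_config")
}

# graph helpers used by the structural rules -------------------------------

.nbrs_of <- function(mol, i) {
  b <- mol$bonds
  c(b[b[, 1] == i, 2], b[b[, 2] == i, 1])
}

.bond_between <- function(mol, i, j) {
  b <- mol$bonds
  hit <- (b[, 1] == i & b[, 2] == j) | (b[, 1] == j & b[, 2] == i)
  if (any(hit)) b[which(hit)[1], "order"] else 0L
}

# carbons double-bonded to at least one oxygen
.carbonyl_carbons <- function(mol) {
  b <- mol$bonds
  dbl <- b[b[, "order"] == 2L, , drop = FALSE]
  out <- integer(0)
  for (k in seq_len(nrow(dbl))) {
    i <- dbl[k, 1]; j <- dbl[k, 2]
    if (mol$element[i] == "C" && mol$element[j] == "O") out <- c(out, i)
    if (mol$element[j] == "C" && mol$element[i] == "O") out <- c(out, j)
  }
  unique(out)
}

#' Reactive / undesirable group rules
#'
#' The shipped deny-list in the spirit of REOS-style structural filtering.
#' Each rule is a predicate over an [fbmol] returning TRUE when the group is
#' present. Rules: aldehyde (carbonyl carbon with an implicit H), acyl halide,
#' alkyl halide (sp3 carbon bearing Cl/Br/I), Michael acceptor (C=C
#' conjugated to a carbonyl), epoxide or aziridine (3-ring with O/N), nitro
#' group, and isocyanate (N=C=O).
#' @return named list of predicate functions.
#' @export
reactive_group_rules <- function() {
  list(
    aldehyde = function(mol) {
      cc <- .carbonyl_carbons(mol)
      any(implicit_h(mol)[cc] >= 1L)
    },
    acyl_halide = function(mol) {
      cc <- .carbonyl_carbons(mol)
      any(vapply(cc, function(i)
        any(mol$element[.nbrs_of(mol, i)] %in% c("F", "Cl", "Br", "I")),
        logical(1)))
    },
    alkyl_halide = function(mol) {
      ar <- aromatic_atoms(mol)
      hal <- which(mol$element %in% c("Cl", "Br", "I"))
      any(vapply(hal, function(h) {
        nb <- .nbrs_of(mol, h)
        length(nb) == 1 && mol$element[nb] == "C" && !ar[nb] &&
          .bond_between(mol, h, nb) == 1L &&
          all(mol$bonds[mol$bonds[, 1] == nb | mol$bonds[, 2] == nb, "order"] <= 1L)
      }, logical(1)))
    },
    michael_acceptor = function(mol) {
      ar <- aromatic_atoms(mol)
      cc <- .carbonyl_carbons(mol)
      b <- mol$bonds
      vinyl <- b[b[, "order"] == 2L &
                 mol$element[b[, 1]] == "C" & mol$element[b[, 2]] == "C" &
                 !ar[b[, 1]] & !ar[b[, 2]], , drop = FALSE]
      any(apply(vinyl, 1, function(e)
        any(.nbrs_of(mol, e[1]) %in% cc) || any(.nbrs_of(mol, e[2]) %in% cc)))
    },
    epoxide_aziridine = function(mol) {
      any(vapply(mol_rings(mol), function(r)
        length(r) == 3 && any(mol$element[r] %in% c("O", "N")), logical(1)))
    },
    nitro = function(mol) {
      ns <- which(mol$element == "N")
      any(vapply(ns, function(i) {
        nb <- .nbrs_of(mol, i)
        os <- nb[mol$element[nb] == "O"]
        length(os) >= 2 && any(vapply(os, function(o)
          .bond_between(mol, i, o) == 2L, logical(1)))
      }, logical(1)))
    },
    isocyanate = function(mol) {
      cs <- which(mol$element == "C")
      any(vapply(cs, function(i) {
        nb <- .nbrs_of(mol, i)
        any(mol$element[nb] == "N" & vapply(nb, function(x)
              .bond_between(mol, i, x) == 2L, logical(1)) ) &&
        any(mol$element[nb] == "O" & vapply(nb, function(x)
              .bond_between(mol, i, x) == 2L, logical(1)))
      }, logical(1)))
    })
}

# amide (C(=O)-N) bond count, the peptide proxy
.count_amide_bonds <- function(mol) {
  cc <- .carbonyl_carbons(mol)
  sum(vapply(cc, function(i) {
    nb <- .nbrs_of(mol, i)
    sum(mol$element[nb] == "N" & vapply(nb, function(x)
      .bond_between(mol, i, x) == 1L, logical(1)))
  }, numeric(1)))
}

#' H-bond donor / acceptor counts of a ligand
#' @param mol an [fbmol].
#' @return list with `hbd` (N/O with at least one hydrogen) and `hba`
#'   (any N or O).
#' @export
hbond_counts <- function(mol) {
  no <- mol$element %in% c("N", "O")
  h <- implicit_h(mol)
  list(hbd = sum(no & h > 0), hba = sum(no))
}

#' Filter a ligand for drug-likeness
#'
#' Applies the element allow-list (phosphorus and inorganic elements
#' rejected), Lipinski-style thresholds, the peptide rule and the
#' reactive-group deny-list. Deterministic: the result lists every violated
#' rule, not just the first.
#'
#' @param lig an [fbmol].
#' @param cfg a [ligand_filter_config].
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   violated rules, empty when passing).
#' @export
filter_ligand <- function(lig, cfg = ligand_filter_config()) {
  reasons <- character(0)
  mw <- tryCatch(mol_weight(lig), error = function(e) NA_real_)
  if (is.na(mw)) return(list(pass = FALSE, reasons = "unperceivable"))
  if ("P" %in% lig$element) reasons <- c(reasons, "phosphorus")
  inorg <- setdiff(unique(lig$element), c(cfg$allowed_elements, "P"))
  if (length(inorg)) reasons <- c(reasons, "inorganic_element")
  if (mw > cfg$mw_cap) reasons <- c(reasons, "lipinski_mw")
  hb <- hbond_counts(lig)
  if (hb$hbd > cfg$hbd_max) reasons <- c(reasons, "lipinski_hbd")
  if (hb$hba > cfg$hba_max) reasons <- c(reasons, "lipinski_hba")
  if (.count_amide_bonds(lig) > cfg$max_amide_bonds)
    reasons <- c(reasons, "peptide")
  rules <- reactive_group_rules()[cfg$reactive_rules]
  for (nm in names(rules)) {
    hit <- tryCatch(rules[[nm]](lig), error = function(e) NA)
    if (is.na(hit)) reasons <- c(reasons, "unperceivable")
    else if (hit) reasons <- c(reasons, paste0("reactive_", nm))
  }
  list(pass = length(reasons) == 0, reasons = unique(reasons))
}

#' Fragment a ligand over acyclic single bonds
#'
#' Enumerates fragments by cutting every subset of at most `max_cuts` acyclic
#' single bonds. Ring bonds are never broken. When a cut bond touches a ring
#' atom on the kept side, the atom across the cut (the alpha-atom) stays
#' attached to the ring fragment. Duplicate atom sets are merged and the
#' 50-300 Da molecular-weight window (hydrogen-capped) is applied. Fragments
#' keep the parent's 3D coordinates.
#'
#' @param lig an [fbmol].
#' @param mw_min,mw_max retention window in Da.
#' @param max_cuts maximum number of simultaneous bond cuts (bounds the
#'   combinatorics; fragments beyond the window are discarded anyway).
#' @return list of [fbmol] fragments with `attachment_points` and
#'   `parent_atoms` attributes.
#' @export
fragment_ligand <- function(lig, mw_min = 50, mw_max = 300, max_cuts = 3L) {
  rb <- ring_bonds(lig)
  cuttable <- which(!rb & lig$bonds[, "order"] == 1L)
  ring <- ring_atoms(lig)
  g <- .mol_graph(lig)

  seen <- new.env(hash = TRUE)
  frags <- list()
  add_set <- function(idx) {
    key <- paste(idx, collapse = ",")
    if (!is.null(seen[[key]])) return()
    seen[[key]] <- TRUE
    f <- sub_molecule(lig, idx)
    mw <- mol_weight(f)
    if (mw >= mw_min && mw <= mw_max) {
      attr(f, "mw") <- mw
      frags[[length(frags) + 1L]] <<- f
    }
  }

  for (ncut in 0:min(max_cuts, length(cuttable))) {
    subsets <- if (ncut == 0) list(integer(0))
               else utils::combn(cuttable, ncut, simplify = FALSE)
    for (cut in subsets) {
      g2 <- if (length(cut)) igraph::delete_edges(g, cut) else g
      comp <- igraph::components(g2)$membership
      for (cid in unique(comp)) {
        idx <- which(comp == cid)
        # alpha rule: the atom across a cut bond adjacent to a ring atom
        # stays with the ring fragment
        for (k in cut) {
          i <- lig$bonds[k, 1]; j <- lig$bonds[k, 2]
          if (i %in% idx && ring[i]) idx <- c(idx, j)
          if (j %in% idx && ring[j]) idx <- c(idx, i)
        }
        add_set(sort(unique(idx)))
      }
    }
  }
  frags
}

#' Environment residues of a fragment
#'
#' All residues of the complex having at least one heavy atom within
#' `env_radius` (inclusive) of any fragment heavy atom.
#' @param fragment an [fbmol].
#' @param residues list of [fb_residue].
#' @param env_radius cutoff in Angstrom.
#' @return integer indices into `residues`.
#' @export
environment_residues <- function(fragment, residues, env_radius = 4.5) {
  which(vapply(residues, function(r)
    min(cross_dist(fragment$xyz, r$xyz)) <= env_radius, logical(1)))
}

#' Extract FRASEs from a complex
#'
#' Filters each ligand for drug-likeness, fragments the survivors, and cuts
#' the residue environment of each retained fragment. Fragments with an empty
#' environment are dropped with a warning.
#'
#' @param cx an [fb_complex].
#' @param env_radius environment cutoff in Angstrom (default 4.5, inclusive).
#' @param filter_cfg a [ligand_filter_config].
#' @param mw_min,mw_max,max_cuts passed to [fragment_ligand].
#' @return list of [frase] objects with label "true".
#' @export
extract_frases <- function(cx, env_radius = 4.5,
                           filter_cfg = ligand_filter_config(),
                           mw_min = 50, mw_max = 300, max_cuts = 3L) {
  out <- list()
  dropped <- 0L
  for (li in seq_along(cx$ligands)) {
    lig <- cx$ligands[[li]]
    if (!filter_ligand(lig, filter_cfg)$pass) next
    for (f in fragment_ligand(lig, mw_min, mw_max, max_cuts)) {
      env_idx <- environment_residues(f, cx$residues, env_radius)
      if (length(env_idx) == 0) { dropped <- dropped + 1L; next }
      f$name <- sprintf("%s_f%02d", lig$name, length(out) + 1L)
      out[[length(out) + 1L]] <-
        frase(f, cx$residues[env_idx], env_radius = env_radius,
              source = cx$pdb_id, label = "true",
              id = sprintf("%s:%s", cx$pdb_id, f$name))
    }
  }
  if (dropped > 0)
    warning(dropped, " fragment(s) dropped for empty environment")
  out
}

#' Apply the high-affinity filter from an annotation table
#'
#' Keeps complex identifiers whose best reported affinity (K_D, K_i, IC50 or
#' EC50) is below the threshold. The table is user-supplied CSV with columns
#' `id` and `affinity_nM`; no network retrieval is performed.
#' @param ids character vector of complex identifiers.
#' @param affinity_csv path to the CSV.
#' @param threshold_nM affinity cutoff in nM (default 100).
#' @return subset of `ids` passing the filter (ids absent from the table are
#'   dropped).
#' @export
filter_high_affinity <- function(ids, affinity_csv, threshold_nM = 100) {
  tab <- utils::read.csv(affinity_csv, stringsAsFactors = FALSE)
  if (!all(c("id", "affinity_nM") %in% names(tab)))
    stop("affinity CSV needs columns 'id' and 'affinity_nM'")
  best <- tapply(tab$affinity_nM, tab$id, min, na.rm = TRUE)
  ids[ids %in% names(best)[best < threshold_nM]]
}

#' Build a FRASE database from complexes
#'
#' Streams each PDB complex through [load_complex] and [extract_frases] and
#' appends the results to an SD file, so memory use is bounded by a single
#' complex.
#' @param complex_paths character vector of PDB files.
#' @param out_sdf output SD file.
#' @param affinity_csv optional affinity table (see [filter_high_affinity]);
#'   complexes failing the filter are skipped.
#' @param ... passed to [extract_frases].
#' @return invisibly, a data.frame of per-complex FRASE counts.
#' @export
build_frase_db <- function(complex_paths, out_sdf, affinity_csv = NULL, ...) {
  ids <- sub("\\.(pdb|ent)(\\.gz)?$", "", basename(complex_paths))
  if (!is.null(affinity_csv))
    complex_paths <- complex_paths[ids %in%
      filter_high_affinity(ids, affinity_csv)]
  counts <- integer(0)
  queue <- list()
  qi <- 0L; pi <- 0L
  feeder <- function() {
    repeat {
      qi <<- qi + 1L
      if (qi <= length(queue)) return(queue[[qi]])
      pi <<- pi + 1L
      if (pi > length(complex_paths)) return(NULL)
      cx <- load_complex(complex_paths[pi])
      queue <<- extract_frases(cx, ...)
      counts[basename(complex_paths[pi])] <<- length(queue)
      qi <<- 0L
    }
  }
  write_frase_sdf(feeder, out_sdf)
  invisible(data.frame(complex = names(counts), n_frases = as.integer(counts)))
}
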