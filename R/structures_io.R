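# Structure input/output: PDB complexes via bio3d, and the package's SDF
# dialect for FRASEs (fragment as the molecule block, residue environment in
# SD data fields -- SDF has no native protein block).

.STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLU", "GLN", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

# HETATM groups never treated as ligands: waters, common ions,
# cryoprotectants and buffer components.
.HET_DENY <- c("HOH", "DOD", "WAT",
               "NA", "K", "CL", "CA", "MG", "ZN", "MN", "FE", "FE2", "CU",
               "CO", "NI", "CD", "HG", "BR", "IOD", "F", "CS", "LI", "SR",
               "BA", "SO4", "PO4", "NO3", "CO3", "ACT", "FMT", "CIT",
               "GOL", "EDO", "PEG", "PG4", "PGE", "MPD", "DMS", "EOH",
               "MOH", "IPA", "TRS", "EPE", "MES", "BME", "DTT", "NH4", "AZI")

#' Construct a residue
#'
#' @param name 3-letter residue code.
#' @param chain chain identifier.
#' @param seq residue number.
#' @param atom_names character vector of PDB atom names (e.g. "CA", "OD1").
#' @param element element symbols, parallel to `atom_names`.
#' @param xyz coordinate matrix (one row per atom, Angstrom).
#' @return object of class `fb_residue`; `$ca` holds the Calpha coordinate or
#'   NULL when no CA atom exists.
#' @export
fb_residue <- function(name, chain, seq, atom_names, element, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(nrow(xyz) == length(atom_names), length(element) == length(atom_names))
  ica <- match("CA", atom_names)
  structure(list(name = name, chain = chain, seq = as.integer(seq),
                 atom_names = as.character(atom_names),
                 element = as.character(element), xyz = xyz,
                 ca = if (!is.na(ica)) xyz[ica, ] else NULL),
            class = "fb_residue")
}

#' @export
print.fb_residue <- function(x, ...) {
  cat(sprintf("<residue %s %s%d, %d atoms%s>\n", x$name, x$chain, x$seq,
              length(x$atom_names), if (is.null(x$ca)) ", no CA" else ""))
  invisible(x)
}

#' Construct a protein-ligand complex
#'
#' @param pdb_id identifier.
#' @param residues list of [fb_residue] (polymer protein residues).
#' @param ligands list of [fbmol] (HETATM ligands after deny-list exclusion).
#' @param hetero_other data.frame of remaining hetero atoms (ions, waters,
#'   buffers) kept for provenance, never entering environments by default.
#' @return object of class `fb_complex`.
#' @export
fb_complex <- function(pdb_id, residues, ligands = list(),
                       hetero_other = NULL) {
  structure(list(pdb_id = pdb_id, residues = residues, ligands = ligands,
                 hetero_other = hetero_other),
            class = "fb_complex")
}

#' @export
print.fb_complex <- function(x, ...) {
  cat(sprintf("<complex %s: %d residues, %d ligands, %d other hetero atoms>\n",
              x$pdb_id, length(x$residues), length(x$ligands),
              if (is.null(x$hetero_other)) 0L else nrow(x$hetero_other)))
  invisible(x)
}

#' All protein heavy-atom coordinates of a complex
#' @param cx an `fb_complex`.
#' @return numeric matrix (rows = atoms).
#' @export
protein_xyz <- function(cx) {
  do.call(rbind, lapply(cx$residues, function(r) r$xyz))
}

.infer_element <- function(elety, elesy) {
  el <- toupper(trimws(elesy))
  bad <- is.na(el) | el == ""
  if (any(bad)) {
    # fall back on the atom name: strip digits, try two- then one-letter symbol
    nm <- gsub("[0-9']", "", toupper(trimws(elety[bad])))
    two <- substr(nm, 1, 2)
    one <- substr(nm, 1, 1)
    el[bad] <- ifelse(two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "NA", "MN"),
                      two, one)
  }
  # normalise case (CL -> Cl)
  paste0(substr(el, 1, 1), tolower(substr(el, 2, nchar(el))))
}

# resolve alternate locations: keep the highest-occupancy conformer,
# ties broken by the alphabetically first altloc code
.resolve_altloc <- function(atm) {
  alt <- atm$alt
  alt[is.na(alt)] <- ""
  if (all(alt %in% c("", "A"))) return(atm[alt %in% c("", "A"), , drop = FALSE])
  key <- paste(atm$chain, atm$resno, atm$resid, atm$elety)
  keep <- rep(TRUE, nrow(atm))
  for (k in unique(key[duplicated(key)])) {
    rows <- which(key == k)
    occ <- atm$o[rows]; occ[is.na(occ)] <- 1
    best <- rows[order(-occ, alt[rows])][1]
    keep[setdiff(rows, best)] <- FALSE
  }
  atm[keep, , drop = FALSE]
}

#' Load a protein-ligand complex from a PDB file
#'
#' Polymer (ATOM) residues become protein residues; HETATM groups become
#' ligands unless their HET code is on the deny-list (waters, common ions and
#' buffer molecules), in which case they are kept in `hetero_other`. Alternate
#' locations are resolved to the highest-occupancy conformer, hydrogens are
#' dropped, and only the first NMR model is read. Ligand connectivity is
#' perceived from interatomic distances against covalent-radius sums (all
#' single bonds); supply ligands as SDF when bond orders matter.
#'
#' @param path PDB file.
#' @param ligand_selector optional character vector of HET codes to treat as
#'   ligands (overrides the deny-list policy); NULL for the default policy.
#' @return an [fb_complex].
#' @export
load_complex <- function(path, ligand_selector = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("cannot parse PDB file '", path,
                                           "': ", conditionMessage(e)))
  atm <- pdb$atom
  atm <- atm[.infer_element(atm$elety, atm$elesy) != "H", , drop = FALSE]
  atm$element <- .infer_element(atm$elety, atm$elesy)
  atm <- .resolve_altloc(atm)

  poly <- atm[atm$type == "ATOM", , drop = FALSE]
  if (nrow(poly) == 0) stop("no polymer chain in '", path, "'")
  key <- paste(poly$chain, poly$resno, poly$resid)
  residues <- lapply(split(seq_len(nrow(poly)), factor(key, levels = unique(key))),
    function(rows) {
      r <- poly[rows, , drop = FALSE]
      fb_residue(r$resid[1], r$chain[1], r$resno[1], r$elety, r$element,
                 cbind(r$x, r$y, r$z))
    })
  names(residues) <- NULL

  het <- atm[atm$type == "HETATM", , drop = FALSE]
  ligands <- list(); other <- NULL
  if (nrow(het) > 0) {
    grp <- paste(het$chain, het$resno, het$resid)
    is_lig <- if (is.null(ligand_selector)) !(het$resid %in% .HET_DENY)
              else het$resid %in% ligand_selector
    other <- het[!is_lig, c("resid", "chain", "resno", "elety", "element",
                            "x", "y", "z"), drop = FALSE]
    lg <- het[is_lig, , drop = FALSE]
    if (nrow(lg) > 0) {
      gk <- paste(lg$chain, lg$resno, lg$resid)
      ligands <- lapply(split(seq_len(nrow(lg)), factor(gk, levels = unique(gk))),
        function(rows) {
          m <- lg[rows, , drop = FALSE]
          xyz <- cbind(m$x, m$y, m$z)
          fbmol(m$element, xyz, perceive_bonds(m$element, xyz),
                name = m$resid[1])
        })
      names(ligands) <- NULL
    }
  }
  fb_complex(sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path)),
             residues, ligands, other)
}

# approximate single-bond covalent radii (Angstrom)
.COV_RADIUS <- c(C = 0.77, N = 0.70, O = 0.66, S = 1.04, P = 1.10, F = 0.64,
                 Cl = 0.99, Br = 1.14, I = 1.33, B = 0.85, Se = 1.17, Si = 1.11)

#' Perceive bonds from distances
#'
#' Two heavy atoms are bonded when their distance is below the sum of covalent
#' radii plus 0.45 A tolerance. Orders are all 1 (PDB carries no orders).
#' @param element element symbols.
#' @param xyz coordinate matrix.
#' @return bond matrix (i, j, order).
#' @export
perceive_bonds <- function(element, xyz) {
  n <- length(element)
  if (n < 2) return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("i", "j", "order"))))
  r <- .COV_RADIUS[element]; r[is.na(r)] <- 1.4
  d <- cross_dist(xyz, xyz)
  lim <- outer(r, r, "+") + 0.45
  hit <- which(d < lim & upper.tri(d) & d > 0.4, arr.ind = TRUE)
  matrix(c(hit[, 1], hit[, 2], rep(1L, nrow(hit))), ncol = 3,
         dimnames = list(NULL, c("i", "j", "order")))
}

#' Construct a FRASE
#'
#' A ligand fragment together with every protein residue having at least one
#' heavy atom within `env_radius` of the fragment.
#' @param fragment an [fbmol] (with optional attachment metadata).
#' @param environment list of [fb_residue].
#' @param env_radius environment cutoff in Angstrom (default 4.5).
#' @param source identifier of the originating complex.
#' @param label "true", "decoy", or NA for unscored target FRASEs.
#' @param id optional stable identifier.
#' @return object of class `frase`.
#' @export
frase <- function(fragment, environment, env_radius = 4.5, source = NA_character_,
                  label = NA_character_, id = NULL) {
  if (length(environment) == 0) stop("FRASE environment must be non-empty")
  structure(list(fragment = fragment, environment = environment,
                 env_radius = env_radius, source = source, label = label,
                 id = if (is.null(id)) paste0(source, ":", fragment$name) else id),
            class = "frase")
}

#' @export
print.frase <- function(x, ...) {
  cat(sprintf("<FRASE %s: fragment %s (%d atoms), %d environment residues, label=%s>\n",
              x$id, x$fragment$name, n_atoms(x$fragment),
              length(x$environment), x$label))
  invisible(x)
}

## ---- SDF dialect ---------------------------------------------------------
# One SDF V2000 record per FRASE. The fragment is the molecule block; the
# protein environment is serialised in the <FRASE_ENV> data field, one line
# per environment atom:
#   resname chain seq atom_name element x y z
# plus <FRASE_SOURCE>, <FRASE_LABEL>, <FRASE_ENV_RADIUS>, <FRASE_ID>.

.sdf_record <- function(fr) {
  m <- fr$fragment
  nb <- nrow(m$bonds)
  out <- c(m$name, "  frasebot", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_atoms(m), nb))
  out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                        m$xyz[, 1], m$xyz[, 2], m$xyz[, 3], m$element))
  if (nb > 0)
    out <- c(out, sprintf("%3d%3d%3d  0", m$bonds[, 1], m$bonds[, 2],
                          pmin(m$bonds[, 3], 4L)))
  chg <- which(m$charge != 0L)
  if (length(chg))
    out <- c(out, paste0("M  CHG", sprintf("%3d", length(chg)),
                         paste0(sprintf("%4d%4d", chg, m$charge[chg]),
                                collapse = "")))
  out <- c(out, "M  END")
  env_lines <- unlist(lapply(fr$environment, function(r)
    sprintf("%s %s %d %s %s %.4f %.4f %.4f", r$name, r$chain, r$seq,
            r$atom_names, r$element, r$xyz[, 1], r$xyz[, 2], r$xyz[, 3])))
  att <- attr(fr$fragment, "attachment_points")
  c(out,
    "> <FRASE_ID>", fr$id, "",
    "> <FRASE_SOURCE>", as.character(fr$source), "",
    "> <FRASE_LABEL>", as.character(fr$label), "",
    "> <FRASE_ENV_RADIUS>", format(fr$env_radius), "",
    if (length(att)) c("> <FRASE_ATTACHMENTS>", paste(att, collapse = " "), ""),
    "> <FRASE_ENV>", env_lines, "",
    "$$$$")
}

#' Write FRASEs to an SD file
#'
#' Streams records one at a time (constant memory in the number of FRASEs):
#' `frases` may be a list or a generator function returning one FRASE per call
#' and NULL when exhausted.
#' @param frases list of [frase] objects, or a zero-argument function yielding
#'   them one by one (NULL terminates).
#' @param path output file.
#' @return invisibly, the number of records written.
#' @export
write_frase_sdf <- function(frases, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  nxt <- if (is.function(frases)) frases else {
    i <- 0L
    function() { i <<- i + 1L; if (i <= length(frases)) frases[[i]] else NULL }
  }
  n <- 0L
  repeat {
    fr <- nxt()
    if (is.null(fr)) break
    writeLines(.sdf_record(fr), con)
    n <- n + 1L
  }
  invisible(n)
}

.parse_sdf_record <- function(lines) {
  cnt <- lines[4]
  na <- as.integer(substr(cnt, 1, 3)); nb <- as.integer(substr(cnt, 4, 6))
  if (is.na(na) || na < 1) stop("bad counts line")
  at <- lines[4 + seq_len(na)]
  xyz <- cbind(as.numeric(substr(at, 1, 10)), as.numeric(substr(at, 11, 20)),
               as.numeric(substr(at, 21, 30)))
  element <- trimws(substr(at, 31, 34))
  bonds <- matrix(integer(0), 0, 3)
  if (nb > 0) {
    bl <- lines[4 + na + seq_len(nb)]
    bonds <- cbind(as.integer(substr(bl, 1, 3)), as.integer(substr(bl, 4, 6)),
                   as.integer(substr(bl, 7, 9)))
  }
  charge <- integer(na)
  for (cl in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(substr(cl, 7, nchar(cl))), "\\s+")[[1]])
    nch <- toks[1]
    for (k in seq_len(nch)) charge[toks[2 * k]] <- toks[2 * k + 1]
  }
  fields <- list()
  hdr <- grep("^> *<", lines)
  for (h in hdr) {
    nm <- sub("^> *<([^>]+)>.*", "\\1", lines[h])
    end <- h
    while (end < length(lines) && nzchar(lines[end + 1]) &&
           !startsWith(lines[end + 1], "$$$$")) end <- end + 1
    fields[[nm]] <- lines[(h + 1):end]
  }
  env <- list()
  if (!is.null(fields$FRASE_ENV)) {
    toks <- strsplit(trimws(fields$FRASE_ENV), "\\s+")
    df <- do.call(rbind, toks)
    key <- paste(df[, 1], df[, 2], df[, 3])
    env <- lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
      function(rows)
        fb_residue(df[rows[1], 1], df[rows[1], 2], as.integer(df[rows[1], 3]),
                   df[rows, 4], df[rows, 5],
                   matrix(as.numeric(df[rows, 6:8]), ncol = 3)))
    names(env) <- NULL
  }
  frag <- fbmol(element, xyz, bonds, name = trimws(lines[1]), charge = charge)
  if (!is.null(fields$FRASE_ATTACHMENTS))
    attr(frag, "attachment_points") <-
      as.integer(strsplit(trimws(fields$FRASE_ATTACHMENTS[1]), "\\s+")[[1]])
  frase(frag, env,
        env_radius = as.numeric(fields$FRASE_ENV_RADIUS %||% 4.5),
        source = fields$FRASE_SOURCE %||% NA_character_,
        label = fields$FRASE_LABEL %||% NA_character_,
        id = fields$FRASE_ID %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stream FRASEs from an SD file
#'
#' Applies `fun` to each record in file order without holding the database in
#' memory. Malformed records are skipped with a warning and counted.
#' @param path SD file written by [write_frase_sdf] (or conforming dialect).
#' @param fun function of one [frase]; its return values are discarded unless
#'   `collect = TRUE`.
#' @param collect if TRUE, return the list of `fun` results.
#' @return if `collect`, a list; otherwise invisibly the number of records
#'   read. Attribute `skipped` carries the malformed-record count.
#' @export
frase_sdf_apply <- function(path, fun, collect = FALSE) {
  con <- file(path, open = "rt")
  on.exit(close(con))
  out <- if (collect) list() else NULL
  n <- 0L; skipped <- 0L
  buf <- character(0)
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0) {
      if (length(buf) >= 4) {  # truncated trailing record
        skipped <- skipped + 1L
        warning("skipping truncated trailing SDF record")
      }
      break
    }
    if (startsWith(ln, "$$$$")) {
      fr <- tryCatch(.parse_sdf_record(c(buf, "$$$$")), error = function(e) e)
      if (inherits(fr, "error")) {
        skipped <- skipped + 1L
        warning("skipping malformed SDF record: ", conditionMessage(fr))
      } else {
        n <- n + 1L
        if (collect) out[[n]] <- fun(fr) else fun(fr)
      }
      buf <- character(0)
    } else buf <- c(buf, ln)
  }
  res <- if (collect) out else invisible(n)
  attr(res, "skipped") <- skipped
  res
}

#' Read all FRASEs from an SD file
#'
#' Convenience wrapper over [frase_sdf_apply] returning the full list.
#' Coordinates are preserved to at least 3 decimals (the dialect writes 4).
#' @param path SD file.
#' @return list of [frase]; attribute `skipped` counts malformed records.
#' @export
read_frase_sdf <- function(path) {
  frase_sdf_apply(path, identity, collect = TRUE)
}
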