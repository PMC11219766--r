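# Residue-triplet fingerprints and the triplet index used to screen a FRASE
# database against a target protein.
#
# Each residue is encoded as a many-hot 11-bit string over
# [positive ionizable, negative ionizable, H-bond acceptor, H-bond donor,
#  aromatic, hydrophobic x3, volume x3].
# Three residues whose Calpha atoms form a near-equilateral triangle with all
# edges in [8, 12] A form a triplet; the six concatenation orders give six
# 33-bit strings whose lexicographic minimum is the order-invariant hash key.

# Rows follow the published 20-residue property table. As printed, the two
# charge columns are swapped for the five ionizable residues (the basic
# residues ARG/LYS/HIS carry the bit under "Negative ionizable":
#   ARG 01000, LYS 01000, HIS 01011, ASP 10000, GLU 10000).
# The shipped table assigns ARG/LYS/HIS -> positive, ASP/GLU -> negative;
# since the same table encodes both database and target, matching is
# unaffected by this choice.
.RESIDUE_BITS <- matrix(c(
  # pos neg hba hbd ar  hyd1 hyd2 hyd3 vol1 vol2 vol3
    0,  0,  0,  0,  0,  1,   0,   0,   1,   0,   0,  # ALA
    1,  0,  0,  0,  0,  0,   0,   0,   1,   1,   1,  # ARG
    0,  0,  1,  1,  0,  0,   0,   0,   1,   1,   0,  # ASN
    0,  1,  0,  0,  0,  0,   0,   0,   1,   1,   0,  # ASP
    0,  0,  1,  1,  0,  1,   1,   0,   1,   1,   0,  # CYS
    0,  1,  0,  0,  0,  0,   0,   0,   1,   1,   1,  # GLU
    0,  0,  1,  1,  0,  0,   0,   0,   1,   1,   0,  # GLN
    0,  0,  0,  0,  0,  0,   0,   0,   0,   0,   0,  # GLY
    1,  0,  0,  1,  1,  0,   0,   0,   1,   1,   0,  # HIS
    0,  0,  0,  0,  0,  1,   1,   0,   1,   1,   0,  # ILE
    0,  0,  0,  0,  0,  1,   1,   0,   1,   1,   0,  # LEU
    1,  0,  0,  0,  0,  0,   0,   0,   1,   1,   1,  # LYS
    0,  0,  0,  0,  0,  1,   1,   1,   1,   1,   1,  # MET
    0,  0,  0,  0,  1,  1,   1,   1,   1,   1,   1,  # PHE
    0,  0,  0,  0,  0,  1,   0,   0,   1,   0,   0,  # PRO
    0,  0,  1,  1,  0,  0,   0,   0,   1,   1,   0,  # SER
    0,  0,  1,  1,  0,  1,   1,   0,   1,   1,   0,  # THR
    0,  0,  0,  1,  1,  1,   1,   0,   1,   1,   1,  # TRP
    0,  0,  1,  1,  0,  1,   1,   0,   1,   1,   1,  # TYR
    0,  0,  0,  0,  0,  1,   1,   0,   1,   1,   0   # VAL
  ), nrow = 20, byrow = TRUE,
  dimnames = list(c("ALA", "ARG", "ASN", "ASP", "CYS", "GLU", "GLN", "GLY",
                    "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                    "THR", "TRP", "TYR", "VAL"),
                  c("pos", "neg", "hba", "hbd", "aromatic",
                    "hyd1", "hyd2", "hyd3", "vol1", "vol2", "vol3")))

.RESIDUE_BITSTR <- apply(.RESIDUE_BITS, 1, paste, collapse = "")

#' Many-hot property bits of a residue
#'
#' The 11-position encoding of a standard residue: positive/negative
#' ionizable, H-bond acceptor/donor, aromatic, then three hydrophobicity and
#' three volume positions (e.g. all six set for tryptophan-sized hydrophobes,
#' all zero for glycine).
#' @param code 3-letter amino-acid code (one of the 20 standard residues).
#' @return named integer vector of length 11 with attribute `string` (the
#'   11-character bit string).
#' @export
residue_bits <- function(code) {
  code <- toupper(code)
  if (!code %in% rownames(.RESIDUE_BITS))
    stop("untypable residue: ", code)
  out <- .RESIDUE_BITS[code, ]
  attr(out, "string") <- .RESIDUE_BITSTR[[code]]
  out
}

#' Enumerate residue triplets
#'
#' All 3-subsets of residues whose three pairwise Calpha distances lie in
#' `[edge_min, edge_max]` (inclusive) -- the operational reading of
#' "approximately equilateral, sides 8-12 A". Residues without a Calpha or
#' with a non-standard code are ineligible. Output order is deterministic
#' (ascending residue indices).
#'
#' @param residues list of [fb_residue].
#' @param edge_min,edge_max edge bounds in Angstrom.
#' @return list of triplets, each `list(idx, codes, ca, edges)` where `idx`
#'   indexes `residues`, `ca` is the 3x3 Calpha coordinate matrix and `edges`
#'   the pairwise distances (d12, d13, d23).
#' @export
enumerate_triplets <- function(residues, edge_min = 8, edge_max = 12) {
  ok <- vapply(residues, function(r)
    !is.null(r$ca) && r$name %in% rownames(.RESIDUE_BITS), logical(1))
  el <- which(ok)
  if (length(el) < 3) return(list())
  ca <- do.call(rbind, lapply(residues[el], `[[`, "ca"))
  d <- cross_dist(ca, ca)
  inb <- d >= edge_min & d <= edge_max
  n <- length(el)
  nbr <- lapply(seq_len(n), function(i) which(inb[i, ] & seq_len(n) > i))
  out <- list()
  for (i in seq_len(n)) {
    ni <- nbr[[i]]
    if (length(ni) < 2) next
    for (j in ni) {
      ks <- intersect(ni[ni > j], nbr[[j]])
      for (k in ks) {
        idx <- el[c(i, j, k)]
        out[[length(out) + 1L]] <- list(
          idx = idx,
          codes = vapply(residues[idx], `[[`, character(1), "name"),
          ca = ca[c(i, j, k), , drop = FALSE],
          edges = c(d[i, j], d[i, k], d[j, k]))
      }
    }
  }
  out
}

.PERMS3 <- matrix(c(1, 2, 3, 1, 3, 2, 2, 1, 3, 2, 3, 1, 3, 1, 2, 3, 2, 1),
                  ncol = 3, byrow = TRUE)

#' Order-invariant fingerprint key of a residue triplet
#'
#' Concatenates the three 11-bit residue strings in all six orders; the set of
#' distinct 33-bit strings is the triplet's fingerprint family and the
#' lexicographically smallest member is the canonical hash key. The key is
#' identical under any input ordering of the three residues.
#'
#' @param codes character vector of three 3-letter codes (or a triplet from
#'   [enumerate_triplets]).
#' @return list: `fps` (distinct permutation strings, sorted), `canonical`
#'   (the key), `canon_order` (the permutation of the input achieving it).
#' @export
triplet_key <- function(codes) {
  if (is.list(codes)) codes <- codes$codes
  if (length(codes) != 3) stop("need exactly three residues")
  bs <- .RESIDUE_BITSTR[toupper(codes)]
  if (anyNA(bs)) stop("untypable residue in triplet: ",
                      paste(codes[is.na(bs)], collapse = ", "))
  all6 <- apply(.PERMS3, 1, function(p) paste0(bs[p[1]], bs[p[2]], bs[p[3]]))
  canon <- min(all6)
  list(fps = sort(unique(all6)), canonical = canon,
       canon_order = .PERMS3[which(all6 == canon)[1], ])
}

#' Build a triplet index over a FRASE database
#'
#' Enumerates qualifying triplets in every FRASE environment and indexes them
#' under their canonical keys. FRASEs are accepted as a list or as a path to
#' an SD file (streamed).
#'
#' @param db list of [frase] objects or a path to a FRASE SD file.
#' @param edge_min,edge_max triplet edge bounds in Angstrom.
#' @return object of class `triplet_index`: `map` (hashed environment keyed
#'   by canonical string, values data of (frase id, triplet)), `n_frases`,
#'   `triplet_counts` (per-FRASE histogram data).
#' @export
build_index <- function(db, edge_min = 8, edge_max = 12) {
  map <- new.env(hash = TRUE, parent = emptyenv())
  counts <- integer(0)
  nf <- 0L
  ingest <- function(fr) {
    nf <<- nf + 1L
    trips <- enumerate_triplets(fr$environment, edge_min, edge_max)
    kept <- 0L
    for (ti in seq_along(trips)) {
      key <- tryCatch(triplet_key(trips[[ti]]), error = function(e) NULL)
      if (is.null(key)) next
      kept <- kept + 1L
      entry <- list(frase_id = fr$id, triplet = trips[[ti]],
                    canon_order = key$canon_order)
      map[[key$canonical]] <- c(map[[key$canonical]], list(entry))
    }
    counts[fr$id] <<- kept
  }
  if (is.character(db)) frase_sdf_apply(db, ingest) else lapply(db, ingest)
  structure(list(map = map, n_frases = nf, triplet_counts = counts,
                 edge_min = edge_min, edge_max = edge_max),
            class = "triplet_index")
}

#' @export
print.triplet_index <- function(x, ...) {
  cat(sprintf("<triplet index: %d FRASEs, %d distinct keys, %d triplets>\n",
              x$n_frases, length(ls(x$map)), sum(x$triplet_counts)))
  invisible(x)
}

#' Match target triplets against an index
#'
#' A target triplet matches a database triplet iff their canonical keys are
#' equal (exact bit-string equality). Each (target triplet, database triplet)
#' pair is reported once, with the Calpha correspondence fixed by the
#' canonicalising permutations of the two triplets.
#'
#' @param target_triplets list from [enumerate_triplets] on the target.
#' @param index a [build_index] result.
#' @return list of matches: `list(target_triplet, target_ca, frase_id,
#'   db_triplet, db_ca)` with `*_ca` rows in corresponding (canonical) order.
#' @export
match_target <- function(target_triplets, index) {
  out <- list()
  for (ti in seq_along(target_triplets)) {
    tt <- target_triplets[[ti]]
    key <- tryCatch(triplet_key(tt), error = function(e) NULL)
    if (is.null(key)) next
    hits <- index$map[[key$canonical]]
    for (h in hits) {
      out[[length(out) + 1L]] <- list(
        target_triplet = ti,
        target_ca = tt$ca[key$canon_order, , drop = FALSE],
        target_idx = tt$idx[key$canon_order],
        frase_id = h$frase_id,
        db_triplet = h$triplet,
        db_ca = h$triplet$ca[h$canon_order, , drop = FALSE])
    }
  }
  out
}

#' Count qualifying triplets in a PDB structure
#'
#' Benchmark helper: loads a structure, optionally restricts to one chain,
#' and counts residue triplets under the default geometry. Run on the
#' deposited CIB1 entry (PDB 6OCX, chain A) this reproduces the published
#' target-side enumeration.
#' @param path PDB file.
#' @param chain optional chain identifier.
#' @param edge_min,edge_max edge bounds in Angstrom.
#' @return integer triplet count.
#' @export
triplet_benchmark <- function(path, chain = NULL, edge_min = 8, edge_max = 12) {
  cx <- load_complex(path)
  res <- cx$residues
  if (!is.null(chain))
    res <- res[vapply(res, function(r) r$chain == chain, logical(1))]
  length(enumerate_triplets(res, edge_min, edge_max))
}
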