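# Screening: align matched FRASEs onto the target by their triplet Calpha
# atoms, seed the ligand fragments, re-cut target-based FRASEs and apply the
# collision / buriedness / fitness filters.

#' Least-squares rigid superposition of two 3-point sets
#'
#' Kabsch superposition with the correspondence fixed by the matched
#' permutation: returns the proper rotation R and translation t minimising
#' sum ||R p_i + t - q_i||^2 over the three Calpha pairs. Reflections are
#' never returned (determinant +1).
#'
#' @param db_ca 3x3 matrix of database Calpha coordinates (rows = points).
#' @param target_ca 3x3 matrix of target Calpha coordinates, row-corresponding.
#' @return object of class `fb_transform`: `rotation` (3x3), `translation`
#'   (length 3), `rmsd` (Angstrom).
#' @export
superpose_triplet <- function(db_ca, target_ca) {
  P <- matrix(as.numeric(db_ca), ncol = 3)
  Q <- matrix(as.numeric(target_ca), ncol = 3)
  if (nrow(P) != 3 || nrow(Q) != 3) stop("need exactly three points per set")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  # collinear points leave the in-plane normal unconstrained
  if (sqrt(sum(.cross3(P0[2, ] - P0[1, ], P0[3, ] - P0[1, ])^2)) < 1e-8 ||
      sqrt(sum(.cross3(Q0[2, ] - Q0[1, ], Q0[3, ] - Q0[1, ])^2)) < 1e-8)
    stop("degenerate triplet: collinear Calpha atoms")
  H <- crossprod(P0, Q0)           # sum_i p_i q_i^T
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cq - as.numeric(R %*% cp)
  moved <- sweep(P %*% t(R), 2, -tr)
  structure(list(rotation = R, translation = tr,
                 rmsd = sqrt(mean(rowSums((moved - Q)^2)))),
            class = "fb_transform")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.fb_transform <- function(x, ...) {
  cat(sprintf("<rigid transform: rmsd %.3f A>\n", x$rmsd))
  invisible(x)
}

#' Filter thresholds for seeded fragments
#'
#' @param clash_min minimum allowed fragment-protein heavy-atom distance in
#'   Angstrom (collision filter; default 1.0).
#' @param burial_radius radius of the buriedness count in Angstrom (default 5).
#' @param burial_min_mean minimum mean number of protein heavy atoms within
#'   `burial_radius` per fragment atom (default 5).
#' @param fitness_min minimum nativeness score (default 0.4).
#' @param rmsd_max optional gate on the triplet superposition residual in
#'   Angstrom (default 1.0); bit-string equality does not guarantee geometric
#'   congruence within the 8-12 A edge bounds, and grossly distorted
#'   alignments are pointless to score. Set to `Inf` to disable.
#' @return object of class `filter_config`.
#' @export
filter_config <- function(clash_min = 1.0, burial_radius = 5.0,
                          burial_min_mean = 5.0, fitness_min = 0.4,
                          rmsd_max = 1.0) {
  stopifnot(clash_min > 0, burial_radius > 0, burial_min_mean > 0,
            fitness_min > 0)
  structure(list(clash_min = clash_min, burial_radius = burial_radius,
                 burial_min_mean = burial_min_mean, fitness_min = fitness_min,
                 rmsd_max = rmsd_max),
            class = "filter_config")
}

#' Seed a FRASE's fragment into the target frame
#'
#' Maps the fragment by the triplet-derived transform and recomputes the
#' collision and buriedness statistics against all target protein heavy atoms
#' (statistics are never copied from the source complex).
#'
#' @param fr a [frase].
#' @param transform an [superpose_triplet] result for a matched triplet of
#'   this FRASE.
#' @param target an [fb_complex].
#' @param burial_radius buriedness count radius in Angstrom.
#' @return object of class `fb_seeded`: the transplanted `fragment`,
#'   `provenance`, `min_clash_dist`, `mean_burial`, `fitness` (NA until
#'   scored).
#' @export
seed_fragment <- function(fr, transform, target, burial_radius = 5.0) {
  frag <- transform_mol(fr$fragment, transform$rotation, transform$translation)
  pxyz <- protein_xyz(target)
  d <- cross_dist(frag$xyz, pxyz)
  structure(list(
    fragment = frag,
    provenance = list(frase_id = fr$id, source = fr$source,
                      transform = transform),
    min_clash_dist = min(d),
    mean_burial = mean(rowSums(d <= burial_radius)),
    fitness = NA_real_),
    class = "fb_seeded")
}

#' @export
print.fb_seeded <- function(x, ...) {
  cat(sprintf(
    "<seeded fragment from %s: min clash %.2f A, mean burial %.1f, fitness %s>\n",
    x$provenance$frase_id, x$min_clash_dist, x$mean_burial,
    if (is.na(x$fitness)) "unscored" else sprintf("%.3f", x$fitness)))
  invisible(x)
}

#' Cut a target-based FRASE around a seeded fragment
#'
#' The transplanted fragment is merged with all target residues having at
#' least one heavy atom within `env_radius` (inclusive): the new FRASE's
#' environment comes from the target, and its label is unset pending scoring.
#'
#' @param sf an [seed_fragment] result.
#' @param target an [fb_complex].
#' @param env_radius cutoff in Angstrom (default 4.5).
#' @return a [frase], or NULL when the environment is empty (fragment seeded
#'   away from the protein).
#' @export
cut_target_frase <- function(sf, target, env_radius = 4.5) {
  idx <- environment_residues(sf$fragment, target$residues, env_radius)
  if (length(idx) == 0) return(NULL)
  frase(sf$fragment, target$residues[idx], env_radius = env_radius,
        source = target$pdb_id, label = NA_character_,
        id = paste0(target$pdb_id, "<-", sf$provenance$frase_id))
}

#' Apply collision, buriedness and fitness filters
#'
#' Retains a seeded fragment iff `min_clash_dist >= clash_min` and
#' `mean_burial >= burial_min_mean` and `fitness >= fitness_min` (all
#' inclusive). Each rejection reason is recorded.
#'
#' @param sfs list of scored [fb_seeded] objects.
#' @param cfg a [filter_config].
#' @return surviving subset; attribute `rejections` is a data.frame of
#'   (frase_id, reason) rows for the rejected poses.
#' @export
filter_seeded <- function(sfs, cfg = filter_config()) {
  keep <- logical(length(sfs))
  rej_id <- character(0); rej_why <- character(0)
  for (i in seq_along(sfs)) {
    sf <- sfs[[i]]
    why <- character(0)
    if (sf$min_clash_dist < cfg$clash_min) why <- c(why, "collision")
    if (sf$mean_burial < cfg$burial_min_mean) why <- c(why, "not_buried")
    if (is.na(sf$fitness) || sf$fitness < cfg$fitness_min)
      why <- c(why, "low_fitness")
    if (length(why) == 0) keep[i] <- TRUE
    else {
      rej_id <- c(rej_id, sf$provenance$frase_id)
      rej_why <- c(rej_why, paste(why, collapse = "+"))
    }
  }
  out <- sfs[keep]
  attr(out, "rejections") <- data.frame(frase_id = rej_id, reason = rej_why,
                                        stringsAsFactors = FALSE)
  out
}

#' Screen a FRASE database against a target protein
#'
#' The full match -> align -> seed -> re-cut -> score -> filter cascade.
#' Returns the surviving seeded fragments together with the attrition funnel
#' (matches, seeded poses, collision/burial survivors, fitness survivors).
#'
#' @param target an [fb_complex] (apo or holo; ligands are ignored).
#' @param db list of [frase] objects or path to a FRASE SD file.
#' @param model optional nativeness model from [train_model]; without it the
#'   fitness filter is skipped and fragments are returned unscored.
#' @param cfg a [filter_config].
#' @param index optional prebuilt [build_index] over `db` (built on the fly
#'   otherwise).
#' @param edge_min,edge_max triplet edge bounds in Angstrom.
#' @return list: `survivors` (list of [fb_seeded] with `target_frase`
#'   attached), `funnel` (named integer vector), `rejections`.
#' @export
screen_target <- function(target, db, model = NULL, cfg = filter_config(),
                          index = NULL, edge_min = 8, edge_max = 12) {
  if (is.character(db)) db <- read_frase_sdf(db)
  by_id <- stats::setNames(db, vapply(db, `[[`, character(1), "id"))
  if (is.null(index)) index <- build_index(db, edge_min, edge_max)
  tt <- enumerate_triplets(target$residues, edge_min, edge_max)
  matches <- match_target(tt, index)

  seeded <- list()
  for (m in matches) {
    tr <- tryCatch(superpose_triplet(m$db_ca, m$target_ca),
                   error = function(e) NULL)
    if (is.null(tr) || tr$rmsd > cfg$rmsd_max) next
    sf <- seed_fragment(by_id[[m$frase_id]], tr, target, cfg$burial_radius)
    tf <- cut_target_frase(sf, target)
    if (is.null(tf)) next
    sf$target_frase <- tf
    seeded[[length(seeded) + 1L]] <- sf
  }

  if (!is.null(model))
    for (i in seq_along(seeded))
      seeded[[i]]$fitness <- score_frase(model, seeded[[i]]$target_frase)

  pre <- Filter(function(sf) sf$min_clash_dist >= cfg$clash_min &&
                             sf$mean_burial >= cfg$burial_min_mean, seeded)
  survivors <- if (is.null(model)) pre else filter_seeded(seeded, cfg)

  list(survivors = survivors,
       funnel = c(target_triplets = length(tt), matches = length(matches),
                  seeded = length(seeded),
                  collision_burial = length(pre),
                  fitness = if (is.null(model)) NA_integer_
                            else length(survivors)),
       rejections = attr(survivors, "rejections"))
}
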