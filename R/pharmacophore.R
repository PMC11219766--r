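# Pharmacophore condensation: perceive typed 3D features on surviving
# fragments, cluster them per type under a diameter bound, rank clusters and
# assemble an exportable query.

.PHARM_TYPES <- c("HBA", "HBD", "Pos", "Neg", "Ar", "Hyd")

#' Perceive pharmacophoric features of a fragment
#'
#' Six feature types: Ar at aromatic-ring centroids; Hyd at the centroids of
#' connected groups of two or more non-aromatic carbons; HBA/HBD at acceptor
#' and donor atoms; Pos at basic amine nitrogens; Neg at the centroid of
#' carboxylate (and phosphate) oxygen pairs. Perception reuses the ligand
#' atom-type rules of [type_atoms_ligand].
#'
#' @param fragment an [fbmol] in the target frame.
#' @param source identifier recorded on each feature (e.g. seeded-pose id).
#' @return data.frame with columns ftype, x, y, z, source (possibly 0 rows).
#' @export
perceive_features <- function(fragment, source = fragment$name) {
  V <- ligand_type_vocab()
  types <- type_atoms_ligand(fragment)
  has <- function(i, nm) match(nm, V) %in% types[[i]]
  feats <- list()
  add <- function(ftype, pos) feats[[length(feats) + 1L]] <<-
    data.frame(ftype = ftype, x = pos[1], y = pos[2], z = pos[3],
               source = source, stringsAsFactors = FALSE)

  ar <- aromatic_atoms(fragment)
  for (ring in mol_rings(fragment))
    if (all(ar[ring])) add("Ar", colMeans(fragment$xyz[ring, , drop = FALSE]))

  # hydrophobic aliphatic: connected components of non-aromatic carbons
  ali <- which(fragment$element == "C" & !ar)
  if (length(ali) >= 2) {
    keep <- fragment$bonds[, 1] %in% ali & fragment$bonds[, 2] %in% ali
    g <- igraph::graph_from_edgelist(
      matrix(match(fragment$bonds[keep, 1:2], ali), ncol = 2),
      directed = FALSE)
    if (igraph::vcount(g) < length(ali))
      g <- igraph::add_vertices(g, length(ali) - igraph::vcount(g))
    comp <- igraph::components(g)$membership
    for (cid in unique(comp)) {
      grp <- ali[comp == cid]
      if (length(grp) >= 2)
        add("Hyd", colMeans(fragment$xyz[grp, , drop = FALSE]))
    }
  }

  for (i in seq_len(n_atoms(fragment))) {
    if (has(i, "H-bond Acceptor")) add("HBA", fragment$xyz[i, ])
    if (has(i, "H-bond Donor")) add("HBD", fragment$xyz[i, ])
    if (has(i, "Positive Ionizable") && fragment$element[i] == "N")
      add("Pos", fragment$xyz[i, ])
  }
  # Neg at the centroid of each carboxylate/phosphate oxygen group (grouped
  # by their shared central atom)
  neg_o <- which(vapply(seq_len(n_atoms(fragment)), function(i)
    has(i, "Negative Ionizable") && fragment$element[i] == "O", logical(1)))
  if (length(neg_o)) {
    adj <- adjacency(fragment)
    centre <- vapply(neg_o, function(i) adj[[i]][1], numeric(1))
    for (ct in unique(centre)) {
      grp <- neg_o[centre == ct]
      add("Neg", colMeans(fragment$xyz[grp, , drop = FALSE]))
    }
  }
  if (length(feats) == 0)
    return(data.frame(ftype = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), source = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, feats)
}

#' Perceive features over a set of seeded fragments
#' @param sfs list of [fb_seeded] objects (or bare [fbmol] fragments).
#' @return combined feature data.frame.
#' @export
perceive_features_all <- function(sfs) {
  out <- lapply(seq_along(sfs), function(i) {
    m <- if (inherits(sfs[[i]], "fb_seeded")) sfs[[i]]$fragment else sfs[[i]]
    perceive_features(m, source = sprintf("pose%03d", i))
  })
  do.call(rbind, out)
}

.cluster_diameter <- function(xyz) {
  if (nrow(xyz) < 2) return(0)
  max(stats::dist(xyz))
}

#' Cluster features by type under a diameter bound
#'
#' Per feature type, k-means with k grown from 1 until every cluster's
#' pairwise member diameter is at most `max_diameter` (3 A default). Restarts
#' and seed are fixed for determinism. All types are pooled in the returned
#' list; cluster ids are assigned in pool order.
#'
#' @param features data.frame from [perceive_features] / ..._all.
#' @param max_diameter diameter bound in Angstrom.
#' @param restarts k-means restarts (`nstart`).
#' @param seed RNG seed.
#' @return list of clusters: `list(id, ftype, members, centroid, size,
#'   diameter, density)` with `density = size / (1 + mean member-centroid
#'   distance)`.
#' @export
cluster_features <- function(features, max_diameter = 3, restarts = 10L,
                             seed = 1L) {
  stopifnot(nrow(features) >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  clusters <- list()
  for (tp in intersect(.PHARM_TYPES, unique(features$ftype))) {
    rows <- which(features$ftype == tp)
    xyz <- as.matrix(features[rows, c("x", "y", "z")])
    n_uni <- nrow(unique(xyz))
    assign_k <- NULL
    for (k in seq_len(n_uni)) {
      if (k >= n_uni) break  # one cluster per distinct point (diameter 0)
      km <- if (k == 1) list(cluster = rep(1L, nrow(xyz)))
            else suppressWarnings(stats::kmeans(xyz, centers = k,
                                                nstart = restarts))
      dia <- vapply(split(seq_len(nrow(xyz)), km$cluster), function(m)
        .cluster_diameter(xyz[m, , drop = FALSE]), numeric(1))
      if (all(dia <= max_diameter)) { assign_k <- km$cluster; break }
    }
    if (is.null(assign_k)) assign_k <- match(
      apply(xyz, 1, paste, collapse = ","),
      unique(apply(xyz, 1, paste, collapse = ",")))
    for (cid in sort(unique(assign_k))) {
      m <- rows[assign_k == cid]
      cxyz <- as.matrix(features[m, c("x", "y", "z")])
      centroid <- colMeans(cxyz)
      dists <- sqrt(rowSums(sweep(cxyz, 2, centroid)^2))
      clusters[[length(clusters) + 1L]] <- list(
        id = length(clusters) + 1L, ftype = tp, members = m,
        centroid = centroid, size = length(m),
        diameter = .cluster_diameter(cxyz),
        density = length(m) / (1 + mean(dists)))
    }
  }
  clusters
}

#' Rank feature clusters
#'
#' Most populous first; ties broken by density (descending) then by cluster
#' id -- a total, deterministic order. The most populous/dense centroids are
#' the candidate query components (top 10 by default downstream).
#' @param clusters list from [cluster_features].
#' @return the same clusters, reordered; each gains a `rank` element.
#' @export
rank_clusters <- function(clusters) {
  sz <- vapply(clusters, `[[`, numeric(1), "size")
  dn <- vapply(clusters, `[[`, numeric(1), "density")
  id <- vapply(clusters, `[[`, numeric(1), "id")
  ord <- order(-sz, -dn, id)
  out <- clusters[ord]
  for (i in seq_along(out)) out[[i]]$rank <- i
  out
}

#' Assemble a pharmacophore query from chosen clusters
#'
#' @param clusters ranked cluster list.
#' @param picks indices into `clusters` of the centroids to retain (the
#'   choice is the user's; see the automated heuristic in [run_pipeline]).
#' @param tolerance matching radius per feature in Angstrom (default 1.0).
#' @return object of class `pharm_query`: data.frame `features` (ftype,
#'   x, y, z, tolerance, cluster_id, rank) plus provenance.
#' @export
build_query <- function(clusters, picks, tolerance = 1.0) {
  if (length(picks) == 0) stop("empty centroid choice")
  rows <- lapply(clusters[picks], function(cl)
    data.frame(ftype = cl$ftype, x = cl$centroid[1], y = cl$centroid[2],
               z = cl$centroid[3], tolerance = tolerance,
               cluster_id = cl$id, rank = cl$rank %||% NA_integer_,
               stringsAsFactors = FALSE))
  structure(list(features = do.call(rbind, rows)), class = "pharm_query")
}

#' @export
print.pharm_query <- function(x, ...) {
  tab <- table(x$features$ftype)
  cat(sprintf("<pharmacophore query: %d features (%s)>\n",
              nrow(x$features),
              paste(names(tab), tab, sep = "x", collapse = ", ")))
  invisible(x)
}

#' Export a pharmacophore query
#'
#' Two plain-text forms: a JSON schema (`type`, `xyz`, `tolerance`,
#' provenance) and a generic whitespace table (`type x y z tolerance`, one
#' feature per line) digestible by common screening tools.
#' @param query a [build_query] result.
#' @param path output file; format from extension (".json" or anything else
#'   for the table form).
#' @return invisibly `path`.
#' @export
write_query <- function(query, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(features = query$features), path, digits = NA, dataframe = "rows")
  } else {
    writeLines(c("# pharmacophore query: type x y z tolerance_A",
                 sprintf("%-4s %10.4f %10.4f %10.4f %6.2f",
                         query$features$ftype, query$features$x,
                         query$features$y, query$features$z,
                         query$features$tolerance)), path)
  }
  invisible(path)
}

#' Read a pharmacophore query written by [write_query]
#' @param path JSON file.
#' @return a `pharm_query`.
#' @export
read_query <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(features = as.data.frame(obj$features)),
            class = "pharm_query")
}
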