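# End-to-end pipeline: screen -> score -> filter -> features -> clusters ->
# query, with a machine-checkable attrition funnel.

#' Pipeline configuration
#'
#' Aggregates every threshold of the workflow with its standard default:
#' environment radius 4.5 A; triplet edges in [8, 12] A; collision minimum
#' 1 A; buriedness 5 protein atoms within 5 A; fitness 0.4; cluster diameter
#' 3 A; 2 decoys per true FRASE; network 32/16 hidden nodes, 500 epochs,
#' batch 50.
#'
#' @param env_radius,edge_min,edge_max,clash_min,burial_radius,burial_min_mean,fitness_min,cluster_max_diameter,decoys_per_frase,hidden,epochs,batch,rmsd_max,query_tolerance,top_clusters,seed
#'   see Description; each overridable.
#' @return object of class `pipeline_config`; its configuration hash (over
#'   all fields) is recorded in pipeline outputs.
#' @export
pipeline_config <- function(env_radius = 4.5, edge_min = 8, edge_max = 12,
                            clash_min = 1.0, burial_radius = 5.0,
                            burial_min_mean = 5.0, fitness_min = 0.4,
                            cluster_max_diameter = 3.0,
                            decoys_per_frase = 2L, hidden = c(32L, 16L),
                            epochs = 500L, batch = 50L, rmsd_max = 1.0,
                            query_tolerance = 1.0, top_clusters = 10L,
                            seed = 1L) {
  cfg <- list(env_radius = env_radius, edge_min = edge_min,
              edge_max = edge_max, clash_min = clash_min,
              burial_radius = burial_radius,
              burial_min_mean = burial_min_mean, fitness_min = fitness_min,
              cluster_max_diameter = cluster_max_diameter,
              decoys_per_frase = as.integer(decoys_per_frase),
              hidden = as.integer(hidden), epochs = as.integer(epochs),
              batch = as.integer(batch), rmsd_max = rmsd_max,
              query_tolerance = query_tolerance,
              top_clusters = as.integer(top_clusters),
              seed = as.integer(seed))
  key <- utf8ToInt(paste(unlist(cfg), collapse = "|"))
  cfg$hash <- sprintf("%08x", sum(key * seq_along(key)) %% .Machine$integer.max)
  structure(cfg, class = "pipeline_config")
}

#' Run the full hit-finding pipeline
#'
#' Screens the FRASE database against the target, scores seeded fragments
#' when a model is supplied, applies the filters, perceives and clusters
#' pharmacophoric features, and assembles a query from the top-ranked
#' clusters. Every stage count is reported in the funnel (seeded ->
#' collision/burial survivors -> fitness survivors -> features -> clusters
#' -> query features), and one JSON line per stage is written to `log_path`
#' when given.
#'
#' @param target an [fb_complex] or path to a PDB file.
#' @param db list of [frase] objects or path to a FRASE SD file.
#' @param model optional [train_model] result (or [mlp_load]-compatible
#'   path); without it the fitness stage is skipped.
#' @param cfg a [pipeline_config].
#' @param picks explicit cluster picks for the query (indices into the
#'   ranked cluster list); default: the top clusters up to four.
#' @param log_path optional JSON-lines log file.
#' @return list: `survivors`, `features`, `clusters` (ranked), `query`,
#'   `funnel` (named integer vector), `config_hash`.
#' @export
run_pipeline <- function(target, db, model = NULL, cfg = pipeline_config(),
                         picks = NULL, log_path = NULL) {
  if (is.character(target)) target <- load_complex(target)
  logcon <- if (!is.null(log_path)) file(log_path, "wt") else NULL
  if (!is.null(logcon)) on.exit(close(logcon))
  stage <- function(name, count) {
    if (!is.null(logcon))
      writeLines(jsonlite::toJSON(list(stage = name, count = count,
                                       config = cfg$hash),
                                  auto_unbox = TRUE), logcon)
    count
  }

  scr <- screen_target(target, db, model = model,
                       cfg = filter_config(cfg$clash_min, cfg$burial_radius,
                                           cfg$burial_min_mean,
                                           cfg$fitness_min, cfg$rmsd_max),
                       edge_min = cfg$edge_min, edge_max = cfg$edge_max)
  stage("seeded", scr$funnel[["seeded"]])
  stage("collision_burial", scr$funnel[["collision_burial"]])
  stage("fitness", length(scr$survivors))

  if (length(scr$survivors) == 0) {
    warning("empty funnel: no surviving fragments")
    return(list(survivors = list(), features = NULL, clusters = list(),
                query = NULL,
                funnel = c(scr$funnel, features = 0L, clusters = 0L,
                           query_features = 0L),
                config_hash = cfg$hash))
  }

  feats <- perceive_features_all(scr$survivors)
  stage("features", nrow(feats))
  clusters <- rank_clusters(cluster_features(
    feats, max_diameter = cfg$cluster_max_diameter, seed = cfg$seed))
  stage("clusters", length(clusters))
  top <- clusters[seq_len(min(cfg$top_clusters, length(clusters)))]
  if (is.null(picks)) picks <- seq_len(min(4L, length(top)))
  query <- build_query(top, picks, tolerance = cfg$query_tolerance)
  stage("query_features", nrow(query$features))

  list(survivors = scr$survivors, features = feats, clusters = clusters,
       query = query,
       funnel = c(scr$funnel, features = nrow(feats),
                  clusters = length(clusters),
                  query_features = nrow(query$features)),
       config_hash = cfg$hash)
}
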