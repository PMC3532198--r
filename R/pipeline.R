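#' Run the full biomarker-prioritisation pipeline on synthetic data
#'
#' Chains every stage from one configuration and one seed: simulate EST
#' libraries, run the two DDD contrasts (reference tissue vs other tissues,
#' then diseased vs reference), intersect and subtract candidates, simulate
#' an ontology and annotations, score candidates against a reference gene
#' list by GO similarity, cluster with multiscale bootstrap support, and
#' assemble biomarker panels. Intended as the reproducible end-to-end
#' driver for synthetic studies and as executable documentation of how the
#' stages fit together.
#'
#' @param config a [simulation_config()].
#' @param reference_genes optional reference (tissue-specific) gene list;
#'   defaults to the planted group members.
#' @param exclusion optional pan-disease exclusion list applied after the
#'   contrast intersection.
#' @param id_mapping optional identifier mapping data.frame
#'   (`source`, `canonical`).
#' @param min_fold DDD fold filter (default 2).
#' @param nboot,scales,alpha bootstrap replicates, resample scales and AU
#'   threshold for cluster selection.
#' @return list with the artifacts of every stage: `sim`, `ddd1`, `ddd2`,
#'   `candidates`, `annotation`, `ontology`, `similarity`, `bootclust`,
#'   `clusters`, `panels`, and the provenance log.
#' @export
run_pipeline <- function(config, reference_genes = NULL, exclusion = NULL,
                         id_mapping = NULL, min_fold = 2, nboot = 1000,
                         scales = seq(0.5, 1.4, by = 0.1), alpha = 0.95) {
  stopifnot(inherits(config, "simulation_config"))
  sim <- simulate_libraries(config)
  libs <- sim$table
  other <- unique(libs$library_id[libs$condition == "other"])
  ref <- sim$manifest$A
  qry <- sim$manifest$B
  if (!length(other))
    stop_("pipeline needs other-tissue libraries for the first contrast")
  # contrast 1: reference tissue vs other tissues (test pool = tissue)
  man1 <- pool_manifest(A = ref, B = other,
                        roles = c(A = "reference", B = "query"),
                        test_pool = "A")
  # contrast 2: diseased vs reference tissue (test pool = diseased)
  man2 <- pool_manifest(A = ref, B = qry, test_pool = "B")
  ddd1 <- run_ddd(libs, man1, min_fold = min_fold)
  ddd2 <- run_ddd(libs, man2, min_fold = min_fold)

  cand <- intersect_contrasts(ddd1, ddd2)
  if (!is.null(exclusion)) cand <- exclude_genes(cand, exclusion)
  if (!is.null(id_mapping)) cand <- map_identifiers(cand, id_mapping)

  graph <- simulate_ontology(config)
  ann <- simulate_annotations(config, graph)
  reference_genes <- reference_genes %||% names(ann$truth$groups)

  candidates <- cand$ids
  if (length(candidates) < 3) {
    # small synthetic runs may intersect to too few genes to cluster;
    # fall back to clustering the planted group members
    candidates <- names(ann$truth$groups)
  }
  sim_matrix <- build_similarity_matrix(candidates, reference_genes,
                                        ann$annotation, graph)
  bc <- multiscale_bootstrap(sim_matrix, nboot = nboot, scales = scales,
                             seed = config$seed)
  clusters <- pick_clusters(bc, alpha = alpha)
  panels <- assemble_panels(clusters, cand$ids, ddd1, ddd2)
  list(sim = sim, ddd1 = ddd1, ddd2 = ddd2, candidates = cand,
       ontology = graph, annotation = ann$annotation,
       group_truth = ann$truth, similarity = sim_matrix, bootclust = bc,
       clusters = clusters, panels = panels, provenance = cand$log)
}
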