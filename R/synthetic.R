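#' Configuration for the synthetic EST / ontology generator
#'
#' Bundles every knob of the generator with one mandatory seed so that all
#' three simulators are reproducible from a single value. The defaults give
#' a desk-scale study: 300 genes, 6 reference + 6 query + 20 other-tissue
#' libraries of 20k-50k ESTs each — far below a real EST compendium but
#' structurally identical to a two-contrast pooled design.
#'
#' @param seed integer seed (mandatory).
#' @param n_genes number of genes in the universe.
#' @param n_ref_libs,n_query_libs,n_other_libs library counts for the
#'   reference (normal target tissue), query (diseased target tissue) and
#'   other-tissue conditions.
#' @param library_total_range integer interval the per-library sequencing
#'   depth is drawn from (uniformly).
#' @param de_genes `NULL` to auto-plant `n_de` genes, or a data.frame with
#'   columns `gene_id`, `fold` (> 1), `direction` (`"up"`/`"down"`).
#' @param n_de number of auto-planted differential genes.
#' @param de_fold planted fold for auto-planted genes.
#' @param dirichlet_conc symmetric Dirichlet concentration for the baseline
#'   gene proportions; 0.5 gives the realistic skew of transcript abundance.
#' @param namespaces ontology namespaces to simulate.
#' @param ontology_terms_per_namespace terms per namespace (>= 2).
#' @param n_groups number of planted functionally coherent gene groups.
#' @param genes_per_group group size.
#' @param terms_per_gene_mean Poisson mean of annotations per gene per
#'   namespace.
#' @param group_leakage probability that a group gene's annotation is drawn
#'   from the whole namespace instead of its group branch.
#' @return a `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_genes = 300,
                              n_ref_libs = 6, n_query_libs = 6,
                              n_other_libs = 20,
                              library_total_range = c(20000L, 50000L),
                              de_genes = NULL, n_de = 10, de_fold = 5,
                              dirichlet_conc = 0.5,
                              namespaces = c("BP", "MF", "CC"),
                              ontology_terms_per_namespace = 40,
                              n_groups = 2, genes_per_group = 8,
                              terms_per_gene_mean = 4,
                              group_leakage = 0) {
  if (missing(seed)) stop_("a seed is mandatory")
  stopifnot(length(seed) == 1, is.finite(seed))
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_ref_libs = as.integer(n_ref_libs),
              n_query_libs = as.integer(n_query_libs),
              n_other_libs = as.integer(n_other_libs),
              library_total_range = as.integer(library_total_range),
              de_genes = de_genes, n_de = as.integer(n_de),
              de_fold = de_fold, dirichlet_conc = dirichlet_conc,
              namespaces = .ns_short(namespaces),
              ontology_terms_per_namespace =
                as.integer(ontology_terms_per_namespace),
              n_groups = as.integer(n_groups),
              genes_per_group = as.integer(genes_per_group),
              terms_per_gene_mean = terms_per_gene_mean,
              group_leakage = group_leakage)
  with(cfg, {
    stopifnot(n_genes > 0, n_ref_libs > 0, n_query_libs > 0,
              n_other_libs >= 0,
              length(library_total_range) == 2,
              library_total_range[1] > 0,
              library_total_range[2] >= library_total_range[1],
              dirichlet_conc > 0, ontology_terms_per_namespace >= 2,
              n_groups >= 0, genes_per_group > 0,
              terms_per_gene_mean > 0,
              group_leakage >= 0, group_leakage <= 1)
  })
  if (!is.null(cfg$de_genes)) {
    de <- as.data.frame(cfg$de_genes)
    stopifnot(all(c("gene_id", "fold", "direction") %in% names(de)))
    if (any(de$fold <= 1)) stop_("planted folds must exceed 1")
    if (!all(de$direction %in% c("up", "down")))
      stop_("planted directions must be 'up' or 'down'")
    cfg$de_genes <- de
  }
  structure(cfg, class = "simulation_config")
}

.gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Simulate pooled EST libraries with planted differential genes
#'
#' Baseline gene proportions are drawn from a symmetric Dirichlet; each
#' library draws its depth uniformly from `library_total_range` and its
#' gene counts from a multinomial (fixed sequencing depth, as in real EST
#' libraries). In query-condition libraries each planted gene's proportion
#' is multiplied (up) or divided (down) by its fold before renormalisation.
#' Reference and other-tissue libraries sample the unmodified baseline.
#'
#' @param config a [simulation_config()].
#' @return list with `table` (a [library_table()]; zero-count rows are not
#'   tabulated), `manifest` (a [pool_manifest()]: pool A = reference, pool
#'   B = query, test pool B) and `truth` (a `ground_truth` with the planted
#'   DE table and the baseline proportions).
#' @export
simulate_libraries <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  genes <- .gene_ids(config$n_genes)
  theta <- stats::rgamma(config$n_genes, shape = config$dirichlet_conc)
  theta <- theta / sum(theta)
  names(theta) <- genes

  de <- config$de_genes
  if (is.null(de)) {
    n_de <- min(config$n_de, config$n_genes)
    de <- data.frame(gene_id = sample(genes, n_de),
                     fold = rep(config$de_fold, n_de),
                     direction = rep(c("up", "down"), length.out = n_de),
                     stringsAsFactors = FALSE)
  }
  unk <- setdiff(de$gene_id, genes)
  if (length(unk)) stop_("planted DE gene not in gene universe: ",
                         paste(unk, collapse = ", "))
  theta_q <- theta
  mult <- ifelse(de$direction == "up", de$fold, 1 / de$fold)
  theta_q[de$gene_id] <- theta_q[de$gene_id] * mult
  theta_q <- theta_q / sum(theta_q)

  libs <- data.frame(
    library_id = c(sprintf("REF%02d", seq_len(config$n_ref_libs)),
                   sprintf("QRY%02d", seq_len(config$n_query_libs)),
                   if (config$n_other_libs > 0)
                     sprintf("OTH%02d", seq_len(config$n_other_libs))),
    condition = c(rep("reference", config$n_ref_libs),
                  rep("query", config$n_query_libs),
                  rep("other", config$n_other_libs)),
    stringsAsFactors = FALSE)
  other_tissues <- c("brain", "liver", "kidney", "heart", "muscle",
                     "testis", "placenta", "spleen", "pancreas", "eye")
  libs$tissue <- ifelse(libs$condition == "other",
                        rep_len(other_tissues, nrow(libs)), "target")

  rows <- vector("list", nrow(libs))
  for (i in seq_len(nrow(libs))) {
    tot <- sample(config$library_total_range[1]:config$library_total_range[2],
                  1L)
    prob <- if (libs$condition[i] == "query") theta_q else theta
    counts <- as.integer(stats::rmultinom(1, tot, prob))
    nz <- counts > 0L
    rows[[i]] <- data.frame(library_id = libs$library_id[i],
                            tissue = libs$tissue[i],
                            condition = libs$condition[i],
                            gene_id = genes[nz], est_count = counts[nz],
                            library_total = tot, stringsAsFactors = FALSE)
  }
  table <- library_table(do.call(rbind, rows))
  manifest <- pool_manifest(
    A = libs$library_id[libs$condition == "reference"],
    B = libs$library_id[libs$condition == "query"],
    test_pool = "B")
  truth <- structure(list(de = de, groups = NULL, baseline = theta),
                     class = "ground_truth")
  list(table = table, manifest = manifest, truth = truth)
}

#' Simulate a toy ontology
#'
#' Per namespace, a rooted DAG: a fixed set of top-level branch heads is
#' attached to the root, and each subsequent term joins a uniformly chosen
#' branch, attaching to one or (with probability 0.2) two already-present
#' terms of that branch; each edge is `is_a` with probability 0.8 and
#' `part_of` otherwise. Growing within branches keeps the top-level
#' branches disjoint and roughly balanced — the structure the planted gene
#' groups of [simulate_annotations()] rely on — while double parents still
#' create the diamond motifs that exercise max-over-paths S-value
#' propagation. Acyclic by construction; every term reaches its namespace
#' root.
#'
#' @param config a [simulation_config()].
#' @param n_branches top-level branches per namespace (default
#'   `max(3, n_groups + 1)`).
#' @return a [ontology()] object.
#' @export
simulate_ontology <- function(config,
                              n_branches = max(3, config$n_groups + 1)) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  nt <- config$ontology_terms_per_namespace
  nb <- min(as.integer(n_branches), nt - 1L)
  terms <- edges <- list()
  for (ns in config$namespaces) {
    ids <- sprintf("%s:%04d", ns, seq_len(nt))
    terms[[ns]] <- data.frame(
      id = ids,
      name = c(paste(ns, "root"), sprintf("%s term %d", ns, 2:nt)),
      namespace = ns, stringsAsFactors = FALSE)
    branch <- vector("list", nb)           # term ids per branch
    for (b in seq_len(nb)) {
      branch[[b]] <- ids[1L + b]
      edges[[length(edges) + 1L]] <-
        data.frame(child = ids[1L + b], parent = ids[1L],
                   relation = "is_a", stringsAsFactors = FALSE)
    }
    if (nt > nb + 1L) for (i in (nb + 2L):nt) {
      b <- sample.int(nb, 1L)
      pool <- branch[[b]]
      n_par <- 1L + (stats::runif(1) < 0.2 && length(pool) >= 2)
      pars <- sample(pool, n_par)
      rels <- ifelse(stats::runif(n_par) < 0.8, "is_a", "part_of")
      edges[[length(edges) + 1L]] <-
        data.frame(child = ids[i], parent = pars, relation = rels,
                   stringsAsFactors = FALSE)
      branch[[b]] <- c(branch[[b]], ids[i])
    }
  }
  ontology(do.call(rbind, terms), do.call(rbind, edges))
}

# maximal set of root children with mutually disjoint descendant closures,
# largest branches first
.disjoint_branches <- function(graph, ns) {
  root <- intersect(graph$roots, ontology_terms(graph, ns))
  heads <- unique(unlist(graph$children[root], use.names = FALSE))
  desc <- lapply(heads, term_descendants, x = graph)
  names(desc) <- heads
  desc <- desc[order(-lengths(desc))]
  kept <- list()
  used <- character(0)
  for (h in names(desc)) {
    if (!length(intersect(desc[[h]], used))) {
      kept[[h]] <- desc[[h]]
      used <- c(used, desc[[h]])
    }
  }
  kept
}

#' Simulate gene annotations with planted functional groups
#'
#' Each planted group is assigned a branch of the ontology (a child of the
#' namespace root together with all its descendants), with the same
#' group-to-branch assignment in every namespace. Group members draw
#' `Poisson(terms_per_gene_mean)` distinct terms from their branch —
#' except, with probability `group_leakage` per drawn term, a uniform term
#' from the whole namespace. Background genes draw uniformly. Genes whose
#' Poisson draw is zero are present with empty sets.
#'
#' @param config a [simulation_config()].
#' @param graph a [ontology()] object, e.g. from [simulate_ontology()].
#' @return list with `annotation` (a [gene_annotation()] over all genes)
#'   and `truth` (a `ground_truth` whose `groups` is a named vector
#'   gene -> group id).
#' @export
simulate_annotations <- function(config, graph) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(graph, "go_ontology"))
  set.seed(config$seed + 2L)
  genes <- .gene_ids(config$n_genes)
  n_members <- config$n_groups * config$genes_per_group
  if (n_members > config$n_genes)
    stop_("more group members than genes in the universe")
  members <- sample(genes, n_members)
  groups <- stats::setNames(rep(seq_len(config$n_groups),
                                each = config$genes_per_group), members)

  branch_of <- list()
  for (ns in config$namespaces) {
    branches <- .disjoint_branches(graph, ns)
    if (length(branches) < config$n_groups)
      stop_("namespace ", ns, " has only ", length(branches),
            " disjoint branches; ", config$n_groups, " groups requested")
    branch_of[[ns]] <- branches[seq_len(config$n_groups)]
  }

  rows <- list()
  for (ns in config$namespaces) {
    universe <- ontology_terms(graph, ns)
    for (g in genes) {
      k <- stats::rpois(1, config$terms_per_gene_mean)
      if (k == 0) next
      grp <- groups[g]
      if (!is.na(grp)) {
        branch <- branch_of[[ns]][[grp]]
        if (k > length(branch))
          stop_("branch for group ", grp, " in ", ns, " has only ",
                length(branch), " terms but ", k, " were requested")
        terms <- sample(branch, k)
        leak <- stats::runif(k) < config$group_leakage
        if (any(leak))
          terms[leak] <- sample(universe, sum(leak), replace = TRUE)
      } else {
        terms <- sample(universe, min(k, length(universe)))
      }
      terms <- unique(terms)
      rows[[length(rows) + 1L]] <-
        data.frame(gene_id = g, term_id = terms, namespace = ns,
                   stringsAsFactors = FALSE)
    }
  }
  ann <- gene_annotation(do.call(rbind, rows), genes = genes,
                         ontology = graph, on_missing = "error")
  truth <- structure(list(de = NULL, groups = groups, baseline = NULL),
                     class = "ground_truth")
  list(annotation = ann, truth = truth)
}

#' Desk-scale two-group demonstration configuration
#'
#' The packaged configuration used to demonstrate (and test) recovery of
#' planted functional groups by bootstrap clustering: a single-namespace
#' 60-term ontology and two groups of 28 genes on disjoint branches with no
#' annotation leakage and a generous 6 terms per gene. Of each group, 8
#' genes are clustered as candidates and the remaining 20 serve as the
#' reference panel (see [demo_group_data()]), mirroring the design in which
#' candidates are scored against a separate tissue-specific reference list
#' and giving the bootstrap enough reference columns to resample.
#'
#' @param seed integer seed (default 101).
#' @return a [simulation_config()].
#' @export
demo_group_config <- function(seed = 101) {
  simulation_config(seed = seed, n_genes = 56, namespaces = "BP",
                    ontology_terms_per_namespace = 60,
                    n_groups = 2, genes_per_group = 28,
                    terms_per_gene_mean = 6, group_leakage = 0)
}

#' Build the packaged two-group demonstration dataset
#'
#' Simulates the ontology and annotations of [demo_group_config()] and
#' assembles the candidate x reference similarity matrix: the first 8
#' genes (by id) of each planted group are the clustered candidates, the
#' remaining 40 group genes the reference columns.
#'
#' @param seed integer seed passed to [demo_group_config()].
#' @return list with `matrix` (16 x 40 similarity matrix), `groups` (named
#'   vector: candidate gene -> group id), `candidates`, `reference`,
#'   `ontology`, `annotation` and `config`.
#' @export
demo_group_data <- function(seed = 101) {
  config <- demo_group_config(seed)
  graph <- simulate_ontology(config)
  ann <- simulate_annotations(config, graph)
  groups <- ann$truth$groups
  candidates <- unlist(lapply(split(names(groups), groups),
                              function(g) sort(g)[1:8]), use.names = FALSE)
  reference <- setdiff(names(groups), candidates)
  m <- build_similarity_matrix(candidates, reference, ann$annotation, graph)
  list(matrix = m, groups = groups[candidates], candidates = candidates,
       reference = reference, ontology = graph,
       annotation = ann$annotation, config = config)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic-data configuration (seed", x$seed, ")\n")
  cat(sprintf("  %d genes; libraries: %d reference + %d query + %d other\n",
              x$n_genes, x$n_ref_libs, x$n_query_libs, x$n_other_libs))
  cat(sprintf("  library totals %d-%d ESTs; Dirichlet conc %.2f\n",
              x$library_total_range[1], x$library_total_range[2],
              x$dirichlet_conc))
  cat(sprintf("  ontology: %s x %d terms; %d groups x %d genes, leakage %.2f\n",
              paste(x$namespaces, collapse = "/"),
              x$ontology_terms_per_namespace, x$n_groups,
              x$genes_per_group, x$group_leakage))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth\n")
  if (!is.null(x$de))
    cat("  planted DE genes:", nrow(x$de), "\n")
  if (!is.null(x$groups))
    cat("  planted groups:", length(unique(x$groups)), "covering",
        length(x$groups), "genes\n")
  invisible(x)
}
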