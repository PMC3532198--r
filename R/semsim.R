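#' Default Wang edge weights
#'
#' The standard semantic-contribution factors: 0.8 for `is_a`, 0.6 for
#' `part_of` edges.
#'
#' @return named numeric vector.
#' @export
wang_weights <- function() c(is_a = 0.8, part_of = 0.6)

.check_weights <- function(weights) {
  if (!all(c("is_a", "part_of") %in% names(weights)) ||
      any(weights <= 0) || any(weights >= 1))
    stop_("weights must name is_a and part_of with values in (0, 1)")
  weights
}

#' S-values of a term's ancestor closure
#'
#' The Wang construction: the anchor term contributes 1 to itself, and each
#' ancestor t receives `S(t) = max over children t' (within the closure) of
#' w(relation(t' -> t)) * S(t')` — the best decaying path from the anchor.
#' `SV` is the total S-value mass of the closure.
#'
#' @param anchor term id.
#' @param graph a [ontology()] object.
#' @param weights edge weights, see [wang_weights()].
#' @return list with `s` (named numeric, `s[anchor] == 1`) and `sv`
#'   (`sum(s)`).
#' @export
s_values <- function(anchor, graph, weights = wang_weights()) {
  stopifnot(inherits(graph, "go_ontology"))
  weights <- .check_weights(weights)
  if (!anchor %in% graph$terms$id) stop_("term not in ontology: ", anchor)

  # ancestor closure (anchor included); closed under parent edges
  closure <- character(0)
  queue <- anchor
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    if (v %in% closure) next
    closure <- c(closure, v)
    queue <- c(queue, graph$parents[[v]])
  }

  s <- stats::setNames(rep(-Inf, length(closure)), closure)
  s[[anchor]] <- 1
  # process children before parents: count in-closure children per node
  indeg <- stats::setNames(integer(length(closure)), closure)
  for (v in closure)
    for (p in graph$parents[[v]]) indeg[[p]] <- indeg[[p]] + 1L
  queue <- closure[indeg == 0L]  # the anchor
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    pars <- graph$parents[[v]]
    rels <- graph$relations[[v]]
    for (j in seq_along(pars)) {
      p <- pars[[j]]
      cand <- weights[[rels[[j]]]] * s[[v]]
      if (cand > s[[p]]) s[[p]] <- cand
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  list(s = s, sv = sum(s))
}

.s_cached <- function(term, graph, weights, cache) {
  if (is.null(cache)) return(s_values(term, graph, weights))
  if (is.null(cache[[term]])) cache[[term]] <- s_values(term, graph, weights)
  cache[[term]]
}

#' Wang similarity between two ontology terms
#'
#' `Sim(a, b) = sum over shared ancestors t of (S_a(t) + S_b(t)) divided by
#' (SV(a) + SV(b))`; symmetric and in `[0, 1]`, 1 for a term with itself,
#' 0 when the terms share no ancestor.
#'
#' @param a,b term ids (same namespace).
#' @inheritParams s_values
#' @param .cache optional environment caching S-value tables by term id.
#' @return similarity in `[0, 1]`.
#' @export
term_similarity <- function(a, b, graph, weights = wang_weights(),
                            .cache = NULL) {
  stopifnot(inherits(graph, "go_ontology"))
  for (t in c(a, b))
    if (!t %in% graph$terms$id) stop_("term not in ontology: ", t)
  if (graph$namespace[[a]] != graph$namespace[[b]])
    stop_("terms ", a, " and ", b, " are in different namespaces")
  ta <- .s_cached(a, graph, weights, .cache)
  tb <- .s_cached(b, graph, weights, .cache)
  shared <- intersect(names(ta$s), names(tb$s))
  if (!length(shared)) return(0)
  sum(ta$s[shared] + tb$s[shared]) / (ta$sv + tb$sv)
}

.term_set_sim <- function(A, B, graph, weights, cache) {
  # pairwise term-similarity matrix |A| x |B|
  m <- matrix(0, length(A), length(B))
  for (i in seq_along(A))
    for (j in seq_along(B))
      m[i, j] <- term_similarity(A[[i]], B[[j]], graph, weights,
                                 .cache = cache)
  m
}

#' Best-match-average similarity between two genes in one namespace
#'
#' With annotation sets of sizes m and n, each of a gene's terms contributes
#' its maximum similarity to any term of the other gene, and the 2-way sum
#' is divided by `m + n`. Identical sets score 1; if either gene has no
#' annotation in the namespace the score is missing (`NA`).
#'
#' @param gi,gj gene ids (must be present in `annotation`).
#' @param namespace `"BP"`, `"MF"` or `"CC"`.
#' @param annotation a [gene_annotation()].
#' @inheritParams term_similarity
#' @return similarity in `[0, 1]`, or `NA`.
#' @export
gene_similarity <- function(gi, gj, namespace, annotation, graph,
                            weights = wang_weights(), .cache = NULL) {
  A <- annotation_terms(annotation, gi, namespace)
  B <- annotation_terms(annotation, gj, namespace)
  if (!length(A) || !length(B)) return(NA_real_)
  m <- .term_set_sim(A, B, graph, weights, .cache)
  (sum(apply(m, 1, max)) + sum(apply(m, 2, max))) / (length(A) + length(B))
}

#' Gene similarity combined across namespaces
#'
#' The unweighted mean of the per-namespace best-match-average scores over
#' the namespaces in which both genes are annotated; missing when there is
#' no such namespace. The namespaces actually used are attached as the
#' `"namespaces"` attribute for auditability.
#'
#' @inheritParams gene_similarity
#' @param namespaces namespaces to consider (default BP, MF, CC).
#' @return similarity in `[0, 1]` (or `NA`) with attribute `namespaces`.
#' @export
combined_gene_similarity <- function(gi, gj, annotation, graph,
                                     weights = wang_weights(),
                                     namespaces = c("BP", "MF", "CC"),
                                     .cache = NULL) {
  vals <- vapply(namespaces, function(ns)
    gene_similarity(gi, gj, ns, annotation, graph, weights, .cache),
    numeric(1))
  used <- namespaces[!is.na(vals)]
  out <- if (length(used)) mean(vals[!is.na(vals)]) else NA_real_
  attr(out, "namespaces") <- used
  out
}

#' Candidate x reference gene similarity matrix
#'
#' Scores every candidate against every reference gene with
#' [combined_gene_similarity()]. S-value tables are cached so each term's
#' ancestor closure is propagated once. Candidate rows with no usable score
#' (no shared annotated namespace with any reference gene, including genes
#' absent from the annotation) are dropped with a warning and recorded in
#' the `"dropped"` attribute — mirroring how unannotatable candidates fall
#' out of the published analysis.
#'
#' @param candidates,reference character vectors of gene ids.
#' @inheritParams combined_gene_similarity
#' @return numeric matrix (candidates x reference) with attribute `dropped`.
#' @export
build_similarity_matrix <- function(candidates, reference, annotation, graph,
                                    weights = wang_weights(),
                                    namespaces = c("BP", "MF", "CC")) {
  candidates <- as.character(candidates); reference <- as.character(reference)
  if (!length(candidates) || !length(reference))
    stop_("candidate and reference lists must be non-empty")
  cache <- new.env(parent = emptyenv())
  known <- annotation_genes(annotation)
  m <- matrix(NA_real_, length(candidates), length(reference),
              dimnames = list(candidates, reference))
  for (i in seq_along(candidates)) {
    gi <- candidates[[i]]
    if (!gi %in% known) next
    for (j in seq_along(reference)) {
      gj <- reference[[j]]
      if (!gj %in% known) next
      m[i, j] <- as.numeric(combined_gene_similarity(
        gi, gj, annotation, graph, weights, namespaces, .cache = cache))
    }
  }
  all_na <- rowSums(!is.na(m)) == 0L
  if (any(all_na)) {
    warn_("dropping ", sum(all_na),
          " candidate(s) with no usable annotation: ",
          paste(utils::head(candidates[all_na], 5), collapse = ", "))
    m <- m[!all_na, , drop = FALSE]
  }
  attr(m, "dropped") <- candidates[all_na]
  m
}
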