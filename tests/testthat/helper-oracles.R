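# Independent oracles and small generators used across the suite.

# Full-enumeration two-sided Fisher p-value computed directly from
# binomial coefficients (no dhyper), point-probability rule.
fisher_oracle <- function(a, ta, b, tb) {
  k <- a + b
  if (k == 0) return(1)
  xs <- max(0, k - tb):min(k, ta)
  lp <- lchoose(ta, xs) + lchoose(tb, k - xs) - lchoose(ta + tb, k)
  p <- exp(lp)
  pobs <- p[match(a, xs)]
  min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

# Brute-force Wang S-value: max over all upward paths of the product of
# edge weights; enumerates every path explicitly.
s_values_oracle <- function(anchor, graph, weights = wang_weights()) {
  best <- new.env(parent = emptyenv())
  walk <- function(term, score) {
    cur <- best[[term]]
    if (!is.null(cur) && cur >= score) return(invisible(NULL))
    best[[term]] <- score
    pars <- graph$parents[[term]]
    rels <- graph$relations[[term]]
    for (j in seq_along(pars))
      walk(pars[[j]], score * weights[[rels[[j]]]])
  }
  walk(anchor, 1)
  s <- unlist(as.list(best))
  list(s = s[order(names(s))], sv = sum(s))
}

# Random namespace-consistent DAG on <= n terms (child ids always attach
# to earlier terms, so acyclic by construction).
random_dag <- function(n, seed, ns = "BP", p_two = 0.3) {
  set.seed(seed)
  ids <- sprintf("%s:R%03d", ns, seq_len(n))
  kids <- pars <- rels <- character(0)
  for (i in 2:n) {
    np <- 1 + (runif(1) < p_two && i > 2)
    pp <- sample(ids[seq_len(i - 1)], np)
    kids <- c(kids, rep(ids[i], np))
    pars <- c(pars, pp)
    rels <- c(rels, sample(c("is_a", "part_of"), np, replace = TRUE,
                           prob = c(0.8, 0.2)))
  }
  ontology(data.frame(id = ids, name = ids, namespace = ns),
           data.frame(child = kids, parent = pars, relation = rels))
}

# Three-term chain A is_a B is_a R used in several worked examples.
chain_ontology <- function() {
  ontology(data.frame(id = c("R", "B", "A"), name = c("r", "b", "a"),
                      namespace = "BP"),
           data.frame(child = c("A", "B"), parent = c("B", "R"),
                      relation = "is_a"))
}

# Adjusted Rand index between two labelled partitions (named vectors).
ari <- function(a, b) {
  stopifnot(setequal(names(a), names(b)))
  b <- b[names(a)]
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Partition induced by a list of clusters over a gene universe.
clusters_to_labels <- function(clusters, genes) {
  lab <- stats::setNames(rep("singleton", length(genes)), genes)
  for (i in seq_along(clusters))
    lab[clusters[[i]]] <- paste0("c", i)
  lab
}
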