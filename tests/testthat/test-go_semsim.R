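diamond_ontology <- function() {
  # A -> {B (is_a), C (part_of)} -> R: two paths to the shared ancestor
  ontology(data.frame(id = c("R", "B", "C", "A"),
                      name = c("r", "b", "c", "a"), namespace = "BP"),
           data.frame(child = c("A", "A", "B", "C"),
                      parent = c("B", "C", "R", "R"),
                      relation = c("is_a", "part_of", "is_a", "is_a")))
}

test_that("S-values follow the decaying max-path recursion", {
  ont <- chain_ontology()
  sv <- s_values("A", ont)
  expect_equal(sv$s[c("A", "B", "R")], c(A = 1, B = 0.8, R = 0.64))
  expect_equal(sv$sv, 2.44)

  root <- s_values("R", ont)
  expect_equal(root$s, c(R = 1))
  expect_equal(root$sv, 1)

  # diamond: ancestor takes the max over the two paths
  dia <- diamond_ontology()
  sv2 <- s_values("A", dia)
  expect_equal(sv2$s[["R"]], max(0.8 * 0.8, 0.6 * 0.6))
  expect_equal(sv2$s, s_values_oracle("A", dia)$s[names(sv2$s)])

  expect_error(s_values("nope", ont), "not in ontology")
})

test_that("S-values match the path-enumeration oracle on random DAGs", {
  for (seed in 1:8) {
    ont <- random_dag(n = sample(10:30, 1), seed = seed)
    for (anchor in sample(ont$terms$id, 5)) {
      got <- s_values(anchor, ont)
      want <- s_values_oracle(anchor, ont)
      expect_equal(got$s[order(names(got$s))], want$s, tolerance = 1e-12)
      expect_equal(got$sv, want$sv, tolerance = 1e-12)
    }
  }
})

test_that("S-values satisfy the max-propagation fixpoint and bounds", {
  ont <- random_dag(25, seed = 99)
  w <- wang_weights()
  for (anchor in sample(ont$terms$id, 6)) {
    s <- s_values(anchor, ont)$s
    expect_true(all(s > 0 & s <= 1))
    expect_equal(s[[anchor]], 1)
    for (p in setdiff(names(s), anchor)) {
      # each ancestor's S-value is the max over its in-closure children
      contrib <- c()
      for (t in names(s)) {
        pars <- ont$parents[[t]]
        rels <- ont$relations[[t]]
        hit <- which(pars == p)
        if (length(hit))
          contrib <- c(contrib, max(w[rels[hit]]) * s[[t]])
      }
      expect_equal(s[[p]], max(contrib))
    }
  }
})

test_that("term similarity is symmetric, bounded and exact on toys", {
  sib <- ontology(data.frame(id = c("R", "A", "B"),
                             name = c("r", "a", "b"), namespace = "BP"),
                  data.frame(child = c("A", "B"), parent = c("R", "R"),
                             relation = "is_a"))
  expect_equal(term_similarity("A", "A", sib), 1)
  expect_equal(term_similarity("A", "B", sib), (0.8 + 0.8) / (1.8 + 1.8))

  # separate components share no ancestor
  two <- ontology(data.frame(id = c("R1", "R2"), name = c("r1", "r2"),
                             namespace = "BP"),
                  data.frame(child = character(0), parent = character(0),
                             relation = character(0)))
  expect_equal(term_similarity("R1", "R2", two), 0)

  mixed <- ontology(data.frame(id = c("P1", "F1"), name = c("p", "f"),
                               namespace = c("BP", "MF")),
                    data.frame(child = character(0), parent = character(0),
                               relation = character(0)))
  expect_error(term_similarity("P1", "F1", mixed), "namespace")

  ont <- random_dag(30, seed = 3)
  pairs <- replicate(40, sample(ont$terms$id, 2), simplify = FALSE)
  for (p in pairs) {
    s1 <- term_similarity(p[1], p[2], ont)
    s2 <- term_similarity(p[2], p[1], ont)
    expect_equal(s1, s2, tolerance = 1e-12)
    expect_gte(s1, 0); expect_lte(s1, 1)
  }
})

test_that("gene similarity is the best-match average of the formula", {
  sib <- ontology(data.frame(id = c("R", "A", "B"),
                             name = c("r", "a", "b"), namespace = "BP"),
                  data.frame(child = c("A", "B"), parent = c("R", "R"),
                             relation = "is_a"))
  s <- term_similarity("A", "B", sib)
  ann <- gene_annotation(data.frame(
    gene_id = c("g1", "g2", "g2"), term_id = c("A", "A", "B"),
    namespace = "BP"), genes = c("g1", "g2", "g3"))
  # gi = {A}, gj = {A, B}: (max over gi terms) + (per-gj-term maxes) / 3
  expect_equal(gene_similarity("g1", "g2", "BP", ann, sib), (1 + 1 + s) / 3)
  expect_equal(gene_similarity("g2", "g1", "BP", ann, sib),
               gene_similarity("g1", "g2", "BP", ann, sib))
  expect_equal(gene_similarity("g2", "g2", "BP", ann, sib), 1)
  expect_true(is.na(gene_similarity("g1", "g3", "BP", ann, sib)))
  expect_error(gene_similarity("g1", "gX", "BP", ann, sib), "unknown gene")
})

test_that("identical annotation sets always score 1 (property)", {
  ont <- random_dag(25, seed = 17)
  set.seed(17)
  for (i in 1:10) {
    terms <- sample(ont$terms$id, sample(1:5, 1))
    ann <- gene_annotation(data.frame(
      gene_id = rep(c("ga", "gb"), each = length(terms)),
      term_id = rep(terms, 2), namespace = "BP"))
    expect_equal(gene_similarity("ga", "gb", "BP", ann, ont), 1)
  }
})

test_that("cross-namespace combination averages available namespaces", {
  terms <- data.frame(id = c("P", "P1", "P2", "F", "F1", "F2"),
                      name = letters[1:6],
                      namespace = rep(c("BP", "MF"), each = 3))
  edges <- data.frame(child = c("P1", "P2", "F1", "F2"),
                      parent = c("P", "P", "F", "F"), relation = "is_a")
  ont <- ontology(terms, edges)
  ann <- gene_annotation(data.frame(
    gene_id = c("g1", "g1", "g2", "g2"),
    term_id = c("P1", "F1", "P2", "F2"),
    namespace = c("BP", "MF", "BP", "MF")))
  bp <- gene_similarity("g1", "g2", "BP", ann, ont)
  mf <- gene_similarity("g1", "g2", "MF", ann, ont)
  comb <- combined_gene_similarity("g1", "g2", ann, ont)
  expect_equal(as.numeric(comb), mean(c(bp, mf)))
  expect_setequal(attr(comb, "namespaces"), c("BP", "MF"))

  ann_bp <- gene_annotation(data.frame(
    gene_id = c("g1", "g2"), term_id = c("P1", "P2"), namespace = "BP"))
  only_bp <- combined_gene_similarity("g1", "g2", ann_bp, ont)
  expect_equal(as.numeric(only_bp),
               gene_similarity("g1", "g2", "BP", ann_bp, ont))

  ann_split <- gene_annotation(data.frame(
    gene_id = c("g1", "g2"), term_id = c("P1", "F1"),
    namespace = c("BP", "MF")))
  none <- combined_gene_similarity("g1", "g2", ann_split, ont)
  expect_true(is.na(none))
  expect_length(attr(none, "namespaces"), 0)
})

test_that("similarity matrices score all pairs and drop unusable rows", {
  ont <- chain_ontology()
  ann <- gene_annotation(data.frame(
    gene_id = c("g1", "g2"), term_id = c("A", "B"), namespace = "BP"),
    genes = c("g1", "g2", "g3"))
  m1 <- build_similarity_matrix("g1", "g1", ann, ont)
  expect_equal(unname(m1), matrix(1, 1, 1), ignore_attr = TRUE)

  expect_warning(m <- build_similarity_matrix(c("g1", "g3"), c("g1", "g2"),
                                              ann, ont),
                 "no usable annotation")
  expect_equal(rownames(m), "g1")
  expect_equal(attr(m, "dropped"), "g3")

  # permutation invariance up to row/column order
  ann2 <- gene_annotation(data.frame(
    gene_id = c("g1", "g2", "g4"), term_id = c("A", "B", "R"),
    namespace = "BP"))
  ma <- build_similarity_matrix(c("g1", "g2", "g4"), c("g1", "g2"),
                                ann2, ont)
  mb <- build_similarity_matrix(c("g4", "g1", "g2"), c("g2", "g1"),
                                ann2, ont)
  expect_equal(ma, mb[rownames(ma), colnames(ma)], ignore_attr = TRUE)
})
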