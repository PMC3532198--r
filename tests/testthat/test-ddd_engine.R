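make_table <- function(rows) library_table(do.call(rbind, rows))
row_of <- function(lib, gene, count, total,
                   tissue = "lung", condition = "normal") {
  data.frame(library_id = lib, tissue = tissue, condition = condition,
             gene_id = gene, est_count = count, library_total = total)
}

test_that("pooling sums counts, zero-fills and is order-invariant", {
  tab <- make_table(list(
    row_of("L1", "G1", 3, 50), row_of("L1", "G2", 7, 50),
    row_of("L2", "G1", 4, 60),
    row_of("L3", "G3", 9, 70)))
  man <- pool_manifest(A = c("L1", "L2"), B = "L3", test_pool = "B")
  pools <- pool_libraries(tab, man)
  expect_equal(pools$A$counts, c(G1 = 7L, G2 = 7L, G3 = 0L))
  expect_equal(pools$B$counts, c(G1 = 0L, G2 = 0L, G3 = 9L))
  expect_equal(pools$A$total, 110L)

  man_rev <- pool_manifest(A = c("L2", "L1"), B = "L3", test_pool = "B")
  expect_equal(pool_libraries(tab, man_rev)$A$counts, pools$A$counts)

  man_bad <- pool_manifest(A = "L1", B = "L9")
  expect_error(pool_libraries(tab, man_bad), "unknown librar")
})

test_that("transcript frequencies divide count by pool total", {
  expect_equal(transcript_frequency(100, 10000), 0.01)
  expect_equal(transcript_frequency(0, 500), 0)
  expect_equal(transcript_frequency(224, 10000, digits = 4), 0.0224)
  expect_error(transcript_frequency(5, 0), "positive")
  expect_error(transcript_frequency(11, 10), "pool_total")
})

test_that("signed folds reproduce the published conventions", {
  expect_equal(signed_fold(0.0224, 0.0018, digits = 2), 12.44)
  expect_equal(signed_fold(0.0002, 0.0224), -112)
  expect_equal(signed_fold(0.003, 0.003), 1)
  expect_equal(signed_fold(0.0011, 0), Inf)
  expect_equal(signed_fold(0, 0.0011), -Inf)
  expect_error(signed_fold(0, 0), "both")

  expect_equal(format_fold(c(12.444, -112, Inf, -Inf, 3.5)),
               c("+12.44", "-112", "+", "-", "+3.5"))
  expect_equal(parse_fold(c("+12.44", "-112", "+", "-")),
               c(12.44, -112, Inf, -Inf))
})

test_that("finite signed folds are antisymmetric", {
  set.seed(1)
  a <- runif(50, 1e-4, 1e-2)
  b <- runif(50, 1e-4, 1e-2)
  expect_equal(signed_fold(a, b), -signed_fold(b, a))
  expect_true(all(abs(signed_fold(a, b)) >= 1))
})

test_that("Fisher exact matches enumeration oracles", {
  expect_equal(fisher_exact_2x2(5, 100, 5, 100), 1)
  expect_equal(round(fisher_exact_2x2(3, 4, 1, 4), 4), 0.4857)

  set.seed(42)
  for (i in 1:200) {
    ta <- sample(5:60, 1); tb <- sample(5:60, 1)
    a <- sample(0:ta, 1); b <- sample(0:tb, 1)
    p <- fisher_exact_2x2(a, ta, b, tb)
    expect_equal(p, fisher_oracle(a, ta, b, tb), tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(
      matrix(c(a, ta - a, b, tb - b), 2))$p.value, tolerance = 1e-9)
    # symmetry under swapping pools and rows
    expect_equal(p, fisher_exact_2x2(b, tb, a, ta), tolerance = 1e-12)
    expect_equal(p, fisher_exact_2x2(ta - a, ta, tb - b, tb),
                 tolerance = 1e-12)
  }
})

test_that("run_ddd filters, sorts, adjusts and keeps exclusives", {
  tab <- make_table(list(
    row_of("L1", "G1", 100, 10000), row_of("L1", "G2", 10, 10000),
    row_of("L1", "G3", 50, 10000), row_of("L1", "G4", 8, 10000),
    row_of("L2", "G1", 10, 10000), row_of("L2", "G2", 100, 10000),
    row_of("L2", "G3", 52, 10000)))
  man <- pool_manifest(A = "L1", B = "L2", test_pool = "B")
  res <- run_ddd(tab, man, min_fold = 2)
  expect_s3_class(res, "ddd_result")
  expect_equal(attr(res, "n_tested"), 4)
  # G4 seen only in pool A -> exclusive "-", always kept and sorted first
  expect_equal(res$gene_id[1], "G4")
  expect_equal(res$fold[1], -Inf)
  expect_setequal(res$gene_id, c("G1", "G2", "G4"))  # G3 below 2-fold
  expect_equal(res$direction[res$gene_id == "G2"], "up")
  expect_equal(res$direction[res$gene_id == "G1"], "down")
  # BH q-values are monotone in p rank
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= -1e-12))

  # min_fold = Inf keeps exclusives only
  only_excl <- run_ddd(tab, man, min_fold = Inf)
  expect_equal(only_excl$gene_id, "G4")

  # alpha filter removes non-significant records
  strict <- run_ddd(tab, man, min_fold = 2, alpha = 1e-10)
  expect_lt(nrow(strict), nrow(res))
})

test_that("a planted 5-fold gene survives the 2-fold filter, right sign", {
  cfg <- simulation_config(seed = 71, n_genes = 60, n_ref_libs = 3,
                           n_query_libs = 3, n_other_libs = 0,
                           library_total_range = c(20000L, 30000L),
                           de_genes = data.frame(
                             gene_id = c("G0005", "G0006"),
                             fold = c(5, 5),
                             direction = c("up", "down")))
  sim <- simulate_libraries(cfg)
  res <- run_ddd(sim$table, sim$manifest, min_fold = 2)
  expect_true(all(c("G0005", "G0006") %in% res$gene_id))
  expect_equal(res$direction[res$gene_id == "G0005"], "up")
  expect_equal(res$direction[res$gene_id == "G0006"], "down")
})

test_that("null DDD p-values are super-uniform (type-I control)", {
  set.seed(99)
  n_genes <- 2000
  theta <- rgamma(n_genes, 0.5); theta <- theta / sum(theta)
  ca <- as.integer(rmultinom(1, 150000, theta))
  cb <- as.integer(rmultinom(1, 120000, theta))
  keep <- ca + cb > 0
  p <- mapply(fisher_exact_2x2, ca[keep], 150000, cb[keep], 120000)
  expect_lte(mean(p <= 0.05), 0.06)
})
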