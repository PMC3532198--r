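test_that("profile distance is 1 - correlation with pairwise handling", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  d <- as.matrix(profile_distance(m))
  expect_equal(d["a", "b"], 0, tolerance = 1e-12)
  expect_equal(d["a", "c"], 2, tolerance = 1e-12)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))

  # direct covariance-formula oracle on a random matrix
  set.seed(8)
  x <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("g", 1:5), NULL))
  d2 <- as.matrix(profile_distance(x))
  for (i in 1:4) for (j in (i + 1):5) {
    xi <- x[i, ]; xj <- x[j, ]
    r <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(d2[i, j], 1 - r, tolerance = 1e-12)
  }

  flat <- rbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(3, 2, 1))
  expect_error(profile_distance(flat), "constant similarity profile.*a")
  expect_error(profile_distance(m[, 1:2, drop = FALSE]),
               "fewer than 3 complete columns")
  expect_error(profile_distance(m[1:2, ]), "at least 3 genes")
})

test_that("UPGMA reproduces hand arithmetic and ultrametric trees", {
  d <- matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("p1", "p2", "p3"), c("p1", "p2", "p3")))
  h <- hcluster(stats::as.dist(d))
  expect_equal(h$height, c(1, 4.5))
  expect_equal(tree_members(h), list(c("p1", "p2"), c("p1", "p2", "p3")))

  two <- hcluster(stats::as.dist(matrix(c(0, 3, 3, 0), 2,
                                        dimnames = list(c("x", "y"),
                                                        c("x", "y")))))
  expect_equal(two$height, 3)

  # an ultrametric (cophenetic) input reproduces its own tree
  set.seed(21)
  base <- hcluster(stats::dist(matrix(rnorm(36), 9)))
  coph <- stats::cophenetic(base)
  again <- hcluster(coph)
  expect_equal(stats::cophenetic(again), coph, tolerance = 1e-12)
})

test_that("hcluster agrees with stats::hclust away from ties", {
  set.seed(33)
  for (linkage in c("average", "complete", "single")) {
    d <- stats::dist(matrix(rnorm(40), 10))  # continuous: ties measure-zero
    attr(d, "Labels") <- paste0("g", 1:10)
    ours <- hcluster(d, linkage)
    ref <- stats::hclust(d, method = linkage)
    expect_equal(ours$height, ref$height, tolerance = 1e-12)
    ours_sets <- tree_members(ours)
    ref_sets <- vector("list", nrow(ref$merge))
    for (k in seq_len(nrow(ref$merge))) {
      grab <- function(node)
        if (node < 0) ref$labels[-node] else ref_sets[[node]]
      ref_sets[[k]] <- sort(c(grab(ref$merge[k, 1]),
                              grab(ref$merge[k, 2])))
    }
    expect_setequal(vapply(ours_sets, paste, "", collapse = ","),
                    vapply(ref_sets, paste, "", collapse = ","))
  }
})

test_that("tied merges break deterministically by lexicographic members", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  h <- hcluster(stats::as.dist(d))
  expect_equal(tree_members(h)[[1]], c("a", "b"))
  expect_identical(hcluster(stats::as.dist(d)), h)
})

test_that("the AU probit fit recovers noiseless curves exactly", {
  rho <- seq(0.5, 1.4, by = 0.1)
  psi <- 1 * sqrt(rho) + 0.5 / sqrt(rho)
  fit <- fit_au_curve(1 - stats::pnorm(psi), rho, nboot = 1000)
  expect_equal(fit$v, 1, tolerance = 1e-6)
  expect_equal(fit$c, 0.5, tolerance = 1e-6)
  expect_equal(fit$au, 1 - stats::pnorm(0.5), tolerance = 1e-6)
  expect_lt(fit$chisq, 1e-10)

  # c = 0: au equals bp
  psi0 <- 0.7 * sqrt(rho)
  fit0 <- fit_au_curve(1 - stats::pnorm(psi0), rho, nboot = 1000)
  expect_equal(fit0$au, fit0$bp, tolerance = 1e-9)

  # curves degenerate at every scale resolve to their limit
  hi <- fit_au_curve(rep(1, 10), rho, nboot = 1000)
  expect_gt(hi$au, 0.99)
  lo <- fit_au_curve(rep(0, 10), rho, nboot = 1000)
  expect_lt(lo$au, 0.01)

  # one informative scale left: resolves to the degenerate limit
  one <- fit_au_curve(c(0.4, 1, 1), c(0.5, 1, 1.4), nboot = 1000)
  expect_gt(one$au, 0.99)
  # informative scales at a single distinct rho cannot be extrapolated
  una <- fit_au_curve(c(0.4, 0.5, 1), c(0.8, 0.8, 1.4), nboot = 1000)
  expect_true(is.na(una$au))
})

test_that("multiscale bootstrap is reproducible and sane on block data", {
  set.seed(5)
  blocks <- rbind(
    matrix(rnorm(5 * 20, mean = rep(c(4, 0), each = 10)), 5, 20,
           byrow = TRUE),
    matrix(rnorm(5 * 20, mean = rep(c(0, 4), each = 10)), 5, 20,
           byrow = TRUE))
  rownames(blocks) <- paste0("g", 1:10)
  bc1 <- multiscale_bootstrap(blocks, nboot = 100, seed = 4)
  bc2 <- multiscale_bootstrap(blocks, nboot = 100, seed = 4)
  expect_identical(bc1$supports, bc2$supports)
  expect_identical(bc1$bp_table, bc2$bp_table)

  # the root is always recovered in replicates and carries no AU
  n <- length(bc1$hclust$labels)
  expect_equal(unname(bc1$bp_table[n - 1, ]), rep(1, 10))
  expect_true(is.na(bc1$supports$au[n - 1]))

  # the two planted blocks are maximally supported
  mem <- vapply(bc1$members, paste, "", collapse = ",")
  g1 <- paste(sort(paste0("g", 1:5)), collapse = ",")
  g2 <- paste(sort(paste0("g", 6:10)), collapse = ",")
  expect_gt(bc1$supports$au[match(g1, mem)], 0.95)
  expect_gt(bc1$supports$au[match(g2, mem)], 0.95)
})

test_that("larger nboot tightens the AU estimate (variance monotonicity)", {
  # weakly separated blocks keep the BP curves interior so the probit fit
  # is exercised at every seed
  set.seed(6)
  x <- rbind(
    matrix(rnorm(4 * 12, mean = rep(c(1.2, 0), each = 6)), 4, 12,
           byrow = TRUE),
    matrix(rnorm(4 * 12, mean = rep(c(0, 1.2), each = 6)), 4, 12,
           byrow = TRUE))
  rownames(x) <- paste0("g", 1:8)
  au_of <- function(nboot, seed) {
    bc <- multiscale_bootstrap(x, nboot = nboot, seed = seed,
                               scales = seq(0.6, 1.4, by = 0.2))
    mem <- vapply(bc$members, paste, "", collapse = ",")
    bc$supports$au[match(paste(sort(paste0("g", 1:4)), collapse = ","),
                         mem)]
  }
  small <- vapply(1:6, function(s) au_of(200, s), numeric(1))
  large <- vapply(1:6, function(s) au_of(800, s), numeric(1))
  expect_lt(stats::var(large, na.rm = TRUE),
            stats::var(small, na.rm = TRUE))
})

test_that("cluster selection prunes top-down at the AU threshold", {
  d <- matrix(c(0, 1, 5, 5, 1, 0, 5, 5, 5, 5, 0, 1, 5, 5, 1, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tree <- hcluster(stats::as.dist(d))
  # nodes: 1 = {a,b}, 2 = {c,d}, 3 = root
  two_sig <- data.frame(node = 1:3, au = c(0.99, 0.97, 0.5))
  picked <- pick_clusters(two_sig, tree, alpha = 0.95)
  expect_equal(picked, list(c("a", "b"), c("c", "d")))

  root_sig <- data.frame(node = 1:3, au = c(0.99, 0.97, 0.99))
  expect_equal(pick_clusters(root_sig, tree, alpha = 0.95),
               list(letters[1:4]))

  none <- data.frame(node = 1:3, au = c(0.2, 0.3, NA))
  expect_equal(pick_clusters(none, tree, alpha = 0.95), list())
})
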