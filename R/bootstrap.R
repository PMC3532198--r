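#' Fit the multiscale-bootstrap AU curve for one cluster
#'
#' Bootstrap probabilities `BP_r` observed at relative resample sizes
#' `rho_r = n_r / n` are probit-transformed, `psi_r = qnorm(1 - BP_r)`, and
#' regressed on `(sqrt(rho), 1/sqrt(rho))` by weighted least squares with
#' the binomial-delta weights `B * dnorm(psi)^2 / (BP (1 - BP))`. The
#' coefficients `(v, c)` — signed distance and curvature of the cluster
#' boundary — give the approximately unbiased p-value `au = 1 - pnorm(v - c)`
#' and the corrected bootstrap probability `bp = 1 - pnorm(v + c)`.
#'
#' A BP of exactly 0 or 1 carries no information about the curve's shape
#' (its probit is infinite), so such scales are excluded from the fit.
#' When fewer than two informative scales remain the curve cannot be
#' extrapolated and resolves to its degenerate limit: `au = 1 - 1/(2B)`
#' when the mean BP is at least one half and `1/(2B)` otherwise — extreme
#' support up to the Monte-Carlo resolution of `B` replicates. Two or more
#' informative scales that share a single distinct `rho` leave the node
#' unfittable (`au = NA`).
#'
#' @param bp numeric vector of per-scale bootstrap probabilities.
#' @param rho numeric vector of relative resample sizes `n_r / n`.
#' @param nboot replicates per scale (scalar or vector).
#' @return list with `au`, `bp`, `v`, `c`, `chisq`, `df` and `degenerate`.
#' @export
fit_au_curve <- function(bp, rho, nboot) {
  stopifnot(length(bp) == length(rho))
  nboot <- rep_len(nboot, length(bp))
  use <- bp > 0 & bp < 1
  if (sum(use) < 2) {
    lim <- if (mean(bp) >= 0.5) 1 - 1 / (2 * max(nboot))
           else 1 / (2 * max(nboot))
    return(list(au = lim, bp = round(mean(bp)), v = NA_real_,
                c = NA_real_, chisq = NA_real_, df = NA_integer_,
                degenerate = TRUE))
  }
  if (length(unique(rho[use])) < 2)  # cannot separate v from c
    return(list(au = NA_real_, bp = NA_real_, v = NA_real_, c = NA_real_,
                chisq = NA_real_, df = NA_integer_, degenerate = FALSE))
  bpu <- bp[use]; rhou <- rho[use]; nb <- nboot[use]
  psi <- stats::qnorm(1 - bpu)
  w <- nb * stats::dnorm(psi)^2 / (bpu * (1 - bpu))
  X <- cbind(sqrt(rhou), 1 / sqrt(rhou))
  coefs <- solve(crossprod(X, w * X), crossprod(X, w * psi))
  v <- coefs[1, 1]; cc <- coefs[2, 1]
  resid <- psi - as.vector(X %*% coefs)
  list(au = 1 - stats::pnorm(v - cc), bp = 1 - stats::pnorm(v + cc),
       v = v, c = cc, chisq = sum(w * resid^2),
       df = sum(use) - 2L, degenerate = FALSE)
}

# correlation distance tolerant of degenerate resampled profiles:
# undefined correlations are treated as uncorrelated (distance 1)
.boot_distance <- function(x, method) {
  if (method == "euclidean") return(stats::dist(x))
  C <- suppressWarnings(stats::cor(t(x), use = "pairwise.complete.obs"))
  C[!is.finite(C)] <- 0
  d <- 1 - C
  diag(d) <- 0
  stats::as.dist(d)
}

#' Multiscale bootstrap support for hierarchical clusters
#'
#' Clusters the rows of a similarity matrix on their profile distances,
#' then assesses every cluster of the observed dendrogram by multiscale
#' bootstrap: at each scale `r` the reference columns are resampled with
#' replacement to size `n_r = round(p * r)` (minimum 3), the resampled
#' matrix is reclustered with the identical code path, and a cluster scores
#' a hit when a replicate tree contains a node with the same leaf set.
#' The per-scale hit rates are the bootstrap probabilities `BP_r`, from
#' which [fit_au_curve()] extrapolates the approximately unbiased p-value
#' of each cluster.
#'
#' The root is present in every replicate by construction, so it carries no
#' multiscale information and is reported with `au = NA`.
#'
#' @param matrix numeric matrix (genes x reference columns), e.g. from
#'   [build_similarity_matrix()].
#' @param nboot bootstrap replicates per scale (default 1000).
#' @param scales relative resample sizes (default `seq(0.5, 1.4, 0.1)`).
#' @param seed integer seed; the full run is reproducible from it.
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage linkage passed to [hcluster()].
#' @return a `bootclust` object: `hclust` tree, `members` (leaf sets per
#'   node), `supports` data.frame (`node`, `size`, `au`, `bp`, `v`, `c`,
#'   `chisq`), the per-scale `bp_table`, and the resampling design.
#' @export
multiscale_bootstrap <- function(matrix, nboot = 1000,
                                 scales = seq(0.5, 1.4, by = 0.1),
                                 seed = 1, distance = "correlation",
                                 linkage = "average") {
  m <- as.matrix(matrix)
  if (any(scales <= 0)) stop_("scales must be positive")
  if (nboot < 100) stop_("nboot must be at least 100")
  p <- ncol(m)
  d0 <- profile_distance(m, distance)
  tree <- hcluster(d0, linkage)
  members <- tree_members(tree)
  sigs <- vapply(members, paste, "", collapse = "\r")
  nnode <- length(sigs)

  n_r <- pmax(3L, as.integer(round(p * scales)))
  rho <- n_r / p
  hits <- matrix(0L, nnode, length(scales))
  set.seed(seed)
  for (si in seq_along(scales)) {
    for (b in seq_len(nboot)) {
      cols <- sample.int(p, n_r[si], replace = TRUE)
      db <- .boot_distance(m[, cols, drop = FALSE], distance)
      tb <- hcluster(db, linkage)
      sb <- vapply(tree_members(tb), paste, "", collapse = "\r")
      hits[, si] <- hits[, si] + (sigs %in% sb)
    }
  }
  bp_table <- hits / nboot
  fits <- lapply(seq_len(nnode), function(k) {
    if (k == nnode)  # root: membership certain by construction
      return(list(au = NA_real_, bp = 1, v = NA_real_, c = NA_real_,
                  chisq = NA_real_, df = NA_integer_, degenerate = TRUE))
    fit_au_curve(bp_table[k, ], rho, nboot)
  })
  supports <- data.frame(
    node = seq_len(nnode),
    size = lengths(members),
    au = vapply(fits, `[[`, numeric(1), "au"),
    bp = vapply(fits, `[[`, numeric(1), "bp"),
    v = vapply(fits, `[[`, numeric(1), "v"),
    c = vapply(fits, `[[`, numeric(1), "c"),
    chisq = vapply(fits, `[[`, numeric(1), "chisq"))
  structure(list(hclust = tree, members = members, supports = supports,
                 bp_table = bp_table, scales = scales, n_r = n_r, rho = rho,
                 nboot = nboot, seed = seed, distance = distance,
                 linkage = linkage),
            class = "bootclust")
}

#' @export
print.bootclust <- function(x, ...) {
  cat(sprintf(paste0("Multiscale bootstrap clustering: %d genes, ",
                     "%d scales x %d replicates (seed %d)\n"),
              length(x$hclust$labels), length(x$scales), x$nboot, x$seed))
  cat(sprintf("  distance: %s, linkage: %s\n", x$distance, x$linkage))
  df <- x$supports
  df$au <- round(df$au, 3); df$bp <- round(df$bp, 3)
  print.data.frame(df[c("node", "size", "au", "bp")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.bootclust <- function(object, alpha = 0.95, ...) {
  picked <- pick_clusters(object, alpha = alpha)
  cat(sprintf("%d cluster(s) supported at au >= %.2f\n",
              length(picked), alpha))
  for (i in seq_along(picked))
    cat(sprintf("  cluster %d (%d genes): %s\n", i, length(picked[[i]]),
                paste(picked[[i]], collapse = ", ")))
  invisible(picked)
}

#' Plot a bootstrap-supported dendrogram
#'
#' Draws the observed dendrogram and writes each internal node's AU (and
#' optionally BP) value at the merge point, in the style of multiscale
#' bootstrap cluster plots.
#'
#' @param x a `bootclust` object.
#' @param show_bp also print BP values.
#' @param alpha nodes with `au >= alpha` are marked in red.
#' @param ... passed to `plot.hclust`.
#' @return `x`, invisibly.
#' @export
plot.bootclust <- function(x, show_bp = FALSE, alpha = 0.95, ...) {
  tree <- x$hclust
  plot(tree, ...)
  n <- length(tree$labels)
  xpos <- numeric(n - 1L)
  leafx <- match(seq_len(n), tree$order)
  pos <- function(node) if (node < 0) leafx[-node] else xpos[node]
  for (k in seq_len(n - 1L))
    xpos[k] <- mean(c(pos(tree$merge[k, 1]), pos(tree$merge[k, 2])))
  au <- x$supports$au
  lab <- ifelse(is.na(au), "", sprintf("%.2f", au))
  if (show_bp)
    lab <- paste0(lab, ifelse(is.na(au), "", "/"),
                  sprintf("%.2f", x$supports$bp))
  sig <- !is.na(au) & au >= alpha
  graphics::text(xpos, tree$height, lab,
                 col = ifelse(sig, "red", "grey30"),
                 cex = 0.7, pos = 3, offset = 0.2)
  invisible(x)
}

#' Select the supported clusters of a dendrogram
#'
#' Top-down traversal: a node whose AU p-value reaches `alpha` is reported
#' and its subtree pruned, yielding disjoint maximal supported clusters.
#' Leaves are never reported alone, and nodes with missing AU (including
#' the root of a [multiscale_bootstrap()] fit, whose support is structural
#' rather than evidential) are treated as unsupported.
#'
#' @param supports a `bootclust` object, or a data.frame with columns
#'   `node` and `au` (then `tree` is required).
#' @param tree an `hclust` object (ignored when `supports` is a
#'   `bootclust`).
#' @param alpha AU threshold (default 0.95).
#' @return list of character vectors of gene ids (possibly empty).
#' @export
pick_clusters <- function(supports, tree = NULL, alpha = 0.95) {
  if (inherits(supports, "bootclust")) {
    tree <- supports$hclust
    sup <- supports$supports
  } else {
    sup <- as.data.frame(supports)
    stopifnot(all(c("node", "au") %in% names(sup)),
              inherits(tree, "hclust"))
  }
  members <- tree_members(tree)
  au <- rep(NA_real_, length(members))
  au[sup$node] <- sup$au
  out <- list()
  visit <- function(node) {
    if (node < 0) return(invisible(NULL))  # leaves never reported alone
    if (!is.na(au[node]) && au[node] >= alpha) {
      out[[length(out) + 1L]] <<- members[[node]]
      return(invisible(NULL))
    }
    visit(tree$merge[node, 1])
    visit(tree$merge[node, 2])
  }
  visit(length(members))
  out
}
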