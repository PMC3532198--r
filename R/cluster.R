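#' Distance between gene similarity profiles
#'
#' Each clustered gene's profile is its row of the candidate x reference
#' similarity matrix. The default distance is `1 - Pearson correlation` of
#' two profiles (missing entries excluded pairwise); `"euclidean"` is also
#' available. A gene whose profile is constant has no defined correlation
#' and is reported by name; pairs sharing fewer than 3 complete columns are
#' an error.
#'
#' @param matrix numeric matrix, genes in rows (>= 3 rows, >= 2 columns).
#' @param method `"correlation"` (default) or `"euclidean"`.
#' @return a `dist` object over the row genes.
#' @export
profile_distance <- function(matrix, method = c("correlation", "euclidean")) {
  method <- match.arg(method)
  m <- as.matrix(matrix)
  if (nrow(m) < 3) stop_("need at least 3 genes (rows) to cluster")
  if (ncol(m) < 2) stop_("need at least 2 reference columns")
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (method == "euclidean") return(stats::dist(m))
  sds <- apply(m, 1, function(r) stats::sd(r, na.rm = TRUE))
  if (any(is.na(sds) | sds == 0)) {
    bad <- rownames(m)[which(is.na(sds) | sds == 0)]
    stop_("constant similarity profile for gene(s): ",
          paste(bad, collapse = ", "),
          "; correlation distance is undefined")
  }
  shared <- tcrossprod(!is.na(m))
  if (any(shared[upper.tri(shared)] < 3))
    stop_("some gene pairs share fewer than 3 complete columns")
  C <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  if (any(!is.finite(C)))
    stop_("undefined correlation between some profiles")
  d <- 1 - C
  diag(d) <- 0
  stats::as.dist(d)
}

#' Agglomerative hierarchical clustering with deterministic tie-breaking
#'
#' Standard bottom-up merging under average (UPGMA: inter-cluster distance
#' is the mean over all cross pairs), complete or single linkage. When
#' several pairs attain the minimal distance, the pair whose merged leaf
#' set is lexicographically smallest is merged — so the tree, and therefore
#' cluster membership matching across bootstrap replicates, is fully
#' determined by the distances.
#'
#' @param distances a `dist` object or symmetric distance matrix with
#'   labelled rows.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return an object of class `hclust` (plottable, `cutree`-able).
#' @export
hcluster <- function(distances, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  D <- as.matrix(distances)
  n <- nrow(D)
  if (n < 2) stop_("need at least 2 objects")
  labels <- rownames(D) %||% paste0("g", seq_len(n))
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  members <- as.list(labels)              # leaf labels per active slot
  id <- -seq_len(n)                        # hclust coding: leaves negative
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    sub <- D
    sub[!active, ] <- Inf
    sub[, !active] <- Inf
    mval <- min(sub)
    hits <- which(sub == mval, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    if (nrow(hits) > 1L) {
      sigs <- apply(hits, 1, function(h)
        paste(sort(c(members[[h[1]]], members[[h[2]]])), collapse = "\r"))
      hits <- hits[order(sigs)[1], , drop = FALSE]
    }
    i <- hits[1, 1]; j <- hits[1, 2]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- mval
    # Lance-Williams update into slot i
    di <- D[i, ]; dj <- D[j, ]
    newd <- switch(linkage,
      average  = (size[i] * di + size[j] * dj) / (size[i] + size[j]),
      complete = pmax(di, dj),
      single   = pmin(di, dj))
    D[i, ] <- newd
    D[, i] <- newd
    D[i, i] <- Inf
    active[j] <- FALSE
    size[i] <- size[i] + size[j]
    members[[i]] <- c(members[[i]], members[[j]])
    id[i] <- step
  }

  # leaf order for plotting: left-to-right traversal
  ord <- function(node) {
    if (node < 0) return(-node)
    c(ord(merge[node, 1]), ord(merge[node, 2]))
  }
  structure(list(merge = merge, height = height, order = ord(n - 1L),
                 labels = labels,
                 method = if (linkage == "average") "average" else linkage,
                 call = match.call(), dist.method = "profile"),
            class = "hclust")
}

#' Leaf membership of every internal node of a merge tree
#'
#' @param tree an `hclust` object.
#' @return list of character vectors (sorted leaf labels), one per merge
#'   row; the last element is the root (all leaves).
#' @export
tree_members <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  members <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    kids <- tree$merge[k, ]
    mem <- character(0)
    for (kid in kids)
      mem <- c(mem, if (kid < 0) tree$labels[-kid] else members[[kid]])
    members[[k]] <- sort(mem)
  }
  members
}

#' Export a dendrogram as Newick, with optional node labels
#'
#' Internal node labels (typically AU p-values) are written in the standard
#' position after the closing parenthesis; branch lengths are height
#' differences so the tree is ultrametric.
#'
#' @param tree an `hclust` object (or a [multiscale_bootstrap()] result,
#'   whose AU values label the nodes).
#' @param path output file path.
#' @param node_labels optional vector, one label per merge row.
#' @param digits label precision.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, node_labels = NULL, digits = 3) {
  if (inherits(tree, "bootclust")) {
    node_labels <- node_labels %||% tree$supports$au
    tree <- tree$hclust
  }
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$labels)
  lab <- function(k) {
    if (is.null(node_labels) || is.na(node_labels[k])) ""
    else format(round(node_labels[k], digits), scientific = FALSE)
  }
  build <- function(node, parent_h) {
    if (node < 0) {
      h <- parent_h
      return(sprintf("%s:%s", tree$labels[-node], format(h, digits = 10)))
    }
    h <- tree$height[node]
    kids <- vapply(tree$merge[node, ], build, "", parent_h = h)
    sprintf("(%s,%s)%s:%s", kids[1], kids[2], lab(node),
            format(parent_h - h, digits = 10))
  }
  root_h <- tree$height[n - 1L]
  kids <- vapply(tree$merge[n - 1L, ], build, "", parent_h = root_h)
  nwk <- sprintf("(%s,%s)%s;", kids[1], kids[2], lab(n - 1L))
  writeLines(nwk, path)
  invisible(path)
}
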