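#' Pool EST libraries
#'
#' Sums per-gene EST counts over the member libraries of each pool. Every
#' gene seen in either pool appears in both pooled count vectors (zero
#' filled), and the pool total is the sum of the declared library totals.
#'
#' @param table a [library_table()].
#' @param manifest a [pool_manifest()].
#' @return list with elements `A` and `B`, each a `library_pool`:
#'   `list(pool_id, libraries, counts, total)` with `counts` a named integer
#'   vector over the joint gene universe.
#' @export
pool_libraries <- function(table, manifest) {
  stopifnot(inherits(table, "library_table"),
            inherits(manifest, "pool_manifest"))
  totals <- library_totals(table)
  unk <- setdiff(c(manifest$A, manifest$B), names(totals))
  if (length(unk))
    stop_("manifest names unknown libraries: ", paste(unk, collapse = ", "))
  rows <- table[table$library_id %in% c(manifest$A, manifest$B), ,
                drop = FALSE]
  genes <- sort(unique(rows$gene_id))
  one <- function(p) {
    libs <- manifest[[p]]
    sub <- rows[rows$library_id %in% libs, , drop = FALSE]
    counts <- stats::setNames(integer(length(genes)), genes)
    if (nrow(sub)) {
      agg <- tapply(sub$est_count, factor(sub$gene_id, levels = genes), sum)
      agg[is.na(agg)] <- 0L
      counts[] <- as.integer(agg)
    }
    structure(list(pool_id = p, libraries = libs, counts = counts,
                   total = sum(totals[libs])),
              class = "library_pool")
  }
  list(A = one("A"), B = one("B"))
}

#' Transcript frequency
#'
#' A gene's EST count as a fraction of its pool's total EST count.
#'
#' @param count non-negative EST count(s).
#' @param pool_total positive pool total.
#' @param digits optional decimal places for the reporting variant (the
#'   published tables print 4).
#' @return numeric frequency in `[0, 1]`.
#' @export
transcript_frequency <- function(count, pool_total, digits = NULL) {
  if (any(pool_total <= 0)) stop_("pool_total must be positive")
  if (any(count < 0) || any(count > pool_total))
    stop_("count must lie in [0, pool_total]")
  f <- count / pool_total
  if (!is.null(digits)) f <- round_half_up(f, digits)
  f
}

#' Signed fold change between two transcript frequencies
#'
#' The magnitude is the ratio of the larger to the smaller frequency; the
#' sign is positive when the test pool is higher (magnitude 1, sign `+`, on
#' equality). A gene observed in only one pool has no finite fold: it is
#' flagged exclusive, encoded `+Inf` (test pool only) or `-Inf` (other pool
#' only) and printed as a bare `+`/`-` by [format_fold()].
#'
#' @param freq_test frequency in the test pool (vectorised).
#' @param freq_other frequency in the other pool.
#' @param digits optional decimal places for the reported magnitude (the
#'   published tables print 2).
#' @return numeric vector of signed folds (`+-Inf` for exclusives).
#' @examples
#' signed_fold(0.0224, 0.0018, digits = 2)  # +12.44
#' signed_fold(0.0002, 0.0224)              # -112
#' @export
signed_fold <- function(freq_test, freq_other, digits = NULL) {
  n <- max(length(freq_test), length(freq_other))
  ft <- rep_len(as.numeric(freq_test), n)
  fo <- rep_len(as.numeric(freq_other), n)
  if (any(ft < 0) || any(fo < 0)) stop_("frequencies must be non-negative")
  if (any(ft == 0 & fo == 0))
    stop_("both frequencies zero; pre-filter genes absent from both pools")
  mag <- pmax(ft, fo) / pmin(ft, fo)  # Inf when one side is 0
  if (!is.null(digits)) mag <- round_half_up(mag, digits)
  sgn <- ifelse(ft >= fo, 1, -1)      # equality reports +1
  sgn[fo == 0] <- 1
  sgn[ft == 0] <- -1
  sgn * mag
}

#' Format signed folds the way the published tables print them
#'
#' Finite folds become e.g. `"+12.44"`, `"-3.5"`; exclusives become a bare
#' `"+"` or `"-"`.
#'
#' @param fold numeric signed folds (`+-Inf` = exclusive).
#' @param digits decimal places for finite magnitudes.
#' @return character vector.
#' @export
format_fold <- function(fold, digits = 2) {
  out <- character(length(fold))
  fin <- is.finite(fold)
  out[!fin & fold > 0] <- "+"
  out[!fin & fold < 0] <- "-"
  mag <- round_half_up(abs(fold[fin]), digits)
  out[fin] <- paste0(ifelse(fold[fin] >= 0, "+", "-"),
                     vapply(mag, function(m) format(m, scientific = FALSE),
                            ""))
  out[is.na(fold)] <- NA_character_
  out
}

#' Parse printed fold-change strings back to signed numerics
#'
#' Inverse of [format_fold()]: `"+"`/`"-"` become `+Inf`/`-Inf`.
#'
#' @param x character vector such as `"+12.44"`, `"-112"`, `"+"`.
#' @return numeric vector.
#' @export
parse_fold <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  out[x == "+"] <- Inf
  out[x == "-"] <- -Inf
  fin <- !x %in% c("+", "-", "", NA)
  out[fin] <- as.numeric(x[fin])
  out
}

#' Two-sided Fisher exact test for a 2x2 pooled-count table
#'
#' Tests whether a gene's EST count differs between two pools, conditioning
#' on both margins. The two-sided p-value follows the point-probability
#' rule: the sum of hypergeometric probabilities of all tables (margins
#' fixed) whose probability does not exceed that of the observed table, with
#' a relative tolerance factor of `1 + 1e-7` guarding floating-point ties.
#' Probabilities are handled in log space and the enumeration runs over the
#' gene margin, so the cost is O(count_a + count_b) rather than O(total).
#'
#' @param count_a,count_b gene EST counts in pools A and B.
#' @param total_a,total_b pool totals.
#' @return the two-sided p-value in `(0, 1]`.
#' @export
fisher_exact_2x2 <- function(count_a, total_a, count_b, total_b) {
  if (any(c(count_a, total_a, count_b, total_b) < 0))
    stop_("counts and totals must be non-negative")
  if (count_a > total_a || count_b > total_b)
    stop_("counts cannot exceed their pool totals")
  k <- count_a + count_b
  if (k == 0) return(1)
  lo <- max(0, k - total_b)
  hi <- min(k, total_a)
  xs <- lo:hi
  lp <- stats::dhyper(xs, total_a, total_b, k, log = TRUE)
  lobs <- lp[match(count_a, xs)]
  min(1, sum(exp(lp[lp <= lobs + log(1 + 1e-7)])))
}

#' Run digital differential display on two pools
#'
#' Pools the libraries, computes per-gene transcript frequencies, signed
#' fold changes relative to the manifest's test pool, Fisher exact p-values
#' and Benjamini-Hochberg q-values (adjusted over all tested genes), then
#' applies the fold filter: finite folds below `min_fold` are dropped while
#' exclusive genes (seen in only one pool) are always retained. When `alpha`
#' is given, records with `q > alpha` are also dropped; by default no
#' significance filter is applied and the fold rule is the operative filter.
#'
#' @param table a [library_table()].
#' @param manifest a [pool_manifest()].
#' @param min_fold minimum absolute finite fold change (default 2).
#' @param alpha optional BH q-value cutoff (default `NULL`, off).
#' @return a `ddd_result` data.frame (one row per retained gene, sorted by
#'   absolute fold descending with exclusives first, ties by gene id) with
#'   columns `gene_id`, `count_a`, `count_b`, `freq_a`, `freq_b`, `fold`,
#'   `p_value`, `q_value`, `direction`, and attributes `n_tested`,
#'   `pool_totals`, `test_pool`.
#' @export
run_ddd <- function(table, manifest, min_fold = 2, alpha = NULL) {
  pools <- pool_libraries(table, manifest)
  ca <- pools$A$counts; cb <- pools$B$counts
  ta <- pools$A$total;  tb <- pools$B$total
  keep <- ca > 0 | cb > 0
  ca <- ca[keep]; cb <- cb[keep]
  genes <- names(ca)
  fa <- transcript_frequency(ca, ta)
  fb <- transcript_frequency(cb, tb)
  if (manifest$test_pool == "A") {
    ftest <- fa; fother <- fb
  } else {
    ftest <- fb; fother <- fa
  }
  fold <- signed_fold(ftest, fother)
  p <- mapply(fisher_exact_2x2, ca, ta, cb, tb)
  q <- stats::p.adjust(p, method = "BH")
  direction <- ifelse(ftest > fother, "up",
                      ifelse(ftest < fother, "down", "none"))
  res <- data.frame(gene_id = genes, count_a = as.integer(ca),
                    count_b = as.integer(cb), freq_a = fa, freq_b = fb,
                    fold = fold, p_value = p, q_value = q,
                    direction = direction, stringsAsFactors = FALSE,
                    row.names = NULL)
  keep2 <- is.infinite(res$fold) | abs(res$fold) >= min_fold
  if (!is.null(alpha)) keep2 <- keep2 & res$q_value <= alpha
  res <- res[keep2, , drop = FALSE]
  res <- res[order(-abs(res$fold), res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tested") <- length(genes)
  attr(res, "pool_totals") <- c(A = ta, B = tb)
  attr(res, "test_pool") <- manifest$test_pool
  attr(res, "min_fold") <- min_fold
  attr(res, "alpha") <- alpha
  class(res) <- c("ddd_result", "data.frame")
  res
}

#' @export
print.ddd_result <- function(x, ...) {
  tot <- attr(x, "pool_totals")
  cat(sprintf(paste0("DDD contrast: %d of %d tested genes kept ",
                     "(|fold| >= %s, test pool %s)\n"),
              nrow(x), attr(x, "n_tested"),
              format(attr(x, "min_fold")), attr(x, "test_pool")))
  cat(sprintf("  pool totals: A = %d, B = %d ESTs\n", tot[["A"]], tot[["B"]]))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' @export
summary.ddd_result <- function(object, ...) {
  f <- object$fold
  out <- c(kept = nrow(object), tested = attr(object, "n_tested"),
           up = sum(f > 0 & is.finite(f)),
           down = sum(f < 0 & is.finite(f)),
           exclusive_up = sum(f == Inf), exclusive_down = sum(f == -Inf))
  class(out) <- "summary.ddd_result"
  out
}

#' @export
print.summary.ddd_result <- function(x, ...) {
  cat("DDD summary\n")
  for (n in names(x)) cat(sprintf("  %-15s %d\n", n, x[[n]]))
  invisible(x)
}
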