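#' EST library count table
#'
#' Validates and classes a per-library EST count table. Each row gives the
#' EST count of one gene in one cDNA library; `library_total` is the declared
#' sequencing depth of the library (repeated on each of its rows), which may
#' exceed the sum of the tabulated counts because low-abundance transcripts
#' need not be listed.
#'
#' @param x data.frame with columns `library_id`, `tissue`, `condition`,
#'   `gene_id`, `est_count`, `library_total`.
#' @return a `library_table` (a validated data.frame).
#' @export
library_table <- function(x) {
  need <- c("library_id", "tissue", "condition", "gene_id",
            "est_count", "library_total")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_("library table is missing columns: ", paste(miss, collapse = ", "))
  x <- as.data.frame(x)[need]
  for (col in c("library_id", "tissue", "condition", "gene_id"))
    x[[col]] <- as.character(x[[col]])
  if (any(!is.finite(x$est_count)) || any(x$est_count < 0) ||
      any(x$est_count != round(x$est_count)))
    stop_("est_count must be non-negative integers")
  if (any(!is.finite(x$library_total)) || any(x$library_total <= 0) ||
      any(x$library_total != round(x$library_total)))
    stop_("library_total must be positive integers")
  x$est_count <- as.integer(x$est_count)
  x$library_total <- as.integer(x$library_total)
  key <- paste(x$library_id, x$gene_id, sep = "\r")
  if (anyDuplicated(key))
    stop_("duplicate (library_id, gene_id) rows: ",
          paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  tot <- tapply(x$library_total, x$library_id, function(v) length(unique(v)))
  if (any(tot > 1))
    stop_("inconsistent library_total within library: ",
          paste(names(tot)[tot > 1], collapse = ", "))
  sums <- tapply(x$est_count, x$library_id, sum)
  decl <- tapply(x$library_total, x$library_id, `[`, 1)
  bad <- names(sums)[sums > decl[names(sums)]]
  if (length(bad))
    stop_("library_total smaller than the sum of est_count for: ",
          paste(bad, collapse = ", "))
  rownames(x) <- NULL
  class(x) <- c("library_table", "data.frame")
  x
}

#' Declared totals of a library table
#'
#' @param x a `library_table`.
#' @return named integer vector, one declared total per library.
#' @export
library_totals <- function(x) {
  stopifnot(inherits(x, "library_table"))
  out <- tapply(x$library_total, x$library_id, `[`, 1)
  v <- as.integer(out)
  names(v) <- names(out)
  v
}

#' Read an EST library count table
#'
#' Tab-separated with a header line and optional `#` comment lines.
#'
#' @param path file path.
#' @return a [library_table()].
#' @export
read_library_table <- function(path) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  if (!any(keep)) stop_("empty library table file: ", path)
  lines <- raw[keep]
  lineno <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  nf <- lengths(fields)
  bad <- which(nf != length(header))[1]
  if (!is.na(bad))
    stop_("malformed row at line ", lineno[bad], " of ", path,
          " (expected ", length(header), " fields, got ", nf[bad], ")")
  body <- fields[-1]
  df <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  names(df) <- header
  for (col in c("est_count", "library_total")) {
    if (!col %in% names(df)) stop_("missing column '", col, "' in ", path)
    v <- suppressWarnings(as.numeric(df[[col]]))
    nb <- which(is.na(v))[1]
    if (!is.na(nb))
      stop_("non-numeric ", col, " at line ", lineno[nb + 1], " of ", path)
    df[[col]] <- v
  }
  library_table(df)
}

#' Write an EST library count table
#'
#' @param x a `library_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_library_table <- function(x, path) {
  stopifnot(inherits(x, "library_table"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pool manifest
#'
#' Assigns libraries to the two DDD pools. `test_pool` names the pool whose
#' direction defines the fold-change sign: a positive fold means the gene is
#' more abundant in the test pool. In the normal-lung contrast the lung pool
#' is the test pool; in the cancer contrast the tumour pool is.
#'
#' @param A,B character vectors of library ids (disjoint, non-empty).
#' @param roles named character vector giving the role (`"reference"` or
#'   `"query"`) of pools A and B.
#' @param test_pool `"A"` or `"B"`.
#' @return a `pool_manifest`.
#' @export
pool_manifest <- function(A, B, roles = c(A = "reference", B = "query"),
                          test_pool = "B") {
  A <- as.character(A); B <- as.character(B)
  if (!length(A) || !length(B)) stop_("pools A and B must be non-empty")
  if (length(intersect(A, B))) stop_("pools A and B must be disjoint")
  if (!identical(sort(names(roles)), c("A", "B")) ||
      !all(roles %in% c("reference", "query")))
    stop_("roles must name pools A and B as 'reference'/'query'")
  if (!test_pool %in% c("A", "B")) stop_("test_pool must be 'A' or 'B'")
  structure(list(A = A, B = B, roles = roles[c("A", "B")],
                 test_pool = test_pool),
            class = "pool_manifest")
}

#' @export
print.pool_manifest <- function(x, ...) {
  cat("Pool manifest\n")
  for (p in c("A", "B"))
    cat(sprintf("  pool %s (%s%s): %d libraries\n", p, x$roles[[p]],
                if (identical(x$test_pool, p)) ", test pool" else "",
                length(x[[p]])))
  invisible(x)
}

#' Read a plain gene list
#'
#' One identifier per line; `#` starts a comment; blank lines ignored.
#' Order is preserved; duplicates are removed with a warning.
#'
#' @param path file path.
#' @return character vector of unique ids in file order.
#' @export
read_gene_list <- function(path) {
  raw <- readLines(path, warn = FALSE)
  ids <- trimws(sub("#.*$", "", raw))
  ids <- ids[nzchar(ids)]
  if (!length(ids)) stop_("gene list file has no identifiers: ", path)
  if (anyDuplicated(ids)) {
    warn_("dropping ", sum(duplicated(ids)), " duplicate id(s) in ", path)
    ids <- ids[!duplicated(ids)]
  }
  ids
}

#' Write a plain gene list
#'
#' @param ids character vector of identifiers.
#' @param path output file path.
#' @param comment optional comment line written at the top.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(ids, path, comment = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(comment)) writeLines(paste("#", comment), con)
  writeLines(as.character(ids), con)
  invisible(path)
}

#' Write pipeline results to a tab-separated file
#'
#' One writer surface for the pipeline's tabular outputs. `kind` selects the
#' schema: `"ddd"` mirrors the DDD record fields (folds formatted with
#' exclusive `+`/`-` markers, frequencies at 4 decimals), `"similarity_matrix"`
#' writes the matrix with row/column gene ids, `"clusters"` writes
#' (cluster, gene) pairs, and `"panels"` writes the eight-column panel report.
#' An empty record set yields a header-only file.
#'
#' @param x the object to write (see Details).
#' @param path output file path.
#' @param kind one of `"ddd"`, `"similarity_matrix"`, `"clusters"`, `"panels"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path,
                          kind = c("ddd", "similarity_matrix",
                                   "clusters", "panels")) {
  kind <- match.arg(kind)
  switch(kind,
    ddd = {
      df <- as.data.frame(x)
      if (nrow(df)) {
        df$freq_a <- sprintf("%.4f", df$freq_a)
        df$freq_b <- sprintf("%.4f", df$freq_b)
        df$fold <- format_fold(df$fold)
      }
      cols <- c("gene_id", "count_a", "count_b", "freq_a", "freq_b",
                "fold", "p_value", "q_value", "direction")
      empty <- as.data.frame(stats::setNames(
        rep(list(character(0)), length(cols)), cols))
      utils::write.table(if (nrow(df)) df[cols] else empty, path,
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    similarity_matrix = {
      m <- as.matrix(x)
      df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    clusters = {
      stopifnot(is.list(x))
      df <- if (length(x)) {
        data.frame(cluster = rep(seq_along(x), lengths(x)),
                   gene_id = unlist(x, use.names = FALSE))
      } else data.frame(cluster = integer(0), gene_id = character(0))
      utils::write.table(df, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    panels = {
      df <- as.data.frame(x)
      cols <- c("panel", "gene", "ddd1_freq_a", "ddd1_freq_b", "ddd1_fold",
                "ddd2_freq_a", "ddd2_freq_b", "ddd2_fold")
      if (nrow(df)) {
        for (cc in grep("_freq_", cols, value = TRUE))
          df[[cc]] <- ifelse(is.na(df[[cc]]), "", sprintf("%.4f", df[[cc]]))
        for (cc in c("ddd1_fold", "ddd2_fold"))
          if (is.numeric(df[[cc]])) df[[cc]] <- format_fold(df[[cc]])
        out <- df[cols]
      } else {
        out <- as.data.frame(stats::setNames(
          rep(list(character(0)), length(cols)), cols))
      }
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  invisible(path)
}

#' Read back a similarity matrix written by [write_results()]
#'
#' @param path file path.
#' @return numeric matrix with row and column gene ids.
#' @export
read_similarity_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
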