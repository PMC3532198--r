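#' Assemble biomarker panels from supported clusters
#'
#' Intersects each supported cluster (in dendrogram order) with the
#' prioritised biomarker list; non-empty intersections become panels
#' numbered 1..k, and each member is joined with its frequencies and fold
#' changes from the two DDD contrasts. A biomarker found in neither
#' contrast raises a warning and gets blank statistics.
#'
#' @param clusters list of character vectors (e.g. from [pick_clusters()]),
#'   in dendrogram order.
#' @param biomarkers character vector of biomarker gene ids.
#' @param ddd1,ddd2 `ddd_result` objects (or data.frames with `gene_id`,
#'   `freq_a`, `freq_b`, `fold`).
#' @param labels optional character vector of free-text panel labels,
#'   recycled over panels.
#' @return a `panel_report` data.frame with columns `panel`, `label`,
#'   `gene`, `ddd1_freq_a`, `ddd1_freq_b`, `ddd1_fold`, `ddd2_freq_a`,
#'   `ddd2_freq_b`, `ddd2_fold` (folds numeric, `+-Inf` = exclusive).
#' @export
assemble_panels <- function(clusters, biomarkers, ddd1, ddd2,
                            labels = NULL) {
  biomarkers <- as.character(biomarkers)
  ddd1 <- as.data.frame(ddd1); ddd2 <- as.data.frame(ddd2)
  pull <- function(ddd, genes, what) {
    i <- match(genes, ddd$gene_id)
    ddd[[what]][i]
  }
  panels <- list()
  for (cl in clusters) {
    hit <- intersect(cl, biomarkers)
    if (!length(hit)) next
    k <- length(panels) + 1L
    missing_both <- !(hit %in% ddd1$gene_id) & !(hit %in% ddd2$gene_id)
    if (any(missing_both))
      warn_("biomarker(s) absent from both contrasts: ",
            paste(hit[missing_both], collapse = ", "))
    panels[[k]] <- data.frame(
      panel = k, gene = hit,
      ddd1_freq_a = pull(ddd1, hit, "freq_a"),
      ddd1_freq_b = pull(ddd1, hit, "freq_b"),
      ddd1_fold = pull(ddd1, hit, "fold"),
      ddd2_freq_a = pull(ddd2, hit, "freq_a"),
      ddd2_freq_b = pull(ddd2, hit, "freq_b"),
      ddd2_fold = pull(ddd2, hit, "fold"),
      stringsAsFactors = FALSE)
  }
  out <- if (length(panels)) do.call(rbind, panels) else
    data.frame(panel = integer(0), gene = character(0),
               ddd1_freq_a = numeric(0), ddd1_freq_b = numeric(0),
               ddd1_fold = numeric(0), ddd2_freq_a = numeric(0),
               ddd2_freq_b = numeric(0), ddd2_fold = numeric(0),
               stringsAsFactors = FALSE)
  out$label <- if (!is.null(labels) && nrow(out))
    rep_len(as.character(labels), max(out$panel))[out$panel]
  else rep(NA_character_, nrow(out))
  out <- out[c("panel", "label", setdiff(names(out), c("panel", "label")))]
  rownames(out) <- NULL
  class(out) <- c("panel_report", "data.frame")
  out
}

#' @export
print.panel_report <- function(x, ...) {
  cat("Biomarker panel report:", length(unique(x$panel)), "panel(s),",
      nrow(x), "genes\n")
  df <- as.data.frame(x)
  df$ddd1_fold <- format_fold(df$ddd1_fold)
  df$ddd2_fold <- format_fold(df$ddd2_fold)
  print.data.frame(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tally fold-change directions within a panel
#'
#' @param report a `panel_report` or the Table-2 style fixture data.frame.
#' @param contrast `"ddd1"` or `"ddd2"`.
#' @param panel optional panel number; default tallies all rows.
#' @return named integer vector `n_up`, `n_down`, `n_exclusive_up`,
#'   `n_exclusive_down` (finite folds vs exclusive markers).
#' @export
count_direction <- function(report, contrast = c("ddd1", "ddd2"),
                            panel = NULL) {
  contrast <- match.arg(contrast)
  df <- as.data.frame(report)
  if (!is.null(panel)) df <- df[df$panel %in% panel, , drop = FALSE]
  fold <- df[[paste0(contrast, "_fold")]]
  if (is.character(fold)) fold <- parse_fold(fold)
  fold <- fold[!is.na(fold)]
  c(n_up = sum(is.finite(fold) & fold > 0),
    n_down = sum(is.finite(fold) & fold < 0),
    n_exclusive_up = sum(fold == Inf),
    n_exclusive_down = sum(fold == -Inf))
}

#' Published lung-cancer signature biomarker table (packaged fixture)
#'
#' The 38 biomarkers of the four published panels, transcribed verbatim
#' with their printed pool frequencies and fold changes from both
#' contrasts, including the exclusive `+`/`-` markers and the table's own
#' internal inconsistencies (e.g. the two different SFTPA1 pool-A
#' frequencies). Fold columns are kept as printed strings; use
#' [parse_fold()] for numerics.
#'
#' @return data.frame with 38 rows and columns `panel`, `cluster`, `class`,
#'   `gene`, `ddd1_freq_a`, `ddd1_freq_b`, `ddd1_fold`, `ddd2_freq_a`,
#'   `ddd2_freq_b`, `ddd2_fold`.
#' @export
table2_fixture <- function() {
  path <- system.file("extdata", "table2_biomarker_panels.tsv",
                      package = "dddclust", mustWork = TRUE)
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = c(panel = "integer",
                                         cluster = "integer",
                                         class = "character",
                                         gene = "character",
                                         ddd1_freq_a = "numeric",
                                         ddd1_freq_b = "numeric",
                                         ddd1_fold = "character",
                                         ddd2_freq_a = "numeric",
                                         ddd2_freq_b = "numeric",
                                         ddd2_fold = "character"))
  stopifnot(nrow(df) == 38,
            identical(as.integer(table(df$panel)), c(2L, 9L, 21L, 6L)))
  df
}
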