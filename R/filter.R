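#' Candidate gene set with a provenance log
#'
#' An ordered set of gene ids plus a log recording, for each narrowing step,
#' how many ids went in, were removed, and came out — so the published
#' candidate arithmetic (e.g. 76 - 18 = 58) is auditable and reproducible.
#'
#' @param ids character vector of gene ids (order kept, must be unique).
#' @param log optional existing provenance data.frame.
#' @return a `candidate_set`.
#' @export
candidate_set <- function(ids, log = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop_("candidate ids must be unique")
  log <- log %||% data.frame(step = character(0), n_before = integer(0),
                             n_removed = integer(0), n_after = integer(0),
                             stringsAsFactors = FALSE)
  structure(list(ids = ids, log = log), class = "candidate_set")
}

.log_step <- function(cs, step, n_before, n_after) {
  cs$log <- rbind(cs$log, data.frame(
    step = step, n_before = as.integer(n_before),
    n_removed = as.integer(n_before - n_after),
    n_after = as.integer(n_after), stringsAsFactors = FALSE))
  cs
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("Candidate set:", length(x$ids), "genes\n")
  if (nrow(x$log)) {
    cat("Provenance:\n")
    print.data.frame(x$log, row.names = FALSE)
  }
  invisible(x)
}

.ddd_ids <- function(x) {
  if (inherits(x, "ddd_result") || is.data.frame(x)) x$gene_id
  else as.character(x)
}

#' Intersect the two DDD contrasts
#'
#' Keeps the genes differentially expressed in both contrasts, ordered by
#' the second contrast's absolute fold change (exclusives first, ties by
#' gene id), and logs the step.
#'
#' @param ddd1,ddd2 `ddd_result` objects (or data.frames with `gene_id`;
#'   ordering falls back to `ddd2` row order if it has no `fold` column).
#' @return a [candidate_set()].
#' @export
intersect_contrasts <- function(ddd1, ddd2) {
  ids1 <- .ddd_ids(ddd1); ids2 <- .ddd_ids(ddd2)
  if (!length(ids1) || !length(ids2))
    stop_("both contrasts must be non-empty")
  common <- ids2[ids2 %in% ids1]
  if (is.data.frame(ddd2) && "fold" %in% names(ddd2)) {
    sub <- ddd2[ddd2$gene_id %in% common, , drop = FALSE]
    common <- sub$gene_id[order(-abs(sub$fold), sub$gene_id)]
  }
  cs <- candidate_set(common)
  .log_step(cs, "intersect_contrasts", length(ids1), length(common))
}

#' Remove genes on an exclusion list
#'
#' Order-preserving set difference with a logged step; used to subtract
#' pan-cancer genes from the candidate set.
#'
#' @param candidates a [candidate_set()].
#' @param exclusion character vector of gene ids to remove.
#' @param step label recorded in the provenance log.
#' @return the narrowed [candidate_set()].
#' @export
exclude_genes <- function(candidates, exclusion, step = "exclude_genes") {
  stopifnot(inherits(candidates, "candidate_set"))
  before <- length(candidates$ids)
  candidates$ids <- setdiff(candidates$ids, as.character(exclusion))
  .log_step(candidates, step, before, length(candidates$ids))
}

#' Map candidate identifiers to a canonical namespace
#'
#' Translates source ids through a mapping table; sources without a mapping
#' are dropped with a warning and canonical duplicates collapse keeping the
#' first occurrence (this is how identifier conversion shrinks the
#' published candidate counts). The step is logged.
#'
#' @param candidates a [candidate_set()].
#' @param mapping data.frame with columns `source`, `canonical`; source keys
#'   must be unique.
#' @return the mapped [candidate_set()].
#' @export
map_identifiers <- function(candidates, mapping) {
  stopifnot(inherits(candidates, "candidate_set"))
  mapping <- as.data.frame(mapping)
  stopifnot(all(c("source", "canonical") %in% names(mapping)))
  if (anyDuplicated(mapping$source))
    stop_("mapping has duplicate source keys")
  before <- length(candidates$ids)
  hit <- match(candidates$ids, as.character(mapping$source))
  if (anyNA(hit))
    warn_(sum(is.na(hit)), " candidate id(s) had no mapping and were dropped")
  mapped <- as.character(mapping$canonical)[hit[!is.na(hit)]]
  mapped <- mapped[!duplicated(mapped)]
  candidates$ids <- mapped
  .log_step(candidates, "map_identifiers", before, length(mapped))
}
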