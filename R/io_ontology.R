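.NS_LONG <- c(BP = "biological_process", MF = "molecular_function",
              CC = "cellular_component")

.ns_short <- function(ns) {
  out <- ns
  long <- match(ns, .NS_LONG)
  out[!is.na(long)] <- names(.NS_LONG)[long[!is.na(long)]]
  bad <- !out %in% names(.NS_LONG)
  if (any(bad)) stop_("unknown ontology namespace: ",
                      paste(unique(ns[bad]), collapse = ", "))
  out
}

#' Ontology graph
#'
#' A directed acyclic graph of ontology terms. Edges point from child to
#' parent and carry a relation type (`is_a` or `part_of`); namespaces are
#' kept orthogonal (no cross-namespace edges), mirroring the three GO
#' sub-ontologies BP, MF and CC.
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`
#'   (`BP`/`MF`/`CC` or the long GO names).
#' @param edges data.frame with columns `child`, `parent`, `relation`.
#' @return a `go_ontology` object.
#' @export
ontology <- function(terms, edges) {
  terms <- as.data.frame(terms)
  edges <- as.data.frame(edges)
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)))
  if (!nrow(edges))
    edges <- data.frame(child = character(0), parent = character(0),
                        relation = character(0))
  stopifnot(all(c("child", "parent", "relation") %in% names(edges)))
  terms$id <- as.character(terms$id)
  terms$name <- as.character(terms$name)
  terms$namespace <- .ns_short(as.character(terms$namespace))
  if (anyDuplicated(terms$id)) stop_("duplicate term ids")
  for (col in c("child", "parent", "relation"))
    edges[[col]] <- as.character(edges[[col]])
  if (!all(edges$relation %in% c("is_a", "part_of")))
    stop_("edge relations must be is_a or part_of")
  unk <- setdiff(c(edges$child, edges$parent), terms$id)
  if (length(unk)) stop_("edges reference unknown terms: ",
                         paste(utils::head(unk, 3), collapse = ", "))
  ns <- stats::setNames(terms$namespace, terms$id)
  if (any(ns[edges$child] != ns[edges$parent]))
    stop_("cross-namespace edges are not allowed")

  # acyclicity via Kahn's algorithm on child -> parent edges
  indeg <- stats::setNames(integer(nrow(terms)), terms$id)
  tab <- table(edges$parent)
  indeg[names(tab)] <- as.integer(tab)
  out_of <- split(edges$parent, factor(edges$child, levels = terms$id))
  queue <- terms$id[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (p in out_of[[v]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen < nrow(terms)) {
    member <- names(indeg)[indeg > 0L][1]
    stop_("ontology contains a cycle involving term ", member)
  }

  f <- factor(edges$child, levels = terms$id)
  parents <- split(edges$parent, f)
  rels <- split(edges$relation, f)
  children <- split(edges$child, factor(edges$parent, levels = terms$id))
  roots <- terms$id[lengths(parents) == 0L]
  structure(list(terms = terms, edges = edges, parents = parents,
                 relations = rels, children = children, roots = roots,
                 namespace = ns),
            class = "go_ontology")
}

#' @export
print.go_ontology <- function(x, ...) {
  cat("Ontology graph:", nrow(x$terms), "terms,", nrow(x$edges), "edges\n")
  print(table(x$terms$namespace))
  invisible(x)
}

#' Term ids of an ontology, optionally restricted to one namespace
#'
#' @param x a `go_ontology`.
#' @param namespace optional `"BP"`, `"MF"` or `"CC"`.
#' @return character vector of term ids.
#' @export
ontology_terms <- function(x, namespace = NULL) {
  stopifnot(inherits(x, "go_ontology"))
  if (is.null(namespace)) return(x$terms$id)
  x$terms$id[x$terms$namespace == .ns_short(namespace)]
}

#' Descendants of a term (the term plus everything below it)
#'
#' @param x a `go_ontology`.
#' @param id term id.
#' @return character vector of term ids.
#' @export
term_descendants <- function(x, id) {
  stopifnot(inherits(x, "go_ontology"))
  if (!id %in% x$terms$id) stop_("unknown term: ", id)
  seen <- character(0)
  queue <- id
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    if (v %in% seen) next
    seen <- c(seen, v)
    queue <- c(queue, x$children[[v]])
  }
  seen
}

#' Read an OBO 1.2 ontology file
#'
#' Parses the subset needed here: `[Term]` stanzas with `id`, `name`,
#' `namespace`, `is_a`, `relationship: part_of` and `is_obsolete` tags.
#' Obsolete terms (and their edges) are dropped; the result is validated as
#' an acyclic, namespace-orthogonal graph.
#'
#' @param path file path.
#' @return a [ontology()] object.
#' @export
read_obo <- function(path) {
  raw <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", raw)
  term_starts <- grep("^\\[Term\\]$", raw)
  ids <- names <- nss <- character(0)
  ec <- ep <- er <- character(0)
  for (s in term_starts) {
    nxt <- starts[starts > s]
    block <- raw[(s + 1):(if (length(nxt)) nxt[1] - 1 else length(raw))]
    block <- block[nzchar(trimws(block))]
    tagval <- function(tag) {
      v <- sub(paste0("^", tag, ":\\s*"), "",
               grep(paste0("^", tag, ":"), block, value = TRUE))
      sub("\\s*!.*$", "", v)
    }
    if (any(grepl("^is_obsolete:\\s*true", block))) next
    id <- tagval("id")
    if (!length(id)) stop_("[Term] stanza without id in ", path)
    ids <- c(ids, id[1])
    nm <- tagval("name")
    names <- c(names, if (length(nm)) nm[1] else id[1])
    ns <- tagval("namespace")
    if (!length(ns)) stop_("term ", id[1], " has no namespace")
    nss <- c(nss, ns[1])
    for (p in tagval("is_a")) {
      ec <- c(ec, id[1]); ep <- c(ep, trimws(p)); er <- c(er, "is_a")
    }
    rel <- tagval("relationship")
    for (r in rel) {
      parts <- strsplit(trimws(r), "\\s+")[[1]]
      if (length(parts) >= 2 && parts[1] == "part_of") {
        ec <- c(ec, id[1]); ep <- c(ep, parts[2]); er <- c(er, "part_of")
      }
    }
  }
  if (!length(ids)) stop_("no [Term] stanzas found in ", path)
  keep <- ep %in% ids  # edges to obsolete/absent parents are dropped
  ontology(data.frame(id = ids, name = names, namespace = nss,
                      stringsAsFactors = FALSE),
           data.frame(child = ec[keep], parent = ep[keep],
                      relation = er[keep], stringsAsFactors = FALSE))
}

#' Write an ontology as OBO 1.2
#'
#' @param x a `go_ontology`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(x, path) {
  stopifnot(inherits(x, "go_ontology"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(x$terms))) {
    id <- x$terms$id[i]
    lines <- c("[Term]",
               paste0("id: ", id),
               paste0("name: ", x$terms$name[i]),
               paste0("namespace: ", .NS_LONG[[x$terms$namespace[i]]]))
    pars <- x$parents[[id]]
    rels <- x$relations[[id]]
    for (j in seq_along(pars)) {
      lines <- c(lines, if (rels[j] == "is_a") paste0("is_a: ", pars[j])
                        else paste0("relationship: part_of ", pars[j]))
    }
    writeLines(c(lines, ""), con)
  }
  invisible(path)
}

#' Gene annotation sets
#'
#' Per-gene, per-namespace sets of directly annotated ontology terms; the
#' set sizes are the m and n of the best-match-average gene similarity.
#'
#' @param df data.frame with columns `gene_id`, `term_id`, `namespace`.
#'   Genes may appear with zero rows via `genes`.
#' @param genes optional character vector of gene ids to include even when
#'   unannotated (empty sets).
#' @param ontology optional `go_ontology`; if given, annotation terms are
#'   checked against it (see `on_missing`).
#' @param on_missing `"warn"` drops annotations to unknown terms with a
#'   warning, `"error"` fails.
#' @return a `gene_annotation` object.
#' @export
gene_annotation <- function(df, genes = NULL, ontology = NULL,
                            on_missing = c("warn", "error")) {
  on_missing <- match.arg(on_missing)
  df <- as.data.frame(df)
  stopifnot(all(c("gene_id", "term_id", "namespace") %in% names(df)))
  df$gene_id <- as.character(df$gene_id)
  df$term_id <- as.character(df$term_id)
  df$namespace <- .ns_short(as.character(df$namespace))
  if (!is.null(ontology)) {
    stopifnot(inherits(ontology, "go_ontology"))
    bad <- !df$term_id %in% ontology$terms$id
    if (any(bad)) {
      msg <- paste0(sum(bad), " annotation(s) to terms absent from the ",
                    "ontology: ",
                    paste(utils::head(unique(df$term_id[bad]), 3),
                          collapse = ", "))
      if (on_missing == "error") stop_(msg)
      warn_(msg, " (dropped)")
      df <- df[!bad, , drop = FALSE]
    }
  }
  df <- df[!duplicated(df[c("gene_id", "term_id", "namespace")]), ,
           drop = FALSE]
  all_genes <- unique(c(df$gene_id, as.character(genes %||% character(0))))
  sets <- lapply(stats::setNames(all_genes, all_genes), function(g) {
    rows <- df[df$gene_id == g, , drop = FALSE]
    lapply(stats::setNames(names(.NS_LONG), names(.NS_LONG)),
           function(ns) sort(rows$term_id[rows$namespace == ns]))
  })
  structure(list(sets = sets), class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  n <- length(x$sets)
  cat("Gene annotation:", n, "genes\n")
  invisible(x)
}

#' Genes present in an annotation
#'
#' @param x a `gene_annotation`.
#' @return character vector of gene ids.
#' @export
annotation_genes <- function(x) {
  stopifnot(inherits(x, "gene_annotation"))
  names(x$sets)
}

#' Direct term set of one gene in one namespace
#'
#' @param x a `gene_annotation`.
#' @param gene gene id (must be present).
#' @param namespace `"BP"`, `"MF"` or `"CC"`.
#' @return character vector of term ids (possibly empty).
#' @export
annotation_terms <- function(x, gene, namespace) {
  stopifnot(inherits(x, "gene_annotation"))
  if (!gene %in% names(x$sets)) stop_("unknown gene: ", gene)
  x$sets[[gene]][[.ns_short(namespace)]]
}

#' Read gene annotations from a GAF 2.x file
#'
#' Uses columns 2 (object id), 4 (qualifier), 5 (term id) and 9 (aspect).
#' Rows whose qualifier contains `NOT` are dropped; aspects P/F/C map to
#' namespaces BP/MF/CC; duplicate annotations collapse to one. A gene with
#' no remaining rows cannot be represented in GAF, so round-trips are exact
#' on annotated genes only.
#'
#' @param path file path.
#' @inheritParams gene_annotation
#' @return a [gene_annotation()] object.
#' @export
read_gaf <- function(path, ontology = NULL, on_missing = c("warn", "error")) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[!grepl("^!", raw) & nzchar(raw)]
  if (!length(raw)) stop_("GAF file has no annotation lines: ", path)
  fields <- strsplit(raw, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 9)[1]
  if (!is.na(short)) stop_("GAF line with fewer than 9 columns: line ", short)
  m <- do.call(rbind, lapply(fields, `[`, c(2, 4, 5, 9)))
  keep <- !grepl("\\bNOT\\b", m[, 2])
  m <- m[keep, , drop = FALSE]
  aspect <- c(P = "BP", F = "MF", C = "CC")[m[, 4]]
  if (anyNA(aspect)) stop_("unknown GAF aspect: ",
                           paste(unique(m[is.na(aspect), 4]), collapse = ", "))
  gene_annotation(data.frame(gene_id = m[, 1], term_id = m[, 3],
                             namespace = aspect, stringsAsFactors = FALSE),
                  ontology = ontology, on_missing = on_missing)
}

#' Write gene annotations as GAF 2.2
#'
#' @param x a `gene_annotation`.
#' @param path output file path.
#' @param db database label for column 1.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(x, path, db = "SYN") {
  stopifnot(inherits(x, "gene_annotation"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("!gaf-version: 2.2", con)
  aspect <- c(BP = "P", MF = "F", CC = "C")
  for (g in names(x$sets)) {
    for (ns in names(x$sets[[g]])) {
      for (t in x$sets[[g]][[ns]]) {
        writeLines(paste(db, g, g, "involved_in", t, "SYN:0000001", "IEA",
                         "", aspect[[ns]], "", "", "gene", "taxon:9606",
                         "20120101", db, "", "", sep = "\t"), con)
      }
    }
  }
  invisible(path)
}
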