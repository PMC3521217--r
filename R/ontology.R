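# Gene Ontology DAG parsing and annotation handling.
#
# The biological-process branch of GO is a rooted directed acyclic graph in
# which a term may have several parents. Everything downstream (enrichment,
# term-frequency propagation, background matching) is defined over this DAG
# and over an evidence-filtered gene <-> term annotation table.

#' Default experimental evidence codes
#'
#' Annotation rows are kept only when their evidence code reflects direct
#' experimental support or curator inference: EXP (inferred from experiment),
#' IDA (direct assay), IPI (physical interaction), IMP (mutant phenotype),
#' IGI (genetic interaction), IEP (expression pattern) and IC (inferred by
#' curator). Electronic annotations (IEA) and other non-experimental codes
#' are dropped by default.
#'
#' @export
experimental_evidence_codes <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "IC")

new_ontology_dag <- function(terms, parents, namespace, obsolete = character(0)) {
  terms <- sort(unique(terms))
  # normalize: every term keyed, parents sorted, roots get character(0)
  full <- stats::setNames(vector("list", length(terms)), terms)
  for (t in terms) {
    p <- parents[[t]]
    full[[t]] <- if (is.null(p)) character(0) else sort(unique(p))
  }
  parents <- full
  children <- invert_parent_map(parents, terms)
  structure(
    list(terms = terms,
         parents = parents,
         children = children,
         namespace = namespace,
         obsolete = sort(unique(obsolete))),
    class = "ontology_dag")
}

invert_parent_map <- function(parents, terms) {
  children <- vector("list", length(terms))
  names(children) <- terms
  for (child in names(parents)) {
    for (p in parents[[child]]) {
      children[[p]] <- c(children[[p]], child)
    }
  }
  lapply(children, function(x) sort(unique(x)))
}

#' @export
print.ontology_dag <- function(x, ...) {
  n_edges <- sum(lengths(x$parents))
  cat(sprintf("<ontology_dag> %d terms, %d is_a edges, namespace '%s'\n",
              length(x$terms), n_edges, x$namespace))
  invisible(x)
}

#' Parse an OBO ontology file into a DAG
#'
#' Reads OBO 1.2/1.4 flat files, keeping only non-obsolete terms of the
#' requested namespace. `is_a` relations are recorded as parent links;
#' `part_of` relationships can optionally be included as additional parent
#' links. Edges that point at terms outside the kept namespace (or at
#' obsolete terms) are discarded. Acyclicity is verified after parsing.
#'
#' @param path path to an OBO file.
#' @param namespace ontology branch to keep, e.g. `"biological_process"`.
#' @param include_part_of also treat `relationship: part_of` as a parent link
#'   (default `FALSE`; only `is_a` builds the DAG).
#' @return an `ontology_dag` with fields `terms`, `parents` (term -> character
#'   vector of parent terms), `children`, `namespace`, `obsolete` (ids of
#'   obsolete terms that were seen and excluded).
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("format-version: 1.2", "",
#'   "[Term]", "id: GO:1", "name: root", "namespace: biological_process", "",
#'   "[Term]", "id: GO:2", "name: child", "namespace: biological_process",
#'   "is_a: GO:1 ! root"), obo)
#' dag <- parse_obo(obo, "biological_process")
#' dag$parents[["GO:2"]]
#' @export
parse_obo <- function(path, namespace = "biological_process",
                      include_part_of = FALSE) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)

  terms <- character(0)
  obsolete <- character(0)
  term_ns <- character(0)
  edges_child <- character(0)
  edges_parent <- character(0)

  in_term <- FALSE
  cur_id <- NA_character_
  cur_ns <- NA_character_
  cur_obsolete <- FALSE
  cur_parents <- character(0)

  flush_term <- function() {
    if (is.na(cur_id)) return()
    terms[[length(terms) + 1L]] <<- cur_id
    term_ns[[length(term_ns) + 1L]] <<- cur_ns
    if (cur_obsolete) obsolete[[length(obsolete) + 1L]] <<- cur_id
    if (length(cur_parents)) {
      edges_child <<- c(edges_child, rep(cur_id, length(cur_parents)))
      edges_parent <<- c(edges_parent, cur_parents)
    }
  }

  for (i in seq_along(lines)) {
    line <- sub("!.*$", "", lines[[i]])  # strip trailing comments
    line <- trimws(line)
    if (line == "") next
    if (startsWith(line, "[")) {
      flush_term()
      in_term <- identical(line, "[Term]")
      cur_id <- NA_character_
      cur_ns <- NA_character_
      cur_obsolete <- FALSE
      cur_parents <- character(0)
      next
    }
    if (!in_term) next
    if (!grepl("^[A-Za-z_-]+:", line)) {
      stop(sprintf("malformed OBO stanza line %d: '%s'", i, lines[[i]]))
    }
    key <- sub(":.*$", "", line)
    value <- trimws(sub("^[A-Za-z_-]+:", "", line))
    if (key == "id") {
      cur_id <- value
    } else if (key == "namespace") {
      cur_ns <- value
    } else if (key == "is_obsolete") {
      cur_obsolete <- identical(tolower(value), "true")
    } else if (key == "is_a") {
      cur_parents <- c(cur_parents, sub("\\s.*$", "", value))
    } else if (key == "relationship" && include_part_of) {
      parts <- strsplit(value, "\\s+")[[1]]
      if (length(parts) >= 2 && parts[[1]] == "part_of") {
        cur_parents <- c(cur_parents, parts[[2]])
      }
    }
  }
  flush_term()

  keep <- !is.na(term_ns) & term_ns == namespace & !(terms %in% obsolete)
  kept <- terms[keep]
  if (length(kept) == 0L) {
    stop(sprintf("no non-obsolete terms with namespace '%s' in %s",
                 namespace, path))
  }

  ok <- edges_child %in% kept & edges_parent %in% kept
  parents <- split(edges_parent[ok], factor(edges_child[ok], levels = kept))
  parents <- lapply(parents, function(x) sort(unique(x)))

  dag <- new_ontology_dag(kept, parents, namespace,
                          obsolete = intersect(obsolete, terms))
  assert_acyclic(dag)
  dag
}

assert_acyclic <- function(dag) {
  g <- dag_igraph(dag)
  if (!igraph::is_dag(g)) {
    stop("ontology integrity error: cycle detected among is_a relations")
  }
  invisible(TRUE)
}

# igraph representation with edges parent -> child.
dag_igraph <- function(dag) {
  child <- rep(names(dag$parents), lengths(dag$parents))
  parent <- unlist(dag$parents, use.names = FALSE)
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(dag$terms), name = dag$terms)
  if (length(parent)) {
    g <- igraph::add_edges(g, rbind(parent, child))
  }
  g
}

#' All strict descendants of a term
#'
#' Returns every term reachable from `term` by following child links, any
#' number of steps, each term once; `term` itself is excluded. This is the
#' recursive reading of "children" used when propagating annotation counts
#' up the DAG.
#'
#' @param dag an `ontology_dag`.
#' @param term a term identifier in `dag$terms`.
#' @return character vector of descendant term ids (possibly empty), sorted.
#' @export
descendants <- function(dag, term) {
  if (!term %in% dag$terms) stop(sprintf("unknown term '%s'", term))
  seen <- character(0)
  stack <- dag$children[[term]]
  while (length(stack)) {
    t <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    if (t %in% seen) next
    seen <- c(seen, t)
    stack <- c(stack, dag$children[[t]])
  }
  sort(seen)
}

# Descendant sets for every term at once, in one reverse-topological sweep.
# Returns a named list term -> character vector of strict descendants.
descendant_table <- function(dag) {
  g <- dag_igraph(dag)
  ord <- igraph::topo_sort(g, mode = "out")$name
  desc <- vector("list", length(dag$terms))
  names(desc) <- dag$terms
  for (t in rev(ord)) {
    kids <- dag$children[[t]]
    if (length(kids) == 0L) {
      desc[[t]] <- character(0)
    } else {
      desc[[t]] <- sort(unique(c(kids, unlist(desc[kids], use.names = FALSE))))
    }
  }
  desc
}

new_annotation_set <- function(gene_terms, evidence_kept) {
  gene_terms <- gene_terms[order(names(gene_terms))]
  gene_terms <- lapply(gene_terms, function(x) sort(unique(x)))
  gene_terms <- gene_terms[lengths(gene_terms) > 0L]
  term_genes <- invert_membership(gene_terms)
  structure(
    list(gene_terms = gene_terms,
         term_genes = term_genes,
         universe = names(gene_terms),
         evidence_kept = sort(unique(evidence_kept))),
    class = "annotation_set")
}

invert_membership <- function(map) {
  if (length(map) == 0L) return(list())
  owner <- rep(names(map), lengths(map))
  member <- unlist(map, use.names = FALSE)
  out <- split(owner, member)
  lapply(out, function(x) sort(unique(x)))
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d genes, %d terms, evidence: %s\n",
              length(x$universe), length(x$term_genes),
              paste(x$evidence_kept, collapse = ",")))
  invisible(x)
}

#' Load gene-to-GO annotations from a gene2go-style table
#'
#' Reads a tab-separated annotation table in the shape of NCBI's gene2go
#' file: columns `tax_id` (ignored), `GeneID`, `GO_ID`, `Evidence`,
#' `Qualifier`, `GO_term` (ignored), `Category`. Rows are dropped when their
#' evidence code is not in `evidence_kept`, when the qualifier is `NOT`, or
#' when the term is not part of `dag` (wrong namespace, obsolete, unknown);
#' duplicate gene-term associations collapse to one.
#'
#' @param path path to the TSV file (a header line starting with `#` or
#'   `tax_id` is accepted).
#' @param dag the `ontology_dag` the annotations must live in.
#' @param evidence_kept evidence codes to keep
#'   (default [experimental_evidence_codes]).
#' @return an `annotation_set` with `gene_terms`, the inverted `term_genes`,
#'   the annotated `universe` and `evidence_kept`.
#' @export
load_annotations <- function(path, dag,
                             evidence_kept = experimental_evidence_codes) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 4L) stop("annotation table needs >= 4 tab-separated columns")
  # Tolerate an un-commented header row.
  if (nrow(raw) && (raw[1, 1] %in% c("tax_id", "#tax_id"))) raw <- raw[-1, , drop = FALSE]
  names(raw)[1:4] <- c("tax_id", "gene", "term", "evidence")
  qualifier <- if (ncol(raw) >= 5L) raw[[5L]] else rep("", nrow(raw))

  keep <- raw$evidence %in% evidence_kept &
    !(toupper(qualifier) %in% "NOT") &
    raw$term %in% dag$terms
  n_dropped_term <- sum(raw$evidence %in% evidence_kept &
                          !(raw$term %in% dag$terms))
  if (n_dropped_term > 0L) {
    message(sprintf("load_annotations: dropped %d rows annotating terms outside the DAG",
                    n_dropped_term))
  }
  kept <- raw[keep, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop("no annotations survive evidence/namespace filtering")
  }
  gene_terms <- split(kept$term, kept$gene)
  new_annotation_set(gene_terms, evidence_kept)
}

#' Build an annotation set from an in-memory gene -> terms map
#'
#' @param gene_terms named list mapping genes to character vectors of term
#'   ids (already evidence-filtered).
#' @param evidence_kept evidence codes recorded as kept.
#' @return an `annotation_set`.
#' @export
annotation_set <- function(gene_terms,
                           evidence_kept = experimental_evidence_codes) {
  stopifnot(is.list(gene_terms), !is.null(names(gene_terms)))
  new_annotation_set(gene_terms, evidence_kept)
}

#' Number of genes directly annotated to a term
#'
#' Counts genes carrying a direct annotation to `term`, optionally
#' restricted to a gene set (e.g. a pathway). This is the `a` count of the
#' term-frequency formula.
#'
#' @param ann an `annotation_set`.
#' @param dag an `ontology_dag` (used to validate the term).
#' @param term a term id.
#' @param restrict_to optional character vector of genes; when omitted the
#'   count is over the whole annotated universe.
#' @return integer count.
#' @export
annotated_gene_count <- function(ann, dag, term, restrict_to = NULL) {
  if (!term %in% dag$terms) stop(sprintf("unknown term '%s'", term))
  genes <- ann$term_genes[[term]]
  if (is.null(genes)) return(0L)
  if (is.null(restrict_to)) length(genes) else length(intersect(genes, restrict_to))
}
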