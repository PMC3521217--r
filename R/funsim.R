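# Function-based similarity: TF-IDF term-weight vectors per pathway and
# cosine similarity (funSim) between pathway pairs.
#
# The term frequency of term j in pathway i counts genes annotated at j or
# below it in the DAG: when a gene is described by a term, all ancestors of
# that term also apply to the gene, so annotation counts are propagated
# upward before weighting. The inverse document frequency down-weights terms
# that are common across the whole annotated genome.

#' Term frequency of a term within a gene set
#'
#' `mode = "sum"` applies the literal propagation formula: the direct
#' annotation count at `term` plus the sum of direct counts over all strict
#' descendants — a gene annotated to several descendants contributes once
#' per descendant. `mode = "distinct"` counts distinct genes annotated to
#' the term or any descendant.
#'
#' @param genes character vector of genes (a pathway, or the whole universe).
#' @param term a term id in `dag$terms`.
#' @param ann an `annotation_set`.
#' @param dag an `ontology_dag`.
#' @param mode `"sum"` (default) or `"distinct"`.
#' @param children_mode `"recursive"` (default: all strict descendants) or
#'   `"direct"` (immediate children only).
#' @return numeric count (>= 0).
#' @export
term_frequency <- function(genes, term, ann, dag, mode = c("sum", "distinct"),
                           children_mode = c("recursive", "direct")) {
  mode <- match.arg(mode)
  children_mode <- match.arg(children_mode)
  if (!term %in% dag$terms) stop(sprintf("unknown term '%s'", term))
  below <- if (children_mode == "recursive") descendants(dag, term) else dag$children[[term]]
  fam <- c(term, below)
  if (mode == "sum") {
    sum(vapply(fam, function(t) {
      g <- ann$term_genes[[t]]
      if (is.null(g)) 0L else length(intersect(g, genes))
    }, 0L))
  } else {
    covered <- unlist(lapply(fam, function(t) ann$term_genes[[t]]), use.names = FALSE)
    length(intersect(unique(covered), genes))
  }
}

# Vectorised term frequencies for a fixed gene set over many terms, using a
# precomputed descendant table (avoids re-walking the DAG per term).
term_frequencies <- function(genes, terms, ann, dag, desc, mode, children_mode) {
  direct <- vapply(dag$terms, function(t) {
    g <- ann$term_genes[[t]]
    if (is.null(g)) 0L else length(intersect(g, genes))
  }, 0L)
  vapply(terms, function(j) {
    fam <- c(j, if (children_mode == "recursive") desc[[j]] else dag$children[[j]])
    if (mode == "sum") {
      sum(direct[fam])
    } else {
      covered <- unlist(lapply(fam, function(t) ann$term_genes[[t]]), use.names = FALSE)
      length(intersect(unique(covered), genes))
    }
  }, numeric(1))
}

#' Inverse document frequency of a term
#'
#' `log(N_G / tf_G)` with natural log, where `N_G` is the size of the
#' annotated universe and `tf_G` the genome-wide term frequency (propagated
#' by default, matching the pathway-level frequency). Under `mode = "sum"`
#' the propagated genome count can exceed `N_G`; the resulting negative
#' value is clipped to 0 so weights stay non-negative.
#'
#' @inheritParams term_frequency
#' @return non-negative real; terms never annotated (tf_G = 0) are an error.
#' @export
idf <- function(term, ann, dag, mode = c("sum", "distinct"),
                children_mode = c("recursive", "direct")) {
  mode <- match.arg(mode)
  children_mode <- match.arg(children_mode)
  tf_g <- term_frequency(ann$universe, term, ann, dag, mode = mode,
                         children_mode = children_mode)
  if (tf_g == 0) stop(sprintf("idf undefined: term '%s' annotates no gene", term))
  val <- log(length(ann$universe) / tf_g)
  if (val < 0) {
    message(sprintf("idf: propagated frequency of '%s' exceeds the universe size; clipped to 0", term))
    val <- 0
  }
  val
}

new_term_weight_vector <- function(pathway_id, weights) {
  weights <- weights[weights > 0]
  weights <- weights[order(names(weights))]
  structure(list(pathway_id = pathway_id, weights = weights),
            class = "term_weight_vector")
}

#' @export
print.term_weight_vector <- function(x, ...) {
  cat(sprintf("<term_weight_vector> pathway %s: %d non-zero terms\n",
              x$pathway_id, length(x$weights)))
  invisible(x)
}

#' TF-IDF weight vector of a pathway
#'
#' For each representative term the weight is the propagated in-pathway term
#' frequency times the genome-level inverse document frequency; zero weights
#' are dropped.
#'
#' @param genes pathway gene set.
#' @param rep_terms representative terms of the pathway (from
#'   [representative_terms]).
#' @param ann an `annotation_set`.
#' @param dag an `ontology_dag`.
#' @param mode,children_mode see [term_frequency].
#' @param pathway_id id recorded on the vector.
#' @param idf_table optional precomputed named idf vector over `dag$terms`
#'   (see [genome_idf]); computed on the fly when omitted.
#' @return a `term_weight_vector` (sparse named numeric `weights`).
#' @export
pathway_vector <- function(genes, rep_terms, ann, dag,
                           mode = c("sum", "distinct"),
                           children_mode = c("recursive", "direct"),
                           pathway_id = NA_character_, idf_table = NULL) {
  mode <- match.arg(mode)
  children_mode <- match.arg(children_mode)
  if (length(rep_terms) == 0L) {
    return(new_term_weight_vector(pathway_id, stats::setNames(numeric(0), character(0))))
  }
  desc <- descendant_table(dag)
  if (is.null(idf_table)) {
    idf_table <- genome_idf(ann, dag, mode = mode, children_mode = children_mode,
                            desc = desc)
  }
  tf <- term_frequencies(intersect(genes, ann$universe), rep_terms, ann, dag,
                         desc, mode, children_mode)
  w <- tf * idf_table[rep_terms]
  new_term_weight_vector(pathway_id, stats::setNames(as.numeric(w), rep_terms))
}

#' Genome-wide IDF table
#'
#' Precomputes `max(0, log(N_G / tf_G))` for every DAG term; shared across
#' all pathway vectors of a run.
#'
#' @inheritParams pathway_vector
#' @param desc optional precomputed [descendant_table].
#' @return named numeric vector over `dag$terms`; terms with zero genome
#'   frequency get `NA` (they can never be representative).
#' @export
genome_idf <- function(ann, dag, mode = c("sum", "distinct"),
                       children_mode = c("recursive", "direct"), desc = NULL) {
  mode <- match.arg(mode)
  children_mode <- match.arg(children_mode)
  if (is.null(desc)) desc <- descendant_table(dag)
  tf_g <- term_frequencies(ann$universe, dag$terms, ann, dag, desc, mode,
                           children_mode)
  n_g <- length(ann$universe)
  out <- ifelse(tf_g > 0, pmax(0, log(n_g / tf_g)), NA_real_)
  n_clipped <- sum(tf_g > n_g)
  if (n_clipped > 0L) {
    message(sprintf("genome_idf: %d terms with propagated frequency above the universe size; idf clipped to 0",
                    n_clipped))
  }
  stats::setNames(out, dag$terms)
}

#' Cosine functional similarity between two pathway vectors
#'
#' `funSim = v1 . v2 / (||v1|| ||v2||)`; empty or all-zero vectors score 0
#' against everything by convention (never `NaN`).
#'
#' @param v1,v2 `term_weight_vector`s (or bare named numeric vectors).
#' @return similarity in \[0, 1\].
#' @export
funsim <- function(v1, v2) {
  w1 <- if (inherits(v1, "term_weight_vector")) v1$weights else v1
  w2 <- if (inherits(v2, "term_weight_vector")) v2$weights else v2
  n1 <- sqrt(sum(w1^2)); n2 <- sqrt(sum(w2^2))
  if (n1 == 0 || n2 == 0) return(0)
  common <- intersect(names(w1), names(w2))
  if (length(common) == 0L) return(0)
  min(1, sum(w1[common] * w2[common]) / (n1 * n2))
}

#' All-pairs funSim matrix over a collection
#'
#' @param coll a `pathway_collection`.
#' @param vectors named list of `term_weight_vector`, one per pathway id.
#' @return a `funsim_matrix`: list with `pathway_ids` and `scores`, a
#'   symmetric numeric matrix (diagonal 1 for non-zero vectors, 0 for empty
#'   ones).
#' @export
all_pairs <- function(coll, vectors) {
  ids <- coll$ids
  missing <- setdiff(ids, names(vectors))
  if (length(missing)) {
    stop(sprintf("no vector for pathway(s): %s", paste(missing, collapse = ", ")))
  }
  n <- length(ids)
  scores <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    vi <- vectors[[ids[[i]]]]
    scores[i, i] <- if (length(vi$weights) > 0) 1 else 0
    if (i < n) {
      for (j in seq((i + 1), n)) {
        s <- funsim(vi, vectors[[ids[[j]]]])
        scores[i, j] <- s
        scores[j, i] <- s
      }
    }
  }
  structure(list(pathway_ids = ids, scores = scores), class = "funsim_matrix")
}

#' @export
print.funsim_matrix <- function(x, ...) {
  cat(sprintf("<funsim_matrix> %d pathways, %d pairs\n",
              length(x$pathway_ids),
              choose(length(x$pathway_ids), 2)))
  invisible(x)
}

#' Long-format pair table from a funSim matrix
#'
#' @param fm a `funsim_matrix`.
#' @return data.frame of `id1`, `id2`, `funsim` over all unordered pairs.
#' @export
funsim_pairs <- function(fm) {
  ids <- fm$pathway_ids
  n <- length(ids)
  if (n < 2L) {
    return(data.frame(id1 = character(0), id2 = character(0),
                      funsim = numeric(0), stringsAsFactors = FALSE))
  }
  idx <- utils::combn(n, 2L)
  data.frame(id1 = ids[idx[1L, ]], id2 = ids[idx[2L, ]],
             funsim = fm$scores[cbind(idx[1L, ], idx[2L, ])],
             stringsAsFactors = FALSE)
}

#' Call function-related pathway pairs (FRPs)
#'
#' Pairs with funSim strictly greater than the cutoff are flagged as
#' function-related.
#'
#' @param fm a `funsim_matrix`.
#' @param cutoff score threshold in \[0, 1\] (default 0.5).
#' @return data.frame of `id1`, `id2`, `funsim` for passing pairs.
#' @export
frp_call <- function(fm, cutoff = 0.5) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  pairs <- funsim_pairs(fm)
  pairs[pairs$funsim > cutoff, , drop = FALSE]
}

#' Run the full function-based pipeline on a collection
#'
#' Enrichment, TF-IDF vectors and the all-pairs funSim matrix in one call;
#' the building block reused by the background-calibration module.
#'
#' @inheritParams enrich_collection
#' @param mode,children_mode see [term_frequency].
#' @return list with `enrichment` (per-pathway results), `vectors` and
#'   `funsim` (the `funsim_matrix`).
#' @export
fba_pipeline <- function(coll, ann, dag, alpha = 0.05,
                         mode = c("sum", "distinct"),
                         children_mode = c("recursive", "direct")) {
  mode <- match.arg(mode)
  children_mode <- match.arg(children_mode)
  desc <- descendant_table(dag)
  idf_table <- genome_idf(ann, dag, mode = mode, children_mode = children_mode,
                          desc = desc)
  enr <- enrich_collection(coll, ann, dag, alpha = alpha)
  vectors <- lapply(coll$ids, function(id) {
    rep_terms <- enr[[id]]$representative
    genes <- intersect(coll$genes[[id]], ann$universe)
    if (length(rep_terms) == 0L) {
      return(new_term_weight_vector(id, stats::setNames(numeric(0), character(0))))
    }
    tf <- term_frequencies(genes, rep_terms, ann, dag, desc, mode, children_mode)
    new_term_weight_vector(id, stats::setNames(as.numeric(tf * idf_table[rep_terms]),
                                               rep_terms))
  })
  names(vectors) <- coll$ids
  list(enrichment = enr, vectors = vectors, funsim = all_pairs(coll, vectors))
}
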