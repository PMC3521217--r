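# Representative-term selection: one-sided Fisher exact test per term with
# Benjamini-Hochberg correction across the terms tested for a pathway.

#' One-sided Fisher exact test (hypergeometric upper tail)
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' drawn without replacement from a universe of `N` genes of which `K` carry
#' the annotation: `P(X >= k)` under the hypergeometric distribution. This
#' is the one-sided (enrichment) Fisher exact test for the 2x2 table with
#' fixed margins.
#'
#' @param k in-draw annotated count.
#' @param K universe annotated count.
#' @param n draw size (pathway size within the universe).
#' @param N universe size.
#' @return the upper-tail p-value in \[0, 1\].
#' @export
fisher_one_sided <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    stop("fisher_one_sided: inconsistent margins")
  }
  # P(X >= k) = 1 - P(X <= k - 1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment `p * m / rank` with a cumulative minimum applied
#' from the largest rank, clipped at 1. Output order matches input order.
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Representative GO terms of a pathway
#'
#' Tests every term with at least one direct annotation among the pathway's
#' genes for enrichment against the annotated universe, using the one-sided
#' Fisher exact test; p-values are BH-adjusted across exactly the tested
#' terms, and terms with adjusted p below `alpha` form the representative
#' set. Terms are tested on direct annotations only; DAG propagation enters
#' later, in the term-frequency weights.
#'
#' @param genes character vector of pathway genes (a pathway's gene set).
#' @param ann an `annotation_set`.
#' @param dag an `ontology_dag`.
#' @param alpha adjusted-p threshold for calling a term representative
#'   (default 0.05, strict `<`).
#' @param pathway_id optional id recorded on the result.
#' @return an `enrichment_result`: list with `pathway_id`, `table` (a
#'   data.frame of `term`, `p`, `p_adj`, `k` in-pathway count, `K` universe
#'   count, sorted by raw p) and `representative` (character vector of term
#'   ids).
#' @export
representative_terms <- function(genes, ann, dag, alpha = 0.05,
                                 pathway_id = NA_character_) {
  stopifnot(alpha > 0, alpha < 1)
  in_universe <- intersect(genes, ann$universe)
  n <- length(in_universe)
  N <- length(ann$universe)
  if (n == 0L) {
    warning(sprintf("pathway %s has no annotated genes; empty enrichment result",
                    pathway_id))
    tab <- data.frame(term = character(0), p = numeric(0),
                      p_adj = numeric(0), k = integer(0), K = integer(0),
                      stringsAsFactors = FALSE)
    return(structure(list(pathway_id = pathway_id, table = tab,
                          representative = character(0)),
                     class = "enrichment_result"))
  }
  # Terms with >= 1 direct annotation among pathway genes.
  tested <- sort(unique(unlist(ann$gene_terms[in_universe], use.names = FALSE)))
  k <- vapply(tested, function(t) length(intersect(ann$term_genes[[t]], in_universe)), 0L)
  K <- vapply(tested, function(t) length(ann$term_genes[[t]]), 0L)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_adj <- bh_adjust(p)
  ord <- order(p, tested)
  tab <- data.frame(term = tested[ord], p = p[ord], p_adj = p_adj[ord],
                    k = k[ord], K = K[ord], stringsAsFactors = FALSE)
  structure(list(pathway_id = pathway_id, table = tab,
                 representative = tab$term[tab$p_adj < alpha]),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> pathway %s: %d terms tested, %d representative\n",
              x$pathway_id, nrow(x$table), length(x$representative)))
  invisible(x)
}

#' Representative terms for every pathway of a collection
#'
#' @param coll a `pathway_collection`.
#' @param ann an `annotation_set`.
#' @param dag an `ontology_dag`.
#' @param alpha adjusted-p threshold (default 0.05).
#' @return named list of `enrichment_result`, one per pathway id.
#' @export
enrich_collection <- function(coll, ann, dag, alpha = 0.05) {
  res <- lapply(coll$ids, function(id) {
    representative_terms(coll$genes[[id]], ann, dag, alpha = alpha,
                         pathway_id = id)
  })
  stats::setNames(res, coll$ids)
}
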