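# Tissue co-expression of pathway pairs: a pathway is "expressed" in a
# tissue when its components are over-represented among the tissue's
# expressed genes (hypergeometric test); pairs are scored by the mean of
# the Jaccard and overlap coefficients of their expressed-tissue sets.

new_tissue_expression <- function(expressed, genome_size) {
  structure(list(tissues = names(expressed),
                 expressed = expressed,
                 genome_size = genome_size),
            class = "tissue_expression")
}

#' Build a tissue-expression object from per-tissue gene sets
#'
#' @param expressed named list: tissue -> character vector of expressed
#'   genes.
#' @param genome_size total number of genes `N`; defaults to the number of
#'   distinct genes observed across tissues.
#' @return a `tissue_expression`.
#' @export
tissue_expression <- function(expressed, genome_size = NULL) {
  stopifnot(is.list(expressed), !is.null(names(expressed)))
  if (anyDuplicated(names(expressed))) stop("duplicate tissue label")
  expressed <- lapply(expressed, function(g) sort(unique(as.character(g))))
  if (is.null(genome_size)) {
    genome_size <- length(unique(unlist(expressed, use.names = FALSE)))
  }
  new_tissue_expression(expressed, genome_size)
}

#' @export
print.tissue_expression <- function(x, ...) {
  cat(sprintf("<tissue_expression> %d tissues over %d genes\n",
              length(x$tissues), x$genome_size))
  invisible(x)
}

#' Read a gene x tissue expression table
#'
#' TSV with genes in the first column and one column per tissue; values are
#' EST counts or 0/1 presence flags (any value > 0 means expressed).
#'
#' @param path TSV path.
#' @param genome_size optional `N`; defaults to the number of gene rows.
#' @return a `tissue_expression`.
#' @export
read_expression <- function(path, genome_size = NULL) {
  stopifnot(file.exists(path))
  df <- read_tsv(path)
  genes <- as.character(df[[1L]])
  tissues <- names(df)[-1L]
  expressed <- lapply(tissues, function(t) genes[df[[t]] > 0])
  names(expressed) <- tissues
  tissue_expression(expressed,
                    genome_size = if (is.null(genome_size)) length(genes) else genome_size)
}

#' Write a tissue-expression object as a presence table
#' @param expr a `tissue_expression`.
#' @param path output TSV path.
#' @param genes optional row universe; defaults to genes seen in any tissue.
#' @export
write_expression <- function(expr, path, genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(unlist(expr$expressed, use.names = FALSE)))
  df <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (t in expr$tissues) df[[t]] <- as.integer(genes %in% expr$expressed[[t]])
  write_tsv(df, path)
}

#' Hypergeometric test that a pathway is expressed in a tissue
#'
#' Upper-tail probability of seeing at least `k` of the pathway's `n` genes
#' among the `m` genes expressed in the tissue, out of `N` genes total.
#'
#' @param genes pathway gene set.
#' @param tissue_genes genes expressed in the tissue.
#' @param N total gene count (genome size for the test).
#' @return p-value; a pathway is called expressed when `p < 0.05`
#'   (strict).
#' @export
pathway_expressed_p <- function(genes, tissue_genes, N) {
  n <- length(unique(genes))
  m <- length(unique(tissue_genes))
  if (m > N || n > N) stop("pathway_expressed_p: margins exceed genome size")
  k <- length(intersect(genes, tissue_genes))
  fisher_one_sided(k, m, n, N)
}

#' Jaccard/overlap co-expression value
#'
#' `jc = E12 / (E1 + E2 - E12)`, `oc = E12 / min(E1, E2)`, value is their
#' arithmetic mean. Degenerate denominators (a pathway expressed nowhere)
#' yield 0 rather than `NaN`.
#'
#' @param E1,E2 tissue counts of the two pathways.
#' @param E12 common tissue count (`E12 <= min(E1, E2)`).
#' @return list with `jc`, `oc`, `value`, all in \[0, 1\].
#' @export
coexpression_value <- function(E1, E2, E12) {
  stopifnot(E1 >= 0, E2 >= 0, E12 >= 0)
  if (E12 > min(E1, E2)) stop("coexpression_value: E12 exceeds min(E1, E2)")
  jc <- if (E1 + E2 - E12 == 0) 0 else E12 / (E1 + E2 - E12)
  oc <- if (min(E1, E2) == 0) 0 else E12 / min(E1, E2)
  list(jc = jc, oc = oc, value = (jc + oc) / 2)
}

#' Expressed-tissue set of every pathway
#'
#' @param coll a `pathway_collection`.
#' @param expr a `tissue_expression`.
#' @param alpha expression-call threshold (default 0.05, strict `<`).
#' @return named list: pathway id -> character vector of tissues where the
#'   pathway is expressed.
#' @export
expressed_tissues <- function(coll, expr, alpha = 0.05) {
  out <- lapply(coll$ids, function(id) {
    p <- vapply(expr$tissues, function(t) {
      pathway_expressed_p(coll$genes[[id]], expr$expressed[[t]],
                          expr$genome_size)
    }, numeric(1))
    expr$tissues[p < alpha]
  })
  stats::setNames(out, coll$ids)
}

#' Co-expression records for a set of pathway pairs
#'
#' @param pairs data.frame with columns `id1`, `id2` (unordered pairs).
#' @param coll a `pathway_collection`.
#' @param expr a `tissue_expression`.
#' @param alpha expression-call threshold (default 0.05).
#' @return data.frame with `id1`, `id2`, `E1`, `E2`, `E12`, `jc`, `oc`,
#'   `value`.
#' @export
coexpress_pairs <- function(pairs, coll, expr, alpha = 0.05) {
  tset <- expressed_tissues(coll, expr, alpha = alpha)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    t1 <- tset[[pairs$id1[[i]]]]
    t2 <- tset[[pairs$id2[[i]]]]
    E12 <- length(intersect(t1, t2))
    cv <- coexpression_value(length(t1), length(t2), E12)
    data.frame(id1 = pairs$id1[[i]], id2 = pairs$id2[[i]],
               E1 = length(t1), E2 = length(t2), E12 = E12,
               jc = cv$jc, oc = cv$oc, value = cv$value,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(id1 = character(0), id2 = character(0),
                      E1 = integer(0), E2 = integer(0), E12 = integer(0),
                      jc = numeric(0), oc = numeric(0), value = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Compare co-expression values between two groups of pairs
#'
#' Convenience wrapper around the two-sample Wilcoxon rank-sum test, used to
#' ask whether one prediction set is more co-expressed than another.
#'
#' @param values_a,values_b numeric co-expression values of the two groups.
#' @param alternative passed to [stats::wilcox.test] (default `"greater"`:
#'   is group a shifted above group b?).
#' @return the `htest` object.
#' @export
compare_coexpression <- function(values_a, values_b,
                                 alternative = "greater") {
  stats::wilcox.test(values_a, values_b, alternative = alternative,
                     exact = FALSE)
}
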