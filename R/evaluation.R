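# Evaluation of cross-talk predictions: precision/recall against known
# pathway interactions, functional-category enrichment of calls,
# method-overlap bookkeeping, clique finding, and the dissection of pairs
# sharing exactly one gene.

#' Precision and recall of predicted pathway pairs
#'
#' Pairs are unordered; both inputs are canonicalized before comparison.
#'
#' @param predicted data.frame with `id1`, `id2` (predicted pairs).
#' @param positives data.frame with `id1`, `id2` (known interacting pairs;
#'   must be non-empty).
#' @return list with `precision`, `recall`, `tp`, `n_predicted`,
#'   `n_positives`, and `empty_predicted` flag (precision reported as 0
#'   when nothing was predicted).
#' @export
precision_recall <- function(predicted, positives) {
  pos <- unique(pair_key(positives$id1, positives$id2))
  if (length(pos) == 0L) stop("empty positives set")
  pred <- unique(pair_key(predicted$id1, predicted$id2))
  tp <- length(intersect(pred, pos))
  list(precision = if (length(pred) == 0L) 0 else tp / length(pred),
       recall = tp / length(pos),
       tp = tp, n_predicted = length(pred), n_positives = length(pos),
       empty_predicted = length(pred) == 0L)
}

#' Read a two-column positives (known pathway interactions) TSV
#'
#' @param path TSV of two pathway-id columns (lines starting `#` skipped).
#' @param coll optional `pathway_collection`; pairs naming unknown ids are
#'   dropped with a message.
#' @return data.frame `id1`, `id2`, canonicalized and deduplicated.
#' @export
read_positives <- function(path, coll = NULL) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stop("positives file needs two tab-separated columns")
  df <- data.frame(id1 = raw[[1L]], id2 = raw[[2L]], stringsAsFactors = FALSE)
  if (!is.null(coll)) {
    known <- df$id1 %in% coll$ids & df$id2 %in% coll$ids
    if (any(!known)) {
      message(sprintf("read_positives: dropped %d pairs naming unknown pathways",
                      sum(!known)))
    }
    df <- df[known, , drop = FALSE]
  }
  keys <- unique(pair_key(df$id1, df$id2))
  as.data.frame(pair_unkey(keys), stringsAsFactors = FALSE)
}

#' Functional-category enrichment of function-related pairs
#'
#' For a category with `k` member pathways out of `n_total`, the intra
#' stratum holds the `choose(k, 2)` pairs inside the category and the inter
#' stratum the `k * (n_total - k)` pairs between a member and a
#' non-member. The proportion of function-related pairs (FRPs) in each
#' stratum is compared by a one-sided Fisher exact test, and the relative
#' enrichment is the ratio of the two densities.
#'
#' @param category_ids pathway ids assigned to the category (k >= 2).
#' @param frps data.frame of called pairs (`id1`, `id2`).
#' @param all_ids every pathway id of the collection under study.
#' @return list with `n_intra`, `N_intra`, `n_inter`, `N_inter`, `p`
#'   (one-sided Fisher) and `re` (relative enrichment; `Inf` when the inter
#'   density is 0 and the intra density positive).
#' @export
category_enrichment <- function(category_ids, frps, all_ids) {
  category_ids <- intersect(unique(category_ids), all_ids)
  k <- length(category_ids)
  if (k < 2L) stop("category needs at least two member pathways")
  outside <- setdiff(all_ids, category_ids)
  N_intra <- choose(k, 2)
  N_inter <- k * length(outside)
  frp_keys <- unique(pair_key(frps$id1, frps$id2))
  intra_keys <- all_pair_keys(sort(category_ids))
  inter_keys <- as.vector(outer(sort(category_ids), sort(outside), pair_key))
  n_intra <- sum(intra_keys %in% frp_keys)
  n_inter <- sum(inter_keys %in% frp_keys)
  tab <- matrix(c(n_intra, N_intra - n_intra, n_inter, N_inter - n_inter),
                nrow = 2)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  re <- if (N_inter == 0L || n_inter == 0L) {
    if (n_intra > 0) Inf else NaN
  } else {
    (n_intra / N_intra) / (n_inter / N_inter)
  }
  list(n_intra = n_intra, N_intra = N_intra,
       n_inter = n_inter, N_inter = N_inter, p = p, re = re)
}

#' Read a pathway-category assignment TSV
#'
#' Two columns, pathway id and category label; a pathway may appear on
#' several rows (multi-membership).
#'
#' @param path TSV path.
#' @return named list: category -> character vector of pathway ids.
#' @export
read_categories <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stop("categories file needs two tab-separated columns")
  lapply(split(raw[[1L]], raw[[2L]]), function(x) sort(unique(x)))
}

#' Overlap bookkeeping between two prediction sets
#'
#' @param a,b data.frames of pairs (`id1`, `id2`).
#' @return list with `common`, `only_a`, `only_b` counts.
#' @export
method_overlap <- function(a, b) {
  ka <- unique(pair_key(a$id1, a$id2))
  kb <- unique(pair_key(b$id1, b$id2))
  list(common = length(intersect(ka, kb)),
       only_a = length(setdiff(ka, kb)),
       only_b = length(setdiff(kb, ka)))
}

#' Enumerate size-k cliques among predicted pathway pairs
#'
#' Treats the pairs as an undirected graph over pathways and returns every
#' vertex subset of size `k` that is fully connected; each clique once, its
#' members sorted.
#'
#' @param pairs data.frame of edges (`id1`, `id2`).
#' @param k clique size (default 3).
#' @return list of character vectors (sorted member ids), in lexicographic
#'   order.
#' @export
find_k_cliques <- function(pairs, k = 3L) {
  stopifnot(k >= 3L)
  keys <- unique(pair_key(pairs$id1, pairs$id2))
  if (length(keys) == 0L) return(list())
  edges <- pair_unkey(keys)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  cl <- igraph::cliques(g, min = k, max = k)
  out <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
  out[order(vapply(out, paste, "", collapse = "\r"))]
}

#' Dissect pathway pairs sharing exactly one gene
#'
#' Finds every unordered pair of pathways whose gene sets intersect in
#' exactly one gene, reports that gene, and buckets the pair by which
#' method called it: FRP-only, SIP-only, both, or neither.
#'
#' @param coll a `pathway_collection`.
#' @param frps data.frame of function-related pairs (`id1`, `id2`).
#' @param sips data.frame of significantly interacting pairs (`id1`, `id2`).
#' @return data.frame with `id1`, `id2`, `gene`, `frp`, `sip`, `bucket`.
#' @export
single_shared_gene_pairs <- function(coll, frps, sips) {
  ids <- coll$ids
  frp_keys <- unique(pair_key(frps$id1, frps$id2))
  sip_keys <- unique(pair_key(sips$id1, sips$id2))
  rows <- list()
  if (length(ids) >= 2L) {
    idx <- utils::combn(length(ids), 2L)
    for (c in seq_len(ncol(idx))) {
      a <- ids[[idx[1L, c]]]; b <- ids[[idx[2L, c]]]
      common <- intersect(coll$genes[[a]], coll$genes[[b]])
      if (length(common) != 1L) next
      key <- pair_key(a, b)
      is_frp <- key %in% frp_keys
      is_sip <- key %in% sip_keys
      bucket <- if (is_frp && is_sip) "both" else if (is_frp) "frp_only"
                else if (is_sip) "sip_only" else "neither"
      rows[[length(rows) + 1L]] <- data.frame(
        id1 = a, id2 = b, gene = common, frp = is_frp, sip = is_sip,
        bucket = bucket, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(id1 = character(0), id2 = character(0),
                      gene = character(0), frp = logical(0),
                      sip = logical(0), bucket = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Area under the ROC curve for ranking true pairs
#'
#' Ranks every scored pair by funSim and measures how well truth pairs rank
#' above the rest (Mann-Whitney AUC with tie correction).
#'
#' @param pairs data.frame with `id1`, `id2`, `funsim` over all scored
#'   pairs.
#' @param truth data.frame of true pairs (`id1`, `id2`).
#' @return AUC in \[0, 1\]; `NA` when either class is empty.
#' @export
ranking_auc <- function(pairs, truth) {
  keys <- pair_key(pairs$id1, pairs$id2)
  label <- keys %in% unique(pair_key(truth$id1, truth$id2))
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(pairs$funsim)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
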