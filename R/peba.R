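# Physical entity-based comparators: shared-component overlap test (SOP) and
# PPI-connectivity test (SIP) on the pairs the overlap test does not call.

new_ppi_network <- function(edges) {
  # edges: 2-column character matrix; canonicalize, drop self-loops, dedupe.
  keep <- edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  lo <- pmin(edges[, 1L], edges[, 2L])
  hi <- pmax(edges[, 1L], edges[, 2L])
  key <- paste(lo, hi, sep = "\r")
  uniq <- !duplicated(key)
  ord <- order(lo[uniq], hi[uniq])
  edges <- cbind(lo[uniq], hi[uniq])[ord, , drop = FALSE]
  colnames(edges) <- c("a", "b")
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges[, 1L], edges[, 2L])))),
            class = "ppi_network")
}

#' Build a PPI network from an edge list
#'
#' @param a,b character vectors of interacting gene pairs (undirected);
#'   self-loops dropped, duplicates (in either orientation) collapsed.
#' @return a `ppi_network` with `edges` (canonicalized two-column matrix)
#'   and `nodes`.
#' @export
ppi_network <- function(a, b) {
  stopifnot(length(a) == length(b))
  new_ppi_network(cbind(as.character(a), as.character(b)))
}

#' Read a two-column PPI edge list TSV
#'
#' @param path TSV with two gene columns (header optional, detected by a
#'   first row repeated nowhere as a gene is not attempted: any first line
#'   starting with `#` is skipped).
#' @return a `ppi_network`.
#' @export
read_ppi <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stop("PPI edge list needs two tab-separated columns")
  new_ppi_network(as.matrix(raw[, 1:2]))
}

#' Write a PPI network as a two-column TSV
#' @param net a `ppi_network`.
#' @param path output path.
#' @export
write_ppi <- function(net, path) {
  utils::write.table(as.data.frame(net$edges, stringsAsFactors = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, eol = "\n")
  invisible(path)
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Shared-component overlap test between two pathways
#'
#' One-sided Fisher exact test on the 2x2 table of membership in pathway 1
#' by membership in pathway 2 over the gene universe: the upper-tail
#' probability of observing at least the seen number of shared genes.
#'
#' @param genes1,genes2 the two pathway gene sets (non-empty).
#' @param universe gene universe containing both pathways.
#' @return list with `shared` (common-gene count) and `p` (raw upper-tail
#'   p-value).
#' @export
sop_test <- function(genes1, genes2, universe) {
  if (length(genes1) == 0L || length(genes2) == 0L) stop("empty pathway")
  if (!all(c(genes1, genes2) %in% universe)) {
    stop("universe must contain both pathways")
  }
  k <- length(intersect(genes1, genes2))
  n1 <- length(unique(genes1))
  n2 <- length(unique(genes2))
  N <- length(unique(universe))
  list(shared = k, p = fisher_one_sided(k, n1, n2, N))
}

#' Count protein interactions spanning two pathways
#'
#' Counts network edges with one endpoint in pathway 1 and the other in
#' pathway 2. Edges with both endpoints inside the intersection of the two
#' pathways are excluded (they are internal to the shared part, not
#' cross-talk wiring); an edge from a shared gene to an exclusive gene of
#' either pathway counts once. Symmetric in its pathway arguments.
#'
#' @param genes1,genes2 pathway gene sets.
#' @param net a `ppi_network`.
#' @return integer edge count.
#' @export
count_interpathway_ppis <- function(genes1, genes2, net) {
  a <- net$edges[, 1L]
  b <- net$edges[, 2L]
  both <- intersect(genes1, genes2)
  spans <- (a %in% genes1 & b %in% genes2) | (a %in% genes2 & b %in% genes1)
  internal <- a %in% both & b %in% both
  sum(spans & !internal)
}

#' PPI-connectivity (SIP) test for a pathway pair
#'
#' Compares the observed inter-pathway PPI count against a background built
#' from `n_rounds` randomizations in which each pathway is replaced by a
#' random gene set of the same size (its size within the network) drawn
#' uniformly from network nodes. Two p-values are produced: `p`, a
#' one-sided Fisher exact test on the 2x2 table of (inter-pathway edges,
#' remaining edges) for the observed network versus the mean background;
#' and `p_empirical`, the add-one empirical percentile of the observed count
#' in the background.
#'
#' @param genes1,genes2 pathway gene sets.
#' @param net a `ppi_network`.
#' @param n_rounds randomization rounds (default 1000).
#' @return list with `observed`, `background_mean`, `p`, `p_empirical`.
#'   Uses the current RNG state; seed upstream for reproducibility.
#' @export
sip_test <- function(genes1, genes2, net, n_rounds = 1000L) {
  stopifnot(n_rounds >= 1L)
  m1 <- length(intersect(genes1, net$nodes))
  m2 <- length(intersect(genes2, net$nodes))
  if (m1 == 0L || m2 == 0L) {
    warning("sip_test: pathway with no genes in the network; p = 1")
    return(list(observed = 0L, background_mean = NA_real_, p = 1,
                p_empirical = 1))
  }
  observed <- count_interpathway_ppis(genes1, genes2, net)
  total <- nrow(net$edges)
  bg <- vapply(seq_len(n_rounds), function(r) {
    s1 <- sample(net$nodes, m1)
    s2 <- sample(net$nodes, m2)
    count_interpathway_ppis(s1, s2, net)
  }, numeric(1))
  mu <- round(mean(bg))
  if (observed == 0L) {
    p <- 1
  } else {
    tab <- matrix(c(observed, total - observed, mu, total - mu), nrow = 2)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
  }
  list(observed = observed, background_mean = mean(bg), p = p,
       p_empirical = (1 + sum(bg >= observed)) / (n_rounds + 1))
}

#' Run the physical entity-based comparator on a collection
#'
#' SOP p-values over all unordered pairs, BH-adjusted; pairs with adjusted
#' p below `alpha` are SOPs. The remaining (non-SOP) pairs get the SIP test,
#' BH-adjusted across exactly those tested pairs; adjusted p below `alpha`
#' flags a SIP. The union of SOP and SIP calls is the comparator's
#' cross-talk prediction.
#'
#' @param coll a `pathway_collection`.
#' @param net a `ppi_network`.
#' @param alpha adjusted-p threshold (default 0.05).
#' @param n_rounds SIP randomization rounds (default 1000).
#' @param seed RNG seed for the SIP randomizations.
#' @return data.frame with one row per unordered pair: `id1`, `id2`,
#'   `shared`, `sop_p`, `sop_p_adj`, `sop`, `ppi_count`, `sip_p`,
#'   `sip_p_adj`, `sip_p_empirical`, `sip` (SIP columns `NA` for SOP
#'   pairs).
#' @export
run_peba <- function(coll, net, alpha = 0.05, n_rounds = 1000L, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  ids <- coll$ids
  if (length(ids) < 2L) stop("need at least two pathways")
  idx <- utils::combn(length(ids), 2L)
  id1 <- ids[idx[1L, ]]
  id2 <- ids[idx[2L, ]]
  universe <- coll$universe

  sop <- lapply(seq_along(id1), function(i) {
    sop_test(coll$genes[[id1[[i]]]], coll$genes[[id2[[i]]]], universe)
  })
  shared <- vapply(sop, `[[`, 0L, "shared")
  sop_p <- vapply(sop, `[[`, 0, "p")
  sop_p_adj <- bh_adjust(sop_p)
  is_sop <- sop_p_adj < alpha

  ppi_count <- vapply(seq_along(id1), function(i) {
    count_interpathway_ppis(coll$genes[[id1[[i]]]], coll$genes[[id2[[i]]]], net)
  }, numeric(1))

  sip_p <- rep(NA_real_, length(id1))
  sip_emp <- rep(NA_real_, length(id1))
  to_test <- which(!is_sop)
  if (length(to_test)) {
    set.seed(seed)
    for (i in to_test) {
      r <- suppressWarnings(
        sip_test(coll$genes[[id1[[i]]]], coll$genes[[id2[[i]]]], net,
                 n_rounds = n_rounds))
      sip_p[[i]] <- r$p
      sip_emp[[i]] <- r$p_empirical
    }
  }
  sip_p_adj <- rep(NA_real_, length(id1))
  if (length(to_test)) sip_p_adj[to_test] <- bh_adjust(sip_p[to_test])
  is_sip <- !is.na(sip_p_adj) & sip_p_adj < alpha

  data.frame(id1 = id1, id2 = id2, shared = shared,
             sop_p = sop_p, sop_p_adj = sop_p_adj, sop = is_sop,
             ppi_count = as.integer(ppi_count),
             sip_p = sip_p, sip_p_adj = sip_p_adj,
             sip_p_empirical = sip_emp, sip = is_sip,
             stringsAsFactors = FALSE)
}
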