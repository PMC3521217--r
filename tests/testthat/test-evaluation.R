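pairs_df <- function(...) {
  v <- c(...)
  if (is.null(v)) v <- character(0)
  m <- matrix(v, ncol = 2, byrow = TRUE)
  data.frame(id1 = m[, 1], id2 = m[, 2], stringsAsFactors = FALSE)
}

test_that("precision_recall canonicalizes unordered pairs", {
  pred <- pairs_df("a", "b", "c", "d", "e", "f")
  pos <- pairs_df("b", "a", "x", "y")   # reversed order still matches
  pr <- precision_recall(pred, pos)
  expect_equal(pr$precision, 1 / 3)
  expect_equal(pr$recall, 1 / 2)
  # predicted = positives -> (1, 1)
  pr2 <- precision_recall(pred, pred)
  expect_equal(c(pr2$precision, pr2$recall), c(1, 1))
  # disjoint -> (0, 0)
  pr3 <- precision_recall(pred, pairs_df("p", "q"))
  expect_equal(c(pr3$precision, pr3$recall), c(0, 0))
  # empty predictions: flagged, precision reported as 0
  pr4 <- precision_recall(pairs_df(), pos)
  expect_true(pr4$empty_predicted)
  expect_equal(pr4$precision, 0)
  expect_error(precision_recall(pred, pairs_df()), "empty positives")
})

test_that("precision/recall arithmetic on a 143-positive benchmark shape", {
  # counts mirror a benchmark with 143 positives of which 134 are recovered
  positives <- pairs_df()
  positives <- data.frame(id1 = sprintf("p%03d", 1:143),
                          id2 = sprintf("q%03d", 1:143))
  predicted <- rbind(positives[1:134, ],
                     data.frame(id1 = sprintf("r%04d", 1:4527),
                                id2 = sprintf("s%04d", 1:4527)))
  pr <- precision_recall(predicted, positives)
  expect_equal(pr$n_predicted, 4661)
  expect_equal(pr$precision, 134 / 4661, tolerance = 1e-12)
  expect_equal(pr$recall, 134 / 143, tolerance = 1e-12)
  expect_equal(round(pr$recall, 2), 0.94)
})

test_that("category_enrichment builds the intra/inter 2x2 and relative enrichment", {
  all_ids <- paste0("P", 1:5)
  cat_ids <- paste0("P", 1:3)
  # all 3 intra pairs are FRPs, none of the 6 inter pairs
  frps <- pairs_df("P1", "P2", "P1", "P3", "P2", "P3")
  ce <- category_enrichment(cat_ids, frps, all_ids)
  expect_equal(ce$n_intra, 3); expect_equal(ce$N_intra, 3)
  expect_equal(ce$n_inter, 0); expect_equal(ce$N_inter, 6)
  expect_true(is.infinite(ce$re))
  # one-sided Fisher p for table (3,0;0,6) from the enumeration oracle
  expect_equal(ce$p, oracle_upper_tail(3, 3, 3, 9), tolerance = 1e-12)
  # margins account for every intra+inter pair
  expect_equal(ce$N_intra + ce$N_inter, 9)
  expect_error(category_enrichment("P1", frps, all_ids), "at least two")
})

test_that("relative enrichment is near 1 for uniformly random calls", {
  set.seed(60)
  all_ids <- paste0("P", 1:20)
  cat_ids <- paste0("P", 1:8)
  res <- replicate(200, {
    idx <- utils::combn(20, 2)
    take <- runif(ncol(idx)) < 0.4
    frps <- data.frame(id1 = all_ids[idx[1, take]],
                       id2 = all_ids[idx[2, take]])
    category_enrichment(cat_ids, frps, all_ids)$re
  })
  expect_lt(abs(mean(res, na.rm = TRUE) - 1), 0.1)
})

test_that("method_overlap returns the three disjoint counts", {
  a <- pairs_df("a", "b", "c", "d", "e", "f", "g", "h", "i", "j")
  b <- pairs_df("b", "a", "d", "c", "x", "y", "z", "w")
  ov <- method_overlap(a, b)
  expect_equal(ov, list(common = 2, only_a = 3, only_b = 2))
  expect_equal(method_overlap(a, a), list(common = 5, only_a = 0, only_b = 0))
  empty <- pairs_df()
  expect_equal(method_overlap(a, empty),
               list(common = 0, only_a = 5, only_b = 0))
})

test_that("find_k_cliques enumerates complete subgraphs exactly once", {
  triangle <- pairs_df("a", "b", "b", "c", "a", "c")
  expect_equal(find_k_cliques(triangle, 3), list(c("a", "b", "c")))
  path3 <- pairs_df("a", "b", "b", "c")
  expect_equal(find_k_cliques(path3, 3), list())
  # K4 has four size-3 cliques
  k4 <- pairs_df("a", "b", "a", "c", "a", "d", "b", "c", "b", "d", "c", "d")
  expect_length(find_k_cliques(k4, 3), 4L)
  expect_equal(find_k_cliques(k4, 4), list(c("a", "b", "c", "d")))
})

test_that("clique finder agrees with exhaustive subset enumeration on random graphs", {
  oracle_cliques <- function(pairs, k) {
    nodes <- sort(unique(c(pairs$id1, pairs$id2)))
    keys <- pathcrosstalk:::pair_key(pairs$id1, pairs$id2)
    if (length(nodes) < k) return(list())
    out <- list()
    subsets <- utils::combn(nodes, k, simplify = FALSE)
    for (s in subsets) {
      need <- pathcrosstalk:::all_pair_keys(s)
      if (all(need %in% keys)) out[[length(out) + 1L]] <- s
    }
    out
  }
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    nodes <- paste0("v", seq_len(n))
    idx <- utils::combn(n, 2)
    take <- runif(ncol(idx)) < 0.45
    pairs <- data.frame(id1 = nodes[idx[1, take]], id2 = nodes[idx[2, take]])
    if (nrow(pairs) == 0) next
    got <- find_k_cliques(pairs, 3)
    want <- oracle_cliques(pairs, 3)
    expect_equal(got, want[order(vapply(want, paste, "", collapse = "\r"))],
                 info = sprintf("rep %d", rep))
  }
})

test_that("single_shared_gene_pairs buckets one-common-gene pairs by method", {
  coll <- pathway_collection(list(
    A = c("g7", "a1", "a2"),
    B = c("g7", "b1", "b2"),       # shares exactly g7 with A
    C = c("g7", "a1", "c1"),       # shares two genes with A -> excluded
    D = c("d1", "d2", "d3")))      # shares nothing
  frps <- pairs_df("A", "B")
  sips <- pairs_df("B", "C")
  out <- single_shared_gene_pairs(coll, frps, sips)
  ab <- out[out$id1 == "A" & out$id2 == "B", ]
  expect_equal(ab$gene, "g7")
  expect_equal(ab$bucket, "frp_only")
  expect_false(any(out$id1 == "A" & out$id2 == "C"))     # two shared genes
  expect_false(any(out$id2 == "D" | out$id1 == "D"))     # no shared gene
  bc <- out[out$id1 == "B" & out$id2 == "C", ]
  expect_equal(bc$bucket, "sip_only")
})

test_that("ranking_auc separates planted truth from noise", {
  pairs <- data.frame(id1 = c("a", "a", "b", "c"),
                      id2 = c("b", "c", "c", "d"),
                      funsim = c(0.9, 0.8, 0.1, 0.2))
  truth <- pairs_df("a", "b", "c", "a")
  expect_equal(ranking_auc(pairs, truth), 1)
  truth2 <- pairs_df("b", "c")
  expect_equal(ranking_auc(pairs, truth2), 0)
  expect_true(is.na(ranking_auc(pairs, pairs_df())))
})
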