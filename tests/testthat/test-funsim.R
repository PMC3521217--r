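# Brute-force propagation oracle: distinct and multiplicity-preserving
# term frequencies computed by explicit family enumeration.
oracle_tf <- function(genes, term, ann, dag, mode) {
  fam <- c(term, oracle_descendants(dag, term))
  counts <- vapply(fam, function(t) {
    length(intersect(ann$term_genes[[t]], genes))
  }, 0L)
  if (mode == "sum") sum(counts)
  else length(unique(unlist(lapply(fam, function(t)
    intersect(ann$term_genes[[t]], genes)))))
}

test_that("term_frequency propagates annotation counts over the DAG", {
  dd <- diamond_dag()
  ann <- diamond_annotations()
  # leaf D: g2 and g5 directly annotated, both modes agree
  expect_equal(term_frequency(c("g2", "g5"), "D", ann, dd, "sum"), 2)
  expect_equal(term_frequency(c("g2", "g5"), "D", ann, dd, "distinct"), 2)
  # B with child D: g1 at B, g2 at D, disjoint genes
  expect_equal(term_frequency(c("g1", "g2"), "B", ann, dd, "sum"), 2)
  expect_equal(term_frequency(c("g1", "g2"), "B", ann, dd, "distinct"), 2)
  # g5 annotated to both C and D: sum counts it twice under C, distinct once
  expect_equal(term_frequency("g5", "C", ann, dd, "sum"), 2)
  expect_equal(term_frequency("g5", "C", ann, dd, "distinct"), 1)
  expect_error(term_frequency("g1", "missing", ann, dd), "unknown term")
})

test_that("term_frequency matches the brute-force oracle on random DAGs", {
  for (seed in 1:20) {
    dag <- random_dag(50, seed = 1000 + seed)
    set.seed(seed)
    genes <- paste0("g", 1:40)
    ann <- annotation_set(stats::setNames(
      lapply(genes, function(g) sample(dag$terms, sample(1:4, 1))), genes))
    pw <- sample(genes, 12)
    for (term in sample(dag$terms, 8)) {
      for (mode in c("sum", "distinct")) {
        expect_equal(term_frequency(pw, term, ann, dag, mode),
                     oracle_tf(pw, term, ann, dag, mode),
                     info = sprintf("seed %d term %s mode %s", seed, term, mode))
      }
    }
  }
})

test_that("direct children_mode limits propagation to one level", {
  dd <- diamond_dag()
  ann <- diamond_annotations()
  # A -> B -> nothing else in direct mode; D excluded
  expect_equal(term_frequency("g2", "A", ann, dd, "sum", children_mode = "direct"), 0)
  expect_equal(term_frequency("g2", "A", ann, dd, "sum", children_mode = "recursive"), 1)
})

test_that("idf follows log(N/tf) with clipping at zero", {
  dd <- diamond_dag()
  ann <- diamond_annotations()
  # N_G = 5. Term A propagated-sum tf: direct 1 (g3) + B(2) + C(2) + D(2) = 7 > 5
  expect_message(v <- idf("A", ann, dd, mode = "sum"), "clip", all = FALSE)
  expect_equal(v, 0)
  # distinct mode: all 5 genes under A -> log(5/5) = 0 without clipping
  expect_equal(idf("A", ann, dd, mode = "distinct"), 0)
  # B distinct: genes g1, g4 (B) + g2, g5 (D) = 4 -> log(5/4)
  expect_equal(idf("B", ann, dd, mode = "distinct"), log(5 / 4))
  # constructed 100/10 check
  genes <- paste0("g", 1:100)
  ann2 <- annotation_set(stats::setNames(
    lapply(1:100, function(i) if (i <= 10) "X" else "Y"), genes))
  dag2 <- pathcrosstalk:::new_ontology_dag(c("r", "X", "Y"),
                                           list(X = "r", Y = "r"),
                                           "biological_process")
  expect_equal(idf("X", ann2, dag2), log(10), tolerance = 1e-12)
})

test_that("pathway_vector weights equal tf * idf and drop zeros", {
  genes <- paste0("g", 1:100)
  ann <- annotation_set(stats::setNames(
    lapply(1:100, function(i) if (i <= 25) "X" else "Y"), genes))
  dag <- pathcrosstalk:::new_ontology_dag(c("r", "X", "Y"),
                                          list(X = "r", Y = "r"),
                                          "biological_process")
  v <- pathway_vector(paste0("g", 1:5), c("X"), ann, dag, pathway_id = "p")
  expect_equal(unname(v$weights[["X"]]), 5 * log(100 / 25), tolerance = 1e-12)
  # empty representative set -> empty vector
  v0 <- pathway_vector(paste0("g", 1:5), character(0), ann, dag)
  expect_equal(length(v0$weights), 0L)
})

test_that("pathway vectors match a spreadsheet-style recomputation on the fixture", {
  st <- fixture_study()
  res <- suppressMessages(fba_pipeline(st$collection, st$ann, st$dag))
  id <- st$collection$ids[[1]]
  rep_terms <- res$enrichment[[id]]$representative
  skip_if(length(rep_terms) == 0L, "fixture pathway has no representative terms")
  pw <- intersect(st$collection$genes[[id]], st$ann$universe)
  n_g <- length(st$ann$universe)
  expected <- vapply(rep_terms, function(term) {
    tf <- oracle_tf(pw, term, st$ann, st$dag, "sum")
    tf_g <- oracle_tf(st$ann$universe, term, st$ann, st$dag, "sum")
    tf * max(0, log(n_g / tf_g))
  }, numeric(1))
  expected <- expected[expected > 0]
  got <- res$vectors[[id]]$weights
  expect_equal(got[sort(names(expected))],
               expected[sort(names(expected))], tolerance = 1e-12)
})

test_that("funsim computes cosine with the zero-vector convention", {
  v1 <- c(A = 1, B = 1)
  v2 <- c(A = 1, C = 1)
  expect_equal(funsim(v1, v2), 0.5)
  expect_equal(funsim(v1, v1), 1.0)
  expect_equal(funsim(v1, c(C = 2, D = 3)), 0)      # disjoint support
  expect_equal(funsim(numeric(0), v1), 0)            # empty vector
  expect_equal(funsim(c(A = 0, B = 0), v1), 0)       # all-zero vector
})

test_that("funsim is symmetric, bounded, scale- and log-base-invariant", {
  set.seed(123)
  terms <- paste0("T", 1:30)
  for (i in 1:1000) {
    s1 <- sample(terms, sample(0:8, 1))
    s2 <- sample(terms, sample(1:8, 1))
    v1 <- stats::setNames(runif(length(s1), 0, 10), s1)
    v2 <- stats::setNames(runif(length(s2), 0, 10), s2)
    s <- funsim(v1, v2)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_identical(s, funsim(v2, v1))
    # positive rescaling of one vector changes nothing
    expect_equal(funsim(v1 * 3.7, v2), s, tolerance = 1e-12)
  }
  # replacing ln with log10 rescales every weight by 1/ln(10): funSim fixed
  st <- fixture_study()
  res <- suppressMessages(fba_pipeline(st$collection, st$ann, st$dag))
  v <- res$vectors
  for (i in seq_along(v)) {
    for (j in seq_along(v)) {
      if (i < j) {
        s_ln <- funsim(v[[i]], v[[j]])
        s_l10 <- funsim(v[[i]]$weights / log(10), v[[j]]$weights / log(10))
        expect_equal(s_ln, s_l10, tolerance = 1e-12)
      }
    }
  }
})

test_that("all_pairs builds a symmetric matrix with unit diagonal for non-zero vectors", {
  st <- fixture_study()
  res <- suppressMessages(fba_pipeline(st$collection, st$ann, st$dag))
  m <- res$funsim$scores
  expect_equal(m, t(m))
  nz <- vapply(res$vectors, function(v) length(v$weights) > 0, logical(1))
  expect_equal(unname(diag(m)[nz]), rep(1, sum(nz)))
  expect_equal(nrow(funsim_pairs(res$funsim)), choose(6, 2))
  # two copies of the same pathway score 1
  two <- pathway_collection(list(a = st$collection$genes[[1]],
                                 b = st$collection$genes[[1]]))
  res2 <- suppressMessages(fba_pipeline(two, st$ann, st$dag))
  expect_equal(res2$funsim$scores["a", "b"], 1)
})

test_that("frp_call uses a strict cutoff", {
  fm <- structure(list(pathway_ids = c("a", "b", "c"),
                       scores = matrix(c(1, 0.50, 0.51,
                                         0.50, 1, 0.2,
                                         0.51, 0.2, 1), 3, 3,
                                       dimnames = list(c("a","b","c"),
                                                       c("a","b","c")))),
                  class = "funsim_matrix")
  frps <- frp_call(fm, cutoff = 0.5)
  expect_equal(nrow(frps), 1L)            # 0.50 excluded, 0.51 passes
  expect_equal(frps$funsim, 0.51)
  expect_equal(nrow(frp_call(fm, cutoff = 1.0)), 0L)
  expect_equal(nrow(frp_call(fm, cutoff = 0)), 3L)  # every positive score
})

test_that("within-group funSim beats between-group across synthetic collections", {
  wins <- 0L
  for (seed in 1:20) {
    st <- generate_study(synthetic_config(seed = 300 + seed))
    res <- suppressMessages(suppressWarnings(
      fba_pipeline(st$collection, st$ann, st$dag)))
    pairs <- funsim_pairs(res$funsim)
    truth_keys <- pathcrosstalk:::pair_key(st$truth$id1, st$truth$id2)
    keys <- pathcrosstalk:::pair_key(pairs$id1, pairs$id2)
    within <- pairs$funsim[keys %in% truth_keys]
    between <- pairs$funsim[!keys %in% truth_keys]
    wins <- wins + (mean(within) > mean(between))
  }
  expect_gte(wins / 20, 0.95)
})
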