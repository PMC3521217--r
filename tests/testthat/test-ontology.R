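test_that("parse_obo records is_a edges, drops obsolete and foreign-namespace terms", {
  path <- write_fixture_obo()
  dag <- parse_obo(path, "biological_process")
  expect_setequal(dag$terms, c("GO:0000001", "GO:0000002", "GO:0000003"))
  expect_equal(dag$parents[["GO:0000002"]], "GO:0000001")
  # multi-parent term: both is_a parents recorded
  expect_setequal(dag$parents[["GO:0000003"]], c("GO:0000001", "GO:0000002"))
  expect_false("GO:0000004" %in% dag$terms)  # obsolete excluded
  expect_false("GO:0000005" %in% dag$terms)  # other namespace excluded
  expect_true("GO:0000004" %in% dag$obsolete)
})

test_that("parse_obo rejects malformed stanza lines with a line number", {
  path <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: GO:0000001", "namespace: biological_process",
               "this line has no key"), path)
  expect_error(parse_obo(path, "biological_process"), "line 4")
})

test_that("parse_obo detects cycles", {
  path <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A", "namespace: biological_process", "is_a: B",
               "", "[Term]", "id: B", "namespace: biological_process",
               "is_a: A"), path)
  expect_error(parse_obo(path, "biological_process"), "cycle")
})

test_that("descendants walks the transitive closure, counting each term once", {
  path <- write_fixture_obo()
  dag <- parse_obo(path, "biological_process")
  expect_setequal(descendants(dag, "GO:0000001"), c("GO:0000002", "GO:0000003"))
  expect_equal(descendants(dag, "GO:0000003"), character(0))  # leaf

  dd <- diamond_dag()
  expect_setequal(descendants(dd, "A"), c("B", "C", "D"))  # D once
  expect_error(descendants(dd, "nope"), "unknown term")
})

test_that("descendants agrees with a brute-force reachability oracle on random DAGs", {
  for (seed in 1:20) {
    dag <- random_dag(n = sample(10:50, 1), seed = seed)
    for (term in sample(dag$terms, 5)) {
      expect_equal(descendants(dag, term), oracle_descendants(dag, term),
                   info = sprintf("seed %d term %s", seed, term))
    }
  }
})

test_that("descendant_table matches per-term descendants", {
  dag <- random_dag(30, seed = 7)
  tab <- pathcrosstalk:::descendant_table(dag)
  for (term in dag$terms) {
    expect_equal(tab[[term]], descendants(dag, term))
  }
})

test_that("load_annotations applies the experimental-evidence filter", {
  path <- write_fixture_obo()
  dag <- parse_obo(path, "biological_process")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "#tax_id\tGeneID\tGO_ID\tEvidence\tQualifier\tGO_term\tCategory",
    "9606\tg1\tGO:0000002\tIEA\t-\tx\tProcess",   # electronic: dropped
    "9606\tg1\tGO:0000002\tIDA\t-\tx\tProcess",   # kept
    "9606\tg1\tGO:0000002\tIMP\t-\tx\tProcess",   # duplicate association
    "9606\tg2\tGO:0000003\tEXP\tNOT\tx\tProcess", # NOT qualifier: dropped
    "9606\tg2\tGO:0000003\tIC\t-\tx\tProcess",    # kept
    "9606\tg3\tGO:0000005\tIDA\t-\tx\tFunction",  # term outside DAG: dropped
    "9606\tg4\tGO:0000001\tISS\t-\tx\tProcess"),  # non-experimental: dropped
    tsv)
  ann <- suppressMessages(load_annotations(tsv, dag))
  expect_setequal(ann$universe, c("g1", "g2"))
  expect_equal(ann$gene_terms[["g1"]], "GO:0000002")  # IDA+IMP collapse
  expect_equal(ann$gene_terms[["g2"]], "GO:0000003")
})

test_that("load_annotations errors when nothing survives filtering", {
  path <- write_fixture_obo()
  dag <- parse_obo(path, "biological_process")
  tsv <- tempfile(fileext = ".tsv")
  writeLines("9606\tg1\tGO:0000002\tIEA\t-\tx\tProcess", tsv)
  expect_error(load_annotations(tsv, dag), "no annotations survive")
})

test_that("annotation set maps are exact inverses", {
  ann <- diamond_annotations()
  for (g in ann$universe) {
    for (t in ann$gene_terms[[g]]) {
      expect_true(g %in% ann$term_genes[[t]])
    }
  }
  for (t in names(ann$term_genes)) {
    for (g in ann$term_genes[[t]]) {
      expect_true(t %in% ann$gene_terms[[g]])
    }
  }
  expect_setequal(ann$universe, names(ann$gene_terms))
})

test_that("evidence filtering is idempotent", {
  path <- write_fixture_obo()
  dag <- parse_obo(path, "biological_process")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("9606\tg1\tGO:0000002\tIDA\t-\tx\tProcess",
               "9606\tg2\tGO:0000003\tIMP\t-\tx\tProcess"), tsv)
  ann1 <- load_annotations(tsv, dag)
  # Re-serialize the already-filtered set and reload: nothing changes.
  tsv2 <- tempfile(fileext = ".tsv")
  write_gene2go(ann1, tsv2)
  ann2 <- load_annotations(tsv2, dag)
  expect_equal(ann1$gene_terms, ann2$gene_terms)
  expect_equal(ann1$term_genes, ann2$term_genes)
})

test_that("annotated_gene_count restricts correctly", {
  dd <- diamond_dag()
  ann <- diamond_annotations()
  expect_equal(annotated_gene_count(ann, dd, "B"), 2L)          # g1, g4
  expect_equal(annotated_gene_count(ann, dd, "B", c("g1", "g3")), 1L)
  expect_equal(annotated_gene_count(ann, dd, "D", character(0)), 0L)
  # term with no direct annotations
  dd2 <- pathcrosstalk:::new_ontology_dag(c("A", "Z"), list(Z = "A"),
                                          "biological_process")
  ann2 <- annotation_set(list(g1 = "A"))
  expect_equal(annotated_gene_count(ann2, dd2, "Z"), 0L)
})
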