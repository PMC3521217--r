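# Shared in-code fixtures: a hand-written 5-term OBO file, a small diamond
# DAG, and a tiny annotated universe used across module tests.

# OBO text with a chain A <- B <- C, a second parent, and an obsolete term.
write_fixture_obo <- function(path = tempfile(fileext = ".obo")) {
  writeLines(c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: rootA",
    "namespace: biological_process",
    "",
    "[Term]",
    "id: GO:0000002",
    "name: B",
    "namespace: biological_process",
    "is_a: GO:0000001 ! rootA",
    "",
    "[Term]",
    "id: GO:0000003",
    "name: C",
    "namespace: biological_process",
    "is_a: GO:0000002 ! B",
    "is_a: GO:0000001 ! rootA",
    "",
    "[Term]",
    "id: GO:0000004",
    "name: gone",
    "namespace: biological_process",
    "is_obsolete: true",
    "",
    "[Term]",
    "id: GO:0000005",
    "name: other branch",
    "namespace: molecular_function",
    ""), path)
  path
}

# Diamond: A is parent of B and C; D is child of both B and C.
diamond_dag <- function() {
  pathcrosstalk:::new_ontology_dag(
    terms = c("A", "B", "C", "D"),
    parents = list(B = "A", C = "A", D = c("B", "C")),
    namespace = "biological_process")
}

# Small annotated universe over the diamond DAG.
#   g1: B, C   g2: D   g3: A   g4: B   g5: C, D
diamond_annotations <- function() {
  annotation_set(list(g1 = c("B", "C"), g2 = "D", g3 = "A",
                      g4 = "B", g5 = c("C", "D")))
}

# Random DAG for oracle-equivalence properties: n terms, layered levels.
random_dag <- function(n, seed) {
  set.seed(seed)
  ids <- paste0("T", seq_len(n))
  level <- c(0L, sample(1:5, n - 1L, replace = TRUE))
  parents <- list()
  for (i in 2:n) {
    lower <- which(level < level[[i]])
    k <- min(length(lower), sample(1:2, 1))
    parents[[ids[[i]]]] <- ids[sample(lower, k)]
  }
  pathcrosstalk:::new_ontology_dag(ids, parents, "biological_process")
}

# Brute-force reachability oracle: strict descendants by repeated edge
# expansion over the raw parent map (independent of the package's DFS).
oracle_descendants <- function(dag, term) {
  edges_child <- rep(names(dag$parents), lengths(dag$parents))
  edges_parent <- unlist(dag$parents, use.names = FALSE)
  reach <- character(0)
  frontier <- term
  repeat {
    nxt <- setdiff(edges_child[edges_parent %in% frontier], c(reach, term))
    if (length(nxt) == 0L) break
    reach <- c(reach, nxt)
    frontier <- nxt
  }
  sort(reach)
}

# Exhaustive hypergeometric upper tail: sum the point masses of every
# achievable table, via choose() only.
oracle_upper_tail <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, numeric(1)))
}

# A 6-pathway fixture collection with two planted groups over the default
# synthetic study (cheap to regenerate; deterministic).
fixture_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_study(synthetic_config(seed = 42))
    cache
  }
})
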