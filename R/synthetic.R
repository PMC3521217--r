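# Seeded synthetic fixtures: a multi-root-free rooted GO-like DAG with
# multi-parent terms, heavy-tailed gene annotations, pathway groups with
# planted shared functional themes, a PPI network with boosted wiring across
# true cross-talk pairs, and a tissue-expression table in which true pairs
# co-express. Every generator is deterministic under the configured seed,
# and each output serializes to the same text format the readers consume.

#' Configuration for the synthetic-data generators
#'
#' Defaults describe the reference simulation used throughout the test
#' suite: a 60-term DAG of depth 6, 300 annotated genes with heavy-tailed
#' per-gene term counts, 6 pathways of 15-25 genes in 2 planted functional
#' groups with 80% of member genes drawn from the group's theme subtree, 20
#' tissues, a sparse background PPI (density 0.01) with boosted wiring
#' (0.3) across true pairs.
#'
#' @param seed master RNG seed.
#' @param n_terms DAG size (>= 3).
#' @param depth maximum DAG depth.
#' @param n_genes annotated universe size.
#' @param n_pathways number of pathways (multiple of `n_groups`).
#' @param n_groups planted functional groups (>= 2).
#' @param pathway_size_range min/max pathway size.
#' @param theme_strength fraction of a pathway's genes drawn from its
#'   group's theme-annotated gene pool, in (0, 1].
#' @param n_tissues number of tissues.
#' @param ppi_density background edge probability.
#' @param planted_ppi_boost edge probability across true cross-talk pairs.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_terms = 60L, depth = 6L,
                             n_genes = 300L, n_pathways = 6L, n_groups = 2L,
                             pathway_size_range = c(15L, 25L),
                             theme_strength = 0.8, n_tissues = 20L,
                             ppi_density = 0.01, planted_ppi_boost = 0.3) {
  cfg <- list(seed = as.integer(seed), n_terms = as.integer(n_terms),
              depth = as.integer(depth), n_genes = as.integer(n_genes),
              n_pathways = as.integer(n_pathways),
              n_groups = as.integer(n_groups),
              pathway_size_range = as.integer(pathway_size_range),
              theme_strength = theme_strength,
              n_tissues = as.integer(n_tissues),
              ppi_density = ppi_density,
              planted_ppi_boost = planted_ppi_boost)
  stopifnot(cfg$n_terms >= 3L, cfg$depth >= 2L, cfg$n_genes >= 1L,
            cfg$n_groups >= 2L, cfg$n_pathways >= cfg$n_groups,
            cfg$theme_strength > 0, cfg$theme_strength <= 1,
            cfg$ppi_density >= 0, cfg$ppi_density <= 1,
            cfg$planted_ppi_boost >= 0, cfg$planted_ppi_boost <= 1,
            length(cfg$pathway_size_range) == 2L,
            cfg$pathway_size_range[[1L]] >= 1L,
            cfg$pathway_size_range[[1L]] <= cfg$pathway_size_range[[2L]])
  structure(cfg, class = "synthetic_config")
}

synthetic_term_ids <- function(n) sprintf("GO:%07d", seq_len(n))
synthetic_gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Generate a rooted GO-like DAG
#'
#' Terms are layered by depth; every non-root term gets one parent from a
#' shallower layer and at least 10% of terms get a second parent, so
#' multi-parent propagation paths are exercised.
#'
#' @param cfg a `synthetic_config`. Seeds the RNG with `cfg$seed`.
#' @return an `ontology_dag` (namespace `"biological_process"`).
#' @export
generate_dag <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_terms
  ids <- synthetic_term_ids(n)
  level <- integer(n)
  level[[1L]] <- 0L
  if (n >= 2L) level[[2L]] <- 1L
  if (n >= 3L) {
    level[3:n] <- sample(seq_len(cfg$depth - 1L), n - 2L, replace = TRUE)
  }
  parents <- stats::setNames(vector("list", n), ids)
  for (i in 2:n) {
    shallower <- which(level < level[[i]])
    parents[[ids[[i]]]] <- ids[[if (length(shallower) == 1L) shallower else sample(shallower, 1L)]]
  }
  # Second parents until >= 10% of terms are multi-parent.
  need <- ceiling(0.10 * n)
  candidates <- sample(which(level >= 1L))
  for (i in candidates) {
    if (sum(lengths(parents) >= 2L) >= need) break
    shallower <- setdiff(which(level < level[[i]]),
                         match(parents[[ids[[i]]]], ids))
    if (length(shallower) == 0L) next
    extra <- ids[[if (length(shallower) == 1L) shallower else sample(shallower, 1L)]]
    parents[[ids[[i]]]] <- sort(c(parents[[ids[[i]]]], extra))
  }
  if (sum(lengths(parents) >= 2L) < need) {
    stop("generate_dag: cannot satisfy the multi-parent constraint; increase depth or n_terms")
  }
  dag <- new_ontology_dag(ids, parents[lengths(parents) > 0L],
                          "biological_process")
  assert_acyclic(dag)
  dag
}

# Theme subtrees: disjoint term families (a term plus its strict
# descendants) of moderate size, chosen structurally from the DAG. The same
# deterministic choice is made by the annotation and collection generators,
# so the planted functional classes line up without sharing state.
pick_theme_subtrees <- function(dag, n_groups) {
  desc <- descendant_table(dag)
  sizes <- lengths(desc)
  candidates <- names(sizes)[sizes >= 2L & sizes <= 6L]
  # Prefer compact families of about 4 terms, so theme genes annotate most
  # of the family and per-term counts stay concentrated; deterministic order.
  candidates <- candidates[order(abs(sizes[candidates] - 3L), candidates)]
  chosen <- character(0)
  used_terms <- character(0)
  for (t in candidates) {
    fam <- c(t, desc[[t]])
    if (length(intersect(fam, used_terms)) > 0L) next
    chosen <- c(chosen, t)
    used_terms <- c(used_terms, fam)
    if (length(chosen) == n_groups) break
  }
  if (length(chosen) < n_groups) {
    stop("synthetic: cannot place disjoint theme subtrees; increase n_terms or depth")
  }
  list(roots = chosen,
       families = stats::setNames(lapply(chosen, function(t) c(t, desc[[t]])),
                                  chosen),
       desc = desc)
}

#' Generate evidence-style annotations for a synthetic universe
#'
#' Per-gene direct-term counts follow a shifted geometric distribution
#' (heavy-tailed, capped at 8) so the count-matching strata used by the
#' background module are non-trivial; every gene gets at least one term.
#' To plant functional coherence, 25% of genes are assigned (evenly) to one
#' of `n_groups` latent functional classes; a class gene concentrates most
#' of its annotations (the `theme_strength` fraction) inside its group's
#' theme subtree, the way genes acting in one biological process share
#' annotations under that process in real GO data. The remaining genes
#' annotate uniformly.
#'
#' @param dag the DAG the annotations live in (themes are subtrees of it).
#' @param cfg a `synthetic_config`. Seeds the RNG with `cfg$seed + 1`.
#' @return an `annotation_set` over `cfg$n_genes` genes.
#' @export
generate_annotations <- function(dag, cfg) {
  set.seed(cfg$seed + 1L)
  genes <- synthetic_gene_ids(cfg$n_genes)
  themes <- pick_theme_subtrees(dag, cfg$n_groups)
  pool <- setdiff(dag$terms, dag$terms[[1L]])
  n_theme_genes <- floor(0.25 * cfg$n_genes)
  class_of <- rep(0L, cfg$n_genes)  # 0 = background
  if (n_theme_genes > 0L) {
    class_of[seq_len(n_theme_genes)] <-
      rep_len(seq_len(cfg$n_groups), n_theme_genes)
  }
  counts <- pmin(1L + stats::rgeom(cfg$n_genes, prob = 0.25), 8L)
  gene_terms <- lapply(seq_len(cfg$n_genes), function(i) {
    n_i <- min(counts[[i]], length(pool))
    if (class_of[[i]] == 0L) {
      sample(pool, n_i)
    } else {
      fam <- setdiff(themes$families[[class_of[[i]]]], dag$terms[[1L]])
      n_fam <- min(max(1L, round(cfg$theme_strength * n_i)), length(fam))
      in_theme <- sample(fam, n_fam)
      rest <- setdiff(pool, in_theme)
      n_rest <- min(n_i - n_fam, length(rest))
      c(in_theme, if (n_rest > 0L) sample(rest, n_rest))
    }
  })
  names(gene_terms) <- genes
  annotation_set(gene_terms)
}

#' Generate a pathway collection with planted functional groups
#'
#' Pathways are split evenly over `n_groups` groups; each group owns a
#' disjoint theme subtree of the DAG, and `theme_strength` of every member
#' pathway's genes are drawn from the genes annotated within that subtree
#' (the rest uniformly from the universe). Pathways in the same group
#' therefore share enriched terms — the planted functional relation — and
#' all within-group pairs form the truth set.
#'
#' @param dag an `ontology_dag` from [generate_dag].
#' @param ann an `annotation_set` from [generate_annotations].
#' @param cfg a `synthetic_config`. Seeds the RNG with `cfg$seed + 2`.
#' @return list with `collection` (a `pathway_collection`), `truth`
#'   (data.frame `id1`, `id2` of within-group pairs), `groups` (named
#'   membership vector) and `theme_roots`.
#' @export
generate_collection <- function(dag, ann, cfg) {
  set.seed(cfg$seed + 2L)
  per_group <- cfg$n_pathways %/% cfg$n_groups
  extras <- cfg$n_pathways %% cfg$n_groups
  group_of <- rep(seq_len(cfg$n_groups),
                  times = per_group + (seq_len(cfg$n_groups) <= extras))
  themes <- pick_theme_subtrees(dag, cfg$n_groups)
  # Gene pool of a group: genes whose direct annotations are mostly inside
  # the group's theme subtree (the latent class planted at annotation time).
  pools <- lapply(seq_len(cfg$n_groups), function(g) {
    fam <- themes$families[[g]]
    in_fam <- vapply(ann$gene_terms,
                     function(ts) sum(ts %in% fam) >= length(ts) / 2, logical(1))
    names(ann$gene_terms)[in_fam]
  })
  if (any(lengths(pools) < cfg$pathway_size_range[[1L]])) {
    stop("synthetic: theme gene pools too small; increase n_genes")
  }
  ids <- sprintf("P%02d", seq_len(cfg$n_pathways))
  genes <- vector("list", cfg$n_pathways)
  for (i in seq_len(cfg$n_pathways)) {
    g <- group_of[[i]]
    size <- sample(seq(cfg$pathway_size_range[[1L]],
                       cfg$pathway_size_range[[2L]]), 1L)
    n_theme <- min(round(cfg$theme_strength * size), length(pools[[g]]))
    theme_genes <- sample(pools[[g]], n_theme)
    rest_pool <- setdiff(ann$universe, theme_genes)
    rest <- sample(rest_pool, size - n_theme)
    genes[[i]] <- sort(c(theme_genes, rest))
  }
  names(genes) <- ids
  truth_rows <- list()
  for (g in seq_len(cfg$n_groups)) {
    members <- ids[group_of == g]
    if (length(members) >= 2L) {
      idx <- utils::combn(length(members), 2L)
      truth_rows[[g]] <- data.frame(id1 = members[idx[1L, ]],
                                    id2 = members[idx[2L, ]],
                                    stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows)
           else data.frame(id1 = character(0), id2 = character(0))
  list(collection = pathway_collection(genes),
       truth = truth,
       groups = stats::setNames(group_of, ids),
       theme_roots = themes$roots)
}

#' Generate a PPI network with boosted cross-talk wiring
#'
#' Background edges between universe genes appear with probability
#' `ppi_density`; additionally, for every truth pair, edges across the two
#' pathways' exclusive gene sets appear with probability
#' `planted_ppi_boost`.
#'
#' @param coll a `pathway_collection`.
#' @param truth data.frame of true pairs (`id1`, `id2`).
#' @param ann an `annotation_set` (its universe is the node candidate set).
#' @param cfg a `synthetic_config`. Seeds the RNG with `cfg$seed + 3`.
#' @return a `ppi_network`.
#' @export
generate_ppi <- function(coll, truth, ann, cfg) {
  set.seed(cfg$seed + 3L)
  nodes <- ann$universe
  idx <- utils::combn(length(nodes), 2L)
  on <- stats::runif(ncol(idx)) < cfg$ppi_density
  a <- nodes[idx[1L, on]]
  b <- nodes[idx[2L, on]]
  if (nrow(truth) > 0L && cfg$planted_ppi_boost > 0) {
    for (i in seq_len(nrow(truth))) {
      g1 <- setdiff(coll$genes[[truth$id1[[i]]]], coll$genes[[truth$id2[[i]]]])
      g2 <- setdiff(coll$genes[[truth$id2[[i]]]], coll$genes[[truth$id1[[i]]]])
      if (length(g1) == 0L || length(g2) == 0L) next
      grid <- expand.grid(g1, g2, stringsAsFactors = FALSE)
      on2 <- stats::runif(nrow(grid)) < cfg$planted_ppi_boost
      a <- c(a, grid[[1L]][on2])
      b <- c(b, grid[[2L]][on2])
    }
  }
  if (length(a) == 0L) {
    return(structure(list(edges = matrix(character(0), ncol = 2L,
                                         dimnames = list(NULL, c("a", "b"))),
                          nodes = character(0)),
                     class = "ppi_network"))
  }
  ppi_network(a, b)
}

#' Generate a tissue-expression table with co-expressed true pairs
#'
#' Each planted group owns a block of tissues; in those tissues most genes
#' of the group's pathways are expressed on top of a random background, so
#' true (within-group) pairs share expressed-tissue sets while other pairs
#' overlap only by chance. Tissue blocks of different groups are disjoint,
#' with leftover tissues carrying background expression only.
#'
#' @param coll a `pathway_collection`.
#' @param groups named group-membership vector (from [generate_collection]).
#' @param ann an `annotation_set`.
#' @param cfg a `synthetic_config`. Seeds the RNG with `cfg$seed + 4`.
#' @return a `tissue_expression` over `cfg$n_tissues` tissues.
#' @export
generate_expression <- function(coll, groups, ann, cfg) {
  set.seed(cfg$seed + 4L)
  tissues <- sprintf("tissue%02d", seq_len(cfg$n_tissues))
  n_groups <- max(groups)
  block_size <- max(1L, cfg$n_tissues %/% (n_groups + 1L))
  block_of <- lapply(seq_len(n_groups), function(g) {
    tissues[seq((g - 1L) * block_size + 1L, g * block_size)]
  })
  expressed <- stats::setNames(vector("list", length(tissues)), tissues)
  for (t in tissues) {
    base <- ann$universe[stats::runif(length(ann$universe)) < 0.25]
    boosted <- character(0)
    for (g in seq_len(n_groups)) {
      if (t %in% block_of[[g]]) {
        members <- names(groups)[groups == g]
        member_genes <- unique(unlist(coll$genes[members], use.names = FALSE))
        boosted <- c(boosted, member_genes[stats::runif(length(member_genes)) < 0.9])
      }
    }
    expressed[[t]] <- sort(unique(c(base, boosted)))
  }
  tissue_expression(expressed, genome_size = length(ann$universe))
}

#' Generate the full synthetic study
#'
#' Convenience wrapper running every generator with a single config; the
#' one-stop input for end-to-end tests.
#'
#' @param cfg a `synthetic_config`.
#' @return list with `dag`, `ann`, `collection`, `truth`, `groups`,
#'   `theme_roots`, `ppi`, `expression`, `config`.
#' @export
generate_study <- function(cfg = synthetic_config()) {
  dag <- generate_dag(cfg)
  ann <- generate_annotations(dag, cfg)
  coll <- generate_collection(dag, ann, cfg)
  ppi <- generate_ppi(coll$collection, coll$truth, ann, cfg)
  expr <- generate_expression(coll$collection, coll$groups, ann, cfg)
  list(dag = dag, ann = ann, collection = coll$collection,
       truth = coll$truth, groups = coll$groups,
       theme_roots = coll$theme_roots, ppi = ppi, expression = expr,
       config = cfg)
}

#' Serialize an ontology DAG to OBO
#'
#' @param dag an `ontology_dag`.
#' @param path output path.
#' @export
write_obo <- function(dag, path) {
  out <- c("format-version: 1.2", "")
  for (t in dag$terms) {
    out <- c(out, "[Term]",
             sprintf("id: %s", t),
             sprintf("name: synthetic term %s", t),
             sprintf("namespace: %s", dag$namespace),
             sprintf("is_a: %s", dag$parents[[t]]),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Serialize annotations in gene2go-style TSV
#'
#' Columns: tax_id, GeneID, GO_ID, Evidence, Qualifier, GO_term, Category.
#' All rows carry evidence IDA; synthetic annotations are experimental by
#' construction.
#'
#' @param ann an `annotation_set`.
#' @param path output path.
#' @export
write_gene2go <- function(ann, path) {
  rows <- lapply(names(ann$gene_terms), function(g) {
    data.frame(tax_id = "9606", GeneID = g, GO_ID = ann$gene_terms[[g]],
               Evidence = "IDA", Qualifier = "-", GO_term = "-",
               Category = "Process", stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  writeLines(c("#tax_id\tGeneID\tGO_ID\tEvidence\tQualifier\tGO_term\tCategory",
               do.call(paste, c(df, sep = "\t"))), path)
  invisible(path)
}
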