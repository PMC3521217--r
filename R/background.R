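# Empirical null distribution of funSim from annotation-matched random gene
# sets, and cutoff calibration against a target false-positive rate.

#' Annotation-matched random gene set
#'
#' Replaces every annotated gene of a pathway by a gene drawn uniformly from
#' the universe stratum with the same number of directly annotated terms.
#' Genes already drawn for this set are excluded from later draws; when no
#' unused gene with the exact count exists, the nearest count stratum is
#' used (ties resolved toward the smaller count) and a message is emitted.
#' Unannotated pathway genes are dropped: they carry no term counts to
#' match.
#'
#' @param genes pathway gene set.
#' @param ann an `annotation_set`.
#' @return character vector of replacement genes, same length as the
#'   annotated portion of the pathway. Uses the current RNG state; seed
#'   upstream for reproducibility.
#' @export
matched_random_set <- function(genes, ann) {
  annotated <- intersect(genes, ann$universe)
  counts <- lengths(ann$gene_terms)            # per-gene direct term counts
  strata <- split(names(counts), counts)
  drawn <- character(0)
  for (g in annotated) {
    want <- length(ann$gene_terms[[g]])
    pool <- setdiff(strata[[as.character(want)]], drawn)
    if (length(pool) == 0L) {
      avail <- as.integer(names(strata))
      avail <- avail[vapply(avail, function(c) {
        length(setdiff(strata[[as.character(c)]], drawn)) > 0L
      }, logical(1))]
      if (length(avail) == 0L) stop("matched_random_set: annotation universe exhausted")
      nearest <- avail[order(abs(avail - want), avail)][[1L]]
      message(sprintf("matched_random_set: no unused gene with %d terms; using nearest count %d",
                      want, nearest))
      pool <- setdiff(strata[[as.character(nearest)]], drawn)
    }
    drawn <- c(drawn, if (length(pool) == 1L) pool else sample(pool, 1L))
  }
  drawn
}

#' Empirical null distribution of funSim
#'
#' For each of `n_lists` randomization rounds, every pathway of the
#' collection is replaced by an annotation-matched random gene set, the full
#' function-based pipeline (enrichment, TF-IDF vectors, all-pairs cosine) is
#' run on the randomized collection, and all pair scores are pooled.
#'
#' @inheritParams fba_pipeline
#' @param n_lists number of random gene-set lists (default 100).
#' @param seed master RNG seed; per-list sub-seeds are derived
#'   deterministically from it.
#' @return a `null_distribution`: list with `samples` (numeric vector of
#'   pooled null funSim scores), `n_lists` and `seed`.
#' @export
null_distribution <- function(coll, ann, dag, n_lists = 100L, seed = 1L,
                              alpha = 0.05, mode = c("sum", "distinct"),
                              children_mode = c("recursive", "direct")) {
  stopifnot(n_lists >= 1L)
  mode <- match.arg(mode)
  children_mode <- match.arg(children_mode)
  set.seed(seed)
  list_seeds <- draw_subseeds(n_lists)
  samples <- vector("list", n_lists)
  for (l in seq_len(n_lists)) {
    set.seed(list_seeds[[l]])
    rnd <- lapply(coll$ids, function(id) matched_random_set(coll$genes[[id]], ann))
    names(rnd) <- coll$ids
    rnd_coll <- pathway_collection(rnd)
    fm <- suppressWarnings(
      fba_pipeline(rnd_coll, ann, dag, alpha = alpha, mode = mode,
                   children_mode = children_mode))$funsim
    samples[[l]] <- funsim_pairs(fm)$funsim
  }
  structure(list(samples = unlist(samples, use.names = FALSE),
                 n_lists = n_lists, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d samples from %d lists (seed %d)\n",
              length(x$samples), x$n_lists, x$seed))
  invisible(x)
}

#' False-positive rate of the null at a cutoff
#'
#' Fraction of null funSim scores strictly exceeding the cutoff.
#'
#' @param nd a `null_distribution`.
#' @param cutoff score in \[0, 1\].
#' @return rate in \[0, 1\].
#' @export
fpr_at_cutoff <- function(nd, cutoff) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  if (length(nd$samples) == 0L) stop("empty null distribution")
  mean(nd$samples > cutoff)
}

#' Smallest cutoff achieving a target false-positive rate
#'
#' Scans the 0.01 grid from 0 to 1 and returns the smallest cutoff whose
#' null FPR is at or below the target; returns 1 with a warning when even a
#' cutoff of 1 cannot reach it (impossible by construction, kept as the
#' boundary contract).
#'
#' @param nd a `null_distribution`.
#' @param target FPR target in (0, 1).
#' @return cutoff on the 0.01 grid.
#' @export
cutoff_for_fpr <- function(nd, target) {
  stopifnot(target > 0, target < 1)
  grid <- seq(0, 1, by = 0.01)
  for (c in grid) {
    if (fpr_at_cutoff(nd, c) <= target) return(c)
  }
  warning("cutoff_for_fpr: target unattainable, returning 1.0")
  1.0
}

#' Persist a null distribution as TSV plus JSON metadata sidecar
#'
#' @param nd a `null_distribution`.
#' @param path output TSV path (one `funsim` column); metadata written to
#'   `<path>.meta.json`.
#' @export
write_null_distribution <- function(nd, path) {
  write_tsv(data.frame(funsim = nd$samples), path)
  meta <- list(seed = nd$seed, n_lists = nd$n_lists,
               n_samples = length(nd$samples))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
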