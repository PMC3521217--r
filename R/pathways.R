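# Pathway gene-set collections: GMT reading and curation filters.

new_pathway_collection <- function(ids, names_, genes) {
  structure(
    list(ids = ids,
         names = stats::setNames(names_, ids),
         genes = stats::setNames(genes, ids),
         universe = sort(unique(unlist(genes, use.names = FALSE)))),
    class = "pathway_collection")
}

#' Construct a pathway collection from a named list of gene sets
#'
#' @param genes named list: pathway id -> character vector of gene ids
#'   (duplicates collapsed; empty sets rejected).
#' @param names_ optional display names, defaults to the ids.
#' @return a `pathway_collection` with fields `ids` (in input order),
#'   `names`, `genes` and `universe` (union of all member genes).
#' @export
pathway_collection <- function(genes, names_ = names(genes)) {
  stopifnot(is.list(genes), !is.null(names(genes)))
  if (anyDuplicated(names(genes))) stop("duplicate pathway id")
  genes <- lapply(genes, function(g) sort(unique(as.character(g))))
  if (any(lengths(genes) == 0L)) stop("pathway with no genes")
  new_pathway_collection(names(genes), names_, genes)
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d pathways, %d genes in union\n",
              length(x$ids), length(x$universe)))
  invisible(x)
}

#' @export
length.pathway_collection <- function(x) length(x$ids)

#' Read a GMT gene-set file
#'
#' One pathway per line: `id<TAB>description<TAB>gene1<TAB>gene2...`.
#' Duplicate genes within a line collapse to one; duplicate pathway ids are
#' an error.
#'
#' @param path path to the GMT file.
#' @return a `pathway_collection`.
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("empty GMT file: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("GMT parse error: line %d has fewer than 3 tab-separated fields",
                 bad[[1L]]))
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate pathway id in GMT: '%s'", ids[duplicated(ids)][[1L]]))
  }
  descs <- vapply(fields, `[[`, "", 2L)
  genes <- lapply(fields, function(f) sort(unique(f[-(1:2)])))
  new_pathway_collection(ids, descs, genes)
}

#' Write a collection to GMT
#'
#' @param coll a `pathway_collection`.
#' @param path output path.
#' @export
write_gmt <- function(coll, path) {
  lines <- vapply(coll$ids, function(id) {
    paste(c(id, unname(coll$names[[id]]), coll$genes[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Filter a pathway collection by size and subsumption
#'
#' Applies the curation rules used when assembling a pathway compendium:
#' pathways with fewer than `min_genes` genes are removed, then any pathway
#' whose gene set is a subset of another surviving pathway's gene set is
#' removed (the larger set survives). Among identical gene sets the pathway
#' listed first survives.
#'
#' @param coll a `pathway_collection`.
#' @param min_genes minimum pathway size kept (default 5).
#' @return list with `collection` (the filtered `pathway_collection`) and
#'   `removed`, a data.frame of columns `id`, `reason` (`"size"` or
#'   `"subsumed"`) and `by` (the subsuming pathway id, or `NA`).
#' @export
filter_collection <- function(coll, min_genes = 5L) {
  stopifnot(min_genes >= 1L)
  removed_id <- character(0)
  removed_reason <- character(0)
  removed_by <- character(0)

  sizes <- lengths(coll$genes)
  small <- coll$ids[sizes < min_genes]
  removed_id <- c(removed_id, small)
  removed_reason <- c(removed_reason, rep("size", length(small)))
  removed_by <- c(removed_by, rep(NA_character_, length(small)))

  ids <- setdiff(coll$ids, small)
  # Subsumption: drop any set contained in another survivor. Process ids in
  # file order; a set identical to an earlier one is dropped (first wins),
  # a strict subset is dropped regardless of order (larger set wins).
  drop <- stats::setNames(rep(FALSE, length(ids)), ids)
  by <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (i in seq_along(ids)) {
    a <- ids[[i]]
    if (drop[[a]]) next
    for (j in seq_along(ids)) {
      if (i == j) next
      b <- ids[[j]]
      if (drop[[b]]) next
      ga <- coll$genes[[a]]; gb <- coll$genes[[b]]
      if (length(ga) > length(gb)) next
      if (all(ga %in% gb)) {
        if (length(ga) == length(gb) && i < j) next  # identical: first wins
        drop[[a]] <- TRUE
        by[[a]] <- b
        break
      }
    }
  }
  subsumed <- ids[drop]
  removed_id <- c(removed_id, subsumed)
  removed_reason <- c(removed_reason, rep("subsumed", length(subsumed)))
  removed_by <- c(removed_by, unname(by[subsumed]))

  keep <- setdiff(coll$ids, removed_id)
  if (length(keep) == 0L) {
    warning("filter_collection removed every pathway")
  }
  out <- new_pathway_collection(keep,
                                unname(coll$names[keep]),
                                coll$genes[keep])
  list(collection = out,
       removed = data.frame(id = removed_id, reason = removed_reason,
                            by = removed_by, stringsAsFactors = FALSE))
}

#' Number of unordered pathway pairs
#'
#' @param coll a `pathway_collection`.
#' @return `n * (n - 1) / 2` for `n` pathways.
#' @examples
#' coll <- pathway_collection(list(a = "g1", b = "g2", c = "g3"))
#' pair_count(coll)  # 3
#' @export
pair_count <- function(coll) {
  n <- length(coll$ids)
  as.numeric(n) * (n - 1) / 2
}
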