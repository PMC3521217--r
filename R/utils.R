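# Internal helpers shared across modules.

#' Canonical key for an unordered pathway pair
#'
#' Pairs of pathway identifiers are unordered throughout the package; this
#' sorts the two ids and joins them so that (a, b) and (b, a) map to the same
#' key.
#'
#' @param a,b character vectors of pathway identifiers (recycled together).
#' @return character vector of canonical pair keys.
#' @keywords internal
pair_key <- function(a, b) {
  swap <- a > b
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  paste(lo, hi, sep = "||")
}

# Split canonical keys back into a two-column character matrix.
pair_unkey <- function(keys) {
  if (length(keys) == 0L) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("id1", "id2"))))
  }
  parts <- strsplit(keys, "||", fixed = TRUE)
  matrix(c(vapply(parts, `[[`, "", 1L), vapply(parts, `[[`, "", 2L)),
         ncol = 2L, dimnames = list(NULL, c("id1", "id2")))
}

# All unordered pairs of ids as a canonical key vector (sorted, stable).
all_pair_keys <- function(ids) {
  n <- length(ids)
  if (n < 2L) return(character(0))
  idx <- utils::combn(n, 2L)
  pair_key(ids[idx[1L, ]], ids[idx[2L, ]])
}

# Deterministic TSV writer: no quoting, no row names, "\n" endings.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

# Seeds drawn for sub-streams must fit in a 32-bit integer.
draw_subseeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n)
}
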