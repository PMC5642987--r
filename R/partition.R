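#' Canonicalize a membership vector
#'
#' Relabels community labels to `0..K-1` in order of first appearance. The
#' relabeling preserves the co-membership relation exactly, is idempotent,
#' and maps any two label-permuted versions of the same partition to the
#' same canonical vector, so canonical vectors can be compared directly.
#'
#' @param x a nonempty vector of community labels (any atomic type).
#' @return an integer vector of canonical labels `0..K-1`, with attribute
#'   `"K"` giving the number of communities.
#' @examples
#' canonicalize_membership(c("b", "b", "a"))  # 0 0 1
#' canonicalize_membership(c(5, 3, 5, 3))    # 0 1 0 1
#' @export
canonicalize_membership <- function(x) {
  if (length(x) == 0L) stop("empty partition")
  if (anyNA(x)) stop("membership contains NA")
  f <- match(x, unique(x)) - 1L
  attr(f, "K") <- max(f) + 1L
  f
}

#' Number of communities of a canonical membership vector
#' @param x canonical membership vector.
#' @param min_size count only communities with at least this many nodes.
#' @return integer count.
#' @export
n_communities <- function(x, min_size = 1L) {
  sum(tabulate(x + 1L) >= min_size)
}

#' Deduplicate a collection of partitions
#'
#' Partitions are compared after canonicalization, so any relabeling of the
#' same node grouping collapses to one representative. First-occurrence
#' order is preserved and multiplicities are recorded; this is the counting
#' convention behind "unique partitions" totals for a heuristic sweep.
#'
#' @param parts a list of membership vectors, or a matrix with one row per
#'   partition and one column per node.
#' @return list with `partitions` (matrix of canonical memberships, one row
#'   each; 0 rows for empty input), `multiplicity` (integer vector), and
#'   `first_index` (index of each unique partition's first occurrence).
#' @export
deduplicate_partitions <- function(parts) {
  if (is.matrix(parts)) parts <- lapply(seq_len(nrow(parts)),
                                        function(i) parts[i, ])
  if (length(parts) == 0L)
    return(list(partitions = matrix(integer(0), nrow = 0, ncol = 0),
                multiplicity = integer(0), first_index = integer(0)))
  lens <- lengths(parts)
  if (length(unique(lens)) != 1L) stop("partitions have mixed lengths")
  canon <- lapply(parts, canonicalize_membership)
  keys <- vapply(canon, paste, character(1), collapse = ",")
  first <- !duplicated(keys)
  uniq <- canon[first]
  mult <- as.integer(table(factor(keys, levels = keys[first])))
  mat <- do.call(rbind, lapply(uniq, as.integer))
  list(partitions = mat, multiplicity = mult,
       first_index = which(first))
}
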