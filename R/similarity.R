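#' Adjusted mutual information between two partitions
#'
#' Chance-corrected mutual information,
#' \deqn{AMI(X,Y) = \frac{MI(X,Y) - E(MI)}{\max(H(X), H(Y)) - E(MI)},}
#' where the expectation of MI is taken over the hypergeometric
#' (permutation) model with both marginals fixed, computed by the exact
#' closed-form sum of Vinh et al.; logs are natural. Equals 1 exactly when
#' the two partitions are identical up to label permutation, and is at most
#' 0 when the partitions agree no better than chance.
#'
#' Degenerate cases: if both partitions are single-community they are
#' identical, so AMI is 1; if exactly one is, AMI is 0 (MI and E(MI) both
#' vanish).
#'
#' @param x,y membership vectors of equal length (any label types).
#' @return a scalar in \eqn{(-\infty, 1]}.
#' @examples
#' ami(c(0, 0, 1, 1, 2), c(5, 5, 3, 3, 9))  # 1
#' @export
ami <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  x <- canonicalize_membership(x)
  y <- canonicalize_membership(y)
  n <- length(x)
  ct <- contingency_counts(x, y)
  hx <- entropy_nat(rowSums(ct), n)
  hy <- entropy_nat(colSums(ct), n)
  if (hx == 0 && hy == 0) return(1)
  mi <- mutual_information(ct, n)
  emi <- expected_mi(rowSums(ct), colSums(ct), n)
  denom <- max(hx, hy) - emi
  if (identical(unname(x), unname(y))) return(1)
  (mi - emi) / denom
}

contingency_counts <- function(x, y) {
  # x, y canonical 0-based labels
  kx <- max(x) + 1L; ky <- max(y) + 1L
  ct <- matrix(0, kx, ky)
  tab <- table(factor(x, levels = 0:(kx - 1L)),
               factor(y, levels = 0:(ky - 1L)))
  ct[] <- as.numeric(tab)
  ct
}

entropy_nat <- function(counts, n) {
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

mutual_information <- function(ct, n) {
  a <- rowSums(ct); b <- colSums(ct)
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- ct[i, j]
    if (nij > 0)
      mi <- mi + (nij / n) * log(n * nij / (a[i] * b[j]))
  }
  mi
}

#' Exact expected mutual information under the permutation model
#'
#' Closed-form hypergeometric sum over all feasible cell counts given the
#' two marginals; equals the average of MI over all node permutations of
#' one labeling.
#'
#' @param a,b integer marginal counts of the two partitions.
#' @param n total number of nodes (`sum(a) == sum(b) == n`).
#' @return scalar E(MI) in nats.
#' @export
expected_mi <- function(a, b, n) {
  emi <- 0
  lgn <- lgamma(n + 1)
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      for (nij in lo:hi) {
        lp <- lgamma(ai + 1) + lgamma(bj + 1) +
          lgamma(n - ai + 1) + lgamma(n - bj + 1) -
          lgn - lgamma(nij + 1) - lgamma(ai - nij + 1) -
          lgamma(bj - nij + 1) - lgamma(n - ai - bj + nij + 1)
        emi <- emi + (nij / n) * log(n * nij / (ai * bj)) * exp(lp)
      }
    }
  }
  emi
}

#' Pairwise AMI matrix over an admissible set
#'
#' Symmetric matrix of AMI values with unit diagonal; rows and columns
#' follow the supplied order (typically the envelope's domain order, so
#' that blocks of similar adjacent domains are visible).
#'
#' @param partitions list of membership vectors, or matrix with one row per
#'   partition; names/ids are taken from `ids`.
#' @param ids optional partition ids used as dimnames; default sequence.
#' @param order optional permutation (indices into `partitions`) giving the
#'   row/column order, e.g. the envelope domain order.
#' @return symmetric numeric matrix.
#' @export
pairwise_ami_matrix <- function(partitions, ids = NULL, order = NULL) {
  if (is.matrix(partitions))
    partitions <- lapply(seq_len(nrow(partitions)),
                         function(i) partitions[i, ])
  np <- length(partitions)
  if (np < 1L) stop("need at least one partition")
  if (is.null(ids)) ids <- seq_len(np)
  if (is.null(order)) order <- seq_len(np)
  partitions <- partitions[order]
  ids <- ids[order]
  m <- diag(1, np)
  if (np >= 2L) {
    for (i in seq_len(np - 1L)) for (j in seq.int(i + 1L, np)) {
      v <- ami(partitions[[i]], partitions[[j]])
      m[i, j] <- v; m[j, i] <- v
    }
  }
  dimnames(m) <- list(ids, ids)
  m
}

#' Border-weighted neighbor-averaged AMI over a 2-D domain map
#'
#' For each domain, the AMI with each adjacent domain's partition is
#' averaged with weights proportional to the shared border lengths. Low
#' values flag transitions in the landscape of optimal community
#' structure. Domains with no neighbors get `NA`.
#'
#' @param map a `champ_domains2d` with populated adjacency.
#' @param partitions named list (or matrix with rownames) mapping partition
#'   id to membership vector, covering every admissible id.
#' @return data frame with columns `partition_id`, `neighbor_ami`,
#'   `n_neighbors`.
#' @export
neighbor_averaged_ami <- function(map, partitions) {
  stopifnot(inherits(map, "champ_domains2d"))
  if (is.matrix(partitions)) {
    nm <- rownames(partitions)
    partitions <- lapply(seq_len(nrow(partitions)),
                         function(i) partitions[i, ])
    names(partitions) <- nm
  }
  adj <- map$adjacency
  ids <- vapply(map$domains, function(d) d$partition_id, numeric(1))
  res <- lapply(ids, function(id) {
    sel <- adj$id1 == id | adj$id2 == id
    if (!any(sel))
      return(data.frame(partition_id = id, neighbor_ami = NA_real_,
                        n_neighbors = 0L))
    nbr <- ifelse(adj$id1[sel] == id, adj$id2[sel], adj$id1[sel])
    w <- adj$border_length[sel]
    amis <- vapply(nbr, function(o)
      ami(partitions[[as.character(id)]], partitions[[as.character(o)]]),
      numeric(1))
    data.frame(partition_id = id,
               neighbor_ami = sum(w * amis) / sum(w),
               n_neighbors = length(nbr))
  })
  do.call(rbind, res)
}

#' Layer-averaged AMI against metadata labels
#'
#' Restricts a multilayer partition and a metadata labeling to each layer,
#' computes the per-layer AMI, and returns the unweighted mean across
#' layers — e.g. community labels versus party affiliations per Congress.
#'
#' @param part membership vector over state nodes.
#' @param labels metadata label vector over state nodes.
#' @param layer_of layer index of each state node.
#' @return scalar mean AMI across layers.
#' @export
layer_averaged_ami <- function(part, labels, layer_of) {
  if (length(part) != length(labels) || length(part) != length(layer_of))
    stop("length mismatch")
  if (is.numeric(layer_of) &&
      !all(seq_len(max(layer_of)) %in% layer_of))
    stop("empty layer")
  layers <- sort(unique(layer_of))
  vals <- vapply(layers, function(l) {
    ami(part[layer_of == l], labels[layer_of == l])
  }, numeric(1))
  mean(vals)
}
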