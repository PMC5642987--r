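#' Reduce partitions to modularity coefficients
#'
#' For a partition \eqn{\sigma} of a single-layer network, modularity with
#' the configuration null model is affine in the resolution parameter:
#' \deqn{Q_\sigma(\gamma) = \hat{A}_\sigma - \gamma \hat{P}_\sigma,}
#' where \eqn{\hat{A}_\sigma = \sum_{ij} A_{ij}\,\delta(c_i, c_j)} and
#' \eqn{\hat{P}_\sigma = \sum_{ij} (k_i k_j / 2m)\,\delta(c_i, c_j)} are
#' within-community sums over all ordered node pairs (including \eqn{i=j}).
#' The conventional multiplicative prefactor \eqn{1/(2m)} is deliberately
#' not applied, so the coefficients are exact sums of the input weights;
#' see [modularity_normalized()] for the normalized value.
#'
#' @param net a [champ_network()].
#' @param partitions a single membership vector, a list of them, or a
#'   matrix with one row per partition.
#' @param ids optional partition ids (default `seq_len`).
#' @return a data frame with one row per partition and columns
#'   `partition_id`, `a_hat`, `p_hat`, `c_hat` (always 0 for single-layer),
#'   `n_communities`, `n_communities_min5`.
#' @examples
#' tri <- champ_network(cbind(c(1, 1, 2), c(2, 3, 3)))
#' partition_coefficients(tri, list(c(0, 0, 0), c(0, 1, 2)))
#' @export
partition_coefficients <- function(net, partitions, ids = NULL) {
  stopifnot(inherits(net, "champ_network"))
  if (net$m <= 0) stop("m = 0")
  if (!is.list(partitions) && !is.matrix(partitions))
    partitions <- list(partitions)
  if (is.matrix(partitions))
    partitions <- lapply(seq_len(nrow(partitions)),
                         function(i) partitions[i, ])
  if (is.null(ids)) ids <- seq_along(partitions)
  ed <- net$edges
  out <- lapply(seq_along(partitions), function(i) {
    memb <- canonicalize_membership(partitions[[i]])
    if (length(memb) != net$n_nodes)
      stop("partition length does not match n_nodes")
    same <- memb[ed$src] == memb[ed$dst]
    a_hat <- 2 * sum(ed$weight[same])
    comm_strength <- tapply(net$strengths, memb, sum)
    p_hat <- sum(comm_strength^2) / (2 * net$m)
    data.frame(partition_id = ids[i], a_hat = a_hat, p_hat = p_hat,
               c_hat = 0,
               n_communities = n_communities(memb),
               n_communities_min5 = n_communities(memb, 5L))
  })
  do.call(rbind, out)
}

#' Multilayer modularity coefficients
#'
#' Reduces partitions of a multilayer network to the scalars
#' \eqn{(\hat{A}_\sigma, \hat{P}_\sigma, \hat{C}_\sigma)} so that
#' \eqn{Q_\sigma(\gamma, \omega) = \hat{A}_\sigma - \gamma \hat{P}_\sigma
#' + \omega \hat{C}_\sigma}: each partition is a plane in
#' \eqn{(\gamma, \omega, Q)}. The null-model sum uses the per-layer
#' configuration model \eqn{k_i k_j / 2m_l} (block-diagonal across layers);
#' layers with zero intralayer weight contribute nothing.
#'
#' @param mlnet a [champ_multilayer()].
#' @param partitions membership vector(s) over state nodes (vector, list,
#'   or matrix with one row per partition).
#' @param ids optional partition ids.
#' @return data frame as in [partition_coefficients()], with `c_hat` the
#'   within-community interlayer coupling sum (ordered pairs).
#' @export
multilayer_coefficients <- function(mlnet, partitions, ids = NULL) {
  stopifnot(inherits(mlnet, "champ_multilayer"))
  if (!is.list(partitions) && !is.matrix(partitions))
    partitions <- list(partitions)
  if (is.matrix(partitions))
    partitions <- lapply(seq_len(nrow(partitions)),
                         function(i) partitions[i, ])
  if (is.null(ids)) ids <- seq_along(partitions)
  out <- lapply(seq_along(partitions), function(i) {
    memb <- canonicalize_membership(partitions[[i]])
    if (length(memb) != mlnet$n_state_nodes)
      stop("partition refers to unknown state nodes")
    same_a <- memb[mlnet$intra$src] == memb[mlnet$intra$dst]
    a_hat <- 2 * sum(mlnet$intra$weight[same_a])
    same_c <- memb[mlnet$inter$src] == memb[mlnet$inter$dst]
    c_hat <- 2 * sum(mlnet$inter$weight[same_c])
    p_hat <- 0
    for (l in seq_len(mlnet$n_layers)) {
      if (mlnet$layer_2m[l] <= 0) next
      in_l <- mlnet$layer_of == l
      cs <- tapply(mlnet$layer_strengths[in_l], memb[in_l], sum)
      p_hat <- p_hat + sum(cs^2) / mlnet$layer_2m[l]
    }
    data.frame(partition_id = ids[i], a_hat = a_hat, p_hat = p_hat,
               c_hat = c_hat,
               n_communities = n_communities(memb),
               n_communities_min5 = n_communities(memb, 5L))
  })
  do.call(rbind, out)
}

#' Evaluate modularity at given parameter values
#'
#' Exact affine evaluation
#' \eqn{Q = \hat{A} - \gamma \hat{P} + \omega \hat{C}}; for single-layer
#' records `c_hat` is 0 so `omega` has no effect.
#'
#' @param rec one or more coefficient records (data frame with columns
#'   `a_hat`, `p_hat`, `c_hat`).
#' @param gamma resolution parameter value.
#' @param omega interlayer coupling value (default 0).
#' @return numeric vector of unnormalized modularity values, one per record.
#' @export
modularity_at <- function(rec, gamma, omega = 0) {
  rec$a_hat - gamma * rec$p_hat + omega * rec$c_hat
}

#' Normalized single-layer modularity
#'
#' Applies the conventional \eqn{1/(2m)} prefactor dropped by
#' [partition_coefficients()], giving the familiar modularity value at
#' resolution `gamma` (at `gamma = 1`, Newman-Girvan modularity).
#'
#' @inheritParams modularity_at
#' @param net the network the coefficients were computed on.
#' @return numeric vector of normalized modularity values.
#' @export
modularity_normalized <- function(rec, net, gamma = 1) {
  modularity_at(rec, gamma) / (2 * net$m)
}
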