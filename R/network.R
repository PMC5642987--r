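#' Construct a single-layer weighted undirected network
#'
#' A `champ_network` stores an undirected weighted graph as a deduplicated
#' edge table together with derived quantities used throughout: per-node
#' strengths \eqn{k_i} and the total edge weight \eqn{m} (so that
#' \eqn{2m = \sum_i k_i}).
#'
#' Each undirected edge is stored once; duplicate edges (either orientation)
#' are merged by summing their weights. A self-loop stored with weight
#' \eqn{w} follows the standard undirected convention: it contributes
#' \eqn{2w} to the node's strength and \eqn{2w} to the diagonal adjacency
#' entry, and \eqn{w} to \eqn{m}.
#'
#' @param edges a matrix or data frame with columns `src`, `dst` and
#'   optionally `weight` (default 1). `src`/`dst` are 1-based node indices
#'   in `1..n_nodes`.
#' @param n_nodes number of nodes; defaults to the largest index present.
#' @param labels optional character vector of external node labels
#'   (length `n_nodes`); defaults to `as.character(seq_len(n_nodes))`.
#' @return an object of class `champ_network` with components `n_nodes`,
#'   `edges` (data frame `src`, `dst`, `weight` with `src <= dst`),
#'   `strengths`, `m`, `labels`.
#' @examples
#' tri <- champ_network(cbind(c(1, 1, 2), c(2, 3, 3)))
#' tri$m          # 3
#' tri$strengths  # 2 2 2
#' @export
champ_network <- function(edges, n_nodes = NULL, labels = NULL) {
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0L) stop("no edges")
  if (ncol(edges) == 2L) edges$weight <- 1.0
  if (ncol(edges) != 3L) stop("edges must have columns src, dst[, weight]")
  names(edges) <- c("src", "dst", "weight")
  if (!is.numeric(edges$weight) || anyNA(edges$weight))
    stop("non-numeric edge weight")
  if (any(edges$weight < 0)) stop("edge weights must be >= 0")
  src <- as.integer(edges$src)
  dst <- as.integer(edges$dst)
  if (anyNA(src) || anyNA(dst) || any(src < 1L) || any(dst < 1L))
    stop("node indices must be positive integers")
  if (is.null(n_nodes)) n_nodes <- max(src, dst)
  n_nodes <- as.integer(n_nodes)
  if (max(src, dst) > n_nodes) stop("edge index exceeds n_nodes")
  # canonical orientation src <= dst, then merge duplicates by summing
  lo <- pmin(src, dst)
  hi <- pmax(src, dst)
  key <- paste(lo, hi)
  w <- as.numeric(tapply(edges$weight, key, sum))
  uk <- names(tapply(edges$weight, key, sum))
  parts <- do.call(rbind, strsplit(uk, " ", fixed = TRUE))
  ed <- data.frame(src = as.integer(parts[, 1]),
                   dst = as.integer(parts[, 2]),
                   weight = w)
  ed <- ed[order(ed$src, ed$dst), , drop = FALSE]
  rownames(ed) <- NULL
  strengths <- numeric(n_nodes)
  off <- ed$src != ed$dst
  s1 <- tapply(ed$weight[off], ed$src[off], sum)
  s2 <- tapply(ed$weight[off], ed$dst[off], sum)
  strengths[as.integer(names(s1))] <- strengths[as.integer(names(s1))] + s1
  strengths[as.integer(names(s2))] <- strengths[as.integer(names(s2))] + s2
  if (any(!off)) {
    sl <- tapply(ed$weight[!off], ed$src[!off], sum)
    strengths[as.integer(names(sl))] <- strengths[as.integer(names(sl))] + 2 * sl
  }
  m <- sum(ed$weight)
  if (is.null(labels)) labels <- as.character(seq_len(n_nodes))
  if (length(labels) != n_nodes) stop("labels length must equal n_nodes")
  structure(list(n_nodes = n_nodes, edges = ed, strengths = strengths,
                 m = m, labels = as.character(labels)),
            class = "champ_network")
}

#' @export
print.champ_network <- function(x, ...) {
  cat(sprintf("champ_network: %d nodes, %d edges, total weight m = %g\n",
              x$n_nodes, nrow(x$edges), x$m))
  invisible(x)
}

#' Construct a multilayer network (supra-adjacency form)
#'
#' State nodes are (node, layer) pairs indexed `1..n_state_nodes`.
#' Intralayer edges live within a layer and define the per-layer
#' configuration null model \eqn{P_{ij} = k_i k_j / 2m_l}; interlayer edges
#' join state nodes of different layers and carry the coupling structure
#' multiplied by the interlayer coupling parameter omega.
#'
#' @param intra_edges matrix/data frame `src, dst[, weight]` of intralayer
#'   edges (1-based state-node indices; both endpoints in the same layer).
#' @param inter_edges matrix/data frame `src, dst[, weight]` of interlayer
#'   edges (endpoints in different layers); may have zero rows.
#' @param layer_of integer vector, layer index of each state node.
#' @param labels optional external labels for the state nodes.
#' @return object of class `champ_multilayer` with components
#'   `n_state_nodes`, `intra`, `inter`, `layer_of`, `n_layers`,
#'   `layer_strengths` (intralayer strength of each state node),
#'   `layer_2m` (per-layer total of intralayer strengths), `labels`.
#' @export
champ_multilayer <- function(intra_edges, inter_edges, layer_of,
                             labels = NULL) {
  layer_of <- as.integer(layer_of)
  n <- length(layer_of)
  if (n == 0L) stop("no state nodes")
  norm_edges <- function(e, what) {
    e <- as.data.frame(e)
    if (nrow(e) == 0L)
      return(data.frame(src = integer(0), dst = integer(0),
                        weight = numeric(0)))
    if (ncol(e) == 2L) e$weight <- 1.0
    names(e) <- c("src", "dst", "weight")
    e$src <- as.integer(e$src); e$dst <- as.integer(e$dst)
    if (anyNA(e$src) || anyNA(e$dst) || max(e$src, e$dst) > n ||
        min(e$src, e$dst) < 1L)
      stop(sprintf("%s edge refers to unknown state node", what))
    if (any(e$weight < 0)) stop("edge weights must be >= 0")
    lo <- pmin(e$src, e$dst); hi <- pmax(e$src, e$dst)
    agg <- aggregate(e$weight, by = list(src = lo, dst = hi), FUN = sum)
    data.frame(src = agg$src, dst = agg$dst, weight = agg$x)
  }
  intra <- norm_edges(intra_edges, "intralayer")
  inter <- norm_edges(inter_edges, "interlayer")
  if (nrow(intra) && any(layer_of[intra$src] != layer_of[intra$dst]))
    stop("intralayer edge joins state nodes of different layers")
  if (nrow(inter) && any(layer_of[inter$src] == layer_of[inter$dst]))
    stop("interlayer edge joins state nodes of the same layer")
  ks <- numeric(n)
  off <- intra$src != intra$dst
  for (idx in which(off)) {
    ks[intra$src[idx]] <- ks[intra$src[idx]] + intra$weight[idx]
    ks[intra$dst[idx]] <- ks[intra$dst[idx]] + intra$weight[idx]
  }
  for (idx in which(!off))
    ks[intra$src[idx]] <- ks[intra$src[idx]] + 2 * intra$weight[idx]
  n_layers <- max(layer_of)
  layer_2m <- vapply(seq_len(n_layers),
                     function(l) sum(ks[layer_of == l]), numeric(1))
  if (is.null(labels)) labels <- as.character(seq_len(n))
  structure(list(n_state_nodes = n, intra = intra, inter = inter,
                 layer_of = layer_of, n_layers = n_layers,
                 layer_strengths = ks, layer_2m = layer_2m,
                 labels = as.character(labels)),
            class = "champ_multilayer")
}

#' @export
print.champ_multilayer <- function(x, ...) {
  cat(sprintf(paste0("champ_multilayer: %d state nodes in %d layers, ",
                     "%d intralayer + %d interlayer edges\n"),
              x$n_state_nodes, x$n_layers, nrow(x$intra), nrow(x$inter)))
  invisible(x)
}

#' Zero out self-loops in a network
#'
#' Convenience preprocessing used e.g. for similarity networks where a
#' node's perfect agreement with itself is uninformative.
#'
#' @param net a `champ_network`.
#' @return a `champ_network` without self-loops.
#' @export
drop_self_loops <- function(net) {
  stopifnot(inherits(net, "champ_network"))
  keep <- net$edges$src != net$edges$dst
  if (all(keep)) return(net)
  if (!any(keep)) stop("no edges")
  champ_network(net$edges[keep, , drop = FALSE], n_nodes = net$n_nodes,
                labels = net$labels)
}
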