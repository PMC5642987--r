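# Heuristic sweep driver, built-in greedy optimizer and planted-structure
# generators. The built-in heuristic is a minimal Louvain-style greedy on
# the dense generalized modularity matrix B = A - gamma*P + omega*C; it is
# meant for modest networks and dependency-free tests, not for performance
# parity with optimized Louvain implementations. Production heuristics plug
# in through the callable contract of `sweep_config()`.

# splittable per-run seed: mixes (master, grid index, run index) into a
# 31-bit seed so parallel or reordered execution reproduces the same runs
derive_seed <- function(master, grid_index, run_index) {
  s <- (as.double(master) %% 2147483647) * 48271 +
    as.double(grid_index) * 69621 + as.double(run_index) * 16807
  as.integer(s %% 2147483646) + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Configuration for a heuristic parameter sweep
#'
#' @param gamma_grid sorted numeric grid of resolution values (uniform grids
#'   inclusive of both endpoints are conventional; see [uniform_grid()]).
#' @param omega_grid optional sorted grid of interlayer coupling values; if
#'   supplied the sweep runs over the full `gamma x omega` grid.
#' @param runs_per_point number of heuristic runs at each grid point.
#' @param seed master seed; per-run seeds are derived from
#'   (seed, grid index, run index) by a splittable mixing scheme.
#' @param heuristic callable `(net, gamma, omega, seed) -> membership`;
#'   defaults to the built-in [greedy_louvain()].
#' @return a `sweep_config` list.
#' @export
sweep_config <- function(gamma_grid, omega_grid = NULL, runs_per_point = 1L,
                         seed = 1L, heuristic = greedy_louvain) {
  if (length(gamma_grid) == 0L || is.unsorted(gamma_grid))
    stop("gamma grid must be nonempty and sorted")
  if (!is.null(omega_grid) &&
      (length(omega_grid) == 0L || is.unsorted(omega_grid)))
    stop("omega grid must be nonempty and sorted")
  if (runs_per_point < 1L) stop("runs_per_point must be >= 1")
  structure(list(gamma_grid = gamma_grid, omega_grid = omega_grid,
                 runs_per_point = as.integer(runs_per_point),
                 seed = as.integer(seed), heuristic = heuristic),
            class = "sweep_config")
}

#' Uniformly spaced parameter grid
#' @param from,to range endpoints (both included).
#' @param n number of grid points.
#' @return numeric vector of length `n`.
#' @export
uniform_grid <- function(from, to, n) seq(from, to, length.out = n)

#' Run a heuristic sweep and collect the deduplicated ensemble
#'
#' For every grid point and run, the node order is randomly permuted under
#' the run's derived seed (so the heuristic can find different partitions
#' at identical parameters), the heuristic is invoked, and its membership
#' is mapped back to the original node order and canonicalized. The sweep
#' output is deduplicated across all runs and reduced to coefficient
#' records. Fully reproducible given the configuration.
#'
#' @param net a `champ_network` or `champ_multilayer`.
#' @param cfg a [sweep_config()].
#' @return list of class `champ_ensemble`: `partitions` (matrix, one row
#'   per unique partition), `multiplicity`, `coefficients` (data frame with
#'   `partition_id` = row index), `provenance` (data frame with the grid
#'   point and run of each unique partition's first occurrence).
#' @export
run_sweep <- function(net, cfg) {
  stopifnot(inherits(cfg, "sweep_config"))
  multilayer <- inherits(net, "champ_multilayer")
  n <- if (multilayer) net$n_state_nodes else net$n_nodes
  grid <- if (is.null(cfg$omega_grid)) {
    data.frame(gamma = cfg$gamma_grid, omega = 0)
  } else {
    expand.grid(gamma = cfg$gamma_grid, omega = cfg$omega_grid)
  }
  raw <- list(); prov <- list()
  for (g in seq_len(nrow(grid))) {
    for (r in seq_len(cfg$runs_per_point)) {
      seed <- derive_seed(cfg$seed, g, r)
      perm <- with_seed(seed, sample.int(n))
      pnet <- permute_nodes(net, perm)
      memb_perm <- cfg$heuristic(pnet, grid$gamma[g], grid$omega[g], seed)
      if (length(memb_perm) != n)
        stop(sprintf(
          "heuristic returned membership of length %d (expected %d) at gamma=%g, omega=%g",
          length(memb_perm), n, grid$gamma[g], grid$omega[g]))
      memb <- memb_perm[perm]       # back to original node order
      raw[[length(raw) + 1L]] <- canonicalize_membership(memb)
      prov[[length(prov) + 1L]] <-
        data.frame(gamma = grid$gamma[g], omega = grid$omega[g], run = r)
    }
  }
  dd <- deduplicate_partitions(raw)
  prov <- do.call(rbind, prov)[dd$first_index, , drop = FALSE]
  rownames(prov) <- NULL
  coeffs <- if (multilayer) {
    multilayer_coefficients(net, dd$partitions)
  } else {
    partition_coefficients(net, dd$partitions)
  }
  structure(list(partitions = dd$partitions,
                 multiplicity = dd$multiplicity,
                 coefficients = coeffs, provenance = prov),
            class = "champ_ensemble")
}

#' @export
print.champ_ensemble <- function(x, ...) {
  cat(sprintf("champ_ensemble: %d unique partitions (from %d runs)\n",
              nrow(x$partitions), sum(x$multiplicity)))
  invisible(x)
}

# permute node identities: node i becomes perm[i]
permute_nodes <- function(net, perm) {
  if (inherits(net, "champ_multilayer")) {
    remap <- function(e) data.frame(src = perm[e$src], dst = perm[e$dst],
                                    weight = e$weight)
    lay <- integer(length(perm)); lay[perm] <- net$layer_of
    lab <- character(length(perm)); lab[perm] <- net$labels
    champ_multilayer(remap(net$intra), remap(net$inter), lay, labels = lab)
  } else {
    e <- net$edges
    lab <- character(net$n_nodes); lab[perm] <- net$labels
    champ_network(data.frame(src = perm[e$src], dst = perm[e$dst],
                             weight = e$weight),
                  n_nodes = net$n_nodes, labels = lab)
  }
}

# dense generalized modularity matrix B = A - gamma*P + omega*C
modularity_matrix <- function(net, gamma, omega = 0) {
  if (inherits(net, "champ_multilayer")) {
    n <- net$n_state_nodes
    A <- matrix(0, n, n)
    for (i in seq_len(nrow(net$intra))) {
      s <- net$intra$src[i]; d <- net$intra$dst[i]; w <- net$intra$weight[i]
      if (s == d) A[s, s] <- A[s, s] + 2 * w
      else { A[s, d] <- A[s, d] + w; A[d, s] <- A[d, s] + w }
    }
    P <- matrix(0, n, n)
    for (l in seq_len(net$n_layers)) {
      if (net$layer_2m[l] <= 0) next
      idx <- which(net$layer_of == l)
      k <- net$layer_strengths[idx]
      P[idx, idx] <- outer(k, k) / net$layer_2m[l]
    }
    C <- matrix(0, n, n)
    for (i in seq_len(nrow(net$inter))) {
      s <- net$inter$src[i]; d <- net$inter$dst[i]; w <- net$inter$weight[i]
      C[s, d] <- C[s, d] + w; C[d, s] <- C[d, s] + w
    }
    A - gamma * P + omega * C
  } else {
    n <- net$n_nodes
    A <- matrix(0, n, n)
    e <- net$edges
    for (i in seq_len(nrow(e))) {
      s <- e$src[i]; d <- e$dst[i]; w <- e$weight[i]
      if (s == d) A[s, s] <- A[s, s] + 2 * w
      else { A[s, d] <- A[s, d] + w; A[d, s] <- A[d, s] + w }
    }
    k <- net$strengths
    A - gamma * outer(k, k) / (2 * net$m)
  }
}

#' Built-in Louvain-style greedy modularity optimizer
#'
#' Maximizes the ordered-pair objective \eqn{\sum_{ij} B_{ij}
#' \delta(c_i, c_j)} with \eqn{B = A - \gamma P + \omega C} by repeated
#' phases of single-node local moves (in seeded random order, accepting
#' only strictly improving moves) followed by community aggregation, until
#' a phase makes no move. Deterministic given `seed`; carries no optimality
#' guarantee. Works on both single-layer and multilayer networks; uses a
#' dense matrix internally, so it is intended for modest network sizes.
#'
#' @param net a `champ_network` or `champ_multilayer`.
#' @param gamma resolution parameter.
#' @param omega interlayer coupling (ignored for single-layer nets).
#' @param seed integer seed for the node-visit order.
#' @return integer membership vector (raw labels, not canonicalized).
#' @export
greedy_louvain <- function(net, gamma, omega = 0, seed = 1L) {
  B <- modularity_matrix(net, gamma, omega)
  with_seed(seed, louvain_dense(B))
}

louvain_dense <- function(B, tol = 1e-10) {
  n0 <- nrow(B)
  memb_global <- seq_len(n0)      # node -> current super-node
  repeat {
    n <- nrow(B)
    memb <- seq_len(n)
    moved_any <- FALSE
    repeat {
      moved <- FALSE
      for (i in sample.int(n)) {
        # gain of moving i into community c: 2 * sum_{j in c, j != i} B[ij]
        row <- B[i, ]
        row[i] <- 0
        gains <- tapply(row, memb, sum)
        cur <- as.character(memb[i])
        rel <- 2 * (gains - gains[[cur]])
        best <- names(which.max(rel))
        if (rel[[best]] > tol && best != cur) {
          memb[i] <- as.integer(best)
          moved <- TRUE; moved_any <- TRUE
        }
      }
      if (!moved) break
    }
    if (!moved_any) break
    # aggregate communities into super-nodes
    labs <- match(memb, unique(memb))
    memb_global <- labs[memb_global]
    S <- length(unique(labs))
    Bn <- matrix(0, S, S)
    for (a in seq_len(S)) {
      ia <- which(labs == a)
      for (b in seq_len(S)) {
        Bn[a, b] <- sum(B[ia, labs == b, drop = FALSE])
      }
    }
    if (S == nrow(B)) break
    B <- Bn
  }
  memb_global
}

#' Planted-partition random graph
#'
#' Undirected simple graph on `n` nodes split as evenly as possible into
#' `n_blocks` blocks; each within-block pair is an edge independently with
#' probability `p_in`, each between-block pair with `p_out`.
#'
#' @param n number of nodes.
#' @param n_blocks number of blocks (>= 1).
#' @param p_in,p_out within/between-block edge probabilities
#'   (`0 <= p_out <= p_in <= 1`).
#' @param seed integer seed.
#' @return list with `network` (a `champ_network`; isolated nodes allowed)
#'   and `membership` (ground-truth canonical block labels).
#' @export
planted_partition_graph <- function(n, n_blocks, p_in, p_out, seed = 1L) {
  if (n_blocks < 1L || n < n_blocks) stop("invalid block configuration")
  if (p_out > p_in || p_in > 1 || p_out < 0)
    stop("need 0 <= p_out <= p_in <= 1")
  blocks <- rep(seq_len(n_blocks), length.out = n)
  blocks <- sort(blocks)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pr <- ifelse(blocks[pairs[, 1]] == blocks[pairs[, 2]], p_in, p_out)
  keep <- with_seed(seed, stats::runif(nrow(pairs)) < pr)
  if (!any(keep)) stop("generated graph has no edges; increase p_in")
  net <- champ_network(data.frame(src = pairs[keep, 1],
                                  dst = pairs[keep, 2], weight = 1),
                       n_nodes = n)
  list(network = net, membership = canonicalize_membership(blocks))
}

#' Temporally coupled multilayer planted structure
#'
#' Emulates a temporal multilayer network: every layer is a planted
#' partition graph over the same `n` nodes, block labels persist from one
#' layer to the next with probability `persistence` (otherwise the node is
#' reassigned to a uniformly random block), and each node is coupled to its
#' own appearance in the adjacent layer by an identity interlayer edge of
#' weight `coupling`. State node `(i, l)` has index `(l-1)*n + i`.
#'
#' @param n nodes per layer.
#' @param n_blocks number of blocks.
#' @param n_layers number of layers (>= 2).
#' @param p_in,p_out within/between-block edge probabilities.
#' @param persistence probability a node keeps its block label in the next
#'   layer (1 = communities span all layers).
#' @param coupling interlayer edge weight (0 = uncoupled layers).
#' @param seed integer seed.
#' @return list with `network` (a `champ_multilayer`) and `membership`
#'   (ground-truth labels over state nodes; a block keeps one global label
#'   across layers, so persistent communities span layers).
#' @export
planted_multilayer <- function(n, n_blocks, n_layers, p_in, p_out,
                               persistence = 1, coupling = 1, seed = 1L) {
  if (n_layers < 2L) stop("n_layers must be >= 2")
  if (p_out > p_in || p_in > 1 || p_out < 0)
    stop("need 0 <= p_out <= p_in <= 1")
  with_seed(seed, {
    blocks <- matrix(0L, n_layers, n)
    blocks[1, ] <- sort(rep(seq_len(n_blocks), length.out = n))
    for (l in seq_len(n_layers - 1L)) {
      keep <- stats::runif(n) < persistence
      blocks[l + 1L, ] <- ifelse(keep, blocks[l, ],
                                 sample.int(n_blocks, n, replace = TRUE))
    }
    intra <- list()
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    for (l in seq_len(n_layers)) {
      bl <- blocks[l, ]
      pr <- ifelse(bl[pairs[, 1]] == bl[pairs[, 2]], p_in, p_out)
      keep <- stats::runif(nrow(pairs)) < pr
      if (any(keep))
        intra[[l]] <- data.frame(src = (l - 1L) * n + pairs[keep, 1],
                                 dst = (l - 1L) * n + pairs[keep, 2],
                                 weight = 1)
    }
    intra <- do.call(rbind, intra)
    if (is.null(intra)) stop("generated multilayer graph has no edges")
    inter <- if (coupling > 0) {
      do.call(rbind, lapply(seq_len(n_layers - 1L), function(l)
        data.frame(src = (l - 1L) * n + seq_len(n),
                   dst = l * n + seq_len(n), weight = coupling)))
    } else {
      data.frame(src = integer(0), dst = integer(0), weight = numeric(0))
    }
    layer_of <- rep(seq_len(n_layers), each = n)
    labels <- paste0(rep(seq_len(n), n_layers), "@",
                     rep(seq_len(n_layers), each = n))
    mlnet <- champ_multilayer(intra, inter, layer_of, labels = labels)
    list(network = mlnet,
         membership = canonicalize_membership(as.integer(t(blocks))))
  })
}
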