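# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: coefficients by brute-force double loops over a
# dense adjacency matrix, envelopes by dense-grid argmax, E(MI) by
# exhaustive permutation averaging.

# dense symmetric adjacency from a champ_network (self-loop diagonal = 2w)
dense_adjacency <- function(net) {
  A <- matrix(0, net$n_nodes, net$n_nodes)
  for (i in seq_len(nrow(net$edges))) {
    s <- net$edges$src[i]; d <- net$edges$dst[i]; w <- net$edges$weight[i]
    if (s == d) A[s, s] <- A[s, s] + 2 * w
    else { A[s, d] <- A[s, d] + w; A[d, s] <- A[d, s] + w }
  }
  A
}

# brute-force (a_hat, p_hat) by explicit double loop over ordered pairs
oracle_coefficients <- function(net, memb) {
  A <- dense_adjacency(net)
  k <- rowSums(A)
  m2 <- sum(A)
  a_hat <- 0; p_hat <- 0
  n <- net$n_nodes
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (memb[i] == memb[j]) {
      a_hat <- a_hat + A[i, j]
      p_hat <- p_hat + k[i] * k[j] / m2
    }
  }
  c(a_hat = a_hat, p_hat = p_hat)
}

# brute-force multilayer (a, p, c) by double loops
oracle_ml_coefficients <- function(ml, memb) {
  n <- ml$n_state_nodes
  A <- matrix(0, n, n); C <- matrix(0, n, n)
  for (i in seq_len(nrow(ml$intra))) {
    s <- ml$intra$src[i]; d <- ml$intra$dst[i]; w <- ml$intra$weight[i]
    if (s == d) A[s, s] <- A[s, s] + 2 * w
    else { A[s, d] <- A[s, d] + w; A[d, s] <- A[d, s] + w }
  }
  for (i in seq_len(nrow(ml$inter))) {
    s <- ml$inter$src[i]; d <- ml$inter$dst[i]; w <- ml$inter$weight[i]
    C[s, d] <- C[s, d] + w; C[d, s] <- C[d, s] + w
  }
  k <- rowSums(A)
  a_hat <- 0; p_hat <- 0; c_hat <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (memb[i] == memb[j]) {
      a_hat <- a_hat + A[i, j]
      c_hat <- c_hat + C[i, j]
      if (ml$layer_of[i] == ml$layer_of[j]) {
        l <- ml$layer_of[i]
        if (ml$layer_2m[l] > 0)
          p_hat <- p_hat + k[i] * k[j] / ml$layer_2m[l]
      }
    }
  }
  c(a_hat = a_hat, p_hat = p_hat, c_hat = c_hat)
}

# dense-grid envelope oracle: max and argmax id at each gamma
oracle_envelope_1d <- function(records, gammas) {
  Q <- outer(records$a_hat, rep(1, length(gammas))) -
    outer(records$p_hat, gammas)
  mx <- apply(Q, 2, max)
  arg <- records$partition_id[apply(Q, 2, which.max)]
  list(max = mx, argmax = arg, Q = Q)
}

# 2-D grid argmax oracle over plane records
oracle_argmax_2d <- function(records, gamma, omega) {
  pts <- expand.grid(gamma = gamma, omega = omega)
  Q <- outer(rep(1, nrow(pts)), records$a_hat) -
    pts$gamma %o% records$p_hat + pts$omega %o% records$c_hat
  top <- apply(Q, 1, function(r) {
    o <- order(r, decreasing = TRUE)
    c(id = records$partition_id[o[1]], gap = r[o[1]] - r[o[2]])
  })
  data.frame(gamma = pts$gamma, omega = pts$omega,
             id = top["id", ], gap = top["gap", ])
}

# all permutations of 1..n (n <= 7)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

oracle_mi <- function(x, y) {
  n <- length(x)
  ct <- table(x, y)
  a <- rowSums(ct); b <- colSums(ct)
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- ct[i, j]
    if (nij > 0) mi <- mi + (nij / n) * log(n * nij / (a[i] * b[j]))
  }
  mi
}

# exact E(MI) by averaging MI over every node permutation of y (n <= 7)
oracle_emi_perm <- function(x, y) {
  P <- all_perms(length(x))
  mean(apply(P, 1, function(p) oracle_mi(x, y[p])))
}

# reference AMI via the exhaustive-permutation expectation
oracle_ami <- function(x, y) {
  n <- length(x)
  hx <- {p <- table(x) / n; -sum(p * log(p))}
  hy <- {p <- table(y) / n; -sum(p * log(p))}
  mi <- oracle_mi(x, y)
  emi <- oracle_emi_perm(x, y)
  unname((mi - emi) / (max(hx, hy) - emi))
}

# all set partitions of 1..n (Bell(6) = 203), as list of membership vectors
all_set_partitions <- function(n) {
  parts <- list(c(0L))
  for (i in seq_len(n - 1L)) {
    parts <- unlist(lapply(parts, function(p) {
      k <- max(p) + 1L
      lapply(0:k, function(lab) c(p, lab))
    }), recursive = FALSE)
  }
  parts
}

random_membership <- function(n, kmax = 5L) {
  sample.int(kmax, n, replace = TRUE)
}

# random positive coefficient records for envelope property tests
random_records <- function(n_lines, seed = NULL) {
  data.frame(partition_id = seq_len(n_lines),
             a_hat = runif(n_lines, 0, 100),
             p_hat = runif(n_lines, 0.1, 50))
}

# reference AMI values from scikit-learn (average_method = "max"),
# computed through the system python; pairs is a list of list(x, y)
sklearn_ami <- function(pairs) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".txt")
  jsonlite::write_json(lapply(pairs, function(p)
    list(x = as.integer(p$x), y = as.integer(p$y))), infile)
  script <- paste(
    "import json, sys",
    "from sklearn.metrics import adjusted_mutual_info_score as ami",
    sprintf("pairs = json.load(open(%s))", deparse(infile)),
    "vals = [ami(p['x'], p['y'], average_method='max') for p in pairs]",
    sprintf("open(%s, 'w').write('\\n'.join(repr(v) for v in vals) + '\\n')",
            deparse(outfile)),
    sep = "\n")
  status <- system2("python", c("-c", shQuote(script)))
  if (status != 0) return(NULL)
  as.numeric(readLines(outfile))
}
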