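# Small hand-built fixtures shared across tests.

fixture_k3 <- function() champ_network(cbind(c(1, 1, 2), c(2, 3, 3)))

fixture_star4 <- function() champ_network(cbind(1, c(2, 3, 4)))

fixture_two_triangles <- function() {
  champ_network(rbind(c(1, 2), c(1, 3), c(2, 3),
                      c(4, 5), c(4, 6), c(5, 6)))
}

# 2 layers x 2 nodes: one intralayer edge per layer, identity interlayer
# coupling; state nodes (1,2) = layer 1, (3,4) = layer 2
fixture_ml22 <- function() {
  champ_multilayer(intra_edges = rbind(c(1, 2, 1), c(3, 4, 1)),
                   inter_edges = rbind(c(1, 3, 1), c(2, 4, 1)),
                   layer_of = c(1, 1, 2, 2))
}

# K3 coefficient records: all-in-one, a 2+1 split, all singletons
fixture_k3_records <- function() {
  data.frame(partition_id = 1:3,
             a_hat = c(6, 2, 0), p_hat = c(6, 10 / 3, 2))
}

# three planes with a triple point at (0, 2) inside the box [0,2] x [0,2]
fixture_planes3 <- function() {
  data.frame(partition_id = 1:3, a_hat = c(6, 4, 0),
             p_hat = c(6, 3, 2), c_hat = c(0, 1, 3))
}

random_graph <- function(n, p = 0.2, weighted = FALSE) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample.int(length(keep), 2)] <- TRUE
  w <- if (weighted) runif(sum(keep), 0.5, 3) else rep(1, sum(keep))
  champ_network(data.frame(src = pairs[keep, 1], dst = pairs[keep, 2],
                           weight = w), n_nodes = n)
}
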