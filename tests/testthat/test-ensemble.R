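test_that("a deterministic stub heuristic yields one unique partition", {
  net <- fixture_two_triangles()
  # deterministic stub: connected components of whatever network it is
  # handed (equivariant under the sweep's node permutation)
  stub <- function(net, gamma, omega, seed) {
    g <- igraph::graph_from_data_frame(
      net$edges, directed = FALSE,
      vertices = data.frame(name = seq_len(net$n_nodes)))
    igraph::components(g)$membership
  }
  cfg <- sweep_config(uniform_grid(0.5, 1.5, 5), runs_per_point = 4,
                      seed = 7, heuristic = stub)
  ens <- run_sweep(net, cfg)
  expect_equal(nrow(ens$partitions), 1L)
  expect_equal(sum(ens$multiplicity), 20L)
  expect_equal(as.integer(ens$partitions[1, ]), c(0, 0, 0, 1, 1, 1))
})

test_that("unique-partition count is bounded by the number of runs", {
  set.seed(87)
  sim <- planted_partition_graph(30, 3, 0.8, 0.1, seed = 2)
  cfg <- sweep_config(uniform_grid(0.5, 1.5, 5), runs_per_point = 10,
                      seed = 11)
  ens <- run_sweep(sim$network, cfg)
  expect_lte(nrow(ens$partitions), 50L)
  expect_equal(sum(ens$multiplicity), 50L)
  expect_equal(nrow(ens$coefficients), nrow(ens$partitions))
})

test_that("sweeps are exactly reproducible from the configuration", {
  sim <- planted_partition_graph(25, 2, 0.8, 0.15, seed = 5)
  cfg <- sweep_config(uniform_grid(0.8, 1.2, 3), runs_per_point = 3,
                      seed = 19)
  e1 <- run_sweep(sim$network, cfg)
  e2 <- run_sweep(sim$network, cfg)
  expect_identical(e1$partitions, e2$partitions)
  expect_identical(e1$coefficients, e2$coefficients)
  # the splittable scheme gives distinct per-run seeds below 2^31
  seeds <- outer(1:9, 1:10,
                 function(g, r) champr:::derive_seed(19, g, r))
  expect_equal(anyDuplicated(c(seeds)), 0L)
  expect_true(all(seeds > 0 & seeds < 2^31))
})

test_that("a wrong-length heuristic result names the grid point", {
  net <- fixture_k3()
  bad <- function(net, gamma, omega, seed) c(1L, 2L)
  cfg <- sweep_config(c(0.75), runs_per_point = 1, seed = 1,
                      heuristic = bad)
  expect_error(run_sweep(net, cfg), "gamma=0.75")
})

test_that("greedy heuristic finds the exhaustive-search optimum on K3+K3", {
  net <- fixture_two_triangles()
  memb <- canonicalize_membership(greedy_louvain(net, gamma = 1, seed = 3))
  # exhaustive search over all 203 partitions of 6 nodes
  parts <- all_set_partitions(6)
  q <- vapply(parts, function(p) {
    cf <- partition_coefficients(net, p)
    cf$a_hat - cf$p_hat
  }, numeric(1))
  best <- parts[[which.max(q)]]
  expect_equal(as.integer(memb),
               as.integer(canonicalize_membership(best)))
  expect_equal(as.integer(memb), c(0L, 0L, 0L, 1L, 1L, 1L))
})

test_that("at gamma = 0 the greedy merges each connected component", {
  set.seed(91)
  net <- random_graph(20, 0.3)
  memb <- greedy_louvain(net, gamma = 0, seed = 5)
  cf <- partition_coefficients(net, memb)
  expect_equal(cf$a_hat, 2 * net$m)   # connected net: one community
})

test_that("greedy heuristic is deterministic given the seed", {
  sim <- planted_partition_graph(40, 4, 0.8, 0.1, seed = 9)
  m1 <- greedy_louvain(sim$network, 1, seed = 123)
  m2 <- greedy_louvain(sim$network, 1, seed = 123)
  expect_identical(m1, m2)
})

test_that("multilayer greedy respects the coupling parameter", {
  sim <- planted_multilayer(n = 8, n_blocks = 2, n_layers = 3,
                            p_in = 1, p_out = 0, persistence = 1,
                            coupling = 1, seed = 3)
  memb <- canonicalize_membership(
    greedy_louvain(sim$network, gamma = 1, omega = 1, seed = 1))
  expect_equal(as.integer(memb), as.integer(sim$membership))
})

test_that("planted graphs realize their block structure", {
  # p_in = 1, p_out = 0: components are exactly the blocks
  sim <- planted_partition_graph(12, 3, 1, 0, seed = 4)
  g <- igraph::graph_from_data_frame(sim$network$edges, directed = FALSE,
                                     vertices = data.frame(name = 1:12))
  comp <- igraph::components(g)$membership
  expect_equal(canonicalize_membership(comp), sim$membership,
               ignore_attr = TRUE)
  # p_in = p_out = p: mean edge count approximates C(n,2) p
  n <- 20; p <- 0.3
  counts <- vapply(1:100, function(s)
    nrow(planted_partition_graph(n, 2, p, p, seed = s)$network$edges),
    numeric(1))
  npairs <- choose(n, 2)
  se <- sqrt(npairs * p * (1 - p)) / sqrt(100)
  expect_lt(abs(mean(counts) - npairs * p), 3 * se)
  expect_error(planted_partition_graph(10, 0, 0.5, 0.1), "invalid block")
  expect_error(planted_partition_graph(10, 2, 0.5, 0.9), "p_out <= p_in")
})

test_that("multilayer planted structure follows persistence and coupling", {
  # persistence 1: communities span layers
  sim <- planted_multilayer(n = 6, n_blocks = 2, n_layers = 4,
                            p_in = 1, p_out = 0, persistence = 1,
                            coupling = 1, seed = 6)
  expect_equal(n_communities(sim$membership), 2L)
  expect_equal(nrow(sim$network$inter), 6 * 3)
  # persistence 0, coupling 0: independent layers, no interlayer edges
  sim0 <- planted_multilayer(n = 6, n_blocks = 2, n_layers = 3,
                             p_in = 1, p_out = 0, persistence = 0,
                             coupling = 0, seed = 6)
  expect_equal(nrow(sim0$network$inter), 0L)
  # 2 layers x 2 nodes, one block, p_in = 1 reproduces the hand fixture
  sim2 <- planted_multilayer(n = 2, n_blocks = 1, n_layers = 2,
                             p_in = 1, p_out = 0, persistence = 1,
                             coupling = 1, seed = 1)
  ref <- fixture_ml22()
  expect_equal(sim2$network$intra, ref$intra)
  expect_equal(sim2$network$inter, ref$inter)
  expect_equal(sim2$network$layer_of, ref$layer_of)
  cf <- multilayer_coefficients(sim2$network, rep(0, 4))
  expect_equal(unlist(cf[, c("a_hat", "p_hat", "c_hat")]), c(4, 4, 4),
               ignore_attr = TRUE)
})

test_that("the planted partition is recovered into the admissible set", {
  sim <- planted_partition_graph(80, 4, 0.9, 0.05, seed = 42)
  cfg <- sweep_config(uniform_grid(0.5, 1.5, 10), runs_per_point = 5,
                      seed = 42)
  ens <- run_sweep(sim$network, cfg)
  truth_key <- paste(sim$membership, collapse = ",")
  keys <- apply(ens$partitions, 1, paste, collapse = ",")
  expect_true(truth_key %in% keys)
  env <- champ_prune_1d(ens$coefficients, 0, 6)
  truth_id <- which(keys == truth_key)
  dom <- env$domains[env$domains$partition_id == truth_id, ]
  expect_equal(nrow(dom), 1L)
  expect_lte(dom$gamma_lo, 1)
  expect_gt(dom$gamma_hi, 1)
})
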