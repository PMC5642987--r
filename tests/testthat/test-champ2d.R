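test_that("three-plane worked fixture: domains, triple point, areas", {
  m <- champ_prune_2d(fixture_planes3(), c(0, 2), c(0, 2))
  ids <- vapply(m$domains, function(d) d$partition_id, numeric(1))
  expect_setequal(ids, 1:3)
  areas <- vapply(m$domains, function(d) d$area, numeric(1))[order(ids)]
  # plane 1 below omega = 2 - 3*gamma; plane 3 above omega = (4 - gamma)/2
  expect_equal(areas[1], 2 / 3, tolerance = 1e-9)
  expect_equal(areas[3], 1, tolerance = 1e-9)
  expect_equal(sum(areas), 4, tolerance = 1e-9)
  # the triple point (0, 2) is a vertex of all three domains
  for (d in m$domains) {
    dists <- sqrt((d$vertices[, 1] - 0)^2 + (d$vertices[, 2] - 2)^2)
    expect_lt(min(dists), 1e-7)
  }
})

test_that("three-plane fixture: border lengths and non-adjacency", {
  m <- champ_prune_2d(fixture_planes3(), c(0, 2), c(0, 2))
  adj <- m$adjacency
  get_len <- function(i, j) {
    sel <- (adj$id1 == i & adj$id2 == j) | (adj$id1 == j & adj$id2 == i)
    if (!any(sel)) return(NA_real_)
    adj$border_length[sel]
  }
  expect_equal(get_len(1, 2), 2 * sqrt(10) / 3, tolerance = 1e-7)
  expect_equal(get_len(2, 3), sqrt(5), tolerance = 1e-7)
  # planes 1 and 3 meet only at the point (0, 2): not adjacent
  expect_true(is.na(get_len(1, 3)))
})

test_that("a single plane owns the whole box; dominated planes are pruned", {
  one <- champ_prune_2d(data.frame(partition_id = 1, a_hat = 6,
                                   p_hat = 6, c_hat = 0),
                        c(0, 2), c(0, 2), find_out_of_box = FALSE)
  expect_length(one$domains, 1L)
  expect_equal(one$domains[[1]]$area, 4, tolerance = 1e-12)

  two <- champ_prune_2d(data.frame(partition_id = 1:2, a_hat = c(6, 5),
                                   p_hat = c(6, 6), c_hat = c(0, 0)),
                        c(0, 2), c(0, 2), find_out_of_box = FALSE)
  expect_equal(vapply(two$domains, function(d) d$partition_id, numeric(1)),
               1)
  expect_equal(two$pruned_count, 1L)
})

test_that("point assignment matches direct plane evaluation on the fixture", {
  m <- champ_prune_2d(fixture_planes3(), c(0, 2), c(0, 2))
  expect_equal(assign_point(m, 0.5, 0), 1L)   # 3 beats 2.5 and -1
  expect_equal(assign_point(m, 0.5, 1), 2L)   # 3.5 beats 3 and 2
  expect_equal(assign_point(m, 0.5, 2), 3L)   # 5 beats 4.5 and 3
  expect_error(assign_point(m, 3, 0), "outside box")
})

test_that("domain maps agree with the grid argmax oracle", {
  set.seed(43)
  for (rep in 1:8) {
    np <- sample(10:60, 1)
    recs <- data.frame(partition_id = seq_len(np),
                       a_hat = runif(np, 0, 50),
                       p_hat = runif(np, 0.1, 20),
                       c_hat = runif(np, 0, 10))
    m <- champ_prune_2d(recs, c(0, 3), c(0, 3), find_out_of_box = FALSE)
    gs <- seq(0.01, 2.99, length.out = 60)
    ws <- seq(0.01, 2.99, length.out = 60)
    ora <- oracle_argmax_2d(recs, gs, ws)
    away <- ora$gap > 1e-5
    got <- assign_point(m, ora$gamma[away], ora$omega[away])
    expect_equal(got, as.integer(ora$id[away]))
    areas <- vapply(m$domains, function(d) d$area, numeric(1))
    expect_equal(sum(areas), 9, tolerance = 1e-9)
  }
})

test_that("domain polygons are convex and inside the box", {
  set.seed(47)
  recs <- data.frame(partition_id = 1:40, a_hat = runif(40, 0, 50),
                     p_hat = runif(40, 0.1, 20), c_hat = runif(40, 0, 10))
  m <- champ_prune_2d(recs, c(0.3, 2), c(0, 2), find_out_of_box = FALSE)
  for (d in m$domains) {
    v <- d$vertices
    nv <- nrow(v)
    expect_gte(nv, 3L)
    expect_true(all(v[, 1] >= 0.3 - 1e-9 & v[, 1] <= 2 + 1e-9))
    expect_true(all(v[, 2] >= 0 - 1e-9 & v[, 2] <= 2 + 1e-9))
    cross <- vapply(seq_len(nv), function(i) {
      j <- if (i == nv) 1L else i + 1L
      k <- if (j == nv) 1L else j + 1L
      (v[j, 1] - v[i, 1]) * (v[k, 2] - v[j, 2]) -
        (v[j, 2] - v[i, 2]) * (v[k, 1] - v[j, 1])
    }, numeric(1))
    expect_true(all(cross >= -1e-9))   # CCW convex
  }
})

test_that("with c_hat = 0 and a thin omega band, 2-D domains project to 1-D", {
  set.seed(53)
  recs <- random_records(30)
  recs$c_hat <- 0
  env <- champ_prune_1d(recs, 0, 8)
  m <- champ_prune_2d(recs, c(0, 8), c(0, 1e-6), find_out_of_box = FALSE)
  ids2 <- sort(vapply(m$domains, function(d) d$partition_id, numeric(1)))
  expect_equal(ids2, sort(env$domains$partition_id))
  for (d in m$domains) {
    row <- env$domains[env$domains$partition_id == d$partition_id, ]
    expect_equal(min(d$vertices[, 1]), row$gamma_lo, tolerance = 1e-6)
    expect_equal(max(d$vertices[, 1]), min(row$gamma_hi, 8),
                 tolerance = 1e-6)
  }
})

test_that("2-D pruning is order invariant and ignores dominated planes", {
  set.seed(59)
  recs <- data.frame(partition_id = 1:25, a_hat = runif(25, 0, 50),
                     p_hat = runif(25, 0.1, 20), c_hat = runif(25, 0, 5))
  m <- champ_prune_2d(recs, c(0, 2), c(0, 2), find_out_of_box = FALSE)
  ids <- sort(vapply(m$domains, function(d) d$partition_id, numeric(1)))
  m2 <- champ_prune_2d(recs[sample.int(25), ], c(0, 2), c(0, 2),
                       find_out_of_box = FALSE)
  expect_equal(sort(vapply(m2$domains, function(d) d$partition_id,
                           numeric(1))), ids)
  below <- data.frame(partition_id = 26, a_hat = -10,
                      p_hat = max(recs$p_hat), c_hat = 0)
  m3 <- champ_prune_2d(rbind(recs, below), c(0, 2), c(0, 2),
                       find_out_of_box = FALSE)
  expect_equal(sort(vapply(m3$domains, function(d) d$partition_id,
                           numeric(1))), ids)
})

test_that("planes optimal only beyond the box are reported out_of_box", {
  # plane 2 overtakes plane 1 at gamma = 10, far outside the box
  recs <- data.frame(partition_id = 1:2, a_hat = c(10, 0),
                     p_hat = c(2, 1), c_hat = c(0, 0))
  m <- champ_prune_2d(recs, c(0, 2), c(0, 2))
  expect_equal(vapply(m$domains, function(d) d$partition_id, numeric(1)), 1)
  expect_equal(m$out_of_box, 2L)
})

test_that("degenerate 2-D inputs error cleanly", {
  expect_error(champ_prune_2d(data.frame(), c(0, 1), c(0, 1)), "empty")
  expect_error(champ_prune_2d(fixture_planes3(), c(1, 1), c(0, 1)),
               "degenerate")
  expect_error(champ_prune_2d(data.frame(partition_id = 1, a_hat = Inf,
                                         p_hat = 1, c_hat = 0),
                              c(0, 1), c(0, 1)), "non-finite")
})
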