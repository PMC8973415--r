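dmap_from_array <- function(arr4, mask = NULL) {
  structure(list(data = arr4, scheme = window_scheme(5),
                 mask = mask %||% array(TRUE, dim(arr4)[1:3]),
                 affine = diag(4), tr = 2, params = sampen_params()),
            class = "dynamic_entropy_map")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("region series are masked means of defined voxels", {
  arr <- array(NA_real_, c(4, 1, 1, 3))
  arr[1, 1, 1, ] <- c(1, 1, 1)
  arr[2, 1, 1, ] <- c(3, 3, 3)
  arr[3, 1, 1, ] <- c(5, 6, 7)
  arr[4, 1, 1, ] <- c(5, NA, 7)    # undefined window -> voxel excluded
  labels <- array(c(1L, 1L, 2L, 2L), c(4, 1, 1))
  atlas <- parcellation_atlas(labels)
  rem <- extract_region_series(dmap_from_array(arr), atlas)
  expect_identical(rem$region_ids, c(1L, 2L))
  expect_equal(rem$values[1, ], c(2, 2, 2))     # mean of the two sequences
  expect_equal(rem$values[2, ], c(5, 6, 7))     # NA voxel dropped

  # a fully undefined region is dropped with a warning
  arr[3, 1, 1, 2] <- NA
  expect_warning(rem2 <- extract_region_series(dmap_from_array(arr), atlas),
                 "no defined voxels")
  expect_identical(rem2$region_ids, 1L)

  # random fixture against an independent masked-mean oracle
  withr::with_seed(31, big <- array(rnorm(6 * 6 * 6 * 4), c(6, 6, 6, 4)))
  at3 <- generate_atlas_grid(synthetic_spec(grid_shape = c(6, 6, 6),
                                            n_regions = 8, n_per_group = 2))
  rem3 <- extract_region_series(dmap_from_array(big), at3)
  for (g in c(1L, 5L, 8L)) {
    sel <- at3$labels == g
    want <- vapply(1:4, function(w) mean(big[, , , w][sel]), numeric(1))
    expect_equal(rem3$values[match(g, rem3$region_ids), ], want)
  }
})

test_that("pearson connectivity matches the textbook formula", {
  rem <- structure(list(values = rbind(c(1, 2, 3, 4),
                                       c(2, 4, 6, 8),
                                       c(-1, -2, -3, -4),
                                       c(2, 4, 5, 9)),
                        region_ids = 1:4, scheme = window_scheme(2)),
                   class = "region_entropy_matrix")
  conn <- pearson_connectivity(rem)
  expect_equal(conn$values[1, 2], 1)
  expect_equal(conn$values[1, 3], -1)
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(conn$values[1, 4], hand)
  expect_identical(conn$values, t(conn$values))

  # zero-variance region is dropped with a warning
  rem$values[2, ] <- 7
  expect_warning(c2 <- pearson_connectivity(rem), "zero-variance")
  expect_identical(c2$region_ids, c(1L, 3L, 4L))
})

conn_from_matrix <- function(m) {
  structure(list(values = m, region_ids = seq_len(nrow(m))),
            class = "connectivity_matrix")
}

test_that("proportional threshold keeps exactly the strongest edges", {
  m <- diag(4)
  vals <- c("12" = 0.9, "13" = 0.1, "14" = 0.5, "23" = 0.7, "24" = -0.3,
            "34" = 0.2)
  m[1, 2] <- m[2, 1] <- 0.9; m[1, 3] <- m[3, 1] <- 0.1
  m[1, 4] <- m[4, 1] <- 0.5; m[2, 3] <- m[3, 2] <- 0.7
  m[2, 4] <- m[4, 2] <- -0.3; m[3, 4] <- m[4, 3] <- 0.2
  bg <- proportional_threshold(conn_from_matrix(m), 0.5)
  expect_identical(sum(bg$adjacency) / 2, 3)       # round(0.5 * 6)
  expect_true(bg$adjacency[1, 2] && bg$adjacency[2, 3] && bg$adjacency[1, 4])
  expect_false(bg$adjacency[1, 3] || bg$adjacency[2, 4] || bg$adjacency[3, 4])
  expect_identical(diag(bg$adjacency), rep(FALSE, 4))

  # k = 1 gives the complete graph
  bgc <- proportional_threshold(conn_from_matrix(m), 1)
  expect_identical(sum(bgc$adjacency) / 2, 6)

  # absolute ranking promotes strong negative edges
  m2 <- m; m2[2, 4] <- m2[4, 2] <- -0.95
  bga <- proportional_threshold(conn_from_matrix(m2), 0.5, rank = "absolute")
  expect_true(bga$adjacency[2, 4])

  # all-equal off-diagonals: lexicographic tie rule, deterministic
  me <- matrix(0.5, 4, 4); diag(me) <- 1
  b1 <- proportional_threshold(conn_from_matrix(me), 0.5)
  b2 <- proportional_threshold(conn_from_matrix(me), 0.5)
  expect_identical(b1$adjacency, b2$adjacency)
  # lexicographic (i, j): (1,2) < (1,3) < (1,4) < (2,3)
  expect_true(b1$adjacency[1, 2] && b1$adjacency[1, 3] && b1$adjacency[1, 4])
  expect_false(b1$adjacency[2, 3])

  expect_error(proportional_threshold(conn_from_matrix(m), 0), "in \\(0, 1]")
  expect_error(proportional_threshold(conn_from_matrix(m), 1.2), "in \\(0, 1]")
})

test_that("closed-form graphs reproduce hand-derived metrics exactly", {
  # complete K5
  k5 <- binary_graph(adj_complete(5))
  cl <- clustering_and_path(k5)
  expect_identical(cl$cp, 1)
  expect_identical(cl$lp, 1)
  expect_identical(global_efficiency(k5), 1)
  expect_identical(local_efficiency(binary_graph(adj_complete(4))), 1)

  # 4-cycle: no triangles, lp = 4/3
  c4 <- binary_graph(adj_cycle(4))
  cl <- clustering_and_path(c4)
  expect_identical(cl$cp, 0)
  expect_equal(cl$lp, 4 / 3)

  # star with 4 leaves: lp = (4*1 + 6*2)/10
  st <- binary_graph(adj_star(4))
  cl <- clustering_and_path(st)
  expect_identical(cl$cp, 0)
  expect_equal(cl$lp, 1.6)
  expect_identical(local_efficiency(st), 0)

  # path P3: e_glob = (2*1 + 2*1 + 2*0.5)/6
  p3 <- binary_graph(adj_path(3))
  expect_equal(global_efficiency(p3), 5 / 6)

  # two disconnected dyads: unreachable pairs contribute 0
  dy <- matrix(0, 4, 4)
  dy[1, 2] <- dy[2, 1] <- dy[3, 4] <- dy[4, 3] <- 1
  expect_equal(global_efficiency(binary_graph(dy)), 1 / 3)
  cl <- clustering_and_path(binary_graph(dy))
  expect_equal(cl$lp, 1)            # connected pairs only
  expect_identical(cl$n_unreachable, 4L)
})

test_that("efficiency agrees with brute force and an independent library", {
  withr::with_seed(17, {
    g <- igraph::sample_gnp(12, 0.3)
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  })
  bg <- binary_graph(adj)
  expect_equal(global_efficiency(bg), eglob_brute(adj), tolerance = 1e-12)
  expect_equal(local_efficiency(bg), eloc_brute(adj), tolerance = 1e-12)
  expect_equal(clustering_and_path(bg)$cp, cp_brute(adj), tolerance = 1e-12)
  expect_equal(clustering_and_path(bg)$lp, lp_brute(adj), tolerance = 1e-12)
  # cross-check against igraph's own implementation
  expect_equal(global_efficiency(bg),
               igraph::global_efficiency(igraph::graph_from_adjacency_matrix(
                 adj, mode = "undirected")),
               tolerance = 1e-12)

  # 4-cycle plus one chord, local efficiency by subgraph enumeration
  ch <- adj_cycle(4); ch[1, 3] <- ch[3, 1] <- 1
  expect_equal(local_efficiency(binary_graph(ch)), eloc_brute(ch),
               tolerance = 1e-12)
})

test_that("rewired reference graphs preserve the degree sequence exactly", {
  withr::with_seed(23, {
    g <- igraph::sample_gnp(20, 0.2)
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  })
  bg <- binary_graph(adj)
  deg <- rowSums(adj)
  # degree preservation is an invariant of the swap operation: check via a
  # hand-rolled loop mirroring the ensemble construction
  withr::with_seed(5, {
    ig <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "undirected")
    for (i in 1:20) {
      gr <- igraph::rewire(ig, igraph::keeping_degseq(niter = 10 * igraph::ecount(ig)))
      expect_identical(igraph::degree(gr), igraph::degree(ig))
    }
  })
  # ensemble is reproducible given the seed
  r1 <- random_reference_ensemble(bg, null_model_config(10, seed = 99))
  r2 <- random_reference_ensemble(bg, null_model_config(10, seed = 99))
  expect_identical(r1, r2)

  # complete graph is rewiring-invariant
  rc <- random_reference_ensemble(binary_graph(adj_complete(6)),
                                  null_model_config(5, seed = 1))
  expect_equal(rc$crand, 1)
  expect_equal(rc$lrand, 1)

  # a clustered ring lattice loses clustering under randomisation
  lat <- adj_watts_strogatz(30, nei = 3, p = 0, seed = 2)
  cl <- clustering_and_path(binary_graph(lat))
  rl <- random_reference_ensemble(binary_graph(lat),
                                  null_model_config(20, seed = 3))
  expect_lt(rl$crand, cl$cp)
})

test_that("small-world indices compose correctly and detect WS structure", {
  expect_equal(small_world_metrics(0.5, 2, 0.5, 2), list(gamma = 1, lambda = 1, s = 1))
  sw <- small_world_metrics(2.0, 2.5, 1.0, 2.0)
  expect_equal(sw$s, 1.6)
  expect_warning(sw0 <- small_world_metrics(0.4, 2, 0, 1.8), "crand = 0")
  expect_true(is.na(sw0$gamma))

  adj <- adj_watts_strogatz(30, nei = 2, p = 0.1, seed = 4)
  bg <- binary_graph(adj)
  cl <- clustering_and_path(bg)
  nul <- random_reference_ensemble(bg, null_model_config(20, seed = 6))
  sw <- small_world_metrics(cl$cp, cl$lp, nul$crand, nul$lrand)
  expect_gt(sw$s, 1)
})

test_that("metrics across thresholds nest edges and never lose efficiency", {
  withr::with_seed(41, {
    z <- matrix(rnorm(27 * 40), 27)
    m <- cor(t(z))
  })
  conn <- conn_from_matrix(m)
  ks <- seq(0.05, 0.30, by = 0.05)
  tab <- metrics_over_thresholds(conn, ks, null_model_config(5, seed = 2))
  expect_identical(nrow(tab), 6L)
  expect_true(all(diff(tab$n_edges) >= 0))
  expect_true(all(diff(tab$e_glob) >= 0))
  expect_equal(tab$s, tab$gamma / tab$lambda)
  # edge-set nesting: K1 < K2 implies edges(K1) subset of edges(K2)
  b1 <- proportional_threshold(conn, 0.1)
  b2 <- proportional_threshold(conn, 0.25)
  expect_true(all(b2$adjacency[b1$adjacency]))
  # K = 1: complete graph metrics
  full <- metrics_over_thresholds(conn, 1, null_model_config(2, seed = 1))
  expect_equal(full$cp, 1)
  expect_equal(full$lp, 1)
  expect_equal(full$e_glob, 1)
  # determinism of the whole metric set
  tab2 <- metrics_over_thresholds(conn, ks, null_model_config(5, seed = 2))
  expect_identical(tab, tab2)
})
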