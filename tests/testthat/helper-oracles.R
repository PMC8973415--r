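# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles (explicit enumeration, no
# shared code with the package internals).

# Sample entropy by explicit enumeration of every template pair (i < j),
# Chebyshev distance, strict inequality, r = r_factor * sample SD.
sampen_brute <- function(x, m = 2, r_factor = 0.3) {
  n <- length(x)
  s <- stats::sd(x)
  if (s == 0) return(NA_real_)
  r <- r_factor * s
  nt <- n - m
  B <- 0L
  A <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm < r) {
        B <- B + 1L
        if (max(dm, abs(x[i + m] - x[j + m])) < r) A <- A + 1L
      }
    }
  }
  if (B == 0L || A == 0L) return(NA_real_)
  -log(A / B)
}

# All-pairs shortest paths by Floyd-Warshall on an adjacency matrix.
floyd_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

eglob_brute <- function(adj) {
  n <- nrow(adj)
  d <- floyd_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

eloc_brute <- function(adj) {
  n <- nrow(adj)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    eglob_brute(adj[nb, nb, drop = FALSE])
  }, numeric(1)))
}

cp_brute <- function(adj) {
  n <- nrow(adj)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / (k * (k - 1))
  }, numeric(1)))
}

lp_brute <- function(adj) {
  d <- floyd_distances(adj)
  dv <- d[upper.tri(d)]
  mean(dv[is.finite(dv)])
}

# standard adjacency builders
adj_complete <- function(n) {
  a <- matrix(1, n, n) - diag(n)
  a
}
adj_cycle <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    a[i, j] <- a[j, i] <- 1
  }
  a
}
adj_path <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  a
}
adj_star <- function(n_leaves) {
  n <- n_leaves + 1
  a <- matrix(0, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1
  a
}

# Watts-Strogatz-style ring lattice with neighbourhood `nei`, rewired with
# probability p (seeded); returned as an adjacency matrix.
adj_watts_strogatz <- function(n, nei = 2, p = 0.1, seed = 1) {
  withr::with_seed(seed, {
    g <- igraph::sample_smallworld(1, n, nei, p)
    g <- igraph::simplify(g)
    igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  })
}

# small synthetic specs shared across tests (kept tiny for speed)
smoke_spec <- function(seed = 1, ...) {
  synthetic_spec(grid_shape = c(8L, 8L, 8L), n_regions = 8L,
                 n_timepoints = 80L, n_per_group = 4L,
                 noise_sd = 0.1, seed = seed, ...)
}
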