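# Independent brute-force oracles. These deliberately share no helpers with
# the package internals: everything is recomputed from first principles.

# step-up FDR adjustment straight from the definition
bf_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  prev <- Inf
  for (i in rev(seq_len(n))) {
    v <- min(n * p[ord[i]] / i, 1)
    prev <- min(prev, v)
    adj[ord[i]] <- prev
  }
  adj
}

# Fisher's combination closed form
bf_fisher <- function(p) {
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

# niche breadth from the definition
bf_b <- function(counts_row) {
  p <- counts_row / sum(counts_row)
  1 / sum(p^2)
}

# full classification recomputed from the definitions (no shared code)
bf_classify <- function(counts, region, gen_b = 17, gen_occ = 0.5,
                        min_ab = 2e-5,
                        spec_b = c(subtropical = 12, warm_temperate = 17,
                                   temperate = 17),
                        spec_occ = 4) {
  n <- ncol(counts)
  labels <- character(nrow(counts))
  relab <- apply(counts, 2, function(col) col / sum(col))
  for (i in seq_len(nrow(counts))) {
    x <- counts[i, ]
    occ <- sum(x > 0)
    mean_ab <- mean(relab[i, ])
    bg <- if (sum(x) > 0) bf_b(x) else NA
    is_gen <- !is.na(bg) && mean_ab >= min_ab && bg > gen_b && occ / n > gen_occ
    best_reg <- NA; best_bv <- Inf
    for (r in unique(region)) {
      xr <- x[region == r]
      if (sum(xr) == 0) next
      br <- bf_b(xr)
      if (br < spec_b[[r]] && sum(xr > 0) > spec_occ && br < best_bv) {
        best_bv <- br; best_reg <- r
      }
    }
    labels[i] <- if (is_gen) "generalist"
    else if (!is.na(best_reg)) paste0("specialist:", best_reg)
    else if (mean_ab < min_ab) "filtered"
    else "medium"
  }
  labels
}

# --- graph oracles on adjacency matrices -------------------------------

bf_degree <- function(A) unname(rowSums(A))

bf_shortest_paths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A > 0] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

bf_closeness <- function(A) {
  n <- nrow(A)
  D <- bf_shortest_paths(A)
  out <- numeric(n)
  for (v in seq_len(n)) {
    reach <- which(is.finite(D[v, ]) & seq_len(n) != v)
    k <- length(reach) + 1
    if (k > 1 && n > 1)
      out[v] <- ((k - 1) / sum(D[v, reach])) * ((k - 1) / (n - 1))
  }
  out
}

# betweenness by exhaustive shortest-path enumeration (small graphs only)
bf_betweenness <- function(A) {
  n <- nrow(A)
  D <- bf_shortest_paths(A)
  # count geodesics by DP: sigma[s,t]
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    sigma[s, s] <- 1
    for (t in ord) {
      if (t == s || !is.finite(D[s, t])) next
      pred <- which(A[, t] > 0 & D[s, ] == D[s, t] - 1)
      sigma[s, t] <- sum(sigma[s, pred])
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s == v || t == v || s >= t) next
      if (!is.finite(D[s, t])) next
      if (D[s, v] + D[v, t] == D[s, t])
        tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    btw[v] <- tot
  }
  if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw
}

bf_eigen <- function(A) {
  if (all(A == 0)) return(rep(0, nrow(A)))
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  v <- abs(v)
  v / max(v)
}

# eigenvector-centrality check robust to a degenerate top eigenvalue
# (tied spectral radii across components make the dominant eigenvector
# non-unique; any unit-infinity-norm vector satisfying A v = lambda v is
# correct)
expect_valid_dominant_eigen <- function(g, A, tol = 1e-8) {
  ec <- unname(eigen_centrality_scores(g))
  if (all(A == 0)) return(testthat::expect_equal(ec, rep(0, nrow(A))))
  ev <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  if (length(ev) > 1 && ev[1] - ev[2] > 1e-8) {
    testthat::expect_equal(ec, bf_eigen(A), tolerance = tol)
  } else {
    testthat::expect_lt(max(abs(A %*% ec - ev[1] * ec)), 1e-6)
    testthat::expect_equal(max(ec), 1, tolerance = 1e-9)
  }
}

bf_modularity <- function(A, mem) {
  m <- sum(A) / 2
  deg <- rowSums(A)
  Q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A)))
    if (mem[i] == mem[j]) Q <- Q + A[i, j] - deg[i] * deg[j] / (2 * m)
  unname(Q / (2 * m))
}

random_graph_adj <- function(n, p_edge = 0.4) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p_edge) A[i, j] <- A[j, i] <- 1
  dimnames(A) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  A
}

graph_from_adj <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

random_count_table <- function(n_otu, n_samp, lambda = 5) {
  counts <- matrix(stats::rpois(n_otu * n_samp, lambda), n_otu, n_samp)
  # ensure no all-zero row or column
  pick <- sample.int(n_samp, n_otu, replace = TRUE)
  ix <- cbind(seq_len(n_otu), pick)
  counts[ix] <- counts[ix] + 1L
  zc <- which(colSums(counts) == 0)
  counts[1, zc] <- counts[1, zc] + 1L
  otu_table(counts)
}

canon_pairs <- function(a, b) paste(pmin(a, b), pmax(a, b))
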