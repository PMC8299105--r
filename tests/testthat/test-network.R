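test_that("brown_merge reduces to known closed forms", {
  expect_equal(brown_merge(0.05), 0.05, tolerance = 1e-12)
  # two independent p-values: Fisher's chi-square with 4 df
  expect_equal(brown_merge(c(0.1, 0.1)),
               pchisq(-2 * (log(0.1) + log(0.1)), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(brown_merge(c(0.1, 0.1)), 0.05605170, tolerance = 1e-6)
  # full dependence: merging k copies of p returns p
  C <- matrix(4, 3, 3)
  expect_equal(brown_merge(rep(0.07, 3), C), 0.07, tolerance = 1e-10)
  expect_warning(p0 <- brown_merge(c(0, 0.5)), "clamped")
  expect_true(p0 > 0)
})

test_that("brown_merge with diagonal covariance is Fisher's method", {
  set.seed(8)
  for (i in 1:500) {
    k <- sample(2:5, 1)
    p <- runif(k)
    expect_equal(brown_merge(p, diag(4, k)), bf_fisher(p), tolerance = 1e-10)
  }
})

test_that("bh_adjust equals the brute-force step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  set.seed(9)
  for (i in 1:300) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bf_bh(p), tolerance = 1e-14)
  }
})

test_that("the p-statistic covariance estimator recognises duplicated and
           independent measures", {
  set.seed(10)
  s <- rnorm(500)
  C <- estimate_p_covariance(cbind(s, s))
  expect_equal(C[1, 2], 4, tolerance = 1e-9)
  expect_equal(C, t(C))
  ind <- matrix(rnorm(1000 * 3), 1000, 3)
  Ci <- estimate_p_covariance(ind)
  expect_true(all(abs(Ci[upper.tri(Ci)]) < 0.5))
  expect_equal(diag(Ci), rep(4, 3))
  expect_error(estimate_p_covariance(matrix(rnorm(20), 10, 2)), "30")
})

test_that("permutation p-values are small for strong signal, uniform under
           the null, and deterministic", {
  set.seed(11)
  x <- rlnorm(100)
  r1 <- permutation_pvalue(x, x + rnorm(100, 0, 0.01), "pearson",
                           n_permutations = 999, seed = 1)
  expect_lte(r1$p, 0.01)
  expect_identical(r1$direction, "positive")
  r2 <- permutation_pvalue(x, x, "pearson", n_permutations = 99, seed = 5)
  r3 <- permutation_pvalue(x, x, "pearson", n_permutations = 99, seed = 5)
  expect_identical(r2$p, r3$p)

  # null uniformity: fraction of p < 0.1 over repeated independent pairs
  set.seed(12)
  hits <- vapply(1:400, function(i) {
    a <- rpois(40, 6); b <- rpois(40, 6)
    permutation_pvalue(a, b, "spearman", n_permutations = 99, seed = i)$p
  }, numeric(1))
  expect_gt(mean(hits < 0.1), 0.05)
  expect_lt(mean(hits < 0.1), 0.15)
})

test_that("dissimilarity directions read co-presence from the null mean", {
  set.seed(13)
  x <- rlnorm(80)
  near <- x * rlnorm(80, 0, 0.05)
  r <- permutation_pvalue(x, near, "bray_curtis", n_permutations = 199, seed = 2)
  expect_identical(r$direction, "positive")   # similarity below null mean
  far <- rev(sort(x))  # anti-aligned
  r2 <- permutation_pvalue(sort(x), far, "bray_curtis", n_permutations = 199,
                           seed = 2)
  expect_identical(r2$direction, "negative")
})

test_that("bootstrap stability separates real from spurious association", {
  set.seed(14)
  x <- rlnorm(200)
  y <- x * rlnorm(200, 0, 0.1)
  expect_true(bootstrap_stability(x, y, "pearson", n_bootstraps = 200,
                                  null_mean = 0, seed = 3))
  flips <- vapply(1:20, function(i) {
    a <- rnorm(60); b <- rnorm(60)
    bootstrap_stability(a, b, "pearson", n_bootstraps = 199, null_mean = 0,
                        seed = i)
  }, logical(1))
  expect_gte(mean(!flips), 0.9)
  s1 <- bootstrap_stability(x, y, "spearman", 99, null_mean = 0, seed = 4)
  s2 <- bootstrap_stability(x, y, "spearman", 99, null_mean = 0, seed = 4)
  expect_identical(s1, s2)
})

test_that("infer_network respects unsatisfiable support and determinism", {
  sim <- simulate_block_table(n_otus = 20, n_samples = 60, seed = 15)
  cfg <- network_config(n_permutations = 60, n_bootstraps = 60,
                        min_support = 6L, seed = 1)
  expect_identical(nrow(infer_network(sim$table, cfg)$edges), 0L)

  cfg2 <- network_config(n_permutations = 80, n_bootstraps = 80, seed = 2)
  n1 <- infer_network(sim$table, cfg2)
  n2 <- infer_network(sim$table, cfg2)
  expect_identical(n1$edges, n2$edges)
  expect_error(infer_network(sim$table[, 1:2], cfg2), "3 samples")
})

test_that("network output is invariant to OTU row order", {
  sim <- simulate_block_table(n_otus = 25, n_samples = 80, seed = 16)
  cfg <- network_config(n_permutations = 100, n_bootstraps = 100, seed = 3)
  n1 <- infer_network(sim$table, cfg)
  perm <- sample(nrow(sim$table))
  n2 <- infer_network(sim$table[perm, ], cfg)
  key <- function(net) {
    e <- net$edges[order(canon_pairs(net$edges$otu_a, net$edges$otu_b)), ]
    rownames(e) <- NULL
    e[, c("otu_a", "otu_b", "merged_p", "support_count")]
  }
  k1 <- key(n1); k2 <- key(n2)
  expect_identical(canon_pairs(k1$otu_a, k1$otu_b),
                   canon_pairs(k2$otu_a, k2$otu_b))
  expect_equal(sort(k1$merged_p), sort(k2$merged_p), tolerance = 1e-12)
})

test_that("edges recover a small planted block and respect the support
           invariant", {
  sim <- simulate_block_table(n_otus = 30, n_samples = 80, block_size = 4,
                              rho = 0.9, seed = 17)
  net <- infer_network(sim$table, network_config(n_permutations = 150,
                                                 n_bootstraps = 150, seed = 4))
  te <- canon_pairs(sim$true_edges$otu_a, sim$true_edges$otu_b)
  pe <- canon_pairs(net$edges$otu_a, net$edges$otu_b)
  expect_gte(mean(te %in% pe), 0.8)
  # NetworkEdge invariants on the candidate table
  cd <- net$candidates
  pm <- as.matrix(cd[, paste0("p_", net$config$measures)])
  expect_true(all(cd$support_count == rowSums(pm < 0.05, na.rm = TRUE)))
  expect_true(all(cd$adjusted_p >= cd$merged_p - 1e-15))
  expect_true(all(cd$merged_p >= 0 & cd$adjusted_p <= 1))
})

test_that("graph exports round-trip", {
  sim <- simulate_block_table(n_otus = 20, n_samples = 60, seed = 18)
  net <- infer_network(sim$table, network_config(n_permutations = 80,
                                                 n_bootstraps = 80, seed = 5))
  tsv <- tempfile(fileext = ".tsv")
  gml <- tempfile(fileext = ".graphml")
  write_edges(net, tsv)
  write_network_graphml(net, gml)
  back <- read.delim(tsv, stringsAsFactors = FALSE)
  expect_identical(nrow(back), nrow(net$edges))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), length(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
})
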