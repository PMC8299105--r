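test_that("degree matches the definition on canonical graphs", {
  star <- graph_from_adj(rbind(c(0, 1, 1, 1), c(1, 0, 0, 0),
                               c(1, 0, 0, 0), c(1, 0, 0, 0)))
  expect_equal(unname(degree_centrality(star)), c(3, 1, 1, 1))
  tri <- graph_from_adj(matrix(1, 3, 3) - diag(3))
  expect_equal(unname(degree_centrality(tri)), rep(2, 3))
  empty <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(empty)$name <- paste0("v", 1:4)
  expect_equal(unname(degree_centrality(empty)), rep(0, 4))
  loop <- igraph::graph_from_edgelist(rbind(c("a", "a")), directed = FALSE)
  expect_error(degree_centrality(loop), "self-loop")
})

test_that("closeness uses the component-scaled convention", {
  path3 <- graph_from_adj(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(unname(closeness_centrality(path3))[2], 1)
  iso <- graph_from_adj(rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)))
  expect_equal(unname(closeness_centrality(iso))[3], 0)
  K4 <- graph_from_adj(matrix(1, 4, 4) - diag(4))
  expect_equal(unname(closeness_centrality(K4)), rep(1, 4))
})

test_that("betweenness matches enumeration on canonical graphs", {
  path3 <- graph_from_adj(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(unname(betweenness_centrality(path3)), c(0, 1, 0))
  tri <- graph_from_adj(matrix(1, 3, 3) - diag(3))
  expect_equal(unname(betweenness_centrality(tri)), rep(0, 3))
  A <- matrix(0, 5, 5); A[1, 2:5] <- A[2:5, 1] <- 1
  star5 <- graph_from_adj(A)
  expect_equal(unname(betweenness_centrality(star5))[1], 1)
})

test_that("eigenvector centrality has its closed forms", {
  K5 <- graph_from_adj(matrix(1, 5, 5) - diag(5))
  expect_equal(unname(eigen_centrality_scores(K5)), rep(1, 5), tolerance = 1e-9)
  A <- matrix(0, 5, 5); A[1, 2:5] <- A[2:5, 1] <- 1
  ec <- unname(eigen_centrality_scores(graph_from_adj(A)))
  expect_equal(ec[1], 1, tolerance = 1e-9)
  expect_equal(ec[2:5], rep(1 / sqrt(4), 4), tolerance = 1e-8)
})

test_that("all four centralities match brute force on random graphs", {
  set.seed(20)
  for (i in 1:60) {
    n <- sample(3:7, 1)
    A <- random_graph_adj(n)
    g <- graph_from_adj(A)
    expect_equal(unname(degree_centrality(g)), bf_degree(A))
    expect_equal(unname(closeness_centrality(g)), bf_closeness(A),
                 tolerance = 1e-10)
    expect_equal(unname(betweenness_centrality(g)), bf_betweenness(A),
                 tolerance = 1e-10)
    expect_valid_dominant_eigen(g, A)
  }
})

test_that("module detection finds planted partitions with the exact Q", {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1
  diag(A) <- 0
  dimnames(A) <- list(paste0("v", 1:6), paste0("v", 1:6))
  mod <- detect_modules(graph_from_adj(A), seed = 1)
  expect_identical(length(unique(mod$membership)), 2L)
  expect_equal(mod$modularity, 0.5, tolerance = 1e-12)
  expect_equal(mod$modularity, bf_modularity(A, mod$membership),
               tolerance = 1e-12)
  K4 <- matrix(1, 4, 4) - diag(4)
  dimnames(K4) <- list(paste0("v", 1:4), paste0("v", 1:4))
  expect_identical(length(unique(detect_modules(graph_from_adj(K4),
                                                seed = 1)$membership)), 1L)
  mod2 <- detect_modules(graph_from_adj(A), seed = 1)
  expect_identical(mod$membership, mod2$membership)
})

test_that("zi and pi follow their definitions", {
  # two triangles joined by one bridge
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; diag(A) <- 0
  A[3, 4] <- A[4, 3] <- 1
  dimnames(A) <- list(paste0("v", 1:6), paste0("v", 1:6))
  g <- graph_from_adj(A)
  mem <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), paste0("v", 1:6))
  zp <- zi_pi(g, mem)
  expect_equal(zp$pi[1], 0)                       # all links inside module
  expect_equal(zp$pi[3], 1 - (2 / 3)^2 - (1 / 3)^2)
  # node with 2 links into 2 different modules
  hub <- matrix(0, 4, 4); hub[1, 2] <- hub[2, 1] <- 1; hub[1, 3] <- hub[3, 1] <- 1
  dimnames(hub) <- list(paste0("w", 1:4), paste0("w", 1:4))
  memH <- setNames(c(1L, 2L, 3L, 3L), paste0("w", 1:4))
  zpH <- zi_pi(graph_from_adj(hub), memH)
  expect_equal(zpH$pi[1], 0.5)                    # 1 - 2*(1/2)^2
  # identical within-module degrees give Zi = 0 everywhere
  tri2 <- matrix(0, 6, 6); tri2[1:3, 1:3] <- 1; tri2[4:6, 4:6] <- 1
  diag(tri2) <- 0
  dimnames(tri2) <- list(paste0("t", 1:6), paste0("t", 1:6))
  zp2 <- zi_pi(graph_from_adj(tri2),
               setNames(rep(1:2, each = 3), paste0("t", 1:6)))
  expect_equal(zp2$zi, rep(0, 6))
  expect_true(all(zp2$role == "peripheral"))
})

test_that("regression summaries match hand arithmetic", {
  r <- regress(c(1, 2, 3, 4), 2 * c(1, 2, 3, 4) + 1)
  expect_equal(r$slope, 2); expect_equal(r$intercept, 1)
  expect_equal(r$r_squared, 1)
  r2 <- regress(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r2$slope, 0.5); expect_equal(r2$r_squared, 0.25)
  r3 <- regress(c(-1, 0, 1, -1, 0, 1), c(1, 1, 1, -1, -1, -1))
  expect_equal(r3$slope, 0); expect_equal(r3$r_squared, 0)
  expect_error(regress(rep(2, 5), 1:5), "zero variance")
})

test_that("the degree ANOVA and letter display behave on constructed groups", {
  same <- compare_degree_groups(c(5, 5, 5, 5), c("a", "a", "b", "b"))
  expect_equal(same$F, 0)
  expect_identical(length(unique(same$letters)), 1L)

  an <- compare_degree_groups(c(1, 2, 3, 101, 102, 103),
                              rep(c("lo", "hi"), each = 3))
  expect_equal(an$F, 15000, tolerance = 1e-9)
  expect_true(an$letters[["lo"]] != an$letters[["hi"]])
  expect_warning(
    compare_degree_groups(c(1, 2, 3, 4, 9), c("a", "a", "b", "b", "c")),
    "singleton")
})

test_that("network_topology assembles a coherent per-node report", {
  sim <- simulate_block_table(n_otus = 25, n_samples = 80, seed = 21)
  net <- infer_network(sim$table, network_config(n_permutations = 100,
                                                 n_bootstraps = 100, seed = 6))
  md <- data.frame(sample_id = colnames(sim$table),
                   region = rep(c("subtropical", "warm_temperate"), each = 40),
                   row.names = colnames(sim$table))
  cl <- niche_classify(sim$table, md, classification_config(
    specialist_b_thresholds = c(subtropical = 5, warm_temperate = 5)))
  tp <- network_topology(net, cl, seed = 2)
  df <- tp$nodes
  expect_identical(nrow(df), length(net$nodes))
  expect_true(all(df$degree == unname(degree_centrality(tp$graph)[df$node])))
  expect_true(all(df$pi >= 0 & df$pi <= 1 + 1e-12))
  expect_true(all(df$role %in% c("module_hub", "connector", "peripheral",
                                 "kinless")))
  expect_true("b_global" %in% names(df))
  reg <- suppressWarnings(b_centrality_regressions(tp))
  expect_true(is.finite(reg$closeness$r_squared))
  out <- tempfile(fileext = ".tsv")
  write_topology(tp, out)
  expect_identical(nrow(read.delim(out)), nrow(df))
})
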