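test_that("niche breadth matches its closed forms", {
  expect_equal(niche_breadth(rep(0.25, 4)), 4)
  expect_equal(niche_breadth(c(1, 0, 0)), 1)
  expect_equal(niche_breadth(c(0.75, 0.25)), 1.6)
  expect_error(niche_breadth(c(0, 0)), "zero-sum")
  expect_error(niche_breadth(c(0.5, 0.4)), "sum to 1")
})

test_that("B is bounded by occurrence and invariant to uniform scaling", {
  set.seed(10)
  for (i in 1:200) {
    tab <- random_count_table(sample(2:15, 1), sample(3:12, 1))
    for (otu in rownames(tab)) {
      x <- as.numeric(tab[otu, ])
      b <- niche_breadth(x / sum(x))
      expect_gte(b, 1 - 1e-12)
      expect_lte(b, sum(x > 0) + 1e-9)
      expect_equal(b, niche_breadth(7 * x / sum(7 * x)), tolerance = 1e-12)
    }
  }
})

test_that("outlier fences follow the interpolated-quartile rule", {
  expect_equal(suggest_outlier_threshold(1:100, "upper"), 149.5)
  expect_equal(suggest_outlier_threshold(rep(3, 10), "upper"), 3)
  expect_equal(suggest_outlier_threshold(rep(3, 10), "lower"), 3)
  fence <- suggest_outlier_threshold(c(0, 0, 0, 100), "upper")
  expect_lt(fence, 100)   # 100 is flagged as an outlier
  expect_error(suggest_outlier_threshold(c(1, 2, 3), "upper"), "at least 4")
})

test_that("classification applies strict thresholds as stated", {
  # one OTU per rule branch over 20 samples in two regions of 10
  ids <- sprintf("s%02d", 1:20)
  region <- rep(c("subtropical", "warm_temperate"), each = 10)
  md <- data.frame(sample_id = ids, region = region, row.names = ids)
  reg_medium <- c(30L, 20L, 15L, 15L, 10L, 0L, 0L, 0L, 0L, 0L)
  counts <- rbind(
    generalist = rep(100L, 20),   # B = 20, occurrence 100%
    spec_sub   = c(20L, 5L, 5L, 5L, 5L, rep(0L, 15)),  # B_region 3.2, occ 5
    medium     = c(reg_medium, reg_medium))  # B_region 4.38, B_global 8.76
  tab <- otu_table(counts, rownames(counts), ids)
  cfg <- classification_config(
    generalist_b_threshold = 15, generalist_occurrence_fraction = 0.5,
    specialist_b_thresholds = c(subtropical = 4, warm_temperate = 4),
    specialist_min_occurrence = 4)
  cl <- niche_classify(tab, md, cfg)
  lab <- setNames(cl$results$label, cl$results$otu_id)
  expect_identical(lab[["generalist"]], "generalist")
  expect_identical(lab[["spec_sub"]], "specialist:subtropical")
  expect_identical(lab[["medium"]], "medium")
  # strict inequalities: sitting exactly at a threshold is not enough
  cfg2 <- classification_config(
    generalist_b_threshold = 20, generalist_occurrence_fraction = 0.5,
    specialist_b_thresholds = c(subtropical = 3.2, warm_temperate = 3.2),
    specialist_min_occurrence = 5)
  lab2 <- setNames(niche_classify(tab, md, cfg2)$results$label,
                   rownames(tab))
  expect_false(lab2[["generalist"]] == "generalist")   # B = 20 is not > 20
  expect_false(startsWith(lab2[["spec_sub"]], "specialist")) # 3.2 not < 3.2; occ 5 not > 5
})

test_that("an abundant OTU below the filter is never a generalist", {
  region <- rep(c("subtropical", "warm_temperate"), each = 5)
  md <- data.frame(sample_id = paste0("s", 1:10), region = region,
                   row.names = paste0("s", 1:10))
  counts <- rbind(rare = rep(1L, 10), filler = rep(100000L, 10))
  tab <- otu_table(counts, rownames(counts), paste0("s", 1:10))
  cfg <- classification_config(
    generalist_b_threshold = 5,
    specialist_b_thresholds = c(subtropical = 2, warm_temperate = 2))
  cl <- niche_classify(tab, md, cfg)
  lab <- setNames(cl$results$label, cl$results$otu_id)
  # mean relabund of "rare" is ~1e-5 < 2e-5: filtered despite B = 10
  expect_identical(lab[["rare"]], "filtered")
})

test_that("classification agrees with an independent brute force on random
           tables", {
  set.seed(77)
  regions3 <- c("subtropical", "warm_temperate", "temperate")
  for (i in 1:40) {
    n_samp <- 12L
    tab <- random_count_table(sample(4:12, 1), n_samp, lambda = 3)
    region <- sample(rep(regions3, each = 4))
    md <- data.frame(sample_id = colnames(tab), region = region,
                     row.names = colnames(tab))
    cfg <- classification_config(
      generalist_b_threshold = 6, generalist_occurrence_fraction = 0.5,
      specialist_b_thresholds = c(subtropical = 3, warm_temperate = 3.5,
                                  temperate = 3.5),
      specialist_min_occurrence = 2)
    got <- niche_classify(tab, md, cfg)$results
    want <- bf_classify(unclass(tab), region, gen_b = 6, gen_occ = 0.5,
                        spec_b = c(subtropical = 3, warm_temperate = 3.5,
                                   temperate = 3.5), spec_occ = 2)
    expect_identical(got$label, want)
  }
})

test_that("auto thresholds come from the outlier fences of the data", {
  sim <- generate_community(synthetic_spec(
    samples_per_region = 20L, n_generalists = 5L,
    n_specialists_per_region = 5L, n_medium = 40L, depth = 2000L,
    block_spec = list(), seed = 21L))
  cl <- niche_classify(sim$table, sim$metadata,
                       classification_config(auto_threshold = TRUE))
  expect_true(is.finite(cl$thresholds$generalist_b))
  expect_identical(sort(names(cl$thresholds$specialist_b)),
                   sort(unique(sim$metadata$region)))
})

test_that("region errors are caught", {
  tab <- otu_table(matrix(1L, 2, 3), c("a", "b"), c("s1", "s2", "s3"))
  md <- data.frame(sample_id = c("s1", "s2", "s3"),
                   region = c("x", "x", "y"),
                   row.names = c("s1", "s2", "s3"))
  expect_error(niche_classify(tab, md, classification_config(
    specialist_b_thresholds = c(x = 2, y = 2))), "fewer than 2")
  md2 <- md[1:2, ]
  expect_error(niche_classify(tab, md2), "missing from metadata")
})
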