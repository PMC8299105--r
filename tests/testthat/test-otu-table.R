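test_that("TSV read preserves counts, ids and order, and round-trips", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\ts1\ts2", "otuA\t1\t2", "otuB\t3\t4"), tmp)
  tab <- read_otu_table(tmp)
  expect_identical(rownames(tab), c("otuA", "otuB"))
  expect_identical(colnames(tab), c("s1", "s2"))
  expect_identical(as.integer(tab), c(1L, 3L, 2L, 4L))

  set.seed(1)
  tab2 <- random_count_table(8, 5)
  out <- tempfile(fileext = ".tsv")
  write_otu_table(tab2, out)
  back <- read_otu_table(out)
  expect_identical(unclass(back), unclass(tab2))
})

test_that("BIOM v1 JSON round-trips through biomformat", {
  set.seed(2)
  tab <- random_count_table(6, 4)
  out <- tempfile(fileext = ".biom")
  write_otu_table(tab, out, format = "biom_json")
  back <- read_otu_table(out, format = "biom_json")
  expect_identical(dim(back), dim(tab))
  expect_equal(unname(unclass(back)[rownames(tab), colnames(tab)]),
               unname(unclass(tab)))
})

test_that("malformed tables are rejected with the offending cell named", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("#OTU ID\ts1\ts2", "otuA\t1\t-1"), tmp)
  expect_error(read_otu_table(tmp), "otuA.*s2")
  writeLines(c("#OTU ID\ts1", "otuA\t1", "otuA\t2"), tmp)
  expect_error(read_otu_table(tmp), "duplicate")
  writeLines(c("#OTU ID\ts1", "otuA\tx"), tmp)
  expect_error(read_otu_table(tmp), "otuA")
  expect_error(otu_table(matrix(c(1, 2.5), 1), "a", c("s1", "s2")),
               "non-integer")
})

test_that("rarefy subsamples to exact depth, drops shallow samples, and is
           seed-deterministic", {
  tab <- otu_table(matrix(c(6L, 0L, 10L, 10L, 2L, 1L), 2),
                   c("a", "b"), c("s1", "s2", "s3"))
  expect_message(r <- rarefy(tab, 4, seed = 5), "dropping 1")
  expect_identical(attr(r, "dropped_samples"), "s3")
  expect_true(all(colSums(r) == 4))
  # single-OTU column has only one possible outcome
  expect_identical(as.integer(r[, "s1"]), c(4L, 0L))
  # column already at depth is untouched
  tab2 <- otu_table(matrix(c(2L, 1L), 2), c("a", "b"), "s1")
  r3 <- rarefy(tab2, 3, seed = 1)
  attr(r3, "dropped_samples") <- NULL
  expect_identical(unclass(r3), unclass(tab2))
  # determinism
  r2 <- rarefy(tab, 4, seed = 5)
  expect_identical(unclass(r), unclass(r2))
  expect_error(rarefy(tab2, 99, seed = 1), "fewer than")
})

test_that("rarefaction is unbiased: cell proportions match pre-rarefaction
           expectation", {
  tab <- otu_table(matrix(c(30L, 10L, 60L, 5L, 15L, 80L), 3),
                   c("a", "b", "c"), c("s1", "s2"))
  reps <- vapply(seq_len(1000), function(i)
    as.numeric(suppressWarnings(rarefy(tab, 20, seed = i)))[1:3] / 20,
    numeric(3))
  expected <- as.numeric(tab[, 1]) / sum(tab[, 1])
  se <- sqrt(expected * (1 - expected) / 20) / sqrt(1000)
  expect_true(all(abs(rowMeans(reps) - expected) < 3 * se + 1e-12))
})

test_that("within-sample relative abundance normalises every column", {
  tab <- otu_table(matrix(c(2L, 2L, 1L, 3L, 5L, 0L), 2),
                   c("a", "b"), c("s1", "s2", "s3"))
  P <- within_sample_relabund(tab)
  expect_equal(unname(colSums(P)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(P[, "s1"]), c(0.5, 0.5))
  expect_equal(unname(P[, "s2"]), c(0.25, 0.75))
  bad <- otu_table(matrix(c(1L, 0L), 1), "a", c("s1", "s2"))
  expect_error(within_sample_relabund(bad), "s2")
})

test_that("otu_profile is the within-OTU normalisation across samples", {
  tab <- otu_table(matrix(c(10L, 3L, 10L, 1L, 10L, 0L, 10L, 0L), 2),
                   c("a", "b"), paste0("s", 1:4))
  expect_equal(unname(otu_profile(tab, "a")), rep(0.25, 4))
  expect_equal(unname(otu_profile(tab, "b")), c(0.75, 0.25, 0, 0))
  zero <- otu_table(matrix(c(0L, 1L), 2), c("z", "a"), "s1")
  expect_error(otu_profile(zero, "z"), "zero total")
})

test_that("profiles and relative abundances commute with permutations", {
  set.seed(3)
  tab <- random_count_table(6, 5)
  pr <- sample(nrow(tab)); pc <- sample(ncol(tab))
  perm <- tab[pr, pc]
  expect_equal(within_sample_relabund(perm),
               within_sample_relabund(tab)[pr, pc])
  expect_equal(otu_profile(perm, rownames(tab)[1]),
               otu_profile(tab, rownames(tab)[1])[pc])
})

test_that("prevalence filter applies inclusive thresholds and is idempotent", {
  counts <- rbind(c(50L, 40L, 30L, 0L, 0L),   # 3 occurrences, many reads
                  c(3L, 3L, 2L, 2L, 0L),      # 4 occurrences, 10 reads
                  c(1L, 1L, 1L, 1L, 1L))      # 5 occurrences, 5 reads
  tab <- otu_table(counts, c("few_occ", "boundary", "few_reads"),
                   paste0("s", 1:5))
  kept <- prevalence_filter(tab, 4, 10)
  expect_identical(rownames(kept), "boundary")
  expect_identical(ncol(kept), 5L)
  expect_identical(rownames(prevalence_filter(tab, 0, 0)), rownames(tab))
  expect_identical(unclass(prevalence_filter(kept, 4, 10)), unclass(kept))
})

test_that("sample metadata round-trips and validates coverage", {
  md <- data.frame(sample_id = c("s1", "s2"), region = c("a", "b"),
                   pH = c(6.5, 7.1), row.names = c("s1", "s2"),
                   stringsAsFactors = FALSE)
  tmp <- tempfile(fileext = ".tsv")
  write_sample_metadata(md, tmp)
  back <- read_sample_metadata(tmp)
  expect_equal(back$pH, md$pH)
  tab <- otu_table(matrix(1L, 1, 3), "a", c("s1", "s2", "s3"))
  expect_error(fungalnet:::check_metadata(tab, back), "s3")
})
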