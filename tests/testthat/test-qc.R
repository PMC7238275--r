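make_em <- function(v, unit = "log1p_fpkm") expression_matrix(v, unit)

test_that("common top gene selection follows the smallest-R rule", {
  # hand oracle: tops {A,B,C} and {B,C,D}, k = 2 -> {B, C}
  v <- matrix(c(4, 3, 2, 1,
                1, 2, 3, 4), 4, 2,
              dimnames = list(c("A", "B", "C", "D"), c("s1", "s2")))
  expect_setequal(select_common_top_genes(make_em(v), k = 2L), c("B", "C"))
  # identical samples: exactly the k globally top genes
  v2 <- matrix(rep(c(5, 4, 3, 2, 1), 2), 5, 2,
               dimnames = list(letters[1:5], c("s1", "s2")))
  expect_identical(select_common_top_genes(make_em(v2), k = 3L),
                   c("a", "b", "c"))
  # k = n_genes returns all genes
  expect_setequal(select_common_top_genes(make_em(v2), k = 5L), letters[1:5])
  expect_error(select_common_top_genes(make_em(v2), k = 6L), "exceeds")
  # ties broken lexicographically
  v3 <- matrix(1, 3, 2, dimnames = list(c("z", "m", "a"), c("s1", "s2")))
  expect_identical(select_common_top_genes(make_em(v3), k = 2L), c("a", "m"))
})

test_that("Chebyshev distance is the max absolute coordinate gap", {
  v <- matrix(c(0, 0, 1, 3), 2, 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  m <- make_em(v)
  expect_equal(max_distance(m, "a", "b"), 3)
  expect_equal(max_distance(m, "a", "a"), 0)
  expect_error(max_distance(m, "a", "zz"), "unknown")
  set.seed(1)
  v4 <- matrix(runif(40), 10, 4,
               dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:4)))
  m4 <- make_em(v4)
  for (i in 1:3) for (j in (i + 1):4) {
    a <- colnames(v4)[i]; b <- colnames(v4)[j]
    expect_equal(max_distance(m4, a, b), max_distance(m4, b, a))
    expect_equal(max_distance(m4, a, b), max(abs(v4[, a] - v4[, b])))
  }
})

test_that("UPGMA reproduces hand-traced merges", {
  # two leaves: single merge at their distance
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- average_linkage(d2)
  expect_equal(t2$height, 3)
  # three points at mutual distance 1: both merges at height 1,
  # first pair (a, b) by the smallest-pair tiebreak
  d3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  t3 <- average_linkage(d3)
  expect_equal(t3$height, c(1, 1))
  expect_identical(sort(tree_merges(t3)[[1]]$members), c("a", "b"))
  # {ab: 1, ac: 10, bc: 10}: merge (a, b) at 1, then at 10
  d3b <- d3; d3b["a", "c"] <- d3b["c", "a"] <- 10
  d3b["b", "c"] <- d3b["c", "b"] <- 10
  t3b <- average_linkage(d3b)
  expect_equal(t3b$height, c(1, 10))
  # weighted average rule: joining c to (a, b) with unequal distances
  d3c <- d3b; d3c["b", "c"] <- d3c["c", "b"] <- 4
  expect_equal(average_linkage(d3c)$height, c(1, 7))
  expect_error(average_linkage(matrix(c(0, NA, NA, 0), 2, 2,
    dimnames = list(c("a", "b"), c("a", "b")))), "NaN|NA")
})

test_that("UPGMA agrees with the flat-average oracle on random matrices", {
  set.seed(99)
  for (n in 3:6) {
    for (rep in 1:5) {
      d <- random_dist(n)
      got <- tree_merges(average_linkage(d))
      want <- upgma_oracle(d)
      for (k in seq_along(want)) {
        expect_identical(got[[k]]$members, want[[k]]$members)
        expect_equal(got[[k]]$height, want[[k]]$height, tolerance = 1e-12)
      }
      # merge heights are nondecreasing
      expect_true(all(diff(vapply(got, `[[`, 0, "height")) >= -1e-12))
    }
  }
})

test_that("discordance flagging follows the G-cluster own-group rule", {
  dsn <- sample_design(
    sample_id = c("a1", "a2", "b1", "b2"),
    genotype = "G", stage = rep(c("S1", "S2"), each = 2),
    replicate = rep(1:2, 2),
    maturity = rep(c("immature", "mature"), each = 2))
  # groups cleanly separated: no flags
  d <- matrix(10, 4, 4, dimnames = list(dsn$sample_id, dsn$sample_id))
  diag(d) <- 0
  d["a1", "a2"] <- d["a2", "a1"] <- 1
  d["b1", "b2"] <- d["b2", "b1"] <- 1
  expect_equal(nrow(flag_discordant_replicates(average_linkage(d), dsn)), 0L)
  # fully interleaved groups: everything flagged as not separable
  d2 <- matrix(10, 4, 4, dimnames = list(dsn$sample_id, dsn$sample_id))
  diag(d2) <- 0
  d2["a1", "b1"] <- d2["b1", "a1"] <- 1
  d2["a2", "b2"] <- d2["b2", "a2"] <- 1
  fl <- flag_discordant_replicates(average_linkage(d2), dsn)
  expect_setequal(fl$sample_id, dsn$sample_id)
  expect_true(all(fl$reason == "group not separable"))
})

test_that("a singleton is flagged only when its group co-clusters elsewhere", {
  ids <- c("a1", "a2", "a3", "b1", "b2", "b3", "c1", "c2", "c3")
  dsn <- sample_design(
    sample_id = ids, genotype = "G",
    stage = rep(c("S1", "S2", "S3"), each = 3),
    replicate = rep(1:3, 3),
    maturity = rep(c("immature", "mature", "mature"), each = 3))
  d <- matrix(2, 9, 9, dimnames = list(ids, ids))
  diag(d) <- 0
  grp <- rep(1:3, each = 3)
  d[grp == 1, grp == 1] <- 0.1; d[grp == 2, grp == 2] <- 0.1
  d[grp == 3, grp == 3] <- 0.1
  diag(d) <- 0
  d["a3", ] <- d[, "a3"] <- 5; d["a3", "a3"] <- 0   # a3 is an outlier
  fl <- flag_discordant_replicates(average_linkage(d), dsn)
  expect_identical(fl$sample_id, "a3")
  expect_identical(fl$reason, "separated from co-clustered group")
  # single-replicate groups warn and are never flagged
  dsn1 <- sample_design(
    sample_id = c("a1", "a2", "x1"), genotype = "G",
    stage = c("S1", "S1", "S2"), replicate = c(1, 2, 1),
    maturity = c("immature", "immature", "mature"))
  d1 <- matrix(c(0, 1, 8, 1, 0, 8, 8, 8, 0), 3, 3,
               dimnames = list(dsn1$sample_id, dsn1$sample_id))
  expect_warning(fl1 <- flag_discordant_replicates(average_linkage(d1), dsn1),
                 "single replicate")
  expect_equal(nrow(fl1), 0L)
})

test_that("qc_report flags the planted discordant replicate", {
  ds <- generate_dataset(synth_params(n_genes = 200L,
                                      with_sequences = FALSE), seed = 31)
  f <- compute_fpkm(merged_counts(ds), ds$models)
  qc <- qc_report(f, ds$design, k = 100L)
  expect_identical(qc$rejected_samples$sample_id,
                   ds$manifest$discordant_replicate)
  expect_length(qc$selected_genes, 100L)
  expect_error(qc_report(merged_counts(ds), ds$design), "counts")
  # Newick export is parseable and covers every leaf
  nwk <- tree_newick(qc$tree)
  expect_match(nwk, ";$")
  if (requireNamespace("ape", quietly = TRUE)) {
    ph <- ape::read.tree(text = nwk)
    expect_setequal(ph$tip.label, ds$design$sample_id)
  }
})
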