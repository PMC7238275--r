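two_stage_means <- function(imm, mat) {
  # single-gene means matrix over named stages
  m <- matrix(c(imm, mat), 1,
              dimnames = list("g", c(sprintf("I%d", seq_along(imm)),
                                     sprintf("M%d", seq_along(mat)))))
  m
}

design_for <- function(imm_stages, mat_stages) {
  st <- c(imm_stages, mat_stages)
  sample_design(
    sample_id = paste0("G_", st, "_R1"), genotype = "G", stage = st,
    replicate = 1L,
    maturity = c(rep("immature", length(imm_stages)),
                 rep("mature", length(mat_stages))))
}

reorder_design <- function(d) {
  d <- d[rev(seq_len(nrow(d))), ]
  class(d) <- c("sample_design", "data.frame")
  d
}

test_that("stage means average surviving replicates", {
  dsn <- tiny_design()
  v <- matrix(1, 4, 8, dimnames = list(sprintf("g%d", 1:4), dsn$sample_id))
  v["g1", c("G1_S1_R1", "G1_S1_R2")] <- c(2, 4)
  m <- expression_matrix(v, "fpkm")
  mn <- stage_means(m, dsn, "G1")
  expect_equal(mn["g1", "S1"], 3)
  # single replicate is itself
  d1 <- drop_samples(dsn, "G1_S1_R2")
  expect_equal(stage_means(m, d1, "G1")["g1", "S1"], 2)
  # replicate order does not matter
  mn2 <- stage_means(m, reorder_design(dsn), "G1")
  expect_equal(mn2[, colnames(mn)], mn)
  expect_error(stage_means(m, dsn, "nope"), "unknown genotype")
})

test_that("signed fold change follows the ratio-with-sign convention", {
  expect_equal(signed_fold_change(25, 10, 0), 2.5)
  expect_equal(signed_fold_change(10, 10, 0), 1)
  expect_equal(signed_fold_change(4, 10, 0), -2.5)
  expect_error(signed_fold_change(0, 0, 0), "undefined")
  expect_equal(signed_fold_change(0, 0, 0.01), 1)
  # antisymmetry for unequal means
  set.seed(5)
  a <- runif(50, 0, 100); b <- runif(50, 0, 100)
  expect_equal(signed_fold_change(a, b, 0.01),
               -signed_fold_change(b, a, 0.01))
  # magnitude never inside (-1, 1)
  expect_true(all(abs(signed_fold_change(a, b, 0.01)) >= 1))
})

test_that("DEG calls require all pairwise comparisons to clear the bar", {
  # imm {5, 4}, mat {12, 11, 20}: min ratio 11/5 = 2.2 > 2 -> up
  m <- two_stage_means(c(5, 4), c(12, 11, 20))
  d <- design_for(c("I1", "I2"), c("M1", "M2", "M3"))
  expect_identical(call_degs(m, d, pseudocount = 0)$call, "up")
  # one failing pair (7/4 = 1.75) spoils the call
  m2 <- two_stage_means(c(5, 4), c(12, 11, 7))
  expect_identical(call_degs(m2, d, pseudocount = 0)$call, "not_de")
  # boundary pair exactly at -2 is not enough (strict inequality)
  m3 <- two_stage_means(c(10, 10), c(4, 5, 3))
  expect_identical(call_degs(m3, d, pseudocount = 0)$call, "not_de")
  # all pairs below -2 -> down
  m4 <- two_stage_means(c(10, 12), c(4, 4.5, 3))
  expect_identical(call_degs(m4, d, pseudocount = 0)$call, "down")
  expect_error(call_degs(m4, design_for(character(0), c("M1", "M2", "M3")),
                         pseudocount = 0))
})

test_that("calls are invariant under common positive rescaling", {
  set.seed(7)
  d <- design_for(c("I1", "I2"), c("M1", "M2", "M3"))
  v <- matrix(exp(rnorm(50 * 5, 3, 1.5)), 50,
              dimnames = list(sprintf("g%02d", 1:50), colnames(
                two_stage_means(c(1, 1), c(1, 1, 1)))))
  # pseudocount must rescale with the data for exact invariance
  c1 <- call_degs(v, d, pseudocount = 0)
  c2 <- call_degs(v * 37.5, d, pseudocount = 0)
  expect_identical(c1$call, c2$call)
})

test_that("genotype intersection partitions calls correctly", {
  mk <- function(ids, calls) data.frame(gene_id = ids, call = calls,
                                        stringsAsFactors = FALSE)
  calls <- list(
    A = mk(c("g1", "g2", "g3", "g4"), c("up", "up", "down", "not_de")),
    B = mk(c("g1", "g2", "g3", "g4"), c("up", "down", "down", "up")))
  out <- intersect_genotypes(calls)
  expect_identical(out$shared_up, "g1")
  expect_identical(out$shared_down, "g3")
  expect_identical(out$conflicting, "g2")      # up in A, down in B
  expect_identical(out$exclusive$B, "g4")
  expect_length(out$exclusive$A, 0L)
  # partition property: per genotype, DE calls = shared + conflicting +
  # exclusive
  for (g in names(calls)) {
    de <- calls[[g]]$gene_id[calls[[g]]$call != "not_de"]
    expect_setequal(de, c(out$shared_up, out$shared_down, out$conflicting,
                          out$exclusive[[g]]))
  }
  expect_error(intersect_genotypes(calls["A"]), ">= 2")
})

test_that("noise-free fixture calls recover the manifest exactly", {
  p <- synth_params(n_genes = 400L, dispersion = 0, with_sequences = FALSE)
  ds <- generate_dataset(p, seed = 17)
  res <- run_pipeline(ds)
  mf <- ds$manifest
  expect_setequal(res$intersection$shared_up, mf$planted_up)
  expect_setequal(res$intersection$shared_down, mf$planted_down)
  for (g in names(mf$genotype_exclusive))
    expect_setequal(res$intersection$exclusive[[g]],
                    mf$genotype_exclusive[[g]])
  expect_length(res$intersection$conflicting, 0L)
})

test_that("stage profiles export tidily", {
  m <- two_stage_means(c(5, 4), c(12, 11, 20))
  pr <- stage_profiles(m, "G1")
  expect_equal(nrow(pr), 5L)
  expect_setequal(names(pr), c("gene_id", "genotype", "stage", "mean_fpkm"))
  expect_equal(pr$mean_fpkm[pr$stage == "M3"], 20)
})
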