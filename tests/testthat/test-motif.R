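test_that("PWM construction validates its probability matrix", {
  good <- matrix(0.25, 4, 4)
  expect_s3_class(pwm("m", good), "pwm")
  expect_error(pwm("m", good * 1.1), "sum to 1")
  expect_error(pwm("m", -good), "nonnegative")
  expect_error(pwm("m", good[, 1:3]), "W x 4")
})

test_that("log-odds scoring matches hand arithmetic", {
  # rows equal to background: every word scores 0
  x <- pwm("flat", matrix(0.25, 3, 4))
  for (w in c("AAA", "ACG", "TTT")) expect_equal(log_odds(x, w), 0)
  # W = 1, p = (1,0,0,0), pseudo 0.001, uniform background
  x1 <- pwm("one", matrix(c(1, 0, 0, 0), 1, 4), pseudo = 0.001)
  expect_equal(log_odds(x1, "A"), log2(0.997 / 0.25))
  expect_equal(log_odds(x1, "C"), log2(0.001 / 0.25))
  expect_error(log_odds(x1, "AC"), "length")
  expect_error(log_odds(x1, "N"), "non-ACGT")
  # strand symmetry: score of a word equals the score of its reverse
  # complement under the reverse-complement PWM
  set.seed(11)
  x4 <- random_pwm("r", 4)
  for (w in c("ACGT", "TTAG", "CCCC")) {
    rcw <- chartr("ACGT", "TGCA", paste(rev(strsplit(w, "")[[1]]),
                                        collapse = ""))
    expect_equal(log_odds(x4, w), log_odds(pwm_revcomp(x4), rcw))
  }
})

test_that("DP p-values are exact for tiny widths and bounded in general", {
  x1 <- pwm("one", matrix(c(0.7, 0.1, 0.1, 0.1), 1, 4))
  # minimal achievable score has p = 1
  smin <- min(vapply(c("A", "C", "G", "T"), function(w) log_odds(x1, w), 0))
  expect_equal(pwm_pvalue_dp(x1, smin), 1)
  # unique best letter: p(best) = 0.25 under uniform background
  smax <- log_odds(x1, "A")
  expect_equal(pwm_pvalue_dp(x1, smax), 0.25)
  # W = 2: match exhaustive enumeration over all 16 words within one
  # word-level lattice step
  set.seed(12)
  for (rep in 1:5) {
    x2 <- random_pwm(paste0("w2_", rep), 2)
    enum <- enumerate_words(x2)
    dp <- podmat:::pwm_dp(x2, 1000L)
    band <- x2$width * dp$delta
    for (t in unique(enum$score)) {
      p_exact <- enum_pvalue(enum, t)
      p_dp <- pwm_pvalue_dp(x2, t)
      slack <- sum(enum$prob[abs(enum$score - t) <= band + 1e-12])
      expect_lte(abs(p_dp - p_exact), slack + 1e-12)
    }
  }
  expect_error(pwm_pvalue_dp(x1, 0, bins = 10L), "bins")
})

test_that("promoter extraction is strand-aware, clipped and 5'->3'", {
  chrom <- paste(rep(c("A", "C", "G", "T"), length.out = 2000),
                 collapse = "")
  genome <- Biostrings::DNAStringSet(c(Chr = chrom))
  models <- data.frame(
    gene_id = c("plus", "minus", "edge"), chrom = "Chr",
    strand = c("+", "-", "+"), tss = c(1000L, 1000L, 100L),
    length_bp = 100L, stringsAsFactors = FALSE)
  pr <- extract_promoters(models, genome, upstream = 500L, downstream = 100L)
  expect_equal(as.character(pr[["plus"]]), substr(chrom, 501, 1100))
  rc_window <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substr(chrom, 902, 1501))))
  expect_equal(as.character(pr[["minus"]]), rc_window)
  expect_equal(nchar(as.character(pr[["edge"]])), 200L)   # clipped at 0
  expect_equal(as.character(pr[["edge"]]), substr(chrom, 1, 200))
  models$chrom <- "nope"
  expect_error(extract_promoters(models, genome), "missing contig")
})

test_that("scanning finds planted sites and nothing in N runs", {
  set.seed(13)
  x <- random_pwm("sharp", 6, sharp = 0.05)    # near-deterministic PWM
  cons <- paste(c("A", "C", "G", "T")[apply(x$mat, 1, which.max)],
                collapse = "")
  left <- random_dna(1, 40); right <- random_dna(1, 40)
  seqs <- Biostrings::DNAStringSet(c(p1 = paste0(left, cons, right)))
  hits <- scan_sites(x, seqs, p_threshold = 1e-3)
  expect_true(any(hits$offset == 40 & hits$strand == "+"))
  # all-N promoter yields nothing
  nn <- Biostrings::DNAStringSet(c(p2 = strrep("N", 100)))
  expect_equal(nrow(scan_sites(x, nn, p_threshold = 1)), 0L)
})

test_that("scanning equals the sliding-window oracle on random promoters", {
  set.seed(14)
  seqs <- setNames(random_dna(6, 200), paste0("g", 1:6))
  prom <- Biostrings::DNAStringSet(seqs)
  for (W in c(3L, 5L)) {
    x <- random_pwm(paste0("w", W), W, sharp = 0.3)
    got <- scan_sites(x, prom, p_threshold = 1e-2)
    want <- scan_oracle(x, seqs, p_threshold = 1e-2)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$offset, want$offset)
    expect_identical(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
})

test_that("scan monotonicity and reverse-complement mirror symmetry", {
  set.seed(15)
  seqs <- setNames(random_dna(4, 150), paste0("g", 1:4))
  prom <- Biostrings::DNAStringSet(seqs)
  x <- random_pwm("m", 5, sharp = 0.3)
  loose <- scan_sites(x, prom, p_threshold = 1e-2)
  tight <- scan_sites(x, prom, p_threshold = 1e-4)
  key <- function(d) paste(d$gene_id, d$offset, d$strand)
  expect_true(all(key(tight) %in% key(loose)))
  # scanning reverse-complemented promoters with the reverse-complement
  # PWM mirrors the site table: offsets reflect, and each physical site
  # keeps its relative strand (rc(PWM) matches rc(word) forward)
  mirrored <- scan_sites(pwm_revcomp(x),
                         Biostrings::reverseComplement(prom),
                         p_threshold = 1e-2)
  L <- nchar(seqs[1])
  expect_setequal(paste(mirrored$gene_id, L - x$width - mirrored$offset,
                        mirrored$strand),
                  paste(loose$gene_id, loose$offset, loose$strand))
  expect_equal(sort(mirrored$score), sort(loose$score), tolerance = 1e-9)
})

test_that("evidence filtering applies the strict majority-overlap rule", {
  sites <- data.frame(
    motif_id = "m", gene_id = c("g1", "g2", "g3"),
    offset = c(10L, 20L, 30L), strand = "+", score = 1, p_value = 1e-6,
    evidence = "motif", stringsAsFactors = FALSE)
  conserved <- data.frame(
    gene_id = c("g1", "g2"), start = c(14L, 25L), end = c(100L, 100L))
  # 10-bp sites: g1 overlaps 6 bp (kept), g2 exactly 5 bp (dropped)
  out <- filter_evidence(sites, conserved = conserved, mode = "motif_CE",
                         site_width = 10L)
  expect_identical(out$gene_id, "g1")
  expect_identical(out$evidence, "motif_CE")
  # motif mode is the identity
  expect_identical(filter_evidence(sites, mode = "motif"), sites)
  expect_error(filter_evidence(sites, mode = "motif_CE", site_width = 10L),
               "conserved")
  # FunTFBS keeps exactly the labeled sites
  labels <- data.frame(motif_id = "m", gene_id = "g3", offset = 30L)
  out2 <- filter_evidence(sites, labels = labels, mode = "FunTFBS")
  expect_identical(out2$gene_id, "g3")
  expect_identical(out2$evidence, "FunTFBS")
})

test_that("MEME minimal format round-trips", {
  set.seed(16)
  xs <- list(random_pwm("alpha", 4), random_pwm("beta", 7))
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(xs, f)
  back <- read_meme(f)
  expect_length(back, 2L)
  expect_identical(vapply(back, `[[`, "", "motif_id"), c("alpha", "beta"))
  for (i in 1:2) {
    expect_equal(back[[i]]$mat, xs[[i]]$mat, tolerance = 1e-5,
                 ignore_attr = TRUE)
    expect_equal(back[[i]]$width, xs[[i]]$width)
  }
})
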