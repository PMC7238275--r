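# Independent reference implementations used to validate the package's
# algorithms.  These deliberately take the naive route: flat averages
# recomputed from the original distances, exhaustive word enumeration,
# sliding windows over substrings.

# UPGMA by definition: cluster-to-cluster distance is the plain mean of
# the ORIGINAL pairwise distances between members, recomputed from
# scratch at every step (no Lance-Williams update).  Ties broken by the
# smallest sample-id pair, as in the implementation contract.
upgma_oracle <- function(d) {
  labels <- rownames(d)
  clusters <- as.list(labels)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1L):length(clusters)) {
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || dij < best$d - 1e-15 ||
            (abs(dij - best$d) <= 1e-15 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = dij, key = key)
        }
      }
    }
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    merges[[length(merges) + 1L]] <-
      list(members = sort(merged), height = best$d)
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
  }
  merges
}

# member sets and heights of each merge in a podmat tree, for comparison
tree_merges <- function(tree) {
  n <- length(tree$labels)
  members <- function(k)
    if (k < 0) tree$labels[-k]
    else c(members(tree$merge[k, 1L]), members(tree$merge[k, 2L]))
  lapply(seq_len(n - 1L), function(k)
    list(members = sort(members(k)), height = tree$height[k]))
}

# random symmetric distance matrix with zero diagonal
random_dist <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 10)
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# exhaustive word enumeration of a PWM score distribution; independent
# re-derivation of the smoothing and scoring rules
enumerate_words <- function(x) {
  W <- x$width
  p <- x$mat * (1 - 4 * x$pseudo) + x$pseudo
  s <- log2(sweep(p, 2L, x$bkg, "/"))
  grids <- rep(list(1:4), W)
  words <- as.matrix(expand.grid(grids))
  score <- numeric(nrow(words))
  prob <- numeric(nrow(words))
  for (w in seq_len(nrow(words))) {
    idx <- words[w, ]
    score[w] <- sum(s[cbind(1:W, idx)])
    prob[w] <- prod(x$bkg[idx])
  }
  list(score = score, prob = prob)
}

enum_pvalue <- function(enum, t) sum(enum$prob[enum$score >= t - 1e-12])

# naive sliding-window scan of one promoter sequence with one PWM;
# returns the same columns as scan_sites()
scan_oracle <- function(x, seqs, p_threshold = 1e-5, bins = 1000L) {
  rc <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  }
  rows <- list()
  for (g in names(seqs)) {
    sq <- toupper(seqs[[g]])
    L <- nchar(sq)
    for (off in seq_len(max(0L, L - x$width + 1L)) - 1L) {
      for (strand in c("+", "-")) {
        word <- substr(sq, off + 1L, off + x$width)
        if (strand == "-") word <- rc(word)
        if (grepl("[^ACGT]", word)) next
        sc <- tryCatch(log_odds(x, word), error = function(e) NA)
        if (is.na(sc)) next
        pv <- pwm_pvalue_dp(x, sc, bins)
        if (pv <= p_threshold)
          rows[[length(rows) + 1L]] <- data.frame(
            motif_id = x$motif_id, gene_id = g, offset = off,
            strand = strand, score = sc, p_value = pv,
            evidence = "motif", stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif_id = character(0), gene_id = character(0),
               offset = integer(0), strand = character(0),
               score = numeric(0), p_value = numeric(0),
               evidence = character(0), stringsAsFactors = FALSE)
  out[order(out$motif_id, out$gene_id, out$offset, out$strand), ]
}

# larger-scale scan oracle: same naive window enumeration, but the
# p-value lattice is computed once per PWM (the p-value primitive is
# validated independently against word enumeration)
scan_oracle_fast <- function(x, seqs, p_threshold = 1e-5, bins = 1000L) {
  dp <- podmat:::pwm_dp(x, bins)
  smat <- podmat:::pwm_score_matrix(x)
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  rows <- list()
  for (g in names(seqs)) {
    sq <- toupper(seqs[[g]])
    L <- nchar(sq)
    for (off in seq_len(max(0L, L - x$width + 1L)) - 1L) {
      fwd <- substr(sq, off + 1L, off + x$width)
      for (strand in c("+", "-")) {
        word <- if (strand == "+") fwd else rc(fwd)
        idx <- match(strsplit(word, "")[[1L]], c("A", "C", "G", "T"))
        if (anyNA(idx)) next
        sc <- sum(smat[cbind(seq_len(x$width), idx)])
        pv <- podmat:::dp_pvalue(dp, sc)
        if (pv <= p_threshold)
          rows[[length(rows) + 1L]] <- data.frame(
            motif_id = x$motif_id, gene_id = g, offset = off,
            strand = strand, score = sc, p_value = pv,
            stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif_id = character(0), gene_id = character(0),
               offset = integer(0), strand = character(0),
               score = numeric(0), p_value = numeric(0),
               stringsAsFactors = FALSE)
  out[order(out$motif_id, out$gene_id, out$offset, out$strand), ]
}

random_pwm <- function(id, W, seed = NULL, sharp = 2) {
  if (!is.null(seed)) set.seed(seed)
  raw <- matrix(rgamma(W * 4, shape = 1 / sharp), W, 4)
  pwm(id, raw / rowSums(raw))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
}

# small expression fixture: deterministic two-genotype design
tiny_design <- function() {
  g <- rep(c("G1", "G2"), each = 4)
  st <- rep(c("S1", "S2"), times = 4)
  rep_ <- rep(rep(1:2, each = 2), 2)
  sample_design(
    sample_id = sprintf("%s_%s_R%d", g, st, rep_),
    genotype = g, stage = st, replicate = rep_,
    maturity = ifelse(st == "S1", "immature", "mature"))
}
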