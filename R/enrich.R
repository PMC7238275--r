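#' Validate 2x2 over-representation counts
#'
#' @param k foreground successes, `n` foreground size, `K` background
#'   successes, `N` background (universe) size.
#' @return A list of class `contingency_counts`.
#' @export
contingency_counts <- function(k, n, K, N) {
  if (k < 0 || k > min(n, K) || n > N || K > N || k < n - (N - K))
    stop("invalid contingency counts (need 0 <= k <= min(n, K), n, K <= N)")
  structure(list(k = k, n = n, K = K, N = N), class = "contingency_counts")
}

#' Hypergeometric upper-tail probability (one-sided Fisher test)
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n), accumulated in log space;
#' identical to the one-sided (enrichment) Fisher exact test on the 2x2
#' table.
#'
#' @param counts a [contingency_counts()] (or list with k, n, K, N).
#' @return p-value in (0, 1].
#' @export
hypergeom_upper_tail <- function(counts) {
  c <- contingency_counts(counts$k, counts$n, counts$K, counts$N)
  hi <- min(c$n, c$K)
  if (c$k <= max(0L, c$n - (c$N - c$K))) return(1)
  x <- c$k:hi
  lp <- lchoose(c$K, x) + lchoose(c$N - c$K, c$n - x) - lchoose(c$N, c$n)
  m <- max(lp)
  min(1, exp(m) * sum(exp(lp - m)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR control: sort p ascending, multiply by m/i,
#' enforce monotonicity from the largest p downwards, cap at 1, and
#' return values in the original input order.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  stepped <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(stepped)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Over-representation analysis of a gene set against term annotations
#'
#' One hypergeometric upper-tail test per term with at least one
#' foreground hit, Benjamini-Hochberg adjustment across the tested
#' terms.  Up- and down-regulated sets are conventionally tested in
#' separate calls.
#'
#' @param gene_set foreground gene ids (must be a subset of `universe`).
#' @param annotation data.frame (`term_id`, `gene_id`) or named list of
#'   gene-id vectors.
#' @param universe background gene ids.
#' @param alpha_adj adjusted-p significance cutoff (default 0.01).
#' @return data.frame sorted by (p_adj, term_id): `term_id`, `k`, `n`,
#'   `K`, `N`, `p_raw`, `p_adj`, `significant`.
#' @export
ora <- function(gene_set, annotation, universe, alpha_adj = 0.01) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% universe))
    stop("gene_set must be a subset of the universe")
  terms <- if (is.data.frame(annotation))
    split(annotation$gene_id, annotation$term_id) else annotation
  terms <- lapply(terms, function(g) intersect(unique(g), universe))
  n <- length(gene_set); N <- length(universe)
  k <- vapply(terms, function(g) length(intersect(g, gene_set)), 0L)
  K <- vapply(terms, length, 0L)
  tested <- which(k >= 1L)
  if (!length(tested))
    return(data.frame(term_id = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p_raw = numeric(0),
                      p_adj = numeric(0), significant = logical(0)))
  p_raw <- vapply(tested, function(i)
    hypergeom_upper_tail(list(k = k[i], n = n, K = K[i], N = N)), 0)
  p_adj <- bh_adjust(p_raw)
  out <- data.frame(term_id = names(terms)[tested], k = k[tested], n = n,
                    K = K[tested], N = N, p_raw = p_raw, p_adj = p_adj,
                    significant = p_adj <= alpha_adj,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_adj, out$term_id), ]
  rownames(out) <- NULL
  out
}

#' TFBS enrichment in maturation-gene promoters with target assignment
#'
#' For each transcription factor, genes carrying at least one binding
#' site in their promoter are the TF's potential targets (site
#' multiplicity is ignored).  A one-sided Fisher test then asks whether
#' targets are over-represented among the maturation genes relative to
#' the rest of the universe.  Significance uses the raw p-value at
#' `alpha` by default; set `adjust = TRUE` for Benjamini-Hochberg.
#' TFs without a single site anywhere in the universe are skipped with a
#' note.  For each significant TF the maturation-gene targets are
#' returned.
#'
#' @param maturation_genes foreground gene ids.
#' @param sites site table from [scan_sites()] (uses `motif_id` as the
#'   TF identifier unless `tf_map` is given), or a data.frame of
#'   TF-to-target pairs with columns `tf_id` and `gene_id`.
#' @param universe background gene ids (all genes with a scanned
#'   promoter).
#' @param alpha significance cutoff (default 0.05).
#' @param tf_map optional data.frame (`tf_id`, `motif_id`) mapping motifs
#'   to their transcription factors.
#' @param adjust apply BH across TFs before thresholding.
#' @return A list: `results` (data.frame per TF sorted by p, with
#'   counts, p_raw, p_adj, significant), `targets` (named list of
#'   maturation-gene targets per significant TF), `skipped`.
#' @export
tfbs_enrichment <- function(maturation_genes, sites, universe,
                            alpha = 0.05, tf_map = NULL, adjust = FALSE) {
  universe <- unique(universe)
  maturation_genes <- intersect(unique(maturation_genes), universe)
  if (!is.null(sites$tf_id)) {
    pairs <- unique(sites[, c("tf_id", "gene_id")])
  } else {
    pairs <- unique(sites[, c("motif_id", "gene_id")])
    names(pairs)[1L] <- "tf_id"
    if (!is.null(tf_map))
      pairs$tf_id <- tf_map$tf_id[match(pairs$tf_id, tf_map$motif_id)]
  }
  pairs <- pairs[pairs$gene_id %in% universe, , drop = FALSE]
  tfs <- sort(unique(pairs$tf_id))
  skipped <- character(0)
  rows <- list(); targets <- list()
  N <- length(universe); n <- length(maturation_genes)
  for (tf in tfs) {
    tg <- unique(pairs$gene_id[pairs$tf_id == tf])
    if (!length(tg)) { skipped <- c(skipped, tf); next }
    K <- length(tg)
    k <- length(intersect(tg, maturation_genes))
    p <- hypergeom_upper_tail(list(k = k, n = n, K = K, N = N))
    rows[[tf]] <- data.frame(tf_id = tf, k = k, n = n, K = K, N = N,
                             p_raw = p, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(list(results = data.frame(), targets = list(), skipped = skipped))
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p_raw)
  crit <- if (adjust) res$p_adj else res$p_raw
  res$significant <- crit <= alpha
  res <- res[order(res$p_raw, res$tf_id), ]
  rownames(res) <- NULL
  for (tf in res$tf_id[res$significant])
    targets[[tf]] <- sort(intersect(
      unique(pairs$gene_id[pairs$tf_id == tf]), maturation_genes))
  list(results = res, targets = targets, skipped = skipped)
}
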