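DNA_ALPHABET <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param motif_id motif identifier.
#' @param mat W x 4 probability matrix over A, C, G, T; rows must sum
#'   to 1 (within 1e-9).
#' @param bkg background letter frequencies (length 4, sums to 1).
#' @param pseudo pseudo-probability smoothed into every entry before
#'   log-odds scoring: `p' = p * (1 - 4 * pseudo) + pseudo`, which keeps
#'   zero entries finite.
#' @return An object of class `pwm`.
#' @export
pwm <- function(motif_id, mat, bkg = rep(0.25, 4), pseudo = 1e-3) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L || nrow(mat) < 1L) stop("PWM must be W x 4 with W >= 1")
  if (any(mat < 0)) stop("PWM entries must be nonnegative")
  if (max(abs(rowSums(mat) - 1)) > 1e-9) stop("PWM rows must sum to 1")
  if (abs(sum(bkg) - 1) > 1e-9 || any(bkg < 0)) stop("invalid background")
  colnames(mat) <- DNA_ALPHABET
  structure(list(motif_id = motif_id, mat = mat, bkg = bkg, pseudo = pseudo,
                 width = nrow(mat)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d\n", x$motif_id, x$width))
  invisible(x)
}

#' Reverse complement of a PWM
#' @param x a [pwm()].
#' @return The PWM scoring the reverse-complement strand.
#' @export
pwm_revcomp <- function(x) {
  m <- x$mat[rev(seq_len(x$width)), rev(seq_len(4L)), drop = FALSE]
  colnames(m) <- DNA_ALPHABET
  pwm(x$motif_id, m, rev(x$bkg), x$pseudo)
}

# smoothed log2-odds score matrix, W x 4
pwm_score_matrix <- function(x) {
  p <- x$mat * (1 - 4 * x$pseudo) + x$pseudo
  log2(sweep(p, 2L, x$bkg, "/"))
}

#' Log-odds score of a word under a PWM
#'
#' `sum_i log2(p'_i[w_i] / b[w_i])` with the pseudo-probability smoothing
#' documented in [pwm()] applied to all entries.
#'
#' @param x a [pwm()].
#' @param word character string of length equal to the PWM width, over
#'   A/C/G/T.
#' @return The log2 odds score.
#' @export
log_odds <- function(x, word) {
  letters <- strsplit(toupper(word), "")[[1L]]
  if (length(letters) != x$width) stop("word length must equal PWM width")
  idx <- match(letters, DNA_ALPHABET)
  if (anyNA(idx)) stop("word contains non-ACGT characters")
  s <- pwm_score_matrix(x)
  sum(s[cbind(seq_len(x$width), idx)])
}

# Discretized score distribution under the background model.
# Per-position scores are shifted by the row minimum and floored onto an
# integer lattice of width delta = total score range / bins (rounding
# DOWN, so lattice scores never exceed true scores).  Returns the exact
# tail probabilities of the lattice total under iid background letters.
pwm_dp <- function(x, bins = 1000L) {
  if (bins < 100L) stop("bins must be >= 100")
  s <- pwm_score_matrix(x)
  if (any(!is.finite(s))) stop("degenerate PWM: non-finite scores")
  mins <- apply(s, 1L, min)
  smin <- sum(mins)
  rng <- sum(apply(s, 1L, max)) - smin
  delta <- rng / bins
  if (delta == 0) {
    return(list(delta = 0, smin = smin, smax = smin, kmat = NULL,
                tailp = c(1, 0)))
  }
  kmat <- matrix(0L, x$width, 4L)
  for (i in seq_len(x$width))
    kmat[i, ] <- as.integer(floor((s[i, ] - mins[i]) / delta + 1e-9))
  kmax <- sum(apply(kmat, 1L, max))
  dist <- c(1, numeric(kmax))                    # P(lattice total = v)
  for (i in seq_len(x$width)) {
    nd <- numeric(kmax + 1L)
    for (l in 1:4) {
      k <- kmat[i, l]
      if (x$bkg[l] > 0)
        nd[(k + 1L):(kmax + 1L)] <- nd[(k + 1L):(kmax + 1L)] +
          x$bkg[l] * dist[1:(kmax + 1L - k)]
    }
    dist <- nd
  }
  tailp <- rev(cumsum(rev(dist)))                # P(total >= v), v = 0..kmax
  list(delta = delta, smin = smin, smax = smin + rng, kmat = kmat,
       tailp = c(tailp, 0))
}

dp_pvalue <- function(dp, score) {
  if (dp$delta == 0)
    return(ifelse(score <= dp$smin + 1e-12, 1, .Machine$double.xmin))
  kt <- floor((score - dp$smin) / dp$delta + 1e-9)
  kmax <- length(dp$tailp) - 2L
  p <- ifelse(kt <= 0, 1,
              dp$tailp[pmin(kt, kmax + 1L) + 1L])
  pmax(p, .Machine$double.xmin)
}

#' Exact-to-discretization p-value of a PWM score
#'
#' P(score(random word) >= `score`) under the background model, computed
#' by dynamic programming over per-position score distributions floored
#' onto an integer lattice of `bins` steps spanning the total score
#' range.  Rounding down biases lattice scores low, and the queried
#' threshold is floored the same way, so the result is exact for the
#' lattice score function and within one word-level lattice step
#' (`width * range / bins`) of the true distribution.
#'
#' @param x a [pwm()].
#' @param score log2-odds threshold.
#' @param bins lattice resolution (>= 100; default 1000).
#' @return A p-value in (0, 1].
#' @export
pwm_pvalue_dp <- function(x, score, bins = 1000L) {
  dp_pvalue(pwm_dp(x, bins), score)
}

#' Extract strand-aware promoter windows
#'
#' For a plus-strand gene the promoter is `[tss - upstream,
#' tss + downstream)` on the forward strand; for a minus-strand gene it
#' is `[tss - downstream + 1, tss + upstream + 1)` reverse-complemented.
#' Windows are clipped at contig bounds and emitted 5' to 3' relative to
#' the gene.
#'
#' @param models gene-model data frame from [read_gene_models()].
#' @param genome a `DNAStringSet` (or path to a FASTA file).
#' @param upstream,downstream window extents in bp (defaults 500/100).
#' @return A `DNAStringSet` named by gene id.
#' @export
extract_promoters <- function(models, genome, upstream = 500L,
                              downstream = 100L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing <- setdiff(unique(models$chrom), names(genome))
  if (length(missing))
    stop("gene(s) on missing contig(s): ", paste(missing, collapse = ", "))
  clen <- setNames(Biostrings::width(genome), names(genome))[models$chrom]
  plus <- models$strand == "+"
  start0 <- ifelse(plus, models$tss - upstream, models$tss - downstream + 1L)
  end0 <- ifelse(plus, models$tss + downstream, models$tss + upstream + 1L)
  start0 <- pmax(start0, 0L)
  end0 <- pmin(end0, clen)
  if (any(end0 <= start0)) stop("empty promoter window after clipping")
  seqs <- character(nrow(models))
  for (ch in unique(models$chrom)) {
    i <- models$chrom == ch
    chrstr <- as.character(genome[[ch]])
    seqs[i] <- substring(chrstr, start0[i] + 1L, end0[i])
  }
  out <- Biostrings::DNAStringSet(setNames(seqs, models$gene_id))
  if (any(!plus))
    out[!plus] <- Biostrings::reverseComplement(out[!plus])
  out
}

#' Scan promoters with PWMs on both strands
#'
#' Reports every offset and strand whose match p-value is at or below
#' `p_threshold`.  Offsets are 0-based positions of the site's leftmost
#' base on the forward promoter sequence; windows containing non-ACGT
#' characters are skipped.
#'
#' @param pwms a [pwm()] or list of them.
#' @param promoters named `DNAStringSet` (or path to FASTA).
#' @param p_threshold report sites with p <= this value (default 1e-5).
#' @param bins p-value lattice resolution.
#' @return A `data.frame` site table: `motif_id`, `gene_id`, `offset`,
#'   `strand`, `score`, `p_value`, `evidence` (= `"motif"`).
#' @export
scan_sites <- function(pwms, promoters, p_threshold = 1e-5, bins = 1000L) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  if (is.character(promoters))
    promoters <- Biostrings::readDNAStringSet(promoters)
  seqs <- as.character(promoters)
  rcs <- as.character(Biostrings::reverseComplement(promoters))
  rows <- list()
  for (x in pwms) {
    dp <- pwm_dp(x, bins)
    s <- pwm_score_matrix(x)
    for (gi in seq_along(seqs)) {
      for (strand in c("+", "-")) {
        sq <- if (strand == "+") seqs[gi] else rcs[gi]
        sc <- score_windows(s, sq)
        if (!length(sc)) next
        pv <- dp_pvalue(dp, sc)
        pv[is.na(sc)] <- NA
        hit <- which(!is.na(sc) & pv <= p_threshold)
        if (!length(hit)) next
        off <- hit - 1L
        if (strand == "-")                    # leftmost base on forward seq
          off <- nchar(sq) - x$width - off
        rows[[length(rows) + 1L]] <- data.frame(
          motif_id = x$motif_id, gene_id = names(seqs)[gi], offset = off,
          strand = strand, score = sc[hit], p_value = pv[hit],
          evidence = "motif", stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif_id = character(0), gene_id = character(0),
               offset = integer(0), strand = character(0),
               score = numeric(0), p_value = numeric(0),
               evidence = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$motif_id, out$gene_id, out$offset, out$strand), ]
  rownames(out) <- NULL
  out
}

# vectorized sliding-window log-odds; NA where the window has non-ACGT
score_windows <- function(s, sq) {
  W <- nrow(s)
  codes <- match(strsplit(toupper(sq), "")[[1L]], DNA_ALPHABET)
  L <- length(codes)
  if (L < W) return(numeric(0))
  n_off <- L - W + 1L
  total <- numeric(n_off)
  for (i in seq_len(W)) {
    v <- s[i, codes[i:(i + n_off - 1L)]]
    total <- total + v
  }
  total
}

#' Filter a motif site table by evidence class
#'
#' `motif` returns the table unchanged; `motif_CE` keeps sites whose
#' overlap with any conserved interval strictly exceeds 50% of the site
#' length; `FunTFBS` keeps sites matching a supplied functional-site
#' label table (labels are inputs, never computed here).
#'
#' @param sites site table from [scan_sites()].
#' @param conserved for `motif_CE`: data.frame of promoter-local 0-based
#'   half-open intervals (`gene_id`, `start`, `end`).
#' @param labels for `FunTFBS`: data.frame with `motif_id`, `gene_id`,
#'   `offset` identifying functional sites.
#' @param mode one of `"motif"`, `"motif_CE"`, `"FunTFBS"`.
#' @param site_width PWM width used for the overlap fraction; inferred
#'   from a `width` column when present, otherwise required.
#' @return The filtered site table with `evidence` updated.
#' @export
filter_evidence <- function(sites, conserved = NULL, labels = NULL,
                            mode = c("motif", "motif_CE", "FunTFBS"),
                            site_width = NULL) {
  mode <- match.arg(mode)
  if (mode == "motif") return(sites)
  if (mode == "motif_CE") {
    if (is.null(conserved)) stop("motif_CE mode requires a conserved track")
    W <- if (!is.null(sites$width)) sites$width else site_width
    if (is.null(W)) stop("site width required for overlap computation")
    W <- rep_len(W, nrow(sites))
    keep <- logical(nrow(sites))
    for (i in seq_len(nrow(sites))) {
      ci <- conserved[conserved$gene_id == sites$gene_id[i], , drop = FALSE]
      if (!nrow(ci)) next
      ov <- pmin(ci$end, sites$offset[i] + W[i]) - pmax(ci$start, sites$offset[i])
      keep[i] <- any(ov > W[i] / 2)            # strict majority overlap
    }
    out <- sites[keep, , drop = FALSE]
    out$evidence <- rep_len("motif_CE", nrow(out))
  } else {
    if (is.null(labels)) stop("FunTFBS mode requires a label table")
    key <- function(d) paste(d$motif_id, d$gene_id, d$offset, sep = "\r")
    out <- sites[key(sites) %in% key(labels), , drop = FALSE]
    out$evidence <- rep_len("FunTFBS", nrow(out))
  }
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# MEME minimal format
# ---------------------------------------------------------------------------

#' Write PWMs in MEME minimal motif format
#'
#' @param pwms list of [pwm()] objects.
#' @param path output path.
#' @export
write_meme <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_ALPHABET, pwms[[1L]]$bkg),
                     collapse = " "), ""), con)
  for (x in pwms) {
    writeLines(sprintf("MOTIF %s", x$motif_id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      x$width), con)
    for (i in seq_len(x$width))
      writeLines(paste(sprintf("%.6f", x$mat[i, ]), collapse = "  "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read PWMs from MEME minimal motif format
#'
#' @param path path to a MEME-format file.
#' @param pseudo pseudo-probability attached to the parsed PWMs.
#' @return A list of [pwm()] objects.
#' @export
read_meme <- function(path, pseudo = 1e-3) {
  lines <- readLines(path)
  bkg <- rep(0.25, 4)
  bi <- grep("^Background letter frequencies", lines)
  if (length(bi) && bi[1L] < length(lines)) {
    toks <- strsplit(trimws(lines[bi[1L] + 1L]), "\\s+")[[1L]]
    if (length(toks) >= 8L)
      bkg <- as.numeric(toks[c(2L, 4L, 6L, 8L)])
  }
  starts <- grep("^MOTIF\\b", lines)
  out <- list()
  for (st in starts) {
    id <- strsplit(trimws(lines[st]), "\\s+")[[1L]][2L]
    hi <- st
    while (hi <= length(lines) &&
           !grepl("^letter-probability matrix", lines[hi])) hi <- hi + 1L
    if (hi > length(lines)) stop("motif ", id, " lacks a probability matrix")
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hi]))
    rows <- lines[hi + seq_len(w)]
    mat <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1L]][1:4]), numeric(4L)))
    rs <- rowSums(mat)
    mat <- mat / rs                             # renormalize printed rounding
    out[[length(out) + 1L]] <- pwm(id, mat, bkg, pseudo)
  }
  out
}
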