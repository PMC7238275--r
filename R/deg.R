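#' Per-stage mean expression for one genotype
#'
#' Arithmetic mean of the surviving replicates' FPKM per (gene, stage).
#' QC-rejected samples must already have been removed from `design`
#' (see [drop_samples()]).
#'
#' @param m an [expression_matrix()] with unit `"fpkm"`.
#' @param design a [sample_design()].
#' @param genotype genotype to average.
#' @return Numeric matrix genes x stages.
#' @export
stage_means <- function(m, design, genotype) {
  if (em_unit(m) != "fpkm") stop("stage_means expects unit 'fpkm'")
  d <- design[design$genotype == genotype, ]
  if (!nrow(d)) stop("unknown genotype: ", genotype)
  stages <- unique(d$stage)
  v <- unclass(m)
  out <- matrix(NA_real_, nrow(v), length(stages),
                dimnames = list(rownames(v), stages))
  for (st in stages) {
    ids <- d$sample_id[d$stage == st]
    if (!length(ids)) stop("stage with zero surviving replicates: ", st)
    out[, st] <- rowMeans(v[, ids, drop = FALSE])
  }
  out
}

#' Remove samples (e.g. QC rejects) from a design
#'
#' @param design a [sample_design()].
#' @param sample_ids ids to drop.
#' @return The reduced, revalidated design.
#' @export
drop_samples <- function(design, sample_ids) {
  validate_sample_design(design[!design$sample_id %in% sample_ids, ])
}

#' Signed fold change between two nonnegative means
#'
#' With `a = mature + pseudocount` and `b = immature + pseudocount`,
#' returns `a/b` when `a >= b` and `-b/a` otherwise, so the magnitude is
#' symmetric around +1/-1 and the value is antisymmetric under swapping
#' the arguments (equal means give +1 by convention).
#'
#' @param mature_mean,immature_mean nonnegative stage means.
#' @param pseudocount nonnegative stabilizer added to both terms; must be
#'   positive when either mean can be zero.
#' @return Signed fold change (never in (-1, 1)).
#' @export
signed_fold_change <- function(mature_mean, immature_mean, pseudocount = 0.01) {
  a <- mature_mean + pseudocount
  b <- immature_mean + pseudocount
  if (any(a == 0 & b == 0))
    stop("fold change undefined: both means zero with zero pseudocount")
  ifelse(a >= b, a / b, -b / a)
}

#' All-pairwise signed fold changes between mature and immature stages
#'
#' @param means genes x stages matrix from [stage_means()].
#' @param design a [sample_design()] providing the stage -> maturity map.
#' @param pseudocount passed to [signed_fold_change()].
#' @return data.frame (gene_id, mature_stage, immature_stage, signed_fc)
#'   with one row per gene per (mature, immature) stage pair.
#' @export
fold_change_table <- function(means, design, pseudocount = 0.01) {
  mm <- maturity_map(design)
  imm <- intersect(colnames(means), names(mm)[mm == "immature"])
  mat <- intersect(colnames(means), names(mm)[mm == "mature"])
  if (!length(imm) || !length(mat)) stop("empty maturity class")
  rows <- vector("list", length(mat) * length(imm))
  k <- 0L
  for (ms in mat) for (is in imm) {
    k <- k + 1L
    rows[[k]] <- data.frame(
      gene_id = rownames(means), mature_stage = ms, immature_stage = is,
      signed_fc = signed_fold_change(means[, ms], means[, is], pseudocount),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

maturity_map <- function(design) {
  mp <- unique(design[, c("stage", "maturity")])
  setNames(mp$maturity, mp$stage)
}

#' Call maturation DEGs from all-pairwise fold changes
#'
#' A gene is called `up` when its signed fold change exceeds `+threshold`
#' in every (mature, immature) stage pair, `down` when it is below
#' `-threshold` in every pair, and `not_de` otherwise.  Inequalities are
#' strict: a gene sitting exactly at the threshold in any pair is not
#' differentially expressed.  Direction consistency is therefore built
#' in — all pairs must clear the threshold with the same sign.
#'
#' @param means genes x stages matrix from [stage_means()].
#' @param design a [sample_design()].
#' @param threshold fold-change cutoff (default 2).
#' @param pseudocount stabilizer for zero means (default 0.01 FPKM).
#' @return data.frame (gene_id, call, min_fc, max_fc) where `min_fc` /
#'   `max_fc` summarize the pairwise evidence.
#' @export
call_degs <- function(means, design, threshold = 2, pseudocount = 0.01) {
  fc <- fold_change_table(means, design, pseudocount)
  sp <- split(fc$signed_fc, fc$gene_id)
  sp <- sp[rownames(means)]                 # keep input gene order
  lo <- vapply(sp, min, 0); hi <- vapply(sp, max, 0)
  call <- ifelse(lo > threshold, "up",
                 ifelse(hi < -threshold, "down", "not_de"))
  data.frame(gene_id = rownames(means), call = unname(call),
             min_fc = unname(lo), max_fc = unname(hi),
             stringsAsFactors = FALSE)
}

#' Intersect DEG calls across genotypes
#'
#' Shared sets require the same directional call in every genotype; genes
#' differentially expressed in exactly one genotype are that genotype's
#' exclusive set; genes called in several genotypes with conflicting
#' directions are excluded from the shared sets and reported.
#'
#' @param calls_by_genotype named list of [call_degs()] outputs.
#' @return A list of class `deg_intersection`: `shared_up`,
#'   `shared_down`, `exclusive` (named list per genotype), `conflicting`.
#' @export
intersect_genotypes <- function(calls_by_genotype) {
  if (length(calls_by_genotype) < 2L) stop("need calls for >= 2 genotypes")
  de_sets <- lapply(calls_by_genotype, function(d)
    setNames(d$call[d$call != "not_de"], d$gene_id[d$call != "not_de"]))
  all_de <- unique(unlist(lapply(de_sets, names), use.names = FALSE))
  n_called <- vapply(all_de, function(g)
    sum(vapply(de_sets, function(s) g %in% names(s), FALSE)), 0L)
  everywhere <- all_de[n_called == length(de_sets)]
  dirs <- vapply(everywhere, function(g)
    length(unique(vapply(de_sets, function(s) s[[g]], ""))), 0L)
  shared <- everywhere[dirs == 1L]
  conflicting <- everywhere[dirs > 1L]
  dir_of <- vapply(shared, function(g) de_sets[[1L]][[g]], "")
  exclusive <- lapply(names(de_sets), function(gn) {
    g_only <- names(de_sets[[gn]])[names(de_sets[[gn]]) %in%
                                     all_de[n_called == 1L]]
    sort(g_only)
  })
  names(exclusive) <- names(de_sets)
  structure(list(shared_up = sort(shared[dir_of == "up"]),
                 shared_down = sort(shared[dir_of == "down"]),
                 exclusive = exclusive,
                 conflicting = sort(conflicting)),
            class = "deg_intersection")
}

#' @export
print.deg_intersection <- function(x, ...) {
  cat(sprintf("<deg_intersection> shared: %d up, %d down; conflicting: %d\n",
              length(x$shared_up), length(x$shared_down),
              length(x$conflicting)))
  for (g in names(x$exclusive))
    cat(sprintf("  exclusive %s: %d\n", g, length(x$exclusive[[g]])))
  invisible(x)
}

#' Tidy per-gene stage profiles for export
#'
#' @param means genes x stages matrix from [stage_means()].
#' @param genotype label recorded in the output.
#' @param genes optional subset of genes.
#' @return Tidy data.frame (gene_id, genotype, stage, mean_fpkm).
#' @export
stage_profiles <- function(means, genotype, genes = NULL) {
  if (!is.null(genes)) means <- means[genes, , drop = FALSE]
  data.frame(
    gene_id = rep(rownames(means), times = ncol(means)),
    genotype = genotype,
    stage = rep(colnames(means), each = nrow(means)),
    mean_fpkm = as.vector(means),
    stringsAsFactors = FALSE)
}
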