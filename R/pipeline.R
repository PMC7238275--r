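#' Run the pod-maturation inference pipeline end to end
#'
#' From per-genotype count matrices to the final direction-concordant
#' maturation gene set: FPKM normalization, replicate-concordance QC
#' (joint over all samples), per-genotype stage means and all-pairwise
#' fold-change DEG calls, cross-genotype intersection, and the
#' reference-species concordance filter.
#'
#' @param dataset a list shaped like [generate_dataset()] /
#'   [read_fixture_bundle()] output: `counts` (named list per genotype),
#'   `design`, `models`, `homologs`, `ref_up`, `ref_down`.
#' @param threshold fold-change cutoff (default 2).
#' @param pseudocount FPKM stabilizer (default 0.01).
#' @param qc_top size of the QC top-gene set (default 100).
#' @param run_qc perform replicate screening and drop flagged samples.
#' @return A list: `qc`, `design_used`, `fpkm` (per genotype),
#'   `stage_means`, `calls` (per genotype), `intersection`,
#'   `concordant`, `final_set`.
#' @export
run_pipeline <- function(dataset, threshold = 2, pseudocount = 0.01,
                         qc_top = 100L, run_qc = TRUE) {
  design <- dataset$design
  fpkm_all <- compute_fpkm(merged_counts(dataset), dataset$models)
  qc <- NULL
  if (run_qc) {
    qc <- qc_report(fpkm_all, design, k = qc_top)
    if (nrow(qc$rejected_samples))
      design <- drop_samples(design, qc$rejected_samples$sample_id)
  }
  genos <- names(dataset$counts)
  fpkm <- list(); means <- list(); calls <- list()
  for (g in genos) {
    ids <- design$sample_id[design$genotype == g]
    fpkm[[g]] <- em_subset(fpkm_all, j = ids)
    means[[g]] <- stage_means(fpkm[[g]], design, g)
    calls[[g]] <- call_degs(means[[g]], design, threshold, pseudocount)
  }
  inter <- intersect_genotypes(calls)
  conc <- concordant_shared_sets(inter, dataset$homologs,
                                 dataset$ref_up, dataset$ref_down)
  final <- final_maturation_set(conc$shared_up, conc$shared_down)
  list(qc = qc, design_used = design, fpkm = fpkm, stage_means = means,
       calls = calls, intersection = inter, concordant = conc,
       final_set = final)
}

#' Precision and sensitivity of DEG calls against a truth set
#'
#' @param called character vector of called gene ids.
#' @param truth character vector of planted gene ids.
#' @return Named numeric vector with `sensitivity`, `precision`,
#'   `tp`, `fp`, `fn`.
#' @export
call_performance <- function(called, truth) {
  tp <- length(intersect(called, truth))
  fp <- length(setdiff(called, truth))
  fn <- length(setdiff(truth, called))
  c(sensitivity = if (length(truth)) tp / (tp + fn) else NA_real_,
    precision = if (length(called)) tp / (tp + fp) else NA_real_,
    tp = tp, fp = fp, fn = fn)
}
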