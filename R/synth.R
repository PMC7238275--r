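#' Default parameters for the synthetic pod-maturation dataset
#'
#' The generator emulates a two-accession, five-stage bulk RNA-seq design:
#' 2 genotypes x 5 stages (ANT5, ANT10 immature; ANT20, ANT30, ANT45
#' mature) x 3 replicates.  Counts are negative binomial around lognormal
#' base means; planted maturation genes shift their mature-stage means by
#' `effect_ratio` in both genotypes, genotype-exclusive genes in one
#' genotype only, and background genes wobble within `background_ratio`.
#' One replicate of one (genotype, stage) is regenerated from a different
#' stage's mean vector — the discordant replicate the QC step must catch.
#'
#' Planted signal genes are sampled from the expressed fraction of the
#' transcriptome (base mean >= `min_planted_mean`): a fold-change
#' criterion can only ever recover detectably expressed genes, so planting
#' signal on near-zero genes would misstate the ground truth.
#'
#' @param n_genes total number of genes (>= 200).
#' @param genotypes two or more accession labels.
#' @param stages ordered stage labels.
#' @param immature_stages subset of `stages` forming the immature class.
#' @param n_replicates biological replicates per (genotype, stage).
#' @param frac_up,frac_down fractions of genes planted up-/down-regulated
#'   at maturation in both genotypes.
#' @param frac_exclusive fraction planted as maturation-responsive in a
#'   single genotype (per genotype).
#' @param effect_ratio mature/immature mean ratio of planted genes
#'   (must exceed 2, the DEG threshold).
#' @param frac_stage_markers fraction of genes that peak at one single
#'   stage (by `effect_ratio`).  Markers give every stage its own
#'   transcriptome signature — in real developmental series each stage is
#'   distinguishable, and replicate QC relies on that — yet they are
#'   never maturation DEGs, because a single-stage peak cannot clear the
#'   threshold in all mature-vs-immature pairs.  Markers are drawn from
#'   the top quartile of base means: stage-specific programs
#'   (photosynthesis, storage) sit among the most abundant transcripts,
#'   which is also what places them in the top-expressed QC gene set.
#' @param background_ratio upper bound on any pairwise stage-mean ratio of
#'   background genes (must stay below 2).
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 selects deterministic noise-free counts
#'   `round(mu)`.
#' @param base_meanlog,base_sdlog lognormal parameters of per-gene base
#'   means.
#' @param genotype_sdlog lognormal sd of the per-gene accession divergence
#'   factor (contrasting accessions differ substantially genome-wide).
#' @param depth_sdlog lognormal sd of per-sample sequencing-depth factors.
#' @param min_planted_mean minimum base mean for planted signal genes.
#' @param min_detect detection limit in expected counts: a background or
#'   marker gene whose genotype-level mean falls below this is emitted as
#'   absent (all-zero) in that genotype.  Real count matrices do not
#'   contain flat genes trickling fractional counts — a gene is either
#'   detected or it is not — and without this rule integer rounding at
#'   the detection boundary can fabricate presence/absence patterns that
#'   read as genuine on/off differential expression.
#' @param discordant logical; plant one discordant replicate.
#' @param homolog_concordant_frac,homolog_discordant_frac fractions of
#'   planted maturation genes whose reference-species homolog lands in the
#'   same-direction / opposite-direction reference list.
#' @param n_motifs number of transcription-factor motifs emitted.
#' @param n_planted_tfs how many of them have binding sites planted in
#'   maturation-gene promoters.
#' @param motif_width PWM width in bp.
#' @param target_frac fraction of maturation genes assigned as targets of
#'   each planted TF.
#' @param planting_rate probability a target promoter receives a motif
#'   insertion.
#' @param background_rate insertion probability for non-target promoters.
#' @param promoter_upstream,promoter_downstream promoter window around the
#'   TSS, in bp.
#' @param n_terms number of annotation terms (one of them planted as
#'   enriched in the up-regulated set).
#' @param with_sequences generate genome/promoters/motifs (disable for
#'   speed when only expression is needed).
#' @return A named list of generator parameters.
#' @export
synth_params <- function(n_genes = 2000L,
                         genotypes = c("PMB0225", "PHA1037"),
                         stages = c("ANT5", "ANT10", "ANT20", "ANT30", "ANT45"),
                         immature_stages = c("ANT5", "ANT10"),
                         n_replicates = 3L,
                         frac_up = 0.04,
                         frac_down = 0.05,
                         frac_exclusive = 0.03,
                         effect_ratio = 4,
                         frac_stage_markers = 0.1,
                         background_ratio = 1.3,
                         dispersion = 0.05,
                         base_meanlog = log(100),
                         base_sdlog = 1.5,
                         genotype_sdlog = 0.4,
                         depth_sdlog = 0.1,
                         min_planted_mean = 5,
                         min_detect = 2,
                         discordant = TRUE,
                         homolog_concordant_frac = 0.6,
                         homolog_discordant_frac = 0.1,
                         n_motifs = 4L,
                         n_planted_tfs = 2L,
                         motif_width = 10L,
                         target_frac = 0.6,
                         planting_rate = 0.9,
                         background_rate = 0.05,
                         promoter_upstream = 500L,
                         promoter_downstream = 100L,
                         n_terms = 20L,
                         with_sequences = TRUE) {
  p <- as.list(environment())
  validate_synth_params(p)
  p
}

validate_synth_params <- function(p) {
  if (p$n_genes < 200L) stop("n_genes must be >= 200")
  if (p$effect_ratio <= 2) stop("effect_ratio must exceed the DEG threshold 2")
  if (p$background_ratio >= 2) stop("background_ratio must stay below 2")
  if (p$effect_ratio <= p$background_ratio)
    stop("infeasible params: effect_ratio <= background_ratio")
  if (!all(p$immature_stages %in% p$stages))
    stop("immature_stages must be a subset of stages")
  if (length(setdiff(p$stages, p$immature_stages)) < 1L)
    stop("at least one mature stage is required")
  if (p$dispersion < 0) stop("dispersion must be >= 0")
  if (p$n_planted_tfs > p$n_motifs) stop("n_planted_tfs exceeds n_motifs")
  invisible(p)
}

#' Generate a synthetic pod-maturation dataset with ground truth
#'
#' Produces per-genotype count matrices, the sample design, gene models,
#' a toy genome with promoters carrying planted motif insertions, PWMs,
#' a TF-to-motif map, a bean-to-reference homolog map with reference
#' up/down maturation lists, a term annotation, and a manifest recording
#' every planted signal (the acceptance surface for the whole pipeline).
#'
#' All randomness flows from one `set.seed(seed)` call, so identical
#' seeds regenerate byte-identical datasets.
#'
#' @param params parameter list from [synth_params()].
#' @param seed integer seed.
#' @return A list with elements `counts` (named list of count
#'   [expression_matrix()] per genotype), `design`, `models`, `genome`
#'   (`DNAStringSet` or NULL), `promoters`, `pwms`, `tf_map`, `homologs`,
#'   `ref_up`, `ref_down`, `annotation`, `conserved`, and `manifest`.
#' @export
generate_dataset <- function(params = synth_params(), seed = 1L) {
  p <- validate_synth_params(params)
  set.seed(as.integer(seed))

  n <- p$n_genes
  gene_ids <- sprintf("Phvul.SYN%05d", seq_len(n))
  stages <- p$stages
  mature_stages <- setdiff(stages, p$immature_stages)
  genos <- p$genotypes

  # --- role assignment -----------------------------------------------------
  base_mean <- exp(rnorm(n, p$base_meanlog, p$base_sdlog))
  names(base_mean) <- gene_ids
  expressed <- gene_ids[base_mean >= p$min_planted_mean]
  n_up <- round(p$frac_up * n); n_down <- round(p$frac_down * n)
  n_exc <- round(p$frac_exclusive * n)
  need <- n_up + n_down + n_exc * length(genos)
  if (length(expressed) < need)
    stop("too few expressed genes to host the planted signal")
  picked <- sample(expressed, need)
  planted_up <- sort(picked[seq_len(n_up)])
  planted_down <- sort(picked[n_up + seq_len(n_down)])
  rest <- picked[n_up + n_down + seq_len(n_exc * length(genos))]
  exclusive <- lapply(seq_along(genos), function(i)
    sort(rest[(i - 1L) * n_exc + seq_len(n_exc)]))
  names(exclusive) <- genos
  exclusive_dir <- lapply(genos, function(g)
    sample(c("up", "down"), n_exc, replace = TRUE))
  names(exclusive_dir) <- genos
  planted_all <- c(planted_up, planted_down)

  # stage markers: one peak stage each, drawn from abundant non-planted genes
  n_mark <- round(p$frac_stage_markers * n)
  mark_pool <- setdiff(gene_ids[base_mean >= quantile(base_mean, 0.75)],
                       picked)
  n_mark <- min(n_mark, length(mark_pool))
  markers <- sort(sample(mark_pool, n_mark))
  marker_stage <- setNames(sample(stages, n_mark, replace = TRUE), markers)

  # --- per-stage mean structure -------------------------------------------
  # background wobble shared across genotypes (a conserved developmental
  # program); max pairwise ratio bounded by background_ratio
  half <- log(p$background_ratio) / 2
  wob <- matrix(exp(runif(n * length(stages), -half, half)), n,
                dimnames = list(gene_ids, stages))
  if (n_mark)
    wob[cbind(match(markers, gene_ids), match(marker_stage, stages))] <-
      wob[cbind(match(markers, gene_ids), match(marker_stage, stages))] *
      p$effect_ratio
  stagefac <- lapply(genos, function(g) {
    f <- wob
    f[planted_up, ] <- 1
    f[planted_up, mature_stages] <- p$effect_ratio
    f[planted_down, ] <- 1
    f[planted_down, p$immature_stages] <- p$effect_ratio
    ex <- exclusive[[g]]
    dir <- exclusive_dir[[g]]
    f[ex, ] <- 1
    up_ex <- ex[dir == "up"]; dn_ex <- ex[dir == "down"]
    f[up_ex, mature_stages] <- p$effect_ratio
    f[dn_ex, p$immature_stages] <- p$effect_ratio
    # exclusive genes of the OTHER genotypes stay flat in this one
    for (og in setdiff(genos, g)) f[exclusive[[og]], ] <- 1
    f
  })
  names(stagefac) <- genos
  genofac <- matrix(exp(rnorm(n * length(genos), 0, p$genotype_sdlog)), n,
                    dimnames = list(gene_ids, genos))

  # --- design and discordant replicate ------------------------------------
  design <- expand.grid(replicate = seq_len(p$n_replicates), stage = stages,
                        genotype = genos, stringsAsFactors = FALSE)
  design <- design[, c("genotype", "stage", "replicate")]
  design$sample_id <- sprintf("%s_%s_R%d", design$genotype, design$stage,
                              design$replicate)
  design$maturity <- ifelse(design$stage %in% p$immature_stages,
                            "immature", "mature")
  design <- validate_sample_design(
    design[, c("sample_id", "genotype", "stage", "replicate", "maturity")])

  discordant_id <- NA_character_
  donor_stage <- NA_character_
  if (isTRUE(p$discordant)) {
    dg <- sample(genos, 1L)
    ds <- sample(stages, 1L)
    dr <- sample(seq_len(p$n_replicates), 1L)
    # the symptom in real data is a replicate clustering with samples of a
    # different stage; draw the donor from the opposite maturity class
    own_mat <- ds %in% p$immature_stages
    pool <- if (own_mat) mature_stages else p$immature_stages
    donor_stage <- sample(pool, 1L)
    discordant_id <- sprintf("%s_%s_R%d", dg, ds, dr)
  }

  # --- counts --------------------------------------------------------------
  depth <- exp(rnorm(nrow(design), 0, p$depth_sdlog))
  names(depth) <- design$sample_id
  draw_counts <- function(mu) {
    if (p$dispersion == 0) round(mu)
    else rnbinom(length(mu), mu = mu, size = 1 / p$dispersion)
  }
  counts <- list()
  signal_genes <- c(planted_all, unlist(exclusive))
  for (g in genos) {
    dsub <- design[design$genotype == g, ]
    m <- matrix(0, n, nrow(dsub), dimnames = list(gene_ids, dsub$sample_id))
    undetected <- !(gene_ids %in% signal_genes) &
      base_mean * genofac[, g] < p$min_detect
    for (i in seq_len(nrow(dsub))) {
      st <- dsub$stage[i]
      if (identical(dsub$sample_id[i], discordant_id)) st <- donor_stage
      mu <- base_mean * genofac[, g] * stagefac[[g]][, st] *
        depth[dsub$sample_id[i]]
      mu[undetected] <- 0
      m[, i] <- draw_counts(mu)
    }
    storage.mode(m) <- "double"
    counts[[g]] <- expression_matrix(m, "counts")
  }

  # --- gene models ---------------------------------------------------------
  margin <- p$promoter_upstream + p$promoter_downstream + 100L
  glen <- sample(600:3000, n, replace = TRUE)
  slot <- glen + 2L * margin
  gstart <- cumsum(c(0L, slot[-n])) + margin       # 0-based gene starts
  strand <- rep_len(c("+", "-"), n)
  models <- data.frame(
    gene_id = gene_ids, chrom = "Chr01", strand = strand,
    tss = ifelse(strand == "+", gstart, gstart + glen - 1L),
    length_bp = glen, stringsAsFactors = FALSE)

  # --- sequences, motifs, plantings ---------------------------------------
  genome <- NULL; promoters <- NULL; pwms <- list(); tf_map <- NULL
  conserved <- NULL
  planted_tfs <- character(0); tf_targets <- list()
  if (isTRUE(p$with_sequences)) {
    W <- p$motif_width
    plen <- p$promoter_upstream + p$promoter_downstream
    alph <- c("A", "C", "G", "T")
    motif_ids <- sprintf("MOTIF%02d", seq_len(p$n_motifs))
    tf_ids <- sprintf("TF%02d", seq_len(p$n_motifs))
    tf_map <- data.frame(tf_id = tf_ids, motif_id = motif_ids,
                         stringsAsFactors = FALSE)
    consensus <- character(p$n_motifs)
    for (k in seq_len(p$n_motifs)) {
      cons <- sample(alph, W, replace = TRUE)
      mat <- matrix(0.05, W, 4, dimnames = list(NULL, alph))
      mat[cbind(seq_len(W), match(cons, alph))] <- 0.85
      pwms[[k]] <- pwm(motif_ids[k], mat)
      consensus[k] <- paste(cons, collapse = "")
    }
    planted_tfs <- tf_ids[seq_len(p$n_planted_tfs)]

    prom_chr <- matrix(sample(alph, n * plen, replace = TRUE), n, plen)
    cons_rows <- list()
    for (k in seq_len(p$n_planted_tfs)) {
      targ <- sort(sample(planted_all, round(p$target_frac * length(planted_all))))
      tf_targets[[tf_ids[k]]] <- targ
      hit <- runif(n) < ifelse(gene_ids %in% targ, p$planting_rate,
                               p$background_rate)
      for (gi in which(hit)) {
        off <- sample.int(plen - W + 1L, 1L) - 1L
        prom_chr[gi, off + seq_len(W)] <- strsplit(consensus[k], "")[[1L]]
        cons_rows[[length(cons_rows) + 1L]] <-
          data.frame(gene_id = gene_ids[gi], start = off, end = off + W,
                     stringsAsFactors = FALSE)
      }
    }
    conserved <- if (length(cons_rows)) do.call(rbind, cons_rows)
    else data.frame(gene_id = character(0), start = integer(0),
                    end = integer(0))
    prom_str <- apply(prom_chr, 1L, paste, collapse = "")
    promoters <- Biostrings::DNAStringSet(setNames(prom_str, gene_ids))

    # assemble the genome so that extract_promoters() returns exactly the
    # planted promoter sequences
    chrlen <- sum(slot)
    chr <- sample(alph, chrlen, replace = TRUE)
    up <- p$promoter_upstream; down <- p$promoter_downstream
    for (gi in seq_len(n)) {
      if (strand[gi] == "+") {
        w0 <- models$tss[gi] - up
        chr[w0 + seq_len(plen)] <- prom_chr[gi, ]
      } else {
        w0 <- models$tss[gi] - down + 1L
        rc <- rev(c(A = "T", C = "G", G = "C", T = "A")[prom_chr[gi, ]])
        chr[w0 + seq_len(plen)] <- rc
      }
    }
    genome <- Biostrings::DNAStringSet(setNames(paste(chr, collapse = ""),
                                                "Chr01"))
  }

  # --- homologs and reference lists ----------------------------------------
  n_plant <- length(planted_all)
  dir_all <- c(rep("up", length(planted_up)), rep("down", length(planted_down)))
  roll <- runif(n_plant)
  conc <- roll < p$homolog_concordant_frac
  disc <- !conc & roll < p$homolog_concordant_frac + p$homolog_discordant_frac
  ref_id <- sprintf("AT1G%05d", seq_len(n_plant) * 10L)
  homolog_rows <- data.frame(bean_gene_id = planted_all[conc | disc],
                             ref_gene_id = ref_id[conc | disc],
                             stringsAsFactors = FALSE)
  ref_dir <- ifelse(conc, dir_all,
                    ifelse(dir_all == "up", "down", "up"))[conc | disc]
  ref_up <- sort(homolog_rows$ref_gene_id[ref_dir == "up"])
  ref_down <- sort(homolog_rows$ref_gene_id[ref_dir == "down"])
  # background homologs pointing outside the reference lists
  bg_pool <- setdiff(gene_ids, c(planted_all, unlist(exclusive)))
  n_bg_hom <- min(length(bg_pool), round(0.2 * n))
  bg_bean <- sample(bg_pool, n_bg_hom)
  bg_ref <- sprintf("AT5G%05d", seq_len(n_bg_hom) * 10L)
  homologs <- rbind(homolog_rows,
                    data.frame(bean_gene_id = bg_bean, ref_gene_id = bg_ref,
                               stringsAsFactors = FALSE))
  homologs <- homologs[order(homologs$bean_gene_id, homologs$ref_gene_id), ]
  rownames(homologs) <- NULL
  # pad the reference lists with unmapped reference genes
  ref_up <- sort(c(ref_up, sprintf("AT9G%05d", 1:20 * 10L)))
  ref_down <- sort(c(ref_down, sprintf("AT9G%05d", 21:40 * 10L)))

  # --- term annotation ------------------------------------------------------
  term_ids <- sprintf("TERM%04d", seq_len(p$n_terms))
  planted_term <- term_ids[1L]
  ann_rows <- list(
    data.frame(term_id = planted_term,
               gene_id = c(sample(planted_up, max(1L, round(0.6 * length(planted_up)))),
                           sample(gene_ids, round(0.02 * n))),
               stringsAsFactors = FALSE))
  for (t in term_ids[-1L])
    ann_rows[[length(ann_rows) + 1L]] <-
      data.frame(term_id = t, gene_id = sample(gene_ids, round(0.05 * n)),
                 stringsAsFactors = FALSE)
  annotation <- unique(do.call(rbind, ann_rows))
  annotation <- annotation[order(annotation$term_id, annotation$gene_id), ]
  rownames(annotation) <- NULL

  manifest <- list(
    planted_up = planted_up,
    planted_down = planted_down,
    genotype_exclusive = exclusive,
    discordant_replicate = discordant_id,
    donor_stage = donor_stage,
    stage_markers = as.list(marker_stage),
    planted_enriched_tfs = planted_tfs,
    planted_tf_targets = tf_targets,
    homolog_concordant = sort(planted_all[conc]),
    homolog_discordant = sort(planted_all[disc]),
    planted_term = planted_term,
    seed = as.integer(seed),
    params = p)

  list(counts = counts, design = design, models = models, genome = genome,
       promoters = promoters, pwms = pwms, tf_map = tf_map,
       homologs = homologs, ref_up = ref_up, ref_down = ref_down,
       annotation = annotation, conserved = conserved, manifest = manifest)
}

#' Bind per-genotype count matrices into one matrix
#'
#' @param dataset output of [generate_dataset()].
#' @return A single [expression_matrix()] of counts over all samples.
#' @export
merged_counts <- function(dataset) {
  v <- do.call(cbind, lapply(dataset$counts, unclass))
  expression_matrix(v, "counts")
}

#' Write a synthetic dataset to a directory of standard-format files
#'
#' Emits TSV count matrices (one per genotype), the design table, BED6
#' gene models, genome and promoter FASTA, a MEME-format motif file, the
#' TF map, homolog map, reference maturation lists, term annotation,
#' promoter-local conserved intervals, and the ground-truth manifest as
#' JSON.  All files are plain text and re-readable by the package's
#' readers.
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
write_fixture_bundle <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  pth <- function(f) file.path(dir, f)
  for (g in names(dataset$counts)) {
    f <- pth(sprintf("counts_%s.tsv", g))
    write_expression_matrix(dataset$counts[[g]], f)
    paths <- c(paths, f)
  }
  write_sample_design(dataset$design, pth("design.tsv"))
  write_gene_models_bed(dataset$models, pth("genes.bed"))
  tsv <- function(d, f) {
    write.table(d, pth(f), sep = "\t", quote = FALSE, row.names = FALSE)
    pth(f)
  }
  paths <- c(paths, pth("design.tsv"), pth("genes.bed"),
             tsv(dataset$homologs, "homologs.tsv"),
             tsv(data.frame(
               ref_gene_id = c(dataset$ref_up, dataset$ref_down),
               direction = c(rep("up", length(dataset$ref_up)),
                             rep("down", length(dataset$ref_down)))),
               "reference_maturation.tsv"),
             tsv(dataset$annotation, "annotation.tsv"))
  if (!is.null(dataset$genome)) {
    Biostrings::writeXStringSet(dataset$genome, pth("genome.fa"), width = 80L)
    Biostrings::writeXStringSet(dataset$promoters, pth("promoters.fa"),
                                width = 80L)
    write_meme(dataset$pwms, pth("motifs.meme"))
    paths <- c(paths, pth("genome.fa"), pth("promoters.fa"),
               pth("motifs.meme"), tsv(dataset$tf_map, "tf_map.tsv"),
               tsv(dataset$conserved, "conserved.tsv"))
  }
  manifest <- dataset$manifest
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  paths <- c(paths, pth("manifest.json"))
  invisible(paths)
}

#' Read a fixture bundle back from disk
#'
#' @param dir directory written by [write_fixture_bundle()].
#' @return A list shaped like the output of [generate_dataset()] (PWMs
#'   and sequences are included when present in the bundle).
#' @export
read_fixture_bundle <- function(dir) {
  pth <- function(f) file.path(dir, f)
  design <- read_sample_design(pth("design.tsv"))
  genos <- unique(design$genotype)
  counts <- lapply(genos, function(g)
    read_expression_matrix(pth(sprintf("counts_%s.tsv", g)), "counts"))
  names(counts) <- genos
  models <- read_gene_models(pth("genes.bed"))
  refs <- read.delim(pth("reference_maturation.tsv"), stringsAsFactors = FALSE)
  out <- list(
    counts = counts, design = design, models = models,
    homologs = read.delim(pth("homologs.tsv"), stringsAsFactors = FALSE),
    ref_up = refs$ref_gene_id[refs$direction == "up"],
    ref_down = refs$ref_gene_id[refs$direction == "down"],
    annotation = read.delim(pth("annotation.tsv"), stringsAsFactors = FALSE),
    manifest = jsonlite::read_json(pth("manifest.json"), simplifyVector = TRUE))
  if (file.exists(pth("genome.fa"))) {
    out$genome <- Biostrings::readDNAStringSet(pth("genome.fa"))
    out$promoters <- Biostrings::readDNAStringSet(pth("promoters.fa"))
    out$pwms <- read_meme(pth("motifs.meme"))
    out$tf_map <- read.delim(pth("tf_map.tsv"), stringsAsFactors = FALSE)
    out$conserved <- read.delim(pth("conserved.tsv"), stringsAsFactors = FALSE)
  }
  out
}
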