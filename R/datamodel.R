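#' podmat: pod-maturation transcriptome inference for common bean
#'
#' Tools to identify genes involved in pod maturation from stage-wise
#' bulk RNA-seq designs: replicate-concordance QC, all-pairwise
#' fold-change DEG classification between immature and mature stages,
#' cross-genotype intersection, direction-concordant comparison against a
#' reference species, promoter PWM scanning, over-representation
#' statistics, and correspondence-analysis ordination.  A synthetic-data
#' generator with a ground-truth manifest supports end-to-end validation.
#'
#' @importFrom stats phyper rnbinom rnorm runif setNames cutree quantile
#' @importFrom utils read.delim write.table head
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement subseq width
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# SampleDesign
# ---------------------------------------------------------------------------

#' Construct and validate a sample design table
#'
#' A sample design ties every sequencing sample to its genotype,
#' developmental stage, replicate number and maturity class.  The default
#' stage labels follow the days-after-anthesis convention for common bean
#' pods (ANT5, ANT10 immature; ANT20, ANT30, ANT45 mature).
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param genotype character vector, e.g. `"PMB0225"`, `"PHA1037"`.
#' @param stage character vector of stage labels.
#' @param replicate integer vector of replicate numbers within
#'   (genotype, stage).
#' @param maturity character vector, each `"immature"` or `"mature"`;
#'   the stage to maturity mapping must be consistent across genotypes.
#' @return A `data.frame` of class `sample_design` with one row per sample.
#' @examples
#' sample_design(
#'   sample_id = c("g1_ANT5_1", "g1_ANT20_1"),
#'   genotype  = c("g1", "g1"),
#'   stage     = c("ANT5", "ANT20"),
#'   replicate = c(1L, 1L),
#'   maturity  = c("immature", "mature"))
#' @export
sample_design <- function(sample_id, genotype, stage, replicate, maturity) {
  d <- data.frame(
    sample_id = as.character(sample_id),
    genotype  = as.character(genotype),
    stage     = as.character(stage),
    replicate = as.integer(replicate),
    maturity  = as.character(maturity),
    stringsAsFactors = FALSE)
  validate_sample_design(d)
}

validate_sample_design <- function(d) {
  required <- c("sample_id", "genotype", "stage", "replicate", "maturity")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("sample design lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(d$sample_id))
    stop("duplicate sample_id in design: ",
         paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  if (!all(d$maturity %in% c("immature", "mature")))
    stop("maturity must be 'immature' or 'mature'")
  # each stage must map to exactly one maturity class, across genotypes
  map <- unique(d[, c("stage", "maturity")])
  if (anyDuplicated(map$stage))
    stop("inconsistent stage -> maturity mapping")
  if (length(unique(d$maturity)) < 2L)
    stop("design must contain at least one immature and one mature stage")
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Read a sample design table from TSV
#'
#' Expects columns `sample_id`, `genotype`, `stage`, `replicate`,
#' `maturity`.
#'
#' @param path path to a tab-separated file.
#' @return A validated [sample_design()] data frame.
#' @export
read_sample_design <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_design(d)
}

#' @rdname read_sample_design
#' @param design a `sample_design`.
#' @export
write_sample_design <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# ExpressionMatrix
# ---------------------------------------------------------------------------

#' Construct an expression matrix with a unit tag
#'
#' Wraps a genes x samples numeric matrix together with its unit, one of
#' `"counts"` (nonnegative integers), `"fpkm"` or `"log1p_fpkm"`
#' (nonnegative reals).  Gene identifiers are the rownames and must be
#' unique; sample identifiers are the colnames.
#'
#' @param values numeric matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @param unit `"counts"`, `"fpkm"` or `"log1p_fpkm"`.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, unit = c("counts", "fpkm", "log1p_fpkm")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (nrow(values) > 0 && is.null(rownames(values)))
    stop("gene ids (rownames) are required")
  if (nrow(values) > 0 && anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyNA(values)) stop("expression values contain NA")
  if (nrow(values) > 0 && ncol(values) > 0 && min(values) < 0)
    stop("negative expression values are not allowed")
  if (unit == "counts" && length(values) && any(values != floor(values)))
    stop("unit 'counts' requires integer values")
  structure(values, unit = unit, class = c("expression_matrix", "matrix", "array"))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples, unit = %s\n",
              nrow(x), ncol(x), attr(x, "unit")))
  if (nrow(x)) print(head(unclass(x), 4L))
  invisible(x)
}

#' Unit tag of an expression matrix
#' @param m an `expression_matrix`.
#' @return `"counts"`, `"fpkm"` or `"log1p_fpkm"`.
#' @export
em_unit <- function(m) attr(m, "unit")

# matrix subsetting drops our attributes; provide a helper that keeps them
em_subset <- function(m, i = NULL, j = NULL) {
  u <- em_unit(m)
  v <- unclass(m)
  if (!is.null(i)) v <- v[i, , drop = FALSE]
  if (!is.null(j)) v <- v[, j, drop = FALSE]
  expression_matrix(v, u)
}

#' Read an expression matrix from TSV
#'
#' The first column holds gene identifiers, the header row sample
#' identifiers, and the body is numeric.  Duplicate gene ids and
#' malformed numeric cells are rejected with informative errors.
#'
#' @param path path to a tab-separated file.
#' @param unit unit of the stored values; recorded, never guessed.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, unit = c("counts", "fpkm", "log1p_fpkm")) {
  unit <- match.arg(unit)
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  colClasses = "character")
  if (ncol(d) < 1L) stop("matrix file has no columns: ", path)
  gene_ids <- d[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  body <- d[, -1L, drop = FALSE]
  vals <- matrix(NA_real_, nrow = nrow(body), ncol = ncol(body),
                 dimnames = list(gene_ids, names(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]))
    if (length(bad))
      stop(sprintf("malformed numeric cell at row '%s', column '%s' in %s",
                   gene_ids[bad[1L]], names(body)[j], path))
    vals[, j] <- v
  }
  expression_matrix(vals, unit)
}

#' Write an expression matrix to TSV
#'
#' @param m an [expression_matrix()].
#' @param path output path; first column is `gene_id`.
#' @param digits significant digits used for real-valued units; counts are
#'   written as integers.
#' @export
write_expression_matrix <- function(m, path, digits = 10L) {
  v <- unclass(m)
  body <- if (em_unit(m) == "counts") {
    matrix(format(v, scientific = FALSE, trim = TRUE), nrow = nrow(v))
  } else {
    matrix(formatC(v, digits = digits, format = "g"), nrow = nrow(v))
  }
  d <- data.frame(gene_id = rownames(v), body, stringsAsFactors = FALSE,
                  check.names = FALSE)
  names(d) <- c("gene_id", colnames(v))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# FPKM and transforms
# ---------------------------------------------------------------------------

#' Compute FPKM from a count matrix
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `fpkm[g, s] = counts[g, s] * 1e9 / (length_bp[g] * colsum[s])`.  The
#' per-sample "million mapped fragments" denominator is the column sum of
#' the supplied count matrix.  A sample with zero total yields an
#' all-zero column.
#'
#' @param counts an [expression_matrix()] with unit `"counts"`.
#' @param models a gene-model table from [read_gene_models()] (or any
#'   data frame with `gene_id` and `length_bp`); every gene in `counts`
#'   must have a length.
#' @return An [expression_matrix()] with unit `"fpkm"`.
#' @export
compute_fpkm <- function(counts, models) {
  if (em_unit(counts) != "counts") stop("compute_fpkm expects unit 'counts'")
  len <- setNames(models$length_bp, models$gene_id)
  missing <- setdiff(rownames(counts), names(len))
  if (length(missing))
    stop("missing gene length for: ", paste(missing, collapse = ", "))
  v <- unclass(counts)
  colsum <- colSums(v)
  denom <- outer(len[rownames(v)], colsum)
  f <- ifelse(denom > 0, v * 1e9 / denom, 0)
  dimnames(f) <- dimnames(v)
  expression_matrix(f, "fpkm")
}

#' Natural-log transform log(FPKM + 1)
#'
#' @param m an [expression_matrix()] with unit `"fpkm"`.
#' @return An [expression_matrix()] with unit `"log1p_fpkm"`.
#' @export
log1p_transform <- function(m) {
  if (em_unit(m) != "fpkm") stop("log1p_transform expects unit 'fpkm'")
  v <- log1p(unclass(m))
  expression_matrix(v, "log1p_fpkm")
}

# ---------------------------------------------------------------------------
# Gene models
# ---------------------------------------------------------------------------

#' Read gene models from GFF3 or BED6
#'
#' Coordinates are converted to the package-internal 0-based, half-open
#' convention at this boundary.  The transcription start site (TSS) of a
#' plus-strand gene is the 0-based start of its span; for a minus-strand
#' gene it is `end - 1`.  Gene length is the merged (union) exon span for
#' GFF3 input and the interval length for BED input.
#'
#' @param path path ending in `.gff`, `.gff3` (GFF3) or `.bed` (BED6).
#' @return A `data.frame` with columns `gene_id`, `chrom`, `strand`,
#'   `tss` (0-based) and `length_bp`.
#' @export
read_gene_models <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    read_gene_models_gff(gr)
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    if (any(as.character(GenomicRanges::strand(gr)) == "*"))
      stop("BED gene models must carry a strand")
    ids <- gr$name
    if (anyDuplicated(ids)) stop("duplicate gene ids in ", path)
    models_frame(ids, gr)
  } else stop("unsupported gene-model format: ", path)
}

read_gene_models_gff <- function(gr) {
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (!length(genes)) stop("no gene records in GFF3 input")
  ids <- genes$ID
  if (is.null(ids) || anyNA(ids)) stop("GFF3 gene records lack ID attributes")
  if (anyDuplicated(ids)) stop("duplicate gene ids in GFF3 input")
  if (any(as.character(GenomicRanges::strand(genes)) == "*"))
    stop("GFF3 gene records must carry a strand")
  m <- models_frame(ids, genes)
  # length: union of exon intervals per gene when exons are present
  exons <- gr[type == "exon"]
  if (length(exons)) {
    parent <- as.character(unlist(exons$Parent))
    # exon Parent may point at an mRNA; map mRNA -> gene
    mrna <- gr[type == "mRNA"]
    if (length(mrna)) {
      m2g <- setNames(as.character(unlist(mrna$Parent)), mrna$ID)
      hit <- parent %in% names(m2g)
      parent[hit] <- m2g[parent[hit]]
    }
    keep <- parent %in% ids
    if (any(keep)) {
      byg <- split(exons[keep], parent[keep])
      ulen <- vapply(byg, function(g) sum(IRanges::width(IRanges::reduce(IRanges::ranges(g)))), 0L)
      m$length_bp[match(names(ulen), m$gene_id)] <- as.integer(ulen)
    }
  }
  m
}

models_frame <- function(ids, gr) {
  st <- as.character(GenomicRanges::strand(gr))
  start0 <- GenomicRanges::start(gr) - 1L      # to 0-based half-open
  end0 <- GenomicRanges::end(gr)               # exclusive
  data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = st,
    tss = ifelse(st == "+", start0, end0 - 1L),
    length_bp = as.integer(end0 - start0),
    stringsAsFactors = FALSE)
}

#' Write gene models as BED6
#'
#' Emits one interval per gene spanning `length_bp` from the TSS in the
#' transcription direction, which round-trips through
#' [read_gene_models()] for single-exon models.
#'
#' @param models gene-model data frame.
#' @param path output `.bed` path.
#' @export
write_gene_models_bed <- function(models, path) {
  start0 <- ifelse(models$strand == "+", models$tss,
                   models$tss - models$length_bp + 1L)
  d <- data.frame(models$chrom, start0, start0 + models$length_bp,
                  models$gene_id, 0L, models$strand)
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
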