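#' Select the common top-expressed genes across all samples
#'
#' Finds the smallest rank depth R such that the intersection of every
#' sample's top-R genes has at least `k` members, then returns the `k` of
#' those genes with the highest mean expression.  Ranking ties within a
#' sample and mean-expression ties are broken lexicographically by gene
#' id, so the selection is deterministic.
#'
#' @param m an [expression_matrix()]; ranking uses the stored values
#'   (conventionally log1p FPKM, the clustering input).
#' @param design optional [sample_design()]; when given, only its samples
#'   are used.
#' @param k number of genes to select (default 100).
#' @return Character vector of `k` gene ids.
#' @export
select_common_top_genes <- function(m, design = NULL, k = 100L) {
  v <- unclass(m)
  if (!is.null(design)) v <- v[, design$sample_id, drop = FALSE]
  if (k > nrow(v)) stop("k exceeds the number of genes")
  ids <- rownames(v)
  ord_id <- order(ids)                      # lexicographic tiebreak
  # rank of each gene within each sample (1 = highest expression)
  rk <- apply(v[ord_id, , drop = FALSE], 2L, function(x)
    rank_desc_stable(x))
  maxrank <- apply(rk, 1L, max)
  if (sum(maxrank <= nrow(v)) < k)
    stop("degenerate matrix: no rank depth yields ", k, " common genes")
  Rstar <- sort(maxrank)[k]
  common <- ids[ord_id][maxrank <= Rstar]
  mu <- rowMeans(v[common, , drop = FALSE])
  common[order(-mu, common)][seq_len(k)]
}

# dense-free stable descending rank: position in the ordering by
# decreasing value, input already sorted by the tiebreak key
rank_desc_stable <- function(x) {
  o <- order(-x)
  r <- integer(length(x))
  r[o] <- seq_along(x)
  r
}

#' Chebyshev (maximum) distance between two samples
#'
#' @param m an [expression_matrix()].
#' @param a,b sample ids.
#' @param genes optional gene subset over which to take the maximum.
#' @return The maximum absolute per-gene difference.
#' @export
max_distance <- function(m, a, b, genes = NULL) {
  v <- unclass(m)
  for (s in c(a, b)) if (!s %in% colnames(v)) stop("unknown sample: ", s)
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  max(abs(v[, a] - v[, b]))
}

chebyshev_matrix <- function(m, genes = NULL) {
  v <- unclass(m)
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  ns <- ncol(v)
  d <- matrix(0, ns, ns, dimnames = list(colnames(v), colnames(v)))
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns)
    d[i, j] <- d[j, i] <- max(abs(v[, i] - v[, j]))
  d
}

#' UPGMA (average-linkage) agglomerative clustering
#'
#' Repeatedly merges the closest pair of clusters; the distance from a
#' merged cluster to any other is the size-weighted mean of its members'
#' distances, so cluster-to-cluster distance always equals the plain mean
#' of the original pairwise distances between their members.  Ties are
#' broken by the lexicographically smallest pair of cluster
#' representatives (the smallest sample id each cluster contains).
#'
#' @param dist symmetric numeric matrix with zero diagonal and row/column
#'   names, or a `dist` object with labels.
#' @return An object of class `c("podmat_tree", "hclust")`: `merge`,
#'   `height`, `order`, `labels` in `stats::hclust()` layout, usable with
#'   [stats::cutree()].
#' @export
average_linkage <- function(dist) {
  d <- as.matrix(dist)
  if (anyNA(d)) stop("NaN/NA in distance matrix")
  if (is.null(rownames(d))) stop("distance matrix must carry labels")
  if (max(abs(d - t(d))) > 0 || any(diag(d) != 0))
    stop("distance matrix must be symmetric with zero diagonal")
  labels <- rownames(d)
  n <- length(labels)
  if (n < 2L) stop("need at least two leaves")
  active <- seq_len(n)
  size <- rep(1L, n)
  node <- -seq_len(n)                         # hclust leaf coding
  rep_id <- labels                            # smallest member id
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    # closest active pair, ties by smallest (rep_i, rep_j)
    best <- NULL; bestd <- Inf
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1L):length(active)) {
        i <- active[ii]; j <- active[jj]
        dij <- d[i, j]
        key <- sort(c(rep_id[i], rep_id[j]))
        if (dij < bestd ||
            (dij == bestd && (key[1L] < best$key[1L] ||
              (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
          bestd <- dij
          best <- list(i = i, j = j, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort_merge_pair(node[i], node[j])
    height[step] <- bestd
    # Lance-Williams update for UPGMA
    for (kk in setdiff(active, c(i, j))) {
      d[i, kk] <- d[kk, i] <-
        (size[i] * d[i, kk] + size[j] * d[j, kk]) / (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    rep_id[i] <- min(rep_id[i], rep_id[j])
    node[i] <- step
    active <- setdiff(active, j)
  }
  structure(list(merge = merge, height = height,
                 order = leaf_order(merge, n), labels = labels,
                 method = "average", dist.method = "maximum",
                 call = match.call()),
            class = c("podmat_tree", "hclust"))
}

sort_merge_pair <- function(a, b) {
  # hclust convention: singletons (negative) before clusters, then by value
  if ((a < 0 && b < 0 && a > b) || (a > 0 && b > 0 && a > b) || (a > 0 && b < 0))
    c(b, a) else c(a, b)
}

leaf_order <- function(merge, n) {
  expand <- function(k)
    if (k < 0) -k else c(expand(merge[k, 1L]), expand(merge[k, 2L]))
  expand(nrow(merge))
}

#' Newick serialization of a clustering tree
#'
#' @param tree a tree from [average_linkage()].
#' @param digits number of digits for branch lengths.
#' @return A single Newick string (rooted, ultrametric branch lengths).
#' @export
tree_newick <- function(tree, digits = 6L) {
  hts <- tree$height
  fmt <- function(k, parent_h) {
    if (k < 0)
      sprintf("%s:%.*f", tree$labels[-k], digits, parent_h)
    else
      sprintf("(%s,%s):%.*f", fmt(tree$merge[k, 1L], hts[k] / 2),
              fmt(tree$merge[k, 2L], hts[k] / 2), digits,
              parent_h - hts[k] / 2)
  }
  k <- nrow(tree$merge)
  paste0("(", fmt(tree$merge[k, 1L], hts[k] / 2), ",",
         fmt(tree$merge[k, 2L], hts[k] / 2), ");")
}

#' Flag replicates that cluster away from their own (genotype, stage) group
#'
#' Cuts the tree into G clusters, G being the number of (genotype, stage)
#' groups among the leaves.  A replicate is flagged when its cluster
#' contains no other replicate of its own group but does contain members
#' of another group; a replicate left in a singleton cluster is flagged
#' only when the rest of its group co-clusters elsewhere.  When every
#' replicate of a group ends up flagged the reason is downgraded to
#' "group not separable" — the tree carries no usable signal for that
#' group.  Groups with a single replicate are never flagged (warning).
#'
#' @param tree tree from [average_linkage()] over the samples.
#' @param design a [sample_design()] covering every leaf.
#' @return data.frame with columns `sample_id` and `reason` (zero rows
#'   when no replicate is discordant).
#' @export
flag_discordant_replicates <- function(tree, design) {
  d <- design[match(tree$labels, design$sample_id), ]
  if (anyNA(d$sample_id)) stop("tree contains leaves absent from the design")
  group <- paste(d$genotype, d$stage, sep = ":")
  G <- length(unique(group))
  cl <- cutree(tree, k = G)
  gsize <- table(group)
  if (any(gsize == 1L))
    warning("groups with a single replicate are never flagged: ",
            paste(names(gsize)[gsize == 1L], collapse = ", "))
  flagged <- character(0); reason <- character(0)
  for (idx in seq_along(tree$labels)) {
    g <- group[idx]
    if (gsize[g] == 1L) next
    members <- which(cl == cl[idx])
    own <- sum(group[members] == g) - 1L
    foreign <- length(members) - own - 1L
    flag <- FALSE; why <- NA_character_
    if (own == 0L && foreign > 0L) {
      flag <- TRUE; why <- "clustered with foreign group"
    } else if (own == 0L && foreign == 0L) {
      others <- setdiff(which(group == g), idx)
      if (length(others) >= 2L && length(unique(cl[others])) == 1L) {
        flag <- TRUE; why <- "separated from co-clustered group"
      }
    }
    if (flag) {
      flagged <- c(flagged, tree$labels[idx]); reason <- c(reason, why)
    }
  }
  if (length(flagged)) {
    grp_of <- group[match(flagged, tree$labels)]
    for (g in unique(grp_of)) {
      if (sum(grp_of == g) == gsize[g])
        reason[grp_of == g] <- "group not separable"
    }
  }
  data.frame(sample_id = flagged, reason = reason, stringsAsFactors = FALSE)
}

#' Replicate-consistency QC report
#'
#' Runs the full replicate screen: select the common top-`k` expressed
#' genes on log(FPKM+1), compute pairwise Chebyshev distances, cluster by
#' UPGMA, and flag discordant replicates.
#'
#' @param m an [expression_matrix()] with unit `"fpkm"` or
#'   `"log1p_fpkm"` (FPKM is transformed internally).
#' @param design a [sample_design()].
#' @param k size of the common top-expressed gene set.
#' @return A list of class `qc_report`: `selected_genes`,
#'   `rejected_samples` (data.frame with reasons), `tree`.
#' @export
qc_report <- function(m, design, k = 100L) {
  if (em_unit(m) == "counts")
    stop("qc_report expects FPKM (or log1p FPKM), not raw counts")
  if (em_unit(m) == "fpkm") m <- log1p_transform(m)
  m <- em_subset(m, j = design$sample_id)
  genes <- select_common_top_genes(m, design, k)
  d <- chebyshev_matrix(m, genes)
  tree <- average_linkage(d)
  rejected <- flag_discordant_replicates(tree, design)
  structure(list(selected_genes = genes, rejected_samples = rejected,
                 tree = tree),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d selected genes; %d rejected sample(s)\n",
              length(x$selected_genes), nrow(x$rejected_samples)))
  if (nrow(x$rejected_samples)) print(x$rejected_samples)
  invisible(x)
}
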